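# Calibration stiffness estimates, normal-connectivity group (NO).
# Signed segment stiffness over displacement bands [0,1], [1,2], [2,3] mm;
# NV2 carries the opposite sign to INT/NV1 (opposing transmission vector).
# r: per-segment proximal-only vs full-displacement scale factors
# (distal-only-resection subset, n = 3).
group: "NO"
c: 0.9
pathways:
  INT:
    breakpoints_mm: [0, 1, 2, 3]
    k_mN_per_mm: [239.8, 171.7, 143.9]
    symmetric: true
  NV1:
    breakpoints_mm: [0, 1, 2, 3]
    k_mN_per_mm: [21.7, 0.4, 34.6]
    symmetric: true
  NV2:
    breakpoints_mm: [0, 1, 2, 3]
    k_mN_per_mm: [-56.6, -30.8, -17.1]
    symmetric: true
r: [0.07, 0.13, 0.21]
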