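# Calibration stiffness estimates, tissue-integrating-mesh group (TI,
# enhanced connectivity). Signed segment stiffness over displacement bands
# [0,1], [1,2], [2,3] mm; NV2 carries the opposite sign to INT/NV1.
# r was measured in the normal-connectivity subset and is reused here.
group: "TI"
c: 0.9
pathways:
  INT:
    breakpoints_mm: [0, 1, 2, 3]
    k_mN_per_mm: [549.7, 842.5, 681.1]
    symmetric: true
  NV1:
    breakpoints_mm: [0, 1, 2, 3]
    k_mN_per_mm: [19.9, 45.7, 29.6]
    symmetric: true
  NV2:
    breakpoints_mm: [0, 1, 2, 3]
    k_mN_per_mm: [-69.4, -5.6, -35.5]
    symmetric: true
r: [0.07, 0.13, 0.21]
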