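#' Force state at the two LG+PL tendon nodes
#'
#' Snapshot of the lumped model's static force balance: the LG+PL proximal
#' and distal tendon forces, the lumped muscle force (contractile plus
#' parallel elastic contribution, constant across resection conditions since
#' contractions are isometric at fixed muscle-tendon length), and the three
#' epimuscular pathway forces.
#'
#' @param f_prox,f_dist LG+PL proximal and distal tendon forces (N).
#' @param f_muscle Lumped CE + PE muscle force (N).
#' @param f_int,f_nv1,f_nv2 Pathway forces (N).
#' @return An object of class `node_state`.
#' @seealso [node_residuals()]
#' @export
node_state <- function(f_prox, f_dist, f_muscle, f_int, f_nv1, f_nv2) {
  vals <- c(f_prox = f_prox, f_dist = f_dist, f_muscle = f_muscle,
            f_int = f_int, f_nv1 = f_nv1, f_nv2 = f_nv2)
  if (!is.numeric(vals) || length(vals) != 6L || !all(is.finite(vals))) {
    stop("all node forces must be single finite numbers", call. = FALSE)
  }
  structure(as.list(vals), class = "node_state")
}

#' Residuals of the static force balance at the LG+PL nodes
#'
#' Evaluates the two node equilibrium equations of the lumped model:
#' at the proximal node, the proximal tendon force balances the NV2 pathway
#' force plus the muscle force; at the distal node, the distal tendon force
#' balances the muscle force minus the INT and NV1 pathway forces:
#' \deqn{r_{prox} = F_{prox} - F_{NV2} - F_{muscle}}
#' \deqn{r_{dist} = F_{dist} - F_{muscle} + F_{INT} + F_{NV1}}
#' A consistent static equilibrium has both residuals zero; their difference
#' equals \eqn{(F_{prox} - F_{dist}) - (F_{NV2} + F_{INT} + F_{NV1})}, i.e.
#' the measured tendon force difference minus the summed pathway forces.
#'
#' @param state A [node_state()].
#' @return Named numeric vector `c(node_proximal, node_distal)` in N.
#' @export
#' @examples
#' s <- node_state(f_prox = 11.5, f_dist = 11.0, f_muscle = 11.3,
#'                 f_int = 0.25, f_nv1 = 0.05, f_nv2 = 0.2)
#' node_residuals(s)
node_residuals <- function(state) {
  if (!inherits(state, "node_state")) {
    stop("`state` must be a node_state object", call. = FALSE)
  }
  c(node_proximal = state$f_prox - state$f_nv2 - state$f_muscle,
    node_distal = state$f_dist - state$f_muscle + state$f_int + state$f_nv1)
}
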