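#' Isometric force table for one animal and one resection condition
#'
#' One row per protocol position, with passive and total force per tendon
#' channel. Rows are normalised to increasing position order and validated:
#' passive force may not exceed total force in any active recording.
#'
#' @param position_mm Relative positions (mm); must match a valid
#'   [position_protocol()] (strictly increasing after sorting, exactly one 0).
#' @param passive,total Data frames (or matrices) with columns `so_dist`,
#'   `lgpl_prox`, `lgpl_dist`, one row per position, forces in N.
#' @param condition Resection condition: `"intact"`, `"postI"` (intermuscular
#'   tissue resected) or `"postII"` (additionally NV1 resected).
#' @param group Connectivity group `"NO"` or `"TI"`.
#' @param animal_id Animal identifier (scalar).
#' @param mode Protocol mode, `"calibration"` or `"testing"`.
#' @return A data frame of class `isometric_table` with columns
#'   `position_mm`, `passive_<ch>_N` and `total_<ch>_N` for each channel,
#'   and attributes `condition`, `group`, `animal_id` and `protocol`.
#' @export
isometric_table <- function(position_mm, passive, total,
                            condition = c("intact", "postI", "postII"),
                            group = c("NO", "TI"), animal_id = "a1",
                            mode = c("calibration", "testing")) {
  condition <- match.arg(condition)
  group <- match.arg(group)
  mode <- match.arg(mode)
  channels <- c("so_dist", "lgpl_prox", "lgpl_dist")
  passive <- as.data.frame(passive)
  total <- as.data.frame(total)
  for (d in list(passive, total)) {
    if (!all(channels %in% names(d)) || nrow(d) != length(position_mm)) {
      stop("`passive` and `total` need columns ",
           paste(channels, collapse = ", "),
           " and one row per position", call. = FALSE)
    }
  }
  ord <- order(position_mm)
  position_mm <- position_mm[ord]
  passive <- passive[ord, channels, drop = FALSE]
  total <- total[ord, channels, drop = FALSE]
  protocol <- position_protocol(position_mm, mode = mode)
  if (any(as.matrix(passive) > as.matrix(total))) {
    stop("passive force exceeds total force in an active recording",
         call. = FALSE)
  }
  out <- data.frame(position_mm = position_mm)
  for (ch in channels) {
    out[[paste0("passive_", ch, "_N")]] <- passive[[ch]]
    out[[paste0("total_", ch, "_N")]] <- total[[ch]]
  }
  structure(out,
            condition = condition, group = group,
            animal_id = as.character(animal_id), protocol = protocol,
            class = c("isometric_table", "data.frame"))
}

table_meta <- function(table) {
  list(condition = attr(table, "condition"), group = attr(table, "group"),
       animal_id = attr(table, "animal_id"), protocol = attr(table, "protocol"))
}

check_isometric <- function(table) {
  if (!inherits(table, "isometric_table")) {
    stop("expected an isometric_table object", call. = FALSE)
  }
  invisible(table)
}

pick_state <- function(table, channel, state = c("total", "passive")) {
  state <- match.arg(state)
  col <- paste0(state, "_", channel, "_N")
  if (is.null(table[[col]])) {
    stop("table is missing the required channel column `", col, "`",
         call. = FALSE)
  }
  table[[col]]
}

#' Proximal-distal LG+PL tendon force difference per position
#'
#' \eqn{\Delta F_{LGPL} = F_{proximal} - F_{distal}}: a positive value means
#' a higher proximal force, i.e. net epimuscular force transmission away
#' from the LG+PL distal tendon. This difference is the direct measure of
#' net myofascial force transmission used throughout the calibration.
#'
#' @param table An [isometric_table()].
#' @param state `"total"` (default) or `"passive"` forces.
#' @return Numeric vector of force differences (N), one per position.
#' @export
delta_f_lgpl <- function(table, state = "total") {
  check_isometric(table)
  pick_state(table, "lgpl_prox", state) - pick_state(table, "lgpl_dist", state)
}

#' Change in SO distal tendon force relative to the reference position
#'
#' \eqn{\Delta F_{SO}(P_R) = F_{SO}(P_R) - F_{SO}(P_{REF})}, with SO held at
#' constant length. Zero at the reference position by construction.
#'
#' @inheritParams delta_f_lgpl
#' @return Numeric vector (N), one per position.
#' @export
delta_f_so <- function(table, state = "total") {
  check_isometric(table)
  f <- pick_state(table, "so_dist", state)
  ref <- attr(table, "protocol")$reference_index
  f - f[ref]
}

#' @export
print.isometric_table <- function(x, ...) {
  m <- table_meta(x)
  cat("Isometric force table: animal ", m$animal_id, ", group ", m$group,
      ", condition ", m$condition, " (", m$protocol$mode, ")\n", sep = "")
  NextMethod()
  invisible(x)
}
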