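#' Read a stiffness set from YAML
#'
#' Expected layout: top-level `group`, `c`, optional `r` (per-segment
#' proximal-only scale factors, attached as attribute), and `pathways` with
#' entries `INT`, `NV1`, `NV2`, each holding `breakpoints_mm` and
#' `k_mN_per_mm` (signed list).
#'
#' @param path Path to a YAML file.
#' @return A [stiffness_set()]; any `r` entry is attached as attribute
#'   `"r"`.
#' @export
read_stiffness_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  for (field in c("group", "c", "pathways")) {
    if (is.null(y[[field]])) {
      stop("stiffness YAML is missing the `", field, "` field: ", path,
           call. = FALSE)
    }
  }
  mk <- function(nm) {
    p <- y$pathways[[nm]]
    if (is.null(p) || is.null(p$breakpoints_mm) || is.null(p$k_mN_per_mm)) {
      stop("stiffness YAML pathway `", nm,
           "` needs `breakpoints_mm` and `k_mN_per_mm`", call. = FALSE)
    }
    piecewise_stiffness(nm, as.numeric(p$k_mN_per_mm),
                        as.numeric(p$breakpoints_mm), group = y$group,
                        symmetric = !isFALSE(p$symmetric))
  }
  set <- stiffness_set(mk("INT"), mk("NV1"), mk("NV2"),
                       group = y$group, c = y$c)
  if (!is.null(y$r)) attr(set, "r") <- as.numeric(y$r)
  set
}

#' Write a stiffness set to YAML
#'
#' @param set A [stiffness_set()].
#' @param path Output path.
#' @param r Optional per-segment scale factors to store alongside
#'   (defaults to the set's `"r"` attribute, if any).
#' @return `path`, invisibly.
#' @export
write_stiffness_yaml <- function(set, path, r = attr(set, "r")) {
  stopifnot(inherits(set, "stiffness_set"))
  y <- list(group = set$group, c = set$c,
            pathways = lapply(set$pathways, function(p) {
              list(breakpoints_mm = p$breakpoints_mm,
                   k_mN_per_mm = p$k_mN_mm,
                   symmetric = p$symmetric)
            }))
  if (!is.null(r)) y$r <- as.numeric(r)
  writeLines(yaml::as.yaml(y, precision = 12L), path)
  invisible(path)
}

isometric_schema <- c("animal_id", "group", "condition", "mode",
                      "position_mm",
                      "passive_so_dist_N", "total_so_dist_N",
                      "passive_lgpl_prox_N", "total_lgpl_prox_N",
                      "passive_lgpl_dist_N", "total_lgpl_dist_N")

#' Write a collection of isometric force tables to one CSV
#'
#' One row per (animal, condition, position); numeric values are written
#' with 17 significant digits so a write/read round trip is bit-exact.
#' Column headers carry units (`_N`, `_mm`).
#'
#' @param tables List of [isometric_table()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_isometric_csv <- function(tables, path) {
  stopifnot(is.list(tables), length(tables) > 0L)
  rows <- lapply(tables, function(x) {
    check_isometric(x)
    m <- table_meta(x)
    cbind(data.frame(animal_id = m$animal_id, group = m$group,
                     condition = m$condition, mode = m$protocol$mode),
          as.data.frame(x))
  })
  out <- do.call(rbind, rows)
  out <- out[, isometric_schema]
  for (col in isometric_schema[-(1:4)]) {
    out[[col]] <- sprintf("%.17g", out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read isometric force tables from CSV
#'
#' Validates the schema (naming any missing column), coerces numeric
#' columns, splits rows by animal/group/condition and normalises row order
#' by position.
#'
#' @param path Path to a CSV written in the layout of
#'   [write_isometric_csv()].
#' @return Named list of [isometric_table()] objects.
#' @export
read_isometric_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(isometric_schema, names(raw))
  if (length(missing) > 0L) {
    stop("isometric CSV is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in isometric_schema[-(1:4)]) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    if (anyNA(v)) {
      stop("non-numeric values in column `", col, "`", call. = FALSE)
    }
    raw[[col]] <- v
  }
  key <- paste(raw$animal_id,
               ifelse(raw$mode == "testing", "testing", raw$condition),
               sep = "_")
  out <- lapply(split(raw, key), function(d) {
    isometric_table(
      d$position_mm,
      passive = data.frame(so_dist = d$passive_so_dist_N,
                           lgpl_prox = d$passive_lgpl_prox_N,
                           lgpl_dist = d$passive_lgpl_dist_N),
      total = data.frame(so_dist = d$total_so_dist_N,
                         lgpl_prox = d$total_lgpl_prox_N,
                         lgpl_dist = d$total_lgpl_dist_N),
      condition = d$condition[1L], group = d$group[1L],
      animal_id = d$animal_id[1L], mode = d$mode[1L])
  })
  out[order(names(out))]
}

#' Write Bland-Altman agreement statistics to JSON
#'
#' @param stats An [bland_altman()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_agreement_json <- function(stats, path) {
  stopifnot(inherits(stats, "agreement_stats"))
  jsonlite::write_json(unclass(stats), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
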