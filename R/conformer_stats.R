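# Aggregation of per-loop results into the survey's census and consensus
# tables: pucker frequency by loop-residue role, the consensus-triplet
# check, structure-set totals, and long-form torsion profiles with circular
# summary statistics.

#' The consensus type-1 pucker triplet (L1, L2, L3)
#' @export
CONSENSUS_PUCKERS <- c("C1'-exo", "C3'-endo", "C2'-endo")

#' Pucker frequency table by loop-residue role
#'
#' Counts pucker classes per loop-residue role (L1, L2, L3) over a subset of
#' loops and derives per-role percentages (to one decimal place) and modal
#' classes.
#'
#' @param puckers Data frame with one row per loop residue: columns
#'   `loop_id`, `loop_type` (label such as "1", "10"), `role`
#'   ("L1"/"L2"/"L3") and `pucker_class`.
#' @param subset "all", "type1" (label "1") or "non_type1".
#' @return Object of class `pucker_frequency_table`:
#'   `list(counts, percentages, n_loops, modal)` where `counts` and
#'   `percentages` are role x class matrices over [PUCKER_CLASSES].
#' @export
pucker_frequency <- function(puckers, subset = c("all", "type1",
                                                 "non_type1")) {
  subset <- match.arg(subset)
  stopifnot(all(c("loop_id", "loop_type", "role", "pucker_class") %in%
                names(puckers)))
  keep <- switch(subset,
    all = rep(TRUE, nrow(puckers)),
    type1 = puckers$loop_type == "1",
    non_type1 = puckers$loop_type != "1")
  df <- puckers[keep & !is.na(puckers$pucker_class), , drop = FALSE]
  if (nrow(df) == 0) stop(sprintf("no loops in subset '%s'", subset))
  roles <- c("L1", "L2", "L3")
  counts <- table(factor(df$role, levels = roles),
                  factor(df$pucker_class, levels = PUCKER_CLASSES))
  counts <- matrix(as.integer(counts), nrow = 3,
                   dimnames = list(roles, PUCKER_CLASSES))
  n_loops <- length(unique(df$loop_id))
  totals <- rowSums(counts)
  if (any(totals != n_loops)) {
    warning("role totals differ from the number of loops; some loops lack a defined pucker for every residue")
  }
  pct <- round(100 * counts / pmax(totals, 1), 1)
  modal <- apply(counts, 1, function(r) PUCKER_CLASSES[which.max(r)])
  structure(
    list(counts = counts, percentages = pct, n_loops = n_loops,
         totals = totals, modal = modal, subset = subset),
    class = "pucker_frequency_table")
}

#' @export
print.pucker_frequency_table <- function(x, ...) {
  cat(sprintf("Pucker frequencies (%s; %d loops):\n", x$subset, x$n_loops))
  for (role in rownames(x$counts)) {
    m <- x$modal[[role]]
    cat(sprintf("  %s: modal %s %d/%d = %.1f%%\n", role, m,
                x$counts[role, m], x$totals[[role]],
                x$percentages[role, m]))
  }
  invisible(x)
}

#' Does a loop match the consensus pucker triplet?
#'
#' The native (type-1) arrangement has the characteristic pucker triplet
#' C1'-exo, C3'-endo, C2'-endo for L1, L2, L3.
#'
#' @param loop_puckers Character vector of three pucker class names
#'   (L1, L2, L3).
#' @return `TRUE`/`FALSE`, or `NA` when any class is undefined.
#' @export
consensus_match <- function(loop_puckers) {
  stopifnot(length(loop_puckers) == 3)
  if (any(is.na(loop_puckers))) return(NA)
  all(loop_puckers == CONSENSUS_PUCKERS)
}

#' Structure-set census
#'
#' Aggregates per-structure records into the survey totals: number of
#' structures, crystallographically unique (typed) loops, distinct loop
#' types, type-1 occurrences, distinct space groups, and the resolution
#' mean/range.
#'
#' @param records Data frame with one row per structure: columns `pdb_id`,
#'   `resolution`, `space_group` and `loop_types` (semicolon-separated type
#'   labels, "" when no loop survived).  Optional columns
#'   `n_loops_printed` / `n_unresolved` are validated against the typed
#'   count when present.
#' @return Object of class `census_report`.
#' @export
census <- function(records) {
  if (nrow(records) == 0) stop("empty census input")
  if (anyDuplicated(records$pdb_id)) {
    stop(sprintf("duplicate structure id(s): %s",
                 paste(unique(records$pdb_id[duplicated(records$pdb_id)]),
                       collapse = ", ")))
  }
  type_lists <- lapply(strsplit(as.character(records$loop_types), ";",
                                fixed = TRUE),
                       function(x) trimws(x[nzchar(trimws(x))]))
  if (all(c("n_loops_printed", "n_unresolved") %in% names(records))) {
    typed <- vapply(type_lists, length, integer(1))
    bad <- typed != records$n_loops_printed - records$n_unresolved
    if (any(bad)) {
      warning(sprintf(
        "typed-loop count disagrees with printed-minus-excluded for: %s",
        paste(records$pdb_id[bad], collapse = ", ")))
    }
  }
  all_types <- unlist(type_lists)
  sg <- gsub("\\s+", "", as.character(records$space_group))
  res <- records$resolution[!is.na(records$resolution)]
  structure(
    list(n_structures = nrow(records),
         n_unique_loops = length(all_types),
         n_loop_types = length(unique(all_types)),
         n_type1 = sum(all_types == "1"),
         n_space_groups = length(unique(sg[nzchar(sg) & !is.na(sg)])),
         resolution_mean = if (length(res)) round(mean(res), 2) else
           NA_real_,
         resolution_range = if (length(res)) range(res) else
           c(NA_real_, NA_real_),
         per_structure = stats::setNames(type_lists, records$pdb_id)),
    class = "census_report")
}

#' @export
print.census_report <- function(x, ...) {
  cat("Structure-set census:\n")
  cat(sprintf("  structures:             %d\n", x$n_structures))
  cat(sprintf("  unique typed loops:     %d\n", x$n_unique_loops))
  cat(sprintf("  distinct loop types:    %d\n", x$n_loop_types))
  cat(sprintf("  type-1 occurrences:     %d\n", x$n_type1))
  cat(sprintf("  distinct space groups:  %d\n", x$n_space_groups))
  if (!is.na(x$resolution_mean)) {
    cat(sprintf("  resolution:             mean %.2f A (%.2f-%.2f)\n",
                x$resolution_mean, x$resolution_range[1],
                x$resolution_range[2]))
  }
  invisible(x)
}

#' Load the shipped structure-set census fixture
#'
#' A plain-text encoding of the surveyed crystal structures (PDB id,
#' sequence, resolution, space group, printed loop count, number of loops
#' excluded as poorly resolved, and the typed-loop list).
#'
#' @return Data frame suitable for [census()].
#' @export
load_census_fixture <- function() {
  utils::read.csv(system.file("extdata", "table1_census.csv",
                              package = "g4loops", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Load the shipped per-loop pucker fixtures
#'
#' @param which "type1" (the 26 type-1 loops) or "non_type1" (the 17
#'   others).
#' @return Data frame with columns `loop_id`, `loop_type`, `role`,
#'   `pucker_class` (long form, three rows per loop).
#' @export
load_pucker_fixture <- function(which = c("type1", "non_type1")) {
  which <- match.arg(which)
  file <- if (which == "type1") "table3_type1_puckers.csv" else
    "table5_nontype1_puckers.csv"
  wide <- utils::read.csv(system.file("extdata", file, package = "g4loops",
                                      mustWork = TRUE),
                          stringsAsFactors = FALSE)
  data.frame(
    loop_id = rep(wide$loop_id, each = 3),
    loop_type = rep(as.character(wide$loop_type), each = 3),
    role = rep(c("L1", "L2", "L3"), nrow(wide)),
    pucker_class = as.vector(t(as.matrix(wide[, c("L1", "L2", "L3")]))),
    stringsAsFactors = FALSE)
}

#' Circular mean of angles in degrees
#' @param x Angles, degrees.
#' @return Mean direction on `(-180, 180]` (reported as 180 for the
#'   antipodal case), or `NA` for an empty/undefined input.
#' @export
circular_mean <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  s <- mean(sin(deg2rad(x)))
  c0 <- mean(cos(deg2rad(x)))
  if (sqrt(s^2 + c0^2) < 1e-12) return(NA_real_)  # no mean direction
  wrap180(rad2deg(atan2(s, c0)))
}

#' Circular standard deviation of angles in degrees
#' @param x Angles, degrees.
#' @return `sqrt(-2 log R)` in degrees, 0 for identical angles.
#' @export
circular_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(0)
  R <- sqrt(mean(sin(deg2rad(x)))^2 + mean(cos(deg2rad(x)))^2)
  R <- min(1, R)
  rad2deg(sqrt(-2 * log(max(R, 1e-12))))
}

#' Long-form torsion profile with circular summaries
#'
#' Expands per-loop torsion sets into one record per defined angle and
#' appends circular mean and circular spread per (group, role, angle).
#' The survey itself plots raw per-loop traces; the aggregate rows are
#' derived extras, computed circularly so that wrap-around pairs such as
#' 179 / -179 average to 180, not 0.
#'
#' @param torsions Data frame with columns `loop_id`, `group` (e.g. loop
#'   type or structure id), `role`, `angle` (alpha..chi) and `degrees`.
#' @return Object of class `torsion_profile`: `list(values, summary)`.
#' @export
torsion_profile <- function(torsions) {
  stopifnot(all(c("loop_id", "group", "role", "angle", "degrees") %in%
                names(torsions)))
  values <- torsions[!is.na(torsions$degrees), , drop = FALSE]
  key <- interaction(values$group, values$role, values$angle, drop = TRUE)
  summ <- do.call(rbind, lapply(split(values, key), function(d) {
    data.frame(group = d$group[1], role = d$role[1], angle = d$angle[1],
               n = nrow(d),
               circ_mean = circular_mean(d$degrees),
               circ_sd = circular_sd(d$degrees),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(values = values, summary = summ),
            class = "torsion_profile")
}

#' @export
print.torsion_profile <- function(x, ...) {
  cat(sprintf("Torsion profile: %d angle records, %d summary rows\n",
              nrow(x$values), nrow(x$summary)))
  invisible(x)
}

#' Torsion sets for the three residues of a loop, in chain context
#'
#' Looks up the chain the loop belongs to so that alpha (needs the
#' preceding residue) and epsilon/zeta (need the following one) are defined
#' for every loop residue.
#'
#' @param model The `structure_model` the loop came from.
#' @param loop A `loop_instance` from [find_loops()].
#' @return Named list (L1, L2, L3) of `torsion_set` objects.
#' @export
loop_torsions <- function(model, loop) {
  chain <- model$chains[[loop$chain_id]]
  out <- lapply(seq_len(3), function(i) {
    pos <- loop$positions[i]
    prev <- if (pos > 1) chain[[pos - 1]] else NULL
    nxt <- if (pos < length(chain)) chain[[pos + 1]] else NULL
    torsion_set(prev, chain[[pos]], nxt)
  })
  stats::setNames(out, loop$roles)
}
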