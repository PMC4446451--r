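# Stacking-based classification of TTA/UUA propeller loops into twelve
# types.  The descriptors are qualitative (which bases stack, which sit
# perpendicular, whether the remaining base stays close), so all geometric
# cutoffs are explicit, configurable thresholds.

#' Geometric thresholds for loop typing
#'
#' Defaults reflect standard pi-stacking geometry (3.3-3.6 A ring
#' separation) with slack for crystallographic variation:
#' a pair is *stacked* when centroid distance <= `d_stack`, interplanar
#' angle <= `a_stack` and lateral offset <= `o_stack`; *perpendicular* when
#' the interplanar angle >= `a_perp` and the centroids are within `d_near`;
#' a base is *close* to another when their centroids are within `d_close`.
#'
#' @param d_stack Max centroid distance for stacking (A, default 5.0).
#' @param a_stack Max interplanar angle for stacking (deg, default 30).
#' @param o_stack Max lateral (in-plane) offset for stacking (A, default 2.5).
#' @param a_perp Min interplanar angle for perpendicularity (deg, default 60).
#' @param d_near Max centroid distance for perpendicularity (A, default 7.0).
#' @param d_close Centroid distance separating close from away (A, 6.5).
#' @return Object of class `loop_thresholds`.
#' @export
loop_thresholds <- function(d_stack = 5.0, a_stack = 30, o_stack = 2.5,
                            a_perp = 60, d_near = 7.0, d_close = 6.5) {
  th <- list(d_stack = d_stack, a_stack = a_stack, o_stack = o_stack,
             a_perp = a_perp, d_near = d_near, d_close = d_close)
  stopifnot(all(vapply(th, function(x) is.numeric(x) && x > 0, logical(1))))
  structure(th, class = "loop_thresholds")
}

#' Geometric relation between two base planes
#'
#' @param a,b `base_plane` objects.
#' @param thresholds A [loop_thresholds()] object.
#' @return Object of class `stack_relation`:
#'   `list(centroid_distance, interplanar_angle, lateral_offset, relation)`
#'   with `relation` one of "stacked", "perpendicular", "neither".
#' @export
stack_relation <- function(a, b, thresholds = loop_thresholds()) {
  if (is.null(a) || is.null(b)) return(NULL)
  d <- b$centroid - a$centroid
  dist <- vnorm(d)
  ang <- plane_angle(a, b)
  # lateral offset: centroid separation projected into the mean plane
  nb <- if (sum(a$normal * b$normal) < 0) -b$normal else b$normal
  nm <- unitv(a$normal + nb)
  offset <- vnorm(d - sum(d * nm) * nm)
  relation <- if (dist <= thresholds$d_stack && ang <= thresholds$a_stack &&
                  offset <= thresholds$o_stack) {
    "stacked"
  } else if (ang >= thresholds$a_perp && dist <= thresholds$d_near) {
    "perpendicular"
  } else {
    "neither"
  }
  structure(
    list(centroid_distance = dist, interplanar_angle = ang,
         lateral_offset = offset, relation = relation),
    class = "stack_relation")
}

#' Close/away proximity of two base planes
#'
#' @param a,b `base_plane` objects.
#' @param thresholds A [loop_thresholds()] object.
#' @return "close" when the centroid distance is <= `d_close`, else "away".
#' @export
proximity <- function(a, b, thresholds = loop_thresholds()) {
  if (vnorm(b$centroid - a$centroid) <= thresholds$d_close) "close" else "away"
}

.role_pairs <- list(c("L1", "L2"), c("L1", "L3"), c("L2", "L3"))

pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "-")

#' Stacking fingerprint of a loop
#'
#' Computes the three pairwise [stack_relation()]s between the base planes
#' of L1, L2, L3 and assembles the qualitative fingerprint used by the
#' twelve-type rulebook: the set of stacked pairs, the set of perpendicular
#' pairs, and close/away proximity for every pair.
#'
#' @param loop A `loop_instance`.
#' @param thresholds A [loop_thresholds()] object.
#' @return Object of class `loop_fingerprint`; `defined = FALSE` when any
#'   base plane could not be fitted (the loop is then unclassifiable).
#' @export
loop_fingerprint <- function(loop, thresholds = loop_thresholds()) {
  planes <- lapply(loop$residues, base_plane)
  names(planes) <- loop$roles
  if (any(vapply(planes, is.null, logical(1)))) {
    return(structure(list(defined = FALSE), class = "loop_fingerprint"))
  }
  stacked <- character(0)
  perpendicular <- character(0)
  prox <- matrix(NA_character_, 3, 3, dimnames = list(loop$roles, loop$roles))
  relations <- list()
  for (pr in .role_pairs) {
    rel <- stack_relation(planes[[pr[1]]], planes[[pr[2]]], thresholds)
    key <- pair_key(pr[1], pr[2])
    relations[[key]] <- rel
    if (rel$relation == "stacked") stacked <- c(stacked, key)
    if (rel$relation == "perpendicular") perpendicular <- c(perpendicular, key)
    p <- proximity(planes[[pr[1]]], planes[[pr[2]]], thresholds)
    prox[pr[1], pr[2]] <- prox[pr[2], pr[1]] <- p
  }
  structure(
    list(defined = TRUE,
         stacked = stacked, perpendicular = perpendicular,
         prox = prox, relations = relations,
         codes = stats::setNames(vapply(loop$residues, `[[`, "", "code"),
                                 loop$roles),
         planes = planes),
    class = "loop_fingerprint")
}

#' @export
print.loop_fingerprint <- function(x, ...) {
  if (!x$defined) {
    cat("Loop fingerprint: undefined (missing base plane)\n")
    return(invisible(x))
  }
  cat("Loop fingerprint:\n")
  cat("  stacked:      ",
      if (length(x$stacked)) paste(x$stacked, collapse = ", ") else "-", "\n")
  cat("  perpendicular:",
      if (length(x$perpendicular)) paste(x$perpendicular, collapse = ", ")
      else "-", "\n")
  invisible(x)
}

has_pair <- function(set, a, b) pair_key(a, b) %in% set
perp_with <- function(fp, role) {
  any(vapply(strsplit(fp$perpendicular, "-"), function(p) role %in% p,
             logical(1)))
}

#' Assign a loop to one of the twelve stacking types
#'
#' Matches a [loop_fingerprint()] against the twelve-type rulebook.  The
#' dominant native arrangement is type 1: adenine stacked on the first T/U
#' with the central residue either perpendicular to it (sub-type "1a") or
#' stacked on the adenine's outer face ("1b"); both sub-types count as
#' type 1 everywhere.  Types 10 and 12 share identical qualitative
#' descriptors and can only be told apart by overall 3-D shape: without an
#' exemplar library the ambiguity set `c(10, 12)` is returned; with one the
#' type whose exemplar minimizes the all-heavy-atom RMSD after superposition
#' is chosen.  Types 6 and 8 also share descriptors and are separated by
#' chemistry (TTA -> 6, UUA -> 8).
#'
#' @param fp A `loop_fingerprint`.
#' @param exemplars Optional exemplar library, see
#'   [build_exemplar_library()] / [read_exemplar_library()].
#' @param loop The `loop_instance` the fingerprint came from; required for
#'   exemplar disambiguation.
#' @return Object of class `loop_type_assignment`:
#'   `list(assigned_type, subtype, method, exemplar_rmsd, label)`.
#'   `assigned_type` is an integer vector (singleton, ambiguity set, or
#'   empty for "unclassified"); `label` is a printable form such as `"1"`,
#'   `"{10,12}"` or `"unclassified"`.
#' @export
assign_loop_type <- function(fp, exemplars = NULL, loop = NULL) {
  mk <- function(types, subtype = NA_character_, method = "rules",
                 rmsd = NA_real_) {
    label <- if (length(types) == 0) {
      "unclassified"
    } else if (length(types) == 1) {
      as.character(types)
    } else {
      paste0("{", paste(types, collapse = ","), "}")
    }
    structure(list(assigned_type = types, subtype = subtype,
                   method = method, exemplar_rmsd = rmsd, label = label),
              class = "loop_type_assignment")
  }
  if (!isTRUE(fp$defined)) return(mk(integer(0)))

  S <- sort(fp$stacked)
  prox <- fp$prox
  types <- integer(0)
  subtype <- NA_character_

  if (identical(S, "L1-L3")) {
    # adenine on first T/U; central base perpendicular to it
    if (has_pair(fp$perpendicular, "L2", "L3") &&
        prox["L2", "L3"] == "close") {
      types <- 1L; subtype <- "1a"
    }
  } else if (identical(S, c("L1-L3", "L2-L3"))) {
    # adenine on first T/U with the central base stacked on its outer face
    types <- 1L; subtype <- "1b"
  } else if (identical(S, "L1-L2")) {
    if (prox["L3", "L1"] == "away" && prox["L3", "L2"] == "away") types <- 2L
  } else if (identical(S, "L2-L3")) {
    if (perp_with(fp, "L1")) {
      if (has_pair(fp$perpendicular, "L1", "L3") &&
          prox["L1", "L3"] == "close") {
        types <- 3L
      } else if (prox["L1", "L2"] == "away" && prox["L1", "L3"] == "away") {
        types <- if (fp$codes[["L1"]] == "U") 8L else 6L
      }
    } else {
      close2 <- prox["L1", "L2"] == "close"
      close3 <- prox["L1", "L3"] == "close"
      if (close2 && close3) {
        types <- 5L
      } else if (close2) {
        types <- 7L
      } else if (!close2 && !close3) {
        types <- c(10L, 12L)
      }
    }
  } else if (length(S) == 0) {
    all_away <- all(prox[upper.tri(prox)] == "away")
    if (has_pair(fp$perpendicular, "L2", "L3") &&
        prox["L1", "L2"] == "away" && prox["L1", "L3"] == "away") {
      types <- 4L
    } else if (has_pair(fp$perpendicular, "L1", "L2") &&
               prox["L3", "L1"] == "close") {
      types <- 11L
    } else if (length(fp$perpendicular) == 0 && all_away) {
      types <- 9L
    }
  }

  if (length(types) > 1 && !is.null(exemplars) && !is.null(loop)) {
    hit <- nearest_exemplar(loop, exemplars, restrict = types)
    if (!is.null(hit)) {
      return(mk(hit$type, subtype, method = "exemplar", rmsd = hit$rmsd))
    }
  }
  mk(types, subtype)
}

#' @export
print.loop_type_assignment <- function(x, ...) {
  cat(sprintf("Loop type: %s%s (method: %s%s)\n", x$label,
              if (!is.na(x$subtype)) paste0(" [", x$subtype, "]") else "",
              x$method,
              if (!is.na(x$exemplar_rmsd)) {
                sprintf(", exemplar rmsd %.2f A", x$exemplar_rmsd)
              } else ""))
  invisible(x)
}

# all-heavy-atom coordinate matrix of a loop, matched by role + atom name
loop_matched_coords <- function(loop_a, loop_b) {
  A <- B <- NULL
  for (i in 1:3) {
    ra <- loop_a$residues[[i]]
    rb <- loop_b$residues[[i]]
    common <- intersect(ra$atoms$name, rb$atoms$name)
    common <- common[!grepl("^H", common)]
    if (!length(common)) next
    A <- rbind(A, t(vapply(common, function(nm) atom_xyz(ra, nm), numeric(3))))
    B <- rbind(B, t(vapply(common, function(nm) atom_xyz(rb, nm), numeric(3))))
  }
  list(a = A, b = B)
}

# best-matching exemplar among `restrict` types, or NULL
nearest_exemplar <- function(loop, exemplars, restrict = NULL) {
  best <- NULL
  for (ex in exemplars) {
    if (!is.null(restrict) && !(ex$type %in% restrict)) next
    mc <- loop_matched_coords(loop, ex$loop)
    if (is.null(mc$a) || nrow(mc$a) < 3) next
    r <- kabsch(mc$a, mc$b)$rmsd
    if (is.null(best) || r < best$rmsd) best <- list(type = ex$type, rmsd = r)
  }
  best
}

#' Read an exemplar library from disk
#'
#' An exemplar library is a directory of per-type loop coordinate fragments
#' (PDB format) with a `manifest.csv` mapping `type` to `file`.  Each
#' fragment must contain exactly one (T|U)(T|U)A triplet as three
#' consecutive residues.
#'
#' @param dir Directory containing `manifest.csv` and the fragments.
#' @return List of `list(type, loop)` entries usable by
#'   [assign_loop_type()].
#' @export
read_exemplar_library <- function(dir) {
  manifest <- file.path(dir, "manifest.csv")
  if (!file.exists(manifest)) {
    stop(sprintf("no manifest.csv in exemplar directory %s", dir))
  }
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  stopifnot(all(c("type", "file") %in% names(man)))
  lapply(seq_len(nrow(man)), function(i) {
    model <- read_structure(file.path(dir, man$file[i]))[[1]]
    chain <- model$chains[[1]]
    list(type = as.integer(man$type[i]),
         loop = loop_instance(model$structure_id, 1L, names(model$chains)[1],
                              residues = chain[1:3], positions = 1:3,
                              flanking = list(prev = NULL, nxt = NULL),
                              resolved = TRUE))
  })
}
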