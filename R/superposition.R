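# Least-squares superposition (Kabsch) and the G-quartet core alignment used
# to compare quadruplex structures against a reference.

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between two
#' ordered point sets.  Reflections are suppressed by the usual determinant
#' correction, so the result is always a proper rotation.
#'
#' @param moving,fixed Numeric `N x 3` matrices with corresponding rows,
#'   `N >= 3`.
#' @return Object of class `superposition`:
#'   `list(rotation, translation, rmsd, n_atoms, degenerate)`.  The fitted
#'   moving set is `moving %*% t(rotation) + translation` (row-wise).
#'   `degenerate` flags collinear inputs, for which the optimum is still
#'   returned but is not unique.
#' @export
kabsch <- function(moving, fixed) {
  moving <- as.matrix(moving)
  fixed <- as.matrix(fixed)
  if (nrow(moving) < 3) stop("kabsch needs at least 3 points")
  if (!identical(dim(moving), dim(fixed))) {
    stop("point sets must have identical dimensions")
  }
  cm <- colMeans(moving)
  cf <- colMeans(fixed)
  A <- sweep(moving, 2, cm)
  B <- sweep(fixed, 2, cf)
  H <- crossprod(A, B)  # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  fitted <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  # collinearity: second singular value of the centered coordinates ~ 0
  degen <- svd(A, nu = 0, nv = 0)$d[2] < 1e-8
  structure(
    list(rotation = R,
         translation = as.numeric(cf - R %*% cm),
         rmsd = rmsd,
         n_atoms = nrow(moving),
         degenerate = degen,
         correspondence = NULL),
    class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Superposition of %d atoms: rmsd %.4f A%s\n",
              x$n_atoms, x$rmsd,
              if (isTRUE(x$degenerate)) " (degenerate input)" else ""))
  if (!is.null(x$correspondence)) {
    cat("  tract correspondence:",
        paste(x$correspondence, collapse = " -> "), "\n")
  }
  invisible(x)
}

# apply a superposition (or any R, t pair) to an N x 3 matrix
transform_xyz <- function(xyz, rotation, translation) {
  sweep(as.matrix(xyz) %*% t(rotation), 2, translation, "+")
}

# guanine base heavy atoms used for the core alignment
.g_core_atoms <- c("N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3")

# Collect the core guanines of a model: a list of 4 tracts (chain order),
# each a list of `depth` residue_records read 5'->3'.
core_tracts <- function(model, min_tract = 3, depth = 3) {
  tracts <- list()
  for (chain_id in names(model$chains)) {
    tr <- find_gtracts(model, min_tract = min_tract)[[chain_id]]
    if (is.null(tr) || nrow(tr) == 0) next
    for (i in seq_len(nrow(tr))) {
      idx <- tr$start[i]:tr$end[i]
      if (length(idx) < depth) next
      tracts[[length(tracts) + 1L]] <-
        model$chains[[chain_id]][idx[seq_len(depth)]]
    }
  }
  if (length(tracts) != 4) {
    stop(sprintf("structure %s: expected 4 G-tracts forming the quartet core, found %d",
                 model$structure_id, length(tracts)))
  }
  tracts
}

# stacked coordinate matrices for one tract pairing
core_pair_coords <- function(tr_mov, tr_fix, depth = 3) {
  mov <- fix <- NULL
  for (g in seq_len(depth)) {
    rm_ <- tr_mov[[g]]
    rf <- tr_fix[[g]]
    common <- intersect(intersect(.g_core_atoms, rm_$atoms$name),
                        rf$atoms$name)
    if (length(common) == 0) next
    mov <- rbind(mov, t(vapply(common, function(nm) atom_xyz(rm_, nm),
                               numeric(3))))
    fix <- rbind(fix, t(vapply(common, function(nm) atom_xyz(rf, nm),
                               numeric(3))))
  }
  list(mov = mov, fix = fix)
}

#' G-quartet core RMSD against a reference structure
#'
#' Superposes the twelve core guanines (three stacked quartets, four
#' G-tracts of three guanines each) of `model` onto those of `reference`
#' using guanine base heavy atoms (N9, C8, N7, C5, C6, O6, N1, C2, N2, N3).
#' Because the tract labelling of a parallel quadruplex is arbitrary under
#' its four-fold rotational symmetry, all four cyclic permutations of the
#' tract correspondence are tried and the one with the smallest RMSD is
#' reported.
#'
#' @param model,reference `structure_model` objects each containing four
#'   G-tracts (one chain of four, or two chains of two for bimolecular
#'   structures).
#' @param min_tract Minimum run of consecutive guanines counted as a tract.
#' @return A `superposition` with the winning cyclic tract `correspondence`.
#' @seealso [quartet_core_rmsd_ensemble()] for NMR-style multi-model input.
#' @export
quartet_core_rmsd <- function(model, reference, min_tract = 3) {
  tm <- core_tracts(model, min_tract = min_tract)
  tf <- core_tracts(reference, min_tract = min_tract)
  best <- NULL
  for (shift in 0:3) {
    perm <- ((seq_len(4) - 1 + shift) %% 4) + 1
    mov <- fix <- NULL
    for (t in seq_len(4)) {
      pc <- core_pair_coords(tm[[perm[t]]], tf[[t]])
      mov <- rbind(mov, pc$mov)
      fix <- rbind(fix, pc$fix)
    }
    if (is.null(mov) || nrow(mov) < 3) next
    fit <- kabsch(mov, fix)
    if (is.null(best) || fit$rmsd < best$rmsd) {
      fit$correspondence <- perm
      best <- fit
    }
  }
  if (is.null(best)) stop("no usable guanine core atoms in common")
  best
}

#' Ensemble quartet-core RMSD
#'
#' Runs [quartet_core_rmsd()] for each model of a multi-model (e.g. NMR)
#' ensemble against one reference model and reports the per-model values and
#' their mean.
#'
#' @param models List of `structure_model` objects (one per ensemble member).
#' @param reference A single `structure_model`.
#' @param min_tract Minimum G-run length for a tract.
#' @return `list(per_model = data.frame(model_num, rmsd), mean_rmsd)`.
#' @export
quartet_core_rmsd_ensemble <- function(models, reference, min_tract = 3) {
  rmsds <- vapply(models, function(m) {
    quartet_core_rmsd(m, reference, min_tract = min_tract)$rmsd
  }, numeric(1))
  list(per_model = data.frame(
         model_num = vapply(models, function(m) m$model_num, numeric(1)),
         rmsd = rmsds),
       mean_rmsd = mean(rmsds))
}
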