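# Coordinate geometry: dihedrals, nucleotide torsions, pseudorotation,
# base-plane fitting.  Everything works in degrees on the (-180, 180] branch,
# matching the usual plotting convention for nucleic-acid torsions.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# fold an angle onto (-180, 180]
wrap180 <- function(x) {
  x <- (x + 180) %% 360 - 180
  ifelse(x <= -180, x + 360, x)
}

#' Dihedral angle of four points
#'
#' Signed torsion angle defined by four points, using the IUPAC sign
#' convention: looking from `p2` towards `p3`, a clockwise rotation of the
#' far bond (`p3`->`p4`) relative to the near bond (`p2`->`p1`) is positive.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Angstrom).
#' @return Angle in degrees on `(-180, 180]`, or `NA_real_` when the angle is
#'   undefined (coincident consecutive points or a collinear bond triple).
#' @examples
#' dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0))  # 180 (trans)
#' dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))  # 0 (cis)
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (vnorm(b1) < 1e-9 || vnorm(b2) < 1e-9 || vnorm(b3) < 1e-9) {
    return(NA_real_)
  }
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9) {
    return(NA_real_)  # collinear triple: torsion undefined
  }
  y <- sum(cross3(n1, n2) * (b2 / vnorm(b2)))
  x <- sum(n1 * n2)
  ang <- rad2deg(atan2(y, x))
  if (ang <= -180) ang <- ang + 360
  ang
}

# canonical quadruples for the six backbone torsions; "-" marks the previous
# residue, "+" the next
.torsion_defs <- list(
  alpha   = c("O3'-", "P",    "O5'",  "C5'"),
  beta    = c("P",    "O5'",  "C5'",  "C4'"),
  gamma   = c("O5'",  "C5'",  "C4'",  "C3'"),
  delta   = c("C5'",  "C4'",  "C3'",  "O3'"),
  epsilon = c("C4'",  "C3'",  "O3'",  "P+"),
  zeta    = c("C3'",  "O3'",  "P+",   "O5'+")
)

.purines <- c("A", "G")
.pyrimidines <- c("C", "T", "U")

# coordinates of a named atom, or NULL
atom_xyz <- function(res, name) {
  i <- match(name, res$atoms$name)
  if (is.na(i)) return(NULL)
  as.numeric(res$atoms[i, c("x", "y", "z")])
}

#' Backbone and glycosidic torsions of one nucleotide
#'
#' Computes the six backbone torsions alpha--zeta and the glycosidic torsion
#' chi for a residue in its chain context.  Torsion definitions:
#' alpha O3'(i-1)-P-O5'-C5'; beta P-O5'-C5'-C4'; gamma O5'-C5'-C4'-C3';
#' delta C5'-C4'-C3'-O3'; epsilon C4'-C3'-O3'-P(i+1);
#' zeta C3'-O3'-P(i+1)-O5'(i+1); chi O4'-C1'-N9-C4 for purines and
#' O4'-C1'-N1-C2 for pyrimidines.
#'
#' @param prev Previous residue (`residue_record`) or `NULL` at the 5' end.
#' @param res The residue whose torsions are measured.
#' @param nxt Next residue or `NULL` at the 3' end.
#' @return Object of class `torsion_set`: named numeric vector
#'   `(alpha, beta, gamma, delta, epsilon, zeta, chi)` in degrees, `NA` where
#'   an angle could not be computed (missing neighbour or atom).
#' @export
torsion_set <- function(prev, res, nxt) {
  get <- function(tag) {
    if (endsWith(tag, "-")) {
      if (is.null(prev)) return(NULL)
      atom_xyz(prev, substr(tag, 1, nchar(tag) - 1))
    } else if (endsWith(tag, "+")) {
      if (is.null(nxt)) return(NULL)
      atom_xyz(nxt, substr(tag, 1, nchar(tag) - 1))
    } else {
      atom_xyz(res, tag)
    }
  }
  out <- vapply(.torsion_defs, function(quad) {
    pts <- lapply(quad, get)
    if (any(vapply(pts, is.null, logical(1)))) return(NA_real_)
    dihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
  }, numeric(1))
  chi_quad <- if (res$code %in% .purines) {
    c("O4'", "C1'", "N9", "C4")
  } else {
    c("O4'", "C1'", "N1", "C2")
  }
  pts <- lapply(chi_quad, function(nm) atom_xyz(res, nm))
  chi <- if (any(vapply(pts, is.null, logical(1)))) NA_real_ else {
    dihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
  }
  out <- c(out, chi = chi)
  structure(out, class = "torsion_set")
}

#' @export
print.torsion_set <- function(x, ...) {
  cat("Nucleotide torsions (degrees):\n")
  print(round(unclass(x), 2))
  invisible(x)
}

#' Altona-Sundaralingam pseudorotation parameters
#'
#' Converts the five endocyclic furanose torsions nu0..nu4 into the
#' pseudorotation phase angle P and puckering amplitude tau_m via
#' `tan P = ((nu4 + nu1) - (nu3 + nu0)) / (2 nu2 (sin 36 + sin 72))`,
#' with the quadrant fixed so that `nu2 = tau_m cos P` with `tau_m > 0`.
#'
#' @param nu Numeric vector of length 5: nu0..nu4, degrees.
#' @return Named numeric vector `c(phase_P, amplitude_tau_m)`; `phase_P` in
#'   `[0, 360)`.  Returns `c(NA, NA)` for an all-zero (flat) input.
#' @export
pseudorotation <- function(nu) {
  stopifnot(length(nu) == 5)
  if (any(is.na(nu)) || all(abs(nu) < 1e-12)) {
    return(c(phase_P = NA_real_, amplitude_tau_m = NA_real_))
  }
  nu <- unname(nu)
  k <- 2 * (sin(deg2rad(36)) + sin(deg2rad(72)))
  s <- ((nu[5] + nu[2]) - (nu[4] + nu[1])) / k  # tau_m * sin(P)
  c0 <- nu[3]                                   # tau_m * cos(P)
  P <- rad2deg(atan2(s, c0)) %% 360
  tau <- sqrt(s * s + c0 * c0)
  c(phase_P = P, amplitude_tau_m = tau)
}

#' The ten sugar-pucker classes in pseudorotation-wheel order
#' @export
PUCKER_CLASSES <- c(
  "C3'-endo", "C4'-exo", "O4'-endo", "C1'-exo", "C2'-endo",
  "C3'-exo", "C4'-endo", "O4'-exo", "C1'-endo", "C2'-exo"
)

#' Name the sugar pucker from the pseudorotation phase
#'
#' The pseudorotation wheel is divided into ten equal 36-degree decades:
#' C3'-endo `[0, 36)`, C4'-exo `[36, 72)`, ..., C2'-exo `[324, 360)`.
#'
#' @param phase_P Phase angle in degrees; values outside `[0, 360)` are
#'   normalized modulo 360 first.
#' @return Character: one of [PUCKER_CLASSES], `NA` for `NA` input.
#' @export
pucker_class <- function(phase_P) {
  out <- rep(NA_character_, length(phase_P))
  ok <- !is.na(phase_P)
  out[ok] <- PUCKER_CLASSES[floor((phase_P[ok] %% 360) / 36) + 1L]
  out
}

# endocyclic torsion quadruples, nu0..nu4
.ring_defs <- list(
  nu0 = c("C4'", "O4'", "C1'", "C2'"),
  nu1 = c("O4'", "C1'", "C2'", "C3'"),
  nu2 = c("C1'", "C2'", "C3'", "C4'"),
  nu3 = c("C2'", "C3'", "C4'", "O4'"),
  nu4 = c("C3'", "C4'", "O4'", "C1'")
)

#' Sugar pucker of a residue
#'
#' Measures the five endocyclic torsions of the (deoxy)ribose ring, converts
#' them to pseudorotation parameters and names the pucker class.
#'
#' @param res A `residue_record` with the five ring atoms
#'   C1', C2', C3', C4', O4'.
#' @return Object of class `pucker_result`:
#'   `list(nu, phase_P, amplitude_tau_m, pucker_class)`, or `NULL` when any
#'   ring atom is missing (the residue is then excluded from pucker
#'   statistics).
#' @export
sugar_pucker <- function(res) {
  ring_atoms <- c("C1'", "C2'", "C3'", "C4'", "O4'")
  if (!all(ring_atoms %in% res$atoms$name)) return(NULL)
  nu <- vapply(.ring_defs, function(quad) {
    pts <- lapply(quad, function(nm) atom_xyz(res, nm))
    dihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
  }, numeric(1))
  if (any(is.na(nu))) return(NULL)
  pr <- pseudorotation(nu)
  structure(
    list(nu = nu,
         phase_P = unname(pr["phase_P"]),
         amplitude_tau_m = unname(pr["amplitude_tau_m"]),
         pucker_class = pucker_class(unname(pr["phase_P"]))),
    class = "pucker_result")
}

#' @export
print.pucker_result <- function(x, ...) {
  cat(sprintf("Sugar pucker: %s  (P = %.1f deg, tau_m = %.1f deg)\n",
              x$pucker_class, x$phase_P, x$amplitude_tau_m))
  invisible(x)
}

# ring atoms used for base-plane fitting
base_ring_atoms <- function(code) {
  if (code %in% .purines) {
    c("N9", "C8", "N7", "C5", "C4", "C6", "N1", "C2", "N3")
  } else {
    c("N1", "C2", "N3", "C4", "C5", "C6")
  }
}

#' Least-squares plane through the base ring
#'
#' Fits a plane to the aromatic ring atoms of a nucleobase (6-membered ring
#' for pyrimidines, the 9-atom fused ring for purines; any subset of at least
#' three non-collinear atoms that is present is used).  The normal is the
#' direction of smallest coordinate variance; its sign carries no meaning and
#' all downstream interplanar angles are folded to `[0, 90]`.
#'
#' @param res A `residue_record`.
#' @return Object of class `base_plane`:
#'   `list(centroid, normal, rms_planarity, ring_atoms_used)`, or `NULL` when
#'   fewer than three ring atoms are present or the atoms are collinear.
#' @export
base_plane <- function(res) {
  names_use <- intersect(base_ring_atoms(res$code), res$atoms$name)
  if (length(names_use) < 3) return(NULL)
  xyz <- t(vapply(names_use, function(nm) atom_xyz(res, nm), numeric(3)))
  centroid <- colMeans(xyz)
  centered <- sweep(xyz, 2, centroid)
  e <- eigen(crossprod(centered), symmetric = TRUE)
  if (e$values[2] < 1e-9) return(NULL)  # collinear points: no unique plane
  normal <- e$vectors[, 3]
  d <- centered %*% normal
  structure(
    list(centroid = centroid,
         normal = as.numeric(normal / vnorm(normal)),
         rms_planarity = sqrt(mean(d^2)),
         ring_atoms_used = names_use),
    class = "base_plane")
}

#' @export
print.base_plane <- function(x, ...) {
  cat(sprintf("Base plane through %d atoms, rms planarity %.3f A\n",
              length(x$ring_atoms_used), x$rms_planarity))
  invisible(x)
}

# interplanar angle folded onto [0, 90] degrees
plane_angle <- function(a, b) {
  d <- abs(sum(a$normal * b$normal))
  rad2deg(acos(min(1, d)))
}
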