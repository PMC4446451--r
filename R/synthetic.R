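# Synthetic structure generators: internal-coordinate chain building,
# furanose rings at a prescribed pseudorotation state, idealized base
# triplets realizing each stacking-descriptor row, and a toy quadruplex
# exercising the whole pipeline.  Fixtures are geometric, not energetic:
# bond lengths and angles are chemically plausible standards, nothing is
# force-field refined.

# Rodrigues rotation matrix about a unit axis
rot_axis <- function(axis, theta_deg) {
  a <- unitv(axis)
  th <- deg2rad(theta_deg)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

rot_z <- function(theta_deg) rot_axis(c(0, 0, 1), theta_deg)

# rotation taking the z axis onto `normal`
rot_z_to <- function(normal) {
  n <- unitv(normal)
  z <- c(0, 0, 1)
  d <- sum(z * n)
  if (d > 1 - 1e-12) return(diag(3))
  if (d < -1 + 1e-12) return(rot_axis(c(1, 0, 0), 180))
  rot_axis(cross3(z, n), rad2deg(acos(d)))
}

#' Place an atom from internal coordinates
#'
#' Natural-extension (NeRF) placement: the new atom D is bonded to `c` with
#' bond length `bond`, bond angle `angle` at `c` (between `b`, `c`, D) and
#' torsion `torsion` for the quadruple (`a`, `b`, `c`, D), measured with the
#' same sign convention as [dihedral()].
#'
#' @param a,b,c Reference positions (3-vectors).
#' @param bond Bond length c-D (Angstrom).
#' @param angle Bond angle b-c-D (degrees, in (0, 180)).
#' @param torsion Target dihedral a-b-c-D (degrees).
#' @return Position of D.
#' @export
place_atom <- function(a, b, c, bond, angle, torsion) {
  if (angle <= 0 || angle >= 180) {
    stop("bond angle must lie strictly between 0 and 180 degrees")
  }
  th <- deg2rad(angle)
  phi <- deg2rad(torsion)
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(th), sin(th) * cos(phi), sin(th) * sin(phi))
  as.numeric(c + d2[1] * bc + d2[2] * m + d2[3] * n)
}

# internal-coordinate standards for the phosphodiester backbone
.chain_geom <- list(
  bond = c(P = 1.60, `O5'` = 1.59, `C5'` = 1.44, `C4'` = 1.51,
           `C3'` = 1.52, `O3'` = 1.42),
  angle = c(P = 119, `O5'` = 104, `C5'` = 120, `C4'` = 111,
            `C3'` = 116, `O3'` = 110)
)

.default_torsions <- c(alpha = -65, beta = 180, gamma = 55, delta = 130,
                       epsilon = 180, zeta = -95, chi = -110)

# base-ring template: named k x 3 matrix in the z = 0 plane, centered on the
# ring-atom centroid.  Purines get the fused 5+6 ring plus O6/N2 for G and
# N6 for A; pyrimidines the 6-ring plus O2/O4/N4.
base_template <- function(code) {
  poly_xy <- function(p0, p1, n, flip = FALSE) {
    # regular n-gon in the plane through p0, p1 (2-vectors)
    side <- vnorm(c(p1 - p0, 0))
    Rc <- side / (2 * sin(pi / n))
    h <- side / (2 * tan(pi / n))
    e <- (p1 - p0) / side
    perp <- c(-e[2], e[1]) * (if (flip) -1 else 1)
    center <- (p0 + p1) / 2 + h * perp
    v0 <- p0 - center
    t(vapply(0:(n - 1), function(k) {
      th <- 2 * pi * k / n * (if (flip) -1 else 1)
      center + c(cos(th) * v0[1] - sin(th) * v0[2],
                 sin(th) * v0[1] + cos(th) * v0[2])
    }, numeric(2)))
  }
  if (code %in% .purines) {
    # five-ring cycle N9 -> C4 -> C5 -> N7 -> C8
    pent <- poly_xy(c(0, 0), c(1.37, 0), 5)
    rownames(pent) <- c("N9", "C4", "C5", "N7", "C8")
    pc <- colMeans(pent)
    # fused six-ring on the C5-C4 edge, opposite side from the pentagon
    hex1 <- poly_xy(pent["C5", ], pent["C4", ], 6)
    hex2 <- poly_xy(pent["C5", ], pent["C4", ], 6, flip = TRUE)
    hex <- if (vnorm(c(colMeans(hex1) - pc, 0)) >
               vnorm(c(colMeans(hex2) - pc, 0))) hex1 else hex2
    rownames(hex) <- c("C5", "C4", "N3", "C2", "N1", "C6")
    ring <- rbind(pent, hex[c("N3", "C2", "N1", "C6"), ])
    hc <- colMeans(hex)
    out_of <- function(at, d = 1.3) {
      ring[at, ] + d * (ring[at, ] - hc) / vnorm(c(ring[at, ] - hc, 0))
    }
    extra <- if (code == "G") {
      rbind(O6 = out_of("C6", 1.23), N2 = out_of("C2", 1.34))
    } else {
      rbind(N6 = out_of("C6", 1.34))
    }
    xy <- rbind(ring, extra)
  } else {
    hex <- poly_xy(c(0, 0), c(1.38, 0), 6)
    rownames(hex) <- c("N1", "C2", "N3", "C4", "C5", "C6")
    hc <- colMeans(hex)
    out_of <- function(at, d) {
      hex[at, ] + d * (hex[at, ] - hc) / vnorm(c(hex[at, ] - hc, 0))
    }
    extra <- switch(code,
      C = rbind(O2 = out_of("C2", 1.24), N4 = out_of("C4", 1.34)),
      rbind(O2 = out_of("C2", 1.24), O4 = out_of("C4", 1.23)))
    xy <- rbind(hex, extra)
  }
  ring_names <- base_ring_atoms(code)
  centroid <- colMeans(xy[intersect(ring_names, rownames(xy)), ,
                          drop = FALSE])
  cbind(sweep(xy, 2, centroid), 0)
}

atoms_df <- function(names, xyz, element = NULL) {
  if (is.null(element)) element <- substr(names, 1, 1)
  data.frame(name = names, element = element,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             occupancy = 1, altloc = "", b_factor = 0,
             stringsAsFactors = FALSE)
}

# rigidly transform a residue's coordinates
transform_residue <- function(res, rotation = diag(3),
                              translation = c(0, 0, 0)) {
  xyz <- as.matrix(res$atoms[, c("x", "y", "z")])
  xyz <- transform_xyz(xyz, rotation, translation)
  res$atoms$x <- xyz[, 1]
  res$atoms$y <- xyz[, 2]
  res$atoms$z <- xyz[, 3]
  res
}

#' Build a furanose ring at a prescribed pseudorotation state
#'
#' Places the five ring atoms (O4', C1', C2', C3', C4') of a sugar ring on a
#' pentagon with out-of-plane displacements `z_j` proportional to
#' `cos(P + 144 (j - 2))`, then calibrates phase and amplitude iteratively
#' against the package's own pseudorotation measurement so the achieved
#' `(P, tau_m)` lands on the target.  Ring closure is approximate by
#' construction (displacement model), hence the documented +/- 2 degree
#' recovery tolerance for amplitudes in the 30-45 degree range.
#'
#' @param phase_P Target pseudorotation phase (degrees).
#' @param amplitude_tau_m Target amplitude (degrees, > 0; a warning is
#'   raised outside the calibrated 30-45 range).
#' @param seed Optional seed, used only when `noise_sd > 0`.
#' @param noise_sd Gaussian coordinate jitter (Angstrom).
#' @return A `residue_record` holding the five ring atoms.
#' @export
build_ring <- function(phase_P, amplitude_tau_m, seed = NULL, noise_sd = 0) {
  stopifnot(amplitude_tau_m > 0)
  if (amplitude_tau_m < 30 || amplitude_tau_m > 45) {
    warning("amplitude outside the calibrated 30-45 degree range; recovery may exceed the stated tolerance")
  }
  nm <- c("O4'", "C1'", "C2'", "C3'", "C4'")
  Rc <- 1.45 / (2 * sin(pi / 5))
  ang <- 2 * pi * (0:4) / 5
  xy <- cbind(Rc * cos(ang), Rc * sin(ang))
  as_res <- function(phi, q) {
    z <- q * cos(deg2rad(phi + 144 * (0:4)))
    residue_record("A", 1L, "T", atoms_df(nm, cbind(xy, z)),
                   original_name = "DT")
  }
  measure <- function(res) {
    sp <- sugar_pucker(res)
    c(sp$phase_P, sp$amplitude_tau_m)
  }
  phi <- phase_P
  q <- amplitude_tau_m * 0.4 / 38
  # direction in which the measured phase responds to the construction phase
  m1 <- measure(as_res(phi, q))[1]
  m2 <- measure(as_res(phi + 10, q))[1]
  sgn <- if (wrap180(m2 - m1) > 0) 1 else -1
  for (i in 1:12) {
    m <- measure(as_res(phi, q))
    dphi <- wrap180(phase_P - m[1])
    q <- q * amplitude_tau_m / m[2]
    phi <- phi + sgn * dphi
    if (abs(dphi) < 1e-9 && abs(m[2] - amplitude_tau_m) < 1e-9) break
  }
  res <- as_res(phi, q)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    res$atoms[, c("x", "y", "z")] <- res$atoms[, c("x", "y", "z")] +
      stats::rnorm(15, sd = noise_sd)
  }
  res
}

#' Build a nucleotide chain from prescribed torsions
#'
#' Atoms are placed sequentially by internal coordinates (standard bond
#' lengths and angles, target torsions), so re-measuring every targeted
#' torsion on the noise-free output reproduces the target to numerical
#' precision.  Each residue gets the six backbone atoms, the sugar branch
#' (O4', C1', C2') and a full planar base so that the glycosidic torsion chi
#' and the base plane are defined.
#'
#' @param sequence Character string of canonical codes (e.g. "TTA").
#' @param torsions Either a single named vector (recycled for every residue)
#'   or a data frame with one row per residue; recognised names are
#'   alpha, beta, gamma, delta, epsilon, zeta, chi.  Missing entries fall
#'   back on B-form-like defaults.
#' @param seed Optional seed, used only when `noise_sd > 0`.
#' @param noise_sd Gaussian coordinate jitter (Angstrom, default 0).
#' @return A `structure_model` with one chain "A".
#' @export
build_chain <- function(sequence, torsions = NULL, seed = NULL,
                        noise_sd = 0) {
  codes <- strsplit(toupper(sequence), "")[[1]]
  stopifnot(length(codes) >= 1,
            all(codes %in% c("A", "G", "C", "T", "U")))
  n <- length(codes)
  tors <- matrix(rep(.default_torsions, n), nrow = n, byrow = TRUE,
                 dimnames = list(NULL, names(.default_torsions)))
  if (!is.null(torsions)) {
    if (is.null(dim(torsions))) torsions <- as.data.frame(as.list(torsions))
    torsions <- as.data.frame(torsions)
    if (nrow(torsions) == 1) torsions <- torsions[rep(1, n), , drop = FALSE]
    stopifnot(nrow(torsions) == n)
    for (cn in intersect(colnames(tors), names(torsions))) {
      val <- torsions[[cn]]
      tors[!is.na(val), cn] <- val[!is.na(val)]
    }
  }
  if (!all(is.finite(tors))) stop("torsion targets must be finite")

  g <- .chain_geom
  residues <- vector("list", n)
  prev <- NULL  # list(C4, C3, O3) of previous residue
  for (i in seq_len(n)) {
    if (i == 1) {
      P <- c(0, 0, 0)
      O5 <- c(g$bond[["O5'"]], 0, 0)
      C5 <- O5 + g$bond[["C5'"]] *
        c(cos(deg2rad(180 - g$angle[["C5'"]])),
          sin(deg2rad(180 - g$angle[["C5'"]])), 0)
    } else {
      P <- place_atom(prev$C4, prev$C3, prev$O3, g$bond[["P"]],
                      g$angle[["P"]], tors[i - 1, "epsilon"])
      O5 <- place_atom(prev$C3, prev$O3, P, g$bond[["O5'"]],
                       g$angle[["O5'"]], tors[i - 1, "zeta"])
      C5 <- place_atom(prev$O3, P, O5, g$bond[["C5'"]],
                       g$angle[["C5'"]], tors[i, "alpha"])
    }
    C4 <- place_atom(P, O5, C5, g$bond[["C4'"]], g$angle[["C4'"]],
                     tors[i, "beta"])
    C3 <- place_atom(O5, C5, C4, g$bond[["C3'"]], g$angle[["C3'"]],
                     tors[i, "gamma"])
    O3 <- place_atom(C5, C4, C3, g$bond[["O3'"]], g$angle[["O3'"]],
                     tors[i, "delta"])
    # sugar branch and glycosidic attachment
    O4 <- place_atom(C5, C3, C4, 1.45, 105, -121)
    C1 <- place_atom(C3, C4, O4, 1.41, 109.5, 20)
    C2 <- place_atom(C4, O4, C1, 1.53, 106, -20)
    Ng <- place_atom(C4, O4, C1, 1.47, 108, -140)  # N9 / N1
    Cg <- place_atom(O4, C1, Ng, 1.37, 127, tors[i, "chi"])  # C4 / C2

    code <- codes[i]
    n_name <- if (code %in% .purines) "N9" else "N1"
    c_name <- if (code %in% .purines) "C4" else "C2"
    names_bk <- c("P", "O5'", "C5'", "C4'", "C3'", "O3'", "O4'", "C1'",
                  "C2'")
    xyz <- rbind(P, O5, C5, C4, C3, O3, O4, C1, C2)
    # complete the planar base from the template, anchored on the
    # glycosidic N and its chi-defining ring neighbour
    tmpl <- base_template(code)
    anchor <- tmpl[c(n_name, c_name), ]
    target <- rbind(Ng, Cg)
    # third anchor: a point off the base plane on the C1' side
    tn <- c(0, 0, 1)
    w <- unitv(cross3(Cg - Ng, C1 - Ng))
    fit <- kabsch(rbind(anchor, anchor[1, ] + tn),
                  rbind(target, Ng + w))
    base_xyz <- transform_xyz(tmpl, fit$rotation, fit$translation)
    keep <- setdiff(rownames(tmpl), c(n_name, c_name))
    xyz <- rbind(xyz, Ng, Cg, base_xyz[keep, , drop = FALSE])
    atom_names <- c(names_bk, n_name, c_name, keep)
    rownames(xyz) <- NULL
    residues[[i]] <- residue_record(
      "A", i, code, atoms_df(atom_names, xyz),
      original_name = if (code == "U") "U" else paste0("D", code))
    prev <- list(C4 = C4, C3 = C3, O3 = O3)
  }
  model <- structure_model("synthetic_chain", list(A = residues))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    model$chains$A <- lapply(model$chains$A, function(r) {
      r$atoms[, c("x", "y", "z")] <- r$atoms[, c("x", "y", "z")] +
        stats::rnorm(3 * nrow(r$atoms), sd = noise_sd)
      r
    })
  }
  model
}

# idealized posed base with optional dummy sugar/backbone, used by the
# triplet and toy-quadruplex builders
make_synthetic_residue <- function(code, centroid, normal, spin = 0,
                                   seq_num = 1L, chain_id = "A",
                                   with_backbone = TRUE) {
  R <- rot_z_to(normal) %*% rot_z(spin)
  tmpl <- base_template(code)
  base_xyz <- transform_xyz(tmpl, R, centroid)
  names_all <- rownames(tmpl)
  xyz <- base_xyz
  if (with_backbone) {
    ring <- build_ring(150, 38)
    rxyz <- as.matrix(ring$atoms[, c("x", "y", "z")])
    rxyz <- transform_xyz(sweep(rxyz, 2, colMeans(rxyz)), R,
                          centroid + as.numeric(R %*% c(4.8, 0, -0.5)))
    rownames(rxyz) <- ring$atoms$name
    C5 <- rxyz["C4'", ] + as.numeric(R %*% c(1.0, 0.5, 0.9))
    O5 <- C5 + as.numeric(R %*% c(1.0, 0.5, 0.2))
    Pp <- O5 + as.numeric(R %*% c(1.0, 0.3, 0.4))
    O3 <- rxyz["C3'", ] + as.numeric(R %*% c(0.7, 0.7, 0.7))
    xyz <- rbind(xyz, rxyz, `C5'` = C5, `O5'` = O5, P = Pp, `O3'` = O3)
    names_all <- c(names_all, rownames(rxyz), "C5'", "O5'", "P", "O3'")
  }
  rownames(xyz) <- NULL
  residue_record(chain_id, seq_num, code, atoms_df(names_all, xyz),
                 original_name = if (code == "U") "U" else
                   paste0("D", code))
}

# (centroid, normal, spin) placements realizing each descriptor row; roles
# in order L1, L2, L3
triplet_geometry <- function(row, subtype = "a") {
  z <- c(0, 0, 1)
  x <- c(1, 0, 0)
  d45 <- unitv(c(1, 0, 1))
  G <- function(c1, n1, c2, n2, c3, n3) {
    list(L1 = list(c = c1, n = n1), L2 = list(c = c2, n = n2),
         L3 = list(c = c3, n = n3))
  }
  if (row == 1 && subtype == "b") {
    return(G(c(0, 0, 0), z, c(0.3, 0, 6.8), z, c(0.3, 0, 3.4), z))
  }
  switch(as.character(row),
    "1"  = G(c(0, 0, 0), z, c(5.5, 0, 5.0), x, c(0.3, 0, 3.4), z),
    "2"  = G(c(0, 0, 0), z, c(0.3, 0, 3.4), z, c(12, 0, 0), z),
    "3"  = G(c(5.5, 0, 5.0), x, c(0, 0, 0), z, c(0.3, 0, 3.4), z),
    "4"  = G(c(-12, 0, 0), z, c(0, 0, 0), z, c(5, 0, 0), x),
    "5"  = G(c(6, 0, 1.7), d45, c(0, 0, 0), z, c(0.3, 0, 3.4), z),
    "6"  = G(c(6.6, 0, 5.1), x, c(0, 0, 0), z, c(0.3, 0, 3.4), z),
    "7"  = G(c(0, 6, -1), d45, c(0, 0, 0), z, c(0.3, 0, 3.4), z),
    "8"  = G(c(6.6, 0, 5.1), x, c(0, 0, 0), z, c(0.3, 0, 3.4), z),
    "9"  = G(c(0, 0, 0), z, c(12, 0, 0), z, c(0, 12, 0), z),
    "10" = G(c(-12, 0, 0), z, c(0, 0, 0), z, c(0.3, 0, 3.4), z),
    "11" = G(c(0, 0, 0), z, c(5, 0, 0), x, c(0, 5, 0), d45),
    "12" = G(c(0, -12, 2), z, c(0, 0, 0), z, c(0.3, 0, 3.4), z),
    stop(sprintf("no descriptor row %s", row)))
}

#' Build an idealized loop triplet realizing one descriptor row
#'
#' Poses three idealized bases (plus a dummy sugar/backbone so the residues
#' pass atom-completeness checks) so that their pairwise stacking /
#' perpendicularity / proximity relations reproduce the requested row of
#' the twelve-type descriptor table under the default thresholds.
#'
#' @param table2_row Integer 1-12.
#' @param subtype For row 1: "a" (central base perpendicular to the
#'   adenine) or "b" (central base stacked on the adenine's outer face).
#' @param seq_offset Residue numbering offset for the three residues.
#' @return A `loop_instance` (codes UUA for row 8, TTA otherwise).
#' @export
build_triplet <- function(table2_row, subtype = "a", seq_offset = 0L) {
  geo <- triplet_geometry(table2_row, subtype)
  codes <- if (table2_row == 8) c("U", "U", "A") else c("T", "T", "A")
  spins <- c(0, 25, 50)
  residues <- lapply(1:3, function(i) {
    make_synthetic_residue(codes[i], geo[[i]]$c, geo[[i]]$n,
                           spin = spins[i],
                           seq_num = seq_offset + i)
  })
  loop_instance(sprintf("synthetic_row%d%s", table2_row,
                        if (table2_row == 1) subtype else ""),
                1L, "A", residues, positions = seq_offset + 1:3,
                flanking = list(prev = NULL, nxt = NULL), resolved = TRUE)
}

#' Build a toy parallel quadruplex
#'
#' Assembles a 22-nucleotide single chain, 5'-A G3 (TTA G3)3, with three
#' stacked four-fold-symmetric G-quartets as the core and three loop
#' triplets (one per requested descriptor row) on the outside -- the
#' sequence layout of the native unimolecular telomeric quadruplex.  The
#' geometry is idealized, not physical; its purpose is to exercise parsing,
#' loop finding, typing, and core superposition end to end without any
#' downloaded coordinates.
#'
#' @param loop_rows Integer vector of length 3: descriptor row for each
#'   loop.
#' @param path Optional output path; when given the model is also written
#'   as a PDB-format file.
#' @param seed Seed for the coordinate jitter (used when `noise_sd > 0`).
#' @param noise_sd Gaussian coordinate jitter (Angstrom, default 0).
#' @param drop_atoms Optional list of `list(seq, atom)` entries naming
#'   atoms to delete, e.g. to fabricate an unresolved loop.
#' @return The `structure_model`, invisibly when `path` is given.
#' @export
build_toy_quadruplex <- function(loop_rows = c(1, 1, 1), path = NULL,
                                 seed = 1, noise_sd = 0,
                                 drop_atoms = NULL) {
  stopifnot(length(loop_rows) == 3)
  z <- c(0, 0, 1)
  # core guanines: tract t at 90 (t - 1) degrees, layers at z = 0/3.3/6.6
  tract0 <- lapply(1:3, function(g2) {
    make_synthetic_residue("G", c(5.5, 0, 3.3 * (g2 - 1)), z)
  })
  tracts <- lapply(1:4, function(t) {
    R <- rot_z(90 * (t - 1))
    lapply(tract0, transform_residue, rotation = R)
  })
  loops <- lapply(1:3, function(k) {
    tri <- build_triplet(loop_rows[k])
    R <- rot_z(45 + 90 * (k - 1))
    lapply(tri$residues, function(r) {
      transform_residue(r, diag(3), c(10.5, 0, 3)) |>
        transform_residue(rotation = R)
    })
  })
  flank <- make_synthetic_residue("A", c(13, 0, -4), z)
  residues <- c(list(flank), tracts[[1]], loops[[1]], tracts[[2]],
                loops[[2]], tracts[[3]], loops[[3]], tracts[[4]])
  for (i in seq_along(residues)) residues[[i]]$seq_num <- i
  if (noise_sd > 0) {
    set.seed(seed)
    residues <- lapply(residues, function(r) {
      r$atoms[, c("x", "y", "z")] <- r$atoms[, c("x", "y", "z")] +
        stats::rnorm(3 * nrow(r$atoms), sd = noise_sd)
      r
    })
  }
  if (!is.null(drop_atoms)) {
    for (spec in drop_atoms) {
      r <- residues[[spec$seq]]
      r$atoms <- r$atoms[r$atoms$name != spec$atom, , drop = FALSE]
      residues[[spec$seq]] <- r
    }
  }
  model <- structure_model("toy_quadruplex", list(A = residues))
  if (!is.null(path)) {
    write_structure(model, path)
    return(invisible(model))
  }
  model
}

#' Build an in-memory exemplar library from the synthetic triplets
#'
#' One idealized exemplar per descriptor row (both sub-types for row 1),
#' usable by [assign_loop_type()] to break the row-10/12 ambiguity on
#' synthetic loops and as a template for user-supplied libraries of real
#' coordinates.
#'
#' @param rows Which descriptor rows to include.
#' @return List of `list(type, loop)` entries.
#' @export
build_exemplar_library <- function(rows = 1:12) {
  out <- lapply(rows, function(r) list(type = as.integer(r),
                                       loop = build_triplet(r)))
  if (1 %in% rows) {
    out <- c(out, list(list(type = 1L,
                            loop = build_triplet(1, subtype = "b"))))
  }
  out
}

#' Write an exemplar library to disk
#'
#' @param exemplars Library from [build_exemplar_library()].
#' @param dir Output directory; fragments are written as PDB files next to
#'   a `manifest.csv`.
#' @return `dir`, invisibly.
#' @export
write_exemplar_library <- function(exemplars, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  types <- integer(0)
  for (i in seq_along(exemplars)) {
    ex <- exemplars[[i]]
    file <- sprintf("exemplar_%02d_type%d.pdb", i, ex$type)
    model <- structure_model(sub("\\.pdb$", "", file),
                             list(A = ex$loop$residues))
    write_structure(model, file.path(dir, file))
    files <- c(files, file)
    types <- c(types, ex$type)
  }
  utils::write.csv(data.frame(type = types, file = files),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}
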