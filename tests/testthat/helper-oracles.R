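# Shared helpers: rigid-motion generators and independent oracles used to
# cross-check the analytic geometry (tolerances stated at the assertion
# sites).

rot_from_quat <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

random_rotation <- function() rot_from_quat(rnorm(4))

apply_rigid <- function(xyz, R, t) {
  sweep(as.matrix(xyz) %*% t(R), 2, t, "+")
}

# rigidly transform every residue of a model / loop
transform_model <- function(model, R, t) {
  model$chains <- lapply(model$chains, function(chain) {
    lapply(chain, transform_residue_xyz, R = R, t = t)
  })
  model
}

transform_residue_xyz <- function(res, R, t) {
  xyz <- apply_rigid(res$atoms[, c("x", "y", "z")], R, t)
  res$atoms$x <- xyz[, 1]
  res$atoms$y <- xyz[, 2]
  res$atoms$z <- xyz[, 3]
  res
}

transform_loop <- function(loop, R, t) {
  loop$residues <- lapply(loop$residues, transform_residue_xyz, R = R, t = t)
  loop
}

# brute-force minimum RMSD over rotation space: dense quaternion sampling
# followed by Nelder-Mead refinement from the best starts; independent of
# the SVD route used by kabsch()
oracle_min_rmsd <- function(moving, fixed, n_samples = 3000) {
  A <- sweep(as.matrix(moving), 2, colMeans(moving))
  B <- sweep(as.matrix(fixed), 2, colMeans(fixed))
  f <- function(q) {
    R <- rot_from_quat(q)
    sqrt(mean(rowSums((A %*% t(R) - B)^2)))
  }
  qs <- matrix(rnorm(4 * n_samples), ncol = 4)
  vals <- apply(qs, 1, f)
  best <- Inf
  for (i in order(vals)[1:3]) {
    o <- stats::optim(qs[i, ], f, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-15))
    best <- min(best, o$value)
  }
  best
}

# least-squares plane by full eigen-decomposition of the covariance matrix
# (kept separate from base_plane's internals on purpose)
oracle_plane <- function(xyz) {
  xyz <- as.matrix(xyz)
  centroid <- colMeans(xyz)
  cc <- sweep(xyz, 2, centroid)
  ev <- eigen(stats::cov(cc), symmetric = TRUE)
  normal <- ev$vectors[, 3]
  list(centroid = centroid, normal = normal,
       rms = sqrt(mean((cc %*% normal)^2)))
}

# build a bare sugar-ring residue from explicit coordinates
ring_residue <- function(xyz) {
  nm <- c("O4'", "C1'", "C2'", "C3'", "C4'")
  residue_record("A", 1L, "T", data.frame(
    name = nm, element = substr(nm, 1, 1),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, altloc = "", b_factor = 0,
    stringsAsFactors = FALSE))
}

# hand-rolled fixed-column PDB lines for parser edge cases (altlocs,
# HETATM-encoded modified residues, MODEL blocks, waters)
pdb_line <- function(record, serial, name, alt, resid, chain, resno,
                     x, y, z, occ = 1, b = 0, elem = substr(name, 1, 1)) {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, paste0(" ", name), alt, resid, chain, resno,
          x, y, z, occ, b, elem)
}
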