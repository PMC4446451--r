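# Dihedral machinery, pseudorotation, base planes and superposition.
# Tolerances: 1e-6 degrees for angle round trips, 1e-9 for orthogonality.

test_that("dihedral reproduces planar and orthogonal constructions", {
  expect_equal(dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0)), 180)
  expect_equal(dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)), 0)
  expect_equal(dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1)), 90)
})

test_that("dihedral is invariant under chain reversal, negated by mirror", {
  set.seed(101)
  for (i in 1:25) {
    p <- matrix(rnorm(12), 4, 3)
    d1 <- dihedral(p[1, ], p[2, ], p[3, ], p[4, ])
    # reading the quadruple backwards leaves the signed torsion unchanged
    expect_equal(dihedral(p[4, ], p[3, ], p[2, ], p[1, ]), d1,
                 tolerance = 1e-9)
    # a mirror image negates it (away from the +/-180 boundary)
    q <- p %*% diag(c(1, 1, -1))
    if (abs(abs(d1) - 180) > 1e-9) {
      expect_equal(dihedral(q[1, ], q[2, ], q[3, ], q[4, ]), -d1,
                   tolerance = 1e-9)
    }
  }
})

test_that("degenerate dihedrals signal undefined, not a number", {
  expect_true(is.na(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0))))
  expect_true(is.na(dihedral(c(0, 0, 0), c(0, 0, 0), c(1, 1, 0), c(2, 1, 0))))
})

test_that("torsion sets recover construction targets and flag boundaries", {
  tor <- c(alpha = -60, beta = -60, gamma = -60, delta = -60,
           epsilon = -60, zeta = -60, chi = -60)
  m <- build_chain("TTA", tor)
  ch <- m$chains$A
  ts1 <- torsion_set(NULL, ch[[1]], ch[[2]])
  ts2 <- torsion_set(ch[[1]], ch[[2]], ch[[3]])
  ts3 <- torsion_set(ch[[2]], ch[[3]], NULL)
  # 5'-terminal: alpha needs the previous O3', everything else defined
  expect_true(is.na(ts1["alpha"]))
  expect_equal(as.numeric(ts1[c("beta", "gamma", "delta", "epsilon",
                                "zeta", "chi")]),
               rep(-60, 6), tolerance = 1e-6)
  expect_equal(as.numeric(ts2), rep(-60, 7), tolerance = 1e-6)
  # 3'-terminal: epsilon/zeta need the next phosphate
  expect_true(all(is.na(ts3[c("epsilon", "zeta")])))
  expect_equal(as.numeric(ts3[c("alpha", "beta", "gamma", "delta", "chi")]),
               rep(-60, 5), tolerance = 1e-6)
})

test_that("chi uses the purine and pyrimidine atom quadruples", {
  m <- build_chain("TA", c(chi = -115))
  ch <- m$chains$A
  for (i in 1:2) {
    res <- ch[[i]]
    ts <- torsion_set(if (i > 1) ch[[i - 1]], res, if (i < 2) ch[[i + 1]])
    expect_equal(as.numeric(ts["chi"]), -115, tolerance = 1e-6)
    nms <- if (res$code == "A") c("N9", "C4") else c("N1", "C2")
    expect_true(all(nms %in% res$atoms$name))
  }
})

test_that("pseudorotation inverts the cosine model exactly", {
  for (P0 in c(18, 162, 305)) {
    for (tau in c(40, 20)) {
      nu <- tau * cos(pi / 180 * (P0 + 144 * ((0:4) - 2)))
      pr <- pseudorotation(nu)
      expect_equal(unname(pr["phase_P"]), P0, tolerance = 1e-6)
      expect_equal(unname(pr["amplitude_tau_m"]), tau, tolerance = 1e-6)
      # homogeneity: scaling nu scales tau_m, leaves P alone
      pr2 <- pseudorotation(nu * 0.5)
      expect_equal(unname(pr2["phase_P"]), P0, tolerance = 1e-6)
      expect_equal(unname(pr2["amplitude_tau_m"]), tau / 2,
                   tolerance = 1e-6)
    }
  }
  # nu2 = 0 sits on the atan2 quadrant boundary: P = 90 or 270
  nu <- 40 * cos(pi / 180 * (90 + 144 * ((0:4) - 2)))
  expect_equal(unname(pseudorotation(nu)["phase_P"]), 90, tolerance = 1e-6)
  expect_true(all(is.na(pseudorotation(rep(0, 5)))))
})

test_that("pucker bins tile the wheel with no gaps or overlaps", {
  expect_identical(pucker_class(18), "C3'-endo")
  expect_identical(pucker_class(126), "C1'-exo")
  expect_identical(pucker_class(162), "C2'-endo")   # adenine consensus
  P <- seq(0, 359.999, by = 0.25)
  cls <- pucker_class(P)
  expect_false(anyNA(cls))
  expect_identical(sort(unique(cls)), sort(PUCKER_CLASSES))
  expect_identical(as.integer(table(cls)[PUCKER_CLASSES]),
                   rep(144L, 10))
  # out-of-range phases normalize modulo 360
  expect_identical(pucker_class(378), pucker_class(18))
  expect_identical(pucker_class(-198), pucker_class(162))
})

test_that("sugar_pucker signals undefined when a ring atom is missing", {
  r <- build_ring(10, 38)
  sp <- sugar_pucker(r)
  expect_equal(sp$phase_P, 10, tolerance = 2)
  expect_identical(sp$pucker_class, "C3'-endo")
  r$atoms <- r$atoms[r$atoms$name != "O4'", ]
  expect_null(sugar_pucker(r))
})

test_that("base planes match the eigen-decomposition oracle", {
  hexagon <- function(z = rep(0, 6)) {
    ang <- 2 * pi * (0:5) / 6
    residue_record("A", 1L, "T", data.frame(
      name = c("N1", "C2", "N3", "C4", "C5", "C6"), element = "C",
      x = 1.39 * cos(ang), y = 1.39 * sin(ang), z = z,
      occupancy = 1, altloc = "", b_factor = 0))
  }
  bp <- base_plane(hexagon())
  expect_equal(abs(bp$normal[3]), 1, tolerance = 1e-9)
  expect_equal(bp$rms_planarity, 0, tolerance = 1e-9)
  expect_equal(sqrt(sum(bp$normal^2)), 1, tolerance = 1e-9)

  lifted <- hexagon(c(0.1, rep(0, 5)))
  bp <- base_plane(lifted)
  or <- oracle_plane(as.matrix(lifted$atoms[, c("x", "y", "z")]))
  expect_gt(bp$rms_planarity, 0)
  expect_equal(bp$rms_planarity, or$rms, tolerance = 1e-9)
  expect_equal(abs(sum(bp$normal * or$normal)), 1, tolerance = 1e-9)
  expect_lt(acos(min(1, abs(bp$normal[3]))) * 180 / pi, 5)

  two <- hexagon()
  two$atoms <- two$atoms[1:2, ]
  expect_null(base_plane(two))
})

test_that("kabsch recovers rigid motions and matches brute force", {
  set.seed(7)
  X <- matrix(rnorm(15, sd = 3), 5, 3)
  expect_equal(kabsch(X, X)$rmsd, 0, tolerance = 1e-12)

  ax <- c(1, 2, 3) / sqrt(14)
  R <- rot_from_quat(c(cos(18.5 * pi / 180), sin(18.5 * pi / 180) * ax))
  Y <- apply_rigid(X, R, c(4, -2, 9))
  fit <- kabsch(X, Y)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_equal(crossprod(fit$rotation), diag(3), tolerance = 1e-9,
               ignore_attr = TRUE)

  for (i in 1:5) {
    A <- matrix(rnorm(15), 5, 3)
    B <- matrix(rnorm(15), 5, 3)
    fit <- kabsch(A, B)
    expect_equal(fit$rmsd, oracle_min_rmsd(A, B), tolerance = 1e-6)
    # naive (untransformed) RMSD is never beaten by the optimum
    expect_lte(fit$rmsd, sqrt(mean(rowSums((A - B)^2))))
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  }
  expect_error(kabsch(matrix(0, 2, 3), matrix(0, 2, 3)), "at least 3")
  degen <- kabsch(cbind(1:4, 0, 0), cbind(0, 1:4, 0))
  expect_true(degen$degenerate)
})

test_that("torsions, puckers and core RMSD are rigid-motion invariant", {
  set.seed(23)
  m <- build_toy_quadruplex(c(1, 9, 4))
  R <- random_rotation()
  t <- rnorm(3, sd = 15)
  mt <- transform_model(m, R, t)
  ch <- m$chains$A
  cht <- mt$chains$A
  for (i in c(5, 6, 7, 12)) {
    ts <- torsion_set(ch[[i - 1]], ch[[i]], ch[[i + 1]])
    tst <- torsion_set(cht[[i - 1]], cht[[i]], cht[[i + 1]])
    expect_equal(as.numeric(tst), as.numeric(ts), tolerance = 1e-6)
    sp <- sugar_pucker(ch[[i]])
    spt <- sugar_pucker(cht[[i]])
    expect_equal(spt$phase_P, sp$phase_P, tolerance = 1e-6)
    expect_identical(spt$pucker_class, sp$pucker_class)
  }
  expect_equal(quartet_core_rmsd(mt, m)$rmsd, 0, tolerance = 1e-6)
})

test_that("quartet core alignment is symmetric and permutation-aware", {
  m <- build_toy_quadruplex(c(1, 9, 4))
  expect_equal(quartet_core_rmsd(m, m)$rmsd, 0, tolerance = 1e-9)
  # relabelling the tracts by the four-fold symmetry must still give 0
  m90 <- transform_model(m, rot_from_quat(c(cos(pi / 4), 0, 0, sin(pi / 4))),
                         c(0, 0, 0))
  expect_equal(quartet_core_rmsd(m90, m)$rmsd, 0, tolerance = 1e-6)

  m2 <- build_toy_quadruplex(c(1, 1, 1), seed = 4, noise_sd = 0.3)
  f12 <- quartet_core_rmsd(m, m2)
  f21 <- quartet_core_rmsd(m2, m)
  expect_equal(f12$rmsd, f21$rmsd, tolerance = 1e-6)
  expect_gt(f12$rmsd, 0)

  # a model without four tracts is refused by name
  expect_error(quartet_core_rmsd(build_chain("GGGTTAGGG"), m), "G-tracts")
})

test_that("ensemble alignment reports per-model values and their mean", {
  ref <- build_toy_quadruplex(c(1, 1, 1))
  mods <- lapply(1:3, function(i) {
    m <- build_toy_quadruplex(c(1, 1, 1), seed = i, noise_sd = 0.1)
    m$model_num <- i
    m
  })
  ens <- quartet_core_rmsd_ensemble(mods, ref)
  expect_equal(nrow(ens$per_model), 3)
  expect_equal(ens$mean_rmsd, mean(ens$per_model$rmsd))
  expect_true(all(ens$per_model$rmsd > 0))
})
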