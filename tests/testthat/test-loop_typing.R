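# Stacking descriptors and the twelve-type rulebook.

plane_at <- function(centroid, normal) {
  structure(list(centroid = centroid, normal = normal / sqrt(sum(normal^2)),
                 rms_planarity = 0, ring_atoms_used = character(0)),
            class = "base_plane")
}

test_that("stack relations follow the threshold rules", {
  z <- c(0, 0, 1)
  # ideal pi-stack: 3.4 A apart, parallel, no offset
  r <- stack_relation(plane_at(c(0, 0, 0), z), plane_at(c(0, 0, 3.4), z))
  expect_identical(r$relation, "stacked")
  expect_equal(r$centroid_distance, 3.4)
  expect_equal(r$interplanar_angle, 0, tolerance = 1e-9)
  expect_equal(r$lateral_offset, 0, tolerance = 1e-9)
  # 85-degree tilt at 5 A: perpendicular
  n85 <- c(sin(85 * pi / 180), 0, cos(85 * pi / 180))
  r <- stack_relation(plane_at(c(0, 0, 0), z), plane_at(c(5, 0, 0), n85))
  expect_identical(r$relation, "perpendicular")
  expect_equal(r$interplanar_angle, 85, tolerance = 1e-9)
  # parallel but 9 A apart: neither
  r <- stack_relation(plane_at(c(0, 0, 0), z), plane_at(c(0, 0, 9), z))
  expect_identical(r$relation, "neither")
  # large lateral offset defeats stacking even when close and parallel
  r <- stack_relation(plane_at(c(0, 0, 0), z), plane_at(c(3.5, 0, 3), z))
  expect_identical(r$relation, "neither")
})

test_that("stack relations are symmetric in their arguments", {
  set.seed(5)
  for (i in 1:10) {
    a <- plane_at(rnorm(3, sd = 3), rnorm(3))
    b <- plane_at(rnorm(3, sd = 3), rnorm(3))
    r1 <- stack_relation(a, b)
    r2 <- stack_relation(b, a)
    expect_identical(r1$relation, r2$relation)
    expect_equal(r1$centroid_distance, r2$centroid_distance)
    expect_equal(r1$interplanar_angle, r2$interplanar_angle)
    expect_equal(r1$lateral_offset, r2$lateral_offset, tolerance = 1e-9)
  }
})

test_that("proximity uses the inclusive close threshold", {
  z <- c(0, 0, 1)
  expect_identical(proximity(plane_at(c(0, 0, 0), z),
                             plane_at(c(4, 0, 0), z)), "close")
  expect_identical(proximity(plane_at(c(0, 0, 0), z),
                             plane_at(c(12, 0, 0), z)), "away")
  expect_identical(proximity(plane_at(c(0, 0, 0), z),
                             plane_at(c(6.5, 0, 0), z)), "close")
  expect_identical(proximity(plane_at(c(0, 0, 0), z),
                             plane_at(c(6.5 + 1e-9, 0, 0), z)), "away")
})

test_that("fingerprints capture the descriptor table rows", {
  fp <- loop_fingerprint(build_triplet(1))
  expect_identical(fp$stacked, "L1-L3")
  expect_identical(fp$perpendicular, "L2-L3")
  expect_identical(fp$prox["L2", "L3"], "close")

  fp <- loop_fingerprint(build_triplet(10))
  expect_identical(fp$stacked, "L2-L3")
  expect_length(fp$perpendicular, 0)
  expect_identical(unname(fp$prox["L1", c("L2", "L3")]), c("away", "away"))

  fp <- loop_fingerprint(build_triplet(9))
  expect_length(fp$stacked, 0)
  expect_length(fp$perpendicular, 0)
  expect_true(all(fp$prox[upper.tri(fp$prox)] == "away"))
})

test_that("undefined base planes yield an unclassifiable fingerprint", {
  tri <- build_triplet(1)
  tri$residues[[2]]$atoms <-
    tri$residues[[2]]$atoms[!grepl("^[NC][0-9]$", tri$residues[[2]]$atoms$name), ]
  fp <- loop_fingerprint(tri)
  expect_false(fp$defined)
  expect_identical(assign_loop_type(fp)$label, "unclassified")
})

test_that("all twelve descriptor rows classify to their type", {
  expected <- as.list(1:12)
  expected[[10]] <- c(10L, 12L)
  expected[[12]] <- c(10L, 12L)
  for (row in 1:12) {
    asg <- assign_loop_type(loop_fingerprint(build_triplet(row)))
    expect_identical(asg$assigned_type, as.integer(expected[[row]]),
                     label = sprintf("row %d", row))
  }
  # both type-1 sub-types count as type 1
  a1a <- assign_loop_type(loop_fingerprint(build_triplet(1, "a")))
  a1b <- assign_loop_type(loop_fingerprint(build_triplet(1, "b")))
  expect_identical(a1a$assigned_type, 1L)
  expect_identical(a1b$assigned_type, 1L)
  expect_identical(c(a1a$subtype, a1b$subtype), c("1a", "1b"))
})

test_that("the UUA analogue of the perpendicular-first-base row is type 8", {
  asg6 <- assign_loop_type(loop_fingerprint(build_triplet(6)))
  asg8 <- assign_loop_type(loop_fingerprint(build_triplet(8)))
  expect_identical(asg6$assigned_type, 6L)
  expect_identical(asg8$assigned_type, 8L)
})

test_that("exemplars break the 10/12 ambiguity by shape", {
  ex <- build_exemplar_library()
  for (row in c(10, 12)) {
    tri <- build_triplet(row)
    asg <- assign_loop_type(loop_fingerprint(tri), exemplars = ex,
                            loop = tri)
    expect_identical(asg$assigned_type, as.integer(row))
    expect_identical(asg$method, "exemplar")
    expect_lt(asg$exemplar_rmsd, 0.5)
  }
})

test_that("rulebook misses return unclassified", {
  # three mutually stacked bases match no descriptor row
  z <- c(0, 0, 1)
  tri <- build_triplet(1)
  fp <- loop_fingerprint(tri)
  fp$stacked <- c("L1-L2", "L1-L3", "L2-L3")
  fp$perpendicular <- character(0)
  expect_identical(assign_loop_type(fp)$label, "unclassified")
})

test_that("assignment is deterministic and rigid-motion invariant", {
  set.seed(31)
  for (row in c(1, 3, 5, 7, 9, 11)) {
    tri <- build_triplet(row)
    asg0 <- assign_loop_type(loop_fingerprint(tri))
    trit <- transform_loop(tri, random_rotation(), rnorm(3, sd = 25))
    asg1 <- assign_loop_type(loop_fingerprint(trit))
    expect_identical(asg1$assigned_type, asg0$assigned_type)
    expect_identical(asg1$label,
                     assign_loop_type(loop_fingerprint(trit))$label)
  }
})

test_that("exemplar libraries survive a disk round trip", {
  dir <- withr::local_tempdir()
  write_exemplar_library(build_exemplar_library(c(9, 10, 12)), dir)
  ex <- read_exemplar_library(dir)
  expect_length(ex, 3)
  expect_setequal(vapply(ex, `[[`, 0L, "type"), c(9L, 10L, 12L))
  tri <- build_triplet(12)
  asg <- assign_loop_type(loop_fingerprint(tri), exemplars = ex, loop = tri)
  expect_identical(asg$assigned_type, 12L)
  expect_error(read_exemplar_library(withr::local_tempdir()), "manifest")
})
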