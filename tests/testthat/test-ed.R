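test_that("rigid motions are removed exactly and fitting is idempotent", {
  set.seed(21)
  ref <- matrix(rnorm(24, sd = 0.2), 8, 3)
  masses <- c(12, 12, 12, 12, 16, 12, 16, 12)
  ## frame = reference under a pure rigid motion: recovered exactly
  rot90z <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3)
  moved <- ref %*% rot90z + matrix(c(1, -2, 0.5), 8, 3, byrow = TRUE)
  xyz <- rbind(as.numeric(t(ref)), as.numeric(t(moved)))
  fitted <- fit_trajectory(xyz, masses, reference = xyz[1, ])
  expect_lt(max(abs(fitted[2, ] - xyz[1, ])), 1e-10)
  expect_lt(max(abs(fitted[1, ] - xyz[1, ])), 1e-10)
  ## idempotence
  fitted2 <- fit_trajectory(fitted, masses, reference = fitted[1, ])
  expect_lt(max(abs(fitted2 - fitted)), 1e-10)
  ## internal geometry preserved
  d_before <- dist(matrix(xyz[2, ], ncol = 3, byrow = TRUE))
  d_after <- dist(matrix(fitted[2, ], ncol = 3, byrow = TRUE))
  expect_equal(as.numeric(d_after), as.numeric(d_before), tolerance = 1e-10)
})

test_that("the superposition is optimal against random rigid transforms", {
  set.seed(22)
  masses <- rep(c(12, 16), 4)
  ref <- matrix(rnorm(24, sd = 0.2), 8, 3)
  distorted <- ref + matrix(rnorm(24, sd = 0.02), 8, 3)
  moved <- random_rigid(distorted)
  xyz <- rbind(as.numeric(t(ref)), as.numeric(t(moved)))
  fitted <- fit_trajectory(xyz, masses, reference = xyz[1, ])
  w <- masses / sum(masses)
  wrmsd <- function(flat) {
    d <- matrix(flat - xyz[1, ], ncol = 3, byrow = TRUE)
    sqrt(sum(w * rowSums(d^2)))
  }
  best <- wrmsd(fitted[2, ])
  for (it in 1:300) {
    cand <- random_rigid(distorted)
    expect_gte(wrmsd(as.numeric(t(cand))), best - 1e-12)
  }
})

test_that("superposition agrees with an independent implementation on equal masses", {
  skip_if_not_installed("bio3d")
  set.seed(23)
  ref <- matrix(rnorm(18, sd = 0.3), 6, 3)
  moved <- random_rigid(ref + matrix(rnorm(18, sd = 0.03), 6, 3))
  xyz <- rbind(as.numeric(t(ref)), as.numeric(t(moved)))
  ours <- fit_trajectory(xyz, masses = rep(1, 6), reference = xyz[1, ])
  theirs <- bio3d::fit.xyz(fixed = xyz[1, ], mobile = xyz,
                           fixed.inds = 1:18, mobile.inds = 1:18)
  expect_equal(ours[2, ], unname(theirs[2, ]), tolerance = 1e-8)
})

test_that("covariance eigendecomposition recovers a planted direction and conserves trace", {
  set.seed(24)
  n3 <- 24
  d <- rnorm(n3); d <- d / sqrt(sum(d^2))
  amp <- rnorm(500, sd = 0.1)
  frames <- outer(amp, d) + matrix(rnorm(500 * n3, sd = 0.002), 500, n3)
  ed <- covariance_eigendecomposition(frames, n_select = 2)
  expect_gt(abs(sum(ed$eigenvectors[, 1] * d)), 0.999)
  expect_lt(ed$eigenvalues[2] / ed$eigenvalues[1], 0.01)
  expect_equal(sum(ed$eigenvalues), ed$trace, tolerance = 1e-8)
  ## orthonormal columns
  G <- crossprod(ed$eigenvectors)
  expect_lt(max(abs(G - diag(n3))), 1e-10)
  expect_error(covariance_eigendecomposition(frames, n_select = 25),
               class = "pmmcd_validation_error")
})

test_that("isotropic coordinates give a flat eigenvalue spectrum", {
  set.seed(25)
  frames <- matrix(rnorm(4000 * 12, sd = 0.05), 4000, 12)
  ed <- covariance_eigendecomposition(frames, 2)
  expect_lt(ed$eigenvalues[1] / ed$eigenvalues[12], 1.35)
})

test_that("free-energy differences follow -kT log of the count ratio", {
  ## two occupied cells engineered by hand: equal counts give zero
  pr <- rbind(matrix(c(0, 0), 50, 2, byrow = TRUE),
              matrix(c(1, 1), 50, 2, byrow = TRUE))
  g <- free_energy_landscape(pr, bins = 4, temperature = 300)
  occ <- which(!is.na(g$free_energy))
  expect_equal(unname(g$free_energy[occ]), c(0, 0))
  ## counts 1000 : 368 at 300 K (about a factor e)
  pr2 <- rbind(matrix(c(0, 0), 1000, 2, byrow = TRUE),
               matrix(c(1, 1), 368, 2, byrow = TRUE))
  g2 <- free_energy_landscape(pr2, bins = 4, temperature = 300)
  da <- max(g2$free_energy, na.rm = TRUE)
  expect_equal(da, -kT300 * log(368 / 1000), tolerance = 1e-12)
  ## about 2.494 kJ/mol for a count ratio of e at 300 K
  expect_equal(-kT300 * log(exp(-1)), 2.49435, tolerance = 1e-4)
  ## minimum exactly zero, counts conserved
  expect_equal(min(g2$free_energy, na.rm = TRUE), 0)
  expect_equal(sum(g2$counts), 1368L)
})

test_that("free energies are invariant under uniform count scaling", {
  set.seed(26)
  pr <- matrix(rnorm(400), 200, 2)
  g1 <- free_energy_landscape(pr, bins = 10)
  g3 <- free_energy_landscape(pr[rep(1:200, each = 3), ], bins = 10)
  expect_equal(g3$free_energy, g1$free_energy, tolerance = 1e-12)
})

test_that("a two-basin density is recovered within 0.15 kJ/mol at large n", {
  set.seed(27)
  da_true <- 3
  p2 <- exp(-da_true / kT300)
  n <- 20000
  lab <- runif(n) < p2 / (1 + p2)
  ctr <- ifelse(lab, 1, -1)
  pr <- cbind(rnorm(n, ctr, 0.15), rnorm(n, 0, 0.15))
  g <- free_energy_landscape(pr, bins = 40, temperature = 300)
  rcs <- locate_basins_and_extract(g, matrix(0, n, 6), pr, n_rc = 2)
  b <- attr(rcs, "basins")
  expect_equal(nrow(b), 2)
  da_rec <- -kT300 * log(min(b$occupancy) / max(b$occupancy))
  expect_lt(abs(da_rec - da_true), 0.15)
})

test_that("dihedrals match an independent vector-algebra oracle and flag collinearity", {
  expect_equal(dihedral_series(rbind(c(0, 1, 0, 0, 0, 0, 1, 0, 0, 1, 1, 0)),
                               1:4), 0)      # cis
  expect_equal(dihedral_series(rbind(c(0, 1, 0, 0, 0, 0, 1, 0, 0, 1, -1, 0)),
                               1:4), 180)    # trans
  set.seed(28)
  for (rep in 1:25) {
    pts <- matrix(rnorm(12), 4, 3)
    ours <- dihedral_series(rbind(as.numeric(t(pts))), 1:4)
    ## oracle: signed angle between plane normals about the central bond
    b1 <- pts[2, ] - pts[1, ]; b2 <- pts[3, ] - pts[2, ]; b3 <- pts[4, ] - pts[3, ]
    cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])
    n1 <- cr(b1, b2); n2 <- cr(b2, b3)
    cosphi <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
    phi <- acos(pmin(1, pmax(-1, cosphi))) * 180 / pi
    if (sum(cr(n1, n2) * b2) < 0) phi <- 360 - phi
    expect_equal(ours, phi, tolerance = 1e-9)
  }
  collinear <- rbind(c(0, 0, 0, 1, 0, 0, 2, 0, 0, 3, 1, 0))
  expect_error(dihedral_series(collinear, 1:4), "frame 1",
               class = "pmmcd_data_error")
})

test_that("rotamer classes have the documented centers and circular boundaries", {
  expect_equal(classify_rotamer(180), "GT")
  expect_equal(classify_rotamer(c(60, 240)), c("GG", "GG"))
  expect_equal(classify_rotamer(0), "TG")
  expect_equal(classify_rotamer(359), "TG")
  ## one degree either side of every boundary midpoint
  expect_equal(classify_rotamer(c(29, 31)), c("TG", "GG"))
  expect_equal(classify_rotamer(c(119, 121)), c("GG", "GT"))
  expect_equal(classify_rotamer(c(209, 211)), c("GT", "GG"))
  expect_equal(classify_rotamer(c(299, 301)), c("GG", "TG"))
  ## total and piecewise-constant: exactly four switch points on the circle
  grid <- seq(0, 359.5, by = 0.5)
  cls <- classify_rotamer(grid)
  expect_true(all(nzchar(cls)))
  switches <- sum(cls != c(cls[-1], cls[1]))
  expect_equal(switches, 4L)
})

test_that("basin extraction allocates RCs by occupancy and normalizes probabilities", {
  set.seed(29)
  ## single basin: one RC at the mode with probability 1
  pr1 <- cbind(rnorm(2000, 0, 0.1), rnorm(2000, 0, 0.1))
  g1 <- free_energy_landscape(pr1, bins = 25)
  rc1 <- locate_basins_and_extract(g1, matrix(0, 2000, 6), pr1, n_rc = 1)
  expect_length(rc1, 1)
  expect_equal(rc1[[1]]$probability, 1)
  expect_lt(sum(rc1[[1]]$essential_coords^2), 0.01)
  ## two equal basins: probabilities near 0.5/0.5
  n <- 10000
  ctr <- rep(c(-1, 1), each = n / 2)
  pr2 <- cbind(rnorm(n, ctr, 0.12), rnorm(n, 0, 0.12))
  g2 <- free_energy_landscape(pr2, bins = 40)
  rc2 <- locate_basins_and_extract(g2, matrix(0, n, 6), pr2, n_rc = 2)
  probs <- sort(vapply(rc2, `[[`, numeric(1), "probability"))
  expect_equal(sum(probs), 1, tolerance = 1e-12)
  expect_lt(abs(probs[1] - 0.5), 0.03)
  expect_error(locate_basins_and_extract(g2, matrix(0, n, 6), pr2, n_rc = 1),
               class = "pmmcd_validation_error")
})
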