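test_that("field at the center of mass matches Coulomb closed forms", {
  qc <- matrix(0, 1, 3)
  d_nm <- 0.4
  fr <- perturbing_frame(matrix(c(d_nm, 0, 0), 1, 3), 1, qc)
  f <- field_at_center(fr, masses = 1)
  d_au <- d_nm / 0.0529177210903
  expect_equal(f$v0, 1 / d_au, tolerance = 1e-14)
  expect_equal(f$efield, c(-1 / d_au^2, 0, 0), tolerance = 1e-14)
  ## opposite charges symmetric about the center: potential cancels,
  ## field does not
  fr2 <- perturbing_frame(rbind(c(d_nm, 0, 0), c(-d_nm, 0, 0)),
                          c(1, -1), qc)
  f2 <- field_at_center(fr2, masses = 1)
  expect_equal(f2$v0, 0, tolerance = 1e-14)
  expect_gt(abs(f2$efield[1]), 0)
})

test_that("field sum over 100 random charges matches a brute-force double loop", {
  set.seed(42)
  envp <- matrix(rnorm(300, sd = 2), ncol = 3)
  q <- runif(100, -1, 1)
  qcp <- matrix(rnorm(9, sd = 0.05), ncol = 3)
  m <- c(12, 16, 1)
  f <- field_at_center(perturbing_frame(envp, q, qcp), m)
  r0 <- colSums(qcp * m) / sum(m)
  v0 <- 0; ef <- c(0, 0, 0)
  for (j in 1:100) {
    d <- (envp[j, ] - r0) / 0.0529177210903
    r <- sqrt(sum(d^2))
    v0 <- v0 + q[j] / r
    ef <- ef - q[j] * d / r^3
  }
  expect_equal(f$v0, v0, tolerance = 1e-12)
  expect_equal(f$efield, ef, tolerance = 1e-12)
})

test_that("an environment charge inside the clash radius is a hard error naming the frame", {
  fr <- perturbing_frame(matrix(c(0.01, 0, 0), 1, 3), 1,
                         matrix(0, 1, 3), frame_index = 7L)
  expect_error(field_at_center(fr, 1), "frame 7", class = "pmmcd_data_error")
})

test_that("the perturbed Hamiltonian has the exact matrix structure", {
  set <- small_set(5)
  ## zero perturbation: H is the unperturbed diagonal
  expect_identical(build_perturbed_hamiltonian(set, 0, c(0, 0, 0)),
                   diag(set$state_energies))
  ## neutral molecule in a uniform potential: still the unperturbed diagonal
  expect_identical(build_perturbed_hamiltonian(set, 3.7, c(0, 0, 0)),
                   diag(set$state_energies))
  ## field couples through the dipole matrices, Hermitian by construction
  H <- build_perturbed_hamiltonian(set, 0.1, c(0.01, -0.02, 0.005))
  expect_lt(max(abs(H - t(H))), 1e-12)
  expect_equal(H[2, 4],
               -0.01 * set$elec_dipole$x[2, 4] +
                 0.02 * set$elec_dipole$y[2, 4] -
                 0.005 * set$elec_dipole$z[2, 4])
})

test_that("two-level eigenvalues match the closed-form quadratic over a field sweep", {
  set2 <- two_level_set(e1 = 0.25, mu = 0.8)
  for (eps in seq(-0.5, 0.5, length.out = 100)) {
    H <- build_perturbed_hamiltonian(set2, 0, c(eps, 0, 0))
    ev <- diagonalize(H)$values
    an <- 0.125 + c(-1, 1) * sqrt(0.125^2 + (eps * 0.8)^2)
    expect_equal(ev, an, tolerance = 1e-12)
  }
})

test_that("diagonalization is deterministic, unitary and reconstructs the matrix", {
  ## diagonal input: identity eigenvectors under the phase convention
  d <- diag(c(1, 2, 5))
  es <- diagonalize(d)
  expect_equal(es$values, c(1, 2, 5))
  expect_equal(es$vectors, diag(3), tolerance = 1e-14)
  ## random Hermitian 17x17: ascending values, unitarity, reconstruction
  set.seed(8)
  a <- matrix(rnorm(289), 17) + 1i * matrix(rnorm(289), 17)
  H <- (a + Conj(t(a))) / 2
  es <- diagonalize(H)
  expect_true(all(diff(es$values) >= 0))
  U <- es$vectors
  expect_lt(max(abs(Conj(t(U)) %*% U - diag(17))), 1e-10)
  rec <- Conj(t(U)) %*% H %*% U
  expect_lt(max(abs(rec - diag(es$values))), 1e-10)
  ## phase convention: the largest-magnitude component is real positive
  for (k in 1:17) {
    j <- which.max(abs(U[, k]))
    expect_gt(Re(U[j, k]), 0)
    expect_lt(abs(Im(U[j, k])), 1e-12)
  }
  expect_error(diagonalize(matrix(c(1, 2, 3, 4), 2)),
               class = "pmmcd_validation_error")
})

test_that("transition dipoles rotate correctly into the perturbed basis", {
  set <- small_set(5)
  n <- 5
  ## identity eigenvectors: unperturbed matrix elements come back
  td <- perturbed_transition_dipoles(set, diag(n) + 0i, 1, 3)
  expect_equal(td$mu, sapply(c("x", "y", "z"),
                             function(p) set$elec_dipole[[p]][1, 3]),
               ignore_attr = TRUE)
  expect_equal(td$m, sapply(c("x", "y", "z"),
                            function(p) set$mag_dipole[[p]][1, 3]),
               ignore_attr = TRUE)
  ## swapping two eigenvectors swaps the transition dipoles
  P <- diag(n)[, c(2, 1, 3:5)] + 0i
  td_swap <- perturbed_transition_dipoles(set, P, 1, 3)
  td_direct <- perturbed_transition_dipoles(set, diag(n) + 0i, 2, 3)
  expect_equal(td_swap$mu, td_direct$mu)
  ## random unitary mixing vs brute-force triple product
  set.seed(9)
  U <- qr.Q(qr(matrix(rnorm(n * n), n) + 1i * matrix(rnorm(n * n), n)))
  td_u <- perturbed_transition_dipoles(set, U, 2, 4)
  for (p in 1:3) {
    brute <- sum(Conj(U[, 2]) * (set$elec_dipole[[p]] %*% U[, 4]))
    expect_equal(td_u$mu[p], Re(brute), tolerance = 1e-12)
    brute_m <- sum(Conj(U[, 2]) * (set$mag_dipole[[p]] %*% U[, 4]))
    expect_equal(td_u$m[p], brute_m, tolerance = 1e-12)
  }
})

test_that("rotational strength is Im{mu.m} in cgs with the right symmetries", {
  expect_equal(rotational_strength(c(1, 0, 0), c(1 + 0i, 0, 0)), 0)
  r_unit <- rotational_strength(c(1, 0, 0), c(1i, 0, 0))
  expect_equal(r_unit, 4.714443e-38, tolerance = 1e-4)
  mu <- c(0.3, -0.2, 0.5)
  m <- complex(real = c(0.1, 0, -0.2), imaginary = c(0.4, 0.2, -0.1))
  expect_equal(rotational_strength(mu, -m), -rotational_strength(mu, m))
})

test_that("zero-environment trajectories reproduce unperturbed values to machine precision", {
  set <- small_set(6)
  frames <- lapply(1:4, function(i) empty_frame(set, i))
  recs <- pmm_trajectory(set, frames)
  exc0 <- set$state_energies[-1] - set$state_energies[1]
  for (f in 1:4)
    expect_equal(recs$exc_freqs[f, ], exc0, tolerance = 1e-14)
  R0 <- sapply(2:6, function(k) rotational_strength(
    sapply(c("x", "y", "z"), function(p) set$elec_dipole[[p]][1, k]),
    sapply(c("x", "y", "z"), function(p) set$mag_dipole[[p]][1, k])))
  expect_equal(recs$rot_strengths[1, ], R0, tolerance = 1e-14)
})

test_that("trajectory processing composes per-frame evaluation and handles failures", {
  spec <- fixture_spec(n_states = 4, seed = 6, n_frames = 3, n_env_triplets = 30)
  set <- mock_unperturbed_set(spec)
  frames <- mock_solvent_frames(spec, set$qc_positions)
  recs <- pmm_trajectory(set, frames)
  one <- pmm_frame(set, frames[[2]])
  expect_equal(recs$exc_freqs[2, ], one$excitation_freqs)
  expect_equal(recs$rot_strengths[2, ], one$rot_strengths)
  ## a generator source gives identical results (streaming contract)
  recs_gen <- pmm_trajectory(set, function(i) frames[[i]], n_frames = 3)
  expect_equal(recs_gen$exc_freqs, recs$exc_freqs)
  ## clashing frame: abort by default, skip under the permissive flag
  clash <- frames
  clash[[2]]$env_positions[1, ] <- colMeans(set$qc_positions) + c(0.001, 0, 0)
  expect_error(pmm_trajectory(set, clash), class = "pmmcd_data_error")
  recs_p <- suppressMessages(pmm_trajectory(set, clash, permissive = TRUE))
  expect_equal(recs_p$failed, 2L)
  expect_equal(nrow(recs_p$exc_freqs), 2)
})

test_that("weak-field excitation shifts follow first-order perturbation theory", {
  spec <- fixture_spec(n_states = 5, seed = 12, n_frames = 200,
                       n_env_triplets = 60)
  set <- mock_unperturbed_set(spec)
  frames <- mock_solvent_frames(spec, set$qc_positions)
  ## scale charges down so second-order terms are negligible
  frames <- lapply(frames, function(f) {
    f$env_charges <- f$env_charges * 0.2
    f
  })
  recs <- pmm_trajectory(set, frames)
  exc0 <- set$state_energies[-1] - set$state_energies[1]
  dmu <- sapply(c("x", "y", "z"), function(p)
    diag(set$elec_dipole[[p]]))        # 5 x 3 diagonal dipoles
  shift_actual <- sweep(recs$exc_freqs, 2, exc0)
  shift_pt1 <- -recs$efield %*% t(dmu[-1, , drop = FALSE] -
                                    matrix(dmu[1, ], 4, 3, byrow = TRUE))
  expect_lt(mean(abs(shift_actual - shift_pt1)),
            0.1 * mean(abs(shift_pt1)))
})

test_that("a neutral QC is insensitive to a uniform potential shift", {
  set <- small_set(5)   # total_charge 0
  spec <- fixture_spec(n_states = 5, seed = 13, n_frames = 1, n_env_triplets = 40)
  fr <- mock_solvent_frames(spec, set$qc_positions)[[1]]
  fld <- field_at_center(fr, set$qc_masses)
  H1 <- build_perturbed_hamiltonian(set, fld$v0, fld$efield)
  H2 <- build_perturbed_hamiltonian(set, fld$v0 + 5, fld$efield)
  expect_identical(H1, H2)
})

test_that("negating the magnetic matrices flips every rotational strength", {
  spec <- fixture_spec(n_states = 5, seed = 14, n_frames = 5, n_env_triplets = 50)
  set <- mock_unperturbed_set(spec)
  frames <- mock_solvent_frames(spec, set$qc_positions)
  set_neg <- set
  for (p in c("x", "y", "z"))
    set_neg$mag_dipole[[p]] <- -set_neg$mag_dipole[[p]]
  r1 <- pmm_trajectory(set, frames)
  r2 <- pmm_trajectory(set_neg, frames)
  expect_equal(r2$rot_strengths, -r1$rot_strengths, tolerance = 1e-14)
  expect_equal(r2$exc_freqs, r1$exc_freqs)
})
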