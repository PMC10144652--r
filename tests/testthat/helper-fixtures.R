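## Shared fixture builders. Everything is generated in code at test time;
## no binary or external data.

## minimal two-level set with a single x-polarized bright transition;
## closed-form eigenvalues make it the analytic oracle workhorse
two_level_set <- function(e1 = 0.25, mu = 0.8, m_mag = 0.1) {
  unperturbed_set(
    state_energies = c(0, e1),
    elec_dipole = list(x = matrix(c(0, mu, mu, 0), 2),
                       y = matrix(0, 2, 2), z = matrix(0, 2, 2)),
    mag_dipole = list(x = matrix(c(0, 1i, -1i, 0), 2) * m_mag,
                      y = matrix(0i, 2, 2), z = matrix(0i, 2, 2)),
    qc_charges = c(0, 0), qc_masses = c(1, 1),
    qc_positions = matrix(c(0, 0, 0, 0.1, 0, 0), 2, 3, byrow = TRUE)
  )
}

## small randomized set via the fixture generator
small_set <- function(n = 5, seed = 3, dipole_scale = 0.5) {
  mock_unperturbed_set(fixture_spec(n_states = n, seed = seed,
                                    dipole_scale = dipole_scale))
}

## frame with no environment charges (zero perturbation)
empty_frame <- function(set, idx = 1L) {
  perturbing_frame(matrix(numeric(0), 0, 3), numeric(0),
                   set$qc_positions, frame_index = idx)
}

## hand-rolled pmm_records object for spectrum tests that need exact
## control over excitation frequencies and strengths
fake_records <- function(exc_hartree, R, D = abs(R), label = "fake") {
  exc <- as.matrix(exc_hartree)
  structure(list(
    exc_freqs = exc,
    rot_strengths = matrix(R, nrow(exc), ncol(exc)),
    dip_strengths = matrix(D, nrow(exc), ncol(exc)),
    v0 = numeric(nrow(exc)), efield = matrix(0, nrow(exc), 3),
    frame_index = seq_len(nrow(exc)), failed = integer(0), label = label
  ), class = "pmm_records")
}

## random rigid motion applied to an N x 3 coordinate block
random_rigid <- function(pos, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rot <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  pos %*% rot + matrix(stats::rnorm(3), nrow(pos), 3, byrow = TRUE)
}

kT300 <- 0.0083145 * 300

extdata <- function(f) system.file("extdata", f, package = "pmmcd")
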