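#' Specification for synthetic test fixtures
#'
#' Bundles every knob of the synthetic generators: a mock unperturbed
#' electronic set, solvent-like neutral charge shells, and a two-basin
#' conformational trajectory with known ground truth. A fixed `seed` makes
#' every generated artifact bit-reproducible.
#'
#' Defaults emulate the study conditions of a far-UV monosaccharide
#' chromophore in water: 17 electronic states with the lowest excitation
#' near 6.5 eV, solvent shells of neutral 3-charge groups standing in for
#' water molecules, and a hydroxymethyl-like soft dihedral sampled from a
#' GG/GT two-basin mixture at 60:40 weights.
#'
#' @param n_states electronic states including the ground state.
#' @param energy_range excitation energy range, eV (lowest excitation sits
#'   at the floor).
#' @param dipole_scale scale of random dipole matrix elements, a.u.
#' @param n_env_triplets neutral 3-charge solvent groups per frame.
#' @param env_shell_radii inner/outer shell radii, nm.
#' @param n_frames frames to generate.
#' @param seed RNG seed.
#' @param basin_centers,basin_widths,basin_weights dihedral mixture
#'   components: centers and widths (circular standard deviation) in
#'   degrees, weights summing to 1.
#' @param temperature K (used by downstream free-energy analysis).
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_states = 17,
                         energy_range = c(6.5, 9.5),
                         dipole_scale = 0.5,
                         n_env_triplets = 300,
                         env_shell_radii = c(0.5, 1.5),
                         n_frames = 100,
                         seed = 1,
                         basin_centers = c(60, 180),
                         basin_widths = c(15, 15),
                         basin_weights = c(0.6, 0.4),
                         temperature = 300) {
  if (n_states < 2) abort_validation("n_states must be >= 2")
  if (abs(sum(basin_weights) - 1) > 1e-8)
    abort_validation("basin weights must sum to 1")
  if (length(energy_range) != 2 || diff(energy_range) <= 0)
    abort_validation("energy_range must be (lo, hi) eV with lo < hi")
  structure(list(
    n_states = as.integer(n_states), energy_range = energy_range,
    dipole_scale = dipole_scale, n_env_triplets = as.integer(n_env_triplets),
    env_shell_radii = env_shell_radii, n_frames = as.integer(n_frames),
    seed = as.integer(seed), basin_centers = basin_centers,
    basin_widths = basin_widths, basin_weights = basin_weights,
    temperature = temperature
  ), class = "fixture_spec")
}

## fixed 6-atom quantum-center template (nm): compact, chiral-ish, rigid
qc_template <- function() {
  pos <- matrix(c(
    0.00, 0.00, 0.00,
    0.15, 0.00, 0.00,
    0.22, 0.13, 0.02,
    0.15, 0.25, -0.04,
    0.00, 0.26, 0.03,
    -0.07, 0.12, -0.02
  ), ncol = 3, byrow = TRUE)
  list(positions = pos,
       masses = c(12, 12, 16, 12, 16, 12),
       charges = c(0.15, -0.20, -0.35, 0.25, -0.30, 0.45))
}

#' Mock unperturbed electronic set
#'
#' Randomized but physically structured electronic set: ascending energies
#' with the lowest excitation at the floor of `energy_range`, random
#' symmetric electric-dipole matrices and random purely imaginary
#' antisymmetric magnetic-dipole matrices at `dipole_scale`, over a fixed
#' compact 6-atom neutral quantum center. Passes all electronic-set
#' validation; regeneration under the same seed is bit-identical.
#'
#' @param spec a `fixture_spec`.
#' @param label label for the set.
#' @return an `unperturbed_set`.
#' @export
mock_unperturbed_set <- function(spec, label = "mock") {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  n <- spec$n_states
  exc_ev <- if (n == 2) {
    spec$energy_range[1]
  } else {
    c(spec$energy_range[1],
      sort(stats::runif(n - 2, spec$energy_range[1] + 1e-3,
                        spec$energy_range[2])))
  }
  energies <- c(0, exc_ev) / HARTREE_EV
  sym_mat <- function() {
    a <- matrix(stats::rnorm(n * n, sd = spec$dipole_scale), n, n)
    (a + t(a)) / 2
  }
  antisym_imag <- function() {
    a <- matrix(stats::rnorm(n * n, sd = spec$dipole_scale), n, n)
    1i * (a - t(a)) / 2
  }
  qc <- qc_template()
  unperturbed_set(
    state_energies = energies,
    elec_dipole = list(x = sym_mat(), y = sym_mat(), z = sym_mat()),
    mag_dipole = list(x = antisym_imag(), y = antisym_imag(), z = antisym_imag()),
    qc_charges = qc$charges - mean(qc$charges),   # neutral by construction
    qc_masses = qc$masses,
    qc_positions = qc$positions,
    total_charge = 0,
    label = label
  )
}

#' Mock solvent perturbing frames
#'
#' Places `n_env_triplets` neutral three-charge groups (charge pattern
#' `(-2q, +q, +q)`, q = 0.4238 e, geometry loosely water-like) uniformly in
#' a spherical shell around the quantum-center center of geometry, one
#' independent arrangement per frame. Neutral groups preserve the far-field
#' Coulomb decay the tests rely on; no attempt is made at realistic water
#' structure.
#'
#' @param spec a `fixture_spec`.
#' @param qc_positions `n x 3` QC coordinates, nm (frozen across frames).
#' @return list of `perturbing_frame`s.
#' @export
mock_solvent_frames <- function(spec, qc_positions) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed + 1L)
  qc_positions <- matrix(as.numeric(qc_positions), ncol = 3)
  ctr <- colMeans(qc_positions)
  qc_extent <- max(sqrt(rowSums(sweep(qc_positions, 2, ctr)^2)))
  r_in <- spec$env_shell_radii[1]
  r_out <- spec$env_shell_radii[2]
  if (r_in <= qc_extent)
    abort_validation("inner shell radius ", r_in,
                     " nm does not clear the QC extent ", round(qc_extent, 3), " nm")
  q <- 0.4238
  lapply(seq_len(spec$n_frames), function(f) {
    nt <- spec$n_env_triplets
    if (nt == 0) {
      return(perturbing_frame(matrix(numeric(0), 0, 3), numeric(0),
                              qc_positions, frame_index = f))
    }
    u <- matrix(stats::rnorm(3 * nt), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    rad <- (stats::runif(nt, r_in^3, r_out^3))^(1 / 3)   # uniform in shell volume
    centers <- sweep(u * rad, 2, ctr, `+`)
    h1 <- matrix(stats::rnorm(3 * nt), ncol = 3)
    h1 <- h1 / sqrt(rowSums(h1^2)) * 0.1
    h2 <- matrix(stats::rnorm(3 * nt), ncol = 3)
    h2 <- h2 / sqrt(rowSums(h2^2)) * 0.1
    pos <- rbind(centers, centers + h1, centers + h2)
    charges <- c(rep(-2 * q, nt), rep(q, nt), rep(q, nt))
    perturbing_frame(pos, charges, qc_positions, frame_index = f)
  })
}

## NeRF placement: position of atom D given A, B, C and internal coords
place_atom <- function(a, b, c_, bond, angle_deg, dihedral_deg) {
  th <- angle_deg * pi / 180
  ph <- dihedral_deg * pi / 180
  bc <- c_ - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(ph), bond * sin(th) * sin(ph))
  c_ + d2[1] * bc + d2[2] * m + d2[3] * n
}

## build an 8-atom chain with given dihedral sequence (degrees); bond
## 0.15 nm, bond angle 112 deg; dihedral i applies to atoms (i-3..i)
chain_coords <- function(dihedrals) {
  b <- 0.15
  th <- 112
  pos <- matrix(0, 8, 3)
  pos[1, ] <- c(0, 0, 0)
  pos[2, ] <- c(b, 0, 0)
  pos[3, ] <- pos[2, ] + b * c(cos(pi - th * pi / 180),
                               sin(pi - th * pi / 180), 0)
  for (i in 4:8) {
    pos[i, ] <- place_atom(pos[i - 3, ], pos[i - 2, ], pos[i - 1, ],
                           b, th, dihedrals[i - 3])
  }
  pos
}

#' Mock two-basin conformational trajectory
#'
#' Generates frames of an abstract 8-atom chain molecule with one soft
#' dihedral (atoms 2-3-4-5) sampled from a mixture of wrapped-Gaussian
#' basins at the specified centers, widths and weights; the remaining
#' dihedrals stay near 180 deg. Every frame receives Cartesian jitter and
#' an independent random rigid rotation + translation, so the
#' roto-translational fitting step is genuinely exercised. True per-frame
#' basin labels are returned for recovery tests.
#'
#' @param spec a `fixture_spec`.
#' @param jitter_sd Cartesian jitter standard deviation, nm.
#' @return list with `xyz` (`n_frames x 24` matrix, nm), `labels` (true
#'   basin index per frame), `dihedrals` (true sampled dihedral, degrees),
#'   `dihedral_idx` (`c(2, 3, 4, 5)`), `masses`, `elements`.
#' @export
mock_conformational_trajectory <- function(spec, jitter_sd = 0.004) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed + 2L)
  nf <- spec$n_frames
  comp <- sample.int(length(spec$basin_weights), nf, replace = TRUE,
                     prob = spec$basin_weights)
  phi <- (spec$basin_centers[comp] +
            stats::rnorm(nf, sd = spec$basin_widths[comp])) %% 360
  xyz <- matrix(0, nf, 24)
  for (f in seq_len(nf)) {
    ## dihedral j spans atoms (j .. j+3); the soft one is atoms 2-3-4-5
    dih <- c(180 + stats::rnorm(1, sd = 5), phi[f], 180 + stats::rnorm(3, sd = 5))
    pos <- chain_coords(dih)
    pos <- pos + matrix(stats::rnorm(24, sd = jitter_sd), 8, 3)
    ## random rigid motion: rotation from QR of a random matrix + shift
    qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
    rot <- qr.Q(qr_)
    if (det(rot) < 0) rot[, 1] <- -rot[, 1]
    pos <- pos %*% rot + matrix(stats::rnorm(3, sd = 0.5), 8, 3, byrow = TRUE)
    xyz[f, ] <- as.numeric(t(pos))
  }
  list(xyz = xyz, labels = comp, dihedrals = phi,
       dihedral_idx = c(2L, 3L, 4L, 5L),
       masses = c(12, 12, 12, 12, 16, 12, 16, 12),
       elements = c("C", "C", "C", "C", "O", "C", "O", "C"))
}

#' Write perturbing frames as an XYZ-with-charges trajectory
#'
#' Emits the combined QC + environment trajectory in the dialect read back
#' by [read_xyzq()] and [frames_to_perturbing()]: QC atoms first (indices
#' `1..n_qc`), environment atoms after.
#'
#' @param frames list of `perturbing_frame`s.
#' @param qc_charges per-atom QC charges written into the file.
#' @param path output path.
#' @return `path` invisibly; attribute `qc_index` gives the QC atom range.
#' @export
write_perturbing_frames <- function(frames, qc_charges, path) {
  n_qc <- nrow(frames[[1]]$qc_positions)
  raw <- lapply(frames, function(fr) {
    list(
      elements = c(rep("Q", n_qc), rep("X", nrow(fr$env_positions))),
      positions = rbind(fr$qc_positions, fr$env_positions),
      charges = c(qc_charges, fr$env_charges),
      comment = paste("frame", fr$frame_index)
    )
  })
  write_xyzq(raw, path)
  invisible(structure(path, qc_index = seq_len(n_qc)))
}
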