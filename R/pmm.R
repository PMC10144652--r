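#' Perturbing environment frame
#'
#' One MD frame of the perturbing environment: point charges and positions
#' of the solvent (or any surroundings) plus the quantum-center coordinates
#' at the same frame, from which the QC center of mass is taken.
#'
#' @param env_positions `n_env x 3` matrix, nm.
#' @param env_charges length `n_env`, elementary charges.
#' @param qc_positions `n_qc x 3` matrix, nm.
#' @param frame_index integer frame identifier.
#' @return an object of class `perturbing_frame`.
#' @export
perturbing_frame <- function(env_positions, env_charges, qc_positions,
                             frame_index = 1L) {
  env_positions <- matrix(as.numeric(env_positions), ncol = 3)
  if (nrow(env_positions) != length(env_charges))
    abort_validation("frame ", frame_index, ": ", nrow(env_positions),
                     " environment positions vs ", length(env_charges),
                     " charges")
  structure(list(
    env_positions = env_positions,
    env_charges = as.numeric(env_charges),
    qc_positions = matrix(as.numeric(qc_positions), ncol = 3),
    frame_index = as.integer(frame_index)
  ), class = "perturbing_frame")
}

#' Electrostatic potential and field at the QC center of mass
#'
#' Direct Coulomb sum over the environment point charges, evaluated at the
#' mass-weighted center of the quantum-center coordinates: the monopole and
#' dipole terms of the multipolar expansion of the perturbation. In atomic
#' units (Gaussian convention, no 4*pi*eps0):
#' `V(r0) = sum_j q_j / |r_j - r0|` and
#' `E(r0) = sum_j q_j (r0 - r_j) / |r_j - r0|^3`.
#'
#' No distance cutoff is applied by default; the sum is O(n_env) per frame.
#'
#' @param frame a `perturbing_frame`.
#' @param masses per-atom QC masses, amu.
#' @param min_dist minimum allowed environment-charge distance from the
#'   center, nm; a closer charge signals a clash or mismatched inputs and
#'   is a hard error.
#' @return list with `v0` (potential, a.u.), `efield` (3-vector, a.u.) and
#'   `r0` (center of mass, nm).
#' @export
field_at_center <- function(frame, masses, min_dist = 0.05) {
  stopifnot(inherits(frame, "perturbing_frame"))
  if (length(masses) != nrow(frame$qc_positions))
    abort_validation("frame ", frame$frame_index, ": ", length(masses),
                     " masses for ", nrow(frame$qc_positions), " QC atoms")
  if (any(masses <= 0)) abort_validation("masses must be positive")
  r0 <- colSums(frame$qc_positions * masses) / sum(masses)
  if (nrow(frame$env_positions) == 0)
    return(list(v0 = 0, efield = c(0, 0, 0), r0 = r0))
  d_nm <- sweep(frame$env_positions, 2, r0)          # r_j - r0, nm
  dist_nm <- sqrt(rowSums(d_nm^2))
  if (any(dist_nm < min_dist))
    abort_data("frame ", frame$frame_index, ": environment charge within ",
               min_dist, " nm of the QC center (min distance ",
               format(min(dist_nm), digits = 4), " nm)")
  d_au <- d_nm / BOHR_NM
  dist_au <- dist_nm / BOHR_NM
  v0 <- sum(frame$env_charges / dist_au)
  efield <- -colSums(frame$env_charges * d_au / dist_au^3)
  list(v0 = v0, efield = efield, r0 = r0)
}

#' Build the perturbed electronic Hamiltonian matrix
#'
#' In the unperturbed eigenstate basis the electrostatic perturbation,
#' truncated at dipole order about the QC center of mass, collapses to
#' `H = diag(E0) + q_tot V(r0) I - E(r0) . mu0`: the identity carries the
#' net charge times the potential, and the field couples through the three
#' electric-dipole matrices. The result is real symmetric because the
#' unperturbed electric-dipole matrices are.
#'
#' @param set an `unperturbed_set`.
#' @param v0 potential at the center, a.u.
#' @param efield field 3-vector at the center, a.u.
#' @return `n_states x n_states` real symmetric matrix, hartree.
#' @export
build_perturbed_hamiltonian <- function(set, v0, efield) {
  stopifnot(inherits(set, "unperturbed_set"),
            is_scalar_number(v0), length(efield) == 3L)
  H <- diag(set$state_energies + set$total_charge * v0)
  for (p in 1:3)
    H <- H - efield[p] * set$elec_dipole[[p]]
  H
}

#' Diagonalize a Hermitian Hamiltonian with a fixed phase convention
#'
#' Eigenvalues are returned ascending. Each eigenvector is rephased so its
#' largest-magnitude component is real positive (ties broken by lowest
#' index), which makes the decomposition deterministic across platforms and
#' removes the arbitrary eigenvector sign/phase.
#'
#' @param H Hermitian (or real symmetric) matrix.
#' @param tol Hermiticity tolerance relative to the matrix scale.
#' @return list with `values` (ascending) and `vectors` (columns).
#' @export
diagonalize <- function(H, tol = 1e-10) {
  scale <- max(1, max(abs(H)))
  if (max(abs(H - Conj(t(H)))) > tol * scale)
    abort_validation("matrix is not Hermitian within tolerance")
  es <- eigen(H, symmetric = TRUE)
  ord <- order(es$values)          # eigen() returns descending
  vals <- es$values[ord]
  vecs <- es$vectors[, ord, drop = FALSE]
  for (k in seq_len(ncol(vecs))) {
    v <- vecs[, k]
    j <- which.max(abs(v))         # ties -> lowest index
    ph <- v[j] / abs(v[j])
    vecs[, k] <- v / ph
  }
  list(values = vals, vectors = vecs)
}

#' Perturbed transition dipoles between two eigenstates
#'
#' Rotates the unperturbed electric and magnetic dipole matrices into the
#' perturbed eigenbasis: component p of the i->j transition dipole is
#' `ci^dagger M_p cj` for each of the three Cartesian matrices.
#'
#' @param set an `unperturbed_set`.
#' @param eigenvectors matrix of phase-fixed eigenvector columns.
#' @param i,j state indices (1 = ground state).
#' @return list with `mu` (real 3-vector, a.u.) and `m` (complex 3-vector,
#'   a.u.).
#' @export
perturbed_transition_dipoles <- function(set, eigenvectors, i, j) {
  n <- n_states(set)
  if (i < 1 || i > n || j < 1 || j > n)
    abort_validation("state index out of range (n_states = ", n, ")")
  ci <- Conj(eigenvectors[, i])
  cj <- eigenvectors[, j]
  mu <- vapply(1:3, function(p) {
    Re(sum(ci * (set$elec_dipole[[p]] %*% cj)))
  }, numeric(1))
  m <- vapply(1:3, function(p) {
    sum(ci * (set$mag_dipole[[p]] %*% cj))
  }, complex(1))
  list(mu = mu, m = m)
}

#' Rotational strength of one transition
#'
#' `R = Im{ mu . m }` with both vectors in atomic units, converted to cgs
#' (erg esu cm / gauss). This is the chiroptical intensity of a 0 -> k
#' transition; its sign distinguishes enantiomers.
#'
#' @param mu electric transition dipole 3-vector, a.u.
#' @param m magnetic transition dipole complex 3-vector, a.u.
#' @return scalar rotational strength, cgs.
#' @export
rotational_strength <- function(mu, m) {
  stopifnot(length(mu) == 3L, length(m) == 3L)
  Im(sum(mu * m)) * ROTSTR_AU_TO_CGS
}

#' PMM evaluation of one perturbing frame
#'
#' Builds and diagonalizes the perturbed Hamiltonian for one frame and
#' evaluates, for every ground -> k transition, the excitation frequency,
#' the perturbed electric and magnetic transition dipoles, the rotational
#' strength (cgs) and the dipole strength (cgs).
#'
#' @param set an `unperturbed_set`.
#' @param frame a `perturbing_frame`.
#' @param min_dist passed to [field_at_center()].
#' @return an object of class `pmm_record`: list with `frame_index`,
#'   `v0`, `efield`, `eigenvalues`, `eigenvectors`, `excitation_freqs`
#'   (hartree), `elec_tdm` (`(n-1) x 3`), `mag_tdm` (complex `(n-1) x 3`),
#'   `rot_strengths` (cgs), `dip_strengths` (cgs).
#' @export
pmm_frame <- function(set, frame, min_dist = 0.05) {
  fld <- field_at_center(frame, set$qc_masses, min_dist = min_dist)
  H <- build_perturbed_hamiltonian(set, fld$v0, fld$efield)
  es <- diagonalize(H)
  n <- n_states(set)
  nk <- n - 1L
  mu <- matrix(0, nk, 3)
  m <- matrix(complex(real = 0), nk, 3)
  R <- numeric(nk)
  D <- numeric(nk)
  for (k in seq_len(nk)) {
    td <- perturbed_transition_dipoles(set, es$vectors, 1L, k + 1L)
    mu[k, ] <- td$mu
    m[k, ] <- td$m
    R[k] <- rotational_strength(td$mu, td$m)
    D[k] <- sum(td$mu^2) * DIPSTR_AU_TO_CGS
  }
  structure(list(
    frame_index = frame$frame_index,
    v0 = fld$v0, efield = fld$efield, r0 = fld$r0,
    eigenvalues = es$values,
    eigenvectors = es$vectors,
    excitation_freqs = es$values[-1] - es$values[1],
    elec_tdm = mu, mag_tdm = m,
    rot_strengths = R, dip_strengths = D
  ), class = "pmm_record")
}

#' PMM over a trajectory of perturbing frames
#'
#' Applies [pmm_frame()] frame by frame, keeping only the per-transition
#' summary (excitation frequencies, rotational and dipole strengths) so
#' memory does not grow with eigenvector storage. `frames` may be a list of
#' `perturbing_frame` objects or a generator `function(i)` returning the
#' i-th frame (paired with `n_frames`), which keeps memory independent of
#' trajectory length for file-backed sources.
#'
#' @param set an `unperturbed_set`.
#' @param frames list of `perturbing_frame`s, or `function(i)` generator.
#' @param n_frames number of frames (required when `frames` is a function).
#' @param permissive if `TRUE`, per-frame failures are recorded and the
#'   frame skipped; otherwise the first failure aborts.
#' @param progress_every log a progress line every this many frames
#'   (`0` = silent).
#' @param min_dist passed to [field_at_center()].
#' @return an object of class `pmm_records`: list with `exc_freqs`
#'   (`n_frames x n_trans`, hartree), `rot_strengths`, `dip_strengths`
#'   (same shape, cgs), `v0`, `efield` (`n_frames x 3`), `frame_index`,
#'   `failed` (indices of skipped frames), `label`.
#' @export
pmm_trajectory <- function(set, frames, n_frames = NULL, permissive = FALSE,
                           progress_every = 0, min_dist = 0.05) {
  get_frame <- if (is.function(frames)) {
    if (is.null(n_frames))
      abort_validation("n_frames is required with a generator")
    frames
  } else {
    n_frames <- length(frames)
    function(i) frames[[i]]
  }
  if (n_frames < 1) abort_validation("need at least one frame")
  nk <- n_states(set) - 1L
  exc <- matrix(NA_real_, n_frames, nk)
  R <- matrix(NA_real_, n_frames, nk)
  D <- matrix(NA_real_, n_frames, nk)
  v0 <- numeric(n_frames)
  ef <- matrix(NA_real_, n_frames, 3)
  idx <- integer(n_frames)
  failed <- integer(0)
  for (i in seq_len(n_frames)) {
    rec <- if (permissive) {
      tryCatch(pmm_frame(set, get_frame(i), min_dist = min_dist),
               pmmcd_error = function(e) e)
    } else {
      pmm_frame(set, get_frame(i), min_dist = min_dist)
    }
    if (inherits(rec, "error")) {
      failed <- c(failed, i)
      message("frame ", i, " skipped: ", conditionMessage(rec))
    } else {
      exc[i, ] <- rec$excitation_freqs
      R[i, ] <- rec$rot_strengths
      D[i, ] <- rec$dip_strengths
      v0[i] <- rec$v0
      ef[i, ] <- rec$efield
      idx[i] <- rec$frame_index
    }
    if (progress_every > 0 && i %% progress_every == 0)
      message("PMM: processed ", i, "/", n_frames, " frames")
  }
  keep <- setdiff(seq_len(n_frames), failed)
  structure(list(
    exc_freqs = exc[keep, , drop = FALSE],
    rot_strengths = R[keep, , drop = FALSE],
    dip_strengths = D[keep, , drop = FALSE],
    v0 = v0[keep], efield = ef[keep, , drop = FALSE],
    frame_index = idx[keep], failed = failed,
    label = set$label
  ), class = "pmm_records")
}

#' @export
print.pmm_records <- function(x, ...) {
  cat("PMM trajectory records:", x$label, "\n")
  cat("  frames:", nrow(x$exc_freqs),
      if (length(x$failed)) paste0(" (", length(x$failed), " skipped)") else "",
      "\n", sep = "")
  cat("  transitions per frame:", ncol(x$exc_freqs), "\n")
  cat(sprintf("  mean lowest excitation: %.4f eV\n",
              mean(x$exc_freqs[, 1]) * HARTREE_EV))
  invisible(x)
}

#' @export
as.data.frame.pmm_records <- function(x, ...) {
  nk <- ncol(x$exc_freqs)
  nf <- nrow(x$exc_freqs)
  data.frame(
    frame = rep(x$frame_index, each = nk),
    k = rep(seq_len(nk), times = nf),
    exc_freq_hartree = as.numeric(t(x$exc_freqs)),
    exc_freq_wavenumber = as.numeric(t(x$exc_freqs)) * HARTREE_WAVENUMBER,
    rot_strength_cgs = as.numeric(t(x$rot_strengths)),
    dip_strength_cgs = as.numeric(t(x$dip_strengths))
  )
}
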