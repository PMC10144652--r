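#' Unperturbed electronic set of the quantum center
#'
#' Container for the precomputed (gas-phase, e.g. TDDFT) electronic
#' structure of the quantum center (QC): the unperturbed state energies and
#' the electric and magnetic transition-dipole matrices over those states,
#' plus the QC particle charges, masses and coordinates of the conformation
#' the set was computed at. This is the basis in which the perturbed
#' Hamiltonian is built: the unperturbed energies sit on the diagonal, the
#' environment potential couples through the net charge, and the field
#' couples through the electric-dipole matrices.
#'
#' Conventions: energies in hartree, ascending, index 1 = ground state;
#' dipole matrices in atomic units; coordinates in nm. Electric-dipole
#' matrices are real symmetric. Magnetic-dipole matrices are purely
#' imaginary with antisymmetric imaginary part (the matrix of a Hermitian,
#' purely imaginary operator over real wavefunctions), stored as complex so
#' the `Im{mu . m}` rotational strength needs no sign bookkeeping.
#'
#' @param state_energies numeric, ascending state energies in hartree.
#' @param elec_dipole list of three real `n x n` matrices, named x, y, z.
#' @param mag_dipole list of three complex `n x n` matrices, named x, y, z.
#' @param qc_charges per-nucleus partial charges, elementary charge units.
#' @param qc_masses per-nucleus masses, amu.
#' @param qc_positions `n_atoms x 3` matrix, nm.
#' @param total_charge net molecular charge, elementary charges.
#' @param label conformation identifier (e.g. `"Alpha-Glu/A"`).
#' @return an object of class `unperturbed_set`.
#' @export
unperturbed_set <- function(state_energies, elec_dipole, mag_dipole,
                            qc_charges, qc_masses, qc_positions,
                            total_charge = 0, label = "unlabeled") {
  set <- structure(list(
    state_energies = as.numeric(state_energies),
    elec_dipole = lapply(elec_dipole, function(m) {
      storage.mode(m) <- "double"; m
    }),
    mag_dipole = lapply(mag_dipole, function(m) {
      storage.mode(m) <- "complex"; m
    }),
    qc_charges = as.numeric(qc_charges),
    qc_masses = as.numeric(qc_masses),
    qc_positions = matrix(as.numeric(qc_positions), ncol = 3,
                          dimnames = NULL),
    total_charge = as.numeric(total_charge),
    label = as.character(label)
  ), class = "unperturbed_set")
  validate_unperturbed_set(set)
  set
}

#' Validate an unperturbed electronic set
#'
#' Checks the structural invariants: at least two states, strictly
#' ascending energies, three electric and three magnetic dipole matrices of
#' matching dimension, symmetry of the electric matrices and purely
#' imaginary antisymmetry of the magnetic matrices (relative tolerance
#' `tol`), and consistent QC particle arrays.
#'
#' @param set an `unperturbed_set`.
#' @param tol relative tolerance for the matrix symmetry checks.
#' @return `set`, invisibly; signals a validation error otherwise.
#' @export
validate_unperturbed_set <- function(set, tol = 1e-8) {
  n <- length(set$state_energies)
  if (n < 2)
    abort_validation("unperturbed set needs at least 2 states, got ", n)
  if (any(diff(set$state_energies) <= 0))
    abort_validation("state energies must be strictly ascending")
  for (nm in c("x", "y", "z")) {
    if (is.null(set$elec_dipole[[nm]]))
      abort_validation("missing electric dipole matrix component '", nm, "'")
    if (is.null(set$mag_dipole[[nm]]))
      abort_validation("missing magnetic dipole matrix component '", nm, "'")
  }
  for (nm in c("x", "y", "z")) {
    e <- set$elec_dipole[[nm]]
    m <- set$mag_dipole[[nm]]
    if (!all(dim(e) == c(n, n)))
      abort_validation("elec_dipole '", nm, "' is ", nrow(e), "x", ncol(e),
                       ", expected ", n, "x", n)
    if (!all(dim(m) == c(n, n)))
      abort_validation("mag_dipole '", nm, "' is ", nrow(m), "x", ncol(m),
                       ", expected ", n, "x", n)
    scale_e <- max(1, max(abs(e)))
    if (max(abs(e - t(e))) > tol * scale_e)
      abort_validation("elec_dipole '", nm, "' is not symmetric within tolerance")
    scale_m <- max(1, max(abs(m)))
    if (max(abs(Re(m))) > tol * scale_m)
      abort_validation("mag_dipole '", nm, "' is not purely imaginary within tolerance")
    if (max(abs(m + t(m))) > tol * scale_m)
      abort_validation("mag_dipole '", nm, "' is not antisymmetric within tolerance")
  }
  na <- nrow(set$qc_positions)
  if (length(set$qc_charges) != na || length(set$qc_masses) != na)
    abort_validation("qc charges/masses/positions lengths disagree (",
                     length(set$qc_charges), "/", length(set$qc_masses),
                     "/", na, ")")
  if (any(set$qc_masses <= 0))
    abort_validation("qc masses must be positive")
  invisible(set)
}

#' @export
print.unperturbed_set <- function(x, ...) {
  n <- length(x$state_energies)
  exc_ev <- (x$state_energies[-1] - x$state_energies[1]) * HARTREE_EV
  cat("Unperturbed electronic set:", x$label, "\n")
  cat("  states:", n, " (", n - 1L, "excitations )\n")
  cat(sprintf("  lowest/highest excitation: %.3f / %.3f eV\n",
              min(exc_ev), max(exc_ev)))
  cat("  QC atoms:", nrow(x$qc_positions),
      " net charge:", x$total_charge, "e\n")
  invisible(x)
}

#' Number of electronic states in a set
#' @param set an `unperturbed_set`.
#' @return integer count of states.
#' @export
n_states <- function(set) length(set$state_energies)

## ---- on-disk schema (structured JSON text) -------------------------------

ENERGY_UNIT_TO_HARTREE <- c(hartree = 1, au = 1,
                            ev = 1 / 27.211386245988,
                            wavenumber = 1 / 219474.6313632)
LENGTH_UNIT_TO_NM <- c(nm = 1, bohr = 0.0529177210903, angstrom = 0.1)

#' Read an unperturbed electronic set file
#'
#' The file is structured JSON with keys `n_states`, `units` (with `energy`,
#' `dipole`, `length`), `energies`, `elec_dipole` (`x`, `y`, `z` real
#' matrices), `mag_dipole` (`x`, `y`, `z` matrices of `[re, im]` pairs),
#' `qc` (`charges`, `masses`, `positions`), `total_charge` and `label`. The
#' units header is honored on read: energies are converted to hartree and
#' coordinates to nm no matter how the file declares them; dipoles must be
#' atomic units.
#'
#' @param path file path.
#' @return an `unperturbed_set`.
#' @export
read_unperturbed_set <- function(path) {
  if (!file.exists(path))
    abort_data("unperturbed set file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (key in c("n_states", "units", "energies", "elec_dipole",
                "mag_dipole", "qc", "total_charge", "label")) {
    if (is.null(raw[[key]]))
      abort_validation("unperturbed set file missing field '", key, "'")
  }
  for (key in c("energy", "dipole", "length")) {
    if (is.null(raw$units[[key]]))
      abort_validation("units header missing '", key, "'")
  }
  eunit <- tolower(raw$units$energy)
  lunit <- tolower(raw$units$length)
  if (!eunit %in% names(ENERGY_UNIT_TO_HARTREE))
    abort_validation("unknown energy unit '", raw$units$energy, "'")
  if (!lunit %in% names(LENGTH_UNIT_TO_NM))
    abort_validation("unknown length unit '", raw$units$length, "'")
  if (!tolower(raw$units$dipole) %in% c("au", "atomic"))
    abort_validation("dipole matrices must be in atomic units, got '",
                     raw$units$dipole, "'")
  nst <- as.integer(raw$n_states)
  if (length(raw$energies) != nst)
    abort_validation("energies length ", length(raw$energies),
                     " does not match n_states = ", nst)
  as_mat <- function(x, what) {
    m <- as.matrix(x)
    if (nrow(m) != nst || ncol(m) != nst)
      abort_validation(what, " has dimension ", nrow(m), "x", ncol(m),
                       ", expected ", nst, "x", nst)
    m
  }
  elec <- lapply(stats::setNames(c("x", "y", "z"), c("x", "y", "z")),
                 function(p) as_mat(raw$elec_dipole[[p]],
                                    paste0("elec_dipole '", p, "'")))
  mag <- lapply(stats::setNames(c("x", "y", "z"), c("x", "y", "z")), function(p) {
    a <- raw$mag_dipole[[p]]   # n x n x 2 array of [re, im]
    if (length(dim(a)) != 3L || dim(a)[3] != 2L)
      abort_validation("mag_dipole '", p, "' must be an array of [re, im] pairs")
    if (dim(a)[1] != nst || dim(a)[2] != nst)
      abort_validation("mag_dipole '", p, "' has dimension ", dim(a)[1], "x",
                       dim(a)[2], ", expected ", nst, "x", nst)
    matrix(complex(real = a[, , 1], imaginary = a[, , 2]), nst, nst)
  })
  qc_pos <- as.matrix(raw$qc$positions)
  unperturbed_set(
    state_energies = as.numeric(raw$energies) * ENERGY_UNIT_TO_HARTREE[[eunit]],
    elec_dipole = elec,
    mag_dipole = mag,
    qc_charges = raw$qc$charges,
    qc_masses = raw$qc$masses,
    qc_positions = qc_pos * LENGTH_UNIT_TO_NM[[lunit]],
    total_charge = raw$total_charge,
    label = raw$label
  )
}

#' Write an unperturbed electronic set file
#'
#' Writes the JSON schema read by [read_unperturbed_set()], always in
#' internal units (hartree / atomic-unit dipoles / nm) with full double
#' precision, so a read/write cycle round-trips every numeric field
#' bit-exactly.
#'
#' @param set an `unperturbed_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_unperturbed_set <- function(set, path) {
  validate_unperturbed_set(set)
  mag_pairs <- lapply(set$mag_dipole, function(m) {
    n <- nrow(m)
    a <- array(0, c(n, n, 2))
    a[, , 1] <- Re(m)
    a[, , 2] <- Im(m)
    a
  })
  obj <- list(
    n_states = length(set$state_energies),
    units = list(energy = "hartree", dipole = "au", length = "nm"),
    energies = set$state_energies,
    elec_dipole = set$elec_dipole,
    mag_dipole = mag_pairs,
    qc = list(charges = set$qc_charges, masses = set$qc_masses,
              positions = set$qc_positions),
    total_charge = set$total_charge,
    label = set$label
  )
  ## 17 significant digits: doubles survive the text round-trip bit-exactly
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor", pretty = FALSE)
  invisible(path)
}
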