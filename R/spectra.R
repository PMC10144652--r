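#' Bin per-frame transitions by excitation frequency
#'
#' Assigns every (frame, transition) pair to a frequency bin of width
#' `bin_width` by its vertical excitation frequency, and accumulates the
#' per-bin frame count `n(nu_ref)` and the per-bin mean rotational and
#' dipole strengths. Bin reference frequencies `nu_ref` are the bin middle
#' values of a zero-anchored regular grid.
#'
#' @param records a `pmm_records` object.
#' @param bin_width bin width, cm^-1; default 250.
#' @param k_max number of transitions retained (default all).
#' @return data.frame with columns `k`, `nu_ref` (cm^-1), `n`, `mean_R`
#'   (cgs), `mean_D` (cgs); attributes `n_frames`, `bin_width`, `k_max`,
#'   `label`.
#' @export
bin_transitions <- function(records, bin_width = 250, k_max = NULL) {
  stopifnot(inherits(records, "pmm_records"))
  if (bin_width <= 0) abort_validation("bin_width must be positive")
  nk_avail <- ncol(records$exc_freqs)
  k_max <- k_max %||% nk_avail
  if (k_max > nk_avail)
    abort_validation("k_max = ", k_max, " exceeds the ", nk_avail,
                     " available transitions")
  n_frames <- nrow(records$exc_freqs)
  out <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    nu <- records$exc_freqs[, k] * HARTREE_WAVENUMBER
    idx <- floor(nu / bin_width)
    agg_n <- tapply(nu, idx, length)
    agg_R <- tapply(records$rot_strengths[, k], idx, mean)
    agg_D <- tapply(records$dip_strengths[, k], idx, mean)
    ib <- as.numeric(names(agg_n))
    out[[k]] <- data.frame(
      k = k,
      nu_ref = (ib + 0.5) * bin_width,
      n = as.integer(agg_n),
      mean_R = as.numeric(agg_R),
      mean_D = as.numeric(agg_D)
    )
  }
  tb <- do.call(rbind, out)
  rownames(tb) <- NULL
  attr(tb, "n_frames") <- n_frames
  attr(tb, "bin_width") <- bin_width
  attr(tb, "k_max") <- k_max
  attr(tb, "label") <- records$label
  tb
}

## shared Gaussian-broadened assembly; `strength` column name and cgs
## prefactor differ between CD and UV
broadened_curve <- function(bin_table, sigma, grid, strength, prefactor) {
  if (sigma <= 0) abort_validation("sigma must be positive")
  if (length(grid) < 2 || any(diff(grid) <= 0))
    abort_validation("grid must be increasing frequencies (cm^-1)")
  n_frames <- attr(bin_table, "n_frames")
  ks <- sort(unique(bin_table$k))
  per_k <- matrix(0, length(grid), length(ks))
  for (ki in seq_along(ks)) {
    rows <- bin_table[bin_table$k == ks[ki], ]
    for (r in seq_len(nrow(rows))) {
      g <- stats::dnorm(grid, mean = rows$nu_ref[r], sd = sigma)
      per_k[, ki] <- per_k[, ki] +
        rows[[strength]][r] * grid / prefactor * (rows$n[r] / n_frames) * g
    }
  }
  list(per_k = per_k, ks = ks)
}

#' Gaussian-broadened circular dichroism spectrum
#'
#' Assembles the molar circular dichroism `Delta-eps(nu)` from a binned
#' transition table: each occupied bin contributes its mean rotational
#' strength times `nu / 2.296e-39`, weighted by its occupancy fraction
#' `n(nu_ref)/N`, under a unit-normalized Gaussian of width `sigma`
#' centered at `nu_ref`; transitions are then summed. The broadening only
#' smooths the curve: the integral of `Delta-eps/nu` per transition is
#' sigma-independent.
#'
#' @param bin_table output of [bin_transitions()].
#' @param sigma Gaussian width, cm^-1 (0.15 eV is about 1210 cm^-1).
#' @param grid evaluation frequencies, cm^-1, increasing.
#' @return an object of class `spectrum_curve` with fields `grid` (cm^-1),
#'   `wavelength_nm`, `values` (M^-1 cm^-1), `per_transition` (matrix),
#'   `transitions`, `sigma`, `n_frames`, `kind`, `label`.
#' @export
cd_curve <- function(bin_table, sigma, grid) {
  bc <- broadened_curve(bin_table, sigma, grid, "mean_R", CD_PREFACTOR_CGS)
  new_spectrum_curve(grid, bc, sigma, attr(bin_table, "n_frames"),
                     kind = "cd", label = attr(bin_table, "label") %||% "")
}

#' Gaussian-broadened UV absorption spectrum
#'
#' Same binning and broadening machinery as [cd_curve()] with the mean
#' dipole strength `|mu|^2` in place of the rotational strength and the
#' standard cgs extinction prefactor `9.184e-39` (the absorption sum rule
#' `D = 9.184e-39 integral(eps/nu dnu)`, four times the CD constant).
#'
#' @inheritParams cd_curve
#' @return a `spectrum_curve` with `kind = "uv"`, values in M^-1 cm^-1.
#' @export
uv_curve <- function(bin_table, sigma, grid) {
  if (any(bin_table$mean_D < 0))
    abort_validation("negative dipole strength in bin table (upstream bug)")
  bc <- broadened_curve(bin_table, sigma, grid, "mean_D", UV_PREFACTOR_CGS)
  new_spectrum_curve(grid, bc, sigma, attr(bin_table, "n_frames"),
                     kind = "uv", label = attr(bin_table, "label") %||% "")
}

new_spectrum_curve <- function(grid, bc, sigma, n_frames, kind, label) {
  structure(list(
    grid = grid,
    wavelength_nm = WAVENUMBER_PER_NM / grid,
    values = rowSums(bc$per_k),
    per_transition = bc$per_k,
    transitions = bc$ks,
    sigma = sigma,
    n_frames = n_frames,
    kind = kind,
    label = label
  ), class = "spectrum_curve")
}

#' @export
print.spectrum_curve <- function(x, ...) {
  unit <- if (x$kind == "cd") "Delta-eps" else "eps"
  i <- which.max(abs(x$values))
  cat(sprintf("%s spectrum '%s': %d grid points, %.0f-%.0f cm^-1 (%.0f-%.0f nm)\n",
              toupper(x$kind), x$label, length(x$grid), min(x$grid),
              max(x$grid), min(x$wavelength_nm), max(x$wavelength_nm)))
  cat(sprintf("  extremum: %s = %.3f M^-1 cm^-1 at %.1f nm\n",
              unit, x$values[i], x$wavelength_nm[i]))
  invisible(x)
}

#' @export
plot.spectrum_curve <- function(x, ...) {
  ylab <- if (x$kind == "cd")
    expression(Delta * epsilon ~ (M^-1 ~ cm^-1)) else
    expression(epsilon ~ (M^-1 ~ cm^-1))
  ord <- order(x$wavelength_nm)
  graphics::plot(x$wavelength_nm[ord], x$values[ord], type = "l",
                 xlab = "wavelength (nm)", ylab = ylab, main = x$label, ...)
  if (x$kind == "cd") graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' @export
as.data.frame.spectrum_curve <- function(x, ...) {
  data.frame(frequency_wavenumber = x$grid,
             wavelength_nm = x$wavelength_nm,
             value = x$values)
}

#' Probability-weighted combination of spectra
#'
#' Pointwise convex combination of spectra on a shared grid: the conformer
#' (or anomer) mixing step. Weights may be a numeric vector or a
#' normalized `conformer_weights` table.
#'
#' @param curves list of `spectrum_curve`s on identical grids.
#' @param weights numeric weights, one per curve (should sum to 1; use
#'   [normalize_weights()] upstream), or a `conformer_weights` object.
#' @param label label for the combined curve.
#' @return a `spectrum_curve`.
#' @export
combine_spectra <- function(curves, weights, label = "combined") {
  if (inherits(weights, "conformer_weights"))
    weights <- weights$probabilities
  if (length(curves) != length(weights))
    abort_validation(length(curves), " curves but ", length(weights), " weights")
  if (length(curves) == 0) abort_validation("no curves to combine")
  g0 <- curves[[1]]$grid
  for (cv in curves) {
    if (length(cv$grid) != length(g0) || any(cv$grid != g0))
      abort_validation("spectra are not on identical grids")
  }
  same_k <- all(vapply(curves, function(cv)
    identical(dim(cv$per_transition), dim(curves[[1]]$per_transition)), TRUE))
  vals <- Reduce(`+`, Map(function(cv, w) w * cv$values, curves, weights))
  per_k <- if (same_k) {
    Reduce(`+`, Map(function(cv, w) w * cv$per_transition, curves, weights))
  } else NULL
  out <- curves[[1]]
  out$values <- vals
  out$per_transition <- per_k
  out$label <- label
  out$weights <- weights
  out
}

#' Restrict a spectrum to a wavelength window
#'
#' Keeps the grid points whose wavelength lies in `[lo_nm, hi_nm]`
#' (defaults 160-220 nm, the experimentally sampled far-UV domain for
#' aqueous monosaccharides).
#'
#' @param curve a `spectrum_curve`.
#' @param lo_nm,hi_nm window bounds, nm, `lo_nm < hi_nm`.
#' @return the windowed `spectrum_curve`.
#' @export
wavelength_window <- function(curve, lo_nm = 160, hi_nm = 220) {
  stopifnot(inherits(curve, "spectrum_curve"))
  if (lo_nm >= hi_nm) abort_validation("empty wavelength window")
  keep <- curve$wavelength_nm >= lo_nm & curve$wavelength_nm <= hi_nm
  if (!any(keep)) abort_validation("no grid points in window ", lo_nm, "-", hi_nm, " nm")
  curve$grid <- curve$grid[keep]
  curve$wavelength_nm <- curve$wavelength_nm[keep]
  curve$values <- curve$values[keep]
  if (!is.null(curve$per_transition))
    curve$per_transition <- curve$per_transition[keep, , drop = FALSE]
  curve
}

#' Per-transition intensity report
#'
#' Maximum absolute spectral intensity contributed by each transition over
#' the curve's current window, with a reporting floor (default
#' 1.0 M^-1 cm^-1) below which transitions are dropped as insignificant.
#'
#' @param curve a `spectrum_curve` with per-transition components.
#' @param floor minimum reported maximum intensity, M^-1 cm^-1.
#' @return data.frame with `k`, `max_intensity`, `peak_wavelength_nm`.
#' @export
transition_report <- function(curve, floor = 1.0) {
  stopifnot(inherits(curve, "spectrum_curve"))
  if (is.null(curve$per_transition))
    abort_validation("curve carries no per-transition components")
  mx <- apply(abs(curve$per_transition), 2, max)
  pk <- apply(abs(curve$per_transition), 2, which.max)
  df <- data.frame(
    k = curve$transitions,
    max_intensity = mx,
    peak_wavelength_nm = curve$wavelength_nm[pk]
  )
  df[df$max_intensity >= floor, , drop = FALSE]
}
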