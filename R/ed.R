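#' Mass-weighted rigid-body superposition of a trajectory
#'
#' Removes roto-translational motion before covariance analysis: every
#' frame is optimally superposed (Kabsch SVD algorithm, mass-weighted) onto
#' a reference structure. Internal geometry is untouched; only a rigid
#' rotation + translation is applied per frame.
#'
#' @param xyz `n_frames x 3N` coordinate matrix, nm (row = frame,
#'   columns x1, y1, z1, x2, ...).
#' @param masses length-N atomic masses, amu.
#' @param reference length-3N reference coordinates; default first frame.
#' @return fitted coordinate matrix, same shape as `xyz`.
#' @export
fit_trajectory <- function(xyz, masses, reference = xyz[1, ]) {
  if (nrow(xyz) < 2) abort_validation("trajectory fitting needs >= 2 frames")
  n3 <- ncol(xyz)
  if (n3 %% 3 != 0) abort_validation("coordinate columns not a multiple of 3")
  n <- n3 %/% 3
  if (length(masses) != n)
    abort_validation(length(masses), " masses for ", n, " atoms")
  if (length(reference) != n3)
    abort_validation("reference length ", length(reference),
                     " does not match ", n3, " coordinates")
  ref <- matrix(reference, ncol = 3, byrow = TRUE)
  w <- masses / sum(masses)
  cref <- colSums(ref * w)
  refc <- sweep(ref, 2, cref)
  out <- xyz
  for (f in seq_len(nrow(xyz))) {
    x <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    cx <- colSums(x * w)
    xc <- sweep(x, 2, cx)
    cvm <- t(xc) %*% (w * refc)       # 3x3 mass-weighted covariance
    sv <- svd(cvm)
    d <- sign(det(sv$v %*% t(sv$u)))
    rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    out[f, ] <- as.numeric(t(xc %*% t(rot) + rep(cref, each = n)))
  }
  out
}

#' Essential-dynamics covariance eigendecomposition
#'
#' Builds the all-atom positional covariance matrix of a fitted trajectory
#' (denominator `n_frames`, so eigenvalues are mean-squared fluctuations in
#' nm^2 along each eigenvector), diagonalizes it, and projects every frame
#' onto the leading `n_select` eigenvectors (the essential space).
#'
#' @param fitted `n_frames x 3N` fitted coordinate matrix, nm.
#' @param n_select number of essential eigenvectors to project on.
#' @return an object of class `ed_space`: `mean_structure`, `eigenvalues`
#'   (descending, nm^2), `eigenvectors` (3N x 3N, orthonormal columns),
#'   `projections` (`n_frames x n_select`, nm), `trace` (total variance).
#' @export
covariance_eigendecomposition <- function(fitted, n_select = 2) {
  if (nrow(fitted) < 2) abort_validation("covariance needs >= 2 frames")
  n3 <- ncol(fitted)
  if (n_select > n3)
    abort_validation("n_select = ", n_select, " exceeds 3N = ", n3)
  mu <- colMeans(fitted)
  cen <- sweep(fitted, 2, mu)
  cvm <- crossprod(cen) / nrow(fitted)
  es <- eigen(cvm, symmetric = TRUE)   # descending already
  vals <- pmax(es$values, 0)           # clip eigen() round-off negatives
  structure(list(
    mean_structure = mu,
    eigenvalues = vals,
    eigenvectors = es$vectors,
    projections = cen %*% es$vectors[, seq_len(n_select), drop = FALSE],
    trace = sum(diag(cvm)),
    n_frames = nrow(fitted)
  ), class = "ed_space")
}

#' @export
print.ed_space <- function(x, ...) {
  cat("Essential-dynamics space:", x$n_frames, "frames,",
      length(x$eigenvalues), "coordinates\n")
  frac <- cumsum(x$eigenvalues) / sum(x$eigenvalues)
  k <- min(5L, length(frac))
  cat("  top eigenvalues (nm^2):",
      paste(format(x$eigenvalues[seq_len(k)], digits = 3), collapse = ", "), "\n")
  cat(sprintf("  variance captured by first 2: %.1f%%\n", 100 * frac[2]))
  invisible(x)
}

#' @export
plot.ed_space <- function(x, ...) {
  graphics::plot(seq_along(x$eigenvalues), x$eigenvalues, type = "h",
                 xlab = "eigenvector index",
                 ylab = "mean-squared fluctuation (nm^2)",
                 main = "Covariance eigenvalue spectrum", ...)
  invisible(x)
}

#' Helmholtz free-energy landscape on the essential plane
#'
#' Bins the two essential-plane projections on a regular grid, converts
#' cell occupancies to relative Helmholtz free energies
#' `dA = -kB T ln(P / P_max)` (zero at the most populated cell), and
#' optionally attaches the per-cell circular mean of a designated dihedral.
#' Unsampled cells carry `NA`, never a number.
#'
#' @param projections `n_frames x 2` essential-plane coordinates, nm.
#' @param bins bins per axis (grid is `bins x bins`); default 60.
#' @param temperature K; default 300.
#' @param dihedrals optional per-frame dihedral angles (degrees) whose
#'   circular mean is recorded per cell.
#' @param pad fractional padding of the sampled range per axis.
#' @return an object of class `fe_grid`: `bin_edges` (list x, y),
#'   `counts`, `free_energy` (kJ/mol, `NA` where unsampled),
#'   `dihedral_mean` (degrees or `NULL`), `temperature`, `cell_index`
#'   (`n_frames x 2` integer cell of each frame).
#' @export
free_energy_landscape <- function(projections, bins = 60, temperature = 300,
                                  dihedrals = NULL, pad = 0.05) {
  projections <- as.matrix(projections)
  if (nrow(projections) < 1) abort_validation("no projections to bin")
  if (ncol(projections) != 2)
    abort_validation("free-energy landscape needs 2-dimensional projections")
  if (temperature <= 0) abort_validation("temperature must be positive")
  edges <- lapply(1:2, function(a) {
    r <- range(projections[, a])
    span <- diff(r)
    if (span == 0) span <- max(abs(r), 1e-12)   # degenerate axis
    seq(r[1] - pad * span, r[2] + pad * span, length.out = bins + 1L)
  })
  ix <- findInterval(projections[, 1], edges[[1]], rightmost.closed = TRUE,
                     all.inside = TRUE)
  iy <- findInterval(projections[, 2], edges[[2]], rightmost.closed = TRUE,
                     all.inside = TRUE)
  counts <- matrix(0L, bins, bins)
  for (f in seq_len(nrow(projections)))
    counts[ix[f], iy[f]] <- counts[ix[f], iy[f]] + 1L
  fe <- matrix(NA_real_, bins, bins)
  occ <- counts > 0
  fe[occ] <- -KB_KJMOL * temperature * log(counts[occ] / max(counts))
  dmean <- NULL
  if (!is.null(dihedrals)) {
    if (length(dihedrals) != nrow(projections))
      abort_validation("dihedrals length does not match projections")
    dmean <- matrix(NA_real_, bins, bins)
    cell <- (iy - 1L) * bins + ix
    for (cl in unique(cell)) {
      sel <- cell == cl
      dmean[cl] <- circular_mean_deg(dihedrals[sel])
    }
  }
  structure(list(
    bin_edges = stats::setNames(edges, c("x", "y")),
    counts = counts, free_energy = fe, dihedral_mean = dmean,
    temperature = temperature,
    cell_index = cbind(ix, iy, deparse.level = 0)
  ), class = "fe_grid")
}

#' @export
print.fe_grid <- function(x, ...) {
  cat("Free-energy grid:", nrow(x$counts), "x", ncol(x$counts),
      "bins,", sum(x$counts), "frames,", x$temperature, "K\n")
  cat(sprintf("  sampled cells: %d; max dA: %.2f kJ/mol\n",
              sum(x$counts > 0), max(x$free_energy, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.fe_grid <- function(x, ...) {
  cx <- (utils::head(x$bin_edges$x, -1) + utils::tail(x$bin_edges$x, -1)) / 2
  cy <- (utils::head(x$bin_edges$y, -1) + utils::tail(x$bin_edges$y, -1)) / 2
  graphics::image(cx, cy, x$free_energy,
                  col = grDevices::hcl.colors(30, "viridis"),
                  xlab = "essential eigenvector 1 (nm)",
                  ylab = "essential eigenvector 2 (nm)",
                  main = "Helmholtz free energy (kJ/mol)", ...)
  invisible(x)
}

## circular mean of angles in degrees, result in [0, 360)
circular_mean_deg <- function(deg) {
  rad <- deg * pi / 180
  (atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi) %% 360
}

#' Per-frame dihedral angle series
#'
#' Signed dihedral of four atoms by the standard convention
#' (atan2 of the cross/dot construction on the three bond vectors),
#' reported in degrees on `[0, 360)`.
#'
#' @param xyz `n_frames x 3N` coordinate matrix, nm.
#' @param idx integer vector of four distinct atom indices (i, j, k, l).
#' @return numeric vector of per-frame dihedrals, degrees.
#' @export
dihedral_series <- function(xyz, idx) {
  if (length(idx) != 4L || anyDuplicated(idx))
    abort_validation("dihedral needs four distinct atom indices")
  n <- ncol(xyz) %/% 3
  if (any(idx < 1 | idx > n))
    abort_validation("dihedral atom index out of range (N = ", n, ")")
  cols <- function(a) (3 * (a - 1) + 1):(3 * a)
  p1 <- xyz[, cols(idx[1]), drop = FALSE]
  p2 <- xyz[, cols(idx[2]), drop = FALSE]
  p3 <- xyz[, cols(idx[3]), drop = FALSE]
  p4 <- xyz[, cols(idx[4]), drop = FALSE]
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cross(b1, b2)
  n2 <- cross(b2, b3)
  bad <- rowSums(n1^2) < 1e-24 | rowSums(n2^2) < 1e-24
  if (any(bad))
    abort_data("collinear atoms for dihedral at frame ", which(bad)[1])
  b2n <- b2 / sqrt(rowSums(b2^2))
  x <- rowSums(n1 * n2)
  y <- rowSums(cross(n1, n2) * b2n)
  (atan2(y, x) * 180 / pi) %% 360
}

#' Classify a hydroxymethyl dihedral into GT / GG / TG rotamer classes
#'
#' Nearest-center classification on the circle with centers TG = 0 deg,
#' GG = 60 and 240 deg, GT = 180 deg; class boundaries fall at the circular
#' midpoints 30, 120, 210 and 300 deg (boundary values go to the
#' higher-angle class).
#'
#' @param dihedral dihedral angles in degrees (any value; reduced mod 360).
#' @return character vector of `"GT"`, `"GG"`, `"TG"`.
#' @export
classify_rotamer <- function(dihedral) {
  d <- dihedral %% 360
  out <- character(length(d))
  out[d >= 300 | d < 30] <- "TG"
  out[(d >= 30 & d < 120) | (d >= 210 & d < 300)] <- "GG"
  out[d >= 120 & d < 210] <- "GT"
  out
}

#' Detect free-energy basins and extract reference configurations
#'
#' Basins are found by ordered flooding (a discrete watershed): sampled
#' cells are visited in ascending free energy; a cell with no labeled
#' neighbor (8- or 4-connectivity) seeds a new basin at a local minimum,
#' otherwise it joins the label of its lowest-free-energy labeled neighbor.
#' Within each basin the cells within `threshold` kJ/mol of the basin
#' minimum form the low-free-energy region from which reference
#' configurations (RCs) are taken. `n_rc` RCs are allocated to basins
#' proportionally to basin occupancy (each basin gets at least one);
#' each RC is the trajectory frame nearest (Euclidean, essential plane) to
#' a selected low-free-energy cell center, and its probability is the
#' occupancy of the basin cells nearest to it, renormalized over all RCs.
#'
#' @param grid an `fe_grid`.
#' @param fitted `n_frames x 3N` fitted coordinates the RC geometries are
#'   taken from.
#' @param projections `n_frames x 2` essential-plane coordinates.
#' @param n_rc total number of RCs to extract (must be >= number of
#'   basins).
#' @param threshold kJ/mol above each basin minimum defining its
#'   low-free-energy region; default 3.
#' @param connectivity 8 (default) or 4 cell neighborhood.
#' @param dihedrals optional per-frame dihedral (degrees) used to attach a
#'   rotamer class to each RC.
#' @param min_basin_frac basins holding less than this fraction of all
#'   frames are discarded as sampling noise; default 0.05 (a conformational
#'   basin worth a reference configuration holds at least a few percent of
#'   the sampling).
#' @return list of `reference_configuration` objects (fields `label`,
#'   `coordinates`, `essential_coords`, `basin_id`, `probability`,
#'   `rotamer`), with attribute `basins` (per-basin occupancy table).
#' @export
locate_basins_and_extract <- function(grid, fitted, projections, n_rc,
                                      threshold = 3, connectivity = 8,
                                      dihedrals = NULL,
                                      min_basin_frac = 0.05) {
  stopifnot(inherits(grid, "fe_grid"))
  if (!connectivity %in% c(4, 8))
    abort_validation("connectivity must be 4 or 8")
  nb <- nrow(grid$counts)
  occ_cells <- which(grid$counts > 0, arr.ind = TRUE)
  if (nrow(occ_cells) == 0) abort_validation("free-energy grid is empty")
  fe_vals <- grid$free_energy[occ_cells]
  ord <- order(fe_vals)
  label_mat <- matrix(0L, nb, ncol(grid$counts))
  basin_min <- numeric(0)
  offs <- if (connectivity == 8) {
    expand.grid(dx = -1:1, dy = -1:1)[-5, ]
  } else {
    data.frame(dx = c(-1, 1, 0, 0), dy = c(0, 0, -1, 1))
  }
  ## ordered flooding with persistence merging: a sub-minimum shallower
  ## than `threshold` at the point where it meets a deeper basin is
  ## sampling noise, not a conformational basin, and is merged into it
  parent <- integer(0)
  find_root <- function(b) {
    while (parent[b] != b) b <- parent[b]
    b
  }
  for (r in ord) {
    i <- occ_cells[r, 1]; j <- occ_cells[r, 2]
    ni <- i + offs$dx; nj <- j + offs$dy
    ok <- ni >= 1 & ni <= nb & nj >= 1 & nj <= ncol(grid$counts)
    labs <- label_mat[cbind(ni[ok], nj[ok])]
    labs <- unique(vapply(labs[labs > 0L], find_root, 1L))
    if (length(labs) == 0L) {
      basin_min <- c(basin_min, grid$free_energy[i, j])
      parent <- c(parent, length(basin_min))
      label_mat[i, j] <- length(basin_min)
    } else {
      target <- labs[which.min(basin_min[labs])]
      label_mat[i, j] <- target
      for (b in setdiff(labs, target)) {
        if (grid$free_energy[i, j] - basin_min[b] < threshold)
          parent[b] <- target
      }
    }
  }
  roots <- vapply(seq_along(basin_min), find_root, 1L)
  label_mat[label_mat > 0L] <- roots[label_mat[label_mat > 0L]]
  n_frames_tot <- sum(grid$counts)
  basin_occ <- vapply(seq_along(basin_min), function(b) {
    sum(grid$counts[label_mat == b])
  }, numeric(1))
  keep_basin <- which(basin_occ >= min_basin_frac * n_frames_tot)
  if (length(keep_basin) == 0) abort_validation("no basin survives the occupancy filter")
  if (n_rc < length(keep_basin))
    abort_validation("n_rc = ", n_rc, " is fewer than the ", length(keep_basin),
                     " detected basins; every basin needs at least one RC")
  ## proportional allocation with each basin >= 1 (largest remainder)
  occ_frac <- basin_occ[keep_basin] / sum(basin_occ[keep_basin])
  alloc <- pmax(1L, floor(occ_frac * n_rc))
  while (sum(alloc) > n_rc) {
    cand <- which(alloc > 1L)
    # remove from the basin most over-allocated
    drop <- cand[which.max(alloc[cand] - occ_frac[cand] * n_rc)]
    alloc[drop] <- alloc[drop] - 1L
  }
  while (sum(alloc) < n_rc) {
    add <- which.max(occ_frac * n_rc - alloc)
    alloc[add] <- alloc[add] + 1L
  }
  cx <- (utils::head(grid$bin_edges$x, -1) + utils::tail(grid$bin_edges$x, -1)) / 2
  cy <- (utils::head(grid$bin_edges$y, -1) + utils::tail(grid$bin_edges$y, -1)) / 2
  rcs <- list()
  for (bi in seq_along(keep_basin)) {
    b <- keep_basin[bi]
    cells <- which(label_mat == b, arr.ind = TRUE)
    fe_b <- grid$free_energy[cells]
    low <- cells[fe_b <= basin_min[b] + threshold, , drop = FALSE]
    if (nrow(low) == 0) low <- cells[which.min(fe_b), , drop = FALSE]
    k <- min(alloc[bi], nrow(low))
    sel <- low[order(grid$free_energy[low])[seq_len(k)], , drop = FALSE]
    sel_centers <- cbind(cx[sel[, 1]], cy[sel[, 2]])
    ## partition the basin's occupancy among its RC cells (nearest center)
    cell_centers <- cbind(cx[cells[, 1]], cy[cells[, 2]])
    d2 <- outer(rowSums(cell_centers^2), rowSums(sel_centers^2), "+") -
      2 * cell_centers %*% t(sel_centers)
    nearest <- max.col(-d2, ties.method = "first")
    for (ri in seq_len(k)) {
      dproj <- (projections[, 1] - sel_centers[ri, 1])^2 +
        (projections[, 2] - sel_centers[ri, 2])^2
      fidx <- which.min(dproj)
      occ <- sum(grid$counts[cells[nearest == ri, , drop = FALSE]])
      rcs[[length(rcs) + 1L]] <- structure(list(
        label = "",                       # filled below
        frame = fidx,
        coordinates = fitted[fidx, ],
        essential_coords = projections[fidx, ],
        basin_id = bi,
        probability = occ / n_frames_tot,
        rotamer = if (!is.null(dihedrals))
          classify_rotamer(dihedrals[fidx]) else NA_character_
      ), class = "reference_configuration")
    }
  }
  probs <- vapply(rcs, `[[`, numeric(1), "probability")
  labs <- make_rc_labels(length(rcs))
  for (i in seq_along(rcs)) {
    rcs[[i]]$probability <- probs[i] / sum(probs)
    rcs[[i]]$label <- labs[i]
  }
  attr(rcs, "basins") <- data.frame(
    basin = seq_along(keep_basin),
    occupancy = basin_occ[keep_basin],
    min_free_energy = basin_min[keep_basin],
    n_rc = alloc
  )
  rcs
}

## A, B, C, ... Z, AA, AB ... labels for RCs
make_rc_labels <- function(n) {
  if (n <= 26) return(LETTERS[seq_len(n)])
  c(LETTERS, as.vector(outer(LETTERS, LETTERS, paste0)))[seq_len(n)]
}

#' @export
print.reference_configuration <- function(x, ...) {
  cat(sprintf("RC %s: basin %d, p = %.3f, rotamer %s, plane (%.3f, %.3f) nm\n",
              x$label, x$basin_id, x$probability,
              x$rotamer, x$essential_coords[1], x$essential_coords[2]))
  invisible(x)
}
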