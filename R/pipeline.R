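#' Run configuration for the pipeline commands
#'
#' Flat key-value configuration shared by the pipeline stages
#' ([run_fixtures()], [run_ed()], [run_pmm()], [run_spectrum()],
#' [run_all()]). Any subset of keys may be supplied; the rest take the
#' defaults below. A configuration file is plain `key = value` text
#' (`#` comments allowed); vector values are comma-separated.
#'
#' @param ... configuration overrides (see Details).
#' @details Keys: `seed`, `outdir`, `temperature` (K), `bins` (per axis),
#' `n_rc`, `basin_threshold` (kJ/mol), `bin_width` (cm^-1), `sigma_ev`
#' (Gaussian width, eV), `grid_lo_nm`, `grid_hi_nm`, `grid_points`,
#' `window_lo_nm`, `window_hi_nm`, `k_max`, `n_states`, `n_frames_ed`,
#' `n_frames_pmm`, `n_env_triplets`, `intensity_floor` (M^-1 cm^-1),
#' plus stage input paths `trajectory`, `unperturbed_set`, `pmm_trajectory`,
#' `weights_file`.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    outdir = "pmmcd_out",
    temperature = 300,
    bins = 60,
    n_rc = 2L,
    basin_threshold = 3,
    bin_width = 250,
    sigma_ev = 0.15,
    grid_lo_nm = 120, grid_hi_nm = 260, grid_points = 400,
    window_lo_nm = 160, window_hi_nm = 220,
    k_max = NA,
    n_states = 17L,
    n_frames_ed = 2000L,
    n_frames_pmm = 50L,
    n_env_triplets = 300L,
    intensity_floor = 1.0,
    trajectory = NULL, unperturbed_set = NULL, pmm_trajectory = NULL,
    weights_file = NULL
  )
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  for (k in names(over)) cfg[[k]] <- over[[k]]
  structure(cfg, class = "run_config")
}

#' Read a flat key = value configuration file
#'
#' @param path configuration file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_data("config file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  over <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
    over[[key]] <- if (anyNA(num)) val else num
  }
  run_config(over)
}

## provenance header for every output file; path-valued keys are excluded
## from the hash (input identity is captured by the per-file checksums) so
## identical runs into different directories stay byte-identical
config_hash <- function(config) {
  cfg <- unclass(config)
  for (k in c("outdir", "trajectory", "unperturbed_set", "pmm_trajectory",
              "records", "weights_file"))
    cfg[[k]] <- NULL
  md5_string(paste(deparse(cfg[order(names(cfg))]), collapse = "\n"))
}

provenance_header <- function(config, inputs = character(0)) {
  h <- c(
    paste0("# pmmcd ", as.character(utils::packageVersion("pmmcd"))),
    paste0("# config_hash ", config_hash(config)),
    paste0("# seed ", config$seed)
  )
  for (p in inputs)
    h <- c(h, paste0("# input ", basename(p), " md5 ", unname(tools::md5sum(p))))
  h
}

write_tsv <- function(df, path, header_lines) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_lines, con)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  rows <- do.call(paste, c(lapply(df, function(col) {
    if (is.numeric(col)) fmt_num(col, 12) else as.character(col)
  }), sep = "\t"))
  writeLines(rows, con)
  invisible(path)
}

read_records_tsv <- function(path, label = "") {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  ks <- sort(unique(df$k))
  frames <- sort(unique(df$frame))
  nf <- length(frames)
  shape <- function(col) {
    m <- matrix(NA_real_, nf, length(ks))
    m[cbind(match(df$frame, frames), match(df$k, ks))] <- df[[col]]
    m
  }
  structure(list(
    exc_freqs = shape("exc_freq_hartree"),
    rot_strengths = shape("rot_strength_cgs"),
    dip_strengths = shape("dip_strength_cgs"),
    v0 = numeric(nf), efield = matrix(0, nf, 3),
    frame_index = frames, failed = integer(0), label = label
  ), class = "pmm_records")
}

default_grid <- function(config) {
  rev(WAVENUMBER_PER_NM /
        seq(config$grid_lo_nm, config$grid_hi_nm, length.out = config$grid_points))
}

#' Generate the synthetic fixture inputs for a pipeline run
#'
#' Writes into `outdir`: a mock unperturbed electronic set
#' (`unperturbed_set.json`), a two-basin chromophore trajectory for the ED
#' stage (`conf_trajectory.xyzq`) and a solvent-charge trajectory around
#' the mock quantum center for the PMM stage (`pmm_trajectory.xyzq`). All
#' files go through the package's own writers, so downstream stages
#' exercise the real parsers.
#'
#' @param config a `run_config`.
#' @return named list of generated file paths, invisibly.
#' @export
run_fixtures <- function(config = run_config()) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  spec <- fixture_spec(n_states = config$n_states,
                       n_env_triplets = config$n_env_triplets,
                       n_frames = config$n_frames_ed,
                       seed = config$seed,
                       temperature = config$temperature)
  set <- mock_unperturbed_set(spec)
  set_path <- file.path(config$outdir, "unperturbed_set.json")
  write_unperturbed_set(set, set_path)
  traj <- mock_conformational_trajectory(spec)
  conf_path <- file.path(config$outdir, "conf_trajectory.xyzq")
  write_xyzq(xyz_to_frames(traj$xyz, traj$elements,
                           charges = rep(0, length(traj$elements))), conf_path)
  spec_pmm <- fixture_spec(n_states = config$n_states,
                           n_env_triplets = config$n_env_triplets,
                           n_frames = config$n_frames_pmm,
                           seed = config$seed,
                           temperature = config$temperature)
  frames <- mock_solvent_frames(spec_pmm, set$qc_positions)
  pmm_path <- file.path(config$outdir, "pmm_trajectory.xyzq")
  write_perturbing_frames(frames, set$qc_charges, pmm_path)
  invisible(list(unperturbed_set = set_path, trajectory = conf_path,
                 pmm_trajectory = pmm_path))
}

#' Essential-dynamics stage
#'
#' Reads a chromophore trajectory, removes roto-translations by
#' mass-weighted superposition, computes the covariance eigendecomposition
#' and the essential-plane free-energy landscape, detects basins and
#' extracts reference configurations. Writes `ed_eigenvalues.tsv`,
#' `ed_fe_grid.tsv`, `rc_weights.tsv` (readable by [read_weight_table()])
#' and `rc_coords.xyzq`.
#'
#' @param config a `run_config`; `config$trajectory` names the input
#'   (defaults to the fixture path under `outdir`).
#' @param masses per-atom masses; default the fixture chain masses.
#' @param dihedral_idx four atom indices of the classified dihedral.
#' @return list with the `ed_space`, `fe_grid`, RC list and output paths,
#'   invisibly.
#' @export
run_ed <- function(config = run_config(),
                   masses = c(12, 12, 12, 12, 16, 12, 16, 12),
                   dihedral_idx = c(2L, 3L, 4L, 5L)) {
  traj_path <- config$trajectory %||%
    file.path(config$outdir, "conf_trajectory.xyzq")
  frames <- read_xyzq(traj_path)
  if (length(frames) < 2)
    abort_validation("ED analysis needs at least 2 frames, got ", length(frames))
  xyz <- frames_to_xyz(frames)
  fitted <- fit_trajectory(xyz, masses)
  ed <- covariance_eigendecomposition(fitted, n_select = 2)
  dih <- dihedral_series(fitted, dihedral_idx)
  grid <- free_energy_landscape(ed$projections, bins = config$bins,
                                temperature = config$temperature,
                                dihedrals = dih)
  rcs <- locate_basins_and_extract(grid, fitted, ed$projections,
                                   n_rc = config$n_rc,
                                   threshold = config$basin_threshold,
                                   dihedrals = dih)
  hdr <- provenance_header(config, traj_path)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  eig_path <- file.path(config$outdir, "ed_eigenvalues.tsv")
  write_tsv(data.frame(index = seq_along(ed$eigenvalues),
                       eigenvalue_nm2 = ed$eigenvalues), eig_path, hdr)
  cx <- (utils::head(grid$bin_edges$x, -1) + utils::tail(grid$bin_edges$x, -1)) / 2
  cy <- (utils::head(grid$bin_edges$y, -1) + utils::tail(grid$bin_edges$y, -1)) / 2
  idx <- which(grid$counts >= 0, arr.ind = TRUE)
  fe_df <- data.frame(
    x_nm = cx[idx[, 1]], y_nm = cy[idx[, 2]],
    count = grid$counts[idx],
    free_energy_kjmol = ifelse(is.na(grid$free_energy[idx]), "unsampled",
                               fmt_num(grid$free_energy[idx], 10)),
    dihedral_mean_deg = ifelse(is.na(grid$dihedral_mean[idx]), "unsampled",
                               fmt_num(grid$dihedral_mean[idx], 8))
  )
  fe_path <- file.path(config$outdir, "ed_fe_grid.tsv")
  write_tsv(fe_df, fe_path, hdr)
  ## headerless two-column format readable by read_weight_table()
  w_path <- file.path(config$outdir, "rc_weights.tsv")
  w_con <- file(w_path, "w")
  writeLines(c(hdr, "# label (rotamer)\tprobability"), w_con)
  writeLines(sprintf("%s (%s)\t%s",
                     vapply(rcs, `[[`, "", "label"),
                     vapply(rcs, `[[`, "", "rotamer"),
                     fmt_num(vapply(rcs, `[[`, numeric(1), "probability"), 12)),
             w_con)
  close(w_con)
  rc_path <- file.path(config$outdir, "rc_coords.xyzq")
  rc_xyz <- do.call(rbind, lapply(rcs, `[[`, "coordinates"))
  rc_frames <- xyz_to_frames(rc_xyz, frames[[1]]$elements,
                             charges = rep(0, length(frames[[1]]$elements)))
  for (i in seq_along(rc_frames))
    rc_frames[[i]]$comment <- paste("RC", rcs[[i]]$label)
  write_xyzq(rc_frames, rc_path)
  invisible(list(ed = ed, grid = grid, rcs = rcs,
                 paths = c(eig_path, fe_path, w_path, rc_path)))
}

#' PMM stage
#'
#' Reads an unperturbed electronic set and a combined QC + environment
#' charge trajectory (QC atoms first, as written by
#' [write_perturbing_frames()]), runs the per-frame PMM evaluation and
#' writes the per-frame, per-transition record table `pmm_records.tsv`.
#'
#' @param config a `run_config`; `config$unperturbed_set` and
#'   `config$pmm_trajectory` name the inputs (defaulting to the fixture
#'   paths under `outdir`).
#' @return list with the `pmm_records` and the output path, invisibly.
#' @export
run_pmm <- function(config = run_config()) {
  set_path <- config$unperturbed_set %||%
    file.path(config$outdir, "unperturbed_set.json")
  traj_path <- config$pmm_trajectory %||%
    file.path(config$outdir, "pmm_trajectory.xyzq")
  if (!file.exists(set_path))
    abort_data("unperturbed set file not found for this RC: ", set_path)
  set <- read_unperturbed_set(set_path)
  raw <- read_xyzq(traj_path)
  n_qc <- nrow(set$qc_positions)
  if (nrow(raw[[1]]$positions) <= n_qc)
    abort_data("trajectory frames have no environment atoms beyond the ",
               n_qc, " QC atoms")
  frames <- frames_to_perturbing(raw, qc_index = seq_len(n_qc))
  recs <- pmm_trajectory(set, frames)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- file.path(config$outdir, "pmm_records.tsv")
  write_tsv(as.data.frame(recs), out,
            provenance_header(config, c(set_path, traj_path)))
  invisible(list(records = recs, path = out))
}

#' Spectrum stage
#'
#' Builds binned Gaussian-broadened CD and UV spectra from one or more
#' per-frame record tables, combines them with conformer weights when a
#' weight table is given, restricts to the reporting window and writes
#' `spectrum_cd.tsv`, `spectrum_uv.tsv` and `transition_report.tsv`.
#'
#' @param config a `run_config`; `config$records` (vector of record TSV
#'   paths, default the single `pmm_records.tsv` under `outdir`) and
#'   optional `config$weights_file`.
#' @return list with the windowed CD and UV `spectrum_curve`s and the
#'   transition report, invisibly.
#' @export
run_spectrum <- function(config = run_config()) {
  rec_paths <- config$records %||%
    file.path(config$outdir, "pmm_records.tsv")
  sigma <- config$sigma_ev * EV_WAVENUMBER
  grid <- default_grid(config)
  k_max <- if (is.na(config$k_max)) NULL else config$k_max
  curves_cd <- list()
  curves_uv <- list()
  for (p in rec_paths) {
    recs <- read_records_tsv(p, label = basename(p))
    tb <- bin_transitions(recs, bin_width = config$bin_width, k_max = k_max)
    curves_cd[[length(curves_cd) + 1L]] <- cd_curve(tb, sigma, grid)
    curves_uv[[length(curves_uv) + 1L]] <- uv_curve(tb, sigma, grid)
  }
  if (!is.null(config$weights_file)) {
    wt <- normalize_weights(read_weight_table(config$weights_file))
    if (length(wt$probabilities) != length(curves_cd))
      abort_data("weight table has ", length(wt$probabilities),
                 " entries for ", length(curves_cd), " record tables")
    cd <- combine_spectra(curves_cd, wt, label = "combined")
    uv <- combine_spectra(curves_uv, wt, label = "combined")
  } else if (length(curves_cd) == 1L) {
    cd <- curves_cd[[1]]
    uv <- curves_uv[[1]]
  } else {
    abort_validation("multiple record tables need a weights_file")
  }
  cd_w <- wavelength_window(cd, config$window_lo_nm, config$window_hi_nm)
  uv_w <- wavelength_window(uv, config$window_lo_nm, config$window_hi_nm)
  rep_df <- transition_report(cd_w, floor = config$intensity_floor)
  hdr <- provenance_header(config, rec_paths)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  p_cd <- file.path(config$outdir, "spectrum_cd.tsv")
  p_uv <- file.path(config$outdir, "spectrum_uv.tsv")
  p_rep <- file.path(config$outdir, "transition_report.tsv")
  cd_df <- as.data.frame(cd_w); names(cd_df)[3] <- "delta_epsilon"
  uv_df <- as.data.frame(uv_w); names(uv_df)[3] <- "epsilon"
  write_tsv(cd_df, p_cd, hdr)
  write_tsv(uv_df, p_uv, hdr)
  write_tsv(rep_df, p_rep, hdr)
  invisible(list(cd = cd_w, uv = uv_w, report = rep_df,
                 paths = c(p_cd, p_uv, p_rep)))
}

#' Full fixture-driven pipeline
#'
#' Orchestrates the whole workflow on synthetic inputs: fixture generation,
#' ED analysis with RC extraction, an independent PMM run per RC (each RC
#' gets its own unperturbed set built on the RC geometry and its own
#' solvent trajectory, seeded deterministically from `config$seed`), per-RC
#' spectra, and the probability-weighted conformer combination. The output
#' tree under `config$outdir` is byte-identical across reruns with the same
#' configuration and seed.
#'
#' @param config a `run_config`.
#' @return list with RCs, per-RC record paths and the combined spectra,
#'   invisibly.
#' @export
run_all <- function(config = run_config()) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  fx <- run_fixtures(config)
  ed_out <- run_ed(config)
  rcs <- ed_out$rcs
  rec_paths <- character(length(rcs))
  for (i in seq_along(rcs)) {
    rc <- rcs[[i]]
    rc_dir <- file.path(config$outdir, paste0("rc_", rc$label))
    dir.create(rc_dir, showWarnings = FALSE)
    spec_i <- fixture_spec(n_states = config$n_states,
                           n_env_triplets = config$n_env_triplets,
                           n_frames = config$n_frames_pmm,
                           seed = config$seed + 1000L * i,
                           temperature = config$temperature)
    qc_pos <- matrix(rc$coordinates, ncol = 3, byrow = TRUE)
    set_i <- mock_unperturbed_set(spec_i, label = paste0("RC-", rc$label))
    set_i$qc_positions <- qc_pos
    set_i$qc_masses <- rep(14, nrow(qc_pos))
    set_i$qc_charges <- rep(0, nrow(qc_pos))
    validate_unperturbed_set(set_i)
    set_path <- file.path(rc_dir, "unperturbed_set.json")
    write_unperturbed_set(set_i, set_path)
    frames_i <- mock_solvent_frames(spec_i, qc_pos)
    traj_path <- file.path(rc_dir, "pmm_trajectory.xyzq")
    write_perturbing_frames(frames_i, set_i$qc_charges, traj_path)
    cfg_i <- config
    cfg_i$outdir <- rc_dir
    cfg_i$unperturbed_set <- set_path
    cfg_i$pmm_trajectory <- traj_path
    rec_paths[i] <- run_pmm(cfg_i)$path
  }
  cfg_sp <- config
  cfg_sp$records <- rec_paths
  w_path <- file.path(config$outdir, "rc_weights.tsv")
  cfg_sp$weights_file <- w_path
  sp <- run_spectrum(cfg_sp)
  invisible(list(rcs = rcs, record_paths = rec_paths, cd = sp$cd,
                 uv = sp$uv, report = sp$report, fixtures = fx))
}
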