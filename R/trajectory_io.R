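#' Read an XYZ-with-charges trajectory
#'
#' Extended-XYZ-style dialect: per frame an atom-count line, a comment line
#' (free text; conventionally `frame <i>`), then one line per atom with
#' `element x y z charge`. Coordinates are nm, charges elementary charges.
#' All frames must share the atom count.
#'
#' @param path file path.
#' @return list of frames; each frame is a list with `elements`,
#'   `positions` (`n x 3`, nm), `charges`, `comment`.
#' @export
read_xyzq <- function(path) {
  if (!file.exists(path)) abort_data("trajectory file not found: ", path)
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 0)
      abort_data("bad atom count at line ", i, " of ", path)
    if (i + 1L + nat > length(lines))
      abort_data("truncated frame at line ", i, " of ", path)
    comment <- lines[i + 1L]
    block <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(block), "[[:space:]]+")
    if (any(lengths(toks) < 5L))
      abort_data("frame at line ", i, ": atom lines need 'element x y z charge'")
    mat <- matrix(as.numeric(unlist(lapply(toks, `[`, 2:5))),
                  ncol = 4, byrow = TRUE)
    if (anyNA(mat))
      abort_data("frame at line ", i, ": non-numeric coordinate or charge")
    frames[[length(frames) + 1L]] <- list(
      elements = vapply(toks, `[`, "", 1L),
      positions = mat[, 1:3, drop = FALSE],
      charges = mat[, 4],
      comment = comment
    )
    i <- i + 2L + nat
  }
  if (length(frames) == 0) abort_data("no frames in ", path)
  nat <- vapply(frames, function(f) nrow(f$positions), 1L)
  if (length(unique(nat)) != 1L)
    abort_data("frames have differing atom counts in ", path)
  frames
}

#' Write an XYZ-with-charges trajectory
#'
#' Inverse of [read_xyzq()]. Numbers are written with enough digits to
#' reproduce the double-precision values on re-read.
#'
#' @param frames list of frames as returned by [read_xyzq()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xyzq <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    writeLines(as.character(nrow(f$positions)), con)
    writeLines(f$comment %||% paste("frame", i), con)
    writeLines(sprintf("%s %.12g %.12g %.12g %.12g",
                       f$elements, f$positions[, 1], f$positions[, 2],
                       f$positions[, 3], f$charges), con)
  }
  invisible(path)
}

#' Read a (possibly multi-frame) GRO coordinate stream
#'
#' Fixed-format GRO blocks: title, atom count, atom lines
#' (`resid+resname`, atom name, atom number, x y z in nm at fixed columns),
#' box line. Velocities, if present, are ignored. Charges are not part of
#' GRO; pair with [read_charge_table()] matched by atom order.
#'
#' @param path file path.
#' @return list of frames with `elements` (atom names), `positions`
#'   (`n x 3`, nm), `comment` (title line).
#' @export
read_gro <- function(path) {
  if (!file.exists(path)) abort_data("GRO file not found: ", path)
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    title <- lines[i]
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat))
      abort_data("bad GRO atom count at line ", i + 1L, " of ", path)
    if (i + 2L + nat > length(lines))
      abort_data("truncated GRO frame at line ", i, " of ", path)
    block <- lines[(i + 2L):(i + 1L + nat)]
    atom_name <- trimws(substr(block, 11L, 15L))
    xs <- as.numeric(substr(block, 21L, 28L))
    ys <- as.numeric(substr(block, 29L, 36L))
    zs <- as.numeric(substr(block, 37L, 44L))
    if (anyNA(xs) || anyNA(ys) || anyNA(zs))
      abort_data("unparseable GRO coordinates near line ", i + 2L, " of ", path)
    frames[[length(frames) + 1L]] <- list(
      elements = atom_name,
      positions = cbind(xs, ys, zs, deparse.level = 0),
      comment = title
    )
    i <- i + 3L + nat   # title + count + atoms + box
  }
  if (length(frames) == 0) abort_data("no frames in ", path)
  frames
}

#' Read a one-column per-atom charge table
#'
#' Plain text, one charge per line (elementary charges), `#` comments
#' allowed; matched to GRO atoms by order.
#'
#' @param path file path.
#' @param n_atoms expected number of atoms (checked if given).
#' @return numeric vector of charges.
#' @export
read_charge_table <- function(path, n_atoms = NULL) {
  if (!file.exists(path)) abort_data("charge table not found: ", path)
  q <- utils::read.table(path, header = FALSE, comment.char = "#")[[1]]
  if (!is.null(n_atoms) && length(q) != n_atoms)
    abort_data("charge table has ", length(q), " entries, expected ", n_atoms)
  as.numeric(q)
}

#' Convert raw trajectory frames into PMM perturbing frames
#'
#' Splits each frame's atoms into quantum-center (QC) atoms and environment
#' atoms by index. The QC coordinates carry the center of mass each frame;
#' the environment atoms carry the perturbing charges.
#'
#' @param frames list of frames (from [read_xyzq()] or [read_gro()] plus
#'   charges).
#' @param qc_index integer indices of QC atoms within each frame.
#' @param charges optional per-atom charges overriding those in `frames`.
#' @return list of `perturbing_frame` objects.
#' @export
frames_to_perturbing <- function(frames, qc_index, charges = NULL) {
  lapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    q <- charges %||% f$charges
    if (is.null(q))
      abort_data("frame ", i, " carries no charges and none were supplied")
    if (length(q) != nrow(f$positions))
      abort_data("frame ", i, ": ", length(q), " charges for ",
                 nrow(f$positions), " atoms")
    env_idx <- setdiff(seq_len(nrow(f$positions)), qc_index)
    perturbing_frame(
      env_positions = f$positions[env_idx, , drop = FALSE],
      env_charges = q[env_idx],
      qc_positions = f$positions[qc_index, , drop = FALSE],
      frame_index = i
    )
  })
}

#' Trajectory frames as a coordinate matrix
#'
#' Flattens a list of frames into the `n_frames x 3N` coordinate matrix
#' (x1, y1, z1, x2, ...) used by the essential-dynamics routines.
#'
#' @param frames list of frames with a `positions` matrix each.
#' @return numeric matrix, one row per frame, nm.
#' @export
frames_to_xyz <- function(frames) {
  t(vapply(frames, function(f) as.numeric(t(f$positions)),
           numeric(3L * nrow(frames[[1]]$positions))))
}

#' Coordinate matrix rows as frames
#'
#' Inverse of [frames_to_xyz()] given the per-atom metadata.
#'
#' @param xyz `n_frames x 3N` matrix, nm.
#' @param elements length-N atom names.
#' @param charges optional length-N charges.
#' @return list of frames.
#' @export
xyz_to_frames <- function(xyz, elements, charges = NULL) {
  lapply(seq_len(nrow(xyz)), function(i) {
    pos <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
    f <- list(elements = elements, positions = pos,
              comment = paste("frame", i))
    if (!is.null(charges)) f$charges <- charges
    f
  })
}
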