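#' Coordinate trajectory
#'
#' A time series of coordinate frames with per-atom metadata, the substrate
#' for the stability metrics (RMSD time series, per-residue RMSF).
#'
#' @param atom_meta `data.frame` with columns `atom_name`, `res_index`,
#'   `res_name`, `is_ca` (alpha-carbon flag).
#' @param frames List of n_atoms x 3 coordinate matrices (Angstrom); all
#'   frames must have the same atom count and finite coordinates.
#' @param frame_interval Time between recorded frames in picoseconds
#'   (default 10).
#' @return A `trajectory`.
#' @export
trajectory <- function(atom_meta, frames, frame_interval = 10) {
  atom_meta <- as.data.frame(atom_meta)
  stopifnot(all(c("atom_name", "res_index", "res_name", "is_ca") %in%
                  names(atom_meta)),
            length(frames) >= 1L, frame_interval > 0)
  n <- nrow(atom_meta)
  for (f in frames) {
    if (!is.matrix(f) || nrow(f) != n || ncol(f) != 3L)
      stop("every frame must be an n_atoms x 3 matrix")
    if (!all(is.finite(f))) stop("non-finite coordinates in trajectory")
  }
  structure(list(atom_meta = atom_meta, frames = frames,
                 frame_interval = frame_interval),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory>", nrow(x$atom_meta), "atoms x", length(x$frames),
      "frames @", x$frame_interval, "ps\n")
  invisible(x)
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares superposition of one coordinate set onto another using the
#' closed-form SVD solution, restricted to proper rotations (determinant
#' +1): a mirror image is never superposed by reflection.
#'
#' @param mobile,reference n x 3 coordinate matrices with equal n >= 3, not
#'   all collinear.
#' @return List with `rotation` (3 x 3, det +1), `translation` (length 3),
#'   `rmsd` (Angstrom) and `aligned` (the transformed mobile coordinates,
#'   `mobile %*% rotation + translation`).
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!identical(dim(mobile), dim(reference)))
    stop("point count mismatch between mobile and reference")
  if (nrow(mobile) < 3L) stop("need at least 3 points")
  cen <- sweep(mobile, 2L, colMeans(mobile))
  if (svd(cen)$d[2L] < 1e-10 * max(1, svd(cen)$d[1L]))
    stop("degenerate (collinear) point set")
  kabsch_core(mobile, reference)
}

resolve_selection <- function(traj, selection) {
  n <- nrow(traj$atom_meta)
  sel <- if (is.null(selection)) {
    traj$atom_meta$is_ca
  } else if (is.function(selection)) {
    vapply(seq_len(n), function(i) isTRUE(selection(traj$atom_meta[i, ])),
           TRUE)
  } else if (is.logical(selection)) {
    selection
  } else {
    seq_len(n) %in% selection
  }
  if (!any(sel)) stop("empty atom selection")
  which(sel)
}

#' RMSD time series of a trajectory
#'
#' Per-frame root-mean-square deviation from a reference frame, computed on
#' an atom selection (alpha carbons by default), optionally after optimal
#' rigid superposition of each frame onto the reference on that selection.
#' Reported in both Angstrom (native) and nm (the MD plotting convention).
#'
#' @param traj A [trajectory()].
#' @param ref Reference frame index (default 1).
#' @param selection `NULL` for alpha carbons, or a logical mask / index
#'   vector / predicate `function(atom_row)`.
#' @param superpose Superpose each frame onto the reference before measuring
#'   (default `TRUE`).
#' @return `data.frame` with columns `time_ps`, `rmsd_A`, `rmsd_nm`.
#' @export
rmsd_series <- function(traj, ref = 1L, selection = NULL, superpose = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  idx <- resolve_selection(traj, selection)
  R <- traj$frames[[ref]][idx, , drop = FALSE]
  vals <- vapply(traj$frames, function(fr) {
    X <- fr[idx, , drop = FALSE]
    if (superpose) kabsch_core(X, R)$rmsd
    else sqrt(mean(rowSums((X - R)^2)))
  }, 0)
  data.frame(time_ps = (seq_along(traj$frames) - 1L) * traj$frame_interval,
             rmsd_A = vals, rmsd_nm = vals / 10)
}

#' Per-residue RMSF of a trajectory
#'
#' Each frame is superposed onto the mean structure of the selection (the
#' mean is refined by two superposition iterations to avoid bias toward the
#' arbitrary initial reference); the RMSF of atom i is the root of the
#' time-averaged squared displacement from its time-average position, and
#' per-residue values are the mean over the residue's selected atoms.
#'
#' @inheritParams rmsd_series
#' @return `data.frame` with columns `res_index`, `rmsf_A`, `rmsf_nm`.
#' @export
rmsf_per_residue <- function(traj, selection = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (length(traj$frames) < 2L)
    stop("RMSF needs at least 2 frames")
  idx <- resolve_selection(traj, selection)
  mats <- lapply(traj$frames, function(fr) fr[idx, , drop = FALSE])
  ref <- mats[[1L]]
  for (iter in 1:2) {
    fitted <- lapply(mats, function(X) kabsch_core(X, ref)$aligned)
    ref <- Reduce(`+`, fitted) / length(fitted)
  }
  fitted <- lapply(mats, function(X) kabsch_core(X, ref)$aligned)
  mean_pos <- Reduce(`+`, fitted) / length(fitted)
  sqdisp <- Reduce(`+`, lapply(fitted, function(X)
    rowSums((X - mean_pos)^2))) / length(fitted)
  rmsf_atom <- sqrt(sqdisp)
  res <- traj$atom_meta$res_index[idx]
  agg <- tapply(rmsf_atom, res, mean)
  data.frame(res_index = as.integer(names(agg)),
             rmsf_A = as.numeric(agg), rmsf_nm = as.numeric(agg) / 10,
             row.names = NULL)
}

#' Read a multi-model PDB file as a trajectory
#'
#' Parses `MODEL`/`ENDMDL` blocks of `ATOM`/`HETATM` records (fixed PDB
#' columns). A file without MODEL records is read as a single frame.
#'
#' @param path PDB file path.
#' @param frame_interval Picoseconds between models (default 10).
#' @return A [trajectory()].
#' @export
read_pdb_trajectory <- function(path, frame_interval = 10) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  model_starts <- which(startsWith(lines, "MODEL"))
  if (!length(model_starts)) {
    blocks <- list(lines[atom])
  } else {
    ends <- c(model_starts[-1L] - 1L, length(lines))
    blocks <- lapply(seq_along(model_starts), function(i) {
      seg <- lines[model_starts[i]:ends[i]]
      seg[startsWith(seg, "ATOM") | startsWith(seg, "HETATM")]
    })
  }
  parse_block <- function(bl) {
    if (!length(bl)) stop("PDB model with no atom records")
    data.frame(
      atom_name = trimws(substr(bl, 13L, 16L)),
      res_name = trimws(substr(bl, 18L, 20L)),
      res_index = as.integer(substr(bl, 23L, 26L)),
      x = as.numeric(substr(bl, 31L, 38L)),
      y = as.numeric(substr(bl, 39L, 46L)),
      z = as.numeric(substr(bl, 47L, 54L)))
  }
  first <- parse_block(blocks[[1L]])
  meta <- data.frame(atom_name = first$atom_name,
                     res_index = first$res_index,
                     res_name = first$res_name,
                     is_ca = first$atom_name == "CA")
  frames <- lapply(blocks, function(bl) {
    df <- parse_block(bl)
    if (nrow(df) != nrow(meta)) stop("models differ in atom count")
    as.matrix(df[, c("x", "y", "z")])
  })
  trajectory(meta, frames, frame_interval)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj A [trajectory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb_trajectory <- function(traj, path) {
  m <- traj$atom_meta
  out <- character()
  for (k in seq_along(traj$frames)) {
    out <- c(out, sprintf("MODEL %8d", k))
    fr <- traj$frames[[k]]
    out <- c(out, sprintf(
      "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      seq_len(nrow(m)), substr(m$atom_name, 1, 4), substr(m$res_name, 1, 3),
      m$res_index, fr[, 1L], fr[, 2L], fr[, 3L]))
    out <- c(out, "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Read an XYZ trajectory
#'
#' Plain XYZ frames (`n`, comment, `element x y z` lines). XYZ carries no
#' residue information, so each atom becomes its own residue and the
#' alpha-carbon flag is set for all atoms (select explicitly if needed).
#'
#' @param path XYZ file path.
#' @param frame_interval Picoseconds between frames (default 10).
#' @return A [trajectory()].
#' @export
read_xyz_trajectory <- function(path, frame_interval = 10) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  frames <- list(); meta <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- as.integer(trimws(lines[i]))
    if (is.na(n) || i + 1L + n > length(lines))
      stop("malformed XYZ frame at line ", i)
    body <- lines[(i + 2L):(i + 1L + n)]
    f <- do.call(rbind, strsplit(trimws(body), "\\s+"))
    xyz <- matrix(as.numeric(f[, 2:4]), ncol = 3L)
    if (any(is.na(xyz))) stop("unreadable XYZ coordinates at line ", i)
    if (is.null(meta)) {
      meta <- data.frame(atom_name = f[, 1L], res_index = seq_len(n),
                         res_name = f[, 1L], is_ca = TRUE)
    } else if (n != nrow(meta)) stop("XYZ frames differ in atom count")
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + n
  }
  trajectory(meta, frames, frame_interval)
}
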