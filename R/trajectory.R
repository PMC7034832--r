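#' Construct a trajectory
#'
#' Ordered coordinate frames bound to a topology, with frame times and
#' replica/system metadata.
#'
#' @param topology a topology.
#' @param coords `n_atoms x 3 x n_frames` array (Angstrom).
#' @param times frame times in ps; strictly increasing. Defaults to
#'   `(1:n_frames) * dt`.
#' @param dt frame spacing in ps used when `times` is NULL.
#' @param replica_id,system_label metadata strings.
#' @return object of class `"trajectory"`.
#' @export
new_trajectory <- function(topology, coords, times = NULL, dt = 100,
                           replica_id = "r1", system_label = "system") {
  coords <- as_coords_array(coords, n_atoms(topology))
  nf <- dim(coords)[3]
  if (is.null(times)) times <- seq_len(nf) * dt
  if (length(times) != nf) stop_dyadmd("length(times) != n_frames")
  if (nf > 1 && any(diff(times) <= 0))
    stop_dyadmd("frame_times must be strictly increasing")
  structure(list(topology = topology, coords = coords, times = times,
                 replica_id = replica_id, system_label = system_label),
            class = "trajectory")
}

as_coords_array <- function(coords, na) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(nrow(coords), 3, 1))
  if (!is.array(coords) || length(dim(coords)) != 3 ||
      dim(coords)[1] != na || dim(coords)[2] != 3)
    stop_dyadmd("coords must be an n_atoms x 3 x n_frames array (n_atoms = ",
                na, ")")
  coords
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory '%s' replica '%s': %d atoms x %d frames (%.1f ps spacing)\n",
              x$system_label, x$replica_id, dim(x$coords)[1], dim(x$coords)[3],
              if (dim(x$coords)[3] > 1) stats::median(diff(x$times)) else NA))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory a trajectory
#' @export
n_frames <- function(trajectory) dim(trajectory$coords)[3]

#' Coordinates of one frame
#' @param trajectory a trajectory
#' @param i frame index
#' @return `n_atoms x 3` matrix
#' @export
frame_xyz <- function(trajectory, i) trajectory$coords[, , i, drop = TRUE]

#' Load a coordinate trajectory (multi-model PDB or DCD)
#'
#' @param topology topology describing the atoms (order must match the file).
#' @param path trajectory file; format by extension (`.pdb` multi-model,
#'   `.dcd` CHARMM/NAMD binary) unless `format` is given.
#' @param format `"pdb"` or `"dcd"`, overrides the extension.
#' @param dt,replica_id,system_label passed to [new_trajectory()].
#' @export
load_trajectory <- function(topology, path, format = NULL, dt = 100,
                            replica_id = "r1", system_label = "system") {
  if (is.null(format)) {
    format <- if (grepl("\\.dcd$", path, ignore.case = TRUE)) "dcd" else "pdb"
  }
  na <- n_atoms(topology)
  if (format == "dcd") {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)   # n_frames x 3*n_atoms
  } else {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
  }
  xyz <- matrix(xyz, ncol = 3 * na)
  nf <- nrow(xyz)
  coords <- array(NA_real_, dim = c(na, 3, nf))
  for (f in seq_len(nf)) coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  new_trajectory(topology, coords, dt = dt,
                 replica_id = replica_id, system_label = system_label)
}

#' Write a trajectory as a multi-model PDB
#' @param trajectory a trajectory
#' @param file output path
#' @export
write_trajectory_pdb <- function(trajectory, file) {
  at <- trajectory$topology$atoms
  nf <- n_frames(trajectory)
  xyz <- t(vapply(seq_len(nf),
                  function(f) as.vector(t(frame_xyz(trajectory, f))),
                  numeric(3 * nrow(at))))
  bio3d::write.pdb(file = file, xyz = xyz, resno = at$resid,
                   resid = at$resname, eleno = at$serial, elety = at$name,
                   chain = at$chain, elesy = at$elem)
  invisible(file)
}

#' Write a trajectory as a CHARMM-format DCD file
#'
#' Minimal single-precision CHARMM DCD writer (no unit cell), readable by
#' \code{bio3d::read.dcd} and the usual trajectory tools.
#'
#' @param trajectory a trajectory
#' @param file output path
#' @export
write_dcd <- function(trajectory, file) {
  con <- file(file, "wb")
  on.exit(close(con))
  nf <- n_frames(trajectory)
  na <- dim(trajectory$coords)[1]
  endian <- .Platform$endian
  wr_block <- function(writer) {
    # Fortran unformatted record: length prefix + payload + length suffix
    raw_con <- rawConnection(raw(0), "wb")
    writer(raw_con)
    payload <- rawConnectionValue(raw_con)
    close(raw_con)
    writeBin(length(payload), con, size = 4, endian = endian)
    writeBin(payload, con)
    writeBin(length(payload), con, size = 4, endian = endian)
  }
  wr_block(function(rc) {
    writeChar("CORD", rc, nchars = 4, eos = NULL)
    icntrl <- integer(20)
    icntrl[1] <- nf       # number of frames
    icntrl[2] <- 1L       # first step
    icntrl[3] <- 1L       # step interval
    icntrl[4] <- nf
    icntrl[10] <- 0L      # fixed atoms
    icntrl[20] <- 24L     # CHARMM version stamp
    writeBin(icntrl, rc, size = 4, endian = endian)
  })
  wr_block(function(rc) {
    writeBin(1L, rc, size = 4, endian = endian)
    title <- sprintf("%-80s", "dyadmd trajectory")
    writeChar(title, rc, nchars = 80, eos = NULL)
  })
  wr_block(function(rc) writeBin(as.integer(na), rc, size = 4, endian = endian))
  for (f in seq_len(nf)) {
    xyz <- frame_xyz(trajectory, f)
    for (dim_i in 1:3)
      wr_block(function(rc) writeBin(as.numeric(xyz[, dim_i]), rc,
                                     size = 4, endian = endian))
  }
  invisible(file)
}

#' Keep only the tail of a trajectory
#'
#' Extracts the trailing portion of a trajectory, either as a frame count or
#' as a time window (resolved to frames via the stored frame times). Requests
#' longer than the trajectory are clipped with a warning.
#'
#' @param trajectory a trajectory.
#' @param last_n_frames keep this many trailing frames.
#' @param last_t_ns keep the trailing window of this many nanoseconds.
#' @return trajectory containing the suffix of frames (metadata preserved).
#' @export
slice_tail <- function(trajectory, last_n_frames = NULL, last_t_ns = NULL) {
  nf <- n_frames(trajectory)
  if (is.null(last_n_frames) == is.null(last_t_ns))
    stop_dyadmd("give exactly one of last_n_frames / last_t_ns")
  if (!is.null(last_t_ns)) {
    if (last_t_ns <= 0) stop_dyadmd("last_t_ns must be > 0")
    t_end <- trajectory$times[nf]
    keep <- which(trajectory$times > t_end - last_t_ns * 1000)
    last_n_frames <- length(keep)
  }
  if (last_n_frames <= 0) stop_dyadmd("keep window must be > 0")
  if (last_n_frames > nf) {
    warning("requested tail longer than trajectory; keeping all ", nf, " frames")
    last_n_frames <- nf
  }
  idx <- seq.int(nf - last_n_frames + 1, nf)
  new_trajectory(trajectory$topology,
                 trajectory$coords[, , idx, drop = FALSE],
                 times = trajectory$times[idx],
                 replica_id = trajectory$replica_id,
                 system_label = trajectory$system_label)
}

#' Concatenate replica trajectories into one system trajectory
#'
#' Frames are concatenated in the order given; frame times are re-stamped
#' continuously using the spacing of the first replica.
#'
#' @param trajectories list of trajectories sharing one topology.
#' @param system_label label for the merged trajectory.
#' @export
merge_trajectories <- function(trajectories, system_label = NULL) {
  stopifnot(length(trajectories) >= 1)
  na <- dim(trajectories[[1]]$coords)[1]
  names0 <- trajectories[[1]]$topology$atoms$name
  for (tr in trajectories) {
    if (dim(tr$coords)[1] != na ||
        !identical(tr$topology$atoms$name, names0))
      stop_dyadmd("replicas have differing topologies")
  }
  coords <- array(NA_real_, dim = c(na, 3, sum(vapply(trajectories, n_frames, 1L))))
  f0 <- 0L
  for (tr in trajectories) {
    nf <- n_frames(tr)
    coords[, , f0 + seq_len(nf)] <- tr$coords
    f0 <- f0 + nf
  }
  dt <- if (n_frames(trajectories[[1]]) > 1)
    diff(trajectories[[1]]$times)[1] else 100
  new_trajectory(trajectories[[1]]$topology, coords, dt = dt,
                 replica_id = "merged",
                 system_label = system_label %||% trajectories[[1]]$system_label)
}
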