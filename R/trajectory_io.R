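#' Trajectory ensemble container
#'
#' An ensemble is one or more independent, time-stamped coordinate series
#' over a shared topology (fixed atom count and ordering). Coordinates
#' are stored in nm; times in ns.
#'
#' @param trajectories list of trajectories, each a list with `times`
#'   (ns, strictly increasing) and `coords` (array `n_frames x n_atoms x 3`,
#'   nm).
#' @param frame_interval nominal sampling interval in ns (default 0.1 ns,
#'   i.e. one snapshot every 100 ps).
#' @param atom_names,elements optional per-atom metadata shared by all
#'   trajectories.
#' @return object of class `trajectory_ensemble`.
#' @export
trajectory_ensemble <- function(trajectories, frame_interval = 0.1,
                                atom_names = NULL, elements = NULL) {
  if (!length(trajectories)) stop("no trajectories")
  n_atoms <- dim(trajectories[[1]]$coords)[2]
  for (i in seq_along(trajectories)) {
    tr <- trajectories[[i]]
    d <- dim(tr$coords)
    if (length(d) != 3L || d[3] != 3L) {
      stop("trajectory ", i, ": coords must be n_frames x n_atoms x 3")
    }
    if (d[2] != n_atoms) stop("trajectory ", i, ": atom count differs from first")
    if (d[1] < 1L) stop("trajectory ", i, ": needs at least one frame")
    if (length(tr$times) != d[1]) stop("trajectory ", i, ": times/frames mismatch")
    if (d[1] > 1L && any(diff(tr$times) <= 0)) {
      stop("trajectory ", i, ": times must be strictly increasing")
    }
  }
  structure(
    list(trajectories = trajectories,
         frame_interval = frame_interval,
         n_atoms = n_atoms,
         atom_names = atom_names,
         elements = elements),
    class = "trajectory_ensemble"
  )
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  nf <- vapply(x$trajectories, function(t) dim(t$coords)[1], integer(1))
  cat("trajectory_ensemble:", length(x$trajectories), "trajectorie(s),",
      x$n_atoms, "atoms,", paste(nf, collapse = "/"), "frames,",
      "dt =", x$frame_interval, "ns\n")
  invisible(x)
}

#' Number of frames per trajectory
#' @param ensemble a [trajectory_ensemble()].
#' @return integer vector.
#' @export
n_frames <- function(ensemble) {
  vapply(ensemble$trajectories, function(t) dim(t$coords)[1], integer(1))
}

.read_xyz_frames <- function(path) {
  lines <- readLines(path)
  frames <- list(); names_out <- NULL
  i <- 1L; f <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L) stop("XYZ parse error at line ", i, ": expected atom count")
    if (i + 1L + n > length(lines)) stop("XYZ truncated frame starting at line ", i)
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    bad <- which(vapply(parts, length, integer(1)) < 4L)
    if (length(bad)) stop("XYZ parse error at line ", i + 1L + bad[1])
    el <- vapply(parts, `[[`, character(1), 1L)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(!is.finite(xyz))) stop("XYZ non-numeric coordinates in frame ", f + 1L)
    f <- f + 1L
    if (is.null(names_out)) names_out <- el
    frames[[f]] <- xyz / 10  # Angstrom -> nm
    i <- i + 2L + n
  }
  if (!f) stop("no frames in ", path)
  list(frames = frames, elements = names_out)
}

#' Read one or more trajectory files into an ensemble
#'
#' Each source file becomes one independent trajectory. Multi-model PDB
#' (`MODEL`/`ENDMDL`) and multi-frame XYZ are supported; both store
#' Angstrom and are converted to nm. Frame times default to
#' `(0, dt, 2dt, ...)` from `frame_interval`.
#'
#' @param sources character vector of file paths (`.pdb` or `.xyz`).
#' @param n_atoms expected atom count (e.g. from a ligand topology);
#'   checked per frame when given.
#' @param frame_interval sampling interval in ns.
#' @return a [trajectory_ensemble()].
#' @export
read_trajectory <- function(sources, n_atoms = NULL, frame_interval = 0.1) {
  trajs <- list(); atom_names <- NULL; elements <- NULL
  for (src in sources) {
    ext <- tolower(tools::file_ext(src))
    if (ext == "xyz") {
      parsed <- .read_xyz_frames(src)
      nat <- vapply(parsed$frames, nrow, integer(1))
      if (length(unique(nat)) != 1L) {
        stop("atom-count mismatch at frame ", which(nat != nat[1])[1], " in ", src)
      }
      if (!is.null(n_atoms) && nat[1] != n_atoms) {
        stop("atom-count mismatch in ", src, ": expected ", n_atoms,
             ", found ", nat[1], " at frame 1")
      }
      coords <- aperm(simplify2array(parsed$frames), c(3, 1, 2))
      if (is.null(elements)) elements <- parsed$elements
    } else {
      pdb <- suppressWarnings(bio3d::read.pdb(src, multi = TRUE))
      if (is.null(pdb$atom) || nrow(pdb$atom) == 0L) stop("no atoms in ", src)
      nat <- nrow(pdb$atom)
      if (!is.null(n_atoms) && nat != n_atoms) {
        stop("atom-count mismatch in ", src, ": expected ", n_atoms,
             ", found ", nat, " at frame 1")
      }
      xyz <- pdb$xyz
      if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
      nf <- nrow(xyz)
      coords <- array(NA_real_, c(nf, nat, 3))
      for (k in seq_len(nf)) {
        coords[k, , ] <- matrix(xyz[k, ], ncol = 3, byrow = TRUE) / 10
      }
      if (is.null(atom_names)) atom_names <- trimws(pdb$atom$elety)
      if (is.null(elements)) elements <- trimws(pdb$atom$elesy)
    }
    nf <- dim(coords)[1]
    trajs[[length(trajs) + 1L]] <-
      list(times = (seq_len(nf) - 1) * frame_interval, coords = coords)
  }
  trajectory_ensemble(trajs, frame_interval = frame_interval,
                      atom_names = atom_names, elements = elements)
}

#' Write one trajectory of an ensemble to a PDB or XYZ file
#'
#' @param ensemble a [trajectory_ensemble()].
#' @param path output path; format chosen by extension (`.pdb` or `.xyz`).
#' @param which index of the trajectory to write.
#' @param atom_names,elements per-atom metadata; default from the
#'   ensemble.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(ensemble, path, which = 1L,
                             atom_names = ensemble$atom_names,
                             elements = ensemble$elements) {
  tr <- ensemble$trajectories[[which]]
  nf <- dim(tr$coords)[1]; nat <- dim(tr$coords)[2]
  if (is.null(elements)) elements <- rep("C", nat)
  if (is.null(atom_names)) atom_names <- elements
  ext <- tolower(tools::file_ext(path))
  if (ext == "xyz") {
    con <- file(path, "w"); on.exit(close(con))
    for (k in seq_len(nf)) {
      writeLines(c(as.character(nat), sprintf("t= %.6f ns", tr$times[k])), con)
      xyz <- tr$coords[k, , , drop = TRUE] * 10
      if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
      writeLines(sprintf("%-3s %12.6f %12.6f %12.6f", elements,
                         xyz[, 1], xyz[, 2], xyz[, 3]), con)
    }
  } else {
    xyz <- matrix(NA_real_, nf, 3 * nat)
    for (k in seq_len(nf)) xyz[k, ] <- as.vector(t(tr$coords[k, , ])) * 10
    bio3d::write.pdb(
      file = path, xyz = xyz,
      resno = rep(1L, nat), resid = rep("LIG", nat),
      eleno = seq_len(nat), elety = atom_names,
      chain = rep("X", nat), elesy = elements
    )
  }
  invisible(path)
}
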