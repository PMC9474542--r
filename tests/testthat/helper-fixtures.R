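# Shared fixtures and independent oracles, built in code.

# Rotation matrix about a unit axis by an angle (radians).
rot_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s <- sin(angle); C <- 1 - c_
  matrix(c(
    a[1] * a[1] * C + c_,        a[1] * a[2] * C - a[3] * s, a[1] * a[3] * C + a[2] * s,
    a[2] * a[1] * C + a[3] * s,  a[2] * a[2] * C + c_,       a[2] * a[3] * C - a[1] * s,
    a[3] * a[1] * C - a[2] * s,  a[3] * a[2] * C + a[1] * s, a[3] * a[3] * C + c_
  ), 3, 3, byrow = TRUE)
}

# Ligand frame with the pyrazole-ring COM placed at `pos` (nm).
ligand_frame_at <- function(ligand, pos) {
  mass <- fibrilsite:::.element_mass(ligand$atoms$element)
  pyr <- ligand_group_idx(ligand, "pyrazole_ring")
  com <- fibrilsite:::.com(ligand$ref_coords[pyr, , drop = FALSE], mass[pyr])
  sweep(ligand$ref_coords, 2, com - pos, "-")
}

# Brute-force all-pairs contact oracle: any pair within cutoff, plus
# the per-A-atom indicator.
brute_contact <- function(A, B, cutoff) {
  A <- rbind(A); B <- rbind(B)
  ind <- logical(nrow(A))
  for (i in seq_len(nrow(A))) {
    d2 <- (B[, 1] - A[i, 1])^2 + (B[, 2] - A[i, 2])^2 + (B[, 3] - A[i, 3])^2
    ind[i] <- any(d2 <= cutoff^2)
  }
  list(any = any(ind), n_in_contact = sum(ind), in_contact = ind)
}

# Build a small trajectory_ensemble from a list of per-frame ligand
# coordinate matrices (one trajectory).
ensemble_from_frames <- function(frames_list, frame_interval = 0.1) {
  trajs <- lapply(frames_list, function(frames) {
    coords <- array(NA_real_, c(length(frames), nrow(frames[[1]]), 3))
    for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
    list(times = (seq_along(frames) - 1) * frame_interval, coords = coords)
  })
  trajectory_ensemble(trajs, frame_interval = frame_interval)
}
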