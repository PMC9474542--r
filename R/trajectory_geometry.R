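# Geometry on fibril/ligand trajectories: protofilament axis,
# insertion depth, equilibration trimming, RMSF.

#' Axis definition for the protofilament direction
#'
#' The protofilament axis is the normalized mean of the backbone N-H
#' unit vectors of every `stride`-th residue starting at
#' `start_residue`, restricted to `residue_span`. In a cross-beta
#' stack these N-H vectors point along the hydrogen-bonded rung
#' stacking direction; taking every 2nd residue keeps only the set
#' pointing to the same side of the strand.
#'
#' @param start_residue first residue of the selection (default 36).
#' @param stride residue stride (default 2).
#' @param residue_span inclusive residue range of the folded N-terminal
#'   region used (default `c(36, 56)`).
#' @return object of class `axis_definition`.
#' @export
axis_definition <- function(start_residue = 36L, stride = 2L,
                            residue_span = c(36L, 56L)) {
  stopifnot(stride >= 1L, length(residue_span) == 2L,
            residue_span[1] <= residue_span[2])
  structure(list(start_residue = as.integer(start_residue),
                 stride = as.integer(stride),
                 residue_span = as.integer(residue_span)),
            class = "axis_definition")
}

#' Protofilament axis from backbone N-H vectors
#'
#' @param model a [fibril_model()] (layers assigned if sign orientation
#'   toward increasing layer index is wanted).
#' @param axis_def an [axis_definition()].
#' @return unit vector (length-3 numeric) pointing from layer 0 toward
#'   the last layer.
#' @export
protofilament_axis <- function(model, axis_def = axis_definition()) {
  at <- model$atoms
  sel <- seq(axis_def$start_residue, axis_def$residue_span[2],
             by = axis_def$stride)
  sel <- sel[sel >= axis_def$residue_span[1]]
  sel <- intersect(sel, unique(at$resno))
  if (!length(sel)) stop("no residues selected for the axis definition")
  role <- .backbone_role(at$atom_name)
  vecs <- list()
  for (res in sel) {
    for (ch in unique(at$chain[at$resno == res])) {
      iN <- which(at$resno == res & at$chain == ch & role == "N")
      iH <- which(at$resno == res & at$chain == ch & role == "H")
      if (!length(iN)) next
      if (!length(iH)) stop("residue ", res, " (chain ", ch,
                            ") has no amide hydrogen")
      v <- .coords(at)[iH[1], ] - .coords(at)[iN[1], ]
      vecs[[length(vecs) + 1L]] <- .unit(v)
    }
  }
  if (!length(vecs)) stop("no N-H vectors found for the axis definition")
  axis <- .unit(colMeans(do.call(rbind, vecs)))
  if (!is.na(model$layer_count) && model$layer_count > 1L) {
    cents <- layer_centroids(model)
    stack <- cents[nrow(cents), ] - cents[1, ]
    if (sum(axis * stack) < 0) axis <- -axis
  }
  axis
}

#' Insertion depth of the ligand in one frame
#'
#' Distance between the mass-weighted centroid of the ligand's pyrazole
#' ring and the mass-weighted centroid of all atoms of the tip
#' (edge) beta-strand layer.
#'
#' @param frame_xyz ligand coordinates for one frame (`n_atoms x 3`, nm).
#' @param ligand a [ligand_topology()].
#' @param model a layered [fibril_model()].
#' @param tip_layer edge layer used as the tip (default 0).
#' @param mass_weighted use atomic masses for both centroids (default
#'   TRUE); FALSE gives geometric centroids.
#' @return depth in nm.
#' @export
insertion_depth <- function(frame_xyz, ligand, model, tip_layer = 0L,
                            mass_weighted = TRUE) {
  pyr <- ligand_group_idx(ligand, "pyrazole_ring")
  if (!length(pyr)) stop("pyrazole_ring group is empty")
  if (is.na(model$layer_count) || tip_layer < 0L ||
      tip_layer >= model$layer_count) {
    stop("tip layer ", tip_layer, " does not exist")
  }
  tip_at <- model$atoms[model$atoms$layer == tip_layer, , drop = FALSE]
  if (mass_weighted) {
    m_lig <- .element_mass(ligand$atoms$element[pyr])
    m_tip <- .element_mass(tip_at$element)
  } else {
    m_lig <- NULL; m_tip <- NULL
  }
  com_lig <- .com(frame_xyz[pyr, , drop = FALSE], m_lig)
  com_tip <- .com(.coords(tip_at), m_tip)
  .vnorm(com_lig - com_tip)
}

#' Per-frame insertion-depth series for an ensemble
#'
#' @param ensemble ligand-atom [trajectory_ensemble()].
#' @param ligand,model,tip_layer,mass_weighted as [insertion_depth()].
#' @param projection if TRUE, report the signed projection of the
#'   pyrazole-tip vector onto `axis` (axial coordinate) instead of the
#'   scalar Euclidean depth. The axial form is preferred for dwell-site
#'   detection; the scalar form matches the free-energy profile
#'   definition.
#' @param axis unit vector used when `projection = TRUE`; default
#'   computed from the model layer stacking.
#' @return data.frame `(trajectory, time_ns, x_nm)`.
#' @export
depth_series <- function(ensemble, ligand, model, tip_layer = 0L,
                         mass_weighted = TRUE, projection = FALSE,
                         axis = NULL) {
  pyr <- ligand_group_idx(ligand, "pyrazole_ring")
  if (!length(pyr)) stop("pyrazole_ring group is empty")
  tip_at <- model$atoms[model$atoms$layer == tip_layer, , drop = FALSE]
  if (!nrow(tip_at)) stop("tip layer ", tip_layer, " does not exist")
  m_lig <- if (mass_weighted) .element_mass(ligand$atoms$element[pyr]) else NULL
  m_tip <- if (mass_weighted) .element_mass(tip_at$element) else NULL
  com_tip <- .com(.coords(tip_at), m_tip)
  if (projection && is.null(axis)) {
    cents <- layer_centroids(model)
    axis <- .unit(cents[nrow(cents), ] - cents[1, ])
  }
  out <- lapply(seq_along(ensemble$trajectories), function(tr) {
    co <- ensemble$trajectories[[tr]]$coords
    x <- vapply(seq_len(dim(co)[1]), function(f) {
      v <- .com(co[f, pyr, , drop = TRUE], m_lig) - com_tip
      if (projection) sum(v * axis) else .vnorm(v)
    }, numeric(1))
    data.frame(trajectory = tr, time_ns = ensemble$trajectories[[tr]]$times,
               x_nm = x)
  })
  do.call(rbind, out)
}

#' Discard the equilibration phase of each trajectory
#'
#' Removes the first `floor(fraction * n_frames)` frames of every
#' trajectory independently; the default keeps the last 75% of the
#' data.
#'
#' @param ensemble a [trajectory_ensemble()].
#' @param fraction fraction of frames to discard, in `[0, 1)`.
#' @return the trimmed ensemble.
#' @export
discard_equilibration <- function(ensemble, fraction = 0.25) {
  stopifnot(fraction >= 0, fraction < 1)
  ensemble$trajectories <- lapply(ensemble$trajectories, function(tr) {
    nf <- dim(tr$coords)[1]
    drop <- floor(fraction * nf)
    keep <- seq.int(drop + 1L, nf)
    list(times = tr$times[keep], coords = tr$coords[keep, , , drop = FALSE])
  })
  ensemble
}

#' Root mean squared fluctuations per residue and strand class
#'
#' Per-atom RMSF is the square root of the time-mean squared deviation
#' from the time-mean position, computed per trajectory after optional
#' least-squares superposition of the core-layer backbone onto the
#' trajectory's first frame. The per-residue value averages the
#' backbone heavy atoms (N, CA, C, O); reported residue profiles
#' average over the rungs of each strand class, excluding the two edge
#' layers. SEM is across trajectories.
#'
#' @param ensemble protein-atom [trajectory_ensemble()] whose atom
#'   ordering matches `model$atoms`.
#' @param model a layered [fibril_model()].
#' @param superpose superpose frames on the core-layer backbone first.
#' @param exclude_edge_layers drop the first and last layer from the
#'   report (default TRUE).
#' @param contact_layers integer layer indices classed as `contact`;
#'   remaining core layers are `non_contact`. With `NULL`, all core
#'   layers are classed `all`.
#' @return data.frame `(residue, class, rmsf_nm, sem_nm)` of class
#'   `rmsf_table`; per-atom values per trajectory are attached as
#'   attribute `per_atom`.
#' @export
rmsf <- function(ensemble, model, superpose = TRUE,
                 exclude_edge_layers = TRUE, contact_layers = NULL) {
  at <- model$atoms
  if (ensemble$n_atoms != nrow(at)) {
    stop("ensemble atom count does not match the model")
  }
  if (is.na(model$layer_count)) stop("layers not assigned; see assign_layers()")
  role <- .backbone_role(at$atom_name)
  core <- if (exclude_edge_layers && model$layer_count > 2L) {
    at$layer > 0L & at$layer < model$layer_count - 1L
  } else rep(TRUE, nrow(at))
  fit_idx <- which(core & role %in% c("N", "CA", "C", "O"))

  per_atom <- matrix(NA_real_, nrow(at), length(ensemble$trajectories))
  for (tr in seq_along(ensemble$trajectories)) {
    co <- ensemble$trajectories[[tr]]$coords
    nf <- dim(co)[1]
    if (nf < 2L) {
      warning("trajectory ", tr, " has a single frame; RMSF is 0")
      per_atom[, tr] <- 0
      next
    }
    frames <- lapply(seq_len(nf), function(f) co[f, , , drop = TRUE])
    if (superpose) {
      ref <- frames[[1]]
      frames <- lapply(frames, .superpose, ref = ref, fit_idx = fit_idx)
    }
    arr <- simplify2array(frames)              # atoms x 3 x frames
    mean_pos <- apply(arr, c(1, 2), mean)
    dev2 <- sweep(arr, c(1, 2), mean_pos)^2
    per_atom[, tr] <- sqrt(apply(dev2, 1, sum) / nf)
  }

  bb <- role %in% c("N", "CA", "C", "O")
  if (is.null(contact_layers)) {
    cls <- ifelse(core, "all", NA)
  } else {
    cls <- ifelse(!core, NA,
                  ifelse(at$layer %in% contact_layers, "contact", "non_contact"))
  }
  keep <- bb & !is.na(cls)
  key <- data.frame(residue = at$resno[keep], class = cls[keep])
  rows <- list()
  for (cl in unique(key$class)) {
    for (res in sort(unique(key$residue[key$class == cl]))) {
      idx <- which(keep)[key$residue == res & key$class == cl]
      vals <- colMeans(per_atom[idx, , drop = FALSE])  # per trajectory
      rows[[length(rows) + 1L]] <- data.frame(
        residue = res, class = cl,
        rmsf_nm = mean(vals), sem_nm = .sem(vals))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("rmsf_table", "data.frame")
  attr(out, "per_atom") <- per_atom
  out
}
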