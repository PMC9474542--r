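# Heuristic per-frame binding-mode classification and mode populations.

.MAJOR_MODES <- c("I_unbound", "II_partial", "III_no_polar", "IV_polar")

#' Classify one frame into a binding mode
#'
#' Heuristic modes of ligand binding to a fibril:
#' I "unbound" (no atomic contacts), II "partially bound" (fewer than
#' half of the ligand heavy atoms in contact with protein heavy atoms),
#' III "no HB or XB" (half or more atoms in contact, no polar bonds),
#' IV "polar interactions" (at least one hydrogen or halogen bond, with
#' sub-labels IVa pyrazole HB, IVb benzodioxole HB, IVc bromophenyl
#' XB). The presence of a polar bond dominates: such frames are IV
#' regardless of the contact count.
#'
#' @param n_atoms_in_contact number of ligand heavy atoms in contact.
#' @param n_heavy ligand heavy-atom count (> 0).
#' @param hb_moieties character vector of ligand moieties forming
#'   hydrogen bonds in the frame (`"pyrazole"`, `"benzodioxole"`).
#' @param n_xb number of halogen bonds in the frame.
#' @return list with `major` (one of `I_unbound`, `II_partial`,
#'   `III_no_polar`, `IV_polar`) and `sub` (character subset of
#'   IVa/IVb/IVc).
#' @export
classify_frame <- function(n_atoms_in_contact, n_heavy,
                           hb_moieties = character(0), n_xb = 0L) {
  if (!.is_count(n_heavy) || n_heavy <= 0) stop("n_heavy must be positive")
  if (n_atoms_in_contact < 0 || n_atoms_in_contact > n_heavy) {
    stop("n_atoms_in_contact must lie in [0, n_heavy]")
  }
  sub <- character(0)
  if ("pyrazole" %in% hb_moieties) sub <- c(sub, "IVa_pyrazole_HB")
  if ("benzodioxole" %in% hb_moieties) sub <- c(sub, "IVb_benzodioxole_HB")
  if (n_xb >= 1L) sub <- c(sub, "IVc_bromophenyl_XB")
  has_polar <- length(hb_moieties) > 0L || n_xb >= 1L
  major <- if (has_polar) {
    "IV_polar"
  } else if (n_atoms_in_contact == 0L) {
    "I_unbound"
  } else if (n_atoms_in_contact < n_heavy / 2) {
    "II_partial"
  } else {
    "III_no_polar"
  }
  list(major = major, sub = sub)
}

#' Classify every frame of an ensemble
#'
#' Runs heavy-atom contact counting and polar-bond detection per frame
#' and applies [classify_frame()].
#'
#' @param ensemble ligand-atom [trajectory_ensemble()].
#' @param ligand a [ligand_topology()].
#' @param model a layered [fibril_model()].
#' @param criteria a [contact_criteria()].
#' @param polar a [polar_bond_criteria()].
#' @return list of per-trajectory data.frames `(time_ns, major, IVa,
#'   IVb, IVc)`.
#' @export
classify_frames <- function(ensemble, ligand, model,
                            criteria = contact_criteria(),
                            polar = polar_bond_criteria()) {
  at <- model$atoms
  hp <- .heavy(at)
  pxyz <- .coords(at)[hp, , drop = FALSE]
  lig_heavy <- which(.heavy(ligand$atoms))
  lapply(seq_along(ensemble$trajectories), function(tr) {
    co <- ensemble$trajectories[[tr]]$coords
    nf <- dim(co)[1]
    major <- character(nf); iva <- ivb <- ivc <- logical(nf)
    for (f in seq_len(nf)) {
      fr <- co[f, , , drop = TRUE]
      if (is.null(dim(fr))) fr <- matrix(fr, ncol = 3)
      d2 <- .cross_dist2(fr[lig_heavy, , drop = FALSE], pxyz)
      n_contact <- sum(apply(d2 <= criteria$heavy_cutoff^2, 1, any))
      pb <- ligand_polar_bonds(fr, ligand, model, polar,
                               criteria$exclude_edge_layers)
      lab <- classify_frame(n_contact, ligand$n_heavy,
                            hb_moieties = unique(pb$hb$moiety),
                            n_xb = nrow(pb$xb))
      major[f] <- lab$major
      iva[f] <- "IVa_pyrazole_HB" %in% lab$sub
      ivb[f] <- "IVb_benzodioxole_HB" %in% lab$sub
      ivc[f] <- "IVc_bromophenyl_XB" %in% lab$sub
    }
    data.frame(time_ns = ensemble$trajectories[[tr]]$times,
               major = major, IVa = iva, IVb = ivb, IVc = ivc)
  })
}

#' Mode populations across trajectories
#'
#' Per-mode fraction is the trajectory-mean of the per-trajectory frame
#' fractions (equal weight per independent trajectory); major-mode
#' fractions sum to 1. SEM is across trajectories.
#'
#' @param labels list of per-trajectory label data.frames (from
#'   [classify_frames()]) or a list of character vectors of major
#'   labels.
#' @return data.frame `(mode, fraction, sem)`.
#' @export
mode_populations <- function(labels) {
  if (!length(labels)) stop("need at least one labeled trajectory")
  major_list <- lapply(labels, function(l) {
    if (is.data.frame(l)) l$major else as.character(l)
  })
  if (any(!vapply(major_list, length, integer(1)))) {
    stop("every trajectory needs at least one labeled frame")
  }
  frac <- vapply(major_list, function(m) {
    vapply(.MAJOR_MODES, function(k) mean(m == k), numeric(1))
  }, numeric(length(.MAJOR_MODES)))
  frac <- matrix(frac, nrow = length(.MAJOR_MODES))
  data.frame(mode = .MAJOR_MODES,
             fraction = rowMeans(frac),
             sem = apply(frac, 1, .sem))
}
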