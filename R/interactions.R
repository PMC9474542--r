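# Contact detection, polar-bond (hydrogen / halogen bond) detection and
# contact-probability maps.

#' Contact criteria
#'
#' @param heavy_cutoff heavy-atom contact cutoff in nm (default 0.40).
#' @param nitrogen_backbone_cutoff cutoff for the pyrazole-nitrogen to
#'   backbone C/N rule in nm (default 0.50).
#' @param exclude_edge_layers drop the edge beta-strand layers from
#'   contact maps (default TRUE).
#' @param include_ca count CA among the backbone carbons of the
#'   0.5 nm rule (default TRUE).
#' @return object of class `contact_criteria`.
#' @export
contact_criteria <- function(heavy_cutoff = 0.40,
                             nitrogen_backbone_cutoff = 0.50,
                             exclude_edge_layers = TRUE,
                             include_ca = TRUE) {
  stopifnot(heavy_cutoff > 0, nitrogen_backbone_cutoff > 0)
  structure(list(heavy_cutoff = heavy_cutoff,
                 nitrogen_backbone_cutoff = nitrogen_backbone_cutoff,
                 exclude_edge_layers = exclude_edge_layers,
                 include_ca = include_ca),
            class = "contact_criteria")
}

#' Default empirical hydrogen-bond energy model
#'
#' A smooth distance- and angle-dependent electrostatic-like form,
#' `-E0 * exp(-(d - d0)/rho) * cos^2(theta)`, with `E0 = 8` kJ/mol,
#' `d0 = 0.28` nm, `rho = 0.045` nm. This is a documented surrogate
#' used only for reporting: hydrogen-bond *presence* (what the
#' binding-mode classification consumes) is decided purely by the
#' geometric criteria.
#'
#' @param distance_nm donor-acceptor heavy-atom distance, nm.
#' @param angle_deg donor-H-acceptor angle, degrees (180 = linear).
#' @return energy in kJ/mol (negative = favorable).
#' @export
hb_energy_default <- function(distance_nm, angle_deg) {
  -8 * exp(-(distance_nm - 0.28) / 0.045) * cos(angle_deg * pi / 180)^2
}

#' Polar-bond (hydrogen / halogen bond) criteria
#'
#' @param hb_donor_acceptor_cutoff donor-acceptor heavy distance cutoff,
#'   nm (default 0.35).
#' @param hb_angle_min minimum D-H...A angle, degrees (default 150).
#' @param xb_distance_cutoff halogen to carbonyl-oxygen distance cutoff,
#'   nm (default 0.36).
#' @param xb_angle_min minimum C-Br...O angle at the halogen, degrees
#'   (default 150; 180 = perfectly linear).
#' @param hb_energy_model function(distance_nm, angle_deg) -> kJ/mol.
#' @return object of class `polar_bond_criteria`.
#' @export
polar_bond_criteria <- function(hb_donor_acceptor_cutoff = 0.35,
                                hb_angle_min = 150,
                                xb_distance_cutoff = 0.36,
                                xb_angle_min = 150,
                                hb_energy_model = hb_energy_default) {
  stopifnot(hb_donor_acceptor_cutoff > 0, xb_distance_cutoff > 0,
            hb_angle_min > 0, hb_angle_min <= 180,
            xb_angle_min > 0, xb_angle_min <= 180,
            is.function(hb_energy_model))
  structure(list(hb_donor_acceptor_cutoff = hb_donor_acceptor_cutoff,
                 hb_angle_min = hb_angle_min,
                 xb_distance_cutoff = xb_distance_cutoff,
                 xb_angle_min = xb_angle_min,
                 hb_energy_model = hb_energy_model),
            class = "polar_bond_criteria")
}

# Squared cross-distance matrix between two coordinate sets.
.cross_dist2 <- function(A, B) {
  A <- rbind(A); B <- rbind(B)
  outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
}

#' Heavy-atom contact between a ligand and a protein atom set
#'
#' A contact is formed if any heavy (non-hydrogen) atom of the ligand
#' is within `cutoff` of any heavy atom of the protein selection.
#' Detection uses a cell-list neighbor search (cells of edge `cutoff`,
#' 27-cell stencil), so it scales linearly with atom count while being
#' exactly equivalent to an all-pairs scan.
#'
#' @param lig_xyz ligand coordinates, `n x 3` nm.
#' @param lig_elements ligand element symbols.
#' @param prot_xyz protein coordinates, `m x 3` nm.
#' @param prot_elements protein element symbols.
#' @param cutoff contact cutoff, nm (default 0.40).
#' @return list with `contact` (logical), `n_in_contact` (number of
#'   ligand heavy atoms within cutoff of any protein heavy atom) and
#'   `in_contact` (per-ligand-heavy-atom logical).
#' @export
heavy_atom_contact <- function(lig_xyz, lig_elements, prot_xyz,
                               prot_elements, cutoff = 0.40) {
  hl <- toupper(lig_elements) != "H"
  hp <- toupper(prot_elements) != "H"
  if (!any(hl) || !any(hp)) stop("empty heavy-atom selection")
  q <- .contact_query(rbind(lig_xyz)[hl, , drop = FALSE],
                      rbind(prot_xyz)[hp, , drop = FALSE], cutoff)
  list(contact = q$any, n_in_contact = q$n_in_contact,
       in_contact = q$in_contact)
}

#' Pyrazole-nitrogen to backbone contact (0.5 nm rule)
#'
#' TRUE iff either pyrazole ring nitrogen of the ligand is within
#' `cutoff` of any backbone carbon or nitrogen atom (N, C and, by
#' default, CA) of the residue selection.
#'
#' @param lig_xyz ligand coordinates, nm.
#' @param ligand a [ligand_topology()].
#' @param residue_atoms data.frame of the residue's atoms (columns as in
#'   `fibril_model$atoms`).
#' @param cutoff distance cutoff, nm (default 0.50).
#' @param include_ca count CA as a backbone carbon (default TRUE).
#' @return logical.
#' @export
nitrogen_backbone_contact <- function(lig_xyz, ligand, residue_atoms,
                                      cutoff = 0.50, include_ca = TRUE) {
  nidx <- ligand_group_idx(ligand, "pyrazole_N")
  if (length(nidx) != 2L) stop("pyrazole_N group must have 2 atoms")
  role <- .backbone_role(residue_atoms$atom_name)
  roles <- c("N", "C", if (include_ca) "CA")
  bb <- which(role %in% roles)
  if (!length(bb)) return(FALSE)
  d2 <- .cross_dist2(rbind(lig_xyz)[nidx, , drop = FALSE],
                     .coords(residue_atoms)[bb, , drop = FALSE])
  any(d2 <= cutoff^2)
}

#' Detect hydrogen bonds between explicit donor/acceptor sets
#'
#' A bond is formed iff the donor-acceptor heavy-atom distance is at
#' most the cutoff and the D-H...A angle (at the hydrogen; 180 =
#' linear) is at least the minimum angle. The configured empirical
#' energy model is evaluated for each accepted bond and reported
#' alongside.
#'
#' @param donor_xyz donor heavy-atom coordinates, `n x 3` nm.
#' @param h_xyz matching donor-hydrogen coordinates, `n x 3` nm.
#' @param acceptor_xyz acceptor coordinates, `m x 3` nm.
#' @param criteria a [polar_bond_criteria()].
#' @param donor_labels,acceptor_labels optional labels carried through.
#' @return data.frame `(donor, acceptor, distance_nm, angle_deg,
#'   energy_kJmol)`, zero rows if no bond.
#' @export
detect_hydrogen_bonds <- function(donor_xyz, h_xyz, acceptor_xyz,
                                  criteria = polar_bond_criteria(),
                                  donor_labels = NULL,
                                  acceptor_labels = NULL) {
  donor_xyz <- rbind(donor_xyz); h_xyz <- rbind(h_xyz)
  acceptor_xyz <- rbind(acceptor_xyz)
  if (nrow(donor_xyz) != nrow(h_xyz)) {
    stop("each donor needs a matching hydrogen position")
  }
  if (is.null(donor_labels)) donor_labels <- seq_len(nrow(donor_xyz))
  if (is.null(acceptor_labels)) acceptor_labels <- seq_len(nrow(acceptor_xyz))
  out <- list()
  for (i in seq_len(nrow(donor_xyz))) {
    for (j in seq_len(nrow(acceptor_xyz))) {
      d <- .vnorm(acceptor_xyz[j, ] - donor_xyz[i, ])
      if (d > criteria$hb_donor_acceptor_cutoff) next
      ang <- .angle_deg(donor_xyz[i, ] - h_xyz[i, ],
                        acceptor_xyz[j, ] - h_xyz[i, ])
      if (ang < criteria$hb_angle_min) next
      out[[length(out) + 1L]] <- data.frame(
        donor = donor_labels[i], acceptor = acceptor_labels[j],
        distance_nm = d, angle_deg = ang,
        energy_kJmol = criteria$hb_energy_model(d, ang))
    }
  }
  if (!length(out)) {
    return(data.frame(donor = character(0), acceptor = character(0),
                      distance_nm = numeric(0), angle_deg = numeric(0),
                      energy_kJmol = numeric(0)))
  }
  do.call(rbind, out)
}

#' Detect halogen bonds between the ligand halogen and carbonyl oxygens
#'
#' A halogen bond is formed iff the halogen to oxygen distance is at
#' most `xb_distance_cutoff` and the C-Br...O angle at the halogen is
#' at least `xb_angle_min` (near-linear arrangement of the carbon,
#' halogen and oxygen).
#'
#' @param lig_xyz ligand coordinates, nm.
#' @param ligand a [ligand_topology()].
#' @param oxygen_xyz carbonyl-oxygen coordinates, `m x 3` nm.
#' @param criteria a [polar_bond_criteria()].
#' @param oxygen_labels optional labels carried through.
#' @return data.frame `(halogen, oxygen, distance_nm, angle_deg)`.
#' @export
detect_halogen_bonds <- function(lig_xyz, ligand, oxygen_xyz,
                                 criteria = polar_bond_criteria(),
                                 oxygen_labels = NULL) {
  lig_xyz <- rbind(lig_xyz); oxygen_xyz <- rbind(oxygen_xyz)
  br <- ligand_group_idx(ligand, "halogen")
  cc <- ligand_group_idx(ligand, "halogen_bonded_carbon")
  br_pos <- lig_xyz[br, ]; c_pos <- lig_xyz[cc, ]
  if (is.null(oxygen_labels)) oxygen_labels <- seq_len(nrow(oxygen_xyz))
  out <- list()
  for (j in seq_len(nrow(oxygen_xyz))) {
    d <- .vnorm(oxygen_xyz[j, ] - br_pos)
    if (d > criteria$xb_distance_cutoff) next
    ang <- .angle_deg(c_pos - br_pos, oxygen_xyz[j, ] - br_pos)
    if (ang < criteria$xb_angle_min) next
    out[[length(out) + 1L]] <- data.frame(
      halogen = ligand$groups$halogen, oxygen = oxygen_labels[j],
      distance_nm = d, angle_deg = ang)
  }
  if (!length(out)) {
    return(data.frame(halogen = character(0), oxygen = character(0),
                      distance_nm = numeric(0), angle_deg = numeric(0)))
  }
  do.call(rbind, out)
}

# Protein polar-atom inventory used by ligand_polar_bonds: backbone
# amide N (with H), backbone carbonyl O, and optionally sidechain O/N.
.protein_polar_atoms <- function(model, exclude_edge_layers = TRUE,
                                 include_sidechains = TRUE) {
  at <- model$atoms
  role <- .backbone_role(at$atom_name)
  keep <- rep(TRUE, nrow(at))
  if (exclude_edge_layers && !is.na(model$layer_count) &&
      model$layer_count > 2L) {
    keep <- at$layer > 0L & at$layer < model$layer_count - 1L
  }
  don <- list(); acc <- list()
  idxN <- which(keep & role == "N")
  for (i in idxN) {
    iH <- which(at$resno == at$resno[i] & at$chain == at$chain[i] &
                  .backbone_role(at$atom_name) == "H")
    if (length(iH)) {
      don[[length(don) + 1L]] <- data.frame(iN = i, iH = iH[1])
    }
  }
  accidx <- which(keep & role == "O")
  if (include_sidechains) {
    side <- keep & role == "" & toupper(at$element) %in% c("O", "N")
    accidx <- c(accidx, which(side))
  }
  list(
    donors = if (length(don)) do.call(rbind, don) else
      data.frame(iN = integer(0), iH = integer(0)),
    acceptors = accidx,
    carbonyl_O = which(keep & role == "O")
  )
}

# Find the hydrogen attached to each pyrazole nitrogen (if present) in
# a given frame: any ligand H within 0.115 nm of the nitrogen.
.ligand_nh_donor <- function(lig_xyz, ligand) {
  hidx <- which(toupper(ligand$atoms$element) == "H")
  nidx <- ligand_group_idx(ligand, "pyrazole_N")
  out <- list()
  for (i in nidx) {
    if (!length(hidx)) break
    d <- sqrt(.cross_dist2(rbind(lig_xyz)[i, , drop = FALSE],
                           rbind(lig_xyz)[hidx, , drop = FALSE]))
    j <- which(d <= 0.115)
    if (length(j)) out[[length(out) + 1L]] <- c(iN = i, iH = hidx[j[1]])
  }
  if (!length(out)) return(data.frame(iN = integer(0), iH = integer(0)))
  as.data.frame(do.call(rbind, out))
}

#' All ligand-protein polar bonds in one frame
#'
#' Detects, with the configured geometric criteria: hydrogen bonds
#' donated by the pyrazole N-H to protein acceptors, hydrogen bonds
#' donated by protein backbone amides to the pyrazole nitrogens or the
#' benzodioxole oxygens, and halogen bonds from the ligand halogen to
#' backbone carbonyl oxygens. Each bond is annotated with the ligand
#' moiety involved (`pyrazole`, `benzodioxole`, `bromophenyl`) and the
#' protein partner residue.
#'
#' @param lig_xyz ligand coordinates for one frame, nm.
#' @param ligand a [ligand_topology()].
#' @param model a layered [fibril_model()] (its stored coordinates are
#'   used as the protein frame).
#' @param criteria a [polar_bond_criteria()].
#' @param exclude_edge_layers skip edge-layer partners (default TRUE).
#' @param include_sidechains include sidechain O/N acceptors (default
#'   TRUE).
#' @return list with data.frames `hb` (`moiety, residue, chain,
#'   partner_role, distance_nm, angle_deg, energy_kJmol`) and `xb`
#'   (`moiety, residue, chain, distance_nm, angle_deg`).
#' @export
ligand_polar_bonds <- function(lig_xyz, ligand, model,
                               criteria = polar_bond_criteria(),
                               exclude_edge_layers = TRUE,
                               include_sidechains = TRUE) {
  at <- model$atoms
  prot <- .protein_polar_atoms(model, exclude_edge_layers,
                               include_sidechains)
  pxyz <- .coords(at)
  hb_rows <- list()

  # ligand N-H -> protein acceptors
  nh <- .ligand_nh_donor(lig_xyz, ligand)
  if (nrow(nh) && length(prot$acceptors)) {
    hb <- detect_hydrogen_bonds(
      rbind(lig_xyz)[nh$iN, , drop = FALSE],
      rbind(lig_xyz)[nh$iH, , drop = FALSE],
      pxyz[prot$acceptors, , drop = FALSE], criteria,
      donor_labels = ligand$atoms$name[nh$iN],
      acceptor_labels = prot$acceptors)
    if (nrow(hb)) {
      j <- as.integer(hb$acceptor)
      hb_rows[[length(hb_rows) + 1L]] <- data.frame(
        moiety = "pyrazole", residue = at$resno[j], chain = at$chain[j],
        partner_role = ifelse(.backbone_role(at$atom_name[j]) == "O",
                              "O", "side"),
        distance_nm = hb$distance_nm, angle_deg = hb$angle_deg,
        energy_kJmol = hb$energy_kJmol)
    }
  }

  # protein backbone N-H -> ligand acceptors
  if (nrow(prot$donors)) {
    for (grp in c("pyrazole_N", "benzodioxole_O")) {
      aidx <- ligand_group_idx(ligand, grp)
      hb <- detect_hydrogen_bonds(
        pxyz[prot$donors$iN, , drop = FALSE],
        pxyz[prot$donors$iH, , drop = FALSE],
        rbind(lig_xyz)[aidx, , drop = FALSE], criteria,
        donor_labels = prot$donors$iN,
        acceptor_labels = ligand$atoms$name[aidx])
      if (nrow(hb)) {
        i <- as.integer(hb$donor)
        hb_rows[[length(hb_rows) + 1L]] <- data.frame(
          moiety = if (grp == "pyrazole_N") "pyrazole" else "benzodioxole",
          residue = at$resno[i], chain = at$chain[i],
          partner_role = "N",
          distance_nm = hb$distance_nm, angle_deg = hb$angle_deg,
          energy_kJmol = hb$energy_kJmol)
      }
    }
  }

  xb_rows <- NULL
  if (length(prot$carbonyl_O)) {
    xb <- detect_halogen_bonds(lig_xyz, ligand,
                               pxyz[prot$carbonyl_O, , drop = FALSE],
                               criteria, oxygen_labels = prot$carbonyl_O)
    if (nrow(xb)) {
      j <- as.integer(xb$oxygen)
      xb_rows <- data.frame(moiety = "bromophenyl", residue = at$resno[j],
                            chain = at$chain[j],
                            distance_nm = xb$distance_nm,
                            angle_deg = xb$angle_deg)
    }
  }

  hb_out <- if (length(hb_rows)) do.call(rbind, hb_rows) else
    data.frame(moiety = character(0), residue = integer(0),
               chain = character(0), partner_role = character(0),
               distance_nm = numeric(0), angle_deg = numeric(0),
               energy_kJmol = numeric(0))
  xb_out <- if (!is.null(xb_rows)) xb_rows else
    data.frame(moiety = character(0), residue = integer(0),
               chain = character(0), distance_nm = numeric(0),
               angle_deg = numeric(0))
  list(hb = hb_out, xb = xb_out)
}

#' Contact-probability map over an ensemble
#'
#' For the chosen contact definition, the per-residue contact indicator
#' is averaged over the frames of each trajectory, then over
#' trajectories (so every independent trajectory has equal weight).
#' Residue identity is the residue number; a residue is in contact in a
#' frame if any of its copies in the included layers is. Edge layers
#' are excluded when the criteria say so.
#'
#' @param ensemble ligand-atom [trajectory_ensemble()], already trimmed
#'   with [discard_equilibration()].
#' @param ligand a [ligand_topology()].
#' @param model a layered [fibril_model()].
#' @param definition one of `"heavy"`, `"nitrogen_backbone"`, `"hb"`,
#'   `"xb"`.
#' @param criteria a [contact_criteria()].
#' @param polar a [polar_bond_criteria()] (used for `"hb"`/`"xb"`).
#' @return data.frame `(residue, probability, sem, n_frames)` of class
#'   `contact_map`.
#' @export
contact_probabilities <- function(ensemble, ligand, model,
                                  definition = c("heavy",
                                                 "nitrogen_backbone",
                                                 "hb", "xb"),
                                  criteria = contact_criteria(),
                                  polar = polar_bond_criteria()) {
  definition <- match.arg(definition)
  if (sum(n_frames(ensemble)) == 0L) stop("no frames to analyze")
  at <- model$atoms
  keep <- rep(TRUE, nrow(at))
  if (criteria$exclude_edge_layers && !is.na(model$layer_count) &&
      model$layer_count > 2L) {
    keep <- at$layer > 0L & at$layer < model$layer_count - 1L
  }
  residues <- sort(unique(at$resno[keep]))
  pxyz <- .coords(at)
  heavy_p <- .heavy(at) & keep
  role <- .backbone_role(at$atom_name)
  nb_p <- keep & role %in% c("N", "C", if (criteria$include_ca) "CA")
  lig_heavy <- .heavy(ligand$atoms)
  nidx <- ligand_group_idx(ligand, "pyrazole_N")

  per_traj <- matrix(NA_real_, length(residues),
                     length(ensemble$trajectories))
  for (tr in seq_along(ensemble$trajectories)) {
    co <- ensemble$trajectories[[tr]]$coords
    nf <- dim(co)[1]
    hits <- matrix(FALSE, length(residues), nf)
    for (f in seq_len(nf)) {
      fr <- co[f, , , drop = TRUE]
      if (is.null(dim(fr))) fr <- matrix(fr, ncol = 3)
      res_hit <- switch(
        definition,
        heavy = {
          d2 <- .cross_dist2(fr[lig_heavy, , drop = FALSE],
                             pxyz[heavy_p, , drop = FALSE])
          cm <- apply(d2 <= criteria$heavy_cutoff^2, 2, any)
          residues %in% unique(at$resno[heavy_p][cm])
        },
        nitrogen_backbone = {
          d2 <- .cross_dist2(fr[nidx, , drop = FALSE],
                             pxyz[nb_p, , drop = FALSE])
          cm <- apply(d2 <= criteria$nitrogen_backbone_cutoff^2, 2, any)
          residues %in% unique(at$resno[nb_p][cm])
        },
        hb = {
          pb <- ligand_polar_bonds(fr, ligand, model, polar,
                                   criteria$exclude_edge_layers)
          residues %in% unique(pb$hb$residue)
        },
        xb = {
          pb <- ligand_polar_bonds(fr, ligand, model, polar,
                                   criteria$exclude_edge_layers)
          residues %in% unique(pb$xb$residue)
        })
      hits[, f] <- res_hit
    }
    per_traj[, tr] <- rowMeans(hits)
  }
  out <- data.frame(
    residue = residues,
    probability = rowMeans(per_traj),
    sem = apply(per_traj, 1, .sem),
    n_frames = sum(n_frames(ensemble)))
  class(out) <- c("contact_map", "data.frame")
  out
}
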