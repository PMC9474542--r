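#' Ligand topology: named atom groups of a cavity-binding compound
#'
#' The analyses address ligands of the 3,5-diaryl-pyrazole class: a
#' central pyrazole ring (two ring nitrogens, one carrying the polar
#' N-H), a benzodioxole ring with its two dioxole oxygens, and a
#' halogenated phenyl ring whose halogen can form halogen bonds with
#' backbone carbonyls. The topology names these groups so contact,
#' hydrogen-bond and halogen-bond detection can address them.
#'
#' @param atoms data.frame with columns `name` and `element` (one row
#'   per atom; hydrogens allowed).
#' @param groups named list of character vectors of atom names with
#'   entries `pyrazole_ring`, `pyrazole_N` (2 atoms),
#'   `benzodioxole_ring`, `benzodioxole_O` (2 atoms),
#'   `bromophenyl_ring`, `halogen` (1 atom) and
#'   `halogen_bonded_carbon` (1 atom).
#' @param ref_coords optional `n_atoms x 3` matrix of reference
#'   coordinates in nm (rigid-body geometry used by the synthetic
#'   trajectory generator).
#' @return object of class `ligand_topology` with elements `atoms`,
#'   `groups`, `n_heavy` and (optionally) `ref_coords`.
#' @seealso [anle138b_topology()], [read_ligand_topology()]
#' @export
ligand_topology <- function(atoms, groups, ref_coords = NULL) {
  stopifnot(is.data.frame(atoms), all(c("name", "element") %in% names(atoms)))
  if (anyDuplicated(atoms$name)) stop("duplicate atom names in ligand topology")
  need <- c("pyrazole_ring", "pyrazole_N", "benzodioxole_ring",
            "benzodioxole_O", "bromophenyl_ring", "halogen",
            "halogen_bonded_carbon")
  miss <- setdiff(need, names(groups))
  if (length(miss)) stop("missing group(s): ", paste(miss, collapse = ", "))
  for (g in need) {
    unknown <- setdiff(groups[[g]], atoms$name)
    if (length(unknown)) {
      stop("group ", g, " references unknown atom(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  if (length(groups$pyrazole_N) != 2L) stop("pyrazole_N must have 2 atoms")
  if (length(groups$benzodioxole_O) != 2L) stop("benzodioxole_O must have 2 atoms")
  if (length(groups$halogen) != 1L) stop("halogen must have exactly 1 atom")
  if (length(groups$halogen_bonded_carbon) != 1L) {
    stop("halogen_bonded_carbon must have exactly 1 atom")
  }
  rings <- c(groups$pyrazole_ring, groups$benzodioxole_ring, groups$bromophenyl_ring)
  if (groups$halogen %in% rings) stop("halogen atom cannot be a ring member")
  if (!is.null(ref_coords)) {
    ref_coords <- as.matrix(ref_coords)
    if (nrow(ref_coords) != nrow(atoms) || ncol(ref_coords) != 3L) {
      stop("ref_coords must be n_atoms x 3")
    }
  }
  structure(
    list(atoms = atoms, groups = groups,
         n_heavy = sum(toupper(atoms$element) != "H"),
         ref_coords = ref_coords),
    class = "ligand_topology"
  )
}

#' @export
print.ligand_topology <- function(x, ...) {
  cat("ligand_topology:", nrow(x$atoms), "atoms (", x$n_heavy, "heavy )\n")
  for (g in names(x$groups)) {
    cat(" ", g, ":", paste(x$groups[[g]], collapse = " "), "\n")
  }
  invisible(x)
}

#' Indices of a named ligand group in the topology atom order
#' @param ligand a [ligand_topology()].
#' @param group group name.
#' @return integer atom indices.
#' @export
ligand_group_idx <- function(ligand, group) {
  match(ligand$groups[[group]], ligand$atoms$name)
}

#' Built-in topology for anle138b
#'
#' 3-(1,3-benzodioxol-5-yl)-5-(3-bromophenyl)-1H-pyrazole: 21 heavy atoms
#' (16 C, 2 N, 2 O, 1 Br) plus the polar pyrazole N-H hydrogen. A planar
#' idealized geometry (regular rings, standard bond lengths) is attached
#' as `ref_coords` for use as a rigid body by [simulate_hopping()];
#' it is an idealization, not an experimental conformer.
#'
#' @return a [ligand_topology()].
#' @export
anle138b_topology <- function() {
  deg <- pi / 180
  # pyrazole ring: regular pentagon, bond 0.137 nm
  r5 <- 0.137 / (2 * sin(36 * deg))
  ang5 <- c(N1 = 234, N2 = 306, C3 = 18, C4 = 90, C5 = 162) * deg
  pent <- cbind(r5 * cos(ang5), r5 * sin(ang5), 0)
  rownames(pent) <- names(ang5)
  hn1 <- pent["N1", ] + c(cos(234 * deg), sin(234 * deg), 0) * 0.101

  hexagon <- function(center, radius = 0.139, phase = 0) {
    a <- (phase + (0:5) * 60) * deg
    cbind(center[1] + radius * cos(a), center[2] + radius * sin(a), 0)
  }
  # benzodioxole off C3 (+x side): ipso carbon CB1 faces the pyrazole
  u3 <- .unit(pent["C3", ])
  cenB <- pent["C3", ] + u3 * (0.148 + 0.139)
  phaseB <- atan2(-u3[2], -u3[1]) / deg
  hexB <- hexagon(cenB, phase = phaseB)       # CB1 ipso .. CB4 para
  o1 <- cenB + (hexB[4, ] - cenB) * (0.139 + 0.136) / 0.139 +
    c(-u3[2], u3[1], 0) * 0.06
  o2 <- cenB + (hexB[5, ] - cenB) * (0.139 + 0.136) / 0.139 +
    c(u3[2], -u3[1], 0) * 0.06
  cm <- cenB + u3 * (0.139 + 0.22)            # methylenedioxy carbon

  # bromophenyl off C5 (-x side); Br on the meta carbon CP3, bond radial
  u5 <- .unit(pent["C5", ])
  cenP <- pent["C5", ] + u5 * (0.148 + 0.139)
  phaseP <- atan2(-u5[2], -u5[1]) / deg
  hexP <- hexagon(cenP, phase = phaseP)
  br <- cenP + (hexP[3, ] - cenP) * (0.139 + 0.19) / 0.139

  atoms <- data.frame(
    name = c("N1", "N2", "C3", "C4", "C5", "HN1",
             paste0("CB", 1:6), "O1", "O2", "CM",
             paste0("CP", 1:6), "BR"),
    element = c("N", "N", "C", "C", "C", "H",
                rep("C", 6), "O", "O", "C",
                rep("C", 6), "Br"),
    stringsAsFactors = FALSE
  )
  coords <- rbind(pent["N1", ], pent["N2", ], pent["C3", ], pent["C4", ],
                  pent["C5", ], hn1, hexB, o1, o2, cm, hexP, br)
  rownames(coords) <- atoms$name
  groups <- list(
    pyrazole_ring = c("N1", "N2", "C3", "C4", "C5"),
    pyrazole_N = c("N1", "N2"),
    benzodioxole_ring = paste0("CB", 1:6),
    benzodioxole_O = c("O1", "O2"),
    bromophenyl_ring = paste0("CP", 1:6),
    halogen = "BR",
    halogen_bonded_carbon = "CP3"
  )
  ligand_topology(atoms, groups, ref_coords = coords)
}

#' Read a ligand topology from a YAML config
#'
#' The config lists `atoms` (name/element pairs) and `groups` (group
#' name to atom-name list); an optional `coords_nm` block carries
#' reference coordinates.
#'
#' @param path YAML file path.
#' @return a [ligand_topology()].
#' @export
read_ligand_topology <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$atoms) || is.null(cfg$groups)) {
    stop("ligand topology config needs 'atoms' and 'groups' blocks")
  }
  atoms <- data.frame(
    name = vapply(cfg$atoms, `[[`, character(1), "name"),
    element = vapply(cfg$atoms, `[[`, character(1), "element"),
    stringsAsFactors = FALSE
  )
  ref <- NULL
  if (!is.null(cfg$coords_nm)) {
    ref <- do.call(rbind, lapply(cfg$coords_nm, as.numeric))
  }
  ligand_topology(atoms, lapply(cfg$groups, unlist), ref_coords = ref)
}

#' Write a ligand topology to a YAML config
#' @param ligand a [ligand_topology()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ligand_topology <- function(ligand, path) {
  cfg <- list(
    atoms = lapply(seq_len(nrow(ligand$atoms)), function(i) {
      list(name = ligand$atoms$name[i], element = ligand$atoms$element[i])
    }),
    groups = lapply(ligand$groups, as.list)
  )
  if (!is.null(ligand$ref_coords)) {
    cfg$coords_nm <- lapply(seq_len(nrow(ligand$ref_coords)), function(i) {
      as.numeric(ligand$ref_coords[i, ])
    })
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}
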