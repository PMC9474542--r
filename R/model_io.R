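#' Fibril structure container
#'
#' A `fibril_model` holds the atoms of a protofilament model together with
#' the bookkeeping the downstream analyses need: residue numbers taken
#' verbatim from the input, a layer index per atom (one layer per stacked
#' cross-beta rung, assigned by [assign_layers()]), and coordinates in nm.
#'
#' @param atoms data.frame with columns `atom_id`, `atom_name`, `element`,
#'   `resno` (integer residue number), `chain`, `layer` (integer layer
#'   index or `NA` before assignment), and `x`, `y`, `z` in nm.
#' @param layer_count integer number of layers, or `NA` before assignment.
#'
#' @return An object of class `fibril_model`: a list with elements
#'   `atoms`, `layer_count` and `residue_range` (inclusive range of
#'   residue numbers present).
#' @seealso [read_structure()], [assign_layers()], [build_toy_fibril()]
#' @export
fibril_model <- function(atoms, layer_count = NA_integer_) {
  need <- c("atom_id", "atom_name", "element", "resno", "chain",
            "layer", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) stop("no atoms")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates")
  }
  atoms$resno <- as.integer(atoms$resno)
  if (!is.na(layer_count)) {
    lay <- atoms$layer
    if (anyNA(lay) || any(lay < 0L | lay >= layer_count)) {
      stop("layer indices must lie in [0, layer_count)")
    }
  }
  structure(
    list(atoms = atoms,
         layer_count = as.integer(layer_count),
         residue_range = range(atoms$resno)),
    class = "fibril_model"
  )
}

#' @export
print.fibril_model <- function(x, ...) {
  cat("fibril_model:", nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$resno))), "residues",
      sprintf("(numbering %d-%d)", x$residue_range[1], x$residue_range[2]),
      "\n")
  if (!is.na(x$layer_count)) {
    cat("  layers: 0 -", x$layer_count - 1L, "\n")
  } else {
    cat("  layers: unassigned\n")
  }
  invisible(x)
}

# Backbone role of an atom by its PDB name; "" for sidechain atoms.
.backbone_role <- function(atom_name) {
  out <- rep("", length(atom_name))
  out[atom_name %in% c("N")] <- "N"
  out[atom_name %in% c("H", "HN", "H1")] <- "H"
  out[atom_name %in% c("CA")] <- "CA"
  out[atom_name %in% c("C")] <- "C"
  out[atom_name %in% c("O", "OXT")] <- "O"
  out
}

.heavy <- function(atoms) toupper(atoms$element) != "H"

# Matrix of coordinates (nm) for a fibril_model or atoms data.frame.
.coords <- function(x) {
  atoms <- if (inherits(x, "fibril_model")) x$atoms else x
  as.matrix(atoms[, c("x", "y", "z")])
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM/HETATM records with [bio3d::read.pdb()] and converts
#' coordinates from Angstrom to nm. Residue numbering is taken verbatim
#' from the file; layer indices are left unassigned (see
#' [assign_layers()]).
#'
#' @param pdb_source path to a PDB file.
#' @return A [fibril_model()] with `layer` set to `NA`.
#' @export
read_structure <- function(pdb_source) {
  if (!file.exists(pdb_source)) stop("file not found: ", pdb_source)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(pdb_source, multi = FALSE)),
    error = function(e) stop("malformed PDB '", pdb_source, "': ",
                             conditionMessage(e))
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop("no atoms in ", pdb_source)
  element <- at$elesy
  if (is.null(element) || all(is.na(element)) || all(element == "")) {
    element <- substr(trimws(at$elety), 1, 1)
  }
  atoms <- data.frame(
    atom_id = at$eleno,
    atom_name = trimws(at$elety),
    element = trimws(element),
    resno = at$resno,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    layer = NA_integer_,
    x = at$x / 10, y = at$y / 10, z = at$z / 10,
    stringsAsFactors = FALSE
  )
  fibril_model(atoms)
}

#' Write a fibril model to a PDB file
#'
#' Coordinates are converted from nm back to Angstrom. Residue names are
#' written as `GLY` placeholders unless the model carries a `resid`
#' column.
#'
#' @param model a [fibril_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  at <- model$atoms
  resid <- if ("resid" %in% names(at)) at$resid else rep("GLY", nrow(at))
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(.coords(at))) * 10,
    resno = at$resno,
    resid = resid,
    eleno = at$atom_id,
    elety = at$atom_name,
    chain = at$chain,
    elesy = at$element
  )
  invisible(path)
}

#' Assign stacked-layer indices to a fibril model
#'
#' Each cross-beta rung (one beta-strand copy) of a protofilament is one
#' layer. The mapping is given either per chain (the common case: one
#' chain per rung) or as explicit residue blocks. After assignment,
#' layers are renumbered 0..(L-1) by increasing centroid position along
#' the stack's long axis (first principal component of the layer
#' centroids), so `layer_index` is always monotone along the axis
#' regardless of file order.
#'
#' @param model a [fibril_model()].
#' @param layer_spec `"chain"` (default) to make each chain one layer, or
#'   a list of integer residue-number vectors, one element per layer,
#'   which must partition all residues.
#' @return The model with `layer` filled in and `layer_count` set.
#' @export
assign_layers <- function(model, layer_spec = "chain") {
  at <- model$atoms
  if (identical(layer_spec, "chain")) {
    fac <- factor(at$chain)
    raw <- as.integer(fac) - 1L
  } else if (is.list(layer_spec)) {
    raw <- rep(NA_integer_, nrow(at))
    for (k in seq_along(layer_spec)) {
      hit <- at$resno %in% layer_spec[[k]]
      dup <- hit & !is.na(raw)
      if (any(dup)) {
        stop("residue(s) assigned to more than one layer: ",
             paste(unique(at$resno[dup]), collapse = ", "))
      }
      raw[hit] <- k - 1L
    }
    if (anyNA(raw)) {
      stop("layer_spec does not cover residue(s): ",
           paste(unique(at$resno[is.na(raw)]), collapse = ", "))
    }
  } else {
    stop("layer_spec must be \"chain\" or a list of residue vectors")
  }
  n_lay <- length(unique(raw))
  if (n_lay < 1L) stop("no layers defined")

  # Order layers along the stack axis: project layer centroids on their
  # leading principal component, sign-fixed for determinism.
  cent <- t(vapply(sort(unique(raw)), function(k) {
    colMeans(.coords(at)[raw == k, , drop = FALSE])
  }, numeric(3)))
  if (n_lay > 1L) {
    pc <- stats::prcomp(cent, center = TRUE, scale. = FALSE)
    axis <- pc$rotation[, 1]
    if (axis[which.max(abs(axis))] < 0) axis <- -axis
    proj <- cent %*% axis
  } else {
    proj <- 0
  }
  new_index <- integer(n_lay)
  new_index[order(proj)] <- seq_len(n_lay) - 1L
  at$layer <- new_index[raw + 1L]
  fibril_model(at, layer_count = n_lay)
}

#' Centroid (nm) of every layer, ordered by layer index
#' @param model a layered [fibril_model()].
#' @return matrix `layer_count` x 3 of layer centroids.
#' @export
layer_centroids <- function(model) {
  if (is.na(model$layer_count)) stop("layers not assigned; see assign_layers()")
  t(vapply(0:(model$layer_count - 1L), function(k) {
    colMeans(.coords(model)[model$atoms$layer == k, , drop = FALSE])
  }, numeric(3)))
}

#' Read a per-residue NMR peak table from CSV
#'
#' Expected header: `residue,nucleus,shift_ppm,intensity` with nuclei in
#' HN, N, CA, CB. Duplicate (residue, nucleus) rows, unknown nuclei and
#' negative intensities are rejected.
#'
#' @param csv_source path to a CSV file.
#' @return A `peak_table` data.frame.
#' @export
read_peak_table <- function(csv_source) {
  tab <- utils::read.csv(csv_source, stringsAsFactors = FALSE)
  peak_table(tab)
}

#' Construct / validate a peak table
#' @param tab data.frame with columns `residue`, `nucleus`, `shift_ppm`,
#'   `intensity`.
#' @return the validated data.frame with class `peak_table`.
#' @export
peak_table <- function(tab) {
  need <- c("residue", "nucleus", "shift_ppm", "intensity")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("peak table missing columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(tab$nucleus), c("HN", "N", "CA", "CB"))
  if (length(bad)) stop("unknown nucleus value(s): ", paste(bad, collapse = ", "))
  if (any(tab$intensity < 0)) stop("negative intensities are not allowed")
  key <- paste(tab$residue, tab$nucleus)
  if (anyDuplicated(key)) {
    stop("duplicate (residue, nucleus) row(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  tab$residue <- as.integer(tab$residue)
  class(tab) <- c("peak_table", "data.frame")
  tab
}

#' Write a peak table to CSV
#' @param tab a `peak_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}
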