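# Synthetic-data generators: toy fibrils, Markov-jump ligand hopping
# trajectories with exact ground truth, Boltzmann-distributed insertion
# depths, and paired free/bound NMR peak tables.

#' Build a toy stacked-layer fibril with an axial channel
#'
#' Constructs an idealized cross-beta protofilament: `n_layers`
#' identical beta-strand rungs translated along +z at spacing `rise`.
#' Each rung carries `residues_per_layer` residues on a ring around the
#' z axis; every residue has N, H, CA, C, O backbone atoms and one CB
#' sidechain pseudo-atom. All backbone N-H vectors point along +z
#' (cross-beta hydrogen-bonding geometry) and every carbonyl oxygen is
#' placed at radius `cavity_radius`, so the backbone polar ladder lines
#' an axial channel as in glycine-rich amyloid cavities. The geometry is
#' deterministic; `seed` is recorded for provenance.
#'
#' @param n_layers number of rungs (>= 2).
#' @param residues_per_layer residues per rung.
#' @param rise axial spacing between rungs in nm (default 0.48 nm, the
#'   canonical cross-beta stacking distance).
#' @param cavity_radius radius (nm) of the channel lined by the
#'   carbonyl oxygens.
#' @param seed integer recorded in the model attributes.
#' @return a layered [fibril_model()].
#' @export
build_toy_fibril <- function(n_layers = 10L, residues_per_layer = 8L,
                             rise = 0.48, cavity_radius = 0.4, seed = 1L) {
  stopifnot(n_layers >= 2L, residues_per_layer >= 1L, rise > 0,
            cavity_radius > 0)
  ring_r <- cavity_radius + 0.25
  theta <- 2 * pi * (seq_len(residues_per_layer) - 1) / residues_per_layer
  rows <- vector("list", n_layers * residues_per_layer)
  chain_ids <- if (n_layers <= 26L) LETTERS[seq_len(n_layers)] else
    sprintf("%02d", seq_len(n_layers) - 1L)
  i <- 0L
  for (k in seq_len(n_layers) - 1L) {
    z <- k * rise
    for (j in seq_len(residues_per_layer)) {
      ct <- cos(theta[j]); st <- sin(theta[j])
      i <- i + 1L
      rows[[i]] <- data.frame(
        atom_name = c("N", "H", "CA", "C", "O", "CB"),
        element = c("N", "H", "C", "C", "O", "C"),
        resno = j,
        chain = chain_ids[k + 1L],
        layer = k,
        x = c(ring_r * ct, ring_r * ct, (ring_r + 0.15) * ct,
              (ring_r + 0.05) * ct, cavity_radius * ct, (ring_r + 0.30) * ct),
        y = c(ring_r * st, ring_r * st, (ring_r + 0.15) * st,
              (ring_r + 0.05) * st, cavity_radius * st, (ring_r + 0.30) * st),
        z = c(z, z + 0.102, z + 0.05, z + 0.10, z + 0.10, z + 0.05),
        stringsAsFactors = FALSE
      )
    }
  }
  atoms <- do.call(rbind, rows)
  atoms$atom_id <- seq_len(nrow(atoms))
  model <- fibril_model(atoms, layer_count = n_layers)
  attr(model, "seed") <- as.integer(seed)
  attr(model, "rise") <- rise
  model
}

#' Specification of a Markov-jump hopping trajectory
#'
#' @param n_sites number of discrete cavity sites (one per rung).
#' @param site_spacing distance between neighboring sites in nm.
#' @param rate_up,rate_down jump rates to the next/previous site, 1/ns.
#' @param jitter_sigma per-coordinate Gaussian thermal jitter, nm.
#' @param n_frames frames per trajectory.
#' @param frame_interval sampling interval, ns.
#' @param x0 insertion depth of site 0 measured from the tip layer, nm.
#' @param n_trajectories number of independent trajectories.
#' @param initial_site starting site index (default middle site).
#' @param seed RNG seed (mandatory for reproducibility).
#' @return object of class `hopping_spec`.
#' @export
hopping_spec <- function(n_sites, site_spacing = 0.48, rate_up = 0.5,
                         rate_down = 0.5, jitter_sigma = 0.05,
                         n_frames = 1000L, frame_interval = 0.1,
                         x0 = site_spacing,
                         n_trajectories = 1L,
                         initial_site = (n_sites - 1L) %/% 2L,
                         seed = 1L) {
  stopifnot(n_sites >= 1L, site_spacing > 0, rate_up >= 0, rate_down >= 0,
            jitter_sigma >= 0, n_frames >= 1L, frame_interval > 0,
            n_trajectories >= 1L,
            initial_site >= 0L, initial_site < n_sites)
  structure(list(n_sites = as.integer(n_sites), site_spacing = site_spacing,
                 rate_up = rate_up, rate_down = rate_down,
                 jitter_sigma = jitter_sigma, n_frames = as.integer(n_frames),
                 frame_interval = frame_interval, x0 = x0,
                 n_trajectories = as.integer(n_trajectories),
                 initial_site = as.integer(initial_site),
                 seed = as.integer(seed)),
            class = "hopping_spec")
}

# Gillespie sampling of a birth-death chain with reflecting ends.
# Returns jump times (ns) and the state sequence (states[1] before any
# jump, states[k+1] after the k-th jump).
.gillespie_chain <- function(spec, t_total) {
  s <- spec$initial_site
  t <- 0
  jump_times <- numeric(0)
  states <- s
  repeat {
    # reflecting ends: the outward rate is simply absent at the edge
    # sites, which keeps the symmetric-rate stationary distribution
    # exactly uniform (detailed balance); edge dwells are accordingly
    # longer, so kinetics tests should use enough interior sites
    ku <- if (s < spec$n_sites - 1L) spec$rate_up else 0
    kd <- if (s > 0L) spec$rate_down else 0
    ktot <- ku + kd
    if (ktot <= 0) break
    t <- t + stats::rexp(1, ktot)
    if (t >= t_total) break
    s <- if (stats::runif(1) < ku / ktot) s + 1L else s - 1L
    jump_times <- c(jump_times, t)
    states <- c(states, s)
  }
  list(jump_times = jump_times, states = states)
}

#' Simulate discrete ligand hopping along a fibril cavity
#'
#' The ligand's pyrazole-ring center performs a continuous-time Markov
#' jump process over `n_sites` discrete sites spaced `site_spacing`
#' apart along the protofilament axis (reflecting boundaries at the end
#' sites), sampled by the Gillespie algorithm. The state path is
#' discretized at `frame_interval` and isotropic Gaussian jitter is
#' added to the rigid-body position after discretization, so the
#' returned ground-truth dwell events are exact by construction.
#'
#' @param spec a [hopping_spec()].
#' @param ligand a [ligand_topology()] carrying `ref_coords`.
#' @param fibril a layered [fibril_model()]; sites run from its tip
#'   (layer 0) centroid along the layer-stacking axis.
#' @return list with `ensemble` (ligand-atom [trajectory_ensemble()]),
#'   `events` (ground-truth [dwell_event_set()]), `sites` (list of
#'   per-frame site index vectors) and `spec`.
#' @export
simulate_hopping <- function(spec, ligand, fibril) {
  stopifnot(inherits(spec, "hopping_spec"),
            inherits(ligand, "ligand_topology"),
            inherits(fibril, "fibril_model"))
  if (is.null(ligand$ref_coords)) stop("ligand topology has no ref_coords")
  cents <- layer_centroids(fibril)
  axis <- if (nrow(cents) > 1L) .unit(cents[nrow(cents), ] - cents[1, ]) else c(0, 0, 1)
  tip <- cents[1, ]
  extent <- .vnorm(cents[nrow(cents), ] - cents[1, ])
  max_depth <- spec$x0 + (spec$n_sites - 1L) * spec$site_spacing
  if (max_depth > extent + spec$site_spacing) {
    stop("hopping sites (max depth ", round(max_depth, 3),
         " nm) do not fit inside the fibril extent (", round(extent, 3), " nm)")
  }
  mass <- .element_mass(ligand$atoms$element)
  pyr <- ligand_group_idx(ligand, "pyrazole_ring")
  ref <- sweep(ligand$ref_coords, 2,
               .com(ligand$ref_coords[pyr, , drop = FALSE], mass[pyr]))
  t_total <- spec$n_frames * spec$frame_interval
  frame_t <- (seq_len(spec$n_frames) - 1) * spec$frame_interval

  set.seed(spec$seed)
  trajs <- list(); sites_out <- list(); ev_rows <- list()
  for (tr in seq_len(spec$n_trajectories)) {
    ch <- .gillespie_chain(spec, t_total)
    # per-frame site: index of last jump at or before each frame time
    site <- ch$states[findInterval(frame_t, ch$jump_times) + 1L]
    # exact ground-truth dwell events
    bounds <- c(0, ch$jump_times, t_total)
    durs <- diff(bounds)
    keep <- durs > 0
    st <- ch$states[seq_along(durs)][keep]
    starts <- bounds[-length(bounds)][keep]
    durs <- durs[keep]
    cens <- seq_along(durs) %in% c(1L, length(durs))
    ev_rows[[tr]] <- data.frame(trajectory = tr, site = st,
                                start_ns = starts, duration_ns = durs,
                                censored = cens)
    depth <- spec$x0 + site * spec$site_spacing
    coords <- array(NA_real_, c(spec$n_frames, nrow(ref), 3))
    jit <- matrix(stats::rnorm(3L * spec$n_frames, sd = spec$jitter_sigma),
                  ncol = 3)
    for (f in seq_len(spec$n_frames)) {
      pos <- tip + axis * depth[f] + jit[f, ]
      coords[f, , ] <- sweep(ref, 2, pos, "+")
    }
    trajs[[tr]] <- list(times = frame_t, coords = coords)
    sites_out[[tr]] <- site
  }
  ens <- trajectory_ensemble(trajs, frame_interval = spec$frame_interval,
                             atom_names = ligand$atoms$name,
                             elements = ligand$atoms$element)
  events <- dwell_event_set(do.call(rbind, ev_rows),
                            site_spacing = spec$site_spacing)
  list(ensemble = ens, events = events, sites = sites_out, spec = spec)
}

#' Piecewise-linear potential specification
#'
#' @param x breakpoint positions, nm, strictly increasing.
#' @param G potential values at the breakpoints, kJ/mol; linear in
#'   between.
#' @param temperature temperature in K (default 300).
#' @return object of class `potential_spec`.
#' @export
potential_spec <- function(x, G, temperature = 300) {
  stopifnot(length(x) == length(G), length(x) >= 2L,
            all(diff(x) > 0), all(is.finite(G)), temperature > 0)
  structure(list(x = x, G = G, temperature = temperature),
            class = "potential_spec")
}

#' Gas constant times temperature in kJ/mol
#' @param temperature temperature in K.
#' @return RT in kJ/mol (8.314 J/(mol K) x T / 1000).
#' @export
rt_kjmol <- function(temperature = 300) 8.314462618e-3 * temperature

#' Sample insertion depths from a Boltzmann distribution
#'
#' Draws `n` positions with density proportional to `exp(-G(x)/RT)` on
#' the breakpoint domain of a piecewise-linear potential, by inverse
#' transform sampling on a fine grid.
#'
#' @param spec a [potential_spec()].
#' @param n number of samples (>= 1).
#' @param seed RNG seed.
#' @param grid_n grid resolution for the inverse CDF.
#' @return numeric vector of depths in nm.
#' @export
sample_boltzmann_depths <- function(spec, n, seed = 1L, grid_n = 4096L) {
  stopifnot(inherits(spec, "potential_spec"), n >= 1L)
  RT <- rt_kjmol(spec$temperature)
  xg <- seq(spec$x[1], spec$x[length(spec$x)], length.out = grid_n)
  Gg <- stats::approx(spec$x, spec$G, xout = xg)$y
  w <- exp(-(Gg - min(Gg)) / RT)
  dx <- diff(xg)
  cdf <- c(0, cumsum((w[-1] + w[-length(w)]) / 2 * dx))
  cdf <- cdf / cdf[length(cdf)]
  set.seed(seed)
  u <- stats::runif(n)
  # cdf is non-decreasing; collapse ties for interpolation
  ok <- c(TRUE, diff(cdf) > 0)
  stats::approx(cdf[ok], xg[ok], xout = u, rule = 2)$y
}

#' Specification of NMR perturbations for paired peak tables
#'
#' @param perturbed_residues integer residue numbers carrying the
#'   perturbation.
#' @param csp_ppm named numeric: true shift offsets (ppm) per nucleus in
#'   HN, N, CA, CB applied to the bound state of perturbed residues.
#' @param attenuation_factor bound/free intensity ratio on perturbed
#'   residues, in `[0, 1]`.
#' @param noise_sd per-nucleus shift noise sd in ppm (scalar or named).
#' @param intensity_noise_cv coefficient of variation of multiplicative
#'   lognormal intensity noise.
#' @param seed RNG seed.
#' @return object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(perturbed_residues,
                              csp_ppm = c(HN = 0.02, N = 0.2, CA = 0.1, CB = 0.08),
                              attenuation_factor = 0.5,
                              noise_sd = 0, intensity_noise_cv = 0,
                              seed = 1L) {
  nuclei <- c("HN", "N", "CA", "CB")
  if (is.null(names(csp_ppm))) names(csp_ppm) <- nuclei
  if (length(noise_sd) == 1L) noise_sd <- stats::setNames(rep(noise_sd, 4), nuclei)
  stopifnot(all(nuclei %in% names(csp_ppm)), all(nuclei %in% names(noise_sd)),
            attenuation_factor >= 0, attenuation_factor <= 1,
            all(noise_sd >= 0), intensity_noise_cv >= 0)
  structure(list(perturbed_residues = as.integer(perturbed_residues),
                 csp_ppm = csp_ppm[nuclei], attenuation_factor = attenuation_factor,
                 noise_sd = noise_sd[nuclei],
                 intensity_noise_cv = intensity_noise_cv,
                 seed = as.integer(seed)),
            class = "perturbation_spec")
}

#' Generate paired free/bound NMR peak tables with known ground truth
#'
#' The free table carries random but realistic backbone shifts (HN, N,
#' CA, CB) and lognormal intensities. The bound table equals the free
#' table with the configured shift offsets added and intensities
#' multiplied by `attenuation_factor` on perturbed residues, plus the
#' configured noise. Glycine-like residues omit their CB row.
#'
#' @param n_residues number of residues (numbered
#'   `residue_start ..`).
#' @param spec a [perturbation_spec()].
#' @param residue_start first residue number.
#' @param glycine_residues residues without a CB nucleus.
#' @return list with `free` and `bound` peak tables.
#' @export
generate_peak_tables <- function(n_residues, spec, residue_start = 1L,
                                 glycine_residues = integer(0)) {
  stopifnot(inherits(spec, "perturbation_spec"), n_residues >= 1L)
  residues <- seq.int(residue_start, length.out = n_residues)
  if (!all(spec$perturbed_residues %in% residues)) {
    stop("perturbed_residues outside residue range")
  }
  base_mean <- c(HN = 8.3, N = 119, CA = 58, CB = 35)
  base_sd <- c(HN = 0.4, N = 4, CA = 3, CB = 6)
  set.seed(spec$seed)
  rows <- list()
  for (res in residues) {
    nuclei <- c("HN", "N", "CA", if (!res %in% glycine_residues) "CB")
    for (nuc in nuclei) {
      rows[[length(rows) + 1L]] <- data.frame(
        residue = res, nucleus = nuc,
        shift_ppm = stats::rnorm(1, base_mean[nuc], base_sd[nuc]),
        intensity = 100 * exp(stats::rnorm(1, 0, 0.2))
      )
    }
  }
  free <- peak_table(do.call(rbind, rows))
  bound <- free
  pert <- bound$residue %in% spec$perturbed_residues
  bound$shift_ppm <- bound$shift_ppm +
    ifelse(pert, spec$csp_ppm[bound$nucleus], 0) +
    stats::rnorm(nrow(bound), 0, spec$noise_sd[bound$nucleus])
  mult <- rep(1, nrow(bound))
  if (spec$intensity_noise_cv > 0) {
    sdlog <- sqrt(log(1 + spec$intensity_noise_cv^2))
    mult <- exp(stats::rnorm(nrow(bound), -sdlog^2 / 2, sdlog))
  }
  bound$intensity <- bound$intensity *
    ifelse(pert, spec$attenuation_factor, 1) * mult
  list(free = free, bound = peak_table(bound))
}
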