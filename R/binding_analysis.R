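# Occupancy-derived free-energy profiles along the insertion depth and
# dwell-time kinetics of discrete intra-cavity hopping.

#' Dwell-event container
#'
#' @param events data.frame with columns `trajectory`, `site`,
#'   `start_ns`, `duration_ns`, `censored`.
#' @param site_spacing site spacing in nm.
#' @return the validated data.frame with class `dwell_event_set`.
#' @export
dwell_event_set <- function(events, site_spacing) {
  need <- c("trajectory", "site", "start_ns", "duration_ns", "censored")
  miss <- setdiff(need, names(events))
  if (length(miss)) stop("events missing columns: ", paste(miss, collapse = ", "))
  if (any(events$duration_ns <= 0)) stop("durations must be positive")
  for (tr in unique(events$trajectory)) {
    e <- events[events$trajectory == tr, ]
    e <- e[order(e$start_ns), ]
    if (nrow(e) > 1L) {
      ends <- e$start_ns[-nrow(e)] + e$duration_ns[-nrow(e)]
      if (any(e$start_ns[-1] < ends - 1e-9)) {
        stop("overlapping dwell events in trajectory ", tr)
      }
    }
  }
  attr(events, "site_spacing") <- site_spacing
  class(events) <- c("dwell_event_set", "data.frame")
  events
}

#' Relative free-energy profile from insertion-depth occupancy
#'
#' Depth samples from all trajectories are pooled and sorted into bins
#' of width `bin_width`; for each bin the occupancy probability
#' `p = count/total` is converted to a relative free energy
#' `G = -RT log(p)` (Boltzmann inversion at `temperature`). The profile
#' is shifted so its minimum over occupied bins is zero; empty bins are
#' masked (`NA`), not zero. The SEM per bin is across per-trajectory
#' profiles (each aligned to zero minimum).
#'
#' @param depths list of numeric depth vectors (nm), one per
#'   trajectory, or a data.frame with columns `trajectory` and `x_nm`
#'   (e.g. from [depth_series()]).
#' @param bin_width bin width in nm (default 0.05 nm, about a tenth of
#'   the cross-beta layer spacing).
#' @param temperature temperature in K (default 300).
#' @param range optional numeric length-2 domain; default spans the
#'   pooled samples.
#' @return data.frame `(bin_center_nm, G_kJmol, sem, count, masked)` of
#'   class `free_energy_profile`, with attributes `RT`, `temperature`,
#'   `bin_edges`.
#' @export
free_energy_profile <- function(depths, bin_width = 0.05,
                                temperature = 300, range = NULL) {
  stopifnot(bin_width > 0, temperature > 0)
  if (is.data.frame(depths)) {
    depths <- split(depths$x_nm, depths$trajectory)
  }
  if (!is.list(depths)) depths <- list(depths)
  pooled <- unlist(depths, use.names = FALSE)
  if (!length(pooled)) stop("no depth samples")
  if (is.null(range)) range <- c(min(pooled), max(pooled))
  lo <- floor(range[1] / bin_width) * bin_width
  hi <- ceiling(range[2] / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi, by = bin_width)
  if (edges[length(edges)] < hi - 1e-12) edges <- c(edges, hi)
  RT <- rt_kjmol(temperature)

  bin_G <- function(x) {
    cnt <- graphics::hist(x, breaks = edges, plot = FALSE,
                          include.lowest = TRUE, right = FALSE)$counts
    G <- ifelse(cnt > 0, -RT * log(cnt / sum(cnt)), NA_real_)
    G <- G - min(G, na.rm = TRUE)
    list(G = G, count = cnt)
  }
  pooled_bins <- bin_G(pooled)
  per_traj <- vapply(depths, function(x) bin_G(x)$G,
                     numeric(length(pooled_bins$count)))
  per_traj <- matrix(per_traj, ncol = length(depths))
  sem <- apply(per_traj, 1, .sem)

  out <- data.frame(
    bin_center_nm = (edges[-1] + edges[-length(edges)]) / 2,
    G_kJmol = pooled_bins$G,
    sem = sem,
    count = pooled_bins$count,
    masked = pooled_bins$count == 0L)
  class(out) <- c("free_energy_profile", "data.frame")
  attr(out, "RT") <- RT
  attr(out, "temperature") <- temperature
  attr(out, "bin_edges") <- edges
  out
}

#' @export
print.free_energy_profile <- function(x, ...) {
  occ <- !x$masked
  cat("free_energy_profile:", sum(occ), "occupied /", nrow(x), "bins,",
      "G range", round(min(x$G_kJmol[occ]), 2), "-",
      round(max(x$G_kJmol[occ]), 2), "kJ/mol",
      sprintf("(T = %g K)\n", attr(x, "temperature")))
  invisible(x)
}

#' @export
plot.free_energy_profile <- function(x, ...) {
  occ <- !x$masked
  graphics::plot(x$bin_center_nm[occ], x$G_kJmol[occ], type = "l",
                 xlab = "insertion depth x (nm)", ylab = "G(x) (kJ/mol)",
                 ...)
  if (any(is.finite(x$sem[occ]))) {
    up <- x$G_kJmol[occ] + x$sem[occ]
    dn <- x$G_kJmol[occ] - x$sem[occ]
    graphics::lines(x$bin_center_nm[occ], up, lty = 3)
    graphics::lines(x$bin_center_nm[occ], dn, lty = 3)
  }
  invisible(x)
}

#' Detect dwell events from an axial displacement series
#'
#' The cavity is divided into discrete sites spaced `site_spacing`
#' apart (site centers at `origin + k * site_spacing`). A hop to a new
#' site is committed only when the signal enters the core zone of the
#' new site (the inner `core_fraction` of its cell) and stays assigned
#' to that site for at least `min_residence_frames` consecutive frames
#' (hysteresis against jitter-induced recrossings). Dwell time is the
#' time between committed transitions; the first and last dwell of
#' each series are flagged censored.
#'
#' @param x numeric displacement series (nm), or a data.frame with
#'   columns `trajectory`, `time_ns`, `x_nm` (e.g. from
#'   [depth_series()]).
#' @param times frame times in ns (vector input only); default
#'   `0, dt, ...` with `dt = 0.1`.
#' @param site_spacing site spacing in nm (> 0).
#' @param origin depth of site 0, nm.
#' @param core_fraction inner fraction of a site cell that counts as
#'   its core (default 0.5).
#' @param min_residence_frames frames a new site must persist before a
#'   hop is committed (default 1).
#' @return a [dwell_event_set()].
#' @export
detect_dwell_events <- function(x, times = NULL, site_spacing,
                                origin = 0, core_fraction = 0.5,
                                min_residence_frames = 1L) {
  if (site_spacing <= 0) stop("site_spacing must be positive")
  stopifnot(core_fraction > 0, core_fraction <= 1,
            min_residence_frames >= 1L)
  if (is.data.frame(x)) {
    sp <- split(x, x$trajectory)
    ev <- lapply(names(sp), function(tr) {
      e <- detect_dwell_events(sp[[tr]]$x_nm, sp[[tr]]$time_ns,
                               site_spacing, origin, core_fraction,
                               min_residence_frames)
      e$trajectory <- as.integer(tr)
      e
    })
    return(dwell_event_set(do.call(rbind, ev), site_spacing))
  }
  n <- length(x)
  if (is.null(times)) times <- (seq_len(n) - 1) * 0.1
  if (n > 1L && any(diff(times) <= 0)) stop("times must be increasing")
  dt <- if (n > 1L) stats::median(diff(times)) else 0.1
  site <- as.integer(round((x - origin) / site_spacing))
  in_core <- abs(x - (origin + site * site_spacing)) <=
    core_fraction * site_spacing / 2

  current <- site[1]
  trans_t <- numeric(0); trans_site <- integer(0)
  cand <- NA_integer_; run <- 0L; cand_start <- NA_real_
  for (i in seq_len(n)) {
    if (site[i] == current || !in_core[i]) {
      # back at the committed site, or outside any core: no candidate
      cand <- NA_integer_; run <- 0L
      next
    }
    if (is.na(cand) || site[i] != cand) {
      cand <- site[i]; run <- 1L; cand_start <- times[i]
    } else {
      run <- run + 1L
    }
    if (run >= min_residence_frames) {
      trans_t <- c(trans_t, cand_start); trans_site <- c(trans_site, cand)
      current <- cand; cand <- NA_integer_; run <- 0L
    }
  }
  t_end <- times[n] + dt
  bounds <- c(times[1], trans_t, t_end)
  sites <- c(site[1], trans_site)
  durs <- diff(bounds)
  keep <- durs > 0
  ev <- data.frame(trajectory = 1L, site = sites[keep],
                   start_ns = bounds[-length(bounds)][keep],
                   duration_ns = durs[keep],
                   censored = seq_len(sum(keep)) %in% c(1L, sum(keep)))
  dwell_event_set(ev, site_spacing)
}

#' Summary statistics and cumulative histogram of dwell times
#'
#' @param events a [dwell_event_set()].
#' @param exclude_censored drop censored (first/last, incomplete)
#'   dwells (default TRUE; they bias the mean downward).
#' @param breaks number of histogram bins, or `"log"` for log-spaced
#'   bins (default), or an explicit break vector (ns).
#' @return list with `mean_ns`, `sem_ns` (`NA` for a single event),
#'   `n`, and `cumulative` (data.frame `t_ns, cum_count, cum_fraction`).
#' @export
dwell_time_summary <- function(events, exclude_censored = TRUE,
                               breaks = "log") {
  d <- if (exclude_censored) {
    events$duration_ns[!events$censored]
  } else {
    events$duration_ns
  }
  if (!length(d)) {
    stop("no uncensored dwell events; rerun with exclude_censored = FALSE ",
         "to include the censored dwells")
  }
  if (identical(breaks, "log")) {
    rng <- range(d)
    if (rng[1] == rng[2]) rng <- rng * c(0.5, 2)
    breaks <- exp(seq(log(rng[1] * 0.999), log(rng[2] * 1.001),
                      length.out = 21L))
  }
  h <- graphics::hist(d, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE)
  cum <- cumsum(h$counts)
  list(mean_ns = mean(d),
       sem_ns = .sem(d),
       n = length(d),
       cumulative = data.frame(t_ns = h$breaks[-1], cum_count = cum,
                               cum_fraction = cum / length(d)))
}
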