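# Per-residue chemical-shift perturbation and signal attenuation
# between matched free/bound NMR peak tables.

.NUCLEI <- c("HN", "N", "CA", "CB")

# Long-to-wide helper: matrix residues x nuclei of one peak column.
.peak_wide <- function(tab, col) {
  residues <- sort(unique(tab$residue))
  m <- matrix(NA_real_, length(residues), length(.NUCLEI),
              dimnames = list(residues, .NUCLEI))
  m[cbind(match(tab$residue, residues), match(tab$nucleus, .NUCLEI))] <-
    tab[[col]]
  m
}

#' Per-residue chemical-shift perturbation between two peak tables
#'
#' CSP per residue is the unweighted mean of the absolute shift
#' differences over the nuclei (HN, N, CA, CB) present in both tables.
#' Residues absent from either table, or with no shared nuclei, get a
#' missing value (with a warning for the shared-nucleus case).
#'
#' @param free,bound matched `peak_table`s (same residue numbering).
#' @return data.frame `(residue, csp_ppm, n_nuclei_used)` of class
#'   `perturbation_table`.
#' @export
csp_per_residue <- function(free, bound) {
  residues <- sort(union(free$residue, bound$residue))
  sf <- .peak_wide(free, "shift_ppm")
  sb <- .peak_wide(bound, "shift_ppm")
  out <- data.frame(residue = residues, csp_ppm = NA_real_,
                    n_nuclei_used = 0L)
  for (i in seq_along(residues)) {
    r <- as.character(residues[i])
    if (!(r %in% rownames(sf)) || !(r %in% rownames(sb))) next
    dd <- abs(sb[r, ] - sf[r, ])
    shared <- !is.na(dd)
    if (!any(shared)) {
      warning("residue ", r, ": no shared nuclei; CSP is missing")
      next
    }
    out$csp_ppm[i] <- mean(dd[shared])
    out$n_nuclei_used[i] <- sum(shared)
  }
  class(out) <- c("perturbation_table", "data.frame")
  out
}

#' Per-residue bound/free intensity ratio
#'
#' Ratios are formed per matched peak (same residue and nucleus) and
#' averaged over nuclei. A bound peak absent while the free peak exists
#' contributes a ratio of 0 (signal attenuated beyond detection); a
#' residue absent from the free table is missing. Free peaks with zero
#' intensity are skipped with a warning.
#'
#' @param free,bound matched `peak_table`s.
#' @return data.frame `(residue, intensity_ratio, n_nuclei_used)` of
#'   class `perturbation_table`.
#' @export
intensity_ratio <- function(free, bound) {
  residues <- sort(unique(free$residue))
  fi <- .peak_wide(free, "intensity")
  bi <- .peak_wide(bound, "intensity")
  out <- data.frame(residue = residues, intensity_ratio = NA_real_,
                    n_nuclei_used = 0L)
  for (i in seq_along(residues)) {
    r <- as.character(residues[i])
    f <- fi[r, ]
    b <- if (r %in% rownames(bi)) bi[r, ] else rep(NA_real_, length(.NUCLEI))
    have_free <- !is.na(f)
    if (!any(have_free)) next
    zero <- have_free & f == 0
    if (any(zero)) {
      warning("residue ", r, ": free intensity 0 for ",
              paste(.NUCLEI[zero], collapse = ", "), "; skipped")
      have_free <- have_free & !zero
      if (!any(have_free)) next
    }
    ratio <- ifelse(is.na(b[have_free]), 0, b[have_free] / f[have_free])
    out$intensity_ratio[i] <- mean(ratio)
    out$n_nuclei_used[i] <- sum(have_free)
  }
  class(out) <- c("perturbation_table", "data.frame")
  out
}

#' Missing-aware trailing moving average over residues
#'
#' The smoothed value at residue position `i` is the mean of the
#' defined values in the window `[i, i + window - 1]` (truncated at the
#' series end); windows with only missing values stay missing. With
#' `window = 1` the series is returned unchanged.
#'
#' @param series numeric vector ordered by residue (may contain `NA`).
#' @param window window length in residues (default 2).
#' @return numeric vector of the same length.
#' @export
moving_average <- function(series, window = 2L) {
  stopifnot(window >= 1L)
  n <- length(series)
  vapply(seq_len(n), function(i) {
    w <- series[i:min(n, i + window - 1L)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
}

#' Full perturbation table: CSP, intensity ratio and smoothed tracks
#'
#' Convenience wrapper combining [csp_per_residue()],
#' [intensity_ratio()] and [moving_average()].
#'
#' @param free,bound matched `peak_table`s.
#' @param window smoothing window in residues (default 2).
#' @return data.frame `(residue, csp_ppm, csp_smooth, intensity_ratio,
#'   ratio_smooth, n_nuclei_csp, n_nuclei_ratio)`.
#' @export
perturbation_table <- function(free, bound, window = 2L) {
  csp <- csp_per_residue(free, bound)
  rat <- intensity_ratio(free, bound)
  m <- merge(csp, rat, by = "residue", all = TRUE,
             suffixes = c("_csp", "_ratio"))
  m <- m[order(m$residue), ]
  out <- data.frame(
    residue = m$residue,
    csp_ppm = m$csp_ppm,
    csp_smooth = moving_average(m$csp_ppm, window),
    intensity_ratio = m$intensity_ratio,
    ratio_smooth = moving_average(m$intensity_ratio, window),
    n_nuclei_csp = m$n_nuclei_used_csp,
    n_nuclei_ratio = m$n_nuclei_used_ratio)
  class(out) <- c("perturbation_table", "data.frame")
  out
}
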