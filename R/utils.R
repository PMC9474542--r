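# Internal geometry and bookkeeping helpers shared across modules.

# Standard atomic masses (u) for mass-weighted centroids.
.ATOMIC_MASSES <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
  SE = 78.971
)

.element_mass <- function(element) {
  key <- toupper(element)
  m <- .ATOMIC_MASSES[key]
  if (anyNA(m)) {
    stop("unknown element(s): ", paste(unique(key[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

# Mass-weighted center of mass of an n x 3 coordinate matrix.
.com <- function(xyz, mass = NULL) {
  xyz <- rbind(xyz)
  if (is.null(mass)) mass <- rep(1, nrow(xyz))
  stopifnot(length(mass) == nrow(xyz), all(mass > 0))
  colSums(xyz * mass) / sum(mass)
}

.vnorm <- function(v) sqrt(sum(v^2))

.unit <- function(v) {
  n <- .vnorm(v)
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

# Angle (degrees) between two vectors, in [0, 180].
.angle_deg <- function(v1, v2) {
  ct <- sum(v1 * v2) / (.vnorm(v1) * .vnorm(v2))
  ct <- max(-1, min(1, ct))
  acos(ct) * 180 / pi
}

# Least-squares (Kabsch) superposition of `mobile` onto `ref` using the
# rows in `fit_idx`; returns the transformed full coordinate set.
.superpose <- function(mobile, ref, fit_idx = seq_len(nrow(mobile))) {
  p0 <- colMeans(mobile[fit_idx, , drop = FALSE])
  q0 <- colMeans(ref[fit_idx, , drop = FALSE])
  P <- sweep(mobile[fit_idx, , drop = FALSE], 2, p0)
  Q <- sweep(ref[fit_idx, , drop = FALSE], 2, q0)
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(sweep(mobile, 2, p0) %*% t(R), 2, q0, "+")
}

# Cell-list neighbor query: for each row of A, is any row of B within
# `cutoff` (inclusive)? Cells have edge length `cutoff`, so only the 27
# surrounding cells need inspection. Distances are compared as squared
# values with no tolerance so results are bit-identical to brute force.
.contact_query <- function(A, B, cutoff) {
  stopifnot(cutoff > 0)
  A <- rbind(A); B <- rbind(B)
  ixB <- floor(B / cutoff)
  keyB <- paste(ixB[, 1], ixB[, 2], ixB[, 3], sep = ",")
  cellmap <- split(seq_len(nrow(B)), keyB)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ixA <- floor(A / cutoff)
  c2 <- cutoff^2
  in_contact <- logical(nrow(A))
  for (i in seq_len(nrow(A))) {
    keys <- paste(ixA[i, 1] + offs[, 1], ixA[i, 2] + offs[, 2],
                  ixA[i, 3] + offs[, 3], sep = ",")
    cand <- unlist(cellmap[keys], use.names = FALSE)
    if (length(cand)) {
      d2 <- (B[cand, 1] - A[i, 1])^2 + (B[cand, 2] - A[i, 2])^2 +
        (B[cand, 3] - A[i, 3])^2
      in_contact[i] <- any(d2 <= c2)
    }
  }
  list(any = any(in_contact),
       n_in_contact = sum(in_contact),
       in_contact = in_contact)
}

.is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}

.sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}
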