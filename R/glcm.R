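#' Quantize a sub-band into discrete intensity levels
#'
#' Min–max linear binning into `L` equal-width bins: the minimum maps to
#' level 1, the maximum to level `L`. Wavelet detail coefficients are
#' signed and band-dependent in scale, so binning is applied per sub-band
#' independently. A constant input maps everywhere to level 1.
#'
#' @param x Numeric matrix (one sub-band).
#' @param L Number of levels (default 16).
#' @return Integer matrix with values in `1..L`.
#' @export
quantize <- function(x, L = 16) {
  stopifnot(L >= 2)
  x <- as.matrix(x)
  rng <- range(x)
  if (rng[1] == rng[2]) {
    q <- matrix(1L, nrow(x), ncol(x))
  } else {
    q <- floor((x - rng[1]) / (rng[2] - rng[1]) * L) + 1
    q[q > L] <- L
    storage.mode(q) <- "integer"
  }
  attr(q, "levels") <- as.integer(L)
  q
}

glcm_offsets <- function(delta, orientations) {
  switch(orientations,
    diagonal = list(c(-delta, -delta)),
    all = list(c(0, -delta), c(-delta, -delta), c(-delta, 0), c(-delta, delta)),
    stop("`orientations` must be 'diagonal' or 'all'", call. = FALSE)
  )
}

new_cooccurrence <- function(counts, delta, orientations) {
  L <- nrow(counts)
  n_pairs <- sum(counts)
  structure(
    list(counts = counts, n_pairs = n_pairs,
         p = if (n_pairs > 0) counts / n_pairs else counts,
         L = L, delta = delta, orientations = orientations),
    class = "cooccurrence_matrix"
  )
}

#' Gray-level co-occurrence matrix of a quantized grid
#'
#' Counts, for every ordered level pair `(i, j)`, the positions `(a, b)`
#' whose value is `i` and whose displaced neighbour at
#' `(a - delta, b - delta)` has value `j`. The single diagonal offset is
#' the default; `orientations = "all"` sums the four standard directions
#' (0, 45, 90, 135 degrees) at distance `delta` instead. Counts are
#' directional (not symmetrized).
#'
#' @param q Integer matrix with levels in `1..L` (see [quantize()]).
#' @param delta Displacement distance (default 1).
#' @param orientations `"diagonal"` (single offset) or `"all"` (four).
#' @param L Number of levels; taken from `attr(q, "levels")` or `max(q)`.
#' @return A `cooccurrence_matrix`: `counts` (L x L), `n_pairs`, the
#'   normalized probability matrix `p`, and the configuration.
#' @export
glcm <- function(q, delta = 1, orientations = c("diagonal", "all"), L = NULL) {
  orientations <- match.arg(orientations)
  q <- as.matrix(q)
  if (is.null(L)) L <- attr(q, "levels") %||% max(q)
  if (min(q) < 1 || max(q) > L) stop("levels must lie in 1..L", call. = FALSE)
  m <- nrow(q); n <- ncol(q)
  counts <- matrix(0, L, L)
  for (off in glcm_offsets(delta, orientations)) {
    da <- off[1]; db <- off[2]
    a <- seq_len(m); b <- seq_len(n)
    a <- a[a + da >= 1 & a + da <= m]
    b <- b[b + db >= 1 & b + db <= n]
    if (length(a) == 0 || length(b) == 0) next
    i <- q[a, b, drop = FALSE]
    j <- q[a + da, b + db, drop = FALSE]
    counts <- counts + matrix(tabulate((j - 1L) * L + i, nbins = L * L), L, L)
  }
  if (sum(counts) == 0) {
    warning("grid smaller than displacement: empty co-occurrence matrix",
            call. = FALSE)
  }
  new_cooccurrence(counts, delta, orientations)
}

#' @export
print.cooccurrence_matrix <- function(x, ...) {
  cat(sprintf("<cooccurrence_matrix: L=%d, delta=%d (%s), %d pairs>\n",
              x$L, x$delta, x$orientations, x$n_pairs))
  invisible(x)
}

#' Sum per-sub-band co-occurrence matrices into the WMCM
#'
#' The wavelet multi-sub-band co-occurrence matrix is the element-wise sum
#' of the co-occurrence matrices of the four wavelet sub-bands, pooling
#' second-order texture across frequency components.
#'
#' @param glcms List of `cooccurrence_matrix` objects sharing `L`.
#' @return A `cooccurrence_matrix` with summed counts.
#' @export
build_wmcm <- function(glcms) {
  Ls <- vapply(glcms, function(g) g$L, numeric(1))
  if (length(unique(Ls)) != 1) {
    stop("all co-occurrence matrices must share the same number of levels",
         call. = FALSE)
  }
  counts <- Reduce(`+`, lapply(glcms, function(g) g$counts))
  new_cooccurrence(counts, glcms[[1]]$delta, glcms[[1]]$orientations)
}
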