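# Small seeded fixtures shared across test files. Everything is generated
# in code; the cache avoids regenerating within one test run.

small_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_fixture(seed = 42, tile_size = 64,
                             n_positive = 10, n_negative = 30)
    }
    cache
  }
})

# Two well-separated Gaussian blobs in two features: the canonical
# linearly separable toy problem for classifier sanity checks.
make_blobs <- function(n = 200, sep = 6, seed = 7) {
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), each = n / 2)
    tibble::tibble(
      tile_id = sprintf("blob_%03d", seq_len(n)),
      label = y,
      f1 = stats::rnorm(n, mean = y * sep),
      f2 = stats::rnorm(n, mean = y * sep)
    )
  })
}

# Brute-force co-occurrence oracle: explicit double loop over positions,
# independent of the vectorized implementation.
glcm_brute <- function(q, delta = 1, L = max(q)) {
  counts <- matrix(0, L, L)
  for (a in seq_len(nrow(q))) {
    for (b in seq_len(ncol(q))) {
      a2 <- a - delta; b2 <- b - delta
      if (a2 >= 1 && b2 >= 1) {
        counts[q[a, b], q[a2, b2]] <- counts[q[a, b], q[a2, b2]] + 1
      }
    }
  }
  counts
}

# Rank-free AUC oracle: average over all positive/negative pairs.
auc_brute <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  mean(outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q)))
}

# Plain histogram equalization: direct CDF mapping over 256 levels.
hist_eq <- function(px) {
  h <- tabulate(px + 1L, nbins = 256)
  cdf <- cumsum(h) / length(px)
  matrix(as.integer(round(cdf[px + 1L] * 255)), nrow(px), ncol(px))
}
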