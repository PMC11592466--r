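#' Wavelet filter coefficients
#'
#' Orthonormal analysis filter pairs for the single-level separable 2-D
#' decomposition. `haar` is the default; `d4` (Daubechies, 4 taps) is
#' provided for experimentation. Both preserve total energy under the
#' periodic boundary handling used here.
#'
#' @param wavelet Filter name, `"haar"` or `"d4"`.
#' @return List with low-pass `h` and high-pass `g` coefficient vectors.
#' @export
wavelet_filters <- function(wavelet = "haar") {
  h <- switch(wavelet,
    haar = c(1, 1) / sqrt(2),
    d4 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
    stop(sprintf("unknown wavelet '%s'", wavelet), call. = FALSE)
  )
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)
  list(h = h, g = g)
}

# One analysis step along the rows of X (filters each column pair-wise,
# periodic extension, dyadic downsampling). Returns m/2 x n.
dwt_rows <- function(X, fl) {
  m <- nrow(X)
  ks <- seq(1L, m, by = 2L)
  low <- matrix(0, length(ks), ncol(X))
  high <- low
  for (i in seq_along(fl$h)) {
    idx <- ((ks + i - 2L) %% m) + 1L
    low <- low + fl$h[i] * X[idx, , drop = FALSE]
    high <- high + fl$g[i] * X[idx, , drop = FALSE]
  }
  list(low = low, high = high)
}

#' Single-level 2-D wavelet-packet decomposition into four sub-bands
#'
#' Separable filtering with dyadic downsampling splits the tile into the
#' four frequency sub-bands: `LL` (low-pass in both directions, the
#' approximation), `LH` (low-pass horizontally, high-pass vertically),
#' `HL` (high-pass horizontally, low-pass vertically) and `HH` (high-pass
#' in both, diagonal detail). Each sub-band has half the side lengths of
#' the input — 256x256 for a 512x512 tile. Odd dimensions are padded by
#' edge replication first.
#'
#' @param tile An [image_tile()] or a numeric matrix.
#' @param wavelet Filter name, see [wavelet_filters()].
#' @return A `subband_set`: list with matrices `LL`, `LH`, `HL`, `HH` and
#'   the `wavelet` name.
#' @examples
#' wpt_decompose(matrix(1, 2, 2))$LL  # [[2]] for the orthonormal Haar pair
#' @export
wpt_decompose <- function(tile, wavelet = "haar") {
  X <- if (is_image_tile(tile)) tile$pixels else as.matrix(tile)
  storage.mode(X) <- "double"
  if (nrow(X) %% 2 == 1) X <- rbind(X, X[nrow(X), ])
  if (ncol(X) %% 2 == 1) X <- cbind(X, X[, ncol(X)])
  fl <- wavelet_filters(wavelet)
  v <- dwt_rows(X, fl)                 # vertical (row) direction
  lo <- t(dwt_rows(t(v$low), fl)$low)  # then horizontal (column) direction
  hl <- t(dwt_rows(t(v$low), fl)$high)
  lh <- t(dwt_rows(t(v$high), fl)$low)
  hh <- t(dwt_rows(t(v$high), fl)$high)
  structure(list(LL = lo, LH = lh, HL = hl, HH = hh, wavelet = wavelet),
            class = "subband_set")
}

#' @export
print.subband_set <- function(x, ...) {
  cat(sprintf("<subband_set (%s): 4 bands of %dx%d>\n",
              x$wavelet, nrow(x$LL), ncol(x$LL)))
  invisible(x)
}
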