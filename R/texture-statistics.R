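#' The eleven co-occurrence texture statistics
#'
#' Computed on the normalized co-occurrence matrix `p(i, j)` with 1-based
#' levels `i, j = 1..L` (1-based levels guarantee no division by zero in
#' the level-ratio statistics):
#'
#' * `sgsda` — small gray level with small detail advantage,
#'   `sum p(i,j) / (i^2 j^2)`: mass concentrated at low level pairs.
#' * `sgbda` — small gray level with big detail advantage,
#'   `sum p(i,j) * j^2 / i^2`.
#' * `gla`, `dla` — gray-/detail-level averages, the means of the row and
#'   column marginal distributions.
#' * `glmse`, `dlmse` — the marginal variances about those means.
#' * `correlation` — standard co-occurrence correlation,
#'   `(sum i j p(i,j) - mu_a mu_b) / (sigma_a sigma_b)`; defined as 0 when
#'   either marginal is degenerate.
#' * `contrast` — `sum (i-j)^2 p(i,j)`.
#' * `energy` — `sum p(i,j)^2` (angular second moment).
#' * `entropy` — `-sum p log p`, natural logarithm, `0 log 0 = 0`.
#' * `homogeneity` — `sum p(i,j) / (1 + (i-j)^2)` by default; the
#'   `"abs"` form uses `1 + |i-j|` instead.
#'
#' @param cm A `cooccurrence_matrix` with `n_pairs > 0` (see [glcm()]).
#' @param homogeneity `"squared"` (default) or `"abs"` denominator form.
#' @return A one-row tibble with the eleven statistics, in the order
#'   sgsda, sgbda, gla, dla, glmse, dlmse, correlation, contrast, energy,
#'   entropy, homogeneity.
#' @export
texture_statistics <- function(cm, homogeneity = c("squared", "abs")) {
  homogeneity <- match.arg(homogeneity)
  stopifnot(inherits(cm, "cooccurrence_matrix"))
  if (cm$n_pairs == 0) stop("co-occurrence matrix has no pairs", call. = FALSE)
  p <- cm$p
  L <- cm$L
  i <- matrix(seq_len(L), L, L)        # row level
  j <- t(i)                            # column level
  theta_i <- rowSums(p)
  theta_j <- colSums(p)
  lev <- seq_len(L)
  gla <- sum(lev * theta_i)
  dla <- sum(lev * theta_j)
  glmse <- sum((lev - gla)^2 * theta_i)
  dlmse <- sum((lev - dla)^2 * theta_j)
  sd_a <- sqrt(glmse)
  sd_b <- sqrt(dlmse)
  corr <- if (sd_a > 0 && sd_b > 0) {
    (sum(i * j * p) - gla * dla) / (sd_a * sd_b)
  } else 0
  hden <- if (homogeneity == "squared") 1 + (i - j)^2 else 1 + abs(i - j)
  tibble::tibble(
    sgsda = sum(p / (i^2 * j^2)),
    sgbda = sum(p * j^2 / i^2),
    gla = gla, dla = dla, glmse = glmse, dlmse = dlmse,
    correlation = corr,
    contrast = sum((i - j)^2 * p),
    energy = sum(p^2),
    entropy = -sum(ifelse(p > 0, p * log(p), 0)),
    homogeneity = sum(p / hden)
  )
}

#' Weighted texture score
#'
#' Collapses the eleven statistics into one scalar with non-negative
#' weights that must sum to one (enforced to within 1e-9).
#'
#' @param stats One-row tibble from [texture_statistics()].
#' @param weights Numeric vector of 11 weights, in the statistic order of
#'   [texture_statistics()]. Default uniform `1/11` (no weighting scheme
#'   is singled out by the method; the score is exported alongside, not
#'   instead of, the individual statistics).
#' @return Scalar score.
#' @export
texture_score <- function(stats, weights = rep(1 / 11, 11)) {
  if (length(weights) != 11 || any(weights < 0)) {
    stop("`weights` must be 11 non-negative values", call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("texture weights must sum to 1", call. = FALSE)
  }
  sum(unlist(stats[1, seq_len(11)]) * weights)
}

#' Feature-extraction configuration
#'
#' @param wavelet Wavelet filter name (see [wavelet_filters()]).
#' @param levels Number of quantization levels `L` (default 16).
#' @param delta Co-occurrence displacement (default 1).
#' @param orientations `"diagonal"` or `"all"` (see [glcm()]).
#' @param weights Texture-score weights (see [texture_score()]).
#' @param homogeneity Homogeneity form (see [texture_statistics()]).
#' @return A `feature_config` list.
#' @export
feature_config <- function(wavelet = "haar", levels = 16, delta = 1,
                           orientations = "diagonal",
                           weights = rep(1 / 11, 11),
                           homogeneity = "squared") {
  structure(list(wavelet = wavelet, levels = as.integer(levels),
                 delta = as.integer(delta), orientations = orientations,
                 weights = weights, homogeneity = homogeneity),
            class = "feature_config")
}

#' Extract the texture feature vector of one tile
#'
#' The full feature pipeline for a (preprocessed) tile: single-level
#' wavelet decomposition into LL/LH/HL/HH, per-sub-band quantization into
#' `L` levels, a co-occurrence matrix per sub-band, their sum (the WMCM),
#' and the eleven statistics of the aggregate WMCM plus of each sub-band
#' matrix — 55 named features — together with the weighted texture score
#' of the aggregate statistics. Deterministic.
#'
#' @param tile An [image_tile()].
#' @param config A [feature_config()].
#' @return One-row tibble: `tile_id`, `label`, `tf_score`, then the 55
#'   features named `<band>_<statistic>` with band prefixes `wmcm`, `ll`,
#'   `lh`, `hl`, `hh`.
#' @export
extract_features <- function(tile, config = feature_config()) {
  stopifnot(is_image_tile(tile), inherits(config, "feature_config"))
  sb <- wpt_decompose(tile, config$wavelet)
  bands <- list(ll = sb$LL, lh = sb$LH, hl = sb$HL, hh = sb$HH)
  glcms <- lapply(bands, function(b) {
    glcm(quantize(b, config$levels), delta = config$delta,
         orientations = config$orientations, L = config$levels)
  })
  wmcm <- build_wmcm(glcms)
  all_stats <- c(list(wmcm = wmcm), glcms)
  blocks <- purrr::imap(all_stats, function(cm, band) {
    st <- texture_statistics(cm, homogeneity = config$homogeneity)
    stats::setNames(st, paste(band, names(st), sep = "_"))
  })
  tf <- texture_score(
    texture_statistics(wmcm, homogeneity = config$homogeneity),
    config$weights
  )
  dplyr::bind_cols(
    tibble::tibble(tile_id = tile$tile_id, label = tile$label, tf_score = tf),
    !!!unname(blocks)
  )
}

#' Extract features for a list of tiles
#'
#' @param tiles List of [image_tile()].
#' @inheritParams extract_features
#' @return Tibble with one row per tile (see [extract_features()]).
#' @export
extract_features_dataset <- function(tiles, config = feature_config()) {
  purrr::map_dfr(tiles, extract_features, config = config)
}

#' Names of the numeric feature columns in a feature table
#'
#' @param features Tibble from [extract_features_dataset()].
#' @return Character vector of the 55 `<band>_<statistic>` columns.
#' @export
feature_columns <- function(features) {
  setdiff(names(features),
          c("tile_id", "label", "tf_score", "provenance", "split"))
}
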