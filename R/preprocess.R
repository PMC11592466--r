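#' Blank ratio of a tile
#'
#' Fraction of pixels at or above a near-white threshold. Whole-slide tiles
#' dominated by glass background carry little tissue texture; the pipeline
#' discards tiles whose blank ratio exceeds 30%.
#'
#' @param tile An [image_tile()].
#' @param white_threshold Intensity at or above which a pixel counts as
#'   blank. Default 220, the usual near-white background criterion for
#'   H&E tiles.
#' @return Fraction in `[0, 1]`.
#' @examples
#' blank_ratio(image_tile(matrix(255, 4, 4)))
#' @export
blank_ratio <- function(tile, white_threshold = 220) {
  stopifnot(is_image_tile(tile))
  if (length(tile$pixels) == 0) stop("empty tile", call. = FALSE)
  mean(tile$pixels >= white_threshold)
}

#' Filter tiles by blank ratio
#'
#' Keeps tiles whose blank ratio is at most `max_blank`; rejection is
#' strict (a ratio of exactly `max_blank` is kept, anything higher is
#' dropped). Idempotent.
#'
#' @param tiles List of [image_tile()].
#' @param max_blank Maximum tolerated blank ratio (default 0.30).
#' @inheritParams blank_ratio
#' @return List with `kept` (the surviving tiles) and `log`, a tibble
#'   `tile_id, blank_ratio, kept` covering every input tile.
#' @export
filter_tiles <- function(tiles, max_blank = 0.30, white_threshold = 220) {
  if (length(tiles) == 0) {
    return(list(kept = list(),
                log = tibble::tibble(tile_id = character(),
                                     blank_ratio = numeric(),
                                     kept = logical())))
  }
  ratios <- vapply(tiles, blank_ratio, numeric(1),
                   white_threshold = white_threshold)
  keep <- ratios <= max_blank
  list(
    kept = tiles[keep],
    log = tibble::tibble(
      tile_id = vapply(tiles, function(t) t$tile_id, character(1)),
      blank_ratio = ratios,
      kept = keep
    )
  )
}

#' CLAHE parameters
#'
#' @param n_grid Number of sub-tiles per side of the contextual grid
#'   (default 8, i.e. 8x8 = 64 sub-tiles per image).
#' @param clip_max Clipping parameter. In `standard` mode it is the usual
#'   CLAHE clip limit: histogram counts are clipped at
#'   `clip_max * mean_count` and the excess is redistributed uniformly
#'   before the CDF is formed (default 2). In `paper_literal` mode the CDF
#'   itself is clipped into `[0, clip_max]`; values below 1 then cap the
#'   lookup table below 255 and darken the output globally, which is why
#'   this mode is not the default.
#' @param n_levels Number of histogram levels (256 for 8-bit input).
#' @param mode `"standard"` or `"paper_literal"` (see `clip_max`).
#' @param interpolate If `TRUE`, blend the lookup tables of the four
#'   nearest sub-tile centers bilinearly per pixel (classic CLAHE). The
#'   default `FALSE` maps each sub-tile through its own table only, i.e.
#'   non-overlapping tiles mapped pixel-by-pixel.
#' @return A `clahe_params` list.
#' @export
clahe_params <- function(n_grid = 8, clip_max = if (mode == "standard") 2 else 1,
                         n_levels = 256,
                         mode = c("standard", "paper_literal"),
                         interpolate = FALSE) {
  mode <- match.arg(mode)
  if (n_grid < 1) stop("`n_grid` must be at least 1", call. = FALSE)
  if (clip_max <= 0) stop("`clip_max` must be positive", call. = FALSE)
  structure(list(n_grid = as.integer(n_grid), clip_max = clip_max,
                 n_levels = as.integer(n_levels), mode = mode,
                 interpolate = interpolate),
            class = "clahe_params")
}

# Lookup table (ELT) for one sub-tile: histogram -> (clipped) CDF -> LUT.
clahe_lut <- function(values, params) {
  nl <- params$n_levels
  h <- tabulate(values + 1L, nbins = nl)
  npx <- length(values)
  if (params$mode == "standard") {
    lim <- params$clip_max * npx / nl
    excess <- sum(pmax(h - lim, 0))
    h <- pmin(h, lim) + excess / nl
  }
  cdf <- cumsum(h) / npx
  if (params$mode == "paper_literal") cdf <- pmin(pmax(cdf, 0), params$clip_max)
  as.integer(round(cdf * 255))
}

# Breakpoints splitting `n` pixels into `g` nearly equal runs.
grid_breaks <- function(n, g) {
  cuts <- floor(seq(0, n, length.out = g + 1))
  lapply(seq_len(g), function(i) (cuts[i] + 1L):cuts[i + 1L])
}

#' Contrast-limited adaptive histogram equalization
#'
#' Divides the tile into a grid of non-overlapping sub-tiles; within each,
#' builds the intensity histogram and its cumulative distribution, applies
#' contrast clipping (see [clahe_params()]), and maps pixels through the
#' resulting equalization lookup table `round(255 * CDF)`. Output
#' dimensions equal input; intensities stay in `[0, 255]`, and the mapping
#' is monotone in raw intensity within each sub-tile.
#'
#' If a sub-tile would be smaller than 2x2 the whole image is treated as a
#' single tile (plain, possibly clipped, histogram equalization) and a
#' warning is raised.
#'
#' @param tile An [image_tile()].
#' @param params A [clahe_params()].
#' @return The enhanced [image_tile()].
#' @export
clahe <- function(tile, params = clahe_params()) {
  stopifnot(is_image_tile(tile), inherits(params, "clahe_params"))
  px <- tile$pixels
  m <- nrow(px); n <- ncol(px)
  g <- params$n_grid
  if (m %/% g < 2 || n %/% g < 2) {
    warning("sub-tile grid too fine for image; using a single tile",
            call. = FALSE)
    g <- 1L
  }
  rows <- grid_breaks(m, g)
  cols <- grid_breaks(n, g)
  luts <- array(0L, dim = c(g, g, params$n_levels))
  for (i in seq_len(g)) {
    for (j in seq_len(g)) {
      luts[i, j, ] <- clahe_lut(px[rows[[i]], cols[[j]]], params)
    }
  }
  out <- matrix(0L, m, n)
  if (!params$interpolate || g == 1L) {
    for (i in seq_len(g)) {
      for (j in seq_len(g)) {
        out[rows[[i]], cols[[j]]] <- luts[i, j, ][px[rows[[i]], cols[[j]]] + 1L]
      }
    }
  } else {
    centers_r <- vapply(rows, function(r) mean(range(r)), numeric(1))
    centers_c <- vapply(cols, function(c) mean(range(c)), numeric(1))
    ri <- findInterval(seq_len(m), centers_r, all.inside = TRUE)
    ci <- findInterval(seq_len(n), centers_c, all.inside = TRUE)
    wr <- (seq_len(m) - centers_r[ri]) / (centers_r[ri + 1L] - centers_r[ri])
    wc <- (seq_len(n) - centers_c[ci]) / (centers_c[ci + 1L] - centers_c[ci])
    wr <- pmin(pmax(wr, 0), 1); wc <- pmin(pmax(wc, 0), 1)
    for (a in seq_len(m)) {
      lut00 <- luts[ri[a], , ]; lut10 <- luts[ri[a] + 1L, , ]
      v <- px[a, ] + 1L
      idx <- cbind(ci, v); idx1 <- cbind(ci + 1L, v)
      top <- (1 - wc) * lut00[idx] + wc * lut00[idx1]
      bot <- (1 - wc) * lut10[idx] + wc * lut10[idx1]
      out[a, ] <- as.integer(round((1 - wr[a]) * top + wr[a] * bot))
    }
  }
  image_tile(out, tile_id = tile$tile_id, label = tile$label)
}
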