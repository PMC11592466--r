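#' Specification of a synthetic two-class texture dataset
#'
#' The generator emulates the statistical structure the texture pipeline
#' relies on — a second-order (co-occurrence) difference between classes —
#' without any histology content. The negative class (label 0) is fine
#' high-frequency texture: i.i.d. uniform noise smoothed with a small box
#' kernel. The positive class (label 1) is coarse texture: the same noise
#' smoothed with a much larger kernel, plus a low-frequency sinusoidal
#' grating. Coarse tiles therefore have strongly lower co-occurrence
#' contrast and higher homogeneity than fine tiles, which is exactly the
#' axis the wavelet co-occurrence features measure.
#'
#' The defaults mirror the imbalance shape of a relapse-prediction cohort
#' at desk scale: 25 positive vs 102 negative tiles of 512x512 pixels
#' (so one level of wavelet decomposition gives 256x256 sub-bands).
#'
#' @param n_positive,n_negative Tile counts per class (each at least 1).
#' @param tile_size Pixels per side; must be even.
#' @param class_params Per-class texture parameters: a list with elements
#'   `negative` and `positive`, each a list with `kernel` (box smoothing
#'   width in pixels), `period` (sinusoid period in pixels, `Inf` for none)
#'   and `amplitude` (sinusoid amplitude in intensity units).
#' @param white_patch_fraction Fraction of tiles given a near-white square
#'   patch covering ~40% of the area (fixture for blank filtering).
#' @param seed Integer seed; same spec + same seed gives identical pixels.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_positive = 25, n_negative = 102,
                           tile_size = 512,
                           class_params = list(
                             negative = list(kernel = 3, period = Inf, amplitude = 0),
                             positive = list(kernel = 21, period = 96, amplitude = 40)
                           ),
                           white_patch_fraction = 0,
                           seed = 42) {
  if (n_positive < 1 || n_negative < 1) {
    stop("each class needs at least one tile", call. = FALSE)
  }
  if (tile_size < 4 || tile_size %% 2 != 0) {
    stop("`tile_size` must be even and at least 4", call. = FALSE)
  }
  if (white_patch_fraction < 0 || white_patch_fraction > 1) {
    stop("`white_patch_fraction` must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(n_positive = as.integer(n_positive),
         n_negative = as.integer(n_negative),
         tile_size = as.integer(tile_size),
         class_params = class_params,
         white_patch_fraction = white_patch_fraction,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# Separable box smoothing with circular boundary; width 1 is a no-op.
box_smooth <- function(m, kernel) {
  kernel <- min(kernel, nrow(m) - 1, ncol(m) - 1)
  if (kernel <= 1) return(m)
  k <- rep(1 / kernel, kernel)
  m <- apply(m, 2, function(col) as.numeric(stats::filter(col, k, circular = TRUE)))
  t(apply(t(m), 2, function(col) as.numeric(stats::filter(col, k, circular = TRUE))))
}

texture_field <- function(size, params) {
  z <- matrix(stats::runif(size * size), size, size)
  z <- box_smooth(z, params$kernel)
  # stretch to [10, 210]: well inside 8 bits and below the blank threshold,
  # so clean tiles never trip the blank filter
  rng <- range(z)
  z <- if (rng[2] > rng[1]) 10 + (z - rng[1]) / (rng[2] - rng[1]) * 200
       else matrix(110, size, size)
  if (is.finite(params$period) && params$amplitude > 0) {
    xy <- outer(seq_len(size), seq_len(size), "+")
    z <- z + params$amplitude * sin(2 * pi * xy / params$period)
  }
  matrix(as.integer(pmin(pmax(round(z), 0), 255)), size, size)
}

add_white_patch <- function(px, frac_area = 0.4) {
  side <- max(2L, as.integer(round(sqrt(frac_area) * nrow(px))))
  r0 <- sample.int(nrow(px) - side + 1L, 1L)
  c0 <- sample.int(ncol(px) - side + 1L, 1L)
  px[r0:(r0 + side - 1L), c0:(c0 + side - 1L)] <- 245L
  px
}

#' Generate a labeled, imbalanced synthetic texture dataset
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `tiles` (list of [image_tile()]) and `manifest`, a
#'   tibble with columns `tile_id`, `path` (`NA` until written) and `label`.
#' @examples
#' d <- generate_dataset(synthetic_spec(2, 3, tile_size = 32, seed = 1))
#' d$manifest
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  labels <- c(rep(1L, spec$n_positive), rep(0L, spec$n_negative))
  ids <- sprintf("tile_%03d_c%d", seq_along(labels), labels)
  tiles <- withr::with_seed(spec$seed, {
    n_patch <- round(spec$white_patch_fraction * length(labels))
    patched <- if (n_patch > 0) sample(seq_along(labels), n_patch) else integer()
    lapply(seq_along(labels), function(i) {
      params <- if (labels[i] == 1L) spec$class_params$positive
                else spec$class_params$negative
      px <- texture_field(spec$tile_size, params)
      if (i %in% patched) px <- add_white_patch(px)
      image_tile(px, tile_id = ids[i], label = labels[i])
    })
  })
  manifest <- tibble::tibble(tile_id = ids, path = NA_character_, label = labels)
  list(tiles = tiles, manifest = manifest)
}

#' Generate a tile with an exact blank fraction
#'
#' A fixture for the blank-ratio filter: exactly
#' `round(blank_fraction * tile_size^2)` pixels are set to a near-white
#' value (250, above the default blank threshold of 220); the remaining
#' pixels are textured noise kept strictly below the threshold.
#'
#' @param tile_size Pixels per side.
#' @param blank_fraction Fraction of near-white pixels, in `[0, 1]`.
#' @param seed Integer seed.
#' @return An [image_tile()].
#' @export
generate_blank_tile <- function(tile_size, blank_fraction, seed = 1) {
  if (blank_fraction < 0 || blank_fraction > 1) {
    stop("`blank_fraction` must lie in [0, 1]", call. = FALSE)
  }
  n <- tile_size^2
  n_blank <- round(blank_fraction * n)
  withr::with_seed(seed, {
    px <- matrix(sample(10:210, n, replace = TRUE), tile_size, tile_size)
    if (n_blank > 0) px[sample.int(n, n_blank)] <- 250L
    image_tile(px, tile_id = sprintf("blank_%03d", round(100 * blank_fraction)))
  })
}

#' Write a dataset to disk as PNG tiles plus a manifest
#'
#' @param dataset As returned by [generate_dataset()].
#' @param dir Output directory (created if missing).
#' @return The manifest tibble with the `path` column filled in;
#'   `manifest.csv` is written alongside the tiles.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(dataset$tiles, function(tl) {
    p <- file.path(dir, paste0(tl$tile_id, ".png"))
    write_tile_png(tl, p)
    p
  }, character(1))
  manifest <- dplyr::mutate(dataset$manifest, path = paths)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Read a dataset back from a manifest
#'
#' @param manifest_path Path to a `manifest.csv` with columns
#'   `tile_id`, `path`, `label`.
#' @return A list with `tiles` and `manifest`, as for [generate_dataset()].
#' @export
read_dataset <- function(manifest_path) {
  manifest <- tibble::as_tibble(
    utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  )
  base <- dirname(manifest_path)
  tiles <- purrr::pmap(manifest, function(tile_id, path, label, ...) {
    p <- if (file.exists(path)) path else file.path(base, basename(path))
    read_tile_png(p, tile_id = tile_id, label = label)
  })
  list(tiles = tiles, manifest = manifest)
}
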