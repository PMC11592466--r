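#' Stratified train/test split
#'
#' Splits a labeled feature table into training and test sets at the given
#' fraction with per-class proportional allocation: the training set gets
#' `floor(train_fraction * n)` rows overall, apportioned to classes by
#' floor-plus-largest-remainder (remainder ties go to the lower label).
#' For a balanced 127/127 table at 0.8 this yields 203 training rows
#' (102 label 0 + 101 label 1) and 51 test rows (25 + 26). Both splits are
#' guaranteed to contain both classes; the split is disjoint, exhaustive
#' and deterministic for a given seed.
#'
#' @param features Tibble with a binary `label` column.
#' @param train_fraction Fraction of rows for training (default 0.8).
#' @param seed Integer seed for the within-class shuffles.
#' @return List with tibbles `train` and `test`.
#' @export
stratified_split <- function(features, train_fraction = 0.8, seed = 1) {
  labs <- sort(unique(features$label))
  if (length(labs) < 2) {
    stop("both classes must be present to split", call. = FALSE)
  }
  cls_n <- table(factor(features$label, levels = labs))
  if (any(cls_n < 2)) {
    stop(paste("each class needs at least 2 rows to appear in both splits;",
               "consider the paper_literal pipeline order (oversample first)"),
         call. = FALSE)
  }
  n_train <- floor(train_fraction * nrow(features))
  ideal <- as.numeric(cls_n) * train_fraction
  take <- floor(ideal)
  rem <- n_train - sum(take)
  if (rem > 0) {
    # largest fractional remainder first; ties to the lower label
    ord <- order(-(ideal - take), seq_along(labs))
    take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1
  }
  # keep both classes represented on both sides
  take <- pmin(pmax(take, 1), as.numeric(cls_n) - 1)
  idx_train <- withr::with_seed(seed, {
    unlist(lapply(seq_along(labs), function(k) {
      rows <- which(features$label == labs[k])
      sample(rows)[seq_len(take[k])]
    }))
  })
  list(train = features[sort(idx_train), , drop = FALSE],
       test = features[sort(setdiff(seq_len(nrow(features)), idx_train)), ,
                       drop = FALSE])
}

#' SMOTE minority oversampling
#'
#' Balances a binary feature table by synthesizing minority-class rows:
#' each synthetic row is `x + u * (x_nn - x)` for a randomly chosen
#' minority row `x`, one of its `k_eff` nearest minority neighbours
#' `x_nn`, and `u ~ Uniform(0, 1)`, with `k_eff = min(k, n_minority - 1)`.
#' Nearest neighbours use Euclidean distance on z-scored features (scaled
#' by the minority rows' statistics) because the texture statistics have
#' heterogeneous scales; the interpolation itself happens in the original
#' feature space, so every synthetic row lies componentwise between two
#' real minority rows. Real rows pass through unmodified. An already
#' balanced table is returned unchanged.
#'
#' @param features Tibble with binary `label` and numeric feature columns.
#' @param k Number of nearest neighbours (default 5, capped at
#'   `n_minority - 1`).
#' @param seed Integer seed.
#' @param columns Feature columns to interpolate; defaults to
#'   [feature_columns()] plus `tf_score` when present.
#' @return Tibble with equal class counts and a `provenance` column
#'   (`"real"` or `"synthetic"`).
#' @export
smote <- function(features, k = 5, seed = 1, columns = NULL) {
  if (is.null(columns)) {
    columns <- intersect(c(feature_columns(features), "tf_score"),
                         names(features))
  }
  out <- dplyr::mutate(features, provenance = "real")
  cnt <- table(factor(features$label, levels = c(0, 1)))
  if (cnt[1] == cnt[2]) return(out)
  minority <- as.integer(names(cnt)[which.min(cnt)])
  n_new <- abs(as.integer(cnt[1] - cnt[2]))
  min_rows <- which(features$label == minority)
  n_min <- length(min_rows)
  if (n_min < 2) stop("SMOTE needs at least 2 minority rows", call. = FALSE)
  k_eff <- min(k, n_min - 1)

  X <- as.matrix(features[min_rows, columns])
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  D <- as.matrix(stats::dist(Z))
  diag(D) <- Inf
  nn <- t(apply(D, 1, function(d) order(d)[seq_len(k_eff)]))

  synth <- withr::with_seed(seed, {
    base_i <- sample.int(n_min, n_new, replace = TRUE)
    nb_i <- nn[cbind(base_i, sample.int(k_eff, n_new, replace = TRUE))]
    u <- stats::runif(n_new)
    X[base_i, , drop = FALSE] +
      u * (X[nb_i, , drop = FALSE] - X[base_i, , drop = FALSE])
  })
  synth_tbl <- tibble::as_tibble(as.data.frame(synth))
  synth_tbl$label <- minority
  synth_tbl$provenance <- "synthetic"
  if ("tile_id" %in% names(features)) {
    synth_tbl$tile_id <- sprintf("smote_%03d", seq_len(n_new))
  }
  dplyr::bind_rows(out, synth_tbl)
}
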