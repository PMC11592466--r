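test_that("Haar decomposition has the closed-form behaviour", {
  # 2x2 of ones: approximation 2, all detail bands zero
  sb <- wpt_decompose(matrix(1, 2, 2), "haar")
  expect_equal(sb$LL, matrix(2, 1, 1))
  expect_equal(sb$LH, matrix(0, 1, 1))
  expect_equal(sb$HL, matrix(0, 1, 1))
  expect_equal(sb$HH, matrix(0, 1, 1))
  # constant tiles: detail filters annihilate constants
  sb2 <- wpt_decompose(image_tile(matrix(7, 8, 8)), "haar")
  expect_true(all(abs(sb2$LH) < 1e-12) && all(abs(sb2$HL) < 1e-12) &&
                all(abs(sb2$HH) < 1e-12))
  expect_true(all(abs(sb2$LL - 14) < 1e-12))
  expect_error(wpt_decompose(matrix(1, 4, 4), "sym8"), "unknown wavelet")
})

test_that("orientation of the detail bands follows a pure gradient", {
  # horizontal stripes (variation down rows) load LH, not HL
  stripes <- matrix(rep(c(0, 100), 8), 16, 16)
  sb <- wpt_decompose(stripes, "haar")
  expect_true(sum(sb$LH^2) > 0)
  expect_equal(sum(sb$HL^2), 0)
  sb_t <- wpt_decompose(t(stripes), "haar")
  expect_true(sum(sb_t$HL^2) > 0)
  expect_equal(sum(sb_t$LH^2), 0)
})

test_that("orthonormal filters preserve energy and halve dimensions", {
  for (wv in c("haar", "d4")) {
    x <- withr::with_seed(5, matrix(runif(32 * 48, 0, 255), 32, 48))
    sb <- wpt_decompose(x, wv)
    expect_equal(dim(sb$LL), c(16, 24))
    e <- sum(sb$LL^2) + sum(sb$LH^2) + sum(sb$HL^2) + sum(sb$HH^2)
    expect_equal(e, sum(x^2), tolerance = 1e-6)
  }
  # odd dimensions padded by edge replication
  expect_equal(dim(wpt_decompose(matrix(1:15, 3, 5))$LL), c(2, 3))
})

test_that("quantization maps min to 1, max to L, exact bins exactly", {
  expect_true(all(quantize(matrix(4.2, 5, 5)) == 1))
  q <- quantize(matrix(0:15, 4, 4), L = 16)
  expect_equal(as.vector(q), 1:16)
  x <- withr::with_seed(6, matrix(rnorm(100), 10, 10))
  q2 <- quantize(x, L = 16)
  expect_equal(q2[which.min(x)], 1L)
  expect_equal(q2[which.max(x)], 16L)
  expect_true(all(q2 >= 1 & q2 <= 16))
})

test_that("co-occurrence counts match the enumerated example", {
  q <- matrix(c(1, 1, 2,
                2, 2, 3,
                3, 3, 3), 3, 3, byrow = TRUE)
  g <- glcm(q, delta = 1, L = 3)
  expected <- matrix(0, 3, 3)
  expected[2, 1] <- 1; expected[3, 1] <- 1; expected[3, 2] <- 2
  expect_equal(g$counts, expected)
  expect_equal(g$n_pairs, 4)
  # constant grid: single diagonal cell with (M-1)(N-1) pairs
  gc <- glcm(matrix(1L, 5, 7), L = 1)
  expect_equal(gc$counts[1, 1], 24)
  expect_error(glcm(matrix(0L, 3, 3)), "1..L")
  expect_warning(glcm(matrix(1L, 1, 1), delta = 1, L = 1), "empty")
})

test_that("co-occurrence matches the brute-force oracle on random grids", {
  withr::with_seed(123, {
    for (trial in 1:200) {
      d <- sample(1:2, 1)
      m <- sample((d + 1):8, 1); n <- sample((d + 1):8, 1)
      L <- sample(2:6, 1)
      q <- matrix(sample.int(L, m * n, TRUE), m, n)
      g <- glcm(q, delta = d, L = L)
      expect_equal(g$counts, glcm_brute(q, delta = d, L = L))
      expect_equal(g$n_pairs, max(m - d, 0) * max(n - d, 0))
    }
  })
})

test_that("four-orientation mode sums the standard offsets", {
  q <- withr::with_seed(8, matrix(sample.int(4, 36, TRUE), 6, 6))
  g <- glcm(q, delta = 1, orientations = "all", L = 4)
  # offsets: left, up-left, up, up-right at distance 1
  brute <- matrix(0, 4, 4)
  for (off in list(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1))) {
    for (a in 1:6) for (b in 1:6) {
      a2 <- a + off[1]; b2 <- b + off[2]
      if (a2 >= 1 && a2 <= 6 && b2 >= 1 && b2 <= 6) {
        brute[q[a, b], q[a2, b2]] <- brute[q[a, b], q[a2, b2]] + 1
      }
    }
  }
  expect_equal(g$counts, brute)
})

test_that("the WMCM is the element-wise sum of the sub-band matrices", {
  q <- withr::with_seed(9, matrix(sample.int(16, 64, TRUE), 8, 8))
  g <- glcm(q, L = 16)
  w <- build_wmcm(list(g, g, g, g))
  expect_equal(w$counts, 4 * g$counts)
  expect_equal(w$n_pairs, 4 * g$n_pairs)
  expect_equal(sum(w$p), 1)
  expect_error(build_wmcm(list(g, glcm(matrix(1:4, 2, 2), L = 4))), "same")
})

test_that("texture statistics hit the degenerate closed forms", {
  one_cell <- matrix(0, 16, 16); one_cell[3, 3] <- 10
  cm <- wmcmtex:::new_cooccurrence(one_cell, 1, "diagonal")
  st <- texture_statistics(cm)
  expect_equal(st$energy, 1)
  expect_equal(st$entropy, 0)
  expect_equal(st$contrast, 0)
  expect_equal(st$homogeneity, 1)
  expect_equal(st$correlation, 0)  # degenerate marginals

  unif <- wmcmtex:::new_cooccurrence(matrix(1, 16, 16), 1, "diagonal")
  stu <- texture_statistics(unif)
  expect_equal(stu$energy, 1 / 256)
  expect_equal(stu$entropy, 2 * log(16))
  expect_equal(stu$gla, 8.5)
  expect_equal(stu$correlation, 0)  # independent marginals

  # independent non-uniform marginals still give zero correlation
  a <- (1:16) / sum(1:16); b <- (16:1) / sum(16:1)
  ind <- wmcmtex:::new_cooccurrence(outer(a, b) * 1000, 1, "diagonal")
  expect_equal(texture_statistics(ind)$correlation, 0, tolerance = 1e-12)
})

test_that("contrast is transpose-invariant and zero only on the diagonal", {
  m <- withr::with_seed(10, matrix(rpois(64, 4), 8, 8))
  m <- m + t(m)  # symmetric
  cm <- wmcmtex:::new_cooccurrence(m, 1, "diagonal")
  cmt <- wmcmtex:::new_cooccurrence(t(m), 1, "diagonal")
  expect_equal(texture_statistics(cm)$contrast, texture_statistics(cmt)$contrast)
  expect_gt(texture_statistics(cm)$contrast, 0)
  expect_equal(texture_statistics(
    wmcmtex:::new_cooccurrence(diag(8), 1, "diagonal"))$contrast, 0)
})

test_that("entropy is maximal for the uniform matrix", {
  ent_max <- 2 * log(16)
  withr::with_seed(11, {
    for (i in 1:20) {
      m <- matrix(rexp(256), 16, 16)
      cm <- wmcmtex:::new_cooccurrence(m, 1, "diagonal")
      expect_lte(texture_statistics(cm)$entropy, ent_max + 1e-12)
    }
  })
})

test_that("the weighted texture score enforces the unit weight sum", {
  cm <- wmcmtex:::new_cooccurrence(matrix(1, 16, 16), 1, "diagonal")
  st <- texture_statistics(cm)
  expect_equal(texture_score(st, rep(1 / 11, 11)),
               mean(unlist(st[1, 1:11])))
  one_hot <- replace(rep(0, 11), 9, 1)  # energy position
  expect_equal(texture_score(st, one_hot), st$energy)
  expect_error(texture_score(st, rep(0.9 / 11, 11)), "sum to 1")
  expect_error(texture_score(st, rep(1, 11)), "sum to 1")
})

test_that("per-tile feature vectors are complete, finite and deterministic", {
  t <- small_fixture()$tiles[[1]]
  f1 <- extract_features(t)
  f2 <- extract_features(t)
  expect_identical(f1, f2)
  expect_length(feature_columns(f1), 55)
  bands <- c("wmcm", "ll", "lh", "hl", "hh")
  expect_setequal(unique(sub("_.*", "", feature_columns(f1))), bands)
  expect_true(all(is.finite(unlist(f1[, feature_columns(f1)]))))
  # constant tile: degenerate bands must still yield finite features
  fc <- extract_features(image_tile(matrix(42, 16, 16)))
  expect_true(all(is.finite(unlist(fc[, c("tf_score", feature_columns(fc))]))))
})
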