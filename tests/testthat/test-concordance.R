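test_that("Spearman rho hits the perfect-concordance endpoints", {
  x <- c(3, 9, 1, 7, 5)
  expect_equal(spearman_rank(x, exp(x))$rho, 1)
  expect_equal(spearman_rank(x, -x^3)$rho, -1)
  expect_error(spearman_rank(x, rep(2, 5)), "constant")
})

test_that("ties are resolved by mid-ranks, matching a brute-force oracle", {
  x <- c(10, 20, 20, 30, 40)
  y <- c(1.2, 0.8, 2.5, 2.5, 3.0)
  got <- spearman_rank(x, y)
  # independent computation: explicit average ranks then Pearson formula
  rx <- c(1, 2.5, 2.5, 4, 5)
  ry <- c(2, 1, 3.5, 3.5, 5)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(got$rho, num / den, tolerance = 1e-12)
  # and against the built-in estimate (independent code path)
  expect_equal(got$rho, suppressWarnings(
    cor.test(x, y, method = "spearman")$estimate[[1]]), tolerance = 1e-12)
})

test_that("Spearman rho is invariant under strictly monotone transforms", {
  set.seed(4)
  x <- rnorm(12); y <- rnorm(12)
  base <- spearman_rank(x, y)$rho
  expect_equal(spearman_rank(exp(x), y)$rho, base)
  expect_equal(spearman_rank(x, qlogis(plogis(y)))$rho, base)
  expect_equal(spearman_rank(x^3, atan(y))$rho, base)
})

test_that("Bland-Altman degenerate cases", {
  x <- c(1, 2, 3, 4, 5)
  r <- bland_altman(x, x)
  expect_equal(r$bias, 0)
  expect_equal(r$sd_diff, 0)
  expect_equal(r$outside_count, 0)
  r2 <- suppressWarnings(bland_altman(x + 2, x))  # zero-residual fit
  expect_equal(r2$bias, 2)
  expect_equal(r2$sd_diff, 0)
  expect_equal(r2$slope, 0)
  # identical means force constant mode with a warning
  expect_warning(r3 <- bland_altman(c(4, 6, 5, 5), c(6, 4, 5, 5)),
                 "regression undefined")
  expect_equal(r3$loa_mode, "constant")
})

test_that("trend-adjusted limits equal the closed-form OLS computation", {
  set.seed(10)
  m0 <- seq(40, 70, length.out = 10)
  d0 <- 0.5 * m0 + rnorm(10, sd = 0.8)
  x <- m0 + d0 / 2
  y <- m0 - d0 / 2            # so x - y = d0 and (x+y)/2 = m0 exactly
  r <- bland_altman(x, y)
  expect_equal(r$loa_mode, "regression")
  # independent closed-form OLS of d on m
  mx <- mean(m0); md <- mean(d0)
  b <- sum((m0 - mx) * (d0 - md)) / sum((m0 - mx)^2)
  a <- md - b * mx
  res <- d0 - (a + b * m0)
  sdr <- sqrt(sum(res^2) / (length(res) - 1))
  expect_equal(r$slope, b, tolerance = 1e-12)
  expect_equal(r$intercept, a, tolerance = 1e-12)
  expect_equal(r$loa_lower, (a + b * m0) - 1.96 * sdr, tolerance = 1e-12)
  expect_equal(r$loa_upper, (a + b * m0) + 1.96 * sdr, tolerance = 1e-12)
})

test_that("constant-mode limits have the prescribed width", {
  set.seed(20)
  x <- rnorm(30, 50, 3)
  y <- x + rnorm(30, 0, 1)    # no trend
  r <- bland_altman(x, y)
  if (r$loa_mode == "constant")
    expect_equal(r$loa_upper - r$loa_lower, 2 * 1.96 * r$sd_diff,
                 tolerance = 1e-9)
})

test_that("consistency ICC endpoints and shift invariance", {
  M <- cbind(a = c(1, 5, 9, 2), b = c(1, 5, 9, 2), c = c(1, 5, 9, 2))
  r <- icc_consistency(M)
  expect_equal(r$icc_single, 1)
  expect_equal(r$icc_avg, 1)
  # consistency ignores fixed column offsets
  M2 <- cbind(M[, 1], M[, 2] + 10, M[, 3] - 3)
  r2 <- icc_consistency(M2)
  expect_equal(r2$icc_single, 1)
  expect_equal(r2$icc_avg, 1)
  expect_error(icc_consistency(matrix(5, 4, 3)), "zero total variance")
  Mna <- M; Mna[1, 1] <- NA
  expect_error(icc_consistency(Mna), "complete")
})

test_that("mean squares and ICCs match an independent ANOVA decomposition", {
  set.seed(8)
  M <- matrix(rnorm(32, 50, 5), 8, 4) + rnorm(8, 0, 4)
  r <- icc_consistency(M)
  # independent oracle: stats::aov two-way ANOVA without interaction
  d <- data.frame(y = as.vector(M),
                  row = factor(rep(seq_len(8), 4)),
                  col = factor(rep(seq_len(4), each = 8)))
  tab <- summary(stats::aov(y ~ row + col, data = d))[[1]]
  ms_rows <- tab["row", "Mean Sq"]
  ms_err <- tab["Residuals", "Mean Sq"]
  expect_equal(r$ms_rows, ms_rows, tolerance = 1e-10)
  expect_equal(r$ms_error, ms_err, tolerance = 1e-10)
  k <- 4
  expect_equal(r$icc_single, (ms_rows - ms_err) / (ms_rows + (k - 1) * ms_err),
               tolerance = 1e-10)
  expect_equal(r$icc_avg, (ms_rows - ms_err) / ms_rows, tolerance = 1e-10)
  # Spearman-Brown relation between single and average measures
  r1 <- r$icc_single
  expect_equal(r$icc_avg, k * r1 / (1 + (k - 1) * r1), tolerance = 1e-12)
})

test_that("leave-one-out reliability isolates a pure-noise indicator", {
  set.seed(15)
  common <- rnorm(12, 50, 6)
  M <- cbind(A = common + rnorm(12, 0, 0.5),
             B = common + rnorm(12, 0, 0.5),
             C = common + rnorm(12, 0, 0.5),
             noise = rnorm(12, 50, 6))
  loo <- loo_reliability(M)
  best <- loo$by_excluded$excluded[which.max(loo$by_excluded$delta_avg)]
  expect_equal(best, "noise")
  # duplicate columns: excluding any leaves ICC at 1
  D <- cbind(common, common, common)
  lood <- loo_reliability(D)
  expect_true(all(abs(lood$by_excluded$icc_avg - 1) < 1e-12))
  # k = 3 reduction: each exclusion matches the pairwise ICC
  M3 <- M[, 1:3]
  loo3 <- loo_reliability(M3)
  for (j in 1:3) {
    pair <- icc_consistency(M3[, -j, drop = FALSE])
    expect_equal(loo3$by_excluded$icc_single[j], pair$icc_single)
  }
})

test_that("the battery wires measures together", {
  set.seed(3)
  common <- rnorm(10, 60, 5)
  smph <- do.call(rbind, lapply(c("LE", "DALE", "WAHE"), function(m)
    data.frame(country = paste0("C", 1:10), sex = "male", measure = m,
               scheme = NA, value_years = common + rnorm(10, 0, 1))))
  M <- smph_matrix(smph, "male")
  expect_equal(dim(M), c(10L, 3L))
  v <- validate_smph(M)
  expect_true(all(v$spearman$rho[upper.tri(v$spearman$rho)] > 0.5))
  expect_s3_class(v$icc, "icc_report")
  expect_equal(nrow(v$loo$by_excluded), 3)
  expect_length(v$agreement, 3)
})
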