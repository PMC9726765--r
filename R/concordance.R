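# Empirical validation battery for summary measures of population
# health: Spearman rank concordance, Bland-Altman agreement with
# trend-adjusted limits, and two-way mixed-effects consistency ICC with
# leave-one-out reliability deltas.

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive average ranks), with a
#' two-sided p-value from the t approximation on n - 2 degrees of
#' freedom. For very small samples an exact permutation p-value is
#' available.
#'
#' @param x,y paired numeric vectors (pairwise-complete; pairs with any
#'   NA are dropped).
#' @param exact logical; if TRUE and n <= 10, compute the exact
#'   permutation p-value by full enumeration.
#' @return List with \code{rho}, \code{p}, \code{n}, \code{method}.
#' @export
spearman_rank <- function(x, y, exact = FALSE) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairwise-complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rho undefined: constant input vector")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (exact && n <= 10L) {
    perms <- .permutations(n)
    obs <- abs(rho)
    cnt <- 0L
    for (i in seq_len(nrow(perms))) {
      r <- stats::cor(rx, ry[perms[i, ]])
      if (abs(r) >= obs - 1e-12) cnt <- cnt + 1L
    }
    p <- cnt / nrow(perms)
    method <- "exact permutation"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    method <- "t approximation"
  }
  list(rho = rho, p = p, n = n, method = method)
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Bland-Altman agreement with trend-adjusted limits
#'
#' Differences \eqn{d_i = x_i - y_i} are regressed on pair means
#' \eqn{m_i = (x_i + y_i)/2}. If the slope is significant at
#' \code{alpha} (two-sided t test), the limits of agreement follow the
#' fitted trend: \eqn{(\hat a + \hat b m_i) \pm 1.96\, SD(residuals)}
#' (regression mode). Otherwise the classical constant limits
#' \eqn{\bar d \pm 1.96\, SD(d)} are used. SDs use the n - 1 denominator.
#'
#' @param x,y paired measure values (x - y is the reported difference
#'   orientation).
#' @param alpha two-sided significance level for the slope test
#'   (default 0.05).
#' @param labels optional character pair naming the two measures.
#' @return An object of class \code{agreement_report}: \code{bias}
#'   (mean difference), \code{sd_diff}, \code{slope}, \code{intercept},
#'   \code{slope_p}, \code{loa_mode} ("constant" or "regression"),
#'   \code{loa_lower}/\code{loa_upper} (scalars in constant mode,
#'   per-observation vectors in regression mode), \code{outside_count},
#'   \code{n}, \code{mean}, \code{diff}, \code{labels}, and
#'   \code{orientation} documenting the sign convention.
#' @export
bland_altman <- function(x, y, alpha = 0.05, labels = c("x", "y")) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4L) stop("need at least 4 paired values")
  d <- x - y
  m <- (x + y) / 2
  bias <- mean(d)
  sdd <- stats::sd(d)
  if (stats::sd(m) == 0) {
    warning("all pair means identical; regression undefined, constant limits used")
    slope <- 0; intercept <- bias; slope_p <- NA_real_
    mode <- "constant"
  } else {
    fit <- stats::lm(d ~ m)
    cf <- summary(fit)$coefficients
    slope <- cf["m", "Estimate"]
    intercept <- cf["(Intercept)", "Estimate"]
    slope_p <- cf["m", "Pr(>|t|)"]
    mode <- if (is.finite(slope_p) && slope_p < alpha) "regression" else "constant"
  }
  if (mode == "regression") {
    res <- d - (intercept + slope * m)
    sdr <- stats::sd(res)
    lo <- (intercept + slope * m) - 1.96 * sdr
    hi <- (intercept + slope * m) + 1.96 * sdr
    sd_used <- sdr
  } else {
    lo <- bias - 1.96 * sdd
    hi <- bias + 1.96 * sdd
    sd_used <- sdd
  }
  outside <- sum(d < lo | d > hi)
  structure(list(
    labels = labels, n = n, bias = bias, sd_diff = sdd,
    slope = slope, intercept = intercept, slope_p = slope_p,
    loa_mode = mode, sd_resid = sd_used,
    loa_lower = lo, loa_upper = hi, outside_count = outside,
    mean = m, diff = d,
    orientation = sprintf("diff = %s - %s; bias of the reverse orientation is %g",
                          labels[1], labels[2], -bias)
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %s vs %s (n = %d)\n",
              x$labels[1], x$labels[2], x$n))
  cat(sprintf("  bias %.3f, SD of differences %.3f, LoA mode: %s\n",
              x$bias, x$sd_diff, x$loa_mode))
  if (x$loa_mode == "regression")
    cat(sprintf("  trend: d = %.3f + %.3f m (slope p = %.3g)\n",
                x$intercept, x$slope, x$slope_p))
  cat(sprintf("  %d of %d differences outside the limits\n",
              x$outside_count, x$n))
  invisible(x)
}

#' Two-way mixed-effects consistency ICC
#'
#' Intraclass correlation from the two-way ANOVA without interaction of a
#' complete countries x measures matrix (rows random, columns fixed;
#' the Shrout-Fleiss ICC(3,1)/ICC(3,k) a.k.a. ICC(C,1)/ICC(C,k)
#' consistency coefficients):
#' \deqn{ICC(C,1) = \frac{MS_{rows} - MS_{error}}{MS_{rows} +
#'   (k-1) MS_{error}}, \qquad
#'   ICC(C,k) = \frac{MS_{rows} - MS_{error}}{MS_{rows}}.}
#' 95\% confidence intervals are based on the F ratio
#' \eqn{MS_{rows}/MS_{error}} with \eqn{(n-1, (n-1)(k-1))} degrees of
#' freedom.
#'
#' @param M numeric matrix, rows = subjects (countries), columns =
#'   measures; complete (no NA), n >= 3 rows, k >= 2 columns.
#' @param conf confidence level (default 0.95).
#' @return An object of class \code{icc_report}: \code{icc_single},
#'   \code{icc_avg}, \code{ms_rows}, \code{ms_cols}, \code{ms_error},
#'   \code{n}, \code{k}, \code{ci_single}, \code{ci_avg}, \code{fvalue}.
#' @export
icc_consistency <- function(M, conf = 0.95) {
  M <- as.matrix(M)
  if (anyNA(M)) stop("matrix must be complete (no missing cells); no imputation")
  n <- nrow(M); k <- ncol(M)
  if (n < 3L || k < 2L) stop("need at least 3 rows and 2 columns")
  grand <- mean(M)
  row_m <- rowMeans(M)
  col_m <- colMeans(M)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((M - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_cols <- ss_cols / (k - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  if (ss_tot <= 0) stop("zero total variance: ICC undefined")
  icc1 <- (ms_rows - ms_err) / (ms_rows + (k - 1) * ms_err)
  icck <- (ms_rows - ms_err) / ms_rows
  alpha <- 1 - conf
  Fv <- ms_rows / ms_err
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  FL <- Fv / stats::qf(1 - alpha / 2, df1, df2)
  FU <- Fv * stats::qf(1 - alpha / 2, df2, df1)
  ci1 <- c((FL - 1) / (FL + k - 1), (FU - 1) / (FU + k - 1))
  cik <- c(1 - 1 / FL, 1 - 1 / FU)
  structure(list(icc_single = icc1, icc_avg = icck,
                 ms_rows = ms_rows, ms_cols = ms_cols, ms_error = ms_err,
                 n = n, k = k, fvalue = Fv,
                 ci_single = ci1, ci_avg = cik, conf = conf),
            class = "icc_report")
}

#' @export
print.icc_report <- function(x, ...) {
  cat(sprintf("<icc_report> n = %d subjects, k = %d measures\n", x$n, x$k))
  cat(sprintf("  ICC(C,1) = %.3f [%.3f, %.3f]\n",
              x$icc_single, x$ci_single[1], x$ci_single[2]))
  cat(sprintf("  ICC(C,k) = %.3f [%.3f, %.3f]\n",
              x$icc_avg, x$ci_avg[1], x$ci_avg[2]))
  invisible(x)
}

#' Leave-one-out reliability
#'
#' Recomputes the consistency ICC with each measure (column) excluded in
#' turn, reporting the change relative to the full set: how much each
#' indicator contributes to, or detracts from, the group's reliability.
#'
#' @param M complete numeric matrix, k >= 3 columns.
#' @return List with \code{full} (the full-matrix \code{icc_report}) and
#'   \code{by_excluded}, a data.frame with one row per excluded column:
#'   \code{excluded, icc_single, icc_avg, delta_single, delta_avg}.
#' @export
loo_reliability <- function(M) {
  M <- as.matrix(M)
  if (ncol(M) < 3L) stop("need at least 3 columns to leave one out")
  full <- icc_consistency(M)
  cols <- colnames(M) %||% paste0("V", seq_len(ncol(M)))
  rows <- lapply(seq_len(ncol(M)), function(j) {
    r <- icc_consistency(M[, -j, drop = FALSE])
    data.frame(excluded = cols[j],
               icc_single = r$icc_single, icc_avg = r$icc_avg,
               delta_single = r$icc_single - full$icc_single,
               delta_avg = r$icc_avg - full$icc_avg,
               stringsAsFactors = FALSE)
  })
  list(full = full, by_excluded = do.call(rbind, rows))
}

#' Pivot a tidy SMPH table to a countries x measures matrix
#'
#' @param smph tidy SMPH data.frame (\code{country, sex, measure,
#'   scheme, value_years}); external measures (e.g. DALE) can be row-bound
#'   beforehand in the same layout.
#' @param sex which sex stratum to pivot (measure matrices are always
#'   sex-specific).
#' @param complete logical; if TRUE (default) drop countries with any
#'   missing measure so the matrix is ICC-ready.
#' @return Numeric matrix, rows = countries, columns = measure labels
#'   (\code{measure} or \code{measure.scheme} when a scheme applies).
#' @export
smph_matrix <- function(smph, sex, complete = TRUE) {
  d <- smph[smph$sex == sex, , drop = FALSE]
  if (!nrow(d)) stop(sprintf("no rows for sex '%s'", sex))
  lab <- ifelse(is.na(d$scheme) | d$scheme == "", d$measure,
                paste(d$measure, d$scheme, sep = "."))
  countries <- sort(unique(d$country))
  measures <- unique(lab)
  M <- matrix(NA_real_, length(countries), length(measures),
              dimnames = list(countries, measures))
  M[cbind(match(d$country, countries), match(lab, measures))] <- d$value_years
  if (complete) {
    keep <- stats::complete.cases(M)
    M <- M[keep, , drop = FALSE]
  }
  M
}

#' Run the full SMPH validation battery
#'
#' Pairwise Spearman rank correlations (with a non-significance flag at
#' \code{alpha_flag}), pairwise Bland-Altman agreement, the consistency
#' ICC of the whole group, and leave-one-out reliability.
#'
#' @param M countries x measures matrix (see \code{\link{smph_matrix}}).
#' @param alpha slope-significance level for trend-adjusted limits.
#' @param alpha_flag level at which correlations are flagged
#'   non-significant (default 0.1, the conventional shading level for
#'   rank-correlation displays).
#' @return List with \code{spearman} (list of \code{rho}, \code{p},
#'   \code{nonsig} matrices), \code{agreement} (named list of
#'   \code{agreement_report}s per measure pair), \code{icc},
#'   \code{loo}.
#' @export
validate_smph <- function(M, alpha = 0.05, alpha_flag = 0.1) {
  M <- as.matrix(M)
  k <- ncol(M)
  if (k < 2L) stop("need at least 2 measures")
  cols <- colnames(M) %||% paste0("V", seq_len(k))
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(cols, cols))
  diag(rho) <- 1; diag(p) <- 0
  agreement <- list()
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    # a constant measure (no between-country variation) has no defined
    # rank correlation; report NA rather than aborting the battery
    sp <- tryCatch(spearman_rank(M[, i], M[, j]),
                   error = function(e) list(rho = NA_real_, p = NA_real_))
    rho[i, j] <- rho[j, i] <- sp$rho
    p[i, j] <- p[j, i] <- sp$p
    pair <- paste(cols[i], cols[j], sep = " vs ")
    agreement[[pair]] <- suppressWarnings(
      bland_altman(M[, i], M[, j], alpha = alpha, labels = cols[c(i, j)]))
  }
  icc <- if (anyNA(M)) NULL else icc_consistency(M)
  loo <- if (!anyNA(M) && k >= 3L) loo_reliability(M) else NULL
  list(spearman = list(rho = rho, p = p, nonsig = p > alpha_flag),
       agreement = agreement, icc = icc, loo = loo)
}
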