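# Phase-wise regression comparison (two-line ANCOVA), exact nonparametric
# rank tests and dilution ratios — the statistical layer applied to the
# enrichment curves. All statistics are computed from closed-form sums of
# squares or exact null distributions so that brute-force oracles can verify
# them.

#' Phase windows for up- and downlabeling regressions
#'
#' @param up Closed day interval of the uplabeling phase (default c(0, 7)).
#' @param down Closed day interval of the downlabeling phase
#'   (default c(8, 22)). A day-7 point belongs to the up window only.
#' @return An object of class `phase_windows`.
#' @export
phase_windows <- function(up = c(0, 7), down = c(8, 22)) {
  stopifnot(length(up) == 2L, length(down) == 2L, up[1] <= up[2],
            down[1] <= down[2], up[2] < down[1])
  structure(list(up = up, down = down), class = "phase_windows")
}

#' Simple linear regression from closed-form sums
#'
#' @param day Numeric x values (days).
#' @param enrichment Numeric y values.
#' @return List with `slope`, `intercept`, `residual_ss`, `n`.
#' @export
fit_line <- function(day, enrichment) {
  x <- as.numeric(day); y <- as.numeric(enrichment)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L || length(unique(x)) < 2L)
    stop("degenerate regression design: need >= 2 points on >= 2 distinct days")
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  list(slope = slope, intercept = intercept,
       residual_ss = sum((y - intercept - slope * x)^2), n = n)
}

# residual SS of a single OLS line through (x, y); x must vary. Clamped at
# zero: cancellation on an exact fit can go infinitesimally negative.
line_rss <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  max(0, syy - sxy^2 / sxx)
}

# two-group ANCOVA from sums of squares (classical two-line comparison):
# F test of slope equality, then F test of equal elevations under a common
# slope (only meaningful when slopes are not distinguishable).
ancova_two_lines <- function(xa, ya, xb, yb) {
  na <- length(xa); nb <- length(xb); N <- na + nb
  rss_a <- line_rss(xa, ya); rss_b <- line_rss(xb, yb)
  rss_sep <- rss_a + rss_b                       # separate slopes+intercepts
  # common slope, separate intercepts (pooled within-group slope)
  sxx <- sum((xa - mean(xa))^2) + sum((xb - mean(xb))^2)
  sxy <- sum((xa - mean(xa)) * (ya - mean(ya))) +
         sum((xb - mean(xb)) * (yb - mean(yb)))
  syy <- sum((ya - mean(ya))^2) + sum((yb - mean(yb))^2)
  slope_common <- sxy / sxx
  rss_common <- max(0, syy - sxy^2 / sxx)
  # single line through pooled data
  xp <- c(xa, xb); yp <- c(ya, yb)
  rss_total <- line_rss(xp, yp)

  # F ratios with explicit handling of exactly-fitting models: a zero
  # denominator with a positive numerator is complete separation (F = Inf,
  # p = 0); zero over zero means the restricted model loses nothing (F = 0)
  f_ratio <- function(extra_ss, rss_full, df_full) {
    extra_ss <- max(0, extra_ss)
    if (extra_ss == 0) 0
    else if (rss_full <= 0) Inf
    else extra_ss / (rss_full / df_full)
  }
  df_sep <- N - 4L
  F_slope <- f_ratio(rss_common - rss_sep, rss_sep, df_sep)
  p_slope <- stats::pf(F_slope, 1, df_sep, lower.tail = FALSE)

  df_elev <- N - 3L
  F_elev <- f_ratio(rss_total - rss_common, rss_common, df_elev)
  p_elev <- stats::pf(F_elev, 1, df_elev, lower.tail = FALSE)

  fa <- fit_line(xa, ya); fb <- fit_line(xb, yb)
  list(slope_a = fa$slope, intercept_a = fa$intercept,
       slope_b = fb$slope, intercept_b = fb$intercept,
       slope_common = slope_common,
       F_slope = F_slope, p_slope = p_slope, df_slope = c(1L, df_sep),
       F_elev = F_elev, p_elev = p_elev, df_elev = c(1L, df_elev),
       n_a = na, n_b = nb,
       elevation_valid = p_slope >= 0.05,
       separated = !is.finite(F_slope) || rss_sep <= .Machine$double.eps *
         max(1, syy))
}

#' Compare up- and downlabeling regressions between two groups
#'
#' For each phase window (closed day intervals), fits simple linear
#' regressions of enrichment on day in each group and performs the classical
#' two-line ANCOVA: an F test of slope equality, followed by an F test of
#' equal elevations under a common slope. The elevation test is flagged
#' invalid when slope equality is rejected.
#'
#' @param group_a,group_b Data frames with columns `study_day` (or `day`) and
#'   `normalized_enrichment` (or `enrichment`).
#' @param windows A `phase_windows` object.
#' @param min_points Minimum points per group per window (default 3).
#' @return List of class `regression_comparison` with elements `up` and
#'   `down`; each is either the ANCOVA result list or `NULL` with the reason
#'   recorded in `not_computable`.
#' @export
compare_phase_regressions <- function(group_a, group_b,
                                      windows = phase_windows(),
                                      min_points = 3L) {
  get_xy <- function(d) {
    x <- if ("study_day" %in% names(d)) d$study_day else d$day
    y <- if ("normalized_enrichment" %in% names(d)) d$normalized_enrichment
         else d$enrichment
    ok <- is.finite(x) & is.finite(y)
    data.frame(x = x[ok], y = y[ok])
  }
  a <- get_xy(group_a); b <- get_xy(group_b)
  not_computable <- list()
  run_window <- function(w, name) {
    aw <- a[a$x >= w[1] & a$x <= w[2], ]
    bw <- b[b$x >= w[1] & b$x <= w[2], ]
    if (nrow(aw) < min_points || nrow(bw) < min_points ||
        length(unique(aw$x)) < 2L || length(unique(bw$x)) < 2L) {
      not_computable[[name]] <<- sprintf(
        "insufficient points in %s window (group A: %d, group B: %d)",
        name, nrow(aw), nrow(bw))
      return(NULL)
    }
    ancova_two_lines(aw$x, aw$y, bw$x, bw$y)
  }
  out <- list(up = run_window(windows$up, "up"),
              down = run_window(windows$down, "down"),
              windows = windows, not_computable = not_computable)
  class(out) <- "regression_comparison"
  out
}

# exact null distribution of U (count of y-values each x precedes) via the
# standard recurrence on the number of rank configurations:
# N(u; n, m) = N(u - m; n - 1, m) + N(u; n, m - 1)
mwu_exact_counts <- function(n, m) {
  maxu <- n * m
  prev <- vector("list", m + 1L)
  # base n = 0: single configuration with U = 0 for any m
  for (j in 0:m) prev[[j + 1L]] <- 1
  for (i in seq_len(n)) {
    cur <- vector("list", m + 1L)
    cur[[1L]] <- 1                      # m = 0: U = 0 only
    for (j in seq_len(m)) {
      a <- c(numeric(j), prev[[j + 1L]])          # N(u - j; i - 1, j), shift j
      bvec <- cur[[j]]                            # N(u; i, j - 1)
      len <- max(length(a), length(bvec), i * j + 1L)
      a <- c(a, numeric(len - length(a)))
      bvec <- c(bvec, numeric(len - length(bvec)))
      cur[[j + 1L]] <- a + bvec
    }
    prev <- cur
  }
  counts <- prev[[m + 1L]]
  c(counts, numeric(maxu + 1L - length(counts)))
}

#' Two-sided Mann-Whitney rank-sum test
#'
#' Exact null distribution (dynamic programming over rank configurations)
#' whenever the combined sample size is at most 16 and the pooled data are
#' tie-free; otherwise midranks with a tie-corrected normal approximation
#' (continuity-corrected). Two-sided p is twice the smaller tail, capped at
#' 1.
#'
#' @param x,y Numeric samples.
#' @return List of class `rank_test_result`: `statistic` (U of `x`), `p`,
#'   `method` ("exact" or "normal_approx"), `tie_correction`.
#' @export
rank_sum_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) == 0L || length(y) == 0L)
    stop("rank_sum_test requires two nonempty samples")
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- any(duplicated(pooled))
  if (!ties && n + m <= 16L) {
    counts <- mwu_exact_counts(n, m)
    total <- sum(counts)
    u <- round(U)
    lower <- sum(counts[seq_len(u + 1L)]) / total
    upper <- sum(counts[(u + 1L):length(counts)]) / total
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"; tie_correction <- FALSE
  } else {
    N <- n + m
    tab <- table(pooled)
    tie_term <- sum(tab^3 - tab) / (N * (N - 1))
    sigma2 <- n * m / 12 * (N + 1 - tie_term)
    mu <- n * m / 2
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal_approx"; tie_correction <- ties
  }
  structure(list(statistic = U, p = p, method = method,
                 tie_correction = tie_correction, n = c(n, m)),
            class = "rank_test_result")
}

# exact null counts of the signed-rank statistic W+ for ranks 1..n:
# coefficients of prod (1 + q^r)
signed_rank_counts <- function(ranks) {
  maxw <- sum(ranks)
  counts <- c(1, numeric(maxw))
  for (r in ranks) {
    shifted <- c(numeric(r), counts[seq_len(maxw + 1L - r)])
    counts <- counts + shifted
  }
  counts
}

#' Two-sided Wilcoxon signed-rank test for paired data
#'
#' Zero differences are dropped. Exact sign-flip null distribution for up to
#' 15 nonzero tie-free differences; midranks with tie-corrected,
#' continuity-corrected normal approximation otherwise.
#'
#' @param a,b Paired numeric vectors (or `b` omitted and `a` the
#'   differences).
#' @return A `rank_test_result` with `statistic` = W+ (sum of positive
#'   ranks), and `all_zero` flag when every difference is zero (p = 1).
#' @export
signed_rank_test <- function(a, b = NULL) {
  d <- if (is.null(b)) as.numeric(a) else as.numeric(a) - as.numeric(b)
  d <- d[is.finite(d)]
  if (length(d) == 0L) stop("signed_rank_test requires at least one pair")
  nz <- d[d != 0]
  if (length(nz) == 0L)
    return(structure(list(statistic = 0, p = 1, method = "degenerate",
                          tie_correction = FALSE, all_zero = TRUE,
                          n = length(d)),
                     class = "rank_test_result"))
  n <- length(nz)
  r <- rank(abs(nz))
  W <- sum(r[nz > 0])
  ties <- any(duplicated(abs(nz)))
  if (!ties && n <= 15L) {
    counts <- signed_rank_counts(seq_len(n))
    total <- sum(counts)
    w <- round(W)
    lower <- sum(counts[seq_len(w + 1L)]) / total
    upper <- sum(counts[(w + 1L):length(counts)]) / total
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"; tie_correction <- FALSE
  } else {
    mu <- n * (n + 1) / 4
    tab <- table(abs(nz))
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tab^3 - tab) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"; tie_correction <- ties
  }
  structure(list(statistic = W, p = p, method = method,
                 tie_correction = tie_correction, all_zero = FALSE, n = n),
            class = "rank_test_result")
}

#' Dilution-ratio series relative to the reference (peak) day
#'
#' Ratios of enrichment on each day after the reference day to the
#' enrichment on the reference day (the blood peak, default day 7). Slower
#' turnover in a compartment lowers and flattens the series.
#'
#' @param day Numeric days.
#' @param enrichment Enrichment values matching `day`.
#' @param ref_day Reference day (default 7).
#' @param detection_threshold Reference values at or below this are refused.
#' @return List of class `dilution_ratio_series` with `ref_day`, `days`,
#'   `ratios`; or an error when the reference is missing/below threshold.
#' @export
dilution_ratio <- function(day, enrichment, ref_day = 7,
                           detection_threshold = 5e-4) {
  day <- as.numeric(day); enrichment <- as.numeric(enrichment)
  ref <- enrichment[day == ref_day]
  if (length(ref) == 0L)
    stop("dilution ratio not computable: no value at reference day ", ref_day)
  ref <- mean(ref)
  if (!is.finite(ref) || ref < detection_threshold)
    stop("dilution ratio not computable: reference enrichment at day ",
         ref_day, " is below the detection threshold")
  sel <- day >= ref_day
  structure(list(ref_day = ref_day, days = day[sel],
                 ratios = enrichment[sel] / ref),
            class = "dilution_ratio_series")
}
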