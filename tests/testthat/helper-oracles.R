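# Independent brute-force oracles used to verify the package's statistics.
# These deliberately share no code with the implementation: enumeration and
# normal-equations solves only.

# exact two-sided Mann-Whitney p by exhaustive enumeration of all C(n+m, n)
# group labelings of the pooled sample (tie-free data)
oracle_mwu_p <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  lower <- mean(us <= u_obs)
  upper <- mean(us >= u_obs)
  min(1, 2 * min(lower, upper))
}

# exact two-sided Wilcoxon signed-rank p by enumerating all 2^n sign flips
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- signs %*% r
  lower <- mean(ws <= w_obs)
  upper <- mean(ws >= w_obs)
  min(1, 2 * min(lower, upper))
}

# two-line ANCOVA by explicit normal-equations solves of nested linear
# models: interaction (separate lines), additive (common slope), single line
oracle_ancova <- function(xa, ya, xb, yb) {
  x <- c(xa, xb); y <- c(ya, yb)
  g <- rep(c(0, 1), c(length(xa), length(xb)))
  rss <- function(X) {
    beta <- solve(crossprod(X), crossprod(X, y))
    sum((y - X %*% beta)^2)
  }
  X_int <- cbind(1, x, g, x * g)
  X_add <- cbind(1, x, g)
  X_one <- cbind(1, x)
  N <- length(y)
  rss_int <- rss(X_int); rss_add <- rss(X_add); rss_one <- rss(X_one)
  F_slope <- (rss_add - rss_int) / (rss_int / (N - 4))
  F_elev <- (rss_one - rss_add) / (rss_add / (N - 3))
  list(F_slope = F_slope,
       p_slope = pf(F_slope, 1, N - 4, lower.tail = FALSE),
       F_elev = F_elev,
       p_elev = pf(F_elev, 1, N - 3, lower.tail = FALSE))
}

# attach arm labels from the counts table to an enrichment-points table
label_arms <- function(points, trial) {
  arm <- unique(trial$counts[, c("subject_id", "arm")])
  points$arm <- arm$arm[match(points$subject_id, arm$subject_id)]
  points
}

# down-window slope-equality p for blood eosinophils of one phase
downlabel_slope_p <- function(points, phase) {
  sel <- points$compartment == "blood" & points$cell_type == "eosinophil" &
    points$phase == phase
  ga <- points[sel & points$arm == "placebo", ]
  gb <- points[sel & points$arm == "mepolizumab", ]
  cmp <- compare_phase_regressions(ga, gb)
  if (is.null(cmp$down)) NA_real_ else cmp$down$p_slope
}
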