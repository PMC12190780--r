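# Independent oracles used by the tests.  Each is a deliberately brute-force
# or closed-form computation that shares no code with the implementation it
# checks.

# a known 4PL curve used across calibration tests
make_curve <- function(a = 0.05, d = 2.0, c = 400, b = 1.2,
                       working_range = c(31.3, 2000)) {
  structure(list(a = a, d = d, c = c, b = b, working_range = working_range,
                 fit_residual = 0, n_levels = NA_integer_, data = NULL),
            class = "fgf21_curve")
}

# grid-search 4PL oracle: grid over (c, b); for each, (a, d) solved by linear
# least squares since signal = a*w + d*(1-w) with w = 1/(1 + (x/c)^b)
grid_4pl_oracle <- function(x, y, c_grid, b_grid) {
  best <- NULL
  for (cc in c_grid) for (bb in b_grid) {
    w <- 1 / (1 + (x / cc)^bb)
    fit <- stats::lm.fit(cbind(w, 1 - w), y)
    rss <- sum(fit$residuals^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(a = fit$coefficients[1], d = fit$coefficients[2],
                   c = cc, b = bb, rss = rss)
    }
  }
  best
}

two_sided_from_tails <- function(p_le, p_ge) min(1, 2 * min(p_le, p_ge))

# exhaustive permutation null of the Spearman statistic (no ties assumed)
brute_spearman <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  r_obs <- stats::cor(rx, ry)
  perms <- gtools_permutations(n)
  r_all <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
  eps <- 1e-12
  list(estimate = r_obs,
       p.value = two_sided_from_tails(mean(r_all <= r_obs + eps),
                                      mean(r_all >= r_obs - eps)))
}

# all permutations of 1..n (n small), no external dependency
gtools_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- gtools_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (j in seq_len(nrow(sub))) {
      out[row, ] <- c(i, rest[sub[j, ]])
      row <- row + 1L
    }
  }
  out
}

# exhaustive group-assignment null of the Mann-Whitney U statistic
brute_mann_whitney <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  eps <- 1e-12
  list(U = u_obs,
       p.value = two_sided_from_tails(mean(u_all <= u_obs + eps),
                                      mean(u_all >= u_obs - eps)))
}

# exhaustive sign-flip null of the Wilcoxon signed-rank statistic
# (zeros dropped, no tied absolute differences assumed)
brute_signed_rank <- function(x, y) {
  d <- y - x
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  eps <- 1e-12
  list(V = v_obs,
       p.value = two_sided_from_tails(mean(v_all <= v_obs + eps),
                                      mean(v_all >= v_obs - eps)))
}

# pairwise-comparison AUC oracle: fraction of positive-negative pairs
# correctly ordered, ties counting one half
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

kit_extdata <- function(name) {
  system.file("extdata", name, package = "fgf21val", mustWork = TRUE)
}
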