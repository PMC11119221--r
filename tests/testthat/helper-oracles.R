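# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the enumerator filters raw subset pairs by the
# admissibility rules, and the likelihood oracle maximizes the marginal
# log-likelihood written out directly, group by group.

# Brute-force candidate enumeration: loop over every (fixed subset, random
# structure, slope subset) triple and keep the admissible ones. Returns the
# number of admissible structures; independent of enumerateCandidates().
bruteForceCount <- function(f, s, has_group = TRUE) {
  stopifnot(s <= f)
  fixed_subsets <- expand.grid(rep(list(c(FALSE, TRUE)), f),
                               KEEP.OUT.ATTRS = FALSE)
  if (f == 0L) fixed_subsets <- data.frame(row.names = 1)
  n <- 0L
  for (i in seq_len(nrow(fixed_subsets))) {
    in_model <- if (f > 0) unlist(fixed_subsets[i, ]) else logical(0)
    n <- n + 1L  # fixed-effects-only model
    if (!has_group) next
    n <- n + 1L  # random-intercept model
    if (s == 0L) next
    # slope subsets: slopes are the first s free predictors; a slope is
    # admissible only when its fixed effect is in the model
    slope_subsets <- expand.grid(rep(list(c(FALSE, TRUE)), s),
                                 KEEP.OUT.ATTRS = FALSE)
    for (j in seq_len(nrow(slope_subsets))) {
      sl <- unlist(slope_subsets[j, ])
      if (!any(sl)) next                       # covered by the RI stratum
      if (any(sl & !in_model[seq_len(s)])) next  # slope w/o fixed effect
      n <- n + 1L
    }
  }
  n
}

# Direct maximization of the Gaussian LMM marginal log-likelihood
# LL = -1/2 sum_g [ n_g log(2 pi) + log|V_g| + r_g' V_g^{-1} r_g ],
# V_g = Z_g Psi Z_g' + sigma^2 I, over (beta, log sigma, L) with Psi = L L'.
# Multiple deterministic starts + BFGS polish; returns the best LL found.
oracleMarginalLL <- function(y, X, Z, gid, n_starts = 6L) {
  gid <- as.integer(factor(gid))
  q <- ncol(Z)
  p <- ncol(X)
  n_l <- q * (q + 1L) / 2L
  lt <- which(lower.tri(diag(q), diag = TRUE))

  negll <- function(theta) {
    beta <- theta[seq_len(p)]
    sigma <- exp(theta[p + 1L])
    L <- matrix(0, q, q)
    L[lt] <- theta[(p + 2L):(p + 1L + n_l)]
    Psi <- L %*% t(L)
    r <- y - X %*% beta
    ll <- 0
    for (g in unique(gid)) {
      idx <- which(gid == g)
      Zg <- Z[idx, , drop = FALSE]
      Vg <- Zg %*% Psi %*% t(Zg) + diag(sigma^2, length(idx))
      ch <- tryCatch(chol(Vg), error = function(e) NULL)
      if (is.null(ch)) return(1e10)
      rg <- r[idx]
      u <- backsolve(ch, rg, transpose = TRUE)
      ll <- ll - 0.5 * (length(idx) * log(2 * pi) +
                        2 * sum(log(diag(ch))) + sum(u^2))
    }
    -ll
  }

  ols <- stats::lm.fit(X, y)
  beta0 <- ols$coefficients
  s0 <- log(sqrt(sum(ols$residuals^2) / length(y)))
  best <- Inf
  set.seed(42)
  for (k in seq_len(n_starts)) {
    L0 <- diag(q) * c(0.5, 1, 0.1, 2, 0.25, 1.5)[k]
    th0 <- c(beta0, s0, L0[lt])
    if (k > 3L) th0 <- th0 + stats::rnorm(length(th0), sd = 0.3)
    opt <- tryCatch(
      stats::optim(th0, negll, method = "BFGS",
                   control = list(maxit = 1000, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(opt)) {
      opt2 <- tryCatch(
        stats::optim(opt$par, negll, method = "Nelder-Mead",
                     control = list(maxit = 5000, reltol = 1e-14)),
        error = function(e) NULL)
      if (!is.null(opt2) && opt2$value < opt$value) opt <- opt2
      if (opt$value < best) best <- opt$value
    }
  }
  -best
}

# 30-row, 3-group toy dataset used by the likelihood cross-checks
toyGroupedData <- function(seed = 11) {
  set.seed(seed)
  g <- rep(c("a", "b", "c"), each = 10)
  b0 <- c(-1, 0, 1.2)[rep(1:3, each = 10)]
  b1 <- c(0.5, -0.4, 0.1)[rep(1:3, each = 10)]
  x1 <- rnorm(30)
  y <- 0.5 + b0 + (1 + b1) * x1 + rnorm(30, sd = 0.8)
  data.frame(Y = y, X1 = x1, G = g)
}

# small seeded multi-group generator used where a full simSpec is overkill
quickGrouped <- function(seed, n_groups = 8, size = 15, beta1 = 1,
                         tau0 = 1, tau1 = 0.5, sigma = 1) {
  set.seed(seed)
  g <- rep(seq_len(n_groups), each = size)
  u0 <- rnorm(n_groups, sd = tau0)
  u1 <- rnorm(n_groups, sd = tau1)
  x <- rnorm(n_groups * size)
  y <- u0[g] + (beta1 + u1[g]) * x + rnorm(n_groups * size, sd = sigma)
  data.frame(Y = y, X1 = x, G = factor(g))
}
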