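# Covariance-matrix-adaptation evolution strategy (CMA-ES), standard
# (mu/mu_w, lambda) formulation with cumulative step-size adaptation and
# rank-one + rank-mu covariance updates. Minimizes `fn` over the unit box
# [0,1]^n; candidates outside the box are evaluated at their clamped position
# with a quadratic out-of-box penalty. Deterministic given the RNG state.
#
# This is the optimizer used for all model fitting in the package; it is
# self-contained because the fitting objective (the gamma factor) is
# non-smooth and derivative-free search is required.
cma_es_minimize <- function(fn, x0, sigma0 = 0.3, lambda = 16L,
                            max_evals = 3000L, tol_fun = 1e-6,
                            stagnation_gens = 40L) {
  n <- length(x0)
  lambda <- max(4L, as.integer(lambda))
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mu_eff <- 1 / sum(w^2)
  cc <- (4 + mu_eff / n) / (n + 4 + 2 * mu_eff / n)
  cs <- (mu_eff + 2) / (n + mu_eff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mu_eff)
  cmu <- min(1 - c1, 2 * (mu_eff - 2 + 1 / mu_eff) / ((n + 2)^2 + mu_eff))
  damps <- 1 + 2 * max(0, sqrt((mu_eff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  xmean <- x0
  sigma <- sigma0
  pc <- ps <- numeric(n)
  C <- diag(n)
  evals <- 0L
  best_x <- x0
  best_f <- Inf
  hist_best <- numeric(0)
  gen <- 0L

  while (evals < max_evals) {
    gen <- gen + 1L
    eig <- eigen(C, symmetric = TRUE)
    D <- sqrt(pmax(eig$values, 1e-20))
    B <- eig$vectors
    BD <- B %*% diag(D, n)
    Z <- matrix(rnorm(n * lambda), n, lambda)
    Y <- BD %*% Z
    X <- xmean + sigma * Y
    fvals <- numeric(lambda)
    for (k in seq_len(lambda)) {
      xk <- X[, k]
      xc <- pmin(pmax(xk, 0), 1)
      pen <- sum((xk - xc)^2)
      fvals[k] <- fn(xc) + 1e3 * pen
      evals <- evals + 1L
      if (fvals[k] < best_f) {
        best_f <- fvals[k]
        best_x <- xc
      }
    }
    ord <- order(fvals)
    ysel <- Y[, ord[seq_len(mu)], drop = FALSE]
    ymean <- drop(ysel %*% w)
    xmean <- xmean + sigma * ymean

    Cinv_half <- B %*% diag(1 / D, n) %*% t(B)
    ps <- (1 - cs) * ps +
      sqrt(cs * (2 - cs) * mu_eff) * drop(Cinv_half %*% ymean)
    hsig <- sqrt(sum(ps^2)) / sqrt(1 - (1 - cs)^(2 * gen)) / chiN <
      1.4 + 2 / (n + 1)
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mu_eff) * ymean
    rank_mu <- ysel %*% diag(w, mu) %*% t(ysel)
    C <- (1 - c1 - cmu) * C +
      c1 * (pc %o% pc + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * rank_mu
    C <- (C + t(C)) / 2
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
    sigma <- min(sigma, 1)  # box is unit-scaled; cap runaway steps

    hist_best <- c(hist_best, min(fvals))
    if (length(hist_best) > stagnation_gens) {
      recent <- tail(hist_best, stagnation_gens)
      if (max(recent) - min(recent) < tol_fun) break
    }
  }
  list(x = best_x, f = best_f, evals = evals, generations = gen)
}

# Restarted minimization: the first start is at `x0` (box midpoint by
# default), further starts are drawn uniformly in the central part of the
# box. Returns the best-ever candidate across restarts.
cma_es_restarts <- function(fn, n, sigma0 = 0.3, lambda = 16L,
                            max_evals = 3000L, restarts = 2L) {
  per_run <- max(lambda * 10L, ceiling(max_evals / (restarts + 1L)))
  best <- NULL
  used <- 0L
  for (r in 0:restarts) {
    if (used >= max_evals) break
    x0 <- if (r == 0) rep(0.5, n) else runif(n, 0.25, 0.75)
    res <- cma_es_minimize(fn, x0, sigma0 = sigma0, lambda = lambda,
                           max_evals = min(per_run, max_evals - used))
    used <- used + res$evals
    if (is.null(best) || res$f < best$f) best <- res
  }
  best$evals <- used
  best
}
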