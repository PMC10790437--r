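# Independent oracles and small fixtures shared across test files.
# Oracles are deliberately naive (loops, enumeration, optimize on a
# bracket) and never call the implementation they check.

# step-up BH by explicit sort + cummin from the top
oracle_bh <- function(p) {
  out <- rep(NA_real_, length(p))
  obs <- which(!is.na(p))
  pv <- p[obs]
  m <- length(pv)
  o <- order(pv)
  adj <- numeric(m)
  run <- Inf
  for (i in seq(m, 1)) {
    run <- min(run, pv[o[i]] * m / i)
    adj[o[i]] <- min(1, run)
  }
  out[obs] <- adj
  out
}

# all-pairs concordance by explicit double loop
oracle_harrell_c <- function(time, event, risk) {
  n <- length(time)
  conc <- 0; comp <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || event[i] != 1) next
      if (time[i] < time[j] || (time[i] == time[j] && event[j] == 0)) {
        comp <- comp + 1
        if (risk[i] > risk[j]) conc <- conc + 1
        else if (risk[i] == risk[j]) conc <- conc + 0.5
      }
    }
  }
  if (comp == 0) NA_real_ else conc / comp
}

# AUC by trapezoidal integration of the empirical ROC curve
oracle_auc_trapezoid <- function(labels, score) {
  th <- sort(unique(score), decreasing = TRUE)
  sens <- c(0, vapply(th, function(t) mean(score[labels == 1] >= t), numeric(1)), 1)
  fpr <- c(0, vapply(th, function(t) mean(score[labels == 0] >= t), numeric(1)), 1)
  sum(diff(fpr) * (head(sens, -1) + tail(sens, -1)) / 2)
}

# 1-D conditional-logistic maximizer on a bracket
oracle_clogit_1d <- function(d) {
  f <- function(b) -sum(log1p(exp(-d * b)))
  stats::optimize(f, c(-20, 20), maximum = TRUE, tol = 1e-12)$maximum
}

# iteratively refined dense grid search over 2-D coefficient space:
# each round lays a 41 x 41 grid around the incumbent and shrinks the
# window tenfold; four rounds reach ~2e-5 resolution.  objv must map a
# 2 x k matrix of candidate betas to k objective values (vectorized).
refine_grid_2d <- function(objv, lim = 2, rounds = 5) {
  centre <- c(0, 0); half <- lim
  best <- NULL
  for (r in seq_len(rounds)) {
    g1 <- seq(centre[1] - half, centre[1] + half, length.out = 41)
    g2 <- seq(centre[2] - half, centre[2] + half, length.out = 41)
    gr <- t(as.matrix(expand.grid(g1, g2)))
    vals <- objv(gr)
    i <- which.min(vals)
    centre <- gr[, i]
    best <- vals[i]
    half <- half / 8
  }
  list(beta = centre, value = best)
}

# penalty term for a 2 x k matrix of betas
enet_pen_v <- function(B, alpha, lambda) {
  lambda * (alpha * colSums(abs(B)) + (1 - alpha) / 2 * colSums(B^2))
}

# refined grid minimizer of the penalized pair-difference objective
oracle_clogit_enet_grid <- function(D, alpha, lambda, lim = 2) {
  stopifnot(ncol(D) == 2)
  objv <- function(B) {
    eta <- D %*% B                        # n x k
    colMeans(log1p(exp(-eta))) + enet_pen_v(B, alpha, lambda)
  }
  out <- refine_grid_2d(objv, lim)
  out$obj <- function(b) objv(matrix(b, 2, 1))[1]
  out
}

# refined grid minimizer of the penalized (Breslow) Cox objective
oracle_cox_enet_grid <- function(X, time, event, alpha, lambda, lim = 2) {
  stopifnot(ncol(X) == 2)
  o <- order(time)
  Xo <- X[o, , drop = FALSE]; to <- time[o]; eo <- event[o]
  n <- nrow(Xo)
  first <- !duplicated(to)
  map <- match(to, to[first])
  objv <- function(B) {
    eta <- Xo %*% B
    eta <- sweep(eta, 2, colMeans(eta))
    ex <- exp(eta)
    rs <- apply(ex[n:1, , drop = FALSE], 2, cumsum)[n:1, , drop = FALSE]
    pl <- vapply(seq_len(ncol(B)), function(k) {
      riskmap <- rs[first, k][map]
      sum(eta[eo == 1, k]) - sum(log(riskmap[eo == 1]))
    }, numeric(1))
    -pl / n + enet_pen_v(B, alpha, lambda)
  }
  out <- refine_grid_2d(objv, lim)
  out$obj <- function(b) objv(matrix(b, 2, 1))[1]
  out
}

# small matched toy cohort with an optional planted case effect
toy_cohort <- function(seed = 1, n_pairs = 40, n_features = 30,
                       effect = 0, ...) {
  cfg <- sim_config(seed = seed, n_pairs = n_pairs, n_features = n_features,
                    n_atn_signal = if (effect == 0) 0 else 3,
                    n_ad_signal = if (effect == 0) 0 else 4,
                    n_overlap = if (effect == 0) 0 else 1,
                    effect_log_or = effect, effect_log_hr = effect / 2,
                    ...)
  generate_cohort(cfg, method = "direct")
}

# finite-difference gradient
fd_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- rep(0, length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}
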