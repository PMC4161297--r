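# Independent oracles used across the suite. These deliberately avoid the
# package's computational path: densities via dnorm(), integration via
# Gauss-Hermite quadrature, modes via general-purpose optimizers.

# Gauss-Hermite rule for weight exp(-x^2) (Golub-Welsch on the Jacobi matrix).
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

# Joint NLL of one fish's data and random effects, coded independently.
oracle_joint_nll <- function(ages, lengths, u, v, a, b, t0, su, sv, se) {
  k <- exp(a + su * u)
  linf <- exp(b + sv * v)
  mu <- linf * (1 - exp(-k * (ages - t0)))
  -sum(dnorm(lengths, mu, se, log = TRUE)) -
    dnorm(u, log = TRUE) - dnorm(v, log = TRUE)
}

# Adaptive 2-D Gauss-Hermite marginal NLL for one fish, centered and scaled
# at the joint mode found by a generic optimizer with FD curvature.
oracle_gh_marginal_nll <- function(ages, lengths, a, b, t0, su, sv, se,
                                   n_nodes = 15, start = c(0, 0)) {
  f <- function(z) oracle_joint_nll(ages, lengths, z[1], z[2],
                                    a, b, t0, su, sv, se)
  opt <- optim(start, f, method = "BFGS", control = list(reltol = 1e-14))
  m <- opt$par
  h <- 1e-4
  H <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    ei <- ej <- c(0, 0); ei[i] <- h; ej[j] <- h
    H[i, j] <- (f(m + ei + ej) - f(m + ei - ej) -
                f(m - ei + ej) + f(m - ei - ej)) / (4 * h^2)
  }
  S <- chol(solve((H + t(H)) / 2))  # upper, Sigma = t(S) %*% S
  gh <- gauss_hermite(n_nodes)
  grid <- expand.grid(i = seq_len(n_nodes), j = seq_len(n_nodes))
  g <- mapply(function(i, j) {
    z <- c(gh$nodes[i], gh$nodes[j])
    pt <- m + sqrt(2) * as.numeric(t(S) %*% z)
    sum(z^2) - f(pt) + log(gh$weights[i]) + log(gh$weights[j])
  }, grid$i, grid$j)
  M <- max(g)
  log_marg <- log(2 * abs(prod(diag(S)))) + M + log(sum(exp(g - M)))
  -log_marg
}

# No-predictor parameter vector in the fitted-model layout.
theta_no_pred <- function(linf = 330, k = 0.37, t0 = -0.38,
                          sigma_u = 0.22, sigma_v = 0.22, sigma_eps = 8) {
  c(k_intercept = log(k), linf_intercept = log(linf), t0 = t0,
    log_sigma_u = log(sigma_u), log_sigma_v = log(sigma_v),
    log_sigma_eps = log(sigma_eps))
}

# Small deterministic dataset: one cohort, lengths exactly on one curve.
exact_curve_data <- function(n_fish = 6, ages = 1:8,
                             linf = 330, k = 0.37, t0 = -0.38) {
  records <- do.call(rbind, lapply(seq_len(n_fish), function(i) {
    data.frame(fish_id = paste0("f", i), cohort_id = "c1", age = ages,
               length = vbgf_length(ages, linf, k, t0))
  }))
  growth_data(records)
}
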