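# shared fixtures, built in code

# standardized random matrix with IDs
rand_matrix <- function(n, p, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%03d", seq_len(n)),
                              sprintf("F%03d", seq_len(p))))
  scale(m)
}

# the default planted benchmark: two groups of 30, 200 features, 5 planted
# features at standardized effect 1.5
benchmark_data <- function(seed, n_per_group = 30, p = 200, n_planted = 5,
                           effect = 1.5) {
  set.seed(seed)
  n <- 2 * n_per_group
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%03d", seq_len(n)),
                              sprintf("F%03d", seq_len(p))))
  y <- rep(c("case", "control"), each = n_per_group)
  x[y == "case", seq_len(n_planted)] <- x[y == "case", seq_len(n_planted)] + effect
  list(x = scale(x), y = y, planted = sprintf("F%03d", seq_len(n_planted)))
}

# small count feature table
toy_count_table <- function(seed = 1, n = 10, p = 6, layer = "microbiota") {
  set.seed(seed)
  m <- matrix(rpois(n * p, 20), n, p,
              dimnames = list(sprintf("s%02d", seq_len(n)),
                              sprintf("OTU%02d", seq_len(p))))
  feature_table(m, layer, "count")
}

# unpenalized logistic ML by direct optimization (oracle; independent of
# glm/glmnet)
logistic_ml_oracle <- function(x, y01) {
  nll <- function(par) {
    eta <- par[1] + drop(x %*% par[-1])
    -sum(y01 * eta - log1p(exp(eta)))
  }
  opt <- optim(rep(0, ncol(x) + 1), nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  opt$par
}

# penalized logistic objective (1/n scaled, unpenalized intercept)
penalized_objective <- function(b0, beta, x, y01, alpha, lambda) {
  eta <- b0 + drop(x %*% beta)
  -mean(y01 * eta - log1p(exp(eta))) +
    lambda * (alpha * sum(abs(beta)) + (1 - alpha) / 2 * sum(beta^2))
}

# Mann-Whitney pair-count AUC oracle (ties half credit)
auc_pair_oracle <- function(values, labels, positive) {
  pos <- values[labels == positive]
  neg <- values[labels != positive]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# binomial two-proportion LRT oracle (closed-form MLEs)
binomial_lrt_oracle <- function(xa, na, xb, nb) {
  ll <- function(x, n, p) sum(dbinom(x, n, p, log = TRUE))
  pa <- sum(xa) / sum(na); pb <- sum(xb) / sum(nb)
  p0 <- (sum(xa) + sum(xb)) / (sum(na) + sum(nb))
  2 * (ll(xa, na, pa) + ll(xb, nb, pb) - ll(c(xa, xb), c(na, nb), p0))
}
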