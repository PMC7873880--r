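# Independent oracle implementations used to validate the package's fast
# paths.  These deliberately avoid the eigen-rotation tricks of the
# implementation: likelihoods are evaluated with dense covariance matrices,
# and combinatorial rules (pruning, window matching) by exhaustive
# enumeration.

# Dense univariate ML profile log-likelihood at a given log(delta).
dense_uni_ll <- function(log_delta, X, y, K) {
  n <- length(y)
  V0 <- exp(log_delta) * K + diag(n)
  Vi <- solve(V0)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  se2 <- drop(t(r) %*% Vi %*% r) / n
  -0.5 * (n * log(2 * pi * se2) + determinant(V0)$modulus + n)
}

# Dense univariate ML fit: maximize over log(delta) on the same bounds as
# the implementation.
dense_uni_fit <- function(X, y, K) {
  opt <- stats::optimize(function(ld) dense_uni_ll(ld, X, y, K),
                         c(-10, 10), maximum = TRUE, tol = 1e-8)
  max(opt$objective, dense_uni_ll(-10, X, y, K), dense_uni_ll(10, X, y, K))
}

# Dense univariate scan: per-marker ML LRT p-values without rotation.
dense_uni_scan_p <- function(y, Gm, K) {
  ll0 <- dense_uni_fit(matrix(1, length(y), 1), y, K)
  vapply(seq_len(ncol(Gm)), function(s) {
    lls <- dense_uni_fit(cbind(1, Gm[, s]), y, K)
    stats::pchisq(max(0, 2 * (lls - ll0)), 1, lower.tail = FALSE)
  }, numeric(1))
}

# Dense two-trait negative log-likelihood in 2n x 2n Kronecker form.
dense_mv_negll <- function(theta, X, Y, K) {
  n <- nrow(Y)
  Lg <- matrix(c(exp(theta[1]), theta[2], 0, exp(theta[3])), 2, 2)
  Le <- matrix(c(exp(theta[4]), theta[5], 0, exp(theta[6])), 2, 2)
  Om <- kronecker(tcrossprod(Lg), K) + kronecker(tcrossprod(Le), diag(n))
  X2 <- kronecker(diag(2), X)
  yv <- c(Y[, 1], Y[, 2])
  Oi <- solve(Om)
  beta <- solve(t(X2) %*% Oi %*% X2, t(X2) %*% Oi %*% yv)
  r <- yv - X2 %*% beta
  0.5 * (2 * n * log(2 * pi) + determinant(Om)$modulus + drop(t(r) %*% Oi %*% r))
}

dense_mv_fit <- function(X, Y, K) {
  vy <- diag(stats::cov(Y))
  chol_pack <- function(V) {
    L <- t(chol(V + diag(1e-8, 2)))
    c(log(L[1, 1]), L[2, 1], log(L[2, 2]))
  }
  starts <- list(c(chol_pack(diag(0.5 * vy)), chol_pack(diag(0.5 * vy))),
                 c(chol_pack(diag(0.05 * vy)), chol_pack(diag(0.95 * vy))),
                 c(chol_pack(diag(0.95 * vy)), chol_pack(diag(0.05 * vy))))
  best <- Inf
  for (th in starts) {
    o <- stats::optim(th, dense_mv_negll, X = X, Y = Y, K = K,
                      method = "Nelder-Mead", control = list(maxit = 4000, reltol = 1e-12))
    o <- stats::optim(o$par, dense_mv_negll, X = X, Y = Y, K = K,
                      method = "BFGS", control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, o$value)
  }
  -best
}

# Two-response multivariate regression LRT (no kinship): Wilks-type
# chi-square(2) statistic from ML residual covariances.
mv_regression_p <- function(Y, Gm) {
  n <- nrow(Y)
  S0 <- crossprod(stats::resid(stats::lm(Y ~ 1))) / n
  vapply(seq_len(ncol(Gm)), function(s) {
    S1 <- crossprod(stats::resid(stats::lm(Y ~ Gm[, s]))) / n
    lrt <- n * (determinant(S0)$modulus - determinant(S1)$modulus)
    stats::pchisq(max(0, lrt), 2, lower.tail = FALSE)
  }, numeric(1))
}

# Brute-force re-implementation of the windowed greedy pruning rule, written
# directly from its verbal description (windows of `window` markers advanced
# by `step`; within a window, repeatedly drop the smaller-MAF member of the
# worst pair at or above the threshold, later index on ties).
brute_force_prune <- function(X, map, prune_r2, window, step) {
  mafs <- pmin(colMeans(X) / 2, 1 - colMeans(X) / 2)
  keep <- rep(TRUE, ncol(X))
  for (ch in unique(map$chr)) {
    idx <- which(map$chr == ch)
    start <- 1L
    while (start <= length(idx)) {
      repeat {
        wi <- idx[start:min(start + window - 1L, length(idx))]
        wi <- wi[keep[wi]]
        if (length(wi) < 2) break
        worst <- c(NA, NA, -1)
        for (a in seq_along(wi)) for (b in seq_along(wi)) if (a < b) {
          xa <- X[, wi[a]]; xb <- X[, wi[b]]
          if (stats::var(xa) == 0 || stats::var(xb) == 0) next
          r2 <- stats::cor(xa, xb)^2
          if (r2 > worst[3]) worst <- c(wi[a], wi[b], r2)
        }
        if (worst[3] < prune_r2) break
        a <- worst[1]; b <- worst[2]
        drop <- if (mafs[a] < mafs[b]) a else if (mafs[b] < mafs[a]) b else max(a, b)
        keep[drop] <- FALSE
      }
      start <- start + step
    }
  }
  which(keep)
}

# Small LD panel shared across tests (generated, deterministic).
make_test_panel <- function(n = 80, n_chr = 3, m_chr = 40, seed = 418,
                            profile = "maize-like") {
  filter_markers(generate_genotypes(n, n_chr, m_chr, ld_profile(profile),
                                    seed = seed),
                 min_mac = 2)
}

# Hand-built panel from an explicit dosage matrix (one chromosome,
# positions 1000, 2000, ...).
panel_from_matrix <- function(X, chr = NULL, pos = NULL) {
  X <- as.matrix(X)
  m <- ncol(X)
  map <- data.frame(
    id = paste0("m", seq_len(m)),
    chr = chr %||% rep(1L, m),
    pos = pos %||% (1000L * seq_len(m)),
    a1 = "A", a2 = "C", stringsAsFactors = FALSE
  )
  pleiolink:::new_genotype_panel(X, map, sprintf("i%03d", seq_len(nrow(X))))
}
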