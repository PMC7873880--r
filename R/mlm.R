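# Univariate and two-trait multivariate linear mixed-model association scans.
#
# Model (univariate):  y = X b + u + e,  u ~ N(0, sg2 K),  e ~ N(0, se2 I).
# The kinship K is eigendecomposed once (K = U D U'); rotating all inputs by
# U' diagonalizes the covariance, so the profile log-likelihood over
# delta = sg2 / se2 costs O(n) per evaluation.  Marker tests follow the
# likelihood-ratio convention of GEMMA's `-lmm 2`: maximum likelihood (not
# REML), chi-square(1) for the univariate SNP effect and chi-square(2) for
# the joint two-trait SNP effect.
#
# Model (multivariate): rows of the rotated n x 2 phenotype matrix are
# independent with covariance d_i * Vg + Ve; the six free parameters of
# (Vg, Ve) are optimized through a log-Cholesky parameterization (Ve kept
# positive definite, Vg positive semidefinite).

DELTA_LOG_BOUNDS <- c(-10, 10)

#' VanRaden genomic relationship matrix
#'
#' `K = W W' / (2 * sum_j p_j (1 - p_j))`, where column `j` of `W` holds the
#' dosages of marker `j` centered by twice its sample allele frequency
#' `p_j`.  Monomorphic markers are dropped.
#'
#' @param G A `genotype_panel` or an individuals x markers dosage matrix.
#' @return A symmetric n x n matrix with individual ids as dimnames.
#' @export
vanraden_kinship <- function(G) {
  X <- if (inherits(G, "genotype_panel")) G$dosages else as.matrix(G)
  if (anyNA(X)) stop_invalid("kinship requires a complete dosage matrix")
  p <- colMeans(X) / 2
  poly <- p > 0 & p < 1
  if (sum(poly) < 2) stop_invalid("need >= 2 polymorphic markers for kinship")
  X <- X[, poly, drop = FALSE]
  p <- p[poly]
  W <- sweep(X, 2, 2 * p)
  K <- tcrossprod(W) / (2 * sum(p * (1 - p)))
  K <- (K + t(K)) / 2
  dimnames(K) <- list(rownames(X), rownames(X))
  K
}

#' Eigendecompose a kinship matrix for repeated mixed-model use
#'
#' Eigenvalues below zero (numerical noise) are clamped to zero.  The
#' returned object can be passed wherever a kinship matrix is accepted, to
#' avoid repeating the decomposition across traits and replicates.
#'
#' @param K Symmetric kinship matrix.
#' @return List with `values`, `vectors`, `n`, of class `kinship_eigen`.
#' @export
kinship_eigen <- function(K) {
  if (inherits(K, "kinship_eigen")) return(K)
  if (!isSymmetric(unname(K), tol = 1e-6)) stop_invalid("kinship matrix must be symmetric")
  e <- eigen(K, symmetric = TRUE)
  if (min(e$values) < -1e-4)
    warning(sprintf("kinship has eigenvalue %.3g; clamping to 0", min(e$values)))
  e$values <- pmax(e$values, 0)
  structure(list(values = e$values, vectors = e$vectors, n = nrow(K)),
            class = "kinship_eigen")
}

# Profile log-likelihood machinery: given rotated X*, y* and weights
# v = delta * d + 1, ML profiles out beta and se2 analytically.
rotated_profile_ll <- function(log_delta, d, Xr, yr) {
  n <- length(yr)
  v <- exp(log_delta) * d + 1
  iv <- 1 / v
  XtVX <- crossprod(Xr, Xr * iv)
  XtVy <- crossprod(Xr, yr * iv)
  beta <- solve(XtVX, XtVy)
  r <- yr - Xr %*% beta
  rss <- sum(r * r * iv)
  se2 <- rss / n
  ll <- -0.5 * (n * log(2 * pi * se2) + sum(log(v)) + n)
  list(ll = ll, beta = beta, se2 = se2)
}

optimize_delta <- function(d, Xr, yr) {
  obj <- function(ld) rotated_profile_ll(ld, d, Xr, yr)$ll
  opt <- stats::optimize(obj, DELTA_LOG_BOUNDS, maximum = TRUE, tol = 1e-8)
  cands <- c(opt$maximum, DELTA_LOG_BOUNDS)
  lls <- c(opt$objective, obj(DELTA_LOG_BOUNDS[1]), obj(DELTA_LOG_BOUNDS[2]))
  best <- which.max(lls)
  list(log_delta = cands[best], ll = lls[best],
       boundary = best > 1L || min(abs(cands[best] - DELTA_LOG_BOUNDS)) < 1e-6)
}

#' Fit the no-marker univariate mixed model by maximum likelihood
#'
#' Estimates `(sg2, se2)` for `y = mu + u + e`, `u ~ N(0, sg2 K)`, by scalar
#' bounded search over `log(delta)` on `[-10, 10]` after rotation by the
#' eigenvectors of `K`.  Solutions at the search boundary are reported as
#' such (`boundary = TRUE`), not hidden.
#'
#' @param y Phenotype vector (finite, non-constant, length >= 10).
#' @param K Kinship matrix or a [kinship_eigen()] object.
#' @param X Fixed-effect design matrix (default intercept only).
#' @return List with `sigma_g2`, `sigma_e2`, `delta`, `loglik`, `beta`,
#'   `boundary`.
#' @export
fit_null_univariate <- function(y, K, X = NULL) {
  if (anyNA(y) || !all(is.finite(y))) stop_invalid("`y` must be finite")
  if (length(y) < 10) stop_invalid("need n >= 10")
  if (stats::var(y) == 0) stop_invalid("`y` has zero variance")
  eig <- kinship_eigen(K)
  if (length(y) != eig$n) stop_invalid("length(y) does not match kinship dimension")
  if (is.null(X)) X <- matrix(1, length(y), 1)
  Ut <- t(eig$vectors)
  Xr <- Ut %*% X
  yr <- drop(Ut %*% y)
  opt <- optimize_delta(eig$values, Xr, yr)
  fit <- rotated_profile_ll(opt$log_delta, eig$values, Xr, yr)
  delta <- exp(opt$log_delta)
  list(sigma_g2 = delta * fit$se2, sigma_e2 = fit$se2, delta = delta,
       log_delta = opt$log_delta, loglik = opt$ll, beta = drop(fit$beta),
       boundary = opt$boundary)
}

#' Univariate mixed-model association scan
#'
#' Tests every marker under `y = mu + x_s a + u + e`.  In the default
#' `per_snp_ml` mode, `delta` is re-optimized under every marker's
#' alternative model and the likelihood-ratio statistic against the
#' no-marker null is referred to chi-square(1) (GEMMA `-lmm 2` semantics).
#' In `null_based` mode (EMMAX/P3D-style), `delta` is fixed at its null
#' estimate and a generalized-least-squares Wald test is used; this is much
#' faster and nearly indistinguishable in practice.
#'
#' Constant markers yield `NA` p-values (flagged, excluded from FDR
#' adjustment downstream).
#'
#' @param y Phenotype vector.
#' @param markers A `genotype_panel` or dosage matrix of markers to test
#'   (QTNs already removed upstream).
#' @param K Kinship matrix or [kinship_eigen()] object.
#' @param mode `"per_snp_ml"` or `"null_based"`.
#' @param map Optional marker map (taken from the panel when given).
#' @return Data frame: `chr`, `rs`, `ps`, `beta`, `stat`, `p_lrt`,
#'   one row per tested marker; model tag in `attr(, "model")`.
#' @export
univariate_scan <- function(y, markers, K, mode = c("per_snp_ml", "null_based"),
                            map = NULL) {
  mode <- match.arg(mode)
  if (inherits(markers, "genotype_panel")) {
    map <- markers$map
    Gm <- markers$dosages
  } else {
    Gm <- as.matrix(markers)
    if (is.null(map))
      map <- data.frame(id = colnames(Gm) %||% paste0("m", seq_len(ncol(Gm))),
                        chr = 1L, pos = seq_len(ncol(Gm)))
  }
  eig <- kinship_eigen(K)
  null <- fit_null_univariate(y, eig)
  Ut <- t(eig$vectors)
  yr <- drop(Ut %*% y)
  onesr <- drop(Ut %*% rep(1, length(y)))
  Gr <- Ut %*% Gm
  d <- eig$values
  m <- ncol(Gm)
  beta <- stat <- pval <- rep(NA_real_, m)
  constant <- apply(Gm, 2, function(x) stats::var(x) == 0)
  if (mode == "per_snp_ml") {
    for (s in seq_len(m)) {
      if (constant[s]) next
      Xr <- cbind(onesr, Gr[, s])
      opt <- optimize_delta(d, Xr, yr)
      fit <- rotated_profile_ll(opt$log_delta, d, Xr, yr)
      lrt <- max(0, 2 * (opt$ll - null$loglik))
      beta[s] <- fit$beta[2]
      stat[s] <- lrt
      pval[s] <- max(stats::pchisq(lrt, df = 1, lower.tail = FALSE), 1e-300)
    }
  } else {
    iv <- 1 / (null$delta * d + 1)
    a <- onesr
    A11 <- sum(a * a * iv)
    A12 <- drop(crossprod(Gr, a * iv))
    A22 <- drop(crossprod(Gr^2, iv))
    b1 <- sum(a * yr * iv)
    b2 <- drop(crossprod(Gr, yr * iv))
    det <- A11 * A22 - A12^2
    alpha <- (A11 * b2 - A12 * b1) / det
    va <- null$sigma_e2 * A11 / det
    w <- alpha^2 / va
    beta[!constant] <- alpha[!constant]
    stat[!constant] <- w[!constant]
    pval[!constant] <- pmax(stats::pchisq(w[!constant], df = 1, lower.tail = FALSE), 1e-300)
  }
  out <- data.frame(chr = map$chr, rs = map$id, ps = map$pos,
                    beta = beta, stat = stat, p_lrt = pval,
                    stringsAsFactors = FALSE)
  attr(out, "model") <- "univariate"
  attr(out, "null_fit") <- null
  out
}

# ---- multivariate (two traits) ----------------------------------------------

# log-Cholesky packing of (Vg, Ve): theta = (g1, g21, g2, e1, e21, e2) with
# L = [[exp(g1), 0], [g21, exp(g2)]], V = L L'.
theta_to_V <- function(theta) {
  Lg <- matrix(c(exp(theta[1]), theta[2], 0, exp(theta[3])), 2, 2)
  Le <- matrix(c(exp(theta[4]), theta[5], 0, exp(theta[6])), 2, 2)
  list(Vg = tcrossprod(Lg), Ve = tcrossprod(Le))
}

V_to_theta <- function(Vg, Ve) {
  safe_chol <- function(V) {
    L <- t(chol(V + diag(1e-8, 2)))
    c(log(L[1, 1]), L[2, 1], log(L[2, 2]))
  }
  c(safe_chol(Vg), safe_chol(Ve))
}

# Negative log-likelihood of the rotated two-trait model with GLS-profiled
# fixed effects.  Yr: n x 2 rotated phenotypes, Xr: n x p rotated design,
# d: kinship eigenvalues.  Row i has covariance S_i = d_i Vg + Ve; its
# 2 x 2 inverse is formed in closed form, vectorized over rows.
mv_negll <- function(theta, d, Xr, Yr) {
  if (!all(is.finite(theta)) || max(abs(theta)) > 50) return(1e10)
  V <- theta_to_V(theta)
  s11 <- d * V$Vg[1, 1] + V$Ve[1, 1]
  s12 <- d * V$Vg[1, 2] + V$Ve[1, 2]
  s22 <- d * V$Vg[2, 2] + V$Ve[2, 2]
  det <- s11 * s22 - s12^2
  if (!all(is.finite(det)) || any(det <= 0) || any(s11 <= 0)) return(1e10)
  i11 <- s22 / det; i22 <- s11 / det; i12 <- -s12 / det
  p <- ncol(Xr)
  # GLS for B (p x 2): normal equations in vec(B) with 2x2 blocks
  M <- matrix(0, 2 * p, 2 * p)
  rhs <- numeric(2 * p)
  U1 <- i11 * Yr[, 1] + i12 * Yr[, 2]
  U2 <- i12 * Yr[, 1] + i22 * Yr[, 2]
  for (a in seq_len(p)) {
    for (b in seq_len(p)) {
      xa_xb <- Xr[, a] * Xr[, b]
      M[2 * a - 1, 2 * b - 1] <- sum(xa_xb * i11)
      M[2 * a - 1, 2 * b] <- M[2 * a, 2 * b - 1] <- sum(xa_xb * i12)
      M[2 * a, 2 * b] <- sum(xa_xb * i22)
    }
    rhs[2 * a - 1] <- sum(Xr[, a] * U1)
    rhs[2 * a] <- sum(Xr[, a] * U2)
  }
  bvec <- tryCatch(solve(M, rhs), error = function(e) NULL)
  if (is.null(bvec)) return(1e10)
  B <- matrix(bvec, nrow = p, byrow = TRUE)  # p x 2
  R <- Yr - Xr %*% B
  quad <- sum(R[, 1]^2 * i11 + 2 * R[, 1] * R[, 2] * i12 + R[, 2]^2 * i22)
  n <- length(d)
  0.5 * (2 * n * log(2 * pi) + sum(log(det)) + quad)
}

mv_fit <- function(d, Xr, Yr) {
  vy <- diag(stats::cov(Yr))
  starts <- list(
    V_to_theta(diag(0.5 * vy), diag(0.5 * vy)),
    V_to_theta(diag(0.05 * vy), diag(0.95 * vy)),
    V_to_theta(diag(0.95 * vy), diag(0.05 * vy))
  )
  best <- NULL
  for (th0 in starts) {
    opt <- stats::optim(th0, mv_negll, d = d, Xr = Xr, Yr = Yr,
                        method = "Nelder-Mead",
                        control = list(maxit = 4000, reltol = 1e-12))
    opt <- stats::optim(opt$par, mv_negll, d = d, Xr = Xr, Yr = Yr,
                        method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  best
}

#' Fit the no-marker two-trait mixed model by maximum likelihood
#'
#' Estimates the 2 x 2 genetic and residual covariance matrices `(Vg, Ve)`
#' of the matrix-variate model in which, after rotation by the kinship
#' eigenvectors, phenotype row `i` is bivariate normal with covariance
#' `d_i Vg + Ve`.  The six free parameters are optimized numerically via a
#' log-Cholesky parameterization from three fixed starting points (best
#' likelihood wins), keeping `Ve` positive definite.
#'
#' @param Y n x 2 phenotype matrix (columns finite, non-constant, not
#'   collinear).
#' @param K Kinship matrix or [kinship_eigen()] object.
#' @param X Fixed-effect design (default intercept only).
#' @return List with `Vg`, `Ve`, `loglik`, `B` (fixed effects), and the
#'   genetic correlation `rg`.
#' @export
fit_null_multivariate <- function(Y, K, X = NULL) {
  Y <- as.matrix(Y)
  if (ncol(Y) != 2) stop_invalid("`Y` must have exactly two trait columns")
  if (anyNA(Y) || !all(is.finite(Y))) stop_invalid("`Y` must be finite")
  if (any(apply(Y, 2, stats::var) == 0)) stop_invalid("constant trait column")
  if (abs(stats::cor(Y[, 1], Y[, 2])) > 0.9999)
    stop_invalid("traits are collinear; multivariate model is singular")
  eig <- kinship_eigen(K)
  if (nrow(Y) != eig$n) stop_invalid("nrow(Y) does not match kinship dimension")
  if (is.null(X)) X <- matrix(1, nrow(Y), 1)
  Ut <- t(eig$vectors)
  Xr <- Ut %*% X
  Yr <- Ut %*% Y
  opt <- mv_fit(eig$values, Xr, Yr)
  V <- theta_to_V(opt$par)
  rg <- V$Vg[1, 2] / sqrt(max(V$Vg[1, 1] * V$Vg[2, 2], 1e-300))
  list(Vg = V$Vg, Ve = V$Ve, loglik = -opt$value, theta = opt$par, rg = rg,
       convergence = opt$convergence)
}

#' Two-trait multivariate mixed-model association scan
#'
#' Tests, for every marker, the joint null that the SNP has no effect on
#' either trait (2 degrees of freedom).  Default `null_based` mode fixes
#' `(Vg, Ve)` at their no-marker estimates and computes a generalized
#' least-squares Wald statistic per marker — the P3D analogue chosen for
#' desk-scale runtime.  `per_snp_ml` re-optimizes all six covariance
#' parameters under every marker's alternative and uses the likelihood
#' ratio; it is slow and intended for validating the default on small
#' panels.
#'
#' @param Y n x 2 phenotype matrix.
#' @param markers A `genotype_panel` or dosage matrix (QTNs removed).
#' @param K Kinship matrix or [kinship_eigen()] object.
#' @param mode `"null_based"` or `"per_snp_ml"`.
#' @param map Optional marker map.
#' @return Data frame: `chr`, `rs`, `ps`, `beta_1`, `beta_2`, `stat`,
#'   `p_lrt`; model tag `"multivariate"` in `attr(, "model")`.
#' @export
multivariate_scan <- function(Y, markers, K, mode = c("null_based", "per_snp_ml"),
                              map = NULL) {
  mode <- match.arg(mode)
  Y <- as.matrix(Y)
  if (inherits(markers, "genotype_panel")) {
    map <- markers$map
    Gm <- markers$dosages
  } else {
    Gm <- as.matrix(markers)
    if (is.null(map))
      map <- data.frame(id = colnames(Gm) %||% paste0("m", seq_len(ncol(Gm))),
                        chr = 1L, pos = seq_len(ncol(Gm)))
  }
  eig <- kinship_eigen(K)
  null <- fit_null_multivariate(Y, eig)
  Ut <- t(eig$vectors)
  Yr <- Ut %*% Y
  onesr <- drop(Ut %*% rep(1, nrow(Y)))
  Gr <- Ut %*% Gm
  d <- eig$values
  m <- ncol(Gm)
  beta1 <- beta2 <- stat <- pval <- rep(NA_real_, m)
  constant <- apply(Gm, 2, function(x) stats::var(x) == 0)
  if (mode == "null_based") {
    Vg <- null$Vg; Ve <- null$Ve
    # guard against a near-singular residual covariance estimate (possible
    # when almost all variance is absorbed by the polygenic term): ridge Ve
    # up to a small fraction of its trace so every row covariance d_i Vg + Ve
    # stays invertible
    ev <- eigen(Ve, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-4 * sum(diag(Ve)))
      Ve <- Ve + diag(1e-4 * sum(diag(Ve)), 2)
    s11 <- d * Vg[1, 1] + Ve[1, 1]
    s12 <- d * Vg[1, 2] + Ve[1, 2]
    s22 <- d * Vg[2, 2] + Ve[2, 2]
    det <- s11 * s22 - s12^2
    i11 <- s22 / det; i22 <- s11 / det; i12 <- -s12 / det
    U1 <- i11 * Yr[, 1] + i12 * Yr[, 2]
    U2 <- i12 * Yr[, 1] + i22 * Yr[, 2]
    a2 <- onesr^2
    C0 <- c(sum(a2 * i11), sum(a2 * i12), sum(a2 * i22))
    aG <- Gr * onesr
    C1_11 <- drop(crossprod(aG, i11)); C1_12 <- drop(crossprod(aG, i12))
    C1_22 <- drop(crossprod(aG, i22))
    G2 <- Gr^2
    C2_11 <- drop(crossprod(G2, i11)); C2_12 <- drop(crossprod(G2, i12))
    C2_22 <- drop(crossprod(G2, i22))
    r1 <- c(sum(onesr * U1), sum(onesr * U2))
    r2_1 <- drop(crossprod(Gr, U1)); r2_2 <- drop(crossprod(Gr, U2))
    for (s in seq_len(m)) {
      if (constant[s]) next
      M <- matrix(c(C0[1], C0[2], C1_11[s], C1_12[s],
                    C0[2], C0[3], C1_12[s], C1_22[s],
                    C1_11[s], C1_12[s], C2_11[s], C2_12[s],
                    C1_12[s], C1_22[s], C2_12[s], C2_22[s]), 4, 4)
      rhs <- c(r1, r2_1[s], r2_2[s])
      Minv <- tryCatch(solve(M), error = function(e) NULL)
      if (is.null(Minv)) next
      bvec <- Minv %*% rhs
      slopes <- bvec[3:4]
      Vsl <- Minv[3:4, 3:4]
      w <- tryCatch(drop(t(slopes) %*% solve(Vsl, slopes)), error = function(e) NA_real_)
      beta1[s] <- bvec[3]; beta2[s] <- bvec[4]
      stat[s] <- w
      pval[s] <- max(stats::pchisq(w, df = 2, lower.tail = FALSE), 1e-300)
    }
  } else {
    for (s in seq_len(m)) {
      if (constant[s]) next
      Xr <- cbind(onesr, Gr[, s])
      opt <- mv_fit(d, Xr, Yr)
      lrt <- max(0, 2 * (-opt$value - null$loglik))
      beta_fit <- mv_gls_B(opt$par, d, Xr, Yr)
      beta1[s] <- beta_fit[2, 1]; beta2[s] <- beta_fit[2, 2]
      stat[s] <- lrt
      pval[s] <- max(stats::pchisq(lrt, df = 2, lower.tail = FALSE), 1e-300)
    }
  }
  out <- data.frame(chr = map$chr, rs = map$id, ps = map$pos,
                    beta_1 = beta1, beta_2 = beta2, stat = stat, p_lrt = pval,
                    stringsAsFactors = FALSE)
  attr(out, "model") <- "multivariate"
  attr(out, "null_fit") <- null
  out
}

# GLS fixed-effect matrix at covariance parameters theta (helper for the
# per-marker ML mode).
mv_gls_B <- function(theta, d, Xr, Yr) {
  V <- theta_to_V(theta)
  s11 <- d * V$Vg[1, 1] + V$Ve[1, 1]
  s12 <- d * V$Vg[1, 2] + V$Ve[1, 2]
  s22 <- d * V$Vg[2, 2] + V$Ve[2, 2]
  det <- s11 * s22 - s12^2
  i11 <- s22 / det; i22 <- s11 / det; i12 <- -s12 / det
  p <- ncol(Xr)
  M <- matrix(0, 2 * p, 2 * p)
  rhs <- numeric(2 * p)
  U1 <- i11 * Yr[, 1] + i12 * Yr[, 2]
  U2 <- i12 * Yr[, 1] + i22 * Yr[, 2]
  for (a in seq_len(p)) {
    for (b in seq_len(p)) {
      xa_xb <- Xr[, a] * Xr[, b]
      M[2 * a - 1, 2 * b - 1] <- sum(xa_xb * i11)
      M[2 * a - 1, 2 * b] <- M[2 * a, 2 * b - 1] <- sum(xa_xb * i12)
      M[2 * a, 2 * b] <- sum(xa_xb * i22)
    }
    rhs[2 * a - 1] <- sum(Xr[, a] * U1)
    rhs[2 * a] <- sum(Xr[, a] * U2)
  }
  matrix(solve(M, rhs), nrow = p, byrow = TRUE)
}

#' Write a kinship matrix in GEMMA's plain-text square format
#'
#' @param K Kinship matrix.
#' @param path Output file.
#' @export
write_kinship <- function(K, path) {
  utils::write.table(format(K, digits = 10, trim = TRUE), path,
                     quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(path)
}

#' Read a plain-text square kinship matrix
#'
#' @param path File written by [write_kinship()] or GEMMA.
#' @param ids Optional individual ids for dimnames.
#' @return Symmetric numeric matrix.
#' @export
read_kinship <- function(path, ids = NULL) {
  K <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(K) <- if (!is.null(ids)) list(ids, ids) else NULL
  K
}
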