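#' Read, write and prune phylogenies
#'
#' Thin wrappers around `ape` keeping the package's contract: rooted trees,
#' branch lengths in time units, tips named by six-letter species codes.
#' Pruning preserves path lengths among the kept tips.
#'
#' @param file Newick file path (or a Newick string for `read_tree`).
#' @param tree A `phylo` object.
#' @param keep Character vector of tip labels to retain.
#' @return `read_tree`/`prune_tree` return a `phylo`.
#' @export
read_tree <- function(file) {
  tr <- if (file.exists(file)) ape::read.tree(file)
  else ape::read.tree(text = file)
  if (is.null(tr)) stop("invalid Newick input")
  tr
}

#' @rdname read_tree
#' @export
write_tree <- function(tree, file) {
  ape::write.tree(tree, file = file)
  invisible(file)
}

#' @rdname read_tree
#' @export
prune_tree <- function(tree, keep) {
  miss <- setdiff(keep, tree$tip.label)
  if (length(miss)) stop("unknown tips: ", paste(miss, collapse = ", "))
  ape::keep.tip(tree, keep)
}

#' Phylogenetic covariance matrix
#'
#' `C[i, j]` is the depth of the most recent common ancestor of tips i and j
#' (shared root-to-MRCA path length); the diagonal holds root-to-tip depths.
#' Pagel's lambda multiplies the off-diagonal entries.
#'
#' @param tree A rooted `phylo`.
#' @param lambda Optional Pagel's lambda in `[0, lambda_max(tree)]`.
#' @return `S x S` covariance matrix in tip-label order.
#' @export
phylo_vcv <- function(tree, lambda = NULL) {
  C <- ape::vcv.phylo(tree)
  if (!is.null(lambda)) {
    lmax <- lambda_max(C)
    if (lambda < 0 || lambda > lmax)
      stop(sprintf("lambda outside [0, %.3f]", lmax))
    d <- diag(C)
    C <- C * lambda
    diag(C) <- d
  }
  C
}

# largest lambda keeping the transformed matrix positive definite
lambda_max <- function(C) {
  off <- C[upper.tri(C)]
  if (!length(off) || max(off) <= 0) return(1)
  max(diag(C)) / max(off)
}

# profile the root state and rate out of a Gaussian tree likelihood:
# y ~ N(mu * 1, sigma2 * C); returns ML mu, sigma2 and logL
gls_profile <- function(y, C) {
  n <- length(y)
  R <- chol(C)
  yw <- backsolve(R, y, transpose = TRUE)
  ow <- backsolve(R, rep(1, n), transpose = TRUE)
  mu <- sum(ow * yw) / sum(ow^2)
  r <- yw - mu * ow
  s2 <- sum(r^2) / n
  logdet <- 2 * sum(log(diag(R)))
  list(mu = mu, sigma2 = s2,
       logL = -0.5 * (n * log(2 * pi * s2) + logdet + n))
}

#' Pagel's lambda phylogenetic signal
#'
#' Maximum-likelihood estimate of the multiplier on the off-diagonal
#' phylogenetic covariance, with the Brownian rate and root state profiled
#' out analytically. The search runs over `[0, lambda_max]`, where
#' `lambda_max` keeps the transformed covariance positive definite.
#'
#' @param tree A rooted `phylo` (>= 4 tips).
#' @param trait Named numeric vector (names = tip labels) or unnamed in tip
#'   order.
#' @return List of class `signal_result`: `statistic = "lambda"`, `value`,
#'   `logL`, `logL0` (lambda = 0), `p` (likelihood-ratio test, chi-square
#'   df 1).
#' @export
pagel_lambda <- function(tree, trait) {
  y <- align_trait(tree, trait)
  if (length(y) < 4) stop("need at least 4 tips")
  C <- phylo_vcv(tree)
  # back off the supremum slightly: C(lambda_max) itself is singular
  lmax <- lambda_max(C) * (1 - 1e-8)
  d <- diag(C)
  ll <- function(lam) {
    Cl <- C * lam
    diag(Cl) <- d
    gls_profile(y, Cl)$logL
  }
  opt <- optimize(ll, c(0, lmax), maximum = TRUE, tol = 1e-8)
  # guard the boundaries: optimize() can miss maxima at interval ends
  cand <- c(opt$maximum, 0, lmax)
  vals <- c(opt$objective, ll(0), ll(lmax))
  best <- which.max(vals)
  lam <- cand[best]; logL <- vals[best]
  logL0 <- vals[2]
  stat <- max(0, 2 * (logL - logL0))
  structure(list(statistic = "lambda", value = lam, logL = logL,
                 logL0 = logL0,
                 p = pchisq(stat, df = 1, lower.tail = FALSE)),
            class = "signal_result")
}

#' Blomberg's K phylogenetic signal
#'
#' Ratio of the observed mean squared error of the tip data (about the
#' phylogenetically corrected mean) to the phylogenetically expected mean
#' squared error, scaled by its Brownian-motion expectation, so K = 1 under
#' Brownian evolution. For a trait matrix the squared deviations are summed
#' across columns (the multivariate extension, `K_multi`). Significance by
#' permutation of tips.
#'
#' @param tree A rooted `phylo` (>= 4 tips).
#' @param trait Named numeric vector, or matrix with rownames = tip labels.
#' @param n_perm Tip permutations for the p-value (0 to skip), default 999.
#' @param seed Optional integer seed for the permutations.
#' @return `signal_result` with `statistic` `"K"` or `"K_multi"`, `value`,
#'   `p` (permutation).
#' @export
blomberg_k <- function(tree, trait, n_perm = 999, seed = NULL) {
  Y <- if (is.matrix(trait)) trait else cbind(trait)
  if (is.null(rownames(Y)) && !is.null(names(trait))) rownames(Y) <- names(trait)
  if (!is.null(rownames(Y))) Y <- Y[tree$tip.label, , drop = FALSE]
  n <- nrow(Y)
  if (n < 4) stop("need at least 4 tips")
  if (all(apply(Y, 2, var) == 0)) stop("zero trait variance")
  C <- phylo_vcv(tree)
  Ci <- chol2inv(chol(C))
  one <- rep(1, n)
  denom_mu <- as.numeric(one %*% Ci %*% one)
  expected <- (sum(diag(C)) - n / denom_mu) / (n - 1)
  kstat <- function(Y) {
    mu <- as.numeric(one %*% Ci %*% Y) / denom_mu
    D <- sweep(Y, 2, mu)
    mse0 <- sum(D^2) / (n - 1)
    mse <- sum(vapply(seq_len(ncol(D)), function(j)
      as.numeric(D[, j] %*% Ci %*% D[, j]), numeric(1))) / (n - 1)
    (mse0 / mse) / expected
  }
  K <- kstat(Y)
  p <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    perm <- vapply(seq_len(n_perm),
                   function(i) kstat(Y[sample.int(n), , drop = FALSE]),
                   numeric(1))
    p <- (1 + sum(perm >= K)) / (n_perm + 1)
  }
  structure(list(statistic = if (ncol(Y) > 1) "K_multi" else "K",
                 value = K, p = p), class = "signal_result")
}

#' @exportS3Method base::print
print.signal_result <- function(x, ...) {
  cat(sprintf("%s = %.4f", x$statistic, x$value))
  if (!is.null(x$p) && is.finite(x$p)) cat(sprintf(" (p = %.4g)", x$p))
  cat("\n")
  invisible(x)
}

#' Phylogenetic generalized least squares
#'
#' GLS regression with residual covariance proportional to the tree's shared
#' branch lengths: equivalent to OLS on Cholesky-whitened data. With a star
#' tree (or `lambda = 0`) the fit reduces to OLS.
#'
#' @param y Response, named by tip or in tip order.
#' @param X Predictor vector or matrix (no intercept column; one is added).
#' @param tree A rooted `phylo`.
#' @param lambda Optional Pagel's lambda transform of the covariance.
#' @return List of class `pgls_fit`: `coefficients`, `table` (estimate, SE,
#'   t, p per term), `sigma2`, `r_squared`, `logL`, `p_model`, `df_residual`.
#' @export
pgls <- function(y, X, tree, lambda = NULL) {
  y <- align_trait(tree, y)
  X <- as.matrix(X)
  if (!is.null(rownames(X))) X <- X[tree$tip.label, , drop = FALSE]
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  C <- phylo_vcv(tree, lambda)
  R <- chol(C)
  Xd <- cbind(`(Intercept)` = 1, X)
  if (qr(Xd)$rank < ncol(Xd)) stop("singular design matrix")
  yw <- backsolve(R, y, transpose = TRUE)
  Xw <- backsolve(R, Xd, transpose = TRUE)
  fit <- lm.fit(Xw, yw)
  names(fit$coefficients) <- colnames(Xd)  # backsolve drops dimnames
  p <- ncol(Xd)
  rss <- sum(fit$residuals^2)
  s2 <- rss / (n - p)
  XtXi <- chol2inv(qr.R(fit$qr))
  se <- sqrt(diag(XtXi) * s2)
  est <- fit$coefficients
  tv <- est / se
  pv <- 2 * pt(abs(tv), n - p, lower.tail = FALSE)
  # null (intercept-only) GLS fit for R^2 and the model F-test
  ow <- Xw[, 1]
  mu <- sum(ow * yw) / sum(ow^2)
  tss <- sum((yw - mu * ow)^2)
  r2 <- 1 - rss / tss
  fstat <- if (p > 1) ((tss - rss) / (p - 1)) / (rss / (n - p)) else NA
  pmod <- if (p > 1) pf(fstat, p - 1, n - p, lower.tail = FALSE) else NA
  logdet <- 2 * sum(log(diag(R)))
  s2ml <- rss / n
  logL <- -0.5 * (n * log(2 * pi * s2ml) + logdet + n)
  structure(list(
    coefficients = est,
    table = data.frame(estimate = est, se = se, t = tv, p = pv,
                       row.names = colnames(Xd)),
    sigma2 = s2, r_squared = r2, logL = logL,
    f = fstat, p_model = pmod, df_residual = n - p, n = n),
    class = "pgls_fit")
}

#' @exportS3Method base::print
print.pgls_fit <- function(x, ...) {
  cat("phylogenetic GLS fit\n")
  print(round(x$table, 5))
  cat(sprintf("R^2 = %.4f, logL = %.3f\n", x$r_squared, x$logL))
  invisible(x)
}

# align a named trait vector to the tree's tip order
align_trait <- function(tree, trait) {
  if (!is.null(names(trait))) {
    miss <- setdiff(tree$tip.label, names(trait))
    if (length(miss)) stop("trait missing for tips: ",
                           paste(miss, collapse = ", "))
    trait <- trait[tree$tip.label]
  } else if (length(trait) != length(tree$tip.label)) {
    stop("trait length does not match number of tips")
  }
  as.numeric(trait)
}

# classical one-way ANOVA F statistics, vectorized over columns of Y
anova_f <- function(Y, groups) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  g <- as.factor(groups)
  k <- nlevels(g)
  cnt <- as.numeric(table(g))
  gm <- rowsum(Y, g) / cnt
  tot <- colMeans(Y)
  ss_tot <- colSums(sweep(Y, 2, tot)^2)
  ss_w <- colSums((Y - gm[as.integer(g), , drop = FALSE])^2)
  ss_b <- ss_tot - ss_w
  (ss_b / (k - 1)) / (ss_w / (n - k))
}

#' Phylogenetic ANOVA
#'
#' Classical one-way F statistic whose null distribution is obtained by
#' simulating Brownian-motion traits on the tree (rate estimated from the
#' data by GLS), so group differences are judged against phylogenetically
#' correlated nulls.
#'
#' @param trait Named numeric vector.
#' @param groups Factor of group memberships, same order/names.
#' @param tree A rooted `phylo`.
#' @param n_sim Brownian simulations for the null, default 1000.
#' @param seed Optional integer seed.
#' @return List: `F`, `df`, `p` (simulation), `p_classical` (parametric F
#'   test, for reference), `n_sim`.
#' @export
phylo_anova <- function(trait, groups, tree, n_sim = 1000, seed = NULL) {
  y <- align_trait(tree, trait)
  if (!is.null(names(groups))) groups <- groups[tree$tip.label]
  g <- droplevels(as.factor(groups))
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 2))
    message("groups with a single member present; F-test df are fragile")
  n <- length(y)
  k <- nlevels(g)
  Fobs <- anova_f(y, g)
  if (!is.null(seed)) set.seed(as.integer(seed))
  C <- phylo_vcv(tree)
  prof <- gls_profile(y, C)
  Rt <- t(chol(C))
  Z <- matrix(rnorm(n * n_sim), n, n_sim)
  Ysim <- prof$mu + sqrt(prof$sigma2) * (Rt %*% Z)
  Fsim <- anova_f(Ysim, g)
  structure(list(
    F = Fobs, df = c(k - 1, n - k),
    p = (1 + sum(Fsim >= Fobs)) / (n_sim + 1),
    p_classical = pf(Fobs, k - 1, n - k, lower.tail = FALSE),
    n_sim = n_sim), class = "phylo_anova")
}

#' @exportS3Method base::print
print.phylo_anova <- function(x, ...) {
  cat(sprintf("phylogenetic ANOVA: F(%d, %d) = %.3f, simulation p = %.4g\n",
              x$df[1], x$df[2], x$F, x$p))
  invisible(x)
}

#' Phylogenetically corrected two-block partial least squares
#'
#' Both trait blocks are centred on their phylogenetic (GLS) means and
#' whitened by the Cholesky factor of the tree covariance; the first
#' singular vectors of the cross-covariance give paired scores whose
#' correlation is the r-PLS statistic. Significance by permutation of the
#' rows of block 2.
#'
#' @param block1,block2 Numeric matrices (tips x traits), rownames = tips.
#' @param tree Optional `phylo`; omitted = ordinary two-block PLS.
#' @param n_perm Permutations, default 999.
#' @param seed Optional integer seed.
#' @return List of class `pls_fit`: `r_pls`, `p`, `scores1`, `scores2`,
#'   `adj_r_squared` (both regression directions), `singular_values`.
#' @export
two_block_pls <- function(block1, block2, tree = NULL, n_perm = 999,
                          seed = NULL) {
  B1 <- as.matrix(block1); B2 <- as.matrix(block2)
  if (!is.null(tree)) {
    B1 <- B1[tree$tip.label, , drop = FALSE]
    B2 <- B2[tree$tip.label, , drop = FALSE]
    C <- phylo_vcv(tree)
  } else C <- diag(nrow(B1))
  n <- nrow(B1)
  R <- chol(C)
  whiten <- function(B) {
    Bw <- backsolve(R, B, transpose = TRUE)
    ow <- backsolve(R, rep(1, n), transpose = TRUE)
    mu <- colSums(ow * Bw) / sum(ow^2)
    Bw - outer(ow, mu)
  }
  rpls_of <- function(B2raw) {
    W1 <- whiten(B1); W2 <- whiten(B2raw)
    cc <- crossprod(W1, W2) / (n - 1)
    sv <- svd(cc)
    if (sv$d[1] <= .Machine$double.eps * 10)
      stop("rank-0 cross-covariance between blocks")
    s1 <- W1 %*% sv$u[, 1]
    s2 <- W2 %*% sv$v[, 1]
    list(r = abs(cor(s1, s2)[1]), s1 = s1, s2 = s2, d = sv$d)
  }
  obs <- rpls_of(B2)
  p <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    perm <- vapply(seq_len(n_perm), function(i)
      rpls_of(B2[sample.int(n), , drop = FALSE])$r, numeric(1))
    p <- (1 + sum(perm >= obs$r)) / (n_perm + 1)
  }
  a12 <- summary(lm(obs$s1 ~ obs$s2))$adj.r.squared
  a21 <- summary(lm(obs$s2 ~ obs$s1))$adj.r.squared
  structure(list(r_pls = obs$r, p = p,
                 scores1 = obs$s1, scores2 = obs$s2,
                 adj_r_squared = c(s1_on_s2 = a12, s2_on_s1 = a21),
                 singular_values = obs$d), class = "pls_fit")
}

#' @exportS3Method base::print
print.pls_fit <- function(x, ...) {
  cat(sprintf("two-block PLS: r-PLS = %.4f (p = %.4g)\n", x$r_pls, x$p))
  invisible(x)
}
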