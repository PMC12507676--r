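#' Fit Brownian-motion, Ornstein-Uhlenbeck or early-burst trait models
#'
#' Maximum likelihood over the model-transformed phylogenetic covariance.
#' The Brownian rate and root state are profiled out analytically; OU's
#' pull strength alpha (EB's rate decay r) is optimised by bounded
#' quasi-Newton with random restarts, since these likelihoods can be flat
#' or multimodal on small trees. Parameter counts are 2 (BM: sigma2, z0),
#' 3 (OU: + alpha), 3 (EB: + r <= 0); fits report small-sample corrected
#' AIC.
#'
#' @param tree A rooted, approximately ultrametric `phylo` (>= 5 tips).
#' @param trait Named numeric vector.
#' @param model `"BM"`, `"OU"` or `"EB"`.
#' @param n_restart Random restarts of the 1-D optimiser, default 5.
#' @param seed Optional integer seed for the restart draws.
#' @return List of class `continuous_fit`: `model`, `params` (`sigma2`,
#'   `z0`, and `alpha` or `rate`), `logL`, `k`, `n`, `AICc`, `convergence`.
#' @export
fit_continuous <- function(tree, trait, model = c("BM", "OU", "EB"),
                           n_restart = 5, seed = NULL) {
  model <- match.arg(model)
  y <- align_trait(tree, trait)
  n <- length(y)
  if (n < 5) stop("need at least 5 tips")
  C <- phylo_vcv(tree)
  Tdepth <- max(diag(C))
  if (max(abs(diag(C) - Tdepth)) > 1e-6 * Tdepth && model == "OU")
    warning("tree is not ultrametric; OU stationary covariance is approximate")
  if (!is.null(seed)) set.seed(as.integer(seed))

  profiled <- function(Cm) gls_profile(y, Cm)
  if (model == "BM") {
    pr <- profiled(C)
    k <- 2
    fit <- list(params = c(sigma2 = pr$sigma2, z0 = pr$mu),
                logL = pr$logL, convergence = 0L)
  } else if (model == "OU") {
    trans <- function(alpha) ou_vcv(C, alpha, Tdepth)
    ll <- function(la) profiled(trans(exp(la)))$logL
    opt <- restart_optim(ll, lower = log(1e-9 / Tdepth),
                         upper = log(100 / Tdepth),
                         init = log(1 / Tdepth), n_restart = n_restart)
    alpha <- exp(opt$par)
    pr <- profiled(trans(alpha))
    # a vanishing alpha is the BM limit; report it as such
    bm <- profiled(C)
    if (bm$logL >= pr$logL - 1e-9 && alpha < 1e-6 / Tdepth) {
      alpha <- 0; pr <- bm
    }
    k <- 3
    fit <- list(params = c(sigma2 = pr$sigma2, z0 = pr$mu, alpha = alpha),
                logL = pr$logL, convergence = opt$convergence)
  } else {
    trans <- function(r) if (abs(r) < 1e-12) C else (exp(r * C) - 1) / r
    ll <- function(r) profiled(trans(r))$logL
    opt <- restart_optim(ll, lower = -10 / Tdepth, upper = 0,
                         init = -0.5 / Tdepth, n_restart = n_restart)
    r <- opt$par
    pr <- profiled(trans(r))
    k <- 3
    fit <- list(params = c(sigma2 = pr$sigma2, z0 = pr$mu, rate = r),
                logL = pr$logL, convergence = opt$convergence)
  }
  aicc <- -2 * fit$logL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  structure(c(fit, list(model = model, k = k, n = n, AICc = aicc,
                        tree_depth = Tdepth)),
            class = "continuous_fit")
}

# OU covariance on an ultrametric tree (unit sigma2):
# (1/(2a)) exp(-2a (T - Cij)) (1 - exp(-2a Cij)); the a -> 0 limit is C
ou_vcv <- function(C, alpha, Tdepth) {
  if (alpha < 1e-12) return(C)
  V <- exp(-2 * alpha * (Tdepth - C)) * (1 - exp(-2 * alpha * C)) /
    (2 * alpha)
  # numerical floor keeps the matrix positive definite for large alpha
  diag(V) <- diag(V) + 1e-12 * max(diag(V))
  V
}

# bounded 1-D quasi-Newton with random restarts
restart_optim <- function(fn, lower, upper, init, n_restart = 5) {
  starts <- c(init, runif(max(0, n_restart - 1), lower, upper))
  best <- NULL
  for (s in starts) {
    o <- tryCatch(
      nlminb(s, function(p) -fn(p), lower = lower, upper = upper),
      error = function(e) NULL)
    if (is.null(o)) next
    if (is.null(best) || o$objective < best$objective) best <- o
  }
  if (is.null(best)) stop("optimizer failed to converge from any start")
  list(par = best$par, value = -best$objective,
       convergence = best$convergence)
}

#' @exportS3Method base::print
print.continuous_fit <- function(x, ...) {
  cat(sprintf("%s fit: logL = %.4f, AICc = %.4f\n", x$model, x$logL, x$AICc))
  print(round(x$params, 6))
  invisible(x)
}

#' Ancestral states under a fitted Ornstein-Uhlenbeck model
#'
#' Joint maximum-likelihood ancestral states: along each branch the child
#' state is Gaussian around the parent state shrunk toward the optimum
#' (taken as the fitted root state), which makes the joint likelihood in
#' the internal states a quadratic form solved exactly as a linear system.
#' When the fitted alpha sits at the zero boundary, the reconstruction
#' reduces to (and is reported as) the Brownian-motion ML states.
#'
#' @param tree A rooted `phylo`.
#' @param trait Named numeric vector.
#' @param fit Optional [fit_continuous()] OU fit; fitted here if missing.
#' @return Numeric vector of ancestral states named by internal node number
#'   (ape convention, root = `Ntip + 1`), with attribute `model` (`"OU"` or
#'   `"BM"` fallback).
#' @export
ou_ancestral <- function(tree, trait, fit = NULL) {
  y <- align_trait(tree, trait)
  if (is.null(fit)) fit <- fit_continuous(tree, trait, "OU")
  alpha <- if (fit$model == "OU") unname(fit$params["alpha"]) else 0
  model <- "OU"
  if (alpha <= 0) {
    alpha <- 0
    model <- "BM"
    warning("alpha at the zero boundary; falling back to BM reconstruction")
  }
  theta <- unname(fit$params["z0"])
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  edge <- tree$edge
  el <- tree$edge.length
  a <- exp(-alpha * el)
  v <- if (alpha > 0) (1 - a^2) / (2 * alpha) else el
  # quadratic form in internal-state deviations u = x - theta
  A <- matrix(0, nnode, nnode)
  b <- numeric(nnode)
  u_tip <- y - theta
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1] - ntip
    c_ <- edge[e, 2]
    w <- 1 / v[e]
    A[p, p] <- A[p, p] + a[e]^2 * w
    if (c_ <= ntip) {
      b[p] <- b[p] + a[e] * w * u_tip[c_]
    } else {
      ci <- c_ - ntip
      A[ci, ci] <- A[ci, ci] + w
      A[p, ci] <- A[p, ci] - a[e] * w
      A[ci, p] <- A[ci, p] - a[e] * w
    }
  }
  u <- solve(A, b)
  states <- theta + u
  names(states) <- as.character(ntip + seq_len(nnode))
  attr(states, "model") <- model
  states
}

#' Rank model fits by information criterion
#'
#' @param fits Named list of fits carrying `logL`, `n` and `AICc` (from
#'   [fit_continuous()]) or `AIC` (from [fit_mk()]). All fits must be on the
#'   same data (same `n`).
#' @return Data frame sorted by the criterion with a `dAIC` column (0 for
#'   the best model); ties keep name order.
#' @export
compare_aic <- function(fits) {
  if (length(fits) < 2) stop("need at least 2 fits")
  if (is.null(names(fits)))
    names(fits) <- vapply(fits, function(f)
      if (!is.null(f$model)) f$model else if (!is.null(f$pattern)) f$pattern
      else "fit", character(1))
  ns <- vapply(fits, function(f) as.numeric(f$n), numeric(1))
  if (length(unique(ns)) > 1) stop("fits are not on the same data")
  ic <- vapply(fits, function(f)
    if (!is.null(f$AICc)) f$AICc else f$AIC, numeric(1))
  logL <- vapply(fits, function(f) f$logL, numeric(1))
  kk <- vapply(fits, function(f) as.numeric(f$k), numeric(1))
  ord <- order(ic, names(fits))
  out <- data.frame(model = names(fits)[ord], logL = logL[ord], k = kk[ord],
                    IC = ic[ord], dAIC = ic[ord] - min(ic))
  rownames(out) <- NULL
  out
}
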