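#' Constraint pattern matrix for Mk rate models
#'
#' Builds the parameter-index matrix for a k-state Mk model. Entries share a
#' rate parameter when they hold the same index; 0 marks transitions fixed
#' at rate zero. The `bridge-` patterns forbid direct transitions between
#' the diurnal and nocturnal states in both directions, encoding the
#' crepuscular-bridge hypothesis.
#'
#' @param states Character vector of state names; default the four diel
#'   guilds.
#' @param pattern One of `"ER"`, `"SYM"`, `"ARD"`, `"bridge-SYM"`,
#'   `"bridge-ARD"`.
#' @return Integer `k x k` matrix (diagonal `NA`), attribute `n_free` =
#'   number of free rate parameters (ER 1; SYM k(k-1)/2; ARD k(k-1);
#'   bridge variants one/two fewer).
#' @export
mk_pattern_matrix <- function(states = c("diurnal", "nocturnal",
                                         "crepuscular", "cathemeral"),
                              pattern = c("ER", "SYM", "ARD",
                                          "bridge-SYM", "bridge-ARD")) {
  pattern <- match.arg(pattern)
  k <- length(states)
  M <- matrix(0L, k, k, dimnames = list(states, states))
  if (pattern == "ER") {
    M[] <- 1L
  } else if (pattern %in% c("SYM", "bridge-SYM")) {
    idx <- 0L
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      idx <- idx + 1L
      M[i, j] <- M[j, i] <- idx
    }
  } else {
    idx <- 0L
    for (i in seq_len(k)) for (j in seq_len(k)) if (i != j) {
      idx <- idx + 1L
      M[i, j] <- idx
    }
  }
  diag(M) <- NA_integer_
  if (startsWith(pattern, "bridge")) {
    if (!all(c("diurnal", "nocturnal") %in% states))
      stop("bridge patterns need 'diurnal' and 'nocturnal' states")
    M["diurnal", "nocturnal"] <- 0L
    M["nocturnal", "diurnal"] <- 0L
    # re-index so free parameters are 1..n_free
    used <- sort(unique(M[!is.na(M) & M > 0]))
    M[!is.na(M) & M > 0] <- match(M[!is.na(M) & M > 0], used)
  }
  attr(M, "n_free") <- length(unique(M[!is.na(M) & M > 0]))
  attr(M, "pattern") <- pattern
  M
}

# assemble Q from free rates and a pattern matrix (rows sum to zero)
mk_build_q <- function(rates, pat) {
  Q <- matrix(0, nrow(pat), ncol(pat), dimnames = dimnames(pat))
  off <- !is.na(pat) & pat > 0
  Q[off] <- rates[pat[off]]
  diag(Q) <- -rowSums(Q)
  Q
}

# transition probability function for Q; eigendecomposition with a
# scaling-and-squaring fallback for near-defective matrices
mk_pfun <- function(Q) {
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  ok <- FALSE
  if (!is.null(eg) && all(is.finite(Mod(eg$values)))) {
    Vi <- tryCatch(solve(eg$vectors), error = function(e) NULL)
    if (!is.null(Vi)) {
      rec <- Re(eg$vectors %*% (eg$values * Vi))
      ok <- max(abs(rec - Q)) < 1e-8 * max(1, max(abs(Q)))
    }
  }
  if (ok) {
    V <- eg$vectors; vals <- eg$values
    function(t) {
      P <- Re(V %*% (exp(vals * t) * Vi))
      P[P < 0] <- 0
      P / rowSums(P)
    }
  } else {
    function(t) expm_ss(Q * t)
  }
}

# all edge transition matrices at once: row (i,j) of the result holds
# P(t_e)[i, j] = sum_m V[i,m] exp(lambda_m t_e) Vinv[m,j] for every edge
mk_pall <- function(Q, el) {
  k <- nrow(Q)
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  usable <- FALSE
  if (!is.null(eg) && all(is.finite(Mod(eg$values)))) {
    Vi <- tryCatch(solve(eg$vectors), error = function(e) NULL)
    if (!is.null(Vi)) {
      rec <- Re(eg$vectors %*% (eg$values * Vi))
      usable <- max(abs(rec - Q)) < 1e-8 * max(1, max(abs(Q)))
    }
  }
  if (usable) {
    W <- matrix(0 + 0i, k * k, k)
    for (m in seq_len(k))
      W[, m] <- as.vector(outer(eg$vectors[, m], Vi[m, ]))
    E <- exp(outer(eg$values, el))
    P <- Re(W %*% E)
  } else {
    P <- vapply(el, function(t) as.vector(expm_ss(Q * t)),
                numeric(k * k))
  }
  P[P < 0] <- 0
  # renormalise rows of each P(t): entries (i, j) for fixed i are k apart
  for (i in seq_len(k)) {
    rows <- seq(i, k * k, by = k)
    P[rows, ] <- sweep(P[rows, , drop = FALSE], 2,
                       colSums(P[rows, , drop = FALSE]), "/")
  }
  P
}

# matrix exponential by scaling and squaring with a Taylor core
expm_ss <- function(A) {
  nrm <- max(abs(A))
  s <- max(0L, ceiling(log2(max(nrm, 1e-300)))) + 1L
  As <- A / 2^s
  P <- diag(nrow(A))
  term <- P
  for (i in 1:14) {
    term <- term %*% As / i
    P <- P + term
  }
  for (i in seq_len(s)) P <- P %*% P
  P
}

#' Mk model likelihood by Felsenstein pruning
#'
#' @param tree A rooted `phylo`.
#' @param tip_states Factor/character vector named by tip (or in tip
#'   order); levels must match the rows of `Q`.
#' @param Q Rate matrix (rows sum to 0, off-diagonals >= 0).
#' @param root_prior `"flat"` (default), `"stationary"`, or a numeric
#'   vector of state probabilities.
#' @return Log-likelihood (scalar).
#' @export
mk_loglik <- function(tree, tip_states, Q, root_prior = "flat") {
  prep <- mk_prep(tree, tip_states, rownames(Q))
  mk_loglik_core(prep, Q, root_prior)
}

# preprocess the tree and tip states once; reused across optimizer calls
mk_prep <- function(tree, tip_states, states) {
  s <- tip_state_index(tree, tip_states, states)
  tr <- ape::reorder.phylo(tree, "postorder")
  ne <- nrow(tr$edge)
  list(edge = tr$edge, el = tr$edge.length, ntip = length(tree$tip.label),
       nnode = tr$Nnode, s = s, k = length(states),
       last_child = c(tr$edge[-ne, 1] != tr$edge[-1, 1], TRUE))
}

mk_loglik_core <- function(prep, Q, root_prior = "flat") {
  k <- prep$k
  ntip <- prep$ntip
  Pall <- mk_pall(Q, prep$el)
  L <- matrix(0, ntip + prep$nnode, k)
  L[cbind(seq_len(ntip), prep$s)] <- 1
  L[(ntip + 1):(ntip + prep$nnode), ] <- 1
  logscale <- 0
  edge <- prep$edge
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1]
    P <- matrix(Pall[, e], k, k)
    L[p, ] <- L[p, ] * as.numeric(P %*% L[edge[e, 2], ])
    # rescale after the node's last child to avoid underflow
    if (prep$last_child[e]) {
      m <- max(L[p, ])
      if (m <= 0) return(-Inf)
      L[p, ] <- L[p, ] / m
      logscale <- logscale + log(m)
    }
  }
  pi <- root_prior_vec(root_prior, Q)
  log(sum(pi * L[ntip + 1, ])) + logscale
}

root_prior_vec <- function(root_prior, Q) {
  k <- nrow(Q)
  if (is.numeric(root_prior)) {
    stopifnot(length(root_prior) == k)
    return(root_prior / sum(root_prior))
  }
  if (root_prior == "flat") return(rep(1 / k, k))
  if (root_prior == "stationary") {
    P <- mk_pfun(Q)(1e6 / max(abs(Q), 1e-12))
    return(colMeans(P))
  }
  stop("unknown root prior")
}

tip_state_index <- function(tree, tip_states, states) {
  if (!is.null(names(tip_states))) tip_states <- tip_states[tree$tip.label]
  s <- match(as.character(tip_states), states)
  if (any(is.na(s))) stop("tip states outside the model's state set")
  s
}

#' Fit an Mk model of discrete diel-state evolution
#'
#' Maximum-likelihood fit of a continuous-time Markov model of transitions
#' among diel states under a constraint pattern, by Felsenstein pruning
#' with a flat root prior (configurable). The bridge patterns fix both
#' diurnal-nocturnal rates at zero.
#'
#' @param tree A rooted `phylo`.
#' @param tip_states Factor/character named by tip; its set of levels (or
#'   `states`) defines the state space.
#' @param pattern Constraint pattern, see [mk_pattern_matrix()].
#' @param states Optional explicit state set (default: levels of
#'   `tip_states`, or the four diel guilds when they all occur).
#' @param root_prior `"flat"` (default), `"stationary"`, or probabilities.
#' @param n_restart Optimiser restarts, default 5.
#' @param seed Optional integer seed for restart draws.
#' @return List of class `mk_fit`: `states`, `pattern`, `rates`, `Q`,
#'   `logL`, `k` (free parameters), `AIC`, `n`, `convergence`.
#' @export
fit_mk <- function(tree, tip_states, pattern = "ER", states = NULL,
                   root_prior = "flat", n_restart = 5, seed = NULL) {
  if (is.null(states)) {
    states <- if (is.factor(tip_states)) levels(tip_states)
    else sort(unique(as.character(tip_states)))
  }
  obs <- unique(as.character(tip_states))
  if (!all(obs %in% states)) stop("tip states outside the state set")
  pat <- mk_pattern_matrix(states, pattern)
  nf <- attr(pat, "n_free")
  if (!is.null(seed)) set.seed(as.integer(seed))
  depth <- max(ape::node.depth.edgelength(tree))
  q0 <- 0.5 / depth
  prep <- mk_prep(tree, tip_states, states)
  negll <- function(lr) {
    q <- mk_build_q(exp(lr), pat)
    -mk_loglik_core(prep, q, root_prior)
  }
  best <- NULL
  starts <- rbind(rep(log(q0), nf),
                  matrix(log(q0) + rnorm((n_restart - 1) * nf, 0, 1.5),
                         ncol = nf))
  for (i in seq_len(nrow(starts))) {
    o <- tryCatch(
      nlminb(starts[i, ], negll, lower = log(q0) - 14, upper = log(q0) + 10),
      error = function(e) NULL)
    if (is.null(o) || !is.finite(o$objective)) next
    if (is.null(best) || o$objective < best$objective) best <- o
  }
  if (is.null(best)) stop("non-finite Mk likelihood from every start")
  rates <- exp(best$par)
  Q <- mk_build_q(rates, pat)
  logL <- -best$objective
  structure(list(states = states, pattern = pattern, rates = rates,
                 Q = Q, logL = logL, k = nf, AIC = -2 * logL + 2 * nf,
                 n = length(tree$tip.label),
                 convergence = best$convergence,
                 root_prior = root_prior),
            class = "mk_fit")
}

#' @exportS3Method base::print
print.mk_fit <- function(x, ...) {
  cat(sprintf("Mk fit [%s]: %d free rates, logL = %.4f, AIC = %.4f\n",
              x$pattern, x$k, x$logL, x$AIC))
  print(round(x$Q, 5))
  invisible(x)
}
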