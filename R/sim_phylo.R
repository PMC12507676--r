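#' Simulate a pure-birth ultrametric phylogeny
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Integer seed; identical seeds give identical Newick strings.
#' @param depth Root-to-tip depth to rescale to (time units), default 10.
#' @param tip_prefix Prefix for six-letter tip codes (`spXXXX`).
#' @return Rooted, binary, ultrametric `phylo` with positive branch lengths.
#' @export
simulate_tree <- function(n_tips, seed = 1, depth = 10,
                          tip_prefix = "sp") {
  stopifnot(n_tips >= 2)
  set.seed(as.integer(seed))
  tr <- ape::rphylo(n_tips, birth = 1, death = 0)
  d <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * depth / d
  tr$tip.label <- sprintf("%s%04d", tip_prefix, seq_len(n_tips))
  tr
}

#' Simulate continuous trait evolution on a tree
#'
#' Draws tip values from the multivariate normal implied by Brownian motion
#' (BM), a single-optimum Ornstein-Uhlenbeck process (OU) or an early-burst
#' model (EB, exponentially decaying rate) over the tree. With `rate = 0`
#' the EB draw is identical to BM for the same seed (model nesting), and OU
#' covariances converge to BM as `alpha -> 0`.
#'
#' @param tree A rooted `phylo`.
#' @param model `"BM"`, `"OU"` or `"EB"`.
#' @param params List: `sigma2` (> 0), `z0` (root state, default 0), and
#'   `alpha` (>= 0, OU) or `rate` (<= 0, EB).
#' @param seed Integer seed.
#' @param nsim Number of replicate draws, default 1.
#' @return Named vector of tip values (or a `tips x nsim` matrix).
#' @export
simulate_continuous <- function(tree, model = c("BM", "OU", "EB"),
                                params = list(sigma2 = 1, z0 = 0),
                                seed = 1, nsim = 1) {
  model <- match.arg(model)
  s2 <- params$sigma2 %||% 1
  z0 <- params$z0 %||% 0
  stopifnot(s2 > 0)
  C <- phylo_vcv(tree)
  Tdepth <- max(diag(C))
  if (model == "OU") {
    alpha <- params$alpha %||% 0
    stopifnot(alpha >= 0)
    if (max(abs(diag(C) - Tdepth)) > 1e-6 * Tdepth)
      warning("tree is not ultrametric; OU stationarity is approximate")
    C <- ou_vcv(C, alpha, Tdepth)
  } else if (model == "EB") {
    r <- params$rate %||% 0
    stopifnot(r <= 0)
    if (r < 0) C <- (exp(r * C) - 1) / r
  }
  set.seed(as.integer(seed))
  n <- nrow(C)
  Rt <- t(chol(s2 * C + diag(1e-12 * s2 * Tdepth, n)))
  Z <- matrix(rnorm(n * nsim), n, nsim)
  out <- z0 + Rt %*% Z
  rownames(out) <- tree$tip.label
  if (nsim == 1) setNames(out[, 1], tree$tip.label) else out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate discrete character evolution on a tree
#'
#' Continuous-time Markov simulation of state changes along every branch
#' under rate matrix `Q`; the full jump history is retained as ground truth
#' (so, e.g., the absence of direct diurnal-nocturnal jumps under a
#' bridge-constrained `Q` can be verified).
#'
#' @param tree A rooted `phylo`.
#' @param Q Rate matrix with named states; rows must sum to 0 and
#'   off-diagonals be non-negative (absorbing states are valid).
#' @param root_state State name or index for the root.
#' @param seed Integer seed.
#' @return List: `tip_states` (factor named by tip), `node_states`,
#'   `history` (data.frame `edge`, `time`, `from`, `to` of every jump).
#' @export
simulate_discrete <- function(tree, Q, root_state = 1, seed = 1) {
  Q <- as.matrix(Q)
  if (max(abs(rowSums(Q))) > 1e-8) stop("Q rows must sum to 0")
  offd <- Q[row(Q) != col(Q)]
  if (any(offd < 0)) stop("off-diagonal rates must be >= 0")
  states <- rownames(Q)
  if (is.null(states)) states <- paste0("s", seq_len(nrow(Q)))
  if (is.character(root_state)) root_state <- match(root_state, states)
  set.seed(as.integer(seed))
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  st <- integer(nn)
  st[ntip + 1] <- root_state
  tr <- ape::reorder.phylo(tree, "cladewise")
  hist <- list()
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    s <- st[p]; t <- 0; len <- tr$edge.length[e]
    repeat {
      rate <- -Q[s, s]
      if (rate <= 0) break
      w <- rexp(1, rate)
      if (t + w > len) break
      t <- t + w
      probs <- Q[s, ]; probs[s] <- 0
      s_new <- sample.int(length(states), 1, prob = probs)
      hist[[length(hist) + 1]] <-
        data.frame(edge = e, time = t, from = states[s], to = states[s_new])
      s <- s_new
    }
    st[ch] <- s
  }
  tip_states <- factor(states[st[seq_len(ntip)]], levels = states)
  names(tip_states) <- tree$tip.label
  list(tip_states = tip_states,
       node_states = setNames(states[st[(ntip + 1):nn]],
                              as.character((ntip + 1):nn)),
       history = if (length(hist)) do.call(rbind, hist)
       else data.frame(edge = integer(), time = numeric(),
                       from = character(), to = character()))
}
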