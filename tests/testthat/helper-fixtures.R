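# shared fixtures, built once per test run

sched_12 <- make_light_schedule("07:00", "19:00", 30)

tree8 <- simulate_tree(8, seed = 101)
tree32 <- simulate_tree(32, seed = 202)

# stationary toy trajectory with a given number of frames
flat_track <- function(n, x = 50, y = 80, fps = 10) {
  out <- data.frame(time = (seq_len(n) - 1) / fps,
                    x = rep(x, n), y = rep(y, n),
                    area = rep(300, n), missing = FALSE)
  attr(out, "fps") <- fps
  attr(out, "px_per_mm") <- 1
  attr(out, "units") <- "px"
  out
}

# brute-force Mk likelihood: sum over every internal-state assignment
mk_loglik_brute <- function(tree, tip_states, Q, root_prior = "flat") {
  k <- nrow(Q)
  states <- rownames(Q)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  s <- match(as.character(tip_states[tree$tip.label]), states)
  Pt <- lapply(seq_len(nrow(tree$edge)), function(e)
    as.matrix(Matrix::expm(Q * tree$edge.length[e])))
  pi <- if (identical(root_prior, "flat")) rep(1 / k, k) else root_prior
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), nnode)))
  tot <- 0
  for (r in seq_len(nrow(grid))) {
    assign <- c(s, grid[r, ])
    pr <- pi[grid[r, 1]]
    for (e in seq_len(nrow(tree$edge))) {
      pr <- pr * Pt[[e]][assign[tree$edge[e, 1]], assign[tree$edge[e, 2]]]
    }
    tot <- tot + pr
  }
  log(tot)
}
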