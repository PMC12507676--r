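# build a small synthetic profile set directly from templates (no tracking)
template_profiles <- function(guilds, noise_sd = 0.1, n_ind = 6, seed = 1) {
  set.seed(seed)
  mids <- (seq_len(48) - 0.5) * 1800
  lapply(seq_along(guilds), function(i) {
    tpl <- diel_template(guilds[i])
    base <- template_speed(tpl, sched_12, mids)
    ind <- do.call(rbind, lapply(seq_len(n_ind), function(j)
      matrix(base + rnorm(48, 0, noise_sd * max(1, mean(base))), 1, 48)))
    daily_profile(lapply(seq_len(n_ind), function(j)
      ind[j, , drop = FALSE]),
      species = sprintf("sp%04d", i))
  })
}

test_that("profile z-scoring standardises each species over its 48 bins", {
  m <- rbind(aaa = 1:48, bbb = rnorm(48, 5, 2))
  z <- zscore_profiles(m)
  expect_equal(dim(z), c(48, 2))
  expect_equal(colMeans(z), c(aaa = 0, bbb = 0), tolerance = 1e-12)
  expect_equal(apply(z, 2, sd), c(aaa = 1, bbb = 1), tolerance = 1e-12)
  # an already standardised profile is unchanged
  v <- as.numeric(scale(rnorm(48)))
  expect_equal(unname(zscore_profiles(rbind(ccc = v))[, 1]), v)
  expect_error(zscore_profiles(rbind(ddd = rep(2, 48))), "zero-variance")
})

test_that("two anti-phase species give a rank-1 PCA with opposite loadings", {
  x <- sin(2 * pi * (1:48) / 48)
  m <- zscore_profiles(rbind(spdiur = -x, spnoct = x))
  p <- activity_pca(m, n_components = 2, schedule = sched_12)
  expect_gt(p$var_explained[1], 0.999)
  expect_lt(p$loadings["spdiur", 1] * p$loadings["spnoct", 1], 0)
  # duplicated species column: identical loadings
  m3 <- zscore_profiles(rbind(spdiur = -x, spnoct = x, spnoc2 = x))
  p3 <- activity_pca(m3, n_components = 2, schedule = sched_12)
  expect_equal(p3$loadings["spnoct", ], p3$loadings["spnoc2", ],
               ignore_attr = TRUE)
  expect_error(activity_pca(m, n_components = 10), "n_components")
})

test_that("PCA reconstruction from all components reproduces the matrix", {
  profs <- template_profiles(rep(c("diurnal", "nocturnal", "crepuscular",
                                   "cathemeral"), 3), seed = 5)
  z <- zscore_profiles(profs)
  p <- activity_pca(z, n_components = 12, schedule = sched_12)
  recon <- p$scores %*% t(p$loadings)
  recon <- sweep(recon, 2, -p$center)  # add back column centres
  expect_lt(max(abs(recon - z)), 1e-8)
  expect_true(all(diff(p$var_explained) <= 1e-12))
  expect_lte(sum(p$var_explained_all), 1 + 1e-12)
})

test_that("PCA orientation puts nocturnal species positive on PC1 and crepuscular on PC2", {
  profs <- template_profiles(rep(c("diurnal", "nocturnal", "crepuscular"),
                                 each = 5), noise_sd = 0.05, seed = 7)
  z <- zscore_profiles(profs)
  p <- activity_pca(z, schedule = sched_12, n_components = 10)
  st <- bin_states(sched_12)
  expect_gt(mean(p$scores[st == "night", 1]),
            mean(p$scores[st == "day", 1]))
  noct <- 6:10; diur <- 1:5; crep <- 11:15
  expect_true(all(p$loadings[noct, 1] > 0))
  expect_true(all(p$loadings[diur, 1] < 0))
  expect_gt(min(p$loadings[crep, 2]), max(p$loadings[c(diur, noct), 2]))
  expect_gt(min(p$loadings[crep, 2]), 0)
})

test_that("Ward clustering recovers well-separated guild clouds and names them", {
  set.seed(11)
  pc1 <- c(rnorm(8, -2, 0.1), rnorm(8, 2, 0.1), rnorm(8, 0, 0.1))
  pc2 <- c(rnorm(16, 0, 0.1), rnorm(8, 2, 0.1))
  names(pc1) <- names(pc2) <- sprintf("sp%04d", 1:24)
  cl <- cluster_loadings(pc1, pc2)
  expect_equal(as.character(cl[1:8]), rep("diurnal", 8))
  expect_equal(as.character(cl[9:16]), rep("nocturnal", 8))
  expect_equal(as.character(cl[17:24]), rep("crepuscular", 8))
  # three distinct points: one per cluster
  cl3 <- cluster_loadings(setNames(c(-1, 1, 0), c("a", "b", "c")),
                          setNames(c(0, 0, 1), c("a", "b", "c")))
  expect_equal(length(unique(cl3)), 3)
  expect_error(cluster_loadings(1:2, 1:2), "3 species")
})

test_that("the cathemeral rule is strict at its boundary", {
  flat <- list(species = "aaa", profile = rep(5, 48), sd = rep(1, 48),
               sd_days = rep(1, 48), n = 4)
  expect_true(cathemeral_rule(flat))
  strong <- list(species = "bbb", profile = rep(c(0, 10), 24),
                 sd = rep(0.1, 48), sd_days = rep(0.1, 48), n = 4)
  expect_false(cathemeral_rule(strong))
  # range exactly 2 x mean SD is NOT cathemeral (strict <)
  edge <- list(species = "ccc", profile = c(rep(0, 24), rep(2, 24)),
               sd = rep(1, 48), sd_days = rep(1, 48), n = 4)
  expect_false(cathemeral_rule(edge))
  # single individual falls back to across-days SD with a message
  single <- list(species = "ddd", profile = rep(5, 48),
                 sd = rep(NA_real_, 48), sd_days = rep(1, 48), n = 1)
  expect_message(res <- cathemeral_rule(single), "across days")
  expect_true(res)
})

test_that("guild assignment is invariant to species input order", {
  guilds <- rep(c("diurnal", "nocturnal", "crepuscular", "cathemeral"),
                each = 4)
  profs <- template_profiles(guilds, seed = 13)
  cls <- classify_diel(profs, sched_12)
  perm <- c(9:16, 1:8)
  cls_p <- classify_diel(profs[perm], sched_12)
  tab1 <- cls$table[order(cls$table$species), ]
  tab2 <- cls_p$table[order(cls_p$table$species), ]
  expect_equal(as.character(tab1$guild), as.character(tab2$guild))
})

test_that("the quadratic bridge fit behaves on exact, null and star-tree cases", {
  # exact parabola
  pc1 <- seq(-2, 2, length.out = 20)
  pc2 <- 1 - 0.5 * pc1^2
  f <- quadratic_bridge_fit(pc1, pc2)
  expect_equal(f$ols$r_squared, 1, tolerance = 1e-10)
  expect_equal(unname(f$ols$coefficients[3]), -0.5, tolerance = 1e-10)
  # pure-noise PC2 with symmetric PC1: quadratic term centred on zero
  set.seed(17)
  qcoefs <- vapply(seq_len(200), function(i)
    unname(quadratic_bridge_fit(pc1,
                                rnorm(20))$ols$coefficients[3]),
    numeric(1))
  expect_lt(abs(mean(qcoefs)), 0.05)
  # star tree: PGLS equals OLS
  star <- ape::stree(20, "star"); star$edge.length <- rep(1, 20)
  star$tip.label <- sprintf("sp%04d", 1:20)
  pc2n <- pc2 + rnorm(20, 0, 0.1)
  names(pc1) <- names(pc2n) <- star$tip.label
  f2 <- quadratic_bridge_fit(pc1, pc2n, tree = star)
  expect_equal(unname(f2$pgls$coefficients), unname(f2$ols$coefficients),
               tolerance = 1e-8)
  expect_error(quadratic_bridge_fit(rep(1, 10), rnorm(10)), "collinear")
})
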