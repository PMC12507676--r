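test_that("the quality mask applies the printed clauses with exclusive boundaries", {
  sites <- data.frame(
    QD = c(1.9, 2.0, 25, 25, 25, 25, NA),
    FS = c(10, 60.0, 60.1, 10, 10, 10, NA),
    MQ = c(50, 40.0, 50, 39.9, 50, 50, NA),
    MQRankSum = c(0, -12.5, 0, 0, -12.6, 0, NA),
    ReadPosRankSum = c(0, -8.0, 0, 0, 0, -8.1, NA))
  expect_equal(quality_mask(sites),
               c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE))
})

test_that("the depth mask is inclusive at 900 and 1900", {
  sites <- data.frame(DP = c(899, 900, 1400, 1900, 1901, NA))
  expect_equal(depth_mask(sites),
               c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE))
})

test_that("masks commute: conjunction order does not matter", {
  set.seed(21)
  sites <- data.frame(QD = runif(50, 0, 5), FS = runif(50, 0, 100),
                      MQ = runif(50, 30, 60), MQRankSum = runif(50, -15, 3),
                      ReadPosRankSum = runif(50, -10, 3),
                      DP = sample(500:2500, 50))
  expect_equal(quality_mask(sites) & depth_mask(sites),
               depth_mask(sites) & quality_mask(sites))
})

test_that("site selection drops indels, multiallelics, unplaced and singletons", {
  # 4 individuals; PLs make individual genotypes certain
  pl_of <- function(genos) {
    m <- t(vapply(genos, function(g) {
      v <- c(60, 60, 60); v[g + 1] <- 0; v
    }, numeric(3)))
    array(m, c(1, length(genos), 3))
  }
  base <- data.frame(chrom = "chr1", pos = 100, ref = "A", alt = "T",
                     QD = 20, FS = 5, MQ = 55, MQRankSum = 0,
                     ReadPosRankSum = 0, DP = 1200)
  # singleton: one het, rest hom-ref
  expect_false(site_selection(base, pl_of(c(1, 0, 0, 0))))
  # two het carriers pass
  expect_true(site_selection(base, pl_of(c(1, 1, 0, 0))))
  # one hom-alt individual only: minor allele in a single individual
  expect_false(site_selection(base, pl_of(c(2, 0, 0, 0))))
  # monomorphic fails
  expect_false(site_selection(base, pl_of(c(0, 0, 0, 0))))
  indel <- base; indel$alt <- "AT"
  expect_false(site_selection(indel, pl_of(c(1, 1, 0, 0))))
  multi <- base; multi$alt <- "T,G"
  expect_false(site_selection(multi, pl_of(c(1, 1, 0, 0))))
  unpl <- base; unpl$chrom <- "scaffold_un001"
  expect_false(site_selection(unpl, pl_of(c(1, 1, 0, 0))))
  # mappability BED (0-based half-open): pos 100 is inside [99, 100)
  bed_in <- data.frame(chrom = "chr1", start = 99, end = 100)
  bed_out <- data.frame(chrom = "chr1", start = 100, end = 200)
  expect_true(site_selection(base, pl_of(c(1, 1, 0, 0)),
                             mappability_bed = bed_in))
  expect_false(site_selection(base, pl_of(c(1, 1, 0, 0)),
                              mappability_bed = bed_out))
})

test_that("selection of labelled synthetic sites matches ground truth exactly", {
  tr <- simulate_tree(12, seed = 131)
  sim <- simulate_genotype_likelihoods(tr, n_sites = 1000, n_assoc = 0,
                                       depth = 8, seed = 132,
                                       p_fail_quality = 0.1,
                                       p_fail_depth = 0.08, p_decoy = 0.12)
  keep <- site_selection(sim$sites, sim$pl)
  expect_equal(as.logical(keep), sim$sites$keep)
  expect_gt(sum(!keep), 50)
})

test_that("allele-frequency posteriors honour certain genotypes and missing data", {
  certain <- function(g) { v <- c(600, 600, 600); v[g + 1] <- 0; v }
  # both individuals hom-ref
  expect_equal(af_posterior(rbind(certain(0), certain(0)))$f, 0,
               tolerance = 1e-6)
  # one het, one hom-alt: 3 of 4 chromosomes
  est <- af_posterior(rbind(certain(1), certain(2)))
  expect_equal(est$f, 0.75, tolerance = 1e-6)
  expect_equal(est$f_map, 0.75)
  # all-missing species is flagged at 0.5
  miss <- af_posterior(matrix(NA_real_, 2, 3))
  expect_true(miss$flagged)
  expect_equal(miss$f, 0.5)
})

test_that("the posterior is equivariant under ref/alt swap", {
  set.seed(23)
  for (i in 1:20) {
    pl <- matrix(sample(0:80, 6, replace = TRUE), 2, 3)
    pl <- pl - apply(pl, 1, min)
    f1 <- af_posterior(pl)$f
    f2 <- af_posterior(pl[, 3:1])$f
    expect_equal(f2, 1 - f1, tolerance = 1e-9)
  }
})

test_that("noisy posteriors recover the realised allele frequencies", {
  tr <- simulate_tree(10, seed = 133)
  sim <- simulate_genotype_likelihoods(tr, n_sites = 5000, n_assoc = 0,
                                       depth = 10, seed = 134,
                                       p_fail_quality = 0,
                                       p_fail_depth = 0, p_decoy = 0)
  af <- af_posterior_table(sim$pl, sim$ind_species)
  expect_lt(mean(abs(af - sim$geno_af)), 0.08)
  # vectorised table agrees with the per-species EM
  i <- 17
  one <- af_posterior(sim$pl[i, 1:2, ])
  expect_equal(af[i, 1], one$f, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("allele-frequency scaling round-trips exactly", {
  f <- runif(100)
  expect_identical(unscale_af(scale_af(f)), f)
  expect_equal(scale_af(c(0, 0.5, 1)), c(-1, 0, 1))
})

test_that("GLM GWAS handles degenerate and exact relationships", {
  set.seed(25)
  X <- matrix(rnorm(20 * 5), 20, 5)
  X[, 3] <- 1                      # zero-variance column
  y <- 2 * X[, 1] + rnorm(20, 0, 1e-8)
  res <- glm_gwas(y, X)
  expect_equal(res$p[3], 1)
  expect_equal(res$slope[3], 0)
  expect_lt(res$p[1], 1e-20)
  expect_equal(res$slope[1], 2, tolerance = 1e-6)
  # agrees with lm() per column
  o <- summary(lm(y ~ X[, 2]))
  expect_equal(res$p[2], o$coefficients[2, 4], tolerance = 1e-9)
})

test_that("GLM p-values are uniform for null sites on a star tree", {
  set.seed(27)
  n <- 40
  X <- matrix(runif(n * 400, -1, 1), n, 400)
  y <- rnorm(n)
  res <- glm_gwas(y, X)
  expect_gt(suppressWarnings(ks.test(res$p, "punif"))$p.value, 0.01)
})

test_that("PGLS GWAS equals GLM GWAS on a star tree exactly", {
  star <- ape::stree(30, "star"); star$edge.length <- rep(1, 30)
  star$tip.label <- sprintf("sp%04d", 1:30)
  set.seed(29)
  X <- matrix(runif(30 * 50, -1, 1), 30, 50,
              dimnames = list(star$tip.label, NULL))
  y <- setNames(rnorm(30), star$tip.label)
  g <- glm_gwas(y, X)
  p <- pgls_gwas(y, X, star)
  expect_equal(p$slope, g$slope, tolerance = 1e-10)
  expect_equal(p$p, g$p, tolerance = 1e-10)
})

test_that("PGLS keeps its size on structured nulls where the GLM inflates", {
  tr <- tree32
  set.seed(31)
  nrep <- 400
  Y <- simulate_continuous(tr, "BM", list(sigma2 = 1), seed = 33,
                           nsim = nrep)
  X <- simulate_continuous(tr, "BM", list(sigma2 = 1), seed = 34,
                           nsim = nrep)
  pg <- numeric(nrep); po <- numeric(nrep)
  for (i in seq_len(nrep)) {
    xi <- matrix(X[, i], ncol = 1, dimnames = list(rownames(X), NULL))
    pg[i] <- pgls_gwas(setNames(Y[, i], rownames(Y)), xi, tr)$p
    po[i] <- glm_gwas(Y[, i], xi)$p
  }
  expect_lt(abs(mean(pg < 0.05) - 0.05), 2.58 * sqrt(0.05 * 0.95 / nrep))
  expect_gt(mean(po < 0.05), 0.10)
})

test_that("HAV calling respects its cutoffs at the extremes", {
  set.seed(35)
  res <- data.frame(glm_p = runif(200), pgls_p = runif(200))
  expect_true(all(call_havs(res, glm_cutoff = 1, pgls_cutoff = 1)))
  expect_false(any(call_havs(res, glm_cutoff = 0, pgls_cutoff = 0)))
  hv <- call_havs(res, glm_cutoff = 1, pgls_top_frac = 0.05)
  expect_equal(sum(hv), 10)
})

test_that("HAV pattern clustering groups identical and anti-correlated rows", {
  af <- rbind(a = rep(0.9, 10), b = rep(0.9, 10), c = rep(0.1, 10))
  cl <- cluster_hav_patterns(af, k = 2)
  expect_equal(cl$groups[["a"]], cl$groups[["b"]])
  expect_false(cl$groups[["a"]] == cl$groups[["c"]])
  # row-order permutation preserves the group composition
  cl2 <- cluster_hav_patterns(af[c(3, 1, 2), ], k = 2)
  expect_equal(cl2$groups[["a"]], cl2$groups[["b"]])
  expect_false(cl2$groups[["a"]] == cl2$groups[["c"]])
  expect_error(cluster_hav_patterns(af[1, , drop = FALSE]), "2 HAVs")
})

test_that("the gene-set overlap test matches direct hypergeometric summation", {
  # |A| = |B| = 100, universe 10,000, overlap 10
  A <- paste0("g", 1:100)
  B <- paste0("g", c(1:10, 201:290))
  res <- gene_overlap_test(A, B, 10000)
  expect_equal(res$overlap, 10)
  p_brute <- sum(vapply(10:100, function(k)
    choose(100, k) * choose(10000 - 100, 100 - k) / choose(10000, 100),
    numeric(1)))
  expect_equal(res$p, p_brute, tolerance = 1e-10)
  # disjoint sets in a tiny universe: p near 1
  expect_gt(gene_overlap_test(paste0("x", 1:3), paste0("y", 1:3), 200)$p,
            0.9)
  # identical sets: minimal possible p for the configuration
  expect_lt(gene_overlap_test(A, A, 10000)$p, 1e-200)
  expect_error(gene_overlap_test(A, B, 0), "empty universe")
})

test_that("VCF output round-trips through vcfR with PLs and INFO intact", {
  tr <- simulate_tree(6, seed = 141)
  sim <- simulate_genotype_likelihoods(tr, n_sites = 120, n_assoc = 5,
                                       seed = 142)
  f <- file.path(tempdir(), "roundtrip.vcf")
  write_sites_vcf(sim, f)
  back <- read_sites_vcf(f)
  expect_equal(nrow(back$sites), 120)
  expect_equal(back$sites$QD, sim$sites$QD)
  expect_equal(back$sites$DP, as.numeric(sim$sites$DP))
  expect_equal(back$pl[, , 1], sim$pl[, , 1], ignore_attr = TRUE)
  expect_equal(back$pl[, , 3], sim$pl[, , 3], ignore_attr = TRUE)
  # filtering on the re-read records matches the generator labels
  keep <- site_selection(back$sites, back$pl)
  expect_equal(as.logical(keep), sim$sites$keep)
  unlink(f)
})
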