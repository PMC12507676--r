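#' Simulate genotype likelihoods with phylogenetically structured allele frequencies
#'
#' Per-species true alternative-allele frequencies are drawn on the logit
#' scale by Brownian motion over the tree (so null sites carry exactly the
#' phylogenetic correlation a PGLS must absorb). A subset of sites is
#' planted as trait-associated: those sites' logit frequencies are centred
#' on a shared latent factor `g` — drawn under an Ornstein-Uhlenbeck
#' transform of the tree covariance (`latent_alpha`), i.e. phylogenetically
#' structured but not locked to the deepest splits — and the species trait
#' is `beta * g` plus Brownian noise, so each planted site tracks the trait
#' up to site noise. Two diploid individuals per species are genotyped
#' under Hardy-Weinberg at the species frequency; genotype likelihoods come
#' from a symmetric per-read error model at Poisson depth (the standard
#' diploid read model). Site annotations (QD, FS, MQ, MQRankSum,
#' ReadPosRankSum, DP) are drawn with known pass/fail labels, and a
#' fraction of decoy records (indels, multiallelic, unplaced-scaffold,
#' singleton) is injected for the filtering stage.
#'
#' @param tree A rooted `phylo`; tips are the species.
#' @param n_sites Number of biallelic SNP records to simulate.
#' @param n_assoc Number of planted trait-associated sites (<= n_sites).
#' @param beta Association effect size; the trait's signal-to-noise ratio
#'   is about `beta / trait_noise_sd` (defaults give ~2).
#' @param depth Mean per-individual read depth (Poisson), default 10.
#' @param error Per-read base error rate, default 0.01.
#' @param seed Integer seed.
#' @param sigma_af Brownian SD of logit allele frequencies over unit depth.
#' @param assoc_scale Loading of the latent factor on planted sites' logit
#'   frequencies; the default (5) makes planted loci nearly fixed between
#'   the phenotype extremes, the regime a species-level association scan
#'   is designed to detect.
#' @param latent_alpha OU pull strength (on the unit-depth tree) of the
#'   latent factor's covariance; default 3.
#' @param trait_noise_sd Brownian SD of the trait noise, default 1.
#' @param p_fail_quality,p_fail_depth,p_decoy Fractions of sites given a
#'   failing quality annotation, an out-of-range DP, or converted into
#'   decoy records (indel / multiallelic / unplaced / singleton).
#' @return List of class `gl_sim`: `pl` (`sites x individuals x 3`
#'   Phred-scaled likelihood array), `sites` (annotation data.frame with
#'   ground-truth `keep` labels and components), `true_af`
#'   (`sites x species` model frequencies), `geno_af` (realised genotype
#'   frequencies, allele count / 4 per species — what the posterior
#'   estimates in the noise-free limit), `trait` (named), `assoc` (planted
#'   site indices), `species`, `ind_species`, `tree`.
#' @export
simulate_genotype_likelihoods <- function(tree, n_sites = 1000,
                                          n_assoc = 0, beta = 2,
                                          depth = 10, error = 0.01,
                                          seed = 1, sigma_af = 1.5,
                                          assoc_scale = 5, latent_alpha = 3,
                                          trait_noise_sd = 1,
                                          p_fail_quality = 0.05,
                                          p_fail_depth = 0.03,
                                          p_decoy = 0.05) {
  stopifnot(n_assoc <= n_sites)
  set.seed(as.integer(seed))
  S <- length(tree$tip.label)
  species <- tree$tip.label
  C1 <- phylo_vcv(tree)
  C1 <- C1 / max(diag(C1))
  Rt <- t(chol(C1 + diag(1e-10, S)))
  bm <- function(m, sdv) Rt %*% matrix(rnorm(S * m, 0, sdv), S, m)
  Cg <- ou_vcv(C1, latent_alpha, 1)
  Cg <- Cg / max(diag(Cg))
  Rg <- t(chol(Cg + diag(1e-10, S)))
  oug <- function(m, sdv) Rg %*% matrix(rnorm(S * m, 0, sdv), S, m)

  g <- as.numeric(oug(1, 1))
  trait <- setNames(beta * g + as.numeric(bm(1, trait_noise_sd)), species)

  assoc <- if (n_assoc > 0) sort(sample.int(n_sites, n_assoc)) else integer(0)
  mu <- qlogis(runif(n_sites, 0.15, 0.85))
  Z <- t(bm(n_sites, sigma_af))          # sites x species
  Z <- Z + mu
  if (n_assoc > 0) {
    # planted sites: logit-f centred on the latent factor, smaller site noise
    Zg <- t(oug(n_assoc, sigma_af / 3))
    Z[assoc, ] <- sweep(Zg, 2, assoc_scale * g, "+") + mu[assoc]
  }
  f <- plogis(Z)                          # sites x species true AF

  n_ind <- 2 * S
  ind_species <- rep(species, each = 2)
  fi <- f[, rep(seq_len(S), each = 2), drop = FALSE]
  geno <- matrix(rbinom(n_sites * n_ind, 2, as.numeric(fi)),
                 n_sites, n_ind)
  dp <- matrix(rpois(n_sites * n_ind, depth), n_sites, n_ind)
  geno_af <- t(rowsum(t(geno), ind_species))[, species, drop = FALSE] / 4
  p_alt <- c(error, 0.5, 1 - error)[geno + 1]
  alt_reads <- matrix(rbinom(n_sites * n_ind, as.numeric(dp), p_alt),
                      n_sites, n_ind)
  pl <- gl_from_reads(alt_reads, dp, error)

  # DP is reported on the study's scale (120 diploid samples), so the
  # printed 900-1900 depth window applies regardless of cohort size
  dp_study <- rowSums(dp) * 120 / n_ind
  sites <- draw_site_annotations(n_sites, dp_study, p_fail_quality,
                                 p_fail_depth, p_decoy)
  if (n_assoc > 0) {
    # planted sites are clean, analysable SNPs by construction: the decoy
    # and mask failures exercise the filtering stage on null sites only
    sites$pass_quality[assoc] <- TRUE
    sites$QD[assoc] <- pmax(sites$QD[assoc], 5)
    sites$FS[assoc] <- pmin(sites$FS[assoc], 20)
    sites$MQ[assoc] <- pmax(sites$MQ[assoc], 45)
    sites$MQRankSum[assoc] <- pmax(sites$MQRankSum[assoc], -3)
    sites$ReadPosRankSum[assoc] <- pmax(sites$ReadPosRankSum[assoc], -3)
    sites$pass_depth[assoc] <- TRUE
    sites$DP[assoc] <- as.integer(pmin(pmax(sites$DP[assoc], 900L), 1900L))
    sites$decoy[assoc] <- "none"
    sites$chrom[assoc] <- "chr1"
    sites$is_snp[assoc] <- TRUE
    sites$biallelic[assoc] <- TRUE
    sites$placed[assoc] <- TRUE
    base4 <- c("A", "C", "G", "T")
    sites$ref[assoc] <- substr(sites$ref[assoc], 1, 1)
    sites$alt[assoc] <- vapply(seq_along(assoc), function(i)
      sample(setdiff(base4, sites$ref[assoc[i]]), 1), character(1))
  }
  # minor-allele count from best genotypes (PL argmin)
  best <- apply(pl, c(1, 2), which.min) - 1L
  ac <- rowSums(best)
  mac <- pmin(ac, 2L * n_ind - ac)
  n_carrier <- rowSums(best > 0)
  n_refcar <- rowSums(best < 2)
  carriers <- ifelse(ac <= n_ind, n_carrier, n_refcar)
  sites$mac <- mac
  sites$mac_ok <- mac > 0 & carriers >= 2
  if (any(sites$decoy == "singleton")) {
    idx <- which(sites$decoy == "singleton")
    # force a genuine singleton: one het individual, the rest hom-ref
    for (i in idx) {
      pl[i, , ] <- rep(c(0, 60, 120), each = n_ind)
      pl[i, 1, ] <- c(60, 0, 120)
    }
    sites$mac[idx] <- 1L
    sites$mac_ok[idx] <- FALSE
  }
  sites$keep <- sites$is_snp & sites$biallelic & sites$placed &
    sites$pass_quality & sites$pass_depth & sites$mac_ok
  structure(list(pl = pl, sites = sites, true_af = f, geno_af = geno_af,
                 trait = trait,
                 assoc = assoc, species = species,
                 ind_species = ind_species, tree = tree,
                 error = error),
            class = "gl_sim")
}

# Phred-scaled genotype likelihoods from alt-read counts under the
# symmetric per-read error model (binomial constant cancels on rescaling)
gl_from_reads <- function(alt, dp, error) {
  d <- dim(alt)
  pa <- c(error, 0.5, 1 - error)
  ll <- array(0, c(d[1], d[2], 3))
  for (gg in 0:2) {
    ll[, , gg + 1] <- alt * log10(pa[gg + 1]) +
      (dp - alt) * log10(1 - pa[gg + 1])
  }
  mx <- pmax(ll[, , 1], ll[, , 2], ll[, , 3])
  pl <- round(-10 * (ll - as.numeric(mx)))
  pl
}

draw_site_annotations <- function(n, dp_sum, p_fail_quality, p_fail_depth,
                                  p_decoy) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  qd <- runif(n, 5, 30); fs <- runif(n, 0, 20); mq <- runif(n, 45, 60)
  mqrs <- runif(n, -3, 3); rprs <- runif(n, -3, 3)
  fail_q <- runif(n) < p_fail_quality
  if (any(fail_q)) {
    which_clause <- sample(5, sum(fail_q), replace = TRUE)
    i <- which(fail_q)
    qd[i[which_clause == 1]] <- runif(sum(which_clause == 1), 0, 1.99)
    fs[i[which_clause == 2]] <- runif(sum(which_clause == 2), 60.01, 200)
    mq[i[which_clause == 3]] <- runif(sum(which_clause == 3), 10, 39.99)
    mqrs[i[which_clause == 4]] <- runif(sum(which_clause == 4), -20, -12.51)
    rprs[i[which_clause == 5]] <- runif(sum(which_clause == 5), -15, -8.01)
  }
  dp <- pmin(pmax(dp_sum, 905), 1895)
  fail_d <- runif(n) < p_fail_depth
  if (any(fail_d)) {
    lowhigh <- runif(sum(fail_d)) < 0.5
    dp[fail_d][lowhigh] <- sample(100:899, sum(lowhigh), replace = TRUE)
    dp[fail_d][!lowhigh] <- sample(1901:4000, sum(!lowhigh), replace = TRUE)
  }
  decoy <- rep("none", n)
  is_dec <- runif(n) < p_decoy
  decoy[is_dec] <- sample(c("indel", "multiallelic", "unplaced",
                            "singleton"), sum(is_dec), replace = TRUE)
  alt[decoy == "indel"] <- paste0(ref[decoy == "indel"], "T")
  alt[decoy == "multiallelic"] <- paste0(alt[decoy == "multiallelic"], ",",
                                         ref[decoy == "multiallelic"])
  chrom <- rep("chr1", n)
  chrom[decoy == "unplaced"] <- "scaffold_un001"
  data.frame(chrom = chrom, pos = sort(sample.int(50 * n, n)),
             ref = ref, alt = alt,
             QD = round(qd, 2), FS = round(fs, 3), MQ = round(mq, 2),
             MQRankSum = round(mqrs, 3), ReadPosRankSum = round(rprs, 3),
             DP = as.integer(round(dp)),
             is_snp = decoy != "indel",
             biallelic = decoy != "multiallelic",
             placed = decoy != "unplaced",
             pass_quality = !fail_q, pass_depth = !fail_d,
             decoy = decoy, stringsAsFactors = FALSE)
}

#' Write a simulated variant set as VCF 4.2
#'
#' Emits the records of a [simulate_genotype_likelihoods()] object as an
#' uncompressed VCF with `GT:PL` genotype fields and the INFO annotations
#' used by the quality and depth masks.
#'
#' @param sim A `gl_sim` object.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_sites_vcf <- function(sim, file) {
  s <- sim$sites
  n_ind <- dim(sim$pl)[2]
  ind_names <- paste0(sim$ind_species, "_", rep(1:2, length.out = n_ind))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=dielniche-synthetic",
           paste0("##contig=<ID=", unique(s$chrom), ">"),
           "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
           "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand\">",
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
           "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"MQ rank sum\">",
           "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read pos rank sum\">",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Combined depth\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"Phred-scaled genotype likelihoods\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", ind_names), collapse = "\t"))
  info <- sprintf("QD=%s;FS=%s;MQ=%s;MQRankSum=%s;ReadPosRankSum=%s;DP=%d",
                  s$QD, s$FS, s$MQ, s$MQRankSum, s$ReadPosRankSum, s$DP)
  gt_of <- function(pl_row) {
    g <- max.col(-pl_row, ties.method = "first") - 1L
    c("0/0", "0/1", "1/1")[g + 1]
  }
  body <- vapply(seq_len(nrow(s)), function(i) {
    plm <- sim$pl[i, , ]
    gts <- gt_of(plm)
    samp <- paste0(gts, ":", plm[, 1], ",", plm[, 2], ",", plm[, 3])
    paste(c(s$chrom[i], s$pos[i], ".", s$ref[i], s$alt[i], ".", ".",
            info[i], "GT:PL", samp), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), file)
  invisible(file)
}

#' Read a VCF of biallelic-candidate sites into the package's site table
#'
#' Parses CHROM/POS/REF/ALT, the mask INFO annotations and the PL genotype
#' likelihoods via `vcfR`.
#'
#' @param file VCF path (plain text or gzipped).
#' @return List: `sites` (data.frame `chrom`, `pos`, `ref`, `alt`, `QD`,
#'   `FS`, `MQ`, `MQRankSum`, `ReadPosRankSum`, `DP`), `pl`
#'   (`sites x individuals x 3`, `NA` where missing), `individuals`.
#' @export
read_sites_vcf <- function(file) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  num <- function(key) suppressWarnings(
    as.numeric(vcfR::extract.info(v, element = key)))
  sites <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT,
                      QD = num("QD"), FS = num("FS"), MQ = num("MQ"),
                      MQRankSum = num("MQRankSum"),
                      ReadPosRankSum = num("ReadPosRankSum"),
                      DP = num("DP"), stringsAsFactors = FALSE)
  plc <- vcfR::extract.gt(v, element = "PL")
  n <- nrow(plc); m <- ncol(plc)
  pl <- array(NA_real_, c(n, m, 3))
  for (j in seq_len(m)) {
    parts <- strsplit(plc[, j], ",", fixed = TRUE)
    ok <- lengths(parts) == 3
    vals <- matrix(NA_real_, n, 3)
    vals[ok, ] <- matrix(as.numeric(unlist(parts[ok])), ncol = 3,
                         byrow = TRUE)
    pl[, j, ] <- vals
  }
  list(sites = sites, pl = pl, individuals = colnames(plc))
}
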