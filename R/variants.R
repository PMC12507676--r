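#' GATK-style quality mask
#'
#' A site fails when any printed clause is true: `QD < 2.0`, `FS > 60.0`,
#' `MQ < 40.0`, `MQRankSum < -12.5`, `ReadPosRankSum < -8.0`. Missing
#' annotations pass the clause they belong to (the VariantFiltration
#' convention), and all boundaries are exclusive, following the printed
#' strict inequalities.
#'
#' @param sites Data frame with (any of) columns `QD`, `FS`, `MQ`,
#'   `MQRankSum`, `ReadPosRankSum`; `NA` = missing annotation.
#' @return Logical vector, `TRUE` = pass.
#' @export
quality_mask <- function(sites) {
  clause <- function(x, fails) {
    v <- if (is.null(x)) rep(NA_real_, nrow(sites)) else x
    out <- fails(v)
    out[is.na(out)] <- FALSE
    out
  }
  fail <- clause(sites$QD, function(v) v < 2.0) |
    clause(sites$FS, function(v) v > 60.0) |
    clause(sites$MQ, function(v) v < 40.0) |
    clause(sites$MQRankSum, function(v) v < -12.5) |
    clause(sites$ReadPosRankSum, function(v) v < -8.0)
  !fail
}

#' Summed-depth mask
#'
#' Passes sites whose total read depth across all samples lies in
#' `[low, high]` (900 and 1,900 by default, both inclusive); missing DP
#' fails.
#'
#' @param sites Data frame with a `DP` column.
#' @param low,high Depth bounds.
#' @return Logical vector, `TRUE` = pass.
#' @export
depth_mask <- function(sites, low = 900, high = 1900) {
  ok <- sites$DP >= low & sites$DP <= high
  ok[is.na(ok)] <- FALSE
  ok
}

#' Select analysable biallelic SNPs
#'
#' Applies the full site-selection chain: quality and depth masks,
#' biallelic single-nucleotide records only, placed scaffolds only,
#' optional mappability BED (0-based half-open), and a minor allele
#' observed in at least two individuals under the best (PL-argmin)
#' genotypes.
#'
#' @param sites Site annotation data.frame (`chrom`, `pos`, `ref`, `alt`
#'   plus the mask columns).
#' @param pl `sites x individuals x 3` Phred genotype-likelihood array.
#' @param mappability_bed Optional data.frame `chrom`, `start`, `end`.
#' @param unplaced_pattern Regex marking unplaced scaffolds,
#'   default `"^scaffold"`.
#' @return Logical keep vector with per-criterion columns attached as the
#'   `detail` attribute.
#' @export
site_selection <- function(sites, pl, mappability_bed = NULL,
                           unplaced_pattern = "^scaffold") {
  snp <- nchar(sites$ref) == 1 & nchar(sites$alt) == 1 &
    sites$ref %in% c("A", "C", "G", "T") & sites$alt %in% c("A", "C", "G", "T")
  biallelic <- !grepl(",", sites$alt, fixed = TRUE)
  placed <- !grepl(unplaced_pattern, sites$chrom)
  inbed <- rep(TRUE, nrow(sites))
  if (!is.null(mappability_bed)) {
    inbed <- vapply(seq_len(nrow(sites)), function(i) {
      b <- mappability_bed[mappability_bed$chrom == sites$chrom[i], ,
                           drop = FALSE]
      any(sites$pos[i] > b$start & sites$pos[i] <= b$end)
    }, logical(1))
  }
  n_site <- dim(pl)[1]
  a0 <- matrix(pl[, , 1], n_site)
  a1 <- matrix(pl[, , 2], n_site)
  a2 <- matrix(pl[, , 3], n_site)
  best <- ifelse(a0 <= a1 & a0 <= a2, 0L, ifelse(a1 <= a2, 1L, 2L))
  best[is.na(a0) | is.na(a1) | is.na(a2)] <- NA_integer_
  ac <- rowSums(best, na.rm = TRUE)
  n_chrom <- 2 * rowSums(!is.na(best))
  minor_is_alt <- ac <= n_chrom / 2
  carriers <- ifelse(minor_is_alt, rowSums(best > 0, na.rm = TRUE),
                     rowSums(best < 2, na.rm = TRUE))
  mac <- pmin(ac, n_chrom - ac)
  mac_ok <- mac > 0 & carriers >= 2
  keep <- quality_mask(sites) & depth_mask(sites) & snp & biallelic &
    placed & inbed & mac_ok
  attr(keep, "detail") <- data.frame(
    snp = snp, biallelic = biallelic, placed = placed, in_bed = inbed,
    pass_quality = quality_mask(sites), pass_depth = depth_mask(sites),
    mac_ok = mac_ok)
  keep
}

#' Posterior allele frequency from genotype likelihoods
#'
#' For one species (its diploid individuals at one site), maximises the
#' marginal likelihood `prod_i sum_g L_i(g) HW(g | f)` over the
#' alternative-allele frequency `f` by EM under the Hardy-Weinberg prior,
#' and reports the posterior-mean frequency at the converged `f` (which is
#' the EM fixed point) together with the MAP-genotype frequency.
#'
#' @param pl `individuals x 3` matrix of Phred-scaled likelihoods (`NA`
#'   rows = missing individuals).
#' @param tol,max_iter EM convergence controls.
#' @return List: `f` (posterior mean), `f_map` (from per-individual MAP
#'   genotypes under the HW(f) prior), `n_used`, `flagged` (`TRUE` when all
#'   individuals were missing and f defaults to 0.5).
#' @export
af_posterior <- function(pl, tol = 1e-10, max_iter = 200) {
  pl <- rbind(pl)
  ok <- rowSums(is.na(pl)) == 0
  if (!any(ok))
    return(list(f = 0.5, f_map = 0.5, n_used = 0L, flagged = TRUE))
  L <- 10^(-pl[ok, , drop = FALSE] / 10)
  f <- 0.5
  for (it in seq_len(max_iter)) {
    prior <- c((1 - f)^2, 2 * f * (1 - f), f^2)
    w <- L * rep(prior, each = nrow(L))
    w <- w / rowSums(w)
    f_new <- mean(w[, 2] / 2 + w[, 3])
    if (abs(f_new - f) < tol) { f <- f_new; break }
    f <- f_new
  }
  prior <- c((1 - f)^2, 2 * f * (1 - f), f^2)
  w <- L * rep(prior, each = nrow(L))
  g_map <- max.col(w, ties.method = "first") - 1L
  list(f = f, f_map = sum(g_map) / (2 * nrow(L)), n_used = sum(ok),
       flagged = FALSE)
}

#' Posterior allele-frequency table for all sites and species
#'
#' Vectorised EM over the whole `sites x individuals x 3` PL array,
#' grouping individuals by species (two diploid individuals per species in
#' the study design).
#'
#' @param pl PL array from [simulate_genotype_likelihoods()] or
#'   [read_sites_vcf()].
#' @param ind_species Species code of each individual (column of `pl`).
#' @param tol,max_iter EM controls.
#' @return `sites x species` matrix of posterior alternative-allele
#'   frequencies.
#' @export
af_posterior_table <- function(pl, ind_species, tol = 1e-8,
                               max_iter = 100) {
  species <- unique(ind_species)
  n_sites <- dim(pl)[1]
  out <- matrix(NA_real_, n_sites, length(species),
                dimnames = list(NULL, species))
  for (sp in species) {
    cols <- which(ind_species == sp)
    L <- 10^(-pl[, cols, , drop = FALSE] / 10)   # sites x ind x 3
    miss <- apply(is.na(L), c(1, 2), any)
    L[is.na(L)] <- 1
    use <- !miss
    n_use <- rowSums(use)
    f <- rep(0.5, n_sites)
    for (it in seq_len(max_iter)) {
      p0 <- (1 - f)^2; p1 <- 2 * f * (1 - f); p2 <- f^2
      w0 <- L[, , 1] * p0; w1 <- L[, , 2] * p1; w2 <- L[, , 3] * p2
      s <- w0 + w1 + w2
      eg <- (w1 / 2 + w2) / s
      eg[!use] <- 0
      f_new <- ifelse(n_use > 0, rowSums(eg) / n_use, 0.5)
      if (max(abs(f_new - f)) < tol) { f <- f_new; break }
      f <- f_new
    }
    out[, sp] <- f
  }
  out
}

#' Scale allele frequencies to `[-1, 1]`
#'
#' @param f Frequencies in `[0, 1]`.
#' @return `2 f - 1` (an exact affine map; [unscale_af()] inverts it).
#' @export
scale_af <- function(f) 2 * f - 1

#' @rdname scale_af
#' @param x Scaled values.
#' @export
unscale_af <- function(x) (x + 1) / 2

#' Per-SNP ordinary linear-model association scan
#'
#' Regresses the species trait on each scaled allele-frequency column
#' (OLS, `lm(trait ~ allele frequency)` per SNP, vectorised). Zero-variance
#' columns get slope 0 and p 1.
#'
#' @param trait Per-species trait values.
#' @param X `species x sites` matrix of scaled allele frequencies.
#' @return Data frame `slope`, `se`, `t`, `p` (one row per site).
#' @export
glm_gwas <- function(trait, X) {
  X <- as.matrix(X)
  n <- length(trait)
  if (n < 4) stop("need at least 4 species")
  y <- trait - mean(trait)
  Xc <- sweep(X, 2, colMeans(X))
  sxx <- colSums(Xc^2)
  sxy <- as.numeric(crossprod(Xc, y))
  syy <- sum(y^2)
  b <- ifelse(sxx > 0, sxy / sxx, 0)
  rss <- pmax(0, syy - b * sxy)
  s2 <- rss / (n - 2)
  se <- ifelse(sxx > 0, sqrt(s2 / sxx), NA_real_)
  tv <- ifelse(sxx > 0, b / se, 0)
  p <- ifelse(sxx > 0, 2 * pt(abs(tv), n - 2, lower.tail = FALSE), 1)
  data.frame(slope = b, se = se, t = tv, p = pmin(1, p))
}

#' Per-SNP phylogenetic GLS association scan
#'
#' The PGLS analogue of [glm_gwas()]: trait and allele-frequency columns
#' are whitened once by the Cholesky factor of the tree covariance, then
#' each SNP is a two-parameter GLS regression solved in closed form. On a
#' star tree the result equals [glm_gwas()] exactly.
#'
#' @param trait Named per-species trait values.
#' @param X `species x sites` scaled allele-frequency matrix (rownames =
#'   species).
#' @param tree A rooted `phylo`.
#' @return Data frame `slope`, `se`, `t`, `p`.
#' @export
pgls_gwas <- function(trait, X, tree) {
  X <- as.matrix(X)
  y <- align_trait(tree, trait)
  if (!is.null(rownames(X))) X <- X[tree$tip.label, , drop = FALSE]
  n <- length(y)
  C <- phylo_vcv(tree)
  R <- chol(C)
  yw <- backsolve(R, y, transpose = TRUE)
  ow <- backsolve(R, rep(1, n), transpose = TRUE)
  Xw <- backsolve(R, X, transpose = TRUE)
  o2 <- sum(ow^2)
  oy <- sum(ow * yw)
  yy <- sum(yw^2)
  ox <- as.numeric(crossprod(Xw, ow))
  xy <- as.numeric(crossprod(Xw, yw))
  xx <- colSums(Xw^2)
  denom <- o2 * xx - ox^2
  degenerate <- denom <= .Machine$double.eps * o2 * pmax(xx, 1)
  b1 <- ifelse(degenerate, 0, (o2 * xy - ox * oy) / denom)
  b0 <- ifelse(degenerate, oy / o2, (xx * oy - ox * xy) / denom)
  rss <- pmax(0, yy - b0 * oy - b1 * xy)
  s2 <- rss / (n - 2)
  se <- ifelse(degenerate, NA_real_, sqrt(s2 * o2 / denom))
  tv <- ifelse(degenerate, 0, b1 / se)
  p <- ifelse(degenerate, 1,
              2 * pt(abs(tv), n - 2, lower.tail = FALSE))
  data.frame(slope = b1, se = se, t = tv, p = pmin(1, p))
}

#' Call highly associated variants (HAVs)
#'
#' A site is a HAV when it passes both genome-wide cutoffs: GLM p at or
#' below `glm_cutoff` and PGLS p at or below `pgls_cutoff` (given directly
#' or as the empirical `pgls_top_frac` quantile of the scan's PGLS
#' p-values).
#'
#' @param results Data frame with columns `glm_p` and `pgls_p`.
#' @param glm_cutoff Absolute GLM p cutoff.
#' @param pgls_cutoff Absolute PGLS p cutoff; overrides `pgls_top_frac`.
#' @param pgls_top_frac Fraction of smallest PGLS p-values to admit when no
#'   absolute cutoff is given.
#' @return Logical HAV flags with the resolved cutoffs as attributes.
#' @export
call_havs <- function(results, glm_cutoff = 1e-5, pgls_cutoff = NULL,
                      pgls_top_frac = 1e-4) {
  if (is.null(pgls_cutoff))
    pgls_cutoff <- as.numeric(quantile(results$pgls_p, pgls_top_frac,
                                       type = 1))
  hav <- results$glm_p <= glm_cutoff & results$pgls_p <= pgls_cutoff
  attr(hav, "glm_cutoff") <- glm_cutoff
  attr(hav, "pgls_cutoff") <- pgls_cutoff
  hav
}

#' Cluster HAV allele-frequency patterns across species
#'
#' Hierarchical clustering (average linkage, Euclidean distance) of the
#' HAV rows of the allele-frequency matrix; groups of variants with similar
#' patterns across species.
#'
#' @param af `HAVs x species` allele-frequency matrix (>= 2 rows).
#' @param k Number of groups (or use `h`).
#' @param h Cut height alternative to `k`.
#' @return List: `groups` (integer vector in input row order), `hclust`.
#' @export
cluster_hav_patterns <- function(af, k = NULL, h = NULL) {
  af <- as.matrix(af)
  if (nrow(af) < 2) stop("need at least 2 HAVs")
  hc <- hclust(dist(af, method = "euclidean"), method = "average")
  if (is.null(k) && is.null(h)) k <- 2
  groups <- cutree(hc, k = k, h = h)
  list(groups = groups, hclust = hc)
}

#' Hypergeometric gene-set overlap test
#'
#' Upper-tail hypergeometric probability of observing at least the given
#' overlap between two gene sets drawn from a common universe.
#'
#' @param setA,setB Character vectors of gene identifiers.
#' @param universe Universe size (count) or character vector.
#' @return List: `overlap`, `p`.
#' @export
gene_overlap_test <- function(setA, setB, universe) {
  U <- if (is.numeric(universe)) universe else length(unique(universe))
  if (U <= 0) stop("empty universe")
  a <- length(unique(setA)); b <- length(unique(setB))
  ov <- length(intersect(unique(setA), unique(setB)))
  list(overlap = ov,
       p = phyper(ov - 1, a, U - a, b, lower.tail = FALSE))
}

#' Joint GLM + PGLS association scan
#'
#' Convenience wrapper running both association tests over an
#' allele-frequency matrix and assembling the per-SNP result table.
#'
#' @param trait Named per-species trait.
#' @param af `sites x species` posterior allele-frequency matrix.
#' @param tree A rooted `phylo`.
#' @return Data frame: `glm_slope`, `glm_p`, `pgls_slope`, `pgls_p`.
#' @export
gwas_scan <- function(trait, af, tree) {
  X <- t(scale_af(af))            # species x sites
  rownames(X) <- colnames(af)
  g <- glm_gwas(trait[tree$tip.label], X[tree$tip.label, , drop = FALSE])
  p <- pgls_gwas(trait, X, tree)
  data.frame(glm_slope = g$slope, glm_p = g$p,
             pgls_slope = p$slope, pgls_p = p$p)
}

#' Write per-SNP association results as TSV
#'
#' One row per analysed site: position, per-species posterior allele
#' frequencies, both association p-values and the HAV flag.
#'
#' @param sites Site table rows for the analysed (kept) sites.
#' @param af `sites x species` posterior allele-frequency matrix.
#' @param scan [gwas_scan()] result for the same sites.
#' @param hav Logical HAV flags from [call_havs()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_gwas_tsv <- function(sites, af, scan, hav, file) {
  out <- data.frame(chrom = sites$chrom, pos = sites$pos,
                    ref = sites$ref, alt = sites$alt,
                    round(af, 4),
                    glm_slope = scan$glm_slope, glm_p = scan$glm_p,
                    pgls_slope = scan$pgls_slope, pgls_p = scan$pgls_p,
                    hav = as.logical(hav), check.names = FALSE)
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write called HAVs as a BED file
#'
#' Standard 0-based half-open BED of the highly associated variant
#' positions.
#'
#' @param sites Site table rows for the analysed sites.
#' @param hav Logical HAV flags.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_hav_bed <- function(sites, hav, file) {
  h <- sites[as.logical(hav), , drop = FALSE]
  bed <- data.frame(chrom = h$chrom, start = h$pos - 1L, end = h$pos)
  write.table(bed, file, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(file)
}
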