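#' Z-score species daily profiles
#'
#' Standardises each species' 48-bin daily mean-speed profile to mean 0,
#' SD 1 across its 48 bins, returning the `48 x S` matrix used by the diel
#' PCA (time bins as observations, species as features).
#'
#' @param profiles A list of [daily_profile()] objects, or an `S x 48`
#'   matrix with species as rows.
#' @return `48 x S` numeric matrix, columns named by species.
#' @export
zscore_profiles <- function(profiles) {
  if (is.list(profiles) && !is.matrix(profiles)) {
    m <- do.call(rbind, lapply(profiles, function(p) p$profile))
    rownames(m) <- vapply(profiles, function(p) p$species, character(1))
  } else m <- as.matrix(profiles)
  if (ncol(m) != 48) stop("profiles must have 48 bins")
  sds <- apply(m, 1, sd)
  if (any(sds == 0)) stop("zero-variance profile for species: ",
                          paste(rownames(m)[sds == 0], collapse = ", "))
  t((m - rowMeans(m)) / sds)
}

#' PCA of diel activity profiles
#'
#' PCA of the z-scored `48 x S` profile matrix with the 48 time bins as
#' observations and species as features. Signs are fixed deterministically:
#' PC1 is oriented so that night bins score higher than day bins (so
#' nocturnal species take positive PC1 loadings), PC2 so that dawn/dusk
#' ramp bins score positive (crepuscular species take positive PC2
#' loadings); higher components get their largest-magnitude loading
#' positive.
#'
#' @param m `48 x S` z-scored matrix from [zscore_profiles()].
#' @param n_components Components retained, default 10.
#' @param schedule Light schedule used to identify day/night/ramp bins.
#' @return Object of class `activity_pca`: `scores` (`48 x k` bin scores),
#'   `loadings` (`S x k` species loadings), `var_explained` (fractions of
#'   total variance, all components summarised over the retained `k`),
#'   `bin_state`.
#' @export
activity_pca <- function(m, n_components = 10,
                         schedule = make_light_schedule()) {
  S <- ncol(m)
  if (S < 2) stop("need at least 2 species")
  if (n_components > min(48, S))
    stop("n_components exceeds min(48, n species)")
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(n_components, length(pc$sdev))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  st <- bin_states(schedule)
  night <- st == "night"; day <- st == "day"
  ramp <- st %in% c("dawn-ramp", "dusk-ramp")
  for (j in seq_len(k)) {
    flip <- if (j == 1) {
      mean(scores[night, j]) < mean(scores[day, j])
    } else if (j == 2 && any(ramp)) {
      mean(scores[ramp, j]) < mean(scores[!ramp, j])
    } else {
      loadings[which.max(abs(loadings[, j])), j] < 0
    }
    if (isTRUE(flip)) {
      scores[, j] <- -scores[, j]
      loadings[, j] <- -loadings[, j]
    }
  }
  structure(list(scores = scores, loadings = loadings,
                 var_explained = ve[seq_len(k)],
                 var_explained_all = ve, bin_state = st,
                 center = pc$center),
            class = "activity_pca")
}

#' @exportS3Method base::print
print.activity_pca <- function(x, ...) {
  cat(sprintf("diel activity PCA: %d species, PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$loadings), 100 * x$var_explained[1],
              100 * x$var_explained[2]))
  invisible(x)
}

#' Ward clustering of PC1/PC2 loadings into three diel groups
#'
#' Agglomerative Ward clustering of the species' (PC1, PC2) loading points,
#' cut at three clusters. Clusters are named by their centroid's PC1
#' position: most negative = diurnal, most positive = nocturnal, remaining =
#' crepuscular.
#'
#' @param pc1,pc2 Species loadings (named by species code).
#' @return Factor of labels `diurnal`/`crepuscular`/`nocturnal`, named by
#'   species, in the input order.
#' @export
cluster_loadings <- function(pc1, pc2) {
  if (length(pc1) < 3) stop("need at least 3 species")
  pts <- cbind(PC1 = pc1, PC2 = pc2)
  hc <- hclust(dist(pts), method = "ward.D2")
  cl <- cutree(hc, k = 3)
  cent <- tapply(pc1, cl, mean)
  lab <- character(3)
  lab[which.min(cent)] <- "diurnal"
  lab[which.max(cent)] <- "nocturnal"
  lab[setdiff(1:3, c(which.min(cent), which.max(cent)))] <- "crepuscular"
  out <- factor(lab[cl], levels = c("diurnal", "nocturnal", "crepuscular"))
  names(out) <- names(pc1)
  out
}

#' Cathemeral variability rule
#'
#' A species is called cathemeral when the minimum-to-maximum difference of
#' its mean daily profile is strictly smaller than twice the mean (across
#' bins) of its per-bin standard deviation. This override captures species
#' whose between-individual variability swamps any daily structure.
#'
#' @param profile A [daily_profile()] object.
#' @param sd_source `"individuals"` (default) or `"days"`; single-individual
#'   species fall back to the across-days SD with a message.
#' @return Logical scalar.
#' @export
cathemeral_rule <- function(profile, sd_source = c("individuals", "days")) {
  sd_source <- match.arg(sd_source)
  sdv <- if (sd_source == "days") profile$sd_days else profile$sd
  if (all(is.na(sdv))) {
    message("species ", profile$species,
            " has one individual; using SD across days")
    sdv <- profile$sd_days
  }
  rng <- diff(range(profile$profile))
  rng < 2 * mean(sdv, na.rm = TRUE)
}

#' Classify species into diel guilds
#'
#' Full classification chain: z-score profiles, run the diel PCA, Ward
#' cluster the PC1/PC2 loadings into diurnal/nocturnal/crepuscular, then
#' override with `cathemeral` any species passing the variability rule.
#'
#' @param profiles List of [daily_profile()] objects.
#' @param schedule Light schedule of the assay.
#' @param n_components Components for the PCA, default 10.
#' @param sd_source Passed to [cathemeral_rule()].
#' @return List of class `diel_classification`: `table` (data.frame with
#'   `species`, `pc1`, `pc2`, `guild`), `pca` (the [activity_pca()] fit).
#' @export
classify_diel <- function(profiles, schedule = make_light_schedule(),
                          n_components = 10,
                          sd_source = c("individuals", "days")) {
  sd_source <- match.arg(sd_source)
  z <- zscore_profiles(profiles)
  pca <- activity_pca(z, n_components = min(n_components, ncol(z), 48),
                      schedule = schedule)
  pc1 <- pca$loadings[, 1]; pc2 <- pca$loadings[, 2]
  guild <- as.character(cluster_loadings(pc1, pc2))
  cath <- vapply(profiles, cathemeral_rule, logical(1),
                 sd_source = sd_source)
  guild[cath] <- "cathemeral"
  tab <- data.frame(species = colnames(z), pc1 = unname(pc1),
                    pc2 = unname(pc2),
                    guild = factor(guild, levels = c("diurnal", "nocturnal",
                                                     "crepuscular",
                                                     "cathemeral")))
  structure(list(table = tab, pca = pca), class = "diel_classification")
}

#' Quadratic fit of crepuscularity against diurnal-nocturnal preference
#'
#' Fits `PC2 ~ PC1 + PC1^2` by ordinary least squares and, when a tree is
#' supplied, by phylogenetic GLS — the parabola that describes the
#' crepuscular "bridge" between strongly diurnal and strongly nocturnal
#' species.
#'
#' @param pc1,pc2 Species loadings, named by species when `tree` is given.
#' @param tree Optional `phylo` tree for the PGLS fit.
#' @return List with `ols` and (optionally) `pgls` components, each holding
#'   `coefficients`, `r_squared`, `p_quadratic` (t-test of the squared
#'   term) and `p_model` (overall F).
#' @export
quadratic_bridge_fit <- function(pc1, pc2, tree = NULL) {
  if (length(pc1) < 5) stop("need at least 5 species")
  X <- cbind(pc1, pc1sq = pc1^2)
  if (qr(cbind(1, X))$rank < 3) stop("collinear design (degenerate PC1)")
  ols <- lm(pc2 ~ pc1 + I(pc1^2))
  sm <- summary(ols)
  res <- list(ols = list(
    coefficients = coef(ols),
    r_squared = sm$r.squared,
    p_quadratic = sm$coefficients["I(pc1^2)", 4],
    p_model = pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                 lower.tail = FALSE)))
  if (!is.null(tree)) {
    fit <- pgls(pc2, X, tree)
    res$pgls <- list(coefficients = fit$coefficients,
                     r_squared = fit$r_squared,
                     p_quadratic = fit$table["pc1sq", "p"],
                     p_model = fit$p_model)
  }
  res
}
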