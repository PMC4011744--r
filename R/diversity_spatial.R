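#' Sample-based rarefaction (Mao Tau) curve
#'
#' Analytic expected OTU richness (and its standard deviation) in random
#' subsets of k samples, computed with the exact hypergeometric formula
#' (via [vegan::specaccum()], `method = "exact"`).
#'
#' @param matrix A `bincom` matrix.
#' @return Data frame of class `accum_curve`: `k`, `richness`, `sd`.
#' @export
mao_tau <- function(matrix) {
  stopifnot(nrow(matrix) >= 1)
  sp <- vegan::specaccum(unclass_matrix(matrix), method = "exact")
  out <- data.frame(k = sp$sites, richness = sp$richness,
                    sd = ifelse(is.na(sp$sd), 0, sp$sd))
  class(out) <- c("accum_curve", "data.frame")
  out
}

#' Raup-Crick dissimilarity matrix
#'
#' Probability-scale beta-diversity between samples. Null communities are
#' assembled preserving each sample's richness, with species drawn with
#' probability proportional to their occupancy (the "r1" null model,
#' simulated through [vegan::nullmodel()]). For each sample pair the
#' dissimilarity is the probability that a null pair shares *more* OTUs
#' than observed, with ties split evenly:
#' \deqn{D = [\#\{S_{null} > S_{obs}\} + 0.5\,\#\{S_{null} = S_{obs}\}] / reps,}
#' so identical composition gives D near 0, disjoint composition D near
#' 1, and 0.5 is the exact chance expectation (ties must be split for
#' this to hold in sparse matrices, where tied shared counts are
#' common). Samples with zero richness get dissimilarity 0.5 to all
#' others, with a warning.
#'
#' @param matrix A `bincom` matrix.
#' @param reps Number of null assemblies per pair (default 999).
#' @param seed Integer seed.
#' @param chunk Null matrices simulated per block (memory control).
#' @return A `dist` object with values in \[0, 1\] and attribute
#'   `metric = "raup_crick"`.
#' @export
raup_crick <- function(matrix, reps = 999, seed = 1, chunk = 50) {
  stopifnot(reps >= 1)
  m <- unclass_matrix(matrix)
  empty <- richness(matrix) == 0
  full <- base::matrix(0.5, nrow(m), nrow(m),
                       dimnames = list(rownames(m), rownames(m)))
  if (sum(!empty) >= 2) {
    sub <- m[!empty, , drop = FALSE]
    obs <- tcrossprod(sub)
    gt <- eq <- base::matrix(0, nrow(sub), nrow(sub))
    nm <- vegan::nullmodel(sub, "r1")
    with_seed(seed, {
      done <- 0
      while (done < reps) {
        k <- min(chunk, reps - done)
        sims <- stats::simulate(nm, nsim = k)
        for (s in seq_len(k)) {
          sh <- tcrossprod(sims[, , s])
          gt <- gt + (sh > obs)
          eq <- eq + (sh == obs)
        }
        done <- done + k
      }
    })
    full[!empty, !empty] <- (gt + 0.5 * eq) / reps
  }
  if (any(empty))
    warning(sprintf("%d sample(s) with zero richness set to 0.5", sum(empty)))
  diag(full) <- 0
  out <- as.dist(full)
  attr(out, "metric") <- "raup_crick"
  out
}

#' Mantel correlogram of community dissimilarity against space
#'
#' Per-distance-class Mantel correlations between a community distance
#' matrix and geographic distance classes of fixed width, with permutation
#' P values and progressive Holm correction across classes
#' (via [vegan::mantel.correlog()]).
#'
#' @param community A `dist` of community dissimilarities.
#' @param coords Two-column matrix/data frame of planar sample coordinates
#'   (meters), in the same order as the distance matrix.
#' @param class_width Distance class width in meters (default 2).
#' @param permutations Permutations per class (default 999).
#' @param seed Integer seed.
#' @return Data frame of class `correlogram`: `class_midpoint`, `n_pairs`,
#'   `r`, `P`, `P_corrected`.
#' @export
mantel_correlogram <- function(community, coords, class_width = 2,
                               permutations = 999, seed = 1) {
  coords <- as.matrix(coords)[, 1:2]
  n <- attr(community, "Size")
  if (nrow(coords) != n)
    stop("coordinates must cover every sample in the distance matrix")
  dgeo <- dist(coords)
  breaks <- seq(0, max(dgeo) + class_width, by = class_width)
  mc <- with_seed(seed,
    vegan::mantel.correlog(community, D.geo = dgeo, break.pts = breaks,
                           nperm = permutations, mult = "holm",
                           progressive = TRUE))
  res <- as.data.frame(mc$mantel.res)
  names(res) <- c("class_midpoint", "n_pairs", "r", "P", "P_corrected")
  keep <- !is.na(res$r)
  if (any(!keep))
    message(sprintf("%d distance class(es) omitted (untestable)",
                    sum(!keep)))
  out <- res[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("correlogram", "data.frame")
  out
}

#' Moran's I spatial autocorrelation
#'
#' Moran's I with inverse-distance weights \eqn{w_{ij} = 1/d_{ij}} (zero
#' diagonal), its analytic expectation \eqn{-1/(n-1)}, and a
#' normal-approximation two-sided P value (via [ape::Moran.I()]).
#'
#' @param values Numeric vector (e.g. an OTU's presence/absence across
#'   samples).
#' @param coords Two-column planar coordinates.
#' @param alternative Passed to [ape::Moran.I()] (default
#'   `"two.sided"`).
#' @return List of class `morans_i`: `I`, `expectation`, `sd`, `P`.
#' @export
morans_i <- function(values, coords, alternative = "two.sided") {
  coords <- as.matrix(coords)[, 1:2]
  n <- length(values)
  stopifnot(nrow(coords) == n, n >= 3)
  if (sd(values) == 0) stop("zero variance: values are constant")
  d <- as.matrix(dist(coords))
  if (any(d[upper.tri(d)] == 0))
    stop("coincident sampling points (distance 0); jitter coordinates or exclude duplicates")
  w <- 1 / d
  diag(w) <- 0
  mi <- ape::Moran.I(values, w, alternative = alternative)
  structure(list(I = mi$observed, expectation = mi$expected,
                 sd = mi$sd, P = mi$p.value),
            class = "morans_i")
}

#' @export
print.morans_i <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (expectation %.4f, sd %.4f), P = %.4g\n",
              x$I, x$expectation, x$sd, x$P))
  invisible(x)
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: partitions the
#' (Gower-centered) distance matrix by group and reports the pseudo-F,
#' R-squared and permutation P value (via [vegan::adonis2()]).
#'
#' @param dist A `dist` object.
#' @param groups Group labels, one per sample.
#' @param permutations Number of permutations (default 9999).
#' @param seed Integer seed.
#' @return List of class `permanova`: `F`, `R2`, `P`, `permutations`.
#' @export
permanova <- function(dist, groups, permutations = 9999, seed = 1) {
  groups <- check_groups(dist, groups)
  df <- data.frame(groups = groups)
  fit <- with_seed(seed,
    vegan::adonis2(dist ~ groups, data = df, permutations = permutations))
  structure(list(F = fit$F[1], R2 = fit$R2[1], P = fit$`Pr(>F)`[1],
                 permutations = permutations),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: F = %.3f, R2 = %.4f, P = %.4g (%d permutations)\n",
              x$F, x$R2, x$P, x$permutations))
  invisible(x)
}

#' PERMDISP: homogeneity of multivariate dispersions
#'
#' Per-sample distances to group centroids in principal-coordinate space
#' (with the standard negative-eigenvalue correction), an F statistic on
#' those distances, and a permutation P value
#' (via [vegan::betadisper()] with `type = "centroid"` and
#' [vegan::permutest()]).
#'
#' @inheritParams permanova
#' @return List of class `permdisp`: `F`, `P`, `group_means` (named mean
#'   distance to centroid per group), `distances` (per-sample).
#' @export
permdisp <- function(dist, groups, permutations = 9999, seed = 1) {
  groups <- check_groups(dist, groups)
  bd <- vegan::betadisper(dist, groups, type = "centroid")
  pt <- with_seed(seed, vegan::permutest(bd, permutations = permutations))
  structure(list(F = pt$tab$F[1], P = pt$tab$`Pr(>F)`[1],
                 group_means = tapply(bd$distances, bd$group, mean),
                 distances = bd$distances,
                 permutations = permutations),
            class = "permdisp")
}

#' @export
print.permdisp <- function(x, ...) {
  cat(sprintf("PERMDISP: F = %.3f, P = %.4g; mean distance to centroid: %s\n",
              x$F, x$P,
              paste(names(x$group_means),
                    sprintf("%.4f", x$group_means), collapse = ", ")))
  invisible(x)
}

check_groups <- function(dist, groups) {
  groups <- factor(groups)
  if (length(groups) != attr(dist, "Size"))
    stop("group labels must cover every sample")
  if (nlevels(groups) < 2) stop("at least 2 groups are required")
  if (any(table(groups) < 2)) stop("every group needs at least 2 samples")
  groups
}

#' CLAM multinomial specialist/generalist classification
#'
#' Classifies each OTU as a specialist of one of two hosts, a generalist,
#' or too rare, using the multinomial supermajority procedure with
#' group-size correction (via [vegan::clamtest()]). Abundances are
#' occurrence counts (number of samples occupied) by default, matching a
#' presence/absence analysis.
#'
#' @param counts_host1,counts_host2 Per-OTU occurrence (or read) counts in
#'   each host.
#' @param otu_ids OTU identifiers.
#' @param alpha Significance level for the multinomial test (default
#'   0.001).
#' @param specialization Supermajority threshold (default 2/3).
#' @param coverage_limit OTUs below this total in both groups are "too
#'   rare" (default 10).
#' @return Data frame of class `clam`: `otu_id`, `n_host1`, `n_host2`,
#'   `class` in `{specialist_host1, specialist_host2, generalist,
#'   too_rare}`.
#' @export
clam_test <- function(counts_host1, counts_host2, otu_ids = NULL,
                      alpha = 0.001, specialization = 2 / 3,
                      coverage_limit = 10) {
  stopifnot(length(counts_host1) == length(counts_host2),
            all(counts_host1 >= 0), all(counts_host2 >= 0))
  if (is.null(otu_ids)) otu_ids <- paste0("otu_", seq_along(counts_host1))
  comm <- rbind(host1 = counts_host1, host2 = counts_host2)
  colnames(comm) <- otu_ids
  ct <- vegan::clamtest(comm, groups = c("host1", "host2"),
                        coverage.limit = coverage_limit,
                        specialization = specialization, alpha = alpha)
  cls <- as.character(ct$Classes)
  map <- c(Specialist_host1 = "specialist_host1",
           Specialist_host2 = "specialist_host2",
           Generalist = "generalist",
           Too_rare = "too_rare")
  out <- data.frame(otu_id = as.character(ct$Species),
                    n_host1 = ct$Total_host1, n_host2 = ct$Total_host2,
                    class = unname(map[cls]), row.names = NULL)
  out <- out[match(otu_ids, out$otu_id), ]
  rownames(out) <- NULL
  class(out) <- c("clam", "data.frame")
  out
}

#' Welch t-test on per-sample OTU richness
#'
#' Two-sample Welch t statistic (Welch-Satterthwaite degrees of freedom)
#' comparing per-sample richness between two groups.
#'
#' @param matrix A `bincom` matrix.
#' @param groups Two-level group labels per sample.
#' @return List of class `welch_t`: `t`, `df`, `P`, `group_means`.
#' @export
richness_welch_t <- function(matrix, groups) {
  groups <- factor(groups)
  stopifnot(length(groups) == nrow(matrix), nlevels(groups) == 2)
  r <- richness(matrix)
  if (all(tapply(r, groups, sd) == 0))
    stop("zero richness variance in both groups")
  tt <- t.test(r ~ groups, var.equal = FALSE)
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 P = tt$p.value,
                 group_means = tapply(r, groups, mean)),
            class = "welch_t")
}

#' @export
print.welch_t <- function(x, ...) {
  cat(sprintf("Welch t = %.3f, df = %.3f, P = %.4g; group means: %s\n",
              x$t, x$df, x$P,
              paste(names(x$group_means),
                    sprintf("%.2f", x$group_means), collapse = ", ")))
  invisible(x)
}
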