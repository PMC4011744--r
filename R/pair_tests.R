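#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment of a vector of P values
#' (wrapper over [stats::p.adjust()] with input validation).
#'
#' @param p_values Numeric vector of P values in \[0, 1\].
#' @return Adjusted values, each >= the raw value and capped at 1.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1))
    stop("P values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Per-pair randomization test of C and T scores
#'
#' For each screened pair, the observed standardized score is compared to
#' its distribution over a margin-preserving null ensemble. Tests are
#' one-sided in the upper tail: a large standardized C indicates
#' segregation, a large standardized T aggregation. The P value includes
#' the observed matrix, \eqn{P = (1 + b)/(1 + M)} with `b` the number of
#' null scores at least as large as observed. FDR adjustment is applied
#' separately within each score family.
#'
#' @param matrix A `bincom` matrix.
#' @param pairs A `pair_set` (see [screen_pairs()]) or two-column index
#'   structure.
#' @param ensemble A `null_ensemble` built from the same matrix margins.
#' @param score `"both"` (default), `"C"` or `"T"`.
#' @inheritParams standardize_scores
#' @return Data frame of class `pair_test` with one row per (pair, score
#'   type): `i`, `j`, `otu_i`, `otu_j`, `R_i`, `R_j`, `S`, `score_type`,
#'   `observed`, `null_mean`, `null_sd`, `P`, `q`, `M_used`; sorted by `P`
#'   within score type.
#' @export
pair_randomization_test <- function(matrix, pairs, ensemble,
                                    score = c("both", "C", "T"),
                                    normalize = c("range", "product")) {
  score <- match.arg(score)
  normalize <- match.arg(normalize)
  check_ensemble_matrix(ensemble, matrix)
  idx <- pair_index_matrix(pairs)
  if (nrow(idx) == 0) stop("empty pair set")
  obs <- pair_scores(matrix, idx, normalize)
  M <- ensemble$M

  if (ensemble$model == "fixed_fixed_curveball" &&
      is.null(ensemble$matrices)) {
    st <- cpp_cb_stream(unclass_matrix(matrix), idx - 1L, M,
                        ensemble$burn_in, ensemble$thin,
                        as.double(ensemble$seed),
                        normalize == "product", FALSE)
    c_ge <- st$c_ge; t_ge <- st$t_ge
    c_mean <- st$c_sum / M
    c_sd <- sqrt(pmax(0, st$c_sum2 / M - c_mean^2))
    t_mean <- st$t_sum / M
    t_sd <- sqrt(pmax(0, st$t_sum2 / M - t_mean^2))
  } else {
    mats <- ensemble_matrices(ensemble, matrix)
    sc <- vapply(mats, function(nm) {
      s <- pair_scores(as_bincom(nm), idx, normalize)
      c(s$C_std, s$T_std)
    }, numeric(2 * nrow(idx)))
    P <- nrow(idx)
    Cn <- base::matrix(sc[seq_len(P), , drop = FALSE], nrow = P)
    Tn <- base::matrix(sc[P + seq_len(P), , drop = FALSE], nrow = P)
    eps <- 1e-12
    c_ge <- rowSums(Cn >= obs$C_std - eps)
    t_ge <- rowSums(Tn >= obs$T_std - eps)
    c_mean <- rowMeans(Cn); c_sd <- apply(Cn, 1, sd)
    t_mean <- rowMeans(Tn); t_sd <- apply(Tn, 1, sd)
  }

  mk <- function(type, observed, ge, nm, nsd) {
    d <- data.frame(
      i = obs$i, j = obs$j, otu_i = obs$otu_i, otu_j = obs$otu_j,
      R_i = obs$R_i, R_j = obs$R_j, S = obs$S,
      score_type = type, observed = observed,
      null_mean = nm, null_sd = nsd,
      P = (1 + ge) / (1 + M), q = bh_adjust((1 + ge) / (1 + M)),
      M_used = M, row.names = NULL)
    d[order(d$P, -d$observed), ]
  }
  out <- list()
  if (score %in% c("both", "C"))
    out$C <- mk("C_std", obs$C_std, c_ge, c_mean, c_sd)
  if (score %in% c("both", "T"))
    out$T <- mk("T_std", obs$T_std, t_ge, t_mean, t_sd)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("pair_test", "data.frame")
  res
}

ensemble_matrices <- function(ensemble, matrix) {
  if (!is.null(ensemble$matrices)) return(ensemble$matrices)
  cpp_cb_ensemble(unclass_matrix(matrix), ensemble$M, ensemble$burn_in,
                  ensemble$thin, as.double(ensemble$seed))
}

#' Community-level segregation/aggregation test
#'
#' Tests whether the mean standardized C (or T) score over all pairs of
#' OTUs in a subset exceeds its fixed-fixed null expectation. The subset
#' (e.g. a phylum or guild) defaults to every OTU with at least one
#' occurrence; pairs are all unordered pairs within the subset, without
#' per-pair screening. Reports the one-sided (upper tail) P value and the
#' standard effect size SES = (observed - null mean) / null SD.
#'
#' @param matrix A `bincom` matrix.
#' @param subset OTU names or column indices; `NULL` = all OTUs with
#'   occurrence >= 1.
#' @param ensemble A `null_ensemble` for the matrix.
#' @param score `"C"` or `"T"`.
#' @inheritParams standardize_scores
#' @param label Optional subset label carried into the result.
#' @return A one-row data frame: `subset`, `score_type`, `n_otus`,
#'   `n_pairs`, `mean_score`, `null_mean`, `null_sd`, `SES`, `P`,
#'   `M_used`.
#' @export
community_score_test <- function(matrix, subset = NULL, ensemble,
                                 score = c("C", "T"),
                                 normalize = c("range", "product"),
                                 label = "All") {
  score <- match.arg(score)
  normalize <- match.arg(normalize)
  check_ensemble_matrix(ensemble, matrix)
  R <- occurrence(matrix)
  if (is.null(subset)) subset <- which(R >= 1)
  if (is.character(subset)) subset <- match(subset, colnames(matrix))
  subset <- subset[!is.na(subset) & R[subset] >= 1]
  if (length(subset) < 2)
    stop("subset must contain at least 2 OTUs with positive occurrence")
  idx <- all_pairs(subset)
  obs <- pair_scores(matrix, idx, normalize)
  obs_mean <- if (score == "C") mean(obs$C_std) else mean(obs$T_std)
  M <- ensemble$M
  if (ensemble$model == "fixed_fixed_curveball" &&
      is.null(ensemble$matrices)) {
    st <- cpp_cb_stream(unclass_matrix(matrix), idx - 1L, M,
                        ensemble$burn_in, ensemble$thin,
                        as.double(ensemble$seed),
                        normalize == "product", FALSE)
    null_comm <- if (score == "C") st$comm_C else st$comm_T
  } else {
    mats <- ensemble_matrices(ensemble, matrix)
    null_comm <- vapply(mats, function(nm) {
      s <- pair_scores(as_bincom(nm), idx, normalize)
      if (score == "C") mean(s$C_std) else mean(s$T_std)
    }, numeric(1))
  }
  null_mean <- mean(null_comm)
  null_sd <- sd(null_comm)
  eps <- 1e-12
  P <- (1 + sum(null_comm >= obs_mean - eps)) / (1 + M)
  data.frame(subset = label, score_type = paste0(score, "_std"),
             n_otus = length(subset), n_pairs = nrow(idx),
             mean_score = obs_mean, null_mean = null_mean,
             null_sd = null_sd,
             SES = if (null_sd > 0) (obs_mean - null_mean) / null_sd
                   else NA_real_,
             P = P, M_used = M, row.names = NULL)
}

#' Host-contrast permutation test of pair scores
#'
#' For each eligible pair, computes the difference in standardized C (and
#' T) scores between the two host datasets,
#' \eqn{\Delta = score(host A) - score(host B)}, and tests it against the
#' null obtained by permuting host labels across samples (group sizes
#' preserved). P values are two-sided on \eqn{|\Delta|}; FDR adjustment is
#' applied within each score family. Pairs must pass the per-host
#' screening thresholds in both host subsets; pairs failing in either are
#' excluded (with a message).
#'
#' @param matrix A `bincom` matrix covering both hosts' samples.
#' @param hosts Per-sample host labels (exactly two distinct values; the
#'   first level in sort order is "host A").
#' @param min_occurrence,min_pair_sum Per-host screening thresholds
#'   (defaults 5 and 25).
#' @param M Number of label permutations (default 10000).
#' @param seed Integer seed.
#' @inheritParams standardize_scores
#' @return Data frame of class `host_contrast`: `i`, `j`, `otu_i`,
#'   `otu_j`, `delta_C`, `P_delta_C`, `q_delta_C`, `delta_T`, `P_delta_T`,
#'   `q_delta_T`, `M_used`.
#' @export
host_difference_test <- function(matrix, hosts, min_occurrence = 5,
                                 min_pair_sum = 25, M = 10000, seed = 1,
                                 normalize = c("range", "product")) {
  normalize <- match.arg(normalize)
  hosts <- as.character(hosts)
  stopifnot(length(hosts) == nrow(matrix))
  lev <- sort(unique(hosts))
  if (length(lev) != 2) stop("exactly two host labels are required")
  a <- hosts == lev[1]

  x <- unclass_matrix(matrix)
  pairs_a <- screen_pairs(as_bincom(x[a, , drop = FALSE]),
                          min_occurrence, min_pair_sum)
  pairs_b <- screen_pairs(as_bincom(x[!a, , drop = FALSE]),
                          min_occurrence, min_pair_sum)
  key <- function(p) paste(p$i, p$j)
  shared <- intersect(key(pairs_a), key(pairs_b))
  dropped <- length(union(key(pairs_a), key(pairs_b))) - length(shared)
  if (dropped > 0)
    message(sprintf(
      "%d pair(s) failed screening in one host subset and were excluded",
      dropped))
  if (length(shared) == 0) stop("no pair passes screening in both hosts")
  idx <- pair_index_matrix(do.call(rbind,
    lapply(strsplit(shared, " "), as.integer)))

  idx0 <- idx - 1L
  product <- normalize == "product"
  delta_for <- function(in_a) {
    sa <- std_scores_fast(x[in_a, , drop = FALSE], idx0, product)
    sb <- std_scores_fast(x[!in_a, , drop = FALSE], idx0, product)
    list(dC = sa$C - sb$C, dT = sa$T - sb$T)
  }
  obs <- delta_for(a)
  n <- nrow(x)
  na <- sum(a)
  cnt_C <- cnt_T <- numeric(nrow(idx))
  with_seed(seed, {
    for (k in seq_len(M)) {
      perm <- logical(n)
      perm[sample.int(n, na)] <- TRUE
      d <- delta_for(perm)
      cnt_C <- cnt_C + (abs(d$dC) >= abs(obs$dC) - 1e-12)
      cnt_T <- cnt_T + (abs(d$dT) >= abs(obs$dT) - 1e-12)
    }
  })
  P_C <- (1 + cnt_C) / (1 + M)
  P_T <- (1 + cnt_T) / (1 + M)
  out <- data.frame(
    i = idx[, 1], j = idx[, 2],
    otu_i = colnames(matrix)[idx[, 1]], otu_j = colnames(matrix)[idx[, 2]],
    delta_C = obs$dC, P_delta_C = P_C, q_delta_C = bh_adjust(P_C),
    delta_T = obs$dT, P_delta_T = P_T, q_delta_T = bh_adjust(P_T),
    M_used = M, row.names = NULL)
  out <- out[order(pmin(out$P_delta_C, out$P_delta_T)), ]
  rownames(out) <- NULL
  attr(out, "hosts") <- lev
  class(out) <- c("host_contrast", "data.frame")
  out
}
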