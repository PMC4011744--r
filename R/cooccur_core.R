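#' Pair occurrence counts
#'
#' For a pair of OTU columns, counts the occurrences of each OTU
#' (`R_i`, `R_j`), the number of samples containing both (`S`), and the
#' number of samples (`N`).
#'
#' @param matrix A `bincom` matrix.
#' @param i,j Column indices or OTU names (must differ).
#' @return A list of class `pair_counts` with elements `R_i`, `R_j`, `S`,
#'   `N`.
#' @export
pair_counts <- function(matrix, i, j) {
  if (is.character(i)) i <- match(i, colnames(matrix))
  if (is.character(j)) j <- match(j, colnames(matrix))
  if (is.na(i) || is.na(j) || i < 1 || j < 1 || i > ncol(matrix) ||
      j > ncol(matrix))
    stop("pair indices out of range")
  if (i == j) stop("a pair must consist of two distinct OTUs")
  ci <- unclass(matrix)[, i]
  cj <- unclass(matrix)[, j]
  structure(list(R_i = sum(ci), R_j = sum(cj), S = sum(ci & cj),
                 N = nrow(matrix)),
            class = "pair_counts")
}

as_pair_counts <- function(R_i, R_j, S, N) {
  structure(list(R_i = R_i, R_j = R_j, S = S, N = N), class = "pair_counts")
}

check_pc <- function(pc) {
  with(pc, {
    smin <- pmax(0, R_i + R_j - N)
    smax <- pmin(R_i, R_j)
    if (any(R_i < 0 | R_j < 0 | S < 0 | R_i > N | R_j > N |
            S < smin | S > smax))
      stop("infeasible pair counts: S must lie in [max(0, Ri+Rj-N), min(Ri, Rj)]")
  })
  invisible(pc)
}

#' Checkerboard (C) score
#'
#' The per-pair segregation statistic \eqn{C = (R_i - S)(R_j - S)}: the
#' number of checkerboard units formed by the two OTUs. Large values mean
#' the pair rarely shares samples.
#'
#' @param pc A `pair_counts` object (fields may be vectors of equal
#'   length).
#' @return Numeric C score(s).
#' @export
c_score <- function(pc) {
  check_pc(pc)
  with(pc, (R_i - S) * (R_j - S))
}

#' Togetherness (T) score
#'
#' The per-pair aggregation statistic \eqn{T = S(N + S - R_i - R_j)}: the
#' number of samples jointly occupied times the number jointly empty.
#' Large values mean joint presences and joint absences dominate.
#'
#' @inheritParams c_score
#' @return Numeric T score(s).
#' @export
t_score <- function(pc) {
  check_pc(pc)
  with(pc, S * (N + S - R_i - R_j))
}

s_bounds <- function(R_i, R_j, N) {
  list(smin = pmax(0, R_i + R_j - N), smax = pmin(R_i, R_j))
}

#' Standardized C and T scores
#'
#' Scores are standardized to \[0, 1\] so that 0 is the lowest and 1 the
#' highest level of segregation (C) or aggregation (T) attainable under
#' the pair's margins: with `normalize = "range"` (the default) each score
#' is divided by its maximum over the margin-feasible co-occurrence range
#' \eqn{S \in [S_{min}, S_{max}]}; `normalize = "product"` divides both
#' scores by \eqn{R_i R_j} instead. Degenerate margins (maximum 0) give a
#' standardized score of 0.
#'
#' @inheritParams c_score
#' @param normalize `"range"` (margin-feasible maximum) or `"product"`.
#' @return List with elements `C_std` and `T_std`, each in \[0, 1\].
#' @export
standardize_scores <- function(pc, normalize = c("range", "product")) {
  normalize <- match.arg(normalize)
  check_pc(pc)
  C <- with(pc, (R_i - S) * (R_j - S))
  T <- with(pc, S * (N + S - R_i - R_j))
  b <- with(pc, s_bounds(R_i, R_j, N))
  if (normalize == "range") {
    cmax <- with(pc, (R_i - b$smin) * (R_j - b$smin))
    tmax <- with(pc, b$smax * (N + b$smax - R_i - R_j))
  } else {
    cmax <- tmax <- with(pc, R_i * R_j)
  }
  list(C_std = ifelse(cmax > 0, C / cmax, 0),
       T_std = ifelse(tmax > 0, T / tmax, 0))
}

#' Per-pair co-occurrence scores for a set of pairs
#'
#' Computes raw and standardized C and T scores for every pair in a
#' `pair_set` (or any two-column index structure).
#'
#' @param matrix A `bincom` matrix.
#' @param pairs A `pair_set` from [screen_pairs()], or a data frame /
#'   matrix whose first two columns are OTU column indices.
#' @inheritParams standardize_scores
#' @return Data frame with columns `i`, `j`, `otu_i`, `otu_j`, `R_i`,
#'   `R_j`, `S`, `N`, `C`, `T`, `C_std`, `T_std`.
#' @export
pair_scores <- function(matrix, pairs, normalize = c("range", "product")) {
  normalize <- match.arg(normalize)
  idx <- pair_index_matrix(pairs)
  st <- cpp_pair_stats(unclass_matrix(matrix), idx - 1L)
  pc <- as_pair_counts(st$R_i, st$R_j, st$S, st$N)
  std <- standardize_scores(pc, normalize)
  data.frame(
    i = idx[, 1], j = idx[, 2],
    otu_i = colnames(matrix)[idx[, 1]], otu_j = colnames(matrix)[idx[, 2]],
    R_i = st$R_i, R_j = st$R_j, S = st$S, N = st$N,
    C = c_score(pc), T = t_score(pc),
    C_std = std$C_std, T_std = std$T_std,
    row.names = NULL)
}

pair_index_matrix <- function(pairs) {
  if (is.data.frame(pairs)) pairs <- as.matrix(pairs[, c("i", "j")])
  pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
  storage.mode(pairs) <- "integer"
  if (nrow(pairs) > 0 && any(pairs[, 1] == pairs[, 2]))
    stop("pairs must consist of distinct OTUs")
  pairs
}

unclass_matrix <- function(m) {
  m <- unclass(as.matrix(m))
  storage.mode(m) <- "integer"
  m
}

# Fast standardized-score path used inside permutation loops: same
# arithmetic as standardize_scores() but on bare vectors.
std_scores_fast <- function(x, idx0, product = FALSE) {
  st <- cpp_pair_stats(x, idx0)
  Ri <- st$R_i; Rj <- st$R_j; S <- st$S; N <- st$N
  if (product) {
    cmax <- tmax <- Ri * Rj
  } else {
    smin <- pmax(0L, Ri + Rj - N)
    smax <- pmin(Ri, Rj)
    cmax <- (Ri - smin) * (Rj - smin)
    tmax <- smax * (N + smax - Ri - Rj)
  }
  list(C = ifelse(cmax > 0, (Ri - S) * (Rj - S) / cmax, 0),
       T = ifelse(tmax > 0, S * (N + S - Ri - Rj) / tmax, 0))
}

all_pairs <- function(idx) {
  if (length(idx) < 2) stop("need at least 2 OTUs to form pairs")
  t(combn(as.integer(idx), 2L))
}
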