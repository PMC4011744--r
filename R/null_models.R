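#' Curveball randomization of a binary matrix
#'
#' Runs `steps` curveball trades on the matrix: each trade picks two rows
#' at random and uniformly reshuffles the columns held by exactly one of
#' them, preserving all row and column sums. With `steps = 0` the input is
#' returned unchanged.
#'
#' @param matrix Binary matrix (`bincom` or plain 0/1 matrix).
#' @param steps Number of trade attempts (default `5 * fill`, fill = number
#'   of ones).
#' @param seed Integer seed for the sampler's own RNG stream.
#' @return A matrix of the same class and dimnames with identical margins.
#' @export
curveball_randomize <- function(matrix, steps = NULL, seed = 1) {
  m <- unclass_matrix(matrix)
  if (is.null(steps)) steps <- 5L * sum(m)
  stopifnot(steps >= 0)
  out <- cpp_curveball(m, as.integer(steps), as.double(seed))
  dimnames(out) <- dimnames(matrix)
  if (inherits(matrix, "bincom")) out <- as_bincom(out)
  out
}

#' Equiprobable randomization of a binary matrix
#'
#' Places the observed number of ones uniformly at random among all cells
#' (total fill preserved; margins free).
#'
#' @inheritParams curveball_randomize
#' @export
equiprobable_randomize <- function(matrix, seed = 1) {
  m <- unclass_matrix(matrix)
  fill <- sum(m)
  out <- with_seed(seed, {
    v <- integer(length(m))
    v[sample.int(length(m), fill)] <- 1L
    base::matrix(v, nrow(m), ncol(m))
  })
  dimnames(out) <- dimnames(matrix)
  if (inherits(matrix, "bincom")) out <- as_bincom(out)
  out
}

#' Row-shuffle randomization (fixed row sums, equiprobable columns)
#'
#' @inheritParams curveball_randomize
#' @keywords internal
fixed_rows_randomize <- function(matrix, seed = 1) {
  m <- unclass_matrix(matrix)
  out <- with_seed(seed, t(apply(m, 1, sample)))
  dimnames(out) <- dimnames(matrix)
  if (inherits(matrix, "bincom")) out <- as_bincom(out)
  out
}

default_burn_in <- function(m) 5L * sum(m)
default_thin <- function(m) max(1L, sum(m))

#' Build a null-model ensemble
#'
#' Describes (and optionally materializes) `M` randomizations of a binary
#' matrix. The default model, `fixed_fixed_curveball`, preserves every row
#' and column sum via one long curveball chain with `burn_in` initial
#' trades and `thin` trades between saved states; defaults scale with the
#' matrix fill (burn-in `5 * fill`, thin `fill`), which keeps the lag-1
#' autocorrelation of community mean scores near zero. Alternative models
#' (`fixed_fill_equiprobable`, `fixed_rows`) are available for sensitivity
#' analysis and are always materialized.
#'
#' Given identical arguments the ensemble is bit-reproducible. For the
#' curveball model, `materialize = FALSE` (the default) stores only the
#' chain parameters; downstream tests stream statistics from an identical
#' chain, so results do not depend on materialization.
#'
#' @param matrix A `bincom` (or plain binary) matrix.
#' @param model One of `"fixed_fixed_curveball"`,
#'   `"fixed_fill_equiprobable"`, `"fixed_rows"`.
#' @param M Number of randomized matrices (default 10000).
#' @param seed Integer seed.
#' @param burn_in,thin Curveball chain controls; `NULL` = fill-scaled
#'   defaults.
#' @param materialize Store the matrices themselves (default `FALSE` for
#'   the curveball model).
#' @return An object of class `null_ensemble`.
#' @export
build_ensemble <- function(matrix,
                           model = c("fixed_fixed_curveball",
                                     "fixed_fill_equiprobable",
                                     "fixed_rows"),
                           M = 10000, seed = 1, burn_in = NULL, thin = NULL,
                           materialize = FALSE) {
  model <- match.arg(model)
  stopifnot(M >= 1)
  m <- unclass_matrix(matrix)
  if (is.null(burn_in)) burn_in <- default_burn_in(m)
  if (is.null(thin)) thin <- default_thin(m)
  matrices <- NULL
  if (model == "fixed_fixed_curveball") {
    if (materialize)
      matrices <- cpp_cb_ensemble(m, as.integer(M), as.integer(burn_in),
                                  as.integer(thin), as.double(seed))
  } else {
    fn <- if (model == "fixed_fill_equiprobable") equiprobable_randomize
          else fixed_rows_randomize
    matrices <- lapply(seq_len(M),
                       function(k) unclass_matrix(fn(m, child_seed(seed, k))))
  }
  structure(list(model = model, M = as.integer(M), seed = seed,
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 nrow = nrow(m), ncol = ncol(m),
                 rowsums = rowSums(m), colsums = colSums(m),
                 matrices = matrices),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("Null ensemble: %s, M = %d, seed = %s, burn_in = %d, thin = %d%s\n",
              x$model, x$M, format(x$seed), x$burn_in, x$thin,
              if (is.null(x$matrices)) " (streaming)" else " (materialized)"))
  invisible(x)
}

check_ensemble_matrix <- function(ensemble, matrix) {
  m <- unclass_matrix(matrix)
  if (nrow(m) != ensemble$nrow || ncol(m) != ensemble$ncol ||
      !identical(rowSums(m), ensemble$rowsums) ||
      !identical(colSums(m), ensemble$colsums))
    stop("ensemble was not built from a matrix with these margins")
  invisible(TRUE)
}

#' Exhaustively enumerate the fixed-margin matrix space
#'
#' Lists every distinct binary matrix with the given row and column sums
#' (the uniform support of the fixed-fixed null), for use as an exact
#' verification oracle on small instances.
#'
#' @param matrix Binary matrix whose margins define the space, or `NULL`
#'   if `rowsums`/`colsums` are given directly.
#' @param rowsums,colsums Integer margin vectors (used when `matrix` is
#'   `NULL`).
#' @param cap Abort with an error if the support exceeds this many
#'   matrices (default 1e6).
#' @return An object of class `exact_null`: list with `rowsums`,
#'   `colsums`, and `matrices` (list of 0/1 matrices).
#' @export
enumerate_margin_space <- function(matrix = NULL, rowsums = NULL,
                                   colsums = NULL, cap = 1e6) {
  if (!is.null(matrix)) {
    m <- unclass_matrix(matrix)
    rowsums <- rowSums(m); colsums <- colSums(m)
  }
  stopifnot(!is.null(rowsums), !is.null(colsums),
            sum(rowsums) == sum(colsums))
  n <- length(rowsums); m <- length(colsums)
  out <- vector("list", 0)
  count <- 0L
  acc <- base::matrix(0L, n, m)
  # fill row by row; prune on remaining column capacity
  recurse <- function(r, colcap) {
    if (r > n) {
      if (all(colcap == 0)) {
        count <<- count + 1L
        if (count > cap)
          stop("margin space larger than cap; use Monte-Carlo mode")
        out[[count]] <<- acc + 0L
      }
      return(invisible())
    }
    k <- rowsums[r]
    avail <- which(colcap > 0)
    if (length(avail) < k) return(invisible())
    # feasibility prune: remaining rows must be able to absorb capacity
    rem <- if (r < n) sum(rowsums[(r + 1):n]) else 0L
    choices <- if (k == 0) list(integer(0)) else
      combn(avail, k, simplify = FALSE)
    for (ch in choices) {
      newcap <- colcap
      newcap[ch] <- newcap[ch] - 1L
      if (sum(newcap) != rem) next
      if (max(newcap) > (n - r)) next
      acc[r, ] <<- 0L
      acc[r, ch] <<- 1L
      recurse(r + 1L, newcap)
    }
    acc[r, ] <<- 0L
    invisible()
  }
  recurse(1L, as.integer(colsums))
  structure(list(rowsums = as.integer(rowsums),
                 colsums = as.integer(colsums),
                 matrices = out[seq_len(count)]),
            class = "exact_null")
}

#' @export
print.exact_null <- function(x, ...) {
  cat(sprintf("Exact fixed-margin null: %d x %d, %d matrices in support\n",
              length(x$rowsums), length(x$colsums), length(x$matrices)))
  invisible(x)
}

#' Exact per-pair P values from an enumerated null
#'
#' For each pair, computes the uniform-measure probability that the null
#' C (or T) score is at least the observed score.
#'
#' @param exact An `exact_null` from [enumerate_margin_space()].
#' @param matrix Observed binary matrix (defines the observed scores).
#' @param pairs Two-column pair index structure.
#' @return Data frame with `i`, `j`, `P_C`, `P_T` (exact upper-tail
#'   probabilities).
#' @export
exact_pair_p <- function(exact, matrix, pairs) {
  idx <- pair_index_matrix(pairs)
  obs <- pair_scores(matrix, idx)
  ps <- lapply(exact$matrices, function(nm) {
    st <- cpp_pair_stats(nm, idx - 1L)
    pc <- as_pair_counts(st$R_i, st$R_j, st$S, st$N)
    list(C = c_score(pc), T = t_score(pc))
  })
  Cmat <- do.call(rbind, lapply(ps, `[[`, "C"))
  Tmat <- do.call(rbind, lapply(ps, `[[`, "T"))
  data.frame(
    i = idx[, 1], j = idx[, 2],
    P_C = colMeans(Cmat >= rep(obs$C, each = nrow(Cmat))),
    P_T = colMeans(Tmat >= rep(obs$T, each = nrow(Tmat))),
    row.names = NULL)
}
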