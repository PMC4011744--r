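# Shared fixture builders for the test suite.

# Random binary community matrix with approximate fill p.
rand_bincom <- function(n, m, p = 0.3, seed = 1) {
  withr::with_seed(seed,
    as_bincom(matrix(rbinom(n * m, 1, p), n, m)))
}

# Write a small counts data frame (first column = sample ids) to a temp CSV.
write_counts_csv <- function(df, sep = ",") {
  path <- tempfile(fileext = if (sep == ",") ".csv" else ".tsv")
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  path
}

# All margin-feasible (R_i, R_j, S) triples for sample sizes 0 < N <= nmax.
feasible_grid <- function(nmax) {
  out <- list()
  for (N in 1:nmax) for (Ri in 0:N) for (Rj in 0:N) {
    smin <- max(0, Ri + Rj - N)
    smax <- min(Ri, Rj)
    for (S in smin:smax)
      out[[length(out) + 1]] <- c(N = N, R_i = Ri, R_j = Rj, S = S)
  }
  as.data.frame(do.call(rbind, out))
}

# Independent brute-force margin-space counter: enumerate every row
# pattern combination and filter on column sums (only viable for tiny
# matrices; used as an oracle against enumerate_margin_space()).
brute_force_count <- function(rowsums, colsums) {
  m <- length(colsums)
  row_patterns <- lapply(rowsums, function(k) {
    if (k == 0) return(list(rep(0L, m)))
    lapply(utils::combn(m, k, simplify = FALSE), function(ix) {
      v <- rep(0L, m); v[ix] <- 1L; v
    })
  })
  grid <- expand.grid(lapply(row_patterns, seq_along))
  cnt <- 0L
  for (g in seq_len(nrow(grid))) {
    mat <- do.call(rbind, Map(function(pats, k) pats[[k]],
                              row_patterns, unlist(grid[g, ])))
    if (all(colSums(mat) == colsums)) cnt <- cnt + 1L
  }
  cnt
}

# Matrix key for frequency tables over enumerated supports.
mat_key <- function(m) paste(as.integer(m), collapse = "")

# Path of the bundled table of printed occurrence counts of the 34
# commonly observed OTUs (two oak hosts).
common_otu_path <- function()
  system.file("extdata", "common_otu_occurrences.csv", package = "ctscore")
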