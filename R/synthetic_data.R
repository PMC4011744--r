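#' Joint Bernoulli law with given marginals and odds ratio
#'
#' The unique bivariate Bernoulli distribution with marginal presence
#' probabilities `p_i`, `p_j` and presence odds ratio
#' \eqn{\psi = p_{11} p_{00} / (p_{10} p_{01})}. `p11` is the root of the
#' standard quadratic \eqn{(\psi - 1) p_{11}^2 - [1 + (p_i + p_j)(\psi -
#' 1)] p_{11} + \psi p_i p_j = 0} inside the Frechet bounds. All arguments
#' vectorize.
#'
#' @param p_i,p_j Marginal probabilities in (0, 1).
#' @param psi Odds ratio (> 0); 1 = independence.
#' @return Data frame with columns `p11`, `p10`, `p01`, `p00` (rows sum to
#'   1).
#' @export
joint_bernoulli <- function(p_i, p_j, psi) {
  stopifnot(all(p_i > 0 & p_i < 1), all(p_j > 0 & p_j < 1), all(psi > 0))
  n <- max(length(p_i), length(p_j), length(psi))
  p_i <- rep_len(p_i, n); p_j <- rep_len(p_j, n); psi <- rep_len(psi, n)
  a <- psi - 1
  b <- 1 + (p_i + p_j) * a
  p11 <- ifelse(abs(a) < 1e-12,
                p_i * p_j,
                (b - sqrt(b^2 - 4 * a * psi * p_i * p_j)) / (2 * a))
  # guard rounding at the Frechet bounds
  lo <- pmax(0, p_i + p_j - 1)
  hi <- pmin(p_i, p_j)
  p11 <- pmin(pmax(p11, lo), hi)
  data.frame(p11 = p11, p10 = p_i - p11, p01 = p_j - p11,
             p00 = 1 - p_i - p_j + p11)
}

#' Simulation configuration
#'
#' Bundles and validates the parameters of [simulate_community()]. The
#' defaults emulate a forest-seedling root survey: two host groups,
#' long-tailed per-OTU occupancy drawn from a beta law, planted pairwise
#' odds-ratio couplings, optional host effects and a distance-decaying
#' spatial field on the log-odds scale, and overdispersed read counts for
#' present OTUs.
#'
#' @param n_samples Named or unnamed length-2 integer vector: samples per
#'   host.
#' @param n_otus Number of OTUs (>= 2).
#' @param occupancy Either a length-2 vector `c(shape1, shape2)` of beta
#'   parameters for per-OTU occurrence probability, or a numeric vector of
#'   length `n_otus` of probabilities.
#' @param couplings Data frame with columns `i`, `j`, `psi` (pairwise
#'   presence odds ratios; pairs must be disjoint) and optionally `host`
#'   (`NA`/absent = both hosts, otherwise the host index 1 or 2 in which
#'   the coupling acts; the other host gets psi = 1).
#' @param host_effects `n_otus` x 2 matrix of per-OTU log-odds shifts by
#'   host (default none).
#' @param spatial List with `range` (correlation range, meters; 0
#'   disables) and `sd` (field SD on log-odds scale).
#' @param reads List with `depth` (mean extra reads per present OTU) and
#'   `size` (negative-binomial size; smaller = more overdispersed).
#' @param area Rectangle `c(width, height)` in meters for sample
#'   placement (minimum inter-sample spacing 1 m).
#' @param seed Integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_samples = c(249, 188), n_otus = 30,
                       occupancy = c(0.6, 8), couplings = NULL,
                       host_effects = NULL,
                       spatial = list(range = 0, sd = 0),
                       reads = list(depth = 120, size = 0.8),
                       area = c(300, 200), seed = 1) {
  stopifnot(length(n_samples) == 2, all(n_samples >= 1), n_otus >= 2)
  if (is.null(couplings))
    couplings <- data.frame(i = integer(), j = integer(), psi = numeric())
  couplings <- as.data.frame(couplings)
  if (nrow(couplings) > 0) {
    stopifnot(all(c("i", "j", "psi") %in% names(couplings)),
              all(couplings$psi > 0))
    members <- c(couplings$i, couplings$j)
    if (any(members < 1 | members > n_otus))
      stop("coupling indices out of range")
    if (anyDuplicated(members))
      stop("coupled pairs must be disjoint (no OTU in two couplings)")
  }
  if (!"host" %in% names(couplings))
    couplings$host <- rep(NA_integer_, nrow(couplings))
  if (is.null(host_effects))
    host_effects <- base::matrix(0, n_otus, 2)
  stopifnot(nrow(host_effects) == n_otus, ncol(host_effects) == 2)
  if (length(occupancy) == n_otus && n_otus != 2) {
    stopifnot(all(occupancy > 0 & occupancy < 1))
  } else {
    stopifnot(length(occupancy) == 2, all(occupancy > 0))
  }
  structure(list(n_samples = n_samples, n_otus = n_otus,
                 occupancy = occupancy, couplings = couplings,
                 host_effects = host_effects, spatial = spatial,
                 reads = reads, area = area, seed = seed),
            class = "sim_config")
}

# Jittered-grid placement guaranteeing >= 1 m spacing.
place_samples <- function(n, area) {
  cell <- 2
  nx <- floor(area[1] / cell)
  ny <- floor(area[2] / cell)
  if (nx * ny < n) stop("area too small for the requested samples")
  cells <- sample.int(nx * ny, n)
  cx <- (cells - 1) %% nx
  cy <- (cells - 1) %/% nx
  data.frame(x = cx * cell + cell / 2 + runif(n, -0.5, 0.5),
             y = cy * cell + cell / 2 + runif(n, -0.5, 0.5))
}

#' Simulate a read-count community with planted couplings
#'
#' Generates per-sample coordinates, host labels, presence/absence with
#' the configured marginal occupancies, host effects, spatial field, and
#' pairwise odds-ratio couplings, then overdispersed read counts for the
#' present OTUs. Fully reproducible from the config seed.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_community` with elements `table` (a
#'   `read_count_table`), `metadata` (sample_id, host, x, y,
#'   exclude_flag), and `truth` (marginal probabilities by host, coupling
#'   table, spatial field if any).
#' @export
simulate_community <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_community_(config))
}

simulate_community_ <- function(cfg) {
  n1 <- cfg$n_samples[1]; n2 <- cfg$n_samples[2]
  n <- n1 + n2
  m <- cfg$n_otus
  host <- rep(c("host_A", "host_B"), c(n1, n2))
  coords <- place_samples(n, cfg$area)

  p_base <- if (length(cfg$occupancy) == m && m != 2) cfg$occupancy
            else rbeta(m, cfg$occupancy[1], cfg$occupancy[2])
  p_base <- pmin(pmax(p_base, 1e-4), 1 - 1e-4)

  # per-sample x per-OTU log-odds
  eta <- base::matrix(qlogis(p_base), n, m, byrow = TRUE)
  hidx <- ifelse(host == "host_A", 1L, 2L)
  eta <- eta + cfg$host_effects[cbind(rep(seq_len(m), each = n),
                                      rep(hidx, times = m))]
  field <- NULL
  if (cfg$spatial$sd > 0 && cfg$spatial$range > 0) {
    D <- as.matrix(dist(coords))
    L <- chol(exp(-D / cfg$spatial$range) + diag(1e-8, n))
    field <- cfg$spatial$sd * crossprod(L, base::matrix(rnorm(n * m), n, m))
    eta <- eta + field
  }
  prob <- plogis(eta)

  pres <- base::matrix(0L, n, m)
  coupled <- c(cfg$couplings$i, cfg$couplings$j)
  free <- setdiff(seq_len(m), coupled)
  if (length(free) > 0)
    pres[, free] <- (base::matrix(runif(n * length(free)), n) <
                       prob[, free, drop = FALSE]) * 1L
  if (nrow(cfg$couplings) > 0) {
    for (k in seq_len(nrow(cfg$couplings))) {
      i <- cfg$couplings$i[k]; j <- cfg$couplings$j[k]
      psi <- rep(cfg$couplings$psi[k], n)
      if (!is.na(cfg$couplings$host[k]))
        psi[hidx != cfg$couplings$host[k]] <- 1
      jb <- joint_bernoulli(prob[, i], prob[, j], psi)
      u <- runif(n)
      cell <- 1L + (u >= jb$p11) + (u >= jb$p11 + jb$p10) +
        (u >= jb$p11 + jb$p10 + jb$p01)
      pres[, i] <- as.integer(cell %in% c(1L, 2L))
      pres[, j] <- as.integer(cell %in% c(1L, 3L))
    }
  }

  counts <- base::matrix(0L, n, m)
  npres <- sum(pres)
  if (npres > 0)
    counts[pres == 1] <- 1L + rnbinom(npres, mu = cfg$reads$depth,
                                      size = cfg$reads$size)
  dimnames(counts) <- list(sprintf("s%03d", seq_len(n)),
                           sprintf("otu%03d", seq_len(m)))
  metadata <- data.frame(sample_id = rownames(counts), host = host,
                         x = coords$x, y = coords$y, exclude_flag = FALSE)
  p_host <- cbind(host_A = plogis(qlogis(p_base) + cfg$host_effects[, 1]),
                  host_B = plogis(qlogis(p_base) + cfg$host_effects[, 2]))
  truth <- list(p_host = p_host, couplings = cfg$couplings,
                p_base = p_base, field = field)
  structure(list(table = as_read_count_table(counts), metadata = metadata,
                 truth = truth),
            class = "sim_community")
}

#' Study-shaped synthetic dataset
#'
#' Convenience preset producing a community with the shape of the oak
#' seedling survey: 249 + 188 samples, 319 OTUs, a long-tailed occupancy
#' law under which roughly 34 OTUs occur in 10 or more samples, and mean
#' per-sample richness near 3.5. Intended for end-to-end pipeline
#' exercises.
#'
#' @param seed Integer seed.
#' @param couplings Optional coupling table passed through to
#'   [sim_config()].
#' @return A `sim_community` (see [simulate_community()]).
#' @export
emulate_study_shape <- function(seed = 1, couplings = NULL) {
  cfg <- sim_config(n_samples = c(249, 188), n_otus = 319,
                    occupancy = c(3.2, 250), couplings = couplings,
                    spatial = list(range = 6, sd = 0.6),
                    reads = list(depth = 35, size = 0.8),
                    seed = seed)
  simulate_community(cfg)
}
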