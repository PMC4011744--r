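test_that("Mao Tau curve hits its analytic endpoints and is monotone", {
  b <- rand_bincom(15, 12, 0.3, 41)
  ac <- mao_tau(b)
  expect_equal(ac$k, 1:15)
  expect_equal(ac$richness[15], sum(occurrence(b) > 0))
  expect_equal(ac$richness[1], mean(richness(b)))
  expect_true(all(diff(ac$richness) >= -1e-9))
})

test_that("Mao Tau matches a random-subset resampling oracle", {
  b <- rand_bincom(12, 10, 0.35, 43)
  ac <- mao_tau(b)
  m <- unclass(b)
  withr::with_seed(44, {
    for (k in c(3, 6, 9)) {
      sims <- replicate(4000, {
        rows <- sample(12, k)
        sum(colSums(m[rows, , drop = FALSE]) > 0)
      })
      se <- sd(sims) / sqrt(length(sims))
      expect_lt(abs(mean(sims) - ac$richness[k]), 4 * se + 1e-9)
    }
  })
})

test_that("Raup-Crick dissimilarities are proper probabilities", {
  b <- rand_bincom(10, 20, 0.3, 45)
  d <- raup_crick(b, reps = 199, seed = 1)
  m <- as.matrix(d)
  expect_true(all(m >= 0 & m <= 1))
  expect_true(isSymmetric(m))
  expect_true(all(diag(m) == 0))
  expect_identical(as.matrix(raup_crick(b, reps = 199, seed = 1)), m)
})

test_that("Raup-Crick separates shared-rare from disjoint-common communities", {
  # pool of 24 OTUs; first two samples share exactly the two rarest
  pool <- matrix(0L, 14, 24)
  withr::with_seed(46, {
    for (i in 3:14) pool[i, sample(5:24, 8)] <- 1L  # commons
  })
  pool[cbind(rep(3:8, 2), rep(1:2, each = 6))] <- 0L
  pool[1, 1:2] <- 1L
  pool[2, 1:2] <- 1L
  b <- as_bincom(pool)
  d <- as.matrix(raup_crick(b, reps = 499, seed = 2))
  expect_lt(d[1, 2], 0.2)    # sharing the rarest two OTUs beats the null

  # disjoint samples drawing equally common OTUs
  m2 <- matrix(0L, 10, 12)
  m2[1, 1:4] <- 1L
  m2[2, 5:8] <- 1L
  withr::with_seed(47, for (i in 3:10) m2[i, sample(12, 4)] <- 1L)
  d2 <- as.matrix(raup_crick(as_bincom(m2), reps = 499, seed = 3))
  expect_gt(d2[1, 2], 0.8)
})

test_that("Raup-Crick flags zero-richness samples at chance level", {
  m <- rbind(c(0L, 0L, 0L), c(1L, 1L, 0L), c(1L, 0L, 1L))
  expect_warning(d <- raup_crick(as_bincom(m), reps = 99, seed = 1),
                 "zero richness")
  dm <- as.matrix(d)
  expect_equal(unname(dm[1, 2]), 0.5)
  expect_equal(unname(dm[1, 3]), 0.5)
})

test_that("Mantel correlogram finds planted spatial structure and seeds reproducibly", {
  withr::with_seed(48, {
    n <- 40
    cluster <- rep(1:4, each = 10)
    coords <- cbind(x = cluster * 20 + runif(n), y = runif(n))
    # community composition tied to spatial cluster
    sig <- matrix(0L, n, 20)
    for (g in 1:4) sig[cluster == g, ((g - 1) * 5 + 1):(g * 5)] <- 1L
    noise <- matrix(rbinom(n * 20, 1, 0.1), n, 20)
  })
  b <- as_bincom(pmin(sig + noise, 1))
  d <- dist(unclass(b), method = "binary")
  cg <- mantel_correlogram(d, coords, class_width = 10, permutations = 199,
                           seed = 5)
  expect_gt(cg$r[1], 0)          # nearby samples more similar
  expect_lt(cg$P_corrected[1], 0.05)
  cg2 <- mantel_correlogram(d, coords, class_width = 10, permutations = 199,
                            seed = 5)
  expect_identical(cg, cg2)
})

test_that("Moran's I has exact expectation and detects clustered values", {
  withr::with_seed(49, {
    coords <- rbind(cbind(runif(15), runif(15)),
                    cbind(runif(15) + 50, runif(15)))
    vals <- c(rnorm(15, 0), rnorm(15, 5))
  })
  r <- morans_i(vals, coords)
  expect_equal(r$expectation, -1 / 29)
  expect_gt(r$I, 0)
  expect_lt(r$P, 0.01)

  expect_error(morans_i(rep(1, 10), cbind(runif(10), runif(10))),
               "zero variance")
  cc <- rbind(c(0, 0), c(0, 0), c(1, 1))
  expect_error(morans_i(c(1, 2, 3), cc), "coincident")
})

test_that("Moran's I permutation null rejects at roughly the nominal rate", {
  withr::with_seed(50, {
    coords <- cbind(runif(25), runif(25))
    base_vals <- rnorm(25)
    rej <- mean(replicate(400, {
      morans_i(sample(base_vals), coords)$P < 0.05
    }))
  })
  expect_gt(rej, 0.01)
  expect_lt(rej, 0.10)
})

test_that("PERMANOVA separates planted clusters and is seed-stable", {
  withr::with_seed(51, {
    x <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 6), 20))
  })
  d <- dist(x)
  groups <- rep(c("a", "b"), each = 20)
  pa <- permanova(d, groups, permutations = 199, seed = 6)
  expect_equal(pa$P, 1 / 200)          # permutation floor attained
  expect_true(pa$R2 > 0 && pa$R2 < 1)
  pa2 <- permanova(d, groups, permutations = 199, seed = 6)
  expect_identical(pa[c("F", "R2", "P")], pa2[c("F", "R2", "P")])
  expect_error(permanova(d, rep("a", 40)), "2 groups")
})

test_that("PERMANOVA P is near-uniform under an exchangeable null", {
  withr::with_seed(52, {
    ps <- replicate(60, {
      x <- matrix(rnorm(32 * 3), 32)
      permanova(dist(x), rep(c("a", "b"), each = 16), permutations = 99,
                seed = sample.int(1e6, 1))$P
    })
  })
  expect_gt(mean(ps < 0.05), 0)        # not degenerate at 1
  expect_lt(mean(ps < 0.05), 0.15)
  expect_gt(mean(ps), 0.35)            # mean of uniform ~ 0.5
})

test_that("PERMDISP reports group dispersions and detects inflation", {
  withr::with_seed(53, {
    tight <- matrix(rnorm(50 * 2, sd = 1), 50)
    wide <- matrix(rnorm(50 * 2, sd = 3), 50)
  })
  d <- dist(rbind(tight, wide))
  groups <- rep(c("tight", "wide"), each = 50)
  pd <- permdisp(d, groups, permutations = 499, seed = 7)
  expect_lt(pd$P, 0.01)
  expect_gt(pd$group_means["wide"], pd$group_means["tight"])
  # reported group means equal means of the per-sample distances
  expect_equal(unname(pd$group_means),
               unname(tapply(pd$distances, groups, mean)))

  # identical point sets in both groups: no dispersion difference
  same <- matrix(rnorm(30 * 2), 30)
  d2 <- dist(rbind(same, same))
  pd2 <- permdisp(d2, rep(c("a", "b"), each = 30), permutations = 199,
                  seed = 8)
  expect_lt(abs(pd2$F), 1e-8)
  expect_gt(pd2$P, 0.5)
})

test_that("CLAM classifies specialists, generalists, and rare OTUs", {
  tab <- utils::read.csv(common_otu_path())
  res <- clam_test(tab$n_serrata, tab$n_glauca, tab$otu_id)
  expect_equal(res$class[res$otu_id == "1089"], "specialist_host1")
  expect_true(all(res$class[res$n_host1 < 10 & res$n_host2 < 10] ==
                    "too_rare"))
  res2 <- clam_test(c(100, 1, 0), c(100, 0, 25), c("bal", "rare", "spec2"))
  expect_equal(res2$class, c("generalist", "too_rare", "specialist_host2"))
})

test_that("Welch richness test matches hand computation", {
  ident <- as_bincom(rbind(lower.tri(diag(3), diag = TRUE) * 1L,
                           lower.tri(diag(3), diag = TRUE) * 1L))
  expect_equal(richness_welch_t(ident, rep(c("a", "b"), each = 3))$t, 0)
  expect_error(richness_welch_t(as_bincom(rbind(diag(3), diag(3))),
                                rep(c("a", "b"), each = 3)),
               "zero richness variance")

  b <- as_bincom(rbind(
    matrix(rep(c(1, 0, 0, 0, 0, 0), 1), 1), matrix(rep(1:0, c(2, 4)), 1),
    matrix(rep(1:0, c(3, 3)), 1), matrix(rep(1:0, c(4, 2)), 1),
    matrix(rep(1:0, c(5, 1)), 1), matrix(rep(1, 6), 1)))
  res <- richness_welch_t(b, rep(c("g1", "g2"), each = 3))
  expect_equal(res$t, -3.674235, tolerance = 1e-6)   # groups 1,2,3 vs 4,5,6
  expect_equal(res$df, 4)
})
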