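test_that("BH adjustment matches closed forms and its guarantees", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.04, 0.50)), c(0.08, 0.50))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(-0.1, 0.5)), "\\[0, 1\\]")

  withr::with_seed(3, {
    p <- runif(40)^2
    q <- bh_adjust(p)
    expect_true(all(q >= p) && all(q <= 1))
    # BH rejections are a superset of Bonferroni rejections
    for (alpha in c(0.01, 0.05, 0.1)) {
      bonf <- which(pmin(p * length(p), 1) <= alpha)
      expect_true(all(bonf %in% which(q <= alpha)))
    }
  })
})

test_that("randomization P values respect the (1+b)/(1+M) form", {
  # unique margin-feasible matrix: every null equals the observation
  b <- as_bincom(rbind(c(1L, 1L), c(1L, 0L)))
  ens <- build_ensemble(b, M = 99, seed = 1)
  res <- pair_randomization_test(b, cbind(1, 2), ens)
  expect_true(all(res$P == 1))
  expect_true(all(res$q == 1))

  b2 <- rand_bincom(12, 6, 0.4, 6)
  ens2 <- build_ensemble(b2, M = 200, seed = 2)
  res2 <- pair_randomization_test(b2, screen_pairs(b2, 1, 0), ens2)
  expect_true(all(res2$P >= 1 / 201 & res2$P <= 1))
  expect_true(all(res2$q >= res2$P))
  expect_equal(res2$M_used, rep(200L, nrow(res2)))
  # sorted by P within each score family
  for (fam in split(res2, res2$score_type))
    expect_true(!is.unsorted(fam$P))
})

test_that("Monte-Carlo pair P values approach exact enumeration", {
  b <- as_bincom(rbind(c(1L, 1L, 0L, 0L),
                       c(1L, 0L, 1L, 0L),
                       c(0L, 1L, 1L, 1L)))
  ex <- enumerate_margin_space(b)
  pairs <- t(combn(4, 2))
  exact <- exact_pair_p(ex, b, pairs)
  ens <- build_ensemble(b, M = 4000, seed = 11, thin = 5 * sum(unclass(b)))
  mc <- pair_randomization_test(b, pairs, ens)
  mc_C <- mc[mc$score_type == "C_std", ]
  mc_T <- mc[mc$score_type == "T_std", ]
  ord_C <- match(paste(exact$i, exact$j), paste(mc_C$i, mc_C$j))
  ord_T <- match(paste(exact$i, exact$j), paste(mc_T$i, mc_T$j))
  expect_true(all(abs(mc_C$P[ord_C] - exact$P_C) < 0.03))
  expect_true(all(abs(mc_T$P[ord_T] - exact$P_T) < 0.03))
})

test_that("community score test reports mean scores, SES and errors", {
  b <- rand_bincom(20, 8, 0.35, 9)
  ens <- build_ensemble(b, M = 500, seed = 3)
  for (sc in c("C", "T")) {
    res <- community_score_test(b, NULL, ens, score = sc)
    expect_true(res$mean_score >= 0 && res$mean_score <= 1)
    expect_true(res$P >= 1 / 501 && res$P <= 1)
    expect_equal(res$n_pairs, choose(res$n_otus, 2))
    expect_equal(res$SES, (res$mean_score - res$null_mean) / res$null_sd)
  }
  expect_error(community_score_test(b, 1L, ens), "at least 2")
})

test_that("community SES is 0 when the observation equals the null mean", {
  # unique-support margins: the null distribution is the observation itself
  b <- as_bincom(rbind(c(1L, 1L), c(1L, 0L)))
  ens <- build_ensemble(b, M = 50, seed = 1)
  res <- community_score_test(b, NULL, ens, score = "C")
  expect_equal(res$mean_score, res$null_mean)
  expect_true(is.na(res$SES) || res$SES == 0)   # null SD is 0 here
  expect_equal(res$P, 1)
})

test_that("host contrast is null for identical host datasets", {
  half <- rand_bincom(30, 6, 0.5, 12)
  b <- as_bincom(rbind(unclass(half), unclass(half)))
  hosts <- rep(c("A", "B"), each = 30)
  res <- host_difference_test(b, hosts, min_occurrence = 2,
                              min_pair_sum = 5, M = 200, seed = 4)
  expect_true(all(res$delta_C == 0))
  expect_true(all(res$delta_T == 0))
  expect_true(all(res$P_delta_C == 1))   # |null delta| >= 0 always
  expect_true(all(res$P_delta_T == 1))
})

test_that("host contrast is reproducible and screens per host", {
  withr::with_seed(21, {
    x <- matrix(rbinom(60 * 8, 1, 0.4), 60, 8)
    x[31:60, 8] <- 0L   # OTU 8 absent in host B: fails screening there
  })
  b <- as_bincom(x)
  hosts <- rep(c("A", "B"), each = 30)
  expect_message(
    r1 <- host_difference_test(b, hosts, min_occurrence = 3,
                               min_pair_sum = 8, M = 100, seed = 5),
    "excluded")
  r2 <- suppressMessages(
    host_difference_test(b, hosts, min_occurrence = 3,
                         min_pair_sum = 8, M = 100, seed = 5))
  expect_identical(r1, r2)
  expect_false(any(r1$i == 8 | r1$j == 8))
  expect_true(all(r1$P_delta_C > 0 & r1$P_delta_C <= 1))
  expect_true(all(abs(r1$delta_C) <= 1 & abs(r1$delta_T) <= 1))
})

test_that("ensemble/matrix margin mismatch is rejected", {
  b <- rand_bincom(10, 5, 0.4, 1)
  other <- rand_bincom(10, 5, 0.6, 2)
  ens <- build_ensemble(other, M = 10, seed = 1)
  expect_error(pair_randomization_test(b, cbind(1, 2), ens), "margins")
})
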