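test_that("read_count_table round-trips and normalizes orientation", {
  df <- data.frame(sample_id = c("s1", "s2"), otuA = c(3L, 0L),
                   otuB = c(0L, 7L))
  path <- write_counts_csv(df)
  tab <- read_count_table(path)
  expect_identical(unclass(tab)[, "otuA"], c(s1 = 3L, s2 = 0L))
  expect_identical(unclass(tab)[, "otuB"], c(s1 = 0L, s2 = 7L))

  tdf <- data.frame(otu_id = c("otuA", "otuB"), s1 = c(3L, 0L),
                    s2 = c(0L, 7L))
  ttab <- read_count_table(write_counts_csv(tdf),
                           orientation = "otus_by_samples")
  expect_identical(unclass(ttab), unclass(tab))
})

test_that("read_count_table rejects bad cells and duplicate ids", {
  bad <- data.frame(sample_id = c("s1", "s2"), otuA = c("3.5", "2"),
                    otuB = c(1, 1))
  expect_error(read_count_table(write_counts_csv(bad)),
               "non-integer.*s1.*otuA")
  dup <- data.frame(sample_id = c("s1", "s1"), otuA = c(1L, 2L))
  expect_error(read_count_table(write_counts_csv(dup)), "duplicate")
})

test_that("low-read sample filter uses a strict threshold", {
  m <- rbind(s1 = c(19L, 0L), s2 = c(10L, 10L), s3 = c(50L, 50L))
  colnames(m) <- c("a", "b")
  tab <- as_read_count_table(m)
  out <- filter_low_read_samples(tab, 20)
  expect_identical(rownames(out), c("s2", "s3"))   # 20 kept, 19 dropped
  expect_identical(unclass(filter_low_read_samples(tab, 0)), unclass(tab))
  expect_warning(res <- filter_low_read_samples(tab, 1000), "all samples")
  expect_equal(nrow(res), 0)
})

test_that("minor-OTU filter zeroes strictly-below-threshold counts per sample", {
  m <- rbind(s1 = c(100L, 4L, 0L),    # b = 3.8% -> zeroed
             s2 = c(10L, 10L, 0L),    # each 50% -> kept
             s3 = c(95L, 5L, 0L))     # b = exactly 5% -> kept
  colnames(m) <- c("a", "b", "zero")
  out <- filter_minor_otus(as_read_count_table(m), 0.05)
  expect_identical(colnames(out), c("a", "b"))     # empty column dropped
  expect_identical(unname(unclass(out)[, "b"]), c(0L, 10L, 5L))
})

test_that("minor-OTU filter handles zero-total samples and is idempotent", {
  m <- rbind(s1 = c(0L, 0L), s2 = c(97L, 3L))
  colnames(m) <- c("a", "b")
  tab <- as_read_count_table(m)
  once <- filter_minor_otus(tab, 0.05)
  expect_identical(unname(unclass(once)[1, ]), 0L)
  expect_identical(unclass(filter_minor_otus(once, 0.05)), unclass(once))
})

test_that("minor-OTU filter never increases counts or richness", {
  withr::with_seed(7, {
    for (rep in 1:5) {
      m <- matrix(rpois(60, 15), 6, 10,
                  dimnames = list(paste0("s", 1:6), paste0("o", 1:10)))
      tab <- as_read_count_table(m)
      out <- filter_minor_otus(tab, 0.1, drop_empty = FALSE)
      expect_true(all(unclass(out) <= unclass(tab)))
      expect_true(all(rowSums(unclass(out) > 0) <= rowSums(unclass(tab) > 0)))
    }
  })
})

test_that("flagged-sample removal respects metadata and errors on gaps", {
  m <- rbind(s1 = c(5L, 5L), s2 = c(5L, 5L), s3 = c(5L, 5L))
  colnames(m) <- c("a", "b")
  tab <- as_read_count_table(m)
  md <- data.frame(sample_id = c("s1", "s2", "s3"),
                   exclude_flag = c(FALSE, TRUE, FALSE))
  out <- drop_flagged_samples(tab, md)
  expect_identical(rownames(out), c("s1", "s3"))
  expect_identical(unclass(drop_flagged_samples(tab,
    transform(md, exclude_flag = FALSE))), unclass(tab))
  expect_warning(
    drop_flagged_samples(tab, transform(md, exclude_flag = TRUE)),
    "all samples")
  expect_error(drop_flagged_samples(tab, md[-2, ]), "s2")
})

test_that("binarize maps positive counts to presence and computes margins", {
  m <- rbind(s1 = c(3L, 0L, 0L), s2 = c(0L, 7L, 0L))
  colnames(m) <- c("a", "b", "z")
  b <- binarize(as_read_count_table(m))
  expect_identical(unname(unclass(b)), rbind(c(1L, 0L, 0L), c(0L, 1L, 0L)))
  expect_equal(unname(occurrence(b)), c(1, 1, 0))
  expect_equal(unname(richness(b)), c(1, 1))
  m1 <- rbind(s1 = c(1L)); colnames(m1) <- "a"
  expect_identical(unclass(binarize(as_read_count_table(m1)))[1, 1], 1L)
})

test_that("pair screening applies both occurrence rules", {
  b <- as_bincom(rbind(
    matrix(rep(c(1L, 0L, 0L), 30), ncol = 3, byrow = TRUE),
    matrix(rep(c(0L, 1L, 0L), 10), ncol = 3, byrow = TRUE),
    matrix(rep(c(0L, 0L, 1L), 4), ncol = 3, byrow = TRUE)))
  ps <- screen_pairs(b, min_occurrence = 5, min_pair_sum = 25)
  expect_equal(nrow(ps), 1)
  expect_equal(c(ps$i, ps$j), c(1, 2))   # OTU 3 fails occurrence rule

  b2 <- as_bincom(cbind(rep(1:0, c(12, 12)), rep(0:1, c(12, 12))))
  expect_equal(nrow(screen_pairs(b2, 5, 25)), 0)  # 12 + 12 = 24 < 25
  expect_equal(nrow(screen_pairs(b2, 5, 24)), 1)
})

test_that("pair screening matches the brute-force rule on random matrices", {
  for (seed in 1:4) {
    b <- rand_bincom(20, 8, 0.4, seed)
    R <- occurrence(b)
    got <- screen_pairs(b, 3, 10)
    cmb <- t(combn(8, 2))
    want <- cmb[R[cmb[, 1]] >= 3 & R[cmb[, 2]] >= 3 &
                  R[cmb[, 1]] + R[cmb[, 2]] >= 10, , drop = FALSE]
    expect_identical(cbind(got$i, got$j), unname(want))
  }
  expect_warning(screen_pairs(rand_bincom(5, 3, 0.2, 1), 100, 0),
                 "fewer than 2")
})

test_that("prepare_matrix applies filters in pipeline order", {
  # s1 fails the read filter; s3 is flagged; otu c is minor in s2
  m <- rbind(s1 = c(10L, 5L, 0L), s2 = c(96L, 0L, 4L), s3 = c(30L, 30L, 30L))
  colnames(m) <- c("a", "b", "c")
  md <- data.frame(sample_id = c("s1", "s2", "s3"),
                   exclude_flag = c(FALSE, FALSE, TRUE))
  b <- prepare_matrix(as_read_count_table(m), md)
  expect_identical(rownames(b), "s2")
  expect_identical(colnames(b), "a")   # b, c dropped as empty
})

test_that("binary matrix CSV round-trips, including a host column", {
  b <- rand_bincom(12, 5, 0.4, 3)
  path <- tempfile(fileext = ".csv")
  write_binary_matrix(b, path)
  back <- read_binary_matrix(path)
  expect_identical(unclass(back), unclass(b))

  df <- data.frame(sample_id = rownames(b), host = rep(c("A", "B"), 6),
                   unclass(b), check.names = FALSE)
  path2 <- tempfile(fileext = ".csv")
  utils::write.table(df, path2, sep = ",", row.names = FALSE, quote = FALSE)
  back2 <- read_binary_matrix(path2)
  expect_identical(unname(attr(back2, "host")), rep(c("A", "B"), 6))
  attr(back2, "host") <- NULL
  expect_identical(unclass(back2), unclass(b))
})
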