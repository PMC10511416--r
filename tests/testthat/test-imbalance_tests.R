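test_that("1:1 chi-square matches hand computation and is symmetric", {
  r <- chisq_1to1(30L, 10L)
  expect_equal(r$statistic, 10)            # (30-20)^2/20 + (10-20)^2/20
  expect_equal(r$p_value, 0.0015654, tolerance = 1e-4)
  expect_equal(r$direction, "maternal")
  expect_equal(r$maternal_fraction, 0.75)

  r2 <- chisq_1to1(10L, 30L)
  expect_equal(r2$statistic, r$statistic)
  expect_equal(r2$p_value, r$p_value)
  expect_equal(r2$direction, "paternal")

  tie <- chisq_1to1(15L, 15L)
  expect_equal(tie$statistic, 0)
  expect_equal(tie$p_value, 1)
  expect_equal(tie$direction, "tie")

  expect_error(chisq_1to1(0L, 0L), "zero total")

  # vectorized symmetry over random counts
  withr::local_seed(5)
  m <- rbinom(200, 60, 0.5); p <- rbinom(200, 60, 0.5)
  keep <- m + p > 0
  a <- chisq_1to1(m[keep], p[keep])
  b <- chisq_1to1(p[keep], m[keep])
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p_value, b$p_value)
})

test_that("imbalance calls flag significance at the configured alpha", {
  fc <- data.frame(feature_id = c("f1", "f2"), sample = "cow1.liver.RNA",
                   maternal = c(30L, 16L), paternal = c(10L, 14L),
                   stringsAsFactors = FALSE)
  res <- imbalance_test(fc, alpha = 0.01)
  expect_equal(res$significant, c(TRUE, FALSE))
  res05 <- imbalance_test(fc, alpha = 0.9)
  expect_true(all(res05$significant == (res05$p_value < 0.9)))
})

test_that("tissue heterogeneity uses the same G as the homogeneity test", {
  fc <- data.frame(
    feature_id = "peak1",
    sample = sample_key("cow1", c("liver", "heart"), "H3K27ac"),
    maternal = c(30L, 10L), paternal = c(10L, 30L),
    stringsAsFactors = FALSE
  )
  th <- tissue_heterogeneity(fc)
  expect_equal(th$G, g_test(rbind(c(30, 10), c(10, 30)))$G)
  expect_equal(th$G, 20.92992575, tolerance = 1e-8)
  expect_equal(th$df, 1L)
  expect_lt(th$p_value, 0.05)
  expect_equal(th$n_tissues, 2L)

  # identical ratios: G = 0
  fc$maternal <- c(30L, 60L); fc$paternal <- c(10L, 20L)
  expect_equal(tissue_heterogeneity(fc)$G, 0)

  # one tissue: untestable, dropped
  expect_equal(nrow(tissue_heterogeneity(fc[1, ])), 0L)

  # different animals never share a table
  fc2 <- fc
  fc2$sample <- sample_key(c("cow1", "cow2"), "liver", "H3K27ac")
  expect_equal(nrow(tissue_heterogeneity(fc2)), 0L)
})

test_that("direction sharing bins single-tissue-significant features", {
  mk <- function(fractions, sig_idx, feature = "f1") {
    n <- length(fractions)
    m <- round(fractions * 40)
    fc <- data.frame(
      feature_id = feature,
      sample = sample_key("cow1", sprintf("t%02d", seq_len(n)), "RNA"),
      maternal = as.integer(m), paternal = as.integer(40 - m),
      stringsAsFactors = FALSE
    )
    res <- imbalance_test(fc, alpha = 0.01)
    res$significant <- seq_len(n) %in% sig_idx  # controlled significance
    res
  }
  # significant-maternal tissue, 4 of 5 others maternal too -> bin 80-100
  prof <- direction_sharing_profile(
    mk(c(0.9, 0.6, 0.6, 0.6, 0.6, 0.4), sig_idx = 1))
  expect_equal(prof$per_feature$sharing_fraction, 0.8)
  expect_equal(prof$per_feature$bin, "80-100")
  expect_equal(unname(prof$histogram["80-100"]), 100)

  # all others opposite -> 0, bin 0-20
  prof0 <- direction_sharing_profile(
    mk(c(0.9, 0.3, 0.4, 0.2), sig_idx = 1))
  expect_equal(prof0$per_feature$sharing_fraction, 0)
  expect_equal(prof0$per_feature$bin, "0-20")

  # features significant in 0 or 2+ tissues are excluded
  expect_equal(nrow(direction_sharing_profile(
    mk(c(0.9, 0.1, 0.5), sig_idx = c(1, 2)))$per_feature), 0L)
})

test_that("tissue-independent directions centre the sharing fraction at 0.5", {
  withr::local_seed(31)
  n_feat <- 400; n_tissue <- 11
  rows <- data.frame(
    feature_id = rep(paste0("f", seq_len(n_feat)), each = n_tissue),
    sample = sample_key("cow1", rep(sprintf("t%02d", seq_len(n_tissue)), n_feat),
                        "RNA"),
    maternal = rbinom(n_feat * n_tissue, 50, 0.5),
    stringsAsFactors = FALSE
  )
  rows$paternal <- 50L - rows$maternal
  res <- imbalance_test(rows, alpha = 0.05)
  prof <- direction_sharing_profile(res)
  expect_gt(nrow(prof$per_feature), 30)
  se <- sd(prof$per_feature$sharing_fraction) / sqrt(nrow(prof$per_feature))
  expect_lt(abs(mean(prof$per_feature$sharing_fraction) - 0.5), 4 * se + 0.02)
})

test_that("significance summary counts tested and significant samples", {
  fc <- data.frame(
    feature_id = c("f1", "f1", "f1", "f2", "f3"),
    sample = sample_key("cow1", c("t1", "t2", "t3", "t1", "t1"), "RNA"),
    maternal = c(40L, 26L, 25L, 25L, 48L),
    paternal = c(10L, 24L, 25L, 25L, 2L),
    stringsAsFactors = FALSE
  )
  ss <- summarize_significance(imbalance_test(fc, alpha = 0.01))
  f1 <- ss$per_feature[ss$per_feature$feature_id == "f1", ]
  expect_equal(f1$n_tested, 3L)
  expect_equal(f1$n_significant, 1L)
  expect_equal(f1$n_tissues_significant, 1L)
  # f2 never significant: excluded from the K distribution
  expect_equal(sort(names(ss$k_distribution)), "1")
  expect_equal(sum(ss$k_distribution), 2)

  # null features reject at about the binomial expectation
  withr::local_seed(13)
  null <- data.frame(
    feature_id = paste0("n", 1:1000),
    sample = sample_key("cow1", "t1", "RNA"),
    maternal = rbinom(1000, 50, 0.5),
    stringsAsFactors = FALSE
  )
  null$paternal <- 50L - null$maternal
  k <- sum(imbalance_test(null, alpha = 0.01)$significant)
  # expectation ~10 at alpha = 0.01 (conservative for discrete counts);
  # 3 binomial SDs around the nominal rate
  expect_lt(k, 10 + 3 * sqrt(1000 * 0.01 * 0.99))
})
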