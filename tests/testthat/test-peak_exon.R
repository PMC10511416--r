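iv <- function(start, end, chrom = "chr1") {
  data.frame(chrom = chrom, start = start, end = end, strand = ".",
             stringsAsFactors = FALSE)
}

test_that("consensus peaks are bases covered by at least two samples", {
  res <- call_consensus_peaks(list(a = iv(100, 200), b = iv(150, 250)))
  expect_equal(res$start, 150L)
  expect_equal(res$end, 200L)
  expect_equal(res$support, 2L)

  # a single sample cannot reach support 2
  expect_warning(res1 <- call_consensus_peaks(list(a = iv(100, 200))),
                 "fewer than 2")
  expect_equal(nrow(res1), 0L)

  # three identical intervals
  res3 <- call_consensus_peaks(list(a = iv(0, 10), b = iv(0, 10), c = iv(0, 10)))
  expect_equal(res3$start, 0L)
  expect_equal(res3$end, 10L)
  expect_equal(res3$support, 3L)

  # overlapping intervals within one sample count once
  res4 <- call_consensus_peaks(list(a = iv(c(0, 5), c(10, 15)), b = iv(100, 110)))
  expect_equal(nrow(res4), 0L)
})

test_that("consensus equals the per-base oracle and ignores sample order", {
  withr::local_seed(55)
  for (i in 1:150) {
    cfgiv <- random_interval_config(n_samples = sample(2:6, 1))
    res <- call_consensus_peaks(cfgiv)
    oracle <- consensus_oracle(cfgiv, max_pos = 2000)
    expect_equal(res$start, oracle$start)
    expect_equal(res$end, oracle$end)
    perm <- call_consensus_peaks(cfgiv[sample(length(cfgiv))])
    expect_equal(perm[, c("start", "end", "support")],
                 res[, c("start", "end", "support")])
  }
})

test_that("CPM columns sum to one million and match edgeR", {
  m <- matrix(c(100, 0, 900, 50, 150, 1800), nrow = 3,
              dimnames = list(paste0("f", 1:3), c("s1", "s2")))
  cp <- cpm_normalize(m)
  expect_equal(unname(colSums(cp)), c(1e6, 1e6), tolerance = 1e-6)
  expect_equal(cp["f1", "s1"], 100 / 1000 * 1e6)
  expect_equal(cp["f2", "s1"], 0)

  z <- m; z[, 2] <- 0
  expect_error(cpm_normalize(z), "s2")

  skip_if_not_installed("edgeR")
  expect_equal(unname(cp), unname(edgeR::cpm(m)), tolerance = 1e-9)
})

test_that("window pairing anchors at the stranded exon start", {
  exons <- data.frame(
    chrom = "chr1", start = c(1000000L, 500000L), end = c(1000500L, 500800L),
    strand = c("+", "-"), name = c("exA", "exB"), stringsAsFactors = FALSE
  )
  peaks <- data.frame(
    chrom = "chr1",
    start = c(1090000L, 1150000L, 590000L, 390000L),
    end = c(1091000L, 1151000L, 591000L, 391000L),
    strand = ".", name = paste0("p", 1:4), stringsAsFactors = FALSE
  )
  pr <- window_pairs(exons, peaks, window = 1e5)
  key <- paste(pr$exon_id, pr$peak_id)
  expect_true("exA p1" %in% key)        # 90 kb right of + anchor
  expect_false("exA p2" %in% key)       # 150 kb away
  # minus-strand exon anchors at its right edge (500799): p3 at 590000 is
  # ~89 kb right and included; p4 at 390999 end is ~110 kb left and excluded
  expect_true("exB p3" %in% key)
  expect_false("exB p4" %in% key)

  other_chr <- peaks; other_chr$chrom <- "chr2"
  expect_equal(nrow(window_pairs(exons, other_chr)), 0L)
})

test_that("window pairing equals a brute-force distance oracle", {
  withr::local_seed(66)
  window <- 5000
  exons <- data.frame(chrom = "chr1",
                      start = sample.int(50000, 40) - 1L,
                      strand = sample(c("+", "-"), 40, replace = TRUE),
                      stringsAsFactors = FALSE)
  exons$end <- exons$start + sample.int(500, 40)
  exons$name <- paste0("e", 1:40)
  peaks <- data.frame(chrom = "chr1", start = sample.int(50000, 60) - 1L,
                      strand = ".", stringsAsFactors = FALSE)
  peaks$end <- peaks$start + sample.int(400, 60)
  peaks$name <- paste0("p", 1:60)
  got <- window_pairs(exons, peaks, window = window)
  got_key <- sort(paste(got$exon_id, got$peak_id))
  want <- character()
  for (i in seq_len(nrow(exons))) {
    anchor <- if (exons$strand[i] == "+") exons$start[i] else exons$end[i] - 1L
    for (j in seq_len(nrow(peaks))) {
      # any peak base within [anchor - w, anchor + w]
      if (peaks$start[j] <= anchor + window && peaks$end[j] - 1L >= anchor - window) {
        want <- c(want, paste(exons$name[i], peaks$name[j]))
      }
    }
  }
  expect_equal(got_key, sort(want))
})

test_that("pair correlation recovers exact relationships and skips degenerate ones", {
  ex <- matrix(c(1, 2, 3, 4, 5, 6) * 2, nrow = 1,
               dimnames = list("e1", paste0("s", 1:6)))
  pk <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 1,
               dimnames = list("p1", paste0("s", 1:6)))
  pairs <- data.frame(exon_id = "e1", peak_id = "p1", stringsAsFactors = FALSE)
  res <- correlate_pairs(pairs, ex, pk, alpha = 0.05)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_equal(res$sign, "positive")

  pk_desc <- matrix(6:1, nrow = 1, dimnames = list("p1", paste0("s", 1:6)))
  res_neg <- correlate_pairs(pairs, ex, pk_desc, alpha = 0.05)
  expect_equal(res_neg$r, -1, tolerance = 1e-12)
  expect_equal(res_neg$sign, "negative")

  # constant peak vector: undefined r, skipped entirely
  flat <- pk; flat[1, ] <- 7
  res_flat <- correlate_pairs(pairs, ex, flat, alpha = 1 - 1e-9)
  expect_equal(nrow(res_flat), 0L)
  expect_equal(attr(res_flat, "n_tested"), 0L)

  # p-values agree with cor.test
  withr::local_seed(8)
  x <- matrix(rnorm(22), 1, dimnames = list("e1", paste0("s", 1:22)))
  y <- matrix(rnorm(22), 1, dimnames = list("p1", paste0("s", 1:22)))
  res_r <- correlate_pairs(pairs, abs(x) + 1, abs(y) + 1, alpha = 1 - 1e-9)
  ct <- cor.test(abs(x[1, ]) + 1, abs(y[1, ]) + 1)
  expect_equal(res_r$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res_r$p_value, ct$p.value, tolerance = 1e-12)
})

test_that("null pairs are retained at about the nominal rate and true pairs recalled", {
  withr::local_seed(99)
  null <- simulate_profile_pairs(2000, n_samples = 22, r_true = 0)
  res0 <- correlate_pairs(null$pairs, null$exon_cpm, null$peak_cpm, alpha = 0.05)
  rate <- nrow(res0) / attr(res0, "n_tested")
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)

  strong <- simulate_profile_pairs(500, n_samples = 22, r_true = 0.8)
  res8 <- correlate_pairs(strong$pairs, strong$exon_cpm, strong$peak_cpm,
                          alpha = 0.05)
  expect_gt(nrow(res8) / attr(res8, "n_tested"), 0.9)
  expect_true(all(res8$sign == "positive"))
})

test_that("direction concordance compares doubly significant samples only", {
  links <- data.frame(exon_id = "e1", peak_id = "p1", r = 0.9, p_value = 1e-4,
                      n = 22, sign = "positive", stringsAsFactors = FALSE)
  mk_res <- function(feature, assay, fracs, n = 100L) {
    m <- as.integer(round(fracs * n))
    fc <- data.frame(feature_id = feature,
                     sample = sample_key("cow1", sprintf("t%d", seq_along(fracs)),
                                         assay),
                     maternal = m, paternal = n - m, stringsAsFactors = FALSE)
    imbalance_test(fc, alpha = 0.05)
  }
  asb <- mk_res("p1", "H3K27ac", c(0.7, 0.7, 0.52))
  ase <- mk_res("e1", "RNA", c(0.8, 0.3, 0.9))
  con <- direction_concordance(links, asb, ase, alpha = 0.05)
  # t1 same (0.7 vs 0.8), t2 different (0.7 vs 0.3), t3 not compared
  # because the peak fraction 0.52 is not significant
  expect_equal(con$tally$n_compared[con$tally$sign == "positive"], 2L)
  expect_equal(con$tally$n_same_direction[con$tally$sign == "positive"], 1L)
  expect_equal(nrow(con$scatter), 2L)

  # global maternal/paternal swap leaves concordance invariant
  flip <- function(res) {
    res$maternal_fraction <- 1 - res$maternal_fraction
    res
  }
  con_f <- direction_concordance(links, flip(asb), flip(ase), alpha = 0.05)
  expect_equal(con_f$tally$n_compared, con$tally$n_compared)
  expect_equal(con_f$tally$n_same_direction, con$tally$n_same_direction)
})
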