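small_cfg <- function(seed = 21, ...) {
  simulation_config(seed = seed, n_chrom = 2, chrom_length = 2e5,
                    n_snps = 800, n_peaks_per_assay = 30, n_exons = 25,
                    n_tissues = 4, ...)
}

test_that("a fixed seed reproduces the dataset byte for byte", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  sim1 <- simulate_dataset(small_cfg(), dir = d1)
  sim2 <- simulate_dataset(small_cfg(), dir = d2)
  files <- list.files(d1, recursive = TRUE)
  expect_gt(length(files), 10)
  expect_setequal(files, list.files(d2, recursive = TRUE))
  for (f in files) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  # a different seed changes the data
  sim3 <- simulate_dataset(small_cfg(seed = 22))
  expect_false(identical(sim1$allele_counts, sim3$allele_counts))
})

test_that("generated files parse through the package readers without warnings", {
  d <- withr::local_tempdir()
  sim <- simulate_dataset(small_cfg(), dir = d)
  expect_no_warning({
    geno <- read_vcf_allele_depths(file.path(d, "variants.vcf"))
    exons <- read_intervals(file.path(d, "exons.gtf"), "gtf-exon")
    bed1 <- read_intervals(
      file.path(d, sim$manifest$peaks$H3K27ac[[1]]), "bed")
    fa <- Biostrings::readDNAStringSet(file.path(d, "genome.fa"))
  })
  expect_equal(attr(geno, "n_skipped"), 0L)
  expect_equal(nrow(exons), nrow(sim$exons))
  expect_equal(sort(exons$name), sort(sim$exons$name))
  # VCF round trip: genotype table equals the in-memory one
  key <- paste(geno$variant_id, geno$sample)
  skey <- paste(sim$genotypes$variant_id, sim$genotypes$sample)
  m <- match(skey, key)
  expect_false(anyNA(m))
  expect_equal(geno$zygosity[m], sim$genotypes$zygosity)
  expect_equal(geno$ref_depth[m], sim$genotypes$ref_depth)
  # phased offspring haplotypes survive the round trip
  off <- sim$genotypes$sample %in% sim$config$animals &
    sim$genotypes$zygosity == "het"
  expect_equal(geno$hap1[m][off], sim$genotypes$hap1[off])
  # BED round trip
  expect_equal(bed1[, c("chrom", "start", "end")],
               sim$peak_beds$H3K27ac[[1]][, c("chrom", "start", "end")])
})

test_that("infeasible configurations are rejected before generation", {
  expect_error(simulation_config(n_peaks_per_assay = 5000, chrom_length = 1e5),
               "infeasible")
  expect_error(simulation_config(kappa = 1.5), "kappa")
})

test_that("allele counts recover the true maternal fractions within binomial error", {
  cfg <- small_cfg(seed = 33, bias_fraction = 0.3, mean_coverage = 50,
                   tissue_specific_fraction = 0)
  sim <- simulate_dataset(cfg)
  # aggregate counts per feature x tissue against truth
  ac <- sim$allele_counts
  truth <- sim$truth
  mat_key <- paste(truth$snp_phase$variant_id, truth$snp_phase$animal)
  m <- match(paste(ac$variant_id, ac$animal), mat_key)
  mat_allele <- truth$snp_phase$maternal[m]
  alt <- sim$sites$alt[match(ac$variant_id, sim$sites$variant_id)]
  maternal <- ifelse(mat_allele == alt, ac$alt_count, ac$ref_count)
  total <- ac$ref_count + ac$alt_count
  # per feature x tissue empirical fraction (features looked up via truth links)
  snp_feat <- list()
  for (as_ in names(sim$consensus)) {
    ivs <- interval_to_granges(sim$consensus[[as_]])
    gr <- GenomicRanges::GRanges(
      sim$sites$chrom, IRanges::IRanges(sim$sites$pos + 1, sim$sites$pos + 1))
    hits <- GenomicRanges::findOverlaps(gr, ivs)
    snp_feat[[as_]] <- setNames(
      sim$consensus[[as_]]$name[S4Vectors::subjectHits(hits)],
      sim$sites$variant_id[S4Vectors::queryHits(hits)])
  }
  chip <- ac$assay != "RNA"
  feat <- vapply(seq_len(nrow(ac)), function(i) {
    if (!chip[i]) return(NA_character_)
    unname(snp_feat[[ac$assay[i]]][ac$variant_id[i]])
  }, character(1))
  grp <- paste(ac$assay, feat, ac$tissue)[chip]
  est <- tapply(maternal[chip], grp, sum) / tapply(total[chip], grp, sum)
  n_tot <- tapply(total[chip], grp, sum)
  tkey <- paste(truth$feature_fractions$assay, truth$feature_fractions$feature_id,
                truth$feature_fractions$tissue)
  tf <- truth$feature_fractions$maternal_fraction[match(names(est), tkey)]
  keep <- n_tot >= 100
  rmse <- sqrt(mean((est[keep] - tf[keep])^2))
  expect_lt(rmse, 2 / sqrt(min(n_tot[keep])))
})

test_that("detection power rises with coverage", {
  withr::local_seed(202)
  rates <- vapply(c(20, 60, 180), function(cov) {
    frac <- rbeta(800, 2, 2)
    m <- rbinom(800, cov, frac)
    res <- imbalance_test(data.frame(
      feature_id = paste0("f", 1:800), sample = "a.t.RNA",
      maternal = m, paternal = cov - m, stringsAsFactors = FALSE),
      alpha = 0.01)
    mean(res$significant)
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("kappa sweep produces a monotone concordance curve with the right endpoints", {
  withr::local_seed(404)
  sweep <- concordance_kappa_sweep(c(0, 0.5, 1), n_links = 1500,
                                   n_samples = 12, coverage = 100)
  expect_true(all(diff(sweep$prop_same_direction) >= 0))
  expect_lt(abs(sweep$prop_same_direction[1] - 0.5), 3 * sweep$se[1])
  expect_gt(sweep$prop_same_direction[3], 0.95)
})

test_that("truth evaluation reports calibration and errors on unknown ids", {
  cfg <- small_cfg(seed = 44)
  sim <- simulate_dataset(cfg)
  # build imbalance results directly from generator components
  d <- withr::local_tempdir()
  sim <- simulate_dataset(cfg, dir = d)
  res <- run_pipeline(pipeline_config(d, file.path(d, "out")))
  ev <- truth_evaluation(res$imbalance, sim$truth)
  expect_true(all(ev$null_rejection_rate < 0.05, na.rm = TRUE))
  expect_true(all(ev$sensitivity > ev$null_rejection_rate, na.rm = TRUE))
  expect_true(all(ev$fraction_rmse < 0.2))

  bad <- res$imbalance
  bad$feature_id[1] <- "nonexistent"
  expect_error(truth_evaluation(bad, sim$truth), "not present in truth")
})
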