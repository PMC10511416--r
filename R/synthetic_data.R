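#' Configuration for the synthetic ASE/ASB dataset
#'
#' Defaults emulate the study design the package targets: three adult cows
#' and two foetuses sharing a sire, 22 tissues, four histone marks plus CTCF
#' and RNA, roughly half of the animal-tissue-assay grid actually assayed,
#' heterozygous SNPs nested in peaks and exons, binomially sampled
#' maternal/paternal allele counts with feature-level bias, and cross-tissue
#' peak-height/exon-expression profiles with a tunable latent correlation
#' and a cis-coupling \code{kappa} tying a linked exon's maternal fraction
#' to its peak's.
#'
#' @param seed Integer seed; fixes the full output.
#' @param n_chrom,chrom_length Genome shape (default 2 x 1 Mb).
#' @param n_snps Total SNPs across the genome (default 5000).
#' @param n_peaks_per_assay True peak loci per ChIP assay (default 200).
#' @param n_exons Number of exons (default 100).
#' @param peak_width,exon_width Length ranges (bases) for peaks and exons.
#' @param n_tissues Number of tissues (default 22).
#' @param sample_presence Probability an animal-tissue-assay library exists
#'   (default 0.5, matching roughly half-full real designs).
#' @param peak_presence Probability a true peak is called in a given sample's
#'   peak set (default 0.8).
#' @param het_rate Per-animal heterozygosity rate at a SNP (default 0.4).
#' @param sire_het_fraction Probability the sire is heterozygous at a site
#'   (default 0.10, the regime where the phase fallback is rarely needed).
#' @param phase_accuracy Probability a written phased genotype has the
#'   correct haplotype order (default 1: phase is exact truth).
#' @param wgs_coverage Mean whole-genome sequencing depth for the VCF AD
#'   fields (default 20).
#' @param mean_coverage Mean allele-count depth per SNP per library
#'   (default 30).
#' @param bias_fraction Fraction of features with true allelic bias
#'   (default 0.3).
#' @param bias_shape Shape of the symmetric Beta(\code{bias_shape},
#'   \code{bias_shape}) from which a biased feature's maternal fraction is
#'   drawn (default 2: broad around 0.5).
#' @param tissue_specific_fraction Among biased features, the fraction whose
#'   bias is active only in a random subset of tissues (default 0.5).
#' @param coupled_fraction Fraction of exons coupled to one nearby peak with
#'   latent cross-tissue correlation \code{r_true} (default 0.15).
#' @param r_true Latent correlation for coupled peak-exon profiles
#'   (default 0.8).
#' @param kappa Cis-coupling in \[0, 1\]: a coupled exon's maternal fraction
#'   is \code{kappa * peak fraction + (1 - kappa) * independent draw}
#'   (default 0 — binding bias carries no information about expression
#'   bias, the no-cis-effect regime).
#' @param profile_mu_log,profile_sigma Log-scale mean and spread of feature
#'   baseline counts for the cross-tissue profiles.
#' @param overdispersion Beta-binomial overdispersion rho for allele counts;
#'   0 (default) is pure binomial, the model the downstream tests assume.
#' @return A list of class \code{"aseasb_sim_config"}.
#' @export
simulation_config <- function(seed = 1,
                              n_chrom = 2, chrom_length = 1e6,
                              n_snps = 5000,
                              n_peaks_per_assay = 200, n_exons = 100,
                              peak_width = c(400, 1200),
                              exon_width = c(400, 1200),
                              n_tissues = 22,
                              sample_presence = 0.5,
                              peak_presence = 0.8,
                              het_rate = 0.4,
                              sire_het_fraction = 0.10,
                              phase_accuracy = 1,
                              wgs_coverage = 20,
                              mean_coverage = 30,
                              bias_fraction = 0.3,
                              bias_shape = 2,
                              tissue_specific_fraction = 0.5,
                              coupled_fraction = 0.15,
                              r_true = 0.8,
                              kappa = 0,
                              profile_mu_log = log(200),
                              profile_sigma = 0.5,
                              overdispersion = 0) {
  cfg <- as.list(environment())
  stopifnot(cfg$kappa >= 0, cfg$kappa <= 1,
            cfg$bias_fraction >= 0, cfg$bias_fraction <= 1,
            cfg$sire_het_fraction >= 0, cfg$sire_het_fraction <= 1,
            cfg$sample_presence > 0, cfg$sample_presence <= 1)
  cfg$adults <- c("cow1", "cow2", "cow3")
  cfg$foetuses <- c("foetus1", "foetus2")
  cfg$animals <- c(cfg$adults, cfg$foetuses)
  cfg$tissues <- sprintf("tissue%02d", seq_len(n_tissues))
  cfg$chip_assays <- chip_assays()
  # pedigree: each adult has her own sire and an unknown dam; the two
  # foetuses share a sire and have two of the adult cows as dams
  cfg$pedigree <- data.frame(
    offspring = cfg$animals,
    sire = c("sire1", "sire2", "sire3", "sire4", "sire4"),
    dam = c(NA, NA, NA, "cow1", "cow2"),
    stringsAsFactors = FALSE
  )
  # feasibility: per-chromosome peak slots must fit the widest peak
  slot <- chrom_length / ceiling(n_peaks_per_assay / n_chrom)
  if (slot < max(peak_width) + 200) {
    stop("infeasible config: ", n_peaks_per_assay, " peaks of width up to ",
         max(peak_width), " do not fit ", n_chrom, " x ", chrom_length, " bases")
  }
  if (chrom_length / ceiling(n_exons / n_chrom) < max(exon_width) + 200) {
    stop("infeasible config: exons do not fit the genome")
  }
  class(cfg) <- "aseasb_sim_config"
  cfg
}

# place k non-overlapping intervals per chromosome in evenly spaced slots,
# jittered uniformly inside each slot
place_intervals <- function(chroms, chrom_length, k_total, width_range, prefix) {
  k <- ceiling(k_total / length(chroms))
  out <- lapply(chroms, function(chr) {
    slot <- floor(chrom_length / k)
    width <- floor(runif(k, width_range[1], width_range[2] + 1))
    offset <- floor(runif(k, 0, slot - width))
    start <- (seq_len(k) - 1L) * slot + offset
    data.frame(chrom = chr, start = as.integer(start),
               end = as.integer(start + width), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[seq_len(min(k_total, nrow(out))), , drop = FALSE]
  out$name <- paste0(prefix, seq_len(nrow(out)))
  out$strand <- "."
  rownames(out) <- NULL
  out
}

# maternal-count sampler: binomial, or beta-binomial when rho > 0
sample_maternal <- function(n, size, prob, rho) {
  if (rho > 0) {
    a <- prob * (1 - rho) / rho
    b <- (1 - prob) * (1 - rho) / rho
    prob <- rbeta(n, a, b)
  }
  rbinom(n, size, prob)
}

# draw the per-feature, per-tissue maternal-fraction matrix
draw_fraction_matrix <- function(feature_ids, cfg) {
  n <- length(feature_ids)
  biased <- runif(n) < cfg$bias_fraction
  base <- ifelse(biased, rbeta(n, cfg$bias_shape, cfg$bias_shape), 0.5)
  frac <- matrix(rep(base, cfg$n_tissues), nrow = n,
                 dimnames = list(feature_ids, cfg$tissues))
  ts <- biased & runif(n) < cfg$tissue_specific_fraction
  for (i in which(ts)) {
    active <- runif(cfg$n_tissues) < 0.5
    if (!any(active)) active[sample.int(cfg$n_tissues, 1)] <- TRUE
    frac[i, !active] <- 0.5
  }
  list(fraction = frac, biased = biased, tissue_specific = ts)
}

#' Generate a complete synthetic ASE/ASB dataset
#'
#' Produces every input the analysis pipeline consumes — reference FASTA,
#' multi-sample VCF with phased offspring genotypes and allele depths,
#' pedigree, per-sample peak BEDs, exon GTF, allele-count tables and
#' cross-tissue count matrices — together with truth tables recording each
#' feature's true maternal fraction per tissue, each SNP's true parental
#' phase, and each coupled peak-exon pair. Everything is reproducible from
#' the config seed.
#'
#' @param cfg A [simulation_config()].
#' @param dir Optional directory; when given, all components are written in
#'   their standard file formats plus a \code{manifest.yaml} that
#'   [run_pipeline()] can consume.
#' @return A list with components \code{config}, \code{genome},
#'   \code{genotypes} (long table in [read_vcf_allele_depths()] schema),
#'   \code{pedigree}, \code{peak_beds} (assay -> sample -> intervals),
#'   \code{consensus} (assay -> consensus peak intervals), \code{exons},
#'   \code{allele_counts}, \code{count_matrices} (assay -> matrix),
#'   \code{truth} (\code{snp_phase}, \code{feature_fractions},
#'   \code{links}), and \code{dir}/\code{manifest} when written.
#' @export
simulate_dataset <- function(cfg = simulation_config(), dir = NULL) {
  stopifnot(inherits(cfg, "aseasb_sim_config"))
  set.seed(cfg$seed)
  chroms <- paste0("chr", seq_len(cfg$n_chrom))

  ## genome
  genome <- Biostrings::DNAStringSet(vapply(chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), cfg$chrom_length, replace = TRUE),
          collapse = "")
  }, character(1)))
  names(genome) <- chroms

  ## SNP sites
  per_chrom <- ceiling(cfg$n_snps / cfg$n_chrom)
  sites <- do.call(rbind, lapply(chroms, function(ch) {
    pos <- sort(sample.int(cfg$chrom_length, per_chrom) - 1L)
    data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
  }))
  sites <- sites[seq_len(min(cfg$n_snps, nrow(sites))), , drop = FALSE]
  n_snp <- nrow(sites)
  sites$variant_id <- paste0("snp", seq_len(n_snp))
  sites$ref <- unlist(lapply(chroms, function(ch) {
    p <- sites$pos[sites$chrom == ch]
    as.character(Biostrings::extractAt(genome[[ch]],
                                       IRanges::IRanges(p + 1L, p + 1L)))
  }), use.names = FALSE)
  sites$alt <- vapply(sites$ref, function(r) {
    sample(setdiff(c("A", "C", "G", "T"), r), 1)
  }, character(1), USE.NAMES = FALSE)

  ## haplotypes: hap1 = paternal, hap2 = maternal (truth)
  animals <- cfg$animals
  hap1 <- hap2 <- matrix(NA_character_, n_snp, length(animals),
                         dimnames = list(sites$variant_id, animals))
  sire_a1 <- sire_a2 <- matrix(NA_character_, n_snp,
                               length(unique(cfg$pedigree$sire)),
                               dimnames = list(sites$variant_id,
                                               unique(cfg$pedigree$sire)))
  # adults: direct draw; their sires conditional on the transmitted allele
  for (an in cfg$adults) {
    het <- runif(n_snp) < cfg$het_rate
    pat_is_ref <- runif(n_snp) < 0.5
    hom_is_ref <- runif(n_snp) < 0.5
    hap1[, an] <- ifelse(het, ifelse(pat_is_ref, sites$ref, sites$alt),
                         ifelse(hom_is_ref, sites$ref, sites$alt))
    hap2[, an] <- ifelse(het, ifelse(pat_is_ref, sites$alt, sites$ref),
                         hap1[, an])
    sire <- cfg$pedigree$sire[cfg$pedigree$offspring == an]
    s_het <- runif(n_snp) < cfg$sire_het_fraction
    sire_a1[, sire] <- ifelse(s_het, sites$ref, hap1[, an])
    sire_a2[, sire] <- ifelse(s_het, sites$alt, hap1[, an])
  }
  # shared foetal sire drawn first, then transmission
  fsire <- "sire4"
  fs_het <- runif(n_snp) < cfg$sire_het_fraction
  fs_hom_ref <- runif(n_snp) < 0.5
  sire_a1[, fsire] <- ifelse(fs_het, sites$ref,
                             ifelse(fs_hom_ref, sites$ref, sites$alt))
  sire_a2[, fsire] <- ifelse(fs_het, sites$alt,
                             ifelse(fs_hom_ref, sites$ref, sites$alt))
  for (an in cfg$foetuses) {
    dam <- cfg$pedigree$dam[cfg$pedigree$offspring == an]
    transmit1 <- runif(n_snp) < 0.5
    hap1[, an] <- ifelse(transmit1, sire_a1[, fsire], sire_a2[, fsire])
    dam_pick1 <- runif(n_snp) < 0.5
    hap2[, an] <- ifelse(dam_pick1, hap1[, dam], hap2[, dam])
  }

  ## long genotype table (offspring + sires), VCF-reader schema
  zyg_of <- function(a, b) ifelse(a != b, "het",
                                  ifelse(a == sites$ref, "hom_ref", "hom_alt"))
  geno_rows <- list()
  for (an in animals) {
    het <- hap1[, an] != hap2[, an]
    # phased written order: per animal x chromosome orientation, plus
    # per-site error at rate 1 - phase_accuracy
    orient <- setNames(runif(length(chroms)) < 0.5, chroms)
    flip <- orient[sites$chrom]
    err <- runif(n_snp) >= cfg$phase_accuracy
    flip <- xor(flip, err)
    w1 <- ifelse(flip, hap2[, an], hap1[, an])
    w2 <- ifelse(flip, hap1[, an], hap2[, an])
    depth <- rpois(n_snp, cfg$wgs_coverage)
    refd <- ifelse(het, rbinom(n_snp, depth, 0.5),
                   ifelse(hap1[, an] == sites$ref, depth, 0L))
    geno_rows[[an]] <- data.frame(
      variant_id = sites$variant_id, chrom = sites$chrom, pos = sites$pos,
      ref = sites$ref, alt = sites$alt, sample = an,
      ref_depth = as.integer(refd), alt_depth = as.integer(depth - refd),
      zygosity = zyg_of(hap1[, an], hap2[, an]),
      phased = TRUE, hap1 = w1, hap2 = w2,
      stringsAsFactors = FALSE
    )
  }
  for (sr in colnames(sire_a1)) {
    depth <- rpois(n_snp, cfg$wgs_coverage)
    het <- sire_a1[, sr] != sire_a2[, sr]
    refd <- ifelse(het, rbinom(n_snp, depth, 0.5),
                   ifelse(sire_a1[, sr] == sites$ref, depth, 0L))
    geno_rows[[sr]] <- data.frame(
      variant_id = sites$variant_id, chrom = sites$chrom, pos = sites$pos,
      ref = sites$ref, alt = sites$alt, sample = sr,
      ref_depth = as.integer(refd), alt_depth = as.integer(depth - refd),
      zygosity = zyg_of(sire_a1[, sr], sire_a2[, sr]),
      phased = FALSE, hap1 = NA_character_, hap2 = NA_character_,
      stringsAsFactors = FALSE
    )
  }
  genotypes <- do.call(rbind, geno_rows)
  rownames(genotypes) <- NULL

  ## sample grid
  grid <- expand.grid(animal = animals, tissue = cfg$tissues,
                      assay = assay_levels(), stringsAsFactors = FALSE)
  grid <- grid[order(grid$assay, grid$animal, grid$tissue), , drop = FALSE]
  grid$present <- runif(nrow(grid)) < cfg$sample_presence
  grid <- grid[grid$present, c("animal", "tissue", "assay"), drop = FALSE]
  rownames(grid) <- NULL

  ## per-sample peak BEDs and consensus peaks, per ChIP assay
  peak_beds <- list()
  consensus <- list()
  for (as_ in cfg$chip_assays) {
    loci <- place_intervals(chroms, cfg$chrom_length, cfg$n_peaks_per_assay,
                            cfg$peak_width, paste0(as_, "_locus"))
    smp <- grid[grid$assay == as_, , drop = FALSE]
    if (nrow(smp) < 2) stop("infeasible config: fewer than 2 samples for ", as_)
    beds <- list()
    for (i in seq_len(nrow(smp))) {
      keep <- runif(nrow(loci)) < cfg$peak_presence
      b <- loci[keep, , drop = FALSE]
      js <- sample.int(51, nrow(b), replace = TRUE) - 1L
      je <- sample.int(51, nrow(b), replace = TRUE) - 1L
      b$start <- pmax(b$start - js, 0L)
      b$end <- pmin(b$end + je, cfg$chrom_length)
      b <- b[, c("chrom", "start", "end", "strand", "name")]
      rownames(b) <- NULL
      beds[[sample_key(smp$animal[i], smp$tissue[i], as_)]] <- b
    }
    peak_beds[[as_]] <- beds
    consensus[[as_]] <- call_consensus_peaks(beds, min_support = 2)
    consensus[[as_]]$name <- paste0(as_, "_", consensus[[as_]]$name)
  }

  ## exons
  exons <- place_intervals(chroms, cfg$chrom_length, cfg$n_exons,
                           cfg$exon_width, "exon")
  exons$strand <- sample(c("+", "-"), nrow(exons), replace = TRUE)
  exons$gene_id <- paste0("gene", ceiling(seq_len(nrow(exons)) / 2))

  ## true maternal fractions per feature x tissue
  frac <- list()
  truth_feat <- list()
  for (as_ in cfg$chip_assays) {
    d <- draw_fraction_matrix(consensus[[as_]]$name, cfg)
    frac[[as_]] <- d$fraction
    truth_feat[[as_]] <- data.frame(
      assay = as_, feature_id = consensus[[as_]]$name, biased = d$biased,
      tissue_specific = d$tissue_specific, stringsAsFactors = FALSE)
  }
  d <- draw_fraction_matrix(exons$name, cfg)
  frac[["RNA"]] <- d$fraction
  truth_feat[["RNA"]] <- data.frame(
    assay = "RNA", feature_id = exons$name, biased = d$biased,
    tissue_specific = d$tissue_specific, stringsAsFactors = FALSE)

  ## couple a fraction of exons to one nearby peak
  n_coupled <- floor(cfg$coupled_fraction * nrow(exons))
  coupled_exons <- if (n_coupled > 0)
    sample(exons$name, n_coupled) else character()
  links <- list()
  for (ex in coupled_exons) {
    as_ <- sample(cfg$chip_assays, 1)
    cand <- window_pairs(exons[exons$name == ex, , drop = FALSE],
                         consensus[[as_]], window = 1e5)
    cand <- cand[!(cand$peak_id %in% vapply(links, `[[`, character(1), "peak_id")), ,
                 drop = FALSE]
    if (nrow(cand) == 0) next
    pk <- cand$peak_id[sample.int(nrow(cand), 1)]
    links[[ex]] <- list(exon_id = ex, peak_id = pk, assay = as_)
    # cis coupling of the exon's maternal fraction to the peak's
    frac[["RNA"]][ex, ] <- cfg$kappa * frac[[as_]][pk, ] +
      (1 - cfg$kappa) * frac[["RNA"]][ex, ]
  }
  links <- if (length(links) > 0) {
    data.frame(exon_id = vapply(links, `[[`, character(1), "exon_id"),
               peak_id = vapply(links, `[[`, character(1), "peak_id"),
               assay = vapply(links, `[[`, character(1), "assay"),
               r_true = cfg$r_true, kappa = cfg$kappa,
               stringsAsFactors = FALSE)
  } else {
    data.frame(exon_id = character(), peak_id = character(),
               assay = character(), r_true = numeric(), kappa = numeric(),
               stringsAsFactors = FALSE)
  }
  rownames(links) <- NULL

  ## allele-count tables: SNPs in features, binomial around the feature's
  ## tissue fraction, reported as ref/alt depths via the true maternal allele
  snp_gr <- GenomicRanges::GRanges(sites$chrom,
                                   IRanges::IRanges(sites$pos + 1L, sites$pos + 1L))
  count_rows <- list()
  feature_of_snp <- function(feat) {
    hits <- GenomicRanges::findOverlaps(snp_gr, interval_to_granges(feat),
                                        ignore.strand = TRUE)
    data.frame(snp = S4Vectors::queryHits(hits),
               feature = feat$name[S4Vectors::subjectHits(hits)],
               stringsAsFactors = FALSE)
  }
  for (as_ in c(cfg$chip_assays, "RNA")) {
    feat <- if (as_ == "RNA") exons else consensus[[as_]]
    map <- feature_of_snp(feat)
    map <- map[!duplicated(map$snp), , drop = FALSE]  # first containing feature
    if (nrow(map) == 0) next
    smp <- grid[grid$assay == as_, , drop = FALSE]
    for (i in seq_len(nrow(smp))) {
      an <- smp$animal[i]; ti <- smp$tissue[i]
      het <- hap1[map$snp, an] != hap2[map$snp, an]
      m <- map[het, , drop = FALSE]
      if (nrow(m) == 0) next
      depth <- rpois(nrow(m), cfg$mean_coverage)
      f <- frac[[as_]][cbind(m$feature, ti)]
      mat <- sample_maternal(nrow(m), depth, f, cfg$overdispersion)
      mat_allele <- hap2[m$snp, an]
      is_alt <- mat_allele == sites$alt[m$snp]
      count_rows[[paste(as_, an, ti)]] <- data.frame(
        variant_id = sites$variant_id[m$snp], animal = an, tissue = ti,
        assay = as_,
        ref_count = as.integer(ifelse(is_alt, depth - mat, mat)),
        alt_count = as.integer(ifelse(is_alt, mat, depth - mat)),
        stringsAsFactors = FALSE
      )
    }
  }
  allele_counts <- do.call(rbind, count_rows)
  rownames(allele_counts) <- NULL

  ## cross-tissue count matrices with latent coupling for linked pairs
  at_keys <- as.vector(outer(animals, cfg$tissues,
                             function(a, t) paste(a, t, sep = ".")))
  z <- if (nrow(links) > 0) {
    matrix(rnorm(nrow(links) * length(at_keys)), nrow = nrow(links),
           dimnames = list(links$exon_id, at_keys))
  } else NULL
  count_matrices <- list()
  for (as_ in c(cfg$chip_assays, "RNA")) {
    feat <- if (as_ == "RNA") exons$name else consensus[[as_]]$name
    smp <- grid[grid$assay == as_, , drop = FALSE]
    cols <- paste(smp$animal, smp$tissue, sep = ".")
    mu <- rnorm(length(feat), cfg$profile_mu_log, 0.5)
    g <- matrix(rnorm(length(feat) * length(cols)), length(feat),
                dimnames = list(feat, cols))
    if (nrow(links) > 0) {
      a <- sqrt(cfg$r_true)
      if (as_ == "RNA") {
        hit <- links$exon_id %in% feat
        g[links$exon_id[hit], ] <- a * z[links$exon_id[hit], cols, drop = FALSE] +
          sqrt(1 - cfg$r_true) * g[links$exon_id[hit], , drop = FALSE]
      } else {
        lk <- links[links$assay == as_ & links$peak_id %in% feat, , drop = FALSE]
        if (nrow(lk) > 0) {
          g[lk$peak_id, ] <- a * z[lk$exon_id, cols, drop = FALSE] +
            sqrt(1 - cfg$r_true) * g[lk$peak_id, , drop = FALSE]
        }
      }
    }
    lambda <- exp(mu + cfg$profile_sigma * g)
    counts <- matrix(rpois(length(lambda), lambda), nrow = nrow(lambda),
                     dimnames = dimnames(g))
    count_matrices[[as_]] <- counts
  }

  ## truth tables
  frac_long <- do.call(rbind, lapply(names(frac), function(as_) {
    f <- frac[[as_]]
    data.frame(assay = as_,
               feature_id = rep(rownames(f), times = ncol(f)),
               tissue = rep(colnames(f), each = nrow(f)),
               maternal_fraction = as.vector(f),
               stringsAsFactors = FALSE)
  }))
  truth <- list(
    snp_phase = do.call(rbind, lapply(animals, function(an) {
      data.frame(variant_id = sites$variant_id, animal = an,
                 paternal = hap1[, an], maternal = hap2[, an],
                 stringsAsFactors = FALSE)
    })),
    feature_bias = do.call(rbind, truth_feat),
    feature_fractions = frac_long,
    links = links
  )
  rownames(truth$snp_phase) <- NULL
  rownames(truth$feature_bias) <- NULL

  out <- list(config = cfg, genome = genome, sites = sites,
              genotypes = genotypes, pedigree = cfg$pedigree,
              samples = grid, peak_beds = peak_beds, consensus = consensus,
              exons = exons, allele_counts = allele_counts,
              count_matrices = count_matrices, truth = truth)
  if (!is.null(dir)) out <- write_dataset(out, dir)
  out
}

#' Write a simulated dataset to disk in standard formats
#'
#' FASTA genome, VCF 4.2 with GT:AD for offspring (phased) and sires
#' (unphased), pedigree TSV, per-sample BED peak sets, GTF exon annotation,
#' allele-count TSV, per-assay count matrices, truth tables, and a
#' \code{manifest.yaml} indexing them for [run_pipeline()].
#'
#' @param sim Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return \code{sim} with \code{dir} and \code{manifest} components added.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- sim$config
  p <- function(...) file.path(dir, ...)

  Biostrings::writeXStringSet(sim$genome, p("genome.fa"))

  ## VCF
  samples <- c(cfg$animals, unique(cfg$pedigree$sire))
  sites <- sim$sites
  gt_cols <- vapply(samples, function(sm) {
    g <- sim$genotypes[sim$genotypes$sample == sm, , drop = FALSE]
    g <- g[match(sites$variant_id, g$variant_id), , drop = FALSE]
    sep <- ifelse(g$phased, "|", "/")
    idx <- function(a) ifelse(a == g$ref, "0", "1")
    gt <- ifelse(g$phased, paste0(idx(g$hap1), sep, idx(g$hap2)),
                 ifelse(g$zygosity == "hom_ref", "0/0",
                        ifelse(g$zygosity == "hom_alt", "1/1", "0/1")))
    paste0(gt, ":", g$ref_depth, ",", g$alt_depth)
  }, character(nrow(sites)))
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", names(sim$genome), ",length=",
           Biostrings::width(sim$genome), ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- paste(sites$chrom, sites$pos + 1L, sites$variant_id, sites$ref,
                sites$alt, ".", "PASS", ".", "GT:AD",
                apply(gt_cols, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), p("variants.vcf"))

  write.table(sim$pedigree, p("pedigree.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  ## peaks
  peaks_manifest <- list()
  for (as_ in names(sim$peak_beds)) {
    dir.create(p("peaks", as_), recursive = TRUE, showWarnings = FALSE)
    peaks_manifest[[as_]] <- list()
    for (sm in names(sim$peak_beds[[as_]])) {
      b <- sim$peak_beds[[as_]][[sm]]
      path <- p("peaks", as_, paste0(sm, ".bed"))
      write.table(cbind(b[, c("chrom", "start", "end", "name")], 0,
                        ifelse(b$strand == ".", ".", b$strand)),
                  path, sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = FALSE)
      peaks_manifest[[as_]][[sm]] <- file.path("peaks", as_, paste0(sm, ".bed"))
    }
  }

  ## exons as GTF (1-based closed)
  gtf <- paste(sim$exons$chrom, "sim", "exon", sim$exons$start + 1L,
               sim$exons$end, ".", sim$exons$strand, ".",
               paste0("gene_id \"", sim$exons$gene_id, "\"; exon_id \"",
                      sim$exons$name, "\";"),
               sep = "\t")
  writeLines(gtf, p("exons.gtf"))

  write.table(sim$allele_counts, p("allele_counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  dir.create(p("counts"), showWarnings = FALSE)
  counts_manifest <- list()
  for (as_ in names(sim$count_matrices)) {
    m <- sim$count_matrices[[as_]]
    df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, p("counts", paste0(as_, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
    counts_manifest[[as_]] <- file.path("counts", paste0(as_, ".tsv"))
  }

  dir.create(p("truth"), showWarnings = FALSE)
  for (nm in names(sim$truth)) {
    write.table(sim$truth[[nm]], p("truth", paste0(nm, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    genome = "genome.fa", vcf = "variants.vcf", pedigree = "pedigree.tsv",
    exons = "exons.gtf", allele_counts = "allele_counts.tsv",
    peaks = peaks_manifest, counts = counts_manifest,
    animals = cfg$animals, sires = unique(cfg$pedigree$sire),
    tissues = cfg$tissues, chip_assays = cfg$chip_assays,
    seed = cfg$seed
  )
  yaml::write_yaml(manifest, p("manifest.yaml"))
  sim$dir <- dir
  sim$manifest <- manifest
  sim
}

#' Simulate cross-tissue profile pairs with a known latent correlation
#'
#' Generates \code{n_pairs} (exon, peak) count-profile pairs over
#' \code{n_samples} shared samples from a shared latent factor so the
#' profiles correlate at \code{r_true} on the latent scale (the Poisson
#' count layer and log transform attenuate this slightly). Used to check
#' the calibration and recall of [correlate_pairs()].
#'
#' @param n_pairs Number of pairs.
#' @param n_samples Shared samples per pair (default 22).
#' @param r_true Latent correlation (0 for null pairs).
#' @param mu_log,sigma Feature baseline log-mean and profile spread.
#' @return list of \code{exon_cpm} and \code{peak_cpm} matrices (rows
#'   \code{pair<i>_exon} / \code{pair<i>_peak}) and a \code{pairs}
#'   data.frame for [correlate_pairs()].
#' @export
simulate_profile_pairs <- function(n_pairs, n_samples = 22, r_true = 0,
                                   mu_log = log(200), sigma = 0.5) {
  z <- matrix(rnorm(n_pairs * n_samples), n_pairs)
  gx <- matrix(rnorm(n_pairs * n_samples), n_pairs)
  gy <- matrix(rnorm(n_pairs * n_samples), n_pairs)
  a <- sqrt(r_true); b <- sqrt(1 - r_true)
  x <- a * z + b * gx
  y <- a * z + b * gy
  mux <- rnorm(n_pairs, mu_log, 0.5)
  muy <- rnorm(n_pairs, mu_log, 0.5)
  cols <- paste0("s", seq_len(n_samples))
  exon <- matrix(rpois(length(x), exp(mux + sigma * x)), n_pairs,
                 dimnames = list(paste0("pair", seq_len(n_pairs), "_exon"), cols))
  peak <- matrix(rpois(length(y), exp(muy + sigma * y)), n_pairs,
                 dimnames = list(paste0("pair", seq_len(n_pairs), "_peak"), cols))
  list(exon_cpm = cpm_normalize(exon), peak_cpm = cpm_normalize(peak),
       pairs = data.frame(exon_id = rownames(exon), peak_id = rownames(peak),
                          stringsAsFactors = FALSE))
}

#' Simulate linked peak-exon allele counts under a cis-coupling kappa
#'
#' For \code{n_links} peak-exon pairs and \code{n_samples} samples, each
#' peak's maternal fraction is drawn from Beta(\code{bias_shape},
#' \code{bias_shape}); the linked exon's fraction is
#' \code{kappa * peak + (1 - kappa) * independent draw}. Allele counts are
#' binomial at \code{coverage}. With \code{base}, the same peak/exon
#' fraction draws and binomial quantile noise are reused across calls, so a
#' sweep over \code{kappa} shares its random numbers and isolates the
#' coupling effect.
#'
#' @param n_links Number of peak-exon pairs.
#' @param n_samples Samples (tissues of one animal) per pair.
#' @param kappa Cis-coupling in \[0, 1\].
#' @param coverage Total allele counts per feature per sample.
#' @param bias_shape Beta shape for the fraction draws.
#' @param base Optional draws from a previous call (common random numbers).
#' @return list: \code{links} (all positive sign), \code{asb} and \code{ase}
#'   feature-count data.frames ready for [imbalance_test()], and
#'   \code{base} for reuse.
#' @export
simulate_linked_imbalance <- function(n_links, n_samples = 22, kappa = 0,
                                      coverage = 100, bias_shape = 2,
                                      base = NULL) {
  if (is.null(base)) {
    base <- list(
      fp = rbeta(n_links, bias_shape, bias_shape),
      fi = rbeta(n_links, bias_shape, bias_shape),
      u_peak = matrix(runif(n_links * n_samples), n_links),
      u_exon = matrix(runif(n_links * n_samples), n_links)
    )
  }
  fe <- kappa * base$fp + (1 - kappa) * base$fi
  peak_ids <- paste0("peak", seq_len(n_links))
  exon_ids <- paste0("exon", seq_len(n_links))
  samples_chip <- sample_key("a1", sprintf("t%02d", seq_len(n_samples)), "H3K27ac")
  samples_rna <- sample_key("a1", sprintf("t%02d", seq_len(n_samples)), "RNA")
  m_peak <- qbinom(base$u_peak, coverage, base$fp)
  m_exon <- qbinom(base$u_exon, coverage, fe)
  mk <- function(ids, m, samples) data.frame(
    feature_id = rep(ids, times = n_samples),
    sample = rep(samples, each = n_links),
    maternal = as.integer(m),
    paternal = as.integer(coverage - m),
    stringsAsFactors = FALSE
  )
  list(
    links = data.frame(exon_id = exon_ids, peak_id = peak_ids, r = 1,
                       p_value = 0, n = n_samples, sign = "positive",
                       stringsAsFactors = FALSE),
    asb = mk(peak_ids, m_peak, samples_chip),
    ase = mk(exon_ids, m_exon, samples_rna),
    base = base
  )
}

#' Direction concordance as a function of the cis-coupling kappa
#'
#' Runs [simulate_linked_imbalance()] plus [imbalance_test()] and
#' [direction_concordance()] at each \code{kappa}, with common random
#' numbers across the sweep. Under \code{kappa = 0} the expected
#' same-direction proportion is 50\%; under \code{kappa = 1} the exon
#' direction equals the peak direction up to binomial noise.
#'
#' @param kappas Vector of coupling values.
#' @param n_links,n_samples,coverage,bias_shape Passed through.
#' @param alpha Per-sample significance threshold for comparison
#'   (default 0.05).
#' @return data.frame: \code{kappa}, \code{n_compared},
#'   \code{prop_same_direction}, \code{se} — the Monte-Carlo standard error
#'   of the proportion, computed with links as clusters because the samples
#'   within a link share its true fractions.
#' @export
concordance_kappa_sweep <- function(kappas, n_links = 2000, n_samples = 22,
                                    coverage = 100, bias_shape = 2,
                                    alpha = 0.05) {
  base <- NULL
  rows <- lapply(kappas, function(k) {
    sim <- simulate_linked_imbalance(n_links, n_samples, kappa = k,
                                     coverage = coverage,
                                     bias_shape = bias_shape, base = base)
    base <<- sim$base
    asb <- imbalance_test(sim$asb, alpha = alpha)
    ase <- imbalance_test(sim$ase, alpha = alpha)
    con <- direction_concordance(sim$links, asb, ase, alpha = alpha)
    n <- sum(con$tally$n_compared)
    prop <- sum(con$tally$n_same_direction) / n
    # Monte-Carlo SE of the ratio estimator with links as clusters: the
    # samples within a link share its true fractions, so their indicators
    # are far from independent and the naive binomial SE would understate
    # the error several-fold
    s_i <- tapply(con$scatter$same_direction, con$scatter$peak_id, sum)
    n_i <- tapply(con$scatter$same_direction, con$scatter$peak_id, length)
    se <- sqrt(sum((s_i - prop * n_i)^2)) / n
    data.frame(kappa = k, n_compared = n, prop_same_direction = prop, se = se)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare pipeline output against generator truth
#'
#' Per assay, among tested feature-sample records: detection rate where the
#' generating maternal fraction differed from 0.5 (sensitivity), significant
#' rate where it was exactly 0.5 (empirical type-I error at the discovery
#' alpha), and the RMSE and bias of the estimated maternal fractions.
#'
#' @param imbalance data.frame of [imbalance_test()] results with an
#'   \code{assay} column.
#' @param truth The \code{truth} component of [simulate_dataset()] output.
#' @return data.frame with one row per assay.
#' @export
truth_evaluation <- function(imbalance, truth) {
  ks <- split_sample_key(imbalance$sample)
  key <- paste(imbalance$assay, imbalance$feature_id, ks$tissue)
  tkey <- paste(truth$feature_fractions$assay,
                truth$feature_fractions$feature_id,
                truth$feature_fractions$tissue)
  idx <- match(key, tkey)
  if (anyNA(idx)) stop("feature/tissue ids in results not present in truth")
  tf <- truth$feature_fractions$maternal_fraction[idx]
  rows <- lapply(split(seq_len(nrow(imbalance)), imbalance$assay), function(i) {
    biased <- abs(tf[i] - 0.5) > 1e-12
    data.frame(
      assay = imbalance$assay[i][1],
      n_tested = length(i),
      sensitivity = if (any(biased)) mean(imbalance$significant[i][biased])
                    else NA_real_,
      null_rejection_rate = if (any(!biased)) mean(imbalance$significant[i][!biased])
                            else NA_real_,
      fraction_rmse = sqrt(mean((imbalance$maternal_fraction[i] - tf[i])^2)),
      fraction_bias = mean(imbalance$maternal_fraction[i] - tf[i]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
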