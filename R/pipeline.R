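#' Pipeline configuration
#'
#' Collects the input location, output directory and every analysis
#' threshold. Inputs are located through the \code{manifest.yaml} that
#' [write_dataset()] emits (or an equivalent hand-written manifest for real
#' data laid out the same way).
#'
#' @param input_dir Directory containing \code{manifest.yaml} and the files
#'   it names.
#' @param out_dir Directory for stage outputs (created if needed).
#' @param discovery_alpha Per-sample ASB/ASE significance threshold
#'   (default 0.01).
#' @param homogeneity_alpha Threshold for flagging within-feature SNP
#'   heterogeneity (default 0.05).
#' @param heterogeneity_alpha Threshold for cross-tissue heterogeneity
#'   (default 0.05).
#' @param correlation_alpha Peak-exon correlation retention threshold
#'   (default 0.05).
#' @param concordance_alpha Per-sample threshold when comparing ASB and ASE
#'   directions (default 0.05).
#' @param min_count Minimum combined allele count per feature-sample
#'   (default 10).
#' @param window Peak-exon pairing half-window in bases (default 100000).
#' @param min_support Consensus-peak support (default 2).
#' @param do_mask Build the neutral-allele masked genome (default TRUE).
#' @return A list of class \code{"aseasb_pipeline_config"}.
#' @export
pipeline_config <- function(input_dir, out_dir,
                            discovery_alpha = 0.01,
                            homogeneity_alpha = 0.05,
                            heterogeneity_alpha = 0.05,
                            correlation_alpha = 0.05,
                            concordance_alpha = 0.05,
                            min_count = 10,
                            window = 1e5,
                            min_support = 2,
                            do_mask = TRUE) {
  cfg <- as.list(environment())
  for (a in grep("alpha$", names(cfg), value = TRUE)) {
    if (cfg[[a]] <= 0 || cfg[[a]] >= 1) stop(a, " must be in (0, 1)")
  }
  if (window <= 0) stop("window must be positive")
  class(cfg) <- "aseasb_pipeline_config"
  cfg
}

config_hash <- function(cfg) {
  # hash the analysis parameters only: where the inputs and outputs live
  # must not change what the results claim to be
  cfg <- unclass(cfg)
  cfg <- cfg[setdiff(names(cfg), c("input_dir", "out_dir"))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg[order(names(cfg))]), tmp)
  unname(tools::md5sum(tmp))
}

write_stage_table <- function(df, path, hash) {
  con <- file(path, "w")
  writeLines(paste0("# config_hash=", hash), con)
  close(con)
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- format(out[[j]], digits = 15, trim = TRUE)
  }
  suppressWarnings(
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE, append = TRUE)
  )
  invisible(path)
}

#' Run the full ASE/ASB analysis
#'
#' Executes the stages in analysis order: genome masking, parent-of-origin
#' assignment, SNP filtering, per-feature aggregation with the homogeneity
#' G-test, the minimum-count filter, per-sample imbalance tests, cross-tissue
#' heterogeneity, direction-sharing and significance summaries, consensus
#' peaks, CPM normalization, windowed peak-exon correlation, and direction
#' concordance. Each output TSV starts with a \code{# config_hash=} line so
#' any result file can be traced to the exact configuration; reruns with
#' identical inputs and config are byte-identical.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with all stage results plus \code{summary}
#'   (named numerics) and \code{out_dir}.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "aseasb_pipeline_config"))
  man_path <- file.path(cfg$input_dir, "manifest.yaml")
  if (!file.exists(man_path)) stop("missing input: ", man_path)
  man <- yaml::read_yaml(man_path)
  ip <- function(rel) file.path(cfg$input_dir, rel)
  for (f in c(man$genome, man$vcf, man$pedigree, man$exons, man$allele_counts)) {
    if (!file.exists(ip(f))) stop("missing input: ", ip(f))
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg)
  op <- function(...) file.path(cfg$out_dir, ...)
  filter_log <- list()

  ## genotypes, pedigree, parent of origin
  genotypes <- read_vcf_allele_depths(ip(man$vcf))
  pedigree <- read.delim(ip(man$pedigree), stringsAsFactors = FALSE)
  pedigree$dam[pedigree$dam %in% c("", "NA")] <- NA
  assignments <- assign_parent_of_origin(genotypes, pedigree)
  write_stage_table(assignments, op("assignments.tsv"), hash)
  rate <- classification_rate(assignments)
  filter_log$het_sites <- rate$n_het
  filter_log$assigned <- sum(assignments$assigned)
  filter_log$fallback_assigned <- sum(assignments$method == "phase_fallback")

  ## masked genome
  if (isTRUE(cfg$do_mask)) {
    mask <- build_masked_fasta(ip(man$genome), genotypes,
                               animals = man$animals,
                               out_fasta = op("masked_genome.fa"))
    write_stage_table(mask$plan, op("mask_plan.tsv"), hash)
    filter_log$masked_sites <- nrow(mask$plan)
  }

  ## consensus peaks per mark (from the per-sample BED files)
  consensus <- list()
  for (as_ in man$chip_assays) {
    beds <- lapply(man$peaks[[as_]], function(rel) read_intervals(ip(rel), "bed"))
    consensus[[as_]] <- call_consensus_peaks(beds, min_support = cfg$min_support)
    consensus[[as_]]$name <- paste0(as_, "_", consensus[[as_]]$name)
    write_stage_table(consensus[[as_]],
                      op(paste0("consensus_", as_, ".tsv")), hash)
  }
  exons <- read_intervals(ip(man$exons), "gtf-exon")

  ## maternal/paternal SNP counts per feature
  counts_raw <- read.delim(ip(man$allele_counts), stringsAsFactors = FALSE)
  zyg_key <- paste(genotypes$variant_id, genotypes$sample)
  counts_raw$zygosity <- genotypes$zygosity[
    match(paste(counts_raw$variant_id, counts_raw$animal), zyg_key)]
  amatch <- match(paste(counts_raw$variant_id, counts_raw$animal),
                  paste(assignments$variant_id, assignments$animal))
  counts_raw$maternal_allele <- assignments$maternal[amatch]
  vmatch <- match(counts_raw$variant_id, genotypes$variant_id)
  counts_raw$alt <- genotypes$alt[vmatch]
  counts_raw$chrom <- genotypes$chrom[vmatch]
  counts_raw$pos <- genotypes$pos[vmatch]
  unassigned <- is.na(counts_raw$maternal_allele)
  filter_log$count_rows <- nrow(counts_raw)
  filter_log$count_rows_unassigned <- sum(unassigned)
  counts_raw <- counts_raw[!unassigned, , drop = FALSE]
  mat_is_alt <- counts_raw$maternal_allele == counts_raw$alt
  counts_raw$maternal <- ifelse(mat_is_alt, counts_raw$alt_count,
                                counts_raw$ref_count)
  counts_raw$paternal <- ifelse(mat_is_alt, counts_raw$ref_count,
                                counts_raw$alt_count)
  counts_raw$sample <- sample_key(counts_raw$animal, counts_raw$tissue,
                                  counts_raw$assay)

  filtered <- filter_snp_counts(counts_raw)
  filter_log <- c(filter_log, as.list(attr(filtered, "tally")))

  snp_gr <- GenomicRanges::GRanges(
    filtered$chrom, IRanges::IRanges(filtered$pos + 1L, filtered$pos + 1L))
  assign_features <- function(rows_idx, feat) {
    hits <- GenomicRanges::findOverlaps(snp_gr[rows_idx],
                                        interval_to_granges(feat),
                                        ignore.strand = TRUE)
    data.frame(
      row = rows_idx[S4Vectors::queryHits(hits)],
      feature_id = feat$name[S4Vectors::subjectHits(hits)],
      stringsAsFactors = FALSE
    )
  }
  feature_counts <- list()
  for (as_ in c(man$chip_assays, "RNA")) {
    feat <- if (as_ == "RNA") exons else consensus[[as_]]
    idx <- which(filtered$assay == as_)
    if (length(idx) == 0 || nrow(feat) == 0) next
    fmap <- assign_features(idx, feat)
    snp_counts <- cbind(filtered[fmap$row, c("sample", "maternal", "paternal")],
                        feature_id = fmap$feature_id)
    agg <- aggregate_features(snp_counts)
    agg <- min_count_filter(agg, threshold = cfg$min_count)
    if (nrow(agg) > 0) {
      agg$assay <- as_
      feature_counts[[as_]] <- agg
    }
  }
  feature_counts <- do.call(rbind, feature_counts)
  rownames(feature_counts) <- NULL
  write_stage_table(feature_counts, op("feature_counts.tsv"), hash)
  filter_log$feature_sample_records <- nrow(feature_counts)
  filter_log$heterogeneous_features <-
    sum(feature_counts$homogeneity_p < cfg$homogeneity_alpha)

  ## imbalance tests + summaries
  imbalance <- imbalance_test(feature_counts, alpha = cfg$discovery_alpha)
  write_stage_table(imbalance, op("imbalance.tsv"), hash)
  sig_summary <- list()
  sharing <- list()
  tissue_het <- list()
  for (as_ in unique(imbalance$assay)) {
    sub <- imbalance[imbalance$assay == as_, , drop = FALSE]
    ss <- summarize_significance(sub)
    ss$per_feature$assay <- as_
    sig_summary[[as_]] <- ss$per_feature
    sh <- direction_sharing_profile(sub)
    if (nrow(sh$per_feature) > 0) {
      sh$per_feature$assay <- as_
      sharing[[as_]] <- sh$per_feature
    }
    th <- tissue_heterogeneity(sub)
    if (nrow(th) > 0) {
      th$assay <- as_
      tissue_het[[as_]] <- th
    }
  }
  sig_summary <- do.call(rbind, sig_summary); rownames(sig_summary) <- NULL
  sharing <- if (length(sharing) > 0) do.call(rbind, sharing) else NULL
  tissue_het <- do.call(rbind, tissue_het); rownames(tissue_het) <- NULL
  write_stage_table(sig_summary, op("significance_summary.tsv"), hash)
  if (!is.null(sharing)) {
    rownames(sharing) <- NULL
    write_stage_table(sharing, op("direction_sharing.tsv"), hash)
  }
  write_stage_table(tissue_het, op("tissue_heterogeneity.tsv"), hash)

  ## correlation and concordance
  cpms <- list()
  for (as_ in c(man$chip_assays, "RNA")) {
    tab <- read.delim(ip(man$counts[[as_]]), stringsAsFactors = FALSE,
                      check.names = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab$feature_id
    cpms[[as_]] <- cpm_normalize(m)
  }
  links_all <- list()
  concordance_all <- list()
  scatter_all <- list()
  for (as_ in man$chip_assays) {
    pairs <- window_pairs(exons, consensus[[as_]], window = cfg$window)
    links <- correlate_pairs(pairs, cpms[["RNA"]], cpms[[as_]],
                             alpha = cfg$correlation_alpha)
    if (nrow(links) > 0) links$assay <- as_
    attr_n <- attr(links, "n_tested")
    links_all[[as_]] <- links
    filter_log[[paste0("pairs_tested_", as_)]] <- attr_n
    con <- direction_concordance(
      links,
      imbalance[imbalance$assay == as_, , drop = FALSE],
      imbalance[imbalance$assay == "RNA", , drop = FALSE],
      alpha = cfg$concordance_alpha)
    con$tally$assay <- as_
    concordance_all[[as_]] <- con$tally
    if (nrow(con$scatter) > 0) {
      con$scatter$assay <- as_
      scatter_all[[as_]] <- con$scatter
    }
  }
  links <- do.call(rbind, links_all); rownames(links) <- NULL
  concordance <- do.call(rbind, concordance_all); rownames(concordance) <- NULL
  scatter <- if (length(scatter_all) > 0) do.call(rbind, scatter_all) else
    data.frame()
  rownames(scatter) <- NULL
  write_stage_table(links, op("links.tsv"), hash)
  write_stage_table(concordance, op("concordance.tsv"), hash)
  if (nrow(scatter) > 0) write_stage_table(scatter, op("scatter_pairs.tsv"), hash)

  ## summary
  sig_by_assay <- tapply(sig_summary$n_significant >= 1, sig_summary$assay, mean)
  summary <- c(
    het_sites = filter_log$het_sites,
    assigned = filter_log$assigned,
    fallback_assigned = filter_log$fallback_assigned,
    masked_sites = if (isTRUE(cfg$do_mask)) filter_log$masked_sites else NA,
    snp_count_rows = filter_log$count_rows,
    removed_homozygous = filter_log$homozygous,
    removed_monoallelic = filter_log$monoallelic,
    feature_sample_records = filter_log$feature_sample_records,
    heterogeneous_features = filter_log$heterogeneous_features,
    n_links = nrow(links),
    n_compared = sum(concordance$n_compared),
    n_same_direction = sum(concordance$n_same_direction),
    setNames(as.numeric(sig_by_assay),
             paste0("frac_significant_", names(sig_by_assay)))
  )
  summary_df <- data.frame(quantity = names(summary),
                           value = unname(unlist(summary)),
                           stringsAsFactors = FALSE)
  write_stage_table(summary_df, op("summary.tsv"), hash)

  invisible(list(
    config = cfg, config_hash = hash, assignments = assignments,
    consensus = consensus, exons = exons, feature_counts = feature_counts,
    imbalance = imbalance, significance_summary = sig_summary,
    direction_sharing = sharing, tissue_heterogeneity = tissue_het,
    links = links, concordance = concordance, scatter = scatter,
    filter_log = filter_log, summary = summary, out_dir = cfg$out_dir
  ))
}
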