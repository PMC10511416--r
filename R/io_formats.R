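#' Read per-sample genotypes and allele depths from a VCF
#'
#' Extracts, for every biallelic SNV record and every requested sample, the
#' genotype call and the per-allele read depths (the AD field). Multiallelic
#' records are skipped, not split: the downstream analysis contrasts exactly
#' two parental alleles.
#'
#' @param path Path to a VCF 4.x file with GT and AD per-sample fields.
#' @param sample_ids Character vector of samples to extract; default all
#'   samples in the file. A requested sample absent from the file is an error.
#'
#' @return A data.frame with one row per variant x sample:
#'   \code{variant_id}, \code{chrom}, \code{pos} (0-based), \code{ref},
#'   \code{alt}, \code{sample}, \code{ref_depth}, \code{alt_depth},
#'   \code{zygosity} (\code{"hom_ref"}, \code{"het"}, \code{"hom_alt"},
#'   \code{"missing"}), \code{phased} (logical), and \code{hap1}/\code{hap2}
#'   (the alleles on the two phased haplotypes, \code{NA} when unphased).
#'   The number of skipped non-biallelic-SNV records is attached as
#'   attribute \code{"n_skipped"}.
#' @export
read_vcf_allele_depths <- function(path, sample_ids = NULL) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- VariantAnnotation::readVcf(path)
  hdr_samples <- colnames(vcf)
  if (is.null(sample_ids)) sample_ids <- hdr_samples
  missing <- setdiff(sample_ids, hdr_samples)
  if (length(missing) > 0) {
    stop("sample(s) not present in VCF: ", paste(missing, collapse = ", "))
  }

  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  biallelic_snv <- lengths(altl) == 1L &
    nchar(ref) == 1L &
    vapply(altl, function(a) length(a) == 1L && nchar(as.character(a[1L])) == 1L,
           logical(1))
  n_skipped <- sum(!biallelic_snv)
  if (n_skipped > 0) {
    warning(n_skipped, " non-biallelic-SNV record(s) skipped")
  }
  vcf <- vcf[biallelic_snv, ]
  rr <- rr[biallelic_snv]
  n_var <- length(rr)

  gt <- VariantAnnotation::geno(vcf)$GT[, sample_ids, drop = FALSE]
  ad <- VariantAnnotation::geno(vcf)$AD[, sample_ids, drop = FALSE]

  variant_id <- rownames(vcf)
  if (is.null(variant_id)) {
    variant_id <- paste0(as.character(GenomeInfoDb::seqnames(rr)), ":",
                         BiocGenerics::start(rr))
  }
  ref <- as.character(rr$REF)
  alt <- vapply(rr$ALT, function(a) as.character(a[1L]), character(1))

  gt_vec <- as.vector(gt)
  ad_ref <- vapply(ad, function(x) {
    if (length(x) >= 1 && !is.na(x[1])) as.integer(x[1]) else NA_integer_
  }, integer(1))
  ad_alt <- vapply(ad, function(x) {
    if (length(x) >= 2 && !is.na(x[2])) as.integer(x[2]) else NA_integer_
  }, integer(1))

  # allele indices on the two haplotype slots; "." or malformed -> NA
  gt_clean <- gsub("\\|", "/", gt_vec)
  a1 <- suppressWarnings(as.integer(sub("/.*", "", gt_clean)))
  a2 <- suppressWarnings(as.integer(sub(".*/", "", gt_clean)))
  zyg <- rep("missing", length(gt_vec))
  ok <- !is.na(a1) & !is.na(a2)
  zyg[ok & a1 == 0 & a2 == 0] <- "hom_ref"
  zyg[ok & a1 != a2] <- "het"
  zyg[ok & a1 == 1 & a2 == 1] <- "hom_alt"
  phased <- grepl("\\|", gt_vec)

  allele_chr <- function(idx, refs, alts) {
    out <- rep(NA_character_, length(idx))
    out[!is.na(idx) & idx == 0L] <- refs[!is.na(idx) & idx == 0L]
    out[!is.na(idx) & idx == 1L] <- alts[!is.na(idx) & idx == 1L]
    out
  }
  ref_rep <- rep(ref, times = length(sample_ids))
  alt_rep <- rep(alt, times = length(sample_ids))

  out <- data.frame(
    variant_id = rep(variant_id, times = length(sample_ids)),
    chrom = rep(as.character(GenomeInfoDb::seqnames(rr)), times = length(sample_ids)),
    pos = rep(BiocGenerics::start(rr) - 1L, times = length(sample_ids)),
    ref = ref_rep,
    alt = alt_rep,
    sample = rep(sample_ids, each = n_var),
    ref_depth = ad_ref,
    alt_depth = ad_alt,
    zygosity = zyg,
    phased = phased,
    hap1 = ifelse(phased, allele_chr(a1, ref_rep, alt_rep), NA_character_),
    hap2 = ifelse(phased, allele_chr(a2, ref_rep, alt_rep), NA_character_),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Read genomic intervals from BED or GTF
#'
#' All intervals in this package are 0-based half-open, the BED convention;
#' GTF's 1-based closed coordinates are converted on the way in so that no
#' other module has to know which dialect a feature came from.
#'
#' @param path Path to the file.
#' @param dialect \code{"bed"} (coordinates used as-is) or \code{"gtf-exon"}
#'   (only records with feature type \code{exon} are kept; strand and, when
#'   present, \code{exon_id}/\code{gene_id} attributes are carried through).
#'
#' @return A data.frame with columns \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open), \code{strand} (\code{+}, \code{-} or \code{.}) and
#'   \code{name}.
#' @export
read_intervals <- function(path, dialect = c("bed", "gtf-exon")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("interval file not found: ", path)
  if (file.size(path) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), name = character(),
                      stringsAsFactors = FALSE))
  }
  if (dialect == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
  } else {
    gr <- rtracklayer::import(path, format = "GTF")
    gr <- gr[!is.na(gr$type) & gr$type == "exon"]
  }
  out <- granges_to_interval(gr)
  if (dialect == "gtf-exon") {
    nm <- if (!is.null(gr$exon_id)) gr$exon_id else gr$gene_id
    if (!is.null(nm)) out$name <- as.character(nm)
  } else if (!is.null(gr$name)) {
    out$name <- as.character(gr$name)
  }
  bad <- which(out$end <= out$start)
  if (length(bad) > 0) {
    stop("interval end <= start at record ", bad[1], " of ", path)
  }
  out
}

#' Convert between interval data.frames and GRanges
#'
#' The package stores coordinates 0-based half-open; \code{GRanges} is
#' 1-based closed. These two converters localize the shift so overlap
#' machinery can be used everywhere else without coordinate arithmetic.
#'
#' @param x Interval data.frame (\code{chrom}, \code{start}, \code{end},
#'   optional \code{strand}, \code{name}) or a \code{GRanges}.
#' @return \code{interval_to_granges}: a \code{GRanges};
#'   \code{granges_to_interval}: an interval data.frame.
#' @export
interval_to_granges <- function(x) {
  strand <- if ("strand" %in% names(x)) x$strand else "*"
  strand[strand == "."] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
  if ("name" %in% names(x)) names(gr) <- x$name
  gr
}

#' @rdname interval_to_granges
#' @export
granges_to_interval <- function(x) {
  strand <- as.character(BiocGenerics::strand(x))
  strand[strand == "*"] <- "."
  out <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(x)),
    start = BiocGenerics::start(x) - 1L,
    end = BiocGenerics::end(x),
    strand = strand,
    name = if (!is.null(names(x))) names(x) else
      paste0(as.character(GenomeInfoDb::seqnames(x)), ":",
             BiocGenerics::start(x) - 1L, "-", BiocGenerics::end(x)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Write and read tab-separated result tables
#'
#' All pipeline stages serialize results as TSV with a header row. Floats are
#' written with full precision (\code{format(..., digits = 15)}) so that a
#' write/read round trip preserves values to within double-precision noise.
#'
#' @param rows A data.frame whose rows share one schema.
#' @param path Output path.
#' @return \code{write_results_table} returns \code{path} invisibly;
#'   \code{read_results_table} returns the data.frame.
#' @export
write_results_table <- function(rows, path) {
  if (!is.data.frame(rows)) {
    stop("rows must be a data.frame with a single shared schema")
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("cannot write to ", path, ": directory missing")
  out <- rows
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- format(out[[j]], digits = 15, trim = TRUE)
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  if (!file.exists(path)) stop("results table not found: ", path)
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
             comment.char = "#")
}

#' Build a sample key string from its components
#'
#' A sample is the triple (animal, tissue, assay); replicate libraries of the
#' same triple are summed upstream, so the triple is unique in any table.
#'
#' @param animal,tissue,assay Character vectors, recycled to common length.
#' @return Character vector \code{"animal.tissue.assay"}.
#' @export
sample_key <- function(animal, tissue, assay) {
  paste(animal, tissue, assay, sep = ".")
}

#' Split sample keys back into their components
#' @param key Character vector produced by [sample_key()].
#' @return data.frame with columns \code{animal}, \code{tissue}, \code{assay}.
#' @export
split_sample_key <- function(key) {
  parts <- strsplit(key, ".", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad)) stop("malformed sample key: ", key[which(bad)[1]])
  data.frame(
    animal = vapply(parts, `[`, character(1), 1L),
    tissue = vapply(parts, `[`, character(1), 2L),
    assay = vapply(parts, `[`, character(1), 3L),
    stringsAsFactors = FALSE
  )
}

#' Known assay labels
#'
#' The five ChIP targets (four histone modifications and the transcription
#' factor CTCF) plus RNA for expression.
#' @return Character vector of assay names.
#' @export
assay_levels <- function() {
  c("RNA", "H3K4Me3", "H3K4Me1", "H3K27Me3", "H3K27ac", "CTCF")
}

#' @keywords internal
chip_assays <- function() setdiff(assay_levels(), "RNA")
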