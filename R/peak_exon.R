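#' Call consensus peaks supported by at least two samples
#'
#' A consensus peak is a maximal run of bases each covered by peaks from at
#' least \code{min_support} samples. Overlapping intervals within one sample
#' are merged first so a sample contributes at most one unit of support per
#' base. Peaks are called per assay: the caller passes the per-sample
#' interval sets of a single mark.
#'
#' @param sample_intervals Named list of interval data.frames (one per
#'   sample; columns \code{chrom}, \code{start}, \code{end}, 0-based
#'   half-open).
#' @param min_support Minimum number of samples covering a base (default 2).
#' @return Interval data.frame of consensus peaks, sorted and non-overlapping,
#'   with a \code{support} column giving the maximum per-base support inside
#'   each peak and \code{name} \code{"peak_<chrom>_<n>"}. Fewer than
#'   \code{min_support} input samples yields an empty result with a warning.
#' @export
call_consensus_peaks <- function(sample_intervals, min_support = 2) {
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), name = character(),
                      support = integer(), stringsAsFactors = FALSE)
  if (length(sample_intervals) < min_support) {
    warning("fewer than ", min_support, " samples: no consensus possible")
    return(empty)
  }
  per_sample <- lapply(sample_intervals, function(x) {
    GenomicRanges::reduce(interval_to_granges(x), ignore.strand = TRUE)
  })
  all_gr <- do.call(c, unname(per_sample))
  if (length(all_gr) == 0) return(empty)
  cov <- GenomicRanges::coverage(all_gr)
  sl <- IRanges::slice(cov, lower = min_support, rangesOnly = FALSE)
  res <- lapply(names(sl), function(chr) {
    v <- sl[[chr]]
    if (length(v) == 0) return(NULL)
    data.frame(
      chrom = chr,
      start = BiocGenerics::start(v) - 1L,
      end = BiocGenerics::end(v),
      strand = ".",
      support = as.integer(IRanges::viewMaxs(v)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  if (is.null(out)) return(empty)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$name <- paste0("peak_", out$chrom, "_",
                     stats::ave(seq_len(nrow(out)), out$chrom, FUN = seq_along))
  rownames(out) <- NULL
  out[, c("chrom", "start", "end", "strand", "name", "support")]
}

#' Counts-per-million normalization
#'
#' Each count is divided by its sample's library size (column total) and
#' multiplied by one million, so every column of the result sums to 1e6.
#' Plain CPM, no library-size rescaling factors.
#'
#' @param counts Numeric matrix, features x samples, non-negative.
#' @return Matrix of the same shape in counts per million.
#' @export
cpm_normalize <- function(counts) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  zero <- lib == 0
  if (any(zero)) {
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[zero], collapse = ", "))
  }
  sweep(counts, 2, lib, "/") * 1e6
}

#' Candidate peak-exon pairs within a stranded window
#'
#' The window is anchored at the exon's 5' end in transcript orientation
#' (interval start on the plus strand, last base on the minus strand) and
#' extends \code{window} bases both ways; a peak qualifies when any of its
#' bases falls inside the window on the same chromosome. Exons with unknown
#' strand are treated as plus-strand, with a warning.
#'
#' @param exons,peaks Interval data.frames with \code{name} columns.
#' @param window Half-width in bases (default 100000, i.e. 100 kb either
#'   side).
#' @return data.frame with \code{exon_id}, \code{peak_id}, \code{distance}
#'   (signed peak-start minus anchor).
#' @export
window_pairs <- function(exons, peaks, window = 1e5) {
  if (nrow(exons) == 0 || nrow(peaks) == 0) {
    return(data.frame(exon_id = character(), peak_id = character(),
                      distance = integer(), stringsAsFactors = FALSE))
  }
  strand <- exons$strand
  unknown <- !(strand %in% c("+", "-"))
  if (any(unknown)) {
    warning(sum(unknown), " exon(s) with unknown strand treated as '+'")
    strand[unknown] <- "+"
  }
  anchor <- ifelse(strand == "+", exons$start, exons$end - 1L)
  win <- GenomicRanges::GRanges(
    seqnames = exons$chrom,
    ranges = IRanges::IRanges(start = pmax(anchor - window, 0) + 1L,
                              end = anchor + window + 1L)
  )
  pk <- interval_to_granges(peaks)
  lev <- union(GenomeInfoDb::seqlevels(win), GenomeInfoDb::seqlevels(pk))
  GenomeInfoDb::seqlevels(win) <- lev
  GenomeInfoDb::seqlevels(pk) <- lev
  hits <- GenomicRanges::findOverlaps(win, pk, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  out <- data.frame(
    exon_id = exons$name[q],
    peak_id = peaks$name[s],
    distance = peaks$start[s] - anchor[q],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Cross-tissue Pearson correlation of peak height and exon expression
#'
#' For every candidate pair, the exon's CPM profile and the peak's CPM
#' profile are correlated across the samples shared between the two assays
#' (same animal and tissue measured in both). Pairs with fewer than
#' \code{min_samples} shared samples, or zero variance in either profile,
#' are skipped. The two-sided p-value comes from the t transform
#' \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}}.
#'
#' @param pairs data.frame from [window_pairs()].
#' @param exon_cpm,peak_cpm CPM matrices (rows named by feature, columns by
#'   \code{"animal.tissue"}).
#' @param alpha Retention threshold on the p-value (default 0.05).
#' @param min_samples Minimum shared samples (default 3).
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @return data.frame of retained links: \code{exon_id}, \code{peak_id},
#'   \code{r}, \code{p_value}, \code{n}, \code{sign} (\code{"positive"} /
#'   \code{"negative"}). The number of pairs tested is attached as attribute
#'   \code{"n_tested"}.
#' @export
correlate_pairs <- function(pairs, exon_cpm, peak_cpm, alpha = 0.05,
                            min_samples = 3, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  shared <- intersect(colnames(exon_cpm), colnames(peak_cpm))
  pairs <- pairs[pairs$exon_id %in% rownames(exon_cpm) &
                   pairs$peak_id %in% rownames(peak_cpm), , drop = FALSE]
  empty <- data.frame(exon_id = character(), peak_id = character(),
                      r = numeric(), p_value = numeric(), n = integer(),
                      sign = character(), stringsAsFactors = FALSE)
  if (length(shared) < min_samples || nrow(pairs) == 0) {
    attr(empty, "n_tested") <- 0L
    return(empty)
  }
  X <- exon_cpm[pairs$exon_id, shared, drop = FALSE]
  Y <- peak_cpm[pairs$peak_id, shared, drop = FALSE]
  if (method == "spearman") {
    X <- t(apply(X, 1, rank))
    Y <- t(apply(Y, 1, rank))
  }
  n <- length(shared)
  xc <- X - rowMeans(X)
  yc <- Y - rowMeans(Y)
  sx <- sqrt(rowSums(xc^2))
  sy <- sqrt(rowSums(yc^2))
  ok <- sx > 0 & sy > 0
  r <- rep(NA_real_, nrow(pairs))
  r[ok] <- rowSums(xc * yc)[ok] / (sx * sy)[ok]
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  keep <- ok & !is.na(p) & p < alpha
  out <- data.frame(
    exon_id = pairs$exon_id[keep],
    peak_id = pairs$peak_id[keep],
    r = r[keep],
    p_value = p[keep],
    n = rep.int(n, sum(keep)),
    sign = ifelse(r[keep] > 0, "positive", "negative"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_tested") <- sum(ok)
  out
}

#' Direction concordance of ASB and ASE in correlated peak-exon pairs
#'
#' The cis-regulation hypothesis predicts that, in a positively correlated
#' peak-exon pair, the parental allele favoured in the peak's binding is the
#' one favoured in the exon's expression within the same sample. For every
#' retained link and every animal-tissue where both the peak's ASB and the
#' exon's ASE are significant at \code{alpha}, the directions agree when the
#' two maternal fractions fall on the same side of 0.5 (exact ties are never
#' significant and so never compared).
#'
#' @param links data.frame from [correlate_pairs()] for one mark.
#' @param asb_results [imbalance_test()] output for that mark's peaks.
#' @param ase_results [imbalance_test()] output for exons.
#' @param alpha Per-sample significance threshold for both assays
#'   (default 0.05).
#' @return A list: \code{tally} (per correlation sign: links, compared
#'   sample-pairs, same-direction count and proportion) and \code{scatter}
#'   (one row per compared sample-pair: link ids, sample, peak and exon
#'   maternal fractions, sign, same_direction).
#' @export
direction_concordance <- function(links, asb_results, ase_results, alpha = 0.05) {
  asb <- asb_results[asb_results$p_value < alpha, , drop = FALSE]
  ase <- ase_results[ase_results$p_value < alpha, , drop = FALSE]
  asb_at <- split_sample_key(asb$sample)
  ase_at <- split_sample_key(ase$sample)
  asb$at <- paste(asb_at$animal, asb_at$tissue, sep = ".")
  ase$at <- paste(ase_at$animal, ase_at$tissue, sep = ".")

  scatter_parts <- list()
  if (nrow(links) > 0 && nrow(asb) > 0 && nrow(ase) > 0) {
    m_asb <- merge(links[, c("peak_id", "exon_id", "sign")],
                   asb[, c("feature_id", "at", "maternal_fraction")],
                   by.x = "peak_id", by.y = "feature_id")
    names(m_asb)[names(m_asb) == "maternal_fraction"] <- "peak_fraction"
    m <- merge(m_asb,
               ase[, c("feature_id", "at", "maternal_fraction")],
               by.x = c("exon_id", "at"), by.y = c("feature_id", "at"))
    names(m)[names(m) == "maternal_fraction"] <- "exon_fraction"
    if (nrow(m) > 0) {
      m$same_direction <- (m$peak_fraction - 0.5) * (m$exon_fraction - 0.5) > 0
      scatter_parts[[1]] <- m[, c("peak_id", "exon_id", "at", "sign",
                                  "peak_fraction", "exon_fraction",
                                  "same_direction")]
    }
  }
  scatter <- if (length(scatter_parts) > 0) scatter_parts[[1]] else
    data.frame(peak_id = character(), exon_id = character(), at = character(),
               sign = character(), peak_fraction = numeric(),
               exon_fraction = numeric(), same_direction = logical(),
               stringsAsFactors = FALSE)
  rownames(scatter) <- NULL

  tally <- do.call(rbind, lapply(c("positive", "negative"), function(sg) {
    sc <- scatter[scatter$sign == sg, , drop = FALSE]
    data.frame(
      sign = sg,
      n_links = sum(links$sign == sg),
      n_compared = nrow(sc),
      n_same_direction = sum(sc$same_direction),
      prop_same_direction = if (nrow(sc) > 0) mean(sc$same_direction) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  rownames(tally) <- NULL
  list(tally = tally, scatter = scatter)
}
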