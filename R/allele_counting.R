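#' Log-likelihood-ratio (G) test for an s x 2 table of allele counts
#'
#' Tests the null hypothesis that the maternal:paternal ratio is the same in
#' every row, where rows are SNPs within one feature (homogeneity before
#' combining) or tissues within one animal (tissue specificity). The
#' statistic is
#' \deqn{G = 2\left(\sum_{ij} n_{ij}\ln n_{ij} + n_{..}\ln n_{..}
#'   - \sum_j n_{.j}\ln n_{.j} - \sum_i n_{i.}\ln n_{i.}\right)}
#' with the convention \eqn{0 \ln 0 = 0}, referred to a chi-square
#' distribution on \eqn{s - 1} degrees of freedom. Rows whose total is zero
#' carry no information and are dropped (reducing \eqn{s}); a single
#' remaining row gives \eqn{G = 0}, \eqn{p = 1}.
#'
#' @param tab Numeric matrix with s rows and 2 columns of non-negative
#'   counts.
#' @return A list: \code{G}, \code{df}, \code{p_value}, and \code{s} (rows
#'   used after dropping empty ones).
#' @export
g_test <- function(tab) {
  tab <- as.matrix(tab)
  if (ncol(tab) != 2) stop("g_test expects an s x 2 table")
  if (any(tab < 0) || any(!is.finite(tab))) stop("counts must be finite and >= 0")
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  s <- nrow(tab)
  if (s <= 1) {
    return(list(G = 0, df = 0L, p_value = 1, s = s))
  }
  xlogx <- function(x) ifelse(x > 0, x * log(x), 0)
  n_i <- rowSums(tab)
  n_j <- colSums(tab)
  n_tot <- sum(tab)
  # proportional rows have G = 0 by definition; detect them exactly by
  # cross-multiplication (exact in doubles for any realistic counts) rather
  # than leaving floating-point dust from the entropy cancellation
  if (all(tab[, 1] * n_j[2] == tab[, 2] * n_j[1])) {
    return(list(G = 0, df = s - 1L,
                p_value = 1, s = s))
  }
  G <- 2 * (sum(xlogx(tab)) + xlogx(n_tot) - sum(xlogx(n_j)) - sum(xlogx(n_i)))
  G <- max(G, 0)  # guard against -eps from floating cancellation
  df <- s - 1L
  list(G = G, df = df, p_value = pchisq(G, df = df, lower.tail = FALSE), s = s)
}

#' Filter SNP-level allele counts before combining
#'
#' Removes the two classes of uninformative or suspect counts: SNPs
#' homozygous in the animal (no allelic contrast) and SNP-by-sample entries
#' where one allele has zero reads (monoallelic counts, which may be
#' genotyping errors rather than complete silencing).
#'
#' @param counts data.frame with at least \code{maternal}, \code{paternal}
#'   (integer counts) and \code{zygosity} columns; one row per SNP x sample.
#' @return The retained rows, with a \code{tally} attribute counting
#'   removals by reason (\code{homozygous}, \code{monoallelic}).
#' @export
filter_snp_counts <- function(counts) {
  hom <- counts$zygosity != "het"
  mono <- !hom & (counts$maternal == 0 | counts$paternal == 0)
  out <- counts[!hom & !mono, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tally") <- c(homozygous = sum(hom), monoallelic = sum(mono),
                          retained = nrow(out))
  out
}

#' Combine SNP counts into per-feature totals with a homogeneity check
#'
#' Within each feature x sample group, maternal counts are summed over the
#' contributing SNPs, as are paternal counts, and the s x 2 G-test of
#' [g_test()] records whether the SNPs agreed on the direction of bias.
#' Heterogeneous features are flagged (\code{homogeneity_p}), never dropped:
#' when SNPs within a feature disagree only slightly more often than chance,
#' combining remains the right default, and the flag lets a caller filter.
#'
#' @param counts data.frame with columns \code{feature_id}, \code{sample},
#'   \code{maternal}, \code{paternal}; one row per SNP x feature x sample.
#' @return data.frame with one row per feature x sample: \code{feature_id},
#'   \code{sample}, \code{maternal}, \code{paternal}, \code{n_snps},
#'   \code{homogeneity_G}, \code{homogeneity_p}.
#' @export
aggregate_features <- function(counts) {
  if (nrow(counts) == 0) {
    return(data.frame(feature_id = character(), sample = character(),
                      maternal = integer(), paternal = integer(),
                      n_snps = integer(), homogeneity_G = numeric(),
                      homogeneity_p = numeric(), stringsAsFactors = FALSE))
  }
  key <- paste(counts$feature_id, counts$sample, sep = "\r")
  idx <- split(seq_len(nrow(counts)), key)
  first <- vapply(idx, `[`, integer(1), 1L)
  mat <- vapply(idx, function(i) sum(counts$maternal[i]), numeric(1))
  pat <- vapply(idx, function(i) sum(counts$paternal[i]), numeric(1))
  gstat <- vapply(idx, function(i) {
    if (length(i) == 1) return(c(0, 1))
    g <- g_test(cbind(counts$maternal[i], counts$paternal[i]))
    c(g$G, g$p_value)
  }, numeric(2))
  out <- data.frame(
    feature_id = counts$feature_id[first],
    sample = counts$sample[first],
    maternal = as.integer(mat),
    paternal = as.integer(pat),
    n_snps = lengths(idx),
    homogeneity_G = gstat[1, ],
    homogeneity_p = gstat[2, ],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(out$feature_id, out$sample), , drop = FALSE]
}

#' Drop feature-sample records with too few allele counts
#'
#' Records whose combined maternal + paternal total is below the threshold
#' carry too little information for the 1:1 test; "less than" is strict, so
#' a total exactly at the threshold is retained.
#'
#' @param records data.frame with \code{maternal} and \code{paternal}.
#' @param threshold Minimum total count (default 10).
#' @return The retained rows.
#' @export
min_count_filter <- function(records, threshold = 10) {
  out <- records[records$maternal + records$paternal >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}
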