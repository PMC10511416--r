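#' Chi-square test of allele counts against a 1:1 ratio
#'
#' With \eqn{n = m + p} total counts the statistic is
#' \eqn{(m - n/2)^2/(n/2) + (p - n/2)^2/(n/2) = (m - p)^2/n}, referred to a
#' chi-square distribution on one degree of freedom, with no continuity
#' correction. Vectorized over features.
#'
#' @param maternal,paternal Non-negative integer vectors of allele counts.
#' @return data.frame with \code{statistic}, \code{p_value},
#'   \code{maternal_fraction}, and \code{direction} (\code{"maternal"},
#'   \code{"paternal"}, or \code{"tie"}).
#' @export
chisq_1to1 <- function(maternal, paternal) {
  n <- maternal + paternal
  if (any(n == 0)) stop("zero total count: apply min_count_filter first")
  stat <- (maternal - paternal)^2 / n
  data.frame(
    statistic = stat,
    p_value = pchisq(stat, df = 1, lower.tail = FALSE),
    maternal_fraction = maternal / n,
    direction = ifelse(maternal > paternal, "maternal",
                       ifelse(paternal > maternal, "paternal", "tie")),
    stringsAsFactors = FALSE
  )
}

#' Per-feature, per-sample allelic-imbalance calls
#'
#' Applies [chisq_1to1()] to combined feature counts and flags significance
#' at \code{alpha}. No multiple-testing correction is applied anywhere in
#' this package: thresholds are on raw p-values throughout, so significant
#' counts at any alpha include the corresponding false-positive load.
#'
#' @param feature_counts data.frame from [aggregate_features()] (after
#'   [min_count_filter()]), with \code{feature_id}, \code{sample},
#'   \code{maternal}, \code{paternal}.
#' @param alpha Significance threshold on the raw p-value (default 0.01).
#' @return \code{feature_counts} with \code{statistic}, \code{p_value},
#'   \code{maternal_fraction}, \code{direction}, \code{significant} added.
#' @export
imbalance_test <- function(feature_counts, alpha = 0.01) {
  res <- chisq_1to1(feature_counts$maternal, feature_counts$paternal)
  out <- cbind(feature_counts, res)
  out$significant <- out$p_value < alpha
  out
}

#' Cross-tissue heterogeneity of allelic bias per feature
#'
#' For each feature within each animal, the per-tissue maternal/paternal
#' totals form an s x 2 table (rows = tissues) tested with [g_test()]:
#' a small p-value means the maternal:paternal ratio genuinely differs
#' between tissues. Features measured in fewer than two tissues are
#' untestable and are omitted.
#'
#' @param feature_counts data.frame with \code{feature_id}, \code{sample},
#'   \code{maternal}, \code{paternal}; sample keys encode animal and tissue
#'   (see [sample_key()]).
#' @return data.frame with one row per feature x animal tested:
#'   \code{feature_id}, \code{animal}, \code{n_tissues}, \code{G}, \code{df},
#'   \code{p_value}.
#' @export
tissue_heterogeneity <- function(feature_counts) {
  ks <- split_sample_key(feature_counts$sample)
  key <- paste(feature_counts$feature_id, ks$animal, sep = "\r")
  idx <- split(seq_len(nrow(feature_counts)), key)
  idx <- idx[lengths(idx) >= 2]
  if (length(idx) == 0) {
    return(data.frame(feature_id = character(), animal = character(),
                      n_tissues = integer(), G = numeric(), df = integer(),
                      p_value = numeric(), stringsAsFactors = FALSE))
  }
  first <- vapply(idx, `[`, integer(1), 1L)
  res <- vapply(idx, function(i) {
    g <- g_test(cbind(feature_counts$maternal[i], feature_counts$paternal[i]))
    c(g$G, g$df, g$p_value)
  }, numeric(3))
  out <- data.frame(
    feature_id = feature_counts$feature_id[first],
    animal = ks$animal[first],
    n_tissues = lengths(idx),
    G = res[1, ],
    df = as.integer(res[2, ]),
    p_value = res[3, ],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(out$feature_id, out$animal), , drop = FALSE]
}

#' Direction sharing of single-tissue-significant features
#'
#' For features significant in exactly one tissue (within an animal), asks
#' how often the other tested tissues lean the same way, even without
#' reaching significance themselves. The per-feature sharing fraction —
#' other tissues with the significant tissue's direction over other tissues
#' with any direction (ties excluded from both sides) — is binned into
#' quintiles 0-20 through 80-100%.
#'
#' @param results data.frame from [imbalance_test()] for one assay.
#' @return A list: \code{per_feature} (feature, animal, sharing fraction,
#'   bin) and \code{histogram} (percentage of features per bin).
#' @export
direction_sharing_profile <- function(results) {
  ks <- split_sample_key(results$sample)
  key <- paste(results$feature_id, ks$animal, sep = "\r")
  idx <- split(seq_len(nrow(results)), key)
  idx <- idx[lengths(idx) >= 2]
  bins <- c("0-20", "20-40", "40-60", "60-80", "80-100")
  rows <- lapply(idx, function(i) {
    sig <- results$significant[i]
    if (sum(sig) != 1) return(NULL)
    lead <- i[sig]
    others <- i[!sig]
    dirs <- results$direction[others]
    informative <- dirs != "tie"
    if (!any(informative)) return(NULL)
    frac <- mean(dirs[informative] == results$direction[lead])
    data.frame(
      feature_id = results$feature_id[lead],
      animal = split_sample_key(results$sample[lead])$animal,
      sharing_fraction = frac,
      bin = bins[pmin(floor(frac * 5) + 1, 5)],
      stringsAsFactors = FALSE
    )
  })
  per_feature <- do.call(rbind, rows)
  if (is.null(per_feature)) {
    per_feature <- data.frame(feature_id = character(), animal = character(),
                              sharing_fraction = numeric(), bin = character(),
                              stringsAsFactors = FALSE)
  }
  rownames(per_feature) <- NULL
  counts <- table(factor(per_feature$bin, levels = bins))
  hist <- if (nrow(per_feature) > 0) 100 * as.numeric(counts) / nrow(per_feature)
          else rep(0, length(bins))
  list(per_feature = per_feature,
       histogram = setNames(hist, bins))
}

#' Per-feature significance summary across samples
#'
#' Counts, for every feature, how many samples it was testable in, how many
#' of those were significant, and in how many distinct tissues; the
#' distribution of "significant in K tissues" over features with K >= 1 is
#' how the tissue specificity of allelic bias is usually displayed.
#'
#' @param results data.frame from [imbalance_test()].
#' @return A list: \code{per_feature} (feature, n_tested, n_significant,
#'   n_tissues_significant) and \code{k_distribution}, the table of
#'   n_tissues_significant over features significant at least once.
#' @export
summarize_significance <- function(results) {
  ks <- split_sample_key(results$sample)
  idx <- split(seq_len(nrow(results)), results$feature_id)
  per_feature <- data.frame(
    feature_id = names(idx),
    n_tested = lengths(idx),
    n_significant = vapply(idx, function(i) sum(results$significant[i]), integer(1)),
    n_tissues_significant = vapply(idx, function(i) {
      length(unique(ks$tissue[i][results$significant[i]]))
    }, integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(per_feature) <- NULL
  sig <- per_feature[per_feature$n_significant >= 1, , drop = FALSE]
  list(per_feature = per_feature,
       k_distribution = table(sig$n_tissues_significant))
}
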