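# Independent brute-force oracles used across tests.

# G statistic in its textbook form 2 * sum O * ln(O / E), with expected
# counts from the row/column margins. Independent of the package's
# margin-entropy implementation.
g_oracle <- function(tab) {
  tab <- as.matrix(tab)
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (nrow(tab) <= 1) return(0)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  2 * sum(ifelse(tab > 0, tab * log(tab / E), 0))
}

# per-base consensus oracle: tabulate sample support base by base
consensus_oracle <- function(sample_intervals, min_support = 2, max_pos = 5000) {
  support <- integer(max_pos)
  for (iv in sample_intervals) {
    covered <- logical(max_pos)
    for (i in seq_len(nrow(iv))) {
      covered[(iv$start[i] + 1):iv$end[i]] <- TRUE
    }
    support <- support + covered
  }
  hit <- support >= min_support
  if (!any(hit)) {
    return(data.frame(start = integer(), end = integer()))
  }
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values] - 1L, end = ends[r$values])
}

# random single-chromosome interval sets for consensus property tests
random_interval_config <- function(n_samples, max_intervals = 50, max_pos = 2000) {
  lapply(seq_len(n_samples), function(i) {
    k <- sample.int(max_intervals, 1)
    start <- sample.int(max_pos - 10L, k, replace = TRUE) - 1L
    width <- sample.int(60L, k, replace = TRUE)
    data.frame(chrom = "chr1", start = start,
               end = pmin(start + width, max_pos), strand = ".",
               stringsAsFactors = FALSE)
  })
}

# write a small VCF with GT:AD for the given records
write_test_vcf <- function(path, records, samples) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=100000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(hdr, records), path)
  path
}
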