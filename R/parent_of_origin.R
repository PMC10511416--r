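#' Assign parent of origin to heterozygous offspring alleles
#'
#' At each heterozygous offspring site the two alleles are labelled maternal
#' and paternal using the pedigree:
#' \itemize{
#'   \item Sire homozygous: the sire's allele is paternal, the other
#'     maternal (the sire must have transmitted his only allele).
#'   \item Dam homozygous (where a dam genotype is available): the dam's
#'     allele is maternal. When both rules apply they must agree; a conflict
#'     leaves the site unassigned.
#'   \item Sire heterozygous and no dam information: fall back to phase
#'     linkage — the paternal allele sits on the same phased haplotype as the
#'     paternal allele of the nearest previous assigned SNP on the
#'     chromosome, assuming phasing is correct between the two sites. Sites
#'     with no previous anchor stay unassigned. Every direct (sire- or
#'     dam-homozygous) assignment re-anchors the haplotype side.
#' }
#'
#' @param genotypes data.frame as returned by [read_vcf_allele_depths()],
#'   covering offspring, sires and (optionally) dams, with phased
#'   \code{hap1}/\code{hap2} columns for the offspring.
#' @param pedigree data.frame with columns \code{offspring}, \code{sire} and
#'   optionally \code{dam} (\code{NA} when unknown).
#'
#' @return data.frame with one row per heterozygous offspring site:
#'   \code{variant_id}, \code{chrom}, \code{pos}, \code{animal},
#'   \code{paternal}, \code{maternal} (allele characters, \code{NA} when
#'   unassigned), \code{assigned}, and \code{method} (\code{"sire_hom"},
#'   \code{"dam_hom"}, \code{"phase_fallback"}, or the reason unassigned:
#'   \code{"no_anchor"}, \code{"conflict"}, \code{"sire_missing"},
#'   \code{"unphased"}).
#' @export
assign_parent_of_origin <- function(genotypes, pedigree) {
  if (!all(c("offspring", "sire") %in% names(pedigree))) {
    stop("pedigree needs columns offspring, sire")
  }
  if (!"dam" %in% names(pedigree)) pedigree$dam <- NA_character_

  res <- vector("list", nrow(pedigree))
  for (i in seq_len(nrow(pedigree))) {
    child <- pedigree$offspring[i]
    g_child <- genotypes[genotypes$sample == child & genotypes$zygosity == "het", ,
                         drop = FALSE]
    if (nrow(g_child) == 0) next
    g_child <- g_child[order(g_child$chrom, g_child$pos), , drop = FALSE]

    par_geno <- function(parent) {
      if (is.na(parent)) return(NULL)
      g <- genotypes[genotypes$sample == parent, c("variant_id", "zygosity", "ref", "alt")]
      g[match(g_child$variant_id, g$variant_id), , drop = FALSE]
    }
    g_sire <- par_geno(pedigree$sire[i])
    g_dam <- par_geno(pedigree$dam[i])

    hom_allele <- function(g) {
      if (is.null(g)) return(rep(NA_character_, nrow(g_child)))
      out <- rep(NA_character_, nrow(g_child))
      out[!is.na(g$zygosity) & g$zygosity == "hom_ref"] <-
        g$ref[!is.na(g$zygosity) & g$zygosity == "hom_ref"]
      out[!is.na(g$zygosity) & g$zygosity == "hom_alt"] <-
        g$alt[!is.na(g$zygosity) & g$zygosity == "hom_alt"]
      out
    }
    sire_allele <- hom_allele(g_sire)   # paternal when sire hom
    dam_allele <- hom_allele(g_dam)     # maternal when dam hom
    sire_missing <- if (is.null(g_sire)) rep(TRUE, nrow(g_child)) else
      is.na(g_sire$zygosity) | g_sire$zygosity == "missing"

    n <- nrow(g_child)
    paternal <- rep(NA_character_, n)
    maternal <- rep(NA_character_, n)
    method <- rep(NA_character_, n)
    other <- function(a, ref, alt) ifelse(a == ref, alt, ref)

    direct_pat <- sire_allele
    direct_mat_from_dam <- dam_allele
    for (k in seq_len(n)) {
      ref <- g_child$ref[k]; alt <- g_child$alt[k]
      pat <- NA_character_; mat <- NA_character_; meth <- NA_character_
      sp <- direct_pat[k]
      dm <- direct_mat_from_dam[k]
      if (!is.na(sp) && !is.na(dm)) {
        if (sp == other(dm, ref, alt)) {
          pat <- sp; mat <- dm; meth <- "sire_hom"
        } else meth <- "conflict"
      } else if (!is.na(sp)) {
        pat <- sp; mat <- other(sp, ref, alt); meth <- "sire_hom"
      } else if (!is.na(dm)) {
        mat <- dm; pat <- other(dm, ref, alt); meth <- "dam_hom"
      } else if (sire_missing[k]) {
        meth <- "sire_missing"
      }
      paternal[k] <- pat; maternal[k] <- mat; method[k] <- meth
    }

    # phase-linkage fallback, per chromosome in position order: carry the
    # haplotype side (1 or 2) of the last direct assignment forward
    for (chr in unique(g_child$chrom)) {
      side <- NA_integer_
      for (k in which(g_child$chrom == chr)) {
        if (!is.na(paternal[k])) {
          # direct assignment re-anchors the paternal haplotype side
          side <- if (isTRUE(g_child$phased[k]) && !is.na(g_child$hap1[k])) {
            if (g_child$hap1[k] == paternal[k]) 1L else 2L
          } else NA_integer_
        } else if (is.na(method[k])) {
          # sire het (no dam information): phase linkage to the last anchor
          if (!isTRUE(g_child$phased[k]) || is.na(g_child$hap1[k])) {
            method[k] <- "unphased"
          } else if (is.na(side)) {
            method[k] <- "no_anchor"
          } else {
            pat <- if (side == 1L) g_child$hap1[k] else g_child$hap2[k]
            paternal[k] <- pat
            maternal[k] <- other(pat, g_child$ref[k], g_child$alt[k])
            method[k] <- "phase_fallback"
          }
        }
        # conflict / sire_missing sites keep their method and do not move side
      }
    }

    res[[i]] <- data.frame(
      variant_id = g_child$variant_id, chrom = g_child$chrom,
      pos = g_child$pos, animal = child,
      paternal = paternal, maternal = maternal,
      assigned = !is.na(paternal), method = method,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  if (is.null(out) || nrow(out) == 0) stop("nothing to classify: no heterozygous offspring sites")
  rownames(out) <- NULL
  out
}

#' Summarize parent-of-origin assignment rates
#'
#' @param assignments data.frame from [assign_parent_of_origin()].
#' @return A list: \code{n_het} sites considered, \code{frac_assigned}, and
#'   \code{frac_fallback} — the fraction of het sites assigned through the
#'   previous-SNP phase linkage rather than a homozygous parent.
#' @export
classification_rate <- function(assignments) {
  if (nrow(assignments) == 0) stop("nothing to classify")
  list(
    n_het = nrow(assignments),
    frac_assigned = mean(assignments$assigned),
    frac_fallback = mean(assignments$method == "phase_fallback")
  )
}
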