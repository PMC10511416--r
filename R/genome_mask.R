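#' Pick the neutral substitution allele for a masked reference
#'
#' Reads carrying either real allele of a heterozygous SNP map equally badly
#' to a third, "neutral" base, so neither allele is favoured at alignment.
#' The base is the first member of the fixed order C, G, T, A that is not
#' among the observed alleles (so an A/T site is masked to C), which makes
#' the choice deterministic.
#'
#' @param alleles Character vector of 2 or 3 distinct bases from A, C, G, T.
#' @return A single base not in \code{alleles}.
#' @export
choose_neutral_allele <- function(alleles) {
  alleles <- toupper(unique(as.character(alleles)))
  if (!all(alleles %in% c("A", "C", "G", "T"))) {
    stop("alleles must be from {A, C, G, T}, got: ",
         paste(alleles, collapse = ","))
  }
  if (length(alleles) < 2 || length(alleles) > 3) {
    stop("need 2 or 3 observed alleles; no neutral base exists for ",
         length(alleles))
  }
  setdiff(c("C", "G", "T", "A"), alleles)[1]
}

#' Mask heterozygous sites in a reference genome with a neutral allele
#'
#' Every site that is heterozygous in at least one of the listed animals is
#' replaced by [choose_neutral_allele()] of its observed alleles; all other
#' bases are untouched. Sequences are held in the uppercase DNA alphabet of
#' \pkg{Biostrings}, so repeat soft-masking case is not carried through.
#'
#' @param reference A \code{Biostrings::DNAStringSet} or path to a FASTA file.
#' @param variants data.frame with columns \code{chrom}, \code{pos} (0-based),
#'   \code{ref}, \code{alt}, and per-animal zygosity in long form: columns
#'   \code{sample} and \code{zygosity} as returned by
#'   [read_vcf_allele_depths()].
#' @param animals Character vector of animals whose heterozygous sites define
#'   the mask (typically all sequenced animals).
#' @param out_fasta Optional path; when given the masked genome is written
#'   there as FASTA.
#'
#' @return A list with \code{masked} (a \code{DNAStringSet}) and \code{plan},
#'   a data.frame with one row per substituted site: \code{chrom}, \code{pos}
#'   (0-based), \code{original}, \code{alleles} (comma-joined observed
#'   alleles) and \code{neutral}.
#' @export
build_masked_fasta <- function(reference, variants, animals, out_fasta = NULL) {
  seqs <- if (inherits(reference, "DNAStringSet")) reference else
    Biostrings::readDNAStringSet(reference)
  names(seqs) <- sub("\\s.*", "", names(seqs))

  het <- variants[variants$sample %in% animals &
                    variants$zygosity == "het", , drop = FALSE]
  sites <- unique(het[, c("chrom", "pos", "ref", "alt")])
  if (nrow(sites) == 0) {
    plan <- data.frame(chrom = character(), pos = integer(),
                       original = character(), alleles = character(),
                       neutral = character(), stringsAsFactors = FALSE)
    if (!is.null(out_fasta)) Biostrings::writeXStringSet(seqs, out_fasta)
    return(list(masked = seqs, plan = plan))
  }
  if (anyDuplicated(sites[, c("chrom", "pos")])) {
    stop("conflicting ref/alt records at the same position")
  }
  missing_chr <- setdiff(unique(sites$chrom), names(seqs))
  if (length(missing_chr) > 0) {
    stop("variant chromosome(s) absent from FASTA: ",
         paste(missing_chr, collapse = ", "))
  }

  plan_list <- vector("list", length(unique(sites$chrom)))
  names(plan_list) <- unique(sites$chrom)
  for (chr in unique(sites$chrom)) {
    s <- sites[sites$chrom == chr, , drop = FALSE]
    s <- s[order(s$pos), , drop = FALSE]
    if (any(s$pos < 0 | s$pos >= length(seqs[[chr]]))) {
      stop("variant position outside ", chr, " bounds")
    }
    fasta_base <- as.character(
      Biostrings::extractAt(seqs[[chr]],
                            IRanges::IRanges(s$pos + 1L, s$pos + 1L)))
    mism <- toupper(fasta_base) != toupper(s$ref)
    if (any(mism)) {
      i <- which(mism)[1]
      stop("ref allele mismatch at ", chr, ":", s$pos[i], " (FASTA ",
           fasta_base[i], ", VCF ", s$ref[i], ")")
    }
    sub_base <- mapply(function(r, a) choose_neutral_allele(c(r, a)),
                       s$ref, s$alt, USE.NAMES = FALSE)
    seqs[[chr]] <- Biostrings::replaceLetterAt(
      seqs[[chr]], s$pos + 1L, paste(sub_base, collapse = ""))
    plan_list[[chr]] <- data.frame(
      chrom = chr, pos = s$pos, original = fasta_base,
      alleles = paste(s$ref, s$alt, sep = ","), neutral = sub_base,
      stringsAsFactors = FALSE
    )
  }
  plan <- do.call(rbind, plan_list)
  rownames(plan) <- NULL
  if (!is.null(out_fasta)) Biostrings::writeXStringSet(seqs, out_fasta)
  list(masked = seqs, plan = plan)
}

#' Apply or reverse a mask plan
#'
#' Re-applies the substitutions recorded by [build_masked_fasta()] to a
#' genome, or, with \code{reverse = TRUE}, restores the original bases — a
#' masked genome plus its plan is byte-equivalent to the unmasked input.
#'
#' @param seqs A \code{DNAStringSet}.
#' @param plan Mask-plan data.frame from [build_masked_fasta()].
#' @param reverse Restore originals instead of applying neutrals.
#' @return The edited \code{DNAStringSet}.
#' @export
apply_mask_plan <- function(seqs, plan, reverse = FALSE) {
  for (chr in unique(plan$chrom)) {
    p <- plan[plan$chrom == chr, , drop = FALSE]
    p <- p[order(p$pos), , drop = FALSE]
    letters <- if (reverse) p$original else p$neutral
    seqs[[chr]] <- Biostrings::replaceLetterAt(
      seqs[[chr]], p$pos + 1L, paste(letters, collapse = ""))
  }
  seqs
}
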