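#' Standard genetic code with synonymous-family structure
#'
#' Builds the codon machinery used throughout the package: the 61 sense
#' codons of the standard genetic code, their amino acids, and the partition
#' of codons into synonymous families.  Two partitions are supported:
#'
#' * the classic degeneracy partition used by the effective number of codons
#'   (one family per amino acid; Leu/Ser/Arg are single sixfold families);
#' * the split partition in which each sixfold amino acid is divided into its
#'   fourfold and twofold subfamilies (used for preferred/unpreferred codon
#'   designation and per-family bias reports).
#'
#' Met and Trp are singleton families; they carry no synonymous choice and
#' are excluded from all bias computations.
#'
#' @param split_sixfold logical; if `TRUE`, Leu, Ser and Arg are split into a
#'   fourfold and a twofold subfamily (21 multi-codon families), otherwise
#'   they are kept whole (18 multi-codon families).
#' @return An object of class `genetic_code`: a list with elements
#'   `codons` (character vector of the 61 sense codons), `aa` (named map
#'   codon -> one-letter amino acid), `families` (list of family records,
#'   each with `name`, `aa`, `codons`, `k` = family size, and `enc_class`,
#'   the degeneracy class 2/3/4/6 used by ENC), and `family_of` (named map
#'   codon -> family name; singletons map to `NA`).
#' @examples
#' gc <- genetic_code()
#' length(gc$codons)              # 61
#' length(genetic_code(TRUE)$families)  # 21 multi-codon families
#' @export
genetic_code <- function(split_sixfold = FALSE) {
  key <- if (split_sixfold) "split" else "whole"
  if (!is.null(.gc_cache[[key]])) return(.gc_cache[[key]])

  tab <- Biostrings::GENETIC_CODE
  codons <- sort(names(tab)[tab != "*"])
  aa <- tab[codons]
  stopifnot(length(codons) == 61L)

  fams <- list()
  for (a in sort(unique(aa))) {
    cods <- codons[aa == a]
    if (length(cods) == 1L) next  # Met, Trp
    if (split_sixfold && length(cods) == 6L) {
      # subfamilies share their first two bases; the size-4 group is the
      # fourfold subfamily, the size-2 group the twofold subfamily
      pre <- substr(cods, 1L, 2L)
      for (p in unique(pre)) {
        sub <- cods[pre == p]
        fams[[length(fams) + 1L]] <- list(
          name = paste0(a, length(sub), "_", p),
          aa = a, codons = sub, k = length(sub), enc_class = length(sub))
      }
    } else {
      fams[[length(fams) + 1L]] <- list(
        name = a, aa = a, codons = cods, k = length(cods),
        enc_class = length(cods))
    }
  }
  names(fams) <- vapply(fams, `[[`, "", "name")

  family_of <- stats::setNames(rep(NA_character_, 61L), codons)
  for (f in fams) family_of[f$codons] <- f$name

  gc <- structure(
    list(codons = codons, aa = aa, families = fams, family_of = family_of,
         split_sixfold = split_sixfold),
    class = "genetic_code")
  .gc_cache[[key]] <- gc
  gc
}

.gc_cache <- new.env(parent = emptyenv())

#' @export
print.genetic_code <- function(x, ...) {
  cat("Standard genetic code: 61 sense codons,",
      length(x$families), "multi-codon families",
      if (x$split_sixfold) "(sixfold split 4+2)" else "(sixfold whole)",
      "\n")
  invisible(x)
}

# reverse complement for plain character vectors of DNA
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# split an in-frame sequence into codons
split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3")
  if (n == 0L) return(character(0))
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

is_stop_codon <- function(codon) codon %in% c("TAA", "TAG", "TGA")
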