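#' Designate preferred and unpreferred codons per synonymous family
#'
#' Within each synonymous family (sixfold amino acids split into their
#' fourfold and twofold subfamilies), the most frequently used codon
#' genome-wide is "preferred" and the least frequently used codon
#' "unpreferred".  Ties are broken lexicographically with a warning.
#'
#' @param counts genome-wide `codon_counts` (pooled over genes).
#' @param code a [genetic_code]; defaults to the sixfold-split partition.
#' @return Object of class `preference_map`: data frame with one row per
#'   family (`family`, `preferred`, `unpreferred`, `n_preferred`,
#'   `n_unpreferred`).  Families with zero total count are excluded.
#' @export
designate_preferences <- function(counts,
                                  code = genetic_code(split_sixfold = TRUE)) {
  rows <- lapply(code$families, function(f) {
    cts <- counts$counts[f$codons]
    if (sum(cts) == 0L) return(NULL)
    ord <- order(-cts, names(cts))  # lexicographic tie-break (max side)
    ord_min <- order(cts, names(cts))
    if (sum(cts == max(cts)) > 1L || sum(cts == min(cts)) > 1L) {
      warning("tie in codon usage for family '", f$name,
              "'; broken lexicographically")
    }
    pref <- names(cts)[ord[1L]]
    unpref_cand <- setdiff(names(cts)[ord_min], pref)
    unpref <- unpref_cand[1L]
    data.frame(family = f$name, preferred = pref, unpreferred = unpref,
               n_preferred = cts[[pref]], n_unpreferred = cts[[unpref]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- out$family
  class(out) <- c("preference_map", "data.frame")
  out
}

#' Polarize a site against two outgroups
#'
#' Assigns ancestral and derived states to a segregating or fixed site by
#' comparison with two outgroup genomes.  The ancestral state is the shared
#' outgroup base; it must equal one of the ingroup alleles when the site is
#' polymorphic.  Sites where the outgroups disagree, or that are triallelic
#' in the ingroup, are excluded (`NULL`).
#'
#' @param ingroup_alleles character vector of distinct bases segregating in
#'   the ingroup sample (length 1 = monomorphic, length 2 = biallelic).
#' @param outgroup1,outgroup2 single outgroup bases.
#' @return List with `status` (`"polymorphic"` or `"fixed"`), `ancestral`
#'   and `derived` bases, or `NULL` when the site is excluded.
#' @export
polarize_site <- function(ingroup_alleles, outgroup1, outgroup2) {
  ingroup_alleles <- unique(ingroup_alleles)
  if (length(ingroup_alleles) > 2L) return(NULL)       # triallelic
  if (!identical(outgroup1, outgroup2)) return(NULL)   # outgroups disagree
  anc <- outgroup1
  if (!anc %in% c("A", "C", "G", "T")) return(NULL)
  if (length(ingroup_alleles) == 2L) {
    if (!anc %in% ingroup_alleles) return(NULL)
    list(status = "polymorphic", ancestral = anc,
         derived = setdiff(ingroup_alleles, anc))
  } else {
    if (ingroup_alleles == anc) return(NULL)           # invariant site
    list(status = "fixed", ancestral = anc, derived = ingroup_alleles)
  }
}

#' Classify a codon change as preferred/unpreferred-directional
#'
#' A change counts as `"unpref_to_pref"` only when the ancestral codon is
#' its family's single unpreferred codon and the derived codon the family's
#' single preferred codon (and `"pref_to_unpref"` for the reverse).  All
#' other changes - synonymous changes between middle-ranked codons,
#' changes across families, nonsynonymous changes - are `"other"` and never
#' enter the 2x2 table.
#'
#' @param ancestral,derived codon strings.
#' @param prefs a `preference_map`.
#' @param code the split-partition [genetic_code] used to build `prefs`.
#' @return `"unpref_to_pref"`, `"pref_to_unpref"`, or `"other"`.
#' @export
classify_direction <- function(ancestral, derived, prefs,
                               code = genetic_code(split_sixfold = TRUE)) {
  fa <- code$family_of[ancestral]
  fd <- code$family_of[derived]
  if (is.na(fa) || is.na(fd) || fa != fd) return("other")
  if (!fa %in% rownames(prefs)) return("other")
  row <- prefs[fa, ]
  if (ancestral == row$unpreferred && derived == row$preferred) {
    "unpref_to_pref"
  } else if (ancestral == row$preferred && derived == row$unpreferred) {
    "pref_to_unpref"
  } else "other"
}

#' Build imaginary-codon sites from an intron
#'
#' Forces each retained intronic variant site into the third position of an
#' "imaginary codon" formed with the two immediately preceding bases in
#' coding orientation, giving a selection-free null to which the exonic
#' preferred/unpreferred machinery can be applied unchanged.  Sites within
#' `boundary_exclusion` bp of either intron end are excluded, as are sites
#' without two preceding bases of context.  Minus-strand introns are
#' reverse complemented (with site offsets remapped) before construction.
#'
#' @param intron intron sequence in genome orientation.
#' @param offsets 0-based site offsets within the intron, genome
#'   orientation.
#' @param strand `"+"` or `"-"` (strand of the gene).
#' @param boundary_exclusion minimum distance (bp) from either intron end.
#' @return Data frame with one row per retained site: `offset` (coding
#'   orientation), `codon` (imaginary ancestral-context codon built from
#'   the intron sequence), `quintet` (site +/- 2 bases, coding
#'   orientation).
#' @export
build_intron_sites <- function(intron, offsets, strand = "+",
                               boundary_exclusion = 20L) {
  len <- nchar(intron)
  if (identical(strand, "-")) {
    intron <- revcomp(intron)
    offsets <- len - 1L - offsets
  }
  keep <- offsets >= boundary_exclusion &
    (len - 1L - offsets) >= boundary_exclusion &
    offsets >= 2L & offsets <= len - 3L
  offsets <- sort(offsets[keep])
  if (!length(offsets)) {
    return(data.frame(offset = integer(0), codon = character(0),
                      quintet = character(0), stringsAsFactors = FALSE))
  }
  codon <- substring(intron, offsets - 1L, offsets + 1L)
  quintet <- substring(intron, offsets - 1L, offsets + 3L)
  data.frame(offset = offsets, codon = codon, quintet = quintet,
             stringsAsFactors = FALSE)
}

#' Flag sites that may be mis-polarized by CpG hypermutation
#'
#' Two independent CpG deaminations on the outgroup lineages can make a
#' conserved ingroup state look derived.  On the quintet centred on the
#' varying third position (bases b1..b5, coding orientation), the two
#' suspect patterns are: outgroup consensus `..TG.` with ingroup-derived
#' `..CG.` (deamination on the coding strand), and outgroup `.CA..` with
#' ingroup-derived `.CG..` (deamination on the opposite strand).
#'
#' @param outgroup_quintet,derived_quintet 5-base strings; position 3 is
#'   the varying base.
#' @return Logical flag.
#' @export
cpg_suspect <- function(outgroup_quintet, derived_quintet) {
  o <- strsplit(outgroup_quintet, "")[[1]]
  d <- strsplit(derived_quintet, "")[[1]]
  stopifnot(length(o) == 5L, length(d) == 5L)
  p1 <- o[3] == "T" && o[4] == "G" && d[3] == "C" && d[4] == "G"
  p2 <- o[2] == "C" && o[3] == "A" && d[2] == "C" && d[3] == "G"
  p1 || p2
}

#' Yates-corrected chi-square for a 2x2 table
#'
#' Pearson chi-square with (by default) the Yates continuity correction,
#' df = 1.  Cells are given row-wise: `(a, b)` = first row, `(c, d)` =
#' second row.
#'
#' @param a,b,c,d nonnegative cell counts.
#' @param continuity apply the continuity correction.
#' @return List with `chi2` and `p` (upper tail, df = 1); both `NA` when a
#'   marginal total is zero.
#' @export
chi2_2x2 <- function(a, b, c, d, continuity = TRUE) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    return(list(chi2 = NA_real_, p = NA_real_))
  }
  dev <- abs(a * d - b * c)
  if (continuity) dev <- max(0, dev - n / 2)
  chi2 <- n * dev^2 / (r1 * r2 * c1 * c2)
  list(chi2 = chi2, p = stats::pchisq(chi2, 1L, lower.tail = FALSE))
}

#' Polarized McDonald-Kreitman table for codon preference
#'
#' Cross-tabulates direction class (preferred-to-unpreferred vs
#' unpreferred-to-preferred) against status (polymorphic vs fixed) over a
#' set of polarized sites, and tests independence with a Yates-corrected
#' chi-square.  Sites with direction `"other"` never enter the table; with
#' `cpg_filter = TRUE`, CpG-suspect sites are dropped before counting.
#'
#' @param sites data frame with columns `direction`
#'   (`"pref_to_unpref"` / `"unpref_to_pref"` / `"other"`), `status`
#'   (`"polymorphic"` / `"fixed"`), and `cpg_suspect` (logical).
#' @param cpg_filter drop CpG-suspect sites first.
#' @return Object of class `mk_table`: list with the 2x2 `counts` matrix
#'   (rows pref_to_unpref / unpref_to_pref, columns polymorphic / fixed),
#'   `prop_fixed` per row, `chi2`, `p`, `n`, and `chi2_per_1000` =
#'   1000 * chi2 / n.
#' @export
mk_table <- function(sites, cpg_filter = FALSE) {
  if (cpg_filter) sites <- sites[!sites$cpg_suspect, , drop = FALSE]
  sites <- sites[sites$direction %in%
                   c("pref_to_unpref", "unpref_to_pref"), , drop = FALSE]
  counts <- table(factor(sites$direction,
                         levels = c("pref_to_unpref", "unpref_to_pref")),
                  factor(sites$status,
                         levels = c("polymorphic", "fixed")))
  counts <- matrix(as.numeric(counts), 2L, 2L,
                   dimnames = list(c("pref_to_unpref", "unpref_to_pref"),
                                   c("polymorphic", "fixed")))
  mk_table_from_counts(counts)
}

#' Build an `mk_table` directly from four cell counts
#'
#' @param counts 2x2 numeric matrix, rows = direction (pref_to_unpref,
#'   unpref_to_pref), columns = status (polymorphic, fixed).
#' @param continuity apply the Yates correction.
#' @return An `mk_table` (see [mk_table]).
#' @export
mk_table_from_counts <- function(counts, continuity = TRUE) {
  stopifnot(identical(dim(counts), c(2L, 2L)))
  if (is.null(dimnames(counts))) {
    dimnames(counts) <- list(c("pref_to_unpref", "unpref_to_pref"),
                             c("polymorphic", "fixed"))
  }
  n <- sum(counts)
  test <- chi2_2x2(counts[1, 1], counts[1, 2], counts[2, 1], counts[2, 2],
                   continuity = continuity)
  prop_fixed <- counts[, "fixed"] / rowSums(counts)
  structure(list(counts = counts, prop_fixed = prop_fixed,
                 chi2 = test$chi2, p = test$p, n = n,
                 chi2_per_1000 = if (n > 0) 1000 * test$chi2 / n else NA_real_),
            class = "mk_table")
}

#' @export
print.mk_table <- function(x, ...) {
  print(x$counts)
  cat(sprintf("P(fixed) = %.2f / %.2f; chi2 = %.2f, p = %.3g, chi2/N x1000 = %.2f\n",
              x$prop_fixed[1], x$prop_fixed[2], x$chi2, x$p,
              x$chi2_per_1000))
  invisible(x)
}

#' Run the polarized MK classification over a site table
#'
#' Applies [polarize_site], [classify_direction] and [cpg_suspect] to a raw
#' site table (one row per variant site with ingroup alleles, outgroup
#' states and codon/quintet context) and returns the annotated site table
#' ready for [mk_table].
#'
#' @param raw data frame with columns `region` (`"exon"`/`"intron"`),
#'   `allele1`, `allele2` (`allele2` `NA` when monomorphic), `outgroup1`,
#'   `outgroup2`, `context2` (the two bases preceding the varying third
#'   position, coding orientation), `quintet_flank` (4-character string:
#'   bases b1, b2, b4, b5 of the quintet).
#' @param prefs a `preference_map`.
#' @param code the split-partition [genetic_code].
#' @return Data frame of polarized sites with columns `region`, `status`,
#'   `ancestral_codon`, `derived_codon`, `direction`, `cpg_suspect`;
#'   excluded sites are dropped.
#' @export
polarize_sites <- function(raw, prefs,
                           code = genetic_code(split_sixfold = TRUE)) {
  acgt <- c("A", "C", "G", "T")
  poly <- !is.na(raw$allele2)
  agree <- raw$outgroup1 == raw$outgroup2 & raw$outgroup1 %in% acgt
  anc <- raw$outgroup1
  der <- ifelse(poly,
                ifelse(raw$allele1 == anc, raw$allele2, raw$allele1),
                raw$allele1)
  keep <- agree &
    ifelse(poly,
           anc == raw$allele1 | anc == raw$allele2,  # anc segregates
           raw$allele1 != anc)                       # true fixed difference
  keep[is.na(keep)] <- FALSE
  raw <- raw[keep, , drop = FALSE]
  anc <- anc[keep]; der <- der[keep]; poly <- poly[keep]

  anc_codon <- paste0(raw$context2, anc)
  der_codon <- paste0(raw$context2, der)
  fam_a <- code$family_of[anc_codon]
  fam_d <- code$family_of[der_codon]
  pref_of <- stats::setNames(prefs$preferred, prefs$family)
  unpref_of <- stats::setNames(prefs$unpreferred, prefs$family)
  same <- !is.na(fam_a) & !is.na(fam_d) & fam_a == fam_d &
    fam_a %in% prefs$family
  direction <- rep("other", nrow(raw))
  direction[same & anc_codon == unpref_of[fam_a] &
              der_codon == pref_of[fam_a]] <- "unpref_to_pref"
  direction[same & anc_codon == pref_of[fam_a] &
              der_codon == unpref_of[fam_a]] <- "pref_to_unpref"

  b2 <- substr(raw$quintet_flank, 2L, 2L)
  b4 <- substr(raw$quintet_flank, 3L, 3L)
  cpg <- (anc == "T" & b4 == "G" & der == "C") |
    (b2 == "C" & anc == "A" & der == "G")

  data.frame(region = raw$region,
             status = ifelse(poly, "polymorphic", "fixed"),
             ancestral_codon = anc_codon, derived_codon = der_codon,
             direction = direction, cpg_suspect = cpg,
             stringsAsFactors = FALSE, row.names = NULL)
}
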