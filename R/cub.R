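#' Background base composition from flanks or introns
#'
#' Estimates the local mutational background (A/C/G/T frequencies) of a gene
#' from either its flanking sequence (up to 2 kb per side, 4 kb total) or
#' its concatenated introns.  Ambiguous bases are excluded from both
#' numerator and denominator.  Genes with fewer than `min_intron_bases`
#' intronic bases are dropped from the intron-background analysis (returns
#' `NULL` with a warning).
#'
#' @param record a [transcript_record].
#' @param source `"flank"` or `"introns"`.
#' @param min_intron_bases minimum intronic bases for the intron source.
#' @return Object of class `background_composition` (list with `freqs`, a
#'   named A/C/G/T frequency vector summing to 1, `source`, and `bases`),
#'   or `NULL` when the gene is dropped.
#' @export
background_composition <- function(record, source = c("flank", "introns"),
                                   min_intron_bases = 1000L) {
  source <- match.arg(source)
  seqs <- if (source == "flank") {
    c(record$flank_up, record$flank_down)
  } else {
    record$introns
  }
  counts <- base_counts(paste(seqs, collapse = ""))
  total <- sum(counts)
  if (source == "introns" && total < min_intron_bases) {
    warning("gene '", record$gene_id, "' has ", total,
            " intronic bases (< ", min_intron_bases,
            "); dropped from intron-background analysis")
    return(NULL)
  }
  if (total == 0L) stop("no background sequence available for gene '",
                        record$gene_id, "'")
  structure(list(freqs = counts / total, source = source, bases = total),
            class = "background_composition")
}

base_counts <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  tab <- table(factor(ch, levels = c("A", "C", "G", "T")))
  stats::setNames(as.numeric(tab), c("A", "C", "G", "T"))
}

#' Uniform background composition
#'
#' Convenience constructor for the equal-frequency background under which
#' ENCp reduces to ENC.
#' @return A `background_composition` with all four frequencies 0.25.
#' @export
uniform_background <- function() {
  structure(list(freqs = stats::setNames(rep(0.25, 4), c("A", "C", "G", "T")),
                 source = "uniform", bases = 0L),
            class = "background_composition")
}

# per-family usage statistics: n_a, observed within-family frequencies,
# homozygosity estimate F-hat = (n * sum(p^2) - 1) / (n - 1)
family_usage <- function(counts, code) {
  lapply(code$families, function(f) {
    cts <- counts$counts[f$codons]
    n <- sum(cts)
    p <- if (n > 0L) cts / n else rep(NA_real_, length(cts))
    fhat <- if (n >= 2L) (n * sum(p^2) - 1) / (n - 1) else NA_real_
    list(name = f$name, k = f$k, enc_class = f$enc_class, n = n, p = p,
         fhat = fhat)
  })
}

# combine per-family homozygosities into the effective-number-of-codons
# scale: ENC = 2 + 9/Fbar2 + 1/Fbar3 + 5/Fbar4 + 3/Fbar6, with class
# weights taken from the code's family partition and a missing threefold
# class imputed as the mean of the two- and fourfold class means
combine_enc <- function(fhat, enc_class, code) {
  weights <- table(vapply(code$families, `[[`, 0L, "enc_class"))
  usable <- is.finite(fhat) & fhat > 0
  fbar <- vapply(c(2, 3, 4, 6), function(k) {
    v <- fhat[usable & enc_class == k]
    if (length(v)) mean(v) else NA_real_
  }, 0)
  names(fbar) <- c("2", "3", "4", "6")
  if (is.na(fbar["3"]) && !is.na(fbar["2"]) && !is.na(fbar["4"])) {
    fbar["3"] <- mean(c(fbar["2"], fbar["4"]))
  }
  if (anyNA(fbar) || any(fbar <= 0)) return(NA_real_)
  2 + sum(as.numeric(weights[names(fbar)]) / fbar)
}

cap_enc <- function(raw) {
  if (is.na(raw)) return(structure(NA_real_, raw = NA_real_))
  structure(min(61, max(20, raw)), raw = raw)
}

#' Effective number of codons (ENC)
#'
#' Wright's ENC from per-family homozygosities
#' \eqn{\hat F_a = (n_a \sum_i p_i^2 - 1)/(n_a - 1)}, combined as
#' \eqn{ENC = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6}.
#' Families with fewer than two codons observed are excluded from their
#' class mean; an absent threefold class mean is imputed as the average of
#' the two- and fourfold means.  The value is capped to \[20, 61\]; the
#' uncapped value is kept in the `"raw"` attribute.  Returns `NA` when a
#' degeneracy class has no usable family and no imputation path.
#'
#' @param counts a `codon_counts` object (see [count_codons]).
#' @param code a [genetic_code] (sixfold families kept whole).
#' @return Numeric ENC in \[20, 61\] with attribute `raw`.
#' @export
enc <- function(counts, code = genetic_code()) {
  fu <- family_usage(counts, code)
  cap_enc(combine_enc(vapply(fu, `[[`, 0, "fhat"),
                      vapply(fu, `[[`, 0L, "enc_class"), code))
}

#' Expected within-family codon frequencies from background composition
#'
#' Under mutation alone, a codon's expected frequency within its synonymous
#' family is proportional to the product of the background frequencies of
#' its three bases, normalized within the family.
#'
#' @param code a [genetic_code].
#' @param background a `background_composition`.
#' @return Named list: per family, a named numeric vector of expected
#'   frequencies summing to 1.  Families in which every codon has expected
#'   frequency zero are returned as `NULL` with a warning.
#' @export
expected_family_frequencies <- function(code, background) {
  bg <- background$freqs
  out <- lapply(code$families, function(f) {
    e <- vapply(f$codons, function(cod) {
      prod(bg[strsplit(cod, "")[[1]]])
    }, 0)
    if (sum(e) == 0) {
      warning("family '", f$name,
              "' excluded: all expected frequencies are zero")
      return(NULL)
    }
    e / sum(e)
  })
  out
}

# background-corrected per-family statistics: Pearson chi-square of observed
# vs expected usage and the corrected homozygosity
# F'_a = (chi2_a + n_a - k_a) / (k_a (n_a - 1))
family_usage_corrected <- function(counts, background, code) {
  fu <- family_usage(counts, code)
  ef <- expected_family_frequencies(code, background)
  for (nm in names(fu)) {
    f <- fu[[nm]]
    e <- ef[[nm]]
    if (is.null(e) || f$n < 2L) {
      fu[[nm]]$chi2 <- NA_real_
      fu[[nm]]$fhat_prime <- NA_real_
      next
    }
    chi2 <- f$n * sum((f$p - e)^2 / e)
    fu[[nm]]$e <- e
    fu[[nm]]$chi2 <- chi2
    fu[[nm]]$fhat_prime <- (chi2 + f$n - f$k) / (f$k * (f$n - 1))
  }
  fu
}

#' Background-corrected effective number of codons (ENCp)
#'
#' ENCp replaces each family's homozygosity with a corrected estimate built
#' from the Pearson chi-square of observed versus expected codon usage,
#' \eqn{\hat F'_a = (\chi^2_a + n_a - k_a)/(k_a (n_a - 1))} with
#' \eqn{\chi^2_a = n_a \sum_i (p_i - e_i)^2 / e_i}, so that mutational bias
#' captured by the background composition does not register as codon bias.
#' With a uniform background ENCp equals ENC.
#'
#' @param counts a `codon_counts` object.
#' @param background a `background_composition`.
#' @param code a [genetic_code].
#' @param gene_id optional identifier carried into the result.
#' @return Object of class `enc_result`: list with `gene_id`, `enc`,
#'   `enc_raw`, `encp`, `encp_raw`, per-family `fhat` and `fhat_prime`,
#'   and the pooled significance fields `chi2`, `df`, `p` (see
#'   [encp_significance]).
#' @export
encp <- function(counts, background, code = genetic_code(),
                 gene_id = NA_character_) {
  fu <- family_usage_corrected(counts, background, code)
  enc_class <- vapply(fu, `[[`, 0L, "enc_class")
  enc_v <- cap_enc(combine_enc(vapply(fu, `[[`, 0, "fhat"), enc_class, code))
  encp_v <- cap_enc(combine_enc(vapply(fu, `[[`, 0, "fhat_prime"),
                                enc_class, code))
  sig <- pooled_significance(fu)
  structure(list(gene_id = gene_id,
                 enc = as.numeric(enc_v), enc_raw = attr(enc_v, "raw"),
                 encp = as.numeric(encp_v), encp_raw = attr(encp_v, "raw"),
                 fhat = vapply(fu, `[[`, 0, "fhat"),
                 fhat_prime = vapply(fu, `[[`, 0, "fhat_prime"),
                 chi2 = sig$chi2, df = sig$df, p = sig$p),
            class = "enc_result")
}

#' @export
print.enc_result <- function(x, ...) {
  cat(sprintf("<ENC = %.2f, ENCp = %.2f, chi2 = %.2f (df %d), p = %.3g>\n",
              x$enc, x$encp, x$chi2, x$df, x$p))
  invisible(x)
}

# pool per-family Pearson chi-squares over families passing the
# small-expectation guard (every e_i * n_a >= 1)
pooled_significance <- function(fu) {
  chi2 <- 0
  df <- 0L
  for (f in fu) {
    if (is.na(f$chi2) || is.null(f$e)) next
    if (min(f$e) * f$n < 1) next
    chi2 <- chi2 + f$chi2
    df <- df + (f$k - 1L)
  }
  if (df == 0L) return(list(chi2 = NA_real_, df = 0L, p = NA_real_))
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Chi-square significance of observed versus expected codon usage
#'
#' Pools the per-family Pearson chi-squares of observed versus
#' background-expected codon usage over all families in which every
#' expected count \eqn{e_i n_a} is at least 1, with
#' \eqn{df = \sum_a (k_a - 1)}.
#'
#' @inheritParams encp
#' @return List with `chi2`, `df`, `p` (upper tail).  `p` is `NA` when no
#'   family passes the guard.
#' @export
encp_significance <- function(counts, background, code = genetic_code()) {
  pooled_significance(family_usage_corrected(counts, background, code))
}

#' Benjamini-Hochberg significance flags
#'
#' Standard step-up false-discovery-rate control across genes.
#'
#' @param p numeric vector of p-values.
#' @param alpha FDR level.
#' @return Logical vector (significant after correction), with the BH
#'   adjusted p-values in attribute `"q"`.
#' @export
bh_correct <- function(p, alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  q <- stats::p.adjust(p, method = "BH")
  structure(!is.na(q) & q <= alpha, q = q)
}

#' Average a per-gene statistic across transcript-choice iterations
#'
#' The random transcript choice is repeated (five times by default in the
#' pipeline) and the per-gene statistic is averaged across iterations; genes
#' absent from some iterations are averaged over the iterations in which
#' they appear (with a warning).
#'
#' @param iterations list of named numeric vectors (gene -> value), one per
#'   iteration.
#' @return Named numeric vector of per-gene means.
#' @export
aggregate_transcript_choices <- function(iterations) {
  stopifnot(length(iterations) >= 1L)
  genes <- unique(unlist(lapply(iterations, names)))
  m <- vapply(iterations,
              function(v) unname(v[genes]), numeric(length(genes)))
  m <- matrix(m, nrow = length(genes),
              dimnames = list(genes, NULL))
  if (anyNA(m)) {
    warning(sum(!stats::complete.cases(m)),
            " gene(s) missing from some iterations; ",
            "averaged over available iterations")
  }
  rowMeans(m, na.rm = TRUE)
}

#' Family-restricted background-corrected bias
#'
#' Per-family analogue of ENCp: the effective number of codons used within
#' one synonymous family, \eqn{1 / \hat F'_a} (the inverse corrected
#' homozygosity: \eqn{k_a} under uniform usage, 1 under single-codon
#' usage), capped to the feasible range \[1, k_a\].  Reported per family
#' per gene (sixfold amino acids split into their fourfold and twofold
#' subfamilies).
#'
#' @param counts a `codon_counts` object.
#' @param background a `background_composition`.
#' @param family family name in the sixfold-split partition (see
#'   [genetic_code]).
#' @param code a [genetic_code]; defaults to the split partition.
#' @return Numeric in \[1, k_a\], or `NA` when the family has fewer than
#'   two observed codons.
#' @export
per_family_encp <- function(counts, background, family,
                            code = genetic_code(split_sixfold = TRUE)) {
  fu <- family_usage_corrected(counts, background, code)
  if (!family %in% names(fu)) stop("unknown family '", family, "'")
  f <- fu[[family]]
  if (f$n < 2L || is.na(f$fhat_prime)) return(NA_real_)
  if (f$fhat_prime <= 0) return(f$k)
  min(f$k, max(1, 1 / f$fhat_prime))
}
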