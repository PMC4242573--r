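write_tsv <- function(df, path) {
  if (is.null(path)) return(invisible(NULL))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Per-gene ENC/ENCp report
#'
#' Runs the codon-usage stage over a set of transcripts: codon counts,
#' background composition (flanks or introns), ENC, ENCp, the pooled
#' chi-square significance of observed versus expected usage, and
#' Benjamini-Hochberg correction across genes.
#'
#' @param records list of [transcript_record]s (one per gene).
#' @param background_source `"flank"` or `"introns"`.
#' @param alpha FDR level.
#' @param min_codons minimum codon count per gene.
#' @param out optional TSV path.
#' @return List with `table` (per-gene data frame: `gene_id`, `n_codons`,
#'   `enc`, `encp`, `chi2`, `df`, `p`, `q_bh`, `significant`,
#'   `background_source`) and `frac_significant`.
#' @export
run_enc <- function(records, background_source = "flank", alpha = 0.05,
                    min_codons = 100L, out = NULL) {
  if (length(records) == 0L) stop("input error: no transcripts supplied")
  records <- Filter(function(r) filter_min_codons(r, min_codons), records)
  if (length(records) == 0L) {
    stop("input error: no transcript passes the ", min_codons,
         "-codon minimum")
  }
  rows <- lapply(records, function(r) {
    bg <- background_composition(r, background_source)
    if (is.null(bg)) return(NULL)
    res <- encp(count_codons(r$cds), bg, gene_id = r$gene_id)
    data.frame(gene_id = r$gene_id, n_codons = nchar(r$cds) %/% 3L,
               enc = res$enc, encp = res$encp, chi2 = res$chi2,
               df = res$df, p = res$p,
               background_source = background_source,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(tab) <- NULL
  sig <- bh_correct(tab$p, alpha)
  tab$q_bh <- attr(sig, "q")
  tab$significant <- as.logical(sig)
  write_tsv(tab, out)
  list(table = tab, frac_significant = mean(tab$significant, na.rm = TRUE))
}

#' Polarized MK report (exon + intron, before/after CpG filtering)
#'
#' Designates preferred/unpreferred codons from genome-wide usage,
#' polarizes the raw site table against the two outgroups, and builds the
#' four MK tables: exon and intron regions, each before and after removing
#' CpG-suspect sites.
#'
#' @param records list of [transcript_record]s (genome-wide codon usage for
#'   preference designation).
#' @param raw_sites raw site table (see [polarize_sites] and
#'   [gen_polymorphism_divergence]).
#' @param out optional TSV path for the shaped report.
#' @return List with `prefs`, the annotated `sites`, `tables` (named list
#'   of `mk_table`s: `exon`, `exon_cpg`, `intron`, `intron_cpg`) and the
#'   shaped data frame `report`.
#' @export
run_mk <- function(records, raw_sites, out = NULL) {
  total <- count_codons(paste(vapply(records, `[[`, "", "cds"),
                              collapse = ""))
  prefs <- designate_preferences(total)
  sites <- polarize_sites(raw_sites, prefs)
  tables <- list()
  report <- list()
  for (region in c("exon", "intron")) {
    sub <- sites[sites$region == region, , drop = FALSE]
    for (filt in c(FALSE, TRUE)) {
      tab <- mk_table(sub, cpg_filter = filt)
      key <- paste0(region, if (filt) "_cpg" else "")
      tables[[key]] <- tab
      report[[key]] <- data.frame(
        region = region, cpg_filter = filt,
        p2u_poly = tab$counts[1, 1], p2u_fixed = tab$counts[1, 2],
        u2p_poly = tab$counts[2, 1], u2p_fixed = tab$counts[2, 2],
        prop_fixed_p2u = tab$prop_fixed[1],
        prop_fixed_u2p = tab$prop_fixed[2],
        chi2 = tab$chi2, p = tab$p, chi2_per_1000 = tab$chi2_per_1000,
        stringsAsFactors = FALSE)
    }
  }
  report <- do.call(rbind, report)
  rownames(report) <- NULL
  write_tsv(report, out)
  list(prefs = prefs, sites = sites, tables = tables, report = report)
}

#' Per-gene FMutSel0/FMutSel LRT and |Ne s| report
#'
#' Fits both codon models to each pairwise alignment, performs the df = 41
#' likelihood-ratio test with BH correction across genes, and summarizes
#' |Ne s| from the FMutSel fitness estimates.
#'
#' @param alignments named list; each element a named character vector of
#'   two aligned in-frame sequences (or a 61x61 codon-pair count matrix).
#' @param starts,seed,max_iter passed to [fit_codon_model]; the FMutSel fit
#'   is warm-started from the FMutSel0 fit.
#' @param alpha FDR level.
#' @param out optional TSV path.
#' @return List with `table` (per-gene: `gene`, `logL0`, `logL1`, `lrt`,
#'   `p`, `q_bh`, `significant`, `kappa`, `median_abs_nes`,
#'   `median_abs_nes_unweighted`, `convergence`) and `frac_significant`.
#' @export
run_models <- function(alignments, starts = 2L, seed = 1L, max_iter = 300L,
                       alpha = 0.05, out = NULL) {
  rows <- lapply(seq_along(alignments), function(k) {
    aln <- alignments[[k]]
    N <- if (is.character(aln)) codon_pair_counts(aln[[1]], aln[[2]]) else aln
    fit0 <- fit_codon_model(N, "FMutSel0", starts = starts,
                            seed = seed + k, max_iter = max_iter)
    fit1 <- fit_codon_model(N, "FMutSel", starts = starts,
                            seed = seed + k, max_iter = max_iter,
                            init = fit0)
    test <- lrt(fit0, fit1)
    usage <- rowSums(N) + colSums(N)
    names(usage) <- rownames(N)
    nes <- nes_summary(fit1, usage)
    data.frame(gene = names(alignments)[k] %||% paste0("aln", k),
               logL0 = fit0$logL, logL1 = fit1$logL,
               lrt = test$statistic, p = test$p, kappa = fit1$kappa,
               median_abs_nes = nes$median_weighted,
               median_abs_nes_unweighted = nes$median_unweighted,
               convergence = fit0$convergence + fit1$convergence,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  sig <- bh_correct(tab$p, alpha)
  tab$q_bh <- attr(sig, "q")
  tab$significant <- as.logical(sig)
  write_tsv(tab, out)
  list(table = tab, frac_significant = mean(tab$significant))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Phylogenetic comparative report
#'
#' PGLS of a response trait on a predictor across the tips of a phylogeny,
#' the independent-contrast sign test, ancestral-state estimates, and
#' (optionally) the compartment ANCOVA over a per-gene table.
#'
#' @param tt a `trait_tree` (see [gen_trait_tree]) or a list with `tree`
#'   and `traits` (`tip`, `x`, `y`).
#' @param gene_table optional data frame for [compartment_ancova].
#' @param n_orders tip orders for the robustness report (0 or 1 skips it).
#' @param out optional TSV path for the PGLS summary.
#' @return List with `pgls`, `sign_test`, `ancestral`, `order_robustness`
#'   (or `NULL`), `ancova` (or `NULL`).
#' @export
run_comparative <- function(tt, gene_table = NULL, n_orders = 0L,
                            out = NULL) {
  x <- stats::setNames(tt$traits$x, tt$traits$tip)
  y <- stats::setNames(tt$traits$y, tt$traits$tip)
  fit <- pgls(tt$tree, x, y)
  cx <- independent_contrasts(tt$tree, x)
  cy <- independent_contrasts(tt$tree, y)
  sgn <- contrast_sign_test(cx, cy)
  anc <- ancestral_states(tt$tree, y)
  rob <- if (n_orders > 1L) order_robustness(tt$tree, x, y, n_orders)
  acv <- if (!is.null(gene_table)) compartment_ancova(gene_table)
  write_tsv(data.frame(slope = fit$slope, t = fit$t, df = fit$df,
                       r = fit$r, p = fit$p, lambda = fit$lambda,
                       sign_agree = sgn$n_agree, sign_total = sgn$n_total,
                       sign_p = sgn$p), out)
  list(pgls = fit, sign_test = sgn, ancestral = anc,
       order_robustness = rob, ancova = acv)
}

#' Generate a full synthetic dataset
#'
#' Runs the generator end to end: a gene set (written as FASTA +
#' annotation), the polymorphism/divergence site table, one pairwise codon
#' alignment per gene subset, and a trait-bearing tree.  Identical
#' configurations (including the seed) give byte-identical outputs.
#'
#' @param config a [sim_config].
#' @param dir output directory; `NULL` keeps everything in memory.
#' @param n_alignments pairwise alignments to generate.
#' @return List with `records`, `sites`, `alignments`, `trait_tree`, and
#'   `files` (paths, when `dir` is given).
#' @export
run_simulate <- function(config, dir = NULL, n_alignments = 0L) {
  records <- gen_genes(config)
  sites <- gen_polymorphism_divergence(config)
  alignments <- if (n_alignments > 0L) {
    stats::setNames(lapply(seq_len(n_alignments), function(k) {
      gen_pairwise_alignment(config, seed = config$seed + k)
    }), sprintf("aln%03d", seq_len(n_alignments)))
  }
  tt <- gen_trait_tree(config)
  files <- NULL
  if (!is.null(dir)) {
    files <- write_genome_files(records, dir, config = config)
    write_tsv(sites, file.path(dir, "sites.tsv"))
    ape::write.tree(tt$tree, file.path(dir, "tree.nwk"))
    write_tsv(tt$traits, file.path(dir, "traits.tsv"))
    if (!is.null(alignments)) {
      aln_dir <- file.path(dir, "alignments")
      dir.create(aln_dir, showWarnings = FALSE, recursive = TRUE)
      for (nm in names(alignments)) {
        Biostrings::writeXStringSet(
          Biostrings::DNAStringSet(alignments[[nm]]),
          file.path(aln_dir, paste0(nm, ".fa")))
      }
    }
  }
  list(records = records, sites = sites, alignments = alignments,
       trait_tree = tt, files = files)
}
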