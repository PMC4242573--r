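#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generator: the
#' mutation-selection-drift model for coding sequence (mutational base
#' frequencies, transition/transversion ratio, scaled selection S on
#' preferred codons), the polymorphism/divergence sampler (site-class
#' rates, ingroup sample size, CpG hypermutability), the pairwise-alignment
#' branch length, and the trait-on-tree model (Pagel's lambda, Brownian
#' variance, slope linking the predictor to the response).
#'
#' Defaults emulate a mammalian genome: ~41% GC mutational background,
#' transition bias kappa = 4, 500-codon genes, two introns totalling
#' 1.2 kb, 2 kb flanks, a 100-chromosome ingroup sample, and a pairwise
#' divergence comparable to the human-chimp synonymous distance.
#'
#' @param seed integer seed (mandatory for any stochastic operation).
#' @param n_genes,codons_per_gene gene count and length.
#' @param S scaled selection coefficient (2 Ne s) favoring the preferred
#'   codon of every family; scalar or named per split-partition family.
#' @param pi_star mutational base frequencies (named A/C/G/T).
#' @param kappa transition/transversion rate ratio.
#' @param n_introns,intron_length,flank gene-structure sizes (bp).
#' @param p_x probability a gene is X-linked.
#' @param sample_size ingroup chromosomes sampled at polymorphic sites.
#' @param theta_poly,theta_fix relative rates at which a variant site is
#'   observed as polymorphic / as a fixed difference (before selection).
#' @param exon_site_scale,intron_site_scale expected variant-site counts.
#' @param cpg_base_rate,cpg_multiplier per-lineage CpG deamination scale
#'   and its hypermutability multiplier (artifact sites arise at rate
#'   proportional to the square of their product, one deamination per
#'   outgroup lineage).
#' @param outgroup_mismatch probability the two outgroups disagree at a
#'   site (excluded during polarization).
#' @param t_pair branch length separating the two sequences of a pairwise
#'   alignment.
#' @param n_tips,lambda_x,lambda_y,sigma2_x,sigma2_y,slope,intercept
#'   trait-tree model: tip count, Pagel's lambda of predictor and residual,
#'   Brownian variances, and the linear link y = intercept + slope x +
#'   noise.
#' @param trichotomy_depth if non-`NULL`, a three-tip polytomy of this
#'   depth is grafted onto the tree (the three-mouse trichotomy analogue).
#' @return Object of class `sim_config` (a list).
#' @export
sim_config <- function(seed = 1L, n_genes = 100L, codons_per_gene = 500L,
                       S = 0,
                       pi_star = c(A = 0.295, C = 0.205, G = 0.205,
                                   T = 0.295),
                       kappa = 4, n_introns = 2L, intron_length = 600L,
                       flank = 2000L, p_x = 0.1,
                       sample_size = 100L, theta_poly = 1, theta_fix = 0.7,
                       exon_site_scale = 4000, intron_site_scale = 8000,
                       cpg_base_rate = 0.05, cpg_multiplier = 1,
                       outgroup_mismatch = 0.01, t_pair = 0.05,
                       n_tips = 41L, lambda_x = 1, lambda_y = 1,
                       sigma2_x = 1, sigma2_y = 0.25, slope = 0,
                       intercept = 0, trichotomy_depth = NULL) {
  stopifnot(abs(sum(pi_star) - 1) < 1e-8, all(pi_star >= 0), kappa > 0,
            theta_poly >= 0, theta_fix >= 0, cpg_base_rate >= 0,
            cpg_multiplier >= 0, t_pair >= 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Fitness vector favoring one codon per synonymous family
#'
#' Assigns fitness `S` to the designated preferred codon of every
#' multi-codon family (sixfold-split partition) and 0 elsewhere.  The
#' preferred codon is the C-ending codon of the family when one exists,
#' otherwise the G-ending codon, otherwise the alphabetically first -
#' mirroring the GC-ending optimal codons typical of mammalian genomes.
#'
#' @param S scalar or named per-family scaled selection coefficient.
#' @param code split-partition [genetic_code].
#' @return Named numeric fitness vector over the 61 sense codons
#'   (alphabetical order).
#' @export
sim_fitness <- function(S, code = genetic_code(split_sixfold = TRUE)) {
  all_codons <- genetic_code()$codons
  F <- stats::setNames(rep(0, 61L), all_codons)
  for (f in code$families) {
    s_f <- if (length(S) == 1L) S else S[[f$name]]
    third <- substr(f$codons, 3L, 3L)
    pick <- if ("C" %in% third) {
      f$codons[third == "C"][1L]
    } else if ("G" %in% third) {
      f$codons[third == "G"][1L]
    } else sort(f$codons)[1L]
    F[pick] <- s_f
  }
  F
}

#' Generate one gene at mutation-selection-drift equilibrium
#'
#' Codons are drawn independently from the stationary distribution
#' \eqn{\pi_j \propto \pi^*_{j1}\pi^*_{j2}\pi^*_{j3}e^{F_j}} (the same law
#' as the substitution model's stationary distribution); introns and
#' flanks are drawn base-by-base from the mutational frequencies alone (no
#' selection, no frame).
#'
#' @param config a [sim_config].
#' @param gene_id identifier for the record.
#' @param seed optional seed (defaults to drawing from the current RNG
#'   stream, for use inside [gen_genes]).
#' @return A [transcript_record].
#' @export
gen_gene <- function(config, gene_id = "g1", seed = NULL) {
  gen <- function() {
    F <- sim_fitness(config$S)
    pi <- stationary_codon_dist(config$pi_star, F)
    cods <- sample(names(pi), config$codons_per_gene, replace = TRUE,
                   prob = pi)
    cds <- paste(cods, collapse = "")
    rand_seq <- function(n) {
      paste(sample(names(config$pi_star), n, replace = TRUE,
                   prob = config$pi_star), collapse = "")
    }
    introns <- vapply(seq_len(config$n_introns),
                      function(i) rand_seq(config$intron_length), "")
    n_ex <- config$n_introns + 1L
    ncod <- config$codons_per_gene
    per <- (ncod %/% n_ex) * 3L
    exon_lengths <- c(rep(per, n_ex - 1L),
                      nchar(cds) - per * (n_ex - 1L))
    transcript_record(
      gene_id = gene_id, tx_id = paste0(gene_id, ".t1"), chrom = gene_id,
      strand = "+", cds = cds, exon_lengths = exon_lengths,
      introns = introns, flank_up = rand_seq(config$flank),
      flank_down = rand_seq(config$flank), start = config$flank,
      chrom_class = if (stats::runif(1) < config$p_x) "X" else "A")
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Generate a synthetic genome (a set of genes)
#'
#' @param config a [sim_config]; `config$seed` fixes the whole genome.
#' @return Named list of [transcript_record]s.
#' @export
gen_genes <- function(config) {
  with_seed(config$seed, {
    ids <- sprintf("g%04d", seq_len(config$n_genes))
    stats::setNames(lapply(ids, function(g) gen_gene(config, g)), ids)
  })
}

#' Write a synthetic gene set as FASTA + annotation files
#'
#' Assembles one contig per gene (flank - exon - intron - ... - flank),
#' emits a genome FASTA and the block-based annotation table consumed by
#' [load_gene_models], and a manifest recording the configuration.  Genes
#' can be placed on the minus strand, in which case the contig holds the
#' reverse complement and coordinates are remapped.
#'
#' @param records list of [transcript_record]s.
#' @param dir output directory (created if needed).
#' @param minus_strand logical vector (recycled): place gene on minus
#'   strand.
#' @param config optional [sim_config] recorded in the manifest.
#' @return Invisibly, the paths of the files written.
#' @export
write_genome_files <- function(records, dir, minus_strand = FALSE,
                               config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  minus_strand <- rep_len(minus_strand, length(records))
  contigs <- character(length(records))
  ann <- vector("list", length(records))
  for (k in seq_along(records)) {
    r <- records[[k]]
    pieces <- character(0)
    lens <- r$exon_lengths
    starts_cds <- cumsum(c(0L, lens[-length(lens)]))
    ex_start <- integer(length(lens))
    pos <- nchar(r$flank_up)
    for (i in seq_along(lens)) {
      ex_start[i] <- pos
      pieces <- c(pieces, substring(r$cds, starts_cds[i] + 1L,
                                    starts_cds[i] + lens[i]))
      pos <- pos + lens[i]
      if (i < length(lens)) {
        pieces <- c(pieces, r$introns[i])
        pos <- pos + nchar(r$introns[i])
      }
    }
    contig <- paste0(r$flank_up, paste(pieces, collapse = ""),
                     r$flank_down)
    gstart <- nchar(r$flank_up)
    gend <- pos
    strand <- "+"
    if (minus_strand[k]) {
      L <- nchar(contig)
      contig <- revcomp(contig)
      new_start <- L - gend
      ex_end <- ex_start + lens
      ex_start <- rev(L - ex_end)
      lens <- rev(lens)
      gstart <- new_start
      gend <- L - nchar(r$flank_up)
      strand <- "-"
    }
    contigs[k] <- contig
    ann[[k]] <- data.frame(
      chrom = r$gene_id, start = gstart, end = gend,
      gene_id = r$gene_id, tx_id = r$tx_id, strand = strand,
      block_starts = paste(ex_start - gstart, collapse = ","),
      block_sizes = paste(lens, collapse = ","),
      chrom_class = r$chrom_class, stringsAsFactors = FALSE)
  }
  names(contigs) <- vapply(records, `[[`, "", "gene_id")
  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(contigs), fa)
  ann <- do.call(rbind, ann)
  ann_path <- file.path(dir, "genes.tsv")
  utils::write.table(ann, ann_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- file.path(dir, "manifest.txt")
  if (!is.null(config)) {
    writeLines(c("cubne synthetic genome",
                 paste0(names(config), " = ",
                        vapply(config, function(v)
                          paste(format(v), collapse = ","), ""))),
               manifest)
  }
  invisible(list(fasta = fa, annotation = ann_path, manifest = manifest))
}

# fixation factor h(S) = S / (1 - exp(-S)), h(0) = 1
fixation_factor <- function(S) {
  ifelse(abs(S) < 1e-10, 1 + S / 2, S / (1 - exp(-S)))
}

# mutation rate factor for a base change under the HKY-style mutation model
mutation_rate <- function(from, to, kappa, pi_star) {
  ts <- paste(sort(c(from, to)), collapse = "") %in% c("AG", "CT")
  ifelse(ts, kappa, 1) * pi_star[to]
}

#' Generate polarized-site inputs (polymorphism + divergence + outgroups)
#'
#' Simulates the raw site table consumed by [polarize_sites]: third-position
#' exonic sites whose fixation process is weighted by
#' \eqn{h(S) = S/(1-e^{-S})}, neutrally evolving intronic imaginary-codon
#' sites, and CpG mis-polarization artifacts.  For every synonymous family
#' the preferred/unpreferred codon pair (which always differs at the third
#' position) yields two direction classes; a site is observed polymorphic
#' at rate `theta_poly` times the mutation rate and fixed at rate
#' `theta_fix` times the mutation rate times `h(S)` (exons) or `h(0)`
#' (introns).  Artifact sites arise when both outgroup lineages deaminate
#' the same CpG: at rate proportional to
#' `(cpg_base_rate * cpg_multiplier)^2` a conserved C (preceded-by-C A, on
#' the other strand) is observed as T (A) in both outgroups, which
#' polarization misreads as a fixed unpreferred-to-preferred change; these
#' sites carry the quintet signature targeted by [cpg_suspect].
#'
#' @param config a [sim_config].
#' @return Data frame (one row per variant site) with columns `region`,
#'   `allele1`, `allele2`, `outgroup1`, `outgroup2`, `context2`,
#'   `quintet_flank`, `derived_count`, `sample_size`, `artifact`
#'   (generator truth, not used by the analysis).
#' @export
gen_polymorphism_divergence <- function(config) {
  with_seed(config$seed, {
    code <- genetic_code(split_sixfold = TRUE)
    F <- sim_fitness(config$S)
    pi_sel <- stationary_codon_dist(config$pi_star, F)
    pi_neu <- stationary_codon_dist(config$pi_star,
                                    stats::setNames(rep(0, 61),
                                                    names(F)))
    bases <- names(config$pi_star)
    cpg_rate <- (config$cpg_base_rate * config$cpg_multiplier)^2
    rows <- list()
    add_sites <- function(n, region, anc_codon, der_codon, status,
                          artifact = FALSE, force_b4 = NULL) {
      if (n == 0L) return()
      a3 <- substr(anc_codon, 3L, 3L)
      d3 <- substr(der_codon, 3L, 3L)
      ctx <- substr(anc_codon, 1L, 2L)
      b4 <- if (!is.null(force_b4)) rep(force_b4, n) else
        sample(bases, n, replace = TRUE, prob = config$pi_star)
      b5 <- sample(bases, n, replace = TRUE, prob = config$pi_star)
      og2 <- rep(a3, n)
      mism <- stats::runif(n) < config$outgroup_mismatch
      if (any(mism)) {
        og2[mism] <- vapply(which(mism),
                            function(i) sample(setdiff(bases, a3), 1L), "")
      }
      poly <- status == "polymorphic"
      rows[[length(rows) + 1L]] <<- data.frame(
        region = region,
        allele1 = if (poly) rep(a3, n) else rep(d3, n),
        allele2 = if (poly) rep(d3, n) else rep(NA_character_, n),
        outgroup1 = rep(a3, n), outgroup2 = og2,
        context2 = rep(ctx, n),
        quintet_flank = paste0(ctx, b4, b5),
        derived_count = if (poly) sample_sfs(config$sample_size, n) else
          rep(config$sample_size, n),
        sample_size = rep(config$sample_size, n),
        artifact = rep(artifact, n), stringsAsFactors = FALSE)
    }
    for (region in c("exon", "intron")) {
      scale <- if (region == "exon") config$exon_site_scale else
        config$intron_site_scale
      pi_use <- if (region == "exon") pi_sel else pi_neu
      for (f in code$families) {
        third <- substr(f$codons, 3L, 3L)
        pref <- f$codons[which.max(F[f$codons] + 1e-9 *
                                     (third %in% c("C", "G")))]
        unpref_cands <- setdiff(f$codons, pref)
        unpref <- unpref_cands[which.min(pi_use[unpref_cands])]
        for (dir in c("u2p", "p2u")) {
          anc <- if (dir == "u2p") unpref else pref
          der <- if (dir == "u2p") pref else unpref
          S_dir <- if (region == "exon") F[der] - F[anc] else 0
          mu <- mutation_rate(substr(anc, 3, 3), substr(der, 3, 3),
                              config$kappa, config$pi_star)
          base <- scale * pi_use[[anc]] * mu
          n_poly <- stats::rpois(1L, base * config$theta_poly)
          n_fix <- stats::rpois(1L, base * config$theta_fix *
                                  fixation_factor(S_dir))
          add_sites(n_poly, region, anc, der, "polymorphic")
          add_sites(n_fix, region, anc, der, "fixed")
        }
        # CpG mis-polarization artifacts: conserved preferred codon whose
        # third base is C (next base G) or G preceded by C; both outgroups
        # deaminate, so polarization misreads a fixed unpref -> pref change
        p3 <- substr(pref, 3L, 3L)
        if (cpg_rate > 0) {
          unp <- prefixed_partner(pref, unpref_cands, p3)
          if (!is.null(unp)) {
            mu <- mutation_rate(substr(unp, 3, 3), p3, config$kappa,
                                config$pi_star)
            n_art <- stats::rpois(1L, scale * pi_use[[pref]] * mu *
                                    config$theta_fix * cpg_rate)
            if (p3 == "C") {
              add_sites(n_art, region, unp, pref, "fixed",
                        artifact = TRUE, force_b4 = "G")
            } else if (p3 == "G" && substr(pref, 2L, 2L) == "C") {
              add_sites(n_art, region, unp, pref, "fixed",
                        artifact = TRUE)
            }
          }
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

# the family's unpreferred T-ending (for preferred C) or A-ending (for
# preferred G) partner codon, if any: the state a double deamination mimics
prefixed_partner <- function(pref, candidates, p3) {
  want <- if (p3 == "C") "T" else if (p3 == "G") "A" else return(NULL)
  hit <- candidates[substr(candidates, 3L, 3L) == want]
  if (length(hit)) hit[1L] else NULL
}

# neutral derived-allele counts: P(k) proportional to 1/k on 1..n-1 (the
# standard equilibrium frequency spectrum)
sample_sfs <- function(n, size = 1L) {
  k <- seq_len(n - 1L)
  sample(k, size, replace = TRUE, prob = 1 / k)
}

#' Generate a two-species codon alignment under the FMutSel model
#'
#' The ancestor is sampled from the stationary distribution and the
#' descendant evolved through the transition probabilities \eqn{e^{Qt}}.
#'
#' @param config a [sim_config] (supplies kappa, pi_star, t_pair, seed).
#' @param F codon fitness vector (defaults to [sim_fitness] at
#'   `config$S`).
#' @param t branch length (defaults to `config$t_pair`).
#' @param n_codons alignment length (defaults to `config$codons_per_gene`).
#' @param seed optional override of `config$seed`.
#' @return Named character vector of two in-frame sequences
#'   (`"ancestor"`, `"descendant"`).
#' @export
gen_pairwise_alignment <- function(config, F = NULL, t = NULL,
                                   n_codons = NULL, seed = NULL) {
  if (is.null(F)) F <- sim_fitness(config$S)
  if (is.null(t)) t <- config$t_pair
  if (is.null(n_codons)) n_codons <- config$codons_per_gene
  if (is.null(seed)) seed <- config$seed
  with_seed(seed, {
    pi <- stationary_codon_dist(config$pi_star, F)
    P <- codon_transition_matrix(config$kappa, config$pi_star, F, t)
    anc_idx <- sample.int(61L, n_codons, replace = TRUE, prob = pi)
    des_idx <- integer(n_codons)
    for (i in unique(anc_idx)) {
      sel <- anc_idx == i
      des_idx[sel] <- sample.int(61L, sum(sel), replace = TRUE,
                                 prob = P[i, ])
    }
    codons <- names(pi)
    c(ancestor = paste(codons[anc_idx], collapse = ""),
      descendant = paste(codons[des_idx], collapse = ""))
  })
}

#' Generate a phylogeny with correlated tip traits
#'
#' Simulates a coalescent-shaped tree (or uses a supplied one), a predictor
#' trait x evolving as Brownian motion under a Pagel-lambda covariance, and
#' a response y = intercept + slope * x + Brownian noise with its own
#' lambda.  Optionally grafts a shallow three-tip polytomy (the
#' three-mouse trichotomy analogue).
#'
#' @param config a [sim_config].
#' @param tree optional [ape::phylo]; simulated when `NULL`.
#' @param seed optional override of `config$seed`.
#' @return Object of class `trait_tree`: list with `tree` and `traits`
#'   (data frame `tip`, `x`, `y`).
#' @export
gen_trait_tree <- function(config, tree = NULL, seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  with_seed(seed, {
    if (is.null(tree)) {
      tree <- ape::rcoal(config$n_tips)
      tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))
    }
    if (!is.null(config$trichotomy_depth)) {
      poly <- ape::read.tree(text = sprintf(
        "(m1:%f,m2:%f,m3:%f);", config$trichotomy_depth,
        config$trichotomy_depth, config$trichotomy_depth))
      tree <- ape::bind.tree(tree, poly, where = 1L)
      tree$tip.label <- make.unique(tree$tip.label)
    }
    n <- length(tree$tip.label)
    Cx <- phylo_covariance(tree, config$lambda_x) * config$sigma2_x
    Cy <- phylo_covariance(tree, config$lambda_y) * config$sigma2_y
    x <- MASS::mvrnorm(1L, rep(0, n), Cx)
    y <- config$intercept + config$slope * x +
      MASS::mvrnorm(1L, rep(0, n), Cy)
    names(x) <- names(y) <- tree$tip.label
    structure(list(tree = tree,
                   traits = data.frame(tip = tree$tip.label, x = x, y = y,
                                       stringsAsFactors = FALSE)),
              class = "trait_tree")
  })
}
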