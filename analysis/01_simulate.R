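#!/usr/bin/env Rscript
# Generate the synthetic datasets used by the downstream analyses:
# a genome evolving under weak selection on codon usage (S = 2), a matched
# neutral genome, polymorphism/divergence site tables (with and without
# CpG hypermutability), pairwise codon alignments, and a 41-tip trait tree
# in which log Ne (x) drives expected codon bias (y).

suppressPackageStartupMessages(library(cubne))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sel_cfg <- sim_config(seed = 101, n_genes = 150, codons_per_gene = 500,
                      S = 2, exon_site_scale = 4000,
                      intron_site_scale = 8000)
neu_cfg <- sim_config(seed = 102, n_genes = 150, codons_per_gene = 500,
                      S = 0, exon_site_scale = 4000,
                      intron_site_scale = 8000)
cpg_cfg <- sim_config(seed = 103, n_genes = 150, codons_per_gene = 500,
                      S = 0, cpg_multiplier = 25, exon_site_scale = 4000,
                      intron_site_scale = 8000)

message("simulating selected genome (S = 2) ...")
sel <- run_simulate(sel_cfg, dir = file.path(out, "selected"),
                    n_alignments = 12)
message("simulating neutral genome (S = 0) ...")
neu <- run_simulate(neu_cfg, dir = file.path(out, "neutral"),
                    n_alignments = 12)
message("simulating CpG-hypermutable site table ...")
cpg_sites <- gen_polymorphism_divergence(cpg_cfg)
write.table(cpg_sites, file.path(out, "cpg_sites.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

tt_cfg <- sim_config(seed = 104, n_tips = 41, slope = -0.5,
                     sigma2_y = 0.25)
tt <- gen_trait_tree(tt_cfg)
ape::write.tree(tt$tree, file.path(out, "trait_tree.nwk"))
write.table(tt$traits, file.path(out, "traits.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message("done: synthetic data under ", out)
message("  selected genes: ", length(sel$records),
        "; neutral genes: ", length(neu$records),
        "; exon sites (selected): ",
        sum(sel$sites$region == "exon"))
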