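sim_record <- function(seed = 5, S = 0, codons = 210) {
  cfg <- sim_config(seed = seed, codons_per_gene = codons, S = S)
  gen_gene(cfg, "gA", seed = seed)
}

test_that("gene models round-trip through FASTA/annotation on both strands", {
  rec <- sim_record()
  for (minus in c(FALSE, TRUE)) {
    dir <- withr::local_tempdir()
    write_genome_files(list(rec), dir, minus_strand = minus)
    loaded <- load_gene_models(file.path(dir, "genome.fa"),
                               file.path(dir, "genes.tsv"))
    got <- loaded[[rec$tx_id]]
    expect_identical(got$cds, rec$cds)
    expect_identical(got$introns, rec$introns)
    expect_identical(got$flank_up, rec$flank_up)
    expect_identical(got$flank_down, rec$flank_down)
  }
})

test_that("introns equal direct string slices of the assembled contig", {
  rec <- sim_record(seed = 9)
  dir <- withr::local_tempdir()
  write_genome_files(list(rec), dir)
  contig <- as.character(Biostrings::readDNAStringSet(
    file.path(dir, "genome.fa"))[[1]])
  ann <- read.delim(file.path(dir, "genes.tsv"))
  bs <- as.integer(strsplit(ann$block_starts, ",")[[1]]) + ann$start
  sz <- as.integer(strsplit(ann$block_sizes, ",")[[1]])
  # oracle: slice between consecutive exons by hand
  oracle <- substring(contig, (bs + sz)[-length(bs)] + 1, bs[-1])
  loaded <- load_gene_models(file.path(dir, "genome.fa"), ann)
  expect_identical(loaded[[1]]$introns, oracle)
})

test_that("bad coordinates and frames are rejected by name", {
  genome <- c(chr1 = "ATGAAATTTCCC")
  ann <- data.frame(chrom = "chr1", start = 0L, end = 20L,
                    gene_id = "g", tx_id = "t1", strand = "+",
                    block_starts = "0", block_sizes = "20")
  expect_error(load_gene_models(genome, ann), "coordinate error.*t1")
  ann2 <- data.frame(chrom = "chr1", start = 0L, end = 4L,
                     gene_id = "g", tx_id = "t2", strand = "+",
                     block_starts = "0", block_sizes = "4")
  expect_error(load_gene_models(genome, ann2), "frame error.*t2")
  ann3 <- data.frame(chrom = "chrX", start = 0L, end = 3L,
                     gene_id = "g", tx_id = "t3", strand = "+",
                     block_starts = "0", block_sizes = "3")
  expect_error(load_gene_models(genome, ann3), "t3")
})

test_that("transcript selection honors policy, ties, and seeds", {
  mk <- function(id, ncod) {
    transcript_record("g", id, cds = strrep("ATG", ncod))
  }
  txs <- list(mk("tB", 200), mk("tA", 100), mk("tC", 100))
  expect_identical(select_transcript(txs[1], "longest")$tx_id, "tB")
  expect_identical(select_transcript(txs, "shortest")$tx_id, "tA")
  expect_identical(select_transcript(txs, "longest")$tx_id, "tB")
  r1 <- select_transcript(txs, "random", seed = 42)$tx_id
  r2 <- select_transcript(txs, "random", seed = 42)$tx_id
  expect_identical(r1, r2)
  draws <- vapply(1:5, function(s) select_transcript(txs, "random",
                                                     seed = s)$tx_id, "")
  expect_identical(draws,
                   vapply(1:5, function(s) select_transcript(
                     txs, "random", seed = s)$tx_id, ""))
  expect_error(select_transcript(list(), "random"), "no transcripts")
})

test_that("the 100-codon minimum keeps and drops at the boundary", {
  mk <- function(ncod) transcript_record("g", "t", cds = strrep("AAA", ncod))
  expect_false(filter_min_codons(mk(99)))
  expect_true(filter_min_codons(mk(100)))
  expect_false(filter_min_codons(mk(0)))
})

test_that("ortholog masking removes flagged columns in every species", {
  aln <- c(sp1 = "ATGAAATTTGGG", sp2 = "ATGAAATTT")
  expect_error(mask_ortholog_codons(aln), "unequal length")
  aln <- c(sp1 = "ATGAAATTTGGG", sp2 = "ATGA-ATTTGG-")
  masked <- mask_ortholog_codons(aln)
  expect_identical(unname(masked), c("ATGTTT", "ATGTTT"))
  # stop codon truncates everything at and after its column, all species
  aln2 <- c(sp1 = "ATGAAATTTGGG", sp2 = "ATGTAATTTGGG")
  masked2 <- mask_ortholog_codons(aln2)
  expect_identical(unname(masked2), c("ATG", "ATG"))
  # clean alignments pass unchanged; masking is idempotent
  clean <- c(a = "ATGAAACCC", b = "ATGAAGCCA")
  expect_identical(mask_ortholog_codons(clean), clean)
  messy <- c(a = "ATGNAATTTGGGTAA", b = "ATG-AATTTGGGAAA")
  expect_identical(mask_ortholog_codons(mask_ortholog_codons(messy)),
                   mask_ortholog_codons(messy))
})

test_that("masked output stays in frame with no internal stops", {
  cfg <- sim_config(seed = 3, codons_per_gene = 150)
  aln <- gen_pairwise_alignment(cfg, t = 0.3)
  # corrupt a few codons with gaps/ambiguity
  substr(aln[1], 31, 31) <- "-"
  substr(aln[2], 61, 61) <- "N"
  masked <- mask_ortholog_codons(aln)
  for (s in masked) {
    expect_identical(nchar(s) %% 3L, 0L)
    expect_false(any(cubne:::is_stop_codon(cubne:::split_codons(s))))
  }
})

test_that("splice-enhancer trimming respects the reading frame", {
  # single 300-bp exon starting in frame: 15 bp off each end
  rec <- list(tx_id = "t", cds = strrep("ATGCAA", 50),
              exon_lengths = 300L)
  trimmed <- trim_ese(rec)
  expect_identical(nchar(trimmed), 270L)
  expect_identical(trimmed, substr(rec$cds, 16, 285))
  # enumerate phases: 5' trims are 15/17/16 for phases 0/1/2
  for (l1 in c(99L, 100L, 101L)) {
    rec2 <- list(tx_id = "t", cds = strrep("A", l1 + 120L),
                 exon_lengths = c(l1, 120L))
    phase <- l1 %% 3L
    want5 <- c(15L, 17L, 16L)[phase + 1L]
    # second exon keeps length 120 - want5 - trim3, with
    # trim3 = 15 + ((l1 + 120 - 15) %% 3)
    want3 <- 15L + ((l1 + 120L - 15L) %% 3L)
    t1 <- 15L  # first exon starts at phase 0
    t1_3 <- 15L + ((l1 - 15L) %% 3L)
    expect_identical(nchar(trim_ese(rec2)),
                     (l1 - t1 - t1_3) + (120L - want5 - want3))
    expect_identical(nchar(trim_ese(rec2)) %% 3L, 0L)
  }
  # exons shorter than the combined trims are dropped entirely
  rec3 <- list(tx_id = "t", cds = strrep("AAA", 47L),
               exon_lengths = c(20L, 121L))
  expect_identical(nchar(trim_ese(rec3)), 121L - 16L - 15L)
})

test_that("codon counting matches a naive histogram and conserves totals", {
  code <- genetic_code()
  cc <- count_codons("ATGAAAAAG")
  expect_identical(cc$counts[["ATG"]], 1L)
  expect_identical(cc$counts[["AAA"]], 1L)
  expect_identical(cc$counts[["AAG"]], 1L)
  expect_identical(cc$n, 3L)
  cc2 <- count_codons("ATGANAAAG")
  expect_identical(cc2$skipped, 1L)
  expect_identical(cc2$n, 2L)
  # brute-force histogram oracle on a random 1000-codon sequence
  set.seed(11)
  trip <- sample(code$codons, 1000, replace = TRUE)
  cds <- paste(trip, collapse = "")
  cc3 <- count_codons(cds)
  oracle <- table(factor(trip, levels = code$codons))
  expect_identical(as.integer(cc3$counts), as.integer(oracle))
  # conservation: family totals + Met + Trp + skipped = length/3
  tot <- sum(family_totals(cc3)) + cc3$counts[["ATG"]] +
    cc3$counts[["TGG"]] + cc3$skipped + cc3$stops
  expect_identical(as.integer(tot), 1000L)
})

test_that("compartment classification follows boundary distances", {
  cen <- data.frame(chrom = "chr1", cen_start = 40e6, cen_end = 45e6,
                    chrom_length = 100e6)
  mk <- function(pos, chrom = "chr1") {
    r <- transcript_record("g", "t", chrom = chrom, cds = "ATG")
    r$start <- pos
    r
  }
  expect_identical(classify_compartment(mk(37e6), cen), "centromeric")
  expect_identical(classify_compartment(mk(28e6), cen), "interior")
  expect_identical(classify_compartment(mk(97e6), cen), "telomeric")
  # window flip: 7 Mb from the centromere boundary
  g7 <- mk(33e6)
  expect_identical(classify_compartment(g7, cen, window_mb = 5), "interior")
  expect_identical(classify_compartment(g7, cen, window_mb = 20),
                   "centromeric")
  expect_warning(res <- classify_compartment(mk(1e6, "chrZ"), cen),
                 "unclassified|absent")
  expect_identical(res, "unclassified")
  # both windows hit: centromeric takes precedence, with a warning
  cen2 <- data.frame(chrom = "chr1", cen_start = 5e6, cen_end = 6e6,
                     chrom_length = 30e6)
  expect_warning(both <- classify_compartment(mk(8e6), cen2),
                 "both")
  expect_identical(both, "centromeric")
})
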