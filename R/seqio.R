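#' Transcript record
#'
#' Lightweight container for one transcript in coding orientation: the
#' in-frame coding sequence, intron sequences, up/downstream flanking
#' sequence (up to 2 kb each), exon coordinates and compartment labels.
#'
#' @param gene_id,tx_id identifiers.
#' @param chrom,strand genomic location; strand is `"+"` or `"-"`.
#' @param cds in-frame coding sequence (coding orientation).
#' @param exons integer matrix with columns `start`, `end` (0-based
#'   half-open, genome coordinates, ascending).
#' @param exon_lengths exon lengths in coding order (5' to 3' of the mRNA).
#' @param introns character vector of intron sequences in coding orientation,
#'   ordered 5' to 3' of the mRNA.
#' @param flank_up,flank_down flanking sequence in coding orientation.
#' @param start genomic start of the gene (0-based; used for compartment
#'   classification).
#' @param chrom_class `"A"` (autosome) or `"X"`.
#' @return An object of class `transcript_record`.
#' @export
transcript_record <- function(gene_id, tx_id, chrom = NA_character_,
                              strand = "+", cds = "",
                              exons = NULL, exon_lengths = NULL,
                              introns = character(0),
                              flank_up = "", flank_down = "",
                              start = NA_integer_, chrom_class = "A") {
  if (nchar(cds) %% 3L != 0L) {
    stop("frame error: CDS of transcript '", tx_id,
         "' has length not divisible by 3")
  }
  if (is.null(exon_lengths) && !is.null(exons)) {
    w <- exons[, 2L] - exons[, 1L]
    if (identical(strand, "-")) w <- rev(w)
    exon_lengths <- w
  }
  if (is.null(exon_lengths)) exon_lengths <- nchar(cds)
  structure(list(gene_id = gene_id, tx_id = tx_id, chrom = chrom,
                 strand = strand, cds = cds, exons = exons,
                 exon_lengths = as.integer(exon_lengths),
                 introns = introns, flank_up = flank_up,
                 flank_down = flank_down, start = start,
                 chrom_class = chrom_class, compartment = NA_character_),
            class = "transcript_record")
}

#' @export
print.transcript_record <- function(x, ...) {
  cat(sprintf("<transcript %s/%s: %d codons, %d introns, strand %s>\n",
              x$gene_id, x$tx_id, nchar(x$cds) %/% 3L,
              length(x$introns), x$strand))
  invisible(x)
}

#' Load gene models from a genome and a block-based annotation table
#'
#' Reads transcripts from genomic sequence plus a BED-like annotation with
#' exon blocks, extracting the coding sequence, introns, and up to
#' `flank` bp of flanking sequence on each side, all in coding orientation
#' (minus-strand transcripts are reverse complemented).
#'
#' @param genome named character vector of contig sequences, a
#'   [Biostrings::DNAStringSet], or a path to a FASTA file.
#' @param annotation data frame (or path to a TSV with a header) with
#'   columns `chrom`, `start`, `end`, `gene_id`, `tx_id`, `strand`,
#'   `block_starts`, `block_sizes`; coordinates 0-based half-open, blocks
#'   comma-separated and relative to `start`, ascending.
#' @param flank maximum flanking sequence to extract per side (bp).
#' @return List of [transcript_record] objects, named by `tx_id`.
#' @export
load_gene_models <- function(genome, annotation, flank = 2000L) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*", "", names(genome))
  }
  if (methods::is(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  if (is.character(annotation) && length(annotation) == 1L) {
    annotation <- utils::read.delim(annotation, stringsAsFactors = FALSE)
  }
  out <- list()
  for (i in seq_len(nrow(annotation))) {
    row <- annotation[i, ]
    if (!row$chrom %in% names(genome)) {
      stop("coordinate error: transcript '", row$tx_id,
           "' names unknown sequence '", row$chrom, "'")
    }
    contig <- genome[[row$chrom]]
    clen <- nchar(contig)
    bs <- as.integer(strsplit(as.character(row$block_starts), ",")[[1]])
    sz <- as.integer(strsplit(as.character(row$block_sizes), ",")[[1]])
    ex_start <- row$start + bs
    ex_end <- ex_start + sz
    if (any(ex_start < 0L) || any(ex_end > clen)) {
      stop("coordinate error: transcript '", row$tx_id,
           "' has exons outside sequence '", row$chrom, "'")
    }
    if (is.unsorted(ex_start, strictly = TRUE) ||
        any(ex_start[-1L] < ex_end[-length(ex_end)])) {
      stop("coordinate error: transcript '", row$tx_id,
           "' has overlapping or unordered exon blocks")
    }
    if (!row$strand %in% c("+", "-")) {
      stop("coordinate error: transcript '", row$tx_id, "' has bad strand")
    }
    exon_seq <- substring(contig, ex_start + 1L, ex_end)
    n_ex <- length(exon_seq)
    intr <- if (n_ex > 1L) {
      substring(contig, ex_end[-n_ex] + 1L, ex_start[-1L])
    } else character(0)
    up <- substring(contig, max(0L, row$start - flank) + 1L, row$start)
    dn <- substring(contig, row$end + 1L, min(clen, row$end + flank))
    cds <- paste(exon_seq, collapse = "")
    if (identical(row$strand, "-")) {
      cds <- revcomp(cds)
      intr <- rev(revcomp(intr))
      tmp <- up
      up <- revcomp(dn)
      dn <- revcomp(tmp)
    }
    if (nchar(cds) %% 3L != 0L) {
      stop("frame error: transcript '", row$tx_id,
           "' CDS length not divisible by 3")
    }
    out[[row$tx_id]] <- transcript_record(
      gene_id = row$gene_id, tx_id = row$tx_id, chrom = row$chrom,
      strand = row$strand, cds = cds,
      exons = cbind(start = ex_start, end = ex_end),
      introns = intr, flank_up = up, flank_down = dn,
      start = row$start,
      chrom_class = if (!is.null(row$chrom_class)) row$chrom_class else "A")
  }
  out
}

#' Choose one transcript per gene
#'
#' Picks a transcript among a gene's alternatives: at random (reproducible
#' under `seed`), or the shortest/longest coding sequence with ties broken
#' by lexicographic transcript id.
#'
#' @param transcripts list of [transcript_record]s of one gene.
#' @param policy `"random"`, `"shortest"` or `"longest"`.
#' @param seed integer seed used for the random policy.
#' @return A single [transcript_record].
#' @export
select_transcript <- function(transcripts, policy = c("random", "shortest",
                                                      "longest"),
                              seed = NULL) {
  policy <- match.arg(policy)
  if (length(transcripts) == 0L) stop("no transcripts to select from")
  if (length(transcripts) == 1L) return(transcripts[[1L]])
  ids <- vapply(transcripts, `[[`, "", "tx_id")
  len <- vapply(transcripts, function(r) nchar(r$cds), 0L)
  ord <- order(len, ids)  # lexicographic id tie-break
  switch(policy,
    shortest = transcripts[[ord[1L]]],
    longest = transcripts[[ord[length(ord)]]],
    random = {
      i <- with_seed(seed, sample.int(length(transcripts), 1L))
      transcripts[[i]]
    })
}

#' Keep transcripts with at least `min_codons` codons
#'
#' Short genes give unstable codon-usage estimates; the analysis keeps only
#' transcripts with at least 100 codons by default.
#'
#' @param record a [transcript_record].
#' @param min_codons minimum codon count.
#' @return `TRUE` to keep, `FALSE` to drop.
#' @export
filter_min_codons <- function(record, min_codons = 100L) {
  (nchar(record$cds) %/% 3L) >= min_codons
}

#' Mask an in-frame multi-species codon alignment
#'
#' Removes every codon column containing a gap or ambiguity in any species,
#' and every column at or after the earliest stop codon observed in any
#' species (applied on the aligned codon grid, inclusive of the stop
#' column).  The retained block stays in frame.
#'
#' @param aln named character vector: one aligned, in-frame sequence per
#'   species, all of equal length divisible by 3.
#' @return Named character vector of masked sequences.
#' @export
mask_ortholog_codons <- function(aln) {
  n <- unique(nchar(aln))
  if (length(n) != 1L) stop("alignment error: sequences have unequal length")
  if (n %% 3L != 0L) stop("alignment error: length not divisible by 3")
  if (n == 0L) return(aln)
  codons <- t(vapply(aln, split_codons, character(n %/% 3L)))
  keep <- rep(TRUE, ncol(codons))
  stops <- apply(codons, 2L, function(col) any(is_stop_codon(col)))
  if (any(stops)) keep[seq(which(stops)[1L], ncol(codons))] <- FALSE
  clean <- apply(codons, 2L, function(col) all(grepl("^[ACGT]{3}$", col)))
  keep <- keep & clean
  out <- apply(codons[, keep, drop = FALSE], 1L, paste, collapse = "")
  if (length(out) == 0L) out <- stats::setNames(rep("", length(aln)), names(aln))
  stats::setNames(out, names(aln))
}

# 5'-end trim width for an exon whose first base sits at in-CDS offset `s`
# (0-based): 15 bases plus 0-2 so the removed block ends on a codon boundary
ese_trim5 <- function(s) 15L + ((3L - ((s + 15L) %% 3L)) %% 3L)
# 3'-end trim width for an exon ending at offset `e` (exclusive)
ese_trim3 <- function(e) 15L + ((e - 15L) %% 3L)

#' Trim putative exonic splice enhancers from a coding sequence
#'
#' Removes the first and last five codons' worth of sequence (15 bases plus
#' 0-2 extra so each removed block respects the transcript reading frame)
#' from every coding exon; exons shorter than the combined trims are dropped
#' entirely.  The concatenated remainder is in frame.
#'
#' @param record a [transcript_record], or any list with elements `cds` and
#'   `exon_lengths` (exon lengths in coding order).
#' @return The trimmed coding sequence (character scalar).
#' @export
trim_ese <- function(record) {
  cds <- record$cds
  lens <- record$exon_lengths
  if (sum(lens) != nchar(cds)) {
    stop("exon lengths do not sum to the CDS length for '",
         record$tx_id, "'")
  }
  starts <- cumsum(c(0L, lens[-length(lens)]))
  kept <- character(0)
  for (i in seq_along(lens)) {
    s <- starts[i]
    e <- s + lens[i]
    t5 <- ese_trim5(s)
    t3 <- ese_trim3(e)
    if (lens[i] <= t5 + t3) next
    kept <- c(kept, substring(cds, s + t5 + 1L, e - t3))
  }
  out <- paste(kept, collapse = "")
  stopifnot(nchar(out) %% 3L == 0L)
  out
}

#' Count sense codons in an in-frame coding sequence
#'
#' Tallies the 61 sense codons.  Codons containing a non-ACGT base are
#' skipped (and counted in `skipped`); stop codons are never counted.
#'
#' @param cds in-frame coding sequence.
#' @param code a [genetic_code] object.
#' @return An object of class `codon_counts`: list with `counts` (named
#'   integer vector over the 61 sense codons), `n` (total sense codons),
#'   `skipped` (ambiguous codons), and `stops`.
#' @export
count_codons <- function(cds, code = genetic_code()) {
  triplets <- split_codons(toupper(cds))
  counts <- stats::setNames(integer(61L), code$codons)
  ok <- grepl("^[ACGT]{3}$", triplets)
  skipped <- sum(!ok)
  triplets <- triplets[ok]
  stops <- sum(is_stop_codon(triplets))
  triplets <- triplets[!is_stop_codon(triplets)]
  tab <- table(factor(triplets, levels = code$codons))
  counts[names(tab)] <- as.integer(tab)
  structure(list(counts = counts, n = sum(counts), skipped = skipped,
                 stops = stops),
            class = "codon_counts")
}

#' @export
print.codon_counts <- function(x, ...) {
  cat(sprintf("<codon counts: n = %d sense codons, %d skipped, %d stops>\n",
              x$n, x$skipped, x$stops))
  invisible(x)
}

#' Per-family codon totals
#'
#' @param counts a `codon_counts` object.
#' @param code a [genetic_code]; use `genetic_code(TRUE)` for the
#'   sixfold-split partition.
#' @return Named integer vector of totals, one per multi-codon family.
#' @export
family_totals <- function(counts, code = genetic_code()) {
  vapply(code$families, function(f) sum(counts$counts[f$codons]), 0L)
}

#' Classify genes into centromeric / telomeric / interior compartments
#'
#' A gene is centromeric if its start lies within `window_mb` of either
#' centromere boundary (or inside the centromere), telomeric if within
#' `window_mb` of a chromosome end; a gene qualifying for both is labelled
#' centromeric (with a warning).
#'
#' @param record a [transcript_record] with `chrom` and `start` set.
#' @param cen_table data frame with columns `chrom`, `cen_start`, `cen_end`,
#'   `chrom_length` (bp).
#' @param window_mb window size in megabases (10 by default; 5 and 20 are
#'   used in sensitivity analyses).
#' @return `"centromeric"`, `"telomeric"`, `"interior"`, or `"unclassified"`.
#' @export
classify_compartment <- function(record, cen_table, window_mb = 10) {
  w <- window_mb * 1e6
  row <- cen_table[cen_table$chrom == record$chrom, , drop = FALSE]
  if (nrow(row) == 0L) {
    warning("chromosome '", record$chrom, "' absent from compartment table; ",
            "gene '", record$gene_id, "' unclassified")
    return("unclassified")
  }
  pos <- record$start
  d_cen <- if (pos >= row$cen_start && pos <= row$cen_end) 0 else
    min(abs(pos - row$cen_start), abs(pos - row$cen_end))
  d_tel <- min(pos, row$chrom_length - pos)
  cen <- d_cen <= w
  tel <- d_tel <= w
  if (cen && tel) {
    warning("gene '", record$gene_id,
            "' within window of both centromere and telomere; ",
            "labelled centromeric")
    return("centromeric")
  }
  if (cen) "centromeric" else if (tel) "telomeric" else "interior"
}

# evaluate `expr` under a fixed RNG state without disturbing the caller's
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
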