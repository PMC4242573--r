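# build a codon_counts object from a (possibly partial) named count vector
make_counts <- function(x) {
  gc <- genetic_code()
  counts <- stats::setNames(integer(61L), gc$codons)
  counts[names(x)] <- as.integer(x)
  structure(list(counts = counts, n = sum(counts), skipped = 0L,
                 stops = 0L),
            class = "codon_counts")
}

# multinomial codon counts at given probabilities
random_counts <- function(n, prob, seed = 1) {
  gc <- genetic_code()
  withr::with_seed(seed, {
    draw <- stats::rmultinom(1, n, prob)[, 1]
  })
  make_counts(stats::setNames(draw, gc$codons))
}

# a background_composition with given A/C/G/T frequencies
make_background <- function(freqs) {
  structure(list(freqs = freqs / sum(freqs), source = "flank",
                 bases = 1000L),
            class = "background_composition")
}

uniform_pi <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
mammal_pi <- c(A = 0.295, C = 0.205, G = 0.205, T = 0.295)

# random FMutSel parameter draw for property tests
random_model_params <- function(seed) {
  withr::with_seed(seed, {
    ps <- stats::runif(4, 0.5, 2)
    ps <- stats::setNames(ps / sum(ps), c("A", "C", "G", "T"))
    gc <- genetic_code()
    F <- stats::setNames(stats::rnorm(61, 0, 1), gc$codons)
    list(kappa = stats::runif(1, 0.5, 8), pi_star = ps, F = F,
         t = stats::runif(1, 0.02, 1))
  })
}
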