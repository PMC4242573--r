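# independent transcription of the ENC formula, kept deliberately separate
# from the package's implementation
enc_oracle <- function(counts, code = genetic_code()) {
  cv <- counts$counts
  per_class <- list()
  for (f in code$families) {
    n <- sum(cv[f$codons])
    if (n < 2) next
    p <- cv[f$codons] / n
    Fh <- (n * sum(p^2) - 1) / (n - 1)
    if (Fh > 0) {
      per_class[[length(per_class) + 1L]] <- c(f$enc_class, Fh)
    }
  }
  m <- do.call(rbind, per_class)
  fbar <- sapply(c(2, 3, 4, 6), function(k) mean(m[m[, 1] == k, 2]))
  if (is.nan(fbar[2])) fbar[2] <- mean(fbar[c(1, 3)])
  2 + sum(c(9, 1, 5, 3) / fbar)
}

encp_oracle <- function(counts, bg, code = genetic_code()) {
  cv <- counts$counts
  per_class <- list()
  for (f in code$families) {
    n <- sum(cv[f$codons])
    if (n < 2) next
    p <- cv[f$codons] / n
    e <- sapply(strsplit(f$codons, ""), function(b) prod(bg$freqs[b]))
    e <- e / sum(e)
    chi2 <- n * sum((p - e)^2 / e)
    Fp <- (chi2 + n - f$k) / (f$k * (n - 1))
    if (Fp > 0) per_class[[length(per_class) + 1L]] <- c(f$enc_class, Fp)
  }
  m <- do.call(rbind, per_class)
  fbar <- sapply(c(2, 3, 4, 6), function(k) mean(m[m[, 1] == k, 2]))
  if (is.nan(fbar[2])) fbar[2] <- mean(fbar[c(1, 3)])
  2 + sum(c(9, 1, 5, 3) / fbar)
}

test_that("background composition pools sources and enforces minima", {
  rec <- transcript_record("g", "t", cds = "ATG",
                           introns = c(strrep("A", 500), strrep("C", 499)),
                           flank_up = "AAAA", flank_down = "TTTT")
  bg <- background_composition(rec, "flank")
  expect_equal(unname(bg$freqs), c(0.5, 0, 0, 0.5))
  expect_identical(bg$bases, 8)
  expect_warning(dropped <- background_composition(rec, "introns"),
                 "999.*dropped")
  expect_null(dropped)
  # uniform random fixture: frequencies within 3 SE of 0.25
  cfg <- sim_config(seed = 2, pi_star = uniform_pi)
  rec2 <- gen_gene(cfg, "g2", seed = 2)
  bg2 <- background_composition(rec2, "flank")
  se <- sqrt(0.25 * 0.75 / bg2$bases)
  expect_true(all(abs(bg2$freqs - 0.25) < 3 * se))
})

test_that("ENC attains its analytic limits", {
  gc <- genetic_code()
  uniform <- make_counts(stats::setNames(rep(100L, 61), gc$codons))
  expect_equal(as.numeric(enc(uniform)), 61)
  expect_gt(attr(enc(uniform), "raw"), 61)
  one_per_aa <- integer(0)
  for (a in unique(gc$aa)) {
    one_per_aa[names(gc$aa)[gc$aa == a][1]] <- 100L
  }
  expect_equal(as.numeric(enc(make_counts(one_per_aa))), 20)
})

test_that("ENC matches an independent formula evaluation on skewed usage", {
  for (seed in 1:5) {
    counts <- random_counts(500, stats::runif(61, 0.2, 1), seed = seed)
    expect_equal(as.numeric(attr(enc(counts), "raw")),
                 enc_oracle(counts), tolerance = 1e-12)
  }
})

test_that("expected family frequencies follow base-product weights", {
  code <- genetic_code()
  ef <- expected_family_frequencies(code, make_background(uniform_pi))
  for (f in code$families) {
    expect_equal(unname(ef[[f$name]]), rep(1 / f$k, f$k))
  }
  # hand product oracle on the Gly fourfold family (GGA/GGC/GGG/GGT)
  bg <- make_background(c(A = 0.3, C = 0.1, G = 0.4, T = 0.2))
  w <- c(GGA = .4 * .4 * .3, GGC = .4 * .4 * .1, GGG = .4 * .4 * .4,
         GGT = .4 * .4 * .2)
  expect_equal(ef2 <- expected_family_frequencies(code, bg)$G,
               w / sum(w))
  # a zero background frequency empties all-T-codon families
  bg0 <- make_background(c(A = 1 / 3, C = 1 / 3, G = 1 / 3, T = 0))
  w0 <- capture_warnings(ef0 <- expected_family_frequencies(code, bg0))
  expect_true(any(grepl("excluded", w0)))
  expect_null(ef0$F)  # Phe = TTT/TTC has zero expectation everywhere
})

test_that("ENCp equals ENC under a uniform background", {
  for (seed in 1:100) {
    counts <- random_counts(800, stats::runif(61, 0.05, 1), seed = seed)
    r <- encp(counts, make_background(uniform_pi))
    expect_lt(abs(r$enc_raw - r$encp_raw), 1e-9)
  }
})

test_that("ENCp strips mutational bias that ENC misreads as selection", {
  # GC-rich mutational background, usage sampled exactly at expectation
  bg <- make_background(c(A = 0.15, C = 0.35, G = 0.35, T = 0.15))
  code <- genetic_code()
  ef <- expected_family_frequencies(code, bg)
  prob <- stats::setNames(numeric(61), code$codons)
  for (f in code$families) prob[f$codons] <- ef[[f$name]] / 18
  prob[c("ATG", "TGG")] <- mean(prob[prob > 0])
  counts <- random_counts(20000, prob, seed = 4)
  r <- encp(counts, bg)
  expect_lt(r$enc, 61 - 1)      # ENC alone reports bias
  expect_gt(r$encp, 60.5)       # ENCp recognizes it as mutational
  expect_gt(r$encp, r$enc)
  expect_equal(r$encp_raw, encp_oracle(counts, bg), tolerance = 1e-12)
})

test_that("usage chi-square matches hand computation and is null-calibrated", {
  # counts exactly at expectation: chi2 = 0, p = 1
  bg <- make_background(uniform_pi)
  lys <- make_counts(c(AAA = 50L, AAG = 50L))
  s0 <- encp_significance(lys, bg)
  expect_equal(s0$chi2, 0)
  expect_equal(s0$p, 1)
  # one twofold family, counts (90, 10) vs e = (0.5, 0.5): chi2 = 64
  s1 <- encp_significance(make_counts(c(AAA = 90L, AAG = 10L)), bg)
  expect_equal(s1$chi2, 64)
  expect_identical(s1$df, 1L)
  expect_equal(s1$p, stats::pchisq(64, 1, lower.tail = FALSE))
  # p-values uniform when counts are multinomial at the expectation
  code <- genetic_code()
  ef <- expected_family_frequencies(code, bg)
  prob <- stats::setNames(numeric(61), code$codons)
  for (f in code$families) prob[f$codons] <- ef[[f$name]]
  prob <- prob / sum(prob)
  pvals <- vapply(1:1000, function(s) {
    encp_significance(random_counts(600, prob, seed = s), bg)$p
  }, 0)
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("BH correction applies the step-up rule", {
  flags <- bh_correct(c(0.01, 0.02, 0.03, 0.9), alpha = 0.05)
  expect_identical(as.logical(flags), c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(attr(flags, "q"), stats::p.adjust(c(.01, .02, .03, .9), "BH"))
  expect_false(any(bh_correct(rep(1, 10))))
  expect_true(bh_correct(0.04)[1])
  # flags monotone in p
  p <- sort(stats::runif(50))
  f <- as.logical(bh_correct(p))
  expect_true(all(diff(f) <= 0))
})

test_that("transcript-choice averaging handles missing iterations", {
  its <- list(c(a = 50, b = 48), c(a = 50, b = 49), c(a = 50, b = 50),
              c(a = 50, b = 51), c(a = 50, b = 52))
  m <- aggregate_transcript_choices(its)
  expect_equal(unname(m["a"]), 50)
  expect_equal(unname(m["b"]), 50)
  its[[3]] <- c(a = 50)
  expect_warning(m2 <- aggregate_transcript_choices(its), "missing")
  expect_equal(unname(m2["b"]), mean(c(48, 49, 51, 52)))
})

test_that("per-family bias spans its feasible range", {
  bg <- make_background(uniform_pi)
  # uniform twofold usage, large n: close to k = 2
  expect_equal(per_family_encp(make_counts(c(AAA = 500L, AAG = 500L)),
                               bg, "K"), 2, tolerance = 0.01)
  # single codon used in a fourfold family: close to 1
  expect_equal(per_family_encp(make_counts(c(GGA = 400L)), bg, "G"), 1,
               tolerance = 0.02)
  expect_true(is.na(per_family_encp(make_counts(c(GGA = 1L)), bg, "G")))
  # arbitrary fixture equals direct formula evaluation
  cts <- make_counts(c(GGA = 10L, GGC = 35L, GGG = 4L, GGT = 1L))
  n <- 50; p <- c(10, 35, 4, 1) / 50; e <- rep(.25, 4)
  chi2 <- n * sum((p - e)^2 / e)
  Fp <- (chi2 + n - 4) / (4 * (n - 1))
  expect_equal(per_family_encp(cts, bg, "G"), 1 / Fp)
})

test_that("scale invariance and monotonicity of the ENC estimator", {
  # per-family totals of several hundred make the 1/(n-1) corrections
  # negligible, so a tenfold count inflation barely moves the estimate
  counts <- random_counts(100000, stats::runif(61, 0.3, 1), seed = 8)
  big <- make_counts(counts$counts * 10L)
  expect_lt(abs(attr(enc(counts), "raw") - attr(enc(big), "raw")), 0.05)
  # two-codon family contribution peaks at balanced usage
  vals <- sapply(c(.5, .6, .75, .9, .99), function(q) {
    f <- (10000 * (q^2 + (1 - q)^2) - 1) / (10000 - 1)
    1 / f
  })
  expect_true(all(diff(vals) < 0))
})
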