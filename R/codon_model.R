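# Precomputed structures for the 61-codon state space: base indices per
# codon position, the ordered single-nucleotide neighbour list with
# transition flags, and the amino acid index of each codon.
codon_space <- function() {
  if (!is.null(.cm_cache$space)) return(.cm_cache$space)
  code <- genetic_code()
  codons <- code$codons
  bases <- c("A", "C", "G", "T")
  base_idx <- t(vapply(strsplit(codons, ""),
                       function(b) match(b, bases) - 1L, integer(3L)))
  rownames(base_idx) <- codons
  nbr <- list()
  for (i in seq_along(codons)) {
    bi <- strsplit(codons[i], "")[[1]]
    for (j in seq_along(codons)) {
      if (i == j) next
      bj <- strsplit(codons[j], "")[[1]]
      diff <- which(bi != bj)
      if (length(diff) != 1L) next
      ts <- paste(sort(c(bi[diff], bj[diff])), collapse = "") %in%
        c("AG", "CT")
      nbr[[length(nbr) + 1L]] <- c(i - 1L, j - 1L,
                                   match(bj[diff], bases) - 1L,
                                   as.integer(ts))
    }
  }
  nbr <- do.call(rbind, nbr)
  storage.mode(nbr) <- "integer"
  aa <- code$aa[codons]
  aa_levels <- sort(unique(aa))
  space <- list(codons = codons, base_idx = base_idx, nbr = nbr,
                aa = aa, aa_levels = aa_levels,
                aa_idx = match(aa, aa_levels))
  .cm_cache$space <- space
  space
}
.cm_cache <- new.env(parent = emptyenv())

#' Stationary codon distribution of the mutation-selection model
#'
#' \eqn{\pi_j \propto \pi^*_{j1}\pi^*_{j2}\pi^*_{j3} e^{F_j}} over the 61
#' sense codons.  This single definition is shared by the model fitter and
#' the sequence simulator.
#'
#' @param pi_star mutational base frequencies (named A/C/G/T, summing to 1).
#' @param F codon fitness vector over the 61 sense codons (alphabetical
#'   codon order).
#' @return Named numeric vector of codon frequencies summing to 1.
#' @export
stationary_codon_dist <- function(pi_star, F) {
  sp <- codon_space()
  pi <- cm_stationary(as.numeric(pi_star[c("A", "C", "G", "T")]),
                      as.numeric(F), sp$base_idx)
  stats::setNames(as.numeric(pi), sp$codons)
}

#' FMutSel rate matrix
#'
#' Builds the 61x61 generator of the mutation-selection codon model: for
#' single-nucleotide codon changes i -> j,
#' \eqn{q_{ij} = \kappa^{[ts]} \pi^*_b \, h(F_j - F_i)} with
#' \eqn{h(S) = S/(1 - e^{-S})} and \eqn{h(0) = 1}; multi-nucleotide changes
#' have rate zero and the diagonal is minus the row sum.  The generator
#' satisfies detailed balance against [stationary_codon_dist].
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param pi_star mutational base frequencies.
#' @param F codon fitness vector (length 61).
#' @return 61x61 numeric matrix with codon dimnames.
#' @export
fmutsel_rate_matrix <- function(kappa, pi_star, F) {
  stopifnot(kappa > 0, length(F) == 61L)
  sp <- codon_space()
  Q <- cm_rate_matrix(kappa, as.numeric(pi_star[c("A", "C", "G", "T")]),
                      as.numeric(F), sp$nbr)
  dimnames(Q) <- list(sp$codons, sp$codons)
  Q
}

#' Transition probabilities of the FMutSel model
#'
#' \eqn{P(t) = e^{Qt}} computed through the symmetrized eigendecomposition
#' of the reversible generator.
#'
#' @inheritParams fmutsel_rate_matrix
#' @param t branch length (>= 0).
#' @return 61x61 stochastic matrix.
#' @export
codon_transition_matrix <- function(kappa, pi_star, F, t) {
  sp <- codon_space()
  P <- cm_transition_matrix(kappa,
                            as.numeric(pi_star[c("A", "C", "G", "T")]),
                            as.numeric(F), t, sp$nbr, sp$base_idx)
  dimnames(P) <- list(sp$codons, sp$codons)
  P
}

#' Codon-pair count matrix of a pairwise alignment
#'
#' @param seq1,seq2 in-frame codon sequences of equal length (ACGT only;
#'   mask the alignment first, see [mask_ortholog_codons]).
#' @return 61x61 count matrix over ordered codon pairs.
#' @export
codon_pair_counts <- function(seq1, seq2) {
  sp <- codon_space()
  c1 <- split_codons(seq1)
  c2 <- split_codons(seq2)
  stopifnot(length(c1) == length(c2))
  i <- match(c1, sp$codons)
  j <- match(c2, sp$codons)
  if (anyNA(i) || anyNA(j)) {
    stop("input error: codon outside the 61 sense codons ",
         "(stop codon or ambiguity in the alignment?)")
  }
  N <- matrix(0, 61L, 61L, dimnames = list(sp$codons, sp$codons))
  for (k in seq_along(i)) N[i[k], j[k]] <- N[i[k], j[k]] + 1
  N
}

#' Pairwise log-likelihood under the FMutSel model
#'
#' \eqn{\log L = \sum_{\mathrm{sites}} \log(\pi_i [e^{Qt}]_{ij})} over the
#' observed codon pairs; the model is reversible, so the value does not
#' depend on which sequence is treated as ancestral.
#'
#' @param N 61x61 codon-pair count matrix (see [codon_pair_counts]), or a
#'   named character vector of two aligned sequences.
#' @inheritParams codon_transition_matrix
#' @return Log-likelihood (numeric scalar).
#' @export
pair_log_likelihood <- function(N, kappa, pi_star, F, t) {
  if (is.character(N)) N <- codon_pair_counts(N[[1L]], N[[2L]])
  sp <- codon_space()
  cm_loglik(N, kappa, as.numeric(pi_star[c("A", "C", "G", "T")]),
            as.numeric(F), t, sp$nbr, sp$base_idx)
}

# parameter packing: theta = (log kappa, eta_C, eta_G, eta_T, log t, F...)
# pi* = softmax(0, eta); FMutSel frees 60 codon fitnesses (first codon
# fixed at 0), FMutSel0 frees 19 amino acid fitnesses (first amino acid
# fixed at 0)
cm_unpack <- function(theta, model) {
  sp <- codon_space()
  kappa <- exp(theta[1L])
  eta <- theta[2:4]
  pi_star <- exp(c(0, eta))
  pi_star <- pi_star / sum(pi_star)
  names(pi_star) <- c("A", "C", "G", "T")
  t <- exp(theta[5L])
  if (model == "FMutSel") {
    F <- c(0, theta[-(1:5)])
  } else {
    Faa <- c(0, theta[-(1:5)])
    F <- Faa[sp$aa_idx]
  }
  list(kappa = kappa, pi_star = pi_star, t = t,
       F = stats::setNames(F, sp$codons))
}

cm_n_free <- function(model) if (model == "FMutSel") 60L else 19L

# data-driven starting point: empirical base/codon frequencies and the raw
# proportion of differing codon sites
cm_start <- function(N, model) {
  sp <- codon_space()
  usage <- rowSums(N) + colSums(N)
  usage <- usage + 0.5
  f <- usage / sum(usage)
  base_f <- rep(1e-3, 4)
  for (pos in 1:3) {
    tab <- tapply(usage, sp$base_idx[, pos] + 1L, sum)
    base_f[as.integer(names(tab))] <- base_f[as.integer(names(tab))] + tab
  }
  base_f <- base_f / sum(base_f)
  eta <- log(base_f[2:4] / base_f[1L])
  mut <- exp(rowSums(matrix(log(base_f[sp$base_idx + 1L]), ncol = 3L)))
  Fhat <- log(f) - log(mut / sum(mut))
  pdiff <- 1 - sum(diag(N)) / max(1, sum(N))
  t0 <- max(0.02, min(3, 1.5 * pdiff))
  if (model == "FMutSel") {
    Ffree <- (Fhat - Fhat[1L])[-1L]
  } else {
    Faa <- tapply(Fhat, sp$aa_idx, mean)
    Ffree <- (Faa - Faa[1L])[-1L]
  }
  c(log(2), eta, log(t0), pmin(10, pmax(-10, Ffree)))
}

#' Fit an FMutSel0 or FMutSel model to a pairwise codon alignment
#'
#' Maximizes the pairwise likelihood over the transition/transversion ratio
#' \eqn{\kappa}, the mutational base frequencies \eqn{\pi^*}, the branch
#' length \eqn{t}, and the codon fitness parameters (19 free amino acid
#' fitnesses for FMutSel0; 60 free codon fitnesses for FMutSel, one codon
#' fixed at 0), using bounded quasi-Newton optimization from a data-driven
#' start plus seeded random restarts.
#'
#' @param aln named character vector of two aligned in-frame sequences, or
#'   a 61x61 codon-pair count matrix.
#' @param model `"FMutSel0"` or `"FMutSel"`.
#' @param starts number of optimizer starts (first is data-driven, the rest
#'   jittered).
#' @param seed integer seed for the restarts.
#' @param max_iter iteration cap per start.
#' @param init optional starting parameter list (as returned in a fit) used
#'   to warm-start, e.g. an FMutSel0 fit when fitting FMutSel.
#' @return Object of class `codon_model_fit`: list with `model`, `kappa`,
#'   `pi_star`, `F` (named, length 61), `t`, `logL`, `npar`, `n_codons`,
#'   `convergence` (0 = clean) and `start_logLs`.
#' @export
fit_codon_model <- function(aln, model = c("FMutSel0", "FMutSel"),
                            starts = 5L, seed = 1L, max_iter = 300L,
                            init = NULL) {
  model <- match.arg(model)
  N <- if (is.character(aln)) codon_pair_counts(aln[[1L]], aln[[2L]]) else aln
  if (sum(N) < 100) warning("fewer than 100 aligned codons; ",
                            "estimates will be unstable")
  sp <- codon_space()
  pi_ord <- c("A", "C", "G", "T")
  negll <- function(theta) {
    p <- cm_unpack(theta, model)
    -cm_loglik(N, p$kappa, as.numeric(p$pi_star[pi_ord]),
               as.numeric(p$F), p$t, sp$nbr, sp$base_idx)
  }
  # analytic gradient, chained through the log/softmax reparameterization
  negll_grad <- function(theta) {
    p <- cm_unpack(theta, model)
    ps <- as.numeric(p$pi_star[pi_ord])
    g <- cm_loglik_grad(N, p$kappa, ps, as.numeric(p$F), p$t,
                        sp$nbr, sp$base_idx)
    gps <- as.numeric(g$g_pistar)
    g_eta <- ps[2:4] * (gps[2:4] - sum(ps * gps))
    gF <- as.numeric(g$g_F)
    g_free <- if (model == "FMutSel") gF[-1L] else
      as.numeric(tapply(gF, sp$aa_idx, sum))[-1L]
    out <- -c(g$g_kappa * p$kappa, g_eta, g$g_t * p$t, g_free)
    out[!is.finite(out)] <- 0
    out
  }
  nf <- cm_n_free(model)
  lower <- c(-4, rep(-8, 3), log(1e-4), rep(-15, nf))
  upper <- c(4, rep(8, 3), log(50), rep(15, nf))
  th0 <- cm_start(N, model)
  if (!is.null(init)) {
    th_init <- c(log(init$kappa),
                 log(init$pi_star[2:4] / init$pi_star[1L]),
                 log(max(1e-4, init$t)),
                 if (model == "FMutSel") {
                   (init$F - init$F[1L])[-1L]
                 } else {
                   Faa <- tapply(init$F, sp$aa_idx, mean)
                   (Faa - Faa[1L])[-1L]
                 })
    th0 <- pmin(upper, pmax(lower, th_init))
  }
  fits <- with_seed(seed, {
    lapply(seq_len(max(1L, starts)), function(s) {
      th <- if (s == 1L) th0 else {
        pmin(upper, pmax(lower, th0 + stats::rnorm(length(th0), 0, 0.3)))
      }
      tryCatch(
        stats::optim(th, negll, gr = negll_grad, method = "L-BFGS-B",
                     lower = lower,
                     upper = upper,
                     control = list(maxit = max_iter, factr = 1e7)),
        error = function(e) NULL)
    })
  })
  fits <- fits[!vapply(fits, is.null, TRUE)]
  if (!length(fits)) stop("all optimizer starts failed for model ", model)
  vals <- vapply(fits, `[[`, 0, "value")
  best <- fits[[which.min(vals)]]
  p <- cm_unpack(best$par, model)
  structure(list(model = model, kappa = p$kappa, pi_star = p$pi_star,
                 F = p$F, t = p$t, logL = -best$value,
                 npar = 5L + nf, n_codons = sum(N),
                 convergence = best$convergence,
                 start_logLs = -vals),
            class = "codon_model_fit")
}

#' @export
print.codon_model_fit <- function(x, ...) {
  cat(sprintf("<%s fit: logL = %.3f, kappa = %.2f, t = %.4f, %d codons%s>\n",
              x$model, x$logL, x$kappa, x$t, x$n_codons,
              if (x$convergence != 0) " [convergence flagged]" else ""))
  invisible(x)
}

#' Likelihood-ratio test between nested codon models
#'
#' Twice the difference in maximized log-likelihoods, referred to a
#' chi-square distribution with `df` degrees of freedom.  For FMutSel
#' versus FMutSel0, `df = 41` (60 vs 19 fitness parameters) and the 5%
#' critical value is 56.94.
#'
#' @param fit0 the restricted fit (FMutSel0).
#' @param fit1 the general fit (FMutSel).
#' @param df degrees of freedom.
#' @param alpha significance level.
#' @return Object of class `lrt_result`: list with `statistic` (clipped at
#'   0), `df`, `p`, `critical` (the `1 - alpha` chi-square quantile) and
#'   `significant`.
#' @export
lrt <- function(fit0, fit1, df = 41L, alpha = 0.05) {
  if (df <= 0L) stop("df must be positive")
  stat <- max(0, 2 * (fit1$logL - fit0$logL))
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p = p,
                 critical = stats::qchisq(1 - alpha, df),
                 significant = p <= alpha),  # the critical value rejects
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("<LRT: 2dlogL = %.3f, df = %d, p = %.3g (5%% critical %.2f)>\n",
              x$statistic, x$df, x$p, x$critical))
  invisible(x)
}

weighted_median <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) / sum(w)
  unname(x[which(cw >= 0.5)[1L]])
}

#' Summarize |Ne s| from an FMutSel fit
#'
#' For every synonymous single-nucleotide codon pair (i, j) the scaled
#' selection coefficient is \eqn{S_{ij} = F_j - F_i}; under the convention
#' \eqn{S = 2 N_e s}, \eqn{|N_e s| = |S|/2}.  Reports the median over
#' pairs, both unweighted and weighted by the gene's usage of the two
#' codons.
#'
#' @param fit a converged FMutSel `codon_model_fit`.
#' @param usage optional named codon count vector (e.g. `counts$counts`)
#'   used for the weighted median; defaults to equal weights.
#' @param s_convention `"2Nes"` (default, `|Ne s| = |S|/2`) or `"Nes"`
#'   (`|Ne s| = |S|`).
#' @return List with `median_weighted`, `median_unweighted`, the per-pair
#'   data frame `pairs`, and the convention used.
#' @export
nes_summary <- function(fit, usage = NULL, s_convention = c("2Nes", "Nes")) {
  s_convention <- match.arg(s_convention)
  sp <- codon_space()
  nbr <- sp$nbr
  syn <- nbr[sp$aa[nbr[, 1L] + 1L] == sp$aa[nbr[, 2L] + 1L] &
               nbr[, 1L] < nbr[, 2L], , drop = FALSE]
  i <- syn[, 1L] + 1L
  j <- syn[, 2L] + 1L
  S <- fit$F[j] - fit$F[i]
  nes <- if (s_convention == "2Nes") abs(S) / 2 else abs(S)
  w <- if (is.null(usage)) rep(1, length(i)) else {
    as.numeric(usage[sp$codons[i]] + usage[sp$codons[j]])
  }
  pairs <- data.frame(codon_i = sp$codons[i], codon_j = sp$codons[j],
                      S = as.numeric(S), abs_nes = as.numeric(nes),
                      weight = w, stringsAsFactors = FALSE)
  list(median_weighted = if (sum(w) > 0) weighted_median(nes, w) else NA_real_,
       median_unweighted = stats::median(nes),
       pairs = pairs, s_convention = s_convention)
}
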