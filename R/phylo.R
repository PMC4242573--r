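#' Phylogenetic covariance matrix under Pagel's lambda
#'
#' Brownian-motion tip covariance scaled by lambda: diagonal entries are
#' root-to-tip distances, off-diagonals are lambda times the shared path
#' length of each tip pair.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param lambda Pagel's lambda (0 = star phylogeny, 1 = Brownian).
#' @return n x n covariance matrix with tip-label dimnames.
#' @export
phylo_covariance <- function(tree, lambda = 1) {
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  C <- ape::vcv(tree)
  d <- diag(C)
  C <- C * lambda
  diag(C) <- d
  C
}

# GLS estimates and profile (restricted) log-likelihood at a fixed lambda,
# with the residual variance concentrated out
pgls_core <- function(C0, x, y, lambda, method = "REML") {
  n <- length(y)
  C <- C0 * lambda
  diag(C) <- diag(C0)
  R <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  X <- cbind(1, x)
  Xs <- backsolve(R, X, transpose = TRUE)
  ys <- backsolve(R, y, transpose = TRUE)
  XtX <- crossprod(Xs)
  beta <- tryCatch(solve(XtX, crossprod(Xs, ys)),
                   error = function(e) NULL)
  if (is.null(beta)) return(NULL)
  res <- ys - Xs %*% beta
  rss <- sum(res^2)
  logdet <- 2 * sum(log(diag(R)))
  p <- ncol(X)
  ll <- if (identical(method, "ML")) {
    sigma2 <- max(rss / n, 1e-300)  # keep the profile finite at rss = 0
    -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
  } else {
    sigma2 <- max(rss / (n - p), 1e-300)
    -0.5 * ((n - p) * log(2 * pi * sigma2) + logdet +
              determinant(XtX, logarithm = TRUE)$modulus + (n - p))
  }
  list(beta = as.numeric(beta), rss = rss, XtX = XtX, logLik = ll, n = n)
}

#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' Regresses `y` on `x` across the tips of a phylogeny with residual
#' covariance proportional to the Pagel-lambda structure.  Lambda is
#' estimated by profile restricted maximum likelihood on \[0,
#' `lambda_max`\] (REML, the convention of `nlme::gls`; plain ML is
#' available via `method`); the
#' slope test uses t = slope/SE with df = n - 2, and the correlation-scale
#' effect is \eqn{r = \mathrm{sign}(b)\sqrt{t^2/(t^2 + df)}}.  The
#' estimates depend on the data only through the tree and trait values, so
#' they are invariant to tip input order (see [order_robustness]).
#'
#' @param tree an [ape::phylo].
#' @param x,y named numeric tip traits (names matching tip labels).
#' @param lambda_max upper bound of the lambda search.
#' @param lambda optional fixed lambda (skips profiling).
#' @param method `"REML"` (default) or `"ML"` profile for lambda.
#' @return Object of class `pgls_result`: list with `slope`, `intercept`,
#'   `se`, `t`, `df`, `r`, `p`, `lambda`, `logLik`, `n`.
#' @export
pgls <- function(tree, x, y, lambda_max = 1, lambda = NULL,
                 method = c("REML", "ML")) {
  method <- match.arg(method)
  tips <- tree$tip.label
  stopifnot(all(tips %in% names(x)), all(tips %in% names(y)))
  if (length(tips) < 4L) stop("need at least 4 tips")
  x <- x[tips]; y <- y[tips]
  C0 <- phylo_covariance(tree, 1)
  fit_at <- function(l) pgls_core(C0, x, y, l, method)
  if (is.null(lambda)) {
    prof <- function(l) {
      f <- fit_at(l)
      if (is.null(f)) -Inf else f$logLik
    }
    opt <- stats::optimize(prof, c(0, lambda_max), maximum = TRUE,
                           tol = 1e-6)
    # the optimum can sit at a boundary; compare against both ends
    cand <- c(opt$maximum, 0, lambda_max)
    lambda <- cand[which.max(vapply(cand, prof, 0))]
  }
  f <- fit_at(lambda)
  if (is.null(f)) stop("singular design or non-positive-definite covariance")
  n <- f$n
  df <- n - 2L
  sigma2 <- f$rss / df
  vb <- sigma2 * solve(f$XtX)
  se <- sqrt(vb[2L, 2L])
  if (se == 0) {  # perfect fit
    tval <- sign(f$beta[2L]) * Inf
    p <- 0
    r <- sign(f$beta[2L])
  } else {
    tval <- f$beta[2L] / se
    p <- 2 * stats::pt(-abs(tval), df)
    r <- sign(f$beta[2L]) * sqrt(tval^2 / (tval^2 + df))
  }
  structure(list(slope = f$beta[2L], intercept = f$beta[1L], se = se,
                 t = tval, df = df, r = r, p = p, lambda = lambda,
                 logLik = f$logLik, n = n),
            class = "pgls_result")
}

#' @export
print.pgls_result <- function(x, ...) {
  cat(sprintf(
    "<PGLS: slope = %.4f, t(%d) = %.3f, r = %.3f, p = %.4g, lambda = %.3f>\n",
    x$slope, x$df, x$t, x$r, x$p, x$lambda))
  invisible(x)
}

permutations_of <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in permutations_of(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

#' PGLS robustness to tip input order
#'
#' Repeats the PGLS fit under permuted tip input orders and reports median
#' statistics plus the spread.  For a well-conditioned fit all orders agree
#' to numerical tolerance; the medians are a robustness report, not a
#' correction.
#'
#' @inheritParams pgls
#' @param n_orders number of orders; all `n!` orders are enumerated when
#'   `n_orders` is at least `n!` and the tip count is at most 7, otherwise
#'   `n_orders` random orders are sampled.
#' @param seed seed for sampled orders.
#' @return List with `median_t`, `median_r`, `median_p`, `spread_t`
#'   (max - min), `n_orders`, and the per-order data frame `orders`.
#' @export
order_robustness <- function(tree, x, y, n_orders = 720L, seed = 1L) {
  tips <- tree$tip.label
  n <- length(tips)
  if (n_orders <= 1L) {
    f <- pgls(tree, x, y)
    return(list(median_t = f$t, median_r = f$r, median_p = f$p,
                spread_t = 0, n_orders = 1L,
                orders = data.frame(t = f$t, r = f$r, p = f$p)))
  }
  perms <- if (n <= 7L && factorial(n) <= n_orders) {
    permutations_of(n)
  } else {
    with_seed(seed, replicate(n_orders, sample.int(n), simplify = FALSE))
  }
  C0 <- phylo_covariance(tree, 1)
  stats_df <- do.call(rbind, lapply(perms, function(pm) {
    ord <- tips[pm]
    f <- pgls_ordered(C0[ord, ord], x[ord], y[ord])
    data.frame(t = f$t, r = f$r, p = f$p, lambda = f$lambda)
  }))
  list(median_t = stats::median(stats_df$t),
       median_r = stats::median(stats_df$r),
       median_p = stats::median(stats_df$p),
       spread_t = diff(range(stats_df$t)),
       n_orders = nrow(stats_df), orders = stats_df)
}

# PGLS on a pre-ordered covariance/trait set (used by order_robustness)
pgls_ordered <- function(C0, x, y, lambda_max = 1, method = "REML") {
  prof <- function(l) {
    f <- pgls_core(C0, x, y, l, method)
    if (is.null(f)) -Inf else f$logLik
  }
  opt <- stats::optimize(prof, c(0, lambda_max), maximum = TRUE, tol = 1e-6)
  cand <- c(opt$maximum, 0, lambda_max)
  lambda <- cand[which.max(vapply(cand, prof, 0))]
  f <- pgls_core(C0, x, y, lambda, method)
  n <- f$n; df <- n - 2L
  sigma2 <- f$rss / df
  se <- sqrt(sigma2 * solve(f$XtX)[2L, 2L])
  tval <- f$beta[2L] / se
  list(t = tval, r = sign(f$beta[2L]) * sqrt(tval^2 / (tval^2 + df)),
       p = 2 * stats::pt(-abs(tval), df), lambda = lambda)
}

#' Phylogenetically independent contrasts
#'
#' Standard recursive contrasts (tip-pair differences scaled by the square
#' root of summed, adjusted branch lengths), computed with [ape::pic].
#' Polytomies are resolved to zero-length branches first (with a message).
#'
#' @param tree an [ape::phylo].
#' @param trait named numeric tip trait.
#' @return Numeric vector of n - 1 contrasts (named by internal node).
#' @export
independent_contrasts <- function(tree, trait) {
  if (!ape::is.binary(tree)) {
    message("resolving polytomies to zero-length branches")
    tree <- ape::multi2di(tree, random = FALSE)
  }
  pic <- ape::pic(trait[tree$tip.label], tree)
  if (any(!is.finite(pic))) {
    bad <- names(pic)[!is.finite(pic)]
    stop("zero summed branch length at node(s) ",
         paste(bad, collapse = ", "))
  }
  pic
}

#' Sign test on paired independent contrasts
#'
#' Orients each node so the x-contrast is positive and asks whether the
#' y-contrast tends to share that sign, against a null of 1/2, using a
#' two-sided exact binomial test.  Nodes with a zero x-contrast are
#' dropped (with a warning).
#'
#' @param contrasts_x,contrasts_y aligned contrast vectors.
#' @return List with `n_agree`, `n_total`, `p`.
#' @export
contrast_sign_test <- function(contrasts_x, contrasts_y) {
  stopifnot(length(contrasts_x) == length(contrasts_y))
  keep <- contrasts_x != 0
  if (any(!keep)) {
    warning(sum(!keep), " zero x-contrast(s) dropped")
  }
  ys <- contrasts_y[keep] * sign(contrasts_x[keep])
  n_agree <- sum(ys > 0)
  n_total <- length(ys)
  p <- if (n_total > 0) {
    stats::binom.test(n_agree, n_total, 0.5,
                      alternative = "two.sided")$p.value
  } else NA_real_
  list(n_agree = n_agree, n_total = n_total, p = p)
}

#' Maximum-likelihood ancestral states under Brownian motion
#'
#' Internal-node estimates of a continuous trait via [ape::ace]
#' (restricted ML Brownian reconstruction); polytomies are resolved to
#' zero-length branches first.
#'
#' @param tree an [ape::phylo].
#' @param trait named numeric tip trait.
#' @return Numeric vector of internal-node estimates (named by node
#'   number).
#' @export
ancestral_states <- function(tree, trait) {
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  fit <- ape::ace(trait[tree$tip.label], tree, type = "continuous",
                  method = "REML")
  fit$ace
}

#' Compartment ANCOVA with length covariates
#'
#' Tests whether a per-gene statistic (e.g. ENCp) differs between genomic
#' compartments (X vs autosome, centromeric vs telomeric) after adjusting
#' for exon and intron lengths: `value ~ group + exon_length +
#' intron_length`.
#'
#' @param genes data frame with columns `value`, `group` (factor or
#'   character with >= 2 levels), `exon_length`, `intron_length`.
#' @param log_lengths log10-transform the length covariates.
#' @return List with `effect` (coefficient of the second group level),
#'   `t`, `p`, `term`, and the fitted `lm` object.
#' @export
compartment_ancova <- function(genes, log_lengths = FALSE) {
  genes$group <- factor(genes$group)
  if (nlevels(genes$group) < 2L) stop("need at least 2 groups")
  if (log_lengths) {
    genes$exon_length <- log10(genes$exon_length)
    genes$intron_length <- log10(pmax(1, genes$intron_length))
  }
  fit <- stats::lm(value ~ group + exon_length + intron_length,
                   data = genes)
  co <- summary(fit)$coefficients
  term <- grep("^group", rownames(co), value = TRUE)[1L]
  list(effect = co[term, "Estimate"], t = co[term, "t value"],
       p = co[term, "Pr(>|t|)"], term = term, fit = fit)
}

#' Bootstrap percentile confidence interval for a median
#'
#' @param values numeric vector (length >= 2).
#' @param reps bootstrap replicates.
#' @param level confidence level.
#' @param seed seed for reproducibility.
#' @return List with `median`, `lo`, `hi`.
#' @export
bootstrap_median_ci <- function(values, reps = 10000L, level = 0.95,
                                seed = NULL) {
  stopifnot(length(values) >= 2L)
  meds <- with_seed(seed, {
    vapply(seq_len(reps), function(i) {
      stats::median(sample(values, length(values), replace = TRUE))
    }, 0)
  })
  a <- (1 - level) / 2
  qs <- stats::quantile(meds, c(a, 1 - a), names = FALSE, type = 7)
  list(median = stats::median(values), lo = qs[1L], hi = qs[2L])
}
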