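# brute-force recursive contrasts, transcribed from the textbook algorithm
pic_oracle <- function(tree, x) {
  tree <- stats::reorder(tree, "postorder")
  n <- length(tree$tip.label)
  vals <- c(x[tree$tip.label], rep(NA_real_, tree$Nnode))
  bl <- numeric(n + tree$Nnode)
  bl[tree$edge[, 2]] <- tree$edge.length
  contrasts <- numeric(0)
  for (node in unique(tree$edge[, 1])) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    v <- bl[kids]
    contrasts <- c(contrasts,
                   (vals[kids[1]] - vals[kids[2]]) / sqrt(sum(v)))
    vals[node] <- (vals[kids[1]] / v[1] + vals[kids[2]] / v[2]) /
      (1 / v[1] + 1 / v[2])
    bl[node] <- bl[node] + prod(v) / sum(v)
  }
  contrasts
}

make_tree <- function(seed, n = 8) {
  withr::with_seed(seed, ape::rcoal(n))
}

test_that("the lambda covariance interpolates between star and Brownian", {
  tree <- make_tree(1, 6)
  C1 <- phylo_covariance(tree, 1)
  expect_equal(C1, ape::vcv(tree))
  C0 <- phylo_covariance(tree, 0)
  expect_equal(C0, diag(diag(C1)), ignore_attr = TRUE)
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  expect_equal(phylo_covariance(star, 0.7), diag(4), ignore_attr = TRUE)
  # 4-tip balanced tree: off-diagonals are shared path lengths
  bal <- ape::read.tree(text = "((a:1,b:1):2,(c:1,d:1):2);")
  C <- phylo_covariance(bal, 1)
  expect_equal(C["a", "b"], 2)
  expect_equal(C["a", "c"], 0)
  expect_equal(C["a", "a"], 3)
  bad <- tree; bad$edge.length[1] <- -0.1
  expect_error(phylo_covariance(bad), "negative")
})

test_that("PGLS recovers a perfect linear relationship", {
  tree <- make_tree(2, 10)
  x <- stats::setNames(rnorm(10), tree$tip.label)
  f <- pgls(tree, x, x)
  expect_equal(f$slope, 1, tolerance = 1e-10)
  expect_equal(f$r, 1)
  expect_equal(f$p, 0)
})

test_that("PGLS at lambda = 0 reproduces ordinary least squares", {
  for (seed in 1:10) {
    tree <- make_tree(seed, 12)
    withr::with_seed(100 + seed, {
      x <- stats::setNames(rnorm(12), tree$tip.label)
      y <- stats::setNames(0.5 * x + rnorm(12), tree$tip.label)
    })
    f <- pgls(tree, x, y, lambda = 0)
    # lambda = 0 leaves tip variances (root-to-tip depths) in place; on an
    # ultrametric coalescent tree these are equal, so GLS = OLS
    ols <- stats::lm(y[tree$tip.label] ~ x[tree$tip.label])
    expect_equal(f$slope, unname(coef(ols)[2]), tolerance = 1e-6)
    expect_equal(f$intercept, unname(coef(ols)[1]), tolerance = 1e-6)
    expect_equal(f$t, unname(summary(ols)$coefficients[2, "t value"]),
                 tolerance = 1e-6)
  }
})

test_that("PGLS agrees with the nlme + ape reference implementation", {
  skip_if_not_installed("nlme")
  hits <- 0L
  for (seed in 1:8) {
    cfg <- sim_config(seed = 600 + seed, n_tips = 25, slope = -0.4,
                      lambda_y = 0.8)
    tt <- gen_trait_tree(cfg)
    x <- stats::setNames(tt$traits$x, tt$traits$tip)
    y <- stats::setNames(tt$traits$y, tt$traits$tip)
    mine <- pgls(tt$tree, x, y)
    d <- data.frame(x = x[tt$tree$tip.label], y = y[tt$tree$tip.label],
                    row.names = tt$tree$tip.label)
    ref <- tryCatch(
      suppressWarnings(
        nlme::gls(y ~ x, data = d,
                  correlation = ape::corPagel(0.5, tt$tree, form = ~1))),
      error = function(e) NULL)
    if (is.null(ref)) next
    lam_ref <- stats::coef(ref$modelStruct$corStruct, unconstrained = FALSE)
    if (lam_ref < 0 || lam_ref > 1) next  # outside our feasibility bound
    expect_equal(mine$slope, unname(stats::coef(ref)[2]), tolerance = 0.02)
    expect_equal(mine$lambda, unname(lam_ref), tolerance = 0.05)
    hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("PGLS statistics are invariant to tip input order", {
  cfg <- sim_config(seed = 77, n_tips = 6, slope = -0.5)
  tt <- gen_trait_tree(cfg)
  x <- stats::setNames(tt$traits$x, tt$traits$tip)
  y <- stats::setNames(tt$traits$y, tt$traits$tip)
  rob <- order_robustness(tt$tree, x, y, n_orders = 720)
  expect_identical(rob$n_orders, 720L)
  expect_lt(rob$spread_t, 1e-6)
  base <- pgls(tt$tree, x, y)
  expect_equal(rob$median_t, base$t, tolerance = 1e-6)
  one <- order_robustness(tt$tree, x, y, n_orders = 1)
  expect_equal(one$median_t, base$t)
})

test_that("independent contrasts match the brute-force recursion", {
  two <- ape::read.tree(text = "(a:1,b:1);")
  expect_equal(unname(independent_contrasts(two, c(a = 3, b = 1))),
               2 / sqrt(2), tolerance = 1e-12)
  tree <- make_tree(4, 8)
  flat <- stats::setNames(rep(5, 8), tree$tip.label)
  expect_true(all(independent_contrasts(tree, flat) == 0))
  withr::with_seed(9, x <- stats::setNames(rnorm(8), tree$tip.label))
  expect_equal(sort(abs(unname(independent_contrasts(tree, x)))),
               sort(abs(unname(pic_oracle(tree, x)))), tolerance = 1e-10)
})

test_that("the contrast sign test counts co-directional changes", {
  tree <- make_tree(5, 12)
  withr::with_seed(10, x <- stats::setNames(rnorm(12), tree$tip.label))
  cx <- independent_contrasts(tree, x)
  same <- contrast_sign_test(cx, cx)
  expect_identical(same$n_agree, same$n_total)
  opp <- contrast_sign_test(cx, -cx)
  expect_identical(opp$n_agree, 0L)
  # exact binomial tail by full enumeration: 22 agreements of 40
  d <- stats::dbinom(0:40, 40, 0.5)
  enum <- sum(d[d <= stats::dbinom(22, 40, 0.5) + 1e-12])
  fake_x <- rep(1, 40)
  fake_y <- c(rep(1, 22), rep(-1, 18))
  res <- contrast_sign_test(fake_x, fake_y)
  expect_identical(res$n_agree, 22L)
  expect_equal(res$p, enum, tolerance = 1e-12)
  expect_gt(res$p, 0.6)
  expect_warning(contrast_sign_test(c(0, 1), c(1, 1)), "zero")
})

test_that("ancestral states follow the Brownian conditional mean", {
  two <- ape::read.tree(text = "(a:1,b:1);")
  expect_equal(unname(ancestral_states(two, c(a = 2, b = 6))[1]), 4,
               tolerance = 1e-6)
  tree <- make_tree(6, 8)
  const <- stats::setNames(rep(3.3, 8), tree$tip.label)
  # a constant trait has zero Brownian variance; ace warns but the
  # reconstruction is still exact
  expect_equal(unname(suppressWarnings(ancestral_states(tree, const))),
               rep(3.3, tree$Nnode), tolerance = 1e-6)
  # GLS oracle: anc = C_nt C_tt^{-1} x for the root-extended covariance
  withr::with_seed(12, x <- stats::setNames(rnorm(8), tree$tip.label))
  est <- ancestral_states(tree, x)
  full <- ape::vcv(tree)
  # oracle for the root: the Brownian ML estimate is the GLS generalized
  # mean (1'C^-1 x)/(1'C^-1 1)
  Ci <- solve(full)
  root_hat <- sum(Ci %*% x[tree$tip.label]) / sum(Ci)
  expect_equal(unname(est[1]), unname(root_hat), tolerance = 1e-4)
})

test_that("the compartment ANCOVA isolates the group effect from length", {
  withr::with_seed(31, {
    n <- 2000
    grp <- rep(c("A", "X"), each = n / 2)
    ex_len <- stats::runif(n, 200, 3000)
    in_len <- stats::runif(n, 500, 20000)
    val <- 50 + 0.5 * (grp == "X") + 1e-4 * ex_len + rnorm(n, 0, 1)
    genes <- data.frame(value = val, group = grp, exon_length = ex_len,
                        intron_length = in_len)
  })
  fit <- compartment_ancova(genes)
  expect_identical(fit$term, "groupX")
  expect_equal(fit$effect, 0.5, tolerance = 0.15)
  expect_lt(fit$p, 1e-6)
  # a shift explained entirely by a length covariate is absorbed by it
  withr::with_seed(32, {
    ex2 <- c(stats::runif(1000, 200, 1000), stats::runif(1000, 2000, 3000))
    val2 <- 50 + 1e-3 * ex2 + rnorm(2000, 0, 0.2)
    genes2 <- data.frame(value = val2, group = rep(c("A", "X"), each = 1000),
                         exon_length = ex2, intron_length = 1000)
  })
  fit2 <- compartment_ancova(genes2)
  expect_lt(abs(fit2$effect), 0.1)
  expect_error(compartment_ancova(data.frame(
    value = 1:5, group = "A", exon_length = 1, intron_length = 1)),
    "2 groups")
})

test_that("bootstrap median intervals behave and reproduce under a seed", {
  cst <- bootstrap_median_ci(rep(7, 50), reps = 200, seed = 1)
  expect_equal(cst$lo, 7)
  expect_equal(cst$hi, 7)
  rng <- bootstrap_median_ci(1:1001, reps = 2000, seed = 2)
  expect_equal(rng$median, 501)
  expect_true(rng$lo <= 501 && 501 <= rng$hi)
  again <- bootstrap_median_ci(1:1001, reps = 2000, seed = 2)
  expect_identical(rng, again)
  # coverage of the true median near the nominal level
  withr::with_seed(3, {
    cover <- mean(vapply(1:200, function(r) {
      v <- rnorm(500)
      ci <- bootstrap_median_ci(v, reps = 1000, seed = r)
      ci$lo <= 0 && 0 <= ci$hi
    }, TRUE))
  })
  expect_gt(cover, 0.90)
  expect_lte(cover, 1)
})
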