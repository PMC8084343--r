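test_that("contrasts follow Felsenstein's algorithm on a cherry", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  cs <- pic_contrasts(tr, c(A = 3, B = 1))
  expect_equal(unname(cs$contrasts), 2 / sqrt(2), tolerance = 1e-12)
})

test_that("constant traits give all-zero contrasts, count = tips - 1", {
  set.seed(5)
  tr <- ape::rtree(12)
  cs <- pic_contrasts(tr, stats::setNames(rep(3.5, 12), tr$tip.label))
  expect_equal(unname(cs$contrasts), rep(0, 11))
  expect_equal(length(cs$contrasts), ape::Ntip(cs$tree) - 1)
})

test_that("contrasts agree with the independent ape implementation", {
  set.seed(17)
  for (i in 1:25) {
    tr <- ape::rtree(sample(5:20, 1))
    x <- stats::setNames(rnorm(ape::Ntip(tr)), tr$tip.label)
    mine <- pic_contrasts(tr, x)
    ref <- ape::pic(x[tr$tip.label], tr)
    expect_equal(unname(mine$contrasts[names(ref)]), unname(ref),
                 tolerance = 1e-10)
  }
})

test_that("contrasts are permutation-invariant up to sign", {
  set.seed(23)
  tr <- ape::rtree(10)
  x <- stats::setNames(rnorm(10), tr$tip.label)
  a <- sort(abs(pic_contrasts(tr, x)$contrasts))
  b <- sort(abs(pic_contrasts(tr, x[sample(names(x))])$contrasts))
  expect_equal(unname(a), unname(b), tolerance = 1e-12)
})

test_that("missing tips and bad branch lengths are reported", {
  tr <- ape::rtree(6)
  x <- stats::setNames(rnorm(6), c(tr$tip.label[-1], "ghost"))
  expect_error(pic_contrasts(tr, x), "ghost")
  # tips without trait values are pruned
  cs <- pic_contrasts(tr, stats::setNames(rnorm(4), tr$tip.label[1:4]))
  expect_equal(length(cs$contrasts), 3)
})

test_that("PIC regression through the origin recovers exact relations", {
  set.seed(31)
  tr <- ape::rtree(20)
  x <- stats::setNames(rnorm(20), tr$tip.label)
  xc <- pic_contrasts(tr, x)
  yc <- xc; yc$contrasts <- 2 * xc$contrasts
  fit <- suppressWarnings(pic_regression(xc, yc))  # exact fit warns in lm
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_lt(fit$p_value, 1e-12)
  expect_equal(fit$df, 20 - 2)
  expect_error(pic_regression(xc, pic_contrasts(ape::rtree(5),
    stats::setNames(rnorm(5), paste0("t", 1:5)))), "same tree")
})

test_that("PIC slope recovers a simulated coupling", {
  set.seed(47)
  est <- se <- numeric(50)
  for (i in 1:50) {
    tr <- ape::rcoal(40)
    x <- ape::rTraitCont(tr, sigma = 1)
    y <- 0.6 * x + ape::rTraitCont(tr, sigma = 0.3)
    fit <- pic_regression(pic_contrasts(tr, x), pic_contrasts(tr, y))
    est[i] <- fit$slope; se[i] <- fit$se
  }
  # unbiasedness: one-sample t-test of the slope estimates against truth
  expect_gt(stats::t.test(est, mu = 0.6)$p.value, 0.01)
})

test_that("PGLS equals OLS on a star tree and nlme on ultrametric trees", {
  set.seed(53)
  star <- ape::stree(15, "star")
  star$edge.length <- rep(1, nrow(star$edge))
  x <- stats::setNames(rnorm(15), star$tip.label)
  y <- stats::setNames(1 + 0.5 * x + rnorm(15, 0, 0.2), star$tip.label)
  m <- pgls_fit(star, y, x)
  ols <- stats::lm(y[star$tip.label] ~ x[star$tip.label])
  expect_equal(unname(m$coefficients), unname(stats::coef(ols)),
               tolerance = 1e-6)
  skip_if_not_installed("nlme")
  tr <- ape::rcoal(25)
  x2 <- stats::setNames(rnorm(25), tr$tip.label)
  y2 <- stats::setNames(0.3 + 0.8 * x2 + rnorm(25, 0, 0.3), tr$tip.label)
  m2 <- pgls_fit(tr, y2, x2)
  d <- data.frame(y = y2[tr$tip.label], x = x2[tr$tip.label],
                  sp = tr$tip.label)
  g <- nlme::gls(y ~ x, data = d,
                 correlation = ape::corBrownian(1, tr, form = ~sp))
  expect_equal(unname(m2$coefficients), unname(stats::coef(g)),
               tolerance = 1e-6)
})

test_that("PGLS slope equals the through-origin PIC slope", {
  set.seed(59)
  for (i in 1:10) {
    tr <- ape::rtree(15)
    x <- stats::setNames(rnorm(15), tr$tip.label)
    y <- stats::setNames(0.4 * x + rnorm(15, 0, 0.5), tr$tip.label)
    pic_slope <- pic_regression(pic_contrasts(tr, x),
                                pic_contrasts(tr, y))$slope
    pgls_slope <- pgls_fit(tr, y, x)$coefficients[["x"]]
    expect_equal(pic_slope, pgls_slope, tolerance = 1e-8)
  }
})

test_that("PGLS prediction is the affine fixed-effects map", {
  set.seed(61)
  tr <- ape::rcoal(20)
  x <- stats::setNames(runif(20), tr$tip.label)
  y <- stats::setNames(0.1 + 0.8 * x + rnorm(20, 0, 0.05), tr$tip.label)
  m <- pgls_fit(tr, y, x)
  b <- m$coefficients
  expect_equal(unname(pgls_predict(m, c(new = 0))), unname(b[1]))
  expect_equal(unname(pgls_predict(m, c(new = 0.5))),
               unname(b[1] + 0.5 * b[2]))
  expect_warning(pgls_predict(m, c(new = 1.7)), "outside")
})

test_that("held-out prediction error is bounded on synthetic truth", {
  set.seed(67)
  ok <- 0; total <- 0
  for (rep_i in 1:10) {
    tr <- ape::rcoal(30)
    x <- stats::setNames(runif(30), tr$tip.label)
    y <- stats::setNames(0.2 + 0.6 * x + rnorm(30, 0, 0.08), tr$tip.label)
    hold <- tr$tip.label[1:3]
    m <- pgls_fit(ape::drop.tip(tr, hold), y[setdiff(tr$tip.label, hold)],
                  x[setdiff(tr$tip.label, hold)])
    pred <- pgls_predict(m, x[hold])
    rsd <- sqrt(m$sigma2 * mean(diag(ape::vcv(tr))))
    ok <- ok + sum(abs(pred - y[hold]) <= 2 * rsd)
    total <- total + 3
  }
  expect_gte(ok / total, 0.9)
})

test_that("residual outliers are flagged by injection, not invented", {
  set.seed(71)
  clean_empty <- 0
  for (i in 1:20) {
    tr <- ape::rcoal(30)
    x <- stats::setNames(rnorm(30), tr$tip.label)
    y <- stats::setNames(0.5 * x + ape::rTraitCont(tr, sigma = 0.3),
                         tr$tip.label)
    m <- pgls_fit(tr, y, x)
    clean_empty <- clean_empty + (length(residual_outliers(m)) == 0)
  }
  expect_gte(clean_empty, 19)
  # inject a 10-SD perturbation
  tr <- ape::rcoal(30)
  x <- stats::setNames(rnorm(30), tr$tip.label)
  y <- stats::setNames(0.5 * x + ape::rTraitCont(tr, sigma = 0.3),
                       tr$tip.label)
  m0 <- pgls_fit(tr, y, x)
  y2 <- y
  y2["t5"] <- y["t5"] + 10 * sqrt(m0$sigma2)
  m1 <- pgls_fit(tr, y2, x)
  expect_true("t5" %in% residual_outliers(m1))
  expect_equal(residual_outliers(m1, k = Inf), character(0))
})
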