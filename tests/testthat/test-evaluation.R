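counts_tbl <- function(ids, counts) tibble::tibble(plot_id = ids, boll_count = counts)
truth_tbl <- function(ids, counts, geno = "G1")
  tibble::tibble(plot_id = ids, genotype = geno, boll_count = counts)

test_that("count regression reproduces the hand-evaluated error metrics", {
  ids <- c("a", "b", "c")
  # identity: perfect prediction
  rep0 <- regress_counts(counts_tbl(ids, c(100, 200, 300)),
                         truth_tbl(ids, c(100, 200, 300)))
  expect_equal(rep0$r_squared, 1)
  expect_equal(rep0$nrmse, 0)
  expect_equal(rep0$mape_pct, 0)
  expect_length(rep0$outlier_ids, 0)

  # hand evaluation: truth (100,200,300), predicted (110,180,330)
  rep1 <- regress_counts(counts_tbl(ids, c(110, 180, 330)),
                         truth_tbl(ids, c(100, 200, 300)))
  expect_equal(rep1$mape_pct, 10)
  expect_equal(rep1$nrmse, sqrt((100 + 400 + 900) / 3) / 200)
  expect_equal(rep1$mean_gt, 200)
  # OLS residual mean is zero
  expect_lt(abs(mean(rep1$residuals$residual)), 1e-9)

  # constant truth: zero range -> NRMSE undefined
  repc <- regress_counts(counts_tbl(ids, c(5, 6, 7)), truth_tbl(ids, c(10, 10, 10)))
  expect_true(is.na(repc$nrmse))
  # a zero truth count leaves MAPE undefined
  repz <- regress_counts(counts_tbl(ids, c(5, 6, 7)), truth_tbl(ids, c(0, 10, 20)))
  expect_true(is.na(repz$mape_pct))

  # unmatched plot ids are rejected
  expect_error(regress_counts(counts_tbl(c("a", "b", "x"), 1:3),
                              truth_tbl(ids, c(1, 2, 3))),
               class = "bollcount_validation_error")
})

test_that("NRMSE times the truth range equals the plain RMSE", {
  set.seed(61)
  for (i in 1:30) {
    n <- sample(5:40, 1)
    y <- runif(n, 50, 400); yhat <- y + rnorm(n, 0, 20)
    ids <- as.character(seq_len(n))
    rep <- regress_counts(counts_tbl(ids, yhat), truth_tbl(ids, y))
    rmse <- sqrt(mean((y - yhat)^2))
    expect_equal(rep$nrmse * (max(y) - min(y)), rmse, tolerance = 1e-12)
  }
})

test_that("the 3-SD outlier rule flags constructed and distributional cases", {
  # constructed: one wild residual among tight ones
  set.seed(62)
  n <- 40
  y <- seq(50, 400, length.out = n)
  yhat <- y + rnorm(n, 0, 2)
  yhat[17] <- y[17] + 100
  ids <- as.character(seq_len(n))
  rep <- regress_counts(counts_tbl(ids, yhat), truth_tbl(ids, y))
  expect_equal(rep$outlier_ids, "17")

  # outliers are flagged but kept in the fit; refit mode drops them
  rep2 <- regress_counts(counts_tbl(ids, yhat), truth_tbl(ids, y),
                         refit_without_outliers = TRUE)
  expect_gt(rep2$r_squared, rep$r_squared)
  expect_equal(rep2$outlier_ids, "17")

  # standard normal draws are flagged at about the 3-sigma rate
  set.seed(63)
  frac <- mean(flag_outliers(rnorm(10000)))
  expect_lt(abs(frac - 0.0027), 0.002)
})

test_that("one-way ANOVA matches hand computation and the t-test identity", {
  d <- data.frame(v = c(1, 2, 3, 4, 5, 6),
                  g = rep(c("x", "y"), each = 3))
  res <- anova_oneway(d, "v", "g")
  expect_equal(res$f, 13.5)
  expect_equal(res$df_between, 1L)
  expect_equal(res$df_within, 4L)

  # identical groups: no between-group variance
  d2 <- data.frame(v = rep(c(1, 2), 4), g = rep(c("x", "y"), each = 4))
  d2$v <- 5
  expect_equal(anova_oneway(d2, "v", "g")$f, 0)
  expect_equal(anova_oneway(d2, "v", "g")$p, 1)

  # df arithmetic: 16 groups, 488 values
  set.seed(64)
  sizes <- c(10, 10, 10, 10, 16, 20, 10, 40, 184, 22, 8, 44, 10, 44, 18, 32)
  d3 <- data.frame(v = rnorm(sum(sizes)),
                   g = rep(paste0("g", seq_along(sizes)), sizes))
  res3 <- anova_oneway(d3, "v", "g")
  expect_equal(res3$df_between, 15L)
  expect_equal(res3$df_within, 472L)

  # F = t^2 for two groups, against stats::t.test as the oracle
  set.seed(65)
  for (i in 1:50) {
    n1 <- sample(3:20, 1); n2 <- sample(3:20, 1)
    x1 <- rnorm(n1, sd = runif(1, 0.5, 3)); x2 <- rnorm(n2, 1)
    dd <- data.frame(v = c(x1, x2), g = rep(c("a", "b"), c(n1, n2)))
    tt <- t.test(x1, x2, var.equal = TRUE)
    res <- anova_oneway(dd, "v", "g")
    expect_equal(res$f, unname(tt$statistic)^2, tolerance = 1e-8)
    expect_equal(res$p, tt$p.value, tolerance = 1e-8)
  }
})

test_that("LSD letters reflect the pairwise significance structure", {
  # all means equal -> a single shared letter
  d <- data.frame(v = rep(c(3, 4), 6), g = rep(c("x", "y", "z"), each = 4))
  expect_equal(unique(lsd_letters(d, "v", "g")$letters), "a")

  # far-separated tight groups get distinct letters; verified by hand:
  # MSW ~ 0, so any LSD threshold is tiny relative to the 100-unit gap
  d2 <- data.frame(v = c(0, 0, 0, 1, 100, 100, 100, 101),
                   g = rep(c("lo", "hi"), each = 4))
  l2 <- lsd_letters(d2, "v", "g")
  expect_equal(l2$letters[l2$group == "hi"], "a")
  expect_equal(l2$letters[l2$group == "lo"], "b")

  # overlap chain: middle group not different from either extreme -> 'ab'.
  # constructed exactly: residuals (-3,-2,-1,1,2,3) per group give
  # MSW = 84/15 = 5.6, so LSD = t(.975,15)*sqrt(5.6*(1/6+1/6)) ~= 2.91;
  # adjacent gaps of 2 are NS, the extreme gap of 4 is significant
  resid6 <- c(-3, -2, -1, 1, 2, 3)
  d3 <- data.frame(v = c(resid6 + 0, resid6 + 2, resid6 + 4),
                   g = rep(c("low", "mid", "high"), each = 6))
  aovr <- anova_oneway(d3, "v", "g")
  expect_equal(aovr$ms_within, 5.6)
  lsd <- qt(0.975, aovr$df_within) * sqrt(aovr$ms_within * (1 / 6 + 1 / 6))
  expect_true(4 > lsd && 2 < lsd)  # hand-verified pairwise structure
  l3 <- lsd_letters(d3, "v", "g")
  lets <- setNames(l3$letters, l3$group)
  expect_equal(unname(lets[c("high", "mid", "low")]), c("a", "ab", "b"))

  # consistency invariant on random instances: no two groups sharing a
  # letter are significantly different
  set.seed(67)
  for (i in 1:30) {
    k <- sample(3:6, 1)
    sizes <- sample(3:10, k, replace = TRUE)
    dd <- data.frame(v = rnorm(sum(sizes), rep(runif(k, 0, 5), sizes)),
                     g = rep(paste0("g", 1:k), sizes))
    ll <- lsd_letters(dd, "v", "g")
    aovr <- anova_oneway(dd, "v", "g")
    tcrit <- qt(0.975, aovr$df_within)
    for (p in seq_len(nrow(ll))) for (q in seq_len(nrow(ll))) {
      if (p >= q) next
      share <- length(intersect(strsplit(ll$letters[p], "")[[1]],
                                strsplit(ll$letters[q], "")[[1]])) > 0
      lsd_pq <- tcrit * sqrt(aovr$ms_within * (1 / ll$n[p] + 1 / ll$n[q]))
      sig <- abs(ll$mean[p] - ll$mean[q]) > lsd_pq
      if (share) expect_false(sig)
    }
  }
})

test_that("genotype summaries combine means, SEs, ANOVA and letters", {
  # hand case: counts (10, 20) -> mean 15, SE 5
  d <- tibble::tibble(plot_id = c("p1", "p2", "p3", "p4"),
                      genotype = c("A", "A", "B", "B"),
                      boll_count = c(10, 20, 30, 40))
  gs <- genotype_summary(d)
  a_row <- gs$summary[gs$summary$genotype == "A", ]
  expect_equal(a_row$mean, 15)
  expect_equal(a_row$se, 5)
  expect_equal(gs$anova$df_between, 1L)

  # zero within-genotype variance -> SE 0 everywhere
  d2 <- tibble::tibble(plot_id = paste0("p", 1:6),
                       genotype = rep(c("A", "B", "C"), each = 2),
                       boll_count = rep(c(5, 9, 13), each = 2))
  gs2 <- genotype_summary(d2)
  expect_true(all(gs2$summary$se == 0))

  # a genotype with one plot: SE undefined, excluded from letters
  d3 <- tibble::tibble(plot_id = paste0("p", 1:7),
                       genotype = c("A", "A", "A", "B", "B", "B", "C"),
                       boll_count = c(10, 12, 14, 30, 32, 34, 99))
  gs3 <- genotype_summary(d3)
  c_row <- gs3$summary[gs3$summary$genotype == "C", ]
  expect_true(is.na(c_row$se))
  expect_true(is.na(c_row$letters))

  # genotype lookup can come from a separate table
  gs4 <- genotype_summary(d[c("plot_id", "boll_count")],
                          genotypes = d[c("plot_id", "genotype")])
  expect_equal(tidy(gs4), tidy(gs))
})
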