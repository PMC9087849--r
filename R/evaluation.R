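#' Flag outliers by the 3-standard-deviation rule
#'
#' @param x Numeric vector (typically regression residuals).
#' @param k Number of standard deviations (default 3).
#' @return Logical vector: `TRUE` where `|x - mean(x)| > k * sd(x)`.
#' @export
flag_outliers <- function(x, k = 3) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(FALSE, length(x)))
  abs(x - mean(x)) > k * s
}

#' Regress predicted boll counts against ground truth
#'
#' Ordinary least-squares fit of predicted on true per-plot counts, with
#' the evaluation statistics used for yield models: the coefficient of
#' determination R^2; the root-mean-squared prediction error normalized
#' by the range of the ground-truth counts,
#' \deqn{NRMSE = \sqrt{\tfrac1N\sum_i (y_i-\hat y_i)^2} / (y_{max}-y_{min});}
#' the mean absolute percentage error
#' \deqn{MAPE = \tfrac{100}{N}\sum_i |y_i-\hat y_i|/y_i;}
#' OLS residuals; and plots whose residual lies more than 3 standard
#' deviations from the residual mean, flagged as outliers. Outliers are
#' flagged but kept in the reported fit unless `refit_without_outliers`.
#'
#' @param counts Tibble of predictions with columns `plot_id`,
#'   `boll_count`.
#' @param truth Ground-truth tibble (see [read_ground_truth()]); its
#'   `boll_count` is the reference `y`.
#' @param refit_without_outliers If `TRUE`, refit after dropping flagged
#'   outliers (the flags themselves come from the full fit).
#' @return A `regression_report` object.
#' @export
regress_counts <- function(counts, truth, refit_without_outliers = FALSE) {
  d <- dplyr::inner_join(
    dplyr::rename(counts[c("plot_id", "boll_count")], predicted = "boll_count"),
    dplyr::rename(truth[c("plot_id", "boll_count",
                          intersect("genotype", names(truth)))],
                  truth = "boll_count"),
    by = "plot_id")
  if (nrow(d) < nrow(counts) || nrow(d) < nrow(truth))
    stop_validation("plot_id sets of counts and ground truth do not match")
  if (nrow(d) < 3L) stop_validation("need at least 3 matched plots")
  fit <- lm(predicted ~ truth, data = d)
  res <- residuals(fit)
  d$residual <- as.numeric(res)
  # a numerically perfect fit leaves only floating-point noise in the
  # residuals; do not let the 3-SD rule flag that noise
  scale_tol <- 1e-9 * max(1, max(abs(d$truth)))
  d$outlier <- if (sd(d$residual) <= scale_tol) rep(FALSE, nrow(d))
               else flag_outliers(d$residual)
  rng <- max(d$truth) - min(d$truth)
  err <- d$truth - d$predicted
  nrmse <- if (rng > 0) sqrt(mean(err^2)) / rng else NA_real_
  mape <- if (all(d$truth > 0)) 100 * mean(abs(err) / d$truth) else NA_real_
  report <- list(n = nrow(d),
                 slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 # a perfect fit is legitimate here (e.g. identity checks);
                 # silence summary.lm's reliability warning for that case
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 nrmse = nrmse, mape_pct = mape,
                 mean_gt = mean(d$truth),
                 residuals = as_tibble(d),
                 outlier_ids = d$plot_id[d$outlier],
                 refit_without_outliers = refit_without_outliers)
  if (refit_without_outliers && any(d$outlier)) {
    sub <- regress_counts(
      dplyr::rename(d[!d$outlier, c("plot_id", "predicted")], boll_count = "predicted"),
      dplyr::rename(d[!d$outlier, c("plot_id", "truth")], boll_count = "truth"))
    report[c("slope", "intercept", "r_squared", "nrmse", "mape_pct")] <-
      list(sub$slope, sub$intercept, sub$r_squared, sub$nrmse, sub$mape_pct)
    report$n_fit <- sub$n
  }
  structure(report, class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("Predicted vs ground truth over %d plots\n", x$n))
  cat(sprintf("  fit: predicted = %.3f + %.3f * truth, R^2 = %.3f\n",
              x$intercept, x$slope, x$r_squared))
  cat(sprintf("  NRMSE = %.3f, MAPE = %.3f%%, outliers: %s\n",
              x$nrmse, x$mape_pct,
              if (length(x$outlier_ids)) paste(x$outlier_ids, collapse = ", ")
              else "none"))
  invisible(x)
}

#' @export
tidy.regression_report <- function(x, ...) x$residuals

#' @export
glance.regression_report <- function(x, ...) {
  tibble(n = x$n, slope = x$slope, intercept = x$intercept,
         r_squared = x$r_squared, nrmse = x$nrmse, mape_pct = x$mape_pct,
         mean_gt = x$mean_gt, n_outliers = length(x$outlier_ids))
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA of a response against a single
#' grouping factor. When every value is identical the convention
#' `F = 0, p = 1` is returned rather than 0/0.
#'
#' @param data Data frame.
#' @param value,group Column names (strings) of the response and the
#'   grouping factor.
#' @return A list: `f`, `df_between`, `df_within`, `p`, `ms_within`,
#'   `group_stats` (per-group n and mean).
#' @export
anova_oneway <- function(data, value = "boll_count", group = "genotype") {
  y <- data[[value]]; g <- factor(data[[group]])
  if (nlevels(g) < 2L) stop_validation("need at least 2 groups")
  if (length(y) <= nlevels(g)) stop_validation("need more values than groups")
  df_b <- nlevels(g) - 1L
  df_w <- length(y) - nlevels(g)
  if (var(y) == 0) {
    return(list(f = 0, df_between = df_b, df_within = df_w, p = 1,
                ms_within = 0,
                group_stats = dplyr::count(tibble(g = g), .data$g)))
  }
  fit <- aov(y ~ g)
  tab <- summary(fit)[[1]]
  list(f = tab$`F value`[1], df_between = df_b, df_within = df_w,
       p = tab$`Pr(>F)`[1], ms_within = tab$`Mean Sq`[2],
       group_stats = summarise(group_by(tibble(g = g, y = y), .data$g),
                               n = n(), mean = mean(.data$y)))
}

#' Fisher's LSD letter grouping
#'
#' Pairwise comparisons of group means using the pooled ANOVA error mean
#' square: means i and j differ when
#' `|m_i - m_j| > t(1 - alpha/2, df_w) * sqrt(MSW * (1/n_i + 1/n_j))`.
#' Letters are assigned in the conventional agricultural-trial style:
#' groups are sorted by descending mean, maximal runs of mutually
#' non-different groups each receive one letter (`a`, `b`, ...), and a
#' group belonging to several runs carries several letters. Groups
#' sharing any letter are not significantly different at `alpha`.
#'
#' @inheritParams anova_oneway
#' @param alpha Significance level (default 0.05).
#' @return A tibble: `group`, `n`, `mean`, `letters`, ordered by
#'   descending mean.
#' @export
lsd_letters <- function(data, value = "boll_count", group = "genotype",
                        alpha = 0.05) {
  y <- data[[value]]; g <- factor(data[[group]])
  if (nlevels(g) < 2L) {
    return(tibble(group = levels(g), n = length(y), mean = mean(y),
                  letters = "a"))
  }
  aov_res <- anova_oneway(data, value, group)
  stats <- summarise(group_by(tibble(g = g, y = y), .data$g),
                     n = n(), mean = mean(.data$y)) |>
    arrange(dplyr::desc(.data$mean))
  k <- nrow(stats)
  msw <- aov_res$ms_within
  tcrit <- qt(1 - alpha / 2, aov_res$df_within)
  sig <- function(i, j) {
    lsd <- tcrit * sqrt(msw * (1 / stats$n[i] + 1 / stats$n[j]))
    abs(stats$mean[i] - stats$mean[j]) > lsd
  }
  # maximal intervals of mutually non-different groups (means sorted desc)
  ends <- integer(k)
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !any(vapply(i:j, function(m) sig(m, j + 1L), logical(1))))
      j <- j + 1L
    ends[i] <- j
  }
  keep <- which(!duplicated(ends))                  # drop nested intervals
  keep <- keep[c(TRUE, diff(ends[keep]) > 0)]
  letters_per_group <- rep("", k)
  for (m in seq_along(keep)) {
    i <- keep[m]
    span <- i:ends[i]
    letters_per_group[span] <- paste0(letters_per_group[span], letters[m])
  }
  tibble(group = as.character(stats$g), n = stats$n, mean = stats$mean,
         letters = letters_per_group)
}

#' Per-genotype yield summary with ANOVA and LSD letters
#'
#' Summarizes predicted per-plot boll counts by genotype (sample size,
#' mean, standard error of the mean), tests the null hypothesis of equal
#' genotype means with one-way ANOVA, and groups genotypes with Fisher's
#' LSD letters. A genotype observed on a single plot gets `SE = NA` and
#' no letter (one observation cannot support a pairwise comparison).
#'
#' @param counts Tibble with columns `plot_id`, `boll_count` and either a
#'   `genotype` column or a `genotypes` lookup supplied separately.
#' @param genotypes Optional tibble `plot_id`, `genotype` used when
#'   `counts` lacks the genotype column.
#' @param alpha Significance level for the LSD letters (default 0.05).
#' @return A `genotype_summary` object.
#' @export
genotype_summary <- function(counts, genotypes = NULL, alpha = 0.05) {
  d <- counts
  if (!"genotype" %in% names(d)) {
    if (is.null(genotypes))
      stop_validation("no genotype column and no `genotypes` lookup supplied")
    d <- left_join(d, genotypes[c("plot_id", "genotype")], by = "plot_id")
  }
  if (anyNA(d$genotype)) stop_validation("every plot needs a genotype")
  per <- summarise(group_by(d, .data$genotype),
                   sample_size = n(),
                   mean = mean(.data$boll_count),
                   se = ifelse(n() > 1, sd(.data$boll_count) / sqrt(n()), NA_real_),
                   .groups = "drop") |>
    arrange(dplyr::desc(.data$mean))
  anova <- anova_oneway(d, "boll_count", "genotype")
  lsd_input <- filter(d, .data$genotype %in% per$genotype[per$sample_size > 1])
  lsd <- if (length(unique(lsd_input$genotype)) >= 2)
    lsd_letters(lsd_input, "boll_count", "genotype", alpha)
  else tibble(group = character(), n = integer(), mean = numeric(),
              letters = character())
  per <- left_join(per, lsd[c("group", "letters")],
                   by = c(genotype = "group"))
  structure(list(summary = per, anova = anova, alpha = alpha, n_total = nrow(d)),
            class = "genotype_summary")
}

#' @export
print.genotype_summary <- function(x, ...) {
  cat(sprintf("Genotype summary over %d plots, %d genotypes\n",
              x$n_total, nrow(x$summary)))
  cat(sprintf("  ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$anova$df_between, x$anova$df_within, x$anova$f, x$anova$p))
  print(x$summary, n = Inf)
  invisible(x)
}

#' @export
tidy.genotype_summary <- function(x, ...) x$summary

#' @export
glance.genotype_summary <- function(x, ...) {
  tibble(n_total = x$n_total, n_genotypes = nrow(x$summary),
         f = x$anova$f, df_between = x$anova$df_between,
         df_within = x$anova$df_within, p = x$anova$p, alpha = x$alpha)
}
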