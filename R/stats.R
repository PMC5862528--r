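#' Eclosion rate
#'
#' Percentage of selected larvae that emerged as adults,
#' `100 * n_adults / n_larvae`.
#'
#' @param record data frame (or list) with `n_larvae` and `n_adults`;
#'   vectorised over rows.
#' @return Numeric percentage(s) in `[0, 100]`.
#' @examples
#' eclosion_rate(data.frame(n_larvae = 50, n_adults = 6))  # 12
#' @export
eclosion_rate <- function(record) {
  n_larvae <- record$n_larvae
  n_adults <- record$n_adults
  if (any(n_larvae < 1)) stop("`n_larvae` must be >= 1", call. = FALSE)
  if (any(n_adults < 0 | n_adults > n_larvae)) {
    stop("`n_adults` must be in [0, n_larvae]", call. = FALSE)
  }
  100 * n_adults / n_larvae
}

#' Fold decrease between two condition means
#'
#' `baseline / treated`; e.g. 46% baseline tumor volume over 5% after
#' knock-down gives the reported 9.2-fold decrease.
#'
#' @param baseline_percent,treated_percent condition means; treated must be
#'   positive.
#' @return Fold change (> 0).
#' @examples
#' fold_decrease(46, 5)  # 9.2
#' @export
fold_decrease <- function(baseline_percent, treated_percent) {
  if (any(!is.finite(treated_percent)) || any(treated_percent <= 0)) {
    stop("`treated_percent` must be > 0", call. = FALSE)
  }
  baseline_percent / treated_percent
}

#' Tumor-bearing host fraction
#'
#' Percentage of transplantation hosts carrying a visible GFP+ tumor.
#'
#' @param n_with_tumor hosts with tumors (0..n_hosts).
#' @param n_hosts total hosts analysed (>= 1).
#' @return Percentage in `[0, 100]`.
#' @export
tumor_bearing_fraction <- function(n_with_tumor, n_hosts) {
  if (any(n_hosts < 1)) stop("`n_hosts` must be >= 1", call. = FALSE)
  if (any(n_with_tumor < 0 | n_with_tumor > n_hosts)) {
    stop("`n_with_tumor` must be in [0, n_hosts]", call. = FALSE)
  }
  100 * n_with_tumor / n_hosts
}

#' Condition summary (mean +/- SD)
#'
#' Per-condition summary the way the study's figures report values: mean
#' and sample SD (n - 1 denominator; SD 0 for a single value).
#'
#' @param values numeric vector of per-disc (or per-replicate) measurements.
#' @param condition condition label.
#' @return One-row data frame `condition`, `n`, `mean`, `sd`.
#' @export
summarize_condition <- function(values, condition) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no values to summarise", call. = FALSE)
  data.frame(condition = condition, n = length(values), mean = mean(values),
             sd = if (length(values) > 1L) stats::sd(values) else 0,
             stringsAsFactors = FALSE)
}

#' Significance stars at the study's thresholds
#'
#' @param p numeric p-values.
#' @return Character vector: `****` < 1e-4, `***` < 1e-3, `**` < 0.01,
#'   `*` < 0.05, `ns` otherwise.
#' @export
p_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}

check_groups <- function(groups, min_n = 1L) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("`groups` must be a list of >= 2 numeric vectors", call. = FALSE)
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- sprintf("group%d", seq_along(groups))
  }
  if (any(lengths(groups) < min_n)) {
    stop(sprintf("every group needs >= %d values", min_n), call. = FALSE)
  }
  lapply(groups, as.numeric)
}

#' Kruskal-Wallis rank test across conditions
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square reference
#' (k - 1 degrees of freedom), via [stats::kruskal.test()]. When every
#' pooled value is identical the statistic is degenerate; H is reported as
#' 0 with p = 1 and `degenerate = TRUE`.
#'
#' @param groups named list of numeric vectors, one per condition.
#' @return List `statistic` (H), `df`, `p.value`, `degenerate`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- check_groups(groups, min_n = 1L)
  pooled <- unlist(groups, use.names = FALSE)
  if (length(pooled) < 3L) stop("need >= 3 values in total", call. = FALSE)
  if (length(unique(pooled)) == 1L) {
    return(list(statistic = 0, df = length(groups) - 1L, p.value = 1,
                degenerate = TRUE))
  }
  kt <- stats::kruskal.test(groups)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p.value = kt$p.value, degenerate = FALSE)
}

#' Dunn's post-hoc rank comparisons
#'
#' Pairwise z statistics on mean ranks following a Kruskal-Wallis test,
#' with the tie correction
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))`
#' where `T = sum(t^3 - t)` over tie groups. Two-sided normal p-values are
#' Bonferroni-adjusted over the selected comparison family (all pairs or
#' each treatment vs a control).
#'
#' @param groups named list of numeric vectors.
#' @param mode `"all-pairs"` or `"vs-control"`.
#' @param control control group name (required for `"vs-control"`).
#' @return Object of class `group_comparison`: global Kruskal-Wallis
#'   results plus a `comparisons` data frame (`group1`, `group2`,
#'   `statistic`, `p.value`, `p.adjusted`, `stars`).
#' @export
dunn_posthoc <- function(groups, mode = c("all-pairs", "vs-control"),
                         control = NULL) {
  mode <- match.arg(mode)
  groups <- check_groups(groups, min_n = 1L)
  if (mode == "vs-control") {
    if (is.null(control) || !control %in% names(groups)) {
      stop(sprintf("unknown control label '%s'; groups: %s",
                   as.character(control)[1] %||% "NULL",
                   paste(names(groups), collapse = ", ")), call. = FALSE)
    }
  }
  kw <- kruskal_wallis(groups)
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  rk <- rank(pooled)
  gidx <- rep(seq_along(groups), lengths(groups))
  rbar <- tapply(rk, gidx, mean)
  n <- lengths(groups)
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))
  pairs <- if (mode == "all-pairs") {
    utils::combn(seq_along(groups), 2)
  } else {
    ci <- match(control, names(groups))
    rbind(ci, setdiff(seq_along(groups), ci))
  }
  m <- ncol(pairs)
  z <- p <- numeric(m)
  for (k in seq_len(m)) {
    i <- pairs[1, k]; j <- pairs[2, k]
    denom <- sqrt(sigma2 * (1 / n[i] + 1 / n[j]))
    z[k] <- if (denom > 0) (rbar[i] - rbar[j]) / denom else 0
    p[k] <- if (kw$degenerate) 1 else 2 * stats::pnorm(-abs(z[k]))
  }
  padj <- pmin(1, m * p)
  comparisons <- data.frame(
    group1 = names(groups)[pairs[1, ]], group2 = names(groups)[pairs[2, ]],
    statistic = z, p.value = p, p.adjusted = padj, stars = p_stars(padj),
    stringsAsFactors = FALSE)
  structure(list(test = "Kruskal-Wallis + Dunn", mode = mode,
                 statistic = kw$statistic, df = kw$df, p.value = kw$p.value,
                 degenerate = kw$degenerate, comparisons = comparisons),
            class = "group_comparison")
}

#' One-way ANOVA with Dunnett's comparisons to control
#'
#' Global one-way ANOVA (via [stats::aov()]) followed by Dunnett t
#' statistics of each treatment against the control using the pooled
#' residual variance. Family-wise adjusted p-values are computed by seeded
#' Monte-Carlo of the null maximum-|t| distribution with the design's
#' (balanced or unbalanced) correlation structure, which handles any group
#' sizes uniformly; with two groups the adjustment converges to the
#' two-sided pooled t-test. Adjusted p-values are never below the raw ones.
#'
#' @param groups named list of numeric vectors, each with >= 2 values.
#' @param control control group name.
#' @param n_mc Monte-Carlo draws for the max-|t| null (default 1e5).
#' @param mc_seed seed for the Monte-Carlo draws.
#' @return Object of class `group_comparison` with the ANOVA `statistic`
#'   (F), `df` (numerator, denominator), `p.value` and the `comparisons`
#'   table.
#' @export
anova_dunnett <- function(groups, control, n_mc = 1e5, mc_seed = 1) {
  groups <- check_groups(groups, min_n = 2L)
  if (!control %in% names(groups)) {
    stop(sprintf("control group '%s' missing; groups: %s", control,
                 paste(names(groups), collapse = ", ")), call. = FALSE)
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  fit <- stats::aov(values ~ g)
  an <- summary(fit)[[1]]
  Fstat <- an[["F value"]][1]
  p_global <- an[["Pr(>F)"]][1]
  nu <- an[["Df"]][2]
  s2 <- an[["Mean Sq"]][2]
  n <- lengths(groups)
  means <- vapply(groups, mean, numeric(1))
  treat <- setdiff(names(groups), control)
  if (stats::var(values) <= .Machine$double.eps) {
    # every pooled value identical: no variance to test against
    comparisons <- data.frame(
      group1 = treat, group2 = control, statistic = 0, p.value = 1,
      p.adjusted = 1, stars = "ns", stringsAsFactors = FALSE)
    return(structure(list(test = "one-way ANOVA + Dunnett", statistic = 0,
                          df = c(an[["Df"]][1], nu), p.value = 1,
                          degenerate = TRUE, comparisons = comparisons),
                     class = "group_comparison"))
  }
  tstat <- (means[treat] - means[control]) /
    sqrt(s2 * (1 / n[treat] + 1 / n[control]))
  # null max-|t| by Monte-Carlo with the design's correlation structure
  maxt <- with_seed(mc_seed, {
    zm <- matrix(stats::rnorm(n_mc * length(groups)), ncol = length(groups))
    zm <- sweep(zm, 2, sqrt(n), `/`)  # null group means, sigma = 1
    s <- sqrt(stats::rchisq(n_mc, df = nu) / nu)
    tm <- (zm[, match(treat, names(groups)), drop = FALSE] -
             zm[, match(control, names(groups))]) /
      outer(s, sqrt(1 / n[treat] + 1 / n[control]))
    apply(abs(tm), 1, max)
  })
  p_raw <- 2 * stats::pt(-abs(tstat), df = nu)
  p_adj <- pmax(p_raw,
                vapply(abs(tstat), function(t0) mean(maxt >= t0), numeric(1)))
  comparisons <- data.frame(
    group1 = treat, group2 = control, statistic = unname(tstat),
    p.value = unname(p_raw), p.adjusted = unname(p_adj),
    stars = p_stars(p_adj), stringsAsFactors = FALSE)
  structure(list(test = "one-way ANOVA + Dunnett", statistic = Fstat,
                 df = c(an[["Df"]][1], nu), p.value = p_global,
                 degenerate = FALSE, comparisons = comparisons),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n", x$test, x$statistic,
              x$p.value))
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}
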