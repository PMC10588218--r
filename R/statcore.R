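#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values. This is
#' the multiple-comparison correction applied throughout the package's
#' nonparametric testing cascade.
#'
#' @param p numeric vector of p-values, all in \[0, 1\].
#' @return numeric vector of BH-adjusted p-values, same length and order as
#'   `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) stop("empty p-value vector")
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Kruskal-Wallis omnibus followed by pairwise Wilcoxon rank-sum tests
#'
#' The package's nonparametric testing cascade: a Kruskal-Wallis test across
#' all groups, then all pairwise two-sided Wilcoxon rank-sum tests with the
#' pairwise p-values BH-adjusted jointly. Exact rank-sum p-values are used
#' where the sample sizes permit (no ties, both groups below 50), the
#' normal approximation with tie correction otherwise.
#'
#' @param values numeric vector of observations.
#' @param group vector of group labels, one per observation; at least two
#'   groups, each with at least two observations.
#' @return list with elements `omnibus` (data.frame: statistic, df, p_value,
#'   method) and `pairwise` (data.frame: group1, group2, statistic, p_value,
#'   p_adjusted, method).
#' @export
kw_pairwise_wilcoxon <- function(values, group) {
  stopifnot(length(values) == length(group))
  keep <- !is.na(values) & !is.na(group)
  values <- values[keep]
  group <- as.character(group[keep])
  tab <- table(group)
  if (length(tab) < 2L) stop("need at least two groups")
  if (any(tab < 2L)) {
    stop("degenerate group(s) with fewer than two values: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  }
  kw <- stats::kruskal.test(values, factor(group))
  omnibus <- data.frame(
    statistic = unname(kw$statistic),
    df = unname(kw$parameter),
    p_value = kw$p.value,
    method = "Kruskal-Wallis",
    stringsAsFactors = FALSE
  )
  gl <- names(tab)
  pairs <- utils::combn(gl, 2L)
  pw <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- values[group == pairs[1L, i]]
    b <- values[group == pairs[2L, i]]
    wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
    data.frame(
      group1 = pairs[1L, i], group2 = pairs[2L, i],
      statistic = unname(wt$statistic), p_value = wt$p.value,
      method = "Wilcoxon rank sum", stringsAsFactors = FALSE
    )
  })
  pw <- do.call(rbind, pw)
  pw$p_adjusted <- bh_adjust(pw$p_value)
  list(omnibus = omnibus, pairwise = pw[, c("group1", "group2", "statistic",
                                            "p_value", "p_adjusted", "method")])
}

#' One-sample Wilcoxon signed-rank test against a fixed null value
#'
#' Two-sided signed-rank test of `values - null_value` against zero, used
#' for Y-maze arm-bias testing against the uniform-entry null of 1/3.
#' Observations equal to the null value are dropped (standard signed-rank
#' convention); if none remain the test is undefined.
#'
#' @param values numeric vector of observations.
#' @param null_value the hypothesized center (default `1/3`).
#' @return data.frame with statistic, p_value, n_used, null_value, method.
#' @export
signed_rank_test <- function(values, null_value = 1 / 3) {
  values <- values[!is.na(values)]
  if (all(values == null_value)) {
    stop("signed-rank test undefined: all values equal the null value")
  }
  wt <- suppressWarnings(
    stats::wilcox.test(values, mu = null_value, alternative = "two.sided")
  )
  data.frame(
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    n_used = sum(values != null_value),
    null_value = null_value,
    method = "Wilcoxon signed rank",
    stringsAsFactors = FALSE
  )
}

#' ANOVA with Tukey HSD pairwise comparisons
#'
#' Parametric path used for large pooled behavioral samples and for the
#' image-derived ratio and cell-count data: a fixed-effects linear model
#' (optionally with a replicate blocking term), an F test on the group
#' factor, then Tukey honest-significant-difference pairwise comparisons.
#'
#' @param values numeric vector of observations.
#' @param group group labels (the factor of interest).
#' @param block optional replicate labels entered as a fixed effect.
#' @return list with `anova` (data.frame term/df/F/p) and `tukey`
#'   (data.frame group1, group2, diff, lwr, upr, p_adjusted).
#' @export
anova_tukey <- function(values, group, block = NULL) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need at least two groups")
  if (is.null(block)) {
    fit <- stats::aov(values ~ group)
  } else {
    block <- factor(block)
    fit <- stats::aov(values ~ group + block)
  }
  at <- stats::anova(fit)
  an <- data.frame(
    term = rownames(at),
    df = at$Df,
    statistic = at$`F value`,
    p_value = at$`Pr(>F)`,
    stringsAsFactors = FALSE
  )
  tk <- stats::TukeyHSD(fit, which = "group")$group
  cmp <- strsplit(rownames(tk), "-", fixed = TRUE)
  tukey <- data.frame(
    group1 = vapply(cmp, `[`, "", 1L),
    group2 = vapply(cmp, `[`, "", 2L),
    diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
    p_adjusted = tk[, "p adj"],
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(anova = an, tukey = tukey)
}
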