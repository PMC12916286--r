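## The statistics ladder: normality-gated test selection, omnibus and
## post-hoc comparisons, chi-square independence, and robust outlier
## screening.  Conventions mirror common practice in quantitative imaging
## studies: Shapiro-Wilk gating at alpha = 0.05, Tukey or Sidak post-hoc
## after ANOVA, Dunn after Kruskal-Wallis, and star annotations at
## 0.05/0.01/0.001/0.0001.

#' Normality gate for grouped measurements
#'
#' Runs the Shapiro-Wilk test within each group; the data are treated as
#' parametric iff every group's p-value exceeds `alpha`.  Groups with fewer
#' than 3 values (or degenerate/constant values) force the nonparametric
#' branch with a warning.
#'
#' @param data named list of numeric vectors (group -> values).
#' @param alpha gate level.
#' @return list with `branch` (`"parametric"` or `"nonparametric"`) and
#'   `shapiro_p` (per-group p-values, `NA` where not testable).
#' @export
normality_gate <- function(data, alpha = 0.05) {
  p <- vapply(data, function(v) {
    if (length(v) < 3) return(NA_real_)
    if (length(unique(v)) < 2) return(NA_real_)
    tryCatch(stats::shapiro.test(v)$p.value, error = function(e) NA_real_)
  }, numeric(1))
  if (anyNA(p)) {
    warning("group too small or degenerate for Shapiro-Wilk; using nonparametric branch")
    return(list(branch = "nonparametric", shapiro_p = p))
  }
  list(branch = if (all(p > alpha)) "parametric" else "nonparametric",
       shapiro_p = p)
}

nq_stars <- function(p) {
  ifelse(p < 1e-4, "****",
         ifelse(p < 1e-3, "***",
                ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns"))))
}

#' Compare experimental groups with the normality-gated ladder
#'
#' Selection mirrors the conventional ladder: for two groups, a two-tailed
#' independent-samples t-test (parametric) or Mann-Whitney U test; for more
#' than two, one-way ANOVA followed by Tukey's or Sidak's multiple
#' comparisons (parametric) or Kruskal-Wallis followed by Dunn's test; for
#' grouped (two-factor) data, two-way ANOVA followed by Tukey.
#'
#' @param data named list of numeric vectors for `"two"`/`"oneway"`
#'   designs; for `"grouped_twoway"`, a data.frame with columns `value`,
#'   `group` and `factor2`.
#' @param design `"two"`, `"oneway"` or `"grouped_twoway"`.
#' @param posthoc `"tukey"`, `"sidak"` or `"dunn"` (dunn is used
#'   automatically on the nonparametric branch).
#' @param gate optional result of [normality_gate()]; computed when `NULL`.
#' @param alpha gate level passed to [normality_gate()].
#' @return a `stat_report` list: `test_used`, `statistic`, `p_value`,
#'   `posthoc` (data.frame of pairwise adjusted p, for > 2 groups),
#'   `normality`, `stars`.
#' @export
compare_groups <- function(data, design = c("two", "oneway",
                                            "grouped_twoway"),
                           posthoc = c("tukey", "sidak", "dunn"),
                           gate = NULL, alpha = 0.05) {
  design <- match.arg(design)
  posthoc <- match.arg(posthoc)
  if (design == "grouped_twoway") {
    stopifnot(is.data.frame(data),
              all(c("value", "group", "factor2") %in% names(data)))
    fit <- stats::aov(value ~ group * factor2,
                      data = transform(data, group = factor(group),
                                       factor2 = factor(factor2)))
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit, "group")$group
    ph <- data.frame(pair = rownames(tk), p_adj = tk[, "p adj"],
                     row.names = NULL)
    rep <- list(test_used = "two-way ANOVA + Tukey",
                statistic = an[1, "F value"], p_value = an[1, "Pr(>F)"],
                posthoc = ph, normality = NULL)
    rep$stars <- nq_stars(rep$p_value)
    class(rep) <- "stat_report"
    return(rep)
  }
  stopifnot(is.list(data), length(data) >= 2)
  if (design == "two" && length(data) != 2)
    stop("design 'two' requires exactly 2 groups")
  if (design == "oneway" && length(data) < 3)
    stop("design 'oneway' requires > 2 groups")
  if (is.null(names(data)) || any(names(data) == ""))
    names(data) <- paste0("g", seq_along(data))
  if (is.null(gate)) gate <- normality_gate(data, alpha)
  parametric <- gate$branch == "parametric"
  values <- unlist(data, use.names = FALSE)
  groups <- factor(rep(names(data), lengths(data)), levels = names(data))
  ph <- NULL
  if (design == "two") {
    if (parametric) {
      tt <- stats::t.test(data[[1]], data[[2]], var.equal = TRUE)
      test_used <- "t-test"; statistic <- unname(tt$statistic)
      p_value <- tt$p.value
    } else {
      wt <- suppressWarnings(stats::wilcox.test(data[[1]], data[[2]]))
      test_used <- "Mann-Whitney U"; statistic <- unname(wt$statistic)
      p_value <- wt$p.value
    }
  } else if (parametric) {
    fit <- stats::aov(values ~ groups)
    an <- summary(fit)[[1]]
    statistic <- an[1, "F value"]; p_value <- an[1, "Pr(>F)"]
    if (posthoc == "sidak") {
      pt <- stats::pairwise.t.test(values, groups, p.adjust.method = "none",
                                   pool.sd = TRUE)$p.value
      prs <- which(!is.na(pt), arr.ind = TRUE)
      m <- nrow(prs)
      ph <- data.frame(
        pair = paste(rownames(pt)[prs[, 1]], colnames(pt)[prs[, 2]],
                     sep = "-"),
        p_unadj = pt[prs],
        p_adj = pmin(1 - (1 - pt[prs])^m, 1))
      test_used <- "one-way ANOVA + Sidak"
    } else {
      tk <- stats::TukeyHSD(fit)$groups
      ph <- data.frame(pair = rownames(tk), p_adj = tk[, "p adj"],
                       row.names = NULL)
      test_used <- "one-way ANOVA + Tukey"
    }
  } else {
    kw <- stats::kruskal.test(values, groups)
    statistic <- unname(kw$statistic); p_value <- kw$p.value
    ph <- nq_dunn(values, groups)
    test_used <- "Kruskal-Wallis + Dunn"
  }
  rep <- list(test_used = test_used, statistic = statistic,
              p_value = p_value, posthoc = ph, normality = gate$shapiro_p)
  rep$stars <- nq_stars(rep$p_value)
  class(rep) <- "stat_report"
  rep
}

#' @export
print.stat_report <- function(x, ...) {
  cat(sprintf("<stat_report> %s: statistic = %.4g, p = %.4g %s\n",
              x$test_used, x$statistic, x$p_value, x$stars))
  if (!is.null(x$posthoc)) {
    cat("  post-hoc adjusted p:\n")
    for (i in seq_len(nrow(x$posthoc)))
      cat(sprintf("    %-20s %.4g\n", x$posthoc$pair[i], x$posthoc$p_adj[i]))
  }
  invisible(x)
}

## Dunn's post-hoc on the pooled Kruskal-Wallis ranking, with tie
## correction and Bonferroni adjustment over all pairs.
nq_dunn <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  lv <- levels(groups)
  ni <- tabulate(groups)
  Ri <- tapply(r, groups, mean)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_corr
  out <- list()
  m <- choose(length(lv), 2)
  for (i in 1:(length(lv) - 1)) {
    for (j in (i + 1):length(lv)) {
      z <- (Ri[i] - Ri[j]) / sqrt(s2 * (1 / ni[i] + 1 / ni[j]))
      p <- 2 * stats::pnorm(-abs(z))
      out[[length(out) + 1L]] <-
        data.frame(pair = paste(lv[j], lv[i], sep = "-"),
                   z = unname(z), p_unadj = p,
                   p_adj = min(p * m, 1))
    }
  }
  do.call(rbind, out)
}

#' Chi-square test of independence
#'
#' Pearson chi-square on a 2D contingency table (no continuity correction),
#' with `(r - 1)(c - 1)` degrees of freedom.
#'
#' @param table matrix of counts; all expected counts must be positive.
#' @return a `stat_report` with `statistic`, `df`, `p_value`.
#' @examples
#' chi_square(matrix(c(10, 20, 20, 10), 2))   # chi^2 = 6.667
#' @export
chi_square <- function(table) {
  table <- as.matrix(table)
  if (length(dim(table)) != 2L) stop("table must be 2D")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  rep <- list(test_used = "chi-square", statistic = unname(ct$statistic),
              df = unname(ct$parameter), p_value = ct$p.value,
              posthoc = NULL, normality = NULL)
  rep$stars <- nq_stars(rep$p_value)
  class(rep) <- "stat_report"
  rep
}

#' Robust outlier screen (ROUT-style)
#'
#' A documented approximation to Prism's ROUT outlier identification:
#' values are standardized by the median and the MAD (scaled to be
#' consistent with the normal sd), two-sided normal tail p-values are
#' computed, and points are flagged by Benjamini-Hochberg FDR control at
#' rate `q`.  The exact robust-regression formulation of ROUT is
#' proprietary; this screen reproduces its intent (outlier removal at a
#' stated false-discovery rate) with reproducible components.
#'
#' @param values numeric vector, `n >= 3` for any flagging.
#' @param q target false-discovery rate (Prism's Q; default 1%).
#' @return list with `kept`, `flagged` (values), `flagged_idx` and
#'   `method`.
#' @export
rout_outliers <- function(values, q = 0.01) {
  if (length(values) < 3) {
    warning("fewer than 3 values; nothing flagged")
    return(list(kept = values, flagged = numeric(0),
                flagged_idx = integer(0),
                method = "median/MAD + BH (ROUT-style approximation)"))
  }
  med <- stats::median(values)
  s <- stats::mad(values)
  if (s <= 0) {
    return(list(kept = values, flagged = numeric(0),
                flagged_idx = integer(0),
                method = "median/MAD + BH (ROUT-style approximation)"))
  }
  z <- (values - med) / s
  p <- 2 * stats::pnorm(-abs(z))
  flag <- stats::p.adjust(p, "BH") < q
  list(kept = values[!flag], flagged = values[flag],
       flagged_idx = which(flag),
       method = "median/MAD + BH (ROUT-style approximation)")
}
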