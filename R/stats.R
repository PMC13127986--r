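# --- group-comparison layer ----------------------------------------------
#
# The inferential chain mirrors common practice in behavioral
# pharmacology: a Shapiro-Wilk normality gate decides between a one-way
# ANOVA with Tukey HSD and a Kruskal-Wallis test with Dunn post hoc;
# post hoc tests run only when the omnibus test is significant.

new_stat_report <- function(test, statistic, df, p_value, posthoc = NULL,
                            gate = NULL) {
  structure(list(test = test, statistic = statistic, df = df,
                 p_value = p_value, posthoc = posthoc, gate = gate),
            class = "stat_report")
}

#' @export
print.stat_report <- function(x, ...) {
  cat(sprintf("<stat_report> %s: statistic = %.4g, df = (%s), p = %.4g\n",
              x$test, x$statistic, paste(x$df, collapse = ", "),
              x$p_value))
  if (!is.null(x$gate)) cat("  normality gate:", x$gate, "\n")
  if (!is.null(x$posthoc)) {
    cat("  post hoc:\n")
    print(as.data.frame(x$posthoc), row.names = FALSE)
  } else {
    cat("  post hoc: not run (omnibus not significant or not requested)\n")
  }
  invisible(x)
}

split_groups <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  keep <- is.finite(values)
  split(values[keep], factor(groups[keep]))
}

#' Shapiro-Wilk normality gate
#'
#' Decides between the parametric and non-parametric branch of the
#' group-comparison chain: parametric if and only if every group passes
#' the Shapiro-Wilk test at `alpha`.
#'
#' @param values Numeric vector of per-animal metric values.
#' @param groups Group labels, same length.
#' @param alpha Gate level (default 0.05).
#' @return `"parametric"` or `"nonparametric"`, with attribute
#'   `"shapiro_p"` holding the per-group p-values.
#' @export
normality_gate <- function(values, groups, alpha = 0.05) {
  gs <- split_groups(values, groups)
  if (any(vapply(gs, length, 1L) < 3L)) {
    stop("every group needs at least 3 observations for the normality gate")
  }
  if (any(vapply(gs, function(v) sd(v) == 0, logical(1)))) {
    stop("degenerate (constant) group: normality is undefined")
  }
  p <- vapply(gs, function(v) shapiro.test(v)$p.value, numeric(1))
  out <- if (all(p > alpha)) "parametric" else "nonparametric"
  attr(out, "shapiro_p") <- p
  out
}

#' One-way ANOVA with Tukey HSD post hoc
#'
#' Fixed-effects one-way F test with `(k - 1, N - k)` degrees of freedom;
#' when the omnibus p-value falls below `alpha`, all pairwise comparisons
#' are tested with Tukey's honestly-significant-difference procedure
#' (studentized range, with the Tukey-Kramer correction for unequal group
#' sizes).
#'
#' @param values Numeric vector of per-animal metric values.
#' @param groups Group labels, same length.
#' @param alpha Omnibus significance level gating the post hoc
#'   (default 0.05).
#' @return A `stat_report` with `test = "anova"`; `posthoc` is a tibble
#'   of pairwise contrasts (`pair`, `diff`, `lwr`, `upr`, `p_adj`) when
#'   run.
#' @export
anova_tukey <- function(values, groups, alpha = 0.05) {
  gs <- split_groups(values, groups)
  if (length(gs) < 2L) stop("need at least 2 groups")
  if (any(vapply(gs, length, 1L) < 2L)) {
    stop("every group needs at least 2 observations")
  }
  g <- factor(rep(names(gs), vapply(gs, length, 1L)),
              levels = names(gs))
  v <- unlist(gs, use.names = FALSE)
  k <- length(gs); n <- length(v)
  ss_within <- sum(vapply(gs, function(x) sum((x - mean(x))^2), 1))
  if (ss_within == 0) {
    means <- vapply(gs, mean, 1)
    if (var(means) > 0) {
      return(new_stat_report("anova", Inf, c(k - 1, n - k), 0))
    }
    return(new_stat_report("anova", 0, c(k - 1, n - k), 1))
  }
  fit <- aov(v ~ g)
  a <- anova(fit)
  rep_ <- new_stat_report("anova", a$`F value`[1],
                          c(a$Df[1], a$Df[2]), a$`Pr(>F)`[1])
  if (rep_$p_value < alpha) {
    tk <- TukeyHSD(fit)$g
    rep_$posthoc <- tibble::tibble(pair = rownames(tk),
                                   diff = tk[, "diff"], lwr = tk[, "lwr"],
                                   upr = tk[, "upr"], p_adj = tk[, "p adj"])
  }
  rep_
}

#' Kruskal-Wallis test with Dunn post hoc
#'
#' Tie-corrected Kruskal-Wallis H; when the omnibus p-value falls below
#' `alpha`, Dunn z-tests on all group pairs are run with multiplicity
#' adjustment (Bonferroni by default, Holm available).
#'
#' @param values Numeric vector of per-animal metric values.
#' @param groups Group labels, same length.
#' @param alpha Omnibus significance level gating the post hoc.
#' @param p_adjust `"bonferroni"` (default) or `"holm"`.
#' @return A `stat_report` with `test = "kruskal"`; `posthoc` is a tibble
#'   (`pair`, `z`, `p_raw`, `p_adj`) when run.
#' @export
kw_dunn <- function(values, groups, alpha = 0.05,
                    p_adjust = c("bonferroni", "holm")) {
  p_adjust <- match.arg(p_adjust)
  gs <- split_groups(values, groups)
  if (length(gs) < 2L) stop("need at least 2 groups")
  v <- unlist(gs, use.names = FALSE)
  n <- length(v)
  if (n < 3L) stop("need at least 3 observations in total")
  if (length(unique(v)) == 1L) {
    # complete ties: H defined as 0
    return(new_stat_report("kruskal", 0, length(gs) - 1, 1))
  }
  g <- factor(rep(names(gs), vapply(gs, length, 1L)), levels = names(gs))
  kt <- kruskal.test(v, g)
  rep_ <- new_stat_report("kruskal", unname(kt$statistic),
                          unname(kt$parameter), kt$p.value)
  if (rep_$p_value < alpha) {
    rk <- rank(v)
    rbar <- tapply(rk, g, mean)
    ni <- tapply(rk, g, length)
    ties <- table(v)
    tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
    labs <- names(gs)
    pairs <- utils::combn(labs, 2)
    z <- apply(pairs, 2, function(pp) {
      se <- sqrt((n * (n + 1) / 12 - tie_corr) *
                   (1 / ni[[pp[1]]] + 1 / ni[[pp[2]]]))
      (rbar[[pp[1]]] - rbar[[pp[2]]]) / se
    })
    p_raw <- 2 * pnorm(-abs(z))
    rep_$posthoc <- tibble::tibble(
      pair = apply(pairs, 2, paste, collapse = "-"),
      z = z, p_raw = p_raw,
      p_adj = p.adjust(p_raw, method = p_adjust))
  }
  rep_
}

#' Balanced repeated-measures two-way ANOVA
#'
#' Convenience fit for a complete balanced design (every animal measured
#' on every day): between-subject factor `group`, within-subject factor
#' `day`, subjects nested in group. F tests come from the classical
#' expected-mean-square partition — group against subjects-within-group,
#' day and the group x day interaction against the residual. No
#' sphericity correction is applied.
#'
#' @param data Data frame with columns `animal`, `group`, `day`, `value`.
#' @return A list of three `stat_report`s: `group`, `day`, `interaction`.
#' @export
rm_anova_balanced <- function(data) {
  stopifnot(all(c("animal", "group", "day", "value") %in% names(data)))
  data$animal <- factor(data$animal)
  data$group <- factor(data$group)
  data$day <- factor(data$day)
  tab <- table(data$animal, data$day)
  if (any(tab != 1L)) {
    stop("design is incomplete or unbalanced (every animal needs exactly ",
         "one value per day); fit a mixed-effects model instead ",
         "(e.g. lme4/lmerTest)")
  }
  fit <- aov(value ~ group * day + Error(animal), data = data)
  s <- summary(fit)
  between <- s[["Error: animal"]][[1]]
  within <- s[["Error: Within"]][[1]]
  grab <- function(tbl, term) {
    i <- grep(paste0("^", term, "\\s*$"), trimws(rownames(tbl)))
    new_stat_report(paste0("rm_anova:", term), tbl$`F value`[i],
                    c(tbl$Df[i], tbl$Df[nrow(tbl)]), tbl$`Pr(>F)`[i])
  }
  list(group = grab(between, "group"),
       day = grab(within, "day"),
       interaction = grab(within, "group:day"))
}

#' Correlation between two per-animal metrics
#'
#' @param x,y Paired numeric vectors (`n >= 3`, finite).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A list with `r` (coefficient) and `p` (two-sided p-value).
#' @export
correlate_metrics <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation is undefined for a zero-variance vector")
  }
  ct <- cor.test(x, y, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Mean and standard error of the mean
#'
#' @param values Numeric vector (`n >= 1`; the SEM needs `n >= 2` and is
#'   `NA` otherwise).
#' @return A list with `mean` and `sem` (`sd / sqrt(n)`, sample sd with
#'   `n - 1` denominator).
#' @export
mean_sem <- function(values) {
  stopifnot(length(values) >= 1)
  list(mean = mean(values),
       sem = if (length(values) >= 2) sd(values) / sqrt(length(values))
             else NA_real_)
}

#' Normality-gated group comparison
#'
#' The full inferential chain applied to one metric: Shapiro-Wilk gate,
#' then either [anova_tukey()] (all groups normal) or [kw_dunn()]
#' (otherwise), with the gate outcome recorded in the report.
#'
#' @inheritParams normality_gate
#' @param ... Passed to the selected omnibus test.
#' @return A `stat_report` with the `gate` field set.
#' @export
compare_groups <- function(values, groups, alpha = 0.05, ...) {
  gate <- normality_gate(values, groups, alpha = alpha)
  rep_ <- if (gate == "parametric") {
    anova_tukey(values, groups, alpha = alpha, ...)
  } else {
    kw_dunn(values, groups, alpha = alpha, ...)
  }
  rep_$gate <- as.character(gate)
  rep_
}
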