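#' Normality gate for the comparison battery
#'
#' Runs a Shapiro-Wilk test within each group; the battery proceeds
#' parametrically only when every group is compatible with normality
#' (p > alpha in all groups), otherwise non-parametrically.
#'
#' @param values numeric vector of observations.
#' @param groups grouping vector of the same length.
#' @param alpha gate level, default 0.05.
#' @return list with `branch` (`"parametric"`/`"nonparametric"`) and
#'   `shapiro`, a per-group data frame of W statistics and p-values.
#' @export
normality_gate <- function(values, groups, alpha = 0.05) {
  groups <- as.factor(groups)
  stopifnot(length(values) == length(groups))
  per <- lapply(split(values, groups), function(v) {
    if (length(v) < 3L)
      stop("normality gate needs n >= 3 per group", call. = FALSE)
    if (stats::sd(v) == 0)
      stop("degenerate group (zero variance): normality test undefined",
           call. = FALSE)
    sw <- stats::shapiro.test(v)
    c(W = unname(sw$statistic), p_value = sw$p.value)
  })
  shapiro <- data.frame(group = names(per), do.call(rbind, per),
                        row.names = NULL, stringsAsFactors = FALSE)
  list(branch = if (all(shapiro$p_value > alpha)) "parametric"
       else "nonparametric",
       alpha = alpha, shapiro = shapiro)
}

#' Dunn's rank-based post-hoc test
#'
#' Pairwise z statistics on mean ranks after a Kruskal-Wallis omnibus, with
#' the usual tie correction and (by default) Bonferroni-adjusted two-sided
#' p-values.
#'
#' @param values numeric observations.
#' @param groups grouping vector.
#' @param p_adjust_method passed to [stats::p.adjust()]; default
#'   `"bonferroni"`.
#' @return data frame with `group_a`, `group_b`, `z`, `p_value`,
#'   `p_adjusted`.
#' @export
dunn_test <- function(values, groups, p_adjust_method = "bonferroni") {
  groups <- as.factor(groups)
  rk <- rank(values)
  N <- length(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_term
  rbar <- tapply(rk, groups, mean)
  ns <- tapply(rk, groups, length)
  gl <- levels(groups)
  pairs <- utils::combn(gl, 2)
  z <- apply(pairs, 2, function(pr) {
    (rbar[[pr[1]]] - rbar[[pr[2]]]) /
      sqrt(v0 * (1 / ns[[pr[1]]] + 1 / ns[[pr[2]]]))
  })
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group_a = pairs[1, ], group_b = pairs[2, ], z = z,
             p_value = p,
             p_adjusted = stats::p.adjust(p, method = p_adjust_method),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Gated group comparison with post-hoc tests
#'
#' The comparison battery: given the [normality_gate()] outcome, an
#' independent k-group design runs a one-way ANOVA with Tukey HSD
#' post-hocs (parametric branch) or, non-parametrically, a two-sample
#' Kolmogorov-Smirnov test (k = 2) / Kruskal-Wallis omnibus with Dunn
#' post-hocs (k > 2). A paired two-group design runs a paired t test or a
#' Wilcoxon signed-rank test. All tests are two-sided.
#'
#' @param values numeric observations. For `design = "paired_2"` the pairing
#'   is by position within group (both groups sorted consistently by the
#'   caller, e.g. by age class).
#' @param groups grouping vector.
#' @param design `"independent_k"` or `"paired_2"`.
#' @param gate result of [normality_gate()]; computed from the data when
#'   omitted.
#' @param alpha level used only for the gate default.
#' @return list of class `"test_report"`: `test_name`, `groups`,
#'   `statistic`, `p_value`, `decision_path`, and `posthoc` (a data frame,
#'   or `NULL`).
#' @export
compare_groups <- function(values, groups,
                           design = c("independent_k", "paired_2"),
                           gate = NULL, alpha = 0.05) {
  design <- match.arg(design)
  groups <- as.factor(groups)
  stopifnot(length(values) == length(groups))
  k <- nlevels(groups)
  if (design == "paired_2") {
    if (k != 2L) stop("paired design needs exactly 2 groups", call. = FALSE)
    sp <- split(values, groups)
    if (length(sp[[1]]) != length(sp[[2]]))
      stop("paired design needs equal group lengths", call. = FALSE)
  }
  gate <- gate %||% normality_gate(values, groups, alpha)
  branch <- gate$branch
  posthoc <- NULL
  if (design == "paired_2") {
    sp <- split(values, groups)
    if (all(sp[[1]] == sp[[2]])) {
      # every pairwise difference is zero: no test statistic is defined,
      # report the degenerate no-difference result
      return(structure(list(test_name = "paired (degenerate)",
                            groups = levels(groups), statistic = 0,
                            p_value = 1,
                            decision_path = sprintf(
                              "gate=%s -> all paired differences zero",
                              branch),
                            posthoc = NULL, gate = gate),
                       class = "test_report"))
    }
    if (branch == "parametric") {
      tt <- stats::t.test(sp[[1]], sp[[2]], paired = TRUE)
      test_name <- "paired t-test"
      statistic <- unname(tt$statistic); p_value <- tt$p.value
    } else {
      wt <- stats::wilcox.test(sp[[1]], sp[[2]], paired = TRUE,
                               exact = FALSE)
      test_name <- "Wilcoxon signed-rank"
      statistic <- unname(wt$statistic); p_value <- wt$p.value
    }
    path <- sprintf("gate=%s -> %s", branch, test_name)
  } else if (branch == "parametric") {
    fit <- stats::aov(values ~ groups)
    an <- summary(fit)[[1]]
    test_name <- "one-way ANOVA"
    statistic <- an[["F value"]][1]; p_value <- an[["Pr(>F)"]][1]
    if (k > 2L) {
      tk <- stats::TukeyHSD(fit)$groups
      posthoc <- data.frame(contrast = rownames(tk), tk, row.names = NULL,
                            stringsAsFactors = FALSE)
      names(posthoc) <- c("contrast", "diff", "lwr", "upr", "p_adjusted")
    }
    path <- sprintf("gate=parametric -> ANOVA%s",
                    if (k > 2L) " -> Tukey HSD" else "")
  } else if (k == 2L) {
    sp <- split(values, groups)
    ks <- suppressWarnings(stats::ks.test(sp[[1]], sp[[2]]))
    test_name <- "two-sample Kolmogorov-Smirnov"
    statistic <- unname(ks$statistic); p_value <- ks$p.value
    path <- "gate=nonparametric -> KS (2 groups)"
  } else {
    kw <- stats::kruskal.test(values, groups)
    test_name <- "Kruskal-Wallis"
    statistic <- unname(kw$statistic); p_value <- kw$p.value
    posthoc <- dunn_test(values, groups)
    path <- "gate=nonparametric -> Kruskal-Wallis -> Dunn (Bonferroni)"
  }
  structure(list(test_name = test_name, groups = levels(groups),
                 statistic = statistic, p_value = p_value,
                 decision_path = path, posthoc = posthoc, gate = gate),
            class = "test_report")
}

#' @export
print.test_report <- function(x, ...) {
  cat(sprintf("%s [%s]\n  statistic = %.4g, p = %.4g\n", x$test_name,
              x$decision_path, x$statistic, x$p_value))
  if (!is.null(x$posthoc)) {
    cat("  post-hoc:\n")
    print(x$posthoc, digits = 4)
  }
  invisible(x)
}

#' Isotope-versus-age linear regression
#'
#' Ordinary least-squares fit of a delta value on age (band index in
#' years), per individual or pooled. A trend is flagged `"increasing"`
#' when the slope is positive with p < 0.05. A response with zero variance
#' is reported as slope 0, R-squared 0, p 1 (no trend detectable).
#'
#' @param age numeric ages (>= 3 distinct values).
#' @param delta numeric isotope values.
#' @return data frame row: `slope`, `se_slope`, `intercept`, `r_squared`,
#'   `p_value`, `n`, `increasing`.
#' @export
isotope_age_regression <- function(age, delta) {
  ok <- is.finite(age) & is.finite(delta)
  age <- age[ok]; delta <- delta[ok]
  if (length(unique(age)) < 3L)
    stop("regression needs >= 3 distinct ages", call. = FALSE)
  if (stats::sd(delta) == 0)
    return(data.frame(slope = 0, se_slope = 0, intercept = delta[1L],
                      r_squared = 0, p_value = 1, n = length(age),
                      increasing = FALSE))
  fit <- stats::lm(delta ~ age)
  sm <- summary(fit)
  co <- sm$coefficients
  data.frame(slope = co["age", "Estimate"],
             se_slope = co["age", "Std. Error"],
             intercept = co["(Intercept)", "Estimate"],
             r_squared = sm$r.squared,
             p_value = co["age", "Pr(>|t|)"],
             n = length(age),
             increasing = co["age", "Estimate"] > 0 &&
               co["age", "Pr(>|t|)"] < 0.05)
}

#' Per-individual and pooled ontogenetic regressions
#'
#' @param x a [band_table].
#' @param element `"13C"` or `"15N"`.
#' @param level `"pooled-by-sex"` (one fit per sex plus combined) or
#'   `"individual"`.
#' @return data frame of [isotope_age_regression()] rows with a `unit`
#'   column; individuals with fewer than 3 distinct bands are skipped.
#' @export
ontogeny_regressions <- function(x, element = c("13C", "15N"),
                                 level = c("pooled-by-sex", "individual")) {
  element <- match.arg(element)
  level <- match.arg(level)
  x <- as.data.frame(x)
  x <- x[x$band_index >= 1, , drop = FALSE]
  delta <- if (element == "13C") x$d13C else x$d15N
  if (level == "individual") {
    sp <- split(seq_len(nrow(x)), x$individual_id)
  } else {
    sp <- split(seq_len(nrow(x)), x$sex)
    sp$combined <- seq_len(nrow(x))
  }
  rows <- lapply(names(sp), function(u) {
    i <- sp[[u]]
    if (length(unique(x$band_index[i])) < 3L) return(NULL)
    cbind(unit = u, isotope_age_regression(x$band_index[i], delta[i]),
          stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
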