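#' Delta notation for isotope ratios
#'
#' delta = ((R_sample / R_standard) - 1) * 1000, the per-mil deviation of a
#' sample's heavy/light isotope ratio from a reference standard (AIR for
#' nitrogen, VPDB for carbon). Provided for completeness and for building
#' synthetic data; instrument output normally arrives already in delta
#' units.
#'
#' @param r_sample sample heavy/light isotope ratio (>= 0); vectorized
#' @param r_standard reference ratio (> 0)
#' @return per-mil delta value(s)
#' @export
delta_value <- function(r_sample, r_standard) {
  if (any(!is.finite(r_standard)) || any(r_standard <= 0)) {
    rlang::abort("r_standard must be positive")
  }
  if (any(r_sample < 0, na.rm = TRUE)) {
    rlang::abort("r_sample must be non-negative")
  }
  ((r_sample / r_standard) - 1) * 1000
}

#' Levene's test for homogeneity of variances
#'
#' One-way ANOVA on absolute deviations from the group center (classical
#' Levene with `center = "mean"`, Brown-Forsythe with `center = "median"`).
#'
#' @param values numeric vector
#' @param groups grouping vector (coerced to factor)
#' @param center `"mean"` (default, classical) or `"median"`
#' @return list with `W` (the F statistic), `df1`, `df2`, `p`, `center`
#' @export
levene_test <- function(values, groups, center = c("mean", "median")) {
  center <- match.arg(center)
  g <- factor(groups)
  if (nlevels(g) < 2) rlang::abort("need at least two groups")
  fit <- car::leveneTest(values, g,
                         center = if (center == "mean") mean else median)
  list(W = fit[1, "F value"], df1 = fit[1, "Df"], df2 = fit[2, "Df"],
       p = fit[1, "Pr(>F)"], center = center)
}

#' Variance-based isotopic niche width
#'
#' The variance of a consumer population's delta values is used as a proxy
#' for its dietary niche width. Computes unbiased sample variances per
#' river-year group, an omnibus Levene homoscedasticity test across all
#' groups, and pairwise Levene tests for the requested contrasts.
#'
#' @param samples tibble with columns `river`, `year`, and the isotope
#'   column (contaminated scats must be excluded upstream)
#' @param isotope `"d15N"` or `"d13C"`
#' @param center Levene center, `"mean"` or `"median"`
#' @param contrasts list of 2-element character vectors naming group pairs
#'   as `"river year"`; default all pairs
#' @return list of class `variance_niche`: `group_stats` tibble (`river`,
#'   `year`, `n`, `mean`, `variance`), `omnibus` (Levene list), `pairwise`
#'   tibble, `isotope`, `center`
#' @export
variance_niche <- function(samples, isotope = c("d15N", "d13C"),
                           center = c("mean", "median"), contrasts = NULL) {
  isotope <- match.arg(isotope)
  center <- match.arg(center)
  stopifnot(all(c("river", "year", isotope) %in% names(samples)))
  v <- samples[[isotope]]
  key <- paste(samples$river, samples$year)
  stats_tbl <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(samples), .data$river, .data$year),
    n = dplyr::n(), mean = mean(.data[[isotope]]),
    variance = stats::var(.data[[isotope]]), .groups = "drop")
  small <- stats_tbl[stats_tbl$n < 2, ]
  if (nrow(small) > 0) {
    rlang::abort(paste0("group(s) with fewer than 2 samples: ",
                        paste(paste(small$river, small$year), collapse = ", ")))
  }
  if (nrow(stats_tbl) < 2) rlang::abort("need at least two groups")
  omnibus <- levene_test(v, key, center = center)
  keys <- sort(unique(key))
  if (is.null(contrasts)) {
    contrasts <- utils::combn(keys, 2, simplify = FALSE)
  }
  pw <- purrr::map(contrasts, function(ct) {
    stopifnot(length(ct) == 2)
    if (!all(ct %in% keys)) {
      rlang::abort(paste0("unknown group in contrast: ",
                          paste(setdiff(ct, keys), collapse = ", ")))
    }
    sel <- key %in% ct
    lt <- levene_test(v[sel], key[sel], center = center)
    tibble::tibble(group1 = ct[1], group2 = ct[2],
                   W = lt$W, df1 = lt$df1, df2 = lt$df2, p = lt$p)
  })
  structure(list(group_stats = stats_tbl, omnibus = omnibus,
                 pairwise = dplyr::bind_rows(pw),
                 isotope = isotope, center = center),
            class = "variance_niche")
}

#' @export
print.variance_niche <- function(x, ...) {
  cat("Isotopic niche width (", x$isotope, "), Levene center = ",
      x$center, "\n", sep = "")
  print(x$group_stats, ...)
  cat(sprintf("Omnibus Levene: W = %.3f, df = (%d, %d), p = %.4g\n",
              x$omnibus$W, x$omnibus$df1, x$omnibus$df2, x$omnibus$p))
  invisible(x)
}

#' Shapiro-Wilk normality check
#'
#' Advisory screen used before parametric isotope comparisons; the verdict
#' never blocks a pipeline run. Sample sizes outside 3..5000 are flagged
#' `"not assessed"` with a warning, and constant vectors `"degenerate"`.
#'
#' @param values numeric vector
#' @param alpha significance level for the verdict (default 0.05)
#' @return list with `statistic`, `p`, `verdict` (`"normal"`,
#'   `"non-normal"`, `"not assessed"`, `"degenerate"`)
#' @export
normality_check <- function(values, alpha = 0.05) {
  v <- values[is.finite(values)]
  n <- length(v)
  if (n < 3 || n > 5000) {
    rlang::warn(paste0("n = ", n, " outside 3..5000; normality not assessed"))
    return(list(statistic = NA_real_, p = NA_real_, verdict = "not assessed"))
  }
  if (stats::sd(v) == 0) {
    rlang::warn("constant vector; normality degenerate")
    return(list(statistic = NA_real_, p = NA_real_, verdict = "degenerate"))
  }
  sw <- stats::shapiro.test(v)
  list(statistic = unname(sw$statistic), p = sw$p.value,
       verdict = if (sw$p.value > alpha) "normal" else "non-normal")
}

#' Two-factor ANOVA on isotope values
#'
#' Sequential (Type I) sums of squares with an interaction term, the
#' classical `aov` decomposition. An optional natural-log transformation
#' addresses variance heterogeneity; it requires strictly positive values
#' and is therefore meant for delta-15N (delta-13C is negative and is
#' never transformed).
#'
#' @param values numeric response
#' @param factor_river,factor_year grouping vectors (coerced to factor),
#'   each with at least two levels
#' @param log_transform apply `log()` to the response first
#' @return tibble: `term`, `df`, `sumsq`, `meansq`, `statistic`, `p_value`
#' @export
anova_two_factor <- function(values, factor_river, factor_year,
                             log_transform = FALSE) {
  river <- factor(factor_river)
  year <- factor(factor_year)
  if (nlevels(river) < 2 || nlevels(year) < 2) {
    rlang::abort("each factor needs at least two levels")
  }
  cells <- table(river, year)
  if (any(cells == 0)) {
    idx <- which(cells == 0, arr.ind = TRUE)[1, ]
    rlang::abort(paste0("empty design cell: river=",
                        rownames(cells)[idx[1]], ", year=",
                        colnames(cells)[idx[2]]))
  }
  y <- values
  if (log_transform) {
    if (any(y <= 0, na.rm = TRUE)) {
      rlang::abort("log transformation requires strictly positive values")
    }
    y <- log(y)
  }
  fit <- stats::aov(y ~ river * year)
  tab <- summary(fit)[[1]]
  if (tab[nrow(tab), "Sum Sq"] <= .Machine$double.eps * max(1, sum(y^2))) {
    rlang::abort("zero residual variance; F undefined")
  }
  tibble::tibble(term = trimws(rownames(tab)),
                 df = tab$Df, sumsq = tab$`Sum Sq`, meansq = tab$`Mean Sq`,
                 statistic = tab$`F value`, p_value = tab$`Pr(>F)`)
}

#' Pairwise two-sample t tests with Bonferroni adjustment
#'
#' One two-sample t test per requested contrast, with raw p-values
#' multiplied by the number of contrasts (capped at 1). The variance
#' policy decides between the pooled and Welch statistic: under
#' `"auto"`, Welch is used for a contrast whose pairwise Levene test
#' rejects at 0.05, pooled otherwise.
#'
#' @param values numeric vector
#' @param groups grouping vector
#' @param contrasts list of 2-element character vectors of group labels;
#'   default all pairs
#' @param equal_var_policy `"auto"`, `"pooled"`, or `"welch"`
#' @param center Levene center used by the `"auto"` policy
#' @return tibble: `group1`, `group2`, `method`, `t`, `df`, `p_raw`,
#'   `p_adj`
#' @export
pairwise_t_bonferroni <- function(values, groups, contrasts = NULL,
                                  equal_var_policy = c("auto", "pooled",
                                                       "welch"),
                                  center = c("mean", "median")) {
  equal_var_policy <- match.arg(equal_var_policy)
  center <- match.arg(center)
  g <- as.character(groups)
  labs <- sort(unique(g))
  if (is.null(contrasts)) contrasts <- utils::combn(labs, 2, simplify = FALSE)
  m <- length(contrasts)
  rows <- purrr::map(contrasts, function(ct) {
    stopifnot(length(ct) == 2)
    if (!all(ct %in% labs)) {
      rlang::abort(paste0("unknown group in contrast: ",
                          paste(setdiff(ct, labs), collapse = ", ")))
    }
    x <- values[g == ct[1]]
    y <- values[g == ct[2]]
    if (length(x) < 2 || length(y) < 2) {
      rlang::abort(paste0("contrast ", ct[1], " vs ", ct[2],
                          " needs n >= 2 per group"))
    }
    pooled <- switch(equal_var_policy,
                     pooled = TRUE, welch = FALSE,
                     auto = levene_test(c(x, y), rep(ct, c(length(x), length(y))),
                                        center = center)$p >= 0.05)
    tt <- stats::t.test(x, y, var.equal = pooled)
    tibble::tibble(group1 = ct[1], group2 = ct[2],
                   method = if (pooled) "pooled" else "welch",
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p_raw = tt$p.value, p_adj = min(1, tt$p.value * m))
  })
  dplyr::bind_rows(rows)
}
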