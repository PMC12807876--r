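#' Normalization schemes for measured values
#'
#' Element-wise division per scheme: `to_t0` by the first element of the
#' series; `to_iso_control` by the mean of an isosmotic control sample;
#' `to_reference_signal` by a scalar reference (e.g. a 1 µM protein
#' solution); `to_ca0_pvp_control` by the mean of the calcium-free,
#' osmotically balanced control. Schemes are mutually exclusive and recorded
#' in the output's `normalization` attribute — values normalized under
#' different schemes are not directly comparable.
#'
#' @param values numeric vector.
#' @param scheme one of `"to_t0"`, `"to_iso_control"`,
#'   `"to_reference_signal"`, `"to_ca0_pvp_control"`.
#' @param reference control sample or scalar (not needed for `to_t0`).
#' @return normalized values with attribute `normalization = scheme`.
#' @export
normalize_measure <- function(values,
                              scheme = c("to_t0", "to_iso_control",
                                         "to_reference_signal",
                                         "to_ca0_pvp_control"),
                              reference = NULL) {
  scheme <- match.arg(scheme)
  base <- switch(scheme,
                 to_t0 = values[1],
                 to_reference_signal = {
                   if (is.null(reference) || length(reference) != 1L)
                     stop("to_reference_signal requires a scalar reference")
                   reference
                 },
                 {
                   if (is.null(reference))
                     stop("scheme '", scheme, "' requires a control sample")
                   mean(reference)
                 })
  if (!is.finite(base) || base <= 0)
    stop("zero or negative normalization reference for scheme '", scheme,
         "'")
  out <- values / base
  attr(out, "normalization") <- scheme
  out
}

significance_stars <- function(p) {
  ifelse(p <= 1e-4, "****", ifelse(p <= 1e-3, "***",
         ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", "ns"))))
}

#' Gated two-group comparison
#'
#' Shapiro-Wilk on both groups: if both pass normality, Levene decides
#' between the unpaired two-tailed Student's t-test (equal variance) and
#' Welch's t-test; otherwise the two-tailed Mann-Whitney U test is used.
#' The gate trace records every decision.
#'
#' @param a,b numeric samples (each n >= 3).
#' @param alpha gate significance level.
#' @return a `StatResult` list: `test_name`, `statistic`, `p_value`, `n`,
#'   `stars`, `gate_trace`.
#' @export
gated_two_group <- function(a, b, alpha = 0.05) {
  if (length(a) < 3L || length(b) < 3L)
    stop("each group needs at least 3 observations")
  sw_a <- shapiro_p(a)
  sw_b <- shapiro_p(b)
  normal <- sw_a > alpha && sw_b > alpha
  gate <- list(shapiro_a = sw_a, shapiro_b = sw_b, normal = normal,
               levene = NA_real_, equal_var = NA)
  if (normal) {
    lev <- levene_p(list(a, b))
    gate$levene <- lev
    gate$equal_var <- lev > alpha
    ht <- stats::t.test(a, b, var.equal = gate$equal_var,
                        alternative = "two.sided")
    name <- if (gate$equal_var) "student_t" else "welch_t"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b,
                                              alternative = "two.sided"))
    name <- "mann_whitney_u"
  }
  list(test_name = name, statistic = unname(ht$statistic),
       p_value = ht$p.value, n = c(length(a), length(b)),
       stars = significance_stars(ht$p.value), gate_trace = gate)
}

shapiro_p <- function(x) {
  if (length(unique(x)) == 1L) return(0)   # degenerate: clearly non-normal
  stats::shapiro.test(x)$p.value
}

levene_p <- function(groups) {
  vals <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  car::leveneTest(vals ~ g, center = stats::median)[1, "Pr(>F)"]
}

#' Games-Howell post hoc test
#'
#' Pairwise comparisons after Welch's ANOVA: Welch t statistics with
#' Welch-Satterthwaite degrees of freedom referred to the studentized range
#' distribution.
#'
#' @param groups list of numeric samples.
#' @return data frame of pairwise rows `group_i`, `group_j`, `statistic`,
#'   `df`, `p_value`, `stars`.
#' @export
games_howell <- function(groups) {
  k <- length(groups)
  stopifnot(k >= 2)
  n <- vapply(groups, length, integer(1))
  m <- vapply(groups, mean, numeric(1))
  v <- vapply(groups, stats::var, numeric(1))
  out <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    sij <- v[i] / n[i] + v[j] / n[j]
    t <- abs(m[i] - m[j]) / sqrt(sij)
    df <- sij^2 / ((v[i] / n[i])^2 / (n[i] - 1) +
                     (v[j] / n[j])^2 / (n[j] - 1))
    p <- stats::ptukey(t * sqrt(2), nmeans = k, df = df,
                       lower.tail = FALSE)
    out[[length(out) + 1L]] <- data.frame(group_i = i, group_j = j,
                                          statistic = t, df = df,
                                          p_value = p,
                                          stars = significance_stars(p))
  }
  do.call(rbind, out)
}

#' Dunn's post hoc test
#'
#' Rank-based pairwise z tests after Kruskal-Wallis, with tie correction.
#' No multiplicity adjustment is applied by default; Bonferroni or Holm are
#' selectable.
#'
#' @param groups list of numeric samples.
#' @param p_adjust `"none"`, `"bonferroni"` or `"holm"`.
#' @return data frame of pairwise rows `group_i`, `group_j`, `statistic`
#'   (z), `p_value`, `stars`.
#' @export
dunn_test <- function(groups, p_adjust = c("none", "bonferroni", "holm")) {
  p_adjust <- match.arg(p_adjust)
  k <- length(groups)
  stopifnot(k >= 2)
  n <- vapply(groups, length, integer(1))
  vals <- unlist(groups)
  N <- length(vals)
  r <- rank(vals)
  g <- rep(seq_len(k), n)
  rbar <- tapply(r, g, mean)
  ties <- table(vals)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_corr
  out <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    z <- (rbar[i] - rbar[j]) / sqrt(s2 * (1 / n[i] + 1 / n[j]))
    p <- 2 * stats::pnorm(-abs(z))
    out[[length(out) + 1L]] <- data.frame(group_i = i, group_j = j,
                                          statistic = unname(z),
                                          p_value = unname(p))
  }
  res <- do.call(rbind, out)
  res$p_value <- stats::p.adjust(res$p_value, method = p_adjust)
  res$stars <- significance_stars(res$p_value)
  res
}

#' Gated multi-group comparison
#'
#' Shapiro-Wilk on every group: if all pass, one-way Welch's ANOVA (equal
#' variance is not assumed) followed by a Games-Howell post hoc table;
#' otherwise Kruskal-Wallis followed by Dunn's test. Significance stars use
#' the 0.05 / 0.01 / 0.001 / 0.0001 thresholds.
#'
#' @param groups list of >= 3 numeric samples (each n >= 3).
#' @param alpha gate significance level.
#' @param p_adjust multiplicity adjustment for Dunn's test.
#' @return a `StatResult` list with `test_name`, `statistic`, `p_value`,
#'   `stars`, `posthoc` (pairwise table), `gate_trace`.
#' @export
gated_multi_group <- function(groups, alpha = 0.05,
                              p_adjust = c("none", "bonferroni", "holm")) {
  p_adjust <- match.arg(p_adjust)
  if (length(groups) < 3L) stop("need at least 3 groups")
  if (any(vapply(groups, length, integer(1)) < 3L))
    stop("each group needs at least 3 observations")
  if (all(vapply(groups, function(x) length(unique(x)) == 1L, logical(1))) &&
      length(unique(unlist(groups))) == 1L)
    stop("all groups are identical constants: zero variance")
  sw <- vapply(groups, shapiro_p, numeric(1))
  normal <- all(sw > alpha)
  gate <- list(shapiro = sw, normal = normal, levene = levene_p(groups))
  vals <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  if (normal) {
    ht <- stats::oneway.test(vals ~ g, var.equal = FALSE)
    posthoc <- games_howell(groups)
    name <- "welch_anova"
  } else {
    ht <- stats::kruskal.test(vals, g)
    posthoc <- dunn_test(groups, p_adjust)
    name <- "kruskal_wallis"
  }
  list(test_name = name, statistic = unname(ht$statistic),
       p_value = ht$p.value, stars = significance_stars(ht$p.value),
       n = vapply(groups, length, integer(1)), posthoc = posthoc,
       gate_trace = gate)
}

#' OLS adsorption-rate estimation with diagnostics
#'
#' Fits S ~ time by ordinary least squares over the linear window of the
#' binding curves (default t = 4-5 min), pooled across cells. Diagnostics:
#' Breusch-Pagan (heteroscedasticity), Shapiro-Wilk on residuals
#' (normality), Durbin-Watson (autocorrelation). If Breusch-Pagan or the
#' residual Shapiro-Wilk returns p < 0.05, the model is re-estimated with
#' HC3 heteroscedasticity-consistent standard errors. With exactly two time
#' points in the window, linearity/multicollinearity checks are not
#' applicable and are skipped.
#'
#' @param series data frame with columns `time`, `S` and optionally `cell`.
#' @param window `(min, max)` time window of the linear portion.
#' @param alpha diagnostic significance level.
#' @return a `RateFit` list: `slope`, `se`, `ci`, `r_squared`,
#'   `adj_r_squared`, `p_value`, `robust_se_used`, `diagnostics`
#'   (`breusch_pagan_p`, `shapiro_resid_p`, `durbin_watson`), `n`, `fit`.
#' @export
ols_rate <- function(series, window = c(4, 5), alpha = 0.05) {
  stopifnot(all(c("time", "S") %in% names(series)))
  df <- series[series$time >= window[1] & series$time <= window[2], ,
               drop = FALSE]
  if (length(unique(df$time)) < 2L)
    stop("need at least 2 time points inside the window")
  if (stats::var(df$S) == 0) stop("S has zero variance in the window")
  fit <- stats::lm(S ~ time, data = df)
  sm <- summary(fit)
  bp <- tryCatch(lmtest::bptest(fit)$p.value, error = function(e) NA_real_)
  res <- stats::resid(fit)
  swp <- if (length(res) >= 3 && length(unique(round(res, 12))) > 1)
    tryCatch(stats::shapiro.test(res)$p.value, error = function(e) NA_real_)
  else NA_real_
  dw <- tryCatch(unname(lmtest::dwtest(fit)$statistic),
                 error = function(e) NA_real_)
  robust <- isTRUE(bp < alpha) || isTRUE(swp < alpha)
  if (robust) {
    vc <- sandwich::vcovHC(fit, type = "HC3")
    se <- sqrt(diag(vc))["time"]
    tval <- stats::coef(fit)["time"] / se
    p <- 2 * stats::pt(-abs(tval), df = fit$df.residual)
  } else {
    se <- sm$coefficients["time", "Std. Error"]
    p <- sm$coefficients["time", "Pr(>|t|)"]
  }
  slope <- unname(stats::coef(fit)["time"])
  tq <- stats::qt(0.975, df = fit$df.residual)
  list(slope = slope, se = unname(se),
       ci = c(slope - tq * se, slope + tq * se),
       r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
       p_value = unname(p), robust_se_used = robust,
       diagnostics = list(breusch_pagan_p = unname(bp),
                          shapiro_resid_p = swp, durbin_watson = dw),
       n = nrow(df), fit = fit)
}

#' Pearson correlation with 95% regression band
#'
#' Two-tailed Pearson test plus the OLS line and the parameters of its 95%
#' confidence band.
#'
#' @param x,y paired numeric vectors (n >= 3, non-degenerate).
#' @return list: `r`, `p_value`, `n`, `intercept`, `slope`, `band`
#'   (data frame `x`, `fit`, `lower`, `upper`), `fit`.
#' @export
pearson_fit <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (length(x) < 3L) stop("need at least 3 paired values")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance in x or y")
  ct <- stats::cor.test(x, y, method = "pearson",
                        alternative = "two.sided")
  fit <- stats::lm(y ~ x)
  xs <- seq(min(x), max(x), length.out = 50)
  pr <- stats::predict(fit, newdata = data.frame(x = xs),
                       interval = "confidence", level = 0.95)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       band = data.frame(x = xs, fit = pr[, "fit"], lower = pr[, "lwr"],
                         upper = pr[, "upr"]),
       fit = fit)
}

#' Equivalent radius from a polygon area
#'
#' `r = sqrt(A / pi)` — the radius of the circle with the same area.
#'
#' @param polygon_area area (µm^2), non-negative.
#' @return equivalent radius (µm).
#' @export
area_to_radius <- function(polygon_area) {
  if (any(polygon_area < 0)) stop("area must be non-negative")
  sqrt(polygon_area / pi)
}
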