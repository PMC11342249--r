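#' Regress a behavioural score on covariates and keep standardized residuals
#'
#' Ordinary least squares with intercept of `measure` on the covariate
#' columns (by default age, years post stroke, lesion volume and key-region
#' damage). Standardized residuals are the raw residuals divided by their
#' sample standard deviation (a studentized variant is available). A covariate
#' column that is entirely `NA` -- the undefined key-damage case -- is dropped
#' with a message; rows with any remaining missing value are dropped
#' (complete case).
#'
#' @param data Subjects tibble with `subject_id`, the `measure` column and the
#'   covariate columns.
#' @param measure Name of the outcome column.
#' @param covariates Character vector of covariate column names.
#' @param standardize `"sd"` (default): residual / residual SD;
#'   `"studentized"`: internally studentized residuals ([stats::rstandard()]).
#' @return A `covariate_fit` object: use [tidy()] for the coefficient table
#'   (estimate, t, two-tailed p), [glance()] for multiple R, adjusted R-squared,
#'   model F and p, and `$residuals` for a tibble of `subject_id`,
#'   `std_resid`.
#' @examples
#' cohort <- simulate_cohort(n = 30, seed = 2)
#' fit <- residualize(cohort$subjects, "wab_aq",
#'                    covariates = c("age", "years_post_stroke", "lesion_volume"))
#' glance(fit)
#' @export
residualize <- function(data, measure,
                        covariates = c("age", "years_post_stroke",
                                       "lesion_volume", "key_damage"),
                        standardize = c("sd", "studentized")) {
  standardize <- match.arg(standardize)
  missing_cols <- setdiff(c("subject_id", measure, covariates), names(data))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("column(s) not found: ",
                        paste(missing_cols, collapse = ", ")))
  }
  all_na <- covariates[purrr::map_lgl(covariates, ~ all(is.na(data[[.x]])))]
  if (length(all_na) > 0) {
    rlang::inform(paste0("dropping undefined covariate(s): ",
                         paste(all_na, collapse = ", ")))
    covariates <- setdiff(covariates, all_na)
  }
  if (length(covariates) == 0) {
    rlang::abort("no usable covariates left in the design")
  }
  dat <- dplyr::select(data, "subject_id", dplyr::all_of(c(measure, covariates)))
  dat <- tidyr::drop_na(dat)
  n <- nrow(dat)
  if (n <= length(covariates) + 1) {
    rlang::abort("not enough subjects for the covariate model")
  }
  constant <- covariates[purrr::map_lgl(covariates, ~ stats::sd(dat[[.x]]) == 0)]
  if (length(constant) > 0) {
    rlang::abort(paste0("constant covariate(s): ", paste(constant, collapse = ", ")))
  }
  fml <- stats::reformulate(covariates, response = measure)
  fit <- stats::lm(fml, data = dat)
  aliased <- names(which(is.na(stats::coef(fit))))
  if (length(aliased) > 0) {
    rlang::abort(paste0("collinear design: coefficient(s) not estimable for ",
                        paste(aliased, collapse = ", ")))
  }
  res <- stats::residuals(fit)
  std <- switch(standardize,
                sd = res / stats::sd(res),
                studentized = stats::rstandard(fit))
  structure(
    list(model = fit, measure = measure, covariates = covariates,
         dropped_covariates = all_na, standardize = standardize,
         data = dat,
         residuals = tibble::tibble(subject_id = dat$subject_id,
                                    std_resid = unname(std))),
    class = "covariate_fit"
  )
}

#' @export
print.covariate_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("Covariate model for %s: n = %d, R = %.3f, adj R^2 = %.3f, F(%d, %d) = %.2f, p = %.3g\n",
              x$measure, g$n, g$r, g$adj_r_squared, g$df1, g$df2, g$statistic, g$p_value))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.covariate_fit <- function(x, ...) {
  cf <- summary(x$model)$coefficients
  tibble::tibble(
    term = rownames(cf),
    estimate = cf[, "Estimate"],
    std_error = cf[, "Std. Error"],
    t = cf[, "t value"],
    p_value = cf[, "Pr(>|t|)"]
  )
}

#' @exportS3Method generics::glance
glance.covariate_fit <- function(x, ...) {
  s <- summary(x$model)
  f <- s$fstatistic
  tibble::tibble(
    measure = x$measure,
    n = length(stats::residuals(x$model)),
    r = sqrt(s$r.squared),
    r_squared = s$r.squared,
    adj_r_squared = s$adj.r.squared,
    statistic = unname(f["value"]),
    df1 = as.integer(f["numdf"]), df2 = as.integer(f["dendf"]),
    p_value = stats::pf(f["value"], f["numdf"], f["dendf"], lower.tail = FALSE),
    sigma = s$sigma
  )
}

#' Pearson product-moment correlation with two-tailed p
#'
#' @param x,y Numeric vectors of equal length >= 3, both non-constant.
#' @return One-row tibble `r`, `p_value`, `n` (p from the t transform with
#'   n - 2 degrees of freedom).
#' @examples
#' pearson_r(c(1, 2, 3, 4), c(2, 1, 4, 3))
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) rlang::abort("x and y differ in length")
  if (length(x) < 3) rlang::abort("need at least 3 paired observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) rlang::abort("non-finite input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::abort("undefined correlation: constant input vector")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Residual-fibre-ratio associations with FDR across measures
#'
#' For each behavioural measure, correlates the standardized residuals of the
#' covariate model with the subjects' long:short fibre ratio. The squared
#' correlation is the additional variance explained by the fibre proportion
#' beyond the covariates. Raw two-tailed p-values are Benjamini-Hochberg
#' corrected across the family of measures.
#'
#' Two modes: `"literal"` (default) correlates the residualized outcome with
#' the raw ratio, exactly the two-step procedure of saving regression
#' residuals and correlating them; `"partial"` residualizes the ratio on the
#' same covariates first, giving the partial correlation. The partial value
#' `r_partial` is reported alongside in either mode.
#'
#' @param fits Named list of `covariate_fit` objects, one per measure.
#' @param profiles Tibble with `subject_id` and `long_short_ratio` (e.g. from
#'   [fibre_profiles()]).
#' @param mode `"literal"` or `"partial"` (which correlation feeds `r`,
#'   `delta_r_squared` and the p-values).
#' @param q FDR level across the measure family (default 0.05).
#' @return Tibble of class `association_result`: one row per measure with
#'   `n`, `r`, `delta_r_squared` (= r^2), `r_partial`, `p_raw`, `p_fdr`,
#'   `significant`, `family_size`.
#' @export
residual_association <- function(fits, profiles, mode = c("literal", "partial"),
                                 q = 0.05) {
  mode <- match.arg(mode)
  if (!all(purrr::map_lgl(fits, inherits, "covariate_fit"))) {
    rlang::abort("fits must be a list of covariate_fit objects")
  }
  if (length(fits) == 0) rlang::abort("need at least one fitted measure")
  if (is.null(names(fits))) names(fits) <- purrr::map_chr(fits, "measure")
  rows <- purrr::imap(fits, function(fit, nm) {
    joined <- dplyr::inner_join(fit$residuals,
                                dplyr::select(profiles, "subject_id", "long_short_ratio"),
                                by = "subject_id")
    if (nrow(joined) < nrow(fit$residuals)) {
      rlang::abort(paste0("subjects in the ", nm,
                          " fit are missing from profiles (misaligned subject sets)"))
    }
    lit <- pearson_r(joined$std_resid, joined$long_short_ratio)
    ratio_fit <- stats::lm(
      stats::reformulate(fit$covariates, response = "long_short_ratio"),
      data = dplyr::inner_join(fit$data, joined[c("subject_id", "long_short_ratio")],
                               by = "subject_id")
    )
    par <- pearson_r(fit$residuals$std_resid, stats::residuals(ratio_fit))
    use <- if (mode == "literal") lit else par
    tibble::tibble(measure = nm, n = lit$n, r = use$r,
                   delta_r_squared = use$r^2, r_partial = par$r,
                   p_raw = use$p_value)
  })
  out <- dplyr::bind_rows(rows)
  corr <- fdr_bh(out$p_raw, q = q)
  out$p_fdr <- corr$q_value
  out$significant <- corr$significant
  out$family_size <- nrow(out)
  out$mode <- mode
  class(out) <- c("association_result", class(out))
  out
}

#' One-way ANOVA of the fibre ratio across stroke aetiologies
#'
#' Classical fixed-effects one-way analysis of variance, used to check that
#' stroke type (ischaemic / haemorrhagic / other) is not a confound of the
#' long-range fibre proportion before the main analyses. Groups with fewer
#' than two members are merged into `"other"` with a warning rather than
#' failing the run.
#'
#' @param data Tibble holding the value and group columns.
#' @param value Name of the numeric column (default `"long_short_ratio"`).
#' @param group Name of the grouping column (default `"aetiology"`).
#' @return An `anova_result` object; [glance()] gives `statistic` (F), `df1`,
#'   `df2`, `p_value`; [tidy()] gives per-group n and mean.
#' @examples
#' df <- data.frame(g = rep(c("a", "b", "c"), each = 3),
#'                  v = c(1, 2, 3, 2, 3, 4, 3, 4, 5))
#' glance(aetiology_anova(df, value = "v", group = "g"))
#' @export
aetiology_anova <- function(data, value = "long_short_ratio", group = "aetiology") {
  if (!all(c(value, group) %in% names(data))) {
    rlang::abort("value/group column not found in data")
  }
  v <- data[[value]]
  g <- as.character(data[[group]])
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- g[keep]
  sizes <- table(g)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    rlang::warn(paste0("merging group(s) with < 2 subjects into 'other': ",
                       paste(small, collapse = ", ")))
    g[g %in% small] <- "other"
    sizes <- table(g)
    if (sizes["other"] < 2) {
      rlang::warn("dropping 'other' group: still fewer than 2 subjects after merging")
      keep2 <- g != "other"
      v <- v[keep2]; g <- g[keep2]
      sizes <- table(g)
    }
  }
  if (length(sizes) < 2) rlang::abort("need at least 2 aetiology groups")
  if (any(sizes < 2)) rlang::abort("a group has fewer than 2 members")
  if (stats::sd(v) == 0) rlang::abort("constant values: ANOVA undefined")
  ow <- stats::oneway.test(v ~ factor(g), var.equal = TRUE)
  means <- tibble::tibble(group = names(sizes)) |>
    dplyr::mutate(n = as.integer(sizes[.data$group]),
                  mean = purrr::map_dbl(.data$group, ~ mean(v[g == .x])))
  structure(
    list(statistic = unname(ow$statistic),
         df1 = unname(ow$parameter["num df"]),
         df2 = unname(ow$parameter["denom df"]),
         p_value = ow$p.value,
         group_means = means, value = value, group = group),
    class = "anova_result"
  )
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA of %s by %s: F(%g, %g) = %.3f, p = %.3g\n",
              x$value, x$group, x$df1, x$df2, x$statistic, x$p_value))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.anova_result <- function(x, ...) x$group_means

#' @exportS3Method generics::glance
glance.anova_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df1 = x$df1, df2 = x$df2,
                 p_value = x$p_value)
}
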