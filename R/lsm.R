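#' Validate a subjects x regions damage matrix
#'
#' @param damage Tibble with a `subject_id` column and one numeric column per
#'   region (column name = region id), entries being the fraction of the
#'   region's voxels inside the lesion, in `[0, 1]`.
#' @param atlas Optional atlas; when given, region columns must be a subset of
#'   its region ids.
#' @return The damage tibble, validated.
#' @export
validate_damage <- function(damage, atlas = NULL) {
  if (!"subject_id" %in% names(damage)) {
    rlang::abort("damage must contain a subject_id column")
  }
  damage <- tibble::as_tibble(damage)
  vals <- as.matrix(damage[setdiff(names(damage), "subject_id")])
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    rlang::abort("damage fractions must be finite numerics")
  }
  if (any(vals < 0 | vals > 1)) {
    rlang::abort("damage fractions must lie in [0, 1]")
  }
  if (!is.null(atlas)) {
    extra <- setdiff(colnames(vals), as.character(atlas$region_id))
    if (length(extra) > 0) {
      rlang::abort(paste0("damage regions not in atlas: ",
                          paste(extra, collapse = ", ")))
    }
  }
  damage
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up false-discovery-rate control: flags as significant every p-value
#' whose BH-adjusted value is at most `q`. Adjusted values are the usual
#' monotone `p.adjust(method = "BH")` quantities.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return Tibble with columns `p`, `q_value` (BH-adjusted) and `significant`.
#' @examples
#' fdr_bh(c(0.001, 0.01, 0.02, 0.8))
#' @export
fdr_bh <- function(p, q = 0.05) {
  if (length(p) == 0) rlang::abort("empty p-value vector")
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    rlang::abort("p-values must lie in [0, 1]")
  }
  adj <- stats::p.adjust(p, method = "BH")
  tibble::tibble(p = p, q_value = adj, significant = adj <= q)
}

#' ROI-level univariate lesion-symptom mapping
#'
#' For each candidate region, fits a simple linear regression of the
#' behavioural score on that region's damage fraction and tests the slope
#' one-tailed in the negative direction (the working assumption is that
#' lesions produce worse performance). Regions lesioned in fewer than
#' `min_affected` subjects are excluded before testing; Benjamini-Hochberg
#' FDR is applied across the tested regions only.
#'
#' @param data Subjects tibble containing `subject_id` and the column named by
#'   `measure`; rows with a missing score are dropped (complete case).
#' @param damage Damage matrix tibble (see [validate_damage()]).
#' @param measure Name of the behavioural score column in `data`.
#' @param regions Candidate region ids (character). Default: all damage
#'   columns. Restricting to left-hemisphere regions is the usual choice when
#'   every lesion is left-hemispheric.
#' @param min_affected Minimum number of subjects with nonzero damage for a
#'   region to be tested (default 10).
#' @param q FDR level (default 0.05).
#' @return An object of class `lsm_result`: use [tidy()] for the per-region
#'   table (`region`, `n_affected`, `slope`, `t`, `df`, `p`, `q_value`,
#'   `significant`, `excluded`, `reason`), [glance()] for a one-row summary,
#'   and `$significant_regions` for the flagged set.
#' @examples
#' cohort <- simulate_cohort(n = 30, seed = 7)
#' res <- roi_lsm(cohort$subjects, cohort$damage, "wab_aq",
#'                regions = left_regions(cohort$atlas))
#' tidy(res)
#' @export
roi_lsm <- function(data, damage, measure, regions = NULL,
                    min_affected = 10, q = 0.05) {
  damage <- validate_damage(damage)
  if (!measure %in% names(data)) {
    rlang::abort(paste0("measure column not found in data: ", measure))
  }
  merged <- dplyr::inner_join(
    dplyr::select(data, "subject_id", dplyr::all_of(measure)),
    damage, by = "subject_id"
  )
  merged <- merged[!is.na(merged[[measure]]), , drop = FALSE]
  y <- merged[[measure]]
  if (nrow(merged) < 3) rlang::abort("too few subjects for LSM")
  if (stats::sd(y) == 0) rlang::abort("behaviour vector is constant")
  candidates <- regions %||% setdiff(names(damage), "subject_id")
  candidates <- as.character(candidates)
  absent <- setdiff(candidates, names(merged))
  if (length(absent) > 0) {
    rlang::abort(paste0("candidate regions missing from damage matrix: ",
                        paste(absent, collapse = ", ")))
  }

  rows <- purrr::map(candidates, function(r) {
    d <- merged[[r]]
    n_aff <- sum(d > 0)
    if (n_aff < min_affected) {
      return(tibble::tibble(region = r, n_affected = n_aff,
                            slope = NA_real_, t = NA_real_, df = NA_integer_,
                            p = NA_real_, excluded = TRUE,
                            reason = sprintf("affected in %d < %d subjects",
                                             n_aff, min_affected)))
    }
    if (stats::sd(d) == 0) {
      return(tibble::tibble(region = r, n_affected = n_aff,
                            slope = NA_real_, t = NA_real_, df = NA_integer_,
                            p = NA_real_, excluded = TRUE,
                            reason = "constant damage fraction"))
    }
    fit <- stats::lm(y ~ d)
    cf <- summary(fit)$coefficients
    tval <- cf["d", "t value"]
    df <- fit$df.residual
    tibble::tibble(region = r, n_affected = n_aff,
                   slope = unname(stats::coef(fit)["d"]),
                   t = unname(tval), df = as.integer(df),
                   p = stats::pt(tval, df), # one-tailed, H1: slope < 0
                   excluded = FALSE, reason = NA_character_)
  })
  tab <- dplyr::bind_rows(rows)
  tested <- !tab$excluded
  if (!any(tested)) rlang::abort("all candidate regions were excluded")
  corr <- fdr_bh(tab$p[tested], q = q)
  tab$q_value <- NA_real_
  tab$significant <- FALSE
  tab$q_value[tested] <- corr$q_value
  tab$significant[tested] <- corr$significant
  tab <- dplyr::relocate(tab, "q_value", "significant", .after = "p")

  structure(
    list(table = tab, measure = measure, q_level = q,
         min_affected = min_affected, n_subjects = nrow(merged),
         significant_regions = tab$region[tab$significant],
         excluded_regions = tab$region[tab$excluded]),
    class = "lsm_result"
  )
}

#' @export
print.lsm_result <- function(x, ...) {
  cat(sprintf("ROI lesion-symptom mapping for %s (n = %d)\n",
              x$measure, x$n_subjects))
  cat(sprintf("  %d tested, %d excluded, %d significant at FDR q <= %g\n",
              sum(!x$table$excluded), length(x$excluded_regions),
              length(x$significant_regions), x$q_level))
  if (length(x$significant_regions) > 0) {
    cat("  significant:", paste(x$significant_regions, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.lsm_result <- function(x, ...) x$table

#' @exportS3Method generics::glance
glance.lsm_result <- function(x, ...) {
  tibble::tibble(
    measure = x$measure, n_subjects = x$n_subjects,
    n_tested = sum(!x$table$excluded),
    n_excluded = length(x$excluded_regions),
    n_significant = length(x$significant_regions),
    q_level = x$q_level, min_affected = x$min_affected
  )
}

#' Per-subject mean damage over the LSM-significant regions
#'
#' The "key damage" covariate: for each subject, the arithmetic mean of the
#' damage fractions over the regions flagged significant for a behavioural
#' measure. When no region is significant the covariate is undefined (all
#' `NA` with attribute `defined = FALSE`) and downstream covariate models drop
#' it, mirroring the behaviour of measures for which lesion mapping finds
#' nothing.
#'
#' @param damage Damage matrix tibble.
#' @param regions Character vector of significant region ids (possibly empty),
#'   e.g. `lsm$significant_regions`.
#' @return Tibble `subject_id`, `key_damage` with attribute `defined`.
#' @export
key_damage <- function(damage, regions) {
  damage <- validate_damage(damage)
  regions <- as.character(regions)
  if (length(regions) == 0) {
    out <- tibble::tibble(subject_id = damage$subject_id, key_damage = NA_real_)
    attr(out, "defined") <- FALSE
    return(out)
  }
  absent <- setdiff(regions, names(damage))
  if (length(absent) > 0) {
    rlang::abort(paste0("region(s) not present in damage matrix: ",
                        paste(absent, collapse = ", ")))
  }
  vals <- as.matrix(damage[regions])
  out <- tibble::tibble(subject_id = damage$subject_id,
                        key_damage = rowMeans(vals))
  attr(out, "defined") <- TRUE
  out
}

#' Left-hemisphere region ids of an atlas
#'
#' Convenience accessor for the usual LSM candidate set when all lesions are
#' left-hemispheric.
#'
#' @param atlas ROI atlas table.
#' @return Character vector of region ids with `hemisphere == "L"`.
#' @export
left_regions <- function(atlas) {
  atlas <- validate_atlas(atlas)
  as.character(atlas$region_id[atlas$hemisphere == "L"])
}
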