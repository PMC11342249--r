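# Synthetic lesion-cohort generator. Everything is deterministic per seed:
# seeded entry points wrap their body in withr::with_seed(); seed = NULL draws
# from the current RNG stream (used internally so one cohort seed drives all
# stages).

with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Simulate a two-hemisphere ROI atlas
#'
#' Centroids are sampled uniformly in a left-hemisphere box on an MNI-like mm
#' scale (x in \[-70, -10\], y in \[-90, 60\], z in \[-40, 70\], total extent
#' about 140 mm) and mirrored into the right hemisphere by flipping the sign
#' of x; volumes are log-normal (median about 6 cm^3) and mirror-symmetric.
#'
#' @param n_regions_per_hemisphere Number of regions per hemisphere (>= 4 so
#'   that quartile banding is defined on either hemisphere alone).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return An ROI atlas tibble (see [validate_atlas()]); left regions have
#'   ids `1..n`, their mirrors `n+1..2n`.
#' @export
simulate_atlas <- function(n_regions_per_hemisphere = 10, seed = NULL) {
  n <- n_regions_per_hemisphere
  if (n < 4) rlang::abort("need at least 4 regions per hemisphere")
  with_seed_maybe(seed, {
    left <- tibble::tibble(
      region_id = seq_len(n),
      name = sprintf("L_region_%02d", seq_len(n)),
      hemisphere = "L",
      centroid_x = stats::runif(n, -70, -10),
      centroid_y = stats::runif(n, -90, 60),
      centroid_z = stats::runif(n, -40, 70),
      volume_mm3 = stats::rlnorm(n, meanlog = log(6000), sdlog = 0.5)
    )
    right <- left |>
      dplyr::mutate(region_id = .data$region_id + n,
                    name = sub("^L_", "R_", .data$name),
                    hemisphere = "R",
                    centroid_x = -.data$centroid_x)
    validate_atlas(dplyr::bind_rows(left, right))
  })
}

#' Simulate contiguous left-hemisphere lesions
#'
#' Each subject receives a lesion seeded at a random left-hemisphere region;
#' damage to every left region decays exponentially with centroid distance
#' from the seed, scaled by a subject-specific severity drawn from a Beta
#' distribution. Fractions below 0.01 are floored to zero (regions effectively
#' spared), and right-hemisphere damage is identically zero. This yields the
#' spatially correlated damage columns that real lesion anatomy produces.
#'
#' Lesion seeds are drawn preferentially near the centroid of the left
#' hemisphere (mimicking the concentration of middle-cerebral-artery strokes
#' in peri-Sylvian territory), so a core set of regions is damaged often and
#' heavily while peripheral regions are spared in most subjects.
#'
#' @param atlas ROI atlas.
#' @param n Number of subjects.
#' @param extent_mm Spatial decay length of damage around the seed (default
#'   45 mm).
#' @param severity_shape Beta shape parameters `c(a, b)` of peak damage
#'   (default `c(1.2, 0.9)`, mean 0.57 with wide spread, so some subjects
#'   have near-total core damage and others almost none).
#' @param focality_mm Length scale of the seed-selection weighting around the
#'   hemisphere centre (default 25 mm; smaller = more stereotyped lesions).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return List: `damage` (tibble `subject_id` + one column per region id),
#'   `lesion_volume_cm3` (numeric, damage-weighted atlas volume) and
#'   `seed_region` (per subject).
#' @export
simulate_lesions <- function(atlas, n, extent_mm = 45,
                             severity_shape = c(1.2, 0.9), focality_mm = 25,
                             seed = NULL) {
  atlas <- validate_atlas(atlas)
  with_seed_maybe(seed, {
    left_ids <- atlas$region_id[atlas$hemisphere == "L"]
    cent <- as.matrix(atlas[, c("centroid_x", "centroid_y", "centroid_z")])
    rownames(cent) <- as.character(atlas$region_id)
    d <- as.matrix(stats::dist(cent))
    left_cent <- cent[as.character(left_ids), , drop = FALSE]
    centre <- colMeans(left_cent)
    d_centre <- sqrt(rowSums(sweep(left_cent, 2, centre)^2))
    seeds <- sample(left_ids, n, replace = TRUE,
                    prob = exp(-d_centre / focality_mm))
    severity <- stats::rbeta(n, severity_shape[1], severity_shape[2])
    dmg <- matrix(0, n, nrow(atlas),
                  dimnames = list(NULL, as.character(atlas$region_id)))
    left_chr <- as.character(left_ids)
    for (s in seq_len(n)) {
      frac <- severity[s] * exp(-d[as.character(seeds[s]), left_chr] / extent_mm)
      frac[frac < 0.01] <- 0
      dmg[s, left_chr] <- pmin(frac, 1)
    }
    lesion_volume <- as.numeric(dmg %*% atlas$volume_mm3) / 1000
    list(
      damage = dplyr::bind_cols(
        tibble::tibble(subject_id = sprintf("sub%03d", seq_len(n))),
        tibble::as_tibble(dmg)
      ),
      lesion_volume_cm3 = lesion_volume,
      seed_region = seeds
    )
  })
}

#' Simulate a raw streamline-count matrix
#'
#' The expected count for a region pair decays exponentially with
#' inter-centroid distance and is attenuated multiplicatively by the damage
#' fraction of either endpoint; pairs beyond the atlas's Q3 distance (the
#' long band) receive an extra attenuation factor, emulating the heightened
#' vulnerability of long-range fibres. Counts are drawn independently for the
#' two tracking directions (asymmetric noise), by default from an
#' overdispersed negative binomial.
#'
#' @param atlas ROI atlas.
#' @param damage Named damage-fraction vector over the atlas's region ids
#'   (default: no damage).
#' @param decay_mm Connectivity decay length in mm (default 40).
#' @param base_count Expected streamline count at distance 0 (default 3000).
#' @param long_attenuation Multiplier on expected counts of long-band pairs
#'   (1 = none; smaller = fewer long-range fibres).
#' @param dispersion Negative-binomial size parameter (smaller = noisier;
#'   default 8).
#' @param noise_model `"nbinom"` (default), `"poisson"`, or `"none"`
#'   (deterministic expected counts, useful for tests).
#' @param subject_id Subject label attached to the matrix.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A `connectome` at stage `raw`.
#' @export
simulate_connectome <- function(atlas, damage = NULL, decay_mm = 40,
                                base_count = 3000, long_attenuation = 1,
                                dispersion = 8,
                                noise_model = c("nbinom", "poisson", "none"),
                                subject_id = NA_character_, seed = NULL) {
  noise_model <- match.arg(noise_model)
  atlas <- validate_atlas(atlas)
  if (decay_mm <= 0) rlang::abort("decay_mm must be positive")
  ids <- as.character(atlas$region_id)
  if (is.null(damage)) damage <- stats::setNames(rep(0, nrow(atlas)), ids)
  if (!all(ids %in% names(damage))) {
    rlang::abort("damage vector must be named by atlas region ids")
  }
  damage <- damage[ids]
  with_seed_maybe(seed, {
    cent <- as.matrix(atlas[, c("centroid_x", "centroid_y", "centroid_z")])
    d <- as.matrix(stats::dist(cent))
    q3 <- stats::quantile(d[upper.tri(d)], 0.75, names = FALSE, type = 7)
    lam <- base_count * exp(-d / decay_mm) *
      outer(1 - damage, 1 - damage)
    lam[d > q3] <- lam[d > q3] * long_attenuation
    diag(lam) <- 0
    n <- nrow(lam)
    raw <- switch(noise_model,
      none = lam,
      poisson = matrix(stats::rpois(n * n, lam), n, n),
      nbinom = matrix(stats::rnbinom(n * n, mu = lam, size = dispersion), n, n)
    )
    diag(raw) <- 0
    dimnames(raw) <- list(ids, ids)
    as_connectome(raw, stage = "raw", subject_id = subject_id)
  })
}

#' Simulate a behavioural score from the generative linear model
#'
#' `score = base + b_age (age - 60) + b_ypo (ypo - 4) + b_lv (lv - 60) +
#' b_key (key - 0.3) + b_ratio (ratio - mean(ratio)) + N(0, noise_sd)`,
#' clipped to `range`. Covariates are centred at fixed typical values so the
#' base is the score of a typical subject.
#'
#' @param subjects Tibble with `age`, `years_post_stroke`, `lesion_volume`.
#' @param ratio Per-subject long:short fibre ratio.
#' @param key_dmg Per-subject true key-region damage (mean damage over the
#'   planted critical regions); ignored when `beta[["key"]]` is 0.
#' @param base Intercept (typical-subject score).
#' @param beta Named vector with elements `age`, `ypo`, `lv`, `key`, `ratio`.
#' @param noise_sd Gaussian noise SD.
#' @param range Length-2 clipping range of the score scale.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return Numeric score vector.
#' @export
simulate_behaviour <- function(subjects, ratio, key_dmg, base, beta, noise_sd,
                               range = c(0, 100), seed = NULL) {
  stopifnot(all(c("age", "ypo", "lv", "key", "ratio") %in% names(beta)))
  with_seed_maybe(seed, {
    score <- base +
      beta[["age"]] * (subjects$age - 60) +
      beta[["ypo"]] * (subjects$years_post_stroke - 4) +
      beta[["lv"]] * (subjects$lesion_volume - 60) +
      beta[["key"]] * (key_dmg - 0.3) +
      beta[["ratio"]] * (ratio - mean(ratio)) +
      stats::rnorm(nrow(subjects), 0, noise_sd)
    unname(pmin(pmax(score, range[1]), range[2]))
  })
}

# beta on the ratio that plants a given partial correlation r between the
# score residual (given the covariate design) and the fibre ratio:
# r = b*sd(e_x) / sqrt(b^2 sd(e_x)^2 + noise^2), solved for b, with e_x the
# ratio residualized on the covariates.
beta_for_partial_r <- function(r, noise_sd, sd_ratio_resid) {
  if (r == 0) return(0)
  if (abs(r) >= 1) rlang::abort("target partial correlation must be in (-1, 1)")
  r / sqrt(1 - r^2) * noise_sd / sd_ratio_resid
}

default_measure_params <- function() {
  list(
    wab_aq = list(base = 62, beta = c(age = -0.45, ypo = 0.7, lv = -0.10, key = -28),
                  noise_sd = 11, range = c(0, 100)),
    pnt = list(base = 66, beta = c(age = -0.50, ypo = 0.9, lv = -0.11, key = -30),
               noise_sd = 13, range = c(0, 100)),
    pptt = list(base = 45, beta = c(age = 0, ypo = 0.12, lv = -0.025, key = 0),
                noise_sd = 3.2, range = c(0, 52)),
    matrix_reasoning = list(base = 15, beta = c(age = -0.09, ypo = 0.10, lv = -0.012, key = 0),
                            noise_sd = 3.5, range = c(0, 26))
  )
}

#' Simulate a full stroke cohort with known ground truth
#'
#' Generates an atlas, demographics, contiguous left-hemisphere lesions, raw
#' connectomes whose long-range connections are preferentially attenuated by
#' lesion load, fibre-length profiles, and four behavioural scores (an
#' aphasia-quotient-like 0-100 scale, a naming score, a semantic-processing
#' score and a non-verbal reasoning score) generated as linear functions of
#' age, years post stroke, lesion volume, damage to planted critical regions,
#' and the measured long:short fibre ratio, plus Gaussian noise.
#'
#' Defaults mirror the cohort structure of a typical chronic left-hemisphere
#' stroke sample: n = 87; age about N(60.5, 11.2) truncated to 21-80; years
#' post stroke 1 + Gamma with mean ~3.9; aetiology ischaemic:haemorrhagic:other
#' in 57:23:7 proportions; sex 52:35. Key-region effects are planted for the
#' two language measures only, so ROI lesion mapping typically finds regions
#' for those and none for the other two.
#'
#' The planted ratio effect is specified as a target partial correlation per
#' measure (`target_r`): the corresponding raw coefficient is derived from the
#' noise SD and the SD of the ratio residualized on the covariate design, so
#' the planted effect size is on the scale the association stage estimates.
#'
#' @param n Cohort size (default 87).
#' @param n_regions_per_hemisphere Atlas size per hemisphere (default 10).
#' @param seed Integer seed driving every stage; `NULL` uses the current
#'   stream.
#' @param target_r Named vector of planted partial correlations between each
#'   score's covariate residual and the fibre ratio.
#' @param measure_params Per-measure base/beta/noise/range list; see
#'   `fibreprop:::default_measure_params()` for the shape.
#' @param lesion_coupling Strength of lesion-load attenuation of long-range
#'   expected counts (0 = fibre ratio independent of lesion anatomy).
#' @param atten_sd SD of the subject-level log attenuation noise (gives the
#'   ratio its lesion-independent variability).
#' @param n_critical Number of planted critical ("key") left regions.
#' @param percentile Threshold percentile used when profiling (default 0.20).
#' @param decay_mm,base_count,dispersion Passed to [simulate_connectome()].
#' @param extent_mm Lesion spatial extent, passed to [simulate_lesions()].
#' @return A list of class `synthetic_cohort`: `atlas`, `subjects` (tibble
#'   with demographics, `lesion_volume` in cm^3 and the four scores),
#'   `damage`, `connectomes` (named list of raw matrices), `profiles` (from
#'   [fibre_profiles()]) and `truth` (all generative parameters, realized
#'   betas, planted critical regions, per-subject true key damage, seed).
#' @examples
#' cohort <- simulate_cohort(n = 12, n_regions_per_hemisphere = 5, seed = 1)
#' cohort$profiles
#' @export
simulate_cohort <- function(n = 87, n_regions_per_hemisphere = 10, seed = NULL,
                            target_r = c(wab_aq = 0.33, pnt = 0.25,
                                         pptt = 0.30, matrix_reasoning = 0.40),
                            measure_params = default_measure_params(),
                            lesion_coupling = 6, atten_sd = 0.35,
                            n_critical = 3, percentile = 0.20,
                            decay_mm = 40, base_count = 3000, dispersion = 8,
                            extent_mm = 45) {
  with_seed_maybe(seed, {
    atlas <- simulate_atlas(n_regions_per_hemisphere)
    subject_id <- sprintf("sub%03d", seq_len(n))

    age <- pmin(pmax(stats::rnorm(n, 60.52, 11.24), 21), 80)
    ypo <- 1 + stats::rgamma(n, shape = 0.52, scale = 5.52)
    sex <- sample(c("male", "female"), n, replace = TRUE, prob = c(52, 35))
    aetiology <- sample(c("ischaemic", "haemorrhagic", "other"), n,
                        replace = TRUE, prob = c(57, 23, 7))

    les <- simulate_lesions(atlas, n, extent_mm = extent_mm)
    dmg_mat <- as.matrix(les$damage[setdiff(names(les$damage), "subject_id")])
    rownames(dmg_mat) <- subject_id
    les$damage$subject_id <- subject_id

    left <- left_regions(atlas)
    critical <- left[order(colMeans(dmg_mat[, left, drop = FALSE]),
                           decreasing = TRUE)][seq_len(n_critical)]
    key_true <- rowMeans(dmg_mat[, critical, drop = FALSE])

    lesion_load <- rowMeans(dmg_mat[, left, drop = FALSE])
    atten <- exp(-lesion_coupling * lesion_load +
                   stats::rnorm(n, 0, atten_sd))

    connectomes <- lapply(seq_len(n), function(s) {
      simulate_connectome(atlas, damage = dmg_mat[s, ],
                          decay_mm = decay_mm, base_count = base_count,
                          long_attenuation = atten[s], dispersion = dispersion,
                          subject_id = subject_id[s])
    })
    names(connectomes) <- subject_id
    profiles <- fibre_profiles(connectomes, atlas, percentile = percentile)

    subjects <- tibble::tibble(
      subject_id = subject_id, age = age, years_post_stroke = ypo,
      sex = sex, aetiology = aetiology,
      lesion_volume = les$lesion_volume_cm3
    )

    ratio <- profiles$long_short_ratio
    design <- cbind(1, age, ypo, subjects$lesion_volume, key_true)
    e_x <- stats::lm.fit(design, ratio)$residuals
    sd_ex <- stats::sd(e_x)

    realized_beta <- list()
    for (m in names(measure_params)) {
      p <- measure_params[[m]]
      b_ratio <- beta_for_partial_r(target_r[[m]], p$noise_sd, sd_ex)
      beta <- c(p$beta, ratio = b_ratio)
      subjects[[m]] <- simulate_behaviour(subjects, ratio, key_true,
                                          base = p$base, beta = beta,
                                          noise_sd = p$noise_sd,
                                          range = p$range)
      realized_beta[[m]] <- beta
    }

    structure(
      list(atlas = atlas, subjects = subjects, damage = les$damage,
           connectomes = connectomes, profiles = profiles,
           truth = list(seed = seed, target_r = target_r,
                        beta = realized_beta,
                        noise_sd = purrr::map_dbl(measure_params, "noise_sd"),
                        base = purrr::map_dbl(measure_params, "base"),
                        critical_regions = critical,
                        key_damage_true = tibble::tibble(
                          subject_id = subject_id, key_damage = key_true),
                        lesion_coupling = lesion_coupling, atten_sd = atten_sd,
                        long_attenuation = atten,
                        decay_mm = decay_mm, base_count = base_count,
                        dispersion = dispersion, extent_mm = extent_mm,
                        percentile = percentile,
                        seed_region = les$seed_region)),
      class = "synthetic_cohort"
    )
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects, %d regions, seed %s\n",
              nrow(x$subjects), nrow(x$atlas),
              x$truth$seed %||% "<stream>"))
  cat("  planted critical regions:",
      paste(x$truth$critical_regions, collapse = ", "), "\n")
  invisible(x)
}
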