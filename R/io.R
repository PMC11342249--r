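# Readers/writers for the plain-text interchange formats: TSV connectome
# matrices (square, region ids as header row and first column, one file per
# subject), CSV atlas/subject/damage tables, YAML run configuration.

#' Read a raw connectome matrix from TSV
#'
#' Expects a square tab-separated matrix whose header row and first column
#' both carry the region ids, in the same order. Each validation failure
#' (ragged rows, label mismatch, negative or non-finite entries) produces a
#' distinct error naming the offending location.
#'
#' @param path File path.
#' @param subject_id Subject label; defaults to the file name without
#'   extension.
#' @return A `connectome` at stage `raw`.
#' @export
read_connectome_tsv <- function(path, subject_id = NULL) {
  subject_id <- subject_id %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1) {
    rlang::abort(sprintf("ragged TSV: row %d has %d fields, expected %d",
                         which(widths != widths[1])[1],
                         widths[which(widths != widths[1])[1]], widths[1]))
  }
  header <- fields[[1]][-1]
  body <- fields[-1]
  row_labels <- purrr::map_chr(body, 1)
  if (length(body) != length(header)) {
    rlang::abort(sprintf("matrix is not square: %d rows vs %d columns",
                         length(body), length(header)))
  }
  if (!identical(row_labels, header)) {
    bad <- which(row_labels != header)[1]
    rlang::abort(sprintf("row/column label mismatch at position %d: '%s' vs '%s'",
                         bad, row_labels[bad], header[bad]))
  }
  m <- do.call(rbind, purrr::map(body, ~ suppressWarnings(as.numeric(.x[-1]))))
  dimnames(m) <- list(header, header)
  if (any(is.na(m) | !is.finite(m))) {
    idx <- which(is.na(m) | !is.finite(m), arr.ind = TRUE)[1, ]
    rlang::abort(sprintf("non-numeric or non-finite entry at row '%s', column '%s'",
                         header[idx[1]], header[idx[2]]))
  }
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    rlang::abort(sprintf("negative streamline count at row '%s', column '%s'",
                         header[idx[1]], header[idx[2]]))
  }
  as_connectome(m, stage = "raw", subject_id = subject_id)
}

#' Write a connectome matrix to TSV
#'
#' @param conn A `connectome` (any stage) or named square matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_connectome_tsv <- function(conn, path) {
  m <- unclass(conn)
  lines <- c(paste(c("", colnames(m)), collapse = "\t"),
             purrr::map_chr(seq_len(nrow(m)), function(i) {
               paste(c(rownames(m)[i], format_num(m[i, ])), collapse = "\t")
             }))
  writeLines(lines, path)
  invisible(path)
}

# 12 significant digits: the documented precision of all numeric outputs
format_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 12, format = "g"))
}

#' Read an ROI atlas from CSV
#'
#' Columns: `region_id,name,hemisphere,centroid_x,centroid_y,centroid_z,volume_mm3`.
#'
#' @param path File path.
#' @return Validated atlas tibble.
#' @export
read_atlas_csv <- function(path) {
  validate_atlas(readr::read_csv(path, show_col_types = FALSE))
}

#' Read the subject table from CSV
#'
#' @param path File path. Must contain `subject_id`; demographic, lesion and
#'   behavioural columns are passed through unchanged.
#' @return Tibble.
#' @export
read_subjects_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  if (!"subject_id" %in% names(out)) {
    rlang::abort("subjects file must contain a subject_id column")
  }
  out
}

#' Read a subjects x regions damage matrix from CSV
#'
#' @param path File path (`subject_id` column plus one column per region id).
#' @param atlas Optional atlas for region validation.
#' @return Validated damage tibble.
#' @export
read_damage_csv <- function(path, atlas = NULL) {
  validate_damage(readr::read_csv(path, show_col_types = FALSE), atlas = atlas)
}

#' Per-region damage fractions from NIfTI lesion mask and label atlas
#'
#' For each labelled region, the fraction of its voxels that fall inside the
#' binary lesion mask. Mask and atlas must share grid dimensions and affine.
#'
#' @param lesion_path Path to a binary (0/1) NIfTI lesion mask.
#' @param atlas_path Path to an integer-labelled NIfTI atlas on the same grid
#'   (0 = background).
#' @return Tibble `region_id`, `n_voxels`, `damage` with fractions in
#'   `[0, 1]`.
#' @export
damage_from_nifti <- function(lesion_path, atlas_path) {
  mask <- RNifti::readNifti(lesion_path)
  labels <- RNifti::readNifti(atlas_path)
  if (!identical(dim(mask), dim(labels))) {
    rlang::abort("lesion mask and label atlas have different grid dimensions")
  }
  if (max(abs(RNifti::xform(mask) - RNifti::xform(labels))) > 1e-4) {
    rlang::abort("lesion mask and label atlas have different affines")
  }
  mv <- as.vector(mask)
  if (!all(mv %in% c(0, 1))) {
    rlang::abort("lesion mask must be binary (0/1)")
  }
  lv <- as.vector(labels)
  ids <- sort(unique(lv[lv != 0]))
  tibble::tibble(
    region_id = ids,
    n_voxels = purrr::map_int(ids, ~ sum(lv == .x)),
    damage = purrr::map_dbl(ids, ~ mean(mv[lv == .x]))
  )
}

#' Write a synthetic cohort to the interchange formats
#'
#' Writes `atlas.csv`, `subjects.csv`, `damage.csv`, one raw connectome TSV
#' per subject under `connectomes/`, and `ground_truth.yaml` into `dir`.
#'
#' @param cohort A `synthetic_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(file.path(dir, "connectomes"), recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$atlas, file.path(dir, "atlas.csv"))
  readr::write_csv(cohort$subjects, file.path(dir, "subjects.csv"))
  readr::write_csv(cohort$damage, file.path(dir, "damage.csv"))
  purrr::iwalk(cohort$connectomes, function(m, sid) {
    write_connectome_tsv(m, file.path(dir, "connectomes", paste0(sid, ".tsv")))
  })
  truth <- cohort$truth
  truth$key_damage_true <- as.list(stats::setNames(
    truth$key_damage_true$key_damage, truth$key_damage_true$subject_id))
  truth$beta <- purrr::map(truth$beta, as.list)
  yaml::write_yaml(truth, file.path(dir, "ground_truth.yaml"))
  invisible(dir)
}

#' Assemble a run configuration
#'
#' Validated bundle of paths, analysis parameters and mode switches consumed
#' by [run_pipeline()]. `read_run_config()` loads the same structure from a
#' YAML file (unknown keys are rejected).
#'
#' @param cohort_dir Directory holding `atlas.csv`, `subjects.csv`,
#'   `damage.csv` and `connectomes/*.tsv` (e.g. from [write_cohort()]).
#' @param out_dir Output directory for result tables.
#' @param measures Behavioural score columns to analyse.
#' @param percentile Weight-threshold percentile (default 0.20).
#' @param threshold_method `"nearest_rank"` or `"interpolate"`.
#' @param ratio_mode `"edges"` or `"weights"`.
#' @param association_mode `"literal"` or `"partial"`.
#' @param min_affected LSM minimum-lesioned-subjects cutoff (default 10).
#' @param q_lsm,q_assoc FDR levels for lesion mapping and the association
#'   family (default 0.05 each).
#' @param lsm_candidates `"left"` (default) or `"all"` atlas regions.
#' @param seed Integer seed recorded with the outputs.
#' @return A `run_config` list.
#' @export
run_config <- function(cohort_dir, out_dir,
                       measures = c("wab_aq", "pnt", "pptt", "matrix_reasoning"),
                       percentile = 0.20,
                       threshold_method = "nearest_rank",
                       ratio_mode = "edges",
                       association_mode = "literal",
                       min_affected = 10, q_lsm = 0.05, q_assoc = 0.05,
                       lsm_candidates = "left", seed = 1L) {
  cfg <- list(cohort_dir = cohort_dir, out_dir = out_dir, measures = measures,
              percentile = percentile, threshold_method = threshold_method,
              ratio_mode = ratio_mode, association_mode = association_mode,
              min_affected = min_affected, q_lsm = q_lsm, q_assoc = q_assoc,
              lsm_candidates = lsm_candidates, seed = as.integer(seed))
  validate_config(cfg)
}

validate_config <- function(cfg) {
  allowed <- names(formals(run_config))
  extra <- setdiff(names(cfg), allowed)
  if (length(extra) > 0) {
    rlang::abort(paste0("unknown config key(s): ", paste(extra, collapse = ", ")))
  }
  defaults <- formals(run_config)
  for (k in setdiff(allowed, names(cfg))) {
    if (k %in% c("cohort_dir", "out_dir")) {
      rlang::abort(paste0("config is missing required key: ", k))
    }
    cfg[[k]] <- eval(defaults[[k]])
  }
  stopifnot(cfg$percentile >= 0, cfg$percentile < 1,
            cfg$q_lsm > 0, cfg$q_lsm < 1, cfg$q_assoc > 0, cfg$q_assoc < 1,
            cfg$min_affected >= 1)
  match.arg(cfg$threshold_method, c("nearest_rank", "interpolate"))
  match.arg(cfg$ratio_mode, c("edges", "weights"))
  match.arg(cfg$association_mode, c("literal", "partial"))
  match.arg(cfg$lsm_candidates, c("left", "all"))
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in analysis order -- fibre-length profiling, the
#' aetiology ANOVA, per-measure ROI lesion-symptom mapping and key-damage
#' derivation, covariate regression, and the residual-ratio association with
#' FDR -- and writes `profiles.csv`, `anova.csv`, `lsm_<measure>.csv`,
#' `modelfit.csv`, `coefficients.csv`, `associations.csv`, the resolved
#' `config.yaml` and a `log.txt` audit trail into the output directory.
#' All numeric CSV output is formatted at 12 significant digits, so reruns
#' with the same config and seed are byte-identical.
#'
#' @param config A `run_config` (or a path to a YAML config file).
#' @return Invisibly, a list with `profiles`, `anova`, `lsm` (per measure),
#'   `fits` (per measure), `associations` and the resolved `config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    rlang::inform(msg)
  }

  atlas <- read_atlas_csv(file.path(config$cohort_dir, "atlas.csv"))
  subjects <- read_subjects_csv(file.path(config$cohort_dir, "subjects.csv"))
  damage <- read_damage_csv(file.path(config$cohort_dir, "damage.csv"), atlas = atlas)
  conn_files <- sort(list.files(file.path(config$cohort_dir, "connectomes"),
                                pattern = "\\.tsv$", full.names = TRUE))
  if (length(conn_files) == 0) rlang::abort("no connectome TSV files found")
  connectomes <- purrr::map(conn_files, read_connectome_tsv)
  names(connectomes) <- purrr::map_chr(connectomes, attr, "subject_id")
  say("stage inputs: %d subjects, %d regions, %d connectomes",
      nrow(subjects), nrow(atlas), length(connectomes))

  # stage 1: connectome metrics
  profiles <- fibre_profiles(connectomes, atlas,
                             percentile = config$percentile,
                             method = config$threshold_method,
                             mode = config$ratio_mode)
  say("stage connectome_metrics: band cutoffs q1 = %.3f mm, q3 = %.3f mm",
      profiles$q1_cutoff[1], profiles$q3_cutoff[1])

  merged <- dplyr::inner_join(subjects, profiles, by = "subject_id")

  # stage 2: aetiology confound check
  anova_res <- aetiology_anova(merged)
  say("stage anova: F(%g, %g) = %.3f, p = %.3f",
      anova_res$df1, anova_res$df2, anova_res$statistic, anova_res$p_value)

  candidates <- if (config$lsm_candidates == "left") left_regions(atlas)
                else as.character(atlas$region_id)

  # stages 3-5 per measure: LSM -> key damage -> covariate model
  lsm_list <- list(); fits <- list()
  for (m in config$measures) {
    n_obs <- sum(!is.na(subjects[[m]]))
    if (n_obs < nrow(subjects)) {
      say("measure %s: %d subjects dropped (missing score)", m, nrow(subjects) - n_obs)
    }
    lsm_res <- roi_lsm(subjects, damage, m, regions = candidates,
                       min_affected = config$min_affected, q = config$q_lsm)
    lsm_list[[m]] <- lsm_res
    say("stage lsm (%s): %d tested, %d excluded, %d significant",
        m, sum(!lsm_res$table$excluded), length(lsm_res$excluded_regions),
        length(lsm_res$significant_regions))
    kd <- key_damage(damage, lsm_res$significant_regions)
    dat <- dplyr::left_join(merged, kd, by = "subject_id")
    fits[[m]] <- residualize(dat, m)
  }

  # stage 6: residual-ratio associations, FDR across the measure family
  assoc <- residual_association(fits, profiles,
                                mode = config$association_mode,
                                q = config$q_assoc)
  say("stage association: family of %d measures, %d significant after FDR",
      nrow(assoc), sum(assoc$significant))

  write_out <- function(df, file) {
    df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric), format_num))
    readr::write_csv(df, file.path(config$out_dir, file))
  }
  write_out(profiles, "profiles.csv")
  write_out(glance(anova_res), "anova.csv")
  for (m in config$measures) write_out(tidy(lsm_list[[m]]), paste0("lsm_", m, ".csv"))
  write_out(dplyr::bind_rows(purrr::map(fits, glance)), "modelfit.csv")
  write_out(dplyr::bind_rows(purrr::map(fits, function(f) {
    dplyr::mutate(tidy(f), measure = f$measure, .before = 1)
  })), "coefficients.csv")
  write_out(tibble::as_tibble(assoc), "associations.csv")
  yaml::write_yaml(unclass(config), file.path(config$out_dir, "config.yaml"))
  writeLines(log_lines, file.path(config$out_dir, "log.txt"))

  invisible(list(profiles = profiles, anova = anova_res, lsm = lsm_list,
                 fits = fits, associations = assoc, config = config))
}
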