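#' Construct a connectome matrix
#'
#' A connectome is a square, non-negative region x region weight matrix for a
#' single subject, carrying a processing `stage` flag (`raw`, `normalized` or
#' `thresholded`) and a `subject_id`. Raw matrices may be asymmetric (the two
#' tracking directions are separate); normalized and thresholded matrices are
#' symmetric with a zero diagonal.
#'
#' @param weights Numeric square matrix with identical row and column names
#'   giving the region ids.
#' @param stage Processing stage of `weights`.
#' @param subject_id Subject identifier.
#' @return A `connectome` object (a matrix with `stage` and `subject_id`
#'   attributes).
#' @export
as_connectome <- function(weights, stage = c("raw", "normalized", "thresholded"),
                          subject_id = NA_character_) {
  stage <- match.arg(stage)
  if (!is.matrix(weights) || !is.numeric(weights)) {
    rlang::abort("weights must be a numeric matrix")
  }
  if (nrow(weights) != ncol(weights)) {
    rlang::abort("weights must be square")
  }
  if (is.null(rownames(weights)) || is.null(colnames(weights))) {
    rlang::abort("weights must carry region ids as row and column names")
  }
  if (!identical(rownames(weights), colnames(weights))) {
    rlang::abort("row and column region ids differ")
  }
  if (any(!is.finite(weights))) {
    rlang::abort("weights contain non-finite values")
  }
  if (any(weights < 0)) {
    rlang::abort("weights must be non-negative")
  }
  if (stage != "raw") {
    if (any(abs(weights - t(weights)) > 1e-12)) {
      rlang::abort(paste0(stage, " connectome must be symmetric"))
    }
    if (any(diag(weights) != 0)) {
      rlang::abort(paste0(stage, " connectome must have a zero diagonal"))
    }
  }
  structure(weights, class = c("connectome", "matrix", "array"),
            stage = stage, subject_id = subject_id)
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> subject %s, stage %s, %d regions\n",
              attr(x, "subject_id"), attr(x, "stage"), nrow(x)))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))), drop = FALSE])
  invisible(x)
}

conn_stage <- function(x) attr(x, "stage")

#' Symmetrize and volume-normalize a raw streamline-count matrix
#'
#' Averages each pair of opposite-direction streamline counts (diffusion
#' tractography is undirected) and divides by the sum of the two connected
#' regions' volumes, removing the bias of larger regions receiving more
#' streamlines. Self-connections carry no pair meaning and are zeroed.
#'
#' @param raw A `connectome` at stage `raw` (or a plain named square matrix).
#' @param atlas ROI atlas supplying `volume_mm3` per region; region ids must
#'   match the matrix dimnames exactly.
#' @return A `connectome` at stage `normalized` with
#'   `w[i,j] = ((raw[i,j] + raw[j,i]) / 2) / (vol_i + vol_j)`.
#' @examples
#' atlas <- simulate_atlas(4, seed = 1)
#' raw <- simulate_connectome(atlas, seed = 1)
#' normalize_connectome(raw, atlas)
#' @export
normalize_connectome <- function(raw, atlas) {
  if (!inherits(raw, "connectome")) {
    raw <- as_connectome(raw, stage = "raw")
  }
  if (conn_stage(raw) != "raw") {
    rlang::abort("normalize_connectome() expects a raw-stage connectome")
  }
  atlas <- validate_atlas(atlas)
  ids <- as.character(atlas$region_id)
  if (!identical(rownames(raw), ids)) {
    if (setequal(rownames(raw), ids)) {
      raw_m <- unclass(raw)[ids, ids]
      raw <- as_connectome(raw_m, stage = "raw", subject_id = attr(raw, "subject_id"))
    } else {
      rlang::abort("connectome region ids do not match the atlas")
    }
  }
  m <- unclass(raw)
  sym <- (m + t(m)) / 2
  volsum <- outer(atlas$volume_mm3, atlas$volume_mm3, "+")
  w <- sym / volsum
  diag(w) <- 0
  as_connectome(w, stage = "normalized", subject_id = attr(raw, "subject_id"))
}

# nearest-rank percentile: ceil(p * n)-th order statistic
nearest_rank <- function(x, p) {
  s <- sort(x)
  k <- ceiling(p * length(s))
  if (k < 1) return(-Inf)
  s[k]
}

#' Zero out possibly spurious weak connections
#'
#' Computes a per-subject cutoff as the given percentile of the subject's
#' *nonzero* upper-triangle weights and sets every weight strictly below it to
#' zero. Structural zeros are excluded from the percentile population: a
#' sparse matrix would otherwise yield a cutoff of zero and the step would do
#' nothing. Weights equal to the cutoff survive ("lower than" is strict).
#'
#' @param conn A `connectome` at stage `normalized`.
#' @param percentile Fraction in `[0, 1)`; default 0.20 (the 20th percentile).
#' @param method `"nearest_rank"` (default): the `ceiling(p * n)`-th order
#'   statistic of the nonzero weights, exactly reproducible; or
#'   `"interpolate"`: linear-interpolation quantile ([stats::quantile()] type 7).
#' @return A `connectome` at stage `thresholded` with attribute `cutoff`.
#' @export
threshold_connectome <- function(conn, percentile = 0.20,
                                 method = c("nearest_rank", "interpolate")) {
  method <- match.arg(method)
  if (!inherits(conn, "connectome") || conn_stage(conn) != "normalized") {
    rlang::abort("threshold_connectome() expects a normalized-stage connectome")
  }
  if (percentile < 0 || percentile >= 1) {
    rlang::abort("percentile must be in [0, 1)")
  }
  m <- unclass(conn)
  upper <- m[upper.tri(m)]
  nz <- upper[upper > 0]
  if (length(nz) == 0) {
    rlang::abort("degenerate input: connectome has no nonzero weights to threshold")
  }
  cutoff <- if (percentile == 0) {
    0
  } else if (method == "nearest_rank") {
    nearest_rank(nz, percentile)
  } else {
    stats::quantile(nz, percentile, names = FALSE, type = 7)
  }
  m[m < cutoff] <- 0
  out <- as_connectome(m, stage = "thresholded", subject_id = attr(conn, "subject_id"))
  attr(out, "cutoff") <- cutoff
  out
}

#' Fibre-length profile of a thresholded connectome
#'
#' Counts the surviving (nonzero) upper-triangle connections in each distance
#' band and forms the ratio of long-range to short-range fibres, the
#' "proportion of long-range fibres". `mode = "edges"` (default) counts
#' connections; `mode = "weights"` sums their weights instead.
#'
#' @param conn A `connectome` at stage `thresholded`.
#' @param bands A `distance_bands` object from the same atlas.
#' @param mode Count surviving edges or sum surviving weights per band.
#' @return One-row tibble with `subject_id`, `n_short`, `n_medium`, `n_long`,
#'   `long_short_ratio` and the threshold `cutoff` used. With
#'   `mode = "weights"` the three band columns hold weight sums.
#' @export
fibre_profile <- function(conn, bands, mode = c("edges", "weights")) {
  mode <- match.arg(mode)
  if (!inherits(conn, "connectome") || conn_stage(conn) != "thresholded") {
    rlang::abort("fibre_profile() expects a thresholded-stage connectome")
  }
  ids <- as.character(attr(bands, "region_ids"))
  if (!setequal(rownames(conn), ids)) {
    rlang::abort("distance bands were built from a different atlas than this connectome")
  }
  m <- unclass(conn)[ids, ids]
  bm <- band_matrix(bands)
  ut <- upper.tri(m)
  w <- m[ut]
  lab <- bm[ut]
  surviving <- w > 0
  per_band <- function(band) {
    sel <- surviving & lab == band
    if (mode == "edges") sum(sel) else sum(w[sel])
  }
  n_short <- per_band("short")
  n_medium <- per_band("medium")
  n_long <- per_band("long")
  if (n_short == 0) {
    rlang::abort("undefined long:short ratio: no surviving short-range connections")
  }
  tibble::tibble(
    subject_id = attr(conn, "subject_id"),
    n_short = n_short, n_medium = n_medium, n_long = n_long,
    long_short_ratio = n_long / n_short,
    cutoff = attr(conn, "cutoff") %||% NA_real_
  )
}

#' Fibre-length profiles for a set of subjects
#'
#' Runs the full per-subject chain -- symmetrize + volume-normalize,
#' percentile threshold, band counting -- over a list of raw streamline-count
#' matrices and returns one row per subject.
#'
#' @param connectomes Named list of raw square matrices (names = subject ids),
#'   or of `connectome` objects at stage raw.
#' @param atlas ROI atlas matching the matrices.
#' @param percentile,method Passed to [threshold_connectome()].
#' @param mode Passed to [fibre_profile()].
#' @return Tibble with one row per subject: band counts, `long_short_ratio`,
#'   threshold `cutoff`, plus the atlas-level `q1_cutoff`/`q3_cutoff` (mm).
#' @examples
#' cohort <- simulate_cohort(n = 8, n_regions_per_hemisphere = 5, seed = 1)
#' fibre_profiles(cohort$connectomes, cohort$atlas)
#' @export
fibre_profiles <- function(connectomes, atlas, percentile = 0.20,
                           method = c("nearest_rank", "interpolate"),
                           mode = c("edges", "weights")) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  atlas <- validate_atlas(atlas)
  bands <- distance_bands(atlas)
  q <- band_cutoffs(bands)
  if (is.null(names(connectomes)) || anyDuplicated(names(connectomes))) {
    rlang::abort("connectomes must be a list uniquely named by subject id")
  }
  out <- purrr::imap(connectomes, function(m, sid) {
    conn <- if (inherits(m, "connectome")) m else as_connectome(m, "raw", subject_id = sid)
    attr(conn, "subject_id") <- sid
    conn |>
      normalize_connectome(atlas) |>
      threshold_connectome(percentile = percentile, method = method) |>
      fibre_profile(bands, mode = mode)
  })
  dplyr::bind_rows(out) |>
    dplyr::mutate(q1_cutoff = q[["q1"]], q3_cutoff = q[["q3"]])
}
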