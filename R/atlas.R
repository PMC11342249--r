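#' Validate an ROI atlas table
#'
#' An atlas is a tibble with one row per grey-matter region and columns
#' `region_id` (unique integer label), `name`, `hemisphere` (`"L"`, `"R"` or
#' `"midline"`), centroid coordinates `centroid_x/y/z` in mm (MNI-convention
#' axes: x negative on the left) and `volume_mm3` (strictly positive).
#' Centroids and volumes are fixed properties of the parcellation, so distance
#' quartile cutoffs derived from them are identical across subjects.
#'
#' @param atlas A data frame with the columns listed above.
#' @return The atlas as a tibble, invisibly validated (an error is thrown on
#'   any violated invariant).
#' @examples
#' validate_atlas(simulate_atlas(4, seed = 1))
#' @export
validate_atlas <- function(atlas) {
  required <- c("region_id", "name", "hemisphere",
                "centroid_x", "centroid_y", "centroid_z", "volume_mm3")
  missing <- setdiff(required, names(atlas))
  if (length(missing) > 0) {
    rlang::abort(paste0("atlas is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  atlas <- tibble::as_tibble(atlas)
  if (anyDuplicated(atlas$region_id)) {
    rlang::abort("atlas region_id values must be unique")
  }
  cent <- as.matrix(atlas[, c("centroid_x", "centroid_y", "centroid_z")])
  if (!all(is.finite(cent))) {
    rlang::abort("atlas centroids must be finite")
  }
  if (!all(is.finite(atlas$volume_mm3)) || any(atlas$volume_mm3 <= 0)) {
    rlang::abort("atlas volumes must be finite and strictly positive")
  }
  bad_hemi <- setdiff(unique(atlas$hemisphere), c("L", "R", "midline"))
  if (length(bad_hemi) > 0) {
    rlang::abort(paste0("unknown hemisphere label(s): ",
                        paste(bad_hemi, collapse = ", ")))
  }
  if (nrow(atlas) < 4) {
    rlang::abort("atlas must contain at least 4 regions (quartile banding)")
  }
  atlas
}

#' Distance-quartile bands over all region pairs
#'
#' Computes the Euclidean distance between region centroids for every
#' unordered pair in the atlas and classifies each pair as a `short`,
#' `medium` or `long` range connection by the quartiles of that distance
#' population: `short` when distance <= Q1, `long` when distance > Q3,
#' `medium` otherwise. Quartiles are linear-interpolation sample quantiles
#' ([stats::quantile()] type 7) over all pairs of the atlas, so cutoffs are an
#' atlas property shared by every subject.
#'
#' Degenerate atlases whose pair distances are all equal (e.g. duplicated
#' centroids) are permitted; every pair then falls in the short band and a
#' warning flags the degenerate banding.
#'
#' @param atlas An ROI atlas table (see [validate_atlas()]).
#' @return A tibble of class `distance_bands` with columns `region_a`,
#'   `region_b` (region ids, a < b in atlas order), `distance` (mm) and
#'   `band` (factor short/medium/long), carrying attributes `q1_cutoff` and
#'   `q3_cutoff` (mm) and `region_ids`.
#' @examples
#' atlas <- simulate_atlas(5, seed = 1)
#' bands <- distance_bands(atlas)
#' band_cutoffs(bands)
#' @export
distance_bands <- function(atlas) {
  atlas <- validate_atlas(atlas)
  cent <- as.matrix(atlas[, c("centroid_x", "centroid_y", "centroid_z")])
  rownames(cent) <- as.character(atlas$region_id)
  d <- as.matrix(stats::dist(cent))
  idx <- which(upper.tri(d), arr.ind = TRUE)
  pairs <- tibble::tibble(
    region_a = atlas$region_id[idx[, "row"]],
    region_b = atlas$region_id[idx[, "col"]],
    distance = d[idx]
  )
  q <- stats::quantile(pairs$distance, c(0.25, 0.75), names = FALSE, type = 7)
  if (diff(range(pairs$distance)) == 0) {
    rlang::warn("all pair distances are equal: degenerate banding, every pair is short-range")
  }
  pairs$band <- factor(
    ifelse(pairs$distance <= q[1], "short",
           ifelse(pairs$distance > q[2], "long", "medium")),
    levels = c("short", "medium", "long")
  )
  structure(pairs,
            class = c("distance_bands", class(pairs)),
            q1_cutoff = q[1], q3_cutoff = q[2],
            region_ids = atlas$region_id)
}

#' Quartile cutoffs of a distance banding
#'
#' @param bands A `distance_bands` object.
#' @return Named numeric vector with elements `q1` and `q3` (mm).
#' @export
band_cutoffs <- function(bands) {
  stopifnot(inherits(bands, "distance_bands"))
  c(q1 = unname(attr(bands, "q1_cutoff")),
    q3 = unname(attr(bands, "q3_cutoff")))
}

# region x region matrix of band labels, for fast profile counting
band_matrix <- function(bands) {
  ids <- as.character(attr(bands, "region_ids"))
  n <- length(ids)
  m <- matrix(NA_character_, n, n, dimnames = list(ids, ids))
  a <- match(as.character(bands$region_a), ids)
  b <- match(as.character(bands$region_b), ids)
  lab <- as.character(bands$band)
  m[cbind(a, b)] <- lab
  m[cbind(b, a)] <- lab
  m
}
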