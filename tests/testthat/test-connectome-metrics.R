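test_that("symmetrize-and-normalize matches the hand-evaluated formula", {
  # quartile banding needs >= 4 regions, so the 2-region hand example is
  # embedded in a 4-region atlas with zero weights elsewhere
  atlas <- make_atlas(matrix(c(0, 0, 0, 10, 0, 0, 0, 20, 0, 0, 0, 30),
                             ncol = 3, byrow = TRUE),
                      volumes = c(100, 200, 1000, 1000))
  raw <- matrix(0, 4, 4, dimnames = list(1:4, 1:4))
  raw["1", "2"] <- 10
  raw["2", "1"] <- 20
  norm <- normalize_connectome(as_connectome(raw, "raw"), atlas)
  expect_equal(norm["1", "2"], ((10 + 20) / 2) / (100 + 200)) # = 0.05
  expect_equal(norm["1", "2"], 0.05)
  expect_equal(unclass(norm), t(unclass(norm)), ignore_attr = TRUE)
})

test_that("normalization is identity on symmetric input with unit pair-volume", {
  atlas <- make_atlas(matrix(runif(12, -50, 50), ncol = 3),
                      volumes = rep(0.5, 4)) # vol_i + vol_j = 1 for every pair
  m <- matrix(c(0, 3, 1, 0,
                3, 0, 2, 5,
                1, 2, 0, 4,
                0, 5, 4, 0), 4, 4, dimnames = list(1:4, 1:4))
  norm <- normalize_connectome(as_connectome(m, "raw"), atlas)
  expect_equal(unclass(norm), m, ignore_attr = TRUE)
})

test_that("normalization zeroes a nonzero diagonal and validates input", {
  atlas <- make_atlas(matrix(runif(12, -50, 50), ncol = 3))
  m <- matrix(5, 4, 4, dimnames = list(1:4, 1:4))
  norm <- normalize_connectome(as_connectome(m, "raw"), atlas)
  expect_true(all(diag(norm) == 0))

  bad <- m; bad[1, 2] <- -1
  expect_error(as_connectome(bad, "raw"), "non-negative")
  bad <- m; bad[1, 2] <- NaN
  expect_error(as_connectome(bad, "raw"), "non-finite")
  expect_error(normalize_connectome(as_connectome(m[1:3, 1:3], "raw"), atlas),
               "atlas")
})

test_that("percentile threshold uses nearest rank on nonzero weights and is strict", {
  atlas <- make_atlas(matrix(seq_len(15), ncol = 3), volumes = rep(0.5, 5))
  m <- matrix(0, 5, 5, dimnames = list(1:5, 1:5))
  m[upper.tri(m)] <- 1:10
  m <- m + t(m)
  conn <- normalize_connectome(as_connectome(m, "raw"), atlas)
  thr <- threshold_connectome(conn, percentile = 0.20)
  # nearest rank over {1..10} at p = 0.2: ceil(2) = 2nd order statistic = 2;
  # only the weight 1 is strictly below, weight 2 survives
  expect_equal(attr(thr, "cutoff"), 2)
  expect_equal(sort(thr[upper.tri(thr) & thr > 0]), 2:10)

  # all weights equal: nothing strictly below the cutoff, matrix unchanged
  eq <- matrix(3, 5, 5, dimnames = list(1:5, 1:5)); diag(eq) <- 0
  conn_eq <- normalize_connectome(as_connectome(eq, "raw"), atlas)
  thr_eq <- threshold_connectome(conn_eq, percentile = 0.20)
  expect_equal(unclass(thr_eq), unclass(conn_eq), ignore_attr = TRUE)

  # percentile 0: empty removal set
  thr0 <- threshold_connectome(conn, percentile = 0)
  expect_equal(unclass(thr0), unclass(conn), ignore_attr = TRUE)

  # all-zero matrix is a degenerate input
  z <- matrix(0, 5, 5, dimnames = list(1:5, 1:5))
  conn_z <- normalize_connectome(as_connectome(z, "raw"), atlas)
  expect_error(threshold_connectome(conn_z), "degenerate")
})

test_that("distance quartile cutoffs give 7 pairs per outer band on 1..28 distances", {
  # 8 collinear regions: 28 pair distances; with distances ranked 1..28 the
  # short and long bands must each contain exactly 7 pairs
  # Mian-Chowla (Sidon) positions: all 28 pairwise differences are distinct
  x <- c(1, 2, 4, 8, 13, 21, 31, 45)
  atlas <- make_atlas(cbind(x, 0, 0))
  bands <- distance_bands(atlas)
  dists <- sort(bands$distance)
  expect_equal(length(dists), 28)
  q <- band_cutoffs(bands)
  expect_equal(q[["q1"]], oracle_quantile_interp(dists, 0.25))
  expect_equal(q[["q3"]], oracle_quantile_interp(dists, 0.75))
  expect_equal(sum(bands$band == "short"), sum(dists <= q[["q1"]]))
  expect_equal(sum(bands$band == "long"), sum(dists > q[["q3"]]))
  # quartile boundary check: ranks 1..28 put 7 pairs in each outer band
  ranked <- rank(bands$distance)
  expect_setequal(ranked[bands$band == "short"], 1:7)
  expect_setequal(ranked[bands$band == "long"], 22:28)
})

test_that("square-corner geometry puts sides in short and diagonals in long band", {
  s <- 30
  atlas <- make_atlas(matrix(c(0, 0, 0, s, 0, 0, 0, s, 0, s, s, 0),
                             ncol = 3, byrow = TRUE))
  bands <- distance_bands(atlas)
  sides <- bands$band[abs(bands$distance - s) < 1e-9]
  diags <- bands$band[abs(bands$distance - s * sqrt(2)) < 1e-9]
  expect_equal(length(sides), 4)
  expect_equal(length(diags), 2)
  expect_true(all(sides == "short"))
  expect_true(all(diags == "long"))
})

test_that("identical centroids give degenerate all-short banding with a warning", {
  atlas <- make_atlas(matrix(5, nrow = 4, ncol = 3))
  expect_warning(bands <- distance_bands(atlas), "degenerate")
  expect_true(all(bands$band == "short"))
})

test_that("fibre profile counts surviving edges per band and forms the ratio", {
  set.seed(42)
  inst <- random_instance(12)
  conn <- inst$raw |>
    as_connectome("raw", subject_id = "s1") |>
    normalize_connectome(inst$atlas) |>
    threshold_connectome(percentile = 0.20)
  bands <- distance_bands(inst$atlas)
  prof <- fibre_profile(conn, bands)
  expected <- oracle_band_counts(unclass(conn), inst$atlas)
  expect_equal(prof$n_short, unname(expected["short"]))
  expect_equal(prof$n_medium, unname(expected["medium"]))
  expect_equal(prof$n_long, unname(expected["long"]))
  expect_equal(prof$long_short_ratio, unname(expected["long"] / expected["short"]))
  # conservation: bands partition the surviving upper triangle
  expect_equal(prof$n_short + prof$n_medium + prof$n_long,
               sum(conn[upper.tri(conn)] > 0))
})

test_that("ratio is undefined when no short-band connection survives", {
  # regions on a line; keep only one medium/long connection
  atlas <- make_atlas(cbind(c(0, 10, 20, 100), 0, 0), volumes = rep(0.5, 4))
  m <- matrix(0, 4, 4, dimnames = list(1:4, 1:4))
  m["1", "4"] <- m["4", "1"] <- 8 # distance 100: long band
  conn <- normalize_connectome(as_connectome(m, "raw"), atlas)
  thr <- threshold_connectome(conn, percentile = 0.20)
  expect_error(fibre_profile(thr, distance_bands(atlas)), "undefined long:short")
})

test_that("equal long and short survivor counts give ratio 1", {
  set.seed(7)
  # construct a thresholded connectome with 5 short + 5 long survivors
  atlas <- make_atlas(cbind(runif(8, -60, 60), runif(8, -60, 60), runif(8, -60, 60)))
  bands <- distance_bands(atlas)
  short_pairs <- bands[bands$band == "short", ][seq_len(5), ]
  long_pairs <- bands[bands$band == "long", ][seq_len(5), ]
  expect_gte(nrow(short_pairs), 5)
  expect_gte(nrow(long_pairs), 5)
  m <- matrix(0, 8, 8, dimnames = list(1:8, 1:8))
  for (p in seq_len(5)) {
    m[as.character(short_pairs$region_a[p]), as.character(short_pairs$region_b[p])] <- 4
    m[as.character(long_pairs$region_a[p]), as.character(long_pairs$region_b[p])] <- 4
  }
  m <- m + t(m)
  conn <- normalize_connectome(as_connectome(m, "raw"),
                               dplyr::mutate(atlas, volume_mm3 = 0.5))
  prof <- fibre_profile(threshold_connectome(conn, 0), distance_bands(atlas))
  expect_equal(prof$n_short, 5L)
  expect_equal(prof$n_long, 5L)
  expect_equal(prof$long_short_ratio, 1)
})

test_that("weight-sum ratio mode sums surviving weights per band", {
  set.seed(3)
  inst <- random_instance(10)
  atlas <- inst$atlas
  bands <- distance_bands(atlas)
  conn <- inst$raw |>
    as_connectome("raw") |>
    normalize_connectome(atlas) |>
    threshold_connectome(0.2)
  prof_w <- fibre_profile(conn, bands, mode = "weights")
  bm <- matrix("", nrow(conn), ncol(conn))
  ids <- rownames(conn)
  for (r in seq_len(nrow(bands))) {
    i <- match(as.character(bands$region_a[r]), ids)
    j <- match(as.character(bands$region_b[r]), ids)
    bm[i, j] <- bm[j, i] <- as.character(bands$band[r])
  }
  ut <- upper.tri(conn)
  expect_equal(prof_w$n_short, sum(conn[ut & bm == "short"]))
  expect_equal(prof_w$n_long, sum(conn[ut & bm == "long"]))
  expect_equal(prof_w$long_short_ratio, prof_w$n_long / prof_w$n_short)
})

test_that("profile pipeline is invariant to region relabeling and weight scale", {
  set.seed(99)
  for (rep in 1:10) {
    inst <- random_instance(sample(6:13, 1))
    atlas <- inst$atlas
    prof <- fibre_profiles(list(a = inst$raw), atlas)
    # global scaling of raw weights
    prof_scaled <- fibre_profiles(list(a = inst$raw * 7.3), atlas)
    expect_equal(prof_scaled$long_short_ratio, prof$long_short_ratio)
    expect_equal(prof_scaled[c("n_short", "n_medium", "n_long")],
                 prof[c("n_short", "n_medium", "n_long")])
    # permuted region ordering (atlas rows and matrix jointly)
    perm <- sample(nrow(atlas))
    prof_perm <- fibre_profiles(list(a = inst$raw[perm, perm]),
                                atlas[perm, ])
    expect_equal(prof_perm$long_short_ratio, prof$long_short_ratio)
  }
})

test_that("removing a medium-band connection never changes the ratio", {
  set.seed(5)
  inst <- random_instance(10)
  atlas <- inst$atlas
  bands <- distance_bands(atlas)
  conn <- inst$raw |>
    as_connectome("raw") |>
    normalize_connectome(atlas) |>
    threshold_connectome(0.2)
  prof <- fibre_profile(conn, bands)
  med <- bands[bands$band == "medium", ]
  ids <- rownames(conn)
  for (r in seq_len(nrow(med))) {
    m2 <- unclass(conn)
    m2[as.character(med$region_a[r]), as.character(med$region_b[r])] <- 0
    m2[as.character(med$region_b[r]), as.character(med$region_a[r])] <- 0
    conn2 <- as_connectome(m2, "thresholded")
    expect_equal(fibre_profile(conn2, bands)$long_short_ratio,
                 prof$long_short_ratio)
  }
})
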