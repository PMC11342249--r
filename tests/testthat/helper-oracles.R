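# Independent brute-force oracles used to check the implementation. These are
# written from first principles (explicit loops, hand-coded formulas) and
# deliberately share no code with the package internals.

# nearest-rank percentile: smallest value v such that at least ceil(p*n) of
# the sorted values are <= v
oracle_nearest_rank <- function(x, p) {
  s <- sort(x)
  k <- ceiling(p * length(s))
  s[k]
}

# linear-interpolation quantile (h = (n-1)p + 1 convention), written out
oracle_quantile_interp <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(s[n])
  s[lo] + (h - lo) * (s[lo + 1] - s[lo])
}

# band label for one distance given an atlas's full pair-distance population
oracle_band <- function(d, all_distances) {
  q1 <- oracle_quantile_interp(all_distances, 0.25)
  q3 <- oracle_quantile_interp(all_distances, 0.75)
  if (d <= q1) "short" else if (d > q3) "long" else "medium"
}

# exhaustive pair enumeration: band counts of surviving connections
oracle_band_counts <- function(weights, atlas) {
  ids <- as.character(atlas$region_id)
  cent <- as.matrix(atlas[, c("centroid_x", "centroid_y", "centroid_z")])
  n <- nrow(atlas)
  dists <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dists <- c(dists, sqrt(sum((cent[i, ] - cent[j, ])^2)))
  }
  counts <- c(short = 0, medium = 0, long = 0)
  k <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    k <- k + 1
    if (weights[ids[i], ids[j]] > 0) {
      b <- oracle_band(dists[k], dists)
      counts[b] <- counts[b] + 1
    }
  }
  counts
}

# BH step-up by scanning every candidate rejection threshold
oracle_bh_flags <- function(p, q) {
  m <- length(p)
  s <- sort(p)
  kmax <- 0
  for (i in 1:m) if (s[i] <= i / m * q) kmax <- i
  if (kmax == 0) rep(FALSE, m) else p <= s[kmax]
}

# simple linear regression via explicit normal equations + t distribution
oracle_simple_regression <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  b1 <- sxy / sxx
  b0 <- mean(y) - b1 * mean(x)
  ss_res <- sum((y - b0 - b1 * x)^2)
  se_b1 <- sqrt(ss_res / (n - 2) / sxx)
  tval <- b1 / se_b1
  list(slope = b1, intercept = b0, t = tval, df = n - 2,
       p_lower = pt(tval, n - 2))
}

# multiple OLS through hand-coded normal equations (solve of X'X)
oracle_ols <- function(X, y) {
  X1 <- cbind(1, X)
  solve(t(X1) %*% X1, t(X1) %*% y)[, 1]
}

# one-way ANOVA from explicit sums of squares
oracle_anova <- function(values, groups) {
  groups <- as.character(groups)
  gm <- mean(values)
  lv <- split(values, groups)
  ss_between <- sum(vapply(lv, function(v) length(v) * (mean(v) - gm)^2, 0))
  ss_within <- sum(vapply(lv, function(v) sum((v - mean(v))^2), 0))
  df1 <- length(lv) - 1
  df2 <- length(values) - length(lv)
  f <- (ss_between / df1) / (ss_within / df2)
  list(f = f, df1 = df1, df2 = df2,
       p = pf(f, df1, df2, lower.tail = FALSE))
}

# ---- fixture builders ----

# minimal valid atlas from explicit centroids (matrix n x 3) and volumes
make_atlas <- function(centroids, volumes = NULL, hemisphere = NULL) {
  n <- nrow(centroids)
  tibble::tibble(
    region_id = seq_len(n),
    name = sprintf("r%02d", seq_len(n)),
    hemisphere = hemisphere %||% rep(c("L", "R"), length.out = n),
    centroid_x = centroids[, 1],
    centroid_y = centroids[, 2],
    centroid_z = centroids[, 3],
    volume_mm3 = volumes %||% rep(1000, n)
  )
}

# random atlas + raw connectome of n regions (for oracle-equivalence loops)
random_instance <- function(n_regions, density = 0.8) {
  atlas <- make_atlas(matrix(runif(n_regions * 3, -70, 70), ncol = 3),
                      volumes = runif(n_regions, 500, 9000))
  ids <- as.character(atlas$region_id)
  m <- matrix(rpois(n_regions^2, 40) * rbinom(n_regions^2, 1, density),
              n_regions, n_regions, dimnames = list(ids, ids))
  diag(m) <- 0
  list(atlas = atlas, raw = m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
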