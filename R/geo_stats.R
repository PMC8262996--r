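#' Great-circle distance between coordinates
#'
#' Haversine distance on a sphere of radius 6371.0088 km (the mean Earth
#' radius), via \pkg{geosphere}.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (vectorized).
#' @return Distance in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180)) {
    rlang::abort("coordinates out of range.")
  }
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371008.8) / 1000
}

#' Pairwise geographic distance matrix for a sample set
#'
#' @param meta Metadata with `sample_id`, `latitude`, `longitude`.
#' @return Symmetric km matrix named by sample id.
#' @export
geo_distance_matrix <- function(meta) {
  n <- nrow(meta)
  m <- matrix(0, n, n, dimnames = list(meta$sample_id, meta$sample_id))
  idx <- which(lower.tri(m), arr.ind = TRUE)
  d <- haversine_km(meta$latitude[idx[, 1]], meta$longitude[idx[, 1]],
                    meta$latitude[idx[, 2]], meta$longitude[idx[, 2]])
  m[idx] <- d
  m[cbind(idx[, 2], idx[, 1])] <- d
  m
}

new_mantel_result <- function(r, p, n_perm, kind) {
  structure(list(r = r, p = p, n_perm = n_perm, kind = kind),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("%s: r = %.4f, p = %.4g (%d permutations)\n",
              x$kind, x$r, x$p, x$n_perm))
  invisible(x)
}

#' Mantel and partial Mantel tests
#'
#' Pearson correlation of the lower triangles of two distance matrices, with
#' significance from simultaneous row/column permutation of the second
#' matrix: `p = (1 + #\{r_perm >= r_obs\}) / (1 + n_perm)`. The partial form
#' correlates the residuals of `dx` and `dy` after removing `dz`.
#' Both delegate to \pkg{vegan} and are deterministic given `seed`.
#'
#' @param dx,dy,dz Same-order symmetric distance matrices.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return A `mantel_result` (fields `r`, `p`, `n_perm`); see also
#'   [tidy.mantel_result()].
#' @export
mantel_test <- function(dx, dy, n_perm = 999, seed = 1L) {
  check_dist_pair(dx, dy)
  res <- with_seed(seed, vegan::mantel(stats::as.dist(dx),
                                       stats::as.dist(dy),
                                       permutations = n_perm))
  new_mantel_result(unname(res$statistic), res$signif, n_perm, "Mantel")
}

#' @rdname mantel_test
#' @export
partial_mantel_test <- function(dx, dy, dz, n_perm = 999, seed = 1L) {
  check_dist_pair(dx, dy)
  check_dist_pair(dx, dz)
  res <- with_seed(seed, vegan::mantel.partial(
    stats::as.dist(dx), stats::as.dist(dy), stats::as.dist(dz),
    permutations = n_perm))
  new_mantel_result(unname(res$statistic), res$signif, n_perm,
                    "partial Mantel")
}

check_dist_pair <- function(a, b) {
  if (!is.matrix(a) || !is.matrix(b) || !all(dim(a) == dim(b)) ||
      nrow(a) != ncol(a)) {
    rlang::abort("need same-order square matrices.")
  }
  if (sd(a[lower.tri(a)]) == 0 || sd(b[lower.tri(b)]) == 0) {
    rlang::abort("constant distance matrix: correlation undefined.")
  }
  invisible(NULL)
}

#' @export
tidy.mantel_result <- function(x, ...) {
  tibble::tibble(estimate = x$r, p.value = x$p, n_perm = x$n_perm,
                 method = x$kind)
}

#' @export
glance.mantel_result <- function(x, ...) tidy(x)

new_regression_result <- function(slope, intercept, r, p, boot_slopes,
                                  conf, n_obs, xlab, ylab) {
  alpha <- (1 - conf) / 2
  structure(list(
    slope = slope, intercept = intercept, r = r, p = p,
    boot_slopes = boot_slopes,
    ci95 = unname(quantile(boot_slopes, c(alpha, 1 - alpha), na.rm = TRUE)),
    n_obs = n_obs, xlab = xlab, ylab = ylab
  ), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "OLS %s ~ %s: slope = %.4g [%.4g, %.4g], r = %.3f, p = %.3g (n = %d)\n",
    x$ylab, x$xlab, x$slope, x$ci95[1], x$ci95[2], x$r, x$p, x$n_obs))
  invisible(x)
}

#' @export
tidy.regression_result <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope),
                 ci_lo = c(NA, x$ci95[1]), ci_hi = c(NA, x$ci95[2]),
                 p.value = c(NA, x$p))
}

#' @export
glance.regression_result <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept, r = x$r,
                 p.value = x$p, ci_lo = x$ci95[1], ci_hi = x$ci95[2],
                 n_obs = x$n_obs, n_boot = length(x$boot_slopes))
}

# Bootstrap-over-samples OLS of a pairwise response on a pairwise predictor.
boot_pair_regression <- function(y_mat, x_mat, keep_pair, n_boot, seed,
                                 conf, xlab, ylab) {
  ids <- seq_len(nrow(x_mat))
  sel <- lower.tri(x_mat) & keep_pair
  fit <- lm(y_mat[sel] ~ x_mat[sel])
  r <- cor(x_mat[sel], y_mat[sel])
  boot_slopes <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    take <- sample(ids, replace = TRUE)
    ys <- y_mat[take, take]
    xs <- x_mat[take, take]
    ks <- keep_pair[take, take]
    dup <- outer(take, take, "==") # same original sample resampled twice
    s <- lower.tri(xs) & ks & !dup
    if (sum(s) < 3 || sd(xs[s]) == 0) return(NA_real_)
    unname(coef(lm(ys[s] ~ xs[s]))[2])
  }, numeric(1)))
  boot_ok <- boot_slopes[is.finite(boot_slopes)]
  p <- if (sd(boot_ok) == 0) {
    if (mean(boot_ok) == 0) 1 else 0
  } else {
    t.test(boot_ok, mu = 0)$p.value
  }
  new_regression_result(unname(coef(fit)[2]), unname(coef(fit)[1]), r, p,
                        boot_ok, conf, sum(sel), xlab, ylab)
}

#' Distance-decay regression of community similarity on geographic distance
#'
#' Ordinary least squares of pairwise similarity (`1 - Bray-Curtis`) on
#' pairwise distance in km, over the pairs selected by `pairs_filter`.
#' Uncertainty is assessed by bootstrapping samples (matrix rows), not pair
#' entries, rebuilding the pair set for each of `n_boot` resamples
#' (self-pairs created by resampling are excluded); the slope CI is the
#' percentile interval of the bootstrap slopes and p tests slope = 0 by a
#' one-sample t test on the bootstrap slopes.
#'
#' @param sim Symmetric similarity matrix (e.g. `1 - bray_curtis(table)`).
#' @param geo Symmetric distance matrix in km (see
#'   [geo_distance_matrix()]).
#' @param pairs_filter Optional logical matrix selecting pairs (e.g. only
#'   within-host pairs).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @param conf Confidence level.
#' @return A `regression_result` with `slope`, `intercept`, `r`, `p`,
#'   `boot_slopes`, `ci95`; see [tidy.regression_result()].
#' @export
distance_decay <- function(sim, geo, pairs_filter = NULL, n_boot = 1000,
                           seed = 1L, conf = 0.95) {
  if (!all(dim(sim) == dim(geo))) rlang::abort("matrix dimensions differ.")
  keep <- pairs_filter %||% matrix(TRUE, nrow(sim), ncol(sim))
  sel <- lower.tri(geo) & keep
  if (length(unique(geo[sel])) < 3) {
    rlang::abort("need >= 3 distinct geographic distances.")
  }
  boot_pair_regression(sim, geo, keep, n_boot, seed, conf,
                       xlab = "distance_km", ylab = "similarity")
}

#' Regression of a per-sample variable on a scalar predictor
#'
#' The latitude-diversity machinery: OLS of `y` (e.g. replicate-mean Chao1)
#' on `x` (e.g. latitude) with a bootstrap over samples, sharing the
#' `regression_result` contract of [distance_decay()].
#'
#' @param data A data frame.
#' @param y,x Column names (strings).
#' @param n_boot,seed,conf As in [distance_decay()].
#' @return A `regression_result`.
#' @export
gradient_regression <- function(data, y, x, n_boot = 1000, seed = 1L,
                                conf = 0.95) {
  yy <- data[[y]]
  xx <- data[[x]]
  ok <- is.finite(yy) & is.finite(xx)
  yy <- yy[ok]
  xx <- xx[ok]
  if (sd(xx) == 0) rlang::abort("predictor is constant.")
  fit <- lm(yy ~ xx)
  boot_slopes <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    i <- sample(seq_along(xx), replace = TRUE)
    if (sd(xx[i]) == 0) return(NA_real_)
    unname(coef(lm(yy[i] ~ xx[i]))[2])
  }, numeric(1)))
  boot_ok <- boot_slopes[is.finite(boot_slopes)]
  p <- if (sd(boot_ok) == 0) {
    if (mean(boot_ok) == 0) 1 else 0
  } else {
    t.test(boot_ok, mu = 0)$p.value
  }
  new_regression_result(unname(coef(fit)[2]), unname(coef(fit)[1]),
                        cor(xx, yy), p, boot_ok, conf, length(xx), x, y)
}

#' Test the difference between two bootstrapped slopes
#'
#' `delta = slope_a - slope_b`, with a two-sided p from a t test on the
#' bootstrap slope replicates: unpaired by default (the replicates of the
#' two regressions are independent resamples), paired on request.
#'
#' @param res_a,res_b `regression_result` objects with equally many
#'   bootstrap replicates.
#' @param paired Pair bootstrap replicates by index before testing.
#' @return A tibble with `delta`, `ci_lo`, `ci_hi`, `p`.
#' @export
slope_difference_test <- function(res_a, res_b, paired = FALSE) {
  a <- res_a$boot_slopes
  b <- res_b$boot_slopes
  if (length(a) != length(b)) {
    rlang::abort("bootstrap replicate counts differ.")
  }
  delta <- res_a$slope - res_b$slope
  d <- a - b
  ci <- unname(quantile(d, c(0.025, 0.975)))
  p <- if (isTRUE(all.equal(a, b)) || (sd(a) == 0 && sd(b) == 0)) {
    if (delta == 0) 1 else 0
  } else if (paired) {
    t.test(a, b, paired = TRUE)$p.value
  } else {
    t.test(a, b)$p.value
  }
  tibble::tibble(delta = delta, ci_lo = ci[1], ci_hi = ci[2], p = p)
}

#' Contrast mean community similarity between pair groups
#'
#' Mean pairwise similarity per group of sample pairs, percent change of
#' each group relative to a reference group
#' (`100 * (mean_g - mean_ref) / mean_ref`), bootstrap CIs over samples,
#' and a Student's t test of each group's similarities against the
#' reference group's.
#'
#' @param sim Symmetric similarity matrix.
#' @param groups Character matrix (same order as `sim`) or a function of
#'   `(i, j)` id pairs; most simply, build with [pair_group_matrix()].
#' @param reference Group label used as the percent-change baseline.
#' @param n_boot,seed,conf As in [distance_decay()].
#' @return A tibble with `group`, `n_pairs`, `mean_similarity`,
#'   `pct_change`, `ci_lo`, `ci_hi` (bootstrap CI of pct_change), `p`
#'   (t test vs reference; NA for the reference row).
#' @export
group_similarity_contrast <- function(sim, groups, reference,
                                      n_boot = 1000, seed = 1L,
                                      conf = 0.95) {
  stopifnot(is.matrix(groups), all(dim(groups) == dim(sim)))
  lower <- lower.tri(sim)
  glab <- groups[lower]
  if (!reference %in% glab) rlang::abort("reference group has no pairs.")
  gnames <- unique(glab)
  mean_ref <- mean(sim[lower][glab == reference])
  means <- vapply(gnames, function(g) mean(sim[lower][glab == g]),
                  numeric(1))
  pct <- 100 * (means - mean_ref) / mean_ref
  ids <- seq_len(nrow(sim))
  alpha <- (1 - conf) / 2
  boot <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    take <- sample(ids, replace = TRUE)
    ss <- sim[take, take]
    gg <- groups[take, take]
    dup <- outer(take, take, "==")
    s <- lower.tri(ss) & !dup
    sv <- ss[s]
    gv <- gg[s]
    mr <- mean(sv[gv == reference])
    vapply(gnames, function(g) {
      mg <- mean(sv[gv == g])
      100 * (mg - mr) / mr
    }, numeric(1))
  }, numeric(length(gnames))))
  boot <- matrix(boot, nrow = length(gnames))
  p <- vapply(gnames, function(g) {
    if (g == reference) return(NA_real_)
    a <- sim[lower][glab == g]
    b <- sim[lower][glab == reference]
    if (sd(a) == 0 && sd(b) == 0) {
      return(if (mean(a) == mean(b)) 1 else 0)
    }
    t.test(a, b)$p.value
  }, numeric(1))
  tibble::tibble(
    group = gnames,
    n_pairs = unname(as.integer(table(glab)[gnames])),
    mean_similarity = unname(means),
    pct_change = unname(pct),
    ci_lo = unname(apply(boot, 1, quantile, alpha, na.rm = TRUE)),
    ci_hi = unname(apply(boot, 1, quantile, 1 - alpha, na.rm = TRUE)),
    p = unname(p)
  )
}

#' Build a pair-group label matrix from metadata
#'
#' @param meta Metadata with `sample_id`, `host_species`, `site`.
#' @param by `"host_site"` (four-way S/D classes, as in [group_pairs()]),
#'   `"host"` (within each host vs between), or `"site"`.
#' @return A character matrix over sample pairs, named by sample id.
#' @export
pair_group_matrix <- function(meta, by = c("host_site", "host", "site")) {
  by <- match.arg(by)
  n <- nrow(meta)
  host <- as.character(meta$host_species)
  site <- as.character(meta$site)
  lab <- switch(by,
    host_site = outer(seq_len(n), seq_len(n), function(i, j) {
      paste0(ifelse(host[i] == host[j], "S.host", "D.host"), "&",
             ifelse(site[i] == site[j], "S.site", "D.site"))
    }),
    host = outer(seq_len(n), seq_len(n), function(i, j) {
      ifelse(host[i] == host[j], paste0("within_", host[i]),
             "between_hosts")
    }),
    site = outer(seq_len(n), seq_len(n), function(i, j) {
      ifelse(site[i] == site[j], "within_site", "between_sites")
    })
  )
  dimnames(lab) <- list(meta$sample_id, meta$sample_id)
  lab
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment via [stats::p.adjust()], with
#' input validation.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (elementwise >= input, <= 1).
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.na(p_values) & (p_values < 0 | p_values > 1))) {
    rlang::abort("p-values must lie in [0, 1].")
  }
  p.adjust(p_values, method = "BH")
}
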