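#' Patristic (cophenetic) distance matrix
#'
#' Tip-to-tip path-length distances on the tree, the `d(i, j)` consumed by
#' [beta_mntd()].
#'
#' @param tree A rooted `phylo` with branch lengths and >= 2 tips.
#' @return A symmetric non-negative matrix with zero diagonal, rows/columns
#'   named by tip label.
#' @export
cophenetic_matrix <- function(tree) {
  if (length(tree$tip.label) < 2) rlang::abort("tree needs >= 2 tips.")
  if (is.null(tree$edge.length)) rlang::abort("tree has no branch lengths.")
  ape::cophenetic.phylo(tree)
}

#' Abundance weights for betaMNTD
#'
#' Transforms counts with `g(x) = log(1 + x)` (default, matching log-
#' transformed abundances) or the identity, then normalizes over present
#' taxa so the weights sum to 1; absent taxa get weight 0.
#'
#' @param counts Non-negative numeric vector with at least one positive
#'   entry.
#' @param transform `"log1p"` or `"none"`.
#' @return Weight vector of the same length (and names) as `counts`.
#' @export
abundance_weights <- function(counts, transform = c("log1p", "none")) {
  transform <- match.arg(transform)
  if (all(counts == 0)) rlang::abort("all counts are zero.")
  g <- if (transform == "log1p") log1p(counts) else counts
  g[counts == 0] <- 0
  g / sum(g)
}

# n_taxa x n_samples weight matrix, columns summing to 1.
weight_matrix <- function(table, transform) {
  counts <- t(unclass(table)) # taxa x samples
  g <- if (transform == "log1p") log1p(counts) else counts
  sweep(g, 2, colSums(g), "/")
}

#' Abundance-weighted beta mean nearest taxon distance
#'
#' For communities `j`, `k` with abundance weights `w`,
#' `betaMNTD = 0.5 * (sum_i w_ij min_{k' in k} d(i, k') +
#'                    sum_i w_ik min_{j' in j} d(i, j'))`:
#' the weighted mean phylogenetic distance from each taxon to its nearest
#' relative in the opposite community. Zero iff every present taxon of each
#' community is present in the other.
#'
#' @param weights_i,weights_j Weight vectors (see [abundance_weights()])
#'   aligned to the rows of `dists`; zero marks absence.
#' @param dists Patristic distance matrix from [cophenetic_matrix()].
#' @return betaMNTD in branch-length units.
#' @export
beta_mntd <- function(weights_i, weights_j, dists) {
  if (!is.null(names(weights_i))) {
    if (!all(names(weights_i) %in% rownames(dists)) ||
        !all(names(weights_j) %in% rownames(dists))) {
      rlang::abort("weight names missing from distance matrix.")
    }
    wi <- setNames(numeric(nrow(dists)), rownames(dists))
    wj <- wi
    wi[names(weights_i)] <- weights_i
    wj[names(weights_j)] <- weights_j
  } else {
    stopifnot(length(weights_i) == nrow(dists),
              length(weights_j) == nrow(dists))
    wi <- weights_i
    wj <- weights_j
  }
  pi <- which(wi > 0)
  pj <- which(wj > 0)
  if (!length(pi) || !length(pj)) rlang::abort("empty community.")
  min_to_j <- row_mins(dists, pj)
  min_to_i <- row_mins(dists, pi)
  0.5 * (sum(wi[pi] * min_to_j[pi]) + sum(wj[pj] * min_to_i[pj]))
}

# Full pairwise betaMNTD matrix for a count table against a taxon distance
# matrix (taxa in table column order). The per-sample nearest-taxon profile
# M[i, k] = min over taxa present in k of d(i, .) turns the pairwise sums
# into one matrix product: bMNTD = 0.5 (A + A') with A = W' M.
beta_mntd_engine <- function(W, present, dists) {
  n_taxa <- nrow(W)
  M <- vapply(present, function(p) row_mins(dists, p), numeric(n_taxa))
  A <- crossprod(W, M)
  0.5 * (A + t(A))
}

#' Pairwise beta nearest taxon index (betaNTI)
#'
#' For every sample pair, betaNTI is the z-score of the observed betaMNTD
#' against a null distribution generated by shuffling taxon identities
#' across the tips of the phylogeny (equivalently, permuting rows/columns of
#' the patristic distance matrix) while holding abundances fixed. One shared
#' permutation sequence is applied to all pairs per randomization, and all
#' randomness derives from `seed`, so results are reproducible.
#'
#' `betaNTI < -2` indicates significantly less phylogenetic turnover than
#' the null (homogeneous selection), `> 2` significantly more (variable
#' selection).
#'
#' @param table An [otu_table()] aligned to `tree`.
#' @param tree Rooted `phylo` covering the table's OTUs (ignored when
#'   `dists` is supplied).
#' @param n_randomizations Number of tip shuffles (1000 for inference).
#' @param seed Integer seed.
#' @param transform Abundance transform for the weights (see
#'   [abundance_weights()]).
#' @param dists Optional pre-computed [cophenetic_matrix()].
#' @param permutations Optional list of integer permutations of the taxa to
#'   use as the null (overrides `n_randomizations`; used to enumerate exact
#'   nulls on small problems).
#' @return A list with `bnti` and `bmntd_obs` (symmetric matrices with `NA`
#'   diagonal), and `n_degenerate` (pairs whose null sd was 0, reported as
#'   `NaN` with a warning).
#' @export
bnti_matrix <- function(table, tree = NULL, n_randomizations = 1000,
                        seed = 1L, transform = c("log1p", "none"),
                        dists = NULL, permutations = NULL) {
  transform <- match.arg(transform)
  table <- as_otu_table(table)
  if (nrow(table) < 2) rlang::abort("need >= 2 samples.")
  if (is.null(dists)) {
    if (is.null(tree)) rlang::abort("supply `tree` or `dists`.")
    dists <- cophenetic_matrix(tree)
  }
  missing <- setdiff(otu_ids(table), rownames(dists))
  if (length(missing)) {
    rlang::abort(paste0("OTU(s) without distances: ",
                        paste(missing, collapse = ", ")))
  }
  D <- dists[otu_ids(table), otu_ids(table)]
  W <- weight_matrix(table, transform)
  present <- apply(unclass(table) > 0, 1, which, simplify = FALSE)
  obs <- beta_mntd_engine(W, present, D)

  n_taxa <- ncol(table)
  if (is.null(permutations)) {
    permutations <- with_seed(seed, replicate(
      n_randomizations, sample.int(n_taxa), simplify = FALSE))
  }
  n_rand <- length(permutations)
  lower <- lower.tri(obs)
  nulls <- matrix(NA_real_, n_rand, sum(lower))
  for (r in seq_len(n_rand)) {
    Dp <- D[permutations[[r]], permutations[[r]]]
    nulls[r, ] <- beta_mntd_engine(W, present, Dp)[lower]
  }
  null_mean <- colMeans(nulls)
  null_sd <- apply(nulls, 2, sd)
  z <- (obs[lower] - null_mean) / null_sd
  degenerate <- null_sd == 0
  if (any(degenerate)) {
    z[degenerate] <- NaN
    rlang::warn(paste0(sum(degenerate),
                       " pair(s) with degenerate (sd = 0) betaMNTD null."))
  }
  bnti <- matrix(NA_real_, nrow(obs), ncol(obs), dimnames = dimnames(obs))
  bnti[lower] <- z
  bnti[upper.tri(bnti)] <- t(bnti)[upper.tri(bnti)]
  obs_out <- obs
  diag(obs_out) <- NA_real_
  rownames(bnti) <- colnames(bnti) <- sample_ids(table)
  rownames(obs_out) <- colnames(obs_out) <- sample_ids(table)
  list(bnti = bnti, bmntd_obs = obs_out, n_degenerate = sum(degenerate))
}

# One null community: `richness` distinct taxa drawn without replacement
# with probability proportional to metacommunity occupancy, one read each,
# the remaining reads distributed over the drawn taxa with probability
# proportional to metacommunity relative abundance.
rc_null_community <- function(n_taxa, richness, depth, occ_freq, ab_freq) {
  drawn <- sample.int(n_taxa, richness, replace = FALSE, prob = occ_freq)
  x <- integer(n_taxa)
  x[drawn] <- 1L
  extra <- depth - richness
  if (extra > 0) {
    x[drawn] <- x[drawn] + as.integer(rmultinom(1, extra, ab_freq[drawn]))
  }
  x
}

#' Pairwise abundance-based Raup-Crick index on Bray-Curtis
#'
#' For every sample pair the observed Bray-Curtis dissimilarity is compared
#' with a null distribution in which each sample is re-assembled
#' probabilistically from the metacommunity while preserving its observed
#' richness and total reads: presence is drawn without replacement with
#' probability proportional to metacommunity occupancy frequency, and the
#' remaining reads are assigned to the drawn taxa with probability
#' proportional to metacommunity relative abundance. Then
#' `RC = 2 * ((n_null_less + tie_weight * n_null_equal) / n_rand - 0.5)`,
#' bounded in `[-1, 1]`. `RC < -0.95` flags pairs far more similar than the
#' null (homogeneous dispersal), `RC > 0.95` far less similar (dispersal
#' limitation), for pairs not already dominated by selection.
#'
#' One null community is assembled per sample per randomization and all
#' pairwise null dissimilarities are read off that null table, so every pair
#' shares the same randomization stream; results are deterministic given
#' `seed`.
#'
#' @inheritParams bnti_matrix
#' @param tie_weight Weight given to null values tying the observed value
#'   (default 0.5).
#' @param metacommunity Optional reference pool for the null: a list with
#'   `occurrence_freq` and `abundance_freq`, numeric vectors over the
#'   table's OTUs (any positive scale). By default both are estimated from
#'   the analysis table itself (occupancy counts and summed reads); supply
#'   them to restrict the null to an external or host-specific pool, or to
#'   calibrate against a known generative metacommunity.
#' @return A list with `rc` and `bc_obs` (symmetric matrices, `NA`
#'   diagonal).
#' @export
raup_crick_bray <- function(table, n_randomizations = 1000, seed = 1L,
                            tie_weight = 0.5, metacommunity = NULL) {
  table <- as_otu_table(table)
  if (nrow(table) < 2) rlang::abort("need >= 2 samples.")
  counts <- unclass(table)
  n_taxa <- ncol(counts)
  if (is.null(metacommunity)) {
    occ_freq <- colSums(counts > 0)
    ab_freq <- colSums(counts)
  } else {
    occ_freq <- metacommunity$occurrence_freq
    ab_freq <- metacommunity$abundance_freq
    if (length(occ_freq) != n_taxa || length(ab_freq) != n_taxa) {
      rlang::abort("metacommunity vectors must match the table's OTUs.")
    }
  }
  richness <- rowSums(counts > 0)
  depth <- rowSums(counts)
  obs <- as.matrix(vegan::vegdist(counts, method = "bray"))
  lower <- lower.tri(obs)
  obs_l <- obs[lower]
  less <- numeric(length(obs_l))
  eq <- numeric(length(obs_l))
  with_seed(seed, {
    for (r in seq_len(n_randomizations)) {
      null_tab <- t(vapply(seq_len(nrow(counts)), function(s) {
        rc_null_community(n_taxa, richness[s], depth[s], occ_freq, ab_freq)
      }, integer(n_taxa)))
      null_bc <- as.matrix(vegan::vegdist(null_tab, method = "bray"))[lower]
      d <- null_bc - obs_l
      less <- less + (d < -1e-12)
      eq <- eq + (abs(d) <= 1e-12)
    }
  })
  rc_l <- 2 * ((less + tie_weight * eq) / n_randomizations - 0.5)
  rc <- matrix(NA_real_, nrow(obs), ncol(obs), dimnames = dimnames(obs))
  rc[lower] <- rc_l
  rc[upper.tri(rc)] <- t(rc)[upper.tri(rc)]
  diag(obs) <- NA_real_
  list(rc = rc, bc_obs = obs)
}

#' Per-pair null-model results as a tidy table
#'
#' Runs [bnti_matrix()] and [raup_crick_bray()] on one (typically rarefied)
#' table and returns one row per unordered sample pair.
#'
#' @inheritParams bnti_matrix
#' @inheritParams raup_crick_bray
#' @return A tibble with columns `sample_i`, `sample_j`, `bmntd_obs`,
#'   `bnti`, `bc_obs`, `rc`.
#' @export
pair_null_table <- function(table, tree, n_randomizations = 1000, seed = 1L,
                            transform = c("log1p", "none"),
                            tie_weight = 0.5, dists = NULL) {
  transform <- match.arg(transform)
  seeds <- derive_seeds(seed, 2)
  b <- bnti_matrix(table, tree, n_randomizations, seed = seeds[1],
                   transform = transform, dists = dists)
  r <- raup_crick_bray(table, n_randomizations, seed = seeds[2],
                       tie_weight = tie_weight)
  dist_to_pairs(b$bmntd_obs, "bmntd_obs") |>
    dplyr::mutate(
      bnti = dist_to_pairs(b$bnti, "v")$v,
      bc_obs = dist_to_pairs(r$bc_obs, "v")$v,
      rc = dist_to_pairs(r$rc, "v")$v
    )
}
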