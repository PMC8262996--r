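#' Rarefy an OTU table to even depth
#'
#' Each retained sample's reads are subsampled uniformly without replacement
#' to exactly `depth` reads (via [vegan::rrarefy()]), modelling a re-draw of
#' reads from the observed library. Samples with fewer than `depth` total
#' reads are dropped with a warning, or raise an error when `strict = TRUE`.
#'
#' @param table An [otu_table()].
#' @param depth Target reads per sample.
#' @param seed Integer seed; the result is deterministic given the seed.
#' @param strict Error (rather than drop) on under-depth samples.
#' @return A rarefied [otu_table()] whose rows all sum to `depth`.
#' @export
rarefy <- function(table, depth, seed, strict = FALSE) {
  table <- as_otu_table(table)
  stopifnot(depth >= 1)
  totals <- rowSums(table)
  shallow <- totals < depth
  if (any(shallow)) {
    msg <- paste0(sum(shallow), " sample(s) below depth ", depth, ": ",
                  paste(sample_ids(table)[shallow], collapse = ", "))
    if (strict) rlang::abort(msg)
    rlang::warn(paste0("dropping ", msg))
    table <- otu_table(unclass(table)[!shallow, , drop = FALSE])
  }
  if (!nrow(table)) rlang::abort("no samples at or above the target depth.")
  out <- with_seed(seed, withCallingHandlers(
    vegan::rrarefy(unclass(table), depth),
    # silence vegan's advisory nag about large minimum counts
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }))
  otu_table(out)
}

#' Generate replicate rarefied tables
#'
#' Produces `n_tables` independent rarefactions whose per-replicate seeds are
#' derived reproducibly from `seed`; the study design this package mirrors
#' uses 100 replicates at 19,600 reads per sample.
#'
#' @inheritParams rarefy
#' @param n_tables Number of replicate rarefactions.
#' @return A list of rarefied [otu_table()] objects.
#' @export
rarefy_replicates <- function(table, depth = 19600, n_tables = 100,
                              seed = 1L, strict = FALSE) {
  seeds <- derive_seeds(seed, n_tables)
  lapply(seeds, function(s) rarefy(table, depth, seed = s, strict = strict))
}

#' Bias-corrected Chao1 richness
#'
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`, where `F1`/`F2` are the singleton
#' and doubleton counts. Equals observed richness when there are no
#' singletons; 0 for an all-zero vector.
#'
#' @param counts Non-negative integer vector of OTU counts for one sample.
#' @return Estimated richness (species).
#' @export
chao1 <- function(counts) {
  stopifnot(is.numeric(counts), all(counts >= 0))
  if (!all(is_whole_number(counts))) {
    rlang::abort("chao1 requires integer counts.")
  }
  s_obs <- sum(counts > 0)
  if (s_obs == 0) return(0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Faith's phylogenetic diversity
#'
#' Sum of branch lengths of the minimal subtree spanning the root and all
#' taxa present in the sample (root-inclusive by default, so PD of a single
#' taxon is its root-to-tip depth and PD of all tips is the total branch
#' length of the tree).
#'
#' @param counts Named numeric vector of counts (names = OTU ids), or a
#'   character vector of present OTU ids.
#' @param tree A rooted `phylo` containing the present taxa as tips.
#' @param include_root Include the stem path to the root (default `TRUE`).
#' @return Phylogenetic diversity in branch-length units; 0 if no taxon is
#'   present.
#' @export
faith_pd <- function(counts, tree, include_root = TRUE) {
  present <- if (is.character(counts)) {
    counts
  } else {
    names(counts)[counts > 0]
  }
  if (!length(present)) return(0)
  missing <- setdiff(present, tree$tip.label)
  if (length(missing)) {
    rlang::abort(paste0("taxa absent from tree: ",
                        paste(missing, collapse = ", ")))
  }
  tips <- match(present, tree$tip.label)
  parent_edge <- match(seq_len(max(tree$edge)), tree$edge[, 2])
  used <- logical(nrow(tree$edge))
  for (tip in tips) {
    node <- tip
    repeat {
      e <- parent_edge[node]
      if (is.na(e) || used[e]) break
      used[e] <- TRUE
      node <- tree$edge[e, 1]
    }
  }
  if (!include_root && length(tips)) {
    # drop the shared stem: edges on the path from the root down to the MRCA
    mrca <- if (length(tips) == 1L) tips else ape::getMRCA(tree, tips)
    node <- mrca
    repeat {
      e <- parent_edge[node]
      if (is.na(e)) break
      used[e] <- FALSE
      node <- tree$edge[e, 1]
    }
  }
  sum(tree$edge.length[used])
}

#' Per-sample alpha diversity
#'
#' Computes Chao1 richness and (when a tree is supplied) Faith's PD for every
#' sample. With a list of rarefied replicate tables, indices are computed per
#' replicate and averaged per sample — the replicate-mean alpha diversity.
#'
#' @param table An [otu_table()] or a list of them (rarefied replicates).
#' @param tree Optional rooted `phylo` covering the table's OTUs.
#' @param include_root Passed to [faith_pd()].
#' @return A tibble with columns `sample_id`, `chao1`, and optionally
#'   `faith_pd`; replicate input adds `n_replicates`.
#' @export
alpha_diversity <- function(table, tree = NULL, include_root = TRUE) {
  if (is.list(table) && !is.data.frame(table) && !is.matrix(table)) {
    per <- lapply(table, alpha_diversity, tree = tree,
                  include_root = include_root)
    out <- dplyr::bind_rows(per) |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(dplyr::across(dplyr::everything(), mean),
                       n_replicates = length(per), .groups = "drop")
    return(out)
  }
  table <- as_otu_table(table)
  out <- tibble::tibble(
    sample_id = sample_ids(table),
    chao1 = apply(unclass(table), 1, chao1)
  )
  if (!is.null(tree)) {
    out$faith_pd <- apply(unclass(table), 1, faith_pd, tree = tree,
                          include_root = include_root)
  }
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(j, k) = sum_i |x_ij - x_ik| / sum_i (x_ij + x_ik)`; community
#' similarity used throughout the package is `1 - BC`.
#'
#' @param table An [otu_table()] with at least two samples.
#' @return A symmetric samples x samples matrix with zero diagonal,
#'   entries in `[0, 1]`.
#' @export
bray_curtis <- function(table) {
  table <- as_otu_table(table)
  if (nrow(table) < 2) rlang::abort("need at least two samples.")
  as.matrix(vegan::vegdist(unclass(table), method = "bray"))
}

#' Pairwise dissimilarities as a tidy pair table
#'
#' @param m A symmetric sample distance/similarity matrix.
#' @param value_name Name for the value column.
#' @return A tibble with one row per unordered sample pair.
#' @export
pairwise_tibble <- function(m, value_name = "value") {
  dist_to_pairs(m, value_name)
}

site_relative_abundance <- function(table, samples) {
  sub <- unclass(table)[samples, , drop = FALSE]
  rel <- sweep(sub, 1, rowSums(sub), "/")
  list(mean_rel = colMeans(rel), occ = colSums(sub > 0), n = length(samples))
}

#' Local core OTUs at one site
#'
#' An OTU is a local core member when its abundance passes
#' `min_rel_abundance` and it occurs (count > 0) in at least
#' `ceiling(min_occurrence * n)` of the site's `n` samples — with the
#' defaults, at least 8 of 10 samples. The abundance filter applies to the
#' within-site mean relative abundance by default
#' (`abundance_scope = "site_mean"`); `"any_sample"` instead requires the
#' threshold in at least one sample, the variant used for display trees.
#'
#' @param table An [otu_table()].
#' @param meta Sample metadata with `sample_id` and `site`.
#' @param site Site label to evaluate.
#' @param min_rel_abundance Relative-abundance threshold (default 0.001,
#'   i.e. 0.1%).
#' @param min_occurrence Occurrence threshold as a fraction of the site's
#'   samples (default 0.8).
#' @param abundance_scope `"site_mean"` or `"any_sample"`.
#' @return Character vector of core OTU ids (in table column order).
#' @export
local_core_otus <- function(table, meta, site,
                            min_rel_abundance = 0.001,
                            min_occurrence = 0.8,
                            abundance_scope = c("site_mean", "any_sample")) {
  abundance_scope <- match.arg(abundance_scope)
  stopifnot(min_rel_abundance > 0, min_rel_abundance <= 1,
            min_occurrence > 0, min_occurrence <= 1)
  table <- as_otu_table(table)
  samples <- meta$sample_id[meta$site == site]
  samples <- intersect(samples, sample_ids(table))
  if (!length(samples)) rlang::abort(paste0("unknown or empty site: ", site))
  sub <- unclass(table)[samples, , drop = FALSE]
  rel <- sweep(sub, 1, rowSums(sub), "/")
  abundant <- if (abundance_scope == "site_mean") {
    colMeans(rel) >= min_rel_abundance
  } else {
    apply(rel, 2, max) >= min_rel_abundance
  }
  occurrent <- colSums(sub > 0) >= ceiling(min_occurrence * length(samples))
  otu_ids(table)[abundant & occurrent]
}

#' Regional core OTUs per host species
#'
#' An OTU is a regional core member for a host species when it is a local
#' core OTU at every site sampled for that host. Also reports the fraction
#' of the community the core set accounts for: the summed per-sample-mean
#' relative abundance of the core OTUs across the host's samples.
#'
#' @inheritParams local_core_otus
#' @return A tibble with columns `host_species`, `core_otus` (list column),
#'   `n_core`, `core_abundance_fraction`.
#' @export
regional_core_otus <- function(table, meta,
                               min_rel_abundance = 0.001,
                               min_occurrence = 0.8,
                               abundance_scope = c("site_mean", "any_sample")) {
  abundance_scope <- match.arg(abundance_scope)
  table <- as_otu_table(table)
  hosts <- unique(meta$host_species)
  purrr::map_dfr(hosts, function(h) {
    hmeta <- meta[meta$host_species == h, , drop = FALSE]
    sites <- unique(hmeta$site)
    locals <- lapply(sites, function(s) {
      local_core_otus(table, hmeta, s,
                      min_rel_abundance = min_rel_abundance,
                      min_occurrence = min_occurrence,
                      abundance_scope = abundance_scope)
    })
    core <- Reduce(intersect, locals)
    hsamp <- intersect(hmeta$sample_id, sample_ids(table))
    sub <- unclass(table)[hsamp, , drop = FALSE]
    rel <- sweep(sub, 1, rowSums(sub), "/")
    frac <- if (length(core)) sum(colMeans(rel)[core]) else 0
    tibble::tibble(host_species = h, core_otus = list(core),
                   n_core = length(core), core_abundance_fraction = frac)
  })
}
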