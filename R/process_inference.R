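process_levels <- c("homogeneous_selection", "variable_selection",
                    "homogeneous_dispersal", "dispersal_limitation",
                    "undominated")

#' Classify sample pairs into assembly processes
#'
#' Implements the sequential two-index rule: `betaNTI < -2` is homogeneous
#' selection and `betaNTI > 2` variable selection; for the remaining pairs
#' (`-2 <= betaNTI <= 2`, where selection does not dominate turnover),
#' `RC < -0.95` is homogeneous dispersal, `RC > 0.95` dispersal limitation,
#' and `-0.95 <= RC <= 0.95` the undominated (drift) regime. Selection is
#' always evaluated first: RC never overrides `|betaNTI| > 2`. Boundary
#' values fall on the non-selection / non-dispersal side. Non-finite inputs
#' yield the sentinel `"unclassified"`.
#'
#' @param bnti,rc Numeric vectors (recycled to common length).
#' @param bnti_cut,rc_cut Classification thresholds (defaults 2 and 0.95).
#' @return A factor with levels `homogeneous_selection`,
#'   `variable_selection`, `homogeneous_dispersal`, `dispersal_limitation`,
#'   `undominated`, `unclassified`.
#' @export
classify_process <- function(bnti, rc, bnti_cut = 2, rc_cut = 0.95) {
  stopifnot(bnti_cut > 0, rc_cut > 0)
  n <- max(length(bnti), length(rc))
  bnti <- rep_len(bnti, n)
  rc <- rep_len(rc, n)
  out <- rep("unclassified", n)
  ok <- is.finite(bnti) & is.finite(rc)
  out[ok & bnti < -bnti_cut] <- "homogeneous_selection"
  out[ok & bnti > bnti_cut] <- "variable_selection"
  neutral <- ok & abs(bnti) <= bnti_cut
  out[neutral & rc < -rc_cut] <- "homogeneous_dispersal"
  out[neutral & rc > rc_cut] <- "dispersal_limitation"
  out[neutral & abs(rc) <= rc_cut] <- "undominated"
  factor(out, levels = c(process_levels, "unclassified"))
}

#' Infer assembly processes across rarefied replicate tables
#'
#' Computes betaNTI and RC for every sample pair on each rarefied table
#' (with per-replicate seeds derived from `seed`), averages both indices per
#' pair across replicates, and classifies the means. Replicates where a
#' pair's null was degenerate are excluded from that pair's mean;
#' `n_replicates_used` records how many replicates informed each pair, and
#' pairs degenerate in every replicate come back `"unclassified"`.
#'
#' @param tables An [otu_table()] or a list of rarefied replicates.
#' @param tree Rooted `phylo` covering the OTUs.
#' @param meta Optional metadata; when supplied, pairs are labelled with
#'   [group_pairs()] host/site classes.
#' @inheritParams bnti_matrix
#' @inheritParams raup_crick_bray
#' @inheritParams classify_process
#' @return A tibble (`pair_process` class) with one row per unordered pair:
#'   ids, mean `bnti`/`rc` (plus replicate sds), `bc_obs`, `bmntd_obs`,
#'   `n_replicates_used`, `process`, and `pair_group` when `meta` is given.
#' @export
infer_processes <- function(tables, tree, meta = NULL,
                            n_randomizations = 1000, seed = 1L,
                            transform = c("log1p", "none"),
                            tie_weight = 0.5, bnti_cut = 2, rc_cut = 0.95) {
  transform <- match.arg(transform)
  if (!is.list(tables) || is.matrix(tables)) tables <- list(tables)
  dists <- cophenetic_matrix(tree)
  seeds <- derive_seeds(seed, length(tables))
  per <- purrr::map2(tables, seeds, function(tab, s) {
    pair_null_table(tab, tree, n_randomizations, seed = s,
                    transform = transform, tie_weight = tie_weight,
                    dists = dists)
  })
  out <- dplyr::bind_rows(per) |>
    dplyr::group_by(.data$sample_i, .data$sample_j) |>
    dplyr::summarise(
      bmntd_obs = mean(.data$bmntd_obs),
      bc_obs = mean(.data$bc_obs),
      bnti_sd = sd(.data$bnti[is.finite(.data$bnti)]),
      rc_sd = sd(.data$rc),
      n_replicates_used = sum(is.finite(.data$bnti)),
      bnti = mean(.data$bnti[is.finite(.data$bnti)]),
      rc = mean(.data$rc),
      .groups = "drop"
    ) |>
    dplyr::mutate(process = classify_process(.data$bnti, .data$rc,
                                             bnti_cut, rc_cut)) |>
    dplyr::relocate("bnti", "rc", .after = "bc_obs")
  if (!is.null(meta)) out <- group_pairs(out, meta)
  class(out) <- c("pair_process", class(out))
  out
}

#' Label sample pairs by shared host and site
#'
#' Adds the four-way pair grouping `S.host&S.site`, `S.host&D.site`,
#' `D.host&S.site`, `D.host&D.site` (S = same, D = different) used to
#' summarize process importance across biological and spatial scales.
#'
#' @param pairs A tibble with `sample_i`, `sample_j` columns.
#' @param meta Metadata with `sample_id`, `host_species`, `site`.
#' @return `pairs` with added `host_i`, `host_j`, `site_i`, `site_j`,
#'   `pair_group` columns.
#' @export
group_pairs <- function(pairs, meta) {
  need <- union(pairs$sample_i, pairs$sample_j)
  missing <- setdiff(need, meta$sample_id)
  if (length(missing)) {
    rlang::abort(paste0("samples missing from metadata: ",
                        paste(missing, collapse = ", ")))
  }
  if (anyNA(meta$host_species[match(need, meta$sample_id)]) ||
      anyNA(meta$site[match(need, meta$sample_id)])) {
    rlang::abort("host_species/site must be defined for all samples.")
  }
  ix <- match(pairs$sample_i, meta$sample_id)
  jx <- match(pairs$sample_j, meta$sample_id)
  old_class <- class(pairs)
  out <- pairs |>
    dplyr::mutate(
      host_i = meta$host_species[ix], host_j = meta$host_species[jx],
      site_i = meta$site[ix], site_j = meta$site[jx],
      pair_group = paste0(
        ifelse(.data$host_i == .data$host_j, "S.host", "D.host"), "&",
        ifelse(.data$site_i == .data$site_j, "S.site", "D.site"))
    )
  class(out) <- old_class
  out
}

boot_fractions <- function(labels, n_boot) {
  n <- length(labels)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n_boot, n)
  t(apply(idx, 1, function(i) {
    tabulate(labels[i], nbins = length(process_levels)) / n
  }))
}

#' Relative importance of processes per pair group
#'
#' Fraction of classified pairs carrying each process label within each
#' group, with percentile bootstrap confidence intervals obtained by
#' resampling pairs (1000 resamples by default). Fractions within a group
#' sum to 1 over the five labels. Unclassified pairs are excluded from the
#' denominator; groups without classified pairs are omitted with a warning.
#'
#' @param pair_table Output of [infer_processes()] (or any tibble with a
#'   `process` column).
#' @param group Column name (string) giving the grouping; `NULL` summarizes
#'   all pairs as one group.
#' @param n_boot Bootstrap resamples for the CIs.
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return A tibble with `group`, `process`, `fraction`, `ci_lo`, `ci_hi`,
#'   `n_pairs`.
#' @export
summarize_fractions <- function(pair_table, group = "pair_group",
                                n_boot = 1000, seed = 1L, conf = 0.95) {
  groups <- if (is.null(group)) {
    rep("all", nrow(pair_table))
  } else {
    as.character(pair_table[[group]])
  }
  alpha <- (1 - conf) / 2
  keep <- pair_table$process %in% process_levels
  dropped <- setdiff(unique(groups), unique(groups[keep]))
  if (length(dropped)) {
    rlang::warn(paste0("group(s) without classified pairs omitted: ",
                       paste(dropped, collapse = ", ")))
  }
  labels <- factor(as.character(pair_table$process[keep]),
                   levels = process_levels)
  groups <- groups[keep]
  seeds <- derive_seeds(seed, length(unique(groups)))
  out <- purrr::imap_dfr(
    split(labels, groups)[unique(groups)],
    function(lab, g) {
      frac <- tabulate(lab, nbins = length(process_levels)) / length(lab)
      bf <- with_seed(seeds[match(g, unique(groups))],
                      boot_fractions(lab, n_boot))
      tibble::tibble(
        group = g,
        process = factor(process_levels, levels = process_levels),
        fraction = frac,
        ci_lo = apply(bf, 2, quantile, alpha),
        ci_hi = apply(bf, 2, quantile, 1 - alpha),
        n_pairs = length(lab)
      )
    })
  class(out) <- c("process_summary", class(out))
  out
}

#' Host- or site-induced shift in process importance
#'
#' For the chosen contrast, compares process fractions between pairs that
#' differ in the factor and pairs that share it: e.g. the host-induced shift
#' for a label is `fraction(D.host pairs) - fraction(S.host pairs)`, so a
#' process enhanced by crossing hosts gets a positive delta. Uncertainty
#' comes from bootstrapping pairs within each side (`n_boot` resamples); the
#' 95% CI is the percentile interval of the bootstrap deltas and the
#' two-sided p is a one-sample t test of the bootstrap deltas against 0.
#' P-values are BH-adjusted within the call; use [process_shifts()] for the
#' combined 5-label x 2-contrast family.
#'
#' @param pair_table Output of [infer_processes()] with `pair_group` labels
#'   (see [group_pairs()]).
#' @param contrast `"host"` or `"site"`.
#' @inheritParams summarize_fractions
#' @param adjust BH-adjust p-values across the five labels (default TRUE;
#'   [process_shifts()] turns this off and adjusts over the full family).
#' @return A tibble with `contrast`, `process`, `frac_same`, `frac_diff`,
#'   `delta`, `ci_lo`, `ci_hi`, `p`, `degenerate` (zero-variance bootstrap
#'   flag) and `p_adj` when `adjust`.
#' @export
process_shift <- function(pair_table, contrast = c("host", "site"),
                          n_boot = 1000, seed = 1L, conf = 0.95,
                          adjust = TRUE) {
  contrast <- match.arg(contrast)
  if (is.null(pair_table$pair_group)) {
    rlang::abort("pair_table needs `pair_group`; run group_pairs() first.")
  }
  same <- if (contrast == "host") {
    grepl("^S\\.host", pair_table$pair_group)
  } else {
    grepl("S\\.site$", pair_table$pair_group)
  }
  keep <- pair_table$process %in% process_levels
  lab_s <- factor(as.character(pair_table$process[keep & same]),
                  levels = process_levels)
  lab_d <- factor(as.character(pair_table$process[keep & !same]),
                  levels = process_levels)
  if (!length(lab_s) || !length(lab_d)) {
    rlang::abort("both contrast groups must contain classified pairs.")
  }
  frac <- function(lab) tabulate(lab, nbins = length(process_levels)) /
    length(lab)
  seeds <- derive_seeds(seed, 2)
  bs <- with_seed(seeds[1], boot_fractions(lab_s, n_boot))
  bd <- with_seed(seeds[2], boot_fractions(lab_d, n_boot))
  deltas <- bd - bs
  alpha <- (1 - conf) / 2
  p <- vapply(seq_along(process_levels), function(k) {
    d <- deltas[, k]
    if (sd(d) == 0) return(if (mean(d) == 0) 1 else 0)
    t.test(d, mu = 0)$p.value
  }, numeric(1))
  out <- tibble::tibble(
    contrast = contrast,
    process = factor(process_levels, levels = process_levels),
    frac_same = frac(lab_s),
    frac_diff = frac(lab_d),
    delta = frac(lab_d) - frac(lab_s),
    ci_lo = apply(deltas, 2, quantile, alpha),
    ci_hi = apply(deltas, 2, quantile, 1 - alpha),
    p = p,
    degenerate = apply(deltas, 2, sd) == 0
  )
  if (adjust) out$p_adj <- p.adjust(out$p, method = "BH")
  out
}

#' @rdname process_shift
#' @export
process_shifts <- function(pair_table, n_boot = 1000, seed = 1L,
                           conf = 0.95) {
  seeds <- derive_seeds(seed, 2)
  out <- dplyr::bind_rows(
    process_shift(pair_table, "host", n_boot, seeds[1], conf, adjust = FALSE),
    process_shift(pair_table, "site", n_boot, seeds[2], conf, adjust = FALSE)
  )
  out$p_adj <- p.adjust(out$p, method = "BH")
  out
}
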