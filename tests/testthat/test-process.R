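test_that("classification implements the exact five-region partition", {
  eps <- 1e-9
  # full boundary grid: betaNTI in {-2-eps, -2, 2, 2+eps} x RC in
  # {-0.95-eps, -0.95, 0.95, 0.95+eps}
  b <- c(-2 - eps, -2, 2, 2 + eps)
  r <- c(-0.95 - eps, -0.95, 0.95, 0.95 + eps)
  grid <- expand.grid(bnti = b, rc = r)
  got <- classify_process(grid$bnti, grid$rc)
  want <- with(grid, ifelse(bnti < -2, "homogeneous_selection",
               ifelse(bnti > 2, "variable_selection",
               ifelse(rc < -0.95, "homogeneous_dispersal",
               ifelse(rc > 0.95, "dispersal_limitation", "undominated")))))
  expect_identical(as.character(got), want)

  # spot checks pinned to the threshold definitions
  expect_equal(as.character(classify_process(-2.5, 0.99)),
               "homogeneous_selection") # selection evaluated first
  expect_equal(as.character(classify_process(0, 0)), "undominated")
  expect_equal(as.character(classify_process(2.0, 0.96)),
               "dispersal_limitation") # betaNTI = 2 is not selection
  expect_equal(as.character(classify_process(NaN, 0.5)), "unclassified")
  expect_equal(as.character(classify_process(0.5, NA)), "unclassified")
})

test_that("single-replicate inference equals direct classification", {
  sim <- sim_assemble("drift", n_samples = 6, seed = 3)
  direct <- suppressWarnings(
    pair_null_table(sim$table, sim$tree, n_randomizations = 60, seed = 21))
  via <- suppressWarnings(
    infer_processes(sim$table, sim$tree, n_randomizations = 60, seed = 21))
  direct <- direct[order(direct$sample_i, direct$sample_j), ]
  via <- via[order(via$sample_i, via$sample_j), ]
  # infer_processes derives the per-replicate seed from `seed`
  expect_equal(via$process,
               classify_process(via$bnti, via$rc))
  expect_equal(via$n_replicates_used, rep(1L, nrow(via)))
  expect_equal(dim(via)[1], choose(6, 2))
})

test_that("replicate aggregation averages indices and is order-invariant", {
  sim <- sim_assemble("drift", n_samples = 5, seed = 8)
  reps <- rarefy_replicates(sim$table, depth = 1500, n_tables = 3, seed = 2)
  out1 <- suppressWarnings(
    infer_processes(reps, sim$tree, n_randomizations = 50, seed = 7))
  per <- lapply(seq_along(reps), function(k) {
    seeds <- assemblyproc:::derive_seeds(7, 3)
    suppressWarnings(pair_null_table(reps[[k]], sim$tree,
                                     n_randomizations = 50,
                                     seed = seeds[k]))
  })
  manual_bnti <- rowMeans(sapply(per, function(p) p$bnti))
  key <- paste(per[[1]]$sample_i, per[[1]]$sample_j)
  out_key <- paste(out1$sample_i, out1$sample_j)
  expect_equal(out1$bnti[match(key, out_key)], manual_bnti)
  expect_equal(as.character(out1$process),
               as.character(classify_process(out1$bnti, out1$rc)))
})

test_that("pair groups enumerate the host/site classes combinatorially", {
  meta <- toy_meta()  # 2 hosts x 2 sites x 2 reps = 8 samples
  ids <- meta$sample_id
  pairs <- t(combn(ids, 2))
  pt <- tibble::tibble(sample_i = pairs[, 1], sample_j = pairs[, 2])
  g <- group_pairs(pt, meta)
  counts <- table(g$pair_group)
  expect_equal(unname(counts["S.host&S.site"]), 4)   # 4 cells x C(2,2)
  expect_equal(unname(counts["S.host&D.site"]), 8)
  expect_equal(unname(counts["D.host&S.site"]), 8)
  expect_equal(unname(counts["D.host&D.site"]), 8)
  expect_equal(sum(counts), choose(8, 2))

  bad <- meta[-1, ]
  expect_error(group_pairs(pt, bad), ids[1])
})

test_that("process fractions count labels and sum to one", {
  pt <- tibble::tibble(
    sample_i = letters[1:4], sample_j = letters[5:8],
    process = factor(c("homogeneous_selection", "homogeneous_selection",
                       "homogeneous_dispersal", "undominated"),
                     levels = levels(classify_process(0, 0))),
    pair_group = "g1"
  )
  s <- summarize_fractions(pt, n_boot = 200, seed = 1)
  expect_equal(s$fraction[s$process == "homogeneous_selection"], 0.5)
  expect_equal(s$fraction[s$process == "homogeneous_dispersal"], 0.25)
  expect_equal(s$fraction[s$process == "undominated"], 0.25)
  expect_equal(sum(s$fraction), 1)
  expect_equal(unique(s$n_pairs), 4L)

  # all pairs one label: degenerate CI [1, 1]
  pt2 <- pt
  pt2$process[] <- "undominated"
  s2 <- summarize_fractions(pt2, n_boot = 100, seed = 2)
  row <- s2[s2$process == "undominated", ]
  expect_equal(c(row$fraction, row$ci_lo, row$ci_hi), c(1, 1, 1))

  # unclassified pairs are excluded from the denominator
  pt3 <- pt
  pt3$process[4] <- "unclassified"
  s3 <- summarize_fractions(pt3, n_boot = 100, seed = 3)
  expect_equal(unique(s3$n_pairs), 3L)
  expect_equal(sum(s3$fraction), 1)
})

test_that("bootstrap CIs for a binomial fraction reach nominal coverage", {
  p_true <- 0.3
  n_pairs <- 50
  n_sim <- 400
  labs <- levels(classify_process(0, 0))
  set.seed(77)
  cover <- vapply(seq_len(n_sim), function(k) {
    x <- rbinom(1, n_pairs, p_true)
    pt <- tibble::tibble(
      sample_i = as.character(seq_len(n_pairs)),
      sample_j = as.character(seq_len(n_pairs) + 1000),
      process = factor(rep(c("homogeneous_selection", "undominated"),
                           c(x, n_pairs - x)), levels = labs),
      pair_group = "g"
    )
    s <- summarize_fractions(pt, n_boot = 400, seed = k)
    row <- s[s$process == "homogeneous_selection", ]
    row$ci_lo <= p_true && p_true <= row$ci_hi
  }, logical(1))
  expect_gt(mean(cover), 0.92 - 0.03)
  expect_lt(mean(cover), 0.99)
})

test_that("process shifts measure the difference between pair classes", {
  labs <- levels(classify_process(0, 0))
  mk_pt <- function(frac_dl_same, frac_dl_diff, n = 100) {
    same_dl <- round(n * frac_dl_same)
    diff_dl <- round(n * frac_dl_diff)
    tibble::tibble(
      sample_i = as.character(1:(2 * n)),
      sample_j = as.character(1:(2 * n) + 9000),
      process = factor(c(rep("dispersal_limitation", same_dl),
                         rep("undominated", n - same_dl),
                         rep("dispersal_limitation", diff_dl),
                         rep("undominated", n - diff_dl)), levels = labs),
      pair_group = rep(c("S.host&S.site", "D.host&D.site"), each = n)
    )
  }
  # identical fractions: delta 0, CI contains 0
  sh0 <- process_shift(mk_pt(0.4, 0.4), "host", n_boot = 300, seed = 2)
  row0 <- sh0[sh0$process == "dispersal_limitation", ]
  expect_equal(row0$delta, 0)
  expect_true(row0$ci_lo <= 0 && row0$ci_hi >= 0)

  # strong contrast: delta -0.8 for a 0.9 -> 0.1 drop, CI excludes 0
  sh1 <- process_shift(mk_pt(0.9, 0.1), "host", n_boot = 300, seed = 3)
  row1 <- sh1[sh1$process == "dispersal_limitation", ]
  expect_equal(row1$delta, -0.8)
  expect_lt(row1$ci_hi, 0)
  expect_lt(row1$p, 0.01)

  # sign convention: more dispersal limitation among D.host pairs gives a
  # positive host-induced delta
  sh2 <- process_shift(mk_pt(0.1, 0.9), "host", n_boot = 300, seed = 4)
  expect_gt(sh2$delta[sh2$process == "dispersal_limitation"], 0)

  # the combined host+site family carries 10 BH-adjusted tests
  both <- process_shifts(mk_pt(0.2, 0.6), n_boot = 200, seed = 5)
  expect_equal(nrow(both), 10)
  expect_true(all(both$p_adj >= both$p - 1e-12))
})
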