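test_that("rarefaction preserves totals, bounds, and determinism", {
  tab <- otu_table(matrix(c(10L, 0L, 10L, 50L, 30L, 20L), 2, 3,
                          byrow = TRUE,
                          dimnames = list(c("a", "b"), c("x", "y", "z"))))
  # depth equals a sample's total: that sample is returned unchanged
  r <- rarefy(tab, 20, seed = 1)
  expect_equal(unclass(r)["a", ], c(x = 10L, y = 0L, z = 10L))
  expect_equal(unname(rowSums(unclass(r))), c(20, 20))

  set.seed(10)
  for (k in 1:5) {
    big <- random_table(4, 12, lambda = 30)
    d <- 100
    rr <- rarefy(big, d, seed = k)
    expect_true(all(rowSums(unclass(rr)) == d))
    expect_true(all(unclass(rr) <= unclass(big)[rownames(rr), ]))
  }
  expect_identical(unclass(rarefy(tab, 15, seed = 3)),
                   unclass(rarefy(tab, 15, seed = 3)))

  shallow <- otu_table(matrix(c(5L, 5L, 100L, 100L), 2, 2, byrow = TRUE,
                              dimnames = list(c("lo", "hi"), c("x", "y"))))
  expect_warning(kept <- rarefy(shallow, 50, seed = 1), "lo")
  expect_equal(rownames(kept), "hi")
  expect_error(rarefy(shallow, 50, seed = 1, strict = TRUE), "lo")
})

test_that("rarefied counts match hypergeometric sampling moments", {
  # one sample [1000, 1000], depth 200: first coordinate ~ Hypergeom
  tab <- otu_table(matrix(c(1000L, 1000L), 1, 2,
                          dimnames = list("s", c("x", "y"))))
  n_rep <- 2000
  draws <- vapply(seq_len(n_rep), function(k) {
    unclass(rarefy(tab, 200, seed = k))[1, 1]
  }, integer(1))
  hyper_sd <- sqrt(200 * 0.5 * 0.5 * (2000 - 200) / (2000 - 1))
  se <- hyper_sd / sqrt(n_rep)
  expect_lt(abs(mean(draws) - 100), 3 * se)
  # spread is hypergeometric, not binomial (finite-population correction)
  expect_lt(sd(draws), sqrt(200 * 0.25) * 1.02)
})

test_that("replicate rarefactions are reproducible and unbiased", {
  tab <- random_table(5, 15, lambda = 40, seed = 2)
  reps1 <- rarefy_replicates(tab, depth = 200, n_tables = 4, seed = 9)
  reps2 <- rarefy_replicates(tab, depth = 200, n_tables = 4, seed = 9)
  expect_identical(lapply(reps1, unclass), lapply(reps2, unclass))
  expect_false(identical(unclass(reps1[[1]]), unclass(reps1[[2]])))
  expect_true(all(vapply(reps1, function(r) all(rowSums(unclass(r)) == 200),
                         logical(1))))

  # replicate-mean relative abundance tracks the pre-rarefaction value
  reps <- rarefy_replicates(tab, depth = 200, n_tables = 60, seed = 5)
  rel_obs <- unclass(tab)[1, 1] / sum(unclass(tab)[1, ])
  vals <- vapply(reps, function(r) unclass(r)[1, 1] / 200, numeric(1))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - rel_obs), 3 * se + 1e-8)
})

test_that("chao1 matches the bias-corrected closed form", {
  expect_equal(chao1(c(5, 3, 1, 1, 2)), 5.5)
  expect_equal(chao1(c(4, 4, 4)), 3)
  expect_equal(chao1(numeric(5)), 0)
  set.seed(8)
  for (k in 1:200) {
    v <- rpois(30, sample(1:4, 1))
    expect_gte(chao1(v), sum(v > 0))
    if (sum(v) > 0) {
      ref <- unname(vegan::estimateR(v)["S.chao1"])
      expect_equal(chao1(v), ref, tolerance = 1e-8)
    }
  }
  expect_error(chao1(c(1.5, 2)), "integer")
})

test_that("faith_pd computes spanning branch length and agrees with picante", {
  tr <- tree4()
  expect_equal(faith_pd(c(A = 1), tr), 2)
  expect_equal(faith_pd(c(A = 1, B = 2, C = 3, D = 4), tr), 6)
  expect_equal(faith_pd(c(A = 1, B = 2, C = 3, D = 4), tr),
               sum(tr$edge.length))
  expect_equal(faith_pd(character(0), tr), 0)
  expect_equal(faith_pd(c("A", "B"), tr, include_root = FALSE), 2)

  set.seed(12)
  for (k in 1:20) {
    tr2 <- sim_tree(sample(5:12, 1), seed = k)
    tips <- sample(tr2$tip.label, sample(2:4, 1))
    more <- union(tips, sample(tr2$tip.label, 1))
    expect_lte(faith_pd(tips, tr2), faith_pd(more, tr2))
    comm <- matrix(as.integer(tr2$tip.label %in% tips), 1,
                   dimnames = list("s", tr2$tip.label))
    ref <- suppressWarnings(picante::pd(comm, tr2, include.root = TRUE)$PD)
    expect_equal(faith_pd(tips, tr2), ref, tolerance = 1e-10)
  }
})

test_that("bray_curtis matches hand values and matrix invariants", {
  tab <- otu_table(matrix(c(2L, 2L, 1L, 3L), 2, 2, byrow = TRUE,
                          dimnames = list(c("u", "v"), c("x", "y"))))
  expect_equal(bray_curtis(tab)["u", "v"], 0.25)
  tab2 <- otu_table(matrix(c(1L, 0L, 0L, 1L), 2, 2, byrow = TRUE,
                           dimnames = list(c("u", "v"), c("x", "y"))))
  expect_equal(bray_curtis(tab2)["u", "v"], 1)
  tab3 <- otu_table(matrix(c(3L, 7L, 3L, 7L), 2, 2, byrow = TRUE,
                           dimnames = list(c("u", "v"), c("x", "y"))))
  expect_equal(bray_curtis(tab3)["u", "v"], 0)

  m <- bray_curtis(random_table(6, 10, seed = 4))
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(0, 6))
  expect_true(all(m >= 0 & m <= 1))
})

test_that("alpha_diversity averages across replicate tables", {
  tr <- sim_tree(10, seed = 3)
  tab <- random_table(4, 10, lambda = 30, seed = 5)
  colnames(tab) <- tr$tip.label
  tab <- otu_table(unclass(tab))
  reps <- rarefy_replicates(tab, depth = 100, n_tables = 3, seed = 2)
  single <- alpha_diversity(reps[[1]], tr)
  expect_named(single, c("sample_id", "chao1", "faith_pd"))
  avg <- alpha_diversity(reps, tr)
  expect_equal(avg$n_replicates, rep(3, 4))
  manual <- rowMeans(vapply(reps, function(r) alpha_diversity(r, tr)$chao1,
                            numeric(4)))
  expect_equal(avg$chao1[match(single$sample_id, avg$sample_id)],
               unname(manual))
})

test_that("core OTU rules implement abundance and occurrence thresholds", {
  # 10 samples at one site; otu1 in 8/10 at ~0.5%; otu2 in 7/10; otu3 in
  # 10/10 at ~0.05%
  n <- 10
  base <- matrix(0L, n, 4,
                 dimnames = list(sprintf("s%02d", 1:n),
                                 c("otu1", "otu2", "otu3", "fill")))
  base[1:8, "otu1"] <- 10L
  base[1:7, "otu2"] <- 10L
  base[, "otu3"] <- 1L
  base[, "fill"] <- 2000L - rowSums(base)
  tab <- otu_table(base)
  meta <- tibble::tibble(sample_id = rownames(base), host_species = "A",
                         site = "site1", latitude = 30, longitude = 100,
                         mat = 15, map_mm = 900, haplotype = NA)
  core <- local_core_otus(tab, meta, "site1")
  expect_true("otu1" %in% core)   # 8/10 occurrence, 0.4% mean abundance
  expect_false("otu2" %in% core)  # 7/10 occurrence fails >= ceil(0.8 * 10)
  expect_false("otu3" %in% core)  # abundance 0.05% fails site-mean filter
  expect_true("otu3" %in% local_core_otus(tab, meta, "site1",
                                          min_rel_abundance = 1e-4))
  expect_error(local_core_otus(tab, meta, "nowhere"), "nowhere")

  # anti-monotonicity: raising either threshold can only shrink the set
  set.seed(21)
  tab2 <- random_table(10, 20, lambda = 3)
  meta2 <- meta
  meta2$sample_id <- rownames(tab2)
  loose <- local_core_otus(tab2, meta2, "site1",
                           min_rel_abundance = 0.001, min_occurrence = 0.5)
  tight_ab <- local_core_otus(tab2, meta2, "site1",
                              min_rel_abundance = 0.05, min_occurrence = 0.5)
  tight_oc <- local_core_otus(tab2, meta2, "site1",
                              min_rel_abundance = 0.001, min_occurrence = 0.9)
  expect_true(all(tight_ab %in% loose))
  expect_true(all(tight_oc %in% loose))
})

test_that("regional core OTUs intersect local sets and report coverage", {
  # 2 sites x 4 samples; otuA core everywhere, otuB core at site1 only;
  # filler reads alternate between two OTUs so neither passes occurrence
  m <- matrix(0L, 8, 4, dimnames = list(sprintf("s%d", 1:8),
                                        c("otuA", "otuB", "fillA", "fillB")))
  m[, "otuA"] <- 50L
  m[1:4, "otuB"] <- 50L
  m[c(1, 3, 5, 7), "fillA"] <- 1000L - rowSums(m)[c(1, 3, 5, 7)]
  m[c(2, 4, 6, 8), "fillB"] <- 1000L - rowSums(m)[c(2, 4, 6, 8)]
  tab <- otu_table(m)
  meta <- tibble::tibble(sample_id = rownames(m), host_species = "A",
                         site = rep(c("site1", "site2"), each = 4),
                         latitude = 30, longitude = 100, mat = 15,
                         map_mm = 900, haplotype = NA)
  reg <- regional_core_otus(tab, meta)
  expect_equal(reg$core_otus[[1]], "otuA")
  expect_equal(reg$n_core, 1L)
  # coverage = mean per-sample relative abundance of otuA = 50/1000
  expect_equal(reg$core_abundance_fraction, 0.05)
})
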