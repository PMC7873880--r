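# Synthetic panel generator: determinism, inbreeding, LD decay behaviour,
# filtering semantics, subsampling, and the r2 primitive.

test_that("generation is deterministic and rejects degenerate arguments", {
  prof <- ld_profile("maize-like")
  G1 <- generate_genotypes(30, 2, 25, prof, seed = 7)
  G2 <- generate_genotypes(30, 2, 25, prof, seed = 7)
  expect_identical(G1$dosages, G2$dosages)
  expect_identical(G1$map, G2$map)
  G3 <- generate_genotypes(30, 2, 25, prof, seed = 8)
  expect_false(identical(G1$dosages, G3$dosages))
  expect_error(generate_genotypes(0, 2, 25, prof, seed = 1), "n_individuals")
  expect_error(generate_genotypes(30, 2, 0, prof, seed = 1), "markers_per_chromosome")
  expect_error(generate_genotypes(30, 2, 25, prof), "seed")
})

test_that("fully selfed lines are homozygous; partial inbreeding is not", {
  G <- generate_genotypes(40, 2, 30, ld_profile("maize-like"), inbreeding = 1, seed = 3)
  expect_true(all(G$dosages %in% c(0L, 2L)))
  G05 <- generate_genotypes(200, 2, 30, ld_profile("maize-like"), inbreeding = 0.25, seed = 3)
  expect_true(any(G05$dosages == 1L))
})

test_that("marker maps have strictly increasing positions and valid dosages", {
  G <- generate_genotypes(25, 3, 40, ld_profile("soybean-like"), seed = 11)
  for (ch in unique(G$map$chr)) {
    expect_true(all(diff(G$map$pos[G$map$chr == ch]) > 0))
  }
  expect_identical(sort(unique(as.vector(G$dosages))), c(0L, 2L))
})

test_that("mean r2 near the target decay distance brackets 0.10 for both presets", {
  # frozen expectation from the calibration experiment: mean r2 within
  # [0.05, 0.20] in the bin around the preset's target distance
  est <- function(profile, lo, hi, seeds) {
    mean(vapply(seeds, function(s) {
      G <- generate_genotypes(250, 4, 120, ld_profile(profile), seed = s)
      ld_decay_curve(G, distance_bins = c(lo, hi), max_pairs = 8000, seed = s)$mean_r2
    }, numeric(1)))
  }
  maize <- est("maize-like", 8e3, 1.2e4, 1:6)
  soy <- est("soybean-like", 8e5, 1.2e6, 1:6)
  expect_gt(maize, 0.05); expect_lt(maize, 0.20)
  expect_gt(soy, 0.05); expect_lt(soy, 0.20)
})

test_that("LD decays monotonically with distance for the presets", {
  sp <- vapply(1:20, function(s) {
    G <- generate_genotypes(120, 3, 60, ld_profile("maize-like"), seed = 100 + s)
    d <- ld_decay_curve(G, distance_bins = seq(0, 8e4, by = 1e4),
                        max_pairs = 6000, seed = s)
    ok <- !is.na(d$mean_r2)
    stats::cor(d$midpoint[ok], d$mean_r2[ok], method = "spearman")
  }, numeric(1))
  expect_lt(mean(sp), -0.5)
  expect_gte(mean(sp < 0), 0.9)
})

test_that("soybean-like LD exceeds maize-like LD at 50 kb separation", {
  diffs <- vapply(1:20, function(s) {
    r2_at_50kb <- function(profile) {
      G <- generate_genotypes(100, 2, 50, ld_profile(profile), seed = 200 + s)
      ld_decay_curve(G, distance_bins = c(3e4, 7e4), max_pairs = 4000, seed = s)$mean_r2
    }
    r2_at_50kb("soybean-like") - r2_at_50kb("maize-like")
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gte(mean(diffs > 0), 0.95)
  expect_lt(stats::t.test(diffs, alternative = "greater")$p.value, 0.01)
})

test_that("randomly permuting marker order flattens the decay curve", {
  G <- make_test_panel(n = 150, n_chr = 2, m_chr = 80, seed = 31)
  set.seed(5)
  shuffle <- sample(ncol(G$dosages))
  Gp <- panel_from_matrix(G$dosages[, shuffle],
                          chr = G$map$chr, pos = G$map$pos)
  d <- ld_decay_curve(Gp, distance_bins = seq(0, 3e5, length.out = 7),
                      max_pairs = 8000, seed = 1)
  ok <- !is.na(d$mean_r2) & d$n_pairs > 50
  global <- sum(d$mean_r2[ok] * d$n_pairs[ok]) / sum(d$n_pairs[ok])
  # no bin mean departs from the global mean beyond sampling error
  expect_true(all(abs(d$mean_r2[ok] - global) < 4 * global / sqrt(d$n_pairs[ok]) + 0.02))
})

test_that("decay-curve bin means equal exhaustive all-pairs computation on a small fixture", {
  X <- matrix(c(0, 0, 2, 2, 2, 0,
                0, 2, 2, 0, 2, 0,
                2, 2, 0, 0, 0, 2,
                0, 0, 2, 2, 0, 2), nrow = 6)
  G <- panel_from_matrix(X, pos = c(1000L, 3000L, 8000L, 20000L))
  bins <- c(0, 5000, 25000)
  d <- ld_decay_curve(G, distance_bins = bins, max_pairs = 100, seed = 1)
  pairs <- utils::combn(4, 2)
  r2 <- apply(pairs, 2, function(ij) pairwise_r2(X[, ij[1]], X[, ij[2]]))
  dist <- apply(pairs, 2, function(ij) abs(G$map$pos[ij[2]] - G$map$pos[ij[1]]))
  for (b in 1:2) {
    inb <- dist > bins[b] & dist <= bins[b + 1] | (b == 1 & dist == 0)
    expect_equal(d$mean_r2[b], mean(r2[inb]))
    expect_equal(d$n_pairs[b], sum(inb))
  }
})

test_that("pairwise_r2 matches a direct Pearson computation and rejects constants", {
  expect_equal(pairwise_r2(c(0, 1, 2, 2, 0), c(0, 1, 2, 2, 0)), 1.0)
  expect_equal(pairwise_r2(c(0, 0, 2, 2), c(2, 2, 0, 0)), 1.0)
  x <- c(0, 1, 2, 2, 0); y <- c(0, 0, 2, 1, 1)
  expect_equal(pairwise_r2(x, y), stats::cor(x, y)^2)
  expect_error(pairwise_r2(c(1, 1, 1, 1), c(0, 1, 2, 0)), "monomorphic")
  expect_error(pairwise_r2(c(0, 1), c(0, 1, 2)), "equal length")
})

test_that("filter_markers enforces the minor-allele-count threshold", {
  # 10 individuals; marker 2 has minor allele count 4 (< 5), marker 1 has 5
  X <- cbind(c(2, 2, 0, 0, 0, 0, 0, 0, 1, 0),
             c(2, 2, 0, 0, 0, 0, 0, 0, 0, 0),
             c(2, 2, 2, 2, 2, 0, 0, 0, 0, 0))
  G <- panel_from_matrix(X)
  Gf <- filter_markers(G, min_mac = 5, prune_r2 = 0.99)
  expect_identical(Gf$map$id, c("m1", "m3"))
})

test_that("an exactly duplicated marker is pruned at r2 = 0.9", {
  G <- make_test_panel(n = 40, n_chr = 1, m_chr = 20, seed = 12)
  X <- cbind(G$dosages, G$dosages[, 3])
  pos <- c(G$map$pos, G$map$pos[nrow(G$map)] + 500L)
  Gd <- panel_from_matrix(X, pos = pos)
  Gf <- filter_markers(Gd, min_mac = 1)
  expect_lt(ncol(Gf$dosages), ncol(X))
  # surviving panel has no window pair at r2 >= 0.9 involving the duplicate
  expect_false(paste0("m", ncol(X)) %in% Gf$map$id && "m3" %in% Gf$map$id)
})

test_that("pruning equals the brute-force oracle on small panels", {
  for (s in 1:5) {
    G <- make_test_panel(n = 50, n_chr = 2, m_chr = 20, seed = 500 + s)
    X <- G$dosages
    for (r2thr in c(0.5, 0.9)) {
      got <- filter_markers(G, min_mac = 1, prune_r2 = r2thr,
                            prune_window = 6, prune_step = 2)
      want <- brute_force_prune(X, G$map, r2thr, window = 6, step = 2)
      expect_identical(got$map$id, G$map$id[want])
    }
  }
})

test_that("six-marker hand fixture is pruned exactly as the windowed greedy rule dictates", {
  set.seed(9)
  base <- rbinom(30, 2, 0.4)
  X <- cbind(base,
             ifelse(runif(30) < 0.9, base, 2 - base),   # high LD with m1
             rbinom(30, 2, 0.3),
             base,                                       # duplicate of m1
             rbinom(30, 2, 0.45),
             rbinom(30, 2, 0.2))
  G <- panel_from_matrix(X)
  got <- filter_markers(G, min_mac = 1, prune_r2 = 0.8,
                        prune_window = 6, prune_step = 3)
  want <- brute_force_prune(X, G$map, 0.8, window = 6, step = 3)
  expect_identical(got$map$id, G$map$id[want])
})

test_that("all-filtered panels raise an explicit error", {
  X <- cbind(c(0, 0, 0, 2), c(2, 2, 2, 2))
  expect_error(filter_markers(panel_from_matrix(X), min_mac = 3),
               "all markers filtered")
})

test_that("nested subsamples form a containment chain with markers unchanged", {
  G <- make_test_panel(n = 60, n_chr = 2, m_chr = 15, seed = 21)
  expect_identical(nested_subsample(G, 60, seed = 1)[[1]]$ids, G$ids)
  subs <- nested_subsample(G, c(40, 10, 5), seed = 2)
  expect_true(all(subs[[2]]$ids %in% subs[[1]]$ids))
  expect_true(all(subs[[3]]$ids %in% subs[[2]]$ids))
  expect_identical(subs[[3]]$map, G$map)
  # exhaustive check of the 10 -> 5 containment across seeds
  for (s in 1:10) {
    pair <- nested_subsample(G, c(10, 5), seed = s)
    expect_true(all(pair[[2]]$ids %in% pair[[1]]$ids))
  }
  expect_error(nested_subsample(G, c(100, 10), seed = 1), "exceeds")
  expect_error(nested_subsample(G, c(10, 20), seed = 1), "decreasing")
})
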