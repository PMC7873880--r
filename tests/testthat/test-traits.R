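# QTN selection under the three architectures and single-QTN trait
# simulation: MAF targeting, LD bounds, flanking constraints, exact
# heritability construction.

test_that("maf_candidates returns exactly the markers inside the band", {
  # MAFs over 10 individuals: 0.05, 0.30, 0.41 achievable via dosage counts
  X <- cbind(c(2, rep(0, 9)),                    # maf 0.10
             c(2, 2, 2, rep(0, 7)),              # maf 0.30
             c(2, 2, 2, 2, 1, rep(0, 5)),        # maf 0.45
             c(1, rep(0, 9)),                    # maf 0.05
             c(2, 2, 2, 2, rep(0, 6)))           # maf 0.40
  G <- panel_from_matrix(X)
  expect_setequal(maf_candidates(G, 0.05, tol = 0.02), c(4))
  expect_setequal(maf_candidates(G, 0.05, tol = 0.05), c(1, 4))
  expect_setequal(maf_candidates(G, 0.40, tol = 0.05), c(3, 5))
  # exact match is always included
  expect_true(5 %in% maf_candidates(G, 0.40, tol = 0.02))
  # widening fallback is logged and terminates
  expect_message(hit <- maf_candidates(G, 0.20, tol = 0.001), "widening")
  expect_true(length(hit) >= 1)
})

test_that("independent QTNs land on different chromosomes with incidental r2", {
  G <- make_test_panel(n = 80, n_chr = 3, m_chr = 40, seed = 61)
  set.seed(1)
  for (i in 1:25) {
    a <- select_qtns_independent(G, 0.40, tol = 0.1)
    expect_true(a$qtn_trait1$chr != a$qtn_trait2$chr)
  }
})

test_that("a forced single candidate per chromosome is returned deterministically", {
  base <- c(2, 2, 2, 2, rep(0, 6))
  filler <- matrix(rep(c(2, rep(0, 9)), 4), nrow = 10)  # maf 0.10 fillers
  X <- cbind(base, filler[, 1:2], base[c(2:10, 1)], filler[, 3:4])
  G <- panel_from_matrix(X, chr = c(1L, 1L, 1L, 2L, 2L, 2L))
  set.seed(2)
  a <- select_qtns_independent(G, 0.40, tol = 0.02)
  expect_setequal(c(a$qtn_trait1$index, a$qtn_trait2$index), c(1, 4))
})

test_that("direct LD control never exceeds the bound and maximizes r2 under it", {
  G <- make_test_panel(n = 100, n_chr = 2, m_chr = 60, seed = 62)
  set.seed(3)
  for (r2max in c(0.98, 0.25)) {
    draws <- replicate(20, {
      a <- select_qtns_ld_direct(G, 0.40, r2max, tol = 0.1)
      expect_identical(a$qtn_trait1$chr, a$qtn_trait2$chr)
      a
    }, simplify = FALSE)
    r2s <- vapply(draws, function(a) a$realized_r2, numeric(1))
    expect_true(all(r2s <= r2max))
    # verify the argmax-under-bound rule against exhaustive search
    for (a in draws[1:5]) {
      i1 <- a$qtn_trait1$index
      same <- which(G$map$chr == G$map$chr[i1])
      pool <- setdiff(same[abs(same - i1) <= 100], i1)
      r2 <- vapply(pool, function(j)
        tryCatch(pairwise_r2(G$dosages[, i1], G$dosages[, j]),
                 error = function(e) NA_real_), numeric(1))
      best <- max(r2[!is.na(r2) & r2 <= r2max])
      expect_equal(a$realized_r2, best)
    }
  }
})

test_that("indirect LD control yields flanking QTNs bounded against the middle marker", {
  G <- make_test_panel(n = 100, n_chr = 2, m_chr = 60, seed = 63)
  set.seed(4)
  for (i in 1:15) {
    a <- select_qtns_ld_indirect(G, 0.40, 0.98, tol = 0.1)
    m <- a$middle_marker
    expect_lt(a$qtn_trait1$pos, m$pos)
    expect_gt(a$qtn_trait2$pos, m$pos)
    r2_1m <- pairwise_r2(G$dosages[, a$qtn_trait1$index], G$dosages[, m$index])
    r2_2m <- pairwise_r2(G$dosages[, a$qtn_trait2$index], G$dosages[, m$index])
    expect_lte(r2_1m, 0.98)
    expect_lte(r2_2m, 0.98)
  }
})

test_that("indirect flank choices equal exhaustive search on a small fixture", {
  G <- make_test_panel(n = 80, n_chr = 1, m_chr = 30, seed = 64)
  set.seed(5)
  a <- select_qtns_ld_indirect(G, 0.40, 0.5, tol = 0.1)
  m <- a$middle_marker$index
  for (side in c("up", "down")) {
    pool <- if (side == "up") which(G$map$pos < G$map$pos[m]) else which(G$map$pos > G$map$pos[m])
    pool <- pool[abs(pool - m) <= 100]
    r2 <- vapply(pool, function(j)
      tryCatch(pairwise_r2(G$dosages[, m], G$dosages[, j]),
               error = function(e) NA_real_), numeric(1))
    ok <- !is.na(r2) & r2 <= 0.5
    best <- max(r2[ok])
    got <- if (side == "up") a$qtn_trait1$index else a$qtn_trait2$index
    expect_equal(pairwise_r2(G$dosages[, m], G$dosages[, got]), best)
  }
})

test_that("pleiotropic selection uses one marker for both traits at the target MAF", {
  G <- make_test_panel(n = 80, n_chr = 2, m_chr = 40, seed = 65)
  set.seed(6)
  mafs <- replicate(20, {
    a <- select_qtn_pleiotropic(G, 0.40, tol = 0.05)
    expect_identical(a$qtn_trait1$index, a$qtn_trait2$index)
    a$realized_maf_1
  })
  expect_true(all(abs(mafs - 0.40) <= 0.05))
  # single-candidate fixture forces the outcome
  X <- cbind(c(2, 2, 2, 2, rep(0, 6)), c(2, rep(0, 9)), c(1, rep(0, 9)))
  Gs <- panel_from_matrix(X)
  expect_identical(select_qtn_pleiotropic(Gs, 0.40, tol = 0.02)$qtn_trait1$index, 1L)
})

test_that("simulate_trait hits the inputted heritability exactly by construction", {
  x <- c(0, 0, 2, 2)
  set.seed(7)
  sim <- simulate_trait(x, additive_effect = 0.1, h2 = 0.5)
  expect_equal(sim$residual_sd, sqrt(stats::var(c(0, 0, 0.2, 0.2))))
  expect_equal(stats::var(sim$g) / (stats::var(sim$g) + sim$residual_sd^2), 0.5)
  # h2 = 1: no noise
  sim1 <- simulate_trait(x, 0.1, h2 = 1)
  expect_identical(sim1$y, sim1$g)
  expect_identical(sim1$residual_sd, 0)
  # regression of g on x returns the additive effect exactly
  xl <- rbinom(200, 2, 0.4)
  siml <- simulate_trait(xl, 0.1, 0.3)
  expect_equal(unname(stats::coef(stats::lm(siml$g ~ xl))[2]), 0.1)
  expect_error(simulate_trait(rep(2, 10), 0.1, 0.5), "non-constant")
  expect_error(simulate_trait(x, 0.1, 0), "h2")
})

test_that("pleiotropic trait pairs correlate at sqrt(h2_1 h2_2)", {
  set.seed(8)
  x <- rbinom(5000, 2, 0.4)
  s1 <- simulate_trait(x, 0.1, 0.8)
  s2 <- simulate_trait(x, 0.1, 0.8)
  expect_equal(stats::cor(s1$y, s2$y), 0.8, tolerance = 0.03)
  s3 <- simulate_trait(x, 0.1, 0.3)
  expect_equal(stats::cor(s1$y, s3$y), sqrt(0.8 * 0.3), tolerance = 0.04)
})

test_that("simulate_replicate removes QTNs, keeps the middle marker, and varies QTNs", {
  G <- make_test_panel(n = 80, n_chr = 3, m_chr = 40, seed = 66)
  scen <- structure(list(architecture = "ld_indirect", ld_max = 0.98,
                         maf_target = 0.40, h2_pair = c(0.3, 0.8),
                         additive_effect = 0.10, n_individuals = 80,
                         species_profile = "maize-like",
                         detection_window_bp = 1e4, fdr_level = 0.10,
                         n_replicates = 5, id = "t", seed = 99),
                    class = "scenario_config")
  reps <- lapply(1:4, function(r) simulate_replicate(scen, G, r))
  for (r in reps) {
    ids <- r$gwas_panel$map$id
    expect_false(r$assignment$qtn_trait1$id %in% ids)
    expect_false(r$assignment$qtn_trait2$id %in% ids)
    expect_true(r$assignment$middle_marker$id %in% ids)
    expect_equal(stats::var(r$traits$g1) /
                   (stats::var(r$traits$g1) + r$traits$residual_sd_1^2), 0.3)
  }
  # re-running the same replicate reproduces it; different replicates differ
  again <- simulate_replicate(scen, G, 2)
  expect_identical(again$assignment$qtn_trait1$id, reps[[2]]$assignment$qtn_trait1$id)
  expect_identical(again$traits$y1, reps[[2]]$traits$y1)
  qtn_ids <- vapply(reps, function(r) r$assignment$qtn_trait1$id, character(1))
  expect_gt(length(unique(qtn_ids)), 1)
})
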