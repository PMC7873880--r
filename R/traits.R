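# QTN selection under the three genetic architectures, and single-QTN
# additive trait simulation at specified narrow-sense heritabilities.
#
# Architectures:
#   independent  - one QTN per trait, forced onto different chromosomes
#   ld_direct    - QTN2 is the marker in maximum LD with QTN1 subject to
#                  r2 <= ld_max (the realized QTN-pair LD is bounded directly)
#   ld_indirect  - a "middle" marker is chosen by MAF; the two QTNs flank it,
#                  each in maximum LD with the middle marker subject to the
#                  bound (QTN-pair LD is only indirectly constrained)
#   pleiotropic  - a single QTN controls both traits

QTN_SEARCH_SPAN <- 100L   # marker-index half-window for LD-pair search
QTN_MAX_RETRIES <- 50L

#' Markers whose MAF is close to a target
#'
#' Returns indices of markers with `|MAF - maf_target| <= tol`.  If no marker
#' qualifies, the tolerance is doubled (with a message) until the set is
#' non-empty, mirroring a simulator that must always be able to pick a QTN
#' "based on MAF".
#'
#' @param G A `genotype_panel` (already filtered).
#' @param maf_target Target minor allele frequency in (0, 0.5].
#' @param tol Initial half-width of the acceptance band.
#' @return Integer vector of marker indices (columns of `G$dosages`).
#' @export
maf_candidates <- function(G, maf_target, tol = 0.02) {
  validate_panel(G)
  maf_target <- check_fraction(maf_target, "maf_target", 0, 0.5, open_lo = TRUE)
  mafs <- marker_maf(G)
  if (all(mafs == 0 | is.na(mafs))) stop_invalid("panel contains only monomorphic markers")
  poly <- which(mafs > 0)
  repeat {
    hit <- unname(poly[abs(mafs[poly] - maf_target) <= tol])
    if (length(hit)) return(hit)
    tol <- 2 * tol
    message(sprintf("no markers within tolerance of MAF %.3f; widening to +/- %.3f",
                    maf_target, tol))
  }
}

qtn_slot <- function(G, idx) {
  list(index = idx, id = G$map$id[idx], chr = G$map$chr[idx],
       pos = G$map$pos[idx],
       maf = unname(marker_maf(G$dosages[, idx, drop = FALSE])))
}

new_qtn_assignment <- function(architecture, G, i1, i2, middle = NULL, realized_r2 = NA_real_) {
  structure(list(
    architecture = architecture,
    qtn_trait1 = qtn_slot(G, i1),
    qtn_trait2 = qtn_slot(G, i2),
    middle_marker = if (is.null(middle)) NULL else qtn_slot(G, middle),
    realized_maf_1 = unname(marker_maf(G$dosages[, i1, drop = FALSE])),
    realized_maf_2 = unname(marker_maf(G$dosages[, i2, drop = FALSE])),
    realized_r2 = realized_r2
  ), class = "qtn_assignment")
}

#' @export
print.qtn_assignment <- function(x, ...) {
  cat(sprintf("QTN assignment (%s)\n", x$architecture))
  cat(sprintf("  trait 1: %s (chr %s, pos %d, MAF %.3f)\n", x$qtn_trait1$id,
              x$qtn_trait1$chr, x$qtn_trait1$pos, x$realized_maf_1))
  cat(sprintf("  trait 2: %s (chr %s, pos %d, MAF %.3f)\n", x$qtn_trait2$id,
              x$qtn_trait2$chr, x$qtn_trait2$pos, x$realized_maf_2))
  if (!is.null(x$middle_marker))
    cat(sprintf("  middle marker: %s (pos %d)\n", x$middle_marker$id, x$middle_marker$pos))
  if (!is.na(x$realized_r2)) cat(sprintf("  realized QTN-pair r2: %.4f\n", x$realized_r2))
  invisible(x)
}

# r2 between marker `i` and each of `others`, NA where undefined.
r2_against <- function(G, i, others) {
  if (!length(others)) return(numeric(0))
  pairwise_r2_many(G$dosages, rep.int(i, length(others)), others)
}

#' Select two independent QTNs on different chromosomes
#'
#' Both QTNs are drawn uniformly from the MAF candidate set, redrawing until
#' they land on different chromosomes.  Their incidental interchromosomal r2
#' is recorded: it is not constrained, and occasionally exceeds what direct
#' LD control at a low threshold would allow.
#'
#' @inheritParams maf_candidates
#' @return A `qtn_assignment`.  Uses the current RNG stream.
#' @export
select_qtns_independent <- function(G, maf_target, tol = 0.02) {
  cand <- maf_candidates(G, maf_target, tol)
  if (length(unique(G$map$chr[cand])) < 2)
    stop_invalid("all MAF candidates lie on one chromosome; cannot select independent QTNs")
  for (try in seq_len(1000L)) {
    pick <- if (length(cand) == 1L) c(cand, cand) else sample(cand, 2L, replace = TRUE)
    if (G$map$chr[pick[1]] != G$map$chr[pick[2]]) {
      r2 <- tryCatch(pairwise_r2(G$dosages[, pick[1]], G$dosages[, pick[2]]),
                     error = function(e) NA_real_)
      return(new_qtn_assignment("independent", G, pick[1], pick[2], realized_r2 = r2))
    }
  }
  stop_invalid("failed to draw QTNs on different chromosomes")
}

# Best marker in LD with `anchor` subject to r2 <= r2_max, searching `pool`;
# ties broken by smaller physical distance, then lower index.
argmax_r2_under_bound <- function(G, anchor, pool, r2_max) {
  r2 <- r2_against(G, anchor, pool)
  ok <- !is.na(r2) & r2 <= r2_max
  if (!any(ok)) return(NULL)
  pool <- pool[ok]; r2 <- r2[ok]
  best <- max(r2)
  tie <- which(r2 >= best - 1e-12)
  if (length(tie) > 1L) {
    d <- abs(G$map$pos[pool[tie]] - G$map$pos[anchor])
    tie <- tie[order(d, pool[tie])]
  }
  list(index = pool[tie[1]], r2 = r2[tie[1]])
}

#' Select a linked QTN pair with directly controlled LD
#'
#' QTN1 is drawn from the MAF candidate set; QTN2 is the marker on the same
#' chromosome (within +/- 100 marker indices) with the highest r2 to QTN1
#' subject to `r2 <= r2_max`.  The argmax-under-bound rule makes a high
#' threshold a genuinely high-LD scenario while guaranteeing the bound is
#' never exceeded.
#'
#' @inheritParams maf_candidates
#' @param r2_max Upper bound on the realized QTN-pair r2 (e.g. 0.01 or 0.98).
#' @return A `qtn_assignment` with `realized_r2 <= r2_max`.
#' @export
select_qtns_ld_direct <- function(G, maf_target, r2_max, tol = 0.02) {
  r2_max <- check_fraction(r2_max, "r2_max", 0, 1, open_lo = TRUE, open_hi = TRUE)
  cand <- maf_candidates(G, maf_target, tol)
  for (try in seq_len(QTN_MAX_RETRIES)) {
    i1 <- if (length(cand) == 1L) cand else sample(cand, 1L)
    same <- which(G$map$chr == G$map$chr[i1])
    pool <- setdiff(same[abs(same - i1) <= QTN_SEARCH_SPAN], i1)
    hit <- argmax_r2_under_bound(G, i1, pool, r2_max)
    if (!is.null(hit))
      return(new_qtn_assignment("ld_direct", G, i1, hit$index, realized_r2 = hit$r2))
  }
  stop_invalid("no same-chromosome marker satisfies r2 <= %g near any sampled QTN", r2_max)
}

#' Select a linked QTN pair with indirectly controlled LD
#'
#' A middle marker is drawn from the MAF candidate set; QTN1 is the
#' argmax-under-bound marker strictly upstream of it and QTN2 strictly
#' downstream (same chromosome, +/- 100 marker indices).  The bound applies
#' to each QTN's LD with the middle marker; the realized QTN-pair r2 is
#' recorded but not directly constrained.  The middle marker is *retained*
#' in the GWAS marker set (it is not a QTN).
#'
#' @inheritParams select_qtns_ld_direct
#' @return A `qtn_assignment` with a `middle_marker` slot.
#' @export
select_qtns_ld_indirect <- function(G, maf_target, r2_max, tol = 0.02) {
  r2_max <- check_fraction(r2_max, "r2_max", 0, 1, open_lo = TRUE, open_hi = TRUE)
  cand <- maf_candidates(G, maf_target, tol)
  for (try in seq_len(QTN_MAX_RETRIES)) {
    m <- if (length(cand) == 1L) cand else sample(cand, 1L)
    same <- which(G$map$chr == G$map$chr[m])
    near <- same[abs(same - m) <= QTN_SEARCH_SPAN]
    up <- near[G$map$pos[near] < G$map$pos[m]]
    down <- near[G$map$pos[near] > G$map$pos[m]]
    h1 <- argmax_r2_under_bound(G, m, up, r2_max)
    h2 <- argmax_r2_under_bound(G, m, down, r2_max)
    if (!is.null(h1) && !is.null(h2)) {
      r2 <- tryCatch(pairwise_r2(G$dosages[, h1$index], G$dosages[, h2$index]),
                     error = function(e) NA_real_)
      return(new_qtn_assignment("ld_indirect", G, h1$index, h2$index,
                                middle = m, realized_r2 = r2))
    }
  }
  stop_invalid("no flanking markers satisfy r2 <= %g around any sampled middle marker", r2_max)
}

#' Select a single pleiotropic QTN
#'
#' One marker from the MAF candidate set controls both traits.
#'
#' @inheritParams maf_candidates
#' @return A `qtn_assignment` with `qtn_trait1 == qtn_trait2`.
#' @export
select_qtn_pleiotropic <- function(G, maf_target, tol = 0.02) {
  cand <- maf_candidates(G, maf_target, tol)
  i <- if (length(cand) == 1L) cand else sample(cand, 1L)
  new_qtn_assignment("pleiotropic", G, i, i)
}

#' Simulate one additive single-QTN trait
#'
#' The genetic value is `g = additive_effect * x` (dosage `x` of the causal
#' allele); residual noise is iid Gaussian with standard deviation chosen so
#' that `Var(g) / (Var(g) + sd^2)` equals the inputted heritability exactly:
#' `sd = sqrt(Var(g) * (1 - h2) / h2)` with `Var` the sample variance.
#'
#' @param x Non-constant QTN dosage vector.
#' @param additive_effect Allele substitution effect (default 0.10).
#' @param h2 Narrow-sense heritability in (0, 1]; `h2 = 1` gives `y = g`.
#' @return List with phenotype `y`, genetic values `g`, `residual_sd`, and
#'   the inputted `h2`.  Uses the current RNG stream.
#' @examples
#' sim <- simulate_trait(c(0, 0, 1, 2, 2, 1), additive_effect = 0.1, h2 = 0.5)
#' var(sim$g) / (var(sim$g) + sim$residual_sd^2)  # = 0.5 by construction
#' @export
simulate_trait <- function(x, additive_effect = 0.10, h2) {
  if (anyNA(x) || stats::var(x) == 0)
    stop_invalid("QTN dosage vector must be complete and non-constant")
  h2 <- check_fraction(h2, "h2", 0, 1, open_lo = TRUE)
  g <- additive_effect * x
  residual_sd <- if (h2 == 1) 0 else sqrt(stats::var(g) * (1 - h2) / h2)
  y <- g + stats::rnorm(length(x), 0, residual_sd)
  list(y = y, g = g, residual_sd = residual_sd, h2 = h2)
}

#' Simulate one replicate of a scenario: QTNs, trait pair, GWAS marker set
#'
#' Draws a fresh QTN assignment for the replicate (a different pair of QTNs
#' per replicate), simulates the two traits with the scenario's heritability
#' pair and common additive effect, and returns the marker panel with the
#' QTN marker(s) removed — the causal mutations are absent from the scanned
#' marker set, as in real data.  The indirect architecture's middle marker is
#' retained.  Residuals of the two traits are independent.
#'
#' Each replicate runs in its own seeded substream derived from
#' `(scenario$seed, replicate_index)`, so any replicate is reproducible in
#' isolation.
#'
#' @param scenario A `scenario_config` (see [enumerate_scenarios()]).
#' @param G The filtered `genotype_panel` for the scenario's sample size.
#' @param replicate_index 1-based replicate number.
#' @return List with `traits` (y1, y2, g1, g2, residual sds, inputted h2),
#'   `assignment` (the `qtn_assignment`), and `gwas_panel`.
#' @export
simulate_replicate <- function(scenario, G, replicate_index) {
  replicate_index <- check_count(replicate_index, "replicate_index")
  seed <- mix_seed(scenario$seed, "replicate", replicate_index)
  with_seed(seed, {
    asg <- switch(scenario$architecture,
      independent = select_qtns_independent(G, scenario$maf_target),
      ld_direct = select_qtns_ld_direct(G, scenario$maf_target, scenario$ld_max),
      ld_indirect = select_qtns_ld_indirect(G, scenario$maf_target, scenario$ld_max),
      pleiotropic = select_qtn_pleiotropic(G, scenario$maf_target),
      stop_invalid("unknown architecture '%s'", scenario$architecture)
    )
    x1 <- G$dosages[, asg$qtn_trait1$index]
    x2 <- G$dosages[, asg$qtn_trait2$index]
    t1 <- simulate_trait(x1, scenario$additive_effect, scenario$h2_pair[1])
    t2 <- simulate_trait(x2, scenario$additive_effect, scenario$h2_pair[2])
    drop <- unique(c(asg$qtn_trait1$index, asg$qtn_trait2$index))
    keep <- setdiff(seq_len(ncol(G$dosages)), drop)
    gwas_panel <- new_genotype_panel(G$dosages[, keep, drop = FALSE],
                                     G$map[keep, , drop = FALSE], G$ids)
    list(
      traits = list(y1 = t1$y, y2 = t2$y, g1 = t1$g, g2 = t2$g,
                    h2_in = scenario$h2_pair,
                    residual_sd_1 = t1$residual_sd, residual_sd_2 = t2$residual_sd),
      assignment = asg,
      gwas_panel = gwas_panel
    )
  })
}
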