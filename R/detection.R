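# From scan p-values to detection statistics: genome-wide Benjamini-Hochberg
# FDR control per scan, window-based QTN matching, and the four per-scenario
# percentages (trait-1, trait-2 and simultaneous detection rates, plus the
# error rate counting significant markers outside every QTN window).

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment (sort ascending, `q_(i) = min_{j>=i} m p_(j)/j`,
#' capped at 1, returned in input order), applied genome-wide within one scan.
#' Delegates to [stats::p.adjust()].
#'
#' @param pvals Vector of p-values in (0, 1]; rows with undefined p-values
#'   must be excluded before adjustment.
#' @return Adjusted p-values in the original order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  if (anyNA(pvals) || any(pvals <= 0 | pvals > 1))
    stop_invalid("p-values must lie in (0, 1] with no NAs")
  stats::p.adjust(pvals, method = "BH")
}

#' Is a QTN detected by a set of significant markers?
#'
#' A QTN counts as identified if at least one significant marker lies on its
#' chromosome within `window_bp` of its position.  The boundary is inclusive
#' (a marker exactly `window_bp` away detects the QTN).
#'
#' @param significant Data frame with `chr` and `pos` of significant markers
#'   (may have zero rows).
#' @param qtn List or row with `chr` and `pos` of the QTN.
#' @param window_bp Physical half-window in bp (> 0).
#' @return Logical flag.
#' @export
detect_qtn <- function(significant, qtn, window_bp) {
  if (window_bp <= 0) stop_invalid("`window_bp` must be > 0")
  if (is.null(significant) || nrow(significant) == 0) return(FALSE)
  any(significant$chr == qtn$chr & abs(significant$pos - qtn$pos) <= window_bp)
}

significant_markers <- function(scan, fdr_level) {
  ok <- !is.na(scan$p_lrt)
  out <- data.frame(chr = scan$chr[ok], pos = scan$ps[ok])
  out[bh_adjust(scan$p_lrt[ok]) < fdr_level, , drop = FALSE]
}

#' Score one replicate's three scans against its QTN windows
#'
#' BH adjustment is applied genome-wide per scan (the two univariate traits
#' are adjusted separately, never pooled).  The multivariate model detects a
#' QTN if a significant marker falls in that QTN's window (a single window
#' under pleiotropy); the univariate model detects trait t's QTN from trait
#' t's scan.  The error flag records whether any significant marker of a
#' model lies outside *both* QTN windows.
#'
#' @param scans Named list with elements `univariate_trait1`,
#'   `univariate_trait2`, `multivariate` (scan data frames).
#' @param assignment The replicate's `qtn_assignment`.
#' @param window_bp Detection half-window in bp.
#' @param fdr_level FDR level for the BH decision rule (significant iff
#'   adjusted p < `fdr_level`).
#' @return Data frame with one row per model (`univariate`, `multivariate`)
#'   and logical columns `detected_t1`, `detected_t2`, `detected_both`,
#'   `error`.
#' @export
score_replicate <- function(scans, assignment, window_bp, fdr_level) {
  needed <- c("univariate_trait1", "univariate_trait2", "multivariate")
  if (!all(needed %in% names(scans)))
    stop_invalid("`scans` must contain: %s", paste(needed, collapse = ", "))
  fdr_level <- check_fraction(fdr_level, "fdr_level", 0, 1, open_lo = TRUE, open_hi = TRUE)
  q1 <- assignment$qtn_trait1
  q2 <- assignment$qtn_trait2
  sig <- lapply(scans[needed], significant_markers, fdr_level = fdr_level)
  outside_both <- function(s) {
    if (nrow(s) == 0) return(FALSE)
    in1 <- s$chr == q1$chr & abs(s$pos - q1$pos) <= window_bp
    in2 <- s$chr == q2$chr & abs(s$pos - q2$pos) <= window_bp
    any(!in1 & !in2)
  }
  uni_t1 <- detect_qtn(sig$univariate_trait1, q1, window_bp)
  uni_t2 <- detect_qtn(sig$univariate_trait2, q2, window_bp)
  mv_t1 <- detect_qtn(sig$multivariate, q1, window_bp)
  mv_t2 <- detect_qtn(sig$multivariate, q2, window_bp)
  data.frame(
    model = c("univariate", "multivariate"),
    detected_t1 = c(uni_t1, mv_t1),
    detected_t2 = c(uni_t2, mv_t2),
    detected_both = c(uni_t1 && uni_t2, mv_t1 && mv_t2),
    error = c(outside_both(sig$univariate_trait1) || outside_both(sig$univariate_trait2),
              outside_both(sig$multivariate)),
    stringsAsFactors = FALSE
  )
}

#' Summarize replicate outcomes into per-scenario percentages
#'
#' Converts the per-replicate detection flags into the four percentages per
#' model: trait-1, trait-2 and simultaneous detection rates, and the error
#' rate.  For the multivariate model under the independent and linked
#' architectures the detection rates are labelled "spurious pleiotropy
#' detection rate" (the model cannot know the signal comes from distinct
#' causal loci); otherwise "QTN detection rate".
#'
#' @param outcomes Data frame of stacked [score_replicate()] rows.
#' @param scenario The `scenario_config` the outcomes belong to (optional;
#'   used for labels and prepended config columns).
#' @return Data frame, one row per model, with `rate_t1`, `rate_t2`,
#'   `rate_both`, `error_rate` (percent), `n_replicates`, `label`.
#' @export
summarize_scenario <- function(outcomes, scenario = NULL) {
  if (nrow(outcomes) == 0) stop_invalid("need >= 1 replicate outcome")
  arch <- scenario$architecture %||% NA_character_
  out <- do.call(rbind, lapply(split(outcomes, outcomes$model), function(d) {
    data.frame(
      model = d$model[1],
      rate_t1 = 100 * mean(d$detected_t1),
      rate_t2 = 100 * mean(d$detected_t2),
      rate_both = 100 * mean(d$detected_both),
      error_rate = 100 * mean(d$error),
      n_replicates = nrow(d),
      stringsAsFactors = FALSE
    )
  }))
  out$label <- ifelse(
    out$model == "multivariate" & arch %in% c("independent", "ld_direct", "ld_indirect"),
    "spurious pleiotropy detection rate", "QTN detection rate")
  if (!is.null(scenario)) {
    cfg <- data.frame(architecture = scenario$architecture,
                      ld_max = scenario$ld_max %||% NA_real_,
                      maf_target = scenario$maf_target,
                      h2_1 = scenario$h2_pair[1], h2_2 = scenario$h2_pair[2],
                      n_individuals = scenario$n_individuals,
                      species_profile = scenario$species_profile,
                      window_bp = scenario$detection_window_bp,
                      fdr_level = scenario$fdr_level,
                      stringsAsFactors = FALSE)
    out <- cbind(cfg[rep(1, nrow(out)), , drop = FALSE], out)
  }
  rownames(out) <- NULL
  out
}

#' Regional LD around a QTN
#'
#' r2 between the QTN and up to `flank` markers upstream and `flank`
#' downstream on its chromosome (truncated at chromosome ends); monomorphic
#' neighbours are skipped.
#'
#' @param G A `genotype_panel`.
#' @param qtn_index Column index of the QTN marker.
#' @param flank Number of neighbours on each side (default 20).
#' @return Data frame with neighbour `id`, `distance_bp`, signed marker
#'   `offset`, and `r2`.
#' @export
regional_ld <- function(G, qtn_index, flank = 20) {
  validate_panel(G)
  if (stats::var(G$dosages[, qtn_index]) == 0) stop_invalid("QTN marker is monomorphic")
  same <- which(G$map$chr == G$map$chr[qtn_index])
  k <- match(qtn_index, same)
  nb <- same[seq(max(1, k - flank), min(length(same), k + flank))]
  nb <- setdiff(nb, qtn_index)
  r2 <- r2_against(G, qtn_index, nb)
  skipped <- sum(is.na(r2))
  if (skipped) message(sprintf("skipped %d monomorphic neighbour(s)", skipped))
  data.frame(id = G$map$id[nb],
             distance_bp = abs(G$map$pos[nb] - G$map$pos[qtn_index]),
             offset = nb - qtn_index,
             r2 = r2)[!is.na(r2), ]
}
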