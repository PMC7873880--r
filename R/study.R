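# Scenario grid enumeration and end-to-end orchestration.
#
# The full design crosses six architecture variants (independent QTNs;
# directly and indirectly LD-controlled pairs at each of two thresholds; one
# pleiotropic QTN) with two MAF targets, three heritability pairs, three
# sample sizes and two species LD profiles: 6 x 2 x 3 x 3 x 2 = 216
# scenarios, each replicated (default 100 times).  Seeds are derived from
# scenario identity, never execution order, so results are independent of
# the worker count.

#' Construct a study design
#'
#' Defaults reproduce the full factor grid of the simulation study; any
#' field can be overridden for scaled-down runs.  `windows` and
#' `alt_windows` give the per-species detection windows (primary 10 kb
#' maize-like / 1 Mb soybean-like; alternates 1 kb / 10 kb).
#'
#' @param architectures Architecture names.
#' @param ld_thresholds Upper r2 bounds expanded within the LD architectures.
#' @param maf_targets Target QTN minor allele frequencies.
#' @param h2_pairs List of (trait 1, trait 2) heritability pairs.
#' @param sample_sizes Nested subsample sizes (descending or any order).
#' @param species_profiles LD-profile preset names.
#' @param windows,alt_windows Named per-species detection half-windows (bp).
#' @param fdr_levels FDR levels; the first is used in scenario configs.
#' @param n_replicates Replicates per scenario.
#' @param additive_effect Common QTN allele-substitution effect.
#' @param n_chromosomes,markers_per_chromosome Synthetic panel dimensions.
#' @param master_seed Seed from which all scenario substreams derive.
#' @return A `study_design` list.
#' @export
study_design <- function(architectures = c("independent", "ld_direct", "ld_indirect", "pleiotropic"),
                         ld_thresholds = c(0.01, 0.98),
                         maf_targets = c(0.05, 0.40),
                         h2_pairs = list(c(0.30, 0.30), c(0.30, 0.80), c(0.80, 0.80)),
                         sample_sizes = c(500, 1000, 2815),
                         species_profiles = c("maize-like", "soybean-like"),
                         windows = c("maize-like" = 1e4, "soybean-like" = 1e6),
                         alt_windows = c("maize-like" = 1e3, "soybean-like" = 1e4),
                         fdr_levels = c(0.10, 0.05),
                         n_replicates = 100,
                         additive_effect = 0.10,
                         n_chromosomes = 10,
                         markers_per_chromosome = 220,
                         master_seed = 20210101) {
  design <- list(architectures = architectures, ld_thresholds = ld_thresholds,
                 maf_targets = maf_targets, h2_pairs = h2_pairs,
                 sample_sizes = sample_sizes, species_profiles = species_profiles,
                 windows = windows, alt_windows = alt_windows,
                 fdr_levels = fdr_levels, n_replicates = n_replicates,
                 additive_effect = additive_effect,
                 n_chromosomes = n_chromosomes,
                 markers_per_chromosome = markers_per_chromosome,
                 master_seed = master_seed)
  lens <- vapply(design[c("architectures", "ld_thresholds", "maf_targets",
                          "h2_pairs", "sample_sizes", "species_profiles",
                          "fdr_levels")], length, integer(1))
  if (any(lens == 0)) stop_invalid("design lists must be non-empty")
  structure(design, class = "study_design")
}

#' Load a study design from a YAML config
#'
#' Fields present in the file override [study_design()] defaults;
#' `h2_pairs` is a list of two-element lists.
#'
#' @param path YAML file.
#' @return A `study_design`.
#' @export
design_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$h2_pairs)) cfg$h2_pairs <- lapply(cfg$h2_pairs, as.numeric)
  if (!is.null(cfg$windows)) cfg$windows <- unlist(cfg$windows)
  if (!is.null(cfg$alt_windows)) cfg$alt_windows <- unlist(cfg$alt_windows)
  known <- names(formals(study_design))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) stop_invalid("unknown design fields: %s", paste(unknown, collapse = ", "))
  do.call(study_design, cfg)
}

scenario_id <- function(s) {
  sprintf("%s_ld%s_maf%g_h2_%g_%g_n%d_%s",
          s$architecture,
          ifelse(is.na(s$ld_max), "NA", format(s$ld_max)),
          s$maf_target, s$h2_pair[1], s$h2_pair[2], s$n_individuals,
          s$species_profile)
}

#' Enumerate the scenario grid of a study design
#'
#' Full cross of architecture variants (LD thresholds expanded only inside
#' the `ld_direct` and `ld_indirect` architectures), MAF targets,
#' heritability pairs, sample sizes and species profiles, in deterministic
#' lexicographic order over those fields.  The default design yields 216
#' scenarios.
#'
#' @param design A `study_design`.
#' @return List of `scenario_config` objects, each with a reproducible
#'   scenario seed derived from the master seed and scenario identity.
#' @export
enumerate_scenarios <- function(design = study_design()) {
  variants <- list()
  for (arch in design$architectures) {
    if (arch %in% c("ld_direct", "ld_indirect")) {
      for (thr in design$ld_thresholds)
        variants[[length(variants) + 1]] <- list(architecture = arch, ld_max = thr)
    } else {
      variants[[length(variants) + 1]] <- list(architecture = arch, ld_max = NA_real_)
    }
  }
  out <- list()
  for (v in variants)
    for (maf in design$maf_targets)
      for (h2 in design$h2_pairs)
        for (n in design$sample_sizes)
          for (sp in design$species_profiles) {
            s <- list(architecture = v$architecture, ld_max = v$ld_max,
                      maf_target = maf, h2_pair = h2,
                      additive_effect = design$additive_effect,
                      n_individuals = n, species_profile = sp,
                      detection_window_bp = unname(design$windows[sp]),
                      fdr_level = design$fdr_levels[1],
                      n_replicates = design$n_replicates)
            s$id <- scenario_id(s)
            s$seed <- mix_seed(design$master_seed, s$id)
            out[[length(out) + 1]] <- structure(s, class = "scenario_config")
          }
  out
}

#' Build (and filter) the genotype panels a design needs
#'
#' One panel per species profile at the largest sample size, marker-filtered,
#' then nested subsamples for the smaller sizes — smaller panels' individuals
#' are always subsets of larger ones, as in nested diversity-panel series.
#' Kinship eigendecompositions are attached per panel (computed from all
#' filtered markers, including soon-to-be-removed QTNs, whose removal
#' perturbs K negligibly).
#'
#' @param design A `study_design`.
#' @param with_kinship Attach `kinship_eigen` objects (default TRUE).
#' @return Nested list: `panels[[species]][[as.character(n)]]` with elements
#'   `panel` and `eig`.
#' @export
build_panel_cache <- function(design, with_kinship = TRUE) {
  sizes <- sort(unique(design$sample_sizes), decreasing = TRUE)
  cache <- list()
  for (sp in design$species_profiles) {
    seed <- mix_seed(design$master_seed, "panel", sp)
    G <- generate_genotypes(sizes[1], design$n_chromosomes,
                            design$markers_per_chromosome,
                            ld_profile(sp), inbreeding = 1, seed = seed)
    G <- filter_markers(G)
    subs <- if (length(sizes) > 1) {
      nested_subsample(G, sizes, seed = mix_seed(design$master_seed, "subsample", sp))
    } else list(G)
    names(subs) <- as.character(sizes)
    cache[[sp]] <- lapply(subs, function(g) {
      list(panel = g,
           eig = if (with_kinship) kinship_eigen(vanraden_kinship(g)) else NULL)
    })
  }
  cache
}

#' Run all replicates of one scenario
#'
#' For each replicate: draw QTNs, simulate the trait pair, remove the QTN
#' markers, run the two univariate scans and the multivariate scan against
#' the panel kinship, and score detections.  Replicate-level failures are
#' caught and logged; the scenario fails if more than 5% of replicates are
#' invalid.
#'
#' @param scenario A `scenario_config`.
#' @param panel The filtered `genotype_panel` for the scenario's sample
#'   size, or a cache entry (list with `panel` and `eig`).
#' @param n_replicates Override for the scenario's replicate count.
#' @param uni_mode,mv_mode Scan modes passed to [univariate_scan()] and
#'   [multivariate_scan()]; the defaults fix variance components at their
#'   no-marker estimates for desk-scale runtime.
#' @return List with `summary` (per-model rates), `outcomes` (per-replicate
#'   flags), `assignments`, and `n_invalid`.
#' @export
run_scenario <- function(scenario, panel, n_replicates = scenario$n_replicates,
                         uni_mode = "null_based", mv_mode = "null_based") {
  if (is.list(panel) && !inherits(panel, "genotype_panel")) {
    eig <- panel$eig
    G <- panel$panel
  } else {
    G <- panel
    eig <- NULL
  }
  validate_panel(G)
  if (nrow(G$dosages) != scenario$n_individuals)
    stop_invalid("panel has %d individuals but scenario expects %d",
                 nrow(G$dosages), scenario$n_individuals)
  if (is.null(eig)) eig <- kinship_eigen(vanraden_kinship(G))
  outcomes <- list()
  assignments <- list()
  failures <- character(0)
  for (r in seq_len(n_replicates)) {
    res <- tryCatch({
      rep_data <- simulate_replicate(scenario, G, r)
      scans <- list(
        univariate_trait1 = univariate_scan(rep_data$traits$y1, rep_data$gwas_panel,
                                            eig, mode = uni_mode),
        univariate_trait2 = univariate_scan(rep_data$traits$y2, rep_data$gwas_panel,
                                            eig, mode = uni_mode),
        multivariate = multivariate_scan(cbind(rep_data$traits$y1, rep_data$traits$y2),
                                         rep_data$gwas_panel, eig, mode = mv_mode)
      )
      sc <- score_replicate(scans, rep_data$assignment,
                            scenario$detection_window_bp, scenario$fdr_level)
      sc$replicate <- r
      list(outcome = sc, assignment = rep_data$assignment)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("replicate %d: %s", r, conditionMessage(res)))
    } else {
      outcomes[[length(outcomes) + 1]] <- res$outcome
      assignments[[length(assignments) + 1]] <- res$assignment
    }
  }
  if (length(failures) > 0.05 * n_replicates)
    stop_invalid("scenario %s: %d/%d replicates failed (%s ...)",
                 scenario$id, length(failures), n_replicates, failures[1])
  if (length(failures)) warning(sprintf("scenario %s: %d invalid replicate(s) skipped",
                                        scenario$id, length(failures)))
  outcomes <- do.call(rbind, outcomes)
  list(summary = summarize_scenario(outcomes, scenario),
       outcomes = outcomes, assignments = assignments,
       n_invalid = length(failures))
}

#' Run a full study design
#'
#' Maps [run_scenario()] over [enumerate_scenarios()], reusing one genotype
#' panel per (species, sample size).  Seeds derive from scenario identity,
#' so the worker count cannot change any result.  Optionally writes the
#' long-format summary table and a manifest.
#'
#' @param design A `study_design`.
#' @param workers Number of forked workers (1 = serial).
#' @param output_dir Optional directory for `summary.tsv`, `outcomes.tsv`
#'   and `manifest.yaml`.
#' @param ... Passed to [run_scenario()] (e.g. scan modes, replicate count).
#' @return List with `summary` (long table: one row per scenario x model x
#'   statistic), `scenario_summaries`, and `failed` (ids of failed
#'   scenarios).
#' @export
run_study <- function(design = study_design(), workers = 1, output_dir = NULL, ...) {
  scenarios <- enumerate_scenarios(design)
  if (!length(scenarios)) {
    warning("empty design: no scenarios to run")
    return(list(summary = data.frame(), scenario_summaries = list(), failed = character(0)))
  }
  cache <- build_panel_cache(design)
  run_one <- function(s) {
    tryCatch(run_scenario(s, cache[[s$species_profile]][[as.character(s$n_individuals)]], ...),
             error = function(e) e)
  }
  results <- if (workers > 1) {
    parallel::mclapply(scenarios, run_one, mc.cores = workers)
  } else {
    lapply(scenarios, run_one)
  }
  ids <- vapply(scenarios, `[[`, character(1), "id")
  failed <- ids[vapply(results, inherits, logical(1), "error")]
  ok <- !vapply(results, inherits, logical(1), "error")
  wide <- do.call(rbind, lapply(which(ok), function(i) {
    cbind(scenario = ids[i], results[[i]]$summary, stringsAsFactors = FALSE)
  }))
  long <- if (!is.null(wide)) stats::reshape(
    wide, direction = "long",
    varying = c("rate_t1", "rate_t2", "rate_both", "error_rate"),
    v.names = "rate", timevar = "statistic",
    times = c("rate_t1", "rate_t2", "rate_both", "error_rate")
  ) else data.frame()
  rownames(long) <- NULL
  long$id <- NULL
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(long, file.path(output_dir, "summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest <- list(r_version = R.version.string,
                     package_version = as.character(utils::packageVersion("pleiolink")),
                     master_seed = design$master_seed,
                     n_scenarios = length(scenarios),
                     failed = as.list(failed))
    yaml::write_yaml(manifest, file.path(output_dir, "manifest.yaml"))
  }
  if (length(failed)) warning(sprintf("%d scenario(s) failed: %s",
                                      length(failed), paste(failed, collapse = ", ")))
  list(summary = long, scenario_summaries = results[ok], failed = failed)
}
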