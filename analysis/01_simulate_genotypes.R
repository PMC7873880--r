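#!/usr/bin/env Rscript
# Generate the two synthetic diversity panels (maize-like and soybean-like
# LD decay), apply the marker quality filters (missingness, minor allele
# count >= 5, LD pruning at r2 = 0.9 with the 100/10 window), draw the
# nested subsamples, and serialize everything under results/panels/.
#
# Panel dimensions here are desk-scale (10 chromosomes x 220 markers,
# largest sample 1,000); edit `design` below for other sizes.

suppressMessages(library(pleiolink))

out_dir <- "results/panels"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

design <- study_design(sample_sizes = c(1000, 500),
                       n_chromosomes = 10, markers_per_chromosome = 220,
                       master_seed = 20210101)

for (sp in design$species_profiles) {
  message("profile: ", sp)
  print(ld_profile(sp))
  seed <- mix_seed(design$master_seed, "panel", sp)
  G <- generate_genotypes(max(design$sample_sizes), design$n_chromosomes,
                          design$markers_per_chromosome, ld_profile(sp),
                          seed = seed)
  Gf <- filter_markers(G)
  message(sprintf("  generated %d markers, %d retained after filtering",
                  ncol(G$dosages), ncol(Gf$dosages)))
  subs <- nested_subsample(Gf, sort(design$sample_sizes, decreasing = TRUE),
                           seed = mix_seed(design$master_seed, "subsample", sp))
  for (g in subs) {
    n <- nrow(g$dosages)
    prefix <- file.path(out_dir, sprintf("%s_n%d", gsub("-like", "", sp), n))
    write_panel(g, prefix)                       # PLINK trio
    write_panel(g, paste0(prefix, ".vcf"))       # VCF mirror
    message(sprintf("  wrote %s(.bed/.bim/.fam, .vcf) [n = %d]", prefix, n))
  }
}
message("done.")
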