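#!/usr/bin/env Rscript
# Summarize a finished study run: pleiotropy-vs-linkage contrasts of the
# univariate simultaneous detection rate, multivariate spurious-pleiotropy
# rates, and regional LD around selected QTNs.  Reads results/study/ from
# analysis/03_run_scenarios.R and writes results/contrasts.tsv.

suppressMessages(library(pleiolink))

path <- "results/study/summary.tsv"
if (!file.exists(path)) stop("run analysis/03_run_scenarios.R first")
s <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)

wide <- do.call(rbind, lapply(split(s, interaction(s$scenario, s$model, drop = TRUE)),
  function(d) {
    out <- data.frame(scenario = d$scenario[1], architecture = d$architecture[1],
                      model = d$model[1])
    for (k in seq_len(nrow(d))) out[[d$statistic[k]]] <- d$rate[k]
    out
  }))
rownames(wide) <- NULL

uni <- wide[wide$model == "univariate", ]
uni$gap <- pmin(uni$rate_t1, uni$rate_t2) - uni$rate_both
message("univariate min-vs-both gap by architecture (pleiotropy-like signals have small gaps):")
for (i in seq_len(nrow(uni)))
  message(sprintf("  %-12s min(T1,T2) = %3.0f  T1&T2 = %3.0f  gap = %3.0f",
                  uni$architecture[i], pmin(uni$rate_t1[i], uni$rate_t2[i]),
                  uni$rate_both[i], uni$gap[i]))

mv <- wide[wide$model == "multivariate", ]
message("multivariate detection / spurious pleiotropy rates:")
for (i in seq_len(nrow(mv)))
  message(sprintf("  %-12s T1 = %3.0f  T2 = %3.0f  both = %3.0f  err = %3.0f",
                  mv$architecture[i], mv$rate_t1[i], mv$rate_t2[i],
                  mv$rate_both[i], mv$error_rate[i]))

utils::write.table(wide, "results/contrasts.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("wrote results/contrasts.tsv")
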