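#!/usr/bin/env Rscript

# Per-DIV two-condition comparison of the study metrics produced by
# 01_simulate_study.R: Mann-Whitney tests within each DIV's metric family,
# Benjamini-Yekutieli FDR with the no-increase cap, and the developmental
# fingerprint matrix.

suppressPackageStartupMessages(library(meaburst))

outdir <- "results"
metrics_path <- file.path(outdir, "metrics.csv")
if (!file.exists(metrics_path))
  stop("run analysis/01_simulate_study.R first (missing ", metrics_path, ")")
metrics <- read_metrics(metrics_path)
cfg <- load_config(file.path(outdir, "study_config.yaml"))

cmp <- suppressWarnings(
  compare_study(metrics, alpha = cfg$stats$alpha,
                method = cfg$stats$method))
write_metrics(as.data.frame(cmp), file.path(outdir, "comparisons.csv"), cfg)

fp <- fingerprint(cmp)
writeLines(c("# developmental fingerprint (deficient relative to control)",
             "# cells: significance stars + direction, or ns",
             utils::capture.output(print(fp, quote = FALSE))),
           file.path(outdir, "fingerprint.txt"))

message("fingerprint (deficient relative to control):")
print(fp, quote = FALSE)
sig <- cmp[cmp$significant, c("metric", "div", "median_1", "median_2",
                              "p_raw", "p_adj")]
message(nrow(sig), " significant metric x DIV cells after FDR:")
print(sig, digits = 3, row.names = FALSE)
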