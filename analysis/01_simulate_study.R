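#!/usr/bin/env Rscript

# Simulates the longitudinal two-condition MEA study (control vs
# EHMT1-deficient presets; 25 vs 19 cultures recorded at DIV 10, 13, 15
# and 17) and computes the per-recording activity, irregularity and
# synchrony metrics.  Writes the metrics table that the group comparison
# (03_compare_groups.R) consumes, plus one example recording per condition
# for inspection.

suppressPackageStartupMessages(library(meaburst))

outdir <- "results"
dir.create(outdir, showWarnings = FALSE)
cfg <- study_config(seed = 20160101)

message("simulating ", sum(cfg$n_cultures), " cultures x ",
        length(cfg$divs), " DIVs (", cfg$duration, " s, ",
        cfg$n_electrodes, " electrodes each) ...")
study <- simulate_study(n_cultures = cfg$n_cultures, seed = cfg$seed,
                        divs = cfg$divs,
                        heterogeneity_sd = cfg$heterogeneity_sd)

message("computing per-recording metrics ...")
metrics <- study_metrics(study)
write_metrics(metrics, file.path(outdir, "metrics.csv"), cfg)
save_config(cfg, file.path(outdir, "study_config.yaml"))

# a 60 s excerpt of one example recording per condition at DIV 13 (kept
# small on disk), with its ground truth and detected burst table
for (cond in c("control", "deficient")) {
  ex <- study[[sprintf("%s_01_div13", substr(cond, 1, 4))]]
  cut <- spike_train_set(lapply(ex$trains, function(t) t[t <= 60]), 60,
                         metadata = ex$metadata,
                         ground_truth = list(
                           bursts = subset(ex$ground_truth$bursts,
                                           offset <= 60),
                           config = ex$ground_truth$config,
                           warning_flags = ex$ground_truth$warning_flags))
  write_spike_trains(cut, file.path(outdir,
                                    sprintf("example_%s_div13.csv", cond)))
  write_ground_truth(cut, file.path(outdir,
                                    sprintf("example_%s_div13_truth.json",
                                            cond)))
  act <- select_active(ex)
  bt <- detect_network_bursts(spike_density(act),
                              n_active = length(act$trains))
  write_burst_intervals(bt, file.path(outdir,
                                      sprintf("example_%s_div13_bursts.tsv",
                                              cond)))
}

agg <- aggregate(cbind(mfr, burst_rate, mean_ibi, mean_burst_duration,
                       fano_factor, cv_ibi) ~ condition + div,
                 data = metrics, FUN = function(x) mean(x, na.rm = TRUE))
message("group means by condition and DIV:")
print(agg, digits = 3)
message("wrote ", nrow(metrics), " metric rows to ",
        file.path(outdir, "metrics.csv"))
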