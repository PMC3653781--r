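# Normalize each pooled profile and call methylation-enriched peaks with
# the sliding-window one-sided KS procedure (window 750 bp, min 2 probes
# per peak, -log10 p cutoff 2, max probe spacing 500 bp).

source("analysis/00_config.R")

params <- peak_params()
for (cond in c("nor", "pv")) {
  label <- if (cond == "nor") "Nor" else "PV"
  prof <- read_profile(file.path(DATA_DIR, sprintf("profile_%s.tsv", cond)),
                       label)
  prof <- normalize_profile(prof, "biweight")
  windows <- scan_windows(prof, params)
  peaks <- call_peaks(windows, params)
  validate_peaks(peaks, windows, params)
  cat(sprintf("%s: %d probes -> %d peaks (median peakscore %.2f)\n",
              label, nrow(prof), nrow(peaks), stats::median(peaks$peakscore)))
  write_tsv_plain(peaks, file.path(DATA_DIR, sprintf("peaks_%s.tsv", cond)))
  write_bed(peaks, file.path(DATA_DIR, sprintf("peaks_%s.bed", cond)))
}
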