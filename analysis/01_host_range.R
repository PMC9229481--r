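#!/usr/bin/env Rscript
# Host-range matrix from the published screening table.
#
# Builds the plaque-confirmed virus-host matrix from the transcribed
# titer table (25 virus isolates x 14 Haloferax hosts, of which only
# LR2-5 was susceptible), computes efficiency of plating on LR2-5
# against each virus's own isolation host, and summarizes isolate counts
# with genome-identity deduplication.

library(halorange)

dir.create("results", showWarnings = FALSE)

p <- function(f) system.file("extdata", f, package = "halorange")
m <- build_host_range_matrix(
  read_titer_csv(p("screen_titers.csv")),
  read.csv(p("screen_viruses.csv"), stringsAsFactors = FALSE),
  read_identity_csv(p("screen_identity.csv"))
)
print(m)

n_pos <- count_positive(m, "LR2-5")
n_unique <- dedup_unique(m, "LR2-5")
range_t <- titer_summary(m, "LR2-5")
cat(sprintf("\nPlaque-confirmed isolates on LR2-5: %d (%d unique after\n",
            n_pos, n_unique))
cat("collapsing the genome-identical pairs HCTV-6/13 and HCTV-7/12)\n")
cat(sprintf("Positive titers span %.1e - %.1e pfu/mL\n",
            range_t["min"], range_t["max"]))

eop <- eop_table(m, "LR2-5")
eop_shown <- eop[!is.na(eop$eop_raw),
                 c("virus_id", "titer_reference", "titer_test", "eop_label")]
cat("\nEfficiency of plating on LR2-5 (one significant figure):\n")
print(eop_shown, row.names = FALSE)

write.csv(eop, "results/eop_lr25.csv", row.names = FALSE, na = "")
write_host_range_report(m, "results/host_range_cells.csv",
                        "results/host_range_report.json",
                        test_host = "LR2-5")
cat("\nWrote results/eop_lr25.csv, results/host_range_cells.csv,",
    "results/host_range_report.json\n")
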