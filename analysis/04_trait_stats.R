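#!/usr/bin/env Rscript
# Stage 4: spike-trait statistics of the simulated panel.
#
# One-way ANOVA with Fisher's protected LSD against Chinese Spring for
# the five main-spike traits, combined with the viability phenotype
# into a characteristics-table-style report; plus the two defined
# fertility ratios on a small synthetic spikelet table. Run stage 1
# first.

suppressMessages(library(delbin))

in_dir <- "results/simulated_panel"
out_dir <- "results/traits"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

obs <- utils::read.delim(file.path(in_dir, "traits.tsv"))
pheno <- read_phenotypes(file.path(in_dir, "phenotypes.tsv"))

report <- summarize_panel(obs, control = "CS", phenotype = pheno)
write_panel_report(report, file.path(out_dir, "panel_report.tsv"))

flagged <- report$line[report$grain_number_flag == "**"]
message("lines with grain number ** vs CS: ",
        paste(flagged, collapse = ", "))
message("locus-absent, uncompensated lines should be flagged for grain ",
        "number, TGW and seed set; 1DS deletion lines should not.")

stats <- anova_lsd(obs, control = "CS")
utils::write.table(stats, file.path(out_dir, "anova_lsd.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

# fertility ratios on a synthetic spikelet table: basal / central /
# apical positions with primordia counted at the terminal spikelet
# stage and grains at harvest maturity
spikelets <- data.frame(
  position = c("basal", "central", "apical"),
  primordia_at_ts = c(8.6, 9.2, 6.1),
  grains_at_hm = c(3.4, 2.9, 0.4))
spikelets$potential_productivity <-
  potential_productivity(spikelets$grains_at_hm,
                         spikelets$primordia_at_ts)
utils::write.table(spikelets, file.path(out_dir, "spikelet_productivity.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("potential spikelet productivity (%): ",
        paste(sprintf("%s %.1f", spikelets$position,
                      spikelets$potential_productivity),
              collapse = ", "))
message("seed set for 20 grains over 14 developed spikelets: ",
        sprintf("%.1f%%", seed_set(20, 14)))

message("wrote ", out_dir,
        "/{panel_report.tsv, anova_lsd.tsv, spikelet_productivity.tsv}")
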