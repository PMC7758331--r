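#!/usr/bin/env Rscript
# Stage 1: simulate the 16-line chromosome-1D cytogenetic panel.
#
# Generates GBS-like bin counts (1 Mb bins, mean depth 50 reads/bin in
# the euploid, shared log-normal capture weights, Poisson noise) for
# Chinese Spring plus the nullisomic-tetrasomic, ditelosomic, terminal-
# deletion and arm-addition stocks, with truth copy numbers, the
# deterministic hybrid-seed viability phenotype (locus on 1DL at FL
# 0.60, compensated by 1B tetrasomy) and five spike-trait replicates
# per line. Everything downstream works from these files.

suppressMessages(library(delbin))

out_dir <- "results/simulated_panel"
cfg <- sim_config(seed = 1L)

sim <- simulate_panel(cfg)
paths <- write_sim_panel(sim, out_dir)
write_layout(cfg$layout, file.path(out_dir, "layout.json"))

message("simulated ", length(cfg$panel), " lines x ",
        ncol(sim$counts$counts), " bins (seed ", cfg$seed, ")")
message("viability: ",
        sum(sim$truth_phenotype == "viable"), " viable / ",
        sum(sim$truth_phenotype == "non_viable"), " non-viable")
message("planted locus: 1DL FL 0.60 (",
        format(cfg$locus$position, big.mark = ","), " bp)")
for (p in paths) message("  wrote ", p)
message("  wrote ", file.path(out_dir, "layout.json"))
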