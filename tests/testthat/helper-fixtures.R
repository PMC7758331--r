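# Shared fixtures: small layouts and panels built in code.

toy_layout <- function() {
  # one target chromosome and one homoeolog, small enough to enumerate
  genome_layout(c("T", "H"), length = c(40e6, 40e6),
                centromere = c(15e6, 15e6))
}

# unit-scale layout from the FL arithmetic examples: centromere 100,
# length 200
tiny_layout <- function() genome_layout("chr", 200, 100)

# per-bin copy numbers -> absent intervals (maximal cn-0 runs), bp
absence_from_cn <- function(cn, bins) {
  zero <- cn == 0
  out <- list()
  for (g in unique(bins$chrom)) {
    sel <- which(bins$chrom == g)
    r <- rle(zero[sel])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      out[[length(out) + 1]] <- data.frame(
        chrom = g, start = bins$start[sel[starts[k]]],
        end = bins$end[sel[ends[k]]], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  }
  do.call(rbind, out)
}

# random panel of karyotype events on the toy layout, used by the
# mapper-soundness property tests
random_toy_panel <- function(n_lines = 8) {
  panel <- list(CS = list())
  for (i in seq_len(n_lines)) {
    kind <- sample(c("del_L", "del_S", "nulli_tetra", "telo", "none"),
                   1, prob = c(0.45, 0.2, 0.15, 0.1, 0.1))
    ev <- switch(kind,
      del_L = list(karyotype_event("terminal_deletion", "T", arm = "L",
                                   fl_retained = runif(1, 0.05, 0.95))),
      del_S = list(karyotype_event("terminal_deletion", "T", arm = "S",
                                   fl_retained = runif(1, 0.05, 0.95))),
      nulli_tetra = list(karyotype_event("nullisomy", "T"),
                         karyotype_event("tetrasomy", "H")),
      telo = list(karyotype_event("telosomic", "T",
                                  arm = sample(c("S", "L"), 1))),
      none = list())
    panel[[sprintf("ln%02d", i)]] <- ev
  }
  panel
}
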