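# Simulation of GBS-like bin-count panels for the wheat cytogenetic stocks.
# Expected count for line i, bin b:
#   mu_{i,b} = library_size_factor_i * mean_depth * w_b * cn_{i,b} / 2
# with capture weights w_b shared across lines (log-normal, mean 1) and
# Poisson / negative-binomial / degenerate ("none") count noise.

.preserve_rng <- function() {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' The published 16-line chromosome-1D panel
#'
#' The euploid Chinese Spring reference plus the nullisomic-tetrasomic,
#' ditelosomic, terminal-deletion and arm-addition stocks used for
#' deletion-bin mapping on chromosome 1D, with their FL breakpoints.
#' CSDt1DSAL (originally distributed as deletion line 1DL-8) carries two
#' extra 1D short arms on top of the complete 1D pair.
#'
#' @return named list: per line, a list of [karyotype_event()]s.
#' @export
wheat_1d_panel <- function() {
  del <- function(arm, fl) list(karyotype_event("terminal_deletion", "1D",
                                                arm = arm, fl_retained = fl))
  list(
    "CS"        = list(),
    "N1D/T1A"   = list(karyotype_event("nullisomy", "1D"),
                       karyotype_event("tetrasomy", "1A")),
    "N1D/T1B"   = list(karyotype_event("nullisomy", "1D"),
                       karyotype_event("tetrasomy", "1B")),
    "Dt1DS"     = list(karyotype_event("telosomic", "1D", arm = "S")),
    "Dt1DL"     = list(karyotype_event("telosomic", "1D", arm = "L")),
    "1DS-5"     = del("S", 0.70),
    "1DS-4"     = del("S", 0.66),
    "1DS-1"     = del("S", 0.59),
    "1DS-2"     = del("S", 0.57),
    "1DS-3"     = del("S", 0.48),
    "1DL-4"     = del("L", 0.18),
    "1DL-1"     = del("L", 0.23),
    "1DL-3"     = del("L", 0.25),
    "1DL-6"     = del("L", 0.29),
    "1DL-2"     = del("L", 0.41),
    "CSDt1DSAL" = list(karyotype_event("arm_addition", "1D", arm = "S",
                                       extra_copies = 1L))
  )
}

#' Default trait model for the five main-spike traits
#'
#' Baselines follow the euploid Chinese Spring field values; `effect` is
#' the shift applied to lines in which the target locus is absent and
#' uncompensated (locus-absent lines develop longer spikes but fewer,
#' lighter grains and a lower seed set). Units: spike length cm,
#' thousand-grain weight g, seed set percent.
#'
#' @return data frame with columns `trait`, `baseline`, `sd`, `effect`.
#' @export
default_trait_model <- function() {
  data.frame(
    trait    = c("spike_length", "spikelet_number", "grain_number",
                 "tgw", "seed_set"),
    baseline = c(8.2, 21.4, 63.8, 35.3, 87.3),
    sd       = c(0.5, 1.2, 5.0, 2.0, 5.0),
    effect   = c(2.6, 0.4, -42.0, -12.0, -41.0),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Bundles everything [simulate_panel()] needs. Defaults reproduce the
#' study conditions: the 16-line chromosome-1D panel on a wheat group-1
#' layout, 1 Mb bins, mean GBS depth of 50 reads per bin in the euploid,
#' log-normal per-bin capture-efficiency weights (sigma 0.5) shared by
#' all lines, Poisson count noise, a causal locus on 1DL at FL 0.60 and
#' a homoeologous compensation rule requiring four doses of 1B.
#'
#' @param layout a [genome_layout()].
#' @param bin_width bin width in bp.
#' @param panel named list of event lists (one entry per line).
#' @param reference_line name of the euploid reference; must be in the
#'   panel with no events.
#' @param mean_depth expected reads per bin at copy number 2 and unit
#'   weight.
#' @param library_size_factors positive per-line multipliers (recycled).
#' @param capture_sigma sdlog of the shared log-normal per-bin capture
#'   weights (mean 1); 0 disables heterogeneity.
#' @param noise `"poisson"`, `"negative_binomial"` or `"none"`
#'   (degenerate: counts equal their expectation).
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); required when `noise` is
#'   `"negative_binomial"`.
#' @param locus causal locus: `list(chrom=, position=)` in bp or
#'   `list(chrom=, arm=, fl=)`.
#' @param compensation `list(chrom=, required_copies=)`: a line is
#'   viable without the locus if its homoeolocus on `chrom` is at
#'   `>= required_copies` doses.
#' @param trait_model data frame as in [default_trait_model()].
#' @param compensation_fraction fraction of the trait effect expressed
#'   in compensated lines (0 = fully rescued, 1 = as if uncompensated).
#' @param n_replicates trait replicates per line.
#' @param seed integer seed; all randomness flows from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(layout = wheat_group1_layout(),
                       bin_width = 1e6,
                       panel = wheat_1d_panel(),
                       reference_line = "CS",
                       mean_depth = 50,
                       library_size_factors = 1,
                       capture_sigma = 0.5,
                       noise = c("poisson", "negative_binomial", "none"),
                       nb_dispersion = NULL,
                       locus = list(chrom = "1D", arm = "L", fl = 0.60),
                       compensation = list(chrom = "1B", required_copies = 4),
                       trait_model = default_trait_model(),
                       compensation_fraction = 0.5,
                       n_replicates = 5,
                       seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(inherits(layout, "genome_layout"))
  if (!is.numeric(mean_depth) || mean_depth <= 0) {
    stop("mean_depth must be positive")
  }
  if (anyDuplicated(names(panel))) stop("panel line names must be unique")
  if (!reference_line %in% names(panel)) {
    stop("reference_line '", reference_line, "' is not in the panel")
  }
  lsf <- rep_len(as.numeric(library_size_factors), length(panel))
  if (any(lsf <= 0)) stop("library_size_factors must be positive")
  names(lsf) <- names(panel)
  if (capture_sigma < 0) stop("capture_sigma must be >= 0")
  if (noise == "negative_binomial" &&
      (is.null(nb_dispersion) || nb_dispersion <= 0)) {
    stop("negative_binomial noise requires nb_dispersion > 0")
  }
  if (!is.null(locus$fl)) {
    locus$position <- position_of(layout, locus$chrom, locus$arm, locus$fl)
  }
  i <- .layout_row(layout, locus$chrom)
  if (locus$position < 0 || locus$position >= layout$length[i]) {
    stop("locus position lies outside its chromosome")
  }
  structure(list(layout = layout, bin_width = bin_width, panel = panel,
                 reference_line = reference_line, mean_depth = mean_depth,
                 library_size_factors = lsf, capture_sigma = capture_sigma,
                 noise = noise, nb_dispersion = nb_dispersion, locus = locus,
                 compensation = compensation, trait_model = trait_model,
                 compensation_fraction = compensation_fraction,
                 n_replicates = n_replicates, seed = as.integer(seed)),
            class = "sim_config")
}

# bin index containing a bp position
.bin_at <- function(bins, chrom, position) {
  hit <- which(bins$chrom == chrom & bins$start <= position &
                 bins$end > position)
  if (length(hit) != 1) stop("position ", position,
                             " not covered by a unique bin on ", chrom)
  hit
}

# homoeologous bin of the locus on the compensating chromosome: same arm
# and FL, mapped through the layout
.comp_bin <- function(layout, bins, locus, comp_chrom) {
  lc <- fl_of(layout, locus$chrom, locus$position)
  pos <- position_of(layout, comp_chrom, lc$arm, lc$fl)
  i <- .layout_row(layout, comp_chrom)
  pos <- min(max(pos, 0), layout$length[i] - 1)
  .bin_at(bins, comp_chrom, pos)
}

#' Deterministic viability rule
#'
#' A line develops viable hybrid seed iff it retains at least one dose
#' of the causal locus, or its homoeolocus on the compensating
#' chromosome is at the required dose (whole-chromosome tetrasomy in the
#' published panel). A pure function of the truth copy numbers.
#'
#' @param truth_cn line x bin integer matrix of copy numbers.
#' @param bins bins from [build_bins()].
#' @param layout a [genome_layout()].
#' @param locus `list(chrom=, position=)` (bp).
#' @param compensation `list(chrom=, required_copies=)`.
#' @return named character vector, `"viable"` / `"non_viable"`.
#' @export
simulate_viability <- function(truth_cn, bins, layout, locus,
                               compensation = list(chrom = "1B",
                                                   required_copies = 4)) {
  j <- .bin_at(bins, locus$chrom, locus$position)
  jc <- .comp_bin(layout, bins, locus, compensation$chrom)
  req <- compensation$required_copies
  out <- ifelse(truth_cn[, j] >= 1 | truth_cn[, jc] >= req,
                "viable", "non_viable")
  names(out) <- rownames(truth_cn)
  out
}

#' Trait replicates under the planted locus effect
#'
#' Each line's trait mean is `baseline` plus the full `effect` when the
#' locus is absent and uncompensated, or `compensation_fraction * effect`
#' when absent but compensated; replicates are normal with the trait's
#' `sd`. `sd = 0` is allowed and returns the means exactly.
#'
#' @param locus_absent,compensated named logical vectors per line.
#' @param trait_model data frame as [default_trait_model()].
#' @param n_replicates replicates per line (>= 2).
#' @param compensation_fraction see [sim_config()].
#' @param seed optional integer seed (RNG state is restored on exit).
#' @return long data frame: `line`, `replicate`, `trait`, `value`.
#' @export
simulate_traits <- function(locus_absent, compensated, trait_model,
                            n_replicates = 5, compensation_fraction = 0.5,
                            seed = NULL) {
  if (n_replicates < 2) stop("n_replicates must be >= 2")
  if (any(trait_model$sd < 0)) stop("trait sd must be >= 0")
  if (!is.null(seed)) {
    restore <- .preserve_rng(); on.exit(restore())
    set.seed(seed)
  }
  lines <- names(locus_absent)
  expr <- ifelse(locus_absent & !compensated, 1,
                 ifelse(locus_absent & compensated, compensation_fraction, 0))
  out <- expand.grid(replicate = seq_len(n_replicates), line = lines,
                     trait = trait_model$trait, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  m <- match(out$trait, trait_model$trait)
  mu <- trait_model$baseline[m] + trait_model$effect[m] * expr[out$line]
  out$value <- stats::rnorm(nrow(out), mean = mu, sd = trait_model$sd[m])
  out[, c("line", "replicate", "trait", "value")]
}

#' Simulate a full bin-count panel with known truth
#'
#' Expands every line's karyotype events to truth copy numbers, draws
#' shared per-bin capture weights once, forms expected counts
#' `lsf_i * mean_depth * w_b * cn_{i,b}/2`, draws counts from the
#' configured noise law, and attaches the deterministic viability
#' phenotype and seeded trait replicates. Bit-reproducible for a given
#' configuration and seed.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_panel`: `counts` (a [bin_count_panel()]),
#'   `truth_cn`, `truth_phenotype`, `truth_traits`, `capture_weights`,
#'   `config`.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  restore <- .preserve_rng(); on.exit(restore())
  set.seed(config$seed)

  bins <- build_bins(config$layout, config$bin_width)
  lines <- names(config$panel)
  truth_cn <- t(vapply(config$panel, function(ev) {
    copy_number_track(config$layout, bins, ev)
  }, integer(nrow(bins))))
  rownames(truth_cn) <- lines

  w <- if (config$capture_sigma > 0) {
    stats::rlnorm(nrow(bins), meanlog = -config$capture_sigma^2 / 2,
                  sdlog = config$capture_sigma)
  } else rep(1, nrow(bins))

  mu <- (config$library_size_factors * config$mean_depth / 2) *
    truth_cn * rep(w, each = length(lines))
  counts <- switch(config$noise,
    none = mu,
    poisson = matrix(stats::rpois(length(mu), mu), nrow = nrow(mu),
                     dimnames = dimnames(mu)),
    negative_binomial = matrix(
      stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
      nrow = nrow(mu), dimnames = dimnames(mu))
  )

  pheno <- simulate_viability(truth_cn, bins, config$layout, config$locus,
                              config$compensation)
  j <- .bin_at(bins, config$locus$chrom, config$locus$position)
  jc <- .comp_bin(config$layout, bins, config$locus,
                  config$compensation$chrom)
  locus_absent <- truth_cn[, j] == 0
  compensated <- truth_cn[, jc] >= config$compensation$required_copies
  traits <- simulate_traits(locus_absent, compensated, config$trait_model,
                            config$n_replicates,
                            config$compensation_fraction)

  structure(list(
    counts = bin_count_panel(bins, counts),
    truth_cn = truth_cn,
    truth_phenotype = pheno,
    truth_traits = traits,
    capture_weights = w,
    config = config
  ), class = "sim_panel")
}

#' Write a simulated panel to plain-text files
#'
#' Counts (long TSV), truth copy numbers, phenotypes and trait
#' replicates, under `dir`.
#'
#' @param sim a `sim_panel` from [simulate_panel()].
#' @param dir output directory (created if missing).
#' @return named character vector of the paths written, invisibly.
#' @export
write_sim_panel <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_panel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    truth_cn = file.path(dir, "truth_copy_number.tsv"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    traits = file.path(dir, "traits.tsv")
  )
  write_counts(sim$counts, paths["counts"])
  bins <- sim$counts$bins
  cn_long <- data.frame(
    line = rep(rownames(sim$truth_cn), each = nrow(bins)),
    chrom = rep(bins$chrom, times = nrow(sim$truth_cn)),
    start = rep(bins$start, times = nrow(sim$truth_cn)),
    end = rep(bins$end, times = nrow(sim$truth_cn)),
    copy_number = as.vector(t(sim$truth_cn)), stringsAsFactors = FALSE)
  utils::write.table(cn_long, paths["truth_cn"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_phenotypes(sim$truth_phenotype, paths["phenotypes"])
  utils::write.table(sim$truth_traits, paths["traits"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
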