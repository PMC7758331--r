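#' Karyotype events of wheat cytogenetic stocks
#'
#' An event describes one structural feature of an aneuploid or deletion
#' stock relative to the euploid: loss of a whole chromosome
#' (`nullisomy`), four doses of a chromosome (`tetrasomy`), retention of
#' a single arm as a telocentric pair (`telosomic`), loss of the distal
#' part of an arm (`terminal_deletion`, parameterized by the retained
#' fraction length), or extra copies of one arm beyond the normal
#' complement (`arm_addition`). Stocks are assumed homozygous, so copy
#' numbers move in steps of two.
#'
#' @param kind one of `"nullisomy"`, `"tetrasomy"`, `"telosomic"`,
#'   `"terminal_deletion"`, `"arm_addition"`.
#' @param chrom chromosome name.
#' @param arm `"S"` or `"L"`; required for `telosomic` (the retained
#'   arm), `terminal_deletion` and `arm_addition`.
#' @param fl_retained for `terminal_deletion` only: FL of the
#'   breakpoint; the line retains the proximal `fl_retained` of the arm.
#' @param extra_copies for `arm_addition` (and optionally `tetrasomy`):
#'   number of extra homozygous doses; each adds two copies.
#' @return list of class `karyotype_event`.
#' @examples
#' karyotype_event("terminal_deletion", "1D", arm = "L", fl_retained = 0.41)
#' @export
karyotype_event <- function(kind, chrom, arm = NULL, fl_retained = NULL,
                            extra_copies = NULL) {
  kinds <- c("nullisomy", "tetrasomy", "telosomic", "terminal_deletion",
             "arm_addition")
  kind <- match.arg(kind, kinds)
  if (kind %in% c("telosomic", "terminal_deletion", "arm_addition")) {
    if (is.null(arm) || !arm %in% c("S", "L")) {
      stop(kind, " events require arm \"S\" or \"L\"")
    }
  } else {
    arm <- NULL
  }
  if (kind == "terminal_deletion") {
    if (is.null(fl_retained) || !is.numeric(fl_retained) ||
        fl_retained < 0 || fl_retained > 1) {
      stop("terminal_deletion requires fl_retained in [0, 1]")
    }
  } else if (!is.null(fl_retained)) {
    stop("fl_retained is only meaningful for terminal_deletion events")
  }
  if (kind == "arm_addition") {
    if (is.null(extra_copies)) extra_copies <- 1L
    if (extra_copies < 1) stop("extra_copies must be >= 1")
  }
  if (kind == "tetrasomy") extra_copies <- 1L
  structure(list(kind = kind, chrom = chrom, arm = arm,
                 fl_retained = fl_retained, extra_copies = extra_copies),
            class = "karyotype_event")
}

#' @method format karyotype_event
#' @export
format.karyotype_event <- function(x, ...) {
  extra <- switch(x$kind,
    terminal_deletion = sprintf(" FL %.3g", x$fl_retained),
    arm_addition = sprintf(" +%d dose(s)", x$extra_copies),
    "")
  paste0(x$kind, " ", x$chrom, if (!is.null(x$arm)) x$arm else "", extra)
}

#' @export
print.karyotype_event <- function(x, ...) {
  cat("<karyotype_event>", format(x), "\n")
  invisible(x)
}

# bin -> arm assignment by midpoint
.bin_arms <- function(layout, bins) {
  arms <- character(nrow(bins))
  for (i in seq_len(nrow(layout))) {
    sel <- bins$chrom == layout$name[i]
    mid <- (bins$start[sel] + bins$end[sel]) / 2
    low <- mid < layout$centromere[i]
    low_arm <- if (layout$short_arm_low[i]) "S" else "L"
    high_arm <- if (layout$short_arm_low[i]) "L" else "S"
    arms[sel] <- ifelse(low, low_arm, high_arm)
  }
  arms
}

# FL of bin midpoints on one chromosome (vector over selected bins)
.bin_fl <- function(layout, chrom, starts, ends) {
  mid <- (starts + ends) / 2
  fl_of(layout, chrom, mid)$fl
}

#' Expand karyotype events into a per-bin copy-number track
#'
#' Deterministic expansion of a line's events onto a bin tiling.
#' Baseline is 2 everywhere. Nullisomy sets a whole chromosome to 0,
#' tetrasomy to 4; a telosomic retains one arm at 2 and drops the other
#' to 0; a terminal deletion zeroes the bins of the arm whose midpoint
#' lies distal to the breakpoint (`fl > fl_retained`); an arm addition
#' adds `2 * extra_copies` to one arm. Bins are assigned to arms, and
#' breakpoint membership is decided, by bin midpoint. Two events that
#' assign different copy numbers to the same bin raise an error naming
#' the first offending bin.
#'
#' @param layout a [genome_layout()].
#' @param bins bins from [build_bins()].
#' @param events list of [karyotype_event()]s (possibly empty).
#' @return integer vector of per-bin copy numbers, one per row of `bins`.
#' @export
copy_number_track <- function(layout, bins, events) {
  stopifnot(inherits(layout, "genome_layout"))
  if (inherits(events, "karyotype_event")) events <- list(events)
  n <- nrow(bins)
  arms <- .bin_arms(layout, bins)
  cn <- rep(NA_real_, n)        # NA = untouched (baseline 2)
  origin <- rep(NA_integer_, n)
  for (k in seq_along(events)) {
    ev <- events[[k]]
    stopifnot(inherits(ev, "karyotype_event"))
    .layout_row(layout, ev$chrom)
    on_chrom <- bins$chrom == ev$chrom
    assign_val <- rep(NA_real_, n)
    if (ev$kind == "nullisomy") {
      assign_val[on_chrom] <- 0
    } else if (ev$kind == "tetrasomy") {
      assign_val[on_chrom] <- 2 + 2 * ev$extra_copies
    } else if (ev$kind == "telosomic") {
      assign_val[on_chrom & arms == ev$arm] <- 2
      assign_val[on_chrom & arms != ev$arm] <- 0
    } else if (ev$kind == "terminal_deletion") {
      sel <- on_chrom & arms == ev$arm
      fl <- .bin_fl(layout, ev$chrom, bins$start[sel], bins$end[sel])
      del <- sel
      del[sel] <- fl > ev$fl_retained
      assign_val[del] <- 0
    } else if (ev$kind == "arm_addition") {
      sel <- on_chrom & arms == ev$arm
      assign_val[sel] <- 2 + 2 * ev$extra_copies
    }
    hit <- !is.na(assign_val)
    clash <- hit & !is.na(cn) & cn != assign_val
    if (any(clash)) {
      b <- which(clash)[1]
      stop(sprintf(
        "conflicting copy numbers at bin %d (%s:%s-%s): event %d ('%s') assigns %g over %g",
        bins$index[b], bins$chrom[b],
        format(bins$start[b], scientific = FALSE),
        format(bins$end[b], scientific = FALSE),
        k, format(ev), assign_val[b], cn[b]))
    }
    cn[hit] <- assign_val[hit]
    origin[hit] <- k
  }
  cn[is.na(cn)] <- 2
  as.integer(cn)
}
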