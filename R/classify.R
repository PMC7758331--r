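# Karyotype-event classification from called dosage states.
#
# Templates (per chromosome, arms by bin midpoint, homozygous stocks):
#   whole chromosome 0            -> nullisomy
#   whole chromosome 4            -> tetrasomy
#   one arm 2, other arm 0        -> telosomic (retained arm = the 2 one)
#   proximal 2 then distal 0 on
#   one arm, rest of chromosome 2 -> terminal_deletion, fl_retained = FL
#                                    of the retained/deleted boundary
#   one arm 4, rest 2             -> arm_addition
# Anything else on a non-euploid chromosome is reported as an
# "unclassified" record carrying the raw segments — never dropped.

.arm_pattern <- function(states, fl) {
  # states ordered by increasing FL (centromere -> telomere)
  o <- order(fl)
  s <- states[o]
  r <- rle(s)
  list(runs = r, fl = fl[o], order = o)
}

#' Classify karyotype events from a called state track
#'
#' Matches the per-chromosome dosage-state pattern against the event
#' templates of the wheat cytogenetic stocks (see file header). For a
#' terminal deletion the breakpoint is placed at the boundary between
#' the last retained and the first deleted bin, and reported both as a
#' retained fraction length and as a one-bin-wide physical interval
#' mirroring the breakpoint uncertainty of the bin tiling.
#'
#' @param states integer per-bin states (0..4) for one line.
#' @param bins bins from [build_bins()].
#' @param layout a [genome_layout()].
#' @param segments optional precomputed [segment_states()] output
#'   attached to unclassified records.
#' @param despeckle passed to [despeckle_states()] as `max_frac` before
#'   template matching (default 0.02); 0 disables cleaning.
#' @return list with elements `events` (list of [karyotype_event()]s),
#'   `breakpoints` (data frame: `chrom`, `arm`, `fl_retained`,
#'   `interval_start`, `interval_end`) and `unclassified` (list of
#'   per-chromosome raw patterns that matched no template).
#' @export
classify_events <- function(states, bins, layout, segments = NULL,
                            despeckle = 0.02) {
  stopifnot(length(states) == nrow(bins))
  states <- despeckle_states(states, bins$chrom, despeckle)
  arms <- .bin_arms(layout, bins)
  events <- list()
  unclassified <- list()
  brk <- list()

  for (chrom in layout$name) {
    sel <- bins$chrom == chrom
    s <- states[sel]
    if (all(s == 2)) next
    if (all(s == 0)) {
      events <- c(events, list(karyotype_event("nullisomy", chrom)))
      next
    }
    if (all(s == 4)) {
      events <- c(events, list(karyotype_event("tetrasomy", chrom)))
      next
    }
    a <- arms[sel]
    fl <- .bin_fl(layout, chrom, bins$start[sel], bins$end[sel])
    per_arm <- lapply(c(S = "S", L = "L"), function(arm) {
      list(states = s[a == arm], fl = fl[a == arm],
           start = bins$start[sel][a == arm],
           end = bins$end[sel][a == arm])
    })
    # tolerate a few bins of boundary blur at the centromere: leading
    # (lowest-FL) bins that carry the *other* arm's dominant state are
    # trimmed before template matching, up to the despeckle cap
    dom <- vapply(per_arm, function(p) {
      which.max(tabulate(p$states + 1L, nbins = 5L)) - 1L
    }, integer(1))
    for (arm in c("S", "L")) {
      p <- per_arm[[arm]]
      other <- dom[[setdiff(c("S", "L"), arm)]]
      if (other == dom[[arm]]) next
      o <- order(p$fl)
      slop <- max(3, ceiling(0.02 * length(o)))
      lead <- o[seq_len(min(slop, length(o)))]
      drop <- lead[cumprod(p$states[lead] == other) == 1]
      if (length(drop) && length(drop) < length(o)) {
        keep <- setdiff(seq_along(p$states), drop)
        per_arm[[arm]] <- lapply(p, `[`, keep)
      }
    }
    uni <- vapply(per_arm, function(p) {
      u <- unique(p$states); if (length(u) == 1) u else NA_integer_
    }, integer(1))

    matched <- FALSE
    if (!anyNA(uni)) {
      if (setequal(uni, c(2L, 0L)) && any(uni == 2)) {
        kept <- names(uni)[uni == 2L]
        events <- c(events, list(karyotype_event("telosomic", chrom,
                                                 arm = kept)))
        matched <- TRUE
      } else if (any(uni == 4L) && any(uni == 2L)) {
        arm4 <- names(uni)[uni == 4L]
        events <- c(events, list(karyotype_event("arm_addition", chrom,
                                                 arm = arm4,
                                                 extra_copies = 1L)))
        matched <- TRUE
      }
    } else {
      # exactly one mixed arm, other arm euploid -> candidate deletion
      mixed <- names(uni)[is.na(uni)]
      if (length(mixed) == 1 && identical(uni[[setdiff(c("S", "L"), mixed)]], 2L)) {
        p <- per_arm[[mixed]]
        pat <- .arm_pattern(p$states, p$fl)
        if (length(pat$runs$values) == 2 &&
            identical(pat$runs$values, c(2L, 0L))) {
          first_del <- pat$order[pat$runs$lengths[1] + 1]
          # boundary = proximal edge (in FL terms) of the first deleted bin
          i <- .layout_row(layout, chrom)
          low_side <- .arm_side(layout, i, mixed)
          boundary <- if (low_side) p$end[first_del] else p$start[first_del]
          flr <- .fl_boundary(layout, chrom, boundary)$fl
          events <- c(events, list(karyotype_event(
            "terminal_deletion", chrom, arm = mixed, fl_retained = flr)))
          brk <- c(brk, list(data.frame(
            chrom = chrom, arm = mixed, fl_retained = flr,
            interval_start = p$start[first_del],
            interval_end = p$end[first_del], stringsAsFactors = FALSE)))
          matched <- TRUE
        }
      }
    }
    if (!matched) {
      unclassified <- c(unclassified, list(list(
        chrom = chrom, states = s,
        segments = if (!is.null(segments)) {
          segments[segments$chrom == chrom, , drop = FALSE]
        } else NULL)))
    }
  }
  list(events = events,
       breakpoints = if (length(brk)) do.call(rbind, brk) else
         data.frame(chrom = character(), arm = character(),
                    fl_retained = numeric(), interval_start = numeric(),
                    interval_end = numeric()),
       unclassified = unclassified)
}

#' Full dosage-karyotyping pipeline for a count panel
#'
#' Runs two-step normalization against the reference, optional per-line
#' median recentering, per-chromosome running-median smoothing,
#' dosage-state calling, segmentation and karyotype-event
#' classification for every line.
#'
#' Recentering subtracts each line's genome-wide median log2 ratio
#' before smoothing. In aneuploid lines the step-1 library-size
#' normalization shifts every bin by the (log2) ratio of genomic
#' content, biasing e.g. a tetrasomic chromosome below its nominal +1;
#' since the bulk of the genome is always at copy number 2, the median
#' ratio estimates exactly that shift. For a euploid line the median is
#' 0 and recentering is a no-op.
#'
#' @param panel a [bin_count_panel()].
#' @param reference euploid reference line name.
#' @param layout a [genome_layout()].
#' @param pseudocount see [two_step_normalize()].
#' @param window see [smooth_track()].
#' @param thresholds see [call_states()].
#' @param min_run see [segment_states()].
#' @param recenter subtract the per-line median ratio (default `TRUE`).
#' @param merge_gap see [merge_close_segments()]; 0 disables merging.
#' @param despeckle see [despeckle_states()]; 0 disables cleaning.
#' @return list of class `dosage_profiles`: per line a list with
#'   `line`, `log2_ratio`, `smoothed`, `state`, `segments`, `events`,
#'   `breakpoints`, `unclassified`; plus attributes `bins`, `layout`.
#' @export
karyotype_panel <- function(panel, reference, layout,
                            pseudocount = 0.5, window = 3,
                            thresholds = default_state_thresholds(),
                            min_run = 3, recenter = TRUE, merge_gap = 0.3,
                            despeckle = 0.02) {
  ratios <- two_step_normalize(panel, reference, pseudocount)
  bins <- panel$bins
  arm_groups <- .bin_arms(layout, bins)
  profiles <- lapply(panel$lines, function(ln) {
    r <- ratios[ln, ]
    if (recenter) {
      med <- stats::median(r[is.finite(r)])
      if (is.finite(med)) r <- r - med
    }
    # smoothing never crosses chromosome or arm boundaries: dosage in
    # these stocks changes exactly at the centromere
    sm <- smooth_track(r, window, chrom = paste(bins$chrom, arm_groups))
    st <- call_states(sm, thresholds)
    seg <- segment_states(st, bins$chrom, smoothed = sm, min_run = min_run)
    seg <- merge_close_segments(seg, sm, thresholds, merge_gap)
    # re-derive per-bin states from segments (absorption may relabel
    # bins), then remove residual speckle runs
    st2 <- st
    for (k in seq_len(nrow(seg))) {
      st2[seg$start_bin[k]:seg$end_bin[k]] <- seg$state[k]
    }
    st2 <- despeckle_states(st2, bins$chrom, despeckle, smoothed = sm)
    seg <- segment_states(st2, bins$chrom, smoothed = sm, min_run = 1)
    cls <- classify_events(st2, bins, layout, segments = seg,
                           despeckle = 0)
    list(line = ln, log2_ratio = r, smoothed = sm, state = st2,
         segments = seg, events = cls$events,
         breakpoints = cls$breakpoints, unclassified = cls$unclassified)
  })
  names(profiles) <- panel$lines
  structure(profiles, bins = bins, layout = layout,
            class = "dosage_profiles")
}

#' @export
print.dosage_profiles <- function(x, ...) {
  cat("<dosage_profiles> ", length(x), " lines\n", sep = "")
  for (p in x) {
    ev <- if (length(p$events)) {
      paste(vapply(p$events, format, character(1)), collapse = "; ")
    } else "euploid"
    flag <- if (length(p$unclassified)) " [+unclassified pattern]" else ""
    cat(sprintf("  %-12s %s%s\n", p$line, ev, flag))
  }
  invisible(x)
}

#' Convert dosage profiles to per-line mapping calls
#'
#' Collapses each line's state-0 segments into absent intervals (bp)
#' and attaches phenotypes, producing the [line_call()] records consumed
#' by [map_locus()].
#'
#' @param profiles a `dosage_profiles` object from [karyotype_panel()].
#' @param phenotypes named vector per line: `"viable"`, `"non_viable"`
#'   or `"unknown"` (missing lines default to `"unknown"`).
#' @return list of [line_call()]s.
#' @export
calls_from_profiles <- function(profiles, phenotypes) {
  bins <- attr(profiles, "bins")
  lapply(profiles, function(p) {
    zero <- p$segments[p$segments$state == 0, , drop = FALSE]
    absent <- if (nrow(zero)) {
      data.frame(chrom = zero$chrom,
                 start = bins$start[zero$start_bin],
                 end = bins$end[zero$end_bin], stringsAsFactors = FALSE)
    } else {
      data.frame(chrom = character(), start = numeric(), end = numeric())
    }
    ph <- phenotypes[p$line]
    if (is.na(ph)) ph <- "unknown"
    line_call(p$line, absent, unname(ph))
  })
}

#' Per-line dosage state matrix from profiles
#'
#' @param profiles a `dosage_profiles` object.
#' @return integer matrix, lines x bins.
#' @export
state_matrix <- function(profiles) {
  t(vapply(profiles, function(p) p$state,
           integer(nrow(attr(profiles, "bins")))))
}
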