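#' Bin-count panel container
#'
#' Lines x bins matrix of non-negative read counts tied to a bin tiling.
#' Counts are normally integers; the degenerate "none" noise law of the
#' simulator yields exact (possibly fractional) expectations, which are
#' accepted.
#'
#' @param bins bins from [build_bins()].
#' @param counts numeric matrix, one row per line (rownames required),
#'   one column per bin; all values finite and >= 0.
#' @return list of class `bin_count_panel`: `bins`, `lines`, `counts`.
#' @export
bin_count_panel <- function(bins, counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have line names as rownames")
  if (ncol(counts) != nrow(bins)) {
    stop("counts has ", ncol(counts), " columns but there are ",
         nrow(bins), " bins")
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative")
  }
  structure(list(bins = bins, lines = rownames(counts), counts = counts),
            class = "bin_count_panel")
}

#' @export
print.bin_count_panel <- function(x, ...) {
  cat("<bin_count_panel> ", length(x$lines), " lines x ", nrow(x$bins),
      " bins (", length(unique(x$bins$chrom)), " chromosomes)\n", sep = "")
  invisible(x)
}

#' Two-step normalization of bin counts against a euploid reference
#'
#' Step 1 removes library-size differences: each line's counts (plus a
#' pseudocount) are divided by that line's total, giving per-bin
#' proportions. Step 2 removes shared capture-efficiency structure along
#' the genome: the log2 ratio of each line's proportion to the euploid
#' reference line's proportion is taken per bin. A euploid bin sits at
#' ratio 0; a homozygous deletion at a strongly negative value (exactly
#' -Inf only when `pseudocount = 0`); tetrasomy near +1.
#'
#' @param panel a [bin_count_panel()].
#' @param reference name of the euploid reference line.
#' @param pseudocount value added to every bin before step 1 (default
#'   0.5) so that fully deleted bins stay finite.
#' @return matrix of log2 ratios with the panel's dimnames; the
#'   reference row is identically 0.
#' @export
two_step_normalize <- function(panel, reference, pseudocount = 0.5) {
  stopifnot(inherits(panel, "bin_count_panel"))
  if (!reference %in% panel$lines) {
    stop("reference line '", reference, "' not present in the panel")
  }
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  cp <- panel$counts + pseudocount
  if (pseudocount == 0 && any(cp[reference, ] == 0)) {
    stop("reference line has all-zero bins; set pseudocount > 0 to avoid ",
         "division by zero")
  }
  tot <- rowSums(cp)
  if (tot[reference] == 0) stop("reference line has zero total count")
  p <- cp / tot
  r <- log2(p) - rep(log2(p[reference, ]), each = nrow(p))
  r[reference, ] <- 0
  dimnames(r) <- dimnames(panel$counts)
  r
}

#' Running-median smoothing of a per-bin track
#'
#' Median over a centered window, truncated at the track ends (and, when
#' `chrom` is supplied, at chromosome boundaries — smoothing never
#' crosses them). Window 1 is the identity.
#'
#' @param x numeric per-bin track.
#' @param window odd window size >= 1.
#' @param chrom optional per-bin chromosome labels of the same length.
#' @return smoothed numeric vector.
#' @export
smooth_track <- function(x, window = 3, chrom = NULL) {
  if (window < 1 || window %% 2 == 0) {
    stop("window must be an odd integer >= 1")
  }
  if (window == 1) return(x)
  if (!is.null(chrom)) {
    if (length(chrom) != length(x)) stop("chrom labels must match track length")
    out <- x
    for (g in unique(chrom)) {
      sel <- chrom == g
      out[sel] <- smooth_track(x[sel], window)
    }
    return(out)
  }
  n <- length(x)
  h <- (window - 1) / 2
  vapply(seq_len(n), function(i) {
    stats::median(x[max(1, i - h):min(n, i + h)])
  }, numeric(1))
}

#' Default log2-ratio thresholds for dosage states 0-4
#'
#' Cut points placed near the log2 midpoints between the expected ratios
#' of copy numbers 0..4 relative to the euploid 2 (-Inf, -1, 0, 0.585,
#' 1): a bin is state 0 below -2, state 1 in [-2, -0.5), state 2 in
#' [-0.5, 0.5), state 3 in [0.5, 0.8) and state 4 at or above 0.8.
#'
#' @return numeric vector of four increasing thresholds.
#' @export
default_state_thresholds <- function() c(-2.0, -0.5, 0.5, 0.8)

#' Call integer dosage states from a smoothed log2-ratio track
#'
#' @param smoothed numeric track (log2 ratios).
#' @param thresholds four strictly increasing cut points; see
#'   [default_state_thresholds()].
#' @return integer vector of states in 0..4.
#' @export
call_states <- function(smoothed, thresholds = default_state_thresholds()) {
  if (length(thresholds) != 4 || is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be four strictly increasing values")
  }
  findInterval(smoothed, thresholds)
}

#' Merge adjacent segments whose mean ratios are indistinguishable
#'
#' Threshold-based state calling can split one true dosage segment into
#' several whenever the track hovers near a cut point. True dosage
#' steps in homozygous material separate segment means by at least
#' log2(4/3) (~0.415) and usually by 0.585 or more, so adjacent
#' segments on the same chromosome whose mean smoothed ratios differ by
#' less than `merge_gap` are merged (closest pair first) and the merged
#' segment's state is re-called from its combined mean. At zero noise
#' the means sit exactly on distinct dosage levels and nothing merges.
#'
#' @param segments output of [segment_states()].
#' @param smoothed the smoothed ratio track the segments refer to.
#' @param thresholds state-calling thresholds (see [call_states()]).
#' @param merge_gap maximal mean difference for merging (default 0.3).
#' @return segments data frame of the same shape.
#' @export
merge_close_segments <- function(segments, smoothed,
                                 thresholds = default_state_thresholds(),
                                 merge_gap = 0.3) {
  if (merge_gap <= 0 || nrow(segments) < 2) return(segments)
  seg_mean <- function(k) {
    mean(smoothed[segments$start_bin[k]:segments$end_bin[k]])
  }
  repeat {
    if (nrow(segments) < 2) break
    m <- vapply(seq_len(nrow(segments)), seg_mean, numeric(1))
    same <- segments$chrom[-1] == segments$chrom[-nrow(segments)]
    gap <- abs(diff(m))
    gap[!same] <- Inf
    if (all(gap >= merge_gap)) break
    i <- which.min(gap)           # merge segments i and i+1
    segments$end_bin[i] <- segments$end_bin[i + 1]
    segments$n_bins[i] <- segments$n_bins[i] + segments$n_bins[i + 1]
    segments <- segments[-(i + 1), , drop = FALSE]
    segments$state[i] <- call_states(seg_mean(i), thresholds)
    # re-merge equal-state neighbors
    k <- 1
    while (k < nrow(segments)) {
      if (segments$chrom[k] == segments$chrom[k + 1] &&
          segments$state[k] == segments$state[k + 1]) {
        segments$end_bin[k] <- segments$end_bin[k + 1]
        segments$n_bins[k] <- segments$n_bins[k] + segments$n_bins[k + 1]
        segments <- segments[-(k + 1), , drop = FALSE]
      } else k <- k + 1
    }
  }
  rownames(segments) <- NULL
  segments
}

#' Remove speckle runs from a per-bin state track
#'
#' An interior run of bins whose state differs from two *agreeing*
#' flanking runs is threshold flicker, not structure, when it is short;
#' such runs are relabeled to the flanking state, repeatedly until the
#' track is stable. A short run at a chromosome end is relabeled only
#' when it sits a single state level from its one neighbor (threshold
#' flicker); runs of state 0 are never relabeled anywhere — a short
#' homozygous absence, terminal or not, is evidence, not noise.
#'
#' @param states integer per-bin states.
#' @param chrom per-bin chromosome labels.
#' When a short interior run's flanks disagree, it is relabeled to the
#' unique flank one state level away (e.g. a state-3 blip between a
#' deleted and a euploid segment joins the euploid one); if both flanks
#' are one level away the tie is broken by the closer mean of
#' `smoothed`, or left alone when no track is supplied.
#'
#' @param max_frac maximal run length eligible for relabeling, as a
#'   fraction of the chromosome's bins (default 0.02, floored at 3
#'   bins).
#' @param smoothed optional smoothed ratio track for tie-breaking.
#' @return the cleaned state vector.
#' @export
despeckle_states <- function(states, chrom, max_frac = 0.02,
                             smoothed = NULL) {
  if (max_frac <= 0) return(states)
  for (g in unique(chrom)) {
    idx <- which(chrom == g)
    cap <- max(3, ceiling(max_frac * length(idx)))
    repeat {
      r <- rle(states[idx])
      nr <- length(r$values)
      if (nr < 2) break
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      hit <- FALSE
      relabel <- function(k, to) {
        states[idx[starts[k]:ends[k]]] <<- to
        hit <<- TRUE
      }
      if (nr >= 3) {
        for (k in 2:(nr - 1)) {        # one relabel per pass, then re-run rle
          if (r$values[k] == 0 || r$lengths[k] > cap ||
              r$values[k] == r$values[k - 1]) next
          left <- r$values[k - 1]; right <- r$values[k + 1]
          if (left == right) {
            relabel(k, left); break
          }
          # disagreeing flanks: only a run no longer than either flank
          # can be flicker; relabel toward the unique one-level neighbor
          if (r$lengths[k] > min(r$lengths[k - 1], r$lengths[k + 1])) next
          d <- abs(c(left, right) - r$values[k])
          nb <- c(left, right)[d == 1]
          if (length(nb) == 1) {
            relabel(k, nb); break
          } else if (length(nb) == 2 && !is.null(smoothed)) {
            mk <- mean(smoothed[idx[starts[k]:ends[k]]])
            ml <- mean(smoothed[idx[starts[k - 1]:ends[k - 1]]])
            mr <- mean(smoothed[idx[starts[k + 1]:ends[k + 1]]])
            relabel(k, if (abs(mk - ml) <= abs(mk - mr)) left else right)
            break
          }
        }
      }
      if (!hit) {
        for (k in c(1, nr)) {          # chromosome-end flicker
          nb <- if (k == 1) 2 else nr - 1
          if (r$values[k] != 0 && r$lengths[k] <= cap &&
              r$lengths[k] < r$lengths[nb]) {
            relabel(k, r$values[nb])
          }
        }
      }
      if (!hit) break
    }
  }
  states
}

#' Segment a per-bin state track into constant runs
#'
#' Maximal constant runs per chromosome; runs shorter than `min_run`
#' are absorbed into the neighboring segment whose mean smoothed ratio
#' is closer to the short run's own mean (ties go to the
#' lower-coordinate neighbor). Shortest runs are absorbed first
#' (leftmost on ties), and absorption repeats until every segment is at
#' least `min_run` bins or the chromosome is a single segment.
#'
#' @param states integer per-bin states.
#' @param chrom per-bin chromosome labels.
#' @param smoothed the smoothed ratio track (used to decide absorption).
#' @param min_run minimum segment length in bins (default 3).
#' @return data frame: `chrom`, `start_bin`, `end_bin` (1-based,
#'   inclusive, global track indices), `state`, `n_bins`.
#' @export
segment_states <- function(states, chrom, smoothed = states, min_run = 3) {
  if (min_run < 1) stop("min_run must be >= 1")
  stopifnot(length(states) == length(chrom),
            length(smoothed) == length(states))
  segs <- lapply(unique(chrom), function(g) {
    idx <- which(chrom == g)
    s <- states[idx]
    r <- rle(s)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    runs <- data.frame(start = starts, end = ends, state = r$values)
    while (nrow(runs) > 1 && min(runs$end - runs$start + 1) < min_run) {
      len <- runs$end - runs$start + 1
      i <- which(len < min_run)[which.min(len[len < min_run])]
      mean_of <- function(k) mean(smoothed[idx[runs$start[k]:runs$end[k]]])
      target <- if (i == 1) 2
        else if (i == nrow(runs)) i - 1
        else {
          dl <- abs(mean_of(i) - mean_of(i - 1))
          dr <- abs(mean_of(i) - mean_of(i + 1))
          if (dl <= dr) i - 1 else i + 1
        }
      runs$state[i] <- runs$state[target]
      # merge equal-state neighbors back into maximal runs
      keep <- c(TRUE, runs$state[-1] != runs$state[-nrow(runs)])
      grp <- cumsum(keep)
      runs <- data.frame(
        start = vapply(split(runs$start, grp), min, numeric(1)),
        end = vapply(split(runs$end, grp), max, numeric(1)),
        state = runs$state[keep])
    }
    data.frame(chrom = g, start_bin = idx[runs$start],
               end_bin = idx[runs$end], state = runs$state,
               n_bins = runs$end - runs$start + 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}
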