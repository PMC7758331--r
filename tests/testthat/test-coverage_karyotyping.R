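make_panel <- function(counts, layout, width = 1e6) {
  bins <- build_bins(layout, width)
  bin_count_panel(bins, counts)
}

test_that("two-step normalization matches its defining formulas", {
  layout <- toy_layout()
  bins <- build_bins(layout, 1e6)

  # identity and library-size invariance
  base <- rep(50, nrow(bins))
  counts <- rbind(base, base, 3 * base)
  rownames(counts) <- c("CS", "same", "scaled")
  panel <- bin_count_panel(bins, counts)
  r <- two_step_normalize(panel, "CS", pseudocount = 0)
  expect_equal(unname(r["same", ]), rep(0, nrow(bins)))
  expect_equal(unname(r["scaled", ]), rep(0, nrow(bins)))
  expect_equal(unname(r["CS", ]), rep(0, nrow(bins)))

  # independent direct evaluation on random matrices
  set.seed(21)
  small <- genome_layout("c1", 12e6, 5e6)
  b12 <- build_bins(small, 1e6)
  for (rep in 1:5) {
    m <- matrix(rpois(4 * 12, 60), nrow = 4,
                dimnames = list(paste0("L", 1:4), NULL))
    pc <- sample(c(0.5, 1), 1)
    r <- two_step_normalize(bin_count_panel(b12, m), "L1", pc)
    cp <- m + pc
    p <- cp / rowSums(cp)
    oracle <- log2(sweep(p, 2, p["L1", ], "/"))
    expect_lt(max(abs(r - oracle)), 1e-12)
  }
})

test_that("scale invariance: rescaling one line leaves its track fixed", {
  set.seed(22)
  small <- genome_layout("c1", 12e6, 5e6)
  b12 <- build_bins(small, 1e6)
  m <- matrix(rpois(3 * 12, 80), nrow = 3,
              dimnames = list(c("ref", "a", "b"), NULL))
  r1 <- two_step_normalize(bin_count_panel(b12, m), "ref", 0)
  m2 <- m
  m2["a", ] <- m2["a", ] * 7
  r2 <- two_step_normalize(bin_count_panel(b12, m2), "ref", 0)
  expect_lt(max(abs(r1["a", ] - r2["a", ])), 1e-12)
})

test_that("zero-count handling follows the pseudocount contract", {
  small <- genome_layout("c1", 3e6, 1e6)
  b3 <- build_bins(small, 1e6)
  m <- matrix(c(0, 10, 10, 5, 5, 5), nrow = 2, byrow = TRUE,
              dimnames = list(c("ref", "x"), NULL))
  expect_error(two_step_normalize(bin_count_panel(b3, m), "ref", 0),
               "pseudocount")
  r <- two_step_normalize(bin_count_panel(b3, m), "ref", 0.5)
  expect_true(all(is.finite(r)))
  # the other direction: a zero in a non-reference line is -Inf at pc 0
  m2 <- m[2:1, , drop = FALSE]
  r2 <- two_step_normalize(bin_count_panel(b3, m2), "x", 0)
  expect_true(is.infinite(r2["ref", 1]) && r2["ref", 1] < 0)
})

test_that("running median smoothing truncates at edges and boundaries", {
  expect_identical(smooth_track(c(3, 1, 4, 1), 1), c(3, 1, 4, 1))
  expect_equal(smooth_track(c(1, 1, 9, 1, 1), 3), c(1, 1, 1, 1, 1))
  expect_error(smooth_track(1:4, 2), "odd")

  # brute-force oracle over random tracks, including chromosome groups
  set.seed(23)
  for (rep in 1:10) {
    x <- rnorm(30)
    chrom <- rep(c("a", "b"), c(13, 17))
    w <- sample(c(3, 5, 7), 1)
    got <- smooth_track(x, w, chrom = chrom)
    h <- (w - 1) / 2
    naive <- vapply(seq_along(x), function(i) {
      sel <- which(chrom == chrom[i])
      j <- which(sel == i)
      median(x[sel[max(1, j - h):min(length(sel), j + h)]])
    }, numeric(1))
    expect_equal(got, naive)
  }
})

test_that("state calling uses the documented thresholds", {
  expect_equal(call_states(c(0, 0, 0)), c(2, 2, 2))
  expect_equal(call_states(c(1.0, -6, -1, 0.6, 0.79, 0.8, -2, -0.5)),
               c(4, 0, 1, 3, 3, 4, 1, 2))
  expect_error(call_states(0, thresholds = c(1, 0, 2, 3)), "increasing")
})

test_that("segmentation: runs, absorption, and a naive RLE oracle", {
  # constant track: one segment per chromosome
  seg <- segment_states(rep(2L, 10), rep(c("a", "b"), each = 5))
  expect_equal(nrow(seg), 2)
  expect_equal(seg$state, c(2, 2))

  # lone outlier absorbed under min_run 3
  seg <- segment_states(c(2L, 2L, 0L, 2L, 2L), rep("a", 5),
                        smoothed = c(0, 0, -6, 0, 0), min_run = 3)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$state, 2)

  # min_run 1 equals run-length encoding
  set.seed(24)
  for (rep in 1:10) {
    st <- sample(0:4, 40, replace = TRUE, prob = c(1, 1, 6, 1, 1))
    seg <- segment_states(st, rep("a", 40), min_run = 1)
    r <- rle(st)
    expect_equal(seg$state, r$values)
    expect_equal(seg$end_bin - seg$start_bin + 1, r$lengths)
    # segments partition the bins
    expect_equal(seg$start_bin[1], 1)
    expect_equal(seg$end_bin[nrow(seg)], 40)
    expect_equal(seg$start_bin[-1], seg$end_bin[-nrow(seg)] + 1)
  }
})

test_that("despeckling removes interior flicker but never absence", {
  chrom <- rep("a", 20)
  st <- rep(2L, 20); st[9:10] <- 3L
  expect_equal(unique(despeckle_states(st, chrom)), 2L)
  # state-0 runs are evidence and survive
  st0 <- rep(2L, 20); st0[9:10] <- 0L
  expect_equal(despeckle_states(st0, chrom), st0)
  # terminal flicker one level off is folded in
  st_end <- rep(2L, 20); st_end[19:20] <- 3L
  expect_equal(unique(despeckle_states(st_end, chrom)), 2L)
  st_del <- c(rep(2L, 15), rep(0L, 5))
  expect_equal(despeckle_states(st_del, chrom), st_del)
})

test_that("close-mean segments merge; distinct dosage levels do not", {
  sm <- c(rep(1, 10), rep(0.75, 4), rep(1, 10), rep(0, 10))
  st <- call_states(sm)
  seg <- segment_states(st, rep("a", 34), smoothed = sm, min_run = 3)
  expect_equal(nrow(seg), 4)
  merged <- merge_close_segments(seg, sm, merge_gap = 0.3)
  expect_equal(merged$state, c(4, 2))  # flicker merged, real step kept
})

test_that("zero-noise pipeline classifies all five event kinds and the
           reference stays event-free", {
  cfg <- sim_config(seed = 1, noise = "none", capture_sigma = 0)
  sim <- simulate_panel(cfg)
  prof <- karyotype_panel(sim$counts, "CS", cfg$layout)
  truth <- wheat_1d_panel()
  sig <- function(evs) sort(vapply(evs, function(e) {
    paste(e$kind, e$chrom, if (is.null(e$arm)) "" else e$arm)
  }, character(1)))
  for (ln in names(truth)) {
    expect_equal(sig(prof[[ln]]$events), sig(truth[[ln]]), label = ln)
    expect_length(prof[[ln]]$unclassified, 0)
  }
  expect_length(prof[["CS"]]$events, 0)
  # breakpoint FLs match truth to within one bin of arm length
  for (ln in c("1DL-2", "1DL-6", "1DS-3")) {
    bp <- prof[[ln]]$breakpoints
    truth_fl <- truth[[ln]][[1]]$fl_retained
    arm_bins <- if (grepl("S", ln)) 166 else 330
    expect_lt(abs(bp$fl_retained - truth_fl), 1.5 / arm_bins)
  }
})

test_that("an unmatched pattern is reported, never dropped", {
  layout <- toy_layout()
  bins <- build_bins(layout, 1e6)
  st <- rep(2L, nrow(bins))
  # interstitial absence: proximal 2, a 0 hole, then 2 again on one arm
  onT_L <- bins$chrom == "T" & (bins$start + bins$end) / 2 >= 15e6
  hole <- which(onT_L)[8:12]
  st[hole] <- 0L
  cls <- classify_events(st, bins, layout)
  expect_length(cls$events, 0)
  expect_length(cls$unclassified, 1)
  expect_equal(cls$unclassified[[1]]$chrom, "T")
})

test_that("monotonicity: higher copy number never lowers the expected
           ratio", {
  layout <- toy_layout()
  bins <- build_bins(layout, 1e6)
  counts <- rbind(CS = rep(50, nrow(bins)))
  onT <- bins$chrom == "T"
  for (cn in c(0, 1, 2, 3, 4)) {
    row <- rep(50, nrow(bins))
    row[onT] <- 50 * cn / 2
    counts <- rbind(counts, row)
  }
  rownames(counts) <- c("CS", paste0("cn", 0:4))
  r <- two_step_normalize(bin_count_panel(bins, counts), "CS")
  tracks <- r[paste0("cn", 0:4), onT, drop = FALSE]
  expect_true(all(diff(rowMeans(tracks)) > 0))
})
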