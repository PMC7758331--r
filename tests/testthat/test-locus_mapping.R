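table1_mapped <- function(include_1DL2, required_copies = 4) {
  layout <- wheat_group1_layout()
  td <- table1_truth_dosage(layout, include_1DL2 = include_1DL2)
  calls <- table1_calls(layout, include_1DL2 = include_1DL2)
  calls <- apply_compensation(
    calls, list(chrom = "1B", required_copies = required_copies),
    td$dosage, td$bins)
  list(calls = calls, map = map_locus(calls, layout), layout = layout)
}

test_that("the published panel maps the locus distal to FL 0.29, then
           0.41 once line 1DL-2 is added", {
  res <- table1_mapped(include_1DL2 = FALSE)
  m <- res$map
  expect_equal(nrow(m$intervals), 1)
  expect_equal(m$intervals$chrom, "1D")
  expect_equal(m$intervals$arm_start, "L")
  expect_equal(proximal_fl_bound(m, "1D", "L"), 0.29, tolerance = 1e-6)
  expect_equal(m$intervals$fl_end, 1)
  expect_setequal(m$supporting_lines,
                  c("N1D/T1A", "Dt1DS", "1DL-4", "1DL-1", "1DL-3", "1DL-6"))
  expect_true("N1D/T1B" %in% m$excluded_lines$line)

  res2 <- table1_mapped(include_1DL2 = TRUE)
  expect_equal(proximal_fl_bound(res2$map, "1D", "L"), 0.41,
               tolerance = 1e-6)
})

test_that("compensation flags only whole-chromosome high dosage and an
           impossible dose requirement exposes the contradiction", {
  res <- table1_mapped(include_1DL2 = TRUE)
  comp <- vapply(res$calls, function(x) x$compensated, logical(1))
  names(comp) <- vapply(res$calls, function(x) x$line, character(1))
  expect_true(comp[["N1D/T1B"]])
  expect_false(any(comp[names(comp) != "N1D/T1B"]))

  # required_copies no line can reach: N1D/T1B becomes contradictory
  expect_warning(
    res99 <- table1_mapped(include_1DL2 = TRUE, required_copies = 99),
    "N1D/T1B")
  expect_equal(nrow(res99$map$intervals), 0)
  expect_match(paste(res99$map$diagnostics, collapse = " "), "N1D/T1B")
})

test_that("without the compensation rule, N1D/T1B is the sole conflict", {
  layout <- wheat_group1_layout()
  calls <- table1_calls(layout)          # no compensation applied
  res <- table1_mapped(include_1DL2 = TRUE)
  conf <- detect_conflicts(calls, res$map)
  expect_equal(conf$line, "N1D/T1B")
  expect_match(conf$problem, "viable")
})

test_that("a consistent synthetic panel yields no conflicts and a
           flipped phenotype is pinpointed", {
  layout <- toy_layout()
  bins <- build_bins(layout, 1e6)
  set.seed(31)
  locus_pos <- position_of(layout, "T", "L", 0.7)
  n_found <- 0
  for (trial in 1:100) {
    panel <- random_toy_panel(8)
    cn <- t(vapply(panel, function(e) copy_number_track(layout, bins, e),
                   integer(nrow(bins))))
    pheno <- simulate_viability(cn, bins, layout,
                                list(chrom = "T", position = locus_pos),
                                list(chrom = "H", required_copies = 4))
    calls <- lapply(rownames(cn), function(ln) {
      line_call(ln, absence_from_cn(cn[ln, ], bins), unname(pheno[ln]))
    })
    calls <- apply_compensation(calls, list(chrom = "H",
                                            required_copies = 4), cn, bins)
    nv <- vapply(calls, function(x)
      x$phenotype == "non_viable" && !x$compensated, logical(1))
    if (!any(nv)) next
    m <- suppressWarnings(map_locus(calls, layout))
    if (!nrow(m$intervals)) next
    # conflict scan runs under the no-compensation model, so the only
    # admissible conflicts in a rule-consistent panel are the
    # compensated (nullisomic-tetrasomic) viable lines
    conf0 <- detect_conflicts(calls, m)
    comp_lines <- vapply(calls[vapply(calls, `[[`, logical(1),
                                      "compensated")],
                         `[[`, character(1), "line")
    expect_true(all(conf0$line %in% comp_lines))

    # flip one constraining line's phenotype; it must join the report
    w_nv <- which(nv)
    flip <- if (length(w_nv) == 1) w_nv else sample(w_nv, 1)
    calls2 <- calls
    calls2[[flip]]$phenotype <- "viable"
    conf <- detect_conflicts(calls2, m)
    expect_true(calls2[[flip]]$line %in% conf$line)
    n_found <- n_found + 1
  }
  expect_gt(n_found, 50)  # the property was actually exercised
})

test_that("map_locus equals an exhaustive per-bin oracle on random
           panels and always contains the planted locus", {
  layout <- toy_layout()
  bins <- build_bins(layout, 1e6)
  set.seed(32)
  checked <- 0; informative <- 0; contained <- 0
  for (trial in 1:120) {
    panel <- random_toy_panel(sample(5:9, 1))
    cn <- t(vapply(panel, function(e) copy_number_track(layout, bins, e),
                   integer(nrow(bins))))
    locus_bin <- sample(which(bins$chrom == "T"), 1)
    locus <- list(chrom = "T",
                  position = (bins$start[locus_bin] + bins$end[locus_bin]) / 2)
    pheno <- simulate_viability(cn, bins, layout, locus,
                                list(chrom = "H", required_copies = 4))
    calls <- lapply(rownames(cn), function(ln) {
      line_call(ln, absence_from_cn(cn[ln, ], bins), unname(pheno[ln]))
    })
    calls <- apply_compensation(calls, list(chrom = "H",
                                            required_copies = 4), cn, bins)
    m <- suppressWarnings(map_locus(calls, layout))

    # independent per-bin consistency oracle
    comp <- vapply(calls, function(x) x$compensated, logical(1))
    nv <- which(pheno == "non_viable" & !comp)
    vi <- which(pheno == "viable" & !comp)
    oracle_bins <- if (length(nv)) {
      which(vapply(seq_len(nrow(bins)), function(b) {
        all(cn[nv, b] == 0) && all(cn[vi, b] != 0)
      }, logical(1)))
    } else integer()

    got_bins <- integer()
    if (nrow(m$intervals)) {
      for (k in seq_len(nrow(m$intervals))) {
        got_bins <- c(got_bins, which(
          bins$chrom == m$intervals$chrom[k] &
            bins$start >= m$intervals$start[k] &
            bins$end <= m$intervals$end[k]))
      }
    }
    expect_equal(sort(got_bins), sort(oracle_bins))
    checked <- checked + 1

    n_informative <- sum(vapply(calls[pheno == "non_viable" & !comp],
      function(x) nrow(x$absent_intervals) > 0, logical(1)))
    if (n_informative >= 1 && length(oracle_bins)) {
      informative <- informative + 1
      if (locus_bin %in% got_bins) contained <- contained + 1
    }
  }
  expect_equal(checked, 120)
  expect_gt(informative, 40)
  expect_equal(contained, informative)  # planted locus always recovered
})

test_that("adding lines can only shrink the candidate set", {
  layout <- toy_layout()
  bins <- build_bins(layout, 1e6)
  set.seed(33)
  for (trial in 1:20) {
    panel <- random_toy_panel(8)
    cn <- t(vapply(panel, function(e) copy_number_track(layout, bins, e),
                   integer(nrow(bins))))
    locus <- list(chrom = "T", position = position_of(layout, "T", "L", 0.6))
    pheno <- simulate_viability(cn, bins, layout, locus,
                                list(chrom = "H", required_copies = 4))
    calls <- lapply(rownames(cn), function(ln) {
      line_call(ln, absence_from_cn(cn[ln, ], bins), unname(pheno[ln]))
    })
    calls <- apply_compensation(calls, list(chrom = "H",
                                            required_copies = 4), cn, bins)
    nv <- vapply(calls, function(x)
      x$phenotype == "non_viable" && !x$compensated, logical(1))
    if (sum(nv) < 2) next
    width_of <- function(m) if (nrow(m$intervals)) {
      sum(m$intervals$end - m$intervals$start)
    } else 0
    m_all <- suppressWarnings(map_locus(calls, layout))
    w_nv <- which(nv)
    drop <- if (length(w_nv) == 1) w_nv else sample(w_nv, 1)
    m_less <- suppressWarnings(map_locus(calls[-drop], layout))
    expect_gte(width_of(m_less), width_of(m_all))
  }
})

test_that("no constraining non-viable line returns an explicit empty
           result, not an error", {
  layout <- toy_layout()
  calls <- list(line_call("CS", data.frame(chrom = character(),
                                           start = numeric(),
                                           end = numeric()), "viable"))
  expect_warning(m <- map_locus(calls, layout), "non-viable")
  expect_equal(nrow(m$intervals), 0)
})

test_that("unknown phenotypes are ignored with a notice", {
  layout <- toy_layout()
  bins <- build_bins(layout, 1e6)
  cn <- copy_number_track(layout, bins, list(
    karyotype_event("terminal_deletion", "T", arm = "L",
                    fl_retained = 0.5)))
  calls <- list(
    line_call("del", absence_from_cn(cn, bins), "non_viable"),
    line_call("mystery", absence_from_cn(cn, bins), "unknown"))
  expect_message(m <- map_locus(calls, layout), "unknown phenotype")
  expect_true(nrow(m$intervals) >= 1)
  expect_true("mystery" %in% m$excluded_lines$line)
})

test_that("gene overlap counting follows the any-overlap rule and a
           naive scan", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  # 10 genes of 2 kb every 10 kb on chrT; interval covers genes 3-6
  lines <- c("##gff-version 3", vapply(1:10, function(i) {
    s <- i * 10000 + 1
    sprintf("chrT\ttest\tgene\t%d\t%d\t.\t+\t.\tID=g%d;confidence=%s",
            s, s + 1999, i, if (i %% 2 == 0) "HC" else "LC")
  }, character(1)))
  writeLines(lines, gff)
  genes <- read_gff_genes(gff)
  expect_length(genes, 10)

  res <- genes_in_interval(genes, list(chrom = "chrT", start = 30000,
                                       end = 62001))
  expect_equal(res$count, 4)
  expect_setequal(res$genes$id, c("g3", "g4", "g5", "g6"))

  # 1 bp overlap at the boundary still counts
  res1 <- genes_in_interval(genes, list(chrom = "chrT", start = 10000,
                                        end = 10001))
  expect_equal(res1$count, 1)
  res0 <- genes_in_interval(genes, list(chrom = "chrT", start = 9000,
                                        end = 10000))
  expect_equal(res0$count, 0)

  # confidence filter
  hc <- genes_in_interval(genes, list(chrom = "chrT", start = 0,
                                      end = 2e5), confidence = "HC")
  expect_equal(hc$count, 5)

  # random gene sets against an all-pairs scan
  set.seed(34)
  for (rep in 1:10) {
    n <- 30
    s <- sample(1:5e5, n)
    e <- s + sample(100:5000, n, replace = TRUE)
    g2 <- withr::local_tempfile(fileext = ".gff3")
    writeLines(c("##gff-version 3", sprintf(
      "chrT\tt\tgene\t%d\t%d\t.\t+\t.\tID=r%d", s, e, seq_len(n))), g2)
    gr <- read_gff_genes(g2)
    iv <- sort(sample(1:6e5, 2))
    res <- genes_in_interval(gr, list(chrom = "chrT", start = iv[1],
                                      end = iv[2]))
    naive <- sum(s <= iv[2] & e >= iv[1] + 1)  # 1-based closed overlap
    expect_equal(res$count, naive)
  }
})

test_that("malformed GFF3 records are skipped with warnings, not fatal", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chrT\tt\tgene\t100\t200\t.\t+\t.\tID=ok1",
    "chrT\tt\tgene\tnotanumber\t200\t.\t+\t.\tID=bad1",
    "chrT\tt\tgene\t500\t300\t.\t+\t.\tID=bad2",
    "chrT\tt\tgene\t900\t1200\t.\t+\t.\tID=ok2"), gff)
  w <- capture_warnings(
    expect_message(g <- read_gff_genes(gff), "2 malformed"))
  expect_length(w, 2)
  expect_match(w, "skipping malformed", all = TRUE)
  expect_length(g, 2)
  expect_equal(attr(g, "skipped"), 2)
})

test_that("full-scale reproduction of the physical interval is
           documented with the exact external commands", {
  cmds <- refseq_reproduction_notes()
  txt <- paste(cmds, collapse = "\n")
  expect_match(txt, "PRJEB37818")
  expect_match(txt, "cutadapt")
  expect_match(txt, "minimap2")
  expect_match(txt, "samtools")
  expect_match(txt, "genes_in_interval")
})
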