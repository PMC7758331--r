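# File exchange: long/wide count TSVs, BED, bedGraph, phenotype TSVs.
# Readers reject malformed input instead of coercing; every writer's
# output is accepted by its paired reader (round-trip tested).

#' Read a bin-count panel from TSV
#'
#' Long format (`line`, `chrom`, `start`, `end`, `count`; header
#' required) or wide format (`chrom`, `start`, `end`, then one column
#' per line). Bins are ordered by the layout's chromosome order, then
#' start. Negative counts, unknown chromosomes, duplicated
#' `(line, bin)` rows and bins missing for some line are all rejected
#' with messages naming the offenders.
#'
#' @param path TSV path.
#' @param layout a [genome_layout()] fixing chromosome order.
#' @return a [bin_count_panel()].
#' @export
read_counts <- function(path, layout) {
  stopifnot(inherits(layout, "genome_layout"))
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  long <- all(c("line", "chrom", "start", "end", "count") %in% names(d))
  if (!long) {
    if (!all(c("chrom", "start", "end") %in% names(d))) {
      stop("count TSV must be long (line, chrom, start, end, count) or ",
           "wide (chrom, start, end, <one column per line>)")
    }
    lines <- setdiff(names(d), c("chrom", "start", "end"))
    d <- do.call(rbind, lapply(lines, function(ln) {
      data.frame(line = ln, chrom = d$chrom, start = d$start, end = d$end,
                 count = d[[ln]], stringsAsFactors = FALSE)
    }))
  }
  bad <- which(!d$chrom %in% layout$name)
  if (length(bad)) {
    stop("unknown chromosome(s) in rows ",
         paste(utils::head(bad, 5), collapse = ", "), ": ",
         paste(unique(d$chrom[bad]), collapse = ", "))
  }
  if (any(!is.finite(d$count)) || any(d$count < 0)) {
    bad <- which(!is.finite(d$count) | d$count < 0)
    stop("negative or non-finite counts in row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  key <- paste(d$line, d$chrom, d$start)
  if (anyDuplicated(key)) {
    stop("duplicated (line, bin) row(s): row ",
         paste(utils::head(which(duplicated(key)), 5), collapse = ", "))
  }
  d$chrom_order <- match(d$chrom, layout$name)
  bins <- unique(d[order(d$chrom_order, d$start),
                   c("chrom", "start", "end")])
  bins$index <- seq_len(nrow(bins))
  rownames(bins) <- NULL
  class(bins) <- c("genomic_bins", "data.frame")
  lines <- unique(d$line)
  mat <- matrix(NA_real_, nrow = length(lines), ncol = nrow(bins),
                dimnames = list(lines, NULL))
  i <- match(d$line, lines)
  j <- match(paste(d$chrom, d$start), paste(bins$chrom, bins$start))
  mat[cbind(i, j)] <- d$count
  if (anyNA(mat)) {
    miss <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop("line '", lines[miss[1]], "' is missing bin ",
         bins$chrom[miss[2]], ":", bins$start[miss[2]])
  }
  bin_count_panel(bins, mat)
}

#' Write a bin-count panel as long-format TSV
#'
#' @param panel a [bin_count_panel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(panel, path) {
  stopifnot(inherits(panel, "bin_count_panel"))
  b <- panel$bins
  d <- data.frame(
    line = rep(panel$lines, each = nrow(b)),
    chrom = rep(b$chrom, times = length(panel$lines)),
    start = rep(b$start, times = length(panel$lines)),
    end = rep(b$end, times = length(panel$lines)),
    count = as.vector(t(panel$counts)), stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read intervals as BED
#'
#' BED3 plus optional `name` and `score` columns, 0-based half-open,
#' no header. An empty interval set writes an empty file.
#'
#' @param intervals data frame `chrom`, `start`, `end` and optionally
#'   `name`, `score`.
#' @param path file path.
#' @return `write_bed`: `path` invisibly; `read_bed`: the intervals.
#' @export
write_bed <- function(intervals, path) {
  d <- as.data.frame(intervals)
  if (nrow(d) && (any(d$start < 0) || any(d$start >= d$end))) {
    stop("BED intervals must satisfy 0 <= start < end")
  }
  cols <- intersect(c("chrom", "start", "end", "name", "score"), names(d))
  if (!nrow(d)) {
    file.create(path)
  } else {
    d$start <- format(d$start, scientific = FALSE, trim = TRUE)
    d$end <- format(d$end, scientific = FALSE, trim = TRUE)
    utils::write.table(d[, cols], path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  }
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(d) <- c("chrom", "start", "end", "name", "score")[seq_len(ncol(d))]
  if (any(d$start < 0) || any(d$start >= d$end)) {
    stop("BED intervals must satisfy 0 <= start < end")
  }
  d
}

#' Export per-bin tracks as bedGraph
#'
#' @param bins bins from [build_bins()].
#' @param values numeric per-bin track (e.g. smoothed log2 ratios).
#' @param path output path.
#' @param name track name for the header line.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(bins, values, path, name = "log2_ratio") {
  stopifnot(length(values) == nrow(bins))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s\"", name), con)
  utils::write.table(
    data.frame(bins$chrom,
               format(bins$start, scientific = FALSE, trim = TRUE),
               format(bins$end, scientific = FALSE, trim = TRUE),
               values),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write seed-viability phenotypes
#'
#' TSV with columns `line` and `viability` coded `+` (viable), `-`
#' (non-viable) or `NA` (unknown).
#'
#' @param path TSV path.
#' @param phenotypes named vector of `"viable"`/`"non_viable"`/
#'   `"unknown"` (for writing).
#' @return `read_phenotypes`: named character vector in the package's
#'   vocabulary; `write_phenotypes`: `path` invisibly.
#' @export
read_phenotypes <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  if (!all(c("line", "viability") %in% names(d))) {
    stop("phenotype TSV needs columns 'line' and 'viability'")
  }
  v <- trimws(as.character(d$viability))
  bad <- !v %in% c("+", "-", "−") & !is.na(v)
  if (any(bad)) {
    stop("viability must be '+', '-' or NA; offending line(s): ",
         paste(d$line[bad], collapse = ", "))
  }
  out <- ifelse(is.na(v), "unknown",
                ifelse(v == "+", "viable", "non_viable"))
  names(out) <- d$line
  out
}

#' @rdname read_phenotypes
#' @export
write_phenotypes <- function(phenotypes, path) {
  code <- c(viable = "+", non_viable = "-", unknown = NA)
  utils::write.table(
    data.frame(line = names(phenotypes),
               viability = unname(code[phenotypes])),
    path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' The published panel characteristics table
#'
#' The bundled per-line table of the chromosome-1D panel: karyotype
#' class, FL breakpoint, hybrid-seed viability in crosses with rye, and
#' the five main-spike trait means from the 2015 field experiment.
#' Line 1DL-2 (tested later to refine the map) is marked
#' `initial_panel = FALSE`; line CSDt1DSAL is the re-classified 1DL-8.
#'
#' @return data frame, one row per line.
#' @export
table1_data <- function() {
  path <- system.file("extdata", "table1_lines.tsv", package = "delbin",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
}

# events for one row of table1_data()
.table1_events <- function(row) {
  switch(row$class,
    euploid = list(),
    nulli_tetra = list(
      karyotype_event("nullisomy", row$chrom),
      karyotype_event("tetrasomy", row$tetra_chrom)),
    ditelosomic = list(
      karyotype_event("telosomic", row$chrom, arm = row$arm)),
    deletion = list(
      karyotype_event("terminal_deletion", row$chrom, arm = row$arm,
                      fl_retained = row$fl_breakpoint)),
    addition = list(
      karyotype_event("arm_addition", row$chrom, arm = row$arm,
                      extra_copies = 1L)),
    stop("unknown karyotype class: ", row$class))
}

#' Encode the published panel as mapping calls
#'
#' Converts each line of [table1_data()] into a [line_call()]: absent
#' intervals derived exactly from its karyotype events (FL breakpoints
#' converted to bp through the layout), phenotype from the viability
#' column. Compensation flags are left `FALSE`; apply
#' [apply_compensation()] with the truth dosage from
#' [table1_truth_dosage()] to set them.
#'
#' @param layout a [genome_layout()] containing the panel chromosomes.
#' @param include_1DL2 include the later-tested deletion line 1DL-2
#'   (default `TRUE`); `FALSE` reproduces the initial panel.
#' @return list of [line_call()]s.
#' @export
table1_calls <- function(layout, include_1DL2 = TRUE) {
  tab <- table1_data()
  if (!include_1DL2) tab <- tab[tab$initial_panel, ]
  lapply(seq_len(nrow(tab)), function(k) {
    row <- tab[k, ]
    events <- .table1_events(row)
    absent <- do.call(rbind, lapply(events, function(ev) {
      .event_absence(layout, ev)
    }))
    if (is.null(absent)) {
      absent <- data.frame(chrom = character(), start = numeric(),
                           end = numeric())
    }
    line_call(row$line, absent,
              if (row$viability == "+") "viable" else "non_viable")
  })
}

# exact absent interval(s) implied by one karyotype event
.event_absence <- function(layout, ev) {
  i <- .layout_row(layout, ev$chrom)
  len <- layout$length[i]
  cen <- layout$centromere[i]
  if (ev$kind == "nullisomy") {
    return(data.frame(chrom = ev$chrom, start = 0, end = len))
  }
  if (ev$kind == "telosomic") {
    lost <- setdiff(c("S", "L"), ev$arm)
    if (.arm_side(layout, i, lost)) {
      return(data.frame(chrom = ev$chrom, start = 0, end = cen))
    }
    return(data.frame(chrom = ev$chrom, start = cen, end = len))
  }
  if (ev$kind == "terminal_deletion") {
    b <- position_of(layout, ev$chrom, ev$arm, ev$fl_retained)
    if (.arm_side(layout, i, ev$arm)) {
      return(data.frame(chrom = ev$chrom, start = 0, end = b))
    }
    return(data.frame(chrom = ev$chrom, start = b, end = len))
  }
  NULL  # tetrasomy / arm_addition: nothing absent
}

#' Truth dosage matrix for the published panel
#'
#' Expands each table line's karyotype events onto a bin tiling, for
#' use with [apply_compensation()].
#'
#' @param layout a [genome_layout()].
#' @param bin_width bin width in bp.
#' @param include_1DL2 as in [table1_calls()].
#' @return list: `dosage` (lines x bins integer matrix), `bins`.
#' @export
table1_truth_dosage <- function(layout, bin_width = 1e6,
                                include_1DL2 = TRUE) {
  tab <- table1_data()
  if (!include_1DL2) tab <- tab[tab$initial_panel, ]
  bins <- build_bins(layout, bin_width)
  dosage <- t(vapply(seq_len(nrow(tab)), function(k) {
    copy_number_track(layout, bins, .table1_events(tab[k, ]))
  }, integer(nrow(bins))))
  rownames(dosage) <- tab$line
  list(dosage = dosage, bins = bins)
}
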