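# Deletion-bin mapping: combine per-line absence calls with a binary
# seed-viability phenotype to bound the causal locus.
#
# Candidate region = (intersection of the absent intervals of every
# constraining non-viable line) minus (union of the absent intervals of
# every constraining viable line). Compensated lines (homoeolocus at
# the required dose) and phenotype-unknown lines do not constrain.
# Interval arithmetic is delegated to IRanges; tests check the result
# against an independent per-bin membership oracle.

.df_to_ir <- function(df) {
  IRanges::reduce(IRanges::IRanges(start = df$start + 1, end = df$end))
}

.ir_to_df <- function(ir, chrom) {
  data.frame(chrom = rep_len(chrom, length(ir)),
             start = BiocGenerics::start(ir) - 1,
             end = BiocGenerics::end(ir), stringsAsFactors = FALSE)
}

#' Per-line mapping call
#'
#' One line's evidence for the mapper: the intervals called at copy
#' number 0 (homozygous absence; 0-based half-open bp), the hybrid-seed
#' viability phenotype, and the dosage-compensation flag.
#'
#' @param line line name.
#' @param absent_intervals data frame `chrom`, `start`, `end`; may be
#'   empty. Overlapping intervals on a chromosome are merged.
#' @param phenotype `"viable"`, `"non_viable"` or `"unknown"`.
#' @param compensated logical; set by [apply_compensation()].
#' @return list of class `line_call`.
#' @export
line_call <- function(line, absent_intervals, phenotype,
                      compensated = FALSE) {
  phenotype <- match.arg(phenotype, c("viable", "non_viable", "unknown"))
  ai <- as.data.frame(absent_intervals)
  if (nrow(ai)) {
    if (any(ai$start < 0) || any(ai$end <= ai$start)) {
      stop("absent intervals must satisfy 0 <= start < end")
    }
    ai <- do.call(rbind, lapply(split(ai, ai$chrom), function(d) {
      .ir_to_df(.df_to_ir(d), d$chrom[1])
    }))
    ai <- ai[order(ai$chrom, ai$start), , drop = FALSE]
    rownames(ai) <- NULL
  }
  structure(list(line = line, absent_intervals = ai,
                 phenotype = phenotype, compensated = compensated),
            class = "line_call")
}

#' @export
print.line_call <- function(x, ...) {
  cat("<line_call>", x$line, "-", x$phenotype,
      if (x$compensated) "(compensated)" else "", "-",
      nrow(x$absent_intervals), "absent interval(s)\n")
  invisible(x)
}

#' Flag lines rescued by homoeologous dosage compensation
#'
#' The causal locus is unknown at this point, so a line is flagged
#' compensated when its *entire* compensating chromosome is at
#' `required_copies` or more — then the homoeolocus, wherever it is, is
#' at the required dose. In the published panel this singles out the
#' line carrying whole-chromosome 1B tetrasomy alongside 1D nullisomy.
#' Compensated lines are excluded from the mapping constraints: their
#' phenotype is explained without the target locus.
#'
#' @param calls list of [line_call()]s.
#' @param rule `list(chrom=, required_copies=)` (default 4 doses).
#' @param dosage lines x bins integer matrix of called (or truth) copy
#'   numbers; rownames must cover the call lines.
#' @param bins bins matching `dosage` columns.
#' @return the calls with `compensated` updated.
#' @export
apply_compensation <- function(calls, rule, dosage, bins) {
  if (is.null(rule$required_copies)) rule$required_copies <- 4
  sel <- bins$chrom == rule$chrom
  if (!any(sel)) stop("compensation chromosome '", rule$chrom,
                      "' has no bins in the layout")
  lapply(calls, function(cl) {
    if (!cl$line %in% rownames(dosage)) {
      stop("no dosage track for line '", cl$line, "'")
    }
    cl$compensated <-
      min(dosage[cl$line, sel]) >= rule$required_copies
    cl
  })
}

#' Map the causal locus from absence calls and viability phenotypes
#'
#' Intersects the absent regions of all constraining (non-compensated)
#' non-viable lines and subtracts every region absent in any
#' constraining viable line. Each maximal remaining interval is
#' reported with fraction-length (FL) bounds on its arm, the supporting
#' non-viable lines, and the lines excluded from the constraints with
#' reasons. Multiple disjoint candidates are all returned. An empty
#' result is returned explicitly (with diagnostics naming viable lines
#' whose absences erased the non-viable core), never as an error.
#'
#' @param calls list of [line_call()]s.
#' @param layout a [genome_layout()] (for FL bounds).
#' @return list of class `locus_map`: `intervals` (data frame `chrom`,
#'   `start`, `end`, `arm_start`, `fl_start`, `arm_end`, `fl_end`),
#'   `supporting_lines`, `excluded_lines` (data frame `line`,
#'   `reason`), `diagnostics` (character).
#' @export
map_locus <- function(calls, layout) {
  stopifnot(inherits(layout, "genome_layout"))
  phen <- vapply(calls, function(x) x$phenotype, character(1))
  comp <- vapply(calls, function(x) x$compensated, logical(1))
  nm <- vapply(calls, function(x) x$line, character(1))

  excluded <- data.frame(line = character(), reason = character(),
                         stringsAsFactors = FALSE)
  add_excl <- function(lines, reason) {
    if (length(lines)) {
      excluded <<- rbind(excluded, data.frame(line = lines, reason = reason,
                                              stringsAsFactors = FALSE))
    }
  }
  add_excl(nm[comp], "compensated: phenotype explained by homoeologous dosage")
  add_excl(nm[phen == "unknown" & !comp], "phenotype unknown")
  if (any(phen == "unknown")) {
    message("ignoring ", sum(phen == "unknown"),
            " line(s) with unknown phenotype")
  }

  nv <- calls[phen == "non_viable" & !comp]
  vi <- calls[phen == "viable" & !comp]
  diagnostics <- character()
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), arm_start = character(),
                      fl_start = numeric(), arm_end = character(),
                      fl_end = numeric(), stringsAsFactors = FALSE)
  result <- function(intervals, diag) {
    structure(list(intervals = intervals,
                   supporting_lines = vapply(nv, `[[`, character(1), "line"),
                   excluded_lines = excluded,
                   diagnostics = diag), class = "locus_map")
  }
  if (!length(nv) || all(vapply(nv, function(x) nrow(x$absent_intervals),
                                integer(1)) == 0)) {
    warning("no constraining non-viable line with a called absence; ",
            "candidate set is empty")
    return(result(empty, "no non-viable absence constraints"))
  }

  per_chrom <- lapply(layout$name, function(chrom) {
    nv_ir <- lapply(nv, function(cl) {
      d <- cl$absent_intervals
      .df_to_ir(d[d$chrom == chrom, , drop = FALSE])
    })
    core <- Reduce(IRanges::intersect, nv_ir)
    if (!length(core)) return(list(core = core, cand = core))
    vi_ir <- lapply(vi, function(cl) {
      d <- cl$absent_intervals
      .df_to_ir(d[d$chrom == chrom, , drop = FALSE])
    })
    viable_union <- if (length(vi_ir)) Reduce(IRanges::union, vi_ir) else
      IRanges::IRanges()
    list(core = core, cand = IRanges::setdiff(core, viable_union))
  })
  names(per_chrom) <- layout$name

  cand <- do.call(rbind, lapply(layout$name, function(chrom) {
    .ir_to_df(per_chrom[[chrom]]$cand, chrom)
  }))
  if (!nrow(cand)) {
    # non-viable core existed but viable absences erased it: name them
    culprits <- unique(unlist(lapply(layout$name, function(chrom) {
      core <- per_chrom[[chrom]]$core
      if (!length(core)) return(character())
      hit <- vapply(vi, function(cl) {
        d <- cl$absent_intervals
        ir <- .df_to_ir(d[d$chrom == chrom, , drop = FALSE])
        length(IRanges::setdiff(core, ir)) == 0
      }, logical(1))
      vapply(vi[hit], `[[`, character(1), "line")
    })))
    diagnostics <- c("candidate set empty after viable-line subtraction",
      if (length(culprits)) paste0(
        "contradiction: viable line(s) lacking the entire non-viable core: ",
        paste(culprits, collapse = ", ")))
    warning(paste(diagnostics, collapse = "; "))
    return(result(empty, diagnostics))
  }

  fs <- .fl_boundary_safe(layout, cand$chrom, cand$start)
  fe <- .fl_boundary_safe(layout, cand$chrom, cand$end)
  cand$arm_start <- fs$arm
  cand$fl_start <- fs$fl
  cand$arm_end <- fe$arm
  cand$fl_end <- fe$fl
  result(cand, diagnostics)
}

# vectorized over rows with possibly different chromosomes
.fl_boundary_safe <- function(layout, chrom, position) {
  out <- data.frame(arm = character(length(chrom)),
                    fl = numeric(length(chrom)), stringsAsFactors = FALSE)
  for (k in seq_along(chrom)) {
    b <- .fl_boundary(layout, chrom[k], position[k])
    out$arm[k] <- b$arm
    out$fl[k] <- b$fl
  }
  out
}

#' @export
print.locus_map <- function(x, ...) {
  cat("<locus_map> ", nrow(x$intervals), " candidate interval(s)\n", sep = "")
  if (nrow(x$intervals)) {
    for (k in seq_len(nrow(x$intervals))) {
      iv <- x$intervals[k, ]
      cat(sprintf("  %s:%s-%s  (%s FL %.3f to %s FL %.3f)\n", iv$chrom,
                  format(iv$start, big.mark = ",", scientific = FALSE),
                  format(iv$end, big.mark = ",", scientific = FALSE),
                  iv$arm_start, iv$fl_start, iv$arm_end, iv$fl_end))
    }
    cat("  supported by:", paste(x$supporting_lines, collapse = ", "), "\n")
  }
  if (length(x$diagnostics)) cat("  note:", x$diagnostics, "\n")
  invisible(x)
}

#' Proximal FL bound of the candidate on a given arm
#'
#' The smallest FL (closest to the centromere) covered by any candidate
#' interval on `chrom`'s arm `arm` — the mapped breakpoint bound of the
#' locus.
#'
#' @param map a `locus_map` from [map_locus()].
#' @param chrom,arm the arm of interest.
#' @return numeric FL, or `NA` if no candidate touches that arm.
#' @export
proximal_fl_bound <- function(map, chrom, arm) {
  iv <- map$intervals[map$intervals$chrom == chrom, , drop = FALSE]
  fls <- c(iv$fl_start[iv$arm_start == arm], iv$fl_end[iv$arm_end == arm])
  if (!length(fls)) return(NA_real_)
  min(fls)
}

#' Report lines inconsistent with a candidate interval
#'
#' Checks every line (compensation flags deliberately ignored — this is
#' the no-compensation view that motivates the compensation rule in the
#' first place): a viable line whose absences cover the entire candidate
#' set, or a non-viable line whose absences miss it entirely, is
#' reported with an explanation.
#'
#' @param calls list of [line_call()]s.
#' @param map a `locus_map` from [map_locus()].
#' @return data frame `line`, `phenotype`, `problem`; zero rows when
#'   the panel is fully consistent.
#' @export
detect_conflicts <- function(calls, map) {
  iv <- map$intervals
  out <- data.frame(line = character(), phenotype = character(),
                    problem = character(), stringsAsFactors = FALSE)
  if (!nrow(iv)) return(out)
  cand_ir <- split(iv, iv$chrom)
  for (cl in calls) {
    if (cl$phenotype == "unknown") next
    covered <- all(vapply(names(cand_ir), function(chrom) {
      d <- cl$absent_intervals
      ir <- .df_to_ir(d[d$chrom == chrom, , drop = FALSE])
      length(IRanges::setdiff(.df_to_ir(cand_ir[[chrom]]), ir)) == 0
    }, logical(1)))
    touched <- any(vapply(names(cand_ir), function(chrom) {
      d <- cl$absent_intervals
      ir <- .df_to_ir(d[d$chrom == chrom, , drop = FALSE])
      length(IRanges::intersect(.df_to_ir(cand_ir[[chrom]]), ir)) > 0
    }, logical(1)))
    if (cl$phenotype == "viable" && covered) {
      out <- rbind(out, data.frame(line = cl$line, phenotype = cl$phenotype,
        problem = "viable although the whole candidate region is absent",
        stringsAsFactors = FALSE))
    } else if (cl$phenotype == "non_viable" && !touched) {
      out <- rbind(out, data.frame(line = cl$line, phenotype = cl$phenotype,
        problem = "non-viable although the candidate region is fully present",
        stringsAsFactors = FALSE))
    }
  }
  out
}

#' Serialize a locus map to BED and JSON
#'
#' @param map a `locus_map`.
#' @param bed_path,json_path output paths (either may be `NULL`).
#' @return invisibly, the paths written.
#' @export
write_locus_map <- function(map, bed_path = NULL, json_path = NULL) {
  if (!is.null(bed_path)) {
    iv <- map$intervals
    write_bed(data.frame(chrom = iv$chrom, start = iv$start, end = iv$end,
                         name = sprintf("candidate_%d", seq_len(nrow(iv))),
                         stringsAsFactors = FALSE), bed_path)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      intervals = map$intervals,
      supporting_lines = map$supporting_lines,
      excluded_lines = map$excluded_lines,
      diagnostics = map$diagnostics
    ), json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(c(bed = bed_path, json = json_path))
}
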