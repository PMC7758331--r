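#' Genome layout: chromosomes, arms and centromeres
#'
#' A `genome_layout` is the coordinate frame of the whole pipeline: an
#' ordered set of chromosomes, each with a length, a centromere position
#' and an orientation flag saying which side of the centromere the short
#' arm occupies. All coordinates are 0-based, half-open (BED convention).
#'
#' @param name character vector of unique chromosome names.
#' @param length integer-like vector of chromosome lengths in bp.
#' @param centromere integer-like vector of centromere positions in bp,
#'   strictly inside each chromosome. The short arm occupies
#'   `[0, centromere)` when `short_arm_low` is `TRUE` (the wheat
#'   pseudomolecule convention), else `[centromere, length)`.
#' @param short_arm_low logical, recycled; orientation per chromosome.
#'
#' @return A data frame of class `genome_layout` with columns `name`,
#'   `length`, `centromere`, `short_arm_low`.
#' @examples
#' genome_layout("1D", 495453186, 166000000)
#' @export
genome_layout <- function(name, length, centromere, short_arm_low = TRUE) {
  name <- as.character(name)
  length <- as.numeric(length)
  centromere <- as.numeric(centromere)
  short_arm_low <- rep_len(as.logical(short_arm_low), base::length(name))
  if (anyDuplicated(name)) {
    stop("chromosome names must be unique: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  }
  if (base::length(length) != base::length(name) ||
      base::length(centromere) != base::length(name)) {
    stop("'name', 'length' and 'centromere' must have equal length")
  }
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop("chromosome lengths must be positive and finite")
  }
  if (any(!is.finite(centromere)) || any(centromere <= 0) ||
      any(centromere >= length)) {
    stop("centromere positions must satisfy 0 < centromere < length")
  }
  out <- data.frame(name = name, length = length, centromere = centromere,
                    short_arm_low = short_arm_low,
                    stringsAsFactors = FALSE)
  class(out) <- c("genome_layout", "data.frame")
  out
}

#' Representative hexaploid wheat group-1 layout
#'
#' Chromosomes 1A, 1B and 1D with pseudomolecule lengths close to the
#' Chinese Spring RefSeq v1.0 assembly and round-number centromere
#' positions. Centromere coordinates are not part of the assembly
#' release and differ between studies; treat them as adjustable
#' parameters (they control the FL <-> bp conversion), not as facts.
#'
#' @return A [genome_layout()].
#' @export
wheat_group1_layout <- function() {
  genome_layout(name = c("1A", "1B", "1D"),
                length = c(594102056, 689851870, 495453186),
                centromere = c(213000000, 240000000, 166000000))
}

.layout_row <- function(layout, chrom) {
  i <- match(chrom, layout$name)
  if (anyNA(i)) {
    stop("unknown chromosome: ", paste(chrom[is.na(i)], collapse = ", "))
  }
  i
}

#' Tile a genome layout with fixed-width bins
#'
#' Bins tile each chromosome without gaps or overlaps; the last bin of a
#' chromosome may be shorter than `width` (terminal sequence is kept).
#' Global bin indices are 1-based and consecutive in layout order.
#'
#' @param layout a [genome_layout()].
#' @param width bin width in bp (> 0); 1e6 reproduces the 1 Mb bins used
#'   for GBS coverage karyotyping.
#' @return data frame of class `genomic_bins`: `chrom`, `start`, `end`
#'   (0-based half-open), `index`.
#' @examples
#' build_bins(genome_layout("chr", 2.5e6, 1e6), 1e6)
#' @export
build_bins <- function(layout, width) {
  stopifnot(inherits(layout, "genome_layout"))
  if (!is.numeric(width) || length(width) != 1 || !is.finite(width) ||
      width <= 0) {
    stop("bin 'width' must be a single positive number")
  }
  pieces <- lapply(seq_len(nrow(layout)), function(i) {
    len <- layout$length[i]
    starts <- seq(0, len - 1, by = width)
    data.frame(chrom = layout$name[i], start = starts,
               end = pmin(starts + width, len), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out$index <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("genomic_bins", "data.frame")
  out
}

.arm_side <- function(layout, i, arm) {
  # "low" side = [0, centromere); returns TRUE if `arm` sits on the low side
  if (layout$short_arm_low[i]) arm == "S" else arm == "L"
}

#' Arm coordinate (FL) of a physical position
#'
#' Converts a bp position to the fraction-length (FL) coordinate used in
#' wheat deletion-stock nomenclature: the arm containing the position,
#' and the distance from the centromere as a fraction of that arm's
#' length. FL 0 is the centromere, FL 1 the telomere; a deletion line
#' with breakpoint FL 0.41 retains the proximal 41% of the arm.
#'
#' @param layout a [genome_layout()].
#' @param chrom chromosome name (scalar).
#' @param position bp position(s) in `[0, length)`.
#' @return data frame with columns `chrom`, `arm` (`"S"`/`"L"`), `fl`.
#' @seealso [position_of()] for the inverse.
#' @export
fl_of <- function(layout, chrom, position) {
  stopifnot(inherits(layout, "genome_layout"), length(chrom) == 1)
  i <- .layout_row(layout, chrom)
  position <- as.numeric(position)
  if (any(position < 0) || any(position >= layout$length[i])) {
    stop("position out of range [0, ", format(layout$length[i], scientific = FALSE),
         ") on chromosome ", chrom)
  }
  cen <- layout$centromere[i]
  len <- layout$length[i]
  low <- position < cen
  low_arm <- if (layout$short_arm_low[i]) "S" else "L"
  high_arm <- if (layout$short_arm_low[i]) "L" else "S"
  data.frame(chrom = chrom,
             arm = ifelse(low, low_arm, high_arm),
             fl = ifelse(low, (cen - position) / cen,
                         (position - cen) / (len - cen)),
             stringsAsFactors = FALSE)
}

#' Physical position of an arm (FL) coordinate
#'
#' Inverse of [fl_of()] up to integer truncation. The result is rounded
#' half away from the centromere, so `position_of` followed by `fl_of`
#' reproduces an FL coordinate to within one bp-equivalent. `fl = 0`
#' maps to the centromere; `fl = 1` maps to the arm's telomeric boundary
#' (`length` for the high-coordinate arm, `0` for the low one).
#'
#' @param layout a [genome_layout()].
#' @param chrom chromosome name (scalar).
#' @param arm `"S"` or `"L"` (scalar).
#' @param fl fraction(s) of arm length in `[0, 1]`.
#' @return numeric bp position(s).
#' @export
position_of <- function(layout, chrom, arm, fl) {
  stopifnot(inherits(layout, "genome_layout"), length(chrom) == 1,
            length(arm) == 1)
  if (!arm %in% c("S", "L")) stop("unknown arm '", arm, "' (use \"S\" or \"L\")")
  i <- .layout_row(layout, chrom)
  fl <- as.numeric(fl)
  if (any(fl < 0) || any(fl > 1)) stop("fl must lie in [0, 1]")
  cen <- layout$centromere[i]
  len <- layout$length[i]
  if (.arm_side(layout, i, arm)) {
    # low-coordinate arm: positions decrease away from the centromere;
    # round half away from the centromere = round half down
    x <- cen - fl * cen
    ceiling(x - 0.5)
  } else {
    x <- cen + fl * (len - cen)
    floor(x + 0.5)
  }
}

# FL of an interval boundary; accepts position == length (telomere edge).
.fl_boundary <- function(layout, chrom, position) {
  i <- .layout_row(layout, chrom)
  cen <- layout$centromere[i]
  len <- layout$length[i]
  low <- position < cen
  low_arm <- if (layout$short_arm_low[i]) "S" else "L"
  high_arm <- if (layout$short_arm_low[i]) "L" else "S"
  data.frame(arm = ifelse(low, low_arm, high_arm),
             fl = ifelse(low, (cen - position) / cen,
                         (position - cen) / (len - cen)),
             stringsAsFactors = FALSE)
}

#' Read / write a genome layout (JSON or YAML)
#'
#' Serialized as a list of records `{name, length, centromere,
#' short_arm_low}`. The format is chosen by file extension
#' (`.json` vs `.yaml`/`.yml`).
#'
#' @param path file path.
#' @param layout a [genome_layout()] (for writing).
#' @return `read_layout` returns a [genome_layout()];
#'   `write_layout` returns `path` invisibly.
#' @export
read_layout <- function(path) {
  recs <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  }
  if (is.data.frame(recs)) recs <- split(recs, seq_len(nrow(recs)))
  genome_layout(
    name = vapply(recs, function(r) as.character(r$name), character(1)),
    length = vapply(recs, function(r) as.numeric(r$length), numeric(1)),
    centromere = vapply(recs, function(r) as.numeric(r$centromere), numeric(1)),
    short_arm_low = vapply(recs, function(r) {
      if (is.null(r$short_arm_low)) TRUE else as.logical(r$short_arm_low)
    }, logical(1))
  )
}

#' @rdname read_layout
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "genome_layout"))
  recs <- lapply(seq_len(nrow(layout)), function(i) {
    list(name = layout$name[i], length = layout$length[i],
         centromere = layout$centromere[i],
         short_arm_low = layout$short_arm_low[i])
  })
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(recs, path)
  } else {
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Export bins as BED3 plus index column
#'
#' @param bins a `genomic_bins` data frame from [build_bins()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bins_bed <- function(bins, path) {
  write_bed(data.frame(chrom = bins$chrom, start = bins$start,
                       end = bins$end, name = bins$index,
                       stringsAsFactors = FALSE), path)
}
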