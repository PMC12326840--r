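## TAD tracks: per-species sorted, non-overlapping intervals from BED3.
## TAD callers emit a partition of the chromosome axis, so overlap within a
## chromosome is treated as corrupt input rather than silently merged.

#' Construct a TAD track
#'
#' A `tad_track` is a data frame of 0-based half-open intervals
#' (`chrom`, `start`, `end`) for one species, sorted by (chrom, start), with
#' exact duplicates removed. Overlapping intervals on one chromosome are an
#' error: TAD calls partition the axis.
#'
#' @param species Species name.
#' @param intervals Data frame with columns `chrom` (character) and
#'   `start`, `end` (base pairs, 0-based half-open).
#' @return A `tad_track`: the sorted interval data frame with attribute
#'   `species`.
#' @export
tad_track <- function(species, intervals) {
  assert_that(is.character(species) && length(species) == 1L,
              "species must be a single string")
  if (nrow(intervals) == 0L) {
    tr <- data.frame(chrom = character(), start = numeric(), end = numeric())
    attr(tr, "species") <- species
    class(tr) <- c("tad_track", "data.frame")
    return(tr)
  }
  intervals <- intervals[, c("chrom", "start", "end")]
  intervals$chrom <- as.character(intervals$chrom)
  bad <- which(intervals$end <= intervals$start)
  assert_that(length(bad) == 0L,
              sprintf("interval end <= start at line(s) %s",
                      paste(bad, collapse = ", ")))
  intervals <- unique(intervals)
  intervals <- intervals[order(intervals$chrom, intervals$start, intervals$end), ]
  rownames(intervals) <- NULL
  ## overlap check within chromosome on the sorted track
  for (chr in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == chr, ]
    if (nrow(iv) > 1L && any(iv$start[-1L] < iv$end[-nrow(iv)])) {
      i <- which(iv$start[-1L] < iv$end[-nrow(iv)])[1L]
      stop(sprintf(
        "overlapping TAD intervals on %s: [%d,%d) and [%d,%d) (%s)",
        chr, iv$start[i], iv$end[i], iv$start[i + 1L], iv$end[i + 1L], species),
        call. = FALSE)
    }
  }
  attr(intervals, "species") <- species
  class(intervals) <- c("tad_track", "data.frame")
  intervals
}

#' Read TAD calls from a BED file
#'
#' Reads a 3+ column BED file (0-based half-open) into a [tad_track()].
#' Extra columns are ignored. An empty file yields an empty track with a
#' logged warning. Malformed intervals (`end <= start`) and within-chromosome
#' overlaps are errors that name the offending line.
#'
#' @param path Path to a BED file.
#' @param species Species name attached to the track.
#' @return A `tad_track`.
#' @export
read_tad_bed <- function(path, species) {
  assert_that(file.exists(path), sprintf("BED file not found: %s", path))
  if (file.size(path) == 0L ||
      length(readLines(path, n = 1L, warn = FALSE)) == 0L) {
    tv_log(sprintf("empty BED file for %s: %s", species, path), stage = "io")
    return(tad_track(species, data.frame(chrom = character(),
                                         start = numeric(), end = numeric())))
  }
  raw <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  assert_that(ncol(raw) >= 3L, sprintf("%s: BED needs >= 3 columns", path))
  bed <- data.frame(chrom = as.character(raw[[1L]]),
                    start = as.numeric(raw[[2L]]),
                    end = as.numeric(raw[[3L]]))
  assert_that(all(is.finite(bed$start)) && all(is.finite(bed$end)),
              sprintf("%s: non-numeric coordinates", path))
  bad <- which(bed$end <= bed$start)
  assert_that(length(bad) == 0L,
              sprintf("%s: end <= start at line(s) %s", path,
                      paste(bad, collapse = ", ")))
  tad_track(species, bed)
}

#' Write a TAD track to BED3
#'
#' Inverse of [read_tad_bed()]: coordinates are written as stored (0-based
#' half-open), so a read/write round trip is exact.
#'
#' @param track A `tad_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tad_bed <- function(track, path) {
  write.table(as.data.frame(track)[, c("chrom", "start", "end")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
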