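## Block profiles: the per-(block, species) summary every analysis consumes —
## TAD count in the segment, normalized internal border positions on the
## oriented 0-1 scale, and the gene -> TAD assignment.

#' Profile one species' TADs within one syntenic block
#'
#' Intersects a species' TAD track with its segment of a syntenic block and
#' derives:
#' \itemize{
#'   \item `tad_count`: number of TADs overlapping the segment by at least
#'     `min_overlap` of the shorter of (TAD, segment) — default any-overlap
#'     (>= 1 bp), the `bedtools intersect` default;
#'   \item `borders`: every start/end of a counted TAD that lies strictly
#'     inside the segment, normalized to `(p - start)/(end - start)` and, for
#'     inverted segments, reflected `x -> 1 - x` and re-sorted so that the
#'     scale runs in the block's oriented gene order;
#'   \item `gene_to_tad`: each gene (by midpoint) assigned to the counted TAD
#'     covering it, indexed 0-based in oriented block order; genes whose
#'     midpoint falls in no counted TAD get `NA` and are excluded from
#'     gene-level metrics.
#' }
#'
#' @param block A [synteny_block()].
#' @param track The species' [tad_track()].
#' @param species Species name (must be in the block and match the track).
#' @param min_overlap Minimum overlap fraction of the shorter feature for a
#'   TAD to be counted (0 = any overlap; default).
#' @return A `block_profile`: list with `block_id`, `species`, `tad_count`,
#'   `borders` (increasing fractions in (0,1)), `gene_to_tad` (named integer
#'   vector over ortholog groups, `NA` = unassigned) and `length_mbp`.
#' @export
profile_block <- function(block, track, species, min_overlap = 0) {
  assert_that(species %in% block_species(block),
              sprintf("species %s not in block %s", species, block$block_id))
  seg <- block$segments[[species]]
  assert_that(seg$end > seg$start,
              sprintf("block %s/%s: zero-length segment",
                      block$block_id, species))
  iv <- as.data.frame(track)
  iv <- iv[iv$chrom == seg$chrom & iv$end > seg$start & iv$start < seg$end, ,
           drop = FALSE]
  if (min_overlap > 0 && nrow(iv) > 0L) {
    ov <- pmin(iv$end, seg$end) - pmax(iv$start, seg$start)
    shorter <- pmin(iv$end - iv$start, seg$end - seg$start)
    iv <- iv[ov / shorter >= min_overlap, , drop = FALSE]
  }
  iv <- iv[order(iv$start), , drop = FALSE]
  n <- nrow(iv)
  L <- seg$end - seg$start
  inv <- identical(seg$orientation, "inverted")

  ## borders: all counted start/ends strictly inside the segment
  pts <- sort(unique(c(iv$start, iv$end)))
  pts <- pts[pts > seg$start & pts < seg$end]
  borders <- (pts - seg$start) / L
  if (inv) borders <- sort(1 - borders)

  ## gene -> TAD by midpoint; TAD index is oriented rank (0-based)
  g <- block$genes[[species]]
  mid <- (g$start + g$end) / 2
  idx <- rep(NA_integer_, nrow(g))
  if (n > 0L) {
    for (i in seq_len(nrow(g))) {
      hit <- which(iv$start <= mid[i] & mid[i] < iv$end)
      if (length(hit) == 1L) idx[i] <- hit - 1L
    }
    if (inv) idx <- ifelse(is.na(idx), NA_integer_, (n - 1L) - idx)
  }
  names(idx) <- g$ortholog_group
  if (anyNA(idx))
    tv_log(sprintf("block %s/%s: %d gene(s) in no counted TAD, excluded",
                   block$block_id, species, sum(is.na(idx))),
           stage = "profiles")
  structure(list(block_id = block$block_id, species = species,
                 tad_count = n, borders = borders, gene_to_tad = idx,
                 length_mbp = L / 1e6,
                 orientation = seg$orientation),
            class = "block_profile")
}

#' Build profiles for all blocks and species
#'
#' @param blocks Named list of [synteny_block()] objects.
#' @param tracks Named list (by species) of [tad_track()] objects covering
#'   every species that appears in any block.
#' @inheritParams profile_block
#' @return A `block_profile_set`: nested named list
#'   `profiles[[block_id]][[species]]`, with a `counts` matrix (blocks x
#'   species, `NA` where absent) and a `lengths_mbp` matrix as attributes.
#' @export
build_block_profiles <- function(blocks, tracks, min_overlap = 0) {
  sp_all <- sort(unique(unlist(lapply(blocks, block_species))))
  missing <- setdiff(sp_all, names(tracks))
  assert_that(length(missing) == 0L,
              sprintf("no TAD track for species: %s",
                      paste(missing, collapse = ", ")))
  out <- list()
  ids <- unname(vapply(blocks, function(b) b$block_id, ""))
  counts <- matrix(NA_real_, length(blocks), length(sp_all),
                   dimnames = list(ids, sp_all))
  lens <- counts
  for (b in seq_along(blocks)) {
    blk <- blocks[[b]]
    prof <- list()
    for (sp in block_species(blk)) {
      p <- profile_block(blk, tracks[[sp]], sp, min_overlap = min_overlap)
      prof[[sp]] <- p
      counts[blk$block_id, sp] <- p$tad_count
      lens[blk$block_id, sp] <- p$length_mbp
    }
    out[[blk$block_id]] <- prof
  }
  structure(out, counts = counts, lengths_mbp = lens,
            class = "block_profile_set")
}

#' TAD-count matrix of a profile set
#'
#' @param profiles A `block_profile_set`.
#' @return Numeric matrix blocks x species of TAD counts (`NA` where the
#'   species is absent from the block).
#' @export
profile_counts <- function(profiles) attr(profiles, "counts")

#' Block-length matrix (Mbp) of a profile set
#' @param profiles A `block_profile_set`.
#' @return Numeric matrix blocks x species of segment lengths in Mbp.
#' @export
profile_lengths <- function(profiles) attr(profiles, "lengths_mbp")

#' @export
print.block_profile_set <- function(x, ...) {
  cm <- profile_counts(x)
  cat(sprintf("<block_profile_set: %d blocks x %d species, median TAD count %g>\n",
              nrow(cm), ncol(cm), stats::median(cm, na.rm = TRUE)))
  invisible(x)
}
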