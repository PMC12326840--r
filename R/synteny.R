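## Syntenic blocks: conserved segments with an ordered list of orthologous
## genes per species. The on-disk dialect is a documented TSV with one row
## per (block, species):
##
##   block_id  clade  species  chrom  start  end  orientation  genes
##
## start/end are 0-based half-open; orientation is "forward" or "inverted";
## genes is a semicolon-separated list of gene_id:ortholog_group:start:end:strand
## entries sorted by genomic coordinate. A best-effort importer for raw
## Cyntenator alignment output is provided separately.

#' Construct one syntenic block
#'
#' A syntenic block is a genomic segment conserved across species with
#' preserved orthologous gene order. Validation enforces: at least two
#' ortholog groups per member species; genes inside their segment and sorted
#' by coordinate; and, after orientation correction (reversal of inverted
#' segments), an identical ortholog-group order in every species. The first
#' species listed is the reference for gene order.
#'
#' @param block_id Block identifier.
#' @param clade Clade / alignment label the block belongs to.
#' @param segments Named list (by species) of lists with `chrom`, `start`,
#'   `end` (bp, 0-based half-open) and `orientation`
#'   (`"forward"`/`"inverted"`).
#' @param genes Named list (by species) of data frames with columns
#'   `gene_id`, `ortholog_group`, `start`, `end`, `strand`, sorted by `start`.
#' @return An object of class `synteny_block`.
#' @export
synteny_block <- function(block_id, clade, segments, genes) {
  species <- names(segments)
  assert_that(length(species) >= 1L && !is.null(species),
              "segments must be a named list")
  assert_that(identical(sort(species), sort(names(genes))),
              sprintf("block %s: segments and genes name different species",
                      block_id))
  ref_order <- NULL
  for (sp in species) {
    seg <- segments[[sp]]
    assert_that(seg$end > seg$start,
                sprintf("block %s/%s: segment has non-positive length",
                        block_id, sp))
    assert_that(seg$orientation %in% c("forward", "inverted"),
                sprintf("block %s/%s: bad orientation '%s'",
                        block_id, sp, seg$orientation))
    g <- genes[[sp]]
    assert_that(nrow(g) >= 2L && length(unique(g$ortholog_group)) >= 2L,
                sprintf("block %s/%s: needs >= 2 ortholog groups",
                        block_id, sp))
    assert_that(all(g$start >= seg$start) && all(g$end <= seg$end),
                sprintf("block %s/%s: gene outside its segment",
                        block_id, sp))
    assert_that(!is.unsorted(g$start),
                sprintf("block %s/%s: genes not sorted by coordinate",
                        block_id, sp))
    ord <- g$ortholog_group
    if (seg$orientation == "inverted") ord <- rev(ord)
    if (is.null(ref_order)) {
      ref_order <- ord
    } else {
      shared_ref <- ref_order[ref_order %in% ord]
      shared_sp <- ord[ord %in% ref_order]
      assert_that(identical(shared_ref, shared_sp),
                  sprintf(paste0("block %s/%s: ortholog order mismatch after ",
                                 "orientation correction"), block_id, sp))
    }
  }
  structure(list(block_id = block_id, clade = clade,
                 segments = segments, genes = genes),
            class = "synteny_block")
}

#' @export
print.synteny_block <- function(x, ...) {
  cat(sprintf("<synteny_block %s [%s]: %d species, %d ortholog groups>\n",
              x$block_id, x$clade, length(x$segments),
              length(block_ortholog_order(x))))
  invisible(x)
}

#' Species present in a block
#' @param block A `synteny_block`.
#' @return Character vector of species names.
#' @export
block_species <- function(block) names(block$segments)

#' Oriented ortholog-group order of a block
#'
#' The shared gene order of the block, read from its reference species (the
#' first species listed) after orientation correction.
#'
#' @param block A `synteny_block`.
#' @return Character vector of ortholog-group labels in block order.
#' @export
block_ortholog_order <- function(block) {
  sp <- block_species(block)[1L]
  ord <- block$genes[[sp]]$ortholog_group
  if (block$segments[[sp]]$orientation == "inverted") ord <- rev(ord)
  ord
}

#' Segment length in Mbp
#' @param block A `synteny_block`.
#' @param species Species name.
#' @return Length of the species' segment in megabase pairs.
#' @export
block_length_mbp <- function(block, species) {
  seg <- block$segments[[species]]
  (seg$end - seg$start) / 1e6
}

#' Read syntenic blocks from the documented TSV
#'
#' Parses the package's block TSV dialect (see file header of the source, or
#' [write_synteny_blocks()]) and validates every block against the
#' `synteny_block` invariants. Blocks missing one of `species_list` are
#' retained but flagged via the `complete` attribute on each block.
#'
#' @param path Path to the block TSV.
#' @param species_list Optional character vector of required species; when
#'   given, each block gains attribute `complete` (TRUE if all are present).
#' @return A named list of `synteny_block` objects (names = block ids).
#' @export
read_synteny_blocks <- function(path, species_list = NULL) {
  assert_that(file.exists(path), sprintf("block file not found: %s", path))
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    quote = "", comment.char = "")
  need <- c("block_id", "clade", "species", "chrom", "start", "end",
            "orientation", "genes")
  assert_that(all(need %in% names(tab)),
              sprintf("%s: missing columns %s", path,
                      paste(setdiff(need, names(tab)), collapse = ", ")))
  out <- list()
  for (bid in unique(tab$block_id)) {
    rows <- tab[tab$block_id == bid, , drop = FALSE]
    segments <- list()
    genes <- list()
    for (i in seq_len(nrow(rows))) {
      sp <- rows$species[i]
      segments[[sp]] <- list(chrom = rows$chrom[i], start = rows$start[i],
                             end = rows$end[i],
                             orientation = rows$orientation[i])
      genes[[sp]] <- parse_gene_field(rows$genes[i], bid, sp)
    }
    blk <- synteny_block(bid, rows$clade[1L], segments, genes)
    if (!is.null(species_list)) {
      complete <- all(species_list %in% names(segments))
      attr(blk, "complete") <- complete
      if (!complete)
        tv_log(sprintf("block %s missing species: %s", bid,
                       paste(setdiff(species_list, names(segments)),
                             collapse = ", ")), stage = "io")
    }
    out[[bid]] <- blk
  }
  out
}

#' @noRd
parse_gene_field <- function(field, block_id, species) {
  entries <- strsplit(field, ";", fixed = TRUE)[[1L]]
  parts <- strsplit(entries, ":", fixed = TRUE)
  ok <- vapply(parts, length, 1L) == 5L
  assert_that(all(ok),
              sprintf("block %s/%s: malformed gene entry '%s'",
                      block_id, species, entries[!ok][1L]))
  m <- do.call(rbind, parts)
  data.frame(gene_id = m[, 1L], ortholog_group = m[, 2L],
             start = as.numeric(m[, 3L]), end = as.numeric(m[, 4L]),
             strand = m[, 5L], stringsAsFactors = FALSE)
}

#' Write syntenic blocks to the documented TSV
#'
#' Inverse of [read_synteny_blocks()]; a write/read round trip reproduces the
#' blocks exactly.
#'
#' @param blocks List of `synteny_block` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_synteny_blocks <- function(blocks, path) {
  rows <- list()
  for (blk in blocks) {
    for (sp in block_species(blk)) {
      seg <- blk$segments[[sp]]
      g <- blk$genes[[sp]]
      gene_field <- paste(sprintf("%s:%s:%s:%s:%s", g$gene_id,
                                  g$ortholog_group,
                                  format(g$start, scientific = FALSE,
                                         trim = TRUE),
                                  format(g$end, scientific = FALSE,
                                         trim = TRUE),
                                  g$strand),
                          collapse = ";")
      rows[[length(rows) + 1L]] <- data.frame(
        block_id = blk$block_id, clade = blk$clade, species = sp,
        chrom = seg$chrom, start = seg$start, end = seg$end,
        orientation = seg$orientation, genes = gene_field,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Best-effort import of raw Cyntenator alignment output
#'
#' Cyntenator reports syntenic alignments as blocks of lines, one gene per
#' line, each carrying the per-genome gene name and coordinates. Dialects
#' vary between runs; this importer handles the common tab-separated layout
#'
#' \preformatted{
#' >alignment <id> score <s>
#' <species> <chrom> <start> <end> <strand> <gene_id> <ortholog_group>
#' ...
#' }
#'
#' with 1-based inclusive coordinates, converted to the package's 0-based
#' half-open convention on read. Segment bounds are the span of the block's
#' genes per species; orientation is inferred from ortholog order relative to
#' the first species. Records that cannot be reconciled into a valid block
#' are dropped with a logged message rather than aborting the import.
#'
#' @param path Path to a Cyntenator-style alignment file.
#' @param clade Clade label to attach to imported blocks.
#' @return A named list of `synteny_block` objects.
#' @export
read_cyntenator <- function(path, clade = "imported") {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  assert_that(length(starts) > 0L,
              sprintf("%s: no '>' alignment headers found", path))
  bounds <- c(starts, length(lines) + 1L)
  out <- list()
  for (k in seq_along(starts)) {
    hdr <- lines[starts[k]]
    id <- sub("^>\\s*alignment\\s+(\\S+).*$", "\\1", hdr)
    if (identical(id, hdr)) id <- sprintf("aln_%d", k)
    body <- lines[seq(starts[k] + 1L, bounds[k + 1L] - 1L)]
    fields <- strsplit(body, "[\t ]+")
    ok <- vapply(fields, length, 1L) >= 7L
    if (!all(ok)) {
      tv_log(sprintf("alignment %s: skipping %d malformed line(s)",
                     id, sum(!ok)), stage = "io")
      fields <- fields[ok]
    }
    if (length(fields) == 0L) next
    m <- do.call(rbind, lapply(fields, `[`, 1:7))
    tab <- data.frame(species = m[, 1L], chrom = m[, 2L],
                      start = as.numeric(m[, 3L]) - 1,  # 1-based -> 0-based
                      end = as.numeric(m[, 4L]),
                      strand = m[, 5L], gene_id = m[, 6L],
                      ortholog_group = m[, 7L], stringsAsFactors = FALSE)
    blk <- tryCatch(cyntenator_block(id, clade, tab),
                    error = function(e) {
                      tv_log(sprintf("alignment %s dropped: %s", id,
                                     conditionMessage(e)), stage = "io")
                      NULL
                    })
    if (!is.null(blk)) out[[blk$block_id]] <- blk
  }
  out
}

#' @noRd
cyntenator_block <- function(id, clade, tab) {
  species <- unique(tab$species)
  segments <- list()
  genes <- list()
  ref_ord <- NULL
  for (sp in species) {
    g <- tab[tab$species == sp, , drop = FALSE]
    g <- g[order(g$start), ]
    ord <- g$ortholog_group
    orientation <- "forward"
    if (!is.null(ref_ord)) {
      shared <- ref_ord[ref_ord %in% ord]
      if (identical(rev(ord[ord %in% ref_ord]), shared))
        orientation <- "inverted"
    } else {
      ref_ord <- ord
    }
    segments[[sp]] <- list(chrom = g$chrom[1L], start = min(g$start),
                           end = max(g$end), orientation = orientation)
    genes[[sp]] <- data.frame(gene_id = g$gene_id,
                              ortholog_group = g$ortholog_group,
                              start = g$start, end = g$end,
                              strand = g$strand, stringsAsFactors = FALSE)
  }
  synteny_block(id, clade, segments, genes)
}
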