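## Shared fixture builders. Everything is constructed in code; no files ship
## with the tests except what a test writes to tempdir().

nwk <- function(text) ape::read.tree(text = text)

## Minimal block_profile, bypassing interval plumbing, for metric-level tests.
make_profile <- function(block_id, species, tad_count, borders = numeric(),
                         gene_to_tad = integer(), length_mbp = 1) {
  structure(list(block_id = block_id, species = species,
                 tad_count = tad_count, borders = borders,
                 gene_to_tad = gene_to_tad, length_mbp = length_mbp,
                 orientation = "forward"),
            class = "block_profile")
}

## Assemble a block_profile_set from a blocks x species count matrix (and
## optional per-cell profile objects / length matrix).
make_profile_set <- function(counts, lengths = NULL, profiles = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- if (!is.null(profiles)) names(profiles)
                        else sprintf("b%02d", seq_len(nrow(counts)))
  }
  if (is.null(lengths))
    lengths <- matrix(1, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  if (is.null(profiles)) {
    profiles <- lapply(rownames(counts), function(bid) {
      pr <- lapply(colnames(counts), function(sp)
        make_profile(bid, sp, counts[bid, sp], length_mbp = lengths[bid, sp]))
      names(pr) <- colnames(counts)
      pr
    })
    names(profiles) <- rownames(counts)
  }
  structure(profiles, counts = counts, lengths_mbp = lengths,
            class = "block_profile_set")
}

## One synteny block with evenly spaced genes, for io/profile tests.
simple_block <- function(block_id = "b1", species = c("A", "B"),
                         n_genes = 3, seg_len = 300, invert = character()) {
  segments <- list()
  genes <- list()
  for (sp in species) {
    inv <- sp %in% invert
    mids <- seq_len(n_genes) / (n_genes + 1) * seg_len
    if (inv) mids <- sort(seg_len - mids)
    og <- sprintf("og%d", seq_len(n_genes))
    if (inv) og <- rev(og)
    segments[[sp]] <- list(chrom = "chr1", start = 0, end = seg_len,
                           orientation = if (inv) "inverted" else "forward")
    genes[[sp]] <- data.frame(gene_id = paste0(sp, "_", og),
                              ortholog_group = og,
                              start = mids - 5, end = mids + 5,
                              strand = "+", stringsAsFactors = FALSE)
  }
  synteny_block(block_id, "test", segments, genes)
}

## Independent oracle: breadth-first search over single-cut edits between two
## partitions of an n-gene list, states encoded as bitmasks over cut slots.
bfs_edit_distance <- function(cuts_a, cuts_b, n) {
  slots <- n - 1L
  mask <- function(cuts) sum(bitwShiftL(1L, cuts - 1L))
  start <- mask(cuts_a)
  goal <- mask(cuts_b)
  if (start == goal) return(0L)
  dist <- rep(NA_integer_, bitwShiftL(1L, slots))
  dist[start + 1L] <- 0L
  frontier <- start
  while (length(frontier)) {
    nxt <- integer(0)
    for (s in frontier) {
      for (k in seq_len(slots)) {
        nb <- bitwXor(s, bitwShiftL(1L, k - 1L))
        if (is.na(dist[nb + 1L])) {
          dist[nb + 1L] <- dist[s + 1L] + 1L
          if (nb == goal) return(dist[nb + 1L])
          nxt <- c(nxt, nb)
        }
      }
    }
    frontier <- nxt
  }
  stop("BFS failed to reach goal")
}

## All partitions of an ordered n-gene list, as cut-index vectors.
all_partitions <- function(n) {
  slots <- n - 1L
  lapply(seq_len(bitwShiftL(1L, slots)) - 1L, function(m)
    which(bitwAnd(bitwShiftL(1L, seq_len(slots) - 1L), m) > 0L))
}

## Profile pair realizing given TAD-index vectors over shared genes.
profiles_from_indices <- function(idx_i, idx_j, length_mbp = 1) {
  og <- sprintf("og%d", seq_along(idx_i))
  list(i = make_profile("b1", "A", max(idx_i) + 1L,
                        gene_to_tad = setNames(as.integer(idx_i), og),
                        length_mbp = length_mbp),
       j = make_profile("b1", "B", max(idx_j) + 1L,
                        gene_to_tad = setNames(as.integer(idx_j), og),
                        length_mbp = length_mbp))
}
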