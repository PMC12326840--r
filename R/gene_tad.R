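## Gene-TAD conformation: do orthologous genes stay in the same TAD, and how
## many border insertions/deletions separate two species' conformations?
## The canonical encoding of "which genes share a TAD" is the cut set of the
## ordered shared ortholog list.

#' Gene partition of a block profile as a cut set
#'
#' Encodes the gene -> TAD assignment of a profile as the set of cut indices
#' `c` in `1..n-1` where genes `g_c` and `g_(c+1)` of the ordered shared
#' ortholog list `order` fall in different TADs. Genes unassigned in the
#' profile (or absent from `order`) are dropped from the list before cutting
#' (logged), so cut indices refer to positions in the retained list.
#'
#' @param profile A `block_profile`.
#' @param order Character vector: the block's oriented ortholog-group order
#'   (see [block_ortholog_order()]). Defaults to the order of
#'   `profile$gene_to_tad`.
#' @return Integer vector of cut indices (possibly empty), with the retained
#'   ortholog list as attribute `genes`.
#' @export
gene_partition <- function(profile, order = names(profile$gene_to_tad)) {
  idx <- profile$gene_to_tad[order]
  drop <- is.na(idx)
  if (any(drop))
    tv_log(sprintf("block %s/%s: dropping %d unassigned gene(s) from partition",
                   profile$block_id, profile$species, sum(drop)),
           stage = "genes")
  idx <- idx[!drop]
  n <- length(idx)
  cuts <- if (n >= 2L) which(idx[-n] != idx[-1L]) else integer(0)
  attr(cuts, "genes") <- names(idx)
  cuts
}

#' Same-TAD gene conservation for a species pair
#'
#' Over blocks where both species have the same TAD count, counts orthologous
#' genes whose oriented TAD index is identical in the two species ("the gene
#' stayed in the same TAD"). The summary is normalised per Mbp of block
#' length (mean of the two species' segment lengths) and per Myr of
#' divergence, giving genes·Mbp⁻¹·Myr⁻¹.
#'
#' @param profiles A `block_profile_set`.
#' @param species_i,species_j Species names.
#' @param tree Optional phylogeny for the per-Myr normalisation.
#' @return A list of class `gene_conservation`: `same_tad_genes`,
#'   `total_genes`, `same_tad_fraction`, `genes_per_mbp`,
#'   `genes_per_mbp_per_myr`, `n_blocks`, `divergence_myr`, and the
#'   per-block table `blocks`.
#' @export
same_tad_fraction <- function(profiles, species_i, species_j, tree = NULL) {
  ids <- select_equal_tad_blocks(profiles, species_i, species_j,
                                 min_count = 1)
  rows <- list()
  for (bid in ids) {
    pi_ <- profiles[[bid]][[species_i]]
    pj <- profiles[[bid]][[species_j]]
    shared <- intersect(names(pi_$gene_to_tad), names(pj$gene_to_tad))
    ii <- pi_$gene_to_tad[shared]
    jj <- pj$gene_to_tad[shared]
    ok <- !is.na(ii) & !is.na(jj)
    rows[[bid]] <- data.frame(
      block_id = bid, n_genes = sum(ok), same_tad = sum(ii[ok] == jj[ok]),
      length_mbp = mean(c(pi_$length_mbp, pj$length_mbp)),
      stringsAsFactors = FALSE)
  }
  blocks <- if (length(rows)) do.call(rbind, rows) else
    data.frame(block_id = character(), n_genes = integer(),
               same_tad = integer(), length_mbp = numeric())
  rownames(blocks) <- NULL
  same <- sum(blocks$same_tad)
  total <- sum(blocks$n_genes)
  mbp <- sum(blocks$length_mbp)
  div <- if (!is.null(tree)) divergence_time(tree, species_i, species_j)
         else NA_real_
  structure(list(species_i = species_i, species_j = species_j,
                 same_tad_genes = same, total_genes = total,
                 same_tad_fraction = if (total > 0) same / total else NA_real_,
                 genes_per_mbp = if (mbp > 0) same / mbp else NA_real_,
                 genes_per_mbp_per_myr =
                   if (mbp > 0) same / mbp / div else NA_real_,
                 n_blocks = length(ids), divergence_myr = div,
                 blocks = blocks),
            class = "gene_conservation")
}

#' Gene-shuffle permutation null for same-TAD conservation
#'
#' Null model for [same_tad_fraction()]: in each permutation every shared
#' gene of one species is independently reassigned a uniform-random TAD index
#' in `[0, tad_count)` of its block, preserving the number of genes per block
#' and the block's TAD count; the same-TAD count is recomputed. Conservation
#' means the observed count *exceeds* the null, so the empirical p-value is
#' the upper-tail add-one estimator.
#'
#' @inheritParams same_tad_fraction
#' @param n_permutations Number of shuffles (default 1000).
#' @param seed Integer seed.
#' @return A list of class `gene_null`: `observed` (same-TAD gene count),
#'   `null_counts`, `fold_vs_null`, `empirical_p`, plus the fields of the
#'   observed [same_tad_fraction()] under `$conservation`.
#' @export
gene_shuffle_null <- function(profiles, species_i, species_j,
                              n_permutations = 1000, seed = 1L,
                              tree = NULL) {
  assert_that(is_count(n_permutations) && n_permutations >= 1,
              "n_permutations must be a positive integer")
  cons <- same_tad_fraction(profiles, species_i, species_j, tree = tree)
  ids <- cons$blocks$block_id
  ## collect per-block fixed indices of species i and tad counts
  fixed <- list()
  for (bid in ids) {
    pi_ <- profiles[[bid]][[species_i]]
    pj <- profiles[[bid]][[species_j]]
    shared <- intersect(names(pi_$gene_to_tad), names(pj$gene_to_tad))
    ii <- pi_$gene_to_tad[shared]
    jj <- pj$gene_to_tad[shared]
    ok <- !is.na(ii) & !is.na(jj)
    fixed[[bid]] <- list(i = unname(ii[ok]), k = pj$tad_count,
                         n = sum(ok))
  }
  set.seed(stage_seed(seed, "genes"))
  null <- vapply(seq_len(n_permutations), function(p) {
    s <- 0L
    for (f in fixed) {
      if (f$n == 0L) next
      rand <- sample.int(f$k, f$n, replace = TRUE) - 1L
      s <- s + sum(rand == f$i)
    }
    s
  }, numeric(1))
  obs <- cons$same_tad_genes
  structure(list(observed = obs, null_counts = null,
                 fold_vs_null = if (mean(null) == 0) 1 else obs / mean(null),
                 empirical_p = (1 + sum(null >= obs)) / (n_permutations + 1),
                 conservation = cons),
            class = "gene_null")
}

#' TAD-border edit distance between two species in a block
#'
#' The minimal number of single TAD-border insertions or deletions turning
#' one species' gene partition into the other's, over the shared ordered
#' ortholog list. Each edit adds or removes exactly one cut, so the minimum
#' equals the size of the symmetric difference of the two cut sets. No
#' equal-TAD-count requirement applies.
#'
#' @param profile_i,profile_j `block_profile` objects for the same block.
#' @param order The block's oriented ortholog-group order; defaults to the
#'   shared genes of the two profiles in profile-i order.
#' @return A list of class `edit_result`: `block_id`, `n_edits`,
#'   `edits_per_mbp` (denominator: mean of the two segment lengths),
#'   `n_genes`, and the two cut sets.
#' @export
edit_distance <- function(profile_i, profile_j, order = NULL) {
  if (is.null(order))
    order <- intersect(names(profile_i$gene_to_tad),
                       names(profile_j$gene_to_tad))
  ## restrict to genes assigned in both species so cut indices align
  ok <- !is.na(profile_i$gene_to_tad[order]) &
    !is.na(profile_j$gene_to_tad[order])
  order <- order[ok]
  assert_that(length(order) >= 1L,
              sprintf("block %s: no shared assigned genes",
                      profile_i$block_id))
  ci <- gene_partition(profile_i, order)
  cj <- gene_partition(profile_j, order)
  n_edits <- length(union(setdiff(ci, cj), setdiff(cj, ci)))
  mbp <- mean(c(profile_i$length_mbp, profile_j$length_mbp))
  structure(list(block_id = profile_i$block_id,
                 species_i = profile_i$species,
                 species_j = profile_j$species,
                 n_edits = n_edits, edits_per_mbp = n_edits / mbp,
                 n_genes = length(order),
                 cuts_i = as.integer(ci), cuts_j = as.integer(cj)),
            class = "edit_result")
}

#' Edit distances for all shared blocks of a species pair
#'
#' @inheritParams same_tad_fraction
#' @return Data frame with one row per shared block (`block_id`, `n_edits`,
#'   `edits_per_mbp`, `n_genes`) plus attributes `mean_edits_per_mbp` and
#'   `divergence_myr`.
#' @export
edit_distance_table <- function(profiles, species_i, species_j, tree = NULL) {
  cm <- profile_counts(profiles)
  keep <- rownames(cm)[complete.cases(cm[, c(species_i, species_j),
                                         drop = FALSE])]
  rows <- lapply(keep, function(bid) {
    e <- edit_distance(profiles[[bid]][[species_i]],
                       profiles[[bid]][[species_j]])
    data.frame(block_id = bid, n_edits = e$n_edits,
               edits_per_mbp = e$edits_per_mbp, n_genes = e$n_genes,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "mean_edits_per_mbp") <- mean(out$edits_per_mbp)
  attr(out, "divergence_myr") <-
    if (!is.null(tree)) divergence_time(tree, species_i, species_j)
    else NA_real_
  out
}
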