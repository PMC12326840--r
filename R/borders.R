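## Border-position conservation. Comparisons are restricted to blocks where
## both species carry the same number of TADs (>= 2, so at least one internal
## border exists); borders are matched by rank on the oriented 0-1 scale.

#' Blocks with equal TAD counts for a species pair
#'
#' @param profiles A `block_profile_set`.
#' @param species_i,species_j Species names.
#' @param min_count Minimum shared TAD count (default 2, i.e. at least one
#'   internal border; gene-level metrics use 1 since a single shared TAD
#'   still carries gene-position information).
#' @return Character vector of block ids where both species are present and
#'   `tad_count_i == tad_count_j >= min_count`. May be empty (logged).
#' @export
select_equal_tad_blocks <- function(profiles, species_i, species_j,
                                    min_count = 2) {
  cm <- profile_counts(profiles)
  assert_that(all(c(species_i, species_j) %in% colnames(cm)),
              "species not present in profiles")
  ci <- cm[, species_i]
  cj <- cm[, species_j]
  ids <- rownames(cm)[!is.na(ci) & !is.na(cj) & ci == cj & ci >= min_count]
  if (length(ids) == 0L)
    tv_log(sprintf("no equal-count blocks for %s vs %s",
                   species_i, species_j), stage = "borders")
  ids
}

#' Match borders of two equal-count profiles by rank
#'
#' With equal TAD counts the k-th smallest normalized border of one species
#' corresponds to the k-th smallest of the other; crossing borders (rank
#' inversions between species) are still paired by rank.
#'
#' @param profile_i,profile_j `block_profile` objects with equal numbers of
#'   borders (orientation correction has already happened in the profiles).
#' @return Data frame with columns `x` (borders of i) and `y` (matched
#'   borders of j).
#' @export
match_borders <- function(profile_i, profile_j) {
  bi <- profile_i$borders
  bj <- profile_j$borders
  assert_that(length(bi) == length(bj),
              sprintf("block %s: border counts differ (%d vs %d)",
                      profile_i$block_id, length(bi), length(bj)))
  data.frame(x = sort(bi), y = sort(bj))
}

#' Pooled border comparison for one species pair
#'
#' Pools rank-matched border pairs over all equal-count blocks of the pair
#' and summarises: mean absolute difference of matched positions (a fraction
#' of block length), the same divided by divergence time (per-Myr variant),
#' and the coefficient of determination R² of the OLS fit `y ~ x` on the
#' pooled pairs. R² on a constant-`x` pool is undefined and returned as `NA`
#' with a warning.
#'
#' @inheritParams select_equal_tad_blocks
#' @param tree Optional phylogeny for the per-Myr normalisation.
#' @return A list of class `border_comparison`: `species_i`, `species_j`,
#'   `pairs` (pooled x/y with block ids), `n_blocks`, `mean_abs_diff`,
#'   `mean_abs_diff_per_myr` (`NA` without a tree), `r2`, `divergence_myr`.
#' @export
compare_borders <- function(profiles, species_i, species_j, tree = NULL) {
  ids <- select_equal_tad_blocks(profiles, species_i, species_j)
  pairs <- list()
  for (bid in ids) {
    m <- match_borders(profiles[[bid]][[species_i]],
                       profiles[[bid]][[species_j]])
    if (nrow(m) > 0L) {
      m$block_id <- bid
      pairs[[bid]] <- m
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(x = numeric(), y = numeric(), block_id = character())
  rownames(pairs) <- NULL
  mad_ <- if (nrow(pairs)) mean(abs(pairs$x - pairs$y)) else NA_real_
  div <- if (!is.null(tree)) divergence_time(tree, species_i, species_j)
         else NA_real_
  structure(list(species_i = species_i, species_j = species_j,
                 pairs = pairs, n_blocks = length(ids),
                 mean_abs_diff = mad_,
                 mean_abs_diff_per_myr = mad_ / div,
                 r2 = border_r2(pairs),
                 divergence_myr = div),
            class = "border_comparison")
}

#' R² of matched border positions
#'
#' Coefficient of determination of the simple OLS fit `y ~ x` on pooled
#' matched border pairs: the proportion of variance in one species' border
#' positions explained by the other's. For simple regression this equals the
#' squared correlation, hence is symmetric in x and y.
#'
#' @param pairs Data frame with numeric columns `x`, `y` (matched borders).
#' @return R² in \[0, 1\], or `NA` (with a warning) when fewer than 2 pairs or
#'   constant `x` make it undefined.
#' @export
border_r2 <- function(pairs) {
  if (nrow(pairs) < 2L || sd(pairs$x) == 0 || sd(pairs$y) == 0) {
    warning("R^2 undefined (fewer than 2 pairs or constant positions)",
            call. = FALSE)
    return(NA_real_)
  }
  fit <- lm(y ~ x, data = pairs)
  1 - sum(residuals(fit)^2) / sum((pairs$y - mean(pairs$y))^2)
}

#' Per-clade border divergence summary
#'
#' Computes [compare_borders()] for every within-clade species pair and
#' averages the pair-level mean absolute differences within each clade. Both
#' the raw fraction and its divergence-time-normalised variant are reported.
#'
#' @param profiles A `block_profile_set`.
#' @param tree A validated phylogeny.
#' @param clades Named list: clade name -> character vector of species.
#' @return A list with `pairs` (per-pair data frame: clade, species, n
#'   blocks/borders, `mean_abs_diff`, `mean_abs_diff_per_myr`, `r2`) and
#'   `clades` (per-clade means of the same quantities).
#' @export
border_divergence <- function(profiles, tree, clades) {
  assert_that(is.list(clades) && !is.null(names(clades)),
              "clades must be a named list of species vectors")
  rows <- list()
  for (cl in names(clades)) {
    sp <- clades[[cl]]
    for (i in seq_along(sp)) for (j in seq_along(sp)) if (i < j) {
      cmp <- compare_borders(profiles, sp[i], sp[j], tree = tree)
      rows[[length(rows) + 1L]] <- data.frame(
        clade = cl, species_i = sp[i], species_j = sp[j],
        n_blocks = cmp$n_blocks, n_borders = nrow(cmp$pairs),
        mean_abs_diff = cmp$mean_abs_diff,
        mean_abs_diff_per_myr = cmp$mean_abs_diff_per_myr,
        r2 = cmp$r2, divergence_myr = cmp$divergence_myr,
        stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, rows)
  clades_df <- do.call(rbind, lapply(split(pairs, pairs$clade), function(d)
    data.frame(clade = d$clade[1L], n_pairs = nrow(d),
               mean_abs_diff = mean(d$mean_abs_diff, na.rm = TRUE),
               mean_abs_diff_per_myr = mean(d$mean_abs_diff_per_myr,
                                            na.rm = TRUE),
               r2 = mean(d$r2, na.rm = TRUE), stringsAsFactors = FALSE)))
  rownames(clades_df) <- NULL
  list(pairs = pairs, clades = clades_df)
}
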