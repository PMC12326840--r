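## TAD-number conservation: symmetric relative differences in per-block TAD
## counts, the ARD summary, its block-shuffle permutation null, and the
## regression of per-Mbp count differences on divergence time.

#' Symmetric relative difference of two TAD counts
#'
#' `|t_i - t_j| / ((t_i + t_j)/2)`: the absolute difference scaled by the
#' mean of the two counts, giving a value in \[0, 2\] that is symmetric in its
#' arguments. Two zero counts are defined as perfectly conserved (0).
#' Vectorised over pairs.
#'
#' @param t_i,t_j Non-negative TAD counts (vectors of equal length).
#' @return Relative differences in \[0, 2\].
#' @export
relative_difference <- function(t_i, t_j) {
  assert_that(length(t_i) == length(t_j), "count vectors differ in length")
  assert_that(all(t_i >= 0) && all(t_j >= 0), "counts must be >= 0")
  s <- (t_i + t_j) / 2
  rd <- ifelse(s == 0, 0, abs(t_i - t_j) / s)
  if (any(s == 0))
    tv_log(sprintf("%d block(s) with zero counts in both species: RD = 0",
                   sum(s == 0)), stage = "tadnum")
  rd
}

#' Average relative difference (ARD) in TAD counts for a species pair
#'
#' The unweighted mean of [relative_difference()] over all syntenic blocks in
#' which both species are present. Lower values indicate stronger
#' conservation of TAD numbers; 0 means identical counts everywhere.
#'
#' @param profiles A `block_profile_set` (see [build_block_profiles()]).
#' @param species_i,species_j Species names.
#' @return The ARD (unitless, in \[0, 2\]).
#' @export
compute_ard <- function(profiles, species_i, species_j) {
  cm <- profile_counts(profiles)
  assert_that(all(c(species_i, species_j) %in% colnames(cm)),
              "species not present in profiles")
  keep <- complete.cases(cm[, c(species_i, species_j), drop = FALSE])
  assert_that(any(keep),
              sprintf("no shared blocks between %s and %s",
                      species_i, species_j))
  mean(relative_difference(cm[keep, species_i], cm[keep, species_j]))
}

#' ARD with a block-shuffle permutation null
#'
#' Builds the null distribution of the ARD by randomly permuting one species'
#' per-block TAD-count vector across blocks (the other species held fixed)
#' and recomputing the ARD, `n_permutations` times. Conservation means the
#' observed ARD is *smaller* than the null, so the empirical p-value is the
#' lower-tail add-one estimator
#' `(1 + #\{null <= observed\}) / (n_permutations + 1)`.
#'
#' @inheritParams compute_ard
#' @param n_permutations Number of shuffles (default 1000).
#' @param seed Integer seed; the null is reproducible given the seed.
#' @return A list of class `pairwise_ard`: `species_i`, `species_j`,
#'   `ard_observed`, `null_ards`, `fold_vs_null` (= observed / mean(null)),
#'   `empirical_p`, `n_blocks`.
#' @export
ard_null <- function(profiles, species_i, species_j,
                     n_permutations = 1000, seed = 1L) {
  assert_that(is_count(n_permutations) && n_permutations >= 1,
              "n_permutations must be a positive integer")
  cm <- profile_counts(profiles)
  keep <- complete.cases(cm[, c(species_i, species_j), drop = FALSE])
  ti <- cm[keep, species_i]
  tj <- cm[keep, species_j]
  assert_that(length(ti) >= 2L, "need >= 2 shared blocks for a shuffle null")
  obs <- mean(relative_difference(ti, tj))
  rng <- local({
    set.seed(stage_seed(seed, "ard"))
    replicate(n_permutations, sample.int(length(tj)))
  })
  null <- vapply(seq_len(n_permutations), function(p)
    mean(relative_difference(ti, tj[rng[, p]])), numeric(1))
  structure(list(species_i = species_i, species_j = species_j,
                 ard_observed = obs, null_ards = null,
                 fold_vs_null = if (mean(null) == 0) 1 else obs / mean(null),
                 empirical_p = (1 + sum(null <= obs)) / (n_permutations + 1),
                 n_blocks = length(ti)),
            class = "pairwise_ard")
}

#' @export
print.pairwise_ard <- function(x, ...) {
  cat(sprintf("<ARD %s vs %s: %.4f (%.2f-fold vs null, p = %.4g, %d blocks)>\n",
              x$species_i, x$species_j, x$ard_observed, x$fold_vs_null,
              x$empirical_p, x$n_blocks))
  invisible(x)
}

#' ARD and permutation null for every species pair
#'
#' @inheritParams ard_null
#' @param tree Optional validated phylogeny; when given, a
#'   `divergence_myr` column is added.
#' @return Data frame with one row per unordered species pair: `species_i`,
#'   `species_j`, `n_blocks`, `ard`, `null_mean`, `fold_vs_null`,
#'   `empirical_p` (and `divergence_myr` if `tree` given).
#' @export
ard_table <- function(profiles, n_permutations = 1000, seed = 1L,
                      tree = NULL) {
  cm <- profile_counts(profiles)
  sp <- colnames(cm)
  rows <- list()
  for (i in seq_along(sp)) for (j in seq_along(sp)) if (i < j) {
    a <- ard_null(profiles, sp[i], sp[j],
                  n_permutations = n_permutations,
                  seed = stage_seed(seed, "ard") + i * 131L + j)
    rows[[length(rows) + 1L]] <- data.frame(
      species_i = sp[i], species_j = sp[j], n_blocks = a$n_blocks,
      ard = a$ard_observed, null_mean = mean(a$null_ards),
      fold_vs_null = a$fold_vs_null, empirical_p = a$empirical_p,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (!is.null(tree)) {
    d <- divergence_matrix(tree)
    out$divergence_myr <- d[cbind(out$species_i, out$species_j)]
  }
  out
}

#' Rate of TAD-number change per Mbp per Myr
#'
#' For each species pair, computes the mean over shared blocks of the
#' absolute difference in length-normalised TAD counts,
#' `|T_i/L_i - T_j/L_j|` (counts per Mbp, each species' own segment length),
#' then fits an ordinary least squares regression of these pair means on
#' pairwise divergence time. The slope is the average rate of TAD-number
#' change in TADs/Mbp/Myr.
#'
#' @param profiles A `block_profile_set`.
#' @param tree A validated ultrametric phylogeny covering the species.
#' @return A list of class `rate_fit`: `slope` (TADs/Mbp/Myr), `intercept`,
#'   `n_pairs`, and the per-pair table `pairs` (`divergence_myr`,
#'   `mean_abs_diff_per_mbp`).
#' @export
rate_regression <- function(profiles, tree) {
  cm <- profile_counts(profiles)
  lm_ <- profile_lengths(profiles)
  dens <- cm / lm_
  sp <- colnames(cm)
  d <- divergence_matrix(tree)
  assert_that(all(sp %in% rownames(d)), "profiles contain species not in tree")
  rows <- list()
  for (i in seq_along(sp)) for (j in seq_along(sp)) if (i < j) {
    keep <- complete.cases(dens[, c(i, j), drop = FALSE])
    if (!any(keep)) next
    rows[[length(rows) + 1L]] <- data.frame(
      species_i = sp[i], species_j = sp[j],
      divergence_myr = d[sp[i], sp[j]],
      mean_abs_diff_per_mbp = mean(abs(dens[keep, i] - dens[keep, j])),
      n_blocks = sum(keep), stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows)
  assert_that(nrow(pairs) >= 2L, "need >= 2 species pairs")
  assert_that(length(unique(pairs$divergence_myr)) >= 2L,
              "all divergence times equal: slope undefined")
  fit <- lm(mean_abs_diff_per_mbp ~ divergence_myr, data = pairs)
  structure(list(slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 n_pairs = nrow(pairs), pairs = pairs),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("<rate_fit: %.4g TADs/Mbp/Myr over %d pairs>\n",
              x$slope, x$n_pairs))
  invisible(x)
}
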