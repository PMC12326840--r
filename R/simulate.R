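## Seeded synthetic data with the statistical structure the analyses assume:
## an ultrametric tree, syntenic blocks with a shared ortholog order, TAD
## counts evolving by OU or BM along the tree, borders descended from shared
## ancestral positions with Gaussian jitter, and border insertions/deletions
## at a clock-like rate. Defaults emulate a mammal-scale comparison; see the
## methods vignette for the rationale behind each value.

#' Simulation configuration
#'
#' @param seed Master integer seed; the whole dataset is a pure function of
#'   the config including this value.
#' @param n_species Number of tips when no `tree` is supplied.
#' @param tree_height_myr Height of the generated ultrametric tree (Myr).
#' @param tree Optional explicit `phylo` to use instead of a generated one.
#' @param n_blocks Number of syntenic blocks.
#' @param genes_min Minimum genes per block (>= 2).
#' @param genes_mean_extra Mean of the Poisson excess over `genes_min`.
#' @param block_length_meanlog,block_length_sdlog Log-normal parameters of
#'   block length in Mbp (defaults: median 5 Mbp, sdlog 0.4).
#' @param regime Trait regime: `"OU"` or `"BM"`, or a function
#'   `function(block_index)` returning one of the two for mixtures.
#' @param ou_alpha,ou_sigma,ou_theta,ou_x0 OU parameters (selection strength
#'   1/Myr, drift intensity, optimum and ancestral state in TAD counts).
#' @param bm_sigma BM drift intensity (TAD counts per sqrt(Myr)).
#' @param theta_scale `"length"` (default) scales each block's optimum and
#'   ancestral state with its length — `theta_b = ou_theta * L_b / median L`
#'   — so that bigger blocks hold more TADs and TAD *density* is what is
#'   conserved, as in real synteny data; `"constant"` uses `ou_theta` for
#'   every block.
#' @param border_jitter_sd SD of Gaussian jitter applied to each inherited
#'   border position, as a fraction of block length.
#' @param border_indel_rate Border insertion/deletion events per Mbp per Myr
#'   of root-to-tip time.
#' @param p_inverted Probability that a non-reference species carries the
#'   block in inverted orientation.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_species = 10L, tree_height_myr = 100,
                       tree = NULL, n_blocks = 200L,
                       genes_min = 2L, genes_mean_extra = 6,
                       block_length_meanlog = log(5),
                       block_length_sdlog = 0.4,
                       regime = "OU",
                       ou_alpha = 5, ou_sigma = 2, ou_theta = 6, ou_x0 = 6,
                       bm_sigma = 0.2, theta_scale = "length",
                       border_jitter_sd = 0.05, border_indel_rate = 0.004,
                       p_inverted = 0) {
  assert_that(n_blocks >= 1L, "n_blocks must be >= 1")
  assert_that(genes_min >= 2L, "genes_min must be >= 2")
  assert_that(border_jitter_sd >= 0 && border_indel_rate >= 0 &&
                p_inverted >= 0, "rates must be >= 0")
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a random ultrametric tree
#'
#' Coalescent topology ([ape::rcoal()]) rescaled to the requested height —
#' a generic time-calibrated tree shape for simulation.
#'
#' @param n_species Number of tips.
#' @param height_myr Tree height in Myr.
#' @param seed Integer seed.
#' @return A validated ultrametric `phylo` with tips `sp01, sp02, ...`.
#' @export
simulate_tree <- function(n_species, height_myr = 100, seed = 1L) {
  set.seed(stage_seed(seed, "tree"))
  tree <- ape::rcoal(n_species,
                     tip.label = sprintf("sp%02d", seq_len(n_species)))
  tree$edge.length <- tree$edge.length * height_myr / tree_height(tree)
  validate_phylogeny(tree)
}

#' Simulate per-block tip traits (TAD counts) along the tree
#'
#' One exact multivariate-normal draw per block: mean `C theta` and
#' covariance `V` from the OU regime ([ou_design()], [ou_covariance()]), or
#' ancestral mean `x0` and covariance `sigma^2 * t_(root->MRCA)` under BM.
#' No time-stepping is involved, so the tip distribution is exact. With
#' `integerize = TRUE` (default) values are rounded to the nearest
#' non-negative integer, as TAD counts are.
#'
#' @param config A [sim_config()].
#' @param tree A validated ultrametric `phylo`.
#' @param integerize Round to non-negative integers (default TRUE).
#' @param lengths_mbp Optional per-block lengths (Mbp) used for the
#'   length-scaled optimum (see `theta_scale` in [sim_config()]); drawn from
#'   the configured length distribution when `NULL` and needed.
#' @return Matrix blocks x tips of trait values, with attributes `regime`
#'   (character vector per block) and `lengths_mbp`.
#' @export
simulate_traits <- function(config, tree, integerize = TRUE,
                            lengths_mbp = NULL) {
  n <- length(tree$tip.label)
  B <- config$n_blocks
  regime_of <- if (is.function(config$regime)) config$regime
               else function(b) config$regime
  regimes <- vapply(seq_len(B), regime_of, "")
  assert_that(all(regimes %in% c("OU", "BM")), "regime must be 'OU' or 'BM'")
  s <- shared_time_matrix(tree)

  if (identical(config$theta_scale, "length")) {
    if (is.null(lengths_mbp)) lengths_mbp <- draw_block_lengths(config)
    scale_b <- lengths_mbp / exp(config$block_length_meanlog)
  } else {
    scale_b <- rep(1, B)
  }

  chol_or_zero <- function(V) {
    if (all(V == 0)) return(matrix(0, n, n))
    chol(V + diag(1e-10 * max(diag(V)), n))
  }
  mean_cov <- list(
    OU = function() {
      if (config$ou_sigma > 0) {
        V <- ou_covariance(config$ou_alpha, config$ou_sigma, tree)
      } else {
        V <- matrix(0, n, n)
      }
      C <- ou_design(config$ou_alpha, tree)
      list(mu = drop(C %*% c(config$ou_x0, config$ou_theta)),
           R = chol_or_zero(V))
    },
    BM = function() list(mu = rep(config$ou_x0, n),
                         R = chol_or_zero(config$bm_sigma^2 * s)))
  prep <- lapply(mean_cov[unique(regimes)], function(f) f())

  set.seed(stage_seed(config$seed, "traits"))
  out <- matrix(NA_real_, B, n,
                dimnames = list(sprintf("block%03d", seq_len(B)),
                                tree$tip.label))
  for (b in seq_len(B)) {
    p <- prep[[regimes[b]]]
    out[b, ] <- scale_b[b] * p$mu + drop(crossprod(p$R, rnorm(n)))
  }
  if (integerize) out <- pmax(round(out), 0)
  attr(out, "regime") <- regimes
  attr(out, "lengths_mbp") <- lengths_mbp
  out
}

#' @noRd
draw_block_lengths <- function(config) {
  set.seed(stage_seed(config$seed, "lengths"))
  rlnorm(config$n_blocks, config$block_length_meanlog,
         config$block_length_sdlog)
}

#' Realize blocks, TAD tracks and gene annotations from simulated traits
#'
#' For each block and species, lays a segment on the species' single
#' simulated chromosome (blocks end to end with gaps), tiles it with
#' `trait` TADs whose internal borders descend from shared ancestral
#' fractions with per-species Gaussian jitter and clock-like
#' insertion/deletion events, reconciled so the realized TAD count equals
#' the simulated trait (clamped to >= 1, logged), and places genes at shared
#' relative positions so the ortholog order is identical across species.
#'
#' @param traits Trait matrix from [simulate_traits()].
#' @param config The [sim_config()] used.
#' @param tree The tree the traits were simulated on.
#' @param lengths_mbp Per-block lengths in Mbp; defaults to the lengths the
#'   traits were simulated with (attribute on `traits`), else drawn.
#' @return List of class `sim_dataset`: `tree`, `blocks` (named list of
#'   [synteny_block()]), `tracks` (named list of [tad_track()]), `traits`,
#'   `config`.
#' @export
realize_blocks <- function(traits, config, tree,
                           lengths_mbp = attr(traits, "lengths_mbp")) {
  set.seed(stage_seed(config$seed, "blocks"))
  species <- colnames(traits)
  B <- nrow(traits)
  height <- tree_height(tree)
  gap <- 5e5

  if (any(traits < 1)) {
    tv_log(sprintf("%d trait value(s) < 1 clamped to 1 TAD",
                   sum(traits < 1)), stage = "simulate")
    traits <- pmax(traits, 1)
  }

  ## per-block shared draws
  len_mbp <- lengths_mbp %||% draw_block_lengths(config)
  n_genes <- config$genes_min + rpois(B, config$genes_mean_extra)
  gene_frac <- lapply(seq_len(B), function(b) sort(runif(n_genes[b], 0.02, 0.98)))
  anc_borders <- lapply(seq_len(B), function(b) {
    k <- max(round(mean(traits[b, ])), 1)
    sort(runif(max(k - 1, 0)))
  })
  len_sp <- matrix(len_mbp, B, length(species)) *
    matrix(exp(rnorm(B * length(species), 0, 0.05)), B)
  inverted <- matrix(FALSE, B, length(species))
  if (config$p_inverted > 0 && length(species) > 1L)
    inverted[, -1L] <- runif(B * (length(species) - 1L)) < config$p_inverted

  blocks <- list()
  tads <- lapply(species, function(s) list())
  names(tads) <- species
  cursor <- setNames(rep(0, length(species)), species)

  for (b in seq_len(B)) {
    bid <- rownames(traits)[b]
    segments <- list()
    genes <- list()
    for (si in seq_along(species)) {
      sp <- species[si]
      L <- round(len_sp[b, si] * 1e6)
      start <- cursor[sp]
      end <- start + L
      cursor[sp] <- end + gap
      inv <- inverted[b, si]

      ## borders: jitter + indels + reconciliation to trait - 1
      fr <- jitter_borders(anc_borders[[b]], config$border_jitter_sd)
      fr <- apply_border_indels(fr, config$border_indel_rate *
                                  len_sp[b, si] * height)
      fr <- reconcile_borders(fr, traits[b, si] - 1)
      ## genomic coordinates; inverted species store the reflected layout
      fr_genomic <- if (inv) sort(1 - fr) else fr
      cuts <- unique(round(start + fr_genomic * L))
      cuts <- cuts[cuts > start & cuts < end]
      ## base-pair-level reconciliation: clamping/rounding collisions must
      ## not change the realized TAD count away from the simulated trait
      n_tgt <- traits[b, si] - 1
      while (length(cuts) > n_tgt) cuts <- cuts[-sample.int(length(cuts), 1L)]
      while (length(cuts) < n_tgt) {
        cand <- start + sample.int(L - 1L, 1L)
        if (!cand %in% cuts) cuts <- c(cuts, cand)
      }
      bounds <- c(start, sort(cuts), end)
      tads[[sp]][[bid]] <- data.frame(
        chrom = "chr1", start = bounds[-length(bounds)], end = bounds[-1L])

      gf <- if (inv) rev(1 - gene_frac[[b]]) else gene_frac[[b]]
      gw <- min(0.01, 0.2 / n_genes[b])
      gs <- round(start + pmax(gf - gw / 2, 0) * L)
      ge <- pmin(round(start + (gf + gw / 2) * L), end)
      og_idx <- if (inv) rev(seq_len(n_genes[b])) else seq_len(n_genes[b])
      genes[[sp]] <- data.frame(
        gene_id = sprintf("%s_%s_g%02d", bid, sp, og_idx),
        ortholog_group = sprintf("%s_og%02d", bid, og_idx),
        start = gs, end = ge, strand = "+", stringsAsFactors = FALSE)
      segments[[sp]] <- list(chrom = "chr1", start = start, end = end,
                             orientation = if (inv) "inverted" else "forward")
    }
    blocks[[bid]] <- synteny_block(bid, "simulated", segments, genes)
  }
  tracks <- lapply(species, function(sp)
    tad_track(sp, do.call(rbind, tads[[sp]])))
  names(tracks) <- species
  structure(list(tree = tree, blocks = blocks, tracks = tracks,
                 traits = traits, config = config),
            class = "sim_dataset")
}

#' @noRd
jitter_borders <- function(fr, sd) {
  if (length(fr) == 0L || sd == 0) return(fr)
  f <- fr + rnorm(length(fr), 0, sd)
  sort(pmin(pmax(f, 0.001), 0.999))
}

#' @noRd
apply_border_indels <- function(fr, expected_events) {
  if (expected_events <= 0) return(fr)
  k <- rpois(1L, expected_events)
  for (i in seq_len(k)) {
    if (runif(1) < 0.5 && length(fr) > 0L) {
      fr <- fr[-sample.int(length(fr), 1L)]
    } else {
      fr <- sort(c(fr, runif(1, 0.001, 0.999)))
    }
  }
  fr
}

#' @noRd
reconcile_borders <- function(fr, target) {
  target <- max(target, 0)
  while (length(fr) > target) fr <- fr[-sample.int(length(fr), 1L)]
  while (length(fr) < target) fr <- sort(c(fr, runif(1, 0.001, 0.999)))
  unique(fr)
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: generates (or takes) the tree, simulates traits,
#' realizes blocks/tracks/genes, and optionally writes everything to `dir`
#' in the package's external formats (Newick, block TSV, per-species BED)
#' plus a JSON manifest.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory; created if missing.
#' @return A `sim_dataset` (invisibly carries `dir` as attribute `dir` when
#'   written).
#' @export
simulate_dataset <- function(config = sim_config(), dir = NULL) {
  tree <- config$tree %||%
    simulate_tree(config$n_species, config$tree_height_myr, config$seed)
  validate_phylogeny(tree)
  traits <- simulate_traits(config, tree)
  ds <- realize_blocks(traits, config, tree)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    ape::write.tree(ds$tree, file.path(dir, "tree.nwk"))
    write_synteny_blocks(ds$blocks, file.path(dir, "blocks.tsv"))
    for (sp in names(ds$tracks))
      write_tad_bed(ds$tracks[[sp]], file.path(dir, sprintf("%s.tads.bed", sp)))
    write_manifest(dir, config = config, seed = config$seed,
                   inputs = character())
    attr(ds, "dir") <- dir
  }
  invisible(ds)
}
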