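## End-to-end orchestration: inputs (files or a simulation) -> profiles ->
## TAD-number, border, gene and edit analyses -> OU fits -> summary TSVs +
## JSON run manifest. Every stochastic stage derives its stream from the one
## config seed, so reruns with an identical config are byte-identical.

#' Assemble a pipeline configuration
#'
#' Either point at input files (`tree`, `blocks`, `tad_beds`) or supply a
#' [sim_config()] under `simulate`; exactly one of the two modes is active.
#'
#' @param tree Path to a Newick tree (file mode).
#' @param blocks Path to the block TSV (file mode).
#' @param tad_beds Named character vector/list, species -> BED path
#'   (file mode).
#' @param simulate A [sim_config()] (simulation mode).
#' @param clades Named list clade -> species vector; defaults to one clade
#'   `"all"` containing every species.
#' @param n_permutations Permutations for both nulls (default 1000).
#' @param seed Master seed (default 1).
#' @param grid An [ou_grid()] for the OU stage.
#' @param ou_species Species subset for OU fitting (default: all; fitting is
#'   complete-case over these).
#' @param min_overlap Minimum TAD-segment overlap fraction (see
#'   [build_block_profiles()]).
#' @return List of class `run_config`.
#' @export
run_config <- function(tree = NULL, blocks = NULL, tad_beds = NULL,
                       simulate = NULL, clades = NULL,
                       n_permutations = 1000, seed = 1L, grid = ou_grid(),
                       ou_species = NULL, min_overlap = 0) {
  file_mode <- !is.null(tree) || !is.null(blocks) || !is.null(tad_beds)
  sim_mode <- !is.null(simulate)
  assert_that(xor(file_mode, sim_mode),
              "configure either input files or a simulation, not both")
  if (file_mode)
    assert_that(!is.null(tree) && !is.null(blocks) && !is.null(tad_beds),
                "file mode needs tree, blocks and tad_beds")
  structure(as.list(environment())[c("tree", "blocks", "tad_beds",
                                     "simulate", "clades", "n_permutations",
                                     "seed", "grid", "ou_species",
                                     "min_overlap")],
            class = "run_config")
}

#' Run the full conservation pipeline
#'
#' Fail-fast input validation, then: block profiles -> ARD + permutation
#' null -> TAD-rate regression -> border comparisons -> gene-TAD
#' conservation + null -> edit distances -> per-block OU grid fits ->
#' selection/drift classification. One TSV per analysis plus a JSON manifest
#' is written when `out_dir` is given.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @return List of class `run_result` with elements `profiles`, `ard`,
#'   `rate`, `borders` (list: pairs, clades), `genes`, `edits`, `ou_fit`,
#'   `classification`, `tree`, `config`.
#' @export
run_all <- function(config, out_dir = NULL) {
  t0 <- Sys.time()
  inputs <- character()
  if (!is.null(config$simulate)) {
    tv_log("simulating dataset", stage = "pipeline")
    ds <- simulate_dataset(config$simulate)
    tree <- ds$tree
    blocks <- ds$blocks
    tracks <- ds$tracks
  } else {
    for (f in c(config$tree, config$blocks, unlist(config$tad_beds)))
      assert_that(file.exists(f), sprintf("missing input: %s", f))
    sp_needed <- names(config$tad_beds)
    tree <- read_newick(config$tree)
    blocks <- read_synteny_blocks(config$blocks, species_list = sp_needed)
    missing_sp <- setdiff(sort(unique(unlist(lapply(blocks, block_species)))),
                          sp_needed)
    assert_that(length(missing_sp) == 0L,
                sprintf("no TAD BED configured for species: %s",
                        paste(missing_sp, collapse = ", ")))
    tracks <- lapply(sp_needed, function(sp)
      read_tad_bed(config$tad_beds[[sp]], sp))
    names(tracks) <- sp_needed
    inputs <- c(config$tree, config$blocks, unlist(config$tad_beds))
  }
  stage <- function(name, expr) {
    t <- Sys.time()
    r <- force(expr)
    tv_log(sprintf("%s done in %.2fs", name,
                   as.numeric(Sys.time() - t, units = "secs")),
           stage = "pipeline")
    r
  }
  species <- sort(unique(unlist(lapply(blocks, block_species))))
  assert_that(all(species %in% tree$tip.label),
              sprintf("species missing from tree: %s",
                      paste(setdiff(species, tree$tip.label), collapse = ", ")))
  clades <- config$clades %||% list(all = species)

  profiles <- stage("profiles",
                    build_block_profiles(blocks, tracks,
                                         min_overlap = config$min_overlap))
  ard <- stage("tadnum", ard_table(profiles,
                                   n_permutations = config$n_permutations,
                                   seed = config$seed, tree = tree))
  rate <- stage("rate", rate_regression(profiles, tree))
  borders <- stage("borders", border_divergence(profiles, tree, clades))
  genes <- stage("genes", gene_conservation_table(
    profiles, tree, n_permutations = config$n_permutations,
    seed = config$seed))
  edits <- stage("edits", edit_summary_table(profiles, tree))

  ou_sp <- config$ou_species %||% species
  cm <- profile_counts(profiles)[, ou_sp, drop = FALSE]
  cm <- cm[complete.cases(cm), , drop = FALSE]
  ou_fit <- NULL
  classification <- NULL
  if (nrow(cm) >= 1L && length(ou_sp) >= 2L) {
    sub <- ape::keep.tip(tree, ou_sp)
    ou_fit <- stage("oufit", fit_ou_grid(cm, sub, grid = config$grid))
    classification <- classify_blocks(ou_fit)
  } else {
    tv_log("skipping OU stage: no complete-case blocks", stage = "pipeline")
  }

  res <- structure(list(profiles = profiles, ard = ard, rate = rate,
                        borders = borders, genes = genes, edits = edits,
                        ou_fit = ou_fit, classification = classification,
                        tree = tree, config = config),
                   class = "run_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_results(res, out_dir)
    write_manifest(out_dir, config = config, seed = config$seed,
                   inputs = inputs)
  }
  tv_log(sprintf("pipeline finished in %.2fs",
                 as.numeric(Sys.time() - t0, units = "secs")),
         stage = "pipeline")
  res
}

#' Gene-TAD conservation for every species pair
#'
#' @param profiles A `block_profile_set`.
#' @param tree A validated phylogeny.
#' @param n_permutations,seed Passed to [gene_shuffle_null()].
#' @return Data frame, one row per pair: same-TAD genes, totals,
#'   `genes_per_mbp_per_myr`, `fold_vs_null`, `empirical_p`, and a
#'   Benjamini-Hochberg adjusted column `p_bh` (an extension beyond the raw
#'   per-pair p-values).
#' @export
gene_conservation_table <- function(profiles, tree, n_permutations = 1000,
                                    seed = 1L) {
  sp <- colnames(profile_counts(profiles))
  rows <- list()
  for (i in seq_along(sp)) for (j in seq_along(sp)) if (i < j) {
    gn <- gene_shuffle_null(profiles, sp[i], sp[j],
                            n_permutations = n_permutations,
                            seed = stage_seed(seed, "genes") + i * 131L + j,
                            tree = tree)
    cons <- gn$conservation
    rows[[length(rows) + 1L]] <- data.frame(
      species_i = sp[i], species_j = sp[j], n_blocks = cons$n_blocks,
      same_tad_genes = cons$same_tad_genes, total_genes = cons$total_genes,
      same_tad_fraction = cons$same_tad_fraction,
      genes_per_mbp = cons$genes_per_mbp,
      genes_per_mbp_per_myr = cons$genes_per_mbp_per_myr,
      fold_vs_null = gn$fold_vs_null, empirical_p = gn$empirical_p,
      divergence_myr = cons$divergence_myr, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_bh <- p.adjust(out$empirical_p, method = "BH")
  out
}

#' Edit-distance summary for every species pair
#'
#' @inheritParams gene_conservation_table
#' @return Data frame, one row per pair: `n_blocks`, `mean_edits_per_mbp`,
#'   `mean_edits`, `divergence_myr`.
#' @export
edit_summary_table <- function(profiles, tree) {
  sp <- colnames(profile_counts(profiles))
  rows <- list()
  for (i in seq_along(sp)) for (j in seq_along(sp)) if (i < j) {
    tab <- edit_distance_table(profiles, sp[i], sp[j], tree = tree)
    rows[[length(rows) + 1L]] <- data.frame(
      species_i = sp[i], species_j = sp[j], n_blocks = nrow(tab),
      mean_edits = mean(tab$n_edits),
      mean_edits_per_mbp = attr(tab, "mean_edits_per_mbp"),
      divergence_myr = attr(tab, "divergence_myr"), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' @noRd
write_results <- function(res, out_dir) {
  w <- function(d, name) write.table(
    d, file.path(out_dir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)
  w(res$ard, "ard_pairs.tsv")
  w(res$rate$pairs, "rate_pairs.tsv")
  w(data.frame(slope = res$rate$slope, intercept = res$rate$intercept,
               n_pairs = res$rate$n_pairs), "rate_fit.tsv")
  w(res$borders$pairs, "border_pairs.tsv")
  w(res$borders$clades, "border_clades.tsv")
  w(res$genes, "gene_conservation.tsv")
  w(res$edits, "edit_distance.tsv")
  if (!is.null(res$ou_fit)) {
    w(res$ou_fit$fits, "ou_fits.tsv")
    cl <- res$classification
    jsonlite::write_json(
      cl[c("n_blocks", "n_drift", "n_selection", "pct_drift",
           "pct_selection", "modal_alpha", "modal_sigma",
           "alpha_threshold")],
      file.path(out_dir, "ou_classification.json"), auto_unbox = TRUE,
      digits = NA)
  }
  invisible(out_dir)
}

#' Write the JSON run manifest
#'
#' Records the configuration (hashed and in full), the master seed, digests
#' of all file inputs, the package version and a timestamp. Exactly one
#' manifest per output directory.
#'
#' @param out_dir Output directory.
#' @param config The run or simulation configuration.
#' @param seed Master seed.
#' @param inputs Character vector of input file paths (digested with MD5).
#' @return Manifest path, invisibly.
#' @export
write_manifest <- function(out_dir, config, seed, inputs = character()) {
  cfg_file <- tempfile()
  on.exit(unlink(cfg_file))
  saveRDS(unclass(strip_functions(config)), cfg_file)
  manifest <- list(
    package = "tadevolve",
    version = as.character(packageVersion("tadevolve")),
    seed = seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    inputs = as.list(setNames(
      unname(tools::md5sum(inputs)), basename(inputs))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @noRd
strip_functions <- function(x) {
  if (is.function(x)) return("<function>")
  if (is.list(x)) return(lapply(x, strip_functions))
  x
}
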