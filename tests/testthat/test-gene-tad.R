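test_that("gene partitions encode TAD co-membership as cut sets", {
  p <- make_profile("b1", "A", 3,
                    gene_to_tad = setNames(c(0L, 0L, 1L, 1L, 2L),
                                           paste0("og", 1:5)))
  expect_equal(as.integer(gene_partition(p)), c(2L, 4L))
  one_tad <- make_profile("b1", "A", 1,
                          gene_to_tad = setNames(rep(0L, 4), paste0("og", 1:4)))
  expect_length(gene_partition(one_tad), 0L)
  single <- make_profile("b1", "A", 2,
                         gene_to_tad = setNames(1L, "og1"))
  expect_length(gene_partition(single), 0L)
  ## unassigned genes are dropped before cutting
  withNA <- make_profile("b1", "A", 2,
                         gene_to_tad = setNames(c(0L, NA, 1L),
                                                paste0("og", 1:3)))
  suppressMessages(cuts <- gene_partition(withNA))
  expect_equal(as.integer(cuts), 1L)
  expect_equal(attr(cuts, "genes"), c("og1", "og3"))
})

test_that("same-TAD counting requires equal oriented ranks", {
  pp <- profiles_from_indices(c(0, 0, 1), c(0, 1, 1))
  ps <- make_profile_set(cbind(A = 2, B = 2),
                         profiles = list(b1 = list(A = pp$i, B = pp$j)))
  cons <- same_tad_fraction(ps, "A", "B")
  expect_equal(cons$same_tad_genes, 2L)   # first and last stay
  expect_equal(cons$total_genes, 3L)
  expect_equal(cons$same_tad_fraction, 2 / 3)
  ## identical maps: everything stays; per-Myr normalisation applies
  qq <- profiles_from_indices(c(0, 1, 2), c(0, 1, 2))
  ps2 <- make_profile_set(cbind(A = 3, B = 3),
                          profiles = list(b1 = list(A = qq$i, B = qq$j)))
  cons2 <- same_tad_fraction(ps2, "A", "B", tree = nwk("(A:10,B:10);"))
  expect_equal(cons2$same_tad_fraction, 1)
  expect_equal(cons2$genes_per_mbp_per_myr, 3 / 1 / 10)
})

test_that("gene shuffle with a single TAD has no freedom: fold 1, p 1", {
  pp <- profiles_from_indices(c(0, 0, 0), c(0, 0, 0))
  ps <- make_profile_set(cbind(A = 1, B = 1),
                         profiles = list(b1 = list(A = pp$i, B = pp$j)))
  gn <- gene_shuffle_null(ps, "A", "B", n_permutations = 50, seed = 4)
  expect_true(all(gn$null_counts == gn$observed))
  expect_equal(gn$fold_vs_null, 1)
  expect_equal(gn$empirical_p, 1)
})

test_that("uniform reassignment null matches its closed-form expectation", {
  ## per shared gene, P(random index equals the fixed one) = 1/tad_count,
  ## so E[null] = sum over blocks of n_genes / tad_count
  pp1 <- profiles_from_indices(c(0, 1, 1, 2), c(0, 0, 1, 2))  # k = 3
  pp2 <- profiles_from_indices(c(0, 1), c(1, 1))              # k = 2
  ps <- make_profile_set(
    cbind(A = c(3, 2), B = c(3, 2)),
    profiles = list(b1 = list(A = pp1$i, B = pp1$j),
                    b2 = list(A = pp2$i, B = pp2$j)))
  gn <- gene_shuffle_null(ps, "A", "B", n_permutations = 1e4, seed = 12)
  closed_form <- 4 / 3 + 2 / 2
  expect_equal(mean(gn$null_counts), closed_form, tolerance = 0.03)
  expect_equal(gn$empirical_p,
               (1 + sum(gn$null_counts >= gn$observed)) / (1e4 + 1))
})

test_that("edit distance equals the cut-set symmetric difference", {
  same <- profiles_from_indices(c(0, 1, 2), c(0, 1, 2))
  expect_equal(edit_distance(same$i, same$j)$n_edits, 0L)
  ## cuts {1,3} vs {1}: one deletion
  e <- profiles_from_indices(c(0, 1, 1, 2), c(0, 1, 1, 1))
  expect_equal(edit_distance(e$i, e$j)$n_edits, 1L)
  expect_equal(edit_distance(e$i, e$j)$edits_per_mbp, 1)
  ## zero iff identical partition
  expect_true(edit_distance(same$i, same$j)$n_edits == 0)
})

test_that("edit distance is a metric, matching BFS search for all small partitions", {
  for (n in 2:5) {
    parts <- all_partitions(n)
    profs <- lapply(parts, function(cuts) {
      idx <- cumsum(c(0L, as.integer(seq_len(n - 1) %in% cuts)))
      make_profile("b1", "A", max(idx) + 1L,
                   gene_to_tad = setNames(idx, sprintf("og%d", 1:n)))
    })
    d <- matrix(0L, length(parts), length(parts))
    for (a in seq_along(parts)) for (b in seq_along(parts)) {
      d[a, b] <- edit_distance(profs[[a]], profs[[b]])$n_edits
      expect_equal(d[a, b], bfs_edit_distance(parts[[a]], parts[[b]], n))
    }
    expect_equal(d, t(d))
    expect_true(all((d == 0) == diag(length(parts))))
    ## triangle inequality, exhaustively
    for (a in seq_along(parts)) for (b in seq_along(parts))
      expect_true(all(d[a, b] <= d[a, ] + d[, b]))
  }
})
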