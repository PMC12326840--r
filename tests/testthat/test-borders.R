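test_that("equal-count selection keeps >= 2 shared TADs only", {
  ps <- make_profile_set(cbind(A = c(3, 3, 1, 2, NA),
                               B = c(3, 4, 1, 2, 2)))
  expect_equal(select_equal_tad_blocks(ps, "A", "B"), c("b01", "b04"))
  ## single-TAD blocks come back when gene-level metrics ask for them
  expect_equal(select_equal_tad_blocks(ps, "A", "B", min_count = 1),
               c("b01", "b03", "b04"))
  suppressMessages(
    expect_length(select_equal_tad_blocks(
      make_profile_set(cbind(A = 3, B = 4)), "A", "B"), 0))
})

test_that("borders pair by rank and summarise to the mean absolute difference", {
  pi_ <- make_profile("b1", "A", 3, borders = c(0.2, 0.6))
  pj <- make_profile("b1", "B", 3, borders = c(0.25, 0.55))
  m <- match_borders(pi_, pj)
  expect_equal(m$x, c(0.2, 0.6))
  expect_equal(m$y, c(0.25, 0.55))
  expect_equal(mean(abs(m$x - m$y)), 0.05)
  expect_equal(nrow(match_borders(make_profile("b1", "A", 2, borders = 0.4),
                                  make_profile("b1", "B", 2, borders = 0.7))),
               1L)
  expect_error(match_borders(pi_, make_profile("b1", "B", 2, borders = 0.4)),
               "border counts differ")
})

test_that("pooled comparison: identical borders give zero MAD and R^2 of 1", {
  profs <- list(b1 = list(A = make_profile("b1", "A", 3, borders = c(0.2, 0.6)),
                          B = make_profile("b1", "B", 3, borders = c(0.2, 0.6))),
                b2 = list(A = make_profile("b2", "A", 2, borders = 0.8),
                          B = make_profile("b2", "B", 2, borders = 0.8)))
  ps <- make_profile_set(cbind(A = c(3, 2), B = c(3, 2)), profiles = profs)
  tree <- nwk("(A:10,B:10);")
  cmp <- compare_borders(ps, "A", "B", tree = tree)
  expect_equal(cmp$mean_abs_diff, 0)
  expect_equal(cmp$mean_abs_diff_per_myr, 0)
  expect_equal(cmp$r2, 1)
  expect_equal(nrow(cmp$pairs), 3L)
})

test_that("MAD is symmetric in species and invariant to joint reflection", {
  set.seed(3)
  bx <- sort(runif(4))
  by <- sort(pmin(pmax(bx + rnorm(4, 0, 0.05), 0.01), 0.99))
  profs <- function(x, y) {
    p <- list(b1 = list(A = make_profile("b1", "A", 5, borders = x),
                        B = make_profile("b1", "B", 5, borders = y)))
    make_profile_set(cbind(A = 5, B = 5), profiles = p)
  }
  fwd <- compare_borders(profs(bx, by), "A", "B")
  swp <- compare_borders(profs(by, bx), "A", "B")
  refl <- compare_borders(profs(sort(1 - bx), sort(1 - by)), "A", "B")
  expect_equal(fwd$mean_abs_diff, swp$mean_abs_diff)
  expect_equal(fwd$mean_abs_diff, refl$mean_abs_diff)
  expect_equal(fwd$r2, swp$r2)   # correlation-squared identity
})

test_that("R^2 is 1 on the diagonal, ~0 for independent positions, NA when undefined", {
  x <- seq(0.1, 0.9, length.out = 50)
  expect_equal(border_r2(data.frame(x = x, y = x)), 1)
  set.seed(17)
  big <- data.frame(x = runif(1e4), y = runif(1e4))
  expect_lt(abs(border_r2(big)), 0.01)
  expect_warning(r <- border_r2(data.frame(x = rep(0.5, 3), y = runif(3))),
                 "undefined")
  expect_true(is.na(r))
})

test_that("measured MAD under pure border jitter matches the half-normal mean", {
  ## both species inherit ancestral borders with independent N(0, s) jitter,
  ## so a matched pair differs by N(0, s*sqrt(2)):
  ## E|diff| = s * sqrt(2) * sqrt(2/pi)
  s <- 0.02
  cfg <- sim_config(seed = 21, n_species = 6, n_blocks = 150,
                    ou_sigma = 0, border_jitter_sd = s,
                    border_indel_rate = 0)
  ds <- simulate_dataset(cfg)
  suppressMessages(pr <- build_block_profiles(ds$blocks, ds$tracks))
  cmp <- compare_borders(pr, "sp01", "sp02")
  expect_gt(nrow(cmp$pairs), 200)
  expected <- s * sqrt(2) * sqrt(2 / pi)
  expect_equal(cmp$mean_abs_diff, expected, tolerance = 0.15)
})

test_that("clade summaries average pair-level divergence within clades", {
  profs <- list(b1 = list(
    A = make_profile("b1", "A", 3, borders = c(0.2, 0.6)),
    B = make_profile("b1", "B", 3, borders = c(0.25, 0.55)),
    C = make_profile("b1", "C", 3, borders = c(0.4, 0.9))))
  ps <- make_profile_set(cbind(A = 3, B = 3, C = 3), profiles = profs)
  tree <- nwk("((A:5,B:5):5,C:10);")
  out <- border_divergence(ps, tree, clades = list(inner = c("A", "B"),
                                                   all = c("A", "B", "C")))
  expect_equal(sort(out$clades$clade), c("all", "inner"))
  inner <- out$clades[out$clades$clade == "inner", ]
  expect_equal(inner$mean_abs_diff, 0.05)
  expect_equal(inner$mean_abs_diff_per_myr, 0.05 / 5)
  expect_equal(out$pairs$n_borders, c(2, 2, 2, 2))
})
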