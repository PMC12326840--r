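## Hand-built fixture: one block, configurable TAD layout.
profile_fixture <- function(tads, seg = c(0, 300), invert = FALSE,
                            gene_mids = NULL, min_overlap = 0) {
  segments <- list(A = list(chrom = "chr1", start = seg[1], end = seg[2],
                            orientation = "forward"),
                   B = list(chrom = "chr1", start = seg[1], end = seg[2],
                            orientation = if (invert) "inverted" else "forward"))
  if (is.null(gene_mids)) gene_mids <- seg[1] + c(0.2, 0.8) * diff(seg)
  genes <- lapply(c(A = 1, B = 1), function(.) data.frame(
    gene_id = sprintf("g%d", seq_along(gene_mids)),
    ortholog_group = sprintf("og%d", seq_along(gene_mids)),
    start = gene_mids - 1, end = gene_mids + 1, strand = "+"))
  if (invert) {
    genes$B <- genes$B[rev(seq_len(nrow(genes$B))), ]
    genes$B$start <- seg[1] + seg[2] - rev(gene_mids) - 1
    genes$B$end <- genes$B$start + 2
    rownames(genes$B) <- NULL
  }
  blk <- synteny_block("b1", "test", segments, genes)
  track <- tad_track("B", data.frame(chrom = "chr1", start = tads[, 1],
                                     end = tads[, 2]))
  profile_block(blk, track, "B", min_overlap = min_overlap)
}

test_that("contiguous TADs give count and evenly spaced internal borders", {
  p <- profile_fixture(cbind(c(0, 100, 200), c(100, 200, 300)))
  expect_equal(p$tad_count, 3L)
  expect_equal(p$borders, c(1, 2) / 3)
})

test_that("inverted segments reflect borders; symmetric sets are fixed points", {
  p <- profile_fixture(cbind(c(0, 100, 200), c(100, 200, 300)), invert = TRUE)
  expect_equal(p$borders, c(1, 2) / 3)
  ## asymmetric set reflects
  q_f <- profile_fixture(cbind(c(0, 30), c(30, 300)))
  q_r <- profile_fixture(cbind(c(0, 30), c(30, 300)), invert = TRUE)
  expect_equal(q_f$borders, 0.1)
  expect_equal(q_r$borders, 0.9)
  ## reflecting twice returns the original border set
  expect_equal(sort(1 - sort(1 - q_f$borders)), q_f$borders)
})

test_that("any-overlap counts edge TADs; all interior endpoints are borders", {
  p <- profile_fixture(cbind(c(0, 100, 280), c(100, 200, 400)))
  expect_equal(p$tad_count, 3L)   # [280,400) overlaps by 20 bp
  expect_equal(p$borders, c(100, 200, 280) / 300)
  ## a minimum-overlap fraction drops the edge TAD ([280,400) covers 20/120)
  q <- profile_fixture(cbind(c(0, 100, 280), c(100, 200, 400)),
                       min_overlap = 0.5)
  expect_equal(q$tad_count, 2L)
  expect_equal(q$borders, c(100, 200) / 300)
})

test_that("normalized borders are invariant under affine shifts of coordinates", {
  shift <- 1.7e7
  p0 <- profile_fixture(cbind(c(0, 100, 280), c(100, 200, 400)))
  p1 <- profile_fixture(cbind(c(0, 100, 280), c(100, 200, 400)) + shift,
                        seg = c(0, 300) + shift)
  expect_equal(p1$borders, p0$borders)
  expect_equal(p1$tad_count, p0$tad_count)
  expect_equal(p1$gene_to_tad, p0$gene_to_tad)
})

test_that("genes map to oriented TAD ranks by midpoint; gaps are unassigned", {
  ## TADs [0,100) and [200,300): gene at 150 falls in the gap
  suppressMessages(
    p <- profile_fixture(cbind(c(0, 200), c(100, 300)),
                         gene_mids = c(60, 150, 240)))
  expect_equal(unname(p$gene_to_tad), c(0L, NA_integer_, 1L))
  ## inverted orientation flips the rank
  suppressMessages(
    q <- profile_fixture(cbind(c(0, 200), c(100, 300)),
                         gene_mids = c(60, 150, 240), invert = TRUE))
  ## oriented ranks agree with the forward species: first gene in TAD 0
  expect_equal(unname(q$gene_to_tad[order(names(q$gene_to_tad))]),
               c(0L, NA_integer_, 1L))
})

test_that("build_block_profiles assembles count and length matrices", {
  blk <- simple_block(seg_len = 3e6)
  tracks <- list(
    A = tad_track("A", data.frame(chrom = "chr1", start = c(0, 1e6, 2e6),
                                  end = c(1e6, 2e6, 3e6))),
    B = tad_track("B", data.frame(chrom = "chr1", start = c(0, 15e5),
                                  end = c(15e5, 3e6))))
  ps <- build_block_profiles(list(b1 = blk), tracks)
  cm <- profile_counts(ps)
  expect_equal(cm["b1", ], c(A = 3, B = 2))
  expect_equal(profile_lengths(ps)["b1", "A"], 3)
  expect_error(build_block_profiles(list(b1 = blk), tracks["A"]),
               "no TAD track")
})
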