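test_that("per-line introgression detection collapses and filters blocks", {
  # all-M82 line yields nothing
  m82 <- line_with_blocks("L1", data.frame(start = numeric(0),
                                           end = numeric(0),
                                           state = character(0)))
  expect_equal(nrow(detect_line_bins(m82)), 0)

  # one block, marker support carried through
  seg <- line_with_blocks("L2", data.frame(start = 2e6, end = 4e6,
                                           state = "PEN"))
  seg$n_markers <- c(10, 50, 30)
  out <- detect_line_bins(seg)
  expect_equal(nrow(out), 1)
  expect_equal(out$n_supporting_markers, 50)

  # single-marker block dropped under min_markers = 2
  seg$n_markers <- c(10, 1, 30)
  out2 <- detect_line_bins(seg, min_markers = 2)
  expect_equal(nrow(out2), 0)
  expect_equal(attr(out2, "filter_log")$blocks_dropped_min_markers, 1)
})

test_that("population boundary merge is the breakpoint-union partition", {
  intro <- tibble::tibble(
    line_id = c("A", "B"), chrom = "ch1",
    start_bp = c(10, 15), end_bp = c(20, 25), state = "PEN"
  )
  bins <- merge_population_boundaries(intro)
  expect_equal(bins$start_bp, c(10, 15, 20))
  expect_equal(bins$end_bp, c(15, 20, 25))

  # a single block maps to exactly one bin
  one <- merge_population_boundaries(intro[1, ])
  expect_equal(nrow(one), 1)
  expect_equal(c(one$start_bp, one$end_bp), c(10, 20))

  # identical blocks in two lines collapse to one bin
  dup <- tibble::tibble(line_id = c("A", "B"), chrom = "ch1",
                        start_bp = 10, end_bp = 20, state = "PEN")
  expect_equal(nrow(merge_population_boundaries(dup)), 1)

  # gaps between introgressions are excluded but reported
  gap <- tibble::tibble(line_id = c("A", "B"), chrom = "ch1",
                        start_bp = c(0, 50), end_bp = c(10, 60),
                        state = "PEN")
  bg <- merge_population_boundaries(gap)
  expect_equal(nrow(bg), 2)
  expect_equal(attr(bg, "uncovered")$start_bp, 10)
})

test_that("boundary refinement snaps only sub-tolerance boundary pairs", {
  bins <- tibble::tibble(
    bin_id = c("b1", "b2", "b3"), chrom = "ch1",
    start_bp = c(1000000, 1000200, 1005000),
    end_bp = c(1000200, 1005000, 1100000)
  )
  # tolerance 0 is the identity
  expect_equal(refine_boundaries(bins, 0), bins)
  # 200 bp apart with 1 kb tolerance: snapped to the midpoint, sliver gone
  out <- refine_boundaries(bins, 1000)
  expect_equal(nrow(out), 2)
  expect_equal(out$start_bp[1], 1000100)
  expect_equal(out$end_bp[1], 1005000)
  # distant boundaries (>= tolerance) untouched
  far <- tibble::tibble(bin_id = c("b1", "b2"), chrom = "ch1",
                        start_bp = c(1000000, 1000400),
                        end_bp = c(1000400, 1200000))
  expect_equal(refine_boundaries(far, 400)$start_bp, far$start_bp)
})

test_that("bin genotype codes come from the covering segment", {
  bins <- tibble::tibble(bin_id = c("b1", "b2"), chrom = "ch1",
                         start_bp = c(2e6, 4e6), end_bp = c(4e6, 5e6))
  lines <- dplyr::bind_rows(
    line_with_blocks("L1", data.frame(start = numeric(0), end = numeric(0),
                                      state = character(0))),
    line_with_blocks("L2", data.frame(start = 2e6, end = 4e6, state = "HET")),
    line_with_blocks("L3", data.frame(start = 2e6, end = 5e6, state = "PEN"))
  )
  bm <- bin_genotype_matrix(lines, bins)
  expect_equal(unname(bm$codes["L1", ]), c(0L, 0L))
  expect_equal(unname(bm$codes["L2", ]), c(1L, 0L))
  expect_equal(unname(bm$codes["L3", ]), c(2L, 2L))
  expect_equal(unname(presence_matrix(bm)["L2", ]), c(1, 0))
  expect_equal(unname(presence_matrix(bm, "dosage")["L2", ]), c(0.5, 0))

  # a line changing genotype inside a bin violates the bin property
  bad_bins <- tibble::tibble(bin_id = "b", chrom = "ch1",
                             start_bp = 1e6, end_bp = 3e6)
  expect_error(bin_genotype_matrix(lines, bad_bins), "changes genotype")
})

test_that("bins from truth equal bins from error-free HMM calls", {
  gm <- toy_genome(2, 8e6)
  pop <- simulate_pedigree(pedigree_scheme(2, 5, lines = 25, bc_mixture = 0.5),
                           gm, seed = 21)
  mk <- marker_panel(gm, 5e3)
  cov <- coverage_model(mean_depth = 6, zero_inflation = 0, seq_error = 0,
                        other_rate = 0)
  cts <- emit_read_counts(pop, mk, cov, seed = 22)
  geno <- genotype_population(cts, gm, seq_error = 1e-4)
  # same introgression count and near-identical boundaries
  intro_truth <- detect_line_bins(pop, min_markers = 0)
  intro_hmm <- detect_line_bins(geno$segments, min_markers = 2)
  big_t <- intro_truth[intro_truth$end_bp - intro_truth$start_bp >= 3e4, ]
  for (k in seq_len(nrow(big_t))) {
    match_k <- intro_hmm$line_id == big_t$line_id[k] &
      intro_hmm$chrom == big_t$chrom[k] &
      intro_hmm$start_bp < big_t$end_bp[k] &
      intro_hmm$end_bp > big_t$start_bp[k] &
      intro_hmm$state == big_t$state[k]
    expect_true(any(match_k))
    if (any(match_k)) {
      hm <- intro_hmm[which(match_k)[1], ]
      expect_lt(abs(hm$start_bp - big_t$start_bp[k]), 2.5e4)
      expect_lt(abs(hm$end_bp - big_t$end_bp[k]), 2.5e4)
    }
  }
  # genotype matrices agree on the truth-defined bins
  bins <- merge_population_boundaries(intro_truth, gm)
  bm_truth <- bin_genotype_matrix(pop, bins)
  expect_true(all(bm_truth$codes %in% 0:2))
})

test_that("genes attach to every overlapping bin", {
  bins <- tibble::tibble(bin_id = c("b1", "b2"), chrom = "ch1",
                         start_bp = c(0, 1000), end_bp = c(1000, 2000))
  genes <- tibble::tibble(
    gene_id = c("g_in", "g_straddle", "g_out", "g_other_chrom"),
    chrom = c("ch1", "ch1", "ch1", "ch2"),
    start_bp = c(100, 900, 2500, 100),
    end_bp = c(200, 1100, 2600, 200)
  )
  out <- assign_genes_to_bins(bins, genes)
  expect_equal(out$gene_ids[[1]], c("g_in", "g_straddle"))
  expect_equal(out$gene_ids[[2]], "g_straddle")
  expect_equal(out$n_genes, c(2L, 1L))
  # empty annotation
  out0 <- assign_genes_to_bins(bins, genes[0, ])
  expect_equal(out0$n_genes, c(0L, 0L))
  # half-open: a gene ending exactly at a bin start does not overlap it
  edge <- tibble::tibble(gene_id = "g_edge", chrom = "ch1",
                         start_bp = 900, end_bp = 1000)
  oute <- assign_genes_to_bins(bins, edge)
  expect_equal(oute$n_genes, c(1L, 0L))
})

test_that("population summaries reproduce the published worked example", {
  tab1 <- read_bins_tsv(system.file("extdata",
                                    "bil_table1_chromosome_stats.tsv",
                                    package = "bilqtl"))
  s <- summarize_population_counts(tab1, n_lines = 439)
  expect_equal(s$total_introgressions, 1372)
  expect_equal(round(s$mean_introgressions_per_line, 3), 3.125)
  expect_equal(s$total_bins, 1049)
  expect_equal(s$bins_per_chromosome, 87)
})

test_that("introgression_stats aggregates per line and per chromosome", {
  gm <- toy_genome(2, 1e7)
  lines <- dplyr::bind_rows(
    line_with_blocks("L1", data.frame(start = 1e6, end = 3e6, state = "PEN")),
    line_with_blocks("L2", data.frame(start = c(2e6, 5e6), end = c(4e6, 6e6),
                                      state = c("PEN", "HET"))),
    line_with_blocks("L3", data.frame(start = numeric(0), end = numeric(0),
                                      state = character(0)))
  )
  # all three lines need ch2 tiling as well
  ch2 <- tibble::tibble(line_id = rep(c("L1", "L2", "L3")),
                        chrom = "ch2", start_bp = 0, end_bp = 1e7,
                        state = "M82")
  lines <- dplyr::bind_rows(lines, ch2)
  intro <- detect_line_bins(lines, min_markers = 0)
  bins <- merge_population_boundaries(intro, gm)
  st <- introgression_stats(intro, bins, gm, line_ids = c("L1", "L2", "L3"))
  expect_equal(st$per_line$n_introgressions,
               c(1, 2, 0)[match(st$per_line$line_id, c("L1", "L2", "L3"))])
  expect_equal(st$totals$total_introgressions, 3)
  expect_equal(st$totals$mean_introgressions_per_line, 1)
  l1 <- st$per_line[st$per_line$line_id == "L1", ]
  expect_equal(l1$pct_donor, 100 * 2e6 / 2e7)
})
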