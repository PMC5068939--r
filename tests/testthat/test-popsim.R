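test_that("closed-form state fractions follow the Mendelian recursion", {
  expect_equal(unname(round(expected_state_fractions(pedigree_scheme(2, 5)), 4)),
               c(0.8711, 0.0078, 0.1211))
  expect_equal(unname(round(expected_state_fractions(pedigree_scheme(3, 4)), 4)),
               c(0.9336, 0.0078, 0.0586))
  # an F1 is heterozygous everywhere
  expect_equal(unname(expected_state_fractions(pedigree_scheme(0, 0, 1))),
               c(0, 1, 0))
  # unbounded selfing fixes every locus
  deep <- expected_state_fractions(pedigree_scheme(2, 60))
  expect_equal(unname(deep[["HET"]]), 0, tolerance = 1e-15)
  expect_true(all(abs(sum(expected_state_fractions(
    pedigree_scheme(2, 5, bc_mixture = 0.3))) - 1) < 1e-12))
})

test_that("meiosis of a homozygous parent returns the parent haplotype", {
  gm <- toy_genome(1)
  hom <- tibble::tibble(chrom = "ch1", start_bp = 0, end_bp = 1e7,
                        origin = "M82")
  gam <- simulate_meiosis(list(h1 = hom, h2 = hom), gm, seed = 1)
  expect_equal(nrow(gam), 1)
  expect_equal(gam$origin, "M82")
  expect_equal(gam$end_bp, 1e7)
})

test_that("crossover count matches the Poisson map-length expectation", {
  # 100 cM chromosome: crossovers per meiosis ~ Poisson(1)
  gm <- genome_model(data.frame(chrom = "ch1", length_bp = 1e7),
                     cm_per_mb = 10)
  h1 <- tibble::tibble(chrom = "ch1", start_bp = 0, end_bp = 1e7,
                       origin = "M82")
  h2 <- dplyr::mutate(h1, origin = "PEN")
  parent <- list(h1 = h1, h2 = h2)
  set.seed(42)
  n_rep <- 4000
  xo <- vapply(seq_len(n_rep), function(i) {
    nrow(simulate_meiosis(parent, gm)) - 1
  }, numeric(1))
  # mean within 3 Monte-Carlo SEs of 1 (Poisson sd = 1)
  expect_lt(abs(mean(xo) - 1), 3 / sqrt(n_rep))
})

test_that("two-marker recombinant fractions follow the Haldane map function", {
  gm <- genome_model(data.frame(chrom = "ch1", length_bp = 1e7),
                     cm_per_mb = 10) # 10 cM between markers 1 Mb apart
  h1 <- tibble::tibble(chrom = "ch1", start_bp = 0, end_bp = 1e7,
                       origin = "M82")
  h2 <- dplyr::mutate(h1, origin = "PEN")
  parent <- list(h1 = h1, h2 = h2)
  pos <- c(4e6, 5e6) # 10 cM apart
  set.seed(7)
  n_rep <- 4000
  rec <- vapply(seq_len(n_rep), function(i) {
    gam <- simulate_meiosis(parent, gm)
    org <- vapply(pos, function(p) {
      gam$origin[findInterval(p - 1, gam$start_bp)]
    }, character(1))
    org[1] != org[2]
  }, logical(1))
  r_expected <- (1 - exp(-2 * 0.10)) / 2 # Haldane r(10 cM) = 0.0906
  se <- sqrt(r_expected * (1 - r_expected) / n_rep)
  expect_lt(abs(mean(rec) - r_expected), 3 * se)
})

test_that("simulated lines tile their chromosomes exactly", {
  gm <- toy_genome(2, 5e6)
  pop <- simulate_pedigree(pedigree_scheme(2, 5, lines = 40, bc_mixture = 0.5),
                           gm, seed = 11)
  for (id in unique(pop$line_id)) {
    for (ch in c("ch1", "ch2")) {
      seg <- pop[pop$line_id == id & pop$chrom == ch, ]
      seg <- seg[order(seg$start_bp), ]
      expect_equal(seg$start_bp[1], 0)
      expect_equal(seg$end_bp[nrow(seg)], 5e6)
      if (nrow(seg) > 1) {
        expect_equal(seg$start_bp[-1], seg$end_bp[-nrow(seg)])
        expect_true(all(seg$state[-1] != seg$state[-nrow(seg)]))
      }
    }
  }
})

test_that("simulated state frequencies match the closed form", {
  gm <- genome_model(data.frame(chrom = "ch1", length_bp = 5e6),
                     cm_per_mb = 1.5)
  n <- 600
  pop <- simulate_pedigree(pedigree_scheme(2, 5, lines = n), gm, seed = 99)
  loci <- seq(5e5, 4.5e6, by = 1e6)
  freq <- matrix(0, length(loci), 3, dimnames = list(NULL, c("M82", "HET", "PEN")))
  for (id in unique(pop$line_id)) {
    seg <- pop[pop$line_id == id, ]
    seg <- seg[order(seg$start_bp), ]
    st <- seg$state[findInterval(loci, seg$start_bp)]
    for (k in seq_along(loci)) freq[k, st[k]] <- freq[k, st[k]] + 1
  }
  freq <- freq / n
  expt <- expected_state_fractions(pedigree_scheme(2, 5))
  for (s in c("M82", "HET", "PEN")) {
    se <- sqrt(expt[s] * (1 - expt[s]) / n)
    expect_lt(abs(mean(freq[, s]) - expt[s]), 3 * se)
  }
})

test_that("pedigree simulation is reproducible and honours contaminants", {
  gm <- toy_genome(1, 2e6)
  a <- simulate_pedigree(pedigree_scheme(2, 5, lines = 5), gm, seed = 3)
  b <- simulate_pedigree(pedigree_scheme(2, 5, lines = 5), gm, seed = 3)
  expect_identical(a, b)
  cont <- simulate_pedigree(
    pedigree_scheme(2, 5, lines = 10, p_contaminant = 1), gm, seed = 4)
  expect_true(all(cont$state == "M82"))
  expect_true(all(attr(cont, "pedigree")$contaminant))
})

test_that("read counts reflect the underlying genotype and coverage model", {
  gm <- toy_genome(1, 1e6)
  m82_line <- tibble::tibble(line_id = "L1", chrom = "ch1", start_bp = 0,
                             end_bp = 1e6, state = "M82")
  mk <- marker_panel(gm, 1e4)
  # error-free M82 line: no donor reads anywhere
  cts <- emit_read_counts(m82_line, mk,
                          coverage_model(mean_depth = 5, zero_inflation = 0,
                                         seq_error = 0, other_rate = 0),
                          seed = 5)
  expect_true(all(cts$n_pen == 0))
  expect_true(all(cts$n_other == 0))

  # heterozygous line at deep coverage: donor fraction near 1/2
  het_line <- dplyr::mutate(m82_line, state = "HET")
  cts <- emit_read_counts(het_line, mk,
                          coverage_model(mean_depth = 200, zero_inflation = 0,
                                         seq_error = 0, other_rate = 0),
                          seed = 6)
  frac <- sum(cts$n_pen) / sum(cts$n_pen + cts$n_m82)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / sum(cts$n_pen + cts$n_m82)))

  # donor line with 1% error: recurrent-allele fraction near 0.01
  pen_line <- dplyr::mutate(m82_line, state = "PEN")
  cts <- emit_read_counts(pen_line, mk,
                          coverage_model(mean_depth = 1000, zero_inflation = 0,
                                         seq_error = 0.01, other_rate = 0),
                          seed = 7)
  tot <- sum(cts$n_pen + cts$n_m82)
  expect_lt(abs(sum(cts$n_m82) / tot - 0.01), 3 * sqrt(0.01 * 0.99 / tot))
})

test_that("trait simulation composes additive and epistatic effects", {
  bins <- tibble::tibble(bin_id = c("b1", "b2", "b3"), chrom = "ch1",
                         start_bp = c(0, 1e6, 2e6), end_bp = c(1e6, 2e6, 3e6))
  lines <- dplyr::bind_rows(
    line_with_blocks("L1", data.frame(start = 0, end = 2e6, state = "PEN"),
                     len = 3e6),
    line_with_blocks("L2", data.frame(start = 1e6, end = 3e6, state = "PEN"),
                     len = 3e6),
    line_with_blocks("L3", data.frame(start = 0, end = 0.5, state = "M82")[0, ],
                     len = 3e6)
  )
  bm <- bin_genotype_matrix(lines, bins)

  # all effects and sds zero: flat zero trait
  arch0 <- trait_architecture()
  sim0 <- simulate_traits(bm, arch0, seed = 1)
  expect_true(all(sim0$replicates$value == 0))

  # single additive effect: value = beta * presence
  arch1 <- trait_architecture(additive = data.frame(bin = "b1", effect = 2))
  sim1 <- simulate_traits(bm, arch1, seed = 1)
  expect_equal(sim1$line_values$genetic_value,
               2 * unname(presence_matrix(bm)[, "b1"]))

  # epistatic pair with no marginal effect: only co-carriers deviate
  arch2 <- trait_architecture(
    epistatic = data.frame(bin_a = "b1", bin_b = "b3", effect = 1.5))
  sim2 <- simulate_traits(bm, arch2, seed = 1)
  P <- presence_matrix(bm)
  expect_equal(sim2$line_values$genetic_value,
               1.5 * unname(P[, "b1"] * P[, "b3"]))

  # unknown bin in the architecture is an error
  expect_error(
    simulate_traits(bm, trait_architecture(
      additive = data.frame(bin = "nope", effect = 1))),
    "unknown bin")
})
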