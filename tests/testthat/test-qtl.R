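make_presence <- function(n, p, prob = 0.3, seed = 1) {
  set.seed(seed)
  matrix(rbinom(n * p, 1, prob), n, p,
         dimnames = list(sprintf("L%03d", seq_len(n)),
                         sprintf("b%03d", seq_len(p))))
}

test_that("marginal scan finds an exact single-bin signal", {
  P <- make_presence(60, 12)
  y <- P[, "b007"] # trait equals presence, no noise
  scan <- marginal_scan(P, y, q_threshold = 0.001)
  row <- scan[scan$bin == "b007", ]
  expect_equal(row$estimate, 1)
  expect_lt(row$p, 1e-20)
  expect_true(row$significant)
})

test_that("marginal scan flags untestable bins and constant traits", {
  P <- make_presence(30, 5)
  P[, 1] <- 0          # monomorphic
  P[1:2, 2] <- 1; P[-(1:2), 2] <- 0 # only 2 carriers
  scan <- marginal_scan(P, rnorm(30), min_class = 3)
  expect_false(scan$testable[1])
  expect_false(scan$testable[2])
  expect_true(all(is.na(scan$q[1:2])))
  expect_warning(marginal_scan(P, rep(1, 30)), "constant trait")
})

test_that("null marginal scans control the family-wise error at q", {
  # under a global null every rejection is false; BH at level q bounds the
  # probability of any rejection by q
  set.seed(77)
  P <- make_presence(80, 60, seed = 78)
  n_rep <- 150
  any_hit <- vapply(seq_len(n_rep), function(i) {
    any(marginal_scan(P, rnorm(80), q_threshold = 0.05)$significant)
  }, logical(1))
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(mean(any_hit), 0.05 + 3 * se)
})

test_that("epistatic design enumerates observed pairs only", {
  # spec-scale arithmetic
  counts <- epistatic_pair_counts(1049, 306291)
  expect_equal(counts$total_pairs, 549676)
  expect_equal(counts$unobserved_pairs, 243385)
  expect_equal(counts$model_effects, 307340)

  # 3 bins, lines {110, 011}: pairs (1,2) and (2,3) observed, (1,3) not
  P <- matrix(c(1, 1, 0, 0, 1, 1), 2, 3, byrow = TRUE,
              dimnames = list(c("L1", "L2"), c("b1", "b2", "b3")))
  des <- build_epistatic_design(P)
  expect_equal(nrow(des$pairs), 2)
  expect_setequal(paste(des$pairs$bin_a, des$pairs$bin_b),
                  c("b1 b2", "b2 b3"))

  # one line carrying everything observes all pairs
  P1 <- matrix(1, 1, 4, dimnames = list("L1", paste0("b", 1:4)))
  expect_equal(nrow(build_epistatic_design(P1)$pairs), choose(4, 2))
})

test_that("the MC+ operator interpolates between soft and hard thresholding", {
  # alpha = 0 is the identity
  b <- seq(-3, 3, by = 0.1)
  expect_equal(mcplus_threshold(b, 0, 2), b)
  # large gamma approaches the soft threshold
  expect_equal(mcplus_threshold(b, 0.5, 1e8),
               sign(b) * pmax(abs(b) - 0.5, 0), tolerance = 1e-7)
  # continuity at the knee: beta = alpha * gamma maps to itself
  expect_equal(mcplus_threshold(2, 1, 2), 2)
  # odd function, continuous, identity beyond alpha*gamma
  expect_equal(mcplus_threshold(-b, 1, 3), -mcplus_threshold(b, 1, 3))
  expect_equal(mcplus_threshold(5, 1, 3), 5)
  expect_error(mcplus_threshold(1, 1, 1), "gamma")
})

test_that("orthonormal designs reduce the fit to univariate thresholding", {
  set.seed(9)
  n <- 64
  M <- matrix(rnorm(n * 8), n, 8)
  M <- sweep(M, 2, colMeans(M)) # mean-zero input => mean-zero Q columns
  X <- sqrt(n) * qr.Q(qr(M))    # orthonormal with unit mean-square columns
  colnames(X) <- paste0("x", 1:8)
  beta_true <- c(3, -2, 1.5, 0, 0, 0, 0, 0)
  y <- as.vector(X %*% beta_true)
  alpha <- 0.8; gamma <- 3
  fit <- sparsenet_fit(X, y, sparsenet_config(gamma_grid = c(150, gamma)),
                       alpha_grid = c(2, alpha))
  got <- coef(fit, alpha = alpha, gamma = gamma)
  bt <- as.vector(crossprod(X, y) / n) # univariate OLS under orthonormality
  want <- mcplus_threshold(bt, alpha, gamma)
  # compare on the standardized scale used internally
  scales <- sqrt(colMeans(sweep(X, 2, colMeans(X))^2))
  expect_equal(unname(got * scales), want, tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("an alpha at the gradient maximum yields the empty model", {
  set.seed(10)
  X <- make_presence(50, 10)
  y <- rnorm(50)
  std <- bilqtl:::standardize_design(X, y)
  amax <- max(abs(crossprod(std$X, std$y))) / nrow(X)
  fit <- sparsenet_fit(X, y, alpha_grid = c(amax * 1.001))
  expect_true(all(coef(fit, alpha = amax, gamma = 150) == 0))
})

test_that("the most convex fit matches an independent lasso oracle", {
  set.seed(11)
  n <- 80; p <- 25
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  beta_true <- c(rep(2, 3), rep(0, p - 3))
  y <- as.vector(X %*% beta_true + rnorm(n, 0, 0.5))
  std <- bilqtl:::standardize_design(X, y)
  alpha <- 0.25
  cfg <- sparsenet_config(gamma_grid = c(1e6, 10)) # lasso-like extreme first
  fit <- sparsenet_fit(X, y, cfg, alpha_grid = c(1, alpha))
  got <- coef(fit, alpha = alpha, gamma = 1e6)
  oracle <- lasso_cd_oracle(std$X, std$y, alpha)
  got_std <- got[std$keep] * std$scales[std$keep]
  expect_equal(unname(got_std), oracle, tolerance = 1e-5)
})

test_that("glmnet agrees with the lasso end of the path", {
  skip_if_not_installed("glmnet")
  set.seed(12)
  n <- 90; p <- 30
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  y <- as.vector(X %*% c(3, -2, rep(0, p - 2)) + rnorm(n, 0, 0.3))
  std <- bilqtl:::standardize_design(X, y)
  alpha <- 0.3
  fit <- sparsenet_fit(X, y, sparsenet_config(gamma_grid = c(1e7, 5)),
                       alpha_grid = c(1.5, alpha))
  got_std <- coef(fit, alpha = alpha, gamma = 1e7)[std$keep] *
    std$scales[std$keep]
  gl <- glmnet::glmnet(std$X, std$y, lambda = alpha, standardize = FALSE,
                       intercept = FALSE, thresh = 1e-14)
  expect_equal(unname(got_std), as.vector(gl$beta), tolerance = 1e-5)
})

test_that("cross-validated tuning is seed-reproducible and noise-robust", {
  set.seed(13)
  P <- make_presence(60, 15, seed = 14)
  y <- rnorm(60)
  cfg <- sparsenet_config(n_alpha = 12, cv_reps = 3)
  t1 <- cv_tune(P, y, cfg, seed = 5)
  t2 <- cv_tune(P, y, cfg, seed = 5)
  expect_identical(t1[c("alpha", "gamma")], t2[c("alpha", "gamma")])
  # pure noise: the chosen alpha sits near the sparse end of the path
  expect_gte(which(t1$alpha_grid == t1$alpha), 1)
  fit <- sparsenet_fit(P, y, cfg, alpha_grid = t1$alpha_grid)
  expect_lte(sum(coef(fit, t1$alpha, t1$gamma) != 0), 5)
  expect_error(cv_tune(P[1:4, ], y[1:4], cfg), "fewer lines")
})

test_that("a strong single bin is selected by the tuned fit", {
  P <- make_presence(100, 20, seed = 15)
  set.seed(16)
  y <- 2 * P[, "b004"] + rnorm(100, 0, 0.4)
  cfg <- sparsenet_config(n_alpha = 15, cv_reps = 3)
  tune <- cv_tune(P, y, cfg, seed = 6)
  fit <- sparsenet_fit(P, y, cfg, alpha_grid = tune$alpha_grid)
  sel <- coef(fit, tune$alpha, tune$gamma)
  expect_gt(abs(sel["b004"]), 1)
  # and the marginal scan agrees on the causal bin
  scan <- marginal_scan(P, y, q_threshold = 0.001)
  expect_equal(scan$bin[which.min(scan$p)], "b004")
})

test_that("QTL intervals collect bins correlated at or above 0.90", {
  P <- make_presence(400, 6, seed = 17)
  P <- cbind(P, dup = P[, "b001"]) # a perfect duplicate
  iv <- qtl_intervals("b001", P)
  expect_true(all(c("b001", "dup") %in% iv$interval_bins[[1]]))
  # independent random columns essentially never reach 0.90 at n = 400
  expect_equal(setdiff(iv$interval_bins[[1]], c("b001", "dup")), character(0))
  # zero-variance selected bin degrades gracefully
  P0 <- cbind(P, flat = 0)
  expect_warning(iv0 <- qtl_intervals("flat", P0), "zero variance")
  expect_equal(iv0$interval_bins[[1]], "flat")
})

test_that("epistatic reporting drops linked pairs and ranks by magnitude", {
  gm <- toy_genome(2, 3e7)
  bins <- tibble::tibble(
    bin_id = c("a", "b", "c", "d"),
    chrom = c("ch1", "ch1", "ch2", "ch2"),
    start_bp = c(0, 4e6, 0, 2.5e7), end_bp = c(1e6, 5e6, 1e6, 2.6e7)
  )
  pairs <- tibble::tibble(
    bin_a = c("a", "a", "c"), bin_b = c("b", "c", "d"),
    coefficient = c(5, 1, 2)
  )
  # a-b on ch1 are ~6.4 cM apart -> dropped; a-c cross-chromosome kept;
  # c-d ~37 cM apart on ch2 -> kept
  out <- filter_epistatic(pairs, bins, gm, min_cm_separation = 20, top_n = 10)
  expect_setequal(paste(out$bin_a, out$bin_b), c("a c", "c d"))
  expect_equal(out$coefficient, c(2, 1)) # ordered by |coefficient|
  expect_true(is.na(out$distance_cm[out$bin_a == "a"]))
  # top-n truncation
  out1 <- filter_epistatic(pairs, bins, gm, min_cm_separation = 0, top_n = 2)
  expect_equal(nrow(out1), 2)
  expect_equal(out1$coefficient, c(5, 2))
})

test_that("discrete fine-mapping follows interval set algebra", {
  len <- 1e3
  pos1 <- line_with_blocks("P1", data.frame(start = 100, end = 400,
                                            state = "PEN"), len = len)
  pos2 <- line_with_blocks("P2", data.frame(start = 200, end = 500,
                                            state = "PEN"), len = len)
  neg <- line_with_blocks("N1", data.frame(start = 0, end = 250,
                                           state = "PEN"), len = len)
  lines <- dplyr::bind_rows(pos1, pos2, neg)
  ph <- tibble::tibble(line_id = c("P1", "P2", "N1"),
                       phenotype = c("present", "present", "absent"))
  res <- finemap_discrete(lines, ph, "ch1")
  expect_equal(res$candidate$start_bp, 250)
  expect_equal(res$candidate$end_bp, 400)

  # without negatives the candidate is the intersection of positives
  res2 <- finemap_discrete(lines, ph[1:2, ], "ch1")
  expect_equal(c(res2$candidate$start_bp, res2$candidate$end_bp), c(200, 400))

  # inconsistent lines are excluded from both sides
  ph3 <- ph; ph3$phenotype[3] <- "inconsistent"
  res3 <- finemap_discrete(lines, ph3, "ch1")
  expect_equal(c(res3$candidate$start_bp, res3$candidate$end_bp), c(200, 400))

  # gene counting on the candidate region
  genes <- tibble::tibble(gene_id = c("g1", "g2", "g3"), chrom = "ch1",
                          start_bp = c(260, 450, 600), end_bp = c(300, 480, 700))
  res4 <- finemap_discrete(lines, ph, "ch1", genes = genes)
  expect_equal(res4$genes, "g1")
  expect_equal(res4$n_genes, 1L)
})

test_that("fine-mapping contains the causal gene and shrinks monotonically", {
  set.seed(19)
  gm <- toy_genome(1, 1e7)
  causal <- c(4.2e6, 4.3e6)
  pop <- simulate_pedigree(pedigree_scheme(2, 3, lines = 60), gm, seed = 20)
  # noise-free dominant phenotype: donor DNA covering the causal locus
  carriers <- vapply(split(pop, pop$line_id), function(seg) {
    any(seg$state != "M82" & seg$start_bp < causal[2] &
          seg$end_bp > causal[1])
  }, logical(1))
  ph <- tibble::tibble(line_id = names(carriers),
                       phenotype = ifelse(carriers, "present", "absent"))
  if (sum(carriers) >= 2) {
    neg_ids <- ph$line_id[ph$phenotype == "absent"]
    widths <- numeric(0)
    for (k in c(0, length(neg_ids) %/% 2, length(neg_ids))) {
      keep <- ph[ph$phenotype == "present" | ph$line_id %in% neg_ids[seq_len(k)], ]
      res <- finemap_discrete(pop[pop$line_id %in% keep$line_id, ], keep, "ch1")
      expect_true(res$mappable)
      expect_true(any(res$candidate$start_bp <= causal[1] &
                        res$candidate$end_bp >= causal[2]))
      widths <- c(widths, sum(res$candidate$end_bp - res$candidate$start_bp))
    }
    expect_true(all(diff(widths) <= 0))
  }
})

test_that("interval overlap tables report spans and narrowing factors", {
  bil <- tibble::tibble(trait = c("t", "t"), chrom = c("ch1", "ch2"),
                        start_bp = c(100, 0), end_bp = c(200, 50))
  il <- tibble::tibble(trait = "t", chrom = "ch1",
                       start_bp = 0, end_bp = 1000)
  out <- overlap_qtl(bil, il)
  expect_equal(nrow(out), 1) # the ch2 interval is disjoint from everything
  expect_equal(out$overlap_bp, 100)
  expect_equal(out$narrowing_factor, 0.1)
  # identical intervals: factor exactly 1
  out2 <- overlap_qtl(il, il)
  expect_equal(out2$narrowing_factor, 1)
})
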