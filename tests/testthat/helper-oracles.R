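# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# brute-force posterior marginals by summing over all 3^n state paths
fb_enumerate <- function(genotype_probs, d_prev, cfg) {
  gp <- as.matrix(genotype_probs)
  n <- nrow(gp)
  eps <- cfg$emission_error
  E <- matrix(eps / 2, 3, 3); diag(E) <- 1 - eps
  emit <- gp %*% E
  trans <- lapply(seq_len(n), function(t) {
    if (t == 1) return(NULL)
    transition_matrix(d_prev[t], cfg)
  })
  paths <- as.matrix(expand.grid(rep(list(1:3), n)))
  w <- apply(paths, 1, function(s) {
    lp <- cfg$priors[s[1]] * emit[1, s[1]]
    if (n > 1) {
      for (t in 2:n) lp <- lp * trans[[t]][s[t - 1], s[t]] * emit[t, s[t]]
    }
    lp
  })
  post <- matrix(0, n, 3, dimnames = list(NULL, c("M82", "HET", "PEN")))
  for (t in seq_len(n)) {
    for (k in 1:3) post[t, k] <- sum(w[paths[, t] == k])
  }
  post / rowSums(post)
}

# plain R coordinate-descent lasso on a standardized design (unit mean-square
# columns, centered response); penalty parameterization matches RSS/(2n) +
# alpha * |beta|_1
lasso_cd_oracle <- function(X, y, alpha, tol = 1e-10, max_iter = 5000) {
  n <- nrow(X); p <- ncol(X)
  beta <- rep(0, p)
  r <- y
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(p)) {
      bt <- beta[j] + sum(X[, j] * r) / n
      bn <- sign(bt) * max(abs(bt) - alpha, 0)
      if (bn != beta[j]) {
        r <- r - X[, j] * (bn - beta[j])
        delta <- max(delta, abs(bn - beta[j]))
        beta[j] <- bn
      }
    }
    if (delta < tol) break
  }
  beta
}

# rank-based percentile-window oracle: is value v inside the [lo, hi]
# percentile window of vals, by explicit sort and linear interpolation
percentile_window_oracle <- function(vals, lo, hi) {
  s <- sort(vals)
  n <- length(s)
  q_at <- function(p) {
    h <- (n - 1) * p / 100 + 1
    fl <- floor(h)
    s[fl] + (h - fl) * (s[min(fl + 1, n)] - s[fl])
  }
  c(q_at(lo), q_at(hi))
}

# tiny two-chromosome test genome
toy_genome <- function(n_chrom = 2, length_bp = 1e7, cm_per_mb = 1.5) {
  genome_model(
    tibble::tibble(chrom = paste0("ch", seq_len(n_chrom)),
                   length_bp = length_bp),
    cm_per_mb = cm_per_mb
  )
}

# hand-built line segments: one line with the given introgression blocks
# (data frame start, end, state), background M82, chromosome length len
line_with_blocks <- function(id, blocks, len = 1e7, chrom = "ch1") {
  blocks <- as.data.frame(blocks)
  cuts <- sort(unique(c(0, blocks$start, blocks$end, len)))
  seg <- tibble::tibble(
    line_id = id, chrom = chrom,
    start_bp = cuts[-length(cuts)], end_bp = cuts[-1], state = "M82"
  )
  for (k in seq_len(nrow(blocks))) {
    idx <- seg$start_bp >= blocks$start[k] & seg$end_bp <= blocks$end[k]
    seg$state[idx] <- blocks$state[k]
  }
  seg
}
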