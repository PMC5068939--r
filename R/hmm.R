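#' Configuration of the heterogeneous genotyping HMM
#'
#' The HMM has three hidden states — homozygous recurrent parent (`M82`),
#' heterozygous (`HET`), homozygous donor (`PEN`) — and a transition matrix
#' that varies with the genetic distance `d` (cM) between adjacent markers:
#' the probability of staying in a state is `exp(-d^2 / (2 sigma^2))` and the
#' probability of changing to either alternative state is half the complement
#' (under equal allocation). This kernel approaches the Haldane/Kosambi 1/2
#' asymptote at large `d` but, unlike those map functions, has zero slope at
#' `d = 0`, which makes it robust to marker-level noise at short distances.
#'
#' @param sigma Transition length scale in cM (default 0.5).
#' @param priors Initial state distribution, named `(M82, HET, PEN)`;
#'   default `c(0.88, 0.02, 0.10)`, the rough expectation for a mixed
#'   BC2/BC3 selfed population.
#' @param emission_error Probability that the observed genotype class is wrong
#'   (split evenly between the two wrong states); default 0.01.
#' @param posterior_threshold Posterior probability required to call a change
#'   of state (default 0.95).
#' @param change_allocation How the off-diagonal transition mass is split:
#'   `"equal"` (half to each alternative state) or `"prior"` (proportional to
#'   the target-state priors).
#' @return An object of class `hmm_config`.
#' @export
hmm_config <- function(sigma = 0.5,
                       priors = c(M82 = 0.88, HET = 0.02, PEN = 0.10),
                       emission_error = 0.01, posterior_threshold = 0.95,
                       change_allocation = c("equal", "prior")) {
  change_allocation <- match.arg(change_allocation)
  priors <- priors[.states]
  stopifnot(sigma > 0, abs(sum(priors) - 1) < 1e-8,
            emission_error >= 0, emission_error < 0.5,
            posterior_threshold > 0, posterior_threshold < 1)
  structure(list(sigma = sigma, priors = priors,
                 emission_error = emission_error,
                 posterior_threshold = posterior_threshold,
                 change_allocation = change_allocation),
            class = "hmm_config")
}

#' State-change probability at a genetic distance
#'
#' `(1 - exp(-d^2 / (2 sigma^2))) / 2`: the probability of transitioning to a
#' given alternative state across a gap of `d` cM. Monotone non-decreasing in
#' `d`, 0 at `d = 0` (with zero slope), and 1/2 as `d` grows — the Haldane
#' asymptote.
#'
#' @param d Genetic distance(s) in cM, non-negative.
#' @param sigma Length scale in cM.
#' @return Probability vector, same length as `d`.
#' @export
recomb_prob <- function(d, sigma = 0.5) {
  if (any(d < 0)) stop("genetic distance must be non-negative", call. = FALSE)
  stopifnot(sigma > 0)
  (1 - exp(-d^2 / (2 * sigma^2))) / 2
}

#' Distance-dependent transition matrix of the genotyping HMM
#'
#' @param d Genetic distance in cM (scalar).
#' @param cfg An [hmm_config()].
#' @return 3x3 row-stochastic matrix with rows/columns `M82`, `HET`, `PEN`;
#'   diagonal `exp(-d^2 / (2 sigma^2))`.
#' @export
transition_matrix <- function(d, cfg = hmm_config()) {
  stopifnot(length(d) == 1)
  if (d < 0) stop("genetic distance must be non-negative", call. = FALSE)
  stay <- exp(-d^2 / (2 * cfg$sigma^2))
  change <- 1 - stay
  Tm <- matrix(0, 3, 3, dimnames = list(.states, .states))
  for (i in 1:3) {
    for (j in 1:3) {
      if (i == j) {
        Tm[i, j] <- stay
      } else if (cfg$change_allocation == "equal") {
        Tm[i, j] <- change / 2
      } else {
        others <- setdiff(1:3, i)
        Tm[i, j] <- change * cfg$priors[j] / sum(cfg$priors[others])
      }
    }
  }
  Tm
}

#' Genotype probabilities from parental allele counts
#'
#' Binomial likelihood of the donor-allele count given the donor-read
#' probability for each state (`seq_error`, `0.5`, `1 - seq_error` for
#' M82 / HET / PEN), normalized to sum to one — i.e. genotype likelihoods
#' scaled under a uniform prior. Markers with no reads get the uniform triple.
#'
#' @param n_m82,n_pen Read counts for the recurrent- and donor-parent alleles
#'   (vectors recycle).
#' @param seq_error Per-read error probability.
#' @return Matrix with one row per marker, columns `M82`, `HET`, `PEN`.
#' @export
likelihoods_from_counts <- function(n_m82, n_pen, seq_error = 0.01) {
  stopifnot(all(n_m82 >= 0), all(n_pen >= 0))
  n <- n_m82 + n_pen
  p_pen <- c(seq_error, 0.5, 1 - seq_error)
  ll <- vapply(p_pen, function(p) {
    stats::dbinom(n_pen, n, p, log = TRUE)
  }, numeric(length(n)))
  ll <- matrix(ll, ncol = 3, dimnames = list(NULL, .states))
  ll <- exp(ll - apply(ll, 1, max))
  out <- ll / rowSums(ll)
  out[n == 0, ] <- 1 / 3
  out
}

#' Emission probability of a marker observation given a hidden state
#'
#' The emission confuses the true state with either wrong state with total
#' probability `epsilon`: `E(state, g) = 1 - epsilon` when `g == state`, else
#' `epsilon / 2`. The marker's likelihood is the genotype-probability triple
#' contracted with this confusion kernel.
#'
#' @param state One of `"M82"`, `"HET"`, `"PEN"`.
#' @param genotype_probs Probability triple over `(M82, HET, PEN)` summing to 1.
#' @param epsilon Emission error rate.
#' @return Scalar likelihood.
#' @export
emission_prob <- function(state, genotype_probs, epsilon = 0.01) {
  s <- match(state, .states)
  if (is.na(s)) stop("unknown state: ", state, call. = FALSE)
  E <- rep(epsilon / 2, 3)
  E[s] <- 1 - epsilon
  sum(E * genotype_probs)
}

# emission likelihood matrix for all markers x states
emission_matrix <- function(genotype_probs, epsilon) {
  gp <- as.matrix(genotype_probs)
  E <- matrix(epsilon / 2, 3, 3)
  diag(E) <- 1 - epsilon
  out <- gp %*% E # (n x 3) x (3 x 3): column s = sum_g gp[,g] E[s,g]; E symm.
  colnames(out) <- .states
  out
}

#' Forward-backward posterior decoding along one chromosome
#'
#' Standard scaled forward-backward with the per-gap transition matrix
#' [transition_matrix()] evaluated at each marker's distance to its
#' predecessor, the configured priors as the initial distribution, and
#' [emission_prob()] emissions. Scaling keeps chains of hundreds of thousands
#' of markers from underflowing.
#'
#' @param genotype_probs Matrix (markers x 3) of genotype probability triples,
#'   columns in `(M82, HET, PEN)` order, rows summing to 1.
#' @param d_prev Vector of cM distances of each marker to the previous one
#'   (first element ignored). Must be non-negative.
#' @param cfg An [hmm_config()].
#' @return Posterior matrix (markers x 3), rows summing to 1, columns named
#'   `M82`, `HET`, `PEN`.
#' @export
forward_backward <- function(genotype_probs, d_prev, cfg = hmm_config()) {
  gp <- as.matrix(genotype_probs)
  if (nrow(gp) == 0) {
    return(matrix(numeric(0), 0, 3, dimnames = list(NULL, .states)))
  }
  stopifnot(ncol(gp) == 3, length(d_prev) == nrow(gp))
  if (any(d_prev[-1] < 0)) {
    stop("markers must be sorted by position (negative inter-marker distance)",
         call. = FALSE)
  }
  if (any(abs(rowSums(gp) - 1) > 1e-9)) {
    stop("genotype probability rows must sum to 1", call. = FALSE)
  }
  emit <- emission_matrix(gp, cfg$emission_error)
  post <- .fb_cpp(emit, as.numeric(d_prev), cfg$sigma,
                  as.numeric(cfg$priors),
                  as.integer(cfg$change_allocation == "prior"))
  colnames(post) <- .states
  post
}

#' Threshold-and-hysteresis state calls from a posterior matrix
#'
#' The running call starts as the argmax state of the first marker if its
#' posterior reaches the threshold, otherwise as the prior-modal state (M82),
#' flagged low-confidence. The call then switches to a different state only at
#' markers where that state's posterior is at or above the threshold; markers
#' between confident calls inherit the running state.
#'
#' @param post Posterior matrix from [forward_backward()].
#' @param cfg An [hmm_config()].
#' @return List with `states` (character vector per marker), `change_points`
#'   (marker indices where the call switches), and `flagged_start` (TRUE when
#'   the leading call fell below the threshold).
#' @export
call_states <- function(post, cfg = hmm_config()) {
  n <- nrow(post)
  if (n == 0) {
    return(list(states = character(0), change_points = integer(0),
                flagged_start = FALSE))
  }
  tau <- cfg$posterior_threshold
  states <- character(n)
  flagged <- FALSE
  first <- which.max(post[1, ])
  if (post[1, first] >= tau) {
    cur <- first
  } else {
    cur <- which.max(cfg$priors)
    flagged <- TRUE
  }
  change_points <- integer(0)
  states[1] <- .states[cur]
  for (t in seq_len(n)[-1]) {
    best <- which.max(post[t, ])
    if (best != cur && post[t, best] >= tau) {
      cur <- best
      change_points <- c(change_points, t)
    }
    states[t] <- .states[cur]
  }
  list(states = states, change_points = change_points, flagged_start = flagged)
}

#' Genotype one line from sparse marker counts
#'
#' Runs the full per-line genotyping stack: binomial genotype likelihoods from
#' counts, posterior decoding with the heterogeneous HMM per chromosome,
#' thresholded state calls, and collapse into genotype segments. Segment
#' boundaries in bp are placed at the midpoint between the last marker of the
#' outgoing state and the first marker of the incoming state; terminal
#' segments extend to the chromosome ends.
#'
#' @param counts Tibble of per-marker counts for one line (`chrom`, `pos`,
#'   `n_m82`, `n_pen`; extra columns ignored).
#' @param genome A [genome_model()].
#' @param cfg An [hmm_config()].
#' @param line_id Line identifier copied to the output (default taken from a
#'   `line_id` column if present).
#' @param seq_error Per-read sequencing error used for the binomial genotype
#'   likelihoods (distinct from the HMM's per-marker emission error).
#' @return List with `segments` (tibble `line_id`, `chrom`, `start_bp`,
#'   `end_bp`, `state`, `n_markers`, `mean_posterior`) and `calls` (tibble of
#'   marker-level `chrom`, `pos`, `state`, and the three posterior columns).
#' @export
genotype_line <- function(counts, genome, cfg = hmm_config(), line_id = NULL,
                          seq_error = 0.01) {
  if (is.null(line_id)) {
    line_id <- if ("line_id" %in% names(counts)) counts$line_id[1] else "line"
  }
  per_chrom <- split(counts, counts$chrom)
  segs <- list()
  calls <- list()
  for (ch in names(per_chrom)) {
    d <- per_chrom[[ch]]
    d <- d[order(d$pos), , drop = FALSE]
    gp <- likelihoods_from_counts(d$n_m82, d$n_pen, seq_error)
    dist <- c(0, genetic_distance(d$pos[-nrow(d)], d$pos[-1], ch, genome))
    post <- forward_backward(gp, dist, cfg)
    cs <- call_states(post, cfg)
    calls[[ch]] <- tibble::tibble(
      line_id = line_id, chrom = ch, pos = d$pos, state = cs$states,
      p_m82 = post[, "M82"], p_het = post[, "HET"], p_pen = post[, "PEN"]
    )
    segs[[ch]] <- segments_from_calls(cs$states, d$pos, post, ch,
                                      chrom_length_bp(genome, ch), line_id)
  }
  list(segments = dplyr::bind_rows(segs), calls = dplyr::bind_rows(calls))
}

# collapse marker-level calls into bp segments with midpoint boundaries
segments_from_calls <- function(states, pos, post, chrom, len, line_id) {
  n <- length(states)
  if (n == 0) {
    return(tibble::tibble(line_id = character(0), chrom = character(0),
                          start_bp = numeric(0), end_bp = numeric(0),
                          state = character(0), n_markers = integer(0),
                          mean_posterior = numeric(0)))
  }
  run <- rle(states)
  ends_idx <- cumsum(run$lengths)
  starts_idx <- c(1, ends_idx[-length(ends_idx)] + 1)
  # midpoint between last marker of previous run and first marker of next
  cut_bp <- (pos[ends_idx[-length(ends_idx)]] + pos[starts_idx[-1]]) / 2
  start_bp <- c(0, cut_bp)
  end_bp <- c(cut_bp, len)
  mean_post <- vapply(seq_along(run$values), function(k) {
    idx <- starts_idx[k]:ends_idx[k]
    mean(post[idx, run$values[k]])
  }, numeric(1))
  tibble::tibble(line_id = line_id, chrom = chrom, start_bp = start_bp,
                 end_bp = end_bp, state = run$values,
                 n_markers = run$lengths, mean_posterior = mean_post)
}

#' Genotype every line of a population
#'
#' @param counts Tibble of counts for all lines (`line_id`, `chrom`, `pos`,
#'   `n_m82`, `n_pen`).
#' @param genome A [genome_model()].
#' @param cfg An [hmm_config()].
#' @param keep_calls Also return marker-level calls (default FALSE to save
#'   memory on large populations).
#' @param seq_error Per-read sequencing error for the genotype likelihoods.
#' @return List with `segments` for all lines and (optionally) `calls`.
#' @export
genotype_population <- function(counts, genome, cfg = hmm_config(),
                                keep_calls = FALSE, seq_error = 0.01) {
  per_line <- split(counts, counts$line_id)
  res <- purrr::imap(per_line, function(d, id) {
    genotype_line(d, genome, cfg, line_id = id, seq_error = seq_error)
  })
  out <- list(segments = dplyr::bind_rows(purrr::map(res, "segments")))
  if (keep_calls) out$calls <- dplyr::bind_rows(purrr::map(res, "calls"))
  out
}
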