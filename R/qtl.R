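#' Marginal (single-bin) regression QTL scan
#'
#' Fits, for every bin, a simple linear regression of the trait on the
#' donor-presence indicator of that bin, and controls the false discovery
#' rate over the testable bins with the Benjamini-Hochberg adjustment. A bin
#' is testable when both presence classes contain at least `min_class` lines.
#'
#' @param bin_matrix A [bin_genotype_matrix()] result, or a numeric
#'   lines-by-bins presence matrix with dimnames.
#' @param trait Per-line trait values: a numeric vector named by line, or a
#'   data frame with columns `line_id` and `value`.
#' @param q_threshold BH q-value significance threshold (default 0.001).
#' @param min_class Minimum lines per presence class for a bin to be testable.
#' @param coding Passed to [presence_matrix()] when `bin_matrix` is a
#'   `bin_matrix` object.
#' @return Tibble `bin`, `n`, `estimate`, `p`, `q`, `significant`,
#'   `testable`, of class `marginal_scan`.
#' @export
marginal_scan <- function(bin_matrix, trait, q_threshold = 0.001,
                          min_class = 3, coding = "presence") {
  stopifnot(q_threshold > 0, q_threshold < 1)
  P <- if (inherits(bin_matrix, "bin_matrix")) {
    presence_matrix(bin_matrix, coding)
  } else {
    as.matrix(bin_matrix)
  }
  y <- align_trait(trait, rownames(P))
  n <- length(y)
  if (stats::sd(y) == 0) {
    warning("constant trait: all p-values set to 1", call. = FALSE)
  }
  ones <- colSums(P > 0)
  testable <- ones >= min_class & (n - ones) >= min_class
  yc <- y - mean(y)
  est <- p <- rep(NA_real_, ncol(P))
  for (j in which(testable)) {
    x <- P[, j]
    sxx <- sum((x - mean(x))^2)
    b <- sum((x - mean(x)) * yc) / sxx
    res <- yc - b * (x - mean(x))
    s2 <- sum(res^2) / (n - 2)
    if (s2 == 0) {
      p[j] <- if (b == 0) 1 else 0
    } else {
      tstat <- b / sqrt(s2 / sxx)
      p[j] <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    }
    est[j] <- b
  }
  if (stats::sd(y) == 0) p[testable] <- 1
  q <- rep(NA_real_, ncol(P))
  q[testable] <- stats::p.adjust(p[testable], method = "BH")
  out <- tibble::tibble(
    bin = colnames(P), n = n, estimate = est, p = p, q = q,
    significant = !is.na(q) & q < q_threshold, testable = testable
  )
  class(out) <- c("marginal_scan", class(out))
  attr(out, "q_threshold") <- q_threshold
  out
}

align_trait <- function(trait, line_ids) {
  if (is.data.frame(trait)) {
    trait <- stats::setNames(trait$value, trait$line_id)
  }
  if (!is.null(names(trait))) {
    miss <- setdiff(line_ids, names(trait))
    if (length(miss)) {
      stop("trait values missing for line(s): ",
           paste(utils::head(miss, 3), collapse = ", "), call. = FALSE)
    }
    trait <- trait[line_ids]
  } else if (length(trait) != length(line_ids)) {
    stop("unnamed trait vector must match the number of lines", call. = FALSE)
  }
  as.numeric(trait)
}

#' Enumerate the epistatic (two-bin) model space
#'
#' One predictor per bin plus one product predictor per unordered bin pair
#' that is observed in the population — i.e. at least `min_count` lines carry
#' donor DNA at both bins. Unobserved combinations carry no information in
#' the population and are excluded, exactly as in the mapping design.
#'
#' @param bin_matrix A [bin_genotype_matrix()] result or presence matrix.
#' @param min_count Minimum number of lines carrying both bins (default 1).
#' @return Object of class `epistatic_design`: list with `bins`, `pairs`
#'   (tibble `bin_a`, `bin_b`, `n_lines`), and `counts`
#'   (`n_bins`, `total_pairs`, `observed_pairs`, `unobserved_pairs`).
#' @export
build_epistatic_design <- function(bin_matrix, min_count = 1) {
  P <- if (inherits(bin_matrix, "bin_matrix")) presence_matrix(bin_matrix)
       else as.matrix(bin_matrix)
  co <- crossprod(P) # pairwise co-presence line counts
  co[lower.tri(co, diag = TRUE)] <- 0
  obs <- which(co >= min_count, arr.ind = TRUE)
  pairs <- tibble::tibble(
    bin_a = colnames(P)[obs[, 1]],
    bin_b = colnames(P)[obs[, 2]],
    n_lines = co[obs]
  )
  p <- ncol(P)
  counts <- epistatic_pair_counts(p, nrow(pairs))
  structure(list(bins = colnames(P), pairs = pairs, counts = counts),
            class = "epistatic_design")
}

#' Pair-count arithmetic for an epistatic model space
#'
#' @param n_bins Number of bins.
#' @param n_observed Number of observed (informative) unordered pairs.
#' @return List `n_bins`, `total_pairs` = `choose(n_bins, 2)`,
#'   `observed_pairs`, `unobserved_pairs`, and `model_effects` =
#'   `n_bins + observed_pairs` (the epistatic-model dimension).
#' @export
epistatic_pair_counts <- function(n_bins, n_observed = NA_integer_) {
  total <- choose(n_bins, 2)
  list(n_bins = n_bins, total_pairs = total, observed_pairs = n_observed,
       unobserved_pairs = total - n_observed,
       model_effects = n_bins + n_observed)
}

# drop exact duplicate columns, keeping the first occurrence; duplicates are
# detected by double random projection (collision probability negligible)
dedup_columns <- function(X) {
  if (ncol(X) < 2) return(X)
  v1 <- sin(seq_len(nrow(X)) * 1.6180339887)
  v2 <- cos(seq_len(nrow(X)) * 2.7182818284)
  key <- paste(signif(crossprod(X, v1), 12), signif(crossprod(X, v2), 12))
  X[, !duplicated(key), drop = FALSE]
}

# materialize the numeric design matrix of an epistatic design
design_matrix <- function(design, P) {
  X1 <- P[, design$bins, drop = FALSE]
  if (nrow(design$pairs) == 0) return(X1)
  X2 <- P[, design$pairs$bin_a, drop = FALSE] *
    P[, design$pairs$bin_b, drop = FALSE]
  colnames(X2) <- paste(design$pairs$bin_a, design$pairs$bin_b, sep = ":")
  cbind(X1, X2)
}

#' MC+ univariate thresholding operator
#'
#' The penalized univariate solution of the MC+ (minimax concave) penalty
#' family: zero inside `[-alpha, alpha]`, a linearly relaxed shrinkage zone up
#' to `alpha * gamma`, and the identity beyond it. `gamma -> Inf` recovers the
#' soft (lasso) threshold; `gamma -> 1+` approaches hard thresholding.
#'
#' @param beta_tilde Unpenalized univariate coefficient(s).
#' @param alpha Penalty severity (>= 0).
#' @param gamma Concavity parameter (> 1).
#' @return Thresholded value(s), same shape as `beta_tilde`.
#' @export
mcplus_threshold <- function(beta_tilde, alpha, gamma) {
  if (gamma <= 1) stop("gamma must be > 1", call. = FALSE)
  stopifnot(alpha >= 0)
  a <- abs(beta_tilde)
  out <- beta_tilde
  mid <- a > alpha & a <= alpha * gamma
  out[a <= alpha] <- 0
  out[mid] <- sign(beta_tilde[mid]) * (a[mid] - alpha) / (1 - 1 / gamma)
  out
}

#' SparseNet tuning configuration
#'
#' @param n_alpha Length of the data-driven log-spaced alpha path.
#' @param alpha_min_ratio Smallest alpha as a fraction of the null-model
#'   alpha (the max absolute gradient).
#' @param gamma_grid Concavity grid, traversed from most convex (largest,
#'   lasso-like) to most concave (near 1, subset-selection-like).
#' @param k_folds,cv_reps Cross-validation folds and number of seeded
#'   repetitions whose selected tuning values are averaged.
#' @param interval_corr_threshold Correlation defining empirical QTL
#'   intervals around selected bins.
#' @param tol,max_sweeps Coordinate-descent convergence tolerance (max
#'   absolute coefficient change) and sweep cap.
#' @return Object of class `sparsenet_config`.
#' @export
sparsenet_config <- function(n_alpha = 50, alpha_min_ratio = 0.001,
                             gamma_grid = c(150, 50, 20, 10, 5, 3, 2, 1.5, 1.1),
                             k_folds = 6, cv_reps = 10,
                             interval_corr_threshold = 0.90,
                             tol = 1e-7, max_sweeps = 10000L) {
  stopifnot(all(gamma_grid > 1), k_folds >= 2, cv_reps >= 1, n_alpha >= 2)
  structure(list(n_alpha = n_alpha, alpha_min_ratio = alpha_min_ratio,
                 gamma_grid = sort(gamma_grid, decreasing = TRUE),
                 k_folds = k_folds, cv_reps = cv_reps,
                 interval_corr_threshold = interval_corr_threshold,
                 tol = tol, max_sweeps = as.integer(max_sweeps)),
            class = "sparsenet_config")
}

standardize_design <- function(X, y) {
  centers <- colMeans(X)
  Xc <- sweep(X, 2, centers)
  scales <- sqrt(colMeans(Xc^2))
  keep <- scales > 0
  Xs <- sweep(Xc[, keep, drop = FALSE], 2, scales[keep], "/")
  list(X = Xs, centers = centers, scales = scales, keep = keep,
       y_center = mean(y), y = y - mean(y))
}

#' Fit the MC+ coordinate-descent coefficient surface
#'
#' Cyclic coordinate descent applying [mcplus_threshold()] per coordinate on
#' a standardized design. The alpha path is warm-started from sparse to
#' dense; at each alpha the gamma sequence is relaxed from most convex
#' (lasso-like) to most concave, each solve starting from the previous
#' gamma's solution at the same alpha, so the nonconvex fits stay on the
#' solution branch reached from the convex end instead of falling into
#' arbitrary local minima. Columns are standardized internally (unit mean
#' square after centering); constant columns are dropped. The default alpha
#' path is log-spaced from the smallest alpha yielding the all-zero model.
#'
#' @param X Numeric design matrix (lines x predictors, dimnames required).
#' @param y Response vector.
#' @param cfg A [sparsenet_config()].
#' @param alpha_grid Optional explicit alpha path (descending).
#' @return Object of class `sparsenet_fit` with the per-(gamma, alpha)
#'   nonzero sets, the grids, and the standardization needed to express
#'   coefficients on the original scale.
#' @export
sparsenet_fit <- function(X, y, cfg = sparsenet_config(), alpha_grid = NULL) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  std <- standardize_design(X, y)
  if (!all(std$keep)) {
    message(sum(!std$keep), " constant column(s) dropped from the design")
  }
  n <- nrow(std$X)
  if (is.null(alpha_grid)) {
    alpha_max <- max(abs(crossprod(std$X, std$y))) / n
    if (alpha_max == 0) alpha_max <- 1e-3
    alpha_grid <- exp(seq(log(alpha_max), log(alpha_max * cfg$alpha_min_ratio),
                          length.out = cfg$n_alpha))
  }
  path <- .mcplus_path_cpp(std$X, std$y, as.numeric(alpha_grid),
                           as.numeric(cfg$gamma_grid), cfg$tol,
                           cfg$max_sweeps)
  nonconv <- sum(vapply(path, function(g) {
    sum(!vapply(g, function(a) isTRUE(a$converged), logical(1)))
  }, numeric(1)))
  if (nonconv > 0) {
    warning(nonconv, " path point(s) hit the sweep cap; best iterate kept",
            call. = FALSE)
  }
  structure(list(path = path, alpha_grid = alpha_grid,
                 gamma_grid = cfg$gamma_grid, std = std,
                 colnames = colnames(X), n = n, cfg = cfg),
            class = "sparsenet_fit")
}

#' @export
print.sparsenet_fit <- function(x, ...) {
  cat("<sparsenet_fit> ", x$n, " obs, ", length(x$colnames), " predictors, ",
      length(x$alpha_grid), " alphas x ", length(x$gamma_grid), " gammas\n",
      sep = "")
  invisible(x)
}

#' Coefficients of a SparseNet fit at one grid point
#'
#' @param object A [sparsenet_fit()] result.
#' @param alpha,gamma Grid values (matched to the nearest grid point).
#' @param ... Unused.
#' @return Named coefficient vector on the original predictor scale, with the
#'   intercept as attribute `"intercept"`.
#' @method coef sparsenet_fit
#' @export
coef.sparsenet_fit <- function(object, alpha = NULL, gamma = NULL, ...) {
  ai <- if (is.null(alpha)) length(object$alpha_grid) else
    which.min(abs(log(object$alpha_grid) - log(alpha)))
  gi <- if (is.null(gamma)) 1L else
    which.min(abs(log(object$gamma_grid) - log(gamma)))
  sol <- object$path[[gi]][[ai]]
  beta <- stats::setNames(rep(0, length(object$colnames)), object$colnames)
  kept_names <- object$colnames[object$std$keep]
  beta_std <- stats::setNames(rep(0, length(kept_names)), kept_names)
  beta_std[sol$index] <- sol$beta
  beta[kept_names] <- beta_std / object$std$scales[object$std$keep]
  icpt <- object$std$y_center - sum(beta * object$std$centers)
  attr(beta, "intercept") <- icpt
  beta
}

#' Cross-validation-averaged tuning of (alpha, gamma)
#'
#' Runs `cv_reps` seeded k-fold cross-validations; each repetition selects
#' the (alpha, gamma) grid point minimizing mean held-out squared error, and
#' the selected alphas and gammas are arithmetically averaged over
#' repetitions (for reproducible tuning), then snapped to the nearest grid
#' points (log scale) for the final full-data refit.
#'
#' @param X,y Design and response, as in [sparsenet_fit()].
#' @param cfg A [sparsenet_config()].
#' @param seed Optional integer seed for the fold assignments.
#' @return List `alpha`, `gamma` (snapped), `alpha_mean`, `gamma_mean` (raw
#'   averages), `per_rep` (tibble of per-repetition selections), and the
#'   shared `alpha_grid`.
#' @export
cv_tune <- function(X, y, cfg = sparsenet_config(), seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < cfg$k_folds) stop("fewer lines than folds", call. = FALSE)
  # common alpha path from the full data so selections are comparable
  std_all <- standardize_design(X, y)
  alpha_max <- max(abs(crossprod(std_all$X, std_all$y))) / n
  if (alpha_max == 0) alpha_max <- 1e-3
  alpha_grid <- exp(seq(log(alpha_max), log(alpha_max * cfg$alpha_min_ratio),
                        length.out = cfg$n_alpha))
  ng <- length(cfg$gamma_grid)
  na <- length(alpha_grid)
  with_seed(seed, {
    per_rep <- vector("list", cfg$cv_reps)
    for (r in seq_len(cfg$cv_reps)) {
      folds <- sample(rep(seq_len(cfg$k_folds), length.out = n))
      err <- matrix(0, ng, na)
      for (k in seq_len(cfg$k_folds)) {
        tr <- folds != k
        std <- standardize_design(X[tr, , drop = FALSE], y[tr])
        path <- .mcplus_path_cpp(std$X, std$y, alpha_grid,
                                 as.numeric(cfg$gamma_grid), cfg$tol,
                                 cfg$max_sweeps)
        Xt <- sweep(X[!tr, std$keep, drop = FALSE], 2,
                    std$centers[std$keep])
        Xt <- sweep(Xt, 2, std$scales[std$keep], "/")
        yt <- y[!tr]
        for (gi in seq_len(ng)) {
          for (ai in seq_len(na)) {
            sol <- path[[gi]][[ai]]
            pred <- rep(std$y_center, nrow(Xt))
            if (length(sol$index)) {
              pred <- pred + Xt[, sol$index, drop = FALSE] %*% sol$beta
            }
            err[gi, ai] <- err[gi, ai] + sum((yt - pred)^2)
          }
        }
      }
      best <- arrayInd(which.min(err), dim(err))
      per_rep[[r]] <- tibble::tibble(
        rep = r, alpha = alpha_grid[best[2]],
        gamma = cfg$gamma_grid[best[1]],
        cv_mse = min(err) / n
      )
    }
    per_rep <- dplyr::bind_rows(per_rep)
    alpha_mean <- mean(per_rep$alpha)
    gamma_mean <- mean(per_rep$gamma)
    alpha_star <- alpha_grid[which.min(abs(log(alpha_grid) - log(alpha_mean)))]
    gamma_star <- cfg$gamma_grid[
      which.min(abs(log(cfg$gamma_grid) - log(gamma_mean)))]
    list(alpha = alpha_star, gamma = gamma_star, alpha_mean = alpha_mean,
         gamma_mean = gamma_mean, per_rep = per_rep, alpha_grid = alpha_grid)
  })
}

#' Empirical QTL intervals by presence correlation
#'
#' Because penalized selection keeps one representative among a set of highly
#' correlated bins, the empirical QTL interval of a selected bin is the set
#' of bins whose presence column correlates with it at or above the
#' threshold (the selected bin is always included).
#'
#' @param selected_bins Character vector of selected bin ids.
#' @param bin_matrix A [bin_genotype_matrix()] result or presence matrix.
#' @param threshold Pearson correlation cutoff (default 0.90).
#' @return Tibble `selected_bin`, `interval_bins` (list-column),
#'   `interval_size`.
#' @export
qtl_intervals <- function(selected_bins, bin_matrix, threshold = 0.90) {
  P <- if (inherits(bin_matrix, "bin_matrix")) presence_matrix(bin_matrix)
       else as.matrix(bin_matrix)
  sds <- apply(P, 2, stats::sd)
  ivs <- lapply(selected_bins, function(b) {
    if (!b %in% colnames(P)) stop("unknown bin: ", b, call. = FALSE)
    if (sds[b] == 0) {
      warning("selected bin ", b, " has zero variance; interval = itself",
              call. = FALSE)
      return(b)
    }
    ok <- sds > 0
    r <- rep(NA_real_, ncol(P))
    r[ok] <- suppressWarnings(stats::cor(P[, b], P[, ok, drop = FALSE]))
    union(b, colnames(P)[!is.na(r) & r >= threshold])
  })
  tibble::tibble(selected_bin = selected_bins, interval_bins = ivs,
                 interval_size = lengths(ivs))
}

#' Filter and rank epistatic QTL pairs for reporting
#'
#' Same-chromosome pairs whose bin midpoints are closer than
#' `min_cm_separation` cM are removed (such pairs may be broad-peaked single
#' QTL rather than genuine interactions); survivors are ranked by absolute
#' coefficient and the strongest `top_n` are reported. Cross-chromosome
#' pairs always pass the distance rule.
#'
#' @param pairs Tibble with `bin_a`, `bin_b`, `coefficient`.
#' @param bins Bin tibble (for midpoints).
#' @param genome A [genome_model()] (for cM positions).
#' @param min_cm_separation Minimum same-chromosome separation (default 20 cM).
#' @param top_n Number of pairs reported (default 10).
#' @return Filtered, ranked tibble with added `distance_cm` (NA across
#'   chromosomes).
#' @export
filter_epistatic <- function(pairs, bins, genome, min_cm_separation = 20,
                             top_n = 10) {
  if (nrow(pairs) == 0) return(dplyr::mutate(pairs, distance_cm = numeric(0)))
  binfo <- function(id) bins[match(id, bins$bin_id), , drop = FALSE]
  a <- binfo(pairs$bin_a)
  b <- binfo(pairs$bin_b)
  dist_cm <- rep(NA_real_, nrow(pairs))
  same <- a$chrom == b$chrom
  for (i in which(same)) {
    mid_a <- (a$start_bp[i] + a$end_bp[i]) / 2
    mid_b <- (b$start_bp[i] + b$end_bp[i]) / 2
    dist_cm[i] <- abs(genetic_distance(mid_a, mid_b, a$chrom[i], genome))
  }
  pairs$distance_cm <- dist_cm
  keep <- is.na(dist_cm) | dist_cm >= min_cm_separation
  pairs[keep, , drop = FALSE] |>
    dplyr::arrange(dplyr::desc(abs(.data$coefficient))) |>
    utils::head(top_n)
}

#' Fine-map a discrete trait by interval algebra
#'
#' The candidate region on a chromosome is the intersection of the donor
#' (introgressed) intervals of all consistently phenotype-positive lines,
#' minus the union of the donor intervals of all consistently negative
#' lines; lines scored inconsistent are excluded from both sets.
#'
#' @param lines Segment tibble tiling each line (`line_id`, `chrom`,
#'   `start_bp`, `end_bp`, `state`).
#' @param phenotype Tibble `line_id`, `phenotype` with values `"present"`,
#'   `"absent"`, `"inconsistent"`.
#' @param chrom Chromosome to fine-map on.
#' @param genes Optional gene tibble (as in [assign_genes_to_bins()]) to
#'   count candidate genes in the result.
#' @return List with `candidate` (tibble `chrom`, `start_bp`, `end_bp`; zero
#'   rows when unmappable), `mappable`, `n_positive`, `n_negative`, and (when
#'   `genes` given) `genes`, `n_genes`.
#' @export
finemap_discrete <- function(lines, phenotype, chrom, genes = NULL) {
  ph <- stats::setNames(phenotype$phenotype, phenotype$line_id)
  donor_ranges <- function(id) {
    s <- lines[lines$line_id == id & lines$chrom == chrom &
                 lines$state != "M82", , drop = FALSE]
    IRanges::reduce(IRanges::IRanges(s$start_bp + 1, s$end_bp))
  }
  pos_ids <- names(ph)[ph == "present"]
  neg_ids <- names(ph)[ph == "absent"]
  pos_ranges <- lapply(pos_ids, donor_ranges)
  pos_ranges <- pos_ranges[vapply(pos_ranges, length, integer(1)) > 0]
  if (length(pos_ranges) == 0) {
    stop("no consistently positive line with an introgression on ", chrom,
         call. = FALSE)
  }
  cand <- Reduce(IRanges::intersect, pos_ranges)
  neg_all <- IRanges::IRanges()
  for (id in neg_ids) neg_all <- c(neg_all, donor_ranges(id))
  if (length(neg_all)) {
    cand <- IRanges::setdiff(cand, IRanges::reduce(neg_all))
  }
  candidate <- tibble::tibble(chrom = chrom,
                              start_bp = IRanges::start(cand) - 1,
                              end_bp = IRanges::end(cand))
  out <- list(candidate = candidate, mappable = nrow(candidate) > 0,
              n_positive = length(pos_ranges), n_negative = length(neg_ids))
  if (!is.null(genes) && nrow(candidate) > 0) {
    fake_bins <- dplyr::mutate(candidate,
                               bin_id = paste0("cand_", dplyr::row_number()),
                               .before = 1)
    withg <- assign_genes_to_bins(fake_bins, genes)
    out$genes <- sort(unique(unlist(withg$gene_ids)))
    out$n_genes <- length(out$genes)
  } else if (!is.null(genes)) {
    out$genes <- character(0)
    out$n_genes <- 0L
  }
  out
}

#' Overlap table between two sets of QTL intervals
#'
#' For each trait, finds every pair of overlapping intervals (half-open
#' overlap) between a fine-resolution set (e.g. BIL QTL) and a coarser
#' confirmation set (e.g. IL QTL), and reports the overlap span and the
#' narrowing factor (fine span / coarse span).
#'
#' @param bil_intervals,il_intervals Tibbles with columns `trait`, `chrom`,
#'   `start_bp`, `end_bp` (0-based half-open) and optionally `id`.
#' @return Tibble with one row per overlapping pair: trait, both intervals,
#'   `overlap_bp`, `narrowing_factor`.
#' @export
overlap_qtl <- function(bil_intervals, il_intervals) {
  out <- list()
  for (tr in intersect(unique(bil_intervals$trait),
                       unique(il_intervals$trait))) {
    b <- bil_intervals[bil_intervals$trait == tr, , drop = FALSE]
    i <- il_intervals[il_intervals$trait == tr, , drop = FALSE]
    for (ch in intersect(unique(b$chrom), unique(i$chrom))) {
      bb <- b[b$chrom == ch, , drop = FALSE]
      ii <- i[i$chrom == ch, , drop = FALSE]
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(bb$start_bp + 1, bb$end_bp),
        IRanges::IRanges(ii$start_bp + 1, ii$end_bp)
      )
      if (length(hits) == 0) next
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      ov_start <- pmax(bb$start_bp[qh], ii$start_bp[sh])
      ov_end <- pmin(bb$end_bp[qh], ii$end_bp[sh])
      out[[length(out) + 1]] <- tibble::tibble(
        trait = tr, chrom = ch,
        bil_start_bp = bb$start_bp[qh], bil_end_bp = bb$end_bp[qh],
        il_start_bp = ii$start_bp[sh], il_end_bp = ii$end_bp[sh],
        overlap_bp = ov_end - ov_start,
        narrowing_factor = (bb$end_bp[qh] - bb$start_bp[qh]) /
          (ii$end_bp[sh] - ii$start_bp[sh])
      )
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(trait = character(0), chrom = character(0),
                          bil_start_bp = numeric(0), bil_end_bp = numeric(0),
                          il_start_bp = numeric(0), il_end_bp = numeric(0),
                          overlap_bp = numeric(0),
                          narrowing_factor = numeric(0)))
  }
  dplyr::bind_rows(out)
}

#' Map QTL with cross-validation-tuned MC+ regression
#'
#' The full penalized mapping pipeline for one trait: build the additive or
#' epistatic design from the bin matrix, tune (alpha, gamma) by averaged
#' cross-validation ([cv_tune()]), refit on all lines at the snapped tuning
#' values, and report the selected effects with their empirical correlation
#' intervals.
#'
#' @param bin_matrix A [bin_genotype_matrix()] result.
#' @param trait Per-line trait values (vector named by line, or data frame
#'   `line_id`, `value`).
#' @param model `"additive"` (single-bin effects only) or `"epistatic"`
#'   (single bins plus observed pairs).
#' @param cfg A [sparsenet_config()].
#' @param seed Optional integer seed for the CV fold stream.
#' @param coding Presence coding, see [presence_matrix()].
#' @param min_count Pair observation threshold for the epistatic design.
#' @return Object of class `sparsenet_qtl`: list with `effects` (tibble
#'   `effect`, `bin_a`, `bin_b`, `coefficient`, `type`), `intervals`,
#'   `tuning`, `fit`, `design_counts`, `trait_name`.
#' @export
sparsenet_qtl <- function(bin_matrix, trait, model = c("additive", "epistatic"),
                          cfg = sparsenet_config(), seed = NULL,
                          coding = "presence", min_count = 1) {
  model <- match.arg(model)
  P <- presence_matrix(bin_matrix, coding)
  y <- align_trait(trait, rownames(P))
  if (model == "epistatic") {
    design <- build_epistatic_design(P >= 0.5, min_count = min_count)
    X <- design_matrix(design, P)
    counts <- design$counts
  } else {
    X <- P
    counts <- list(n_bins = ncol(P))
  }
  # identical columns (duplicate bins, coincident pair products) carry the
  # same information; keep one representative each — penalized selection
  # would keep at most one anyway, and the empirical r >= threshold interval
  # recovers the duplicates afterwards
  X <- dedup_columns(X)
  tune <- cv_tune(X, y, cfg, seed = seed)
  fit <- sparsenet_fit(X, y, cfg, alpha_grid = tune$alpha_grid)
  beta <- coef(fit, alpha = tune$alpha, gamma = tune$gamma)
  nz <- beta[beta != 0]
  eff <- tibble::tibble(
    effect = names(nz),
    coefficient = as.numeric(nz)
  ) |>
    tidyr::separate(col = "effect", into = c("bin_a", "bin_b"), sep = ":",
                    fill = "right", remove = FALSE) |>
    dplyr::mutate(type = ifelse(is.na(.data$bin_b), "additive", "epistatic"))
  sel_bins <- unique(stats::na.omit(c(eff$bin_a, eff$bin_b)))
  intervals <- qtl_intervals(sel_bins, P, cfg$interval_corr_threshold)
  structure(list(effects = eff, intervals = intervals, tuning = tune,
                 fit = fit, design_counts = counts, model = model,
                 n_lines = nrow(P)),
            class = "sparsenet_qtl")
}

#' @export
print.sparsenet_qtl <- function(x, ...) {
  cat("<sparsenet_qtl> ", x$model, " model, ", x$n_lines, " lines\n",
      "  tuning: alpha = ", signif(x$tuning$alpha, 4),
      ", gamma = ", signif(x$tuning$gamma, 4), "\n",
      "  selected effects: ", nrow(x$effects), " (",
      sum(x$effects$type == "additive"), " additive, ",
      sum(x$effects$type == "epistatic"), " epistatic)\n", sep = "")
  invisible(x)
}
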