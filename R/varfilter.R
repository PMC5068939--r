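#' Polymorphism filter thresholds
#'
#' Thresholds of the three-stage parental polymorphism filter: a candidate
#' site must show > `parental_concordance_min` of each parent's reads matching
#' that parent's assigned allele (strict inequality); in the pooled population
#' data its donor-allele ratio must fall between the chromosome-wise
#' percentile window (inclusive), its nonparental read fraction must be
#' strictly below `nonparental_ratio_max`, and its total coverage at most
#' `coverage_max` (inclusive).
#'
#' @param parental_concordance_min Minimum per-parent concordance (default 0.90).
#' @param pen_ratio_percentile_window Percentile window (default `c(25, 75)`).
#' @param nonparental_ratio_max Maximum nonparental read fraction (default 0.025).
#' @param coverage_max Maximum pooled coverage (default 2000).
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(parental_concordance_min = 0.90,
                          pen_ratio_percentile_window = c(25, 75),
                          nonparental_ratio_max = 0.025,
                          coverage_max = 2000) {
  stopifnot(parental_concordance_min >= 0, parental_concordance_min <= 1,
            length(pen_ratio_percentile_window) == 2,
            all(pen_ratio_percentile_window >= 0),
            all(pen_ratio_percentile_window <= 100),
            nonparental_ratio_max >= 0, nonparental_ratio_max <= 1,
            coverage_max > 0)
  structure(list(parental_concordance_min = parental_concordance_min,
                 pen_ratio_percentile_window = pen_ratio_percentile_window,
                 nonparental_ratio_max = nonparental_ratio_max,
                 coverage_max = coverage_max),
            class = "filter_config")
}

# allele count columns of a pileup-count table = everything numeric beyond
# the coordinate/reference columns
allele_columns <- function(tbl) {
  setdiff(names(tbl), c("chrom", "pos", "ref"))
}

# majority allele per row; ties return NA
majority_allele <- function(tbl) {
  alleles <- allele_columns(tbl)
  cnt <- as.matrix(tbl[, alleles, drop = FALSE])
  if (nrow(cnt) == 0) return(character(0))
  top <- apply(cnt, 1, max)
  n_top <- rowSums(cnt == top & top > 0)
  idx <- apply(cnt, 1, which.max)
  out <- alleles[idx]
  out[top == 0 | n_top > 1] <- NA_character_
  out
}

#' Identify candidate parental polymorphisms from two parent pileups
#'
#' Assigns each parent its majority allele at every site genotyped in both
#' parents and retains sites where the two majority alleles differ. Sites
#' where the parents share an allele that differs from the reference
#' (reference-specific variants) are thereby discarded, as are sites with a
#' tied majority in either parent. Site coordinates are 1-based.
#'
#' @param m82,pen Pileup count tibbles for the recurrent and donor parent:
#'   columns `chrom`, `pos`, optional `ref`, plus one numeric count column per
#'   allele (e.g. `A`, `C`, `G`, `T`, indel columns).
#' @return Tibble `chrom`, `pos`, (`ref`,) `m82_allele`, `pen_allele`.
#'   Per-stage drop counts are attached as attribute `"filter_log"`.
#' @export
call_parental_variants <- function(m82, pen) {
  m82 <- tibble::as_tibble(m82)
  pen <- tibble::as_tibble(pen)
  keys_m <- paste(m82$chrom, m82$pos)
  keys_p <- paste(pen$chrom, pen$pos)
  common <- intersect(keys_m, keys_p)
  n_skipped <- length(union(keys_m, keys_p)) - length(common)
  m <- m82[match(common, keys_m), , drop = FALSE]
  p <- pen[match(common, keys_p), , drop = FALSE]
  am <- majority_allele(m)
  ap <- majority_allele(p)
  tie <- is.na(am) | is.na(ap)
  same <- !tie & am == ap
  keep <- !tie & !same
  out <- tibble::tibble(chrom = m$chrom, pos = m$pos)
  if ("ref" %in% names(m)) out$ref <- m$ref
  out$m82_allele <- am
  out$pen_allele <- ap
  out <- out[keep, , drop = FALSE]
  attr(out, "filter_log") <- list(
    sites_single_parent = n_skipped,
    sites_tied = sum(tie),
    sites_monomorphic = sum(same),
    candidates = nrow(out)
  )
  out
}

#' Parental-concordance noise reduction
#'
#' Keeps a candidate site only if, in both parental alignments, the fraction
#' of reads matching that parent's assigned allele strictly exceeds the
#' concordance threshold. Candidates with zero coverage in either parent are
#' dropped.
#'
#' @param candidates Output of [call_parental_variants()].
#' @param m82,pen Parent pileup count tibbles (as in
#'   [call_parental_variants()]).
#' @param cfg A [filter_config()].
#' @return Filtered candidate tibble with updated `"filter_log"` attribute.
#' @export
noise_reduce <- function(candidates, m82, pen, cfg = filter_config()) {
  key <- paste(candidates$chrom, candidates$pos)
  m <- m82[match(key, paste(m82$chrom, m82$pos)), , drop = FALSE]
  p <- pen[match(key, paste(pen$chrom, pen$pos)), , drop = FALSE]
  conc <- function(tbl, allele) {
    cnt <- as.matrix(tbl[, allele_columns(tbl), drop = FALSE])
    tot <- rowSums(cnt)
    own <- cnt[cbind(seq_len(nrow(cnt)), match(allele, colnames(cnt)))]
    list(frac = ifelse(tot > 0, own / tot, NA_real_), tot = tot)
  }
  cm <- conc(m, candidates$m82_allele)
  cp <- conc(p, candidates$pen_allele)
  zero_cov <- cm$tot == 0 | cp$tot == 0
  pass <- !zero_cov &
    cm$frac > cfg$parental_concordance_min &
    cp$frac > cfg$parental_concordance_min
  out <- candidates[pass, , drop = FALSE]
  attr(out, "filter_log") <- c(attr(candidates, "filter_log"), list(
    noise_zero_coverage = sum(zero_cov),
    noise_discordant = sum(!pass & !zero_cov),
    after_noise_reduction = nrow(out)
  ))
  out
}

#' Population-level outlier filter
#'
#' Using allele counts pooled over the whole population, keeps a site when
#' (i) its donor-allele ratio lies within the chromosome-wise percentile
#' window (linear-interpolation quantiles, boundary inclusive), (ii) its
#' nonparental read fraction is strictly below the threshold, and (iii) its
#' total coverage does not exceed the cap. Chromosomes with fewer than 4
#' covered sites skip the percentile filter with a warning. The donor ratio
#' is computed among parental reads; the nonparental fraction among all reads.
#'
#' @param candidates Candidate polymorphisms (from [noise_reduce()]).
#' @param merged Pooled population pileup counts (same layout as the parents).
#' @param cfg A [filter_config()].
#' @param covered_only Compute the percentile window over sites with at least
#'   one pooled read (default TRUE).
#' @return Final polymorphism tibble with updated `"filter_log"`.
#' @export
population_filter <- function(candidates, merged, cfg = filter_config(),
                              covered_only = TRUE) {
  key <- paste(candidates$chrom, candidates$pos)
  mg <- merged[match(key, paste(merged$chrom, merged$pos)), , drop = FALSE]
  cnt <- as.matrix(mg[, allele_columns(mg), drop = FALSE])
  cnt[is.na(cnt)] <- 0
  tot <- rowSums(cnt)
  idx <- seq_len(nrow(candidates))
  n_m82 <- ifelse(is.na(match(candidates$m82_allele, colnames(cnt))), 0,
                  cnt[cbind(idx, match(candidates$m82_allele, colnames(cnt)))])
  n_pen <- ifelse(is.na(match(candidates$pen_allele, colnames(cnt))), 0,
                  cnt[cbind(idx, match(candidates$pen_allele, colnames(cnt)))])
  parental <- n_m82 + n_pen
  pen_ratio <- ifelse(parental > 0, n_pen / parental, NA_real_)
  nonpar <- ifelse(tot > 0, (tot - parental) / tot, NA_real_)

  # the window is a property of the population-wide site set: computed once
  # per chromosome and carried on the output, so re-filtering survivors
  # reuses it (making the filter idempotent) instead of re-estimating from
  # the already-truncated ratio distribution
  window_ref <- attr(candidates, "percentile_window")
  if (is.null(window_ref)) window_ref <- list()
  in_window <- rep(TRUE, nrow(candidates))
  probs <- cfg$pen_ratio_percentile_window / 100
  for (ch in unique(candidates$chrom)) {
    sel <- candidates$chrom == ch
    vals <- pen_ratio[sel]
    if (is.null(window_ref[[ch]])) {
      base <- if (covered_only) vals[!is.na(vals)] else vals
      if (length(base) < 4) {
        warning("chromosome ", ch, " has fewer than 4 covered sites; ",
                "percentile filter skipped", call. = FALSE)
        next
      }
      window_ref[[ch]] <- unname(
        stats::quantile(base, probs = probs, na.rm = TRUE, type = 7))
    }
    qq <- window_ref[[ch]]
    in_window[sel] <- !is.na(vals) & vals >= qq[1] & vals <= qq[2]
  }
  cov_ok <- tot <= cfg$coverage_max
  nonpar_ok <- !is.na(nonpar) & nonpar < cfg$nonparental_ratio_max
  pass <- in_window & cov_ok & nonpar_ok
  pass[is.na(pass)] <- FALSE
  out <- candidates[pass, , drop = FALSE]
  attr(out, "percentile_window") <- window_ref
  attr(out, "filter_log") <- c(attr(candidates, "filter_log"), list(
    population_out_of_window = sum(!in_window, na.rm = TRUE),
    population_nonparental = sum(!nonpar_ok),
    population_coverage = sum(!cov_ok),
    final_polymorphisms = nrow(out)
  ))
  out
}

#' Run the full three-stage polymorphism filter
#'
#' Convenience wrapper: [call_parental_variants()], then [noise_reduce()],
#' then [population_filter()].
#'
#' @inheritParams call_parental_variants
#' @inheritParams population_filter
#' @return Final polymorphism tibble with the cumulative `"filter_log"`.
#' @export
filter_polymorphisms <- function(m82, pen, merged, cfg = filter_config(),
                                 covered_only = TRUE) {
  call_parental_variants(m82, pen) |>
    noise_reduce(m82, pen, cfg) |>
    population_filter(merged, cfg, covered_only = covered_only)
}
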