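#' Permutation enrichment of a gene set within trait-associated bins
#'
#' The observed statistic is the number of gene-set members contained in the
#' QTL bins. The null resamples `|qtl_bins|` bins uniformly without
#' replacement from the full bin set `n_perm` times; the p-value uses the
#' add-one estimator `(1 + #{perm >= obs}) / (n_perm + 1)`, which can never
#' return zero at finite permutation counts.
#'
#' @param qtl_bins Bin tibble of trait-associated bins, with gene content
#'   (`gene_ids` list-column from [assign_genes_to_bins()]).
#' @param gene_set Character vector of gene ids.
#' @param all_bins Bin tibble of the full population bin set, with gene
#'   content.
#' @param n_perm Number of permutations (default 10000).
#' @param significance_level Declared significance threshold (default 0.05).
#' @param seed Optional integer seed.
#' @return Tibble with `statistic`, `p`, `significant`, `n_perm`, `n_qtl_bins`.
#' @export
candidate_gene_enrichment <- function(qtl_bins, gene_set, all_bins,
                                      n_perm = 10000,
                                      significance_level = 0.05,
                                      seed = NULL) {
  stopifnot(n_perm >= 1, "gene_ids" %in% names(all_bins))
  if (nrow(qtl_bins) > nrow(all_bins)) {
    stop("more QTL bins than population bins", call. = FALSE)
  }
  gene_set <- unique(gene_set)
  count_hits <- function(gene_lists) {
    length(intersect(unique(unlist(gene_lists)), gene_set))
  }
  observed <- count_hits(qtl_bins$gene_ids)
  k <- nrow(qtl_bins)
  with_seed(seed, {
    perm <- vapply(seq_len(n_perm), function(i) {
      count_hits(all_bins$gene_ids[sample.int(nrow(all_bins), k)])
    }, numeric(1))
    p <- (1 + sum(perm >= observed)) / (n_perm + 1)
    tibble::tibble(statistic = observed, p = p,
                   significant = p < significance_level,
                   n_perm = n_perm, n_qtl_bins = k)
  })
}

#' Permutation enrichment of eQTL overlap among epistatic QTL pairs
#'
#' The observed statistic counts epistatic pairs in which *both* member
#' intervals overlap at least one eQTL interval (half-open overlap). The
#' null draws the same number of pairs uniformly from the universe of
#' observed bin pairs, `n_perm` times; the add-one p-value estimator is used.
#'
#' @param epistatic_pairs Tibble of reported pairs: columns `chrom_a`,
#'   `start_a`, `end_a`, `chrom_b`, `start_b`, `end_b` (0-based half-open).
#' @param eqtl_intervals Tibble of eQTL intervals: `chrom`, `start_bp`,
#'   `end_bp`.
#' @param pair_universe Tibble of all candidate pairs, same layout as
#'   `epistatic_pairs`.
#' @param n_perm,significance_level,seed As in
#'   [candidate_gene_enrichment()].
#' @param both_members Require both pair members to overlap an eQTL
#'   (default TRUE); FALSE counts pairs with at least one member overlapping.
#' @return Tibble with `statistic`, `p`, `significant`, `n_perm`, `n_pairs`.
#' @export
eqtl_epistasis_enrichment <- function(epistatic_pairs, eqtl_intervals,
                                      pair_universe, n_perm = 10000,
                                      significance_level = 0.05,
                                      seed = NULL, both_members = TRUE) {
  stopifnot(n_perm >= 1)
  if (nrow(pair_universe) == 0) stop("empty pair universe", call. = FALSE)
  hits_interval <- function(chrom, start, end) {
    if (nrow(eqtl_intervals) == 0) return(rep(FALSE, length(chrom)))
    vapply(seq_along(chrom), function(i) {
      e <- eqtl_intervals[eqtl_intervals$chrom == chrom[i], , drop = FALSE]
      any(e$start_bp < end[i] & e$end_bp > start[i])
    }, logical(1))
  }
  pair_stat <- function(pairs) {
    ha <- hits_interval(pairs$chrom_a, pairs$start_a, pairs$end_a)
    hb <- hits_interval(pairs$chrom_b, pairs$start_b, pairs$end_b)
    if (both_members) sum(ha & hb) else sum(ha | hb)
  }
  observed <- pair_stat(epistatic_pairs)
  k <- nrow(epistatic_pairs)
  # precompute per-universe-pair hit status once; permutations just resample
  ua <- hits_interval(pair_universe$chrom_a, pair_universe$start_a,
                      pair_universe$end_a)
  ub <- hits_interval(pair_universe$chrom_b, pair_universe$start_b,
                      pair_universe$end_b)
  uhit <- if (both_members) (ua & ub) else (ua | ub)
  with_seed(seed, {
    perm <- vapply(seq_len(n_perm), function(i) {
      sum(uhit[sample.int(length(uhit), k)])
    }, numeric(1))
    p <- (1 + sum(perm >= observed)) / (n_perm + 1)
    tibble::tibble(statistic = observed, p = p,
                   significant = p < significance_level,
                   n_perm = n_perm, n_pairs = k)
  })
}
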