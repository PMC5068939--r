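#' Reassign short introgression runs to the recurrent-parent background
#'
#' Non-M82 segments supported by fewer than `min_markers` markers are
#' indistinguishable from residual genotyping error; this smoother recodes
#' them as M82 and re-merges adjacent same-state segments, so the per-line
#' tiling invariant is preserved before bin construction.
#'
#' @param segments Segment tibble (`line_id`, `chrom`, `start_bp`, `end_bp`,
#'   `state`, `n_markers`).
#' @param min_markers Minimum supporting markers for a non-M82 block.
#' @return Segment tibble with the same tiling and the small blocks absorbed.
#' @export
smooth_segments <- function(segments, min_markers = 2) {
  stopifnot("n_markers" %in% names(segments))
  segments |>
    dplyr::group_by(.data$line_id, .data$chrom) |>
    dplyr::arrange(.data$start_bp, .by_group = TRUE) |>
    dplyr::group_modify(function(d, key) {
      st <- ifelse(d$state != "M82" & d$n_markers < min_markers, "M82", d$state)
      run <- rle(st)
      ends_idx <- cumsum(run$lengths)
      starts_idx <- c(1, ends_idx[-length(ends_idx)] + 1)
      tibble::tibble(
        start_bp = d$start_bp[starts_idx],
        end_bp = d$end_bp[ends_idx],
        state = run$values,
        n_markers = vapply(seq_along(run$values), function(k) {
          sum(d$n_markers[starts_idx[k]:ends_idx[k]])
        }, numeric(1))
      )
    }) |>
    dplyr::ungroup()
}

#' Detect per-line introgression blocks
#'
#' Collapses a line's genotype segments to its introgressions: maximal runs of
#' non-M82 state. Blocks supported by fewer than `min_markers` markers are
#' dropped (and counted in the `"filter_log"` attribute) as likely residual
#' genotyping error.
#'
#' @param calls Segment calls (`line_id`, `chrom`, `start_bp`, `end_bp`,
#'   `state`, optionally `n_markers`) from [genotype_population()] or
#'   simulator truth.
#' @param min_markers Minimum supporting markers (default 2). Segments
#'   without an `n_markers` column are never dropped.
#' @return Tibble of introgressions (`line_id`, `chrom`, `start_bp`,
#'   `end_bp`, `state` in HET/PEN, `n_supporting_markers`).
#' @export
detect_line_bins <- function(calls, min_markers = 2) {
  if (!"n_markers" %in% names(calls)) calls$n_markers <- Inf
  blocks <- calls |>
    dplyr::filter(.data$state != "M82")
  dropped <- sum(blocks$n_markers < min_markers)
  out <- blocks |>
    dplyr::filter(.data$n_markers >= min_markers) |>
    dplyr::transmute(.data$line_id, .data$chrom, .data$start_bp, .data$end_bp,
                     .data$state, n_supporting_markers = .data$n_markers) |>
    dplyr::arrange(.data$line_id, .data$chrom, .data$start_bp)
  attr(out, "filter_log") <- list(blocks_dropped_min_markers = dropped)
  out
}

#' Merge introgression boundaries into population-wide bins
#'
#' The sorted union of all introgression start/end coordinates on a chromosome
#' partitions it into sub-bins; within a bin, by construction, no line's
#' genotype changes. Bins not overlapped by any introgression in the
#' population are omitted from the mapping set and reported in the
#' `"uncovered"` attribute.
#'
#' @param introgressions Tibble from [detect_line_bins()].
#' @param genome Optional [genome_model()] used only for the coverage report.
#' @return Tibble of bins (`bin_id`, `chrom`, `start_bp`, `end_bp`).
#' @export
merge_population_boundaries <- function(introgressions, genome = NULL) {
  stopifnot(nrow(introgressions) > 0)
  per_chrom <- split(introgressions, introgressions$chrom)
  res <- purrr::imap_dfr(per_chrom, function(d, ch) {
    cuts <- sort(unique(c(d$start_bp, d$end_bp)))
    cand <- tibble::tibble(chrom = ch,
                           start_bp = cuts[-length(cuts)],
                           end_bp = cuts[-1])
    # event sweep: a candidate is covered iff some introgression starts at or
    # before its left edge and ends strictly after it
    n_starts <- findInterval(cand$start_bp, sort(d$start_bp))
    n_ends <- findInterval(cand$start_bp, sort(d$end_bp))
    cand$covered <- (n_starts - n_ends) > 0
    cand
  })
  res <- dplyr::arrange(res, .data$chrom, .data$start_bp)
  bins <- res[res$covered, c("chrom", "start_bp", "end_bp")]
  bins$bin_id <- sprintf("bin_%s_%04d", bins$chrom,
                         stats::ave(seq_len(nrow(bins)), bins$chrom,
                                    FUN = seq_along))
  bins <- bins[, c("bin_id", "chrom", "start_bp", "end_bp")]
  attr(bins, "uncovered") <- res[!res$covered, c("chrom", "start_bp", "end_bp")]
  bins
}

#' Snap near-coincident bin boundaries
#'
#' Boundaries on the same chromosome closer than `tolerance_bp` are clustered
#' (single linkage) and snapped to the cluster midpoint, collapsing spurious
#' sliver bins created by almost-identical breakpoints in different lines.
#' Bins whose ends coincide after snapping are removed. `tolerance_bp = 0`
#' is the identity.
#'
#' @param bins Bin tibble from [merge_population_boundaries()].
#' @param tolerance_bp Snapping tolerance in bp (default 0 = off).
#' @return Bin tibble with snapped boundaries and refreshed `bin_id`s.
#' @export
refine_boundaries <- function(bins, tolerance_bp = 0) {
  if (tolerance_bp <= 0) return(bins)
  per_chrom <- split(bins, bins$chrom)
  out <- purrr::imap_dfr(per_chrom, function(d, ch) {
    bnd <- sort(unique(c(d$start_bp, d$end_bp)))
    cl <- cumsum(c(1, diff(bnd) >= tolerance_bp))
    snapped <- stats::ave(bnd, cl, FUN = mean)
    remap <- stats::setNames(snapped, bnd)
    d$start_bp <- unname(remap[as.character(d$start_bp)])
    d$end_bp <- unname(remap[as.character(d$end_bp)])
    if (any(d$end_bp < d$start_bp)) {
      stop("boundary snapping inverted an interval on ", ch, call. = FALSE)
    }
    d[d$end_bp > d$start_bp, , drop = FALSE]
  })
  out <- dplyr::distinct(out, .data$chrom, .data$start_bp, .data$end_bp) |>
    dplyr::arrange(.data$chrom, .data$start_bp)
  out$bin_id <- sprintf("bin_%s_%04d", out$chrom,
                        stats::ave(seq_len(nrow(out)), out$chrom,
                                   FUN = seq_along))
  out[, c("bin_id", "chrom", "start_bp", "end_bp")]
}

#' Lines-by-bins genotype matrix
#'
#' Reads each line's genotype code at every bin from its segment tiling:
#' 0 = M82, 1 = HET, 2 = PEN. A line whose genotype changes inside a bin
#' violates the defining bin property and raises an error.
#'
#' @param lines Segment tibble tiling each line's chromosomes (`line_id`,
#'   `chrom`, `start_bp`, `end_bp`, `state`).
#' @param bins Bin tibble ([merge_population_boundaries()]).
#' @return An object of class `bin_matrix`: list with `codes` (integer matrix
#'   lines x bins), `bins`, and `line_ids`.
#' @export
bin_genotype_matrix <- function(lines, bins) {
  line_ids <- unique(lines$line_id)
  codes <- matrix(NA_integer_, length(line_ids), nrow(bins),
                  dimnames = list(line_ids, bins$bin_id))
  per_line <- split(lines, lines$line_id)
  bins_by_chrom <- split(seq_len(nrow(bins)), bins$chrom)
  for (id in line_ids) {
    segs <- per_line[[id]]
    for (ch in names(bins_by_chrom)) {
      bi <- bins_by_chrom[[ch]]
      s <- segs[segs$chrom == ch, , drop = FALSE]
      if (nrow(s) == 0) {
        stop("line ", id, " has no segments on chromosome ", ch, call. = FALSE)
      }
      s <- s[order(s$start_bp), , drop = FALSE]
      ix <- findInterval(bins$start_bp[bi], s$start_bp)
      bad <- ix < 1 | s$end_bp[pmax(ix, 1)] < bins$end_bp[bi]
      if (any(bad)) {
        b <- bi[which(bad)[1]]
        stop("line ", id, " changes genotype inside bin ", bins$bin_id[b],
             " (", ch, ":", bins$start_bp[b], "-", bins$end_bp[b], ")",
             call. = FALSE)
      }
      codes[id, bi] <- match(s$state[ix], .states) - 1L
    }
  }
  structure(list(codes = codes, bins = bins, line_ids = line_ids),
            class = "bin_matrix")
}

#' @export
print.bin_matrix <- function(x, ...) {
  cat("<bin_matrix> ", length(x$line_ids), " lines x ", nrow(x$bins),
      " bins\n", sep = "")
  tab <- table(factor(x$codes, levels = 0:2, labels = .states))
  cat("  genotype codes: ", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Donor-presence view of a bin genotype matrix
#'
#' @param bin_matrix A [bin_genotype_matrix()] result.
#' @param coding `"presence"` (HET and PEN both count as donor DNA present,
#'   the default) or `"dosage"` (M82 = 0, HET = 0.5, PEN = 1).
#' @return Numeric matrix lines x bins.
#' @export
presence_matrix <- function(bin_matrix, coding = c("presence", "dosage")) {
  coding <- match.arg(coding)
  codes <- bin_matrix$codes
  if (coding == "presence") {
    out <- (codes >= 1) * 1
  } else {
    out <- codes / 2
  }
  out
}

#' Attach gene content to bins
#'
#' A gene belongs to every bin its span overlaps (half-open interval overlap).
#'
#' @param bins Bin tibble.
#' @param genes Gene tibble (`gene_id`, `chrom`, `start_bp`, `end_bp`,
#'   0-based half-open), e.g. from [read_gff3_genes()].
#' @return `bins` with list-column `gene_ids` and integer `n_genes`.
#' @export
assign_genes_to_bins <- function(bins, genes) {
  gene_ids <- vector("list", nrow(bins))
  for (ch in unique(bins$chrom)) {
    bi <- which(bins$chrom == ch)
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0) {
      gene_ids[bi] <- list(character(0))
      next
    }
    # half-open intervals: IRanges is closed, so shift ends by -1
    q <- IRanges::IRanges(bins$start_bp[bi] + 1, bins$end_bp[bi])
    s <- IRanges::IRanges(g$start_bp + 1, g$end_bp)
    hits <- IRanges::findOverlaps(q, s)
    hl <- split(g$gene_id[S4Vectors::subjectHits(hits)],
                factor(S4Vectors::queryHits(hits), levels = seq_along(bi)))
    gene_ids[bi] <- lapply(hl, as.character)
  }
  bins$gene_ids <- gene_ids
  bins$n_genes <- lengths(gene_ids)
  bins
}

#' Population introgression and bin summary statistics
#'
#' @param introgressions Tibble from [detect_line_bins()].
#' @param bins Bin tibble.
#' @param genome A [genome_model()].
#' @param line_ids All line identifiers (so contaminant-free lines count with
#'   zero introgressions); defaults to the lines present in `introgressions`.
#' @return List with `per_line` (introgression count, donor-genome
#'   percentage), `per_chromosome` (lines with an introgression,
#'   introgression count, bin count), and `totals` (lines, total and mean
#'   introgressions, total bins, mean bins per chromosome).
#' @export
introgression_stats <- function(introgressions, bins, genome,
                                line_ids = NULL) {
  if (is.null(line_ids)) line_ids <- unique(introgressions$line_id)
  genome_bp <- sum(genome$chromosomes$length_bp)
  per_line <- introgressions |>
    dplyr::group_by(.data$line_id) |>
    dplyr::summarise(
      n_introgressions = dplyr::n(),
      donor_bp = sum(.data$end_bp - .data$start_bp),
      pen_bp = sum((.data$end_bp - .data$start_bp)[.data$state == "PEN"]),
      .groups = "drop"
    )
  per_line <- tibble::tibble(line_id = line_ids) |>
    dplyr::left_join(per_line, by = "line_id") |>
    tidyr::replace_na(list(n_introgressions = 0, donor_bp = 0, pen_bp = 0)) |>
    dplyr::mutate(pct_donor = 100 * .data$donor_bp / genome_bp,
                  pct_pen = 100 * .data$pen_bp / genome_bp)
  per_chrom <- introgressions |>
    dplyr::group_by(chrom = .data$chrom) |>
    dplyr::summarise(n_lines_with_introgression = dplyr::n_distinct(.data$line_id),
                     n_introgressions = dplyr::n(), .groups = "drop") |>
    dplyr::left_join(
      dplyr::count(bins, .data$chrom, name = "n_bins"), by = "chrom"
    ) |>
    tidyr::replace_na(list(n_bins = 0))
  totals <- list(
    n_lines = length(line_ids),
    total_introgressions = nrow(introgressions),
    mean_introgressions_per_line = nrow(introgressions) / length(line_ids),
    total_bins = nrow(bins),
    mean_bins_per_chromosome = nrow(bins) / nrow(genome$chromosomes)
  )
  list(per_line = per_line, per_chromosome = per_chrom, totals = totals)
}

#' Summarize a per-chromosome introgression/bin count table
#'
#' Computes population summaries from an already-tabulated per-chromosome
#' count table (columns `chrom`, `n_introgressions`, `n_bins`), the form in
#' which published population statistics are reported.
#'
#' @param per_chromosome Per-chromosome count tibble.
#' @param n_lines Number of uniquely genotyped lines in the population.
#' @return List with `total_introgressions`, `mean_introgressions_per_line`,
#'   `total_bins`, `bins_per_chromosome` (rounded mean).
#' @export
summarize_population_counts <- function(per_chromosome, n_lines) {
  stopifnot(all(c("n_introgressions", "n_bins") %in% names(per_chromosome)),
            n_lines > 0)
  total_intro <- sum(per_chromosome$n_introgressions)
  total_bins <- sum(per_chromosome$n_bins)
  list(
    total_introgressions = total_intro,
    mean_introgressions_per_line = total_intro / n_lines,
    total_bins = total_bins,
    bins_per_chromosome = round(total_bins / nrow(per_chromosome))
  )
}
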