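# File formats: BED-like segment/bin tables are TSV with a header and
# 0-based half-open coordinates; count and polymorphism tables are TSV with
# 1-based positions; traits are CSV. Every writer has a reader that
# round-trips its output.

#' Write / read genotype or truth segments (BED-like TSV)
#'
#' Columns `chrom`, `start_bp`, `end_bp` (0-based half-open), `line_id`,
#' `state`, plus any extra columns present.
#'
#' @param segments Segment tibble.
#' @param path Output path.
#' @return `write_segments_bed()` returns `path` invisibly;
#'   `read_segments_bed()` returns the tibble.
#' @export
write_segments_bed <- function(segments, path) {
  cols <- c("chrom", "start_bp", "end_bp", "line_id", "state")
  extra <- setdiff(names(segments), cols)
  utils::write.table(segments[, c(cols, extra)], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_segments_bed
#' @export
read_segments_bed <- function(path) {
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write / read per-line marker counts (TSV, 1-based positions)
#'
#' @param counts Count tibble (`line_id`, `chrom`, `pos`, `n_m82`, `n_pen`,
#'   `n_other`).
#' @param path Output path.
#' @return Path invisibly / the tibble.
#' @export
write_counts_tsv <- function(counts, path) {
  cols <- c("chrom", "pos", "n_m82", "n_pen", "n_other", "line_id")
  utils::write.table(counts[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write / read per-line trait values (CSV)
#'
#' @param traits Tibble with `line_id` and one or more value columns.
#' @param path Output path.
#' @return Path invisibly / the tibble.
#' @export
write_traits_csv <- function(traits, path) {
  utils::write.csv(traits, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_traits_csv
#' @export
read_traits_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write / read population bins (BED-like TSV)
#'
#' @param bins Bin tibble (list-columns such as `gene_ids` are dropped).
#' @param path Output path.
#' @return Path invisibly / the tibble.
#' @export
write_bins_tsv <- function(bins, path) {
  flat <- bins[, !vapply(bins, is.list, logical(1)), drop = FALSE]
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bins_tsv
#' @export
read_bins_tsv <- function(path) {
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write / read a bin genotype matrix (CSV)
#'
#' Lines as rows (first column `line_id`), bins as columns, integer codes
#' 0 = M82, 1 = HET, 2 = PEN. Reading requires the accompanying bin table to
#' rebuild the full object.
#'
#' @param bin_matrix A [bin_genotype_matrix()] result.
#' @param path Output path.
#' @param bins Bin tibble (for `read_bin_matrix_csv`).
#' @return Path invisibly / a `bin_matrix` object.
#' @export
write_bin_matrix_csv <- function(bin_matrix, path) {
  df <- data.frame(line_id = bin_matrix$line_ids, bin_matrix$codes,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bin_matrix_csv
#' @export
read_bin_matrix_csv <- function(path, bins) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  codes <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(codes) <- "integer"
  rownames(codes) <- df$line_id
  structure(list(codes = codes, bins = bins, line_ids = df$line_id),
            class = "bin_matrix")
}

#' Read gene models from a GFF3 annotation
#'
#' Imports `gene` features and converts the 1-based inclusive GFF3
#' coordinates to the package's 0-based half-open convention.
#'
#' @param path Path to a GFF3 file.
#' @return Tibble `gene_id`, `chrom`, `start_bp`, `end_bp`, `strand`.
#' @export
read_gff3_genes <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("read_gff3_genes() needs the rtracklayer package", call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df <- df[df$type == "gene", , drop = FALSE]
  if (nrow(df) == 0) {
    return(tibble::tibble(gene_id = character(0), chrom = character(0),
                          start_bp = numeric(0), end_bp = numeric(0),
                          strand = character(0)))
  }
  ids <- if (!is.null(df$ID)) df$ID else df$Name
  if (anyDuplicated(ids)) {
    stop("duplicate gene ID in ", path, ": ", ids[duplicated(ids)][1],
         call. = FALSE)
  }
  tibble::tibble(
    gene_id = as.character(ids),
    chrom = as.character(df$seqnames),
    start_bp = df$start - 1,   # GFF3 1-based inclusive -> 0-based half-open
    end_bp = as.numeric(df$end),
    strand = as.character(df$strand)
  )
}

# ---- run configuration ------------------------------------------------------

.config_schema <- c(
  "seed",
  "genome.n_chrom", "genome.length_bp", "genome.cm_per_mb",
  "scheme.n_backcross", "scheme.n_self", "scheme.lines", "scheme.bc_mixture",
  "scheme.p_contaminant",
  "markers.spacing_bp",
  "coverage.mean_depth", "coverage.zero_inflation", "coverage.seq_error",
  "coverage.other_rate",
  "traits.n_additive", "traits.n_epistatic", "traits.effect_size",
  "traits.block_sd", "traits.plant_sd", "traits.residual_sd",
  "traits.n_blocks",
  "hmm.sigma", "hmm.emission_error", "hmm.threshold",
  "bins.min_markers",
  "qtl.model", "qtl.k_folds", "qtl.cv_reps", "qtl.n_alpha", "qtl.q_threshold"
)

#' Read a plain-text key-value run configuration
#'
#' Lines of the form `section.key = value`; `#` starts a comment. Unknown
#' keys are rejected. Values parse as numbers when possible.
#'
#' @param path Path to the config file.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1])
    if (!key %in% .config_schema) {
      stop("unknown config key: ", key, call. = FALSE)
    }
    val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

cfg_get <- function(config, key, default) {
  if (!is.null(config[[key]])) config[[key]] else default
}

#' Run the simulate-genotype-bin-map pipeline
#'
#' Executes the full stack on a simulated population: crossing-scheme
#' simulation and sparse read counts, HMM genotyping, bin construction, trait
#' simulation with planted effects, and marginal plus penalized QTL mapping.
#' Each stage writes its outputs under `out_dir` and is skipped on re-runs
#' when its outputs already exist (delete a stage's files to recompute from
#' that point).
#'
#' @param config Named list (see [read_run_config()]) or path to a config
#'   file.
#' @param out_dir Output directory (created if missing).
#' @param force Recompute all stages even when outputs exist.
#' @param quiet Suppress progress messages.
#' @param through Last stage to execute: one of `"simulate"`, `"genotype"`,
#'   `"bins"`, `"traits"`, `"qtl"` (the default runs everything).
#' @return Invisible list with the in-memory stage results and output paths.
#' @export
pipeline_run <- function(config, out_dir, force = FALSE, quiet = FALSE,
                         through = "qtl") {
  stage_order <- c("simulate", "genotype", "bins", "traits", "qtl")
  last_stage <- match.arg(through, stage_order)
  n_stages <- match(last_stage, stage_order)
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  seed <- as.integer(cfg_get(config, "seed", 1))

  # resolved configuration is written next to the outputs
  writeLines(
    vapply(names(config), function(k) paste(k, "=", config[[k]]),
           character(1)),
    file.path(out_dir, "resolved_config.txt")
  )

  n_chrom <- cfg_get(config, "genome.n_chrom", 2)
  len <- cfg_get(config, "genome.length_bp", 2e7)
  genome <- genome_model(
    tibble::tibble(chrom = sprintf("ch%02d", seq_len(n_chrom)),
                   length_bp = len),
    cm_per_mb = cfg_get(config, "genome.cm_per_mb", 1.5)
  )
  paths <- list(
    truth = file.path(out_dir, "truth_segments.tsv"),
    counts = file.path(out_dir, "counts.tsv"),
    segments = file.path(out_dir, "hmm_segments.tsv"),
    bins = file.path(out_dir, "bins.tsv"),
    matrix = file.path(out_dir, "bin_matrix.csv"),
    traits = file.path(out_dir, "traits.csv"),
    marginal = file.path(out_dir, "qtl_marginal.csv"),
    sparse = file.path(out_dir, "qtl_sparse.csv")
  )

  # -- simulate ---------------------------------------------------------------
  if (force || !file.exists(paths$truth) || !file.exists(paths$counts)) {
    say("stage simulate: ", cfg_get(config, "scheme.lines", 50), " lines")
    scheme <- pedigree_scheme(
      n_backcross = cfg_get(config, "scheme.n_backcross", 2),
      n_self = cfg_get(config, "scheme.n_self", 5),
      lines = cfg_get(config, "scheme.lines", 50),
      bc_mixture = cfg_get(config, "scheme.bc_mixture", 0.5),
      p_contaminant = cfg_get(config, "scheme.p_contaminant", 0)
    )
    truth <- simulate_pedigree(scheme, genome, seed = seed)
    markers <- marker_panel(genome,
                            cfg_get(config, "markers.spacing_bp", 10000))
    cov <- coverage_model(
      mean_depth = cfg_get(config, "coverage.mean_depth", 1),
      zero_inflation = cfg_get(config, "coverage.zero_inflation", 0.2),
      seq_error = cfg_get(config, "coverage.seq_error", 0.01),
      other_rate = cfg_get(config, "coverage.other_rate", 0.005)
    )
    counts <- emit_read_counts(truth, markers, cov, seed = seed + 1)
    write_segments_bed(truth, paths$truth)
    write_counts_tsv(counts, paths$counts)
  } else {
    say("stage simulate: outputs exist, skipping")
    truth <- read_segments_bed(paths$truth)
    counts <- read_counts_tsv(paths$counts)
  }

  if (n_stages < 2) {
    return(invisible(list(genome = genome, truth = truth, counts = counts,
                          paths = paths)))
  }

  # -- genotype ---------------------------------------------------------------
  if (force || !file.exists(paths$segments)) {
    say("stage genotype: HMM posterior decoding")
    cfg_hmm <- hmm_config(
      sigma = cfg_get(config, "hmm.sigma", 0.5),
      emission_error = cfg_get(config, "hmm.emission_error", 0.01),
      posterior_threshold = cfg_get(config, "hmm.threshold", 0.95)
    )
    geno <- genotype_population(counts, genome, cfg_hmm,
                                seq_error = cfg_get(config,
                                                    "coverage.seq_error",
                                                    0.01))
    write_segments_bed(geno$segments, paths$segments)
    segments <- geno$segments
  } else {
    say("stage genotype: outputs exist, skipping")
    segments <- read_segments_bed(paths$segments)
  }

  if (n_stages < 3) {
    return(invisible(list(genome = genome, truth = truth, counts = counts,
                          segments = segments, paths = paths)))
  }

  # -- bins -------------------------------------------------------------------
  if (force || !file.exists(paths$bins) || !file.exists(paths$matrix)) {
    say("stage bins: population bin construction")
    smoothed <- smooth_segments(segments,
                                cfg_get(config, "bins.min_markers", 2))
    intro <- detect_line_bins(smoothed,
                              cfg_get(config, "bins.min_markers", 2))
    bins <- merge_population_boundaries(intro, genome)
    bm <- bin_genotype_matrix(smoothed, bins)
    write_bins_tsv(bins, paths$bins)
    write_bin_matrix_csv(bm, paths$matrix)
  } else {
    say("stage bins: outputs exist, skipping")
    bins <- read_bins_tsv(paths$bins)
    bm <- read_bin_matrix_csv(paths$matrix, bins)
  }

  if (n_stages < 4) {
    return(invisible(list(genome = genome, truth = truth, counts = counts,
                          segments = segments, bins = bins, bin_matrix = bm,
                          paths = paths)))
  }

  # -- traits -----------------------------------------------------------------
  if (force || !file.exists(paths$traits)) {
    say("stage traits: planting genetic architecture")
    arch <- plant_architecture(
      bm,
      n_additive = cfg_get(config, "traits.n_additive", 2),
      n_epistatic = cfg_get(config, "traits.n_epistatic", 1),
      effect_size = cfg_get(config, "traits.effect_size", 1),
      min_presence = max(3, round(0.05 * length(bm$line_ids))),
      min_separation_bp = min(5e6, len / 3),
      block_sd = cfg_get(config, "traits.block_sd", 0.1),
      plant_sd = cfg_get(config, "traits.plant_sd", 0.1),
      residual_sd = cfg_get(config, "traits.residual_sd", 0.25),
      n_blocks = cfg_get(config, "traits.n_blocks", 3),
      seed = seed + 2
    )
    sim <- simulate_traits(bm, arch, seed = seed + 3)
    traits <- sim$line_values
    traits$planted <- NULL
    write_traits_csv(traits, paths$traits)
    planted <- list(additive = arch$additive, epistatic = arch$epistatic)
  } else {
    say("stage traits: outputs exist, skipping")
    traits <- read_traits_csv(paths$traits)
    planted <- NULL
  }

  if (n_stages < 5) {
    return(invisible(list(genome = genome, truth = truth, counts = counts,
                          segments = segments, bins = bins, bin_matrix = bm,
                          traits = traits, planted = planted, paths = paths)))
  }

  # -- qtl --------------------------------------------------------------------
  if (force || !file.exists(paths$marginal) || !file.exists(paths$sparse)) {
    say("stage qtl: marginal scan + penalized fit")
    y <- stats::setNames(traits$line_mean, traits$line_id)
    scan <- marginal_scan(bm, y,
                          q_threshold = cfg_get(config, "qtl.q_threshold",
                                                0.001))
    utils::write.csv(scan, paths$marginal, row.names = FALSE)
    qcfg <- sparsenet_config(
      n_alpha = cfg_get(config, "qtl.n_alpha", 30),
      k_folds = cfg_get(config, "qtl.k_folds", 6),
      cv_reps = cfg_get(config, "qtl.cv_reps", 10)
    )
    qtl <- sparsenet_qtl(bm, y,
                         model = cfg_get(config, "qtl.model", "additive"),
                         cfg = qcfg, seed = seed + 4)
    utils::write.csv(qtl$effects, paths$sparse, row.names = FALSE)
  } else {
    say("stage qtl: outputs exist, skipping")
    scan <- tibble::as_tibble(utils::read.csv(paths$marginal))
    qtl <- NULL
  }

  invisible(list(genome = genome, truth = truth, counts = counts,
                 segments = segments, bins = bins, bin_matrix = bm,
                 traits = traits, planted = planted, marginal = scan,
                 qtl = qtl, paths = paths))
}

#' Draw a random planted trait architecture over a bin matrix
#'
#' Picks `n_additive` polymorphic, mutually well-separated bins and
#' `n_epistatic` well-separated (cross-chromosome or physically distant)
#' observed bin pairs, and assigns them the
#' given effect size (alternating sign), producing a [trait_architecture()]
#' suitable for power studies. The separation constraints make the planted
#' architecture identifiable: additive effects closer than
#' `min_separation_bp` bp would share one empirical QTL interval, and
#' same-chromosome epistatic pairs are nearly collinear with a single broad
#' locus (which is why linked pairs are filtered at reporting time, see
#' [filter_epistatic()]).
#'
#' @param bin_matrix A [bin_genotype_matrix()] result.
#' @param n_additive,n_epistatic Number of planted effects.
#' @param effect_size Absolute additive effect size (trait units).
#' @param epistatic_effect_size Absolute interaction effect size; defaults
#'   to twice `effect_size` — interactions are observable in far fewer
#'   lines than main effects, so a power study plants them proportionally
#'   larger, as interaction designs conventionally do.
#' @param min_presence Minimum lines carrying a bin for eligibility.
#' @param min_pair_presence Minimum lines carrying both bins of a planted
#'   pair (defaults to `min_presence`); interactions supported by very few
#'   lines are not identifiable in any population.
#' @param min_separation_bp Minimum physical separation between planted
#'   same-chromosome additive bins.
#' @param block_sd,plant_sd,residual_sd,n_blocks Passed to
#'   [trait_architecture()].
#' @param seed Optional integer seed.
#' @return A [trait_architecture()].
#' @export
plant_architecture <- function(bin_matrix, n_additive = 2, n_epistatic = 1,
                               effect_size = 1,
                               epistatic_effect_size = 2 * effect_size,
                               min_presence = 5,
                               min_pair_presence = min_presence,
                               min_separation_bp = 5e6,
                               block_sd = 0.1, plant_sd = 0.1,
                               residual_sd = 0.25, n_blocks = 3,
                               seed = NULL) {
  P <- presence_matrix(bin_matrix)
  bins <- bin_matrix$bins
  mid <- stats::setNames((bins$start_bp + bins$end_bp) / 2, bins$bin_id)
  chrom_of <- stats::setNames(bins$chrom, bins$bin_id)
  with_seed(seed, {
    eligible <- colnames(P)[colSums(P) >= min_presence &
                              colSums(P) <= nrow(P) - min_presence]
    if (length(eligible) < n_additive) {
      stop("not enough polymorphic bins to plant ", n_additive,
           " additive effects", call. = FALSE)
    }
    # greedy draw honouring the separation constraint
    pool <- sample(eligible)
    add_bins <- character(0)
    for (b in pool) {
      if (length(add_bins) == n_additive) break
      ok <- all(chrom_of[add_bins] != chrom_of[b] |
                  abs(mid[add_bins] - mid[b]) >= min_separation_bp)
      if (length(add_bins) == 0 || ok) add_bins <- c(add_bins, b)
    }
    if (length(add_bins) < n_additive) {
      stop("cannot place ", n_additive, " additive effects ",
           min_separation_bp, " bp apart", call. = FALSE)
    }
    additive <- tibble::tibble(
      bin = add_bins,
      effect = effect_size * (-1)^(seq_len(n_additive) - 1)
    )
    epistatic <- tibble::tibble(bin_a = character(0), bin_b = character(0),
                                effect = numeric(0))
    if (n_epistatic > 0) {
      co <- crossprod(P[, eligible, drop = FALSE])
      co[lower.tri(co, diag = TRUE)] <- 0
      ok <- which(co >= min_pair_presence, arr.ind = TRUE)
      sep <- chrom_of[eligible[ok[, 1]]] != chrom_of[eligible[ok[, 2]]] |
        abs(mid[eligible[ok[, 1]]] - mid[eligible[ok[, 2]]]) >=
          min_separation_bp
      free <- !(eligible[ok[, 1]] %in% add_bins) &
        !(eligible[ok[, 2]] %in% add_bins)
      ok <- ok[sep & free, , drop = FALSE]
      if (nrow(ok) < n_epistatic) {
        stop("not enough observed well-separated pairs to plant ",
             n_epistatic, " epistatic effects", call. = FALSE)
      }
      pick <- ok[sample.int(nrow(ok), n_epistatic), , drop = FALSE]
      epistatic <- tibble::tibble(
        bin_a = eligible[pick[, 1]],
        bin_b = eligible[pick[, 2]],
        effect = epistatic_effect_size * (-1)^(seq_len(n_epistatic))
      )
    }
    trait_architecture(additive = additive, epistatic = epistatic,
                       block_sd = block_sd, plant_sd = plant_sd,
                       residual_sd = residual_sd, n_blocks = n_blocks)
  })
}
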