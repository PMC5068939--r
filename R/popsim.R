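#' @keywords internal
"_PACKAGE"

#' @importFrom Rcpp evalCpp
#' @useDynLib bilqtl, .registration = TRUE
NULL

# canonical state order used throughout the package
.states <- c("M82", "HET", "PEN")

# evaluate expr under a temporary RNG state seeded with `seed` (NULL = leave
# the session RNG alone)
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Pedigree scheme for an advanced backcross population
#'
#' Describes how lines are produced: an F1 between the recurrent (M82) and
#' donor (S. pennellii) parents is backcrossed to the recurrent parent
#' `n_backcross` times and then selfed `n_self` generations by single-seed
#' descent. Populations mixing two backcross depths (the classic BC2-selfed-5
#' plus BC3-selfed-4 design) are expressed with `bc_mixture`, the fraction of
#' lines following the primary (`n_backcross`, `n_self`) class; the remainder
#' follow (`n_backcross_alt`, `n_self_alt`).
#'
#' @param n_backcross Backcrosses to the recurrent parent after the F1 (>= 0).
#' @param n_self Selfing generations after the last backcross (>= 0).
#' @param lines Number of lines to simulate.
#' @param bc_mixture Fraction of lines in the primary class, in [0, 1].
#' @param n_backcross_alt,n_self_alt The alternative class (defaults 3 and 4).
#' @param p_contaminant Probability that a line is a contaminant genetically
#'   identical to the recurrent parent (such lines occur in real populations
#'   through seed or pollen contamination).
#' @return An object of class `pedigree_scheme`.
#' @export
pedigree_scheme <- function(n_backcross = 2, n_self = 5, lines = 100,
                            bc_mixture = 1, n_backcross_alt = 3,
                            n_self_alt = 4, p_contaminant = 0) {
  stopifnot(n_backcross >= 0, n_self >= 0, lines >= 1,
            bc_mixture >= 0, bc_mixture <= 1,
            p_contaminant >= 0, p_contaminant <= 1)
  structure(
    list(n_backcross = n_backcross, n_self = n_self, lines = lines,
         bc_mixture = bc_mixture, n_backcross_alt = n_backcross_alt,
         n_self_alt = n_self_alt, p_contaminant = p_contaminant),
    class = "pedigree_scheme"
  )
}

#' Expected per-locus genotype fractions under a pedigree scheme
#'
#' Closed-form Mendelian recursion for a neutral locus: the F1 is heterozygous
#' everywhere; each backcross to the recurrent parent halves the probability
#' of remaining heterozygous (the rest fixes to the recurrent allele); each
#' selfing generation halves heterozygosity again, and the heterozygosity lost
#' per selfing splits equally between the two homozygotes. Hence
#' `pHET = 2^-(n_backcross + n_self)` and
#' `pPEN = (2^-n_backcross - pHET) / 2`. Mixtures are averaged with weight
#' `bc_mixture`.
#'
#' @param scheme A [pedigree_scheme()].
#' @return Named numeric triple `(M82, HET, PEN)` summing to 1.
#' @examples
#' expected_state_fractions(pedigree_scheme(2, 5)) # 0.8711 0.0078 0.1211
#' @export
expected_state_fractions <- function(scheme) {
  one <- function(nbc, ns) {
    p_het <- 2^(-nbc) * 2^(-ns)
    p_pen <- (2^(-nbc) - p_het) / 2
    c(M82 = 1 - p_het - p_pen, HET = p_het, PEN = p_pen)
  }
  w <- scheme$bc_mixture
  w * one(scheme$n_backcross, scheme$n_self) +
    (1 - w) * one(scheme$n_backcross_alt, scheme$n_self_alt)
}

# ---- internal compact haplotype representation ------------------------------
# one chromosome of one haplotype: list(ends = bp segment ends (last = length),
# org = integer origins, 0 = recurrent (M82), 1 = donor (PEN));
# segments are 0-based half-open and tile [0, length)

hap_const <- function(len, org) list(ends = len, org = org)

# extract the part of `hap` covering [from, to) as (ends, org), clipped
hap_slice <- function(hap, from, to) {
  starts <- c(0, hap$ends[-length(hap$ends)])
  keep <- which(hap$ends > from & starts < to)
  list(ends = pmin(hap$ends[keep], to), org = hap$org[keep])
}

hap_simplify <- function(hap) {
  if (length(hap$org) <= 1) return(hap)
  keep <- c(diff(hap$org) != 0, TRUE)
  list(ends = hap$ends[keep], org = hap$org[keep])
}

# recombine two haplotypes of one chromosome at sorted cut positions,
# starting from haplotype `first` (1 or 2)
hap_recombine <- function(h1, h2, cuts, first, len) {
  bounds <- c(0, cuts, len)
  ends <- numeric(0)
  org <- integer(0)
  cur <- first
  for (i in seq_len(length(bounds) - 1)) {
    piece <- hap_slice(if (cur == 1) h1 else h2, bounds[i], bounds[i + 1])
    ends <- c(ends, piece$ends)
    org <- c(org, piece$org)
    cur <- 3L - cur
  }
  hap_simplify(list(ends = ends, org = org))
}

# one meiosis for one chromosome: Poisson crossover count with mean = map
# length in Morgans, positions uniform in cM mapped back to bp (no
# interference; Haldane model)
meiose_chrom <- function(h1, h2, genome, chrom) {
  len <- chrom_length_bp(genome, chrom)
  if (len <= 0) stop("zero-length chromosome: ", chrom, call. = FALSE)
  len_cm <- chrom_length_cm(genome, chrom)
  n_xo <- stats::rpois(1, len_cm / 100)
  cuts <- numeric(0)
  if (n_xo > 0) {
    cuts_cm <- sort(stats::runif(n_xo, 0, len_cm))
    cuts <- map_bp(genome, chrom, cuts_cm)
    cuts <- unique(cuts[cuts > 0 & cuts < len])
  }
  first <- sample.int(2L, 1L)
  hap_recombine(h1, h2, cuts, first, len)
}

hap_to_tibble <- function(hap_list, origin_labels = c("M82", "PEN")) {
  purrr::imap_dfr(hap_list, function(hap, chrom) {
    tibble::tibble(
      chrom = chrom,
      start_bp = c(0, hap$ends[-length(hap$ends)]),
      end_bp = hap$ends,
      origin = origin_labels[hap$org + 1L]
    )
  })
}

tibble_to_hap <- function(tbl) {
  split(tbl, tbl$chrom) |>
    lapply(function(d) {
      d <- d[order(d$start_bp), , drop = FALSE]
      list(ends = d$end_bp, org = as.integer(d$origin == "PEN"))
    })
}

#' Simulate one meiosis of a diploid parent
#'
#' Draws a gamete from a diploid parent under a no-interference (Poisson)
#' crossover model: per chromosome the crossover count is Poisson with mean
#' equal to the genetic map length in Morgans, crossover positions are uniform
#' in cM and mapped to bp through the genome's genetic map, and the gamete
#' alternates between the two parental haplotypes at each crossover.
#'
#' @param parent List with elements `h1` and `h2`, each a tibble of haploid
#'   segments (`chrom`, `start_bp`, `end_bp`, `origin` in `"M82"`/`"PEN"`,
#'   0-based half-open, tiling each chromosome).
#' @param genome A [genome_model()].
#' @param seed Optional integer seed (NULL uses the session RNG).
#' @return Tibble of gamete segments in the same layout as the inputs.
#' @export
simulate_meiosis <- function(parent, genome, seed = NULL) {
  with_seed(seed, {
    h1 <- tibble_to_hap(parent$h1)
    h2 <- tibble_to_hap(parent$h2)
    chroms <- genome$chromosomes$chrom
    gam <- lapply(stats::setNames(chroms, chroms), function(ch) {
      meiose_chrom(h1[[ch]], h2[[ch]], genome, ch)
    })
    hap_to_tibble(gam)
  })
}

# collapse a diploid (two compact haplotypes) into genotype segments coded
# M82 / HET / PEN
collapse_diploid_chrom <- function(h1, h2) {
  ends <- sort(unique(c(h1$ends, h2$ends)))
  mids <- (c(0, ends[-length(ends)]) + ends) / 2
  o1 <- hap_org_at(h1, mids)
  o2 <- hap_org_at(h2, mids)
  state <- ifelse(o1 == 0 & o2 == 0, 1L, ifelse(o1 == 1 & o2 == 1, 3L, 2L))
  keep <- c(diff(state) != 0, TRUE)
  list(ends = ends[keep], state = state[keep])
}

# origin codes of a compact haplotype at query positions
hap_org_at <- function(hap, pos) {
  starts <- c(0, hap$ends[-length(hap$ends)])
  idx <- findInterval(pos, starts)
  hap$org[idx]
}

#' Simulate a backcrossed inbred line population
#'
#' Realizes the crossing scheme by single-seed descent: for each line an F1
#' (one donor and one recurrent haplotype per chromosome) is backcrossed to
#' the recurrent parent `n_backcross` times, then selfed `n_self` times, with
#' one offspring carried per generation. The final diploid is collapsed to
#' genotype segments coded `M82`, `HET`, `PEN`. A configurable fraction of
#' lines is emitted as recurrent-parent contaminants.
#'
#' @param scheme A [pedigree_scheme()].
#' @param genome A [genome_model()].
#' @param seed Optional integer seed.
#' @return Tibble with columns `line_id`, `chrom`, `start_bp`, `end_bp`
#'   (0-based half-open, tiling each chromosome) and `state`. The per-line
#'   class assignment is attached as attribute `"pedigree"` (tibble with
#'   `line_id`, `n_backcross`, `n_self`, `contaminant`).
#' @export
simulate_pedigree <- function(scheme, genome, seed = NULL) {
  stopifnot(inherits(scheme, "pedigree_scheme"), inherits(genome, "genome_model"))
  with_seed(seed, {
    chroms <- genome$chromosomes$chrom
    lens <- stats::setNames(genome$chromosomes$length_bp, chroms)
    m82_hap <- lapply(lens, function(l) hap_const(l, 0L))
    pen_hap <- lapply(lens, function(l) hap_const(l, 1L))

    n <- scheme$lines
    ids <- sprintf("BIL_%04d", seq_len(n))
    primary <- stats::runif(n) < scheme$bc_mixture
    contam <- stats::runif(n) < scheme$p_contaminant

    one_line <- function(nbc, ns) {
      cur <- list(pen_hap, m82_hap) # h1, h2 per chromosome lists
      for (b in seq_len(nbc)) {
        gam <- lapply(stats::setNames(chroms, chroms), function(ch) {
          meiose_chrom(cur[[1]][[ch]], cur[[2]][[ch]], genome, ch)
        })
        cur <- list(gam, m82_hap)
      }
      for (s in seq_len(ns)) {
        gam1 <- lapply(stats::setNames(chroms, chroms), function(ch) {
          meiose_chrom(cur[[1]][[ch]], cur[[2]][[ch]], genome, ch)
        })
        gam2 <- lapply(stats::setNames(chroms, chroms), function(ch) {
          meiose_chrom(cur[[1]][[ch]], cur[[2]][[ch]], genome, ch)
        })
        cur <- list(gam1, gam2)
      }
      cur
    }

    res <- vector("list", n)
    for (i in seq_len(n)) {
      if (contam[i]) {
        seg <- purrr::imap_dfr(lens, function(l, ch) {
          tibble::tibble(chrom = ch, start_bp = 0, end_bp = l, state = "M82")
        })
      } else {
        nbc <- if (primary[i]) scheme$n_backcross else scheme$n_backcross_alt
        ns <- if (primary[i]) scheme$n_self else scheme$n_self_alt
        dip <- one_line(nbc, ns)
        seg <- purrr::imap_dfr(stats::setNames(chroms, chroms), function(ch, nm) {
          coll <- collapse_diploid_chrom(dip[[1]][[ch]], dip[[2]][[ch]])
          tibble::tibble(
            chrom = ch,
            start_bp = c(0, coll$ends[-length(coll$ends)]),
            end_bp = coll$ends,
            state = .states[coll$state]
          )
        })
      }
      res[[i]] <- dplyr::mutate(seg, line_id = ids[i], .before = 1)
    }
    out <- dplyr::bind_rows(res)
    attr(out, "pedigree") <- tibble::tibble(
      line_id = ids,
      n_backcross = ifelse(contam, NA_integer_,
                           ifelse(primary, scheme$n_backcross,
                                  scheme$n_backcross_alt)),
      n_self = ifelse(contam, NA_integer_,
                      ifelse(primary, scheme$n_self, scheme$n_self_alt)),
      contaminant = contam
    )
    out
  })
}

#' Sequencing coverage model for sparse marker read counts
#'
#' Emulates the sparse, low-coverage counts produced by reduced-representation
#' sequencing: marker depth is zero-inflated Poisson capped at `max_depth_cap`;
#' each read reports the donor allele with probability `seq_error`, `0.5`, or
#' `1 - seq_error` for true states M82 / HET / PEN; a small `other_rate`
#' produces nonparental reads.
#'
#' @param mean_depth Poisson mean reads per marker (before zero inflation).
#' @param zero_inflation Probability a marker receives no reads at all.
#' @param seq_error Per-read probability of reporting the wrong parental allele.
#' @param other_rate Per-read probability of a nonparental ("other") allele.
#' @param max_depth_cap Hard cap on per-marker depth.
#' @return An object of class `coverage_model`.
#' @export
coverage_model <- function(mean_depth = 1, zero_inflation = 0.2,
                           seq_error = 0.01, other_rate = 0.005,
                           max_depth_cap = 1000L) {
  stopifnot(mean_depth >= 0, zero_inflation >= 0, zero_inflation <= 1,
            seq_error >= 0, seq_error <= 1, other_rate >= 0, other_rate <= 1)
  structure(list(mean_depth = mean_depth, zero_inflation = zero_inflation,
                 seq_error = seq_error, other_rate = other_rate,
                 max_depth_cap = as.integer(max_depth_cap)),
            class = "coverage_model")
}

#' Regular marker panel over a genome
#'
#' @param genome A [genome_model()].
#' @param spacing_bp Distance between adjacent markers in bp.
#' @return Tibble with columns `chrom`, `pos` (1-based marker positions).
#' @export
marker_panel <- function(genome, spacing_bp = 10000) {
  purrr::pmap_dfr(genome$chromosomes, function(chrom, length_bp, ...) {
    tibble::tibble(chrom = chrom,
                   pos = seq(spacing_bp, length_bp, by = spacing_bp))
  })
}

# state (1/2/3) of each marker position given one line's segments on a chrom
state_at_positions <- function(segs, pos) {
  segs <- segs[order(segs$start_bp), , drop = FALSE]
  idx <- findInterval(pos - 1, segs$start_bp)
  ok <- idx >= 1 & (pos - 1) < segs$end_bp[pmax(idx, 1)]
  if (!all(ok)) stop("marker position outside chromosome segments", call. = FALSE)
  match(segs$state[idx], .states)
}

#' Simulate sparse marker read counts for genotyped lines
#'
#' @param line_geno Tibble of genotype segments (`line_id`, `chrom`,
#'   `start_bp`, `end_bp`, `state`), e.g. from [simulate_pedigree()].
#' @param markers Marker panel tibble (`chrom`, `pos` 1-based), e.g. from
#'   [marker_panel()].
#' @param cov A [coverage_model()].
#' @param seed Optional integer seed.
#' @param keep_uncovered Keep zero-depth markers as rows (default FALSE:
#'   output is sparse, like real reduced-representation data).
#' @return Tibble with columns `line_id`, `chrom`, `pos`, `n_m82`, `n_pen`,
#'   `n_other`.
#' @export
emit_read_counts <- function(line_geno, markers, cov, seed = NULL,
                             keep_uncovered = FALSE) {
  stopifnot(inherits(cov, "coverage_model"))
  with_seed(seed, {
    per_line <- split(line_geno, line_geno$line_id)
    out <- purrr::imap_dfr(per_line, function(segs, id) {
      per_chrom <- split(markers, markers$chrom)
      purrr::imap_dfr(per_chrom, function(mk, ch) {
        segs_ch <- segs[segs$chrom == ch, , drop = FALSE]
        if (nrow(segs_ch) == 0) stop("line ", id, " has no segments on ", ch,
                                     call. = FALSE)
        st <- state_at_positions(segs_ch, mk$pos)
        m <- nrow(mk)
        depth <- stats::rpois(m, cov$mean_depth)
        depth[stats::runif(m) < cov$zero_inflation] <- 0L
        depth <- pmin(depth, cov$max_depth_cap)
        n_other <- stats::rbinom(m, depth, cov$other_rate)
        parental <- depth - n_other
        p_pen <- c(cov$seq_error, 0.5, 1 - cov$seq_error)[st]
        n_pen <- stats::rbinom(m, parental, p_pen)
        res <- tibble::tibble(line_id = id, chrom = ch, pos = mk$pos,
                              n_m82 = parental - n_pen, n_pen = n_pen,
                              n_other = n_other)
        if (!keep_uncovered) res <- res[depth > 0, , drop = FALSE]
        res
      })
    })
    out
  })
}

#' Trait architecture with planted additive and epistatic bin effects
#'
#' @param additive Tibble/data frame with columns `bin`, `effect` (may be
#'   empty). Effects act on the presence (0/1) of donor DNA in the bin.
#' @param epistatic Tibble with columns `bin_a`, `bin_b`, `effect`; each pair
#'   contributes `effect * presence(bin_a) * presence(bin_b)`.
#' @param block_sd,plant_sd,residual_sd Standard deviations of the block
#'   random effect, the per-plant effect, and the residual.
#' @param n_blocks,n_plants_per_line Replication structure: each line is grown
#'   `n_plants_per_line` times in each of `n_blocks` randomized blocks.
#' @return An object of class `trait_architecture`.
#' @export
trait_architecture <- function(additive = NULL, epistatic = NULL,
                               block_sd = 0, plant_sd = 0, residual_sd = 0,
                               n_blocks = 3L, n_plants_per_line = 1L) {
  stopifnot(block_sd >= 0, plant_sd >= 0, residual_sd >= 0,
            n_blocks >= 1, n_plants_per_line >= 1)
  additive <- if (is.null(additive)) {
    tibble::tibble(bin = character(), effect = numeric())
  } else tibble::as_tibble(additive)
  epistatic <- if (is.null(epistatic)) {
    tibble::tibble(bin_a = character(), bin_b = character(), effect = numeric())
  } else tibble::as_tibble(epistatic)
  structure(list(additive = additive, epistatic = epistatic,
                 block_sd = block_sd, plant_sd = plant_sd,
                 residual_sd = residual_sd, n_blocks = as.integer(n_blocks),
                 n_plants_per_line = as.integer(n_plants_per_line)),
            class = "trait_architecture")
}

#' Simulate replicated trait values over a bin genotype matrix
#'
#' The genetic value of each line is the sum of planted additive effects times
#' donor-presence indicators plus planted epistatic effects times presence
#' products. Replicated observations add Gaussian block, plant, and residual
#' noise.
#'
#' @param bin_matrix A [bin_genotype_matrix()] result.
#' @param arch A [trait_architecture()].
#' @param seed Optional integer seed.
#' @return List with `replicates` (tibble `line_id`, `block`, `plant`,
#'   `value`), and `line_values` (tibble `line_id`, `genetic_value`,
#'   `line_mean` of the replicates; `line_mean` is the QTL-mapping input).
#' @export
simulate_traits <- function(bin_matrix, arch, seed = NULL) {
  stopifnot(inherits(arch, "trait_architecture"))
  P <- presence_matrix(bin_matrix)
  bins <- colnames(P)
  miss <- setdiff(c(arch$additive$bin, arch$epistatic$bin_a,
                    arch$epistatic$bin_b), bins)
  if (length(miss)) {
    stop("effect on unknown bin(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  g <- rep(0, nrow(P))
  if (nrow(arch$additive)) {
    g <- g + as.vector(P[, arch$additive$bin, drop = FALSE] %*%
                         arch$additive$effect)
  }
  if (nrow(arch$epistatic)) {
    for (k in seq_len(nrow(arch$epistatic))) {
      g <- g + arch$epistatic$effect[k] *
        P[, arch$epistatic$bin_a[k]] * P[, arch$epistatic$bin_b[k]]
    }
  }
  with_seed(seed, {
    ids <- rownames(P)
    grid <- tidyr::expand_grid(line_id = ids,
                               block = seq_len(arch$n_blocks),
                               plant = seq_len(arch$n_plants_per_line))
    block_eff <- stats::rnorm(arch$n_blocks, 0, arch$block_sd)
    plant_key <- paste(grid$line_id, grid$block, grid$plant)
    plant_eff <- stats::rnorm(length(unique(plant_key)), 0, arch$plant_sd)
    names(plant_eff) <- unique(plant_key)
    grid$value <- g[match(grid$line_id, ids)] + block_eff[grid$block] +
      plant_eff[plant_key] +
      stats::rnorm(nrow(grid), 0, arch$residual_sd)
    line_mean <- tapply(grid$value, grid$line_id, mean)
    list(
      replicates = grid,
      line_values = tibble::tibble(
        line_id = ids,
        genetic_value = unname(g),
        line_mean = as.numeric(line_mean[ids])
      )
    )
  })
}
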