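#' Genome model: chromosomes plus a genetic map
#'
#' A `genome_model` holds the physical chromosomes of the population's genome
#' together with a genetic map, either a constant recombination rate in cM/Mb
#' or a per-chromosome monotone piecewise-linear cM-vs-bp function. The map is
#' what converts physical marker spacing into the genetic distances that drive
#' both the meiosis simulator and the distance-dependent HMM transitions.
#'
#' @param chromosomes A data frame with columns `chrom` (character) and
#'   `length_bp` (positive integer). One row per chromosome.
#' @param cm_per_mb Constant genetic-map rate in cM per Mb, used for any
#'   chromosome without an entry in `map`. Default 1.5.
#' @param map Optional named list (names = chromosome) of data frames with
#'   columns `pos_bp` and `cm`, each non-decreasing in both columns with
#'   `cm[pos_bp = 0] = 0` implied. Linear interpolation between knots;
#'   extrapolation beyond the last knot continues at the terminal slope.
#'
#' @return An object of class `genome_model`.
#' @examples
#' gm <- genome_model(data.frame(chrom = "ch1", length_bp = 2e6), cm_per_mb = 1.5)
#' genetic_distance(0, 2e6, "ch1", gm) # 3 cM
#' @export
genome_model <- function(chromosomes, cm_per_mb = 1.5, map = NULL) {
  chromosomes <- tibble::as_tibble(chromosomes)
  stopifnot(all(c("chrom", "length_bp") %in% names(chromosomes)))
  if (any(chromosomes$length_bp <= 0)) {
    stop("all chromosome lengths must be > 0", call. = FALSE)
  }
  if (anyDuplicated(chromosomes$chrom)) {
    stop("duplicate chromosome names", call. = FALSE)
  }
  if (!is.null(map)) {
    for (nm in names(map)) {
      m <- map[[nm]]
      stopifnot(all(c("pos_bp", "cm") %in% names(m)))
      if (is.unsorted(m$pos_bp, strictly = TRUE)) {
        stop("map positions must be strictly increasing on ", nm, call. = FALSE)
      }
      if (is.unsorted(m$cm)) {
        stop("map cM values must be non-decreasing on ", nm, call. = FALSE)
      }
      if (m$cm[1] < 0 || m$pos_bp[1] < 0) {
        stop("map knots must be non-negative on ", nm, call. = FALSE)
      }
    }
  }
  structure(
    list(
      chromosomes = chromosomes,
      cm_per_mb = cm_per_mb,
      map = map
    ),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat("<genome_model> ", nrow(x$chromosomes), " chromosome(s), ",
      format(sum(x$chromosomes$length_bp), big.mark = ","), " bp total\n", sep = "")
  src <- if (is.null(x$map)) paste0("constant ", x$cm_per_mb, " cM/Mb") else
    paste0("piecewise map (", length(x$map), " chromosome(s)), fallback ",
           x$cm_per_mb, " cM/Mb")
  cat("  genetic map: ", src, "\n", sep = "")
  invisible(x)
}

chrom_length_bp <- function(genome, chrom) {
  i <- match(chrom, genome$chromosomes$chrom)
  if (anyNA(i)) stop("unknown chromosome: ", chrom[which(is.na(i))[1]], call. = FALSE)
  genome$chromosomes$length_bp[i]
}

# cumulative genetic position (cM) of physical positions on one chromosome
map_cm <- function(genome, chrom, pos_bp) {
  stopifnot(length(chrom) == 1)
  m <- genome$map[[chrom]]
  if (is.null(m)) {
    return(genome$cm_per_mb * pos_bp / 1e6)
  }
  knots_bp <- c(0, m$pos_bp)
  knots_cm <- c(0, m$cm)
  if (m$pos_bp[1] == 0) {
    knots_bp <- m$pos_bp
    knots_cm <- m$cm
  }
  n <- length(knots_bp)
  # terminal-slope extrapolation beyond the last knot
  slope_end <- if (n >= 2) {
    (knots_cm[n] - knots_cm[n - 1]) / (knots_bp[n] - knots_bp[n - 1])
  } else {
    genome$cm_per_mb / 1e6
  }
  out <- stats::approx(knots_bp, knots_cm, xout = pmin(pos_bp, knots_bp[n]),
                       rule = 2, ties = "ordered")$y
  over <- pos_bp > knots_bp[n]
  out[over] <- knots_cm[n] + slope_end * (pos_bp[over] - knots_bp[n])
  out
}

# inverse of map_cm; on plateaus (zero-slope stretches) returns the left edge
map_bp <- function(genome, chrom, cm) {
  stopifnot(length(chrom) == 1)
  m <- genome$map[[chrom]]
  if (is.null(m)) {
    return(cm / genome$cm_per_mb * 1e6)
  }
  len <- chrom_length_bp(genome, chrom)
  grid_bp <- unique(sort(c(0, m$pos_bp, len)))
  grid_cm <- map_cm(genome, chrom, grid_bp)
  keep <- !duplicated(grid_cm)
  stats::approx(grid_cm[keep], grid_bp[keep], xout = cm, rule = 2,
                ties = "ordered")$y
}

chrom_length_cm <- function(genome, chrom) {
  map_cm(genome, chrom, chrom_length_bp(genome, chrom))
}

#' Genetic distance between two physical positions
#'
#' Evaluates the genome's genetic map at two positions on the same chromosome
#' and returns the cM separation. With a constant-rate map this is
#' `rate * (pos_b - pos_a) / 1e6`.
#'
#' @param pos_a,pos_b Physical positions in bp (vectors recycle).
#' @param chrom Chromosome name (scalar).
#' @param genome A [genome_model()].
#' @return Genetic distance(s) in cM; non-negative when `pos_b >= pos_a`.
#' @export
genetic_distance <- function(pos_a, pos_b, chrom, genome) {
  if (length(chrom) != 1) {
    stop("genetic_distance() works on one chromosome at a time", call. = FALSE)
  }
  map_cm(genome, chrom, pos_b) - map_cm(genome, chrom, pos_a)
}

#' Read a genetic map file into a genome model
#'
#' Parses a TSV with columns `chrom`, `pos_bp`, `cm` (non-decreasing cM per
#' chromosome) and returns the `map` component consumed by [genome_model()].
#'
#' @param path Path to the TSV file (header required).
#' @return Named list of per-chromosome tibbles with columns `pos_bp`, `cm`.
#' @export
read_genetic_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos_bp", "cm") %in% names(tab)))
  split(tab, tab$chrom) |>
    lapply(function(m) {
      m <- m[order(m$pos_bp), , drop = FALSE]
      bad <- which(diff(m$cm) < 0)
      if (length(bad)) {
        stop("decreasing cM in ", path, " on ", m$chrom[1],
             " near pos_bp=", m$pos_bp[bad[1] + 1], call. = FALSE)
      }
      tibble::tibble(pos_bp = m$pos_bp, cm = m$cm)
    })
}
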