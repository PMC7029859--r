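#' Genetic map objects
#'
#' A `genetic_map` is a data frame with columns `marker`, `chromosome` and
#' `position_cM`, ordered by chromosome (in order of first appearance) and,
#' within each chromosome, by non-decreasing centimorgan position.  Marker
#' names are unique across the whole map.
#'
#' @param marker character vector of marker names.
#' @param chromosome character vector of chromosome (linkage group) names.
#' @param position_cM numeric vector of non-negative map positions in
#'   centimorgans.
#' @return An object of class `genetic_map`.
#' @examples
#' genetic_map(c("m1", "m2"), "1A", c(0, 12.5))
#' @export
genetic_map <- function(marker, chromosome, position_cM) {
  marker <- as.character(marker)
  chromosome <- as.character(chromosome)
  position_cM <- as.numeric(position_cM)
  n <- length(marker)
  if (length(chromosome) == 1L) chromosome <- rep(chromosome, n)
  if (n == 0L) stop("a genetic map needs at least one marker")
  if (length(chromosome) != n || length(position_cM) != n)
    stop("marker, chromosome and position_cM must have equal length")
  if (anyNA(position_cM)) stop("positions must be numeric and non-missing")
  if (any(position_cM < 0)) stop("map positions must be non-negative")
  if (anyDuplicated(marker)) stop("marker names must be unique within a map")
  # stable sort: chromosomes in order of first appearance, ties keep file order
  chrom_levels <- unique(chromosome)
  ord <- order(match(chromosome, chrom_levels), position_cM)
  df <- data.frame(marker = marker[ord], chromosome = chromosome[ord],
                   position_cM = position_cM[ord], stringsAsFactors = FALSE)
  rownames(df) <- NULL
  class(df) <- c("genetic_map", "data.frame")
  df
}

#' @export
print.genetic_map <- function(x, ...) {
  chrs <- chromosomes(x)
  cat("Genetic map:", nrow(x), "markers on", length(chrs),
      if (length(chrs) == 1L) "chromosome\n" else "chromosomes\n")
  for (ch in chrs) {
    p <- x$position_cM[x$chromosome == ch]
    cat(sprintf("  %s: %d markers, %.2f cM\n", ch, length(p),
                max(p) - min(p)))
  }
  invisible(x)
}

#' @rdname genetic_map
#' @param x a `genetic_map`.
#' @export
chromosomes <- function(x) unique(x$chromosome)

#' Chromosome lengths of a genetic map
#'
#' Length is the span from the first to the last marker on each chromosome.
#'
#' @param map a `genetic_map`.
#' @return Named numeric vector of per-chromosome lengths in cM.
#' @export
map_lengths <- function(map) {
  vapply(split(map$position_cM, factor(map$chromosome,
                                       levels = chromosomes(map))),
         function(p) max(p) - min(p), numeric(1))
}

# per-chromosome row indices and positions, used by the simulator
.chrom_blocks <- function(map) {
  chrs <- chromosomes(map)
  lapply(chrs, function(ch) {
    idx <- which(map$chromosome == ch)
    list(name = ch, idx = idx, pos = map$position_cM[idx])
  })
}

#' Evenly spaced marker map
#'
#' Places `n_markers` markers at uniform intervals from 0 to `length_cM` on a
#' single chromosome (e.g. 20 markers totalling 100 cM).
#'
#' @param n_markers number of markers (>= 1).
#' @param length_cM total map length in cM.
#' @param chromosome chromosome name.
#' @param prefix marker name prefix.
#' @return A `genetic_map`.
#' @examples
#' make_uniform_map(20, 100)
#' @export
make_uniform_map <- function(n_markers, length_cM, chromosome = "1A",
                             prefix = "M") {
  n_markers <- as.integer(n_markers)
  if (is.na(n_markers) || n_markers < 1L)
    stop("n_markers must be a positive integer")
  if (length_cM < 0) stop("length_cM must be non-negative")
  pos <- if (n_markers == 1L) 0 else seq(0, length_cM, length.out = n_markers)
  genetic_map(sprintf("%s%03d", prefix, seq_len(n_markers)), chromosome, pos)
}

#' Map from explicit marker positions
#'
#' @param positions_cM numeric vector of non-negative cM positions; sorted
#'   ascending on construction.
#' @param chromosome chromosome name.
#' @param marker_names optional marker names; auto-generated when `NULL`.
#' @return A `genetic_map`.
#' @examples
#' make_custom_map(c(59, 60))
#' @export
make_custom_map <- function(positions_cM, chromosome = "1A",
                            marker_names = NULL) {
  if (any(positions_cM < 0)) stop("map positions must be non-negative")
  if (is.null(marker_names))
    marker_names <- sprintf("M%03d", seq_along(positions_cM))
  genetic_map(marker_names, chromosome, positions_cM)
}

#' Surrogate wheat-like chromosome map with a centromeric marker cluster
#'
#' Builds a deterministic single-chromosome map emulating the marker
#' distribution of a wheat linkage group genotyped with a high-density SNP
#' array: a dense cluster of markers around the centromere (where
#' recombination is suppressed, so many markers map to nearly the same
#' genetic position) flanked by sparser, evenly spaced arms.  Defaults give
#' 224 markers spanning 130.48 cM with 60% of markers inside the central
#' 20% of the map.
#'
#' @param n_markers total marker count.
#' @param length_cM total map length in cM.
#' @param cluster_prop fraction of markers inside the central cluster.
#' @param cluster_span fraction of the map length occupied by the cluster.
#' @param chromosome chromosome name.
#' @return A `genetic_map`.
#' @examples
#' make_clustered_map()
#' @export
make_clustered_map <- function(n_markers = 224, length_cM = 130.48,
                               cluster_prop = 0.6, cluster_span = 0.2,
                               chromosome = "1A") {
  n_markers <- as.integer(n_markers)
  if (n_markers < 3L) stop("need at least 3 markers for a clustered map")
  n_mid <- round(cluster_prop * n_markers)
  n_left <- floor((n_markers - n_mid) / 2)
  n_right <- n_markers - n_mid - n_left
  lo <- length_cM * (1 - cluster_span) / 2
  hi <- length_cM * (1 + cluster_span) / 2
  left <- seq(0, lo, length.out = n_left + 1L)[seq_len(n_left)]
  mid <- seq(lo, hi, length.out = n_mid)
  right <- seq(hi, length_cM, length.out = n_right + 1L)[-1L]
  make_custom_map(c(left, mid, right), chromosome)
}

#' Read / write a genetic map as CSV
#'
#' The CSV dialect is comma-separated with a header containing (case
#' insensitively) the columns `marker`, `chromosome`, `position_cM`.  Rows
#' are grouped by chromosome and sorted by position on load; ties keep file
#' order.
#'
#' @param path file path.
#' @return `read_map_csv` returns a `genetic_map`; `write_map_csv` returns
#'   `path` invisibly.
#' @export
read_map_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need <- c("marker", "chromosome", "position_cm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("map CSV is missing column(s): ", paste(miss, collapse = ", "))
  pos <- suppressWarnings(as.numeric(df$position_cm))
  if (anyNA(pos)) {
    bad <- which(is.na(pos))[1L]
    stop(sprintf("unparseable position_cM in row %d: '%s'", bad,
                 df$position_cm[bad]))
  }
  genetic_map(df$marker, df$chromosome, pos)
}

#' @rdname read_map_csv
#' @param map a `genetic_map`.
#' @export
write_map_csv <- function(map, path) {
  df <- as.data.frame(map)
  names(df) <- c("marker", "chromosome", "position_cM")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Collapse co-located markers to a skeleton map
#'
#' Greedy run-based binning: walking along each chromosome, a run starts at
#' the first unbinned marker and absorbs every following marker whose
#' position is within `epsilon_cM` of the run's first member; only the first
#' marker of each run is retained.  With `epsilon_cM = 0` this collapses
#' exactly co-located markers.
#'
#' @param map a `genetic_map`.
#' @param epsilon_cM non-negative binning window in cM.
#' @return A `genetic_map` whose markers are a subset of `map`'s, in the
#'   same order.
#' @examples
#' bin_to_skeleton(make_custom_map(c(0, 0, 0, 5)), 0)
#' @export
bin_to_skeleton <- function(map, epsilon_cM = 0) {
  if (epsilon_cM < 0) stop("epsilon_cM must be non-negative")
  keep <- logical(nrow(map))
  for (blk in .chrom_blocks(map)) {
    run_first <- -Inf
    for (j in seq_along(blk$idx)) {
      p <- blk$pos[j]
      if (p - run_first > epsilon_cM) {
        keep[blk$idx[j]] <- TRUE
        run_first <- p
      }
    }
  }
  out <- as.data.frame(map)[keep, , drop = FALSE]
  genetic_map(out$marker, out$chromosome, out$position_cM)
}
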