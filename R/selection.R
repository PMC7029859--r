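#' Locus-specific gametic selection
#'
#' A selection target penalises gametes that carry a given parental allele
#' at a given marker: such gametes survive with probability `1 - strength`.
#' A strength of 1/20 therefore makes targeted gametes 5% less viable,
#' giving an expected 100:95 ratio of untargeted to targeted gametes from a
#' heterozygous parent.  Strengths may be given as numbers in \[0, 1\] or as
#' fraction strings such as `"1/20"`.
#'
#' @param chromosome chromosome name the target lies on.
#' @param marker_index 1-based index of the marker within that chromosome.
#' @param allele targeted allele, `"A"` or `"B"`.
#' @param strength selection strength s in \[0, 1\]; numeric or `"1/x"`
#'   string.
#' @return `selection_target` returns an object of class
#'   `selection_target`; `selection_regime` a list of targets of class
#'   `selection_regime`.
#' @examples
#' selection_regime(selection_target("1A", 200, "B", "1/20"))
#' @export
selection_target <- function(chromosome, marker_index, allele, strength) {
  s <- parse_strength(strength)
  allele <- match.arg(toupper(allele), c("A", "B"))
  marker_index <- as.integer(marker_index)
  if (is.na(marker_index) || marker_index < 1L)
    stop("marker_index must be a positive (1-based) integer")
  out <- list(chromosome = as.character(chromosome),
              marker_index = marker_index, allele = allele, strength = s)
  class(out) <- "selection_target"
  out
}

#' @rdname selection_target
#' @param ... `selection_target` objects (or a single list of them).
#' @export
selection_regime <- function(...) {
  targets <- list(...)
  if (length(targets) == 1L && is.list(targets[[1]]) &&
      !inherits(targets[[1]], "selection_target"))
    targets <- targets[[1]]
  for (t in targets)
    if (!inherits(t, "selection_target"))
      stop("all regime elements must be selection_target objects")
  keys <- vapply(targets, function(t)
    paste(t$chromosome, t$marker_index), character(1))
  if (anyDuplicated(keys))
    stop("at most one selection target per (chromosome, marker) locus")
  class(targets) <- "selection_regime"
  targets
}

#' @export
print.selection_target <- function(x, ...) {
  cat(sprintf("Selection target: %s:%d, allele %s, strength %.4g\n",
              x$chromosome, x$marker_index, x$allele, x$strength))
  invisible(x)
}

#' @export
print.selection_regime <- function(x, ...) {
  if (!length(x)) cat("Empty selection regime (neutral)\n")
  else for (t in x) print(t)
  invisible(x)
}

#' Parse a selection strength
#'
#' Accepts a number in \[0, 1\] or a string of the form `"1/20"`.
#'
#' @param strength numeric or character scalar.
#' @return Numeric strength in \[0, 1\].
#' @examples
#' parse_strength("1/20")  # 0.05
#' @export
parse_strength <- function(strength) {
  if (is.character(strength)) {
    parts <- strsplit(strength, "/", fixed = TRUE)[[1]]
    v <- suppressWarnings(as.numeric(parts))
    if (anyNA(v) || length(v) > 2L)
      stop("cannot parse selection strength '", strength, "'")
    strength <- if (length(v) == 2L) v[1] / v[2] else v
  }
  strength <- as.numeric(strength)
  if (is.na(strength) || strength < 0 || strength > 1)
    stop("selection strength must lie in [0, 1]")
  strength
}

#' Parse a selection target string
#'
#' Config/CLI syntax `chromosome:marker_index:allele:strength`, e.g.
#' `"1A:200:B:1/20"`.
#'
#' @param spec character vector of target strings.
#' @return A `selection_regime`.
#' @export
parse_selection <- function(spec) {
  targets <- lapply(spec, function(s) {
    parts <- strsplit(s, ":", fixed = TRUE)[[1]]
    if (length(parts) != 4L)
      stop("selection spec must be chromosome:marker_index:allele:strength")
    selection_target(parts[1], as.integer(parts[2]), parts[3], parts[4])
  })
  selection_regime(targets)
}

# resolve regime targets against a map: global column index, allele code
# (0 = A, 1 = B) and strength; errors if a locus is off-map
.resolve_regime <- function(regime, map) {
  if (is.null(regime) || !length(regime))
    return(list(col = integer(0), allele = integer(0), s = numeric(0)))
  blocks <- .chrom_blocks(map)
  names(blocks) <- vapply(blocks, `[[`, character(1), "name")
  col <- integer(length(regime)); allele <- integer(length(regime))
  s <- numeric(length(regime))
  for (i in seq_along(regime)) {
    t <- regime[[i]]
    blk <- blocks[[t$chromosome]]
    if (is.null(blk))
      stop("selection target chromosome '", t$chromosome, "' not on map")
    if (t$marker_index > length(blk$idx))
      stop("selection target marker_index ", t$marker_index,
           " beyond chromosome '", t$chromosome, "' (",
           length(blk$idx), " markers)")
    col[i] <- blk$idx[t$marker_index]
    allele[i] <- if (t$allele == "B") 1L else 0L
    s[i] <- t$strength
  }
  list(col = col, allele = allele, s = s)
}

# survival probabilities for rows of a 0/1 gamete matrix
.survival_prob <- function(gam, rs) {
  p <- rep(1, nrow(gam))
  for (i in seq_along(rs$col))
    p <- p * ifelse(gam[, rs$col[i]] == rs$allele[i], 1 - rs$s[i], 1)
  p
}

#' Gamete survival probability under a selection regime
#'
#' Multiplicative across targets: each target contributes a factor
#' `1 - strength` when the gamete carries the targeted allele at the target
#' locus, and 1 otherwise.
#'
#' @param gamete a haplotype as returned by [simulate_gamete()]: a vector
#'   over `"A"`/`"B"` aligned to the map's marker order.
#' @param regime a `selection_regime` (may be empty or `NULL`).
#' @param map the `genetic_map` the gamete is aligned to.
#' @return Survival probability in \[0, 1\].
#' @examples
#' map <- make_uniform_map(5, 40)
#' g <- rep("B", 5)
#' gamete_survival_probability(g, selection_regime(
#'   selection_target("1A", 3, "B", "1/20")), map)  # 0.95
#' @export
gamete_survival_probability <- function(gamete, regime, map) {
  rs <- .resolve_regime(regime, map)
  gam <- matrix(as.integer(gamete == "B"), nrow = 1L)
  .survival_prob(gam, rs)
}
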