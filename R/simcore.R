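# Meiosis engine and single-seed-descent population simulator.
#
# Internal genome representation: haplotypes are integer vectors over
# {0 = A, 1 = B}; a set of G gametes is a G x C matrix (C = total markers,
# columns in map order).  Crossovers follow the Haldane model: per
# chromosome the crossover count is Poisson with mean L/100 (L = span in
# cM between first and last marker) and crossover positions are uniform on
# (first, last) -- i.e. a Poisson process at 1 event per Morgan, no
# interference, no obligate chiasma.

# Draw one gamete per row of pidx from parental haplotype matrices
# (mat, pat: n_parents x C).  Vectorised over gametes; only gametes with
# at least one crossover pay a per-gamete cost.
.sim_gametes <- function(mat, pat, blocks, pidx) {
  G <- length(pidx)
  C <- ncol(mat)
  S <- matrix(0L, G, C)  # 0 = read maternal strand, 1 = paternal
  for (blk in blocks) {
    pos <- blk$pos
    c <- length(pos)
    L <- pos[c] - pos[1]
    start <- sample.int(2L, G, replace = TRUE) - 1L
    Sc <- matrix(start, G, c)
    if (c > 1L && L > 0) {
      k <- stats::rpois(G, L / 100)
      nz <- which(k > 0L)
      if (length(nz)) {
        xo <- split(stats::runif(sum(k[nz]), pos[1], pos[c]),
                    rep.int(seq_along(nz), k[nz]))
        for (j in seq_along(nz)) {
          g <- nz[j]
          Sc[g, ] <- (start[g] + findInterval(pos, sort(xo[[j]]))) %% 2L
        }
      }
    }
    S[, blk$idx] <- Sc
  }
  out <- mat[pidx, , drop = FALSE]
  pp <- pat[pidx, , drop = FALSE]
  swap <- S == 1L
  out[swap] <- pp[swap]
  out
}

# Viable-gamete sampler: rejection against the regime's survival
# probabilities, redrawing only rejected gametes.  Fails fast when a
# required parent is homozygous for an allele targeted with s = 1.
.draw_viable_gametes <- function(mat, pat, blocks, pidx, rs,
                                 max_rounds = 1e6) {
  if (!length(rs$col)) return(.sim_gametes(mat, pat, blocks, pidx))
  lethal <- which(rs$s >= 1)
  for (i in lethal) {
    hom <- mat[pidx, rs$col[i]] == rs$allele[i] &
      pat[pidx, rs$col[i]] == rs$allele[i]
    if (any(hom))
      stop("non-viable cross: parent homozygous for allele targeted ",
           "with selection strength 1 at map column ", rs$col[i])
  }
  G <- length(pidx)
  out <- matrix(0L, G, ncol(mat))
  active <- seq_len(G)
  for (round in seq_len(max_rounds)) {
    gam <- .sim_gametes(mat, pat, blocks, pidx[active])
    p <- .survival_prob(gam, rs)
    acc <- stats::runif(length(active)) < p
    if (any(acc)) {
      out[active[acc], ] <- gam[acc, , drop = FALSE]
      active <- active[!acc]
    }
    if (!length(active)) return(out)
  }
  stop("viable-gamete rejection sampling exceeded iteration cap")
}

.as_internal_haplo <- function(h, C) {
  if (is.character(h)) h <- as.integer(h == "B")
  h <- as.integer(h)
  if (length(h) != C || anyNA(h) || any(h < 0L | h > 1L))
    stop("haplotype must be over {A,B} (or {0,1}) and aligned to the map")
  h
}

.as_external_haplo <- function(h, map) {
  out <- c("A", "B")[h + 1L]
  names(out) <- map$marker
  out
}

#' F1 individual of a biparental cross
#'
#' Both founder parents are fully homozygous, so the F1 carries one all-A
#' and one all-B haplotype and is heterozygous at every marker.
#'
#' @param map a `genetic_map`.
#' @return An object of class `individual`: a list with `maternal` and
#'   `paternal` haplotypes (vectors over `"A"`/`"B"` named by marker).
#' @examples
#' make_f1(make_uniform_map(5, 50))
#' @export
make_f1 <- function(map) {
  C <- nrow(map)
  out <- list(maternal = .as_external_haplo(rep(0L, C), map),
              paternal = .as_external_haplo(rep(1L, C), map))
  class(out) <- "individual"
  out
}

#' @export
print.individual <- function(x, ...) {
  C <- length(x$maternal)
  geno <- paste0(x$maternal, x$paternal)
  het <- mean(x$maternal != x$paternal)
  cat(sprintf("Individual: %d markers, heterozygosity %.3f\n", C, het))
  show <- utils::head(geno, 10L)
  cat(" ", paste(show, collapse = " "),
      if (C > 10L) "...\n" else "\n")
  invisible(x)
}

.individual_matrices <- function(parent, C) {
  list(mat = matrix(.as_internal_haplo(parent$maternal, C), 1L),
       pat = matrix(.as_internal_haplo(parent$paternal, C), 1L))
}

#' Simulate one meiotic gamete
#'
#' Per chromosome, the crossover count is Poisson with mean L/100 (L = cM
#' span), crossover positions are uniform along the chromosome, the
#' starting parental strand is chosen with probability 1/2 and the strand
#' switches at every crossover (Haldane model).  Marker alleles are read
#' off the resulting mosaic.
#'
#' @param parent an `individual`.
#' @param map the `genetic_map` the parent is aligned to.
#' @return A haplotype: character vector over `"A"`/`"B"` named by marker.
#' @examples
#' set.seed(1)
#' simulate_gamete(make_f1(make_uniform_map(10, 100)), make_uniform_map(10, 100))
#' @export
simulate_gamete <- function(parent, map) {
  C <- nrow(map)
  pm <- .individual_matrices(parent, C)
  g <- .sim_gametes(pm$mat, pm$pat, .chrom_blocks(map), 1L)
  .as_external_haplo(g[1L, ], map)
}

#' Simulate one viable gamete under gametic selection
#'
#' Draws gametes with [simulate_gamete()] and accepts each with its
#' survival probability under `regime`, repeating until acceptance
#' (rejection sampling), so the returned gamete follows the
#' viability-tilted meiotic distribution.  From a parent heterozygous at a
#' single target of strength s, the targeted allele is returned with
#' probability (1-s)/(2-s).
#'
#' @inheritParams simulate_gamete
#' @param regime a `selection_regime` (may be empty or `NULL`).
#' @return A haplotype as in [simulate_gamete()].
#' @export
draw_viable_gamete <- function(parent, map, regime = NULL) {
  C <- nrow(map)
  pm <- .individual_matrices(parent, C)
  rs <- .resolve_regime(regime, map)
  g <- .draw_viable_gametes(pm$mat, pm$pat, .chrom_blocks(map), 1L, rs)
  .as_external_haplo(g[1L, ], map)
}

#' Self an individual for one generation
#'
#' The offspring is formed from two independently drawn viable gametes of
#' the parent; selection (if any) applies to both gametes.
#'
#' @inheritParams draw_viable_gamete
#' @return An `individual`.
#' @export
self_individual <- function(parent, map, regime = NULL) {
  C <- nrow(map)
  pm <- .individual_matrices(parent, C)
  rs <- .resolve_regime(regime, map)
  blocks <- .chrom_blocks(map)
  g <- .draw_viable_gametes(pm$mat, pm$pat, blocks, c(1L, 1L), rs)
  out <- list(maternal = .as_external_haplo(g[1L, ], map),
              paternal = .as_external_haplo(g[2L, ], map))
  class(out) <- "individual"
  out
}

#' Simulate a single-seed-descent population
#'
#' Simulates `n` independent recombinant inbred lines from a biparental
#' cross: the F1 (heterozygous at every marker) is selfed to give n F2
#' individuals, and each line is then advanced by single seed descent (one
#' selfed offspring per line per generation) to the requested filial
#' generation.  Gametic selection, when a regime is supplied, is applied
#' to every gamete drawn at every generation; non-viable gametes are
#' redrawn so the population size stays fixed at `n`.
#'
#' @param map a `genetic_map`.
#' @param n population size (number of lines).
#' @param generation filial generation, an integer k >= 2 or a string like
#'   `"F2"`.
#' @param regime optional `selection_regime`.
#' @param seed optional integer seed; when supplied the global RNG state is
#'   saved and restored, and the result is fully reproducible.
#' @return An object of class `ssd_pop`: a list with `genotypes` (markers x
#'   individuals integer matrix, 0 = AA, 1 = AB, 2 = BB, NA = missing),
#'   `map`, `generation` (the filial index k) and `seed`.
#' @examples
#' pop <- simulate_ssd_population(make_uniform_map(20, 100), 50, "F2", seed = 1)
#' pop
#' @export
simulate_ssd_population <- function(map, n, generation = 2L, regime = NULL,
                                    seed = NULL) {
  k <- parse_generation(generation)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("population size n must be a positive integer")
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(seed)
  }
  C <- nrow(map)
  blocks <- .chrom_blocks(map)
  rs <- .resolve_regime(regime, map)
  # F1 -> F2: both gametes of each line come from the (single) F1 plant
  f1_mat <- matrix(0L, 1L, C)
  f1_pat <- matrix(1L, 1L, C)
  mat <- .draw_viable_gametes(f1_mat, f1_pat, blocks, rep(1L, n), rs)
  pat <- .draw_viable_gametes(f1_mat, f1_pat, blocks, rep(1L, n), rs)
  # SSD: one selfed offspring per line per generation
  if (k > 2L) for (gen in 3L:k) {
    new_mat <- .draw_viable_gametes(mat, pat, blocks, seq_len(n), rs)
    new_pat <- .draw_viable_gametes(mat, pat, blocks, seq_len(n), rs)
    mat <- new_mat
    pat <- new_pat
  }
  geno <- t(mat + pat)
  dimnames(geno) <- list(map$marker, sprintf("L%04d", seq_len(n)))
  new_ssd_pop(geno, map, k, seed)
}

new_ssd_pop <- function(genotypes, map, generation, seed = NULL) {
  storage.mode(genotypes) <- "integer"
  out <- list(genotypes = genotypes, map = map,
              generation = as.integer(generation), seed = seed)
  class(out) <- "ssd_pop"
  out
}

#' Parse a filial generation label
#'
#' @param generation integer k >= 2 or string `"F<k>"`.
#' @return Integer filial index k.
#' @export
parse_generation <- function(generation) {
  if (is.character(generation))
    generation <- sub("^[Ff]", "", generation)
  k <- suppressWarnings(as.integer(generation))
  if (is.na(k) || k < 2L)
    stop("generation must be F2 or later (k >= 2)")
  k
}

#' @export
print.ssd_pop <- function(x, ...) {
  cat(sprintf("SSD population: F%d, %d individuals x %d markers (%d chromosome%s)\n",
              x$generation, ncol(x$genotypes), nrow(x$genotypes),
              length(chromosomes(x$map)),
              if (length(chromosomes(x$map)) == 1L) "" else "s"))
  cat(sprintf("  heterozygosity: %.4f\n", heterozygosity(x)))
  invisible(x)
}

#' @export
summary.ssd_pop <- function(object, ...) {
  cnt <- tabulate_counts(object)
  cat(sprintf("SSD population, generation F%d, n = %d, %d markers\n",
              object$generation, ncol(object$genotypes),
              nrow(object$genotypes)))
  cat(sprintf("  heterozygosity: %.4f (expected %.4f under neutrality)\n",
              heterozygosity(object), 0.5 ^ (object$generation - 1L)))
  M <- magnitude(cnt)
  cat(sprintf("  magnitude of distortion M: median %.3f, range [%.3f, %.3f]\n",
              stats::median(M, na.rm = TRUE), min(M, na.rm = TRUE),
              max(M, na.rm = TRUE)))
  invisible(object)
}

#' Genotype calls as a character matrix
#'
#' @param pop an `ssd_pop`.
#' @param dialect `"pairs"` (AA/AB/BB, NA missing) or `"letters"`
#'   (A/H/B/-).
#' @return Character matrix, markers x individuals.
#' @export
genotype_calls <- function(pop, dialect = c("pairs", "letters")) {
  dialect <- match.arg(dialect)
  codes <- if (dialect == "pairs") c("AA", "AB", "BB") else c("A", "H", "B")
  out <- matrix(codes[pop$genotypes + 1L], nrow(pop$genotypes),
                dimnames = dimnames(pop$genotypes))
  if (dialect == "letters") out[is.na(out)] <- "-"
  out
}
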