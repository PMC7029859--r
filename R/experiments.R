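# Config-driven Monte-Carlo experiments measuring type-I error, power and
# localization of segregation-distortion detection across population
# sizes, generations and gametic selection strengths.  Every experiment is
# reproducible from its master seed: replicate r runs under an independent
# child seed drawn once from the master stream.

.child_seeds <- function(seed, n) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  sample.int(2147483646L, n)
}

# One replicate: simulate and return raw p-values and M per marker.
.sim_and_test <- function(map, n, k, regime, seed) {
  pop <- simulate_ssd_population(map, n, k, regime, seed = seed)
  cnt <- tabulate_counts(pop)
  ts <- .chisq_scan(cnt$a, cnt$h, cnt$b, use_het = (k == 2L))
  list(p = ts$p, M = magnitude(cnt))
}

# fraction of replicates with >= 1 significant marker under the five
# detection criteria used throughout; prs is a list of p-value vectors
.criteria_hits <- function(prs) {
  crit <- function(f) mean(vapply(prs, f, logical(1)))
  c(p05 = crit(function(p) any(p < 0.05, na.rm = TRUE)),
    p01 = crit(function(p) any(p < 0.01, na.rm = TRUE)),
    p001 = crit(function(p) any(p < 0.001, na.rm = TRUE)),
    fdr05 = crit(function(p) any(adjust_pvalues(p, "fdr") < 0.05,
                                 na.rm = TRUE)),
    bonf05 = crit(function(p) any(adjust_pvalues(p, "bonferroni") < 0.05,
                                  na.rm = TRUE)))
}

#' Null sweep: familywise false-positive rates across population sizes
#'
#' Simulates neutral (no-selection) populations on a map and records, per
#' (population size, generation) cell, the proportion of replicates
#' containing at least one marker significant under each detection
#' criterion (raw p < 0.05/0.01/0.001, FDR 0.05, Bonferroni 0.05), plus
#' the mean over replicates of the peak distortion magnitude
#' max |M - 0.5|.
#'
#' @param map a `genetic_map` (e.g. [make_clustered_map()]).
#' @param sizes population sizes to sweep.
#' @param generations filial generations to sweep.
#' @param reps replicates per cell (default 1000).
#' @param seed master seed.
#' @return Data frame, one row per (n, generation) cell.
#' @export
run_null_sweep <- function(map, sizes = c(96, 300, 1000, 10000),
                           generations = c(2, 6), reps = 1000, seed = 1) {
  grid <- expand.grid(n = sizes, generation = generations)
  seeds <- matrix(.child_seeds(seed, reps * nrow(grid)), nrow = reps)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    k <- parse_generation(grid$generation[i])
    res <- lapply(seq_len(reps), function(r)
      .sim_and_test(map, grid$n[i], k, NULL, seeds[r, i]))
    hits <- .criteria_hits(lapply(res, `[[`, "p"))
    peak <- mean(vapply(res, function(x)
      max(abs(x$M - 0.5), na.rm = TRUE), numeric(1)))
    data.frame(n = grid$n[i], generation = k, t(hits),
               mean_peak_magnitude = peak)
  })
  out <- do.call(rbind, rows)
  attr(out, "reps") <- reps
  attr(out, "seed") <- seed
  out
}

#' Marker-spacing type-I-error experiment
#'
#' Neutral F2 simulations on three minimal map layouts: a single marker, two
#' markers 1 cM apart (positions 59 and 60) and two markers 40 cM apart
#' (positions 20 and 60).  Reports the fraction of replicates with at
#' least one marker significant by raw chi-square at `alpha`.  A single
#' marker recovers the nominal test size; adding a second, loosely linked
#' marker nearly doubles the familywise rate, while a tightly linked pair
#' behaves almost like one marker.
#'
#' @param n population size (default 1000).
#' @param reps replicates per layout (default 1000).
#' @param alpha raw significance threshold.
#' @param seed master seed.
#' @return Data frame with columns `layout`, `prop_significant`.
#' @export
run_marker_spacing_experiment <- function(n = 1000, reps = 1000,
                                          alpha = 0.05, seed = 1) {
  layouts <- list(single = make_custom_map(59),
                  close_pair = make_custom_map(c(59, 60)),
                  far_pair = make_custom_map(c(20, 60)))
  seeds <- matrix(.child_seeds(seed, reps * length(layouts)), nrow = reps)
  prop <- vapply(seq_along(layouts), function(i) {
    mean(vapply(seq_len(reps), function(r) {
      res <- .sim_and_test(layouts[[i]], n, 2L, NULL, seeds[r, i])
      any(res$p < alpha, na.rm = TRUE)
    }, logical(1)))
  }, numeric(1))
  data.frame(layout = names(layouts), prop_significant = prop,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Deviation-score heatmap over population size and selection strength
#'
#' For each (population size, selection strength) tile, simulates F2
#' populations on an evenly spaced 20-marker / 100 cM map with gametic
#' selection at the central marker and averages the deviation score
#' sum((y - 0.5)^2) of the homozygote segregation ratios across markers
#' (20 replicates per tile by default).
#'
#' @param sizes population sizes (grid rows).
#' @param strengths selection strengths (grid columns); numeric or "1/x"
#'   strings.
#' @param reps replicates per tile (default 20).
#' @param n_markers,length_cM map layout (defaults 20 markers / 100 cM).
#' @param seed master seed.
#' @return Data frame with columns `n`, `s`, `mean_deviation`.
#' @export
run_deviation_heatmap <- function(sizes = c(10, 50, 100, 250, 500, 1000, 2000),
                                  strengths = c("1/20", "1/10", "1/8",
                                                "1/6", "1/4", "1/2"),
                                  reps = 20, n_markers = 20,
                                  length_cM = 100, seed = 1) {
  map <- make_uniform_map(n_markers, length_cM)
  s_vals <- vapply(strengths, parse_strength, numeric(1))
  grid <- expand.grid(n = sizes, s = s_vals)
  seeds <- matrix(.child_seeds(seed, reps * nrow(grid)), nrow = reps)
  sel_index <- ceiling(n_markers / 2)
  dev <- vapply(seq_len(nrow(grid)), function(i) {
    regime <- if (grid$s[i] > 0)
      selection_regime(selection_target(chromosomes(map), sel_index, "B",
                                        grid$s[i]))
    mean(vapply(seq_len(reps), function(r) {
      res <- .sim_and_test(map, grid$n[i], 2L, regime, seeds[r, i])
      deviation_score(res$M)
    }, numeric(1)))
  }, numeric(1))
  data.frame(n = grid$n, s = grid$s, mean_deviation = dev)
}

#' Detection-criterion comparison across selection strengths
#'
#' Simulates populations with gametic selection of varying strength at one
#' locus and reports, per strength, the fraction of replicates containing
#' at least one significant marker under each criterion (raw p <
#' 0.05/0.01/0.001, FDR 0.05, Bonferroni 0.05).
#'
#' @param map a `genetic_map`; defaults to the clustered 224-marker
#'   surrogate.
#' @param strengths selection strengths including 0 for the null.
#' @param n population size (default 1000).
#' @param generation filial generation (default F2).
#' @param sel_index 1-based marker index under selection (default 200).
#' @param reps replicates per strength.
#' @param seed master seed.
#' @return Data frame, one row per strength, columns `s`, `p05`, `p01`,
#'   `p001`, `fdr05`, `bonf05`.
#' @export
run_threshold_comparison <- function(map = make_clustered_map(),
                                     strengths = c(0, "1/20", "1/10", "1/8",
                                                   "1/6", "1/4", "1/2"),
                                     n = 1000, generation = 2,
                                     sel_index = 200, reps = 1000,
                                     seed = 1) {
  k <- parse_generation(generation)
  s_vals <- vapply(strengths, parse_strength, numeric(1))
  seeds <- matrix(.child_seeds(seed, reps * length(s_vals)), nrow = reps)
  ch <- chromosomes(map)[1]
  rows <- lapply(seq_along(s_vals), function(i) {
    regime <- if (s_vals[i] > 0)
      selection_regime(selection_target(ch, sel_index, "B", s_vals[i]))
    prs <- lapply(seq_len(reps), function(r)
      .sim_and_test(map, n, k, regime, seeds[r, i])$p)
    data.frame(s = s_vals[i], t(.criteria_hits(prs)))
  })
  do.call(rbind, rows)
}

#' Power and peak localization across population size and selection strength
#'
#' For each (n, s) cell, simulates single-seed-descent populations with
#' selection at one locus and reports the fraction of replicates flagged
#' under each detection criterion together with the fraction whose peak of
#' distortion (argmax |M - 0.5|) lies within `within` markers of the
#' selected locus.
#'
#' @param map a `genetic_map`.
#' @param sizes population sizes.
#' @param strengths selection strengths.
#' @param generation filial generation (default F5).
#' @param sel_index 1-based selected marker index (default 200).
#' @param within localization window in marker indices (default 10).
#' @param reps replicates per cell.
#' @param seed master seed.
#' @return Data frame with one row per (n, s) cell.
#' @export
run_power_grid <- function(map = make_clustered_map(),
                           sizes = c(96, 300, 1000, 10000),
                           strengths = c("1/20", "1/10", "1/4", "1/2"),
                           generation = 5, sel_index = 200, within = 10,
                           reps = 1000, seed = 1) {
  k <- parse_generation(generation)
  s_vals <- vapply(strengths, parse_strength, numeric(1))
  grid <- expand.grid(n = sizes, s = s_vals)
  seeds <- matrix(.child_seeds(seed, reps * nrow(grid)), nrow = reps)
  ch <- chromosomes(map)[1]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    regime <- if (grid$s[i] > 0)
      selection_regime(selection_target(ch, sel_index, "B", grid$s[i]))
    res <- lapply(seq_len(reps), function(r)
      .sim_and_test(map, grid$n[i], k, regime, seeds[r, i]))
    hits <- .criteria_hits(lapply(res, `[[`, "p"))
    near <- mean(vapply(res, function(x)
      abs(peak_marker(x$M) - sel_index) <= within, logical(1)))
    data.frame(n = grid$n[i], s = grid$s[i], t(hits),
               prop_peak_within = near)
  })
  do.call(rbind, rows)
}

#' Peak-localization sweep over selection strength
#'
#' At fixed population size, sweeps selection strength and reports the
#' fraction of replicates whose peak of distortion falls within `within`
#' markers of the selected locus, and the mean number of markers
#' significant by raw chi-square at `alpha`.
#'
#' @inheritParams run_power_grid
#' @param n population size (default 300).
#' @param alpha raw threshold for counting significant markers.
#' @return Data frame with columns `s`, `prop_peak_within`,
#'   `mean_num_significant`.
#' @export
run_peak_localization <- function(map = make_clustered_map(),
                                  strengths = c("1/10", "1/8", "1/6",
                                                "1/4", "1/2"),
                                  n = 300, generation = 2, sel_index = 200,
                                  within = 10, alpha = 0.05, reps = 1000,
                                  seed = 1) {
  k <- parse_generation(generation)
  s_vals <- vapply(strengths, parse_strength, numeric(1))
  seeds <- matrix(.child_seeds(seed, reps * length(s_vals)), nrow = reps)
  ch <- chromosomes(map)[1]
  rows <- lapply(seq_along(s_vals), function(i) {
    regime <- if (s_vals[i] > 0)
      selection_regime(selection_target(ch, sel_index, "B", s_vals[i]))
    res <- lapply(seq_len(reps), function(r)
      .sim_and_test(map, n, k, regime, seeds[r, i]))
    near <- mean(vapply(res, function(x)
      abs(peak_marker(x$M) - sel_index) <= within, logical(1)))
    nsig <- mean(vapply(res, function(x)
      sum(x$p < alpha, na.rm = TRUE), numeric(1)))
    data.frame(s = s_vals[i], prop_peak_within = near,
               mean_num_significant = nsig)
  })
  do.call(rbind, rows)
}
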