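#' Per-marker genotype counts
#'
#' Tallies AA, AB and BB calls per marker; missing calls are excluded from
#' all three counts.
#'
#' @param pop an `ssd_pop`.
#' @return Data frame with columns `marker`, `chromosome`, `a` (AA), `h`
#'   (AB), `b` (BB), one row per marker in map order.
#' @export
tabulate_counts <- function(pop) {
  g <- pop$genotypes
  data.frame(marker = rownames(g),
             chromosome = pop$map$chromosome,
             a = rowSums(g == 0L, na.rm = TRUE),
             h = rowSums(g == 1L, na.rm = TRUE),
             b = rowSums(g == 2L, na.rm = TRUE),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Magnitude of segregation distortion
#'
#' M = a/(a+b), the parent-1 share of homozygous calls at a marker: 0 means
#' no AA genotypes present, 1 no BB, 0.5 an even 1:1 homozygote ratio.
#' Undefined (NA) when a marker has no homozygous calls.
#'
#' @param a AA count, or a data frame with columns `a` and `b` (e.g. from
#'   [tabulate_counts()]).
#' @param b BB count (when `a` is numeric).
#' @return Numeric vector of M values in \[0, 1\], NA where a + b = 0.
#' @examples
#' magnitude(0, 10)   # 0
#' magnitude(95, 100) # 0.48718
#' @export
magnitude <- function(a, b = NULL) {
  if (is.data.frame(a)) {
    b <- a$b
    a <- a$a
  }
  out <- ifelse(a + b > 0, a / (a + b), NA_real_)
  out
}

#' Chi-square goodness-of-fit test for segregation ratios
#'
#' Uncorrected (no continuity correction) chi-square test of observed
#' genotype counts against a Mendelian expectation: `ratio = "1:2:1"`
#' tests (a, h, b) against the F2 expectation on 2 degrees of freedom;
#' `ratio = "1:1"` tests the homozygote counts (a, b) only, on 1 degree of
#' freedom, as appropriate for advanced selfing generations.
#'
#' @param a,h,b genotype counts (`h` ignored for the 1:1 ratio).
#' @param ratio `"1:2:1"` or `"1:1"`.
#' @return List with `chi2`, `df` and `p`.
#' @examples
#' chisq_gof(1, 31, 268, "1:2:1")  # chi2 = 664.07
#' chisq_gof(28, 0, 272, "1:1")    # chi2 = 198.45
#' @export
chisq_gof <- function(a, h = 0, b, ratio = c("1:2:1", "1:1")) {
  ratio <- match.arg(ratio)
  if (ratio == "1:2:1") {
    obs <- c(a, h, b)
    prop <- c(1, 2, 1) / 4
  } else {
    obs <- c(a, b)
    prop <- c(1, 1) / 2
  }
  n <- sum(obs)
  if (n <= 0) stop("chisq_gof: total genotype count is zero")
  e <- prop * n
  chi2 <- sum((obs - e)^2 / e)
  df <- length(obs) - 1L
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

# vectorised chi-square scan over marker count vectors
.chisq_scan <- function(a, h, b, use_het) {
  if (use_het) {
    n <- a + h + b
    chi2 <- (a - n / 4)^2 / (n / 4) + (h - n / 2)^2 / (n / 2) +
      (b - n / 4)^2 / (n / 4)
    df <- 2L
  } else {
    n <- a + b
    chi2 <- (a - n / 2)^2 / (n / 2) + (b - n / 2)^2 / (n / 2)
    df <- 1L
  }
  chi2[n == 0] <- NA_real_
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Multiple-testing adjustment of p-values
#'
#' Implements the identity (`"none"`), Bonferroni (`min(1, m p)`) and
#' Benjamini-Hochberg step-up (`"fdr"`) adjustments over a family of m
#' tests.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed; NAs are
#'   kept out of the family size).
#' @param method `"none"`, `"fdr"` (Benjamini-Hochberg) or `"bonferroni"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @examples
#' adjust_pvalues(c(0.01, 0.2, 0.03), "bonferroni")
#' adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "fdr")
#' @export
adjust_pvalues <- function(p, method = c("none", "fdr", "bonferroni")) {
  method <- match.arg(method)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  m <- sum(ok)
  out <- p
  if (method == "bonferroni") {
    out[ok] <- pmin(1, m * p[ok])
  } else if (method == "fdr") {
    pv <- p[ok]
    o <- order(pv, decreasing = TRUE)   # step-up: walk from largest p down
    q_desc <- pmin(1, cummin(m / (m:1) * pv[o]))
    q <- numeric(m)
    q[o] <- q_desc
    out[ok] <- q
  }
  out
}

#' Scan a population for segregation distortion
#'
#' Computes, for every marker, the genotype counts, the magnitude of
#' distortion M, the chi-square goodness-of-fit statistic against the
#' Mendelian expectation, and raw, FDR- and Bonferroni-adjusted p-values
#' (adjusted jointly across all markers in the scan).  Significance is
#' flagged at `alpha` under the chosen correction.
#'
#' @param pop an `ssd_pop`.
#' @param alpha significance level (default 0.05).
#' @param correction which adjusted p-value drives the `significant`
#'   column: `"none"`, `"fdr"` or `"bonferroni"`.
#' @param ratio `"auto"` (1:2:1 for F2, homozygote 1:1 for later
#'   generations), `"f2_121"` or `"homozygote_11"`.
#' @return An object of class `distortion_scan`: a data frame with columns
#'   `marker`, `chromosome`, `a`, `h`, `b`, `M`, `chi2`, `df`, `p_raw`,
#'   `p_fdr`, `p_bonf`, `significant`, plus attributes recording `alpha`,
#'   `correction`, `ratio` and `generation`.
#' @examples
#' pop <- simulate_ssd_population(make_uniform_map(20, 100), 100, "F2",
#'                                seed = 1)
#' scan_distortion(pop)
#' @export
scan_distortion <- function(pop, alpha = 0.05,
                            correction = c("none", "fdr", "bonferroni"),
                            ratio = c("auto", "f2_121", "homozygote_11")) {
  correction <- match.arg(correction)
  ratio <- match.arg(ratio)
  if (!ncol(pop$genotypes)) stop("population has no individuals")
  cnt <- tabulate_counts(pop)
  use_het <- switch(ratio,
                    auto = pop$generation == 2L,
                    f2_121 = TRUE,
                    homozygote_11 = FALSE)
  ts <- .chisq_scan(cnt$a, cnt$h, cnt$b, use_het)
  tab <- cnt
  tab$M <- magnitude(cnt)
  tab$chi2 <- ts$chi2
  tab$df <- ts$df
  tab$p_raw <- ts$p
  tab$p_fdr <- adjust_pvalues(ts$p, "fdr")
  tab$p_bonf <- adjust_pvalues(ts$p, "bonferroni")
  pcol <- switch(correction, none = "p_raw", fdr = "p_fdr",
                 bonferroni = "p_bonf")
  tab$significant <- !is.na(tab[[pcol]]) & tab[[pcol]] < alpha
  structure(tab,
            class = c("distortion_scan", "data.frame"),
            alpha = alpha, correction = correction,
            ratio = if (use_het) "1:2:1" else "1:1",
            generation = pop$generation)
}

#' @export
print.distortion_scan <- function(x, ...) {
  cat(sprintf("Segregation distortion scan: %d markers, F%d, %s test, %s correction, alpha = %g\n",
              nrow(x), attr(x, "generation"), attr(x, "ratio"),
              attr(x, "correction"), attr(x, "alpha")))
  cat(sprintf("  significant markers: %d\n", sum(x$significant)))
  sdrs <- detect_sdrs(x)
  cat(sprintf("  segregation distortion regions (>= 2 consecutive): %d\n",
              nrow(sdrs)))
  invisible(x)
}

#' @export
summary.distortion_scan <- function(object, ...) {
  print(object)
  pk <- peak_marker(object)
  cat(sprintf("  peak distortion: marker %s (index %d), M = %.4f\n",
              object$marker[pk], pk, object$M[pk]))
  sdrs <- detect_sdrs(object)
  if (nrow(sdrs)) {
    cat("  SDRs:\n")
    print(sdrs)
  }
  invisible(object)
}

#' @export
plot.distortion_scan <- function(x, ...) {
  idx <- seq_len(nrow(x))
  graphics::plot(idx, x$M, type = "l", ylim = c(0, 1),
                 xlab = "marker index", ylab = "M = a/(a+b)", ...)
  graphics::abline(h = 0.5, lty = 3)
  if (any(x$significant))
    graphics::points(idx[x$significant], rep(0.02, sum(x$significant)),
                     pch = 8, cex = 0.6)
  invisible(x)
}

#' Peak-of-distortion marker
#'
#' Index of the marker with the largest |M - 0.5|; ties break to the
#' lowest index.  Markers with undefined M are skipped.
#'
#' @param scan a `distortion_scan`, or a numeric vector of M values.
#' @return 1-based marker index.
#' @export
peak_marker <- function(scan) {
  M <- if (is.data.frame(scan)) scan$M else scan
  dev <- abs(M - 0.5)
  dev[is.na(dev)] <- -Inf
  which.max(dev)
}

#' Detect segregation distortion regions
#'
#' An SDR is a maximal run of at least `min_run` (default 2) consecutive
#' markers on one chromosome all flagged significant.  Each region is
#' annotated with its skew: the majority homozygote direction of the
#' summed counts over the run (`"A"` when sum(a) >= sum(b)).
#'
#' @param scan a `distortion_scan` (uses its `significant` column and
#'   counts), or a logical vector of flags together with `counts`.
#' @param counts optional data frame with columns `a`, `b` (and
#'   `chromosome`) when `scan` is a logical vector.
#' @param min_run minimum run length (default 2).
#' @return Data frame with columns `chromosome`, `start_index`,
#'   `end_index` (1-based, inclusive, within-chromosome), `length`,
#'   `skew`.
#' @export
detect_sdrs <- function(scan, counts = NULL, min_run = 2L) {
  if (is.data.frame(scan)) {
    flags <- scan$significant
    counts <- scan
  } else {
    flags <- as.logical(scan)
    if (is.null(counts))
      counts <- data.frame(a = rep(0, length(flags)),
                           b = rep(0, length(flags)))
  }
  chrom <- if (!is.null(counts$chromosome)) counts$chromosome
           else rep("1", length(flags))
  out <- list()
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    f <- flags[sel]
    r <- rle(f)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values & r$lengths >= min_run)
    for (i in runs) {
      rows <- sel[starts[i]:ends[i]]
      out[[length(out) + 1L]] <- data.frame(
        chromosome = ch, start_index = starts[i], end_index = ends[i],
        length = r$lengths[i],
        skew = if (sum(counts$a[rows]) >= sum(counts$b[rows])) "A" else "B",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chromosome = character(0), start_index = integer(0),
                      end_index = integer(0), length = integer(0),
                      skew = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Overlap of SDRs between two scans
#'
#' All pairwise marker-index-range intersections (width >= 1 marker)
#' between two SDR tables on the same chromosome indexing, with a flag for
#' whether the two regions skew towards the same parental genotype.
#'
#' @param r1,r2 SDR data frames as returned by [detect_sdrs()].
#' @return Data frame with columns `chromosome`, `start_index`,
#'   `end_index`, `width`, `same_skew`.
#' @export
sdr_overlap <- function(r1, r2) {
  out <- list()
  for (i in seq_len(nrow(r1))) for (j in seq_len(nrow(r2))) {
    if (r1$chromosome[i] != r2$chromosome[j]) next
    s <- max(r1$start_index[i], r2$start_index[j])
    e <- min(r1$end_index[i], r2$end_index[j])
    if (e >= s)
      out[[length(out) + 1L]] <- data.frame(
        chromosome = r1$chromosome[i], start_index = s, end_index = e,
        width = e - s + 1L, same_skew = r1$skew[i] == r2$skew[j],
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chromosome = character(0), start_index = integer(0),
                      end_index = integer(0), width = integer(0),
                      same_skew = logical(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Deviation score of a segregation-ratio series
#'
#' Sum of squared deviations of the per-marker homozygote segregation
#' ratio y = a/(a+b) from the even 1:1 value: sum((y - 0.5)^2).  NA values
#' (markers with no homozygote calls) are dropped; an empty series scores
#' 0.
#'
#' @param M_values numeric vector of segregation ratios in \[0, 1\].
#' @return Non-negative deviation score.
#' @examples
#' deviation_score(c(0.6, 0.4))  # 0.02
#' @export
deviation_score <- function(M_values) {
  M_values <- M_values[!is.na(M_values)]
  if (!length(M_values)) return(0)
  sum((M_values - 0.5)^2)
}

#' Population heterozygosity
#'
#' Fraction of non-missing genotype calls that are heterozygous.  Under
#' neutral selfing this halves each generation: E\[het(Fk)\] = 0.5^(k-1).
#'
#' @param pop an `ssd_pop`.
#' @return Heterozygosity in \[0, 1\].
#' @export
heterozygosity <- function(pop) {
  mean(pop$genotypes == 1L, na.rm = TRUE)
}

#' Crossover events per plant from genotype transitions
#'
#' Counts, for each individual, the genotype transitions along the marker
#' order of each chromosome: a homozygote-heterozygote change weighs 1
#' (one gamete recombined), a change between opposite homozygotes weighs 2
#' (both gametes recombined).  Adjacent pairs with a missing call are
#' skipped.
#'
#' @param pop an `ssd_pop`.
#' @return Integer vector, one count per individual.
#' @export
count_crossovers <- function(pop) {
  g <- pop$genotypes
  total <- numeric(ncol(g))
  for (blk in .chrom_blocks(pop$map)) {
    if (length(blk$idx) < 2L) next
    sub <- g[blk$idx, , drop = FALSE]
    d <- abs(sub[-1L, , drop = FALSE] - sub[-nrow(sub), , drop = FALSE])
    total <- total + colSums(d, na.rm = TRUE)
  }
  total
}

#' Pairwise marker distance matrix
#'
#' Recombination-fraction proxy between every marker pair: the mean
#' per-individual genotype mismatch weight, where identical genotypes
#' weigh 0, homozygote vs heterozygote 0.5 and opposite homozygotes 1
#' (the co-dominant Hamming convention).  Pairs involving a missing call
#' are excluded from the mean.
#'
#' @param pop an `ssd_pop` with at least 2 markers.
#' @return Symmetric markers x markers matrix with zero diagonal.
#' @export
pairwise_distance <- function(pop) {
  g <- pop$genotypes
  if (nrow(g) < 2L) stop("pairwise_distance needs at least 2 markers")
  X0 <- (g == 0L); X1 <- (g == 1L); X2 <- (g == 2L)
  X0[is.na(X0)] <- FALSE; X1[is.na(X1)] <- FALSE; X2[is.na(X2)] <- FALSE
  storage.mode(X0) <- storage.mode(X1) <- storage.mode(X2) <- "numeric"
  V <- X0 + X1 + X2                     # 1 where call present
  wsum <- 0.5 * (X0 %*% t(X1) + X1 %*% t(X0) +
                 X1 %*% t(X2) + X2 %*% t(X1)) +
    (X0 %*% t(X2) + X2 %*% t(X0))
  npair <- V %*% t(V)
  D <- ifelse(npair > 0, wsum / npair, NA_real_)
  dimnames(D) <- list(rownames(g), rownames(g))
  D
}

#' Lag-1 autocorrelation of a segregation-ratio series
#'
#' Pearson correlation between the per-marker series and itself shifted by
#' one marker.  Dense linked markers give strongly autocorrelated
#' segregation ratios.
#'
#' @param M_values ordered numeric series (length >= 3, non-constant;
#'   NAs dropped pairwise).
#' @return Correlation in \[-1, 1\], or NA for a constant series.
#' @export
segregation_autocorrelation <- function(M_values) {
  x <- M_values[-length(M_values)]
  y <- M_values[-1L]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(NA_real_)
  stats::cor(x, y)
}

#' Estimate genetic map length from genotype data
#'
#' Adjacent-marker distances are taken from [pairwise_distance()]
#' (interpreted as recombination-fraction proxies, capped at 0.4999) and
#' converted to cM with the inverse Haldane map function
#' d = -50 ln(1 - 2r); per-chromosome interval lengths are summed.
#'
#' @param pop an `ssd_pop`.
#' @return Estimated total map length in cM (summed over chromosomes).
#' @export
estimate_map_length <- function(pop) {
  g <- pop$genotypes
  total <- 0
  for (blk in .chrom_blocks(pop$map)) {
    m <- length(blk$idx)
    if (m < 2L) next
    sub <- g[blk$idx, , drop = FALSE]
    for (j in seq_len(m - 1L)) {
      x <- sub[j, ]; y <- sub[j + 1L, ]
      ok <- !is.na(x) & !is.na(y)
      if (!any(ok)) next
      r <- mean(abs(x[ok] - y[ok]) / 2)
      r <- min(r, 0.4999)
      total <- total - 50 * log(1 - 2 * r)
    }
  }
  total
}

#' Serialize a distortion scan to CSV
#'
#' @param scan a `distortion_scan`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scan_csv <- function(scan, path) {
  utils::write.csv(as.data.frame(scan), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
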