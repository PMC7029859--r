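#' Write / read a genotype matrix as CSV
#'
#' Markers-as-rows CSV: first column `marker`, then one column per
#' individual.  Genotype codes follow the chosen dialect: `"letters"`
#' writes A/H/B with `-` for missing, `"pairs"` writes AA/AB/BB with NA.
#' The filial generation is stored in a leading comment line
#' `#generation=F<k>`, so a write/read round trip preserves genotypes,
#' marker order and generation label.
#'
#' @param pop an `ssd_pop`.
#' @param path file path.
#' @param dialect `"letters"` or `"pairs"`.
#' @return `write_population` returns `path` invisibly; `read_population`
#'   an `ssd_pop`.
#' @export
write_population <- function(pop, path, dialect = c("letters", "pairs")) {
  dialect <- match.arg(dialect)
  calls <- genotype_calls(pop, dialect)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#generation=F%d", pop$generation), con)
  df <- data.frame(marker = rownames(calls), calls, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_population
#' @param map optional `genetic_map` to align the genotypes to; marker
#'   names must match the file's rows.  Without a map the population gets
#'   a placeholder single-chromosome map with markers at 0 cM (distortion
#'   statistics work; distance-based diagnostics do not).
#' @export
read_population <- function(path, map = NULL) {
  first <- readLines(path, n = 1L)
  generation <- 2L
  skip <- 0L
  if (startsWith(first, "#")) {
    skip <- 1L
    m <- regmatches(first, regexec("generation=F?([0-9]+)", first))[[1]]
    if (length(m) == 2L) generation <- as.integer(m[2])
  }
  df <- utils::read.csv(path, skip = skip, check.names = FALSE,
                        colClasses = "character")
  markers <- df[[1]]
  calls <- as.matrix(df[, -1, drop = FALSE])
  rownames(calls) <- markers
  geno <- matrix(NA_integer_, nrow(calls), ncol(calls),
                 dimnames = dimnames(calls))
  lookup <- c(A = 0L, H = 1L, B = 2L, AA = 0L, AB = 1L, BB = 2L)
  known_missing <- c("-", "NA", "U", "")
  for (code in names(lookup)) geno[calls == code] <- lookup[[code]]
  bad <- which(is.na(geno) & !(calls %in% known_missing) & !is.na(calls),
               arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("unknown genotype code '%s' at marker %s, individual %s",
                 calls[bad[1, 1], bad[1, 2]], rownames(calls)[bad[1, 1]],
                 colnames(calls)[bad[1, 2]]))
  if (is.null(map)) {
    map <- genetic_map(markers, "chr1", rep(0, length(markers)))
  } else {
    if (!identical(map$marker, markers))
      stop("map marker names/order do not match the genotype file")
  }
  new_ssd_pop(geno, map, generation)
}

#' Export a population in MSTMap format
#'
#' Writes the plain-text genotype dialect consumed by MSTMap/ASMap: a
#' block of `key value` header lines followed by one row per locus (locus
#' name then one code per individual, whitespace separated).  F2
#' populations are exported as `population_type RIL2` with codes A/B/X
#' (X = heterozygote) and U for missing; later generations as `RIL<k>`
#' with heterozygotes coded U (unknown), the advanced-RIL convention.
#'
#' @param pop an `ssd_pop` (generation F2 or later).
#' @param path output file path.
#' @param population_name name written to the header.
#' @param cut_off_p_value clustering p-value threshold header parameter.
#' @param scientific write `cut_off_p_value` in scientific notation
#'   (`1e-25`); otherwise as a fixed decimal.
#' @param distance_function `"kosambi"` or `"haldane"`.
#' @param no_map_dist,no_map_size,missing_threshold,objective_function
#'   remaining MSTMap header parameters, all overridable.
#' @param estimation_before_clustering,detect_bad_data MSTMap yes/no flags.
#' @return `path`, invisibly.
#' @export
export_mstmap <- function(pop, path, population_name = "simulated_pop",
                          cut_off_p_value = 1e-25, scientific = TRUE,
                          distance_function = c("kosambi", "haldane"),
                          no_map_dist = 15, no_map_size = 2,
                          missing_threshold = 1,
                          estimation_before_clustering = "no",
                          detect_bad_data = "yes",
                          objective_function = "COUNT") {
  distance_function <- match.arg(distance_function)
  k <- pop$generation
  if (k < 2L) stop("MSTMap export supports F2 or later populations")
  if (k == 2L) {
    codes <- c("A", "X", "B")
    ptype <- "RIL2"
  } else {
    codes <- c("A", "U", "B")
    ptype <- sprintf("RIL%d", k)
  }
  g <- pop$genotypes
  calls <- matrix(codes[g + 1L], nrow(g), dimnames = dimnames(g))
  calls[is.na(calls)] <- "U"
  cutoff <- if (scientific) format(cut_off_p_value, scientific = TRUE)
            else formatC(cut_off_p_value, format = "f", digits = 30)
  hdr <- c(
    paste("population_type", ptype),
    paste("population_name", population_name),
    paste("distance_function", distance_function),
    paste("cut_off_p_value", cutoff),
    paste("no_map_dist", no_map_dist),
    paste("no_map_size", no_map_size),
    paste("missing_threshold", missing_threshold),
    paste("estimation_before_clustering", estimation_before_clustering),
    paste("detect_bad_data", detect_bad_data),
    paste("objective_function", objective_function),
    paste("number_of_loci", nrow(g)),
    paste("number_of_individual", ncol(g)))
  rows <- vapply(seq_len(nrow(g)), function(i)
    paste(c(rownames(g)[i], calls[i, ]), collapse = "\t"), character(1))
  writeLines(c(hdr, "", rows), path)
  invisible(path)
}
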