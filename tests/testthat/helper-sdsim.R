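# Shared fixtures: tiny maps and hand-built populations.

tiny_map <- function(n = 5, L = 40, chrom = "1A") {
  make_uniform_map(n, L, chromosome = chrom)
}

# build an ssd_pop from a character genotype matrix (markers x individuals,
# codes AA/AB/BB or NA) without running the simulator
pop_from_calls <- function(calls, map = NULL, generation = 2L) {
  calls <- as.matrix(calls)
  if (is.null(map)) map <- tiny_map(nrow(calls))
  geno <- matrix(NA_integer_, nrow(calls), ncol(calls))
  geno[calls == "AA"] <- 0L
  geno[calls == "AB"] <- 1L
  geno[calls == "BB"] <- 2L
  rownames(geno) <- map$marker
  colnames(geno) <- sprintf("L%04d", seq_len(ncol(geno)))
  sdsim:::new_ssd_pop(geno, map, generation)
}

# brute-force multiple-testing oracles, written from the definitions
oracle_bonferroni <- function(p) pmin(1, length(p) * p)

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) min(1, m * p[o[j]] / j), numeric(1))
    q[o[i]] <- min(vals)
  }
  q
}
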