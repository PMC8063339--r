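## Fixture builders used across the suite: tiny cohorts constructed in
## code, plus independent brute-force oracles for the core statistics.

## build an str_genotypes object from two bp allele-length matrices
make_geno <- function(a1, a2, unit_length = 2, ref_repeats = 10,
                      chrom = "chr1", spacing = 1000, motif = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  L <- nrow(a1)
  units <- rep_len(unit_length, L)
  bases <- c("AC", "ACG", "AGAT", "AATGG", "ACAGCC")
  if (is.null(motif)) motif <- bases[units - 1]
  ref_len <- units * rep_len(ref_repeats, L)
  start <- seq(1, by = spacing, length.out = L)
  loci <- suppressMessages(str_loci(chrom = rep_len(chrom, L), start = start,
                                    end = start + ref_len - 1L, motif = motif))
  samples <- if (!is.null(colnames(a1))) colnames(a1) else
    paste0("s", seq_len(ncol(a1)))
  str_genotypes(loci, samples, a1, a2)
}

## random small cohort: allele lengths are multiples of the unit length
rand_geno <- function(n_loci, n_samples, unit_length = 2, missing_rate = 0,
                      repeat_range = c(5, 15)) {
  draw <- function() {
    matrix(sample(seq(repeat_range[1], repeat_range[2]), n_loci * n_samples,
                  replace = TRUE) * unit_length, n_loci, n_samples)
  }
  a1 <- draw(); a2 <- draw()
  if (missing_rate > 0) {
    mis <- matrix(runif(n_loci * n_samples) < missing_rate, n_loci, n_samples)
    a1[mis] <- NA; a2[mis] <- NA
  }
  make_geno(a1, a2, unit_length = unit_length)
}

## exhaustive-pairwise Rst oracle from two (individuals x 2) allele
## matrices, independent of the package's closed-form implementation:
## mean squared difference over all ordered allele pairs, optionally
## skipping the pairs formed by one individual's own two alleles
oracle_rst <- function(A, B, within_individual = TRUE) {
  msd <- function(alleles, own_pairs) {
    n <- length(alleles)
    tot <- 0; np <- 0
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (!within_individual && i != j &&
            !is.null(own_pairs) && own_pairs[i] == own_pairs[j]) next
        tot <- tot + (alleles[i] - alleles[j])^2
        np <- np + 1
      }
    }
    if (np == 0) return(NA_real_)
    tot / np
  }
  ids_a <- rep(seq_len(nrow(A)), each = 2)
  ids_b <- rep(seq_len(nrow(B)), each = 2) + nrow(A)
  aa <- as.vector(t(A)); bb <- as.vector(t(B))
  sw <- (msd(aa, ids_a) + msd(bb, ids_b)) / 2
  st <- msd(c(aa, bb), c(ids_a, ids_b))
  if (is.na(st) || st == 0) return(NA_real_)
  (st - sw) / st
}

## four-cross-pair Dxy oracle for two samples of one str_genotypes
oracle_dxy <- function(geno, x, y) {
  tot <- 0; n <- 0
  for (i in seq_len(nrow(geno$loci))) {
    u <- geno$loci$unit_length[i]
    cx <- c(geno$a1[i, x], geno$a2[i, x]) / u
    cy <- c(geno$a1[i, y], geno$a2[i, y]) / u
    if (anyNA(cx) || anyNA(cy)) next
    for (a in cx) for (b in cy) tot <- tot + abs(a - b)
    n <- n + 1
  }
  if (n == 0) return(NA_real_)
  tot / (4 * n)
}

## grouped population labels for the simulator's default naming
pop_groups <- function(K) {
  pops <- sprintf("pop%02d", seq_len(K))
  list(a = pops[seq_len(K %/% 2)], b = pops[(K %/% 2 + 1):K])
}
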