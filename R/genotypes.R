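#' strpopgen: population genetics of short tandem repeats
#'
#' Analysis of population-scale short tandem repeat (STR) genotypes:
#' diversity statistics, Rst differentiation scans, stepwise-mutation
#' genetic distances and trees, indicator-matrix PCA, environmental
#' association with principal-component covariates, genomic feature
#' enrichment, hotspot windows, and STR-versus-SNP signal comparison,
#' together with a forward-time stepwise-mutation-model simulator used
#' to validate every stage.
#'
#' @docType package
#' @name strpopgen-package
#' @keywords internal
"_PACKAGE"

#' Construct an STR locus table
#'
#' Builds and validates the locus table used throughout the package.
#' Coordinates are 1-based inclusive (VCF-like); `ref_length` is the
#' reference allele length in bp and must equal `end - start + 1`.
#' Motifs are 2-6 bp over ACGT and are kept strand-as-reported (no
#' reverse-complement canonicalisation). Loci violating these rules, or
#' overlapping an already-retained locus, are dropped with a message;
#' the number dropped is stored in attribute `"n_dropped"`.
#'
#' @param chrom,start,end,motif character/integer vectors, one entry per
#'   locus.
#' @param ref_length reference allele length in bp; defaults to
#'   `end - start + 1`.
#' @param locus_id optional ids; default `chrom_start`.
#' @param max_ref_length loci with longer reference alleles are dropped
#'   (default 80 bp, the usual short-read calling limit).
#' @return data.frame with columns `locus_id`, `chrom`, `start`, `end`,
#'   `motif`, `unit_length`, `ref_length`.
#' @export
str_loci <- function(chrom, start, end, motif,
                     ref_length = end - start + 1L,
                     locus_id = NULL, max_ref_length = 80L) {
  loci <- data.frame(
    locus_id = if (is.null(locus_id)) paste(chrom, start, sep = "_") else as.character(locus_id),
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    motif = toupper(as.character(motif)),
    stringsAsFactors = FALSE
  )
  loci$unit_length <- nchar(loci$motif)
  loci$ref_length <- as.integer(ref_length)
  validate_str_loci(loci, max_ref_length = max_ref_length)
}

#' Validate an STR locus table
#'
#' Enforces the locus invariants (motif 2-6 bp over ACGT, reference
#' length consistent with coordinates and at most `max_ref_length`,
#' positive coordinates) and removes overlapping loci, keeping the first
#' of each overlapping pair in genomic order.
#'
#' @param loci data.frame as produced by [str_loci()].
#' @param max_ref_length maximum reference allele length in bp.
#' @return the retained loci, with attribute `"n_dropped"`.
#' @export
validate_str_loci <- function(loci, max_ref_length = 80L) {
  n0 <- nrow(loci)
  bad_motif <- !grepl("^[ACGT]{2,6}$", loci$motif)
  bad_len <- loci$end - loci$start + 1L != loci$ref_length |
    loci$ref_length > max_ref_length | loci$start < 1L
  keep <- !(bad_motif | bad_len)
  loci <- loci[keep, , drop = FALSE]
  ## overlap screen: genomic order, first-retained wins
  ord <- order(loci$chrom, loci$start, loci$end)
  loci <- loci[ord, , drop = FALSE]
  if (nrow(loci) > 1) {
    keep2 <- rep(TRUE, nrow(loci))
    last_end <- loci$end[1]
    last_chrom <- loci$chrom[1]
    for (i in seq_len(nrow(loci))[-1]) {
      if (loci$chrom[i] == last_chrom && loci$start[i] <= last_end) {
        keep2[i] <- FALSE
      } else {
        last_end <- loci$end[i]
        last_chrom <- loci$chrom[i]
      }
    }
    loci <- loci[keep2, , drop = FALSE]
  }
  if (anyDuplicated(loci$locus_id)) stop("duplicate locus_id after validation")
  rownames(loci) <- NULL
  n_dropped <- n0 - nrow(loci)
  if (n_dropped > 0) message(n_dropped, " locus/loci dropped during validation")
  attr(loci, "n_dropped") <- n_dropped
  loci
}

#' Construct an STR genotype container
#'
#' Holds per-locus, per-sample diploid allele-length calls in bp.
#' Alleles are stored as two loci-by-samples matrices `a1`, `a2`
#' normalised so `a1 <= a2`; a missing call has `NA` in both.
#'
#' @param loci locus table from [str_loci()].
#' @param samples character vector of sample names.
#' @param a1,a2 numeric matrices (loci x samples) of allele lengths in
#'   bp; `NA` marks missing calls.
#' @return object of class `str_genotypes`.
#' @export
str_genotypes <- function(loci, samples, a1, a2) {
  samples <- as.character(samples)
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  stopifnot(nrow(a1) == nrow(loci), ncol(a1) == length(samples),
            all(dim(a1) == dim(a2)))
  if (any(xor(is.na(a1), is.na(a2)))) stop("half-missing calls are not allowed")
  ok <- !is.na(a1)
  if (any(a1[ok] <= 0) || any(a2[!is.na(a2)] <= 0)) stop("allele lengths must be positive")
  lo <- pmin(a1, a2); hi <- pmax(a1, a2)
  dimnames(lo) <- dimnames(hi) <- list(loci$locus_id, samples)
  structure(list(loci = loci, samples = samples, a1 = lo, a2 = hi),
            class = "str_genotypes")
}

#' @export
print.str_genotypes <- function(x, ...) {
  cat("str_genotypes: ", nrow(x$loci), " loci x ", length(x$samples),
      " samples; missing rate ",
      sprintf("%.3f", mean(is.na(x$a1))), "\n", sep = "")
  invisible(x)
}

#' Per-locus call rate
#'
#' Fraction of samples with a non-missing genotype at each locus.
#'
#' @param geno an [str_genotypes()] object.
#' @return named numeric vector over loci.
#' @export
call_rate <- function(geno) {
  rowMeans(!is.na(geno$a1))
}

#' Subset an STR genotype container by locus and/or sample
#'
#' @param geno an [str_genotypes()] object.
#' @param loci locus ids or logical/integer index over loci.
#' @param samples sample names or index over samples.
#' @return a new `str_genotypes` object.
#' @export
subset_genotypes <- function(geno, loci = NULL, samples = NULL) {
  li <- if (is.null(loci)) seq_len(nrow(geno$loci)) else
    if (is.character(loci)) match(loci, geno$loci$locus_id) else loci
  si <- if (is.null(samples)) seq_along(geno$samples) else
    if (is.character(samples)) match(samples, geno$samples) else samples
  if (anyNA(li) || anyNA(si)) stop("unknown locus or sample in subset")
  lo <- geno$loci[li, , drop = FALSE]
  rownames(lo) <- NULL
  structure(list(loci = lo, samples = geno$samples[si],
                 a1 = geno$a1[li, si, drop = FALSE],
                 a2 = geno$a2[li, si, drop = FALSE]),
            class = "str_genotypes")
}

#' Construct a population map
#'
#' Maps samples to population labels, optionally with per-population
#' environment descriptors (longitude, latitude, annual mean temperature
#' in degrees C, altitude in m). Environment values are constant within
#' a population: every sample inherits its population's value.
#'
#' @param sample,population character vectors of equal length.
#' @param env optional data.frame with a `population` column plus any of
#'   `longitude`, `latitude`, `temperature`, `altitude`.
#' @return data.frame of class `pop_map` with one row per sample.
#' @export
pop_map <- function(sample, population, env = NULL) {
  pm <- data.frame(sample = as.character(sample),
                   population = as.character(population),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(pm$sample)) stop("duplicate sample names")
  if (!is.null(env)) {
    if (!"population" %in% names(env)) stop("env table needs a 'population' column")
    miss <- setdiff(pm$population, env$population)
    if (length(miss)) stop("populations missing from env table: ",
                           paste(miss, collapse = ", "))
    pm <- merge(pm, env, by = "population", sort = FALSE)
    pm <- pm[match(sample, pm$sample), c("sample", "population",
                                         setdiff(names(env), "population"))]
    rownames(pm) <- NULL
  }
  class(pm) <- c("pop_map", "data.frame")
  pm
}

#' Check that a population map covers a genotype cohort
#'
#' @param geno an [str_genotypes()] object.
#' @param pm a [pop_map()].
#' @return invisibly, the population label per genotype sample.
#' @export
match_populations <- function(geno, pm) {
  idx <- match(geno$samples, pm$sample)
  if (anyNA(idx)) stop("samples absent from population map: ",
                       paste(geno$samples[is.na(idx)], collapse = ", "))
  invisible(stats::setNames(pm$population[idx], geno$samples))
}

#' Repeat counts from allele lengths
#'
#' Allele lengths in bp divided by the motif unit length; real-valued so
#' imperfect/partial repeats are represented faithfully.
#'
#' @param geno an [str_genotypes()] object.
#' @return list with matrices `c1`, `c2` of repeat counts.
#' @export
repeat_counts <- function(geno) {
  u <- geno$loci$unit_length
  list(c1 = geno$a1 / u, c2 = geno$a2 / u)
}
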