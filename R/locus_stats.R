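## Per-locus and per-sample descriptive statistics for STR cohorts:
## allele spectra, PIC, Shannon's H', heterozygote/homozygote counts,
## dosage, and expansion scores.

#' Allele spectrum of one locus
#'
#' Tally of observed allele lengths (bp) over the non-missing sampled
#' alleles of the cohort; both alleles of every called sample count.
#'
#' @param geno an [str_genotypes()] object.
#' @param locus locus id or row index.
#' @return list of class `allele_spectrum` with `locus_id`, `counts`
#'   (named by allele length), `freqs`, `n_alleles_observed`,
#'   `major_allele_freq`. An all-missing locus yields an empty spectrum
#'   (`n_alleles_observed == 0`).
#' @export
allele_spectrum <- function(geno, locus) {
  i <- if (is.character(locus)) match(locus, geno$loci$locus_id) else locus
  if (is.na(i) || i < 1 || i > nrow(geno$loci)) stop("unknown locus")
  alleles <- c(geno$a1[i, ], geno$a2[i, ])
  alleles <- alleles[!is.na(alleles)]
  if (length(alleles) == 0) {
    return(structure(list(locus_id = geno$loci$locus_id[i],
                          counts = integer(0), freqs = numeric(0),
                          n_alleles_observed = 0L,
                          major_allele_freq = NA_real_),
                     class = "allele_spectrum"))
  }
  tab <- table(alleles)
  counts <- stats::setNames(as.integer(tab), names(tab))
  freqs <- counts / sum(counts)
  structure(list(locus_id = geno$loci$locus_id[i], counts = counts,
                 freqs = freqs, n_alleles_observed = length(counts),
                 major_allele_freq = max(freqs)),
            class = "allele_spectrum")
}

#' Polymorphic information content
#'
#' Botstein's PIC from allele frequencies:
#' \deqn{PIC = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2.}
#' A monomorphic locus scores 0; an empty spectrum returns `NA`.
#'
#' @param spectrum an [allele_spectrum()].
#' @return PIC in \[0, 1).
#' @export
pic <- function(spectrum) {
  p <- spectrum$freqs
  if (length(p) == 0) return(NA_real_)
  s2 <- sum(p^2)
  ## sum_{i<j} 2 p_i^2 p_j^2 = (sum p^2)^2 - sum p^4
  1 - s2 - (s2^2 - sum(p^4))
}

#' Shannon's diversity index
#'
#' \eqn{H' = -\sum_i p_i \log p_i} over the allele frequencies; natural
#' log by default, base 2 by `base = 2`.
#'
#' @param spectrum an [allele_spectrum()].
#' @param base logarithm base (default `exp(1)`).
#' @return H' >= 0; `NA` for an empty spectrum.
#' @export
shannon_index <- function(spectrum, base = exp(1)) {
  p <- spectrum$freqs
  if (length(p) == 0) return(NA_real_)
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Per-sample heterozygote/homozygote counts and ratio
#'
#' For each sample, counts of heterozygous (a1 != a2) and homozygous
#' (a1 == a2) non-missing loci and their ratio He/Ho (infinite when
#' Ho = 0, `NaN` when both are zero).
#'
#' @param geno an [str_genotypes()] object.
#' @param pm optional [pop_map()] to attach population labels.
#' @return data.frame with `sample`, `population` (if `pm` given), `He`,
#'   `Ho`, `ratio`.
#' @export
het_hom_ratio <- function(geno, pm = NULL) {
  het <- geno$a1 != geno$a2
  He <- colSums(het, na.rm = TRUE)
  Ho <- colSums(!het, na.rm = TRUE)
  out <- data.frame(sample = geno$samples, He = as.integer(He),
                    Ho = as.integer(Ho), ratio = He / Ho,
                    stringsAsFactors = FALSE)
  if (!is.null(pm)) {
    out$population <- pm$population[match(out$sample, pm$sample)]
    out <- out[, c("sample", "population", "He", "Ho", "ratio")]
  }
  rownames(out) <- NULL
  out
}

#' STR dosage matrix
#'
#' Dosage of a genotype is the total allele-length deviation from the
#' reference allele, \eqn{(i_A + i_B) - 2r}, in bp; missing calls give
#' `NA`.
#'
#' @param geno an [str_genotypes()] object.
#' @return loci x samples numeric matrix.
#' @export
str_dosage <- function(geno) {
  geno$a1 + geno$a2 - 2 * geno$loci$ref_length
}

#' Expansion score of a locus
#'
#' `(P95 - P5) / unit_length` over the cohort-wide multiset of observed
#' allele lengths, with percentiles by linear interpolation between
#' order statistics (quantile type 7). A score of at least `threshold`
#' (default 10) marks the locus as expanded.
#'
#' @param geno an [str_genotypes()] object.
#' @param locus locus id or index.
#' @param threshold expansion flag cutoff (score units, default 10).
#' @return list with `score` and logical `expanded`; `NA` score on an
#'   all-missing locus.
#' @export
expansion_score <- function(geno, locus, threshold = 10) {
  i <- if (is.character(locus)) match(locus, geno$loci$locus_id) else locus
  alleles <- c(geno$a1[i, ], geno$a2[i, ])
  alleles <- alleles[!is.na(alleles)]
  if (length(alleles) == 0) {
    return(list(score = NA_real_, expanded = NA))
  }
  q <- stats::quantile(alleles, probs = c(0.05, 0.95), names = FALSE,
                       type = 7)
  score <- (q[2] - q[1]) / geno$loci$unit_length[i]
  list(score = score, expanded = score >= threshold)
}

#' Per-locus diversity table
#'
#' One row per locus: observed allele count, major allele frequency,
#' PIC, Shannon's H', expansion score and expanded flag.
#'
#' @param geno an [str_genotypes()] object.
#' @param expansion_threshold cutoff for the expanded flag.
#' @return data.frame keyed by `locus_id`.
#' @export
locus_stats_table <- function(geno, expansion_threshold = 10) {
  n <- nrow(geno$loci)
  out <- data.frame(locus_id = geno$loci$locus_id,
                    n_alleles = integer(n), major_allele_freq = NA_real_,
                    pic = NA_real_, shannon = NA_real_,
                    expansion_score = NA_real_, expanded = NA,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    sp <- allele_spectrum(geno, i)
    out$n_alleles[i] <- sp$n_alleles_observed
    out$major_allele_freq[i] <- sp$major_allele_freq
    out$pic[i] <- pic(sp)
    out$shannon[i] <- shannon_index(sp)
    es <- expansion_score(geno, i, threshold = expansion_threshold)
    out$expansion_score[i] <- es$score
    out$expanded[i] <- es$expanded
  }
  out
}

#' Per-population diversity panel
#'
#' Computes, within each population, the per-sample He/Ho counts and
#' the per-locus PIC and Shannon's H' (population-stratified by
#' default; `pooled = TRUE` computes locus statistics on the pooled
#' cohort instead and repeats them per population).
#'
#' @param geno an [str_genotypes()] object.
#' @param pm a [pop_map()] covering the cohort.
#' @param pooled compute locus diversity on the pooled cohort.
#' @return list with `samples` (per-sample table) and `loci` (per
#'   population x locus table).
#' @export
diversity_panel <- function(geno, pm, pooled = FALSE) {
  pops <- match_populations(geno, pm)
  samp <- het_hom_ratio(geno, pm)
  loc_list <- list()
  if (pooled) {
    tab <- locus_stats_table(geno)
    for (p in unique(pops)) {
      loc_list[[p]] <- cbind(population = p, tab[, c("locus_id", "pic", "shannon")])
    }
  } else {
    for (p in unique(pops)) {
      sub <- subset_genotypes(geno, samples = which(pops == p))
      tab <- locus_stats_table(sub)
      loc_list[[p]] <- cbind(population = p, tab[, c("locus_id", "pic", "shannon")])
    }
  }
  loci <- do.call(rbind, loc_list)
  rownames(loci) <- NULL
  list(samples = samp, loci = loci)
}
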