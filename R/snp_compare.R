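## SNP differentiation / association signals in windows flanking
## significant STRs, and the STR-stronger-than-SNP comparison.

#' Hudson Fst scan over SNP dosages
#'
#' Per biallelic SNP, the Hudson estimator from the two groups' sample
#' allele frequencies,
#' \deqn{F_{st} = \frac{(p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) -
#'   p_2(1-p_2)/(n_2-1)}{p_1(1-p_2) + p_2(1-p_1)},}
#' with \eqn{n} the allele counts; SNPs monomorphic across both groups
#' are undefined and excluded from the genome-wide Z-transform.
#'
#' @param dosage SNPs x samples 0/1/2 matrix (`NA` missing).
#' @param positions data.frame `snp_id`, `chrom`, `pos`.
#' @param pm a [pop_map()] covering the samples.
#' @param group_a,group_b population label vectors defining the two
#'   groups.
#' @return data.frame with `snp_id`, `chrom`, `pos`, `fst`, `Z`.
#' @export
snp_fst_scan <- function(dosage, positions, pm, group_a, group_b) {
  pops <- pm$population[match(colnames(dosage), pm$sample)]
  if (anyNA(pops)) stop("samples absent from population map")
  ia <- which(pops %in% group_a)
  ib <- which(pops %in% group_b)
  fst <- rep(NA_real_, nrow(dosage))
  for (i in seq_len(nrow(dosage))) {
    fst[i] <- hudson_fst(dosage[i, ia], dosage[i, ib])
  }
  out <- data.frame(snp_id = positions$snp_id, chrom = positions$chrom,
                    pos = positions$pos, fst = fst,
                    stringsAsFactors = FALSE)
  z_transform(out, stat = "fst")
}

## Hudson estimator from two dosage vectors (0/1/2, NA allowed)
hudson_fst <- function(da, db) {
  da <- da[!is.na(da)]; db <- db[!is.na(db)]
  n1 <- 2 * length(da); n2 <- 2 * length(db)
  if (n1 < 2 || n2 < 2) return(NA_real_)
  p1 <- sum(da) / n1; p2 <- sum(db) / n2
  denom <- p1 * (1 - p2) + p2 * (1 - p1)
  if (denom == 0) return(NA_real_)   # monomorphic across both groups
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  num / denom
}

#' Compare STR signals with flanking SNP signals
#'
#' For each significant STR, finds the maximum SNP signal within
#' `half_window` bp of the STR start and flags the STR as stronger
#' when its signal strictly exceeds that maximum. In differentiation
#' mode the natural pairing is Z-transformed Rst against Z-transformed
#' Hudson Fst; in association mode, -log10 p from the same OLS design
#' run on STR and SNP dosages.
#'
#' @param str_records scan records with `locus_id`, `chrom`, `start`,
#'   a `significant` column, and the signal column.
#' @param snp_records SNP records with `chrom`, `pos` and the signal
#'   column.
#' @param str_signal,snp_signal names of the signal columns (defaults
#'   `"Z"` both).
#' @param half_window window half-width in bp (default 1e5).
#' @return data.frame with one row per significant STR: `locus_id`,
#'   `chrom`, `start`, `str_signal`, `max_snp_signal`, `n_snps`,
#'   `str_stronger` (`NA` when no SNP lies in the window).
#' @export
compare_window <- function(str_records, snp_records, str_signal = "Z",
                           snp_signal = "Z", half_window = 1e5) {
  sig <- str_records[which(str_records$significant), , drop = FALSE]
  out <- data.frame(locus_id = sig$locus_id, chrom = sig$chrom,
                    start = sig$start, str_signal = sig[[str_signal]],
                    max_snp_signal = NA_real_, n_snps = 0L,
                    str_stronger = NA, stringsAsFactors = FALSE)
  sv <- snp_records[[snp_signal]]
  for (i in seq_len(nrow(out))) {
    inw <- which(snp_records$chrom == out$chrom[i] &
                   abs(snp_records$pos - out$start[i]) <= half_window &
                   !is.na(sv))
    out$n_snps[i] <- length(inw)
    if (length(inw)) {
      out$max_snp_signal[i] <- max(sv[inw])
      out$str_stronger[i] <- out$str_signal[i] > out$max_snp_signal[i]
    }
  }
  rownames(out) <- NULL
  out
}
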