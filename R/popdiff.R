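## Rst differentiation scan between two groups of populations, with
## Z-transformation, top-permille significance flags and candidate
## differentiated region (CDR) merging.

## mean squared difference over all ordered allele pairs (i, j) in `a`,
## self-pairs included, i.e. twice the population variance: the reading
## of "average sum of squares of differences" under which two groups
## sharing one allele multiset give Sw = St exactly. Optionally the two
## cross pairs formed by one individual's own alleles are excluded
## (drop_pairs = matrix with columns a1, a2).
mean_sq_pair_diff <- function(a, drop_pairs = NULL) {
  n <- length(a)
  if (n < 2) return(NA_real_)
  tot <- 2 * (n * sum(a^2) - sum(a)^2)   # sum over ordered (i, j)
  npair <- n * n
  if (!is.null(drop_pairs) && nrow(drop_pairs) > 0) {
    tot <- tot - 2 * sum((drop_pairs[, 1] - drop_pairs[, 2])^2)
    npair <- npair - 2 * nrow(drop_pairs)
  }
  if (npair <= 0) return(NA_real_)
  tot / npair
}

#' Rst at one locus
#'
#' Fixation index for STRs under stepwise mutation,
#' \deqn{R_{st} = (S_t - S_w)/S_t,}
#' where \eqn{S_w} is the average over the two groups of the mean
#' squared allele-length difference over all allele pairs within the
#' group (twice the population variance of allele length), and
#' \eqn{S_t} the same mean over the pooled alleles. Under this pairing
#' two groups sharing an identical allele multiset give exactly
#' \eqn{R_{st} = 0} and complete fixation for different lengths gives
#' exactly 1. By default the two alleles of one individual form a
#' valid within-group pair (`within_individual = FALSE` excludes
#' them), and the two group means receive equal weight
#' (`weighted = TRUE` weights by pair count).
#'
#' @param geno an [str_genotypes()] object.
#' @param pm a [pop_map()].
#' @param group_a,group_b character vectors of population labels.
#' @param locus locus id or index.
#' @param within_individual count the pair formed by one individual's
#'   two alleles (default TRUE).
#' @param weighted weight group means by their pair counts.
#' @param units `"bp"` (default) or `"repeat"`; Rst itself is invariant
#'   to this per-locus rescaling, only Sw/St change.
#' @return list with `locus_id`, `Sw`, `St`, `Rst` (`NA` when
#'   undefined: monomorphic pool or a group with fewer than two
#'   alleles).
#' @export
rst <- function(geno, pm, group_a, group_b, locus,
                within_individual = TRUE, weighted = FALSE,
                units = c("bp", "repeat")) {
  units <- match.arg(units)
  i <- if (is.character(locus)) match(locus, geno$loci$locus_id) else locus
  pops <- match_populations(geno, pm)
  sa <- which(pops %in% group_a)
  sb <- which(pops %in% group_b)
  scale <- if (units == "repeat") geno$loci$unit_length[i] else 1
  grab <- function(idx) {
    a1 <- geno$a1[i, idx]; a2 <- geno$a2[i, idx]
    ok <- !is.na(a1)
    list(alleles = c(a1[ok], a2[ok]) / scale,
         pairs = cbind(a1[ok], a2[ok]) / scale)
  }
  ga <- grab(sa); gb <- grab(sb)
  dp_a <- if (within_individual) NULL else ga$pairs
  dp_b <- if (within_individual) NULL else gb$pairs
  out <- list(locus_id = geno$loci$locus_id[i], Sw = NA_real_,
              St = NA_real_, Rst = NA_real_)
  if (length(ga$alleles) < 2 || length(gb$alleles) < 2) return(out)
  sw_a <- mean_sq_pair_diff(ga$alleles, dp_a)
  sw_b <- mean_sq_pair_diff(gb$alleles, dp_b)
  dp_t <- if (within_individual) NULL else rbind(ga$pairs, gb$pairs)
  st <- mean_sq_pair_diff(c(ga$alleles, gb$alleles), dp_t)
  if (is.na(sw_a) || is.na(sw_b) || is.na(st)) return(out)
  sw <- if (weighted) {
    na <- length(ga$alleles); nb <- length(gb$alleles)
    wa <- na * na - if (within_individual) 0 else 2 * nrow(ga$pairs)
    wb <- nb * nb - if (within_individual) 0 else 2 * nrow(gb$pairs)
    (sw_a * wa + sw_b * wb) / (wa + wb)
  } else {
    (sw_a + sw_b) / 2
  }
  out$Sw <- sw; out$St <- st
  out$Rst <- if (st > 0) (st - sw) / st else NA_real_
  out
}

#' Genome-wide Rst scan
#'
#' Applies [rst()] to every locus and returns one record per locus with
#' coordinates attached, ready for [z_transform()], [top_permille()]
#' and [merge_cdr()].
#'
#' @inheritParams rst
#' @return data.frame with `locus_id`, `chrom`, `start`, `end`, `Sw`,
#'   `St`, `Rst`.
#' @export
rst_scan <- function(geno, pm, group_a, group_b,
                     within_individual = TRUE, weighted = FALSE) {
  n <- nrow(geno$loci)
  recs <- vapply(seq_len(n), function(i) {
    r <- rst(geno, pm, group_a, group_b, i,
             within_individual = within_individual, weighted = weighted)
    c(r$Sw, r$St, r$Rst)
  }, numeric(3))
  data.frame(locus_id = geno$loci$locus_id, chrom = geno$loci$chrom,
             start = geno$loci$start, end = geno$loci$end,
             Sw = recs[1, ], St = recs[2, ], Rst = recs[3, ],
             stringsAsFactors = FALSE)
}

#' Z-transform a scan statistic
#'
#' Standardises the named statistic over all loci where it is defined,
#' using the genome-wide mean and standard deviation computed once.
#'
#' @param records data.frame from [rst_scan()] (or any scan).
#' @param stat column to transform (default `"Rst"`).
#' @return `records` with a `Z` column (`NA` where the statistic is
#'   undefined).
#' @export
z_transform <- function(records, stat = "Rst") {
  x <- records[[stat]]
  ok <- !is.na(x)
  if (sum(ok) < 2) stop("need at least two defined values to Z-transform")
  s <- stats::sd(x[ok])
  if (s == 0) stop("degenerate scan: zero variance in ", stat)
  records$Z <- (x - mean(x[ok])) / s
  records
}

#' Flag the top-permille loci of a scan
#'
#' Flags the \eqn{k = \lceil f \cdot n \rceil} loci with the largest
#' statistic among the \eqn{n} loci where it is defined (default
#' fraction 0.005, i.e. the top 5 per mille). Ties at the cut are
#' broken by genomic order (chromosome, then start).
#'
#' @param records data.frame with the statistic and `chrom`, `start`.
#' @param fraction fraction of defined loci to flag.
#' @param stat column holding the statistic.
#' @return `records` with a logical `significant` column.
#' @export
top_permille <- function(records, fraction = 0.005, stat = "Rst") {
  x <- records[[stat]]
  idx <- which(!is.na(x))
  k <- ceiling(fraction * length(idx))
  ord <- idx[order(-x[idx], records$chrom[idx], records$start[idx])]
  records$significant <- FALSE
  if (k > 0) records$significant[ord[seq_len(min(k, length(ord)))]] <- TRUE
  records
}

#' Merge significant loci into candidate differentiated regions
#'
#' Single-linkage chaining per chromosome: successive significant loci
#' whose start positions (or previous end to next start with
#' `measure = "end"`) lie within `gap` bp join one region. Region span
#' is min start to max end; ids are assigned in genomic order.
#'
#' @param records scan records with a `significant` column and
#'   coordinates.
#' @param gap chaining distance in bp (default 5000).
#' @param measure `"start"` (start-to-start, default) or `"end"`
#'   (end-to-start).
#' @return list with `regions` (data.frame `cdr_id`, `chrom`, `start`,
#'   `end`, `n_loci`) and `records` (input with a `cdr_id` column on
#'   significant loci).
#' @export
merge_cdr <- function(records, gap = 5000, measure = c("start", "end")) {
  measure <- match.arg(measure)
  sig <- records[which(records$significant), , drop = FALSE]
  records$cdr_id <- NA_character_
  if (nrow(sig) == 0) {
    return(list(regions = data.frame(cdr_id = character(), chrom = character(),
                                     start = integer(), end = integer(),
                                     n_loci = integer()),
                records = records))
  }
  sig <- sig[order(sig$chrom, sig$start), , drop = FALSE]
  grp <- integer(nrow(sig))
  grp[1] <- 1L
  if (nrow(sig) > 1) {
    for (i in 2:nrow(sig)) {
      prev <- if (measure == "start") sig$start[i - 1] else sig$end[i - 1]
      same <- sig$chrom[i] == sig$chrom[i - 1] && (sig$start[i] - prev) <= gap
      grp[i] <- if (same) grp[i - 1] else grp[i - 1] + 1L
    }
  }
  regions <- do.call(rbind, lapply(split(seq_len(nrow(sig)), grp), function(ii) {
    data.frame(chrom = sig$chrom[ii[1]], start = min(sig$start[ii]),
               end = max(sig$end[ii]), n_loci = length(ii),
               stringsAsFactors = FALSE)
  }))
  regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
  regions$cdr_id <- sprintf("CDR%04d", seq_len(nrow(regions)))
  regions <- regions[, c("cdr_id", "chrom", "start", "end", "n_loci")]
  rownames(regions) <- NULL
  key <- paste(sig$chrom, sig$start)
  for (g in unique(grp)) {
    ii <- which(grp == g)
    rid <- regions$cdr_id[regions$chrom == sig$chrom[ii[1]] &
                            regions$start == min(sig$start[ii])]
    records$cdr_id[match(sig$locus_id[ii], records$locus_id)] <- rid
  }
  list(regions = regions, records = records)
}

#' Assign genes to loci or regions by flanking overlap
#'
#' Pairs each query interval with every gene whose span extended by
#' `flank` bp on both sides overlaps it by at least one bp.
#'
#' @param query data.frame with an id column (first column), `chrom`,
#'   `start`, `end` (1-based inclusive), e.g. significant scan records
#'   or CDR regions.
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param flank flanking distance in bp (default 5000).
#' @return data.frame of (query id, gene_id, distance 0 when
#'   overlapping the gene body).
#' @export
assign_genes <- function(query, genes, flank = 5000) {
  qid <- query[[1]]
  qgr <- GenomicRanges::GRanges(query$chrom,
                                IRanges::IRanges(query$start, query$end))
  ggr <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(pmax(1L, genes$start - as.integer(flank)),
                                                 genes$end + as.integer(flank)))
  hits <- GenomicRanges::findOverlaps(qgr, ggr)
  qi <- S4Vectors::queryHits(hits); gi <- S4Vectors::subjectHits(hits)
  body <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start, genes$end))
  dist <- GenomicRanges::distance(qgr[qi], body[gi])
  data.frame(id = qid[qi], gene_id = genes$gene_id[gi],
             distance = as.integer(dist), stringsAsFactors = FALSE)
}
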