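## Genomic context of STR loci: single-label annotation with class
## precedence, fold enrichment with chi-squared testing, strand-signed
## TSS distance profiles, and 1-Mb hotspot windows.

#' Annotate loci with a single feature label
#'
#' Each locus receives the highest-precedence feature class whose
#' intervals intersect its span by at least one bp; loci overlapping
#' nothing (or lying on a chromosome absent from every class) are
#' labelled `"intergenic"`.
#'
#' @param loci locus table ([str_loci()]-style data.frame).
#' @param features a [feature_set()].
#' @param precedence character vector ordering the classes from
#'   highest to lowest precedence; defaults to
#'   `CDS > 5UTR > 3UTR > H3K4me3 > H3K27ac > intron` followed by any
#'   remaining classes in the feature set.
#' @return character vector of labels, one per locus.
#' @export
annotate_loci <- function(loci, features,
                          precedence = c("CDS", "5UTR", "3UTR", "H3K4me3",
                                         "H3K27ac", "intron")) {
  precedence <- c(precedence, setdiff(names(features$classes), precedence))
  precedence <- intersect(precedence, names(features$classes))
  labels <- rep("intergenic", nrow(loci))
  covered_chroms <- unique(unlist(lapply(features$classes, function(df) df$chrom)))
  off <- !(loci$chrom %in% covered_chroms)
  if (any(off) && length(covered_chroms)) {
    warning(sum(off), " locus/loci on chromosomes absent from the feature set")
  }
  qgr <- loci_granges(loci)
  for (cls in rev(precedence)) {   # low precedence first, high overwrites
    gr <- class_granges(features, cls)
    if (length(gr) == 0) next
    hit <- unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(qgr, gr)))
    labels[hit] <- cls
  }
  labels
}

#' Fold enrichment of STR classes in feature classes
#'
#' For each (STR class, feature class) pair, builds the 2x2 table
#' a = class-X loci in feature F, b = class-X loci not in F,
#' c = other loci in F, d = other loci not in F, and reports the odds
#' ratio `ad/bc`, the density fold `(a/(a+b)) / ((a+c)/n)`, and a
#' Pearson chi-squared p-value without continuity correction (Yates
#' correction by `correct = TRUE`). Pairs with a zero margin are
#' marked untestable (`NA` chi-squared).
#'
#' @param labels per-locus feature labels from [annotate_loci()].
#' @param str_class per-locus STR class (e.g. unit length or motif).
#' @param correct apply Yates continuity correction.
#' @return data.frame with one record per (STR class, feature class):
#'   `str_class`, `feature`, `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `density_fold`, `chi2`, `p`.
#' @export
enrichment <- function(labels, str_class, correct = FALSE) {
  stopifnot(length(labels) == length(str_class))
  out <- list()
  for (sc in sort(unique(as.character(str_class)))) {
    for (fc in sort(unique(labels))) {
      inX <- str_class == sc
      inF <- labels == fc
      a <- sum(inX & inF); b <- sum(inX & !inF)
      c_ <- sum(!inX & inF); d <- sum(!inX & !inF)
      n <- a + b + c_ + d
      or <- if (b * c_ > 0) (a * d) / (b * c_) else if (a == 0) 0 else NA_real_
      df <- if (a + b > 0) (a / (a + b)) / ((a + c_) / n) else NA_real_
      chi2 <- p <- NA_real_
      if (all(c(a + b, c_ + d, a + c_, b + d) > 0)) {
        tst <- suppressWarnings(
          stats::chisq.test(matrix(c(a, c_, b, d), 2), correct = correct))
        chi2 <- unname(tst$statistic)
        p <- tst$p.value
      }
      out[[length(out) + 1]] <- data.frame(
        str_class = sc, feature = fc, a = a, b = b, c = c_, d = d,
        odds_ratio = or, density_fold = df, chi2 = chi2, p = p,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Strand-signed TSS distance profile
#'
#' Signed distance of each locus midpoint to the nearest transcription
#' start site, negated for minus-strand genes so that upstream is
#' always negative, binned and normalised to a density per bp per
#' locus (counts / bin width / loci per class).
#'
#' @param loci locus table.
#' @param tss data.frame with `chrom`, `pos` (1-based TSS coordinate)
#'   and `strand` (`"+"`/`"-"`).
#' @param str_class optional per-locus class for stratified profiles
#'   (default one pooled class).
#' @param half_window profile half-width in bp (default 5000).
#' @param bin_width bin size in bp (default 100).
#' @return data.frame with `str_class`, `bin_start`, `bin_mid`,
#'   `count`, `density`.
#' @export
tss_profile <- function(loci, tss, str_class = NULL, half_window = 5000,
                        bin_width = 100) {
  if (is.null(tss) || nrow(tss) == 0) stop("empty TSS list")
  if (is.null(str_class)) str_class <- rep("all", nrow(loci))
  mid <- (loci$start + loci$end) / 2
  ## nearest TSS on the same chromosome, then strand-signed distance
  dist_signed <- rep(NA_real_, nrow(loci))
  for (ch in unique(loci$chrom)) {
    ti <- which(tss$chrom == ch)
    li <- which(loci$chrom == ch)
    if (length(ti) == 0 || length(li) == 0) next
    for (i in li) {
      j <- ti[which.min(abs(tss$pos[ti] - mid[i]))]
      d <- mid[i] - tss$pos[j]
      if (tss$strand[j] == "-") d <- -d
      dist_signed[i] <- d
    }
  }
  keep <- !is.na(dist_signed) & abs(dist_signed) <= half_window
  breaks <- seq(-half_window, half_window, by = bin_width)
  out <- list()
  for (sc in sort(unique(str_class))) {
    sel <- keep & str_class == sc
    h <- hist(dist_signed[sel], breaks = breaks, plot = FALSE)
    n_class <- sum(str_class == sc)
    out[[sc]] <- data.frame(str_class = sc, bin_start = utils::head(breaks, -1),
                            bin_mid = h$mids, count = h$counts,
                            density = h$counts / bin_width / max(n_class, 1),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Hotspot windows of polymorphic STR density
#'
#' Tiles each chromosome in non-overlapping windows (1 Mb by default;
#' the final partial window is kept and flagged), counts loci per
#' window by start coordinate, and flags windows whose count strictly
#' exceeds mean + `k` standard deviations, the mean and SD being taken
#' genome-wide over full-length windows only.
#'
#' @param loci locus table (typically restricted to polymorphic loci).
#' @param genome data.frame with `chrom`, `length`.
#' @param window window size in bp (default 1e6).
#' @param k SD multiplier for the hotspot cutoff (default 2).
#' @param include_partial include terminal partial windows in the
#'   mean/SD estimate (default FALSE; they always appear in the
#'   output).
#' @return data.frame with `chrom`, `start` (1-based), `end`, `count`,
#'   `partial`, `hotspot`.
#' @export
hotspots <- function(loci, genome, window = 1e6, k = 2,
                     include_partial = FALSE) {
  wins <- list()
  for (r in seq_len(nrow(genome))) {
    len <- genome$length[r]
    starts <- seq(1, len, by = window)
    ends <- pmin(starts + window - 1, len)
    wins[[r]] <- data.frame(chrom = genome$chrom[r], start = starts,
                            end = ends, partial = ends - starts + 1 < window,
                            stringsAsFactors = FALSE)
  }
  w <- do.call(rbind, wins)
  wkey <- paste(w$chrom, (w$start - 1) %/% window)
  lkey <- paste(loci$chrom, (loci$start - 1) %/% window)
  tab <- table(lkey)
  w$count <- 0L
  hit <- match(names(tab), wkey)
  if (anyNA(hit)) stop("locus start beyond chromosome length")
  w$count[hit] <- as.integer(tab)
  base <- if (include_partial) w$count else w$count[!w$partial]
  mu <- mean(base)
  sdv <- stats::sd(base)
  cutoff <- mu + k * (if (is.na(sdv)) 0 else sdv)
  w$hotspot <- w$count > cutoff
  attr(w, "mean") <- mu
  attr(w, "sd") <- sdv
  rownames(w) <- NULL
  w
}
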