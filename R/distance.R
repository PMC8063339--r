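## Stepwise-mutation-model genetic distances, neighbour-joining trees,
## and the (n-1)-column indicator encoding used for PCA of multiallelic
## STR genotypes.

#' Stepwise-mutation genetic distance between two samples
#'
#' \deqn{D_{xy} = \frac{1}{4N} \sum_{loci} \sum_{i,j \in \{1,2\}}
#'   |C_{Ai} - C_{Bj}|,}
#' where \eqn{C_{Ai}} is the repeat number (allele length divided by
#' unit length, real-valued) of allele \eqn{i} of sample A, the inner
#' sum runs over the four cross pairs of the two samples' alleles, and
#' \eqn{N} counts the loci non-missing in both samples.
#'
#' @param geno an [str_genotypes()] object.
#' @param x,y sample names or indices.
#' @param loci optional locus subset (ids or indices).
#' @return Dxy in repeat units; `NA` if no shared non-missing locus.
#' @export
dxy <- function(geno, x, y, loci = NULL) {
  xi <- if (is.character(x)) match(x, geno$samples) else x
  yi <- if (is.character(y)) match(y, geno$samples) else y
  li <- if (is.null(loci)) seq_len(nrow(geno$loci)) else
    if (is.character(loci)) match(loci, geno$loci$locus_id) else loci
  u <- geno$loci$unit_length[li]
  ax1 <- geno$a1[li, xi] / u; ax2 <- geno$a2[li, xi] / u
  ay1 <- geno$a1[li, yi] / u; ay2 <- geno$a2[li, yi] / u
  ok <- !is.na(ax1) & !is.na(ay1)
  n <- sum(ok)
  if (n == 0) return(NA_real_)
  tot <- abs(ax1 - ay1) + abs(ax1 - ay2) + abs(ax2 - ay1) + abs(ax2 - ay2)
  sum(tot[ok]) / (4 * n)
}

#' Pairwise Dxy distance matrix
#'
#' Computes [dxy()] for every sample pair over loci passing an
#' informativeness screen on the major allele frequency. The default
#' keeps loci whose major allele frequency is at most
#' `major_freq_max = 0.95` (pruning near-fixed loci); the literal
#' minimum screen `major_freq_min` is also available. Each pair uses
#' its own set of mutually non-missing loci.
#'
#' @param geno an [str_genotypes()] object.
#' @param major_freq_max drop loci with major allele frequency above
#'   this (default 0.95; set to 1 to disable).
#' @param major_freq_min drop loci with major allele frequency below
#'   this (default 0.05).
#' @return object of class `str_dist`: list with `D` (symmetric
#'   matrix, repeat units), `n_loci_used` (pairwise counts), `samples`.
#' @export
distance_matrix <- function(geno, major_freq_max = 0.95,
                            major_freq_min = 0.05) {
  maf <- vapply(seq_len(nrow(geno$loci)), function(i) {
    allele_spectrum(geno, i)$major_allele_freq
  }, numeric(1))
  keep <- which(!is.na(maf) & maf <= major_freq_max & maf >= major_freq_min)
  if (length(keep) == 0) stop("no locus passes the major-allele-frequency screen")
  g <- subset_genotypes(geno, loci = keep)
  ns <- length(g$samples)
  u <- g$loci$unit_length
  c1 <- g$a1 / u; c2 <- g$a2 / u
  D <- matrix(0, ns, ns, dimnames = list(g$samples, g$samples))
  Nm <- matrix(nrow(g$loci), ns, ns, dimnames = dimnames(D))
  for (x in seq_len(ns - 1)) {
    for (y in (x + 1):ns) {
      ok <- !is.na(c1[, x]) & !is.na(c1[, y])
      n <- sum(ok)
      if (n == 0) stop("samples ", g$samples[x], " and ", g$samples[y],
                       " share no non-missing locus")
      tot <- abs(c1[ok, x] - c1[ok, y]) + abs(c1[ok, x] - c2[ok, y]) +
        abs(c2[ok, x] - c1[ok, y]) + abs(c2[ok, x] - c2[ok, y])
      D[x, y] <- D[y, x] <- sum(tot) / (4 * n)
      Nm[x, y] <- Nm[y, x] <- n
    }
  }
  structure(list(D = D, n_loci_used = Nm, samples = g$samples,
                 n_loci_screened = length(keep)), class = "str_dist")
}

#' @export
print.str_dist <- function(x, ...) {
  cat("str_dist:", length(x$samples), "samples,", x$n_loci_screened,
      "loci after screening\n")
  invisible(x)
}

#' Neighbour-joining tree from a distance matrix
#'
#' Classical Saitou-Nei neighbour joining on a symmetric non-negative
#' distance matrix (an `str_dist` or a plain matrix). Branch lengths
#' may be negative, as in the classical algorithm; `clamp_negative`
#' truncates them to zero.
#'
#' @param D an `str_dist` from [distance_matrix()] or a symmetric
#'   numeric matrix with dimnames.
#' @param clamp_negative truncate negative branch lengths at zero.
#' @return an [ape::phylo] unrooted tree.
#' @export
neighbor_joining <- function(D, clamp_negative = FALSE) {
  m <- if (inherits(D, "str_dist")) D$D else as.matrix(D)
  if (nrow(m) < 3) stop("neighbour joining needs at least 3 samples")
  if (!isSymmetric(unname(m), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(m < 0)) stop("distance matrix must be non-negative")
  tr <- ape::nj(stats::as.dist(m))
  if (clamp_negative) tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

#' Indicator-matrix encoding of multiallelic STR genotypes
#'
#' Per locus with \eqn{n} observed alleles, emits \eqn{n - 1} columns:
#' alleles are sorted by descending cohort frequency (ties broken by
#' ascending allele length), the most frequent allele is the dropped
#' reference, and each remaining column holds the sample's copy count
#' (0/1/2) of that allele. Over the full \eqn{n} columns each
#' non-missing sample's counts sum to 2. Missing genotypes are
#' mean-imputed per column by default.
#'
#' @param geno an [str_genotypes()] object.
#' @param impute replace missing entries by the column mean of observed
#'   entries (default TRUE); otherwise left `NA`.
#' @return list with `M` (samples x columns numeric matrix), `key`
#'   (data.frame `column`, `locus_id`, `allele` bp).
#' @export
indicator_encode <- function(geno, impute = TRUE) {
  blocks <- list()
  keys <- list()
  for (i in seq_len(nrow(geno$loci))) {
    sp <- allele_spectrum(geno, i)
    if (sp$n_alleles_observed < 2) next   # monomorphic: zero columns
    lens <- as.numeric(names(sp$freqs))
    ord <- order(-sp$freqs, lens)
    kept <- lens[ord][-1]                 # drop most frequent allele
    a1 <- geno$a1[i, ]; a2 <- geno$a2[i, ]
    block <- vapply(kept, function(al) {
      (a1 == al) + (a2 == al)
    }, numeric(length(a1)))
    block <- matrix(block, nrow = length(a1))
    if (impute && anyNA(block)) {
      for (j in seq_len(ncol(block))) {
        mis <- is.na(block[, j])
        if (any(mis)) block[mis, j] <- mean(block[!mis, j])
      }
    }
    blocks[[length(blocks) + 1]] <- block
    keys[[length(keys) + 1]] <- data.frame(
      locus_id = geno$loci$locus_id[i], allele = kept,
      stringsAsFactors = FALSE)
  }
  if (length(blocks) == 0) stop("no polymorphic locus to encode")
  M <- do.call(cbind, blocks)
  key <- do.call(rbind, keys)
  key <- cbind(column = seq_len(nrow(key)), key)
  colnames(M) <- paste(key$locus_id, key$allele, sep = ":")
  rownames(M) <- geno$samples
  list(M = M, key = key)
}

#' Principal component analysis of an indicator matrix
#'
#' Columns are mean-centred (optionally scaled to unit variance) and
#' the top-`k` principal components extracted by singular value
#' decomposition of the sample covariance. Signs follow the convention
#' that each component's largest-magnitude score is positive.
#'
#' @param indicator output of [indicator_encode()] or a samples x
#'   variables numeric matrix.
#' @param k number of components (reduced with a warning when it
#'   exceeds the matrix rank).
#' @param scale. scale columns to unit variance before decomposition.
#' @return list with `scores` (samples x k) and `eigenvalues`
#'   (covariance eigenvalues, length k, non-increasing).
#' @export
str_pca <- function(indicator, k = 10, scale. = FALSE) {
  M <- if (is.list(indicator) && !is.null(indicator$M)) indicator$M else as.matrix(indicator)
  if (nrow(M) < 2) stop("PCA needs more than one sample")
  if (k >= nrow(M)) k <- nrow(M) - 1
  Mc <- scale(M, center = TRUE, scale = scale.)
  if (scale.) Mc[, attr(Mc, "scaled:scale") == 0] <- 0
  Mc[is.na(Mc)] <- 0
  sv <- svd(Mc, nu = min(k, nrow(Mc)), nv = 0)
  pos <- sv$d > max(sv$d[1], 0) * 1e-10
  rank <- sum(pos)
  if (k > rank) {
    warning("requested ", k, " components but rank is ", rank)
    k <- rank
  }
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k, k)
  ## sign convention: largest |score| entry positive per component
  for (j in seq_len(k)) {
    m <- which.max(abs(scores[, j]))
    if (scores[m, j] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- rownames(M)
  colnames(scores) <- paste0("PC", seq_len(k))
  eig <- sv$d[seq_len(k)]^2 / (nrow(M) - 1)
  list(scores = scores, eigenvalues = eig)
}
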