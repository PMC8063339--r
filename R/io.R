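## Readers and writers for every on-disk format the pipeline touches.
## Coordinate conventions are centralised here: STR/SNP loci are 1-based
## inclusive (VCF-like) in memory; feature intervals are 0-based
## half-open on disk (BED) and in the feature_set container, converted
## to 1-based only when building GRanges for overlap queries.

#' Read an STR genotype VCF
#'
#' Consumes the lobSTR-style VCF dialect: per-record INFO keys `MOTIF`
#' and `END`, and a per-sample `GB` FORMAT field holding the two allele
#' length deviations from the reference in bp as `"x|y"` (or `"x/y"`).
#' Allele length = reference length + deviation. Records failing the
#' locus invariants (motif 2-6 bp, reference length at most 80 bp,
#' overlap with a retained record) are dropped with a message.
#'
#' @param path path to an uncompressed or bgzipped VCF.
#' @param max_ref_length passed to [validate_str_loci()].
#' @return list with elements `geno` ([str_genotypes()]) and `loci`.
#' @export
read_str_vcf <- function(path, max_ref_length = 80L) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  motif <- vcfR::extract.info(v, "MOTIF")
  end <- suppressWarnings(as.integer(vcfR::extract.info(v, "END")))
  if (anyNA(motif) || anyNA(end)) stop("malformed STR VCF: INFO MOTIF/END required on every record")
  pos <- as.integer(fx[, "POS"])
  bad_motif <- !grepl("^[ACGTacgt]{2,6}$", motif)
  if (any(bad_motif)) {
    warning(sum(bad_motif), " record(s) with unknown motif characters skipped")
  }
  keep <- !bad_motif
  loci_all <- str_loci(chrom = fx[keep, "CHROM"], start = pos[keep],
                       end = end[keep], motif = motif[keep],
                       max_ref_length = max_ref_length)
  gb <- vcfR::extract.gt(v, element = "GB")
  if (is.null(gb)) stop("malformed STR VCF: FORMAT field GB required")
  gb <- gb[keep, , drop = FALSE]
  rec_id <- paste(fx[keep, "CHROM"], pos[keep], sep = "_")
  ri <- match(loci_all$locus_id, rec_id)
  gb <- gb[ri, , drop = FALSE]
  dev <- parse_gb(gb)
  a1 <- loci_all$ref_length + dev$d1
  a2 <- loci_all$ref_length + dev$d2
  geno <- str_genotypes(loci_all, colnames(gb), a1, a2)
  list(geno = geno, loci = loci_all)
}

## "x|y" or "x/y" bp deviations -> two numeric matrices; "." or NA -> missing
parse_gb <- function(gb) {
  split1 <- function(s) {
    out <- matrix(NA_real_, nrow = length(s), ncol = 2)
    ok <- !is.na(s) & s != "." & s != "./." & s != ".|."
    parts <- strsplit(s[ok], "[|/]")
    if (any(lengths(parts) != 2)) stop("malformed GB field")
    pp <- do.call(rbind, parts)
    out[ok, 1] <- as.numeric(pp[, 1])
    out[ok, 2] <- as.numeric(pp[, 2])
    out
  }
  d1 <- matrix(NA_real_, nrow(gb), ncol(gb))
  d2 <- d1
  for (j in seq_len(ncol(gb))) {
    m <- split1(gb[, j])
    d1[, j] <- m[, 1]; d2[, j] <- m[, 2]
  }
  list(d1 = d1, d2 = d2)
}

#' Write an STR genotype VCF
#'
#' Inverse of [read_str_vcf()]: emits MOTIF/END INFO keys and the GB
#' deviation FORMAT field, so a written cohort reads back identically.
#'
#' @param geno an [str_genotypes()] object.
#' @param path output path.
#' @export
write_str_vcf <- function(geno, path) {
  lo <- geno$loci
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.1",
    "##INFO=<ID=MOTIF,Number=1,Type=String,Description=\"Repeat motif\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End of repeat tract\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GB,Number=1,Type=String,Description=\"Allele length deviations from reference (bp)\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$samples), collapse = "\t")), con)
  d1 <- geno$a1 - lo$ref_length
  d2 <- geno$a2 - lo$ref_length
  for (i in seq_len(nrow(lo))) {
    gbs <- ifelse(is.na(d1[i, ]), ".",
                  paste0(fmt_num(d1[i, ]), "|", fmt_num(d2[i, ])))
    gts <- ifelse(is.na(d1[i, ]), "./.", "0/1")
    ref <- strrep(substr(lo$motif[i], 1, 1), 1)  # placeholder base
    writeLines(paste(c(lo$chrom[i], lo$start[i], lo$locus_id[i], ref, ".",
                       ".", "PASS",
                       paste0("MOTIF=", lo$motif[i], ";END=", lo$end[i]),
                       "GT:GB", paste(gts, gbs, sep = ":")),
                     collapse = "\t"), con)
  }
  invisible(path)
}

fmt_num <- function(x) {
  out <- ifelse(is.na(x), ".", format(x, trim = TRUE, scientific = FALSE))
  sub("\\.0+$", "", out)
}

#' Read a SNP VCF into a dosage matrix
#'
#' Biallelic records only; GT fields 0/0, 0/1, 1/1 (or phased) become
#' dosages 0, 1, 2 of the ALT allele; missing GT becomes `NA`.
#'
#' @param path path to a VCF.
#' @return list with `dosage` (SNPs x samples matrix), `positions`
#'   (data.frame snp_id, chrom, pos).
#' @export
read_snp_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dos[clean == "0/0"] <- 0
  dos[clean %in% c("0/1", "1/0")] <- 1
  dos[clean == "1/1"] <- 2
  pos <- data.frame(snp_id = paste(fx[, "CHROM"], fx[, "POS"], sep = "_"),
                    chrom = fx[, "CHROM"], pos = as.integer(fx[, "POS"]),
                    stringsAsFactors = FALSE)
  rownames(dos) <- pos$snp_id
  list(dosage = dos, positions = pos)
}

#' Write a SNP dosage matrix as a VCF
#'
#' @param dosage SNPs x samples matrix of 0/1/2 ALT dosages (`NA`
#'   missing).
#' @param positions data.frame with `chrom`, `pos` (1-based).
#' @param path output path.
#' @export
write_snp_vcf <- function(dosage, positions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.1",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(dosage)), collapse = "\t")),
             con)
  gt_map <- c("0/0", "0/1", "1/1")
  for (i in seq_len(nrow(dosage))) {
    g <- dosage[i, ]
    gt <- ifelse(is.na(g), "./.", gt_map[g + 1])
    writeLines(paste(c(positions$chrom[i], positions$pos[i],
                       paste(positions$chrom[i], positions$pos[i], sep = "_"),
                       "A", "T", ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Construct a feature set
#'
#' Named collections of strand-agnostic genomic intervals (0-based
#' half-open, BED-like) on a genome with known chromosome lengths.
#' Intervals within a class are merged so each class is non-overlapping.
#'
#' @param classes named list of data.frames with columns `chrom`,
#'   `start`, `end` (0-based half-open).
#' @param genome data.frame with columns `chrom`, `length`.
#' @return object of class `feature_set`.
#' @export
feature_set <- function(classes = list(), genome) {
  stopifnot(all(c("chrom", "length") %in% names(genome)))
  genome$chrom <- as.character(genome$chrom)
  classes <- lapply(classes, function(df) {
    if (nrow(df) == 0) {
      return(data.frame(chrom = character(), start = integer(), end = integer()))
    }
    df$chrom <- as.character(df$chrom)
    glen <- genome$length[match(df$chrom, genome$chrom)]
    if (anyNA(glen) || any(df$start < 0) || any(df$end > glen) ||
        any(df$end <= df$start)) {
      stop("feature interval outside chromosome bounds")
    }
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      df$chrom, IRanges::IRanges(df$start + 1L, df$end)))
    out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr),
                      stringsAsFactors = FALSE)
    out[order(out$chrom, out$start), , drop = FALSE]
  })
  structure(list(classes = classes, genome = genome), class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat("feature_set on", nrow(x$genome), "chromosome(s):\n")
  for (nm in names(x$classes)) {
    cat("  ", nm, ": ", nrow(x$classes[[nm]]), " interval(s)\n", sep = "")
  }
  invisible(x)
}

## 1-based GRanges view of one feature class
class_granges <- function(fs, class_name) {
  df <- fs$classes[[class_name]]
  if (is.null(df) || nrow(df) == 0) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1L, df$end))
}

loci_granges <- function(loci) {
  GenomicRanges::GRanges(loci$chrom, IRanges::IRanges(loci$start, loci$end))
}

#' Read a BED file into one feature class
#'
#' BED is 0-based half-open on disk; intervals are validated against the
#' genome when given, with the offending line named on error.
#'
#' @param path BED3+ file.
#' @param class_name label for the class.
#' @param genome optional data.frame `chrom`,`length` used for bounds
#'   checks and carried into the returned [feature_set()].
#' @return a [feature_set()] with a single class.
#' @export
read_bed <- function(path, class_name, genome = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0) {
    df <- data.frame(chrom = character(), start = integer(), end = integer())
  } else {
    raw <- utils::read.table(text = lines, header = FALSE,
                             stringsAsFactors = FALSE, fill = TRUE)
    df <- data.frame(chrom = as.character(raw[[1]]),
                     start = as.integer(raw[[2]]),
                     end = as.integer(raw[[3]]), stringsAsFactors = FALSE)
  }
  if (is.null(genome)) {
    genome <- if (nrow(df)) {
      stats::aggregate(end ~ chrom, df, max)
    } else {
      data.frame(chrom = character(), end = integer())
    }
    names(genome) <- c("chrom", "length")
  } else if (nrow(df)) {
    glen <- genome$length[match(df$chrom, genome$chrom)]
    bad <- which(is.na(glen) | df$start < 0 | df$end > glen)
    if (length(bad)) stop("BED line ", bad[1], " outside chromosome bounds")
  }
  cls <- stats::setNames(list(df), class_name)
  feature_set(cls, genome)
}

#' Write one feature class as BED
#'
#' @param fs a [feature_set()].
#' @param class_name class to write.
#' @param path output path.
#' @export
write_bed <- function(fs, class_name, path) {
  df <- fs$classes[[class_name]]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a population/environment metadata table
#'
#' Tab-separated with header; columns `sample`, `population` and
#' optionally `longitude`, `latitude`, `temperature`, `altitude`.
#'
#' @param path TSV path.
#' @return a [pop_map()].
#' @export
read_population_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("sample", "population") %in% names(df))) {
    stop("population table needs 'sample' and 'population' columns")
  }
  env_cols <- intersect(c("longitude", "latitude", "temperature", "altitude"),
                        names(df))
  env <- NULL
  if (length(env_cols)) {
    env <- unique(df[, c("population", env_cols), drop = FALSE])
    if (anyDuplicated(env$population)) {
      stop("environment values differ within a population")
    }
  }
  pop_map(df$sample, df$population, env = env)
}

#' Write a population/environment metadata table
#'
#' @param pm a [pop_map()].
#' @param path output path.
#' @export
write_population_table <- function(pm, path) {
  utils::write.table(as.data.frame(pm), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read per-locus scan results
#'
#' Round-trip-stable TSV of a scan result table (any data.frame keyed by
#' `locus_id`); logical and numeric columns survive a write/read cycle.
#'
#' @param result data.frame of per-locus records.
#' @param path TSV path.
#' @export
write_scan_tsv <- function(result, path) {
  utils::write.table(result, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_scan_tsv
#' @export
read_scan_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, na.strings = "NA")
}

#' Filter loci by call rate
#'
#' Removes loci whose fraction of non-missing samples is below
#' `min_rate` (default 0.6, the usual population-scale STR calling
#' screen). Idempotent.
#'
#' @param geno an [str_genotypes()] object.
#' @param min_rate minimum fraction of called samples, in (0, 1].
#' @return filtered `str_genotypes`.
#' @export
filter_call_rate <- function(geno, min_rate = 0.6) {
  stopifnot(min_rate > 0, min_rate <= 1)
  keep <- call_rate(geno) >= min_rate
  subset_genotypes(geno, loci = which(keep))
}

#' Identify polymorphic loci
#'
#' A locus is polymorphic when at least `min_alleles` distinct allele
#' lengths are observed in the cohort (default 2, i.e. at least two
#' alleles segregating; set `min_alleles = 3` for the stricter
#' more-than-two-alleles reading).
#'
#' @param geno an [str_genotypes()] object.
#' @param min_alleles minimum number of distinct observed allele
#'   lengths.
#' @return character vector of polymorphic locus ids.
#' @export
classify_polymorphic <- function(geno, min_alleles = 2L) {
  n_distinct <- vapply(seq_len(nrow(geno$loci)), function(i) {
    length(unique(stats::na.omit(c(geno$a1[i, ], geno$a2[i, ]))))
  }, integer(1))
  geno$loci$locus_id[n_distinct >= min_alleles]
}
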