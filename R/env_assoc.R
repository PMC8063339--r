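## Genome-wide association of STR dosage with population-level
## environmental variables: ordinary least squares with
## principal-component covariates, and Bonferroni control.

#' Environmental association scan
#'
#' Per locus, fits the ordinary least-squares model
#' `env ~ intercept + dosage + PC1 + ... + PCk` on the non-missing
#' samples and reports the dosage coefficient with its two-sided
#' t-test p-value. The environment is the response and the dosage the
#' predictor; `direction = "dosage"` swaps them (identical p for the
#' unadjusted simple regression, different under covariate
#' adjustment). Every sample carries its population's environment
#' value, so significance inherits the usual pseudo-replication caveat
#' of population-level predictors.
#'
#' @param geno an [str_genotypes()] object.
#' @param env named numeric vector of environment values per sample
#'   (or per population, expanded via `pm`).
#' @param pcs samples x components matrix of covariates (typically the
#'   first three columns of [str_pca()] scores); `NULL` for none.
#' @param pm optional [pop_map()], needed only when `env` is keyed by
#'   population.
#' @param n_pcs number of leading PC columns of `pcs` to use (default
#'   3).
#' @param n_min minimum non-missing samples per locus (default 20);
#'   smaller loci are marked untestable.
#' @param direction `"env"` (default: regress environment on dosage)
#'   or `"dosage"`.
#' @return data.frame with `locus_id`, `chrom`, `start`, `beta`, `se`,
#'   `t`, `p`, `n_used`; untestable loci (too few calls or
#'   zero-variance dosage) carry `NA` statistics.
#' @export
assoc_scan <- function(geno, env, pcs = NULL, pm = NULL, n_pcs = 3,
                       n_min = 20, direction = c("env", "dosage")) {
  direction <- match.arg(direction)
  if (!is.null(pm) && !all(geno$samples %in% names(env))) {
    pops <- match_populations(geno, pm)
    if (!all(pops %in% names(env))) stop("environment values missing for some populations")
    env <- stats::setNames(env[pops], geno$samples)
  }
  if (!all(geno$samples %in% names(env))) stop("every sample needs an environment value")
  ev <- as.numeric(env[geno$samples])
  covar <- NULL
  if (!is.null(pcs)) {
    pcs <- as.matrix(pcs)
    if (is.null(rownames(pcs))) rownames(pcs) <- geno$samples
    covar <- pcs[geno$samples, seq_len(min(n_pcs, ncol(pcs))), drop = FALSE]
  }
  dos <- str_dosage(geno)
  dosage_assoc(dos, geno$loci[, c("locus_id", "chrom", "start")], ev,
               covar = covar, n_min = n_min, direction = direction)
}

#' Association scan over an arbitrary dosage matrix
#'
#' Workhorse behind [assoc_scan()], exposed so the identical OLS design
#' (environment on dosage with covariates) can be run on SNP dosage
#' matrices for STR-versus-SNP signal comparison.
#'
#' @param dos markers x samples numeric dosage matrix (`NA` missing).
#' @param info data.frame with one row per marker; its first column is
#'   used as the marker id and any `chrom`/`start`/`pos` columns are
#'   carried through.
#' @param ev numeric environment vector aligned with `colnames(dos)`.
#' @param covar optional samples x covariates matrix aligned with
#'   `ev`.
#' @param n_min minimum non-missing samples per marker.
#' @param direction see [assoc_scan()].
#' @return data.frame as in [assoc_scan()].
#' @export
dosage_assoc <- function(dos, info, ev, covar = NULL, n_min = 20,
                         direction = c("env", "dosage")) {
  direction <- match.arg(direction)
  n <- nrow(dos)
  out <- cbind(info,
               data.frame(beta = rep(NA_real_, n), se = NA_real_,
                          t = NA_real_, p = NA_real_, n_used = 0L))
  rownames(out) <- NULL
  for (i in seq_len(n)) {
    d <- dos[i, ]
    ok <- !is.na(d) & !is.na(ev)
    m <- sum(ok)
    out$n_used[i] <- m
    if (m < n_min || stats::var(d[ok]) == 0) next
    if (direction == "env") {
      y <- ev[ok]
      X <- cbind(1, d[ok], if (is.null(covar)) NULL else covar[ok, , drop = FALSE])
    } else {
      y <- d[ok]
      X <- cbind(1, ev[ok], if (is.null(covar)) NULL else covar[ok, , drop = FALSE])
    }
    ## drop collinear columns (never the intercept or the tested term)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      keep <- sort(qrX$pivot[seq_len(qrX$rank)])
      if (!all(c(1, 2) %in% keep)) next   # tested term collinear: untestable
      warning("collinear covariates dropped at marker ", out[[1]][i])
      X <- X[, keep, drop = FALSE]
      qrX <- qr(X)
    }
    fit <- stats::lm.fit(X, y)
    df <- m - ncol(X)
    if (df <= 0) next
    res <- y - X %*% fit$coefficients
    sigma2 <- sum(res^2) / df
    XtXinv <- chol2inv(qr.R(qrX))
    se <- sqrt(sigma2 * XtXinv[2, 2])
    beta <- fit$coefficients[2]
    tval <- beta / se
    out$beta[i] <- beta
    out$se[i] <- se
    out$t[i] <- tval
    out$p[i] <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  }
  out
}

#' Bonferroni significance threshold
#'
#' Family-wise alpha divided by the number of tests; with alpha 0.05
#' and 600,000 tests this is 8.33e-8.
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param n_tests number of tests (> 0). The usual choice is the
#'   number of testable loci times the number of environmental
#'   variables.
#' @return the per-test threshold `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  if (n_tests < 1) stop("n_tests must be at least 1")
  alpha / n_tests
}

#' Flag significant association records
#'
#' Marks records with `p` strictly below the threshold; a p-value equal
#' to the threshold is not significant.
#'
#' @param records data.frame with a `p` column.
#' @param threshold per-test significance threshold, e.g. from
#'   [bonferroni_threshold()].
#' @return `records` with a logical `significant` column (`FALSE` for
#'   untestable loci).
#' @export
flag_significant <- function(records, threshold) {
  records$significant <- !is.na(records$p) & records$p < threshold
  records
}
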