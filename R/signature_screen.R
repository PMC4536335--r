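#' Pearson correlation screen of gene expression against IC50
#'
#' Correlates each gene's expression across samples with the per-sample
#' IC50 phenotype and reports two-sided p-values from the t-transform
#' t = r * sqrt((n - 2) / (1 - r^2)) with n - 2 degrees of freedom, plus
#' Benjamini-Hochberg adjusted q-values. Dose phenotypes are log-normal in
#' practice, so the phenotype is log10-transformed by default.
#'
#' Pairs with missing values are dropped per gene (pairwise-complete);
#' genes with fewer than 3 complete pairs, or zero variance on the
#' complete pairs, are skipped with a warning.
#'
#' @param expr numeric matrix, genes in rows (rownames = gene IDs),
#'   samples in columns (colnames = sample labels).
#' @param phenotype named numeric vector of per-sample IC50 values.
#' @param log10_phenotype correlate against log10(IC50)? Default TRUE.
#' @return data.frame with columns `gene`, `r`, `p`, `q`, `n`, one row
#'   per screened gene, in input gene order.
#' @export
pearson_screen <- function(expr, phenotype, log10_phenotype = TRUE) {
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (is.null(rownames(expr))) stop("expr must have gene IDs as rownames")
  if (anyDuplicated(rownames(expr))) stop("duplicate gene IDs in expr")
  if (is.null(names(phenotype)) || is.null(colnames(expr))) {
    stop("phenotype and expr columns must be named with sample labels")
  }
  shared <- intersect(colnames(expr), names(phenotype))
  if (length(shared) < 3L) {
    stop("fewer than 3 samples shared between expression and phenotype")
  }
  y <- phenotype[shared]
  if (log10_phenotype) {
    if (any(y <= 0, na.rm = TRUE)) {
      stop("IC50 values must be positive for the log10 transform")
    }
    y <- log10(y)
  }
  if (stats::sd(y, na.rm = TRUE) == 0 || all(is.na(y))) {
    stop("phenotype is constant across shared samples")
  }
  x <- expr[, shared, drop = FALSE]

  genes <- rownames(x)
  n_g <- nrow(x)
  r <- p <- rep(NA_real_, n_g)
  n <- integer(n_g)

  if (!anyNA(x) && !anyNA(y)) {
    # fast path: one matrix product for all genes
    nn <- length(y)
    xc <- x - rowMeans(x)
    yc <- y - mean(y)
    sx <- sqrt(rowSums(xc^2))
    sy <- sqrt(sum(yc^2))
    ok <- sx > 0
    if (any(!ok)) {
      warning(sum(!ok), " gene(s) with zero variance skipped")
    }
    r[ok] <- as.numeric(xc[ok, , drop = FALSE] %*% yc) / (sx[ok] * sy)
    n[] <- nn
  } else {
    for (i in seq_len(n_g)) {
      ok <- is.finite(x[i, ]) & is.finite(y)
      n[i] <- sum(ok)
      if (n[i] < 3L) next
      xi <- x[i, ok]
      if (stats::sd(xi) == 0 || stats::sd(y[ok]) == 0) next
      r[i] <- stats::cor(xi, y[ok])
    }
    skipped <- sum(is.na(r))
    if (skipped > 0L) {
      warning(skipped,
              " gene(s) skipped (fewer than 3 complete pairs or zero variance)")
    }
  }

  # clamp |r| = 1 so the t-transform stays finite; p underflows to 0 there
  usable <- !is.na(r)
  df <- n - 2L
  tt <- r * sqrt(df / pmax(1 - r^2, 0))
  p[usable] <- 2 * stats::pt(abs(tt[usable]), df[usable], lower.tail = FALSE)
  p[usable & !is.finite(tt)] <- 0

  out <- data.frame(gene = genes, r = r, p = p, q = NA_real_, n = n,
                    stringsAsFactors = FALSE)
  out$q[usable] <- bh_fdr(pmax(out$p[usable], .Machine$double.xmin))
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg step-up adjusted values
#'
#' Computes q_i = min over j with p_(j) >= p_(i) of p_(j) * m / rank(j),
#' capped at 1, returned in the input order.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return q-values, same length and order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  m <- length(pvalues)
  ord <- order(pvalues)
  q_sorted <- rev(cummin(rev(pvalues[ord] * m / seq_len(m))))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

#' Select correlated genes at a significance threshold
#'
#' Applies exactly one of the two filters the screen supports — a raw
#' p-value cutoff or an FDR (q-value) cutoff — with strict inequality,
#' and returns the passing gene IDs sorted by |r| descending (ties broken
#' lexicographically by gene ID).
#'
#' @param results data.frame from [pearson_screen()].
#' @param p_threshold raw two-sided p-value cutoff (exclusive), or NULL.
#' @param q_threshold FDR cutoff (exclusive), or NULL.
#' @return Character vector of gene IDs (possibly empty).
#' @export
select_genes <- function(results, p_threshold = NULL, q_threshold = NULL) {
  stopifnot(is.data.frame(results),
            all(c("gene", "r", "p", "q") %in% names(results)))
  if (is.null(p_threshold) == is.null(q_threshold)) {
    stop("set exactly one of p_threshold or q_threshold")
  }
  if (!is.null(p_threshold)) {
    pass <- !is.na(results$p) & results$p < p_threshold
  } else {
    pass <- !is.na(results$q) & results$q < q_threshold
  }
  hits <- results[pass, , drop = FALSE]
  if (nrow(hits) == 0L) {
    message("no genes pass the threshold")
    return(character(0))
  }
  hits$gene[order(-abs(hits$r), hits$gene)]
}
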