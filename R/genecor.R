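#' Per-gene Pearson correlation between two sample-aligned omics layers
#'
#' For every gene present in both matrices, computes the Pearson correlation
#' across samples between the gene's row in `x` and its row in `y`, with the
#' two-sided p-value from the exact t distribution on n - 2 degrees of
#' freedom. Zero-variance rows and perfect (|r| = 1) correlations have no
#' finite Fisher Z and are dropped with a warning.
#'
#' @param x,y `OmicsMatrix` objects over the identical ordered sample set.
#' @return a `data.frame` with columns `gene`, `r`, `p`.
#' @export
pairwise_gene_correlation <- function(x, y) {
  if (!identical(sample_ids(x), sample_ids(y)))
    stop("matrices are not sample-aligned")
  n <- length(sample_ids(x))
  if (n < 3) stop("need at least 3 matched samples")
  genes <- intersect(gene_ids(x), gene_ids(y))
  if (!length(genes)) stop("no shared genes")
  A <- x$values[genes, , drop = FALSE]
  B <- y$values[genes, , drop = FALSE]
  A <- A - rowMeans(A)
  B <- B - rowMeans(B)
  sa <- rowSums(A^2)
  sb <- rowSums(B^2)
  r <- rowSums(A * B) / sqrt(sa * sb)
  bad <- !is.finite(r) | abs(r) >= 1
  if (any(bad)) {
    warning(sum(bad), " gene(s) dropped: zero variance or |r| = 1")
    r <- r[!bad]
    genes <- genes[!bad]
  }
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  data.frame(gene = genes, r = unname(r), p = unname(p),
             stringsAsFactors = FALSE)
}

#' Fisher Z transformation of a Pearson coefficient
#'
#' Z = 0.5 * ln((1 + r) / (1 - r)), the variance-stabilizing transform; a
#' strictly increasing odd bijection from (-1, 1) to the real line.
#'
#' @param r numeric vector with |r| < 1.
#' @return numeric vector of Z values.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("fisher_z requires |r| < 1")
  0.5 * log((1 + r) / (1 - r))
}

#' D'Agostino skewness test
#'
#' Computes the moment-ratio sample skewness g1 = m3 / m2^(3/2) and tests it
#' against symmetry using D'Agostino's transformed statistic, which maps the
#' standardized skewness to an approximately standard-normal Z via a
#' Johnson SU transformation.
#'
#' @param x numeric vector, length >= 9, non-degenerate.
#' @return list with `skewness` (g1), `statistic` (the normal-scale Z) and
#'   `p` (two-sided).
#' @export
skewness_test <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 9) stop("skewness_test needs at least 9 values")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("skewness_test: zero variance")
  m3 <- mean((x - m)^3)
  g1 <- m3 / m2^1.5
  # standardize g1 and apply D'Agostino's normalizing transformation
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  list(skewness = g1, statistic = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Select significantly correlated genes and characterize their Z distribution
#'
#' Keeps genes whose correlation p-value is at or below `alpha` (optionally
#' constrained to a sign), Fisher-Z-transforms the significant coefficients,
#' and tests the skewness of the resulting Z distribution. A right skew of
#' the CNA-mRNA Z values indicates genome-wide positive coupling of copy
#' number with expression; a left skew of the MET-mRNA Z values indicates
#' anti-correlation of methylation with expression.
#'
#' @param records output of [pairwise_gene_correlation()].
#' @param alpha significance threshold on the raw p-value (default 0.05; no
#'   multiple-testing correction at this stage).
#' @param sign_constraint `"any"` (default), `"positive"` or `"negative"`.
#' @return list of class `CorrelationSetResult`: `records` (with a `z`
#'   column, defined for significant genes), `selected` (gene ids),
#'   `skewness`, `skew_p` (NA, with a warning, when fewer than 9 significant
#'   genes).
#' @export
select_correlated_genes <- function(records, alpha = 0.05,
                                    sign_constraint = c("any", "positive", "negative")) {
  sign_constraint <- match.arg(sign_constraint)
  if (!nrow(records)) stop("no correlation records supplied")
  sig <- records$p <= alpha
  sig <- sig & switch(sign_constraint,
                      any = TRUE,
                      positive = records$r > 0,
                      negative = records$r < 0)
  records$z <- ifelse(sig, fisher_z(records$r), NA_real_)
  records$selected <- sig
  zvals <- records$z[sig]
  if (length(zvals) >= 9) {
    st <- skewness_test(zvals)
    skewness <- st$skewness
    skew_p <- st$p
  } else {
    warning("fewer than 9 significant genes; skewness test skipped")
    skewness <- NA_real_
    skew_p <- NA_real_
  }
  structure(list(records = records, selected = records$gene[sig],
                 skewness = skewness, skew_p = skew_p),
            class = "CorrelationSetResult")
}

#' @export
print.CorrelationSetResult <- function(x, ...) {
  cat(sprintf("CorrelationSetResult: %d/%d genes selected; skewness = %.3f (p = %.3g)\n",
              length(x$selected), nrow(x$records), x$skewness, x$skew_p))
  invisible(x)
}

#' Intersection of two gene sets
#' @param a,b character vectors of gene ids.
#' @return list with `genes` (the intersection) and `count`.
#' @export
intersect_gene_sets <- function(a, b) {
  genes <- intersect(a, b)
  list(genes = genes, count = length(genes))
}
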