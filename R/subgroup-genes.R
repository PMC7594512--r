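#' One-way analysis of variance
#'
#' Classical between/within mean-square ratio with (g - 1, n - g) degrees of
#' freedom. Zero within-group variance with a non-zero between-group spread
#' yields F = Inf and p = 0 by convention.
#'
#' @param values numeric vector.
#' @param labels group labels, >= 2 groups with >= 2 members each.
#' @return list with `f_stat` and `p`.
#' @export
one_way_anova <- function(values, labels) {
  labels <- as.factor(labels)
  labels <- droplevels(labels)
  g <- nlevels(labels)
  n <- length(values)
  if (g < 2) stop("one_way_anova needs >= 2 groups")
  sizes <- table(labels)
  if (any(sizes < 2)) stop("every group needs >= 2 members")
  if (stats::var(values) == 0) stop("one_way_anova: zero total variance")
  grand <- mean(values)
  means <- tapply(values, labels, mean)
  ssb <- sum(sizes * (means - grand)^2)
  ssw <- sum((values - means[labels])^2)
  if (ssw == 0) return(list(f_stat = Inf, p = 0))
  f <- (ssb / (g - 1)) / (ssw / (n - g))
  list(f_stat = f, p = stats::pf(f, g - 1, n - g, lower.tail = FALSE))
}

#' Detect subgroup-specific genes
#'
#' Implements the mean-assignment procedure: each candidate gene is assigned
#' to the subgroup where its mean value (expression level, copy-number
#' change, or methylation level, depending on the matrix supplied) is
#' largest, and flagged subgroup-specific when the across-subgroup
#' difference is significant by one-way ANOVA at the raw `alpha` (no
#' multiple-testing correction at this stage). Exact ties in group means are
#' resolved toward the lowest-indexed subgroup and flagged.
#'
#' @param m an `OmicsMatrix`.
#' @param labels subgroup labels aligned with the samples of `m`.
#' @param alpha ANOVA significance threshold (default 0.05).
#' @param candidates optional character vector restricting the genes scanned
#'   (e.g. a CNAcor or METcor list); default: all genes of `m`.
#' @return a `data.frame` with `gene`, `assigned_subgroup`, one `mean_<g>`
#'   column per subgroup, `f_stat`, `p`, `significant`, `tied`.
#' @export
assign_specific_genes <- function(m, labels, alpha = 0.05, candidates = NULL) {
  if (length(labels) != length(sample_ids(m)))
    stop("labels do not align with samples")
  labels <- as.factor(labels)
  genes <- if (is.null(candidates)) gene_ids(m) else intersect(candidates, gene_ids(m))
  levs <- levels(labels)
  rows <- lapply(genes, function(g) {
    v <- m$values[g, ]
    means <- tapply(v, labels, mean)
    tied <- sum(means == max(means)) > 1
    assigned <- levs[which.max(means)]
    if (stats::var(v) == 0) {
      f <- NA_real_; p <- NA_real_; sig <- FALSE; tied <- TRUE
    } else {
      an <- one_way_anova(v, labels)
      f <- an$f_stat; p <- an$p; sig <- p <= alpha
    }
    out <- data.frame(gene = g, assigned_subgroup = assigned,
                      stringsAsFactors = FALSE)
    for (lev in levs) out[[paste0("mean_", lev)]] <- unname(means[lev])
    out$f_stat <- f; out$p <- p; out$significant <- sig; out$tied <- tied
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
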