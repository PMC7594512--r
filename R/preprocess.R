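#' Retain female patients
#'
#' Male and unknown-gender records are minor cases in breast-cancer cohorts
#' and are removed before sample matching.
#'
#' @param clinical a `ClinicalTable`.
#' @return the filtered `ClinicalTable`; warns when empty.
#' @export
filter_patients <- function(clinical) {
  keep <- clinical$gender %in% "female"
  out <- clinical[keep, , drop = FALSE]
  if (!nrow(out)) warning("no female patients remain after gender filter")
  class(out) <- c("ClinicalTable", "data.frame")
  out
}

#' Match samples across three omics matrices and the clinical table
#'
#' Restricts all four components to the samples they share and imposes a
#' single lexicographic sample order, so every downstream stochastic stage
#' sees the samples in the same order regardless of input file order.
#'
#' @param mrna,cna,met `OmicsMatrix` objects.
#' @param clinical a `ClinicalTable`.
#' @return a `MatchedCohort`: list with elements `mrna`, `cna`, `met`
#'   (`OmicsMatrix`) and `clinical` (`ClinicalTable`), all over the identical
#'   ordered sample set.
#' @export
match_samples <- function(mrna, cna, met, clinical) {
  shared <- Reduce(intersect, list(sample_ids(mrna), sample_ids(cna),
                                   sample_ids(met), clinical$sample_id))
  if (!length(shared)) stop("no samples shared across the three omics and clinical data")
  shared <- sort(shared)
  clin <- clinical[match(shared, clinical$sample_id), , drop = FALSE]
  rownames(clin) <- NULL
  class(clin) <- c("ClinicalTable", "data.frame")
  structure(list(mrna = subset_omics(mrna, samples = shared),
                 cna = subset_omics(cna, samples = shared),
                 met = subset_omics(met, samples = shared),
                 clinical = clin),
            class = "MatchedCohort")
}

#' @export
print.MatchedCohort <- function(x, ...) {
  cat(sprintf("MatchedCohort: %d samples; mRNA %d, CNA %d, MET %d genes\n",
              ncol(x$mrna$values), nrow(x$mrna$values),
              nrow(x$cna$values), nrow(x$met$values)))
  invisible(x)
}

#' Remove genes with too many missing values
#'
#' Genes whose missing fraction is strictly greater than `max_missing_frac`
#' (default: more than 50% missing) are dropped; a gene missing in exactly
#' half of the samples is retained.
#'
#' @param m an `OmicsMatrix`.
#' @param max_missing_frac maximum tolerated missing fraction, in \[0, 1\].
#' @return the filtered `OmicsMatrix`.
#' @export
filter_missing_genes <- function(m, max_missing_frac = 0.5) {
  stopifnot(max_missing_frac >= 0, max_missing_frac <= 1)
  frac <- rowMeans(is.na(m$values))
  keep <- frac <= max_missing_frac
  omics_matrix(m$values[keep, , drop = FALSE], kind = m$kind)
}

#' k-nearest-neighbour imputation of missing values
#'
#' Operates gene-wise: genes are the objects and samples the features, as in
#' classical expression-array kNN imputation. For each missing cell
#' (gene g, sample j), the k genes nearest to g — by root-mean-square
#' Euclidean distance over the samples both genes observe, restricted to
#' genes with an observed value in sample j — donate the mean of their values
#' in sample j. Observed cells are never modified.
#'
#' @param m an `OmicsMatrix`; every gene must have at least one observed
#'   value (apply [filter_missing_genes()] first).
#' @param k number of neighbours (default 10); silently truncated to the
#'   number of available donors.
#' @return the imputed `OmicsMatrix` with no missing values.
#' @export
impute_knn <- function(m, k = 10) {
  stopifnot(k >= 1)
  vals <- m$values
  obs <- !is.na(vals)
  if (any(rowSums(obs) == 0))
    stop("impute_knn: gene(s) with zero observed values; filter them first")
  miss_genes <- which(rowSums(!obs) > 0L)
  for (g in miss_genes) {
    # RMS distance from gene g to every gene over commonly observed samples
    diff2 <- sweep(vals, 2L, vals[g, ], "-")^2
    d <- sqrt(rowMeans(diff2, na.rm = TRUE))   # NaN when no shared sample
    d[g] <- Inf
    for (j in which(!obs[g, ])) {
      donors <- which(obs[, j] & is.finite(d))
      if (!length(donors))
        stop("impute_knn: no donor gene observed in sample ", colnames(vals)[j])
      nn <- donors[order(d[donors])][seq_len(min(k, length(donors)))]
      vals[g, j] <- mean(m$values[nn, j])
    }
  }
  omics_matrix(vals, kind = m$kind)
}

#' Truncate follow-up at an administrative horizon
#'
#' Records with follow-up beyond `max_months` are administratively censored:
#' their time is set to the horizon and their event indicator cleared.
#' Patients are never dropped, so event counts can only decrease.
#'
#' @param clinical a `ClinicalTable`.
#' @param max_months positive horizon in months.
#' @return the truncated `ClinicalTable`.
#' @export
truncate_followup <- function(clinical, max_months) {
  stopifnot(max_months > 0)
  over <- !is.na(clinical$os_time) & clinical$os_time > max_months
  clinical$os_event[over] <- FALSE
  clinical$os_time[over] <- max_months
  clinical
}

#' Preprocess raw inputs into an analysis-ready matched cohort
#'
#' Applies the full preprocessing chain: gender filter, four-way sample
#' matching, per-omics removal of genes with more than `max_missing_frac`
#' missing values, kNN imputation of the remainder, and optional follow-up
#' truncation.
#'
#' @param mrna,cna,met `OmicsMatrix` objects or file paths.
#' @param clinical a `ClinicalTable` or a file path.
#' @param max_missing_frac,knn_k see [filter_missing_genes()], [impute_knn()].
#' @param truncate_months optional horizon for [truncate_followup()].
#' @return a fully imputed `MatchedCohort`.
#' @export
preprocess_cohort <- function(mrna, cna, met, clinical,
                              max_missing_frac = 0.5, knn_k = 10,
                              truncate_months = NULL) {
  if (is.character(mrna)) mrna <- read_omics_matrix(mrna, "mRNA")
  if (is.character(cna)) cna <- read_omics_matrix(cna, "CNA")
  if (is.character(met)) met <- read_omics_matrix(met, "MET")
  if (is.character(clinical)) clinical <- read_clinical(clinical)
  clinical <- filter_patients(clinical)
  cohort <- match_samples(mrna, cna, met, clinical)
  for (layer in c("mrna", "cna", "met")) {
    m <- filter_missing_genes(cohort[[layer]], max_missing_frac)
    if (anyNA(m$values)) m <- impute_knn(m, k = knn_k)
    cohort[[layer]] <- m
  }
  if (!is.null(truncate_months))
    cohort$clinical <- truncate_followup(cohort$clinical, truncate_months)
  cohort
}
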