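#' Per-subgroup clinical summaries
#'
#' @param clinical a `ClinicalTable`.
#' @param labels subgroup labels aligned with `clinical`.
#' @return a `data.frame` with per-subgroup `n`, `mean_age`,
#'   `mean_survival_time` (mean observed follow-up, months), and one
#'   `pam50_<label>` proportion column per PAM50 class present.
#' @export
summarize_subgroups <- function(clinical, labels) {
  if (length(labels) != nrow(clinical)) stop("labels do not align with clinical")
  labels <- as.factor(labels)
  if (any(table(labels) == 0)) stop("empty subgroup")
  out <- data.frame(subgroup = levels(labels),
                    n = as.vector(table(labels)),
                    mean_age = as.vector(tapply(clinical$age, labels, mean)),
                    mean_survival_time = as.vector(tapply(clinical$os_time, labels, mean)),
                    stringsAsFactors = FALSE)
  pam <- clinical$pam50
  if (any(!is.na(pam))) {
    classes <- sort(unique(pam[!is.na(pam)]))
    for (cl in classes)
      out[[paste0("pam50_", cl)]] <- as.vector(
        tapply(seq_len(nrow(clinical)), labels,
               function(i) mean(pam[i] == cl, na.rm = TRUE)))
  }
  out
}

#' Age-threshold survival interaction within subgroups
#'
#' Within each subgroup, splits patients at the age threshold (non-old:
#' age <= threshold, old: age > threshold) and runs a logrank test between
#' the two age groups. Subgroups where one side is empty are skipped with a
#' warning.
#'
#' @param clinical a `ClinicalTable`.
#' @param labels subgroup labels.
#' @param age_threshold split point in years (default 65).
#' @return a `data.frame` with `subgroup`, `n_nonold`, `n_old`, `statistic`,
#'   `p`.
#' @export
age_split_survival <- function(clinical, labels, age_threshold = 65) {
  labels <- as.factor(labels)
  rows <- lapply(levels(labels), function(lev) {
    idx <- labels == lev
    clin <- clinical[idx, , drop = FALSE]
    old <- clin$age > age_threshold
    if (!any(old) || all(old)) {
      warning("subgroup ", lev, " has an empty age side; skipped")
      return(NULL)
    }
    lr <- tryCatch(logrank_test(ifelse(old, "old", "nonold"), clin),
                   error = function(e) NULL)
    if (is.null(lr)) {
      warning("logrank failed in subgroup ", lev, "; skipped")
      return(NULL)
    }
    data.frame(subgroup = lev, n_nonold = sum(!old), n_old = sum(old),
               statistic = lr$statistic, p = lr$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(subgroup = character(), n_nonold = integer(),
                      n_old = integer(), statistic = numeric(), p = numeric())
  rownames(out) <- NULL
  out
}

#' Per-sample copy-number aberration burden
#'
#' Burden is defined here as the fraction of genes whose CNA value exceeds
#' `amplitude_threshold` in absolute value — a per-sample summary of
#' genome-wide alteration load on the log-ratio scale. The threshold is a
#' package choice (default 0.3, a conventional gain/loss cutoff for
#' log2-ratio data) and is configurable.
#'
#' @param cna an `OmicsMatrix` of CNA values.
#' @param amplitude_threshold absolute-value cutoff (default 0.3).
#' @return named numeric vector of burdens in \[0, 1\], one per sample.
#' @export
cna_burden <- function(cna, amplitude_threshold = 0.3) {
  colMeans(abs(cna$values) > amplitude_threshold)
}

#' Welch two-sample t-test statistic
#'
#' Textbook unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value.
#'
#' @param x,y numeric vectors.
#' @return list with `t_stat`, `df`, `p`, `mean_x`, `mean_y`.
#' @export
welch_t_test <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("welch_t_test needs >= 2 values per group")
  vx <- stats::var(x) / nx
  vy <- stats::var(y) / ny
  t_stat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (nx - 1) + vy^2 / (ny - 1))
  list(t_stat = t_stat, df = df, p = 2 * stats::pt(-abs(t_stat), df),
       mean_x = mean(x), mean_y = mean(y))
}

#' Compare CNA burden between two subgroups
#'
#' Welch t-test (two-sample assuming unequal variances) of the per-sample
#' burden between the two subgroups.
#'
#' @param burden per-sample burden vector, see [cna_burden()].
#' @param labels two-class subgroup labels aligned with `burden`.
#' @return list with `group_means` (named), `t_stat`, `df`, `p`.
#' @export
compare_burden <- function(burden, labels) {
  labels <- as.factor(droplevels(as.factor(labels)))
  if (nlevels(labels) != 2) stop("compare_burden needs exactly 2 subgroups")
  a <- burden[labels == levels(labels)[1]]
  b <- burden[labels == levels(labels)[2]]
  w <- welch_t_test(a, b)
  list(group_means = stats::setNames(c(w$mean_x, w$mean_y), levels(labels)),
       t_stat = w$t_stat, df = w$df, p = w$p)
}

#' Descriptive regression of the subgroup indicator on omics summaries
#'
#' Ordinary least-squares fit of the binary subgroup indicator on a
#' per-sample CNA summary and a per-sample MET summary (by default the CNA
#' burden and the mean methylation level). A linear fit of a binary outcome
#' is descriptive only; set `logistic = TRUE` for a logistic alternative.
#'
#' @param labels two-class subgroup labels.
#' @param cna_summary,met_summary per-sample numeric summaries.
#' @param logistic fit a logistic model instead of OLS (default `FALSE`).
#' @return a `data.frame` of coefficients with `estimate`, `se`, `p`; the
#'   model carries a `note` attribute flagging the descriptive nature of the
#'   linear fit.
#' @export
subgroup_omics_regression <- function(labels, cna_summary, met_summary,
                                      logistic = FALSE) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2) stop("regression needs exactly 2 subgroups")
  y <- as.integer(labels == levels(labels)[2])
  if (length(y) != length(cna_summary) || length(y) != length(met_summary))
    stop("inputs are not aligned")
  fit <- if (logistic)
    stats::glm(y ~ cna_summary + met_summary, family = stats::binomial())
  else
    stats::lm(y ~ cna_summary + met_summary)
  sm <- summary(fit)$coefficients
  if (any(is.na(stats::coef(fit)))) stop("collinear inputs")
  out <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                    p = sm[, 4], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "note") <- if (logistic) "logistic fit"
    else "OLS fit of a binary outcome: descriptive only"
  out
}

#' Cross-tabulate subgroups against PAM50 intrinsic subtypes
#'
#' @param labels subgroup labels.
#' @param clinical a `ClinicalTable` with PAM50 labels for at least one
#'   sample.
#' @return a matrix of within-subgroup percentages (rows: subgroups, sum to
#'   100 over the PAM50 classes present).
#' @export
crosstab_pam50 <- function(labels, clinical) {
  if (length(labels) != nrow(clinical)) stop("labels do not align with clinical")
  pam <- clinical$pam50
  if (all(is.na(pam))) stop("no PAM50 labels present")
  keep <- !is.na(pam)
  tab <- table(labels[keep], pam[keep])
  100 * sweep(tab, 1L, rowSums(tab), "/")
}
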