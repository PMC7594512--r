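#' Cox-based prognostic gene filtering
#'
#' Fits, per gene, a univariate Cox proportional-hazards model of overall
#' survival on the gene's continuous value (Efron tie handling) and keeps the
#' genes whose score (logrank) test p-value is at or below `alpha`. For a
#' single covariate the score test coincides with the logrank test, which is
#' how Cox output is conventionally labelled in this pipeline.
#'
#' @param m an `OmicsMatrix`, samples aligned with `clinical`.
#' @param clinical a `ClinicalTable` with at least 2 events.
#' @param alpha significance threshold (default 0.05).
#' @return list with `selected` (gene ids) and `table` (gene, coef, p).
#' @export
cox_feature_select <- function(m, clinical, alpha = 0.05) {
  .check_aligned(m, clinical)
  if (sum(clinical$os_event) < 2) stop("need at least 2 events")
  surv <- survival::Surv(clinical$os_time, clinical$os_event)
  genes <- gene_ids(m)
  res <- lapply(genes, function(g) {
    v <- m$values[g, ]
    if (stats::sd(v) == 0) return(NULL)
    fit <- tryCatch(survival::coxph(surv ~ v), error = function(e) NULL,
                    warning = function(w) NULL)
    if (is.null(fit)) return(NULL)
    sc <- summary(fit)$sctest
    data.frame(gene = g, coef = unname(stats::coef(fit)),
               p = unname(sc["pvalue"]), stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(res, is.null, logical(1)))
  if (dropped) warning(dropped, " gene(s) skipped (constant or non-converging fit)")
  tab <- do.call(rbind, res)
  if (is.null(tab)) tab <- data.frame(gene = character(), coef = numeric(), p = numeric())
  rownames(tab) <- NULL
  list(selected = tab$gene[tab$p <= alpha], table = tab)
}

#' Split samples at the median
#'
#' Values strictly greater than the median go to group `"up"`; values less
#' than or equal to the median (ties included) go to `"down"`.
#'
#' @param values numeric vector, length >= 4.
#' @return character vector of `"up"` / `"down"` labels.
#' @export
median_split <- function(values) {
  if (length(values) < 4) stop("median_split needs at least 4 values")
  ifelse(values > stats::median(values), "up", "down")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return the BH-adjusted q-values (capped at 1, monotone in rank).
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  n <- length(p)
  if (n <= 1) return(p)
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(p[o] * n / seq(n, 1)))
  q[order(o)]
}

#' Median-split univariate Cox regression per gene
#'
#' For every gene, dichotomizes the patients at the gene's median value
#' ("up-regulation" above, "down-regulation" at or below), fits a univariate
#' Cox model on the binary indicator, and reports the hazard ratio of up vs
#' down with its Wald 95% CI, the score (logrank) p-value, and the BH
#' q-value computed over all genes tested in this call. Genes are flagged
#' significant when p <= `alpha` and q <= `q_alpha`.
#'
#' @param m an `OmicsMatrix` (typically expression of a candidate gene set).
#' @param clinical a `ClinicalTable`.
#' @param alpha,q_alpha significance thresholds (defaults 0.05).
#' @return a `data.frame` with columns `gene`, `hr`, `ci_low`, `ci_high`,
#'   `p`, `q`, `direction` (`up_worse` when hr > 1), `significant`.
#' @export
univariate_cox_median <- function(m, clinical, alpha = 0.05, q_alpha = 0.05) {
  .check_aligned(m, clinical)
  if (sum(clinical$os_event) < 2) stop("need at least 2 events")
  surv <- survival::Surv(clinical$os_time, clinical$os_event)
  rows <- lapply(gene_ids(m), function(g) {
    grp <- median_split(m$values[g, ])
    if (length(unique(grp)) < 2) return(NULL)
    up <- as.integer(grp == "up")
    fit <- tryCatch(survival::coxph(surv ~ up), error = function(e) NULL,
                    warning = function(w) NULL)
    if (is.null(fit)) return(NULL)
    beta <- unname(stats::coef(fit))
    se <- sqrt(unname(stats::vcov(fit)[1, 1]))
    sc <- summary(fit)$sctest
    data.frame(gene = g, hr = exp(beta),
               ci_low = exp(beta - stats::qnorm(0.975) * se),
               ci_high = exp(beta + stats::qnorm(0.975) * se),
               p = unname(sc["pvalue"]), stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped) warning(dropped, " gene(s) skipped (degenerate split or failed fit)")
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    return(data.frame(gene = character(), hr = numeric(), ci_low = numeric(),
                      ci_high = numeric(), p = numeric(), q = numeric(),
                      direction = character(), significant = logical()))
  tab$q <- bh_adjust(tab$p)
  tab$direction <- ifelse(tab$hr > 1, "up_worse", "down_worse")
  tab$significant <- tab$p <= alpha & tab$q <= q_alpha
  rownames(tab) <- NULL
  tab
}

#' Logrank test between survival groups
#'
#' @param groups a label vector, one per sample, at least 2 non-empty groups.
#' @param clinical a `ClinicalTable` in the same sample order.
#' @return list with `statistic` (chi-square), `df` and `p`.
#' @export
logrank_test <- function(groups, clinical) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("logrank test needs >= 2 groups")
  if (sum(clinical$os_event) < 1) stop("logrank test needs >= 1 event")
  sd <- survival::survdiff(
    survival::Surv(clinical$os_time, clinical$os_event) ~ groups)
  df <- length(sd$n) - 1
  list(statistic = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Kaplan-Meier curves per group
#'
#' Product-limit estimates of the survival function within each group.
#'
#' @param groups label vector (a single common label is allowed).
#' @param clinical a `ClinicalTable` in the same sample order.
#' @return a named list of class `SurvivalCurve` sets: per group, a
#'   `data.frame` with `time`, `survival`, `at_risk`.
#' @export
km_curve <- function(groups, clinical) {
  groups <- as.factor(groups)
  out <- lapply(levels(groups), function(lev) {
    idx <- groups == lev
    if (!any(idx)) stop("empty group: ", lev)
    fit <- survival::survfit(
      survival::Surv(clinical$os_time[idx], clinical$os_event[idx]) ~ 1)
    data.frame(time = fit$time, survival = fit$surv, at_risk = fit$n.risk)
  })
  names(out) <- levels(groups)
  structure(out, class = "SurvivalCurveSet")
}

#' Read a Kaplan-Meier curve at a fixed horizon
#'
#' @param curve one element of the list returned by [km_curve()].
#' @param horizon time in the same units as the curve (e.g. 60 months for
#'   5-year survival).
#' @return the step-function survival estimate at `horizon`.
#' @export
km_survival_at <- function(curve, horizon) {
  idx <- which(curve$time <= horizon)
  if (!length(idx)) return(1)
  curve$survival[max(idx)]
}

.check_aligned <- function(m, clinical) {
  if (!identical(sample_ids(m), clinical$sample_id))
    stop("matrix and clinical table are not sample-aligned")
  invisible(TRUE)
}
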