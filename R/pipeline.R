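#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with the defaults used
#' throughout: raw p <= 0.05 at the correlation, Cox-filter and ANOVA
#' stages, an additional BH q <= 0.05 for the median-split Cox survival
#' screen, cluster numbers 2..10, a 65-year age threshold and a 0.3 CNA
#' burden amplitude cutoff.
#'
#' @param alpha_cor,alpha_cox,q_alpha,alpha_anova significance thresholds.
#' @param k_range candidate cluster numbers.
#' @param n_perturb,noise_scale,linkage,nstart perturbation-clustering
#'   parameters, see [stability_auc()].
#' @param age_threshold years, for [age_split_survival()].
#' @param burden_threshold see [cna_burden()].
#' @param max_missing_frac,knn_k,truncate_months preprocessing parameters.
#' @param mrna_cox_filter restrict the mRNA matrix entering integration to
#'   Cox-significant genes (default `FALSE`: the full preprocessed matrix is
#'   integrated).
#' @param seed integer seed governing all stochastic stages.
#' @return a list of class `PipelineConfig`.
#' @export
pipeline_config <- function(alpha_cor = 0.05, alpha_cox = 0.05,
                            q_alpha = 0.05, alpha_anova = 0.05,
                            k_range = 2:10, n_perturb = 50, noise_scale = 1,
                            linkage = "average", nstart = 20,
                            age_threshold = 65, burden_threshold = 0.3,
                            max_missing_frac = 0.5, knn_k = 10,
                            truncate_months = NULL,
                            mrna_cox_filter = FALSE, seed = 1) {
  cfg <- list(alpha_cor = alpha_cor, alpha_cox = alpha_cox,
              q_alpha = q_alpha, alpha_anova = alpha_anova,
              k_range = k_range, n_perturb = n_perturb,
              noise_scale = noise_scale, linkage = linkage, nstart = nstart,
              age_threshold = age_threshold,
              burden_threshold = burden_threshold,
              max_missing_frac = max_missing_frac, knn_k = knn_k,
              truncate_months = truncate_months,
              mrna_cox_filter = mrna_cox_filter, seed = seed)
  stopifnot(all(unlist(cfg[c("alpha_cor", "alpha_cox", "q_alpha",
                             "alpha_anova")]) > 0),
            all(unlist(cfg[c("alpha_cor", "alpha_cox", "q_alpha",
                             "alpha_anova")]) < 1),
            all(k_range >= 2))
  structure(cfg, class = "PipelineConfig")
}

#' Run the full multi-omics subtyping pipeline
#'
#' Executes, in order: preprocessing (gender filter, four-way sample
#' matching, missing-gene filter, kNN imputation, optional follow-up
#' truncation); per-gene CNA-mRNA and MET-mRNA correlation with Fisher Z
#' and skewness characterization; univariate Cox prognostic filtering of
#' the CNAcor and METcor sets (on the CNA and MET value matrices of those
#' genes); single-omics perturbation clustering of the filtered CNAcor and
#' METcor matrices; integrated clustering of mRNA + CNAcor + METcor by
#' connectivity fusion; subgroup survival analysis (Kaplan-Meier, logrank,
#' Cox hazard ratio), overlap tests between the single and integrated
#' partitions; subgroup-specific gene detection in all three layers;
#' median-split survival screening of the prognostic gene sets; and
#' downstream characterization (subgroup summaries, PAM50 cross-tabulation,
#' age-split survival, CNA burden comparison, subgroup-vs-omics
#' regression).
#'
#' @param mrna,cna,met,clinical `OmicsMatrix`/`ClinicalTable` objects or
#'   file paths in the dialect of [read_omics_matrix()] /
#'   [read_clinical()].
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory; when given, every table is
#'   written as TSV together with a JSON manifest carrying the
#'   configuration, the seed and the md5 checksum of every artifact.
#' @return a list of class `PipelineResult` with elements `cohort`,
#'   `genecor` (cna/met `CorrelationSetResult`s and their intersection),
#'   `cox_filter`, `single` (per-layer `KSelectionTrace`s), `integrated`
#'   (`ClusteringResult`), `subgroup_survival`, `overlap`,
#'   `specific_genes`, `survival_screen`, `downstream`, `config`, and
#'   `out_dir`.
#' @export
run_pipeline <- function(mrna, cna, met, clinical,
                         config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  log_stage <- function(stage, ...) {
    message(jsonlite::toJSON(c(list(stage = stage), list(...)),
                             auto_unbox = TRUE))
  }

  cohort <- preprocess_cohort(mrna, cna, met, clinical,
                              max_missing_frac = config$max_missing_frac,
                              knn_k = config$knn_k,
                              truncate_months = config$truncate_months)
  log_stage("preprocess", samples = ncol(cohort$mrna$values),
            genes_mrna = nrow(cohort$mrna$values),
            genes_cna = nrow(cohort$cna$values),
            genes_met = nrow(cohort$met$values))

  # --- geneCor stage -------------------------------------------------------
  cor_cna <- select_correlated_genes(
    pairwise_gene_correlation(cohort$cna, cohort$mrna), alpha = config$alpha_cor)
  cor_met <- select_correlated_genes(
    pairwise_gene_correlation(cohort$met, cohort$mrna), alpha = config$alpha_cor)
  genecor <- list(cna = cor_cna, met = cor_met,
                  intersection = intersect_gene_sets(cor_cna$selected,
                                                     cor_met$selected))
  log_stage("genecor", n_cnacor = length(cor_cna$selected),
            n_metcor = length(cor_met$selected),
            intersection = genecor$intersection$count)
  if (!length(cor_cna$selected) || !length(cor_met$selected))
    stop("[genecor] empty CNAcor or METcor set; cannot continue")

  # --- Cox prognostic filter on the selected value matrices ----------------
  cna_sel <- subset_omics(cohort$cna, genes = cor_cna$selected)
  met_sel <- subset_omics(cohort$met, genes = cor_met$selected)
  fs_cna <- cox_feature_select(cna_sel, cohort$clinical, config$alpha_cox)
  fs_met <- cox_feature_select(met_sel, cohort$clinical, config$alpha_cox)
  log_stage("cox_filter", n_cnacor = length(fs_cna$selected),
            n_metcor = length(fs_met$selected))
  if (!length(fs_cna$selected) || !length(fs_met$selected))
    stop("[cox_filter] no prognostic CNAcor or METcor genes; cannot continue")
  cna_prog <- subset_omics(cna_sel, genes = fs_cna$selected)
  met_prog <- subset_omics(met_sel, genes = fs_met$selected)
  post_cox_intersection <- intersect_gene_sets(fs_cna$selected, fs_met$selected)

  # --- clustering ----------------------------------------------------------
  k_range <- config$k_range[config$k_range <= ncol(cohort$mrna$values) - 1]
  single <- list(
    cnacor = select_k(t(cna_prog$values), k_range, method = "kmeans",
                      n_perturb = config$n_perturb,
                      noise_scale = config$noise_scale,
                      seed = config$seed, nstart = config$nstart),
    metcor = select_k(t(met_prog$values), k_range, method = "kmeans",
                      n_perturb = config$n_perturb,
                      noise_scale = config$noise_scale,
                      seed = config$seed + 1L, nstart = config$nstart))
  log_stage("single_clustering", k_cnacor = single$cnacor$k_star,
            k_metcor = single$metcor$k_star,
            auc_cnacor = max(single$cnacor$auc),
            auc_metcor = max(single$metcor$auc))

  mrna_int <- cohort$mrna
  if (isTRUE(config$mrna_cox_filter)) {
    fs_mrna <- cox_feature_select(mrna_int, cohort$clinical, config$alpha_cox)
    if (length(fs_mrna$selected))
      mrna_int <- subset_omics(mrna_int, genes = fs_mrna$selected)
  }
  integrated <- integrate_subtype(
    list(mrna = t(mrna_int$values), cnacor = t(cna_prog$values),
         metcor = t(met_prog$values)),
    k_range = k_range, n_perturb = config$n_perturb,
    noise_scale = config$noise_scale, seed = config$seed + 2L,
    linkage = config$linkage, nstart = config$nstart)
  labels <- paste0("IntCl", integrated$labels)
  log_stage("integrated_clustering", k_star = integrated$k_star,
            auc = max(integrated$trace$auc))

  # --- subgroup survival and overlap ---------------------------------------
  lr <- logrank_test(labels, cohort$clinical)
  km <- km_curve(labels, cohort$clinical)
  cox_hr <- NULL
  if (integrated$k_star == 2) {
    up <- as.integer(labels == sort(unique(labels))[2])
    fit <- survival::coxph(survival::Surv(cohort$clinical$os_time,
                                          cohort$clinical$os_event) ~ up)
    beta <- unname(stats::coef(fit))
    se <- sqrt(unname(stats::vcov(fit)[1, 1]))
    cox_hr <- list(hr = exp(beta),
                   ci_low = exp(beta - stats::qnorm(0.975) * se),
                   ci_high = exp(beta + stats::qnorm(0.975) * se))
  }
  subgroup_survival <- list(logrank = lr, km = km, cox = cox_hr)
  overlap <- list(
    cnacor_vs_metcor = tryCatch(
      overlap_chi2(single$cnacor$labels, single$metcor$labels),
      error = function(e) NULL),
    int_vs_cnacor = tryCatch(overlap_chi2(labels, single$cnacor$labels),
                             error = function(e) NULL),
    int_vs_metcor = tryCatch(overlap_chi2(labels, single$metcor$labels),
                             error = function(e) NULL))
  log_stage("subgroup_survival", logrank_p = lr$p)

  # --- subgroup-specific genes (GeneCluster) -------------------------------
  specific <- list(
    mrna = assign_specific_genes(cohort$mrna, labels, config$alpha_anova),
    cna = assign_specific_genes(cna_sel, labels, config$alpha_anova),
    met = assign_specific_genes(met_sel, labels, config$alpha_anova))
  log_stage("specific_genes",
            n_mrna = sum(specific$mrna$significant),
            n_cna = sum(specific$cna$significant),
            n_met = sum(specific$met$significant))

  # --- median-split survival screen of the prognostic sets -----------------
  survival_screen <- list(
    cnacor = univariate_cox_median(
      subset_omics(cohort$mrna,
                   genes = intersect(fs_cna$selected, gene_ids(cohort$mrna))),
      cohort$clinical, config$alpha_cox, config$q_alpha),
    metcor = univariate_cox_median(
      subset_omics(cohort$mrna,
                   genes = intersect(fs_met$selected, gene_ids(cohort$mrna))),
      cohort$clinical, config$alpha_cox, config$q_alpha))

  # --- downstream characterization -----------------------------------------
  burden <- cna_burden(cohort$cna, config$burden_threshold)
  met_mean <- colMeans(cohort$met$values)
  downstream <- list(
    summary = summarize_subgroups(cohort$clinical, labels),
    pam50 = tryCatch(crosstab_pam50(labels, cohort$clinical),
                     error = function(e) NULL),
    age_split = age_split_survival(cohort$clinical, labels,
                                   config$age_threshold),
    burden = if (integrated$k_star == 2)
      compare_burden(burden, labels) else NULL,
    regression = if (integrated$k_star == 2)
      subgroup_omics_regression(labels, burden, met_mean) else NULL)
  log_stage("downstream", done = TRUE)

  res <- structure(list(cohort = cohort, genecor = genecor,
                        cox_filter = list(cna = fs_cna, met = fs_met,
                                          intersection = post_cox_intersection),
                        single = single, integrated = integrated,
                        labels = labels,
                        subgroup_survival = subgroup_survival,
                        overlap = overlap, specific_genes = specific,
                        survival_screen = survival_screen,
                        downstream = downstream, config = config,
                        out_dir = out_dir),
                   class = "PipelineResult")
  if (!is.null(out_dir)) .write_pipeline_outputs(res, out_dir)
  res
}

# write every tabular artifact plus a manifest with md5 checksums
.write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  paths <- character()
  paths <- c(paths, wt(data.frame(sample_id = sample_ids(res$cohort$mrna),
                                  subgroup = res$labels), "labels.tsv"))
  for (layer in c("cna", "met")) {
    cs <- res$genecor[[layer]]
    paths <- c(paths, wt(cs$records, paste0("genecor_", layer, ".tsv")))
  }
  tr <- res$integrated$trace
  paths <- c(paths, wt(data.frame(k = tr$k_values, auc = tr$auc),
                       "k_selection_integrated.tsv"))
  for (layer in c("cnacor", "metcor")) {
    s <- res$single[[layer]]
    paths <- c(paths, wt(data.frame(k = s$k_values, auc = s$auc),
                         paste0("k_selection_", layer, ".tsv")))
    paths <- c(paths, wt(res$survival_screen[[layer]],
                         paste0("survival_screen_", layer, ".tsv")))
  }
  for (layer in names(res$specific_genes))
    paths <- c(paths, wt(res$specific_genes[[layer]],
                         paste0("specific_genes_", layer, ".tsv")))
  paths <- c(paths, wt(res$downstream$summary, "subgroup_summary.tsv"))
  paths <- c(paths, wt(res$downstream$age_split, "age_split_survival.tsv"))
  manifest <- list(
    package = "omicsubtype",
    version = as.character(utils::packageVersion("omicsubtype")),
    seed = res$config$seed,
    config = unclass(res$config),
    logrank_p = res$subgroup_survival$logrank$p,
    k_star = res$integrated$k_star,
    files = as.list(tools::md5sum(sort(paths))))
  names(manifest$files) <- basename(names(manifest$files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.PipelineResult <- function(x, ...) {
  cat(sprintf(paste0("PipelineResult: %d samples, k* = %d (AUC = %.3f), ",
                     "logrank p = %.3g\n"),
              ncol(x$cohort$mrna$values), x$integrated$k_star,
              max(x$integrated$trace$auc), x$subgroup_survival$logrank$p))
  invisible(x)
}
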