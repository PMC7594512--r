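#' Parameters of the synthetic-cohort generator
#'
#' Defines the planted statistical world: a matched three-omics cohort with
#' two (or more) sample subgroups expressed jointly in all layers, a subset
#' of genes whose mRNA is positively coupled to copy number and a subset
#' negatively coupled to methylation, genes that modulate an exponential
#' survival hazard, right-censoring, and subgroup-shifted ages.
#'
#' Defaults describe a cohort of 300 patients split 75/25 into two
#' subgroups, a 1.5-sd subgroup mean shift planted in 10% of the features of
#' each omics layer, linear CNA/MET coupling with slope 1 and noise sd 0.5
#' (implied per-gene Pearson r of 1/sqrt(1.25) ~ 0.894), 20 prognostic genes
#' at log-hazard 0.2 each (linear-predictor sd near 0.9, a realistically
#' heterogeneous cohort) plus a subgroup main effect of log(4.25) (the
#' worse-prognosis minority subgroup), ~60% censoring, ages centred at 58.6
#' years with the minority subgroup 6.2 years older, 5% male samples and 5%
#' missing cells.
#'
#' @param n_samples number of samples.
#' @param subgroup_props subgroup proportions, summing to 1.
#' @param n_genes named or unnamed vector of gene counts per omics
#'   (mrna, cna, met); a scalar is recycled.
#' @param frac_informative fraction of each omics' genes carrying the
#'   subgroup mean shift.
#' @param subgroup_effect subgroup mean shift in sd units.
#' @param n_cnacor,n_metcor numbers of planted coupled genes.
#' @param coupling_slope,coupling_noise_sd linear coupling mRNA = slope*CNA
#'   (resp. -slope*MET) + N(0, noise_sd).
#' @param n_prognostic number of planted prognostic mRNA genes.
#' @param log_hazard_effect per-gene log hazard coefficient.
#' @param subgroup_log_hazard log hazard of the last subgroup vs the first.
#' @param baseline_hazard events per month of the exponential baseline.
#' @param censoring_rate target censored fraction.
#' @param age_mean,age_sd,age_shift age model; `age_shift` gives the
#'   per-subgroup additive shift in years.
#' @param missing_frac fraction of matrix cells masked as missing.
#' @param male_frac fraction of samples flagged male.
#' @param pam50 logical: attach PAM50-style labels with subgroup-dependent
#'   composition.
#' @return a validated list of class `SimulationParams`.
#' @export
simulation_params <- function(n_samples = 300,
                              subgroup_props = c(0.75, 0.25),
                              n_genes = c(mrna = 100, cna = 100, met = 100),
                              frac_informative = 0.10,
                              subgroup_effect = 1.5,
                              n_cnacor = 50, n_metcor = 50,
                              coupling_slope = 1, coupling_noise_sd = 0.5,
                              n_prognostic = 20, log_hazard_effect = 0.2,
                              subgroup_log_hazard = log(4.25),
                              baseline_hazard = 0.01,
                              censoring_rate = 0.6,
                              age_mean = 58.6, age_sd = 12,
                              age_shift = c(0, 6.2),
                              missing_frac = 0.05, male_frac = 0.05,
                              pam50 = TRUE) {
  if (length(n_genes) == 1) n_genes <- rep(n_genes, 3)
  if (is.null(names(n_genes))) names(n_genes) <- c("mrna", "cna", "met")
  p <- list(n_samples = n_samples, subgroup_props = subgroup_props,
            n_genes = n_genes, frac_informative = frac_informative,
            subgroup_effect = subgroup_effect, n_cnacor = n_cnacor,
            n_metcor = n_metcor, coupling_slope = coupling_slope,
            coupling_noise_sd = coupling_noise_sd,
            n_prognostic = n_prognostic, log_hazard_effect = log_hazard_effect,
            subgroup_log_hazard = subgroup_log_hazard,
            baseline_hazard = baseline_hazard, censoring_rate = censoring_rate,
            age_mean = age_mean, age_sd = age_sd, age_shift = age_shift,
            missing_frac = missing_frac, male_frac = male_frac, pam50 = pam50)
  stopifnot(abs(sum(p$subgroup_props) - 1) < 1e-8,
            all(p$subgroup_props > 0),
            length(p$age_shift) == length(p$subgroup_props),
            p$coupling_noise_sd > 0, p$age_sd > 0, p$baseline_hazard > 0,
            p$censoring_rate >= 0, p$censoring_rate < 1,
            p$missing_frac >= 0, p$missing_frac < 1,
            p$frac_informative >= 0, p$frac_informative <= 1)
  if (p$n_cnacor + p$n_metcor > p$n_genes["mrna"] ||
      p$n_cnacor > p$n_genes["cna"] ||
      p$n_cnacor + p$n_metcor > p$n_genes["met"] ||
      p$n_prognostic > p$n_genes["mrna"])
    stop("planted gene sets exceed the gene universe")
  structure(p, class = "SimulationParams")
}

#' Named simulation presets
#'
#' `"default"` is the standard planted world of [simulation_params()].
#' `"null"` zeroes every planted effect (no subgroup structure, no coupling,
#' no prognostic signal, no missingness) — the global null used for type-I
#' checks. `"integration-gain"` spreads the subgroup signal thinly across
#' the three layers so that each single omics clusters weakly while the
#' fused clustering recovers the planted labels.
#'
#' @param preset one of `"default"`, `"null"`, `"integration-gain"`.
#' @param ... overrides forwarded to [simulation_params()].
#' @return a `SimulationParams`.
#' @export
preset_params <- function(preset = c("default", "null", "integration-gain"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    "default" = list(),
    "null" = list(subgroup_effect = 0, n_cnacor = 0, n_metcor = 0,
                  n_prognostic = 0, subgroup_log_hazard = 0,
                  age_shift = c(0, 0), missing_frac = 0, male_frac = 0),
    # thinner per-layer signal than the default world: each single layer
    # clusters imperfectly (ARI typically < 0.9) while the fused
    # connectivity, pooling three layers with independent errors, recovers
    # the planted split
    "integration-gain" = list(frac_informative = 0.10, subgroup_effect = 1.25,
                              missing_frac = 0, male_frac = 0))
  args <- utils::modifyList(base, list(...))
  do.call(simulation_params, args)
}

#' Generate a synthetic matched three-omics cohort with ground truth
#'
#' Draws CNA and MET values as standard normals per gene; plants linear
#' mRNA coupling for the CNAcor (positive) and METcor (negative) gene sets;
#' adds a subgroup mean shift to the informative features of each layer;
#' draws exponential survival times whose log hazard is the sum of
#' `log_hazard_effect` times the standardized planted prognostic gene values
#' plus the subgroup main effect; applies independent exponential censoring
#' calibrated to the target censoring rate; draws subgroup-shifted ages;
#' masks missing cells; and flags a male fraction.
#'
#' @param params a `SimulationParams`.
#' @param seed integer seed governing all randomness of the draw.
#' @return list with `mrna`, `cna`, `met` (`OmicsMatrix`, possibly with
#'   missing cells), `clinical` (`ClinicalTable`), and `truth`: planted
#'   per-sample subgroup labels, the planted gene sets
#'   (`cnacor_genes`, `metcor_genes`, `prognostic_genes`, and the
#'   per-layer `informative_genes`), and the realized effect sizes.
#' @export
generate_cohort <- function(params = simulation_params(), seed = 1) {
  stopifnot(inherits(params, "SimulationParams"))
  set.seed(seed)
  p <- params
  n <- p$n_samples
  k <- length(p$subgroup_props)
  sizes <- .apportion(n, p$subgroup_props)
  subgroup <- rep(seq_len(k), sizes)
  samples <- sprintf("S%04d", seq_len(n))
  gmr <- sprintf("G%04d", seq_len(p$n_genes["mrna"]))
  gcn <- sprintf("G%04d", seq_len(p$n_genes["cna"]))
  gmt <- sprintf("G%04d", seq_len(p$n_genes["met"]))
  # base layers
  cna <- matrix(stats::rnorm(p$n_genes["cna"] * n), ncol = n,
                dimnames = list(gcn, samples))
  met <- matrix(stats::rnorm(p$n_genes["met"] * n), ncol = n,
                dimnames = list(gmt, samples))
  mrna <- matrix(stats::rnorm(p$n_genes["mrna"] * n), ncol = n,
                 dimnames = list(gmr, samples))
  # planted coupled genes: CNAcor first, METcor next (disjoint by design)
  cnacor <- if (p$n_cnacor) gmr[seq_len(p$n_cnacor)] else character()
  metcor <- if (p$n_metcor) gmr[p$n_cnacor + seq_len(p$n_metcor)] else character()
  if (length(cnacor))
    mrna[cnacor, ] <- p$coupling_slope * cna[cnacor, ] +
      matrix(stats::rnorm(length(cnacor) * n, sd = p$coupling_noise_sd),
             ncol = n)
  if (length(metcor))
    mrna[metcor, ] <- -p$coupling_slope * met[metcor, ] +
      matrix(stats::rnorm(length(metcor) * n, sd = p$coupling_noise_sd),
             ncol = n)
  # subgroup-informative features per layer (random draw within each layer)
  informative <- list()
  layers <- list(mrna = mrna, cna = cna, met = met)
  for (nm in names(layers)) {
    ninf <- round(p$frac_informative * nrow(layers[[nm]]))
    genes_inf <- if (ninf) sample(rownames(layers[[nm]]), ninf) else character()
    informative[[nm]] <- genes_inf
    if (length(genes_inf) && p$subgroup_effect != 0) {
      shift <- p$subgroup_effect * (subgroup - 1) / max(1, k - 1)
      layers[[nm]][genes_inf, ] <- layers[[nm]][genes_inf, ] +
        matrix(shift, nrow = length(genes_inf), ncol = n, byrow = TRUE)
    }
  }
  mrna <- layers$mrna; cna <- layers$cna; met <- layers$met
  # survival: exponential hazards, Cox correctly specified
  prognostic <- if (p$n_prognostic) sample(gmr, p$n_prognostic) else character()
  lp <- rep(0, n)
  if (length(prognostic)) {
    zs <- scale(t(mrna[prognostic, , drop = FALSE]))
    lp <- lp + as.vector(zs %*% rep(p$log_hazard_effect, length(prognostic)))
  }
  lp <- lp + p$subgroup_log_hazard * (subgroup - 1) / max(1, k - 1)
  rate <- p$baseline_hazard * exp(lp)
  t_event <- stats::rexp(n, rate)
  if (p$censoring_rate > 0) {
    # calibrate the censoring hazard so the expected censored fraction hits
    # the target under the realized (heterogeneous) event hazards:
    # E[P(censor)] = mean(c / (c + rate)) = censoring_rate
    f <- function(lc) mean(exp(lc) / (exp(lc) + rate)) - p$censoring_rate
    lc <- stats::uniroot(f, c(log(min(rate)) - 20, log(max(rate)) + 20))$root
    t_cens <- stats::rexp(n, exp(lc))
  } else {
    t_cens <- rep(Inf, n)
  }
  os_time <- pmin(t_event, t_cens)
  os_event <- t_event <= t_cens
  age <- stats::rnorm(n, p$age_mean + p$age_shift[subgroup], p$age_sd)
  gender <- rep("female", n)
  if (p$male_frac > 0)
    gender[sample(n, round(p$male_frac * n))] <- "male"
  pam50 <- rep(NA_character_, n)
  if (isTRUE(p$pam50) && k >= 2) {
    # subgroup-dependent intrinsic-subtype composition: the majority
    # subgroup LumA-dominant, the minority LumB-dominant
    classes <- c("LumA", "LumB", "Basal", "HER2", "Normal")
    comp <- rbind(c(0.42, 0.22, 0.21, 0.13, 0.02),
                  c(0.27, 0.43, 0.08, 0.22, 0.00))
    for (i in seq_len(n))
      pam50[i] <- sample(classes, 1, prob = comp[min(subgroup[i], 2), ])
  }
  clinical <- clinical_table(samples, os_time, os_event, age, gender, pam50)
  # mask missing cells
  if (p$missing_frac > 0) {
    for (nm in c("mrna", "cna", "met")) {
      mat <- get(nm)
      idx <- sample(length(mat), round(p$missing_frac * length(mat)))
      mat[idx] <- NA_real_
      assign(nm, mat)
    }
  }
  truth <- list(labels = stats::setNames(subgroup, samples),
                cnacor_genes = cnacor, metcor_genes = metcor,
                prognostic_genes = prognostic,
                informative_genes = informative,
                effects = list(
                  coupling_r = p$coupling_slope /
                    sqrt(p$coupling_slope^2 + p$coupling_noise_sd^2),
                  subgroup_effect = p$subgroup_effect,
                  log_hazard_effect = p$log_hazard_effect,
                  subgroup_log_hazard = p$subgroup_log_hazard))
  list(mrna = omics_matrix(mrna, "mRNA"),
       cna = omics_matrix(cna, "CNA"),
       met = omics_matrix(met, "MET"),
       clinical = clinical, truth = truth, params = p, seed = seed)
}

# largest-remainder apportionment of n into proportions
.apportion <- function(n, props) {
  raw <- n * props
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  as.integer(sizes)
}

#' Write a synthetic cohort to disk
#'
#' Emits the cBioPortal-style dialect read by [read_omics_matrix()] /
#' [read_clinical()] plus a `truth.json`; a write/read round-trip is
#' value-identical and two runs from the same generated object are
#' byte-identical.
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created if absent).
#' @return named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(mrna = file.path(dir, "mrna.tsv"),
             cna = file.path(dir, "cna.tsv"),
             met = file.path(dir, "met.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             truth = file.path(dir, "truth.json"))
  write_omics_matrix(cohort$mrna, paths["mrna"])
  write_omics_matrix(cohort$cna, paths["cna"])
  write_omics_matrix(cohort$met, paths["met"])
  write_clinical(cohort$clinical, paths["clinical"])
  truth <- cohort$truth
  truth$labels <- as.list(truth$labels)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
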