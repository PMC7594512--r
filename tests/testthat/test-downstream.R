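test_that("summarize_subgroups reproduces cohort means and proportions", {
  clin <- toy_clinical(6, time = c(10, 20, 30, 40, 50, 60),
                       age = c(50, 60, 70, 55, 65, 75),
                       pam50 = c("LumA", "LumA", "LumB", "LumA", "Basal",
                                 "LumB"))
  one <- summarize_subgroups(clin, rep("all", 6))
  expect_equal(one$mean_age, mean(clin$age))
  expect_equal(one$mean_survival_time, mean(clin$os_time))
  expect_equal(one$pam50_LumA, 0.5)
  two <- summarize_subgroups(clin, rep(c("a", "b"), each = 3))
  # n-weighted subgroup means reconstruct the cohort mean
  expect_equal(sum(two$n * two$mean_age) / sum(two$n), mean(clin$age),
               tolerance = 1e-9)
  expect_equal(rowSums(as.matrix(two[, grep("pam50_", names(two))])),
               c(1, 1), ignore_attr = TRUE)
  expect_error(summarize_subgroups(clin, rep("a", 5)), "align")
})

test_that("planted age shifts between subgroups are recovered", {
  co <- generate_cohort(simulation_params(n_samples = 400, n_genes = 10,
                                          n_cnacor = 2, n_metcor = 2,
                                          n_prognostic = 2, age_shift = c(0, 6),
                                          missing_frac = 0, male_frac = 0),
                        seed = 61)
  sm <- summarize_subgroups(co$clinical, co$truth$labels)
  expect_equal(sm$mean_age[2] - sm$mean_age[1], 6, tolerance = 1.5)
})

test_that("age_split_survival detects a planted age effect in one subgroup only", {
  set.seed(62)
  n <- 400
  lab <- rep(c("c1", "c2"), each = n / 2)
  age <- rnorm(n, 65, 10)
  # age raises the hazard in c1 only
  rate <- ifelse(lab == "c1" & age > 65, 0.12, 0.03)
  clin <- toy_clinical(n, time = rexp(n, rate), event = rep(TRUE, n),
                       age = age)
  res <- age_split_survival(clin, lab, age_threshold = 65)
  expect_equal(res$subgroup, c("c1", "c2"))
  expect_lt(res$p[1], 0.05)
  expect_gt(res$p[2], 0.05)
  expect_equal(res$n_nonold + res$n_old, c(200, 200))
  # a one-sided subgroup is skipped with a warning
  young <- toy_clinical(20, age = rep(40, 20))
  expect_warning(out <- age_split_survival(young, rep("only", 20)), "empty")
  expect_equal(nrow(out), 0L)
})

test_that("cna_burden counts threshold exceedances", {
  m <- toy_matrix(rbind(c(0, 0.5), c(0.2, -0.4), c(0.1, 0.31), c(0, -0.2)),
                  kind = "CNA")
  expect_equal(unname(cna_burden(m)), c(0, 0.75))
  expect_equal(unname(cna_burden(toy_matrix(matrix(0, 3, 2), kind = "CNA"))),
               c(0, 0))
  # monotone nonincreasing in the threshold, invariant to gene order
  set.seed(63)
  m2 <- toy_matrix(matrix(rnorm(200), 20, 10), kind = "CNA")
  b1 <- cna_burden(m2, 0.2); b2 <- cna_burden(m2, 0.5)
  expect_true(all(b2 <= b1))
  perm <- sample(20)
  m2p <- toy_matrix(m2$values[perm, ], genes = gene_ids(m2)[perm], kind = "CNA")
  expect_equal(cna_burden(m2p, 0.2), b1)
})

test_that("welch_t_test matches the textbook statistic and t.test", {
  x <- c(5.1, 4.8, 5.6, 5.0, 4.9)
  y <- c(4.2, 4.5, 3.9, 4.4, 4.1)
  w <- welch_t_test(x, y)
  vx <- var(x) / 5; vy <- var(y) / 5
  t_hand <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df_hand <- (vx + vy)^2 / (vx^2 / 4 + vy^2 / 4)
  expect_equal(w$t_stat, t_hand, tolerance = 1e-9)
  expect_equal(w$df, df_hand, tolerance = 1e-9)
  tt <- t.test(x, y)           # independent oracle
  expect_equal(w$t_stat, unname(tt$statistic), tolerance = 1e-9)
  expect_equal(w$p, tt$p.value, tolerance = 1e-9)
})

test_that("compare_burden separates groups at the published burden levels", {
  set.seed(64)
  burden <- c(pmin(pmax(rnorm(230, 0.11, 0.03), 0), 1),
              pmin(pmax(rnorm(62, 0.16, 0.03), 0), 1))
  lab <- rep(c("IntCl1", "IntCl2"), c(230, 62))
  res <- compare_burden(burden, lab)
  expect_lt(res$p, 0.01)
  expect_lt(res$group_means["IntCl1"], res$group_means["IntCl2"])
})

test_that("subgroup_omics_regression recovers a planted MET association", {
  set.seed(65)
  n <- 300
  lab <- rep(c("a", "b"), c(220, 80))
  met_sum <- rnorm(n, ifelse(lab == "b", 0.6, 0), 0.5)
  cna_sum <- rnorm(n, 0.12, 0.03)
  fit <- subgroup_omics_regression(lab, cna_sum, met_sum)
  met_row <- fit[fit$term == "met_summary", ]
  expect_gt(met_row$estimate, 0)
  expect_lt(met_row$p, 0.001)
  cna_row <- fit[fit$term == "cna_summary", ]
  expect_gt(cna_row$p, 0.05)
  expect_match(attr(fit, "note"), "descriptive")
  logi <- subgroup_omics_regression(lab, cna_sum, met_sum, logistic = TRUE)
  expect_gt(logi$estimate[logi$term == "met_summary"], 0)
  # a null relationship is typically flat
  null_fit <- subgroup_omics_regression(lab, rnorm(n), rnorm(n))
  expect_gt(min(null_fit$p[-1]), 0.01)
})

test_that("crosstab_pam50 yields within-subgroup percentages", {
  clin <- toy_clinical(8, pam50 = c(rep("LumA", 4), rep("LumB", 2),
                                    rep("Basal", 2)))
  tab <- crosstab_pam50(rep(c("c1", "c2"), each = 4), clin)
  expect_equal(rowSums(tab), c(c1 = 100, c2 = 100))
  expect_equal(tab["c1", "LumA"], 100)
  expect_equal(tab["c2", "LumB"], 50)
  all_lum <- toy_clinical(4, pam50 = rep("LumA", 4))
  expect_true(all(crosstab_pam50(rep(c("x", "y"), 2), all_lum)[, "LumA"] == 100))
  no_pam <- toy_clinical(4)
  expect_error(crosstab_pam50(rep("a", 4), no_pam), "no PAM50")
})
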