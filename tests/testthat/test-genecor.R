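test_that("pairwise correlation matches a brute-force two-pass computation", {
  set.seed(3)
  for (rep in 1:5) {
    x <- toy_matrix(matrix(rnorm(80), 10, 8), kind = "CNA")
    y <- toy_matrix(matrix(rnorm(80), 10, 8))
    rec <- pairwise_gene_correlation(x, y)
    for (g in rec$gene) {
      a <- x$values[g, ]; b <- y$values[g, ]
      cov_ab <- sum((a - mean(a)) * (b - mean(b))) / (length(a) - 1)
      r_brute <- cov_ab / (sd(a) * sd(b))
      expect_equal(rec$r[rec$gene == g], r_brute, tolerance = 1e-12)
      # p-value against the cor.test oracle
      expect_equal(rec$p[rec$gene == g], cor.test(a, b)$p.value,
                   tolerance = 1e-12)
    }
  }
})

test_that("toy 5-sample pair gives the closed-form Pearson value", {
  x <- toy_matrix(matrix(c(1, 2, 3, 4, 5), 1), kind = "CNA")
  y <- toy_matrix(matrix(c(2, 1, 4, 3, 6), 1))
  rec <- pairwise_gene_correlation(x, y)
  expect_equal(rec$r, 10 / sqrt(10 * 14.8), tolerance = 1e-12)
})

test_that("degenerate rows are dropped with a warning", {
  x <- toy_matrix(rbind(c(1, 2, 3, 4), c(1, 1, 1, 1), c(0, 1, 0, 1)),
                  kind = "CNA")
  y <- toy_matrix(rbind(c(2, 4, 6, 8), c(5, 6, 7, 8), c(1, 0, 1, 1)))
  expect_warning(rec <- pairwise_gene_correlation(x, y), "dropped")
  # g1 has y = 2x exactly (|r| = 1), g2 has zero variance in x
  expect_equal(rec$gene, "g3")
  expect_error(pairwise_gene_correlation(
    toy_matrix(matrix(1:2, 1), kind = "CNA"), toy_matrix(matrix(2:3, 1))),
    "3 matched samples")
})

test_that("correlation is invariant to consistent sample reordering", {
  set.seed(9)
  x <- toy_matrix(matrix(rnorm(40), 5, 8), kind = "MET")
  y <- toy_matrix(matrix(rnorm(40), 5, 8))
  perm <- sample(8)
  xp <- toy_matrix(x$values[, perm], samples = sample_ids(x)[perm], kind = "MET")
  yp <- toy_matrix(y$values[, perm], samples = sample_ids(y)[perm])
  expect_equal(pairwise_gene_correlation(x, y)$r,
               pairwise_gene_correlation(xp, yp)$r)
})

test_that("fisher_z evaluates the transform and is a monotone odd bijection", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  grid <- seq(-0.95, 0.95, by = 0.05)
  z <- fisher_z(grid)
  expect_equal(fisher_z(-grid), -z)
  expect_true(all(diff(z) > 0))
  expect_equal(tanh(z), grid)   # inverse recovers r
  expect_error(fisher_z(1), "\\|r\\| < 1")
})

test_that("skewness test calibrates on symmetric and skewed samples", {
  set.seed(11)
  sym <- skewness_test(rnorm(5000))
  expect_lt(abs(sym$skewness), 0.1)
  expect_gt(sym$p, 0.05)
  skew <- skewness_test(rchisq(5000, df = 2))
  expect_gt(skew$skewness, 0.5)
  expect_lt(skew$p, 0.001)
  # left skew gives a negative statistic
  left <- skewness_test(-rchisq(5000, df = 2))
  expect_lt(left$skewness, 0)
  expect_error(skewness_test(rnorm(8)), "at least 9")
  expect_error(skewness_test(rep(1, 20)), "zero variance")
})

test_that("g1 matches the moment-ratio definition on a fixed vector", {
  x <- c(1, 2, 2, 3, 3, 3, 4, 4, 10)
  m <- mean(x)
  g1 <- mean((x - m)^3) / mean((x - m)^2)^1.5
  expect_equal(skewness_test(x)$skewness, g1)
})

test_that("select_correlated_genes applies the alpha and sign rules", {
  rec <- data.frame(gene = c("a", "b", "c", "d"),
                    r = c(0.9, -0.8, 0.1, 0.7),
                    p = c(0.001, 0.01, 0.9, 0.04))
  expect_warning(res <- select_correlated_genes(rec), "fewer than 9")
  expect_equal(res$selected, c("a", "b", "d"))
  expect_equal(res$records$z[1], fisher_z(0.9))
  expect_true(is.na(res$records$z[3]))
  expect_warning(pos <- select_correlated_genes(rec, sign_constraint = "positive"))
  expect_equal(pos$selected, c("a", "d"))
  expect_warning(none <- select_correlated_genes(
    transform(rec, p = 1)), "fewer than 9")
  expect_length(none$selected, 0)
})

test_that("planted coupled genes are recovered and skew is directional", {
  co <- generate_cohort(simulation_params(n_samples = 200, n_genes = 200,
                                          n_cnacor = 50, n_metcor = 50,
                                          n_prognostic = 5, missing_frac = 0,
                                          male_frac = 0), seed = 21)
  res_cna <- select_correlated_genes(
    pairwise_gene_correlation(co$cna, co$mrna))
  res_met <- select_correlated_genes(
    pairwise_gene_correlation(co$met, co$mrna))
  sens_cna <- mean(co$truth$cnacor_genes %in% res_cna$selected)
  sens_met <- mean(co$truth$metcor_genes %in% res_met$selected)
  expect_gte(sens_cna, 0.9)
  expect_gte(sens_met, 0.9)
  # planted CNA coupling is positive, MET coupling negative
  rec_planted <- res_cna$records[res_cna$records$gene %in% co$truth$cnacor_genes, ]
  # subgroup shifts can attenuate a few planted couplings; all stay strong
  expect_true(all(rec_planted$r > 0.6))
  met_planted <- res_met$records[res_met$records$gene %in% co$truth$metcor_genes, ]
  expect_true(all(met_planted$r < -0.6))
  # the significant-Z distributions are far from symmetric-normal here
  expect_lt(res_cna$skew_p, 0.001)
  expect_lt(res_met$skew_p, 0.001)
})

test_that("intersect_gene_sets is an exact set intersection", {
  expect_equal(intersect_gene_sets(c("A", "B", "C"), c("B", "C", "D")),
               list(genes = c("B", "C"), count = 2L))
  expect_equal(intersect_gene_sets(c("A"), c("B"))$count, 0L)
})
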