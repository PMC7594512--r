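test_that("base_cluster recovers well-separated blobs and edge cases", {
  set.seed(31)
  blobs <- make_blobs(50, 2)
  for (method in c("kmeans", "hclust")) {
    lab <- base_cluster(blobs$x, 2, method)
    expect_equal(adjusted_rand_index(lab, blobs$labels), 1)
  }
  # k = n: every sample its own cluster
  x <- matrix(rnorm(12), 6, 2)
  expect_equal(sort(base_cluster(x, 6, "kmeans")), 1:6)
  # duplicated rows co-cluster under hclust
  dup <- rbind(blobs$x, blobs$x[1, , drop = FALSE])
  lab <- base_cluster(dup, 2, "hclust")
  expect_equal(lab[101], lab[1])
  expect_error(base_cluster(x, 7, "kmeans"), "exceeds")
})

test_that("connectivity matrices are exact and permutation-equivariant", {
  expect_equal(connectivity_from_labels(c("A", "A", "B")),
               rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1)),
               ignore_attr = TRUE)
  expect_equal(connectivity_from_labels(rep(1, 4)), matrix(1, 4, 4),
               ignore_attr = TRUE)
  set.seed(32)
  lab <- sample(3, 10, replace = TRUE)
  perm <- sample(10)
  c0 <- connectivity_from_labels(lab)
  expect_equal(connectivity_from_labels(lab[perm]), c0[perm, perm],
               ignore_attr = TRUE)
})

test_that("perturb is seeded, calibrated and identity in the zero limit", {
  set.seed(33)
  x <- matrix(rnorm(500 * 200), 500, 200)
  a <- perturb(x, noise_scale = 1, seed = 99)
  b <- perturb(x, noise_scale = 1, seed = 99)
  expect_identical(a, b)
  # empirical sd of the added noise matches the request within 2%
  target <- median(apply(x, 2, sd))
  expect_equal(sd(a - x), target, tolerance = 0.02)
  tiny <- perturb(x, noise_scale = 1e-12)
  expect_equal(tiny, x, tolerance = 1e-9)
  expect_error(perturb(x, noise_scale = 0), "noise_scale")
})

test_that("stability AUC is high for real structure and ranks k correctly", {
  set.seed(34)
  blobs <- make_blobs(50, 2)
  s2 <- stability_auc(blobs$x, 2, "kmeans", n_perturb = 10)
  s5 <- stability_auc(blobs$x, 5, "kmeans", n_perturb = 10)
  expect_gte(s2$auc, 0.99)
  expect_lt(s5$auc, s2$auc)
  expect_true(all(s2$auc >= 0 & s2$auc <= 1))
  # connectivity output is symmetric with unit diagonal
  expect_equal(s2$connectivity, t(s2$connectivity))
  expect_equal(diag(s2$connectivity), rep(1, 100))
  # label permutation invariance of the AUC
  set.seed(35)
  s2b <- stability_auc(blobs$x[sample(100), ], 2, "kmeans", n_perturb = 10,
                       seed = 1)
  expect_true(abs(s2b$auc - s2$auc) < 0.02)
})

test_that("the AUC summary integrates the empirical CDF of D", {
  # independent oracle: numerical integration of the step CDF
  set.seed(36)
  d <- runif(200)
  cdf <- ecdf(d)
  grid <- seq(0, 1, length.out = 20001)
  oracle <- mean(cdf(grid))
  expect_equal(omicsubtype:::.auc_cdf(d), oracle, tolerance = 1e-3)
  expect_equal(omicsubtype:::.auc_cdf(rep(0, 10)), 1)
})

test_that("select_k finds the planted cluster number and flags pure noise", {
  set.seed(37)
  blobs3 <- make_blobs(40, 3)
  tr <- select_k(blobs3$x, k_range = 2:5, n_perturb = 10, seed = 2)
  expect_equal(tr$k_star, 3)
  expect_true(tr$strong_structure)
  noise <- matrix(rnorm(80 * 10), 80, 10)
  tr0 <- select_k(noise, k_range = 2:5, n_perturb = 10, seed = 3)
  expect_false(tr0$strong_structure)
  expect_true(all(tr0$auc < 0.9))
  expect_error(select_k(noise, k_range = 2:100), "k_range")
})

test_that("seeded runs are bit-identical", {
  set.seed(38)
  x <- make_blobs(30, 2, sep = 5, d_noise = 8)$x
  a <- select_k(x, 2:4, n_perturb = 5, seed = 11)
  b <- select_k(x, 2:4, n_perturb = 5, seed = 11)
  expect_identical(a, b)
  ia <- integrate_subtype(list(x, x + 0), 2:3, n_perturb = 5, seed = 12)
  ib <- integrate_subtype(list(x, x + 0), 2:3, n_perturb = 5, seed = 12)
  expect_identical(ia, ib)
})

test_that("integrating copies of one matrix matches its single-omic partition", {
  set.seed(39)
  blobs <- make_blobs(40, 2)
  ic <- integrate_subtype(list(blobs$x, blobs$x, blobs$x), k_range = 2:4,
                          n_perturb = 8, seed = 4)
  single <- base_cluster(blobs$x, 2, "kmeans")
  expect_equal(ic$k_star, 2)
  expect_equal(adjusted_rand_index(ic$labels, single), 1)
  # fused similarity stays symmetric with unit diagonal
  expect_equal(ic$connectivity, t(ic$connectivity))
  expect_equal(diag(ic$connectivity), rep(1, 80))
  expect_error(integrate_subtype(list(blobs$x), 2:3), ">= 2 omics")
  expect_error(integrate_subtype(list(blobs$x, blobs$x[1:10, ]), 2:3),
               "aligned")
})

test_that("overlap_chi2 equals the hand chi-square on a 2x2 table", {
  labels_a <- rep(c("x", "x", "y", "y"), c(30, 10, 10, 30))
  labels_b <- rep(c("p", "q", "p", "q"), c(30, 10, 10, 30))
  res <- overlap_chi2(labels_a, labels_b)
  # hand computation: n(ad - bc)^2 / (r1 r2 c1 c2) = 80*(900-100)^2/40^4 = 20
  expect_equal(res$chi2, 20)
  expect_equal(res$df, 1)
  expect_equal(res$p, pchisq(20, 1, lower.tail = FALSE))
  # identical balanced labelings are maximally associated
  lab <- rep(c("a", "b"), each = 50)
  expect_lt(overlap_chi2(lab, lab)$p, 1e-10)
  expect_error(overlap_chi2(rep("a", 10), rep(c("x", "y"), 5)), "degenerate")
})

test_that("adjusted_rand_index behaves at its reference points", {
  lab <- rep(1:3, each = 10)
  expect_equal(adjusted_rand_index(lab, lab), 1)
  relabeled <- c("c", "a", "b")[lab]
  expect_equal(adjusted_rand_index(lab, relabeled), 1)
  # hand-checkable small case via the contingency formula
  a <- c(1, 1, 1, 2, 2, 2)
  b <- c(1, 1, 2, 2, 2, 2)
  tab <- table(a, b)
  sij <- sum(choose(tab, 2)); sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2)); ex <- sa * sb / choose(6, 2)
  expect_equal(adjusted_rand_index(a, b),
               (sij - ex) / ((sa + sb) / 2 - ex))
  set.seed(40)
  expect_lt(abs(adjusted_rand_index(sample(2, 500, TRUE),
                                    sample(2, 500, TRUE))), 0.1)
})
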