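#' Partition samples with a base clustering algorithm
#'
#' @param data numeric matrix, samples in rows, features in columns.
#' @param k number of clusters, 2 <= k <= nrow(data).
#' @param method `"kmeans"` (multi-restart Hartigan-Wong, the single-omics
#'   default) or `"hclust"` (agglomerative on Euclidean distance, the
#'   integrative default for compatibility with how the PAM50 scheme was
#'   derived).
#' @param linkage agglomeration method for `hclust` (default `"average"`).
#' @param distance optional `dist` object overriding Euclidean distance for
#'   `hclust`.
#' @param nstart number of k-means restarts (default 20, best inertia kept).
#' @return integer cluster labels, one per sample.
#' @export
base_cluster <- function(data, k, method = c("kmeans", "hclust"),
                         linkage = "average", distance = NULL, nstart = 20) {
  method <- match.arg(method)
  n <- if (is.null(distance)) nrow(data) else attr(distance, "Size")
  if (k > n) stop("k exceeds the number of samples")
  if (k < 1) stop("k must be >= 1")
  if (method == "kmeans") {
    if (k == n) return(seq_len(n))
    fit <- suppressWarnings(stats::kmeans(data, centers = k, nstart = nstart,
                                          iter.max = 50))
    unname(fit$cluster)
  } else {
    d <- if (is.null(distance)) stats::dist(data) else distance
    unname(stats::cutree(stats::hclust(d, method = linkage), k = k))
  }
}

#' Binary connectivity matrix of a partition
#'
#' Entry (i, j) is 1 when samples i and j carry the same label, else 0;
#' symmetric with unit diagonal.
#'
#' @param labels label vector.
#' @return square numeric matrix in \{0, 1\}.
#' @export
connectivity_from_labels <- function(labels) {
  if (!length(labels)) stop("empty label vector")
  outer(labels, labels, FUN = "==") * 1
}

#' Add calibrated Gaussian perturbation noise
#'
#' Adds i.i.d. Gaussian noise with standard deviation
#' `noise_scale * median(per-feature sd)`, the perturbation used to probe
#' partition stability.
#'
#' @param data samples-by-features matrix.
#' @param noise_scale positive multiplier of the median feature sd.
#' @param seed optional integer; when given, the draw is reproducible.
#' @return the perturbed matrix.
#' @export
perturb <- function(data, noise_scale = 1, seed = NULL) {
  stopifnot(noise_scale > 0)
  if (!is.null(seed)) set.seed(seed)
  sd0 <- noise_scale * stats::median(apply(data, 2L, stats::sd))
  data + matrix(stats::rnorm(length(data), sd = sd0), nrow(data), ncol(data))
}

# area under the empirical CDF of d over [0, 1]; for d in [0, 1] the integral
# of the step CDF equals 1 - mean(d)
.auc_cdf <- function(d) {
  d <- pmin(pmax(d, 0), 1)
  1 - mean(d)
}

.offdiag <- function(mat) mat[upper.tri(mat)]

#' Perturbation-stability AUC of a clustering at a given k
#'
#' Clusters the original data, clusters `n_perturb` noise-perturbed copies,
#' averages their binary connectivity matrices, and summarizes the
#' discrepancy matrix D = |C0 - mean connectivity| (off-diagonal entries) by
#' the area under its empirical CDF on \[0, 1\]. Perfect stability (every
#' perturbed partition identical to the original) gives AUC = 1.
#'
#' @inheritParams base_cluster
#' @param n_perturb number of perturbed copies (>= 2).
#' @param noise_scale see [perturb()].
#' @param seed optional integer seed for the whole computation.
#' @return list with `auc`, `labels` (original partition), `connectivity`
#'   (the perturbation-averaged matrix).
#' @export
stability_auc <- function(data, k, method = c("kmeans", "hclust"),
                          n_perturb = 50, noise_scale = 1, seed = NULL,
                          linkage = "average", nstart = 20) {
  method <- match.arg(method)
  stopifnot(n_perturb >= 2)
  if (!is.null(seed)) set.seed(seed)
  labels0 <- base_cluster(data, k, method, linkage = linkage, nstart = nstart)
  c0 <- connectivity_from_labels(labels0)
  acc <- matrix(0, nrow(data), nrow(data))
  for (b in seq_len(n_perturb)) {
    lab <- NULL
    for (try in 1:4) {   # resample a degenerate perturbed partition, max 3 retries
      lab <- tryCatch(
        base_cluster(perturb(data, noise_scale), k, method,
                     linkage = linkage, nstart = nstart),
        error = function(e) NULL)
      if (!is.null(lab) && length(unique(lab)) == k) break
    }
    if (is.null(lab)) stop("degenerate clustering persisted after 3 retries")
    acc <- acc + connectivity_from_labels(lab)
  }
  avg <- acc / n_perturb
  diag(avg) <- 1
  list(auc = .auc_cdf(abs(.offdiag(c0 - avg))), labels = labels0,
       connectivity = avg)
}

#' Select the number of clusters by stability AUC
#'
#' Runs [stability_auc()] for each k in `k_range` and picks the k with the
#' highest AUC (ties broken toward the smallest k). When no k reaches an AUC
#' of 0.9 the trace is flagged as showing no strong cluster structure; the
#' argmax is still returned.
#'
#' @inheritParams stability_auc
#' @param k_range integer vector of candidate cluster numbers (default 2:10).
#' @return list of class `KSelectionTrace`: `k_values`, `auc`, `k_star`,
#'   `labels` (partition at `k_star`), `connectivity` (at `k_star`),
#'   `strong_structure` (logical).
#' @export
select_k <- function(data, k_range = 2:10, method = c("kmeans", "hclust"),
                     n_perturb = 50, noise_scale = 1, seed = NULL,
                     linkage = "average", nstart = 20) {
  method <- match.arg(method)
  if (any(k_range < 2) || any(k_range > nrow(data) - 1))
    stop("k_range must lie within [2, samples - 1]")
  if (!is.null(seed)) set.seed(seed)
  runs <- lapply(k_range, function(k)
    stability_auc(data, k, method, n_perturb, noise_scale, seed = NULL,
                  linkage = linkage, nstart = nstart))
  auc <- vapply(runs, `[[`, numeric(1), "auc")
  best <- which.max(auc)   # which.max returns the first (smallest k) on ties
  structure(list(k_values = k_range, auc = auc, k_star = k_range[best],
                 labels = runs[[best]]$labels,
                 connectivity = runs[[best]]$connectivity,
                 strong_structure = max(auc) >= 0.9),
            class = "KSelectionTrace")
}

#' @export
print.KSelectionTrace <- function(x, ...) {
  cat(sprintf("KSelectionTrace: k* = %d (AUC = %.3f)%s\n", x$k_star,
              max(x$auc), if (x$strong_structure) "" else " [no strong structure]"))
  print(stats::setNames(round(x$auc, 3), paste0("k=", x$k_values)))
  invisible(x)
}

#' Integrated subtyping by connectivity fusion of several omics layers
#'
#' For each candidate k, clusters `n_perturb` perturbed copies of every
#' omics matrix with k-means, averages each layer's binary connectivity
#' matrices, and fuses the layers by the unweighted entrywise mean into a
#' similarity matrix S_k. The fused dissimilarity 1 - S_k is then cut at k
#' by hierarchical clustering, and the k is scored by the AUC of
#' |C(labels_k) - S_k| as in [stability_auc()]. The partition at the
#' highest-AUC k is returned.
#'
#' @param omics list of >= 2 samples-by-features matrices over the identical
#'   ordered sample set (row names are compared when present).
#' @param k_range candidate cluster numbers (default 2:10).
#' @inheritParams stability_auc
#' @return list of class `ClusteringResult`: `labels`, `k_star`, `trace`
#'   (a `KSelectionTrace`), `connectivity` (fused similarity at `k_star`).
#' @export
integrate_subtype <- function(omics, k_range = 2:10, n_perturb = 50,
                              noise_scale = 1, seed = NULL,
                              linkage = "average", nstart = 20) {
  if (length(omics) < 2) stop("integration needs >= 2 omics matrices")
  ns <- vapply(omics, nrow, integer(1))
  if (length(unique(ns)) != 1) stop("omics matrices are not sample-aligned")
  rn <- lapply(omics, rownames)
  if (!all(vapply(rn, is.null, logical(1))) &&
      !all(vapply(rn, identical, logical(1), rn[[1]])))
    stop("omics matrices are not sample-aligned (row names differ)")
  n <- ns[1]
  if (any(k_range < 2) || any(k_range > n - 1))
    stop("k_range must lie within [2, samples - 1]")
  if (!is.null(seed)) set.seed(seed)
  auc <- numeric(length(k_range))
  parts <- vector("list", length(k_range))
  fused <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    s <- matrix(0, n, n)
    for (o in omics) {
      acc <- matrix(0, n, n)
      for (b in seq_len(n_perturb)) {
        lab <- NULL
        for (try in 1:4) {
          lab <- tryCatch(
            base_cluster(perturb(o, noise_scale), k, "kmeans", nstart = nstart),
            error = function(e) NULL)
          if (!is.null(lab) && length(unique(lab)) == k) break
        }
        if (is.null(lab)) stop("degenerate clustering persisted after 3 retries")
        acc <- acc + connectivity_from_labels(lab)
      }
      s <- s + acc / n_perturb
    }
    s <- s / length(omics)
    diag(s) <- 1
    lab_k <- base_cluster(NULL, k, "hclust", linkage = linkage,
                          distance = stats::as.dist(1 - s))
    auc[i] <- .auc_cdf(abs(.offdiag(connectivity_from_labels(lab_k) - s)))
    parts[[i]] <- lab_k
    fused[[i]] <- s
  }
  best <- which.max(auc)
  trace <- structure(list(k_values = k_range, auc = auc,
                          k_star = k_range[best], labels = parts[[best]],
                          connectivity = fused[[best]],
                          strong_structure = max(auc) >= 0.9),
                     class = "KSelectionTrace")
  structure(list(labels = parts[[best]], k_star = k_range[best],
                 trace = trace, connectivity = fused[[best]]),
            class = "ClusteringResult")
}

#' @export
print.ClusteringResult <- function(x, ...) {
  cat(sprintf("ClusteringResult: k* = %d; sizes: %s\n", x$k_star,
              paste(table(x$labels), collapse = "/")))
  invisible(x)
}

#' Chi-square test of overlap between two labelings
#'
#' Pearson chi-square test of independence (no continuity correction) on the
#' contingency table of two partitions of the same samples.
#'
#' @param labels_a,labels_b label vectors of equal length, each with >= 2
#'   classes.
#' @return list with `chi2`, `df`, `p`, `table`.
#' @export
overlap_chi2 <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("labelings differ in length")
  tab <- table(labels_a, labels_b)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("degenerate contingency table (a labeling has a single class)")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, table = tab)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings; 1 for identical
#' partitions (up to renaming), about 0 for independent ones.
#'
#' @param labels_a,labels_b label vectors of equal length.
#' @return the ARI, a scalar <= 1.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("labelings differ in length")
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxind <- (sum_a + sum_b) / 2
  if (maxind == expected) return(1)
  (sum_ij - expected) / (maxind - expected)
}
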