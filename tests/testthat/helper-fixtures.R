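# small in-code fixtures shared across test files

toy_matrix <- function(values, genes = NULL, samples = NULL,
                       kind = "mRNA") {
  values <- as.matrix(values)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(values)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(values)))
  omics_matrix(values, kind = kind, gene_ids = genes, sample_ids = samples)
}

toy_clinical <- function(n, time = NULL, event = NULL, age = NULL,
                         gender = "female", pam50 = NA_character_,
                         ids = paste0("s", seq_len(n))) {
  clinical_table(
    sample_id = ids,
    os_time = if (is.null(time)) seq_len(n) else time,
    os_event = if (is.null(event)) rep(TRUE, n) else event,
    age = if (is.null(age)) rep(60, n) else age,
    gender = gender, pam50 = pam50)
}

# write a cBioPortal-style matrix file and return its path
write_toy_omics_file <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# k Gaussian blobs whose centres sit `sep` within-cluster sds apart
# (equidistant, on orthogonal axes of a signal subspace), plus pure-noise
# features so the median per-feature sd stays ~1 as in omics data
make_blobs <- function(n_per, k, sep = 10, d_noise = 20) {
  centers <- diag(k) * sep / sqrt(2)
  x <- do.call(rbind, lapply(seq_len(k), function(i)
    cbind(matrix(rnorm(n_per * k), n_per, k) +
            matrix(centers[i, ], n_per, k, byrow = TRUE),
          matrix(rnorm(n_per * d_noise), n_per, d_noise))))
  list(x = x, labels = rep(seq_len(k), each = n_per))
}

# independent logrank oracle: observed-minus-expected tabulation over event
# times, two groups
oracle_logrank <- function(time, event, group) {
  lev <- sort(unique(group))
  stopifnot(length(lev) == 2)
  o_a <- 0; e_a <- 0; v <- 0
  for (t in sort(unique(time[event]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n_a <- sum(at_risk & group == lev[1])
    d <- sum(event & time == t)
    d_a <- sum(event & time == t & group == lev[1])
    o_a <- o_a + d_a
    e_a <- e_a + d * n_a / n
    if (n > 1)
      v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  (o_a - e_a)^2 / v
}
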