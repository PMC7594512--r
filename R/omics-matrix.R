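#' Construct an OmicsMatrix
#'
#' An `OmicsMatrix` is a genes-by-samples continuous matrix tagged with the
#' omics layer it carries: mRNA expression, copy-number aberration (CNA, on a
#' log-ratio-like scale) or DNA methylation (MET, beta/M-value scale).
#' Missing values are allowed before imputation.
#'
#' @param values numeric matrix, genes in rows, samples in columns. Row and
#'   column names are taken as gene and sample identifiers unless overridden.
#' @param kind one of `"mRNA"`, `"CNA"`, `"MET"`.
#' @param gene_ids,sample_ids optional character vectors overriding dimnames.
#' @return an object of class `OmicsMatrix` with elements `values` (the named
#'   matrix) and `kind`.
#' @export
omics_matrix <- function(values, kind = c("mRNA", "CNA", "MET"),
                         gene_ids = NULL, sample_ids = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(gene_ids)) rownames(values) <- gene_ids
  if (!is.null(sample_ids)) colnames(values) <- sample_ids
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("OmicsMatrix requires gene and sample identifiers")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers in OmicsMatrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers in OmicsMatrix")
  structure(list(values = values, kind = kind), class = "OmicsMatrix")
}

#' @export
print.OmicsMatrix <- function(x, ...) {
  cat(sprintf("OmicsMatrix [%s]: %d genes x %d samples (%d missing cells)\n",
              x$kind, nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.OmicsMatrix <- function(x) dim(x$values)

#' Gene and sample identifiers of an OmicsMatrix
#' @param x an `OmicsMatrix`.
#' @return character vector of identifiers.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Subset an OmicsMatrix by genes and/or samples
#' @param x an `OmicsMatrix`.
#' @param genes,samples character vectors of identifiers to keep (order is
#'   respected); `NULL` keeps everything.
#' @return an `OmicsMatrix`.
#' @export
subset_omics <- function(x, genes = NULL, samples = NULL) {
  v <- x$values
  if (!is.null(genes)) {
    missing_genes <- setdiff(genes, rownames(v))
    if (length(missing_genes))
      stop("genes not present in matrix: ", paste(utils::head(missing_genes, 5), collapse = ", "))
    v <- v[genes, , drop = FALSE]
  }
  if (!is.null(samples)) {
    missing_samples <- setdiff(samples, colnames(v))
    if (length(missing_samples))
      stop("samples not present in matrix: ", paste(utils::head(missing_samples, 5), collapse = ", "))
    v <- v[, samples, drop = FALSE]
  }
  omics_matrix(v, kind = x$kind)
}

# missing-value tokens accepted in input files (case-insensitive)
.na_tokens <- c("", "na", "nan", "null")

#' Read a cBioPortal-style tab-delimited omics matrix
#'
#' The expected dialect has a header row whose first column is `Hugo_Symbol`,
#' an optional second column `Entrez_Gene_Id`, and one column per sample.
#' Empty cells and the tokens `NA`, `NaN`, `null` (case-insensitive) are read
#' as missing; any other non-numeric cell also becomes missing.
#'
#' @param path path to the tab-delimited file.
#' @param kind omics kind, see [omics_matrix()].
#' @param duplicates how to handle duplicated gene symbols: `"drop"` removes
#'   every copy of an ambiguous symbol (the default, mirroring removal of
#'   same-name gene pairs that cannot be disambiguated), `"keep_first"`
#'   retains the first occurrence.
#' @return an `OmicsMatrix`.
#' @export
read_omics_matrix <- function(path, kind = c("mRNA", "CNA", "MET"),
                              duplicates = c("drop", "keep_first")) {
  kind <- match.arg(kind)
  duplicates <- match.arg(duplicates)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "")
  if (ncol(raw) < 2) stop("omics file has no sample columns: ", path)
  genes <- trimws(raw[[1L]])
  data_cols <- 2L:ncol(raw)
  if (ncol(raw) >= 2 && tolower(names(raw)[2L]) %in% c("entrez_gene_id", "entrez_id"))
    data_cols <- data_cols[-1L]
  if (!length(data_cols)) stop("omics file has zero samples: ", path)
  vals <- vapply(raw[data_cols], function(col) {
    col <- trimws(col)
    col[tolower(col) %in% .na_tokens] <- NA_character_
    suppressWarnings(as.numeric(col))
  }, numeric(nrow(raw)))
  if (nrow(raw) == 1L) vals <- matrix(vals, nrow = 1L, dimnames = list(NULL, names(raw)[data_cols]))
  dup <- duplicated(genes) | duplicated(genes, fromLast = TRUE)
  if (any(dup)) {
    keep <- if (duplicates == "drop") !dup else !duplicated(genes)
    if (!any(keep)) stop("all gene symbols are duplicated in ", path)
    vals <- vals[keep, , drop = FALSE]
    genes <- genes[keep]
  }
  rownames(vals) <- genes
  omics_matrix(vals, kind = kind)
}

#' Write an OmicsMatrix in the cBioPortal-style dialect
#'
#' @param x an `OmicsMatrix`.
#' @param path output path; tab-delimited, header `Hugo_Symbol` then sample
#'   ids, missing cells written as `NA`.
#' @return `path`, invisibly.
#' @export
write_omics_matrix <- function(x, path) {
  df <- data.frame(Hugo_Symbol = gene_ids(x), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a clinical table
#'
#' One record per sample: overall-survival time in months, event status
#' (deceased = `TRUE`), age in years, gender, and an optional PAM50 intrinsic
#' subtype label.
#'
#' @param sample_id character vector, unique.
#' @param os_time numeric, months, non-negative.
#' @param os_event logical, `TRUE` for deceased.
#' @param age numeric, years.
#' @param gender character, `"female"`, `"male"` or `"unknown"`.
#' @param pam50 optional character, one of LumA/LumB/Basal/HER2/Normal, or NA.
#' @return a `data.frame` of class `ClinicalTable`.
#' @export
clinical_table <- function(sample_id, os_time, os_event, age,
                           gender = "female", pam50 = NA_character_) {
  if (anyDuplicated(sample_id)) stop("duplicate sample_id in clinical table")
  if (any(os_time < 0, na.rm = TRUE)) stop("os_time must be non-negative")
  df <- data.frame(sample_id = as.character(sample_id),
                   os_time = as.numeric(os_time),
                   os_event = as.logical(os_event),
                   age = as.numeric(age),
                   gender = as.character(gender),
                   pam50 = as.character(pam50),
                   stringsAsFactors = FALSE)
  class(df) <- c("ClinicalTable", "data.frame")
  df
}

#' Read a clinical table
#'
#' Expects tab-delimited input with columns `SAMPLE_ID`, `OS_MONTHS`,
#' `OS_STATUS`, `AGE`, `GENDER` and optionally `PAM50`. `OS_STATUS` accepts
#' `DECEASED`/`LIVING` and the cBioPortal `1:DECEASED`/`0:LIVING` codings.
#'
#' @param path path to the file.
#' @return a `ClinicalTable`.
#' @export
read_clinical <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  names(raw) <- toupper(names(raw))
  needed <- c("SAMPLE_ID", "OS_MONTHS", "OS_STATUS", "AGE", "GENDER")
  if (!all(needed %in% names(raw)))
    stop("clinical table missing columns: ",
         paste(setdiff(needed, names(raw)), collapse = ", "))
  status <- toupper(as.character(raw$OS_STATUS))
  event <- grepl("DECEASED", status) | status == "1"
  clinical_table(sample_id = raw$SAMPLE_ID,
                 os_time = suppressWarnings(as.numeric(raw$OS_MONTHS)),
                 os_event = event,
                 age = suppressWarnings(as.numeric(raw$AGE)),
                 gender = tolower(as.character(raw$GENDER)),
                 pam50 = if ("PAM50" %in% names(raw)) as.character(raw$PAM50)
                         else NA_character_)
}

#' Write a clinical table
#' @param clinical a `ClinicalTable`.
#' @param path output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  out <- data.frame(SAMPLE_ID = clinical$sample_id,
                    OS_MONTHS = clinical$os_time,
                    OS_STATUS = ifelse(clinical$os_event, "DECEASED", "LIVING"),
                    AGE = clinical$age,
                    GENDER = toupper(clinical$gender),
                    PAM50 = clinical$pam50,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
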