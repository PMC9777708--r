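#' Construct and validate a gene-by-patient count matrix
#'
#' A count matrix is a plain numeric matrix of nonnegative integer read
#' counts with genes in rows and patients in columns; row and column names
#' carry the (unique) gene and patient identifiers. All depthsurv functions
#' that consume counts expect this layout.
#'
#' @param values numeric matrix, genes x patients, nonnegative integers.
#' @param gene_ids,patient_ids optional identifier vectors overriding the
#'   dimnames of `values`.
#' @return the validated matrix with dimnames set.
#' @export
count_matrix <- function(values, gene_ids = rownames(values),
                         patient_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("counts must be a numeric matrix")
  }
  if (is.null(gene_ids)) gene_ids <- sprintf("g%04d", seq_len(nrow(values)))
  if (is.null(patient_ids)) patient_ids <- sprintf("p%04d", seq_len(ncol(values)))
  if (length(gene_ids) != nrow(values) || length(patient_ids) != ncol(values)) {
    stopf("identifier lengths do not match matrix dimensions")
  }
  if (anyDuplicated(gene_ids)) {
    stopf("duplicate gene ids: %s",
          paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  if (anyDuplicated(patient_ids)) {
    stopf("duplicate patient ids: %s",
          paste(unique(patient_ids[duplicated(patient_ids)]), collapse = ", "))
  }
  dimnames(values) <- list(as.character(gene_ids), as.character(patient_ids))
  validate_counts(values)
  values
}

validate_counts <- function(values) {
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stopf("negative or non-finite count at gene '%s', patient '%s'",
          rownames(values)[bad[1, 1]] %||% bad[1, 1],
          colnames(values)[bad[1, 2]] %||% bad[1, 2])
  }
  frac <- which(abs(values - round(values)) > 1e-8, arr.ind = TRUE)
  if (nrow(frac) > 0) {
    stopf("non-integer count at gene '%s', patient '%s'",
          rownames(values)[frac[1, 1]] %||% frac[1, 1],
          colnames(values)[frac[1, 2]] %||% frac[1, 2])
  }
  invisible(values)
}

#' Read / write count matrices
#'
#' Two on-disk dialects are supported: a TSV with the gene id in the first
#' column (`gene_id`) and one column per patient, and MatrixMarket `.mtx`
#' with `<path>.rows` / `<path>.cols` identifier sidecars.
#'
#' @param path file path. For `format = "mtx"` the sidecar paths are derived
#'   by appending `.rows` and `.cols`.
#' @param format `"tsv"`, `"mtx"`, or `"auto"` (by file extension).
#' @return `read_count_matrix` returns a validated count matrix;
#'   `write_count_matrix` returns `path` invisibly.
#' @export
read_count_matrix <- function(path, format = c("auto", "tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  }
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "tsv") {
    tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    genes <- as.character(tab[[1]])
    values <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(values) <- "double"
    count_matrix(values, gene_ids = genes, patient_ids = colnames(tab)[-1])
  } else {
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(paste0(path, ".rows"))
    patients <- readLines(paste0(path, ".cols"))
    count_matrix(m, gene_ids = genes, patient_ids = patients)
  }
}

#' @rdname read_count_matrix
#' @param counts a count matrix (see [count_matrix()]).
#' @export
write_count_matrix <- function(counts, path, format = c("auto", "tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  }
  validate_counts(counts)
  if (format == "tsv") {
    tab <- data.frame(gene_id = rownames(counts), counts,
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    writeLines(rownames(counts), paste0(path, ".rows"))
    writeLines(colnames(counts), paste0(path, ".cols"))
  }
  invisible(path)
}

#' Read / write patient survival tables
#'
#' TSV with columns `patient_id`, `time` (positive follow-up time) and
#' `status` (1 = event/death, 0 = censored).
#'
#' @param path file path.
#' @return a data.frame with columns `patient_id`, `time`, `status`.
#' @export
read_survival_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_survival(tab)
}

#' @rdname read_survival_table
#' @param survival survival data.frame.
#' @export
write_survival_table <- function(survival, path) {
  survival <- as_survival(survival)
  utils::write.table(survival, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Canonicalize and validate a survival outcome table.
as_survival <- function(x) {
  if (inherits(x, "Surv")) {
    x <- data.frame(patient_id = rownames(x) %||% seq_len(nrow(x)),
                    time = as.numeric(x[, "time"]),
                    status = as.numeric(x[, "status"]))
  }
  need <- c("time", "status")
  if (!all(need %in% names(x))) {
    stopf("survival table needs columns: %s", paste(need, collapse = ", "))
  }
  if (!("patient_id" %in% names(x))) {
    x$patient_id <- rownames(x) %||% as.character(seq_len(nrow(x)))
  }
  x <- x[, c("patient_id", "time", "status")]
  x$patient_id <- as.character(x$patient_id)
  x$time <- as.numeric(x$time)
  x$status <- as.numeric(x$status)
  if (any(!is.finite(x$time)) || any(x$time <= 0)) {
    stopf("survival times must be positive and finite")
  }
  if (!all(x$status %in% c(0, 1))) stopf("status must be 0 (censored) or 1 (event)")
  rownames(x) <- NULL
  x
}

#' Read / write clinical covariate tables
#'
#' TSV with `patient_id`, numeric `age`, and categorical `gender`, `grade`,
#' `T`, `N`, `M` (any subset of the categorical columns may be present).
#'
#' @param path file path.
#' @return data.frame with `patient_id` first; categoricals as factors.
#' @export
read_clinical_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!("patient_id" %in% names(tab))) stopf("clinical table needs 'patient_id'")
  tab$patient_id <- as.character(tab$patient_id)
  for (col in intersect(c("gender", "grade", "T", "N", "M"), names(tab))) {
    tab[[col]] <- factor(tab[[col]])
  }
  tab
}

#' @rdname read_clinical_table
#' @param clinical clinical data.frame.
#' @export
write_clinical_table <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align counts, survival and clinical tables on shared patients
#'
#' Inner join on patient ids, with the column order of `counts` as the
#' canonical order; dropped patients are reported via `message()`.
#'
#' @param counts count matrix (genes x patients).
#' @param survival survival data.frame (`patient_id`, `time`, `status`).
#' @param clinical optional clinical data.frame.
#' @return list with elements `counts`, `survival`, and (if given) `clinical`,
#'   all covering the same patients in the same order.
#' @export
align_cohort <- function(counts, survival, clinical = NULL) {
  survival <- as_survival(survival)
  ids <- colnames(counts)
  keep <- intersect(ids, survival$patient_id)
  if (!is.null(clinical)) keep <- intersect(keep, clinical$patient_id)
  if (length(keep) == 0) stopf("no shared patient ids across inputs")
  dropped <- setdiff(union(ids, survival$patient_id), keep)
  if (length(dropped) > 0) {
    message("align_cohort: dropped ", length(dropped), " patient(s): ",
            paste(utils::head(dropped, 10), collapse = ", "),
            if (length(dropped) > 10) ", ..." else "")
  }
  out <- list(
    counts = counts[, keep, drop = FALSE],
    survival = survival[match(keep, survival$patient_id), , drop = FALSE]
  )
  rownames(out$survival) <- NULL
  if (!is.null(clinical)) {
    out$clinical <- clinical[match(keep, clinical$patient_id), , drop = FALSE]
    rownames(out$clinical) <- NULL
  }
  out
}

#' Write a tidy metric table with a configuration stamp
#'
#' Writes a CSV preceded by a `# config-hash:` comment line so a result file
#' can be traced back to the configuration that produced it.
#'
#' @param samples data.frame of metric values (long format).
#' @param path output path.
#' @param config optional configuration object to hash into the header.
#' @export
write_metric_samples <- function(samples, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config-hash: %s", config_hash(config %||% samples)), con)
  utils::write.csv(samples, con, row.names = FALSE)
  invisible(path)
}
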