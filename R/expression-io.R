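#' Construct an expression dataset
#'
#' The central container: a complete numeric samples-by-genes matrix with
#' unique sample and gene identifiers, optional subtype labels covering every
#' sample, and a declared scale. Incomplete profiles (missing or non-finite
#' entries) are rejected at construction, so every downstream stage may assume
#' a dense finite matrix.
#'
#' @param values numeric matrix, samples in rows, genes in columns.
#' @param samples,genes identifier vectors; default to the dimnames.
#' @param labels optional per-sample subtype labels (character or factor,
#'   optionally named by sample id).
#' @param scale one of `"counts"`, `"tpm"`, `"log2tpm"`.
#' @return an object of class `expr_dataset` (a list with elements `values`,
#'   `samples`, `genes`, `labels`, `scale`).
#' @export
expr_dataset <- function(values, samples = rownames(values),
                         genes = colnames(values), labels = NULL,
                         scale = c("counts", "tpm", "log2tpm")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (!is.numeric(values)) abort("'values' must be numeric")
  if (anyNA(values) || !all(is.finite(values)))
    abort("expression matrix contains missing or non-finite entries; ",
          "samples with incomplete expression profiles are not accepted")
  if (is.null(samples)) samples <- sprintf("S%04d", seq_len(nrow(values)))
  if (is.null(genes)) genes <- sprintf("G%05d", seq_len(ncol(values)))
  samples <- as.character(samples); genes <- as.character(genes)
  if (length(samples) != nrow(values)) abort("'samples' length != nrow(values)")
  if (length(genes) != ncol(values)) abort("'genes' length != ncol(values)")
  if (anyDuplicated(samples))
    abort("duplicate sample identifiers: ",
          paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (anyDuplicated(genes))
    abort("duplicate gene identifiers: ",
          paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (!is.null(labels)) {
    if (!is.null(names(labels))) {
      if (!all(samples %in% names(labels)))
        abort("labels missing for samples: ",
              paste(head(setdiff(samples, names(labels)), 5), collapse = ", "))
      labels <- labels[samples]
    }
    if (length(labels) != length(samples))
      abort("labels must cover every sample (got ", length(labels),
            " labels for ", length(samples), " samples)")
    labels <- factor(as.character(labels))
  }
  rownames(values) <- samples
  colnames(values) <- genes
  structure(list(values = values, samples = samples, genes = genes,
                 labels = labels, scale = scale),
            class = "expr_dataset")
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat(sprintf("<expr_dataset> %d samples x %d genes, scale = %s\n",
              length(x$samples), length(x$genes), x$scale))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("labels:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.expr_dataset <- function(x) dim(x$values)

# strict delimited parse with per-line diagnostics; files are modest so a
# line-based reader buys exact error locations cheaply
parse_delim <- function(path, sep) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) abort("'", path, "': need a header row and at least one data row")
  cells <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(cells)
  if (any(widths != widths[1])) {
    bad <- which(widths != widths[1])[1]
    abort(sprintf("'%s': ragged row at line %d (%d fields, expected %d)",
                  path, bad, widths[bad], widths[1]))
  }
  cells
}

#' Read an expression matrix from TSV/CSV
#'
#' The file must carry one header row and one identifier column. The declared
#' `orientation` says what the file's rows are; the returned dataset is always
#' samples-by-genes. Missing cells, non-numeric cells, ragged rows, and
#' duplicate identifiers are fatal.
#'
#' @param path file path; `.csv` implies comma separation, otherwise tab.
#' @param orientation `"genes"` if file rows are genes (the common export),
#'   `"samples"` if file rows are samples. No auto-detection: a silently
#'   transposed matrix is the classic expression-pipeline bug.
#' @param labels optional path to a two-column CSV `sample,label`.
#' @param scale declared scale of the stored values.
#' @return an [expr_dataset()].
#' @export
read_expression <- function(path, orientation = c("genes", "samples"),
                            labels = NULL,
                            scale = c("tpm", "counts", "log2tpm")) {
  orientation <- match.arg(orientation)
  scale <- match.arg(scale)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  cells <- parse_delim(path, sep)
  header <- cells[[1]][-1]
  row_ids <- vapply(cells[-1], `[`, character(1), 1)
  body <- lapply(cells[-1], function(r) r[-1])
  for (i in seq_along(body)) {
    if (any(!nzchar(trimws(body[[i]]))))
      abort(sprintf("'%s': empty cell at data row %d (sample/gene '%s'); ",
                    path, i, row_ids[i]),
            "incomplete expression profiles are rejected")
  }
  num <- suppressWarnings(vapply(body, as.numeric, numeric(length(header))))
  if (anyNA(num)) {
    bad <- which(colSums(is.na(num)) > 0)[1]
    abort(sprintf("'%s': non-numeric value in data row %d ('%s')",
                  path, bad, row_ids[bad]))
  }
  num <- t(matrix(num, nrow = length(header)))  # file rows back in rows
  mat <- if (orientation == "genes") t(num) else num
  if (orientation == "genes") {
    dimnames(mat) <- list(header, row_ids)
  } else {
    dimnames(mat) <- list(row_ids, header)
  }
  lab <- if (!is.null(labels)) read_labels(labels) else NULL
  expr_dataset(mat, labels = lab, scale = scale)
}

#' Write an expression dataset to TSV/CSV
#'
#' Canonical writer: numbers are serialised with up to 17 significant digits
#' so that a write/read round trip reproduces values exactly.
#'
#' @param ds an [expr_dataset()].
#' @param path output path; `.csv` implies comma separation.
#' @param orientation row entity of the written file (default genes-in-rows).
#' @return `path`, invisibly.
#' @export
write_expression <- function(ds, path, orientation = c("genes", "samples")) {
  orientation <- match.arg(orientation)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  mat <- if (orientation == "genes") t(ds$values) else ds$values
  id_name <- if (orientation == "genes") "gene" else "sample"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(id_name, colnames(mat)), collapse = sep), con)
  for (i in seq_len(nrow(mat))) {
    writeLines(paste(c(rownames(mat)[i], format_full(mat[i, ])), collapse = sep), con)
  }
  invisible(path)
}

#' Read a sample-label table (CSV with columns sample,label)
#' @param path CSV path.
#' @return named factor of labels.
#' @export
read_labels <- function(path) {
  cells <- parse_delim(path, if (grepl("\\.tsv$", path)) "\t" else ",")
  rows <- cells[-1]
  ids <- vapply(rows, `[`, character(1), 1)
  labs <- vapply(rows, `[`, character(1), 2)
  if (anyDuplicated(ids))
    abort("duplicate sample ids in label file: ",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  stats::setNames(factor(labs), ids)
}

#' Read a gene-length table (two-column TSV: gene id, length in bases)
#' @param path TSV path.
#' @return named numeric vector of lengths.
#' @export
read_gene_lengths <- function(path) {
  cells <- parse_delim(path, "\t")
  rows <- cells[-1]
  ids <- vapply(rows, `[`, character(1), 1)
  len <- suppressWarnings(as.numeric(vapply(rows, `[`, character(1), 2)))
  if (anyNA(len)) abort("non-numeric gene length in '", path, "'")
  stats::setNames(len, ids)
}

#' Convert raw counts to Transcripts Per Million
#'
#' For sample \eqn{s} and gene \eqn{g}: \eqn{rate_{sg} = counts_{sg}/len_g},
#' \eqn{TPM_{sg} = 10^6 \, rate_{sg} / \sum_g rate_{sg}}. Every sample's TPM
#' values sum to exactly \eqn{10^6} up to floating-point tolerance, and the
#' result is invariant to rescaling any sample's counts by a constant.
#'
#' @param ds an [expr_dataset()] with `scale = "counts"`, nonnegative values.
#' @param gene_lengths numeric vector of transcript lengths in bases, named
#'   by gene id (or unnamed and aligned with `ds$genes`).
#' @return an [expr_dataset()] with `scale = "tpm"`.
#' @export
counts_to_tpm <- function(ds, gene_lengths) {
  if (!inherits(ds, "expr_dataset")) abort("'ds' must be an expr_dataset")
  if (ds$scale != "counts") abort("counts_to_tpm expects scale = 'counts', got '", ds$scale, "'")
  if (any(ds$values < 0)) abort("counts must be nonnegative")
  if (!is.null(names(gene_lengths))) {
    missing <- setdiff(ds$genes, names(gene_lengths))
    if (length(missing))
      abort("no length for genes: ", paste(head(missing, 5), collapse = ", "))
    gene_lengths <- gene_lengths[ds$genes]
  }
  if (length(gene_lengths) != length(ds$genes))
    abort("gene_lengths length != number of genes")
  if (any(!is.finite(gene_lengths)) || any(gene_lengths <= 0))
    abort("all gene lengths must be positive and finite")
  rate <- sweep(ds$values, 2, gene_lengths, `/`)
  tot <- rowSums(rate)
  if (any(tot == 0))
    abort("sample(s) with all-zero counts: ",
          paste(head(ds$samples[tot == 0], 5), collapse = ", "))
  tpm <- rate / tot * 1e6
  out <- ds
  out$values <- tpm
  out$scale <- "tpm"
  out
}

#' Preprocess TPM expression for learning
#'
#' Applies `log2(TPM + 1)` followed by per-gene standardisation. At training
#' time (`fit_stats = NULL`) the per-gene mean and standard deviation are
#' computed from the data and returned; at test time the supplied training
#' statistics are applied unchanged, so no test-set information leaks into
#' the transform. Genes with zero variance in the fitting data are centred
#' but left unscaled.
#'
#' @param ds an [expr_dataset()] with `scale = "tpm"`.
#' @param fit_stats optional statistics from a previous training-time call
#'   (element `fit_stats` of attribute, or the list itself).
#' @return an [expr_dataset()] with `scale = "log2tpm"`; the fitted
#'   statistics are attached as attribute `"fit_stats"` (list with `genes`,
#'   `mean`, `sd`).
#' @export
preprocess <- function(ds, fit_stats = NULL) {
  if (!inherits(ds, "expr_dataset")) abort("'ds' must be an expr_dataset")
  if (ds$scale != "tpm") abort("preprocess expects scale = 'tpm', got '", ds$scale, "'")
  lv <- log2(ds$values + 1)
  if (is.null(fit_stats)) {
    mu <- colMeans(lv)
    sdev <- apply(lv, 2, sd)
    fit_stats <- list(genes = ds$genes, mean = mu, sd = sdev)
  } else {
    if (!identical(fit_stats$genes, ds$genes))
      abort("fit_stats gene set does not match the dataset gene set")
  }
  scale_sd <- ifelse(fit_stats$sd > 0, fit_stats$sd, 1)  # zero-variance rule
  std <- sweep(sweep(lv, 2, fit_stats$mean, `-`), 2, scale_sd, `/`)
  out <- ds
  out$values <- std
  out$scale <- "log2tpm"
  attr(out, "fit_stats") <- fit_stats
  out
}
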