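#' Read a tab-delimited expression matrix
#'
#' Expects genes in rows: first column gene identifiers, header row of
#' sample identifiers, real-valued entries.
#'
#' @param path File path.
#' @return Numeric matrix, genes x samples, with dimnames.
#' @export
read_expression <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("expression file needs a gene-id column plus at least one sample column")
  ids <- as.character(d[[1L]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicated gene id(s): ", paste(unique(utils::head(dup, 5L)), collapse = ", "))
  m <- as.matrix(d[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(d[-1L], is.numeric, logical(1)))
    stop("non-numeric expression column(s): ",
         paste(colnames(d)[-1L][bad], collapse = ", "))
  }
  if (anyNA(m) || any(!is.finite(m)))
    stop("expression file contains missing or non-finite values")
  rownames(m) <- ids
  m
}

#' Read a tab-delimited clinical factor table
#'
#' Expects samples in rows: first column sample identifiers, remaining
#' columns clinical factor scores.
#'
#' @param path File path.
#' @return Numeric matrix, samples x factors, with dimnames.
#' @export
read_clinical <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("clinical file needs a sample-id column plus at least one factor column")
  ids <- as.character(d[[1L]])
  if (anyDuplicated(ids))
    stop("duplicated sample id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(d[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("clinical factor columns must be numeric")
  rownames(m) <- ids
  m
}

#' Write a matrix with an id column as tab-delimited text
#'
#' @param m Matrix with row names.
#' @param path Output path.
#' @param id_name Header for the identifier column.
#' @export
write_matrix_tsv <- function(m, path, id_name = "id") {
  d <- data.frame(rownames(m), m, check.names = FALSE,
                  stringsAsFactors = FALSE)
  colnames(d)[1L] <- id_name
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write the outputs of a fitted model
#'
#' Writes the retained factor scores (samples x factors), the module summary,
#' the per-gene clinical association table, the overlap-test tables and a
#' plain-text run summary into a directory.
#'
#' @param fit A fitted `"glfd"` object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_glfd_result <- function(fit, dir) {
  stopifnot(inherits(fit, "glfd"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(factors = file.path(dir, "retained_factors.tsv"),
             modules = file.path(dir, "module_summary.tsv"),
             assoc = file.path(dir, "clinical_association.tsv"),
             set_tests = file.path(dir, "overlap_set_tests.tsv"),
             factor_tests = file.path(dir, "overlap_factor_tests.tsv"),
             summary = file.path(dir, "run_summary.txt"))
  write_matrix_tsv(fit$factors, paths["factors"], "sample_id")
  mods <- data.frame(module = seq_along(fit$modules),
                     dimensionality = vapply(fit$modules, `[[`, integer(1), "dimensionality"),
                     member_count = vapply(fit$modules, `[[`, integer(1), "member_count"),
                     converged = vapply(fit$modules, `[[`, logical(1), "converged"),
                     n_iterations = vapply(fit$modules, `[[`, integer(1), "n_iterations"))
  utils::write.table(mods, paths["modules"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fit$assoc_clinical, paths["assoc"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fit$set_tests, paths["set_tests"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fit$factor_tests, paths["factor_tests"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  p <- fit$params
  lines <- c("guided latent factor discovery run summary",
             sprintf("pipeline\t%s", fit$pipeline),
             sprintf("search_mode\t%s", p$search_mode),
             sprintf("n_genes\t%d", fit$n_genes),
             sprintf("n_samples\t%d", fit$n_samples),
             sprintf("n_clinical_factors\t%d", ncol(fit$clinical$whitened)),
             sprintf("alpha\t%g", p$alpha),
             sprintf("phi\t%g", p$phi),
             sprintf("lambda_fdr\t%g", p$lambda),
             sprintf("overlap_p\t%g", p$overlap_p),
             sprintf("max_dim\t%d", as.integer(p$max_dim)),
             sprintf("min_module_genes\t%d", as.integer(p$min_module_genes)),
             sprintf("delta\t%g", fit$weighting$delta),
             sprintf("n_guided_genes\t%d", fit$n_guided),
             sprintf("n_modules\t%d", length(fit$modules)),
             sprintf("n_retained_factors\t%d", ncol(fit$factors)))
  writeLines(lines, paths["summary"])
  invisible(paths)
}

#' Run the full pipeline from files
#'
#' Reads an expression table and a clinical table, fits [glfd()], and writes
#' the result tables. A run that retains no latent factor is a successful
#' run with an empty retained-factor table.
#'
#' @param expression_file,clinical_file Tab-delimited inputs (see
#'   [read_expression()], [read_clinical()]).
#' @param out_dir Output directory.
#' @param ... Passed to [glfd()].
#' @return The fitted `"glfd"` object, invisibly.
#' @export
run_glfd_files <- function(expression_file, clinical_file, out_dir, ...) {
  expr <- read_expression(expression_file)
  clin <- read_clinical(clinical_file)
  if (!is.null(colnames(expr)) && !setequal(colnames(expr), rownames(clin)))
    stop("sample ids do not match between expression and clinical files: ",
         paste(utils::head(union(setdiff(colnames(expr), rownames(clin)),
                                 setdiff(rownames(clin), colnames(expr))), 5L),
               collapse = ", "))
  fit <- glfd(expr, clin, ...)
  message(sprintf("%d of %d genes clinically guided; %d module(s); %d factor(s) retained",
                  fit$n_guided, fit$n_genes, length(fit$modules),
                  ncol(fit$factors)))
  write_glfd_result(fit, out_dir)
  invisible(fit)
}
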