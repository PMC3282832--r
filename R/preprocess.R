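#' Standardize gene expression rows
#'
#' Centers every gene (row) to mean zero and rescales it to unit Euclidean
#' length, so that the squared projection length of a gene onto any
#' orthonormal factor basis behaves like an R-squared and its null
#' distribution is governed by an F law.
#'
#' @param x Numeric matrix, genes in rows, samples in columns. Row names are
#'   gene identifiers, column names sample identifiers.
#' @param constant_genes Policy for zero-variance rows: `"drop"` removes them
#'   with a warning listing the gene ids; `"error"` aborts.
#' @return A matrix of the same orientation with attribute
#'   `standardized = TRUE`; every row has mean 0 and Euclidean length 1.
#' @examples
#' g <- matrix(rnorm(60), 10, 6)
#' gs <- standardize_genes(g)
#' range(rowMeans(gs))          # ~0
#' range(sqrt(rowSums(gs^2)))   # ~1
#' @export
standardize_genes <- function(x, constant_genes = c("drop", "error")) {
  constant_genes <- match.arg(constant_genes)
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("expression matrix must be numeric")
  if (nrow(x) < 1L || ncol(x) < 3L)
    stop("need at least 1 gene and 3 samples")
  if (anyNA(x) || any(!is.finite(x)))
    stop("expression matrix contains missing or non-finite values")
  if (is.null(rownames(x)))
    rownames(x) <- paste0("g", seq_len(nrow(x)))
  xc <- x - rowMeans(x)
  len <- sqrt(rowSums(xc^2))
  bad <- len < .Machine$double.eps^0.5
  if (any(bad)) {
    ids <- rownames(x)[bad]
    if (constant_genes == "error")
      stop("constant (zero-variance) gene row(s): ",
           paste(utils::head(ids, 5L), collapse = ", "),
           if (length(ids) > 5L) ", ..." else "")
    warning(sprintf("dropping %d constant gene row(s): %s%s",
                    length(ids), paste(utils::head(ids, 5L), collapse = ", "),
                    if (length(ids) > 5L) ", ..." else ""))
    xc <- xc[!bad, , drop = FALSE]
    len <- len[!bad]
  }
  out <- xc / len
  attr(out, "standardized") <- TRUE
  out
}

is_standardized <- function(x) isTRUE(attr(x, "standardized"))

#' Whiten a clinical factor matrix
#'
#' Column-centers the observed clinical factor matrix B and applies the
#' whitening transformation `B Phi Lambda^(-1/2)`, where `Lambda` and `Phi`
#' are the eigenvalues and eigenvectors of `t(B) %*% B` after centering. The
#' result is an orthonormal basis spanning the same column space as the
#' centered clinical factors.
#'
#' Centering makes the F-distribution null calibration of the projection-
#' length test exact for row-standardized genes.
#'
#' @param b Numeric matrix or data frame, samples in rows, clinical factors
#'   in columns; a vector is taken as a single factor. Row names are sample
#'   identifiers.
#' @return An object of class `"clinical_basis"`: a list with `raw` (the
#'   input matrix), `whitened` (n x m orthonormal), `sample_ids`,
#'   `factor_names`.
#' @export
whiten_clinical <- function(b) {
  if (is.null(dim(b))) b <- matrix(b, ncol = 1L,
                                   dimnames = list(names(b), "clinical"))
  if (is.data.frame(b)) b <- as.matrix(b)
  if (!is.numeric(b)) stop("clinical factor matrix must be numeric")
  if (anyNA(b) || any(!is.finite(b)))
    stop("clinical factor matrix contains missing or non-finite values")
  n <- nrow(b); m <- ncol(b)
  if (m < 1L) stop("need at least one clinical factor")
  if (n <= m + 1L)
    stop(sprintf("need n > m + 1 samples for m factors (n = %d, m = %d)", n, m))
  if (is.null(colnames(b))) colnames(b) <- paste0("B", seq_len(m))
  bc <- sweep(b, 2L, colMeans(b))
  rk <- qr(bc)$rank
  if (rk < m)
    stop(sprintf("clinical factor matrix is rank deficient after centering (rank %d < %d columns)",
                 rk, m))
  eg <- eigen(crossprod(bc), symmetric = TRUE)
  bstar <- bc %*% eg$vectors %*% diag(1 / sqrt(eg$values), m, m)
  dimnames(bstar) <- dimnames(bc)
  structure(list(raw = b, whitened = bstar,
                 sample_ids = rownames(b),
                 factor_names = colnames(b)),
            class = "clinical_basis")
}

#' @export
print.clinical_basis <- function(x, ...) {
  cat(sprintf("Whitened clinical factor basis: %d samples, %d factor(s): %s\n",
              nrow(x$whitened), ncol(x$whitened),
              paste(x$factor_names, collapse = ", ")))
  invisible(x)
}

check_orthonormal <- function(basis, tol = 1e-8) {
  d <- crossprod(basis) - diag(ncol(basis))
  max(abs(d)) < tol
}

#' Projection length of a unit vector onto an orthonormal basis
#'
#' The Euclidean norm of the orthogonal projection of a unit-length gene
#' vector onto the span of an orthonormal basis,
#' `l = sqrt(g %*% basis %*% t(basis) %*% g)`. For a standardized gene it
#' lies in `[0, 1]` and its square plays the role of an R-squared.
#'
#' @param g Numeric vector of unit Euclidean length.
#' @param basis Numeric matrix with orthonormal columns, `length(g)` rows.
#' @return A scalar in `[0, 1]`.
#' @export
projection_length <- function(g, basis) {
  basis <- as.matrix(basis)
  if (length(g) != nrow(basis)) stop("dimension mismatch")
  if (abs(sqrt(sum(g^2)) - 1) > 1e-8) stop("g must have unit length")
  if (!check_orthonormal(basis)) stop("basis columns must be orthonormal")
  min(sqrt(sum(crossprod(basis, g)^2)), 1)
}

#' Residualize standardized genes against the clinical basis
#'
#' Removes from each standardized gene its projection onto the whitened
#' clinical basis: `r_i = g_i - sum_j (g_i . beta_j) beta_j`, and records the
#' per-gene clinical projection length. By Pythagoras,
#' `l_i^2 + ||r_i||^2 = 1` for every gene.
#'
#' @param expr_std Standardized expression matrix from [standardize_genes()].
#' @param clin A `"clinical_basis"` from [whiten_clinical()]; sample ids must
#'   match the expression columns (order is reconciled by id when both are
#'   named).
#' @return An object of class `"weighted_residuals"`: list with `residuals`
#'   (p x n), `projection_lengths` (per gene, in `[0,1]`), `clinical`, and
#'   empty slots for the weighting stage (`weights`, `weighted`, `delta`,
#'   `phi`, `alpha`).
#' @export
residualize <- function(expr_std, clin) {
  if (!is_standardized(expr_std))
    stop("expression must be standardized (see standardize_genes)")
  if (!inherits(clin, "clinical_basis"))
    stop("clin must be a clinical_basis from whiten_clinical()")
  sid_e <- colnames(expr_std); sid_c <- clin$sample_ids
  if (!is.null(sid_e) && !is.null(sid_c)) {
    if (!setequal(sid_e, sid_c)) {
      off <- union(setdiff(sid_e, sid_c), setdiff(sid_c, sid_e))
      stop("sample ids do not match between expression and clinical data: ",
           paste(utils::head(off, 5L), collapse = ", "))
    }
    clin$whitened <- clin$whitened[match(sid_e, sid_c), , drop = FALSE]
    clin$raw <- clin$raw[match(sid_e, sid_c), , drop = FALSE]
    clin$sample_ids <- sid_e
  } else if (ncol(expr_std) != nrow(clin$whitened)) {
    stop("expression and clinical data have different numbers of samples")
  }
  bstar <- clin$whitened
  scores <- expr_std %*% bstar                       # p x m
  res <- expr_std - tcrossprod(scores, bstar)
  attr(res, "standardized") <- NULL                  # residual rows are not unit length
  l <- pmin(sqrt(rowSums(scores^2)), 1)
  structure(list(residuals = res, projection_lengths = l,
                 clinical = clin, weights = NULL, weighted = NULL,
                 delta = NULL, phi = NULL, alpha = NULL),
            class = "weighted_residuals")
}

#' Projection-length threshold for a given significance level
#'
#' The projection length `delta` that a gene independent of an m-dimensional
#' factor basis exceeds with probability `alpha`:
#' `delta = sqrt(m * Fq / ((n - m - 1) + m * Fq))` with `Fq` the `1 - alpha`
#' quantile of `F(m, n - m - 1)`. It is the inflection point of the sigmoid
#' residual weighting and the gene-membership cutoff of the module search.
#'
#' @param alpha Per-gene significance level in (0, 1); default 0.001 accounts
#'   for the multiplicity of ~1000s of genes (expected one false positive per
#'   1000 features); use a more stringent level for larger feature counts.
#' @param m Dimension of the factor basis (>= 1).
#' @param n Number of samples; must exceed `m + 1`.
#' @return A scalar in (0, 1).
#' @export
delta_threshold <- function(alpha, m, n) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  if (n <= m + 1) stop("degenerate degrees of freedom: need n > m + 1")
  fq <- stats::qf(1 - alpha, m, n - m - 1)
  sqrt(m * fq / ((n - m - 1) + m * fq))
}

#' Sigmoid residual weights from projection lengths
#'
#' `w_i = 1 - 1 / (1 + exp(phi * (l_i - delta)))`, a steep sigmoid centered
#' at `delta`. With large `phi` (default 100 in the pipeline) it approaches a
#' step function: genes significantly associated with the factors keep their
#' residual nearly intact, others are near-zeroed. Computed via
#' `stats::plogis` so extreme arguments saturate to 0/1 without overflow.
#'
#' @param lengths Numeric vector of projection lengths.
#' @param phi Steepness, > 0.
#' @param delta Inflection point in (0, 1), from [delta_threshold()].
#' @return Numeric vector of weights in (0, 1).
#' @export
sigmoid_weights <- function(lengths, phi, delta) {
  stopifnot(phi > 0, delta > 0, delta < 1)
  stats::plogis(phi * (lengths - delta))
}

#' Weight residuals by clinical association strength
#'
#' Fills the weighting stage of a [residualize()] result: each residual row
#' is multiplied by the sigmoid weight of its clinical projection length, so
#' that the subsequent module search draws almost exclusively on genes
#' significantly associated with the clinical factors.
#'
#' @param wr A `"weighted_residuals"` object.
#' @param alpha Per-gene significance level used to set the sigmoid midpoint.
#' @param phi Sigmoid steepness.
#' @return The input with `weights`, `weighted`, `delta`, `phi`, `alpha`
#'   populated.
#' @export
weight_residuals <- function(wr, alpha = 0.001, phi = 100) {
  stopifnot(inherits(wr, "weighted_residuals"))
  n <- ncol(wr$residuals)
  m <- ncol(wr$clinical$whitened)
  delta <- delta_threshold(alpha, m, n)
  w <- sigmoid_weights(wr$projection_lengths, phi, delta)
  wr$weights <- w
  wr$weighted <- wr$residuals * w
  wr$delta <- delta
  wr$phi <- phi
  wr$alpha <- alpha
  wr
}
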