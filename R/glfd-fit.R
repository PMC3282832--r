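#' Guided Latent Factor Discovery
#'
#' Finds latent (unobserved) per-sample factors that act in combination with
#' observed clinical factors to regulate gene modules. The guided pipeline
#' proceeds in three steps: (1) standardize genes, whiten the clinical
#' factors, residualize every gene against them and weight each residual by
#' a steep sigmoid of the gene's clinical projection length, so that only
#' genes significantly associated with the clinical outcome drive the
#' search; (2) extract latent modules from the scaled weighted residual
#' matrix by an EM-like subspace search over candidate dimensionalities
#' 1..K; (3) on the original expression matrix, retain only factors whose
#' associated genes overlap significantly (conservative, FDR-deflated
#' hypergeometric test) with the genes associated with the clinical factors.
#'
#' The `"direct"` pipeline variant skips the residualization and weighting:
#' it runs the module search on the standardized expression itself, then
#' forces every found factor to be orthogonal to the clinical basis before
#' the same selection step. It is provided for comparison; the guided
#' variant is the method proper.
#'
#' @param x Numeric expression matrix, genes in rows, samples in columns
#'   (row names gene ids, column names sample ids).
#' @param clinical Numeric matrix, data frame or vector of observed clinical
#'   factor scores, samples in rows (row names sample ids; reconciled to the
#'   expression columns by id when both are named).
#' @param alpha Per-gene significance level for the sigmoid residual
#'   weighting (default 0.001; expected one false call per 1000 genes).
#' @param phi Sigmoid steepness (default 100; near step function).
#' @param lambda FDR cutoff for calling associated genes in the selection
#'   step (default 0.1).
#' @param overlap_p Significance cutoff for the overlap test (default 0.01).
#' @param max_dim Maximum module dimensionality K (default 10).
#' @param min_module_genes Minimum member-gene count for a module to be kept
#'   and extraction to continue (default 10).
#' @param search_mode `"exhaustive"` or `"sequential"` dimensionality search.
#' @param pipeline `"guided"` (the default three-step method) or `"direct"`
#'   (module search on the raw standardized matrix, factors orthogonalized
#'   to the clinical basis afterwards).
#' @param alpha_module Per-gene significance level for membership inside the
#'   module search (defaults to `alpha`).
#' @param max_iter,tol EM iteration cap and subspace convergence tolerance.
#' @param constant_genes Policy for zero-variance genes (see
#'   [standardize_genes()]).
#' @return An object of class `"glfd"`; see Details. Key components:
#'   `factors` (n x q matrix of retained latent factor scores, columns
#'   "M<module>.F<factor>"), `retained` (their provenance and overlap
#'   p-values), `modules` (all candidate modules), `set_tests` /
#'   `factor_tests` (overlap-test tables), `assoc_clinical` (per-gene
#'   clinical association), `n_guided` (genes whose clinical projection
#'   length exceeds the sigmoid midpoint), `clinical` (the whitened basis),
#'   and `params`.
#' @seealso [simulate_glfd_data()] for the benchmark generator,
#'   [associated_genes()], [hypergeometric_overlap()].
#' @examples
#' sim <- simulate_glfd_data(n_genes = 400, n_samples = 60, module_size = 60,
#'                           n_coreg_latent = 1, background_dims = c(2, 3),
#'                           n_noise_genes = 220, snr = 2, seed = 1)
#' fit <- glfd(sim$expr, sim$clinical)
#' fit
#' head(coef(fit))
#' @export
glfd <- function(x, clinical, alpha = 0.001, phi = 100, lambda = 0.1,
                 overlap_p = 0.01, max_dim = 10L, min_module_genes = 10L,
                 search_mode = c("exhaustive", "sequential"),
                 pipeline = c("guided", "direct"),
                 alpha_module = alpha, max_iter = 500L, tol = 1e-6,
                 constant_genes = c("drop", "error")) {
  search_mode <- match.arg(search_mode)
  pipeline <- match.arg(pipeline)
  cl <- match.call()
  expr_std <- standardize_genes(x, constant_genes = match.arg(constant_genes))
  clin <- whiten_clinical(clinical)
  control <- mlsa_control(max_dim = max_dim,
                          min_module_genes = min_module_genes,
                          alpha_module = alpha_module, phi = phi,
                          max_iter = max_iter, tol = tol,
                          search_mode = search_mode)
  wr <- residualize(expr_std, clin)
  clin <- wr$clinical              # sample order reconciled to expression
  wr <- weight_residuals(wr, alpha = alpha, phi = phi)
  n_guided <- sum(wr$projection_lengths > wr$delta)
  if (pipeline == "guided") {
    modules <- if (n_guided == 0L) list() else
      extract_all_modules(scale_to_unit_max(wr), control)
  } else {
    modules <- extract_all_modules(scale_to_unit_max(expr_std), control)
    modules <- lapply(modules, orthogonalize_module, basis = clin$whitened)
    modules <- Filter(Negate(is.null), modules)
  }
  sel <- select_latent_factors(expr_std, clin, modules,
                               lambda = lambda, overlap_p = overlap_p)
  structure(c(list(call = cl, pipeline = pipeline,
                   clinical = clin, weighting = wr[c("projection_lengths",
                                                     "weights", "delta",
                                                     "phi", "alpha")],
                   n_guided = n_guided, n_genes = nrow(expr_std),
                   n_samples = ncol(expr_std), modules = modules,
                   params = list(alpha = alpha, phi = phi, lambda = lambda,
                                 overlap_p = overlap_p, max_dim = max_dim,
                                 min_module_genes = min_module_genes,
                                 alpha_module = alpha_module,
                                 search_mode = search_mode,
                                 max_iter = max_iter, tol = tol,
                                 pipeline = pipeline)),
              sel),
            class = "glfd")
}

## Project a module's factors off the clinical basis and re-orthonormalize;
## drops factors that lie (numerically) inside the clinical span.
orthogonalize_module <- function(mod, basis) {
  f <- mod$factors - basis %*% crossprod(basis, mod$factors)
  keep <- sqrt(colSums(f^2)) > 1e-8
  if (!any(keep)) return(NULL)
  f <- qr.Q(qr(f[, keep, drop = FALSE]))
  f <- fix_signs(f)
  rownames(f) <- rownames(mod$factors)
  colnames(f) <- paste0("F", seq_len(ncol(f)))
  mod$factors <- f
  mod$dimensionality <- ncol(f)
  mod
}

#' @export
print.glfd <- function(x, ...) {
  cat(sprintf("Guided latent factor discovery (%s pipeline, %s search)\n",
              x$pipeline, x$params$search_mode))
  cat(sprintf("  %d genes x %d samples; %d clinical factor(s); %d gene(s) clinically guided (l > delta = %.3f)\n",
              x$n_genes, x$n_samples, ncol(x$clinical$whitened),
              x$n_guided, x$weighting$delta))
  cat(sprintf("  %d candidate module(s); %d latent factor(s) retained",
              length(x$modules), ncol(x$factors)))
  if (ncol(x$factors) > 0)
    cat(": ", paste(colnames(x$factors), collapse = ", "), sep = "")
  cat("\n")
  invisible(x)
}

#' @export
summary.glfd <- function(object, ...) {
  structure(list(fit = object), class = "summary.glfd")
}

#' @export
print.summary.glfd <- function(x, ...) {
  fit <- x$fit
  print(fit)
  if (length(fit$modules)) {
    cat("\nCandidate modules (overlap with clinical-associated genes):\n")
    print(fit$set_tests, row.names = FALSE)
  }
  if (nrow(fit$factor_tests)) {
    cat("\nPer-factor overlap tests:\n")
    print(fit$factor_tests, row.names = FALSE)
  }
  invisible(x)
}

#' Retained latent factor scores
#'
#' @param object A fitted `"glfd"` object.
#' @param ... Unused.
#' @return Numeric matrix, samples x retained factors (possibly 0 columns).
#' @export
coef.glfd <- function(object, ...) object$factors

#' Pairwise projection plot of genes on clinical and latent factors
#'
#' Scatterplot matrix of the per-gene projections onto the whitened clinical
#' factors and the retained latent factors, highlighting genes with a large
#' projection length onto the joint subspace; off-axis point clouds indicate
#' transcriptional responses best read as combinations of observed and
#' latent components.
#'
#' @param x A fitted `"glfd"` object with at least one retained factor.
#' @param expr The expression matrix the model was fitted to.
#' @param highlight Projection-length cutoff for highlighting (default 0.4).
#' @param ... Passed to [graphics::pairs()].
#' @export
plot.glfd <- function(x, expr, highlight = 0.4, ...) {
  if (ncol(x$factors) == 0) stop("no retained latent factors to plot")
  expr_std <- standardize_genes(expr)
  basis <- cbind(x$clinical$whitened, x$factors)
  proj <- expr_std %*% basis
  l <- sqrt(rowSums(proj^2))
  graphics::pairs(proj, col = ifelse(l > highlight, "black", "grey70"),
                  pch = 20, cex = 0.5, ...)
  invisible(proj)
}
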