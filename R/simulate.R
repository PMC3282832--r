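#' Simulate a benchmark expression dataset with planted modules
#'
#' Generates an expression matrix with the structure of the method's
#' validation benchmark: one module of genes governed jointly by a single
#' clinical factor and 0-3 co-regulating latent factors, several background
#' modules each governed by a few latent factors independent of the first,
#' and a block of pure-noise genes. All factor scores are drawn i.i.d. from
#' the standard normal distribution; every gene in a module loads on all of
#' that module's factors (combinatorial regulation). Gaussian measurement
#' noise is added per gene with variance set so that the per-gene ratio of
#' signal variance to noise variance equals `snr`; pure-noise genes are
#' standard normal.
#'
#' Defaults reproduce the stated benchmark: 2000 genes x 100 samples, five
#' modules of 200 genes (background dimensionalities 2, 3, 4, 2), 1000 noise
#' genes, at signal-to-noise ratios 0.5, 1 or 2.
#'
#' @param n_genes Total number of genes (rows).
#' @param n_samples Number of samples (columns).
#' @param module_size Genes per module.
#' @param n_coreg_latent Number of latent factors co-regulating module 1
#'   with the clinical factor (0 = null configuration, 1-3 in the
#'   benchmark).
#' @param background_dims Integer vector: number of independent latent
#'   factors governing each background module.
#' @param n_noise_genes Number of pure-noise genes; the module count times
#'   `module_size` plus `n_noise_genes` must equal `n_genes`.
#' @param snr Per-gene signal-to-noise variance ratio, > 0; `Inf` gives
#'   noiseless module genes.
#' @param loadings `"normal"` draws regulation strengths i.i.d. standard
#'   normal; `"uniform"` draws magnitudes from U(0.5, 1.5) with random sign.
#' @param seed Optional integer seed for reproducibility.
#' @return A list of class `"glfd_simulation"`: `expr` (genes x samples),
#'   `clinical` (n x 1 matrix of clinical factor scores), and `truth` (a
#'   list with `clinical_scores`, `latent_scores` (n x total latent factors,
#'   columns named "M<module>.L<index>"), `latent_module` (module of each
#'   latent factor), `loadings` (per-module loading matrices),
#'   `module_membership` (per-gene module id, 0 = noise), `noise_sd`
#'   (per-gene), `snr`).
#' @export
simulate_glfd_data <- function(n_genes = 2000L, n_samples = 100L,
                               module_size = 200L, n_coreg_latent = 1L,
                               background_dims = c(2L, 3L, 4L, 2L),
                               n_noise_genes = 1000L, snr = 1,
                               loadings = c("normal", "uniform"),
                               seed = NULL) {
  loadings <- match.arg(loadings)
  stopifnot(n_coreg_latent >= 0L, n_coreg_latent <= 3L, snr > 0,
            n_samples >= 3L, module_size >= 1L)
  n_modules <- 1L + length(background_dims)
  if (n_modules * module_size + n_noise_genes != n_genes)
    stop(sprintf("inconsistent sizes: %d modules x %d genes + %d noise genes != %d genes",
                 n_modules, module_size, n_noise_genes, n_genes))
  if (!is.null(seed)) set.seed(seed)
  n <- n_samples
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  sample_ids <- sprintf("S%03d", seq_len(n))
  clinical_scores <- stats::rnorm(n)
  module_dims <- c(n_coreg_latent, background_dims)   # latent factors per module
  total_latent <- sum(module_dims)
  latent_scores <- matrix(stats::rnorm(n * total_latent), n, total_latent)
  latent_module <- rep(seq_len(n_modules), module_dims)
  colnames(latent_scores) <- unlist(lapply(seq_len(n_modules), function(j)
    if (module_dims[j] > 0) sprintf("M%d.L%d", j, seq_len(module_dims[j]))))
  rownames(latent_scores) <- sample_ids

  draw_loadings <- function(q, nf) {
    if (nf == 0L) return(matrix(numeric(0), q, 0))
    if (loadings == "normal") matrix(stats::rnorm(q * nf), q, nf)
    else matrix(stats::runif(q * nf, 0.5, 1.5) *
                  sample(c(-1, 1), q * nf, replace = TRUE), q, nf)
  }

  expr <- matrix(NA_real_, n_genes, n, dimnames = list(gene_ids, sample_ids))
  membership <- integer(n_genes)
  noise_sd <- rep(1, n_genes)
  load_list <- vector("list", n_modules)
  for (j in seq_len(n_modules)) {
    rows <- ((j - 1L) * module_size + 1L):(j * module_size)
    fac <- latent_scores[, latent_module == j, drop = FALSE]
    if (j == 1L) fac <- cbind(clinical = clinical_scores, fac)
    lmat <- draw_loadings(module_size, ncol(fac))
    colnames(lmat) <- colnames(fac)
    load_list[[j]] <- lmat
    signal <- lmat %*% t(fac)                       # module_size x n
    sd_j <- if (is.infinite(snr)) rep(0, module_size) else
      sqrt(rowSums(lmat^2) / snr)                   # factor scores have unit variance
    expr[rows, ] <- signal +
      matrix(stats::rnorm(module_size * n), module_size, n) * sd_j
    membership[rows] <- j
    noise_sd[rows] <- sd_j
  }
  noise_rows <- (n_modules * module_size + 1L):n_genes
  if (n_noise_genes > 0L)
    expr[noise_rows, ] <- matrix(stats::rnorm(n_noise_genes * n),
                                 n_noise_genes, n)
  structure(list(
    expr = expr,
    clinical = matrix(clinical_scores, n, 1L,
                      dimnames = list(sample_ids, "clinical")),
    truth = list(clinical_scores = clinical_scores,
                 latent_scores = latent_scores,
                 latent_module = latent_module,
                 loadings = load_list,
                 module_membership = membership,
                 noise_sd = noise_sd, snr = snr)),
    class = "glfd_simulation")
}

#' Simulate the null configuration (no co-regulating latent factor)
#'
#' Convenience wrapper for [simulate_glfd_data()] with `n_coreg_latent = 0`:
#' module 1 is governed by the clinical factor alone, so any latent factor
#' retained by the pipeline is a false positive.
#'
#' @inheritParams simulate_glfd_data
#' @param ... Passed on to [simulate_glfd_data()].
#' @return See [simulate_glfd_data()].
#' @export
simulate_null <- function(..., seed = NULL) {
  simulate_glfd_data(..., n_coreg_latent = 0L, seed = seed)
}

#' @export
print.glfd_simulation <- function(x, ...) {
  t <- x$truth
  cat(sprintf("Simulated expression benchmark: %d genes x %d samples, S/N = %g\n",
              nrow(x$expr), ncol(x$expr), t$snr))
  cat(sprintf("  module 1: clinical factor + %d co-regulating latent factor(s)\n",
              sum(t$latent_module == 1L)))
  cat(sprintf("  %d background module(s) with %s latent factor(s); %d pure-noise gene(s)\n",
              max(t$latent_module) - 1L,
              paste(tabulate(t$latent_module)[-1L], collapse = "/"),
              sum(t$module_membership == 0L)))
  invisible(x)
}
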