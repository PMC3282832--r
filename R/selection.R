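#' F statistic for a projection length
#'
#' For a standardized gene independent of a k-dimensional factor basis, the
#' squared projection length l^2 behaves like an R-squared, and
#' `F = (l^2 / k) * ((n - k - 1) / (1 - l^2))` follows the F(k, n - k - 1)
#' distribution. `l = 1` returns `Inf`.
#'
#' @param l Projection length(s) in `[0, 1]`; vectorized.
#' @param k Dimension of the factor basis.
#' @param n Number of samples; must exceed `k + 1`.
#' @return F statistic(s), >= 0.
#' @export
f_statistic <- function(l, k, n) {
  stopifnot(k >= 1, all(l >= 0), all(l <= 1))
  if (n <= k + 1) stop("degenerate degrees of freedom: need n > k + 1")
  l2 <- l^2
  ifelse(l2 >= 1, Inf, (l2 / k) * ((n - k - 1) / (1 - l2)))
}

#' Genes associated with a factor subspace at an FDR cutoff
#'
#' Projects every standardized gene onto an orthonormal factor basis,
#' converts projection lengths to F statistics and upper-tail p-values,
#' adjusts them to false-discovery rates (Benjamini-Hochberg step-up), and
#' flags genes significant at the cutoff `lambda`. Results depend only on
#' the span of the basis, not on any rotation of its columns.
#'
#' @param expr_std Standardized expression matrix (genes x samples).
#' @param basis Orthonormal n x k factor basis (whitened clinical factors or
#'   estimated latent factors).
#' @param lambda FDR cutoff (default 0.1).
#' @return A data frame of class `"glfd_association"` with columns
#'   `gene_id`, `projection_length`, `f_statistic`, `p_value`, `fdr`,
#'   `significant`; attribute `lambda`.
#' @export
associated_genes <- function(expr_std, basis, lambda = 0.1) {
  if (!is_standardized(expr_std))
    stop("expression must be standardized (see standardize_genes)")
  basis <- as.matrix(basis)
  if (!check_orthonormal(basis)) stop("basis columns must be orthonormal")
  n <- ncol(expr_std); k <- ncol(basis)
  l <- pmin(sqrt(rowSums((expr_std %*% basis)^2)), 1)
  fs <- f_statistic(l, k, n)
  p <- stats::pf(fs, k, n - k - 1, lower.tail = FALSE)
  fdr <- stats::p.adjust(p, method = "BH")
  out <- data.frame(gene_id = if (is.null(rownames(expr_std)))
                      paste0("g", seq_len(nrow(expr_std))) else rownames(expr_std),
                    projection_length = l, f_statistic = fs,
                    p_value = p, fdr = fdr,
                    significant = fdr <= lambda,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "lambda") <- lambda
  class(out) <- c("glfd_association", "data.frame")
  out
}

#' Conservative hypergeometric overlap test between two gene sets
#'
#' Tests whether the `r_overlap` genes shared by a set of `m1` genes
#' (associated with the clinical factors) and a set of `m2` genes
#' (associated with a latent factor set), out of `p_total` genes, exceed
#' chance. Because both sets were called at FDR `lambda`, the counts are
#' deflated before the tail sum: `m1' = ceiling(m1 (1 - lambda))`,
#' `m2' = ceiling(m2 (1 - lambda))`, `r' = floor(r (1 - lambda)^2)`, and
#' `P = sum_{l >= r'} choose(p - m1', m2' - l) choose(m1', l) / choose(p, m2')`,
#' accumulated in log space.
#'
#' @param p_total Total number of genes under study.
#' @param m1,m2 Sizes of the two associated-gene sets.
#' @param r_overlap Size of their intersection.
#' @param lambda FDR cutoff at which the sets were called (0 disables the
#'   deflation).
#' @param p_cutoff Significance cutoff on the overlap p-value (default 0.01).
#' @return A list of class `"overlap_test"` with the raw and adjusted
#'   counts, `p_value`, and `significant`.
#' @export
hypergeometric_overlap <- function(p_total, m1, m2, r_overlap,
                                   lambda = 0.1, p_cutoff = 0.01) {
  stopifnot(lambda >= 0, lambda < 1)
  if (r_overlap < 0 || r_overlap > min(m1, m2) || max(m1, m2) > p_total)
    stop("inconsistent counts: need 0 <= r <= min(m1, m2) <= p_total")
  m1a <- as.integer(ceiling(m1 * (1 - lambda)))
  m2a <- as.integer(ceiling(m2 * (1 - lambda)))
  ra <- as.integer(floor(r_overlap * (1 - lambda)^2))
  hi <- min(m1a, m2a)
  if (ra <= 0) {
    p <- 1
  } else {
    ll <- ra:hi
    logp <- lchoose(p_total - m1a, m2a - ll) + lchoose(m1a, ll) -
      lchoose(p_total, m2a)
    mx <- max(logp)
    p <- min(exp(mx + log(sum(exp(logp - mx)))), 1)
  }
  structure(list(p_total = p_total, m1 = m1, m2 = m2, r_overlap = r_overlap,
                 m1_adj = m1a, m2_adj = m2a, r_adj = ra,
                 lambda = lambda, p_value = p,
                 significant = p < p_cutoff),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("Overlap: %d of %d vs %d genes (of %d); adjusted %d of %d vs %d; p = %.4g%s\n",
              x$r_overlap, x$m1, x$m2, x$p_total, x$r_adj, x$m1_adj, x$m2_adj,
              x$p_value, if (x$significant) " *" else ""))
  invisible(x)
}

#' Retain latent factors that co-regulate genes with the clinical factors
#'
#' Works on the original standardized expression matrix. For the clinical
#' basis and every candidate latent factor set, finds the associated genes
#' at FDR `lambda`; tests each factor set's gene overlap with the clinical
#' set by the conservative hypergeometric test; and, for factor sets with a
#' significant overlap, retests each factor alone (k = 1) the same way.
#' Only factors passing both the set-level and the individual test are
#' retained.
#'
#' @param expr_std Standardized expression matrix (the original one, not the
#'   residualized one).
#' @param clin A `"clinical_basis"`.
#' @param modules List of `"latent_module"` objects from the subspace search.
#' @param lambda FDR cutoff for association (default 0.1).
#' @param overlap_p Significance cutoff for the overlap p-value (default
#'   0.01).
#' @return A list with `assoc_clinical`, `assoc_modules`, `set_tests`
#'   (data frame, one row per module), `factor_tests` (one row per factor of
#'   significant modules), `factors` (n x q matrix of retained factor
#'   scores, columns named "M<j>.F<i>"), `retained` (data frame of
#'   provenance).
#' @export
select_latent_factors <- function(expr_std, clin, modules,
                                  lambda = 0.1, overlap_p = 0.01) {
  if (!is_standardized(expr_std))
    stop("expression must be standardized (see standardize_genes)")
  p_total <- nrow(expr_std)
  ac <- associated_genes(expr_std, clin$whitened, lambda)
  set_b <- which(ac$significant)
  set_rows <- list(); factor_rows <- list()
  keep <- list(); keep_names <- character(); keep_prov <- list()
  assoc_modules <- vector("list", length(modules))
  for (j in seq_along(modules)) {
    mod <- modules[[j]]
    am <- associated_genes(expr_std, mod$factors, lambda)
    assoc_modules[[j]] <- am
    set_f <- which(am$significant)
    ov <- hypergeometric_overlap(p_total, length(set_b), length(set_f),
                                 length(intersect(set_b, set_f)),
                                 lambda, overlap_p)
    set_rows[[j]] <- data.frame(module = j, dimensionality = mod$dimensionality,
                                module_size = mod$member_count,
                                m1 = ov$m1, m2 = ov$m2, r_overlap = ov$r_overlap,
                                p_value = ov$p_value, significant = ov$significant)
    if (!ov$significant) next
    for (i in seq_len(mod$dimensionality)) {
      f1 <- mod$factors[, i, drop = FALSE]
      af <- associated_genes(expr_std, f1, lambda)
      set_f1 <- which(af$significant)
      ov1 <- hypergeometric_overlap(p_total, length(set_b), length(set_f1),
                                    length(intersect(set_b, set_f1)),
                                    lambda, overlap_p)
      factor_rows[[length(factor_rows) + 1L]] <-
        data.frame(module = j, factor = i,
                   m1 = ov1$m1, m2 = ov1$m2, r_overlap = ov1$r_overlap,
                   p_value = ov1$p_value, significant = ov1$significant)
      if (ov1$significant) {
        keep[[length(keep) + 1L]] <- f1
        keep_names <- c(keep_names, sprintf("M%d.F%d", j, i))
        keep_prov[[length(keep_prov) + 1L]] <-
          data.frame(module = j, factor = i, p_value = ov1$p_value)
      }
    }
  }
  factors <- if (length(keep)) {
    m <- do.call(cbind, keep)
    colnames(m) <- keep_names
    rownames(m) <- colnames(expr_std)
    m
  } else {
    matrix(numeric(0), nrow = ncol(expr_std), ncol = 0,
           dimnames = list(colnames(expr_std), NULL))
  }
  list(assoc_clinical = ac,
       assoc_modules = assoc_modules,
       set_tests = if (length(set_rows)) do.call(rbind, set_rows) else
         data.frame(module = integer(), dimensionality = integer(),
                    module_size = integer(), m1 = integer(), m2 = integer(),
                    r_overlap = integer(), p_value = numeric(),
                    significant = logical()),
       factor_tests = if (length(factor_rows)) do.call(rbind, factor_rows) else
         data.frame(module = integer(), factor = integer(), m1 = integer(),
                    m2 = integer(), r_overlap = integer(), p_value = numeric(),
                    significant = logical()),
       factors = factors,
       retained = if (length(keep_prov)) do.call(rbind, keep_prov) else
         data.frame(module = integer(), factor = integer(),
                    p_value = numeric()))
}
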