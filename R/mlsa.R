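#' Control parameters for the modular subspace search
#'
#' @param max_dim Maximum allowed module dimensionality K (default 10).
#' @param min_module_genes Stop extracting modules once a newly found module
#'   has fewer member genes than this (default 10).
#' @param alpha_module Per-gene significance level for the dimensionality-
#'   dependent membership threshold inside the search (default 0.001).
#' @param phi Sigmoid steepness for the EM row reweighting (default 100).
#' @param max_iter Maximum EM iterations per candidate dimensionality.
#' @param tol Convergence tolerance: the sine of the largest principal angle
#'   between successive factor subspaces.
#' @param search_mode `"exhaustive"` fits every k in 1..K and keeps the
#'   module with most member genes (ties to the smallest k); `"sequential"`
#'   grows k stepwise and stops when the module stops growing.
#' @return A list of class `"mlsa_control"`.
#' @export
mlsa_control <- function(max_dim = 10L, min_module_genes = 10L,
                         alpha_module = 0.001, phi = 100,
                         max_iter = 500L, tol = 1e-6,
                         search_mode = c("exhaustive", "sequential")) {
  search_mode <- match.arg(search_mode)
  stopifnot(max_dim >= 1L, min_module_genes >= 1L, tol > 0,
            alpha_module > 0, alpha_module < 1, phi > 0, max_iter >= 1L)
  structure(list(max_dim = as.integer(max_dim),
                 min_module_genes = as.integer(min_module_genes),
                 alpha_module = alpha_module, phi = phi,
                 max_iter = as.integer(max_iter), tol = tol,
                 search_mode = search_mode),
            class = "mlsa_control")
}

#' Scale a weighted residual matrix by its longest row
#'
#' Divides the matrix by the largest row Euclidean norm so the longest
#' weighted residual has length one. This replaces the per-row unit
#' standardization of a plain modular decomposition: rows down-weighted for
#' weak clinical association stay short and contribute little to subspace
#' finding.
#'
#' @param r Numeric matrix (genes x samples) with at least one nonzero row,
#'   or a `"weighted_residuals"` object with the weighting stage populated.
#' @return The rescaled matrix; maximum row norm exactly 1.
#' @export
scale_to_unit_max <- function(r) {
  if (inherits(r, "weighted_residuals")) {
    if (is.null(r$weighted)) stop("weighting stage not populated; call weight_residuals() first")
    r <- r$weighted
  }
  lmax <- sqrt(max(rowSums(r^2)))
  if (!is.finite(lmax) || lmax < 1e-12)
    stop("no gene passes the clinical-association weighting (all-zero matrix)")
  r / lmax
}

## Top-k right singular vectors via the n x n cross-product (n << p here),
## with deterministic sign: largest-magnitude loading positive.
top_right_singular <- function(x, k) {
  eg <- eigen(crossprod(x), symmetric = TRUE)
  v <- eg$vectors[, seq_len(k), drop = FALSE]
  fix_signs(v)
}

fix_signs <- function(v) {
  for (j in seq_len(ncol(v))) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  v
}

## sin of the largest principal angle between two orthonormal bases
subspace_gap <- function(f1, f2) {
  s <- svd(crossprod(f1, f2), nu = 0, nv = 0)$d
  sqrt(max(0, 1 - min(s)^2))
}

#' EM-like search for one latent module at fixed dimensionality
#'
#' Alternates (E) reweighting every gene by a steep sigmoid of its
#' projection length onto the current factor estimate, with midpoint at the
#' dimensionality-dependent significance threshold, and (M) re-estimating
#' the factors as the top-k right singular vectors of the row-reweighted
#' matrix, until the factor subspace is stable.
#'
#' Projection lengths -- both in the E-step and for the final module
#' membership -- are those of the scaled rows themselves, not of
#' renormalized row directions. The max-norm scaling replaces the per-row
#' unit standardization of a plain modular decomposition precisely so that
#' row length carries the clinical-association weighting into the
#' projection-length inference: a gene down-weighted in the residual step
#' has a short row, hence a short projection, and cannot reach the
#' membership threshold. For full-length rows the threshold is the exact
#' F-law cutoff; for shorter rows it is conservative.
#'
#' Final membership is assessed out of fit: each candidate gene's
#' projection length is evaluated on factors re-estimated with that gene's
#' row left out of the weighted fit. Because the subspace is chosen
#' adaptively, in-fit projections of fitted rows are biased upward -- a
#' handful of noise rows can always be concentrated into an apparent module
#' -- and the leave-one-out projection restores the nominal F-law
#' calibration of the membership test. Genuine modules are unaffected:
#' removing one of many co-regulated rows barely moves the subspace.
#'
#' @param rstar Scaled matrix from [scale_to_unit_max()] (genes x samples).
#' @param k Module dimensionality.
#' @param init Optional n x k orthonormal initialization; defaults to the
#'   first k right singular vectors of `rstar`.
#' @param control A [mlsa_control()] list.
#' @return An object of class `"latent_module"`: `factors` (n x k,
#'   orthonormal), `dimensionality`, `member_genes` (ids), `member_index`,
#'   `member_count`, `converged`, `n_iterations`, `delta_k`.
#' @export
em_module_search <- function(rstar, k, init = NULL, control = mlsa_control()) {
  n <- ncol(rstar)
  if (k > n - 2L) stop("module dimensionality too large for the sample size")
  delta_k <- delta_threshold(control$alpha_module, k, n)
  row_norms <- sqrt(rowSums(rstar^2))
  nmax <- max(row_norms)
  if (!is.finite(nmax) || nmax < 1e-12)
    stop("no gene passes the clinical-association weighting (all-zero matrix)")
  ## rows whose squared norm is < ~1e-14 of the largest cannot influence the
  ## M-step cross-product beyond double precision, nor reach the membership
  ## threshold; skip them for speed
  active <- which(row_norms > nmax * 1e-7)
  xa <- rstar[active, , drop = FALSE]
  f <- if (is.null(init)) top_right_singular(xa, k) else fix_signs(as.matrix(init))
  stopifnot(nrow(f) == n, ncol(f) == k)
  converged <- FALSE
  iter <- 0L
  while (iter < control$max_iter) {
    iter <- iter + 1L
    l <- sqrt(rowSums((xa %*% f)^2))
    w <- stats::plogis(control$phi * (l - delta_k))
    fnew <- top_right_singular(xa * w, k)
    gap <- subspace_gap(f, fnew)
    f <- fnew
    if (gap < control$tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("module search (k = %d) did not converge in %d iterations",
                    k, control$max_iter))
  ## membership: in-fit projection as screen, leave-one-out as the test
  l <- sqrt(rowSums((xa %*% f)^2))
  w <- stats::plogis(control$phi * (l - delta_k))
  cand <- which(l > delta_k)
  mw <- crossprod(xa * w)
  member_ok <- vapply(cand, function(i) {
    mi <- mw - tcrossprod(w[i]^2 * xa[i, ], xa[i, ])
    fi <- eigen(mi, symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
    sqrt(sum(crossprod(fi, xa[i, ])^2)) > delta_k
  }, logical(1))
  members <- active[cand[member_ok]]
  ids <- rownames(rstar)
  rownames(f) <- colnames(rstar)
  colnames(f) <- paste0("F", seq_len(k))
  structure(list(factors = f, dimensionality = as.integer(k),
                 member_genes = if (is.null(ids)) members else ids[members],
                 member_index = members,
                 member_count = length(members),
                 converged = converged, n_iterations = iter,
                 delta_k = delta_k),
            class = "latent_module")
}

#' @export
print.latent_module <- function(x, ...) {
  cat(sprintf("Latent module: k = %d, %d member gene(s), %s after %d iteration(s)\n",
              x$dimensionality, x$member_count,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  invisible(x)
}

#' Choose module dimensionality by exhaustive search
#'
#' Runs [em_module_search()] for every k = 1..K, each initialized from the
#' first k right singular vectors of the matrix, and returns the module with
#' the largest number of member genes; ties go to the smallest k (a longer
#' projection length is demanded of members in higher-dimensional
#' subspaces, so sizes are comparable across k).
#'
#' @inheritParams em_module_search
#' @return The winning `"latent_module"`.
#' @export
select_dimensionality <- function(rstar, control = mlsa_control()) {
  n <- ncol(rstar)
  kmax <- min(control$max_dim, n - 2L)
  row_norms <- sqrt(rowSums(rstar^2))
  active <- which(row_norms > max(row_norms) * 1e-7)
  v <- top_right_singular(rstar[active, , drop = FALSE], kmax)
  fits <- lapply(seq_len(kmax), function(k)
    em_module_search(rstar, k, init = v[, seq_len(k), drop = FALSE],
                     control = control))
  fits[[which.max(vapply(fits, `[[`, integer(1), "member_count"))]]
}

#' Choose module dimensionality by sequential (step-forward) search
#'
#' Starts at k = 1; repeatedly tries k + 1 by augmenting the current factors
#' with the leading right singular vector of the matrix residualized against
#' them, accepting the increment only when the member-gene count strictly
#' increases; stops at the first rejection or at K.
#'
#' @inheritParams em_module_search
#' @return The accepted `"latent_module"`.
#' @export
select_dimensionality_sequential <- function(rstar, control = mlsa_control()) {
  n <- ncol(rstar)
  kmax <- min(control$max_dim, n - 2L)
  current <- em_module_search(rstar, 1L, control = control)
  while (current$dimensionality < kmax) {
    f <- current$factors
    resid <- rstar - (rstar %*% f) %*% t(f)
    rn <- sqrt(rowSums(resid^2))
    if (max(rn) < 1e-12) break
    act <- which(rn > max(rn) * 1e-7)
    vnext <- top_right_singular(resid[act, , drop = FALSE], 1L)
    init <- qr.Q(qr(cbind(f, vnext)))
    init <- fix_signs(init)
    cand <- em_module_search(rstar, current$dimensionality + 1L,
                             init = init, control = control)
    if (cand$member_count > current$member_count) current <- cand else break
  }
  current
}

#' Iteratively extract all latent modules
#'
#' Finds one module (per the configured search mode), and while the module
#' has at least `min_module_genes` members, records it, replaces every row
#' of the working matrix by its residual after projection onto the module's
#' factors, and repeats. Successive modules therefore have mutually
#' orthogonal factor sets, and all inherit orthogonality to the clinical
#' basis when the input comes from the residualization step.
#'
#' @inheritParams em_module_search
#' @return A list of `"latent_module"` objects (possibly empty).
#' @export
extract_all_modules <- function(rstar, control = mlsa_control()) {
  modules <- list()
  work <- rstar
  total_k <- 0L
  n <- ncol(rstar)
  repeat {
    if (max(rowSums(work^2)) < 1e-24) break
    mod <- switch(control$search_mode,
                  exhaustive = select_dimensionality(work, control),
                  sequential = select_dimensionality_sequential(work, control))
    if (mod$member_count < control$min_module_genes) break
    modules[[length(modules) + 1L]] <- mod
    total_k <- total_k + mod$dimensionality
    if (total_k > n - 4L) break
    f <- mod$factors
    work <- work - (work %*% f) %*% t(f)
  }
  modules
}
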