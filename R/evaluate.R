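#' Recovery R-squared of a true factor
#'
#' Multiple R-squared of the ordinary least-squares regression (with
#' intercept) of a true simulated factor on the identified factors: 1 means
#' the factor's direction was fully recovered, 0 means none of it was.
#' Collinear regressors are handled by the pivoting least-squares solution.
#'
#' @param true_factor Numeric vector of length n.
#' @param found_factors Numeric matrix n x d of identified factor scores;
#'   `d = 0` (no factors found) returns 0 by convention.
#' @return A scalar in `[0, 1]`.
#' @export
recovery_r2 <- function(true_factor, found_factors) {
  if (is.null(found_factors) || NCOL(found_factors) == 0L) return(0)
  x <- cbind(1, as.matrix(found_factors))
  stopifnot(length(true_factor) == nrow(x))
  fit <- stats::lm.fit(x, true_factor)
  tss <- sum((true_factor - mean(true_factor))^2)
  if (tss == 0) return(0)
  min(max(1 - sum(fit$residuals^2) / tss, 0), 1)
}

#' Select the first k retained factors by overlap p-value
#'
#' Benchmark protocol: when the truth holds k co-regulating latent factors,
#' keep the k retained factors with the smallest per-factor overlap
#' p-values (ties broken by module then factor index); if fewer than k were
#' retained, keep them all.
#'
#' @param fit A fitted `"glfd"` object.
#' @param k_true Number of true co-regulating latent factors (>= 1).
#' @return Numeric matrix, samples x (at most `k_true`) factor scores.
#' @export
selected_factors <- function(fit, k_true) {
  stopifnot(inherits(fit, "glfd"), k_true >= 1L)
  r <- fit$retained
  if (nrow(r) == 0L) return(fit$factors)
  ord <- order(r$p_value, r$module, r$factor)
  fit$factors[, ord[seq_len(min(k_true, length(ord)))], drop = FALSE]
}

## deterministic per-replicate seeds below 2^31
replicate_seeds <- function(master_seed, n_reps) {
  set.seed(master_seed)
  sample.int(.Machine$integer.max, n_reps)
}

#' Null false-positive frequency experiment
#'
#' Repeatedly simulates the null configuration (module 1 governed by the
#' clinical factor alone), runs the full pipeline on each replicate, and
#' reports the fraction of replicates in which at least one latent factor
#' was (spuriously) retained.
#'
#' @param n_reps Number of replicates (the benchmark uses 100).
#' @param snr Signal-to-noise ratio of the simulated data.
#' @param search_mode `"exhaustive"` or `"sequential"`.
#' @param seed Master seed; per-replicate seeds are derived from it, so
#'   results do not depend on execution order.
#' @param overlap_p Overlap significance cutoff (default 0.01).
#' @param sim_args List of further arguments to [simulate_glfd_data()]
#'   (e.g. smaller sizes for quick checks).
#' @param ... Further arguments to [glfd()].
#' @return A list of class `"glfd_fpr"`: `frequency`, `n_positive`,
#'   `n_reps`, `n_retained` (per replicate), `snr`, `search_mode`.
#' @export
false_positive_experiment <- function(n_reps, snr, search_mode = "exhaustive",
                                      seed = 1L, overlap_p = 0.01,
                                      sim_args = list(), ...) {
  seeds <- replicate_seeds(seed, n_reps)
  n_ret <- vapply(seq_len(n_reps), function(i) {
    sim <- do.call(simulate_glfd_data,
                   c(list(n_coreg_latent = 0L, snr = snr, seed = seeds[i]),
                     sim_args))
    fit <- suppressWarnings(glfd(sim$expr, sim$clinical,
                                 search_mode = search_mode,
                                 overlap_p = overlap_p, ...))
    ncol(fit$factors)
  }, integer(1))
  structure(list(frequency = mean(n_ret >= 1L), n_positive = sum(n_ret >= 1L),
                 n_reps = n_reps, n_retained = n_ret, snr = snr,
                 search_mode = search_mode),
            class = "glfd_fpr")
}

#' @export
print.glfd_fpr <- function(x, ...) {
  cat(sprintf("Null false-positive frequency (%s search, S/N = %g): %d/%d = %.3f\n",
              x$search_mode, x$snr, x$n_positive, x$n_reps, x$frequency))
  invisible(x)
}

#' Factor-recovery experiment
#'
#' Repeatedly simulates data with `n_coreg_latent` true latent factors
#' co-regulating module 1 with the clinical factor, runs the pipeline,
#' selects the first `n_coreg_latent` retained factors by overlap p-value,
#' and scores each true latent factor by its recovery R-squared against the
#' selected factors. R-squared values are aggregated into 10 equal bins on
#' `[0, 1]`.
#'
#' @inheritParams false_positive_experiment
#' @param n_coreg_latent Number of true co-regulating latent factors (1-3).
#' @return A list of class `"glfd_recovery"`: `r2` (replicates x true
#'   factors), `histogram` (10 bin counts), `n_selected` (per replicate),
#'   `snr`, `search_mode`.
#' @export
recovery_experiment <- function(n_reps, snr, n_coreg_latent = 1L,
                                search_mode = "exhaustive", seed = 1L,
                                sim_args = list(), ...) {
  stopifnot(n_coreg_latent >= 1L)
  seeds <- replicate_seeds(seed, n_reps)
  r2 <- matrix(NA_real_, n_reps, n_coreg_latent)
  n_sel <- integer(n_reps)
  for (i in seq_len(n_reps)) {
    sim <- do.call(simulate_glfd_data,
                   c(list(n_coreg_latent = n_coreg_latent, snr = snr,
                          seed = seeds[i]), sim_args))
    fit <- suppressWarnings(glfd(sim$expr, sim$clinical,
                                 search_mode = search_mode, ...))
    found <- selected_factors(fit, n_coreg_latent)
    n_sel[i] <- ncol(found)
    truth <- sim$truth$latent_scores[, sim$truth$latent_module == 1L,
                                     drop = FALSE]
    r2[i, ] <- vapply(seq_len(n_coreg_latent), function(j)
      recovery_r2(truth[, j], found), numeric(1))
  }
  structure(list(r2 = r2,
                 histogram = table(cut(as.vector(r2),
                                       breaks = seq(0, 1, 0.1),
                                       include.lowest = TRUE)),
                 n_selected = n_sel, snr = snr, search_mode = search_mode),
            class = "glfd_recovery")
}

#' @export
print.glfd_recovery <- function(x, ...) {
  cat(sprintf("Factor recovery (%s search, S/N = %g, %d replicates):\n",
              x$search_mode, x$snr, nrow(x$r2)))
  cat(sprintf("  median R^2 = %.3f; mean = %.3f; share in [0.9, 1] = %.2f\n",
              stats::median(x$r2), mean(x$r2), mean(x$r2 >= 0.9)))
  invisible(x)
}
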