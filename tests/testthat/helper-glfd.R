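# shared fixtures, built in code

# random orthonormal basis of k centered columns in n-space
rand_centered_basis <- function(n, k) {
  x <- matrix(rnorm(n * k), n, k)
  x <- sweep(x, 2L, colMeans(x))
  qr.Q(qr(x))
}

# standardized random expression matrix (rows centered, unit length)
rand_std_genes <- function(p, n) {
  standardize_genes(matrix(rnorm(p * n), p, n,
                           dimnames = list(sprintf("g%03d", 1:p),
                                           sprintf("S%03d", 1:n))))
}

# planted-module matrix: n_member rows spanned by a k-dim factor set plus
# inert rows; loading rows have comparable norms (uniform 0.8-1.2 around a
# random direction) so row length does not screen members out
planted_module <- function(n = 60, k = 2, n_member = 50, n_inert = 150,
                           noise_sd = 0) {
  f <- rand_centered_basis(n, k)
  load <- matrix(rnorm(n_member * k), n_member, k)
  load <- load / sqrt(rowSums(load^2)) * runif(n_member, 0.8, 1.2)
  x <- load %*% t(f)
  if (noise_sd > 0)
    x <- x + matrix(rnorm(n_member * n, sd = noise_sd), n_member, n)
  x <- rbind(x, matrix(0, n_inert, n))
  rownames(x) <- sprintf("g%03d", seq_len(nrow(x)))
  list(rstar = scale_to_unit_max(x), factors = f)
}

# exact hypergeometric upper-tail oracle by pmf enumeration
hyper_tail_enum <- function(p, m1, m2, r) {
  if (r <= 0) return(1)
  ll <- r:min(m1, m2)
  sum(choose(p - m1, m2 - ll) * choose(m1, ll)) / choose(p, m2)
}
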