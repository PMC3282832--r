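test_that("max-norm scaling preserves relative row lengths", {
  x <- rbind(c(2, 0, 0, 0), c(0, 0, 0, 0))
  out <- scale_to_unit_max(x)
  expect_equal(sqrt(sum(out[1, ]^2)), 1)

  set.seed(10)
  y <- matrix(rnorm(50 * 8), 50, 8)
  ys <- scale_to_unit_max(y)
  expect_equal(scale_to_unit_max(ys), ys, tolerance = 1e-12)  # idempotent
  norms <- sqrt(rowSums(y^2))
  expect_equal(sqrt(rowSums(ys^2)), norms / max(norms), tolerance = 1e-12)
  expect_error(scale_to_unit_max(matrix(0, 3, 4)), "no gene passes")
})

test_that("rank-1 module search recovers the exact factor", {
  set.seed(11)
  n <- 40
  f <- rand_centered_basis(n, 1)
  x <- outer(sample(c(-1, 1), 30, TRUE) * runif(30, 0.8, 1.2), as.vector(f))
  rownames(x) <- sprintf("g%03d", 1:30)
  mod <- em_module_search(scale_to_unit_max(x), 1)
  expect_true(mod$converged)
  expect_lt(min(sum((mod$factors - f)^2), sum((mod$factors + f)^2)), 1e-16)
  expect_equal(mod$member_count, 30L)
})

test_that("noiseless 2-dim module is recovered with full span and membership", {
  set.seed(12)
  pm <- planted_module(n = 60, k = 2, n_member = 50, n_inert = 150)
  mod <- em_module_search(pm$rstar, 2)
  expect_true(mod$converged)
  # each true factor is fully explained by the recovered pair
  for (j in 1:2)
    expect_gt(recovery_r2(pm$factors[, j], mod$factors), 0.999)
  expect_equal(mod$member_count, 50L)
  expect_lt(max(abs(crossprod(mod$factors) - diag(2))), 1e-8)
})

test_that("module search on pure noise rarely reaches the module-size floor", {
  set.seed(13)
  hits <- 0L
  for (i in 1:30) {
    x <- scale_to_unit_max(matrix(rnorm(200 * 40), 200, 40))
    mod <- suppressWarnings(select_dimensionality(x, mlsa_control(max_dim = 5)))
    if (mod$member_count < 10L) hits <- hits + 1L
  }
  expect_gte(hits, 28L)
})

test_that("exhaustive dimensionality selection finds the true k and breaks ties low", {
  set.seed(14)
  pm <- planted_module(n = 60, k = 3, n_member = 60, n_inert = 100,
                       noise_sd = 0.12)  # ~ S/N 2 per row on unit loadings
  mod <- suppressWarnings(select_dimensionality(pm$rstar, mlsa_control(max_dim = 6)))
  expect_equal(mod$dimensionality, 3L)

  # rank-1 noiseless data: every k >= 1 captures all members, tie -> k = 1
  f <- rand_centered_basis(50, 1)
  x <- outer(rnorm(40), as.vector(f))
  m1 <- suppressWarnings(select_dimensionality(scale_to_unit_max(x),
                                               mlsa_control(max_dim = 4)))
  expect_equal(m1$dimensionality, 1L)

  # K = 1 degenerates to a single em run
  m2 <- select_dimensionality(pm$rstar, mlsa_control(max_dim = 1))
  m3 <- em_module_search(pm$rstar, 1, control = mlsa_control(max_dim = 1))
  expect_equal(m2$factors, m3$factors)
  expect_equal(m2$member_genes, m3$member_genes)
})

test_that("sequential search stops when the module stops growing", {
  set.seed(15)
  f <- rand_centered_basis(50, 1)
  x <- outer(rnorm(40), as.vector(f))
  m1 <- suppressWarnings(
    select_dimensionality_sequential(scale_to_unit_max(x), mlsa_control()))
  expect_equal(m1$dimensionality, 1L)

  # genuinely 2-dim module with unit-norm loadings: every gene needs both
  # factors, so k = 2 strictly grows the member set and k = 3 does not
  f2 <- rand_centered_basis(50, 2)
  ang <- runif(60, 0, 2 * pi)
  y <- cbind(cos(ang), sin(ang)) %*% t(f2)
  rownames(y) <- sprintf("g%03d", 1:60)
  m2 <- suppressWarnings(
    select_dimensionality_sequential(scale_to_unit_max(y),
                                     mlsa_control(max_dim = 5)))
  expect_equal(m2$dimensionality, 2L)
  expect_equal(m2$member_count, 60L)
})

test_that("exhaustive and sequential agree on strong single-factor data", {
  set.seed(16)
  agree <- 0L
  for (i in 1:20) {
    pm <- planted_module(n = 50, k = 1, n_member = 50, n_inert = 100,
                         noise_sd = 0.15)
    me <- suppressWarnings(select_dimensionality(pm$rstar, mlsa_control(max_dim = 4)))
    ms <- suppressWarnings(select_dimensionality_sequential(pm$rstar,
                                                            mlsa_control(max_dim = 4)))
    if (me$dimensionality == ms$dimensionality) agree <- agree + 1L
  }
  expect_gte(agree, 18L)
})

test_that("iterative extraction separates disjoint rank-1 modules and then stops", {
  set.seed(17)
  n <- 60
  fa <- rand_centered_basis(n, 1)
  fb <- rand_centered_basis(n, 1)
  fb <- fb - fa %*% crossprod(fa, fb); fb <- fb / sqrt(sum(fb^2))
  x <- standardize_genes(rbind(
    outer(rnorm(60), as.vector(fa)) + matrix(rnorm(60 * n, sd = 0.05), 60, n),
    outer(rnorm(40), as.vector(fb)) + matrix(rnorm(40 * n, sd = 0.05), 40, n),
    matrix(rnorm(80 * n), 80, n)))
  rstar <- scale_to_unit_max(x)
  mods <- suppressWarnings(extract_all_modules(rstar, mlsa_control(max_dim = 1)))
  expect_length(mods, 2L)
  expect_equal(vapply(mods, `[[`, integer(1), "dimensionality"), c(1L, 1L))
  # larger module extracted first; each recovers its own factor
  expect_gt(mods[[1]]$member_count, mods[[2]]$member_count)
  expect_gt(recovery_r2(fa, mods[[1]]$factors), 0.99)
  expect_gt(recovery_r2(fb, mods[[2]]$factors), 0.99)

  # factor sets of distinct modules are mutually orthogonal
  expect_lt(max(abs(crossprod(mods[[1]]$factors, mods[[2]]$factors))), 1e-6)

  # fixed point: the final residual matrix yields no further module
  work <- rstar
  for (m in mods) work <- work - (work %*% m$factors) %*% t(m$factors)
  expect_length(suppressWarnings(extract_all_modules(work,
                                                     mlsa_control(max_dim = 1))), 0L)

  # extraction strictly decreases the residual Frobenius norm
  work <- rstar; fro <- sum(work^2)
  for (m in mods) {
    work <- work - (work %*% m$factors) %*% t(m$factors)
    expect_lt(sum(work^2), fro)
    fro <- sum(work^2)
  }
})

test_that("when K admits a union subspace, extraction still covers both true spans", {
  set.seed(117)
  n <- 60
  fa <- rand_centered_basis(n, 2)
  fb <- qr.Q(qr(cbind(fa, rand_centered_basis(n, 3))))[, 3:5]
  anga <- runif(50, 0, 2 * pi)
  loadb <- matrix(rnorm(40 * 3), 40, 3)
  loadb <- loadb / sqrt(rowSums(loadb^2))
  x <- standardize_genes(rbind(
    cbind(cos(anga), sin(anga)) %*% t(fa) +
      matrix(rnorm(50 * n, sd = 0.05), 50, n),
    loadb %*% t(fb) + matrix(rnorm(40 * n, sd = 0.05), 40, n),
    matrix(rnorm(60 * n), 60, n)))
  mods <- suppressWarnings(extract_all_modules(scale_to_unit_max(x),
                                               mlsa_control(max_dim = 6)))
  expect_gte(length(mods), 1L)
  all_f <- do.call(cbind, lapply(mods, `[[`, "factors"))
  # member-count maximization may merge the two modules into one subspace;
  # either way every true factor must be covered by the extracted spans
  expect_lte(sum(vapply(mods, `[[`, integer(1), "dimensionality")), 6L)
  for (j in 1:2) expect_gt(recovery_r2(fa[, j], all_f), 0.98)
  for (j in 1:3) expect_gt(recovery_r2(fb[, j], all_f), 0.98)
})

test_that("extraction on pure noise usually returns nothing", {
  set.seed(18)
  empty <- 0L
  for (i in 1:20) {
    x <- scale_to_unit_max(matrix(rnorm(150 * 40), 150, 40))
    mods <- suppressWarnings(extract_all_modules(x, mlsa_control(max_dim = 4)))
    if (length(mods) == 0L) empty <- empty + 1L
  }
  expect_gte(empty, 19L)
})

test_that("module search is deterministic with canonical factor signs", {
  set.seed(19)
  pm <- planted_module(n = 40, k = 2, n_member = 30, n_inert = 70,
                       noise_sd = 0.1)
  m1 <- suppressWarnings(select_dimensionality(pm$rstar, mlsa_control(max_dim = 3)))
  m2 <- suppressWarnings(select_dimensionality(pm$rstar, mlsa_control(max_dim = 3)))
  expect_identical(m1, m2)
  # largest-magnitude loading of every factor is positive
  for (j in seq_len(ncol(m1$factors)))
    expect_gt(m1$factors[which.max(abs(m1$factors[, j])), j], 0)
})
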