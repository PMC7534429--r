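test_that("assembly reproduces covariances from variances and correlations", {
  vm <- c(a = 2, b = 0.5)
  rg <- diag(2)
  dimnames(rg) <- list(names(vm), names(vm))
  m <- assemble_m(vm, rg)
  expect_equal(m$M, diag(c(2, 0.5)), ignore_attr = TRUE)
  # correlations back-computed from the study's printed covariances land on
  # the printed off-diagonals
  vm3 <- c(diploid_growth = 6.72, sporulation = 16.10,
           haploid_growth = 7.62) * 1e-7
  cov3 <- c(8.83, 3.58, 4.45) * 1e-7  # dg-sp, dg-hg, sp-hg
  rg3 <- diag(3)
  rg3[1, 2] <- rg3[2, 1] <- cov3[1] / sqrt(vm3[1] * vm3[2])
  rg3[1, 3] <- rg3[3, 1] <- cov3[2] / sqrt(vm3[1] * vm3[3])
  rg3[2, 3] <- rg3[3, 2] <- cov3[3] / sqrt(vm3[2] * vm3[3])
  dimnames(rg3) <- list(names(vm3), names(vm3))
  m3 <- assemble_m(vm3, rg3)
  expect_equal(m3$M[1, 2], 8.83e-7, tolerance = 1e-12)
  expect_equal(m3$M[1, 3], 3.58e-7, tolerance = 1e-12)
  expect_equal(m3$M[2, 3], 4.45e-7, tolerance = 1e-12)
  expect_error(assemble_m(c(a = -1, b = 1), diag(2)), "negative")
})

test_that("assembled matrices from proper correlation matrices are PSD", {
  set.seed(61)
  for (i in 1:10) {
    k <- sample(3:5, 1)
    A <- matrix(rnorm(k * k), k)
    rg <- cov2cor(crossprod(A) + diag(k) * 0.1)
    vm <- setNames(rexp(k), paste0("t", seq_len(k)))
    dimnames(rg) <- list(names(vm), names(vm))
    m <- assemble_m(vm, rg)
    expect_gte(min(eigen(m$M, symmetric = TRUE)$values), -1e-12)
  }
})

test_that("flagged correlations propagate and complete_submatrix drops them", {
  vm <- c(a = 1, b = 2, c = 3)
  rg <- diag(3)
  rg[1, 3] <- rg[3, 1] <- NA
  dimnames(rg) <- list(names(vm), names(vm))
  m <- assemble_m(vm, rg)
  expect_true(is.na(m$M["a", "c"]))
  sub <- complete_submatrix(m)
  expect_false(any(is.na(sub$M)))
  expect_equal(length(sub$traits), 2)
})

test_that("random skewers is exact for identical and scaled matrices and
           symmetric in its arguments", {
  pm <- published_m_matrices()
  k3 <- complete_submatrix(pm$normal)
  s3 <- complete_submatrix(pm$salt, keep = k3$traits)
  same <- random_skewers(k3, k3, n_vectors = 2000, seed = 1)
  expect_equal(same$metric, 1, tolerance = 1e-12)
  scaled <- as_scaled <- k3
  as_scaled$M <- 17 * k3$M
  expect_equal(random_skewers(k3, as_scaled, n_vectors = 2000,
                              seed = 2)$metric, 1, tolerance = 1e-12)
  ab <- random_skewers(k3, s3, n_vectors = 5000, seed = 3)
  ba <- random_skewers(s3, k3, n_vectors = 5000, seed = 3)
  expect_equal(ab$metric, ba$metric, tolerance = 1e-12)
  expect_error(random_skewers(k3$M, diag(2)), "dimension")
})

test_that("the cosine skewers metric is invariant under a common rotation", {
  # the uncentered vector correlation is exactly rotation-equivariant;
  # the Pearson default centers on components and so is tied to the trait
  # basis, which is what the study's metric measures
  pm <- published_m_matrices()
  k3 <- complete_submatrix(pm$normal)$M
  s3 <- complete_submatrix(pm$salt,
                           keep = complete_submatrix(pm$normal)$traits)$M
  set.seed(62)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  m1r <- (Q %*% k3 %*% t(Q) + t(Q %*% k3 %*% t(Q))) / 2
  m2r <- (Q %*% s3 %*% t(Q) + t(Q %*% s3 %*% t(Q))) / 2
  a <- random_skewers(k3, s3, n_vectors = 50000, seed = 7,
                      method = "cosine")
  b <- random_skewers(m1r, m2r, n_vectors = 50000, seed = 8,
                      method = "cosine")
  expect_lt(abs(a$metric - b$metric), 0.02)
})

test_that("metric spread across seeds shrinks with the vector count", {
  pm <- published_m_matrices()
  k3 <- complete_submatrix(pm$normal)
  s3 <- complete_submatrix(pm$salt, keep = k3$traits)
  m_small <- vapply(1:4, function(s) {
    random_skewers(k3, s3, n_vectors = 2000, seed = s)$metric
  }, numeric(1))
  m_big <- vapply(1:4, function(s) {
    random_skewers(k3, s3, n_vectors = 100000, seed = s)$metric
  }, numeric(1))
  expect_lt(max(m_big) - min(m_big), 0.01)
  expect_lt(sd(m_big), sd(m_small) + 0.01)
})

test_that("maximum evolvability equals the power-iteration dominant
           eigenvalue", {
  expect_equal(evolvability_max(diag(3)), 1)
  set.seed(63)
  A <- matrix(rnorm(16), 4)
  S <- crossprod(A)
  v <- rnorm(4)
  for (i in 1:500) {
    v <- S %*% v
    v <- v / sqrt(sum(v^2))
  }
  lam <- as.numeric(t(v) %*% S %*% v)
  expect_equal(evolvability_max(S), lam, tolerance = 1e-10)
  bad <- S
  bad[1, 2] <- bad[1, 2] + 1
  expect_error(evolvability_max(bad), "asymmetric")
})

test_that("mean standardization rescales entries by products of means", {
  pm <- published_m_matrices()
  k3 <- complete_submatrix(pm$normal)
  ones <- setNames(rep(1, 3), k3$traits)
  expect_equal(mean_standardize(k3, ones)$M, k3$M)
  cmeans <- setNames(rep(2.5, 3), k3$traits)
  expect_equal(mean_standardize(k3, cmeans)$M, k3$M / 6.25)
  mus <- setNames(c(0.35, 0.234, 0.30), k3$traits)
  ms <- mean_standardize(k3, mus)
  expect_equal(evolvability_max(ms),
               max(eigen(k3$M / outer(mus, mus))$values), tolerance = 1e-12)
  expect_error(mean_standardize(k3, setNames(c(1, 0, 1), k3$traits)),
               "zero")
})
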