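# a small centered matrix with k orthogonal planted modules (disjoint gene
# blocks) and block-structured activities
planted_centered <- function(n_genes, n_samples, k, weight = 3, noise = 0.01,
                             seed = 1) {
  set.seed(seed)
  M <- matrix(0, n_genes, k)
  block <- floor(n_genes / (k + 1))
  # module weights carry random signs: heavy-tailed two-sided sources, the
  # regime the logcosh contrast is designed for
  for (j in seq_len(k))
    M[((j - 1) * block + 1):(j * block), j] <-
      rnorm(block, weight, weight / 5) * sample(c(-1, 1), block, TRUE)
  A <- matrix(rnorm(k * n_samples), k, n_samples)
  v <- M %*% A + matrix(rnorm(n_genes * n_samples, 0, noise), n_genes, n_samples)
  v <- v - rowMeans(v)
  list(x = tiny_expr(v, centered = TRUE), M = M, A = A)
}

test_that("a single ICA run is deterministic and recovers planted sources", {
  p <- planted_centered(300, 40, 3, seed = 7)
  r1 <- run_ica_single(p$x, 3, seed = 11)
  r2 <- run_ica_single(p$x, 3, seed = 11)
  expect_identical(r1$components, r2$components)
  expect_true(r1$converged)
  # unit-norm, sign-oriented components
  expect_equal(unname(colSums(r1$components^2)), rep(1, 3))
  for (k in 1:3)
    expect_gt(r1$components[which.max(abs(r1$components[, k])), k], 0)
  # each planted weight vector is matched by some component
  C <- abs(cor(r1$components, p$M))
  expect_true(all(apply(C, 2, max) > 0.99))
})

test_that("invalid single-run inputs error", {
  p <- planted_centered(50, 10, 2)
  expect_error(run_ica_single(p$x, 11, seed = 1), "dimension too large")
  raw <- tiny_expr(matrix(rnorm(20, 5), 4, 5))
  expect_error(run_ica_single(raw, 2, seed = 1), "centered")
})

test_that("component distance is 1 - |rho|: zero for sign flips, exact at rho = -0.8", {
  u <- rep(c(1, -1, 1, -1), 5)
  b <- rep(c(1, 1, -1, -1), 5)
  expect_equal(component_distance(u, u), 0)
  expect_equal(component_distance(u, -u), 0)
  v <- -0.8 * u + 0.6 * b   # exactly rho = -0.8 against u
  expect_equal(component_distance(u, v), 0.2)
  expect_equal(component_distance(u, v), component_distance(v, u))
  expect_error(component_distance(u, rep(1, 20)), "zero-variance")
  expect_error(component_distance(u, u[1:10]), "length")
})

test_that("consensus clustering finds recurring components and drops noise", {
  p <- planted_centered(400, 60, 5, seed = 3)
  runs <- run_ica_ensemble(p$x, 5, n_runs = 20)
  dec <- cluster_components(runs, p$x, min_cluster_size = 10)
  expect_s3_class(dec, "robust_decomposition")
  expect_identical(dec$K, 5L)
  expect_true(all(dec$cluster_support >= 10))
  C <- abs(cor(dec$M, p$M))
  expect_true(all(apply(C, 2, max) > 0.99))
  # X ~ M A: reconstruction captures nearly all variance
  expect_gt(explained_variance(p$x, dec), 0.99)
})

test_that("consensus output is invariant to run order and sign flips", {
  p <- planted_centered(200, 30, 3, seed = 9)
  runs <- run_ica_ensemble(p$x, 3, n_runs = 12)
  dec1 <- cluster_components(runs, p$x, min_cluster_size = 6)
  flipped <- lapply(rev(runs), function(r) {
    r$components <- -r$components
    r
  })
  dec2 <- cluster_components(flipped, p$x, min_cluster_size = 6)
  expect_identical(dec1$K, dec2$K)
  C <- abs(cor(dec1$M, dec2$M))
  expect_true(all(apply(C, 2, max) > 1 - 1e-10))
})

test_that("degenerate clustering parameters behave as specified", {
  p <- planted_centered(200, 30, 3, seed = 5)
  runs <- run_ica_ensemble(p$x, 3, n_runs = 1)
  # min_cluster_size 1, single run: every component its own cluster
  dec <- cluster_components(runs, p$x, min_cluster_size = 1)
  expect_identical(dec$K, 3L)
  # pure noise: no component recurs, K = 0
  set.seed(21)
  noise <- tiny_expr(matrix(rnorm(500 * 40), 500, 40), centered = TRUE)
  noise$values <- noise$values - rowMeans(noise$values)
  nruns <- run_ica_ensemble(noise, 8, n_runs = 15)
  dec0 <- suppressMessages(cluster_components(nruns, noise, min_cluster_size = 8))
  expect_identical(dec0$K, 0L)
  expect_equal(explained_variance(noise, dec0), 0)
})

test_that("explained variance is non-decreasing in the component subset", {
  p <- planted_centered(300, 40, 4, seed = 13)
  runs <- run_ica_ensemble(p$x, 4, n_runs = 10)
  dec <- cluster_components(runs, p$x, min_cluster_size = 5)
  evs <- vapply(0:dec$K, function(k)
    explained_variance(p$x, dec, subset = seq_len(k)), 1)
  expect_equal(evs[1], 0)
  expect_true(all(diff(evs) >= -1e-12))
  expect_error(explained_variance(tiny_expr(matrix(rnorm(10), 5, 2),
                                            centered = TRUE), dec),
               "shape mismatch")
})

test_that("tiny-instance consensus agrees with brute-force unmixing search", {
  set.seed(5)
  G <- 10; N <- 6
  Mp <- matrix(0, G, 2)
  Mp[1:3, 1] <- c(2, -1.5, 1.8)
  Mp[6:9, 2] <- c(1.2, 2.2, -1.7, 1.5)
  A <- matrix(rnorm(2 * N), 2, N)
  v <- Mp %*% A
  v <- v - rowMeans(v)
  x <- tiny_expr(v, centered = TRUE)
  keep <- apply(v, 1, sd) > 0
  runs <- suppressWarnings(run_ica_ensemble(x, 2, n_runs = 20))
  dec <- cluster_components(runs, x, min_cluster_size = 10)
  expect_identical(dec$K, 2L)

  # independent oracle: whiten to 2 dims, grid-search the rotation angle
  # maximizing the logcosh contrast of both sources
  vk <- v[keep, ]
  xt <- t(vk); xt <- xt - rowMeans(xt)
  sv <- svd(xt)
  z <- diag(1 / sv$d[1:2]) %*% t(sv$u[, 1:2]) %*% xt * sqrt(nrow(vk))
  ths <- seq(0, pi, length.out = 4000)
  J <- vapply(ths, function(th) {
    S <- rbind(c(cos(th), sin(th)), c(-sin(th), cos(th))) %*% z
    mean(log(cosh(S[1, ]))) + mean(log(cosh(S[2, ])))
  }, 1)
  S <- rbind(c(cos(ths[which.max(J)]), sin(ths[which.max(J)])),
             c(-sin(ths[which.max(J)]), cos(ths[which.max(J)]))) %*% z
  for (k in 1:2)
    expect_gt(max(abs(cor(dec$M[keep, k], S[1, ])),
                  abs(cor(dec$M[keep, k], S[2, ]))), 0.99)
})

test_that("decomposition TSV + manifest round-trips", {
  p <- planted_centered(300, 40, 3, seed = 7)
  runs <- run_ica_ensemble(p$x, 3, n_runs = 6)
  dec <- cluster_components(runs, p$x, min_cluster_size = 3)
  expect_gte(dec$K, 2L)
  dir <- withr::local_tempdir()
  write_decomposition(dec, dir)
  back <- read_decomposition(dir)
  expect_equal(back$M, dec$M, tolerance = 1e-12)
  expect_equal(back$A, dec$A, tolerance = 1e-12)
  expect_identical(back$K, dec$K)
})
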