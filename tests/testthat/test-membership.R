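test_that("the K-squared statistic matches an independent implementation", {
  # frozen oracle values computed with scipy.stats.normaltest on the same
  # vectors (rounded to 6 decimals before export)
  set.seed(101)
  v1 <- round(rnorm(100), 6)
  v2 <- round(c(rnorm(200), 8, -6, 7.5, 9, -5.5), 6)
  set.seed(202)
  v3 <- round(rexp(60), 6)
  expect_equal(dagostino_k2(v1), 2.554900853694903, tolerance = 1e-12)
  expect_equal(dagostino_k2(v2), 119.12960661323481, tolerance = 1e-12)
  expect_equal(dagostino_k2(v3), 9.311090166329288, tolerance = 1e-12)
})

test_that("the K-squared statistic separates normal background from outliers", {
  # under normality the statistic sits below its chi-squared(2) null
  # quantile in nearly all replicates
  below <- vapply(1:100, function(s) {
    set.seed(s)
    dagostino_k2(rnorm(10000)) < qchisq(0.99, df = 2)
  }, TRUE)
  expect_gte(mean(below), 0.95)

  # a handful of 10-sigma outliers blows the statistic up
  set.seed(7)
  v <- c(rnorm(995), rep(10, 5))
  expect_gt(dagostino_k2(v), 100)

  expect_error(dagostino_k2(rep(1, 50)), "constant")
  expect_error(dagostino_k2(rnorm(10)), "too short")
})

test_that("thresholding recovers planted members and matches brute force", {
  # five planted weights of 1.0: the tie rule removes them in one step and
  # the remaining background passes the normality cutoff
  w <- planted_weights(995, outliers = c(1, -1, 1, 1, -1), sd = 0.01, seed = 4)
  res <- threshold_component(w, k2_cutoff = 550)
  expect_setequal(res$members, names(w)[1:5])
  expect_false(res$degenerate)
  expect_lt(res$threshold, 1)
  # members are exactly the genes above the threshold
  expect_setequal(res$members, names(w)[abs(w) > res$threshold])

  # several cutoffs, several weight shapes
  for (seed in c(11, 12)) {
    set.seed(seed)
    w2 <- rnorm(800)
    w2[1:20] <- w2[1:20] + sample(c(-6, 6), 20, replace = TRUE)
    names(w2) <- sprintf("g%03d", seq_along(w2))
    for (cutoff in c(50, 300, 900)) {
      expect_setequal(threshold_component(w2, cutoff)$members,
                      brute_force_members(w2, cutoff))
    }
  }
})

test_that("thresholding handles no-outlier, tied, and degenerate inputs", {
  set.seed(8)
  w <- rnorm(500); names(w) <- sprintf("g%03d", 1:500)
  res <- threshold_component(w, k2_cutoff = 1e6)
  expect_length(res$members, 0)
  expect_false(res$degenerate)

  # two genes tied at the max |weight| are removed in the same step; the
  # cutoff sits below the saturation level of the statistic at this length
  w2 <- planted_weights(500, outliers = c(2, -2), sd = 0.01, seed = 5)
  res2 <- threshold_component(w2, 100)
  expect_setequal(res2$members, c("g0001", "g0002"))

  # cutoff never reached: flagged degenerate
  w3 <- 2^(seq_len(100)/4); names(w3) <- sprintf("g%03d", 1:100)
  res3 <- threshold_component(w3, 1e-9)
  expect_true(res3$degenerate)
})

test_that("membership is monotone in the cutoff and sign-invariant", {
  set.seed(6)
  w <- rnorm(1000)
  w[1:15] <- w[1:15] + 8
  names(w) <- sprintf("g%04d", seq_along(w))
  sizes <- vapply(c(20, 100, 550, 2000), function(cutoff)
    length(threshold_component(w, cutoff)$members), 1L)
  expect_true(all(diff(sizes) <= 0))
  expect_setequal(threshold_component(-w, 550)$members,
                  threshold_component(w, 550)$members)
})

test_that("cutoff optimization maximizes member-set F1 against the TRN", {
  # 4 components whose true members are exact regulons
  set.seed(9)
  genes <- sprintf("g%04d", 1:1000)
  M <- matrix(rnorm(4000, 0, 0.01), 1000, 4, dimnames = list(genes, NULL))
  members <- split(genes[1:60], rep(1:4, each = 15))
  for (k in 1:4) M[members[[k]], k] <- sample(c(-1, 1), 15, TRUE) * runif(15, 0.8, 1.2)
  trn <- make_trn(data.frame(regulator = rep(paste0("R", 1:4), each = 15),
                             target = unlist(members)), genes)
  cutoff <- optimize_cutoff(M, trn, grid = seq(100, 2000, by = 50))
  f1s <- vapply(1:4, function(k) {
    mem <- threshold_component(M[, k], cutoff)$members
    max(vapply(trn$regulons, function(r) {
      2 * length(intersect(mem, r)) / (length(mem) + length(r))
    }, 1))
  }, 1)
  expect_equal(mean(f1s), 1.0)

  # unrelated TRN: all cutoffs tie at 0, lowest grid value returned
  trn_bad <- make_trn(data.frame(regulator = "RX", target = genes[900:950]), genes)
  M0 <- matrix(rnorm(2000, 0, 0.01), 1000, 2, dimnames = list(genes, NULL))
  expect_equal(optimize_cutoff(M0, trn_bad, grid = c(300, 500, 700)), 300)
  expect_equal(optimize_cutoff(M, trn, grid = 550), 550)
  expect_warning(out <- optimize_cutoff(M, make_trn(
    data.frame(regulator = character(0), target = character(0)), genes)),
    "empty TRN")
  expect_equal(out, 550)
})

test_that("iModulon construction and JSON round-trip preserve member sets", {
  set.seed(10)
  genes <- sprintf("g%04d", 1:500)
  M <- matrix(rnorm(1000, 0, 0.02), 500, 2,
              dimnames = list(genes, c("IC01", "IC02")))
  M[1:10, 1] <- 1; M[21:28, 2] <- -1
  dec <- structure(list(M = M, A = matrix(0, 2, 3), K = 2L),
                   class = "robust_decomposition")
  imods <- make_imodulons(dec, k2_cutoff = 550,
                          categories = c(IC01 = "Metabolism", IC02 = "Stress"))
  expect_setequal(imods[[1]]$members, genes[1:10])
  expect_setequal(imods[[2]]$members, genes[21:28])
  expect_equal(imods[[2]]$category, "Stress")
  path <- withr::local_tempfile(fileext = ".json")
  write_imodulons_json(imods, path)
  back <- read_imodulons_json(path, dec)
  expect_setequal(back[[1]]$members, imods[[1]]$members)
  expect_equal(back[[2]]$threshold, imods[[2]]$threshold)
})
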