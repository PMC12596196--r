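test_that("TRN construction validates duplicates and the universe", {
  genes <- sprintf("g%02d", 1:20)
  assoc <- data.frame(regulator = c("R1", "R1", "R2"),
                      target = c("g01", "g02", "g01"))
  trn <- make_trn(assoc, genes)
  expect_setequal(trn$regulons$R1, c("g01", "g02"))
  expect_error(make_trn(rbind(assoc, assoc[1, ]), genes), "duplicate")
  expect_error(make_trn(data.frame(regulator = "R1", target = "gXX"), genes),
               "universe")
})

test_that("Fisher enrichment equals brute-force hypergeometric enumeration", {
  # perfect overlap closed form
  expect_equal(fisher_enrichment(paste0("g", 1:10), paste0("g", 1:10), 100),
               1 / choose(100, 10), tolerance = 1e-12)
  # zero overlap is certain
  expect_equal(fisher_enrichment("a", "b", 20), 1.0)
  # explicit enumeration, universe 20
  members <- paste0("g", 1:5)
  regulon <- paste0("g", c(3, 4, 5, 11, 12))
  expect_equal(fisher_enrichment(members, regulon, 20),
               brute_force_hyper(5, 5, 3, 20), tolerance = 1e-10)
  # sweep of small configurations against enumeration
  for (u in c(25, 40, 50)) {
    for (ov in 0:4) {
      m <- paste0("g", 1:6)
      r <- paste0("g", c(seq_len(ov), seq(u - 7 + ov, u - 1)))[1:7]
      p <- fisher_enrichment(m, r, u)
      expect_equal(p, brute_force_hyper(6, 7, length(intersect(m, r)), u),
                   tolerance = 1e-10)
      # cross-check against the installed exact test
      k <- length(intersect(m, r))
      ft <- fisher.test(matrix(c(k, 7 - k, 6 - k, u - 13 + k), 2),
                        alternative = "greater")
      expect_equal(p, ft$p.value, tolerance = 1e-8)
    }
  }
  expect_error(fisher_enrichment(character(0), "g1", 10), "empty member set")
})

test_that("BH adjustment is the step-up procedure", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.9)
  expect_equal(fdr_adjust(p), pmin(1, cummin(rev(p * 5 / seq_along(p)))[5:1])[order(order(p))])
  expect_error(fdr_adjust(c(0.5, 0)), "0, 1")
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("null enrichment keeps the false-positive rate at the FDR level", {
  set.seed(77)
  genes <- sprintf("g%04d", 1:1000)
  p <- vapply(1:1000, function(i) {
    fisher_enrichment(sample(genes, 25), sample(genes, 30), 1000)
  }, 1)
  q <- fdr_adjust(p)
  fpr <- mean(q < 0.05)
  expect_lte(fpr, 0.05 + 2 * sqrt(0.05 * 0.95 / 1000))
})

test_that("recalls are overlap fractions and the quadrants partition [0,1]^2", {
  expect_equal(compute_recalls(c("a", "b", "c"), c("a", "b", "c")),
               c(imodulon_recall = 1, regulon_recall = 1))
  expect_equal(compute_recalls(c("a", "b", "c", "d"), c("a", "b")),
               c(imodulon_recall = 0.5, regulon_recall = 1))
  expect_equal(compute_recalls(c("a", "b"), c("c", "d")),
               c(imodulon_recall = 0, regulon_recall = 0))
  expect_error(compute_recalls(character(0), "a"), "empty")

  expect_equal(classify_quadrant(0.8, 0.9), "well-matched")
  expect_equal(classify_quadrant(0.9, 0.3), "regulon subset")
  expect_equal(classify_quadrant(0.3, 0.9), "unknown-containing")
  expect_equal(classify_quadrant(0.1, 0.2), "closest match")
  expect_equal(classify_quadrant(0.7, 0.7), "well-matched")  # boundary inclusive
  # every point of a fine grid receives exactly one of the four labels
  grid <- expand.grid(ir = seq(0, 1, 0.05), rr = seq(0, 1, 0.05))
  labels <- mapply(classify_quadrant, grid$ir, grid$rr)
  expect_true(all(labels %in% c("well-matched", "regulon subset",
                                "unknown-containing", "closest match")))
  expect_length(labels, nrow(grid))
})

make_imod <- function(id, members) {
  structure(list(component_id = id, weights = NULL, threshold = 0,
                 members = members, degenerate = FALSE,
                 category = NA_character_), class = "imodulon")
}

test_that("enrich_all flags exact-regulon components as regulatory", {
  set.seed(30)
  genes <- sprintf("g%04d", 1:2000)
  member_sets <- split(genes[1:160], rep(1:8, each = 20))
  imods <- lapply(1:8, function(k) make_imod(paste0("IC0", k), member_sets[[k]]))
  # TRN matches components 1..5 exactly; 6..8 have no matching regulon
  trn <- make_trn(data.frame(regulator = rep(paste0("R", 1:5), each = 20),
                             target = unlist(member_sets[1:5])), genes)
  res <- enrich_all(imods, trn, regulatory_fdr = 1e-4)
  expect_identical(sum(res$is_regulatory), 5L)
  expect_true(all(res$quadrant[res$is_regulatory] == "well-matched"))
  expect_true(all(res$imodulon_recall[res$is_regulatory] == 1))
  expect_error(enrich_all(imods, make_trn(
    data.frame(regulator = character(0), target = character(0)), genes)),
    "empty TRN")
  # regulatory_fdr = 0: nothing can be flagged
  expect_false(any(enrich_all(imods, trn, regulatory_fdr = 0)$is_regulatory))
})

test_that("one regulator spanning two components is reported for both", {
  genes <- sprintf("g%03d", 1:500)
  m1 <- genes[1:10]; m2 <- genes[11:40]
  trn <- make_trn(data.frame(regulator = "R1", target = c(m1, m2)), genes)
  res <- enrich_all(list(make_imod("IC01", m1), make_imod("IC02", m2)), trn)
  expect_equal(res$regulator, c("R1", "R1"))
  expect_equal(res$imodulon_recall, c(1, 1))
  expect_equal(res$regulon_recall, c(10 / 40, 30 / 40))
})

test_that("TRN expansion accounting counts known plus novel pairs", {
  genes <- sprintf("g%03d", 1:100)
  regulon <- genes[1:10]
  trn <- make_trn(data.frame(regulator = "R1", target = regulon), genes)
  imods <- list(make_imod("IC01", c(regulon, genes[21:23])))
  res <- enrich_all(imods, trn)
  counts <- count_trn_expansion(res, imods, trn)
  expect_identical(counts$total_associations, 13L)
  expect_identical(counts$novel_associations, 3L)
  expect_equal(counts$expansion_fraction, 0.30)
  # invariant: total = known counted + novel
  expect_identical(counts$total_associations,
                   sum(!counts$pairs$novel) + counts$novel_associations)
  expect_equal(counts$expansion_fraction * nrow(trn$associations),
               counts$novel_associations)
  # members already in the regulon add nothing novel
  imods2 <- list(make_imod("IC01", regulon[1:5]))
  res2 <- enrich_all(imods2, trn)
  expect_identical(count_trn_expansion(res2, imods2, trn)$novel_associations, 0L)
})
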