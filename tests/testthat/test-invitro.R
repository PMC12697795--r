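# In vitro screen statistics: normalization contracts, fold-change algebra,
# second-best gene summaries, permutation significance, hit calls, the
# scoring rubric and killing efficiency.

test_that("total normalization equalizes library size and is scale invariant", {
  lib <- toy_library(n_genes = 3, gpg = 2, n_safe = 12)
  cm <- matrix(rpois(18 * 2, 50) + 1, ncol = 2,
               dimnames = list(lib$guide_id, c("a", "b")))
  cm[, 2] <- cm[, 1]  # identical samples
  n <- normalize_counts(cm, "total")
  expect_equal(n[, 1], n[, 2])
  expect_equal(unname(colSums(n)), c(1e7, 1e7))
  # doubling one sample's raw counts changes nothing after normalization
  cm2 <- cm; cm2[, 2] <- 2L * cm2[, 2]
  expect_equal(normalize_counts(cm2, "total"), n)
  cm3 <- cm; cm3[, 1] <- 0L
  expect_error(normalize_counts(cm3, "total"), "all-zero sample.*a")
})

test_that("safe-guide normalization equalizes per-sample safe medians", {
  lib <- toy_library(n_genes = 5, gpg = 2, n_safe = 15)
  set.seed(2)
  cm <- matrix(rpois(nrow(lib) * 3, 100) + 1, ncol = 3,
               dimnames = list(lib$guide_id, c("a", "b", "c")))
  cm[, 2] <- cm[, 2] * 5L
  n <- normalize_counts(cm, "safe_guides", lib)
  safe <- lib$guide_id[lib$guide_class == "safe"]
  med <- apply(n[safe, ], 2, median)
  expect_equal(unname(med), rep(median(cm[safe, ]), 3), tolerance = 1e-12)
  expect_error(normalize_counts(cm, "safe_guides", toy_library(n_safe = 5)),
               ">= 10 safe guides")
})

test_that("guide log2 fold change follows its algebra", {
  lib <- toy_library(n_genes = 2, gpg = 2, n_safe = 10)
  sim <- toy_counts(lib, seed = 4)
  m <- normalize_counts(sim$counts, "total")
  up <- guide_log2fc(m, sim$samples, "trt", "ctrl", lib)
  dn <- guide_log2fc(m, sim$samples, "ctrl", "trt", lib)
  expect_equal(up$log2fc, -dn$log2fc)            # antisymmetry
  expect_true(all(is.finite(up$log2fc)))
  # identity and exact doubling with pseudocount 0
  m2 <- m; m2[, sim$samples$sample[sim$samples$arm == "trt"]] <-
    2 * m[, sim$samples$sample[sim$samples$arm == "ctrl"]]
  gs <- guide_log2fc(m2, sim$samples, "trt", "ctrl", lib, pseudocount = 0)
  expect_equal(gs$log2fc, rep(1, nrow(gs)))
  expect_error(guide_log2fc(m, sim$samples, "nope", "ctrl", lib), "arm")
})

test_that("second-best statistic picks the 2nd guide in the dominant direction", {
  gs <- data.frame(guide_id = letters[1:7],
                   gene = c("A", "A", "A", "B", "B", "B", "C"),
                   log2fc = c(-3, -2, 0, 3, 1, 0, -1.5))
  sb <- gene_second_best_lfc(gs)
  expect_equal(sb$second_best_lfc[sb$gene == "A"], -2)  # dominant negative
  expect_equal(sb$second_best_lfc[sb$gene == "B"], 1)   # dominant positive
  expect_equal(sb$second_best_lfc[sb$gene == "C"], -1.5)  # single guide
  # a median tie breaks toward depletion: ranking {-2, 2} in the depletion
  # direction puts -2 first, so the second-ranked guide is +2 (the
  # enrichment ordering would have returned -2)
  gs2 <- data.frame(guide_id = letters[1:2], gene = "D", log2fc = c(-2, 2))
  expect_equal(gene_second_best_lfc(gs2)$second_best_lfc, 2)
})

test_that("permutation p-values are calibrated, extreme for extreme genes, and one-sided-coherent", {
  lib <- simulate_library(2000, 0, 0, 0, 4, seed = 31)
  sim <- toy_counts(lib, seed = 32, depth = 4e6, dispersion = 0.1)
  m <- normalize_counts(sim$counts, "total")
  gs <- guide_log2fc(m, sim$samples, "trt", "ctrl", lib)
  sig <- gene_significance(gs, n_perm = 400, seed = 33)
  # null calibration within 3 binomial SDs of 0.05 over 2000 genes
  frac <- mean(sig$p_depleted < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 2000) + 1e-9)
  expect_true(all(sig$p_depleted > 0 & sig$p_depleted <= 1))
  # both tails cannot be simultaneously extreme
  expect_false(any(sig$p_depleted < 0.5 & sig$p_enriched < 0.5 &
                     abs(sig$mean_lfc - median(gs$log2fc)) > 1e-6))

  # a gene owning the 5 most negative LFCs in the library hits the p floor
  gs2 <- gs
  worst <- order(gs2$log2fc)[1:5]
  gs2$gene[worst] <- "XWORST"
  gs2$gene[setdiff(which(gs2$gene == "XWORST"), worst)] <- "DEP0001"
  sig2 <- gene_significance(gs2, n_perm = 999, seed = 34)
  expect_equal(sig2$p_depleted[sig2$gene == "XWORST"], 1 / 1000)
})

test_that("hit calling applies both cutoffs and is monotone in them", {
  res <- data.frame(gene = c("A", "B", "C", "D"),
                    second_best_lfc = c(-0.30, -0.20, 0.30, 0.26),
                    p_depleted = c(0.01, 0.001, 0.9, 0.9),
                    p_enriched = c(0.99, 0.999, 0.04, 0.2))
  calls <- call_hits(res)
  expect_equal(calls$call, c("depleted", "ns", "enriched", "ns"))
  # lowering p_cut or raising lfc_cut never adds hits
  n_default <- sum(call_hits(res)$call != "ns")
  expect_lte(sum(call_hits(res, p_cut = 0.01)$call != "ns"), n_default)
  expect_lte(sum(call_hits(res, lfc_cut = 0.35)$call != "ns"), n_default)
})

test_that("the in vitro scoring rubric is signed, capped at 4, and resolves conflicts", {
  mk <- function(lfc, p_dep, p_enr) {
    call_hits(data.frame(gene = "G", second_best_lfc = lfc,
                         p_depleted = p_dep, p_enriched = p_enr))
  }
  dep_hit <- mk(-0.5, 0.01, 1); enr_hit <- mk(0.5, 1, 0.01)
  ns_flat <- mk(0.1, 0.5, 0.5); dep_lfc <- mk(-0.5, 0.5, 1)
  expect_equal(in_vitro_score(dep_hit, dep_hit)$in_vitro_score, -4)
  expect_equal(in_vitro_score(enr_hit, ns_flat)$in_vitro_score, 2)
  expect_equal(in_vitro_score(ns_flat, ns_flat)$in_vitro_score, 0)
  expect_equal(in_vitro_score(dep_hit, dep_lfc)$in_vitro_score, -3)
  # conflicting directions: only the dominant one contributes
  expect_equal(in_vitro_score(dep_hit, enr_hit)$in_vitro_score, -2)
  expect_equal(in_vitro_score(dep_lfc, enr_hit)$in_vitro_score, 2)
})

test_that("killing efficiency matches its formula", {
  expect_equal(killing_efficiency(100, 100), 0)
  expect_equal(killing_efficiency(36, 100), 64)
  expect_equal(killing_efficiency(0, 100), 100)
  expect_error(killing_efficiency(10, 0), "> 0")
})
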