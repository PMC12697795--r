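# Synthetic-data generators: arithmetic contracts, determinism, and
# recovery of planted effects by the downstream statistics.

test_that("library composition follows the requested class counts", {
  lib <- simulate_library(400, 100, 30, 100, guides_per_gene = 5, seed = 1)
  expect_equal(nrow(lib), 2750)
  expect_equal(length(setdiff(unique(lib$gene), safe_gene_label())), 530)
  expect_false(anyDuplicated(lib$guide_id) > 0)
  # every gene maps to exactly one class; >=1 guide per gene
  per_gene <- table(lib$gene[lib$gene != safe_gene_label()])
  expect_true(all(per_gene == 5))
  cls <- tapply(lib$guide_class, lib$gene, function(x) length(unique(x)))
  expect_true(all(cls == 1))

  degenerate <- simulate_library(0, 0, 0, 10, guides_per_gene = 1, seed = 1)
  expect_equal(nrow(degenerate), 10)
  expect_true(all(degenerate$gene == safe_gene_label()))
  expect_error(simulate_library(-1, 0, 0, 0, 1, 1), "non-negative")
})

test_that("all simulators are bit-identical under a repeated seed", {
  expect_identical(simulate_library(20, 5, 3, 10, 3, seed = 42),
                   simulate_library(20, 5, 3, 10, 3, seed = 42))
  lib <- toy_library()
  expect_identical(toy_counts(lib, seed = 9), toy_counts(lib, seed = 9))
  expect_identical(simulate_cohort(30, 10, mode = "response", seed = 3),
                   simulate_cohort(30, 10, mode = "response", seed = 3))
  expect_identical(simulate_te_table(100, seed = 8),
                   simulate_te_table(100, seed = 8))
  # and the generators do not disturb the caller's RNG stream
  set.seed(1); a <- runif(1)
  set.seed(1); invisible(simulate_library(5, 0, 0, 5, 2, seed = 7)); b <- runif(1)
  expect_identical(a, b)
})

test_that("null screens give equal expected counts across arms", {
  lib <- simulate_library(50, 0, 0, 20, 4, seed = 2)
  sim <- toy_counts(lib, seed = 3, depth = 1e6, dispersion = 0.05)
  m <- normalize_counts(sim$counts, "total")
  ratio <- rowMeans(m[, 3:4]) / rowMeans(m[, 1:2])
  expect_equal(mean(ratio), 1, tolerance = 0.05)
})

test_that("a planted effect of -3 shifts mean counts by about 2^-3", {
  lib <- simulate_library(200, 0, 0, 1000, 5, seed = 4)
  genes <- setdiff(unique(lib$gene), safe_gene_label())
  sim <- toy_counts(lib, seed = 6, depth = 5e6, dispersion = 0.1,
                    arm_effects = list(trt = stats::setNames(rep(-3, length(genes)), genes)))
  is_goi <- lib$guide_class == "goi_depleted"
  # >=1000 affected guides: Monte-Carlo mean of the count ratio
  expect_gte(sum(is_goi), 1000)
  trt <- rowMeans(sim$counts[, 3:4]); ctl <- rowMeans(sim$counts[, 1:2])
  # normalize out the compositional shift using the unaffected safe guides
  scale_fac <- mean(trt[!is_goi]) / mean(ctl[!is_goi])
  obs <- mean(trt[is_goi]) / mean(ctl[is_goi]) / scale_fac
  expect_equal(obs, 2^-3, tolerance = 0.1)
})

test_that("an engraftment bottleneck inflates replicate-to-replicate variance", {
  lib <- simulate_library(30, 0, 0, 20, 4, seed = 1)
  truth <- simulation_truth(lib)
  var_at <- function(bn) {
    design <- screen_design(
      data.frame(name = "m", role = "mock", replicates = 2L),
      depth = 2e5, dispersion = 0.1, bottleneck = bn)
    v <- vapply(1:200, function(s) {
      cm <- simulate_screen_counts(lib, design, truth, seed = s,
                                   lineage_coverage = 20)$counts
      l <- log2(cm + 5)
      stats::var(l[, 1] - l[, 2])
    }, numeric(1))
    mean(v)
  }
  expect_gt(var_at(0.05), var_at(1.0))
})

test_that("cohort simulation is null-centered and recovers planted response effects", {
  genes <- sprintf("G%04d", 1:40)
  co <- simulate_cohort(500, genes, mode = "response", seed = 12)
  eff <- cohort_effect(co)
  expect_equal(mean(eff$effects$effect), 0, tolerance = 0.05)

  co2 <- simulate_cohort(500, genes,
                         planted = c(G0001 = 1.5), mode = "response", seed = 13)
  eff2 <- cohort_effect(co2)$effects
  expect_gt(eff2$effect[eff2$gene == "G0001"], 0.2)
  expect_gt(eff2$effect[eff2$gene == "G0001"], max(abs(eff2$effect[-1])) * 0.99)
})

test_that("survival mode plants a recoverable hazard", {
  genes <- sprintf("G%04d", 1:5)
  co <- simulate_cohort(400, genes, planted = c(G0001 = log(2)),
                        mode = "survival", seed = 21)
  a <- gene_survival_association(co, "G0001")
  expect_gt(a$hr, 1)
  expect_lt(a$p, 0.05)
})

test_that("cohort simulation rejects unknown planted genes", {
  expect_error(simulate_cohort(20, 5, planted = c(NOPE = 1), seed = 1),
               "not in gene list")
  expect_error(simulate_cohort(5, 10, seed = 1), ">= 8")
})

test_that("TE tables respect the category mix and planted shifts", {
  t0 <- simulate_te_table(2000, planted_shift = numeric(0), seed = 5)
  r0 <- te_records(t0)
  means <- tapply(r0$te, r0$category_true, mean)
  expect_true(all(abs(means) < 0.1))
  # annotated strengths reproduce the target category
  expect_true(all(r0$category == r0$category_true))

  t1 <- simulate_te_table(2000, planted_shift = c(Supreme = -1), seed = 5)
  s1 <- compare_te_by_category(te_records(t1))
  expect_equal(s1$category[which.min(s1$mean_te)], "Supreme")

  t2 <- simulate_te_table(50, kozak_mix = c(No = 1.0), seed = 2)
  expect_true(all(t2$category_true == "No"))
  expect_error(simulate_te_table(10, kozak_mix = c(No = 0.5), seed = 1),
               "sum to 1")
})

test_that("planted depleted genes rank below safe guides in mean guide LFC", {
  hits <- vapply(1:100, function(s) {
    lib <- simulate_library(6, 0, 0, 30, 4, seed = s)
    genes <- setdiff(unique(lib$gene), safe_gene_label())
    sim <- toy_counts(lib, seed = s + 500, depth = 3e5, dispersion = 0.15,
                      arm_effects = list(trt = stats::setNames(rep(-1.5, 6), genes)))
    m <- normalize_counts(sim$counts, "total")
    gs <- guide_log2fc(m, sim$samples, "trt", "ctrl", lib)
    goi_mean <- tapply(gs$log2fc[gs$gene != safe_gene_label()],
                       gs$gene[gs$gene != safe_gene_label()], mean)
    safe_mean <- mean(gs$log2fc[gs$gene == safe_gene_label()])
    all(goi_mean < safe_mean)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
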