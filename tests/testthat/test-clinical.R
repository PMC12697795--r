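# Clinical scoring: cohort effects, survival association, patient score,
# |P90| normalization, cytolytic activity, stratification, gene sets and
# preranked enrichment.

test_that("response-mode cohort effects follow the pseudocounted fold change", {
  tpm <- rbind(matrix(3, 4, 2), matrix(1, 4, 2))
  colnames(tpm) <- c("G1", "G2"); rownames(tpm) <- paste0("P", 1:8)
  tpm[, 2] <- 2  # identical means across classes for G2
  co <- expression_cohort(tpm, response = rep(c("responder", "nonresponder"), each = 4))
  eff <- cohort_effect(co)$effects
  expect_equal(eff$effect[eff$gene == "G1"], log2(4 / 2))  # 1.0
  expect_equal(eff$effect[eff$gene == "G2"], 0)
  expect_error(cohort_effect(expression_cohort(tpm, response = rep("responder", 8))),
               ">= 2 patients")
})

test_that("survival cohort effects are null-centered without an expression link", {
  co <- simulate_cohort(200, 30, mode = "survival", seed = 41)
  eff <- cohort_effect(co)$effects
  expect_true(all(eff$available))
  expect_equal(mean(eff$effect), 0, tolerance = 0.12)
})

test_that("survival association uses exact upper-quartile groups and calibrated log-rank", {
  co <- simulate_cohort(401, 10, mode = "survival", seed = 42)
  a <- gene_survival_association(co, "G0001")
  expect_equal(a$n_high, ceiling(401 / 4))
  expect_equal(a$n_low, 401 - ceiling(401 / 4))
  # exchangeable survival: HR near 1, p not extreme
  ps <- vapply(sprintf("G%04d", 1:10), function(g)
    gene_survival_association(co, g)$p, numeric(1))
  hrs <- vapply(sprintf("G%04d", 1:10), function(g)
    gene_survival_association(co, g)$hr, numeric(1))
  expect_equal(median(hrs), 1, tolerance = 0.25)
  expect_gt(mean(ps > 0.05), 0.5)
})

test_that("patient score is the weighted mean over available cohorts", {
  e1 <- cohort_effect_table(data.frame(gene = c("A", "B"), effect = c(-1, 2)),
                            "c1", "response", n = 50)
  e2 <- cohort_effect_table(data.frame(gene = c("A", "C"), effect = c(3, 1)),
                            "c2", "response", n = 50)
  ps <- suppressMessages(patient_score(list(e1, e2)))
  expect_equal(ps[["A"]], 1)           # equal n: (-1 + 3) / 2
  expect_equal(ps[["B"]], 2)           # only cohort 1
  expect_equal(ps[["C"]], 1)
  expect_equal(patient_score(list(e1))[["A"]], -1)  # single cohort
  e3 <- cohort_effect_table(data.frame(gene = "A", effect = 3), "c3",
                            "response", n = 150)
  expect_equal(patient_score(list(e1, e3))[["A"]], (50 * -1 + 150 * 3) / 200)
  expect_equal(patient_score(list(e1, e3), weighting = "equal")[["A"]], 1)
})

test_that("q90 normalization hits its target exactly and is idempotent and odd", {
  x <- c(-3, -1, 0, 1, 2, 4, 4, 8, 10, 12)
  n1 <- normalize_q90(x)
  expect_equal(abs(quantile(n1, 0.9, type = 7, names = FALSE)), 2)
  # P90 = 4 exactly: all values halved
  y <- c(rep(0, 8), 4, 4)
  expect_equal(normalize_q90(y), y / 2)
  expect_equal(normalize_q90(n1), n1)             # idempotent
  # the factor uses |P90|, so signs are preserved even when P90 < 0
  neg <- c(-10, -8, -6, -5, -4, -3, -2, -2, -1, -1)
  expect_true(all(sign(normalize_q90(neg)) == sign(neg)))
  expect_equal(abs(quantile(normalize_q90(neg), 0.9, type = 7, names = FALSE)), 2)
  expect_error(normalize_q90(c(-5, -4, 0, 0, 0, 0, 0, 0, 0, 0, 0)), "degenerate")
  # brute force on random vectors: contract holds to 1e-12
  set.seed(99)
  for (i in 1:25) {
    v <- rnorm(sample(10:200, 1), sd = runif(1, 0.1, 10))
    if (quantile(v, 0.9, type = 7) == 0) next
    w <- normalize_q90(v, target = 2)
    expect_lt(abs(abs(quantile(w, 0.9, type = 7, names = FALSE)) - 2), 1e-12)
    expect_equal(normalize_q90(3.7 * v), w)  # positive homogeneity
  }
})

test_that("cytolytic activity is a geometric mean", {
  expect_equal(cytolytic_activity(4, 9), 6)
  expect_equal(cytolytic_activity(7, 7), 7)
  expect_equal(cytolytic_activity(0, 100), 0)
  expect_equal(cytolytic_activity(4, 9), cytolytic_activity(9, 4))
  expect_equal(cytolytic_activity(8, 18), 2 * cytolytic_activity(4, 9) *
                 sqrt(1))  # linear under joint scaling: sqrt(2*2)=2
  expect_error(cytolytic_activity(-1, 2), ">= 0")
})

test_that("high/low stratification labels exactly the top quantile", {
  expr <- stats::setNames(rnorm(200), sprintf("P%03d", 1:200))
  g <- stratify_high_low(expr)
  expect_equal(sum(g == "high"), 50)
  expect_equal(sum(g == "low"), 150)
  expect_true(min(expr[g == "high"]) >= max(expr[g == "low"]))
  # all-equal expression: the first ceiling(qn) by id become high
  tied <- stats::setNames(rep(1, 8), sprintf("P%d", 1:8))
  gt <- stratify_high_low(tied)
  expect_equal(names(gt)[gt == "high"], c("P1", "P2"))
  # q = 0.5 is a median split
  expect_equal(sum(stratify_high_low(expr, q = 0.5) == "high"), 100)
})

test_that("response gene sets are the top and bottom k, disjoint, tie-broken by id", {
  de <- data.frame(gene = sprintf("g%03d", 1:300), log2fc = seq(-3, 3, length.out = 300))
  gs <- derive_response_gene_sets(de, k = 100)
  expect_length(gs$responder$genes, 100)
  expect_length(gs$nonresponder$genes, 100)
  expect_length(intersect(gs$responder$genes, gs$nonresponder$genes), 0)
  one <- derive_response_gene_sets(de, k = 1)
  expect_equal(one$responder$genes, "g300")
  expect_equal(one$nonresponder$genes, "g001")
  tied <- data.frame(gene = c("b", "a", "c", "d"), log2fc = c(1, 1, -1, -2))
  expect_equal(derive_response_gene_sets(tied, k = 1)$responder$genes, "a")
  expect_error(derive_response_gene_sets(de, k = 200), ">= 400")
})

test_that("enrichment score is maximal for a top-ranked set and sign-symmetric", {
  set.seed(7)
  metric <- sort(rnorm(20), decreasing = TRUE)
  names(metric) <- sprintf("g%02d", 1:20)
  # independent oracle: plain running-sum enumeration over all placements
  oracle_es <- function(member) {
    inc <- abs(metric) * member / sum(abs(metric) * member)
    dec <- (!member) / sum(!member)
    rs <- cumsum(inc - dec)
    rs[which.max(abs(rs))]
  }
  placements <- utils::combn(20, 3)
  all_es <- apply(placements, 2, function(ix) {
    m <- logical(20); m[ix] <- TRUE; oracle_es(m)
  })
  top <- preranked_enrichment(metric, gene_set("top", names(metric)[1:3]),
                              n_perm = 200, seed = 1)
  expect_gt(top$es, 0)
  expect_equal(top$es, max(all_es))
  expect_lt(top$p, 0.05)
  # negating the metric flips the ES sign (the set now sits at the bottom)
  flipped <- preranked_enrichment(-metric, gene_set("top", names(metric)[1:3]),
                                  n_perm = 200, seed = 1)
  expect_equal(flipped$es, -top$es, tolerance = 1e-12)
  expect_error(preranked_enrichment(metric, gene_set("x", c("nope1", "nope2")),
                                    n_perm = 200, seed = 1), "intersect")
})

test_that("random gene sets produce null-distributed enrichment", {
  set.seed(8)
  metric <- stats::setNames(rnorm(200), sprintf("g%03d", 1:200))
  ps <- vapply(1:40, function(i) {
    gs <- gene_set("r", sample(names(metric), 15))
    preranked_enrichment(metric, gs, n_perm = 200, seed = i)$p
  }, numeric(1))
  expect_gt(mean(ps > 0.05), 0.8)
  expect_gt(min(ps), 1 / 201 - 1e-12)
})

test_that("enrichment scores agree with fgsea on a toy ranking", {
  skip_if_not_installed("fgsea")
  set.seed(9)
  metric <- stats::setNames(sort(rnorm(50), decreasing = TRUE), sprintf("g%02d", 1:50))
  sets <- list(up = gene_set("up", names(metric)[c(2, 5, 9)]),
               down = gene_set("down", names(metric)[c(44, 48, 50)]))
  mine <- preranked_enrichment(metric, sets, n_perm = 500, seed = 3)
  ref <- suppressWarnings(fgsea::fgsea(
    pathways = list(up = sets$up$genes, down = sets$down$genes),
    stats = metric, minSize = 1, maxSize = 50, nPermSimple = 2000))
  expect_equal(mine$es[mine$set == "up"], ref$ES[ref$pathway == "up"],
               tolerance = 1e-6)
  expect_equal(mine$es[mine$set == "down"], ref$ES[ref$pathway == "down"],
               tolerance = 1e-6)
})
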