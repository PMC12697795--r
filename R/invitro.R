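# In vitro immune-screen statistics: normalization, guide log2 fold changes,
# second-best-guide gene summaries, permutation significance, hit calls and
# the 0-4 in vitro gene score.

#' Normalize a guide count matrix
#'
#' `total`: each sample is scaled to a common library size of 1e7 reads
#' (the convention of pooled-screen count pipelines). `safe_guides`: each
#' sample is scaled so that its median safe-targeting-guide count equals the
#' grand median of safe-guide counts pooled across samples -- the
#' normalization used for libraries skewed toward depleted genes, where
#' total-count scaling would be confounded by the selection itself.
#'
#' @param counts integer guide x sample matrix (rownames = guide ids)
#' @param method `"total"` or `"safe_guides"`
#' @param lib guide library (required for `safe_guides`)
#' @return numeric matrix of normalized abundances, same shape as `counts`
#' @export
normalize_counts <- function(counts, method = c("total", "safe_guides"),
                             lib = NULL) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  tot <- colSums(counts)
  if (any(tot == 0)) {
    stopf("cannot normalize all-zero sample(s): %s",
          paste(colnames(counts)[tot == 0], collapse = ", "))
  }
  if (method == "total") {
    return(sweep(counts, 2, 1e7 / tot, `*`))
  }
  if (is.null(lib)) stopf("`lib` is required for safe-guide normalization")
  safe <- lib$guide_id[lib$guide_class == "safe"]
  safe <- intersect(safe, rownames(counts))
  if (length(safe) < 10) {
    stopf("safe-guide normalization needs >= 10 safe guides present, found %d",
          length(safe))
  }
  med <- apply(counts[safe, , drop = FALSE], 2, stats::median)
  if (any(med == 0)) {
    stopf("zero safe-guide median in sample(s): %s",
          paste(colnames(counts)[med == 0], collapse = ", "))
  }
  grand <- stats::median(counts[safe, , drop = FALSE])
  sweep(counts, 2, grand / med, `*`)
}

arm_means <- function(norm, samples, arm) {
  sel <- samples$sample[samples$arm == arm]
  if (!length(sel)) stopf("unknown or empty arm: '%s'", arm)
  rowMeans(norm[, sel, drop = FALSE])
}

#' Guide-level log2 fold change between two arms
#'
#' Replicates are averaged (arithmetic mean of normalized abundances) before
#' the fold change; a pseudocount keeps every value finite:
#' `log2((mean_treated + pc) / (mean_control + pc))`.
#'
#' @param norm normalized guide x sample matrix
#' @param samples sample sheet (`sample`, `arm`, `replicate`)
#' @param treated,control arm names
#' @param lib guide library (maps guides to genes)
#' @param pseudocount added to both means; default 5
#' @return data.frame `guide_id`, `gene`, `mean_treated`, `mean_control`,
#'   `log2fc`
#' @export
guide_log2fc <- function(norm, samples, treated, control, lib,
                         pseudocount = 5) {
  check_cols(samples, c("sample", "arm"), "`samples`")
  mt <- arm_means(norm, samples, treated)
  mc <- arm_means(norm, samples, control)
  gene <- lib$gene[match(rownames(norm), lib$guide_id)]
  if (anyNA(gene)) stopf("guide(s) missing from library")
  data.frame(guide_id = rownames(norm), gene = gene,
             mean_treated = mt, mean_control = mc,
             log2fc = log2((mt + pseudocount) / (mc + pseudocount)),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Rank a gene's guide LFCs in its dominant direction and return the
# second-most-extreme one (the value itself for single-guide genes).
second_best_one <- function(lfc) {
  med <- stats::median(lfc)
  dominant <- if (med > 0) 1 else -1  # ties toward depletion
  s <- sort(lfc, decreasing = dominant > 0)
  if (length(s) == 1L) s[1] else s[2]
}

#' Second-best-guide log2 fold change per gene
#'
#' For each gene, guides are ranked by log2 fold change in the gene's
#' dominant direction (the sign of the median guide LFC, ties toward
#' depletion) and the second-ranked guide's value is returned -- a gene
#' summary robust to a single outlier guide. Single-guide genes return their
#' only value. Safe-targeting controls are excluded.
#'
#' @param gs guide stats from [guide_log2fc()]
#' @return data.frame `gene`, `n_guides`, `second_best_lfc`
#' @export
gene_second_best_lfc <- function(gs) {
  gs <- gs[gs$gene != safe_gene_label(), , drop = FALSE]
  sp <- split(gs$log2fc, gs$gene)
  data.frame(gene = names(sp),
             n_guides = lengths(sp),
             second_best_lfc = vapply(sp, second_best_one, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Permutation significance of gene-level selection
#'
#' For each gene, the observed mean guide log2 fold change is compared with
#' `n_perm` same-size random draws of guides from the full library.
#' `p_depleted = (1 + #\{perm mean <= observed\}) / (n_perm + 1)`, and
#' mirrored for enrichment, so p-values lie in (0, 1]. Genes sharing a guide
#' count share one set of permutations. This is a documented permutation
#' stand-in for count-model gene tests such as MAGeCK's (metadata attribute
#' `test = "permutation-mean-lfc"`).
#'
#' @param gs guide stats from [guide_log2fc()]
#' @param n_perm number of permutations (>= 100)
#' @param seed integer seed
#' @return data.frame `gene`, `n_guides`, `mean_lfc`, `p_depleted`,
#'   `p_enriched`
#' @export
gene_significance <- function(gs, n_perm = 1000L, seed = 1L) {
  if (n_perm < 100) stopf("`n_perm` must be >= 100")
  pool <- gs$log2fc
  real <- gs[gs$gene != safe_gene_label(), , drop = FALSE]
  sp <- split(real$log2fc, real$gene)
  obs <- vapply(sp, mean, numeric(1))
  sizes <- lengths(sp)
  with_seed(seed, {
    null_by_size <- lapply(sort(unique(sizes)), function(k) {
      draws <- matrix(sample(pool, k * n_perm, replace = TRUE), nrow = k)
      colMeans(draws)
    })
    names(null_by_size) <- as.character(sort(unique(sizes)))
    p_dep <- p_enr <- numeric(length(obs))
    for (i in seq_along(obs)) {
      nul <- null_by_size[[as.character(sizes[i])]]
      p_dep[i] <- (1 + sum(nul <= obs[i])) / (n_perm + 1)
      p_enr[i] <- (1 + sum(nul >= obs[i])) / (n_perm + 1)
    }
    out <- data.frame(gene = names(sp), n_guides = as.integer(sizes),
                      mean_lfc = unname(obs), p_depleted = p_dep,
                      p_enriched = p_enr, row.names = NULL,
                      stringsAsFactors = FALSE)
    attr(out, "test") <- "permutation-mean-lfc"
    out
  })
}

#' Gene-level results for one in vitro contrast
#'
#' Convenience wrapper combining [gene_second_best_lfc()] and
#' [gene_significance()] on one treated-vs-control contrast.
#'
#' @inheritParams guide_log2fc
#' @inheritParams gene_significance
#' @return merged per-gene data.frame
#' @export
invitro_gene_stats <- function(norm, samples, treated, control, lib,
                               pseudocount = 5, n_perm = 1000L, seed = 1L) {
  gs <- guide_log2fc(norm, samples, treated, control, lib, pseudocount)
  merge(gene_second_best_lfc(gs),
        gene_significance(gs, n_perm = n_perm, seed = seed)[
          , c("gene", "mean_lfc", "p_depleted", "p_enriched")],
        by = "gene")
}

#' Call screen hits at fold-change and significance cutoffs
#'
#' A gene is `depleted` iff its second-best LFC is below `-lfc_cut` with
#' `p_depleted < p_cut`; `enriched` iff above `+lfc_cut` with
#' `p_enriched < p_cut`; otherwise `ns`.
#'
#' @param res per-gene table with `second_best_lfc`, `p_depleted`,
#'   `p_enriched`
#' @param lfc_cut absolute log2-fold-change cutoff (default 0.25)
#' @param p_cut significance cutoff (default 0.05)
#' @return `res` with an added `call` column
#' @export
call_hits <- function(res, lfc_cut = 0.25, p_cut = 0.05) {
  check_cols(res, c("second_best_lfc", "p_depleted", "p_enriched"), "`res`")
  call <- rep("ns", nrow(res))
  call[res$second_best_lfc < -lfc_cut & res$p_depleted < p_cut] <- "depleted"
  call[res$second_best_lfc >  lfc_cut & res$p_enriched < p_cut] <- "enriched"
  res$call <- call
  res
}

score_one_contrast <- function(call, lfc, lfc_cut) {
  if (call == "depleted") return(-2)
  if (call == "enriched") return(2)
  if (lfc < -lfc_cut) return(-1)
  if (lfc >  lfc_cut) return(1)
  0
}

#' In vitro gene score from two effector-to-target contrasts
#'
#' Each contrast contributes 2 points for a full hit (passes both the LFC
#' and the significance cutoff), 1 point when only the LFC cutoff is
#' exceeded, else 0, signed by direction (negative = depleted). When the two
#' contrasts disagree in direction, only the dominant direction (larger
#' summed magnitude; ties toward depletion) contributes, so scores stay in
#' \[-4, 4\]. Rubric recorded as attribute `rubric = "default-v1"`.
#'
#' @param calls_et02,calls_et1 per-gene tables from [call_hits()] for the
#'   two E:T ratio contrasts (e.g. 0.2:1 and 1:1)
#' @param lfc_cut the LFC cutoff used for the 1-point tier
#' @return data.frame `gene`, `score_et02`, `score_et1`, `in_vitro_score`
#' @export
in_vitro_score <- function(calls_et02, calls_et1, lfc_cut = 0.25) {
  for (df in list(calls_et02, calls_et1)) {
    check_cols(df, c("gene", "second_best_lfc", "call"), "calls table")
  }
  m <- merge(calls_et02[, c("gene", "second_best_lfc", "call")],
             calls_et1[, c("gene", "second_best_lfc", "call")],
             by = "gene", suffixes = c("_et02", "_et1"))
  if (!nrow(m)) stopf("no genes shared between the two contrasts")
  s1 <- mapply(score_one_contrast, m$call_et02, m$second_best_lfc_et02,
               MoreArgs = list(lfc_cut = lfc_cut))
  s2 <- mapply(score_one_contrast, m$call_et1, m$second_best_lfc_et1,
               MoreArgs = list(lfc_cut = lfc_cut))
  total <- ifelse(sign(s1) * sign(s2) >= 0, s1 + s2, {
    neg <- pmin(s1, 0) + pmin(s2, 0)
    pos <- pmax(s1, 0) + pmax(s2, 0)
    ifelse(abs(neg) >= pos, neg, pos)  # ties toward depletion
  })
  out <- data.frame(gene = m$gene, score_et02 = s1, score_et1 = s2,
                    in_vitro_score = total, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "rubric") <- "default-v1"
  out
}

#' T-cell killing efficiency
#'
#' `(1 - live_treated / live_control) * 100`, the percentage of target cells
#' eliminated in a T-cell co-culture relative to the untreated control.
#'
#' @param live_treated,live_control live cell counts
#' @return percentage
#' @examples
#' killing_efficiency(36, 100)  # 64
#' @export
killing_efficiency <- function(live_treated, live_control) {
  if (any(live_control <= 0)) stopf("`live_control` must be > 0")
  if (any(live_treated < 0)) stopf("`live_treated` must be >= 0")
  (1 - live_treated / live_control) * 100
}
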