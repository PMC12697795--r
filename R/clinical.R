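# Clinical-cohort gene scoring: per-cohort effects (expression fold change
# or survival hazard), cross-cohort patient score with 90th-percentile
# normalization, cytolytic activity, expression stratification, gene sets
# and preranked enrichment.

#' Stratify patients by expression into high and low groups
#'
#' High = the top `q` fraction of patients by expression, exactly
#' `ceiling(q * n)` patients, ties broken by patient id order; the rest are
#' low.
#'
#' @param expr named numeric vector (names = patient ids)
#' @param q fraction labeled high (default 0.25, the top quartile)
#' @return named character vector patient -> `high`/`low`
#' @export
stratify_high_low <- function(expr, q = 0.25) {
  if (length(expr) < 4) stopf("need >= 4 patients to stratify")
  ids <- names(expr)
  if (is.null(ids)) ids <- as.character(seq_along(expr))
  k <- ceiling(q * length(expr))
  ord <- order(-expr, ids)
  out <- rep("low", length(expr))
  out[ord[seq_len(k)]] <- "high"
  stats::setNames(out, ids)
}

#' Survival association of one gene: upper quartile vs rest
#'
#' Patients are split into the top-25% expressors versus the remaining 75%.
#' The log-rank test gives the p-value; the hazard ratio is the ratio of
#' observed-to-expected event counts `(O1/E1)/(O2/E2)` with group 1 = high
#' expression, so HR > 1 means high expression associates with worse
#' survival. A closed-form O/E ratio is used rather than an iterative
#' proportional-hazards fit; it is an approximation adequate for ranking.
#'
#' @param cohort an `expression_cohort` with survival fields
#' @param gene gene symbol
#' @return list `hr`, `p`, `n_high`, `n_low`; `hr` is `NA` (flagged, not
#'   fatal) when a group has zero events
#' @export
gene_survival_association <- function(cohort, gene) {
  stopifnot(inherits(cohort, "expression_cohort"))
  if (is.null(cohort$survival_time)) stopf("cohort has no survival data")
  if (!gene %in% colnames(cohort$tpm)) stopf("gene '%s' not in cohort", gene)
  n <- nrow(cohort$tpm)
  if (n < 8) stopf("need >= 8 patients")
  grp <- stratify_high_low(stats::setNames(cohort$tpm[, gene], rownames(cohort$tpm)))
  high <- grp == "high"
  ev <- cohort$survival_event
  if (sum(ev[high]) == 0 || sum(ev[!high]) == 0) {
    return(list(hr = NA_real_, p = NA_real_,
                n_high = sum(high), n_low = sum(!high)))
  }
  sd <- survival::survdiff(
    survival::Surv(cohort$survival_time, cohort$survival_event) ~ high)
  # survdiff orders groups FALSE, TRUE; group 2 is high expression
  hr <- (sd$obs[2] / sd$exp[2]) / (sd$obs[1] / sd$exp[1])
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  list(hr = unname(hr), p = unname(p), n_high = sum(high), n_low = sum(!high))
}

#' Per-cohort gene effect
#'
#' Response cohorts: `log2((mean TPM in responders + 1) /
#' (mean TPM in nonresponders + 1))`. Survival cohorts: `-log2(HR)` from
#' [gene_survival_association()]. Either way the sign convention is:
#' negative effect = higher expression associated with resistance or worse
#' outcome.
#'
#' @param cohort an `expression_cohort`
#' @return a `cohort_effect`: list with `cohort_id`, `mode`, `n`, and
#'   `effects` (data.frame `gene`, `effect`, `available`)
#' @export
cohort_effect <- function(cohort) {
  stopifnot(inherits(cohort, "expression_cohort"))
  genes <- colnames(cohort$tpm)
  n <- if (!is.null(cohort$n_reported)) cohort$n_reported else nrow(cohort$tpm)
  if (cohort$mode == "response") {
    r <- cohort$response == "responder"
    if (sum(r) < 2 || sum(!r) < 2) stopf("need >= 2 patients per response class")
    eff <- log2((colMeans(cohort$tpm[r, , drop = FALSE]) + 1) /
                (colMeans(cohort$tpm[!r, , drop = FALSE]) + 1))
    avail <- rep(TRUE, length(genes))
  } else {
    if (sum(cohort$survival_event) < 1) stopf("survival cohort has no events")
    assoc <- lapply(genes, function(g) gene_survival_association(cohort, g))
    hr <- vapply(assoc, `[[`, numeric(1), "hr")
    eff <- -log2(hr)
    avail <- is.finite(eff)
  }
  structure(list(cohort_id = cohort$cohort_id, mode = cohort$mode, n = n,
                 effects = data.frame(gene = genes, effect = unname(eff),
                                      available = unname(avail),
                                      row.names = NULL,
                                      stringsAsFactors = FALSE)),
            class = "cohort_effect")
}

#' Pre-tabulated cohort effects
#'
#' Wraps an effect table from a published cohort (gene, effect, cohort n)
#' so it can enter [patient_score()] alongside computed ones.
#'
#' @param effects data.frame with `gene`, `effect`
#' @param cohort_id label
#' @param mode `"response"` or `"survival"`
#' @param n cohort size used as weight
#' @return a `cohort_effect`
#' @export
cohort_effect_table <- function(effects, cohort_id, mode, n) {
  check_cols(effects, c("gene", "effect"), "`effects`")
  if (!mode %in% c("response", "survival")) stopf("invalid mode '%s'", mode)
  if (n < 1) stopf("`n` must be >= 1")
  structure(list(cohort_id = cohort_id, mode = mode, n = n,
                 effects = data.frame(gene = effects$gene,
                                      effect = effects$effect,
                                      available = is.finite(effects$effect),
                                      stringsAsFactors = FALSE)),
            class = "cohort_effect")
}

#' Cross-cohort patient score
#'
#' Per gene, the weighted mean of its available cohort effects; weights are
#' cohort sizes (`"n"`) or equal. Genes covered by no cohort are dropped
#' (count reported via message).
#'
#' @param effects list of `cohort_effect` objects
#' @param weighting `"n"` or `"equal"`
#' @return named numeric vector gene -> score
#' @export
patient_score <- function(effects, weighting = c("n", "equal")) {
  weighting <- match.arg(weighting)
  stopifnot(length(effects) >= 1, all(vapply(effects, inherits, logical(1),
                                             "cohort_effect")))
  genes <- unique(unlist(lapply(effects, function(e) e$effects$gene)))
  num <- den <- stats::setNames(rep(0, length(genes)), genes)
  for (e in effects) {
    tab <- e$effects[e$effects$available & is.finite(e$effects$effect), ]
    w <- if (weighting == "n") e$n else 1
    num[tab$gene] <- num[tab$gene] + w * tab$effect
    den[tab$gene] <- den[tab$gene] + w
  }
  dropped <- sum(den == 0)
  if (dropped > 0) message(sprintf("patient_score: dropped %d gene(s) covered by no cohort", dropped))
  (num / den)[den > 0]
}

#' Rescale scores so the absolute 90th percentile equals a target
#'
#' Every score is multiplied by `target / |P90|`, where P90 is the 90th
#' percentile with linear interpolation. Puts heterogeneous score vectors
#' (expression fold changes, hazard ratios, screen z-scores) on one common
#' scale before they are summed. Idempotent and positively homogeneous.
#'
#' @param scores numeric vector (names preserved)
#' @param target desired `|P90|`; default 2
#' @return rescaled scores
#' @export
normalize_q90 <- function(scores, target = 2) {
  if (!length(scores)) stopf("empty score vector")
  p90 <- quantile_linear(scores, 0.9)
  if (p90 == 0) stopf("degenerate input: 90th percentile is 0")
  scores * (target / abs(p90))
}

#' Intratumoral cytolytic activity score
#'
#' Geometric mean of GZMA and PRF1 expression (TPM) -- a proxy for the
#' magnitude of cytotoxic immune activity in a tumor.
#'
#' @param gzma_tpm,prf1_tpm non-negative TPM values (vectorized)
#' @return `sqrt(gzma_tpm * prf1_tpm)`
#' @export
cytolytic_activity <- function(gzma_tpm, prf1_tpm) {
  if (any(gzma_tpm < 0) || any(prf1_tpm < 0)) stopf("TPM inputs must be >= 0")
  sqrt(gzma_tpm * prf1_tpm)
}

#' Responder and nonresponder gene sets from a differential table
#'
#' The `k` genes with the largest log2 fold change (responder-high) form the
#' responder set, the `k` smallest the nonresponder set; boundary ties break
#' lexicographically by gene id.
#'
#' @param de data.frame with `gene`, `log2fc`
#' @param k set size (default 100)
#' @return list of two `gene_set`s: `responder`, `nonresponder`
#' @export
derive_response_gene_sets <- function(de, k = 100L) {
  check_cols(de, c("gene", "log2fc"), "`de`")
  de <- de[is.finite(de$log2fc), , drop = FALSE]
  if (nrow(de) < 2 * k) {
    stopf("need >= %d genes with finite log2fc, have %d", 2 * k, nrow(de))
  }
  up <- de$gene[order(-de$log2fc, de$gene)][seq_len(k)]
  dn <- de$gene[order(de$log2fc, de$gene)][seq_len(k)]
  list(responder = gene_set("responder", up),
       nonresponder = gene_set("nonresponder", dn))
}

#' A named, duplicate-free gene set
#'
#' @param name set name
#' @param genes character vector of symbols (non-empty, no duplicates)
#' @return a `gene_set`
#' @export
gene_set <- function(name, genes) {
  if (!length(genes)) stopf("gene set '%s' is empty", name)
  if (anyDuplicated(genes)) stopf("gene set '%s' has duplicate genes", name)
  structure(list(name = name, genes = as.character(genes)), class = "gene_set")
}

running_es <- function(metric_sorted, member, weight_p) {
  hit_w <- abs(metric_sorted)^weight_p * member
  denom_hit <- sum(hit_w)
  if (denom_hit == 0) hit_w <- member / sum(member) else hit_w <- hit_w / denom_hit
  miss_w <- (!member) / sum(!member)
  rs <- cumsum(hit_w - miss_w)
  rs[which.max(abs(rs))]
}

#' Preranked gene-set enrichment
#'
#' Classic weighted Kolmogorov-Smirnov running sum over the ranking: member
#' genes increment proportionally to `|metric|^weight_p`, non-members
#' decrement uniformly; ES is the signed extremum. Significance comes from
#' `n_perm` random gene-label permutations: `NES = ES / mean(|perm ES|)`
#' over same-sign permutations, and the p-value is the fraction of same-sign
#' permutation ES at least as extreme. When several gene sets are supplied,
#' BH-FDR is computed across them.
#'
#' @param ranked named numeric vector: gene -> ranking metric
#' @param gene_sets a `gene_set` or list of them (all must intersect
#'   `ranked`)
#' @param weight_p metric weight exponent (default 1)
#' @param n_perm label permutations (>= 100)
#' @param seed integer seed
#' @return data.frame `set`, `size`, `es`, `nes`, `p`, `fdr`
#' @export
preranked_enrichment <- function(ranked, gene_sets, weight_p = 1,
                                 n_perm = 1000L, seed = 1L) {
  if (inherits(gene_sets, "gene_set")) gene_sets <- list(gene_sets)
  if (n_perm < 100) stopf("`n_perm` must be >= 100")
  ord <- order(-ranked, names(ranked))
  metric <- ranked[ord]
  genes <- names(metric)
  with_seed(seed, {
    rows <- lapply(gene_sets, function(gs) {
      stopifnot(inherits(gs, "gene_set"))
      member <- genes %in% gs$genes
      k <- sum(member)
      if (k == 0) stopf("gene set '%s' does not intersect the ranking", gs$name)
      if (k == length(genes)) stopf("gene set '%s' covers the whole ranking", gs$name)
      es <- running_es(metric, member, weight_p)
      perm_es <- vapply(seq_len(n_perm), function(i) {
        pm <- logical(length(genes))
        pm[sample.int(length(genes), k)] <- TRUE
        running_es(metric, pm, weight_p)
      }, numeric(1))
      same <- perm_es[sign(perm_es) == sign(es)]
      nes <- if (length(same)) es / mean(abs(same)) else sign(es) * Inf
      p <- (1 + sum(abs(same) >= abs(es))) / (length(same) + 1)
      data.frame(set = gs$name, size = k, es = es, nes = nes, p = p,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$fdr <- stats::p.adjust(out$p, "BH")
    rownames(out) <- NULL
    out
  })
}
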