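# Score integration: merged score, ICB sublibrary selection, total score.

#' Merged gene score
#'
#' Elementwise sum of the in vitro score and the (already |P90|-normalized)
#' patient score over the genes present in both; genes missing either input
#' are dropped (count reported via message).
#'
#' @param in_vitro named numeric vector gene -> in vitro score
#' @param patient_norm named numeric vector gene -> normalized patient score
#' @return named numeric vector gene -> merged score
#' @export
merged_score <- function(in_vitro, patient_norm) {
  common <- intersect(names(in_vitro), names(patient_norm))
  if (!length(common)) stopf("no genes shared between in vitro and patient scores")
  dropped <- length(union(names(in_vitro), names(patient_norm))) - length(common)
  if (dropped > 0) {
    message(sprintf("merged_score: dropped %d gene(s) missing one input", dropped))
  }
  in_vitro[common] + patient_norm[common]
}

#' Select the ICB sublibrary from merged scores
#'
#' Enriched genes = up to `k_pos` genes with the largest strictly positive
#' merged scores; depleted genes = up to `k_neg` with the most negative
#' strictly negative scores. If fewer qualify, all qualifying genes are
#' taken with a warning. Boundary ties break lexicographically by gene id.
#' Essential and safe-targeting controls ride along as metadata.
#'
#' @param merged named numeric vector gene -> merged score
#' @param k_pos,k_neg selection sizes (defaults 100 and 400)
#' @param essential_genes control genes to carry into the sublibrary
#' @param n_safe number of safe-targeting control guides to include
#' @return list `enriched`, `depleted` (character vectors), `controls`
#'   (list `essential`, `n_safe`)
#' @export
select_sublibrary <- function(merged, k_pos = 100L, k_neg = 400L,
                              essential_genes = character(0), n_safe = 0L) {
  genes <- names(merged)
  pos <- genes[merged > 0]
  neg <- genes[merged < 0]
  if (length(pos) < k_pos) {
    warning(sprintf("only %d strictly positive merged scores for k_pos = %d",
                    length(pos), k_pos))
  }
  if (length(neg) < k_neg) {
    warning(sprintf("only %d strictly negative merged scores for k_neg = %d",
                    length(neg), k_neg))
  }
  enriched <- pos[order(-merged[pos], pos)][seq_len(min(k_pos, length(pos)))]
  depleted <- neg[order(merged[neg], neg)][seq_len(min(k_neg, length(neg)))]
  list(enriched = enriched, depleted = depleted,
       controls = list(essential = essential_genes, n_safe = as.integer(n_safe)))
}

#' Total score and final gene ranking
#'
#' `total = merged + responder DrugZ score` when the merged score is
#' negative, else `merged + nonresponder DrugZ score`; zero merged scores
#' use the branch named by `zero_branch`. All three inputs must already be
#' on the common |P90| = `q90_target` scale ([normalize_q90()]); this is
#' asserted, not silently re-applied. Genes are ranked ascending: the most
#' negative total marks the strongest immune-resistance candidate. Genes
#' missing a needed DrugZ score are dropped (count via message).
#'
#' @param merged_norm,drugz_resp_norm,drugz_nonresp_norm named numeric
#'   vectors, each normalized via [normalize_q90()]
#' @param zero_branch branch for merged == 0; default `"nonresponder"`
#' @param q90_target the normalization target to assert (default 2);
#'   `NA` skips the assertion
#' @return data.frame `gene`, `merged`, `branch`, `drugz`, `total`, `rank`
#' @export
total_score <- function(merged_norm, drugz_resp_norm, drugz_nonresp_norm,
                        zero_branch = c("nonresponder", "responder"),
                        q90_target = 2) {
  zero_branch <- match.arg(zero_branch)
  if (!is.na(q90_target)) {
    for (v in list(merged = merged_norm, responder = drugz_resp_norm,
                   nonresponder = drugz_nonresp_norm)) {
      if (abs(abs(quantile_linear(v, 0.9)) - q90_target) > 1e-8) {
        stopf("inputs must be normalized to |P90| = %g before total_score",
              q90_target)
      }
    }
  }
  genes <- names(merged_norm)
  use_resp <- merged_norm < 0 | (merged_norm == 0 & zero_branch == "responder")
  dz <- ifelse(use_resp, drugz_resp_norm[genes], drugz_nonresp_norm[genes])
  keep <- is.finite(dz)
  if (any(!keep)) {
    message(sprintf("total_score: dropped %d gene(s) missing a DrugZ score",
                    sum(!keep)))
  }
  out <- data.frame(gene = genes[keep], merged = unname(merged_norm[keep]),
                    branch = ifelse(use_resp[keep], "responder", "nonresponder"),
                    drugz = unname(dz[keep]),
                    total = unname(merged_norm[keep] + dz[keep]),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$total, out$gene), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
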