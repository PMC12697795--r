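# Concordance between in vivo screen directions and an external reference
# (clinical expression-survival association or the in vitro screen).

#' Classify per-gene concordance
#'
#' A gene is concordant when its guides were depleted in vivo and the
#' reference marks it as a resistance gene (survival: HR > 1, i.e. lower
#' expression associated with better survival; in vitro: called depleted),
#' or when its guides were enriched and the reference marks it sensitizing
#' (HR < 1 / called enriched). Directionless reference genes (HR exactly 1,
#' or an `ns` in vitro call) are excluded, with the count reported.
#'
#' @param invivo data.frame with `gene` and `direction`
#'   (`depleted`/`enriched`)
#' @param reference for `kind = "survival"`: data.frame `gene`, `hr`; for
#'   `kind = "invitro"`: data.frame `gene`, `call`
#' @param kind `"survival"` or `"invitro"`
#' @return data.frame `gene`, `invivo_direction`, `reference_direction`
#'   (`resistance`/`sensitizing`), `concordant`; attribute `n_excluded`
#' @export
classify_concordance <- function(invivo, reference,
                                 kind = c("survival", "invitro")) {
  kind <- match.arg(kind)
  check_cols(invivo, c("gene", "direction"), "`invivo`")
  if (!all(invivo$direction %in% c("depleted", "enriched"))) {
    stopf("in vivo directions must be 'depleted' or 'enriched'")
  }
  if (kind == "survival") {
    check_cols(reference, c("gene", "hr"), "`reference`")
    ref_dir <- ifelse(reference$hr > 1, "resistance",
                      ifelse(reference$hr < 1, "sensitizing", NA))
  } else {
    check_cols(reference, c("gene", "call"), "`reference`")
    ref_dir <- ifelse(reference$call == "depleted", "resistance",
                      ifelse(reference$call == "enriched", "sensitizing", NA))
  }
  ref <- data.frame(gene = reference$gene, reference_direction = ref_dir,
                    stringsAsFactors = FALSE)
  m <- merge(invivo[, c("gene", "direction")], ref, by = "gene")
  if (!nrow(m)) stopf("no genes shared between the in vivo table and the reference")
  n_excluded <- sum(is.na(m$reference_direction))
  m <- m[!is.na(m$reference_direction), , drop = FALSE]
  if (!nrow(m)) stopf("all shared genes are directionless in the reference")
  out <- data.frame(gene = m$gene, invivo_direction = m$direction,
                    reference_direction = m$reference_direction,
                    concordant = (m$direction == "depleted" &
                                    m$reference_direction == "resistance") |
                                 (m$direction == "enriched" &
                                    m$reference_direction == "sensitizing"),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Concordance rate and exact binomial test against 50%
#'
#' @param records output of [classify_concordance()] (or any data.frame
#'   with a logical `concordant` column)
#' @param label optional group label carried into the summary
#' @return data.frame `label`, `n`, `n_concordant`, `rate`, `binomial_p`
#'   (two-sided exact test vs 0.5)
#' @export
concordance_rate_test <- function(records, label = "all") {
  check_cols(records, "concordant", "`records`")
  n <- nrow(records)
  if (n < 1) stopf("need >= 1 record")
  k <- sum(records$concordant)
  p <- stats::binom.test(k, n, p = 0.5, alternative = "two.sided")$p.value
  data.frame(label = label, n = n, n_concordant = k, rate = k / n,
             binomial_p = p, stringsAsFactors = FALSE)
}
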