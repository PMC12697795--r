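# Translation efficiency from paired ribosome/RNA fold changes, and its
# analysis by Kozak-sequence strength category.

#' Translation efficiency
#'
#' `log2(fc_ribo / fc_rna)`: the change in active-ribosome occupancy not
#' explained by the change in transcript abundance. Inputs are linear-scale
#' fold changes (ratios), both strictly positive.
#'
#' @param fc_ribo,fc_rna positive fold changes (vectorized)
#' @return TE in log2 units
#' @export
translation_efficiency <- function(fc_ribo, fc_rna) {
  if (any(fc_ribo <= 0) || any(fc_rna <= 0)) {
    stopf("fold changes must be strictly positive")
  }
  log2(fc_ribo / fc_rna)
}

#' Kozak-strength category of a transcript
#'
#' From the multiset of Kozak strengths of a transcript's start contexts:
#' two or more strong -> `Supreme`; exactly one strong -> `Strong`; else at
#' least one moderate -> `Moderate`; else (none, or only weak) -> `No`.
#'
#' @param strengths character vector over `weak`, `moderate`, `strong`
#'   (order-irrelevant; may be empty)
#' @return one of `"No"`, `"Moderate"`, `"Strong"`, `"Supreme"`
#' @export
kozak_category <- function(strengths) {
  bad <- setdiff(strengths, c("weak", "moderate", "strong"))
  if (length(bad)) stopf("unknown Kozak strength label(s): %s",
                         paste(unique(bad), collapse = ", "))
  n_strong <- sum(strengths == "strong")
  if (n_strong >= 2) return("Supreme")
  if (n_strong == 1) return("Strong")
  if (any(strengths == "moderate")) return("Moderate")
  "No"
}

#' Build TE records from a fold-change table
#'
#' @param tab data.frame with `transcript_id`, `fc_ribo`, `fc_rna`, `kozak`
#'   (semicolon-joined strength labels; empty string = none)
#' @return the table with added `te` and `category` columns
#' @export
te_records <- function(tab) {
  check_cols(tab, c("transcript_id", "fc_ribo", "fc_rna", "kozak"), "`tab`")
  strengths <- strsplit(ifelse(is.na(tab$kozak), "", tab$kozak), ";", fixed = TRUE)
  strengths <- lapply(strengths, function(s) s[nzchar(s)])
  tab$te <- translation_efficiency(tab$fc_ribo, tab$fc_rna)
  tab$category <- vapply(strengths, kozak_category, character(1))
  tab
}

#' Compare translation efficiency across Kozak categories
#'
#' Per-category summaries plus a two-sided rank-sum (Wilcoxon) test of each
#' category against the `No` (no/weak Kozak) baseline. Categories with a
#' single record get p = 1 with a warning.
#'
#' @param records output of [te_records()]
#' @return data.frame `category`, `n`, `mean_te`, `frac_te_negative`,
#'   `p_vs_no`
#' @export
compare_te_by_category <- function(records) {
  check_cols(records, c("te", "category"), "`records`")
  cats <- intersect(kozak_categories(), unique(records$category))
  if (length(cats) < 2) stopf("need >= 2 non-empty Kozak categories")
  if (!"No" %in% cats) stopf("baseline category 'No' is empty")
  te_no <- records$te[records$category == "No"]
  rows <- lapply(cats, function(cat) {
    te <- records$te[records$category == cat]
    p <- if (cat == "No") {
      NA_real_
    } else if (length(te) < 2 || length(te_no) < 2) {
      warning(sprintf("category '%s' has a single record; p set to 1", cat))
      1
    } else {
      stats::wilcox.test(te, te_no, alternative = "two.sided", exact = FALSE)$p.value
    }
    data.frame(category = cat, n = length(te), mean_te = mean(te),
               frac_te_negative = mean(te < 0), p_vs_no = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
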