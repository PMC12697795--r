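# In vivo screen statistics: responder stratification by tumor size and a
# modified DrugZ analysis (safe-guide normalization; gene scores reported
# without the final z-normalization).

#' Stratify treated mice into responders and nonresponders
#'
#' Anti-PD-1-treated mice below the median tumor volume are responders;
#' those above are nonresponders. Mice exactly at the median are assigned
#' nonresponder so ties never inflate the responder arm. Mock and NSG mice
#' are left unlabeled.
#'
#' @param records data.frame with `mouse_id`, `arm` (`mock`, `anti_pd1`,
#'   `nsg`), `tumor_volume` (mm^3, > 0)
#' @return named character vector mouse_id -> `responder`/`nonresponder`
#'   (treated mice only)
#' @export
stratify_responders <- function(records) {
  check_cols(records, c("mouse_id", "arm", "tumor_volume"), "`records`")
  if (any(records$tumor_volume <= 0)) stopf("tumor volumes must be > 0")
  tr <- records[records$arm == "anti_pd1", , drop = FALSE]
  if (nrow(tr) < 2) stopf("need >= 2 anti_pd1 mice to stratify")
  med <- stats::median(tr$tumor_volume)
  stats::setNames(ifelse(tr$tumor_volume < med, "responder", "nonresponder"),
                  tr$mouse_id)
}

#' DrugZ-style guide z-scores
#'
#' Per replicate pair, the guide fold change is
#' `log2((t + pc) / (c + pc))` on normalized abundances. Guides are ranked
#' by control abundance (descending) and each guide's empirical-Bayes SD is
#' the standard deviation of fold changes within the rank window of
#' `half_window` guides on each side (clipped at the boundaries), borrowing
#' variance information from similarly-abundant guides; `z = fc / EB-SD`.
#' Replicates are paired in order; unpaired extras are dropped with a
#' warning.
#'
#' @param norm safe-guide-normalized guide x sample matrix (see
#'   [normalize_counts()] with `method = "safe_guides"`)
#' @param samples sample sheet (`sample`, `arm`, `replicate`)
#' @param treated,control arm names
#' @param lib guide library
#' @param pseudocount default 5
#' @param half_window rank window half-width; default 500
#' @return data.frame `guide_id`, `gene`, `replicate`, `fc`, `eb_sd`, `z`
#' @export
drugz_guide_z <- function(norm, samples, treated, control, lib,
                          pseudocount = 5, half_window = 500L) {
  check_cols(samples, c("sample", "arm"), "`samples`")
  st <- samples$sample[samples$arm == treated]
  sc <- samples$sample[samples$arm == control]
  if (!length(st)) stopf("unknown or empty arm: '%s'", treated)
  if (!length(sc)) stopf("unknown or empty arm: '%s'", control)
  npair <- min(length(st), length(sc))
  if (length(st) != length(sc)) {
    warning(sprintf("unequal replicates (%d vs %d); pairing the first %d",
                    length(st), length(sc), npair))
  }
  n <- nrow(norm)
  hw <- as.integer(half_window)
  if (n < 2L * hw) {
    warning(sprintf("only %d guides for half_window %d; window shrunk", n, hw))
    hw <- max(1L, n %/% 2L)
  }
  gene <- lib$gene[match(rownames(norm), lib$guide_id)]
  if (anyNA(gene)) stopf("guide(s) missing from library")
  out <- lapply(seq_len(npair), function(i) {
    tt <- norm[, st[i]]
    cc <- norm[, sc[i]]
    fc <- log2((tt + pseudocount) / (cc + pseudocount))
    ord <- order(cc, decreasing = TRUE)
    sd_ranked <- vapply(seq_len(n), function(r) {
      w <- max(1L, r - hw):min(n, r + hw)
      stats::sd(fc[ord][w])
    }, numeric(1))
    eb_sd <- numeric(n)
    eb_sd[ord] <- sd_ranked
    eb_sd[eb_sd == 0 | !is.finite(eb_sd)] <- NA_real_
    z <- fc / eb_sd
    z[is.na(z)] <- 0  # degenerate window: no variance information
    data.frame(guide_id = rownames(norm), gene = gene, replicate = i,
               fc = fc, eb_sd = eb_sd, z = z, row.names = NULL,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Gene-level DrugZ statistics
#'
#' Guide z-scores are summed per gene across replicates (`sumZ`, over
#' `n = guides x replicates` terms). In the default mode the reported
#' `gene_score` is the mean guide z (`sumZ / n`) -- the fold-change scale is
#' kept, not renormalized -- which suits libraries skewed toward depleted
#' genes where the classic normalization recenters real signal. With
#' `z_normalize_final = TRUE` the classic `normZ = sumZ / sqrt(n)` is
#' reported instead. Either way, p-values use the classical normal null on
#' `sumZ / sqrt(n)`: lower tail for depletion, upper for enrichment, with
#' Benjamini-Hochberg FDR within each tail. Safe-targeting controls are
#' excluded from the gene table.
#'
#' @param gz guide z table from [drugz_guide_z()]
#' @param z_normalize_final report classic normZ instead of mean z
#' @return data.frame `gene`, `n`, `n_guides`, `sumZ`, `gene_score`,
#'   `p_depleted`, `p_enriched`, `fdr_depleted`, `fdr_enriched`; attribute
#'   `mode` records which score was reported
#' @export
drugz_gene_stat <- function(gz, z_normalize_final = FALSE) {
  check_cols(gz, c("guide_id", "gene", "z"), "`gz`")
  real <- gz[gz$gene != safe_gene_label(), , drop = FALSE]
  sp <- split(real$z, real$gene)
  sumZ <- vapply(sp, sum, numeric(1))
  n <- lengths(sp)
  n_guides <- vapply(split(real$guide_id, real$gene),
                     function(g) length(unique(g)), integer(1))
  normZ <- sumZ / sqrt(n)
  p_dep <- stats::pnorm(normZ)
  p_enr <- stats::pnorm(normZ, lower.tail = FALSE)
  out <- data.frame(gene = names(sp), n = as.integer(n),
                    n_guides = as.integer(n_guides), sumZ = unname(sumZ),
                    gene_score = unname(if (z_normalize_final) normZ else sumZ / n),
                    p_depleted = unname(p_dep), p_enriched = unname(p_enr),
                    fdr_depleted = unname(stats::p.adjust(p_dep, "BH")),
                    fdr_enriched = unname(stats::p.adjust(p_enr, "BH")),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "mode") <- if (z_normalize_final) "classic-normZ" else "mean-z"
  out
}
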