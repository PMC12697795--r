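#' Simulate a pooled CRISPR guide library
#'
#' Builds a guide-to-gene map of the kind used by pooled immune screens:
#' genes of interest expected to deplete or enrich under immune selection,
#' essential genes (positive controls for editing), and single safe-targeting
#' guides that cut non-functional loci and share the reserved label
#' [safe_gene_label()].
#'
#' @param n_depleted,n_enriched,n_essential number of genes per class
#' @param n_safe number of safe-targeting guides (single, non-genic entries)
#' @param guides_per_gene guides designed per real gene (>= 1)
#' @param seed integer seed; the returned row order is a seeded shuffle so
#'   that guide order never encodes gene class
#' @return a `data.frame` with columns `guide_id`, `gene`, `guide_class`
#'   (one of `goi_depleted`, `goi_enriched`, `essential`, `safe`)
#' @examples
#' lib <- simulate_library(400, 100, 30, 100, guides_per_gene = 5, seed = 1)
#' nrow(lib)                       # 2750 guides
#' length(setdiff(unique(lib$gene), safe_gene_label()))  # 530 genes
#' @export
simulate_library <- function(n_depleted, n_enriched, n_essential, n_safe,
                             guides_per_gene = 5L, seed = 1L) {
  n_depleted  <- check_nonneg_int(n_depleted, "n_depleted")
  n_enriched  <- check_nonneg_int(n_enriched, "n_enriched")
  n_essential <- check_nonneg_int(n_essential, "n_essential")
  n_safe      <- check_nonneg_int(n_safe, "n_safe")
  if (!is.numeric(guides_per_gene) || guides_per_gene < 1) {
    stopf("`guides_per_gene` must be >= 1")
  }
  gpg <- as.integer(guides_per_gene)

  mk <- function(prefix, n) if (n > 0) sprintf("%s%04d", prefix, seq_len(n)) else character(0)
  genes <- c(mk("DEP", n_depleted), mk("ENR", n_enriched), mk("ESS", n_essential))
  class <- rep(c("goi_depleted", "goi_enriched", "essential"),
               times = c(n_depleted, n_enriched, n_essential))

  genic <- if (length(genes)) data.frame(
    guide_id    = paste0(rep(genes, each = gpg), "_g", seq_len(gpg)),
    gene        = rep(genes, each = gpg),
    guide_class = rep(class, each = gpg),
    stringsAsFactors = FALSE
  ) else data.frame(guide_id = character(0), gene = character(0),
                    guide_class = character(0), stringsAsFactors = FALSE)

  safe <- if (n_safe > 0) data.frame(
    guide_id    = sprintf("SAFE_%04d", seq_len(n_safe)),
    gene        = safe_gene_label(),
    guide_class = "safe",
    stringsAsFactors = FALSE
  ) else NULL

  lib <- rbind(genic, safe)
  lib <- with_seed(seed, lib[sample.int(nrow(lib)), , drop = FALSE])
  rownames(lib) <- NULL
  lib
}

#' Describe a screen's arms and sequencing model
#'
#' @param arms data.frame with columns `name`, `role`, `replicates`; roles are
#'   `reference` (pre-selection plasmid/early pool), `control`/`treated`
#'   (in vitro expansion without/with T cells), and the in vivo roles `nsg`,
#'   `mock`, `responder`, `nonresponder`
#' @param depth expected reads per sample
#' @param dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); typical pooled-screen values 0.05-0.5
#' @param bottleneck fraction of injected lineages that engraft, applied to
#'   the in vivo roles only; 1 means no engraftment loss
#' @return a `screen_design` list
#' @export
screen_design <- function(arms, depth = 5e6, dispersion = 0.2, bottleneck = 1) {
  check_cols(arms, c("name", "role", "replicates"), "`arms`")
  roles <- c("reference", "control", "treated", "nsg", "mock",
             "responder", "nonresponder")
  bad <- setdiff(arms$role, roles)
  if (length(bad)) stopf("unknown arm role(s): %s", paste(bad, collapse = ", "))
  if (anyDuplicated(arms$name)) stopf("duplicate arm names")
  if (any(arms$replicates < 1)) stopf("`replicates` must be >= 1")
  if (depth <= 0) stopf("`depth` must be > 0")
  if (dispersion <= 0) stopf("`dispersion` must be > 0")
  if (bottleneck <= 0 || bottleneck > 1) stopf("`bottleneck` must be in (0, 1]")
  structure(list(arms = as.data.frame(arms), depth = depth,
                 dispersion = dispersion, bottleneck = bottleneck),
            class = "screen_design")
}

in_vivo_roles <- function() c("nsg", "mock", "responder", "nonresponder")

#' Ground-truth selection effects for a simulated screen
#'
#' @param lib guide library from [simulate_library()]
#' @param arm_effects named list: arm name -> named numeric vector of per-gene
#'   log2 selection coefficients; genes not named get 0. Safe guides always
#'   have effect 0 and must not be assigned one.
#' @return `simulation_truth`: a gene x arm effect matrix plus class labels
#' @export
simulation_truth <- function(lib, arm_effects = list()) {
  genes <- unique(lib$gene)
  arms <- names(arm_effects)
  eff <- matrix(0, nrow = length(genes), ncol = length(arms),
                dimnames = list(genes, arms))
  for (a in arms) {
    v <- arm_effects[[a]]
    if (is.null(names(v))) stopf("arm_effects[['%s']] must be a named vector", a)
    unknown <- setdiff(names(v), genes)
    if (length(unknown)) {
      stopf("arm_effects[['%s']] names not in library: %s", a,
            paste(utils::head(unknown, 3), collapse = ", "))
    }
    if (safe_gene_label() %in% names(v) && any(v[safe_gene_label()] != 0)) {
      stopf("safe-targeting controls cannot carry a selection effect")
    }
    eff[names(v), a] <- v
  }
  cls <- lib$guide_class[match(genes, lib$gene)]
  structure(list(effects = eff, class = stats::setNames(cls, genes)),
            class = "simulation_truth")
}

truth_effect <- function(truth, genes, arm) {
  if (arm %in% colnames(truth$effects)) truth$effects[genes, arm] else rep(0, length(genes))
}

#' Simulate guide counts for a pooled screen
#'
#' Counts are gamma-Poisson (negative binomial) around `depth` times each
#' guide's relative abundance. A treated arm multiplies the reference
#' abundance of a guide by `2^effect` of its gene in that arm. In vivo arms
#' (`nsg`, `mock`, `responder`, `nonresponder`) first subsample a fixed
#' lineage pool binomially at the design's `bottleneck` fraction, per
#' replicate, before selection acts -- engraftment loss being the dominant
#' extra noise source in transplantation screens.
#'
#' @param lib guide library
#' @param design a [screen_design()]
#' @param truth a [simulation_truth()]; must cover every gene in `lib`
#' @param seed integer seed
#' @param lineage_coverage lineages per guide in the pre-injection pool
#'   (in vivo arms only)
#' @return list with `counts` (integer guide x sample matrix) and `samples`
#'   (data.frame `sample`, `arm`, `role`, `replicate`)
#' @export
simulate_screen_counts <- function(lib, design, truth, seed,
                                   lineage_coverage = 100) {
  stopifnot(inherits(design, "screen_design"), inherits(truth, "simulation_truth"))
  missing_genes <- setdiff(unique(lib$gene), rownames(truth$effects))
  if (length(missing_genes)) {
    stopf("truth does not cover gene(s): %s",
          paste(utils::head(missing_genes, 3), collapse = ", "))
  }
  n <- nrow(lib)
  with_seed(seed, {
    # fixed per-guide representation of the plasmid pool (cloning skew)
    base <- exp(stats::rnorm(n, 0, 0.5))
    p0 <- base / sum(base)

    samples <- do.call(rbind, lapply(seq_len(nrow(design$arms)), function(i) {
      a <- design$arms[i, ]
      data.frame(sample = paste0(a$name, "_r", seq_len(a$replicates)),
                 arm = a$name, role = a$role, replicate = seq_len(a$replicates),
                 stringsAsFactors = FALSE)
    }))
    counts <- matrix(0L, nrow = n, ncol = nrow(samples),
                     dimnames = list(lib$guide_id, samples$sample))
    pool <- max(1L, round(lineage_coverage * n))
    for (j in seq_len(nrow(samples))) {
      eff <- truth_effect(truth, lib$gene, samples$arm[j])
      w <- p0
      if (samples$role[j] %in% in_vivo_roles() && design$bottleneck < 1) {
        lineages <- as.numeric(stats::rmultinom(1, pool, p0))
        kept <- stats::rbinom(n, lineages, design$bottleneck)
        w <- kept
      }
      w <- w * 2^eff
      if (sum(w) == 0) w <- rep(1, n)  # pathological bottleneck wipe-out
      mu <- design$depth * w / sum(w)
      counts[, j] <- stats::rnbinom(n, mu = mu, size = 1 / design$dispersion)
    }
    list(counts = counts, samples = samples)
  })
}

#' Simulate an ICB-treated patient cohort
#'
#' Expression is log-normal per gene; in `response` mode the probability of
#' responding follows a logistic link on the planted genes' standardized
#' log-expression; in `survival` mode times are exponential with log-hazard
#' linear in the same standardized expression, with independent uniform
#' censoring over \[0, 2 x median survival\].
#'
#' @param n_patients cohort size (>= 8)
#' @param n_genes number of genes (named `G0001`, ...), or a character
#'   vector of gene symbols to use directly
#' @param planted named numeric vector gene -> effect per SD of
#'   log2-expression: log-odds of response (`response` mode) or log-hazard
#'   (`survival` mode)
#' @param mode `"response"` or `"survival"`
#' @param seed integer seed
#' @param median_survival baseline median survival in months (survival mode)
#' @return an `expression_cohort`: list with `cohort_id`, `mode`, `tpm`
#'   (patient x gene matrix), and `response` or `survival_time`/`survival_event`
#' @export
simulate_cohort <- function(n_patients, n_genes, planted = numeric(0),
                            mode = c("response", "survival"), seed = 1L,
                            median_survival = 12) {
  mode <- match.arg(mode)
  if (n_patients < 8) stopf("`n_patients` must be >= 8")
  genes <- if (is.character(n_genes)) n_genes else sprintf("G%04d", seq_len(n_genes))
  n_genes <- length(genes)
  if (length(planted)) {
    unknown <- setdiff(names(planted), genes)
    if (length(unknown)) {
      stopf("planted gene(s) not in gene list: %s",
            paste(utils::head(unknown, 3), collapse = ", "))
    }
  }
  with_seed(seed, {
    mu <- stats::runif(n_genes, 1, 6)
    x <- matrix(stats::rnorm(n_patients * n_genes, mean = rep(mu, each = n_patients), sd = 1),
                nrow = n_patients, ncol = n_genes,
                dimnames = list(sprintf("P%04d", seq_len(n_patients)), genes))
    tpm <- 2^x
    lp <- rep(0, n_patients)
    for (g in names(planted)) {
      z <- (x[, g] - mean(x[, g])) / stats::sd(x[, g])
      lp <- lp + planted[[g]] * z
    }
    out <- list(cohort_id = sprintf("SIM%d", seed), mode = mode, tpm = tpm)
    if (mode == "response") {
      pr <- stats::plogis(lp)
      out$response <- ifelse(stats::runif(n_patients) < pr, "responder", "nonresponder")
    } else {
      rate0 <- log(2) / median_survival
      t_event <- stats::rexp(n_patients, rate = rate0 * exp(lp))
      t_cens <- stats::runif(n_patients, 0, 2 * median_survival)
      out$survival_time <- pmin(t_event, t_cens)
      out$survival_event <- t_event <= t_cens
    }
    structure(out, class = "expression_cohort")
  })
}

#' Wrap existing expression and outcome data as a cohort
#'
#' @param tpm patient x gene non-negative matrix
#' @param response optional character vector (`responder`/`nonresponder`)
#' @param survival_time,survival_event optional survival fields
#' @param cohort_id label
#' @param n_reported cohort size to use as weighting `n` (defaults to rows)
#' @return an `expression_cohort`
#' @export
expression_cohort <- function(tpm, response = NULL, survival_time = NULL,
                              survival_event = NULL, cohort_id = "cohort",
                              n_reported = nrow(tpm)) {
  tpm <- as.matrix(tpm)
  if (any(tpm < 0)) stopf("TPM values must be non-negative")
  has_resp <- !is.null(response)
  has_surv <- !is.null(survival_time) && !is.null(survival_event)
  if (!has_resp && !has_surv) stopf("cohort needs a response label or survival data")
  if (has_resp && length(response) != nrow(tpm)) stopf("`response` length mismatch")
  if (has_surv && (length(survival_time) != nrow(tpm) ||
                   length(survival_event) != nrow(tpm))) {
    stopf("survival field length mismatch")
  }
  out <- list(cohort_id = cohort_id, mode = if (has_resp) "response" else "survival",
              tpm = tpm, n_reported = n_reported)
  if (has_resp) out$response <- response
  if (has_surv) { out$survival_time <- survival_time; out$survival_event <- survival_event }
  structure(out, class = "expression_cohort")
}

kozak_categories <- function() c("No", "Moderate", "Strong", "Supreme")

#' Simulate a translation-efficiency table with Kozak annotations
#'
#' Each transcript is assigned a Kozak-strength category, a multiset of
#' strength labels consistent with it, and a pair of linear-scale fold
#' changes (active-ribosome and RNA) whose log-ratio -- the translation
#' efficiency -- is normal around the category's planted shift (SD 0.5).
#'
#' @param n_transcripts number of transcripts
#' @param kozak_mix named fractions over `No`, `Moderate`, `Strong`,
#'   `Supreme`; must sum to 1
#' @param planted_shift named TE shift (log2 units) per category; missing
#'   categories get 0
#' @param seed integer seed
#' @return data.frame `transcript_id`, `fc_ribo`, `fc_rna`, `kozak`
#'   (semicolon-joined strength labels), `category_true`
#' @export
simulate_te_table <- function(n_transcripts,
                              kozak_mix = c(No = 0.4, Moderate = 0.3,
                                            Strong = 0.2, Supreme = 0.1),
                              planted_shift = numeric(0), seed = 1L) {
  cats <- kozak_categories()
  bad <- setdiff(names(kozak_mix), cats)
  if (length(bad)) stopf("unknown Kozak categor(ies): %s", paste(bad, collapse = ", "))
  if (abs(sum(kozak_mix) - 1) > 1e-9) stopf("`kozak_mix` fractions must sum to 1")
  shift <- stats::setNames(rep(0, length(cats)), cats)
  shift[names(planted_shift)] <- planted_shift

  with_seed(seed, {
    category <- sample(names(kozak_mix), n_transcripts, replace = TRUE,
                       prob = kozak_mix)
    strengths <- vapply(category, function(cat) {
      s <- switch(cat,
        No       = sample(list(character(0), "weak", c("weak", "weak")), 1)[[1]],
        Moderate = c("moderate", sample(c("", "weak", "moderate"), 1)),
        Strong   = c("strong", sample(c("", "weak", "moderate"), 1)),
        Supreme  = rep("strong", sample(2:3, 1)))
      paste(s[nzchar(s)], collapse = ";")
    }, character(1))
    te <- stats::rnorm(n_transcripts, mean = shift[category], sd = 0.5)
    fc_rna <- 2^stats::rnorm(n_transcripts, 0, 0.5)
    data.frame(transcript_id = sprintf("T%05d", seq_len(n_transcripts)),
               fc_ribo = fc_rna * 2^te, fc_rna = fc_rna,
               kozak = unname(strengths), category_true = category,
               stringsAsFactors = FALSE)
  })
}
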