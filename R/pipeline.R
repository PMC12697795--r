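# End-to-end orchestration: synthetic study generation, the staged
# computation (in vitro -> patient score -> merge -> sublibrary -> in vivo
# DrugZ -> total score -> concordance), file I/O and the run manifest.

PIPELINE_VERSION <- "icbscreen-pipeline/1"

#' Default pipeline parameters
#'
#' Every tunable stage parameter with its default: hit cutoffs
#' (`lfc_cut = 0.25`, `p_cut = 0.05`), fold-change pseudocount (5, the
#' published DrugZ default), DrugZ empirical-Bayes half-window (500),
#' sublibrary sizes (`k_pos = 100`, `k_neg = 400`), score normalization
#' target (`q90_target = 2`), gene-set size (`k_geneset = 100`), cohort
#' weighting (`"n"`), permutation count (`n_perm = 1000`), DrugZ reporting
#' mode (`"paper"` = mean guide z; `"classic"` = normZ), the zero-merged
#' branch rule, and the master seed.
#'
#' @param ... overrides for any default; unknown names are rejected
#' @return named list of parameters
#' @export
pipeline_params <- function(...) {
  p <- list(lfc_cut = 0.25, p_cut = 0.05, pseudocount = 5, half_window = 500L,
            k_pos = 100L, k_neg = 400L, q90_target = 2, k_geneset = 100L,
            weighting = "n", n_perm = 1000L, drugz_mode = "paper",
            zero_branch = "nonresponder", seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) stopf("unknown parameter(s): %s", paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  if (!p$drugz_mode %in% c("paper", "classic")) stopf("drugz_mode must be 'paper' or 'classic'")
  p
}

#' Simulate a complete synthetic study for the pipeline
#'
#' Generates every input the pipeline needs, with planted ground truth:
#' a guide library (`goi_depleted`/`goi_enriched`/`essential` genes plus
#' safe-targeting guides); an in vitro screen (control and two T-cell
#' effector-to-target arms) where depleted genes lose and enriched genes
#' gain abundance under T-cell pressure; ICB patient cohorts (two response,
#' one survival) whose outcomes are linked to the planted genes' expression;
#' and an in vivo screen (NSG, mock, anti-PD-1 mice) with engraftment
#' bottleneck, where the anti-PD-1 arm splits into responders (strong
#' selection) and nonresponders (weak selection) recoverable from the
#' simulated tumor volumes.
#'
#' @param seed master seed; all per-stage seeds derive from it
#' @param n_depleted,n_enriched,n_essential,n_safe,guides_per_gene library
#'   composition (defaults mirror the ICB sublibrary structure)
#' @param effect_dep,effect_enr planted log2 selection coefficients of
#'   depleted/enriched genes in the treated in vitro arms and the in vivo
#'   responder arm
#' @param cohort_beta per-SD outcome effect of each planted gene in the
#'   simulated cohorts (log-odds of response; half that as log-hazard)
#' @param n_patients patients per cohort
#' @param depth,dispersion,bottleneck sequencing/count model settings
#' @return list with `lib`, `truth`, `invitro` (counts, samples),
#'   `invivo` (counts, samples, tumors), `cohorts`
#' @export
simulate_pipeline_inputs <- function(seed = 1L,
                                     n_depleted = 400L, n_enriched = 100L,
                                     n_essential = 30L, n_safe = 100L,
                                     guides_per_gene = 5L,
                                     effect_dep = -2, effect_enr = 2,
                                     cohort_beta = 0.12, n_patients = 120L,
                                     depth = 5e6, dispersion = 0.2,
                                     bottleneck = 0.2) {
  seeds <- derive_seeds(seed, 10)
  lib <- simulate_library(n_depleted, n_enriched, n_essential, n_safe,
                          guides_per_gene, seed = seeds[1])
  genes <- setdiff(unique(lib$gene), safe_gene_label())
  cls <- lib$guide_class[match(genes, lib$gene)]
  dep <- genes[cls == "goi_depleted"]
  enr <- genes[cls == "goi_enriched"]
  ess <- genes[cls == "essential"]

  eff <- function(dep_e, enr_e, ess_e) {
    stats::setNames(c(rep(dep_e, length(dep)), rep(enr_e, length(enr)),
                      rep(ess_e, length(ess))), c(dep, enr, ess))
  }
  truth <- simulation_truth(lib, list(
    ctrl = eff(0, 0, -3),
    et02 = eff(effect_dep, effect_enr, -3),
    et1  = eff(1.25 * effect_dep, 1.25 * effect_enr, -3),
    nsg  = eff(0, 0, -3),
    mock = eff(0, 0, -3),
    responder    = eff(effect_dep, effect_enr, -3),
    nonresponder = eff(0.25 * effect_dep, 0.25 * effect_enr, -3)
  ))

  design_vitro <- screen_design(
    data.frame(name = c("ctrl", "et02", "et1"),
               role = c("control", "treated", "treated"),
               replicates = 2L),
    depth = depth, dispersion = dispersion)
  invitro <- simulate_screen_counts(lib, design_vitro, truth, seed = seeds[2])

  design_vivo <- screen_design(
    data.frame(name = c("nsg", "mock", "responder", "nonresponder"),
               role = c("nsg", "mock", "responder", "nonresponder"),
               replicates = c(3L, 4L, 4L, 4L)),
    depth = depth, dispersion = 1.5 * dispersion, bottleneck = bottleneck)
  vivo <- simulate_screen_counts(lib, design_vivo, truth, seed = seeds[3])
  # blind the mouse identities: anti-PD-1 mice are labeled only by tumor size
  smp <- vivo$samples
  mouse <- sprintf("M%02d", seq_len(nrow(smp)))
  colnames(vivo$counts) <- mouse
  treated <- smp$arm %in% c("responder", "nonresponder")
  tumors <- with_seed(seeds[4], data.frame(
    mouse_id = mouse,
    arm = ifelse(treated, "anti_pd1", smp$arm),
    tumor_volume = exp(stats::rnorm(nrow(smp),
      mean = log(ifelse(smp$arm == "responder", 150,
                  ifelse(smp$arm == "nonresponder", 650,
                  ifelse(smp$arm == "mock", 700, 900)))), sd = 0.15)),
    stringsAsFactors = FALSE))
  samples_vivo <- data.frame(sample = mouse, arm = tumors$arm,
                             mouse_id = mouse, replicate = smp$replicate,
                             stringsAsFactors = FALSE)

  resp_eff <- stats::setNames(c(rep(-cohort_beta, length(dep)),
                                rep(cohort_beta, length(enr))), c(dep, enr))
  cohorts <- list(
    simulate_cohort(n_patients, genes, planted = resp_eff,
                    mode = "response", seed = seeds[5]),
    simulate_cohort(n_patients, genes, planted = resp_eff,
                    mode = "response", seed = seeds[6]),
    simulate_cohort(as.integer(round(1.25 * n_patients)), genes,
                    planted = -resp_eff / 2,  # log-hazard: planted resistance genes hazardous when high
                    mode = "survival", seed = seeds[7])
  )

  list(lib = lib, truth = truth,
       invitro = list(counts = invitro$counts, samples = invitro$samples),
       invivo = list(counts = vivo$counts, samples = samples_vivo,
                     tumors = tumors),
       cohorts = cohorts)
}

#' Run the integrative scoring pipeline on in-memory inputs
#'
#' Stages, in order: total-normalized in vitro guide statistics and gene
#' calls at the two E:T contrasts; the 0-4 in vitro score; per-cohort
#' effects and the |P90|-normalized patient score; merged score and
#' sublibrary selection; tumor-size responder stratification; safe-guide-
#' normalized modified-DrugZ gene scores for responder-vs-mock and
#' nonresponder-vs-mock; |P90|-normalized total score and final ranking;
#' concordance of in vivo directions against the in vitro calls and, when a
#' survival cohort is present, against per-gene expression-survival hazard
#' ratios.
#'
#' @param inputs list as produced by [simulate_pipeline_inputs()] (or
#'   assembled from the readers in this package): `lib`, `invitro`
#'   (`counts`, `samples` with arms `ctrl`, `et02`, `et1`), `cohorts` (list
#'   of `expression_cohort` and/or `cohort_effect`), `invivo` (`counts`,
#'   `samples` with `mouse_id`, `tumors`)
#' @param params a [pipeline_params()] list
#' @return list of stage results: `invitro_guides` (per contrast),
#'   `invitro_genes` (called tables per contrast), `invitro_score`,
#'   `patient_score_raw`, `patient_score`, `merged`, `sublibrary`,
#'   `responders`, `drugz_responder`, `drugz_nonresponder`, `total`,
#'   `concordance`
#' @export
pipeline_compute <- function(inputs, params = pipeline_params()) {
  seeds <- derive_seeds(params$seed, 6)
  lib <- inputs$lib

  ## --- in vitro screen ---
  norm_iv <- normalize_counts(inputs$invitro$counts, "total")
  contrasts <- list(et02 = c("et02", "ctrl"), et1 = c("et1", "ctrl"))
  guides <- genes <- list()
  for (i in seq_along(contrasts)) {
    cn <- names(contrasts)[i]
    gs <- guide_log2fc(norm_iv, inputs$invitro$samples,
                       treated = contrasts[[i]][1], control = contrasts[[i]][2],
                       lib, pseudocount = params$pseudocount)
    tab <- merge(gene_second_best_lfc(gs),
                 gene_significance(gs, n_perm = params$n_perm, seed = seeds[i])[
                   , c("gene", "mean_lfc", "p_depleted", "p_enriched")],
                 by = "gene")
    guides[[cn]] <- gs
    genes[[cn]] <- call_hits(tab, params$lfc_cut, params$p_cut)
  }
  iv_tab <- in_vitro_score(genes$et02, genes$et1, lfc_cut = params$lfc_cut)
  iv <- stats::setNames(iv_tab$in_vitro_score, iv_tab$gene)

  ## --- patient score ---
  effects <- lapply(inputs$cohorts, function(co) {
    if (inherits(co, "cohort_effect")) co else cohort_effect(co)
  })
  ps_raw <- patient_score(effects, weighting = params$weighting)
  ps <- normalize_q90(ps_raw, target = params$q90_target)

  ## --- merge and sublibrary ---
  merged <- merged_score(iv, ps)
  sublib <- select_sublibrary(merged, params$k_pos, params$k_neg,
                              essential_genes = unique(lib$gene[lib$guide_class == "essential"]),
                              n_safe = sum(lib$guide_class == "safe"))

  ## --- in vivo screen ---
  labels <- stratify_responders(inputs$invivo$tumors)
  smp <- inputs$invivo$samples
  arm2 <- smp$arm
  idx <- smp$arm == "anti_pd1"
  arm2[idx] <- labels[smp$mouse_id[idx]]
  smp$arm <- arm2
  norm_vv <- normalize_counts(inputs$invivo$counts, "safe_guides", lib)
  dz <- lapply(c(responder = "responder", nonresponder = "nonresponder"),
               function(a) {
    gz <- drugz_guide_z(norm_vv, smp, treated = a, control = "mock", lib,
                        pseudocount = params$pseudocount,
                        half_window = params$half_window)
    drugz_gene_stat(gz, z_normalize_final = params$drugz_mode == "classic")
  })

  ## --- total score over the sublibrary ---
  sub_genes <- c(sublib$enriched, sublib$depleted)
  dz_resp <- stats::setNames(dz$responder$gene_score, dz$responder$gene)
  dz_nonr <- stats::setNames(dz$nonresponder$gene_score, dz$nonresponder$gene)
  scored <- intersect(sub_genes, intersect(names(dz_resp), names(dz_nonr)))
  total <- total_score(
    normalize_q90(merged[scored], params$q90_target),
    normalize_q90(dz_resp[scored], params$q90_target),
    normalize_q90(dz_nonr[scored], params$q90_target),
    zero_branch = params$zero_branch, q90_target = params$q90_target)

  ## --- concordance ---
  conc <- pipeline_concordance(dz, genes$et02, inputs$cohorts)

  list(invitro_guides = guides, invitro_genes = genes,
       invitro_score = iv_tab, patient_score_raw = ps_raw, patient_score = ps,
       merged = merged, sublibrary = sublib, responders = labels,
       drugz_responder = dz$responder, drugz_nonresponder = dz$nonresponder,
       total = total, concordance = conc)
}

# Concordance of each in vivo contrast x direction group against the in
# vitro calls and (if a survival cohort exists) expression-survival HRs.
pipeline_concordance <- function(dz, invitro_called, cohorts) {
  surv <- Filter(function(co) inherits(co, "expression_cohort") &&
                   co$mode == "survival", cohorts)
  hr_ref <- if (length(surv)) {
    co <- surv[[1]]
    hr <- vapply(colnames(co$tpm), function(g) {
      gene_survival_association(co, g)$hr
    }, numeric(1))
    data.frame(gene = names(hr), hr = unname(hr), stringsAsFactors = FALSE)
  } else NULL
  rows <- list()
  for (grp in c("responder", "nonresponder")) {
    tab <- dz[[grp]]
    iv_dir <- data.frame(
      gene = tab$gene,
      direction = ifelse(tab$gene_score < 0, "depleted", "enriched"),
      stringsAsFactors = FALSE)[tab$gene_score != 0, ]
    for (dir in c("depleted", "enriched")) {
      sel <- iv_dir[iv_dir$direction == dir, ]
      if (!nrow(sel)) next
      rec_iv <- classify_concordance(sel, invitro_called, "invitro")
      rows[[length(rows) + 1L]] <-
        concordance_rate_test(rec_iv, sprintf("%s_%s_vs_invitro", grp, dir))
      if (!is.null(hr_ref)) {
        rec_sv <- classify_concordance(sel, hr_ref[is.finite(hr_ref$hr), ],
                                       "survival")
        rows[[length(rows) + 1L]] <-
          concordance_rate_test(rec_sv, sprintf("%s_%s_vs_survival", grp, dir))
      }
    }
  }
  do.call(rbind, rows)
}

#' Run the pipeline from a configuration, writing all artifacts
#'
#' The configuration is a list (or YAML/JSON file via
#' [read_pipeline_config()]) with either a `simulate` section (arguments to
#' [simulate_pipeline_inputs()]) or an `inputs` section of file paths
#' (`library`, `invitro_counts`, `invitro_samples`, `cohorts` = list of
#' `expression`/`clinical` path pairs and/or an `effect_table` path,
#' `invivo_counts`, `invivo_samples`, `tumors`), plus optional `params`
#' overrides and an `out_dir`. Every stage table is written as TSV along
#' with a `manifest.json` recording parameters, seeds and stage versions;
#' identical configuration and seeds give identical outputs.
#'
#' @param config configuration list
#' @return the [pipeline_compute()] result, invisibly
#' @export
run_pipeline <- function(config) {
  known <- c("simulate", "inputs", "params", "out_dir")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) stopf("unknown config section(s): %s", paste(unknown, collapse = ", "))
  params <- do.call(pipeline_params, as.list(config$params))
  if (!is.null(config$simulate)) {
    inputs <- do.call(simulate_pipeline_inputs, as.list(config$simulate))
  } else if (!is.null(config$inputs)) {
    inputs <- read_pipeline_inputs(config$inputs)
  } else {
    stopf("config needs a `simulate` or `inputs` section")
  }
  res <- pipeline_compute(inputs, params)
  if (!is.null(config$out_dir)) {
    write_pipeline_artifacts(res, inputs, params, config$out_dir)
  }
  invisible(res)
}

read_pipeline_inputs <- function(paths) {
  lib <- read_guide_library(paths$library)
  cohorts <- list()
  for (co in paths$cohorts) {
    if (!is.null(co$expression)) {
      cohorts[[length(cohorts) + 1L]] <-
        read_cohort(co$expression, co$clinical,
                    cohort_id = if (is.null(co$id)) co$expression else co$id)
    }
  }
  if (!is.null(paths$effect_table)) {
    cohorts <- c(cohorts, read_effect_table(paths$effect_table))
  }
  if (!length(cohorts)) stopf("no cohorts configured")
  list(lib = lib,
       invitro = list(counts = read_count_matrix(paths$invitro_counts),
                      samples = read_sample_sheet(paths$invitro_samples)),
       cohorts = cohorts,
       invivo = list(counts = read_count_matrix(paths$invivo_counts),
                     samples = read_sample_sheet(paths$invivo_samples),
                     tumors = read_tumor_sizes(paths$tumors)))
}

write_pipeline_artifacts <- function(res, inputs, params, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(out_dir, f)
  write_guide_library(inputs$lib, fp("library.tsv"))
  for (cn in names(res$invitro_genes)) {
    write_tsv(res$invitro_genes[[cn]], fp(sprintf("invitro_genes_%s.tsv", cn)))
    write_tsv(res$invitro_guides[[cn]], fp(sprintf("invitro_guides_%s.tsv", cn)))
  }
  write_tsv(res$invitro_score, fp("invitro_score.tsv"))
  write_tsv(data.frame(gene = names(res$patient_score),
                       patient_score_raw = unname(res$patient_score_raw[names(res$patient_score)]),
                       patient_score = unname(res$patient_score)),
            fp("patient_score.tsv"))
  write_tsv(data.frame(gene = names(res$merged), merged = unname(res$merged)),
            fp("merged_score.tsv"))
  write_tsv(rbind(
    data.frame(gene = res$sublibrary$enriched, category = "enriched"),
    data.frame(gene = res$sublibrary$depleted, category = "depleted"),
    data.frame(gene = res$sublibrary$controls$essential, category = "essential")),
    fp("sublibrary.tsv"))
  write_tsv(data.frame(mouse_id = names(res$responders),
                       label = unname(res$responders)), fp("responders.tsv"))
  write_tsv(res$drugz_responder, fp("drugz_responder.tsv"))
  write_tsv(res$drugz_nonresponder, fp("drugz_nonresponder.tsv"))
  write_tsv(res$total, fp("total_score.tsv"))
  write_tsv(res$concordance, fp("concordance.tsv"))
  manifest <- list(
    version = PIPELINE_VERSION,
    params = params,
    invitro_test = "permutation-mean-lfc",
    invitro_rubric = attr(res$invitro_score, "rubric"),
    drugz_mode = attr(res$drugz_responder, "mode"),
    n_genes = list(invitro = nrow(res$invitro_score),
                   patient = length(res$patient_score),
                   merged = length(res$merged),
                   total = nrow(res$total)),
    outputs = list.files(out_dir))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path file ending in `.yaml`/`.yml` or `.json`
#' @return configuration list for [run_pipeline()]
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else stopf("config must be .yaml/.yml or .json")
}
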