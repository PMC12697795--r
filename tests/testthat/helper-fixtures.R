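# Small in-code fixtures shared across test files.

# A toy library: `n_genes` real genes x `gpg` guides plus `n_safe` safe guides.
toy_library <- function(n_genes = 4, gpg = 2, n_safe = 12, seed = 11) {
  simulate_library(n_depleted = n_genes, n_enriched = 0, n_essential = 0,
                   n_safe = n_safe, guides_per_gene = gpg, seed = seed)
}

# A deterministic count matrix over a library, two arms x `reps` replicates.
toy_counts <- function(lib, arms = c("ctrl", "trt"), reps = 2, seed = 5,
                       depth = 2e5, dispersion = 0.1,
                       arm_effects = list()) {
  design <- screen_design(
    data.frame(name = arms, role = c("control", "treated"),
               replicates = reps),
    depth = depth, dispersion = dispersion)
  truth <- simulation_truth(lib, arm_effects)
  simulate_screen_counts(lib, design, truth, seed = seed)
}

# Inputs for pipeline_compute with `n_planted` true resistance genes among
# `n_goi` genes of interest: strong depletion in the T-cell and responder
# arms, higher expression in nonresponding patients. Response-mode cohorts
# only, to keep end-to-end replicates fast.
planted_inputs <- function(seed, n_goi = 1000, n_planted = 20,
                           guides_per_gene = 5, n_patients = 120) {
  seeds <- seed + c(0, 1, 2, 3, 4, 5) * 1000L
  lib <- simulate_library(n_goi, 0, 30, 100, guides_per_gene, seed = seeds[1])
  genes <- setdiff(unique(lib$gene), safe_gene_label())
  cls <- lib$guide_class[match(genes, lib$gene)]
  goi <- genes[cls == "goi_depleted"]
  ess <- genes[cls == "essential"]
  planted <- goi[seq_len(n_planted)]
  eff <- function(dep_e) {
    stats::setNames(c(rep(dep_e, n_planted), rep(-3, length(ess))),
                    c(planted, ess))
  }
  truth <- simulation_truth(lib, list(
    ctrl = eff(0), et02 = eff(-2), et1 = eff(-2.5),
    mock = eff(0), responder = eff(-2), nonresponder = eff(-0.5)))

  iv <- simulate_screen_counts(
    lib,
    screen_design(data.frame(name = c("ctrl", "et02", "et1"),
                             role = c("control", "treated", "treated"),
                             replicates = 2L),
                  depth = 3e6, dispersion = 0.2),
    truth, seed = seeds[2])

  vv <- simulate_screen_counts(
    lib,
    screen_design(data.frame(name = c("mock", "responder", "nonresponder"),
                             role = c("mock", "responder", "nonresponder"),
                             replicates = c(4L, 4L, 4L)),
                  depth = 3e6, dispersion = 0.3, bottleneck = 0.2),
    truth, seed = seeds[3])
  smp <- vv$samples
  mouse <- sprintf("M%02d", seq_len(nrow(smp)))
  colnames(vv$counts) <- mouse
  treated <- smp$arm %in% c("responder", "nonresponder")
  tumors <- data.frame(
    mouse_id = mouse,
    arm = ifelse(treated, "anti_pd1", smp$arm),
    tumor_volume = ifelse(smp$arm == "responder", 150,
                   ifelse(smp$arm == "nonresponder", 650, 700)) +
                   seq_len(nrow(smp)))
  samples_vv <- data.frame(sample = mouse, arm = tumors$arm,
                           mouse_id = mouse, replicate = smp$replicate)

  resp_eff <- stats::setNames(rep(-0.8, n_planted), planted)
  cohorts <- list(
    simulate_cohort(n_patients, genes, planted = resp_eff,
                    mode = "response", seed = seeds[4]),
    simulate_cohort(n_patients, genes, planted = resp_eff,
                    mode = "response", seed = seeds[5]))

  list(lib = lib, truth = truth, planted = planted,
       invitro = list(counts = iv$counts, samples = iv$samples),
       invivo = list(counts = vv$counts, samples = samples_vv,
                     tumors = tumors),
       cohorts = cohorts)
}
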