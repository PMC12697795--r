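# Readers and writers for the pipeline's tab-separated formats and GMT gene
# sets. All tables are TSV with a header row, UTF-8, '.' decimal.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stopf("%s file not found: %s", what, path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  check_cols(df, required, sprintf("%s file '%s'", what, path))
  df
}

#' Write / read a guide library TSV (`guide_id`, `gene`, `class`)
#' @param lib guide library data.frame
#' @param path file path
#' @return the path (writer) or the library data.frame (reader)
#' @export
write_guide_library <- function(lib, path) {
  write_tsv(data.frame(guide_id = lib$guide_id, gene = lib$gene,
                       class = lib$guide_class), path)
}

#' @rdname write_guide_library
#' @export
read_guide_library <- function(path) {
  df <- read_tsv_checked(path, c("guide_id", "gene", "class"), "guide library")
  if (anyDuplicated(df$guide_id)) stopf("duplicate guide_id in %s", path)
  data.frame(guide_id = df$guide_id, gene = df$gene, guide_class = df$class,
             stringsAsFactors = FALSE)
}

#' Write / read a guide x sample count matrix TSV
#' @param counts integer matrix with guide rownames
#' @param path file path
#' @return the path (writer) or a numeric matrix (reader)
#' @export
write_count_matrix <- function(counts, path) {
  df <- data.frame(guide_id = rownames(counts), counts, check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- read_tsv_checked(path, "guide_id", "count matrix")
  m <- as.matrix(df[, setdiff(names(df), "guide_id"), drop = FALSE])
  if (!is.numeric(m)) stopf("non-numeric counts in %s", path)
  bad <- which(m < 0 | m != floor(m), arr.ind = TRUE)
  if (nrow(bad)) {
    stopf("counts must be non-negative integers; first offense at data row %d of %s",
          bad[1, 1], path)
  }
  rownames(m) <- df$guide_id
  m
}

#' Write / read a sample sheet TSV (`sample`, `arm`, `replicate`, ...)
#' @param samples sample sheet data.frame
#' @param path file path
#' @return path or data.frame
#' @export
write_sample_sheet <- function(samples, path) write_tsv(samples, path)

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  read_tsv_checked(path, c("sample", "arm"), "sample sheet")
}

#' Write / read a tumor-size TSV (`mouse_id`, `arm`, `tumor_volume`)
#' @param tumors data.frame
#' @param path file path
#' @return path or data.frame
#' @export
write_tumor_sizes <- function(tumors, path) write_tsv(tumors, path)

#' @rdname write_tumor_sizes
#' @export
read_tumor_sizes <- function(path) {
  read_tsv_checked(path, c("mouse_id", "arm", "tumor_volume"), "tumor size")
}

#' Write / read an expression cohort as a TSV pair
#'
#' The expression file holds `patient` plus one column per gene (TPM); the
#' clinical file holds `patient`, `response`, `time`, `event` (unused fields
#' `NA`).
#'
#' @param cohort an `expression_cohort`
#' @param expr_path,clin_path file paths
#' @param cohort_id label used on read
#' @return paths (writer) or an `expression_cohort` (reader)
#' @export
write_cohort <- function(cohort, expr_path, clin_path) {
  stopifnot(inherits(cohort, "expression_cohort"))
  write_tsv(data.frame(patient = rownames(cohort$tpm), cohort$tpm,
                       check.names = FALSE), expr_path)
  clin <- data.frame(patient = rownames(cohort$tpm),
                     response = if (is.null(cohort$response)) NA else cohort$response,
                     time = if (is.null(cohort$survival_time)) NA else cohort$survival_time,
                     event = if (is.null(cohort$survival_event)) NA else cohort$survival_event)
  write_tsv(clin, clin_path)
  invisible(c(expr_path, clin_path))
}

#' @rdname write_cohort
#' @export
read_cohort <- function(expr_path, clin_path, cohort_id = "cohort") {
  ex <- read_tsv_checked(expr_path, "patient", "cohort expression")
  cl <- read_tsv_checked(clin_path, c("patient", "response", "time", "event"),
                         "cohort clinical")
  if (!identical(ex$patient, cl$patient)) {
    stopf("patient ids differ between %s and %s", expr_path, clin_path)
  }
  tpm <- as.matrix(ex[, setdiff(names(ex), "patient"), drop = FALSE])
  rownames(tpm) <- ex$patient
  has_resp <- !all(is.na(cl$response))
  expression_cohort(
    tpm,
    response = if (has_resp) cl$response else NULL,
    survival_time = if (!all(is.na(cl$time))) cl$time else NULL,
    survival_event = if (!all(is.na(cl$event))) as.logical(cl$event) else NULL,
    cohort_id = cohort_id)
}

#' Write / read a published-cohort effect table TSV
#'
#' Columns `gene`, `effect`, `cohort`, `n`, `mode`; one row per gene per
#' cohort. Reading returns a list of `cohort_effect` objects.
#'
#' @param effects list of `cohort_effect` objects
#' @param path file path
#' @return path or list of `cohort_effect`
#' @export
write_effect_table <- function(effects, path) {
  rows <- lapply(effects, function(e) {
    data.frame(gene = e$effects$gene,
               effect = ifelse(e$effects$available, e$effects$effect, NA),
               cohort = e$cohort_id, n = e$n, mode = e$mode,
               stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, rows), path)
}

#' @rdname write_effect_table
#' @export
read_effect_table <- function(path) {
  df <- read_tsv_checked(path, c("gene", "effect", "cohort", "n", "mode"),
                         "effect table")
  lapply(split(df, df$cohort), function(d) {
    cohort_effect_table(d[, c("gene", "effect")], cohort_id = d$cohort[1],
                        mode = d$mode[1], n = d$n[1])
  })
}

#' Write / read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param sets list of `gene_set` objects
#' @param path file path
#' @return path (writer) or named list of `gene_set` (reader)
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, "icbscreen gene set", s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stopf("malformed GMT line %d in %s", i, path)
    gene_set(f[1], f[-(1:2)])
  })
  stats::setNames(sets, vapply(sets, `[[`, character(1), "name"))
}

#' Write / read a translation-efficiency input TSV
#'
#' Columns `transcript_id`, `fc_ribo`, `fc_rna`, `kozak` (semicolon-joined
#' strength labels, empty allowed).
#'
#' @param tab data.frame
#' @param path file path
#' @return path or data.frame
#' @export
write_te_table <- function(tab, path) {
  write_tsv(tab[, c("transcript_id", "fc_ribo", "fc_rna", "kozak")], path)
}

#' @rdname write_te_table
#' @export
read_te_table <- function(path) {
  df <- read_tsv_checked(path, c("transcript_id", "fc_ribo", "fc_rna", "kozak"),
                         "TE table")
  df$kozak[is.na(df$kozak)] <- ""
  bad <- which(!(df$fc_ribo > 0 & df$fc_rna > 0))
  if (length(bad)) stopf("non-positive fold change at data row %d of %s", bad[1], path)
  df
}

#' Write / read a ground-truth TSV (gene, class, one effect column per arm)
#' @param truth a `simulation_truth`
#' @param path file path
#' @return path or `simulation_truth`-shaped list
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "simulation_truth"))
  write_tsv(data.frame(gene = rownames(truth$effects),
                       class = unname(truth$class[rownames(truth$effects)]),
                       truth$effects, check.names = FALSE), path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- read_tsv_checked(path, c("gene", "class"), "truth")
  eff <- as.matrix(df[, setdiff(names(df), c("gene", "class")), drop = FALSE])
  rownames(eff) <- df$gene
  structure(list(effects = eff, class = stats::setNames(df$class, df$gene)),
            class = "simulation_truth")
}
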