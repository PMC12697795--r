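# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded simulators never
#' perturb user code. All package randomness flows through this helper; there
#' is no hidden global state.
#'
#' @param seed integer scalar
#' @param code expression to evaluate
#' @return the value of `code`
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Derive a stream of child seeds from one parent seed, kept within 32-bit
# integer range so set.seed() never overflows.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_nonneg_int <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != floor(x)) {
    stopf("`%s` must be a single non-negative integer", name)
  }
  as.integer(x)
}

check_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stopf("%s is missing required column(s): %s", what,
          paste(miss, collapse = ", "))
  }
  invisible(df)
}

# Quantile with the linear-interpolation convention (type 7) frozen
# package-wide; every percentile in the scoring pipeline goes through this.
quantile_linear <- function(x, probs) {
  stats::quantile(x, probs = probs, type = 7, names = FALSE)
}

#' Reserved gene label carried by safe-targeting guides
#'
#' Safe-targeting guides cut non-functional loci and are not genes; they share
#' this reserved label, distinct from any real gene symbol, so that gene-level
#' statistics can exclude or single them out.
#'
#' @return a string
#' @export
safe_gene_label <- function() "SAFE_CONTROL"
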