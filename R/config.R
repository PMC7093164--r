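#' Analysis configuration
#'
#' Bundles every tunable threshold of the coordination analysis into one
#' validated object. The defaults reproduce the published workflow: genes
#' with at least 70 reads (on average) in the reference group are "highly
#' expressed", correlated sets use a strict R > 0.5 cut-off, and the three
#' lowest-Pc plus three highest-Pc seed genes are carried into the
#' functional comparison.
#'
#' @param min_reads Non-negative numeric. High-expression threshold applied
#'   to the aggregated reference-group value of each gene (inclusive,
#'   "at least"). Default 70.
#' @param read_aggregation How reference-group samples are aggregated before
#'   thresholding: `"mean"` (default), `"min"` or `"sum"`.
#' @param r_cutoff Numeric in (0, 1). Correlated-set membership requires
#'   R strictly greater than this. Default 0.5.
#' @param pc_method Correlation used between the two groups' R-profiles when
#'   computing Pc: `"pearson"` (default) or `"spearman"`.
#' @param transform Transform applied to expression values before any
#'   correlation: `"none"` (default), `"log1p"`, or `"cpm_log1p"`
#'   (counts-per-million then log1p).
#' @param bottom_k,top_k Positive integers; how many lowest-Pc ("lost
#'   coordination") and highest-Pc ("retained coordination") seed genes are
#'   selected downstream. Default 3 each.
#' @param fdr_alpha Numeric in (0, 1). Benjamini-Hochberg threshold defining
#'   the "functions" of a gene set. Default 0.05.
#' @param min_term_size Positive integer. Annotation terms with fewer genes
#'   than this (after intersection with the background) are not tested.
#'   Default 5.
#' @param rng_seed Integer seed for any stochastic step. Default 1.
#'
#' @return An object of class `coord_config` (a validated list).
#' @examples
#' cfg <- coord_config(min_reads = 70, r_cutoff = 0.5)
#' cfg$bottom_k
#' @export
coord_config <- function(min_reads = 70,
                         read_aggregation = c("mean", "min", "sum"),
                         r_cutoff = 0.5,
                         pc_method = c("pearson", "spearman"),
                         transform = c("none", "log1p", "cpm_log1p"),
                         bottom_k = 3L,
                         top_k = 3L,
                         fdr_alpha = 0.05,
                         min_term_size = 5L,
                         rng_seed = 1L) {
  read_aggregation <- match.arg(read_aggregation)
  pc_method <- match.arg(pc_method)
  transform <- match.arg(transform)
  stopifnot(
    is.numeric(min_reads), length(min_reads) == 1L, min_reads >= 0,
    is.numeric(r_cutoff), length(r_cutoff) == 1L,
    r_cutoff > 0, r_cutoff < 1,
    is.numeric(bottom_k), bottom_k >= 1, bottom_k == as.integer(bottom_k),
    is.numeric(top_k), top_k >= 1, top_k == as.integer(top_k),
    is.numeric(fdr_alpha), fdr_alpha > 0, fdr_alpha < 1,
    is.numeric(min_term_size), min_term_size >= 1,
    is.numeric(rng_seed), length(rng_seed) == 1L
  )
  structure(
    list(
      min_reads = as.numeric(min_reads),
      read_aggregation = read_aggregation,
      r_cutoff = as.numeric(r_cutoff),
      pc_method = pc_method,
      transform = transform,
      bottom_k = as.integer(bottom_k),
      top_k = as.integer(top_k),
      fdr_alpha = as.numeric(fdr_alpha),
      min_term_size = as.integer(min_term_size),
      rng_seed = as.integer(rng_seed)
    ),
    class = "coord_config"
  )
}

#' @export
print.coord_config <- function(x, ...) {
  cat("coordination analysis configuration\n")
  for (nm in names(x)) cat(sprintf("  %-17s %s\n", nm, x[[nm]]))
  invisible(x)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# Keeps library-level functions from clobbering the user's random stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}
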