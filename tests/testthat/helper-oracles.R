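# Independent oracles and tiny fixture builders. The oracles deliberately
# avoid the code paths they check: correlation by the explicit
# product-moment sum, hypergeometric tails by combinatorial enumeration
# with choose().

# Brute-force product-moment correlation.
oracle_pearson <- function(x, y) {
  xb <- mean(x)
  yb <- mean(y)
  num <- sum((x - xb) * (y - yb))
  den <- sqrt(sum((x - xb)^2) * sum((y - yb)^2))
  num / den
}

# Exact upper-tail hypergeometric P(X >= k) by enumeration:
# X = hits when drawing n from N containing K successes.
oracle_hyper_tail <- function(k, K, N, n) {
  lo <- max(k, max(0L, n - (N - K)))
  hi <- min(K, n)
  if (lo > hi) return(0)
  sum(vapply(lo:hi, function(i) {
    choose(K, i) * choose(N - K, n - i) / choose(N, n)
  }, numeric(1L)))
}

# Jaccard similarity of two character sets.
jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(NA_real_)
  length(intersect(a, b)) / u
}

# Write a genes x samples matrix to a temp TSV; returns the path.
write_counts_fixture <- function(values, gene_ids, sample_ids,
                                 header_gene_col = "gene_id") {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  lines <- c(
    paste(c(header_gene_col, sample_ids), collapse = "\t"),
    vapply(seq_along(gene_ids), function(i) {
      paste(c(gene_ids[i], values[i, ]), collapse = "\t")
    }, character(1L))
  )
  writeLines(lines, path)
  path
}

write_design_fixture <- function(sample_ids, labels) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(c("sample_id\tgroup_label",
               paste(sample_ids, labels, sep = "\t")), path)
  path
}

write_gmt_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gmt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# A small but analysis-grade simulation: 300 genes, 3 modules x 40,
# 30 + 30 samples, 15 seeds. Fast enough to rerun dozens of times.
small_sim_config <- function(rng_seed = 1L, n_rewired = 3L,
                             coherence_amplification = 1.15, ...) {
  sim_config(n_genes = 300L, n_samples_ref = 30L, n_samples_cond = 30L,
             n_modules = 3L, module_size = 40L, latent_rho = 0.7,
             coherence_amplification = coherence_amplification,
             n_seed_genes = 15L, n_rewired = n_rewired,
             rng_seed = rng_seed, ...)
}

# Hand-built correlation profile for unit tests.
make_profile <- function(seed, group, bg, r) {
  structure(list(seed_gene = seed, group = group,
                 background_gene_ids = bg,
                 r_values = stats::setNames(r, bg)),
            class = "correlation_profile")
}
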