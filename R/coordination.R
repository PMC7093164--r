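#' Pearson product-moment correlation with explicit undefined handling
#'
#' The core statistic of the coordination analysis. Unlike [stats::cor()],
#' a constant input vector yields `NA_real_` (an explicit "undefined" flag)
#' without warnings, and unequal lengths are an error rather than a recycle.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in \[-1, 1\], or `NA_real_` if either vector is
#'   constant.
#' @examples
#' pearson_r(1:4, c(4, 3, 2, 1))  # -1
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) {
    stop("pearson_r: vectors of unequal length (", length(x), " vs ",
         length(y), ")", call. = FALSE)
  }
  if (length(x) < 3L) {
    stop("pearson_r: need at least 3 observations", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) {
    stop("pearson_r: missing values not allowed", call. = FALSE)
  }
  xc <- x - mean(x)
  yc <- y - mean(y)
  sx <- sum(xc * xc)
  sy <- sum(yc * yc)
  if (sx == 0 || sy == 0) return(NA_real_)
  r <- sum(xc * yc) / sqrt(sx * sy)
  # guard round-off outside [-1, 1]
  max(-1, min(1, r))
}

# Apply the configured expression transform to a genes x samples matrix.
apply_transform <- function(mat, transform) {
  switch(transform,
    none = mat,
    log1p = log1p(mat),
    cpm_log1p = {
      libsize <- colSums(mat)
      libsize[libsize == 0] <- 1  # all-zero sample: leave as zeros
      log1p(sweep(mat, 2L, libsize, "/") * 1e6)
    },
    stop("unknown transform: ", transform, call. = FALSE)
  )
}

#' Select highly expressed genes in the reference group
#'
#' A gene passes if its aggregated value over the reference-group samples is
#' at least `config$min_reads` (inclusive). Aggregation is configurable
#' (`mean`, `min` or `sum`); the threshold applies to raw values, before any
#' correlation transform.
#'
#' @param mat Genes x samples matrix.
#' @param design A `sample_design`.
#' @param config A `coord_config`.
#' @return Character vector of passing gene identifiers, in input order
#'   (possibly empty, with a warning).
#' @export
filter_high_expression <- function(mat, design, config = coord_config()) {
  ref_samples <- design_samples(design, "reference")
  missing <- setdiff(ref_samples, colnames(mat))
  if (length(missing)) {
    stop("reference samples absent from matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sub <- mat[, ref_samples, drop = FALSE]
  agg <- switch(config$read_aggregation,
                mean = rowMeans(sub),
                min = apply(sub, 1L, min),
                sum = rowSums(sub))
  keep <- rownames(mat)[agg >= config$min_reads]
  if (!length(keep)) {
    warning("no gene passes the high-expression filter (min_reads = ",
            config$min_reads, ")", call. = FALSE)
  }
  keep
}

#' Pairwise correlation matrix among selected genes within one group
#'
#' Computes all pairwise Pearson correlations among `genes` over the samples
#' of one group, after applying the configured transform. Genes with zero
#' variance in the group produce undefined (NA) entries and are flagged.
#'
#' @param mat Genes x samples matrix.
#' @param genes Gene identifiers (subset of rownames of `mat`).
#' @param design A `sample_design`.
#' @param group `"reference"`, `"condition"`, or an explicit label.
#' @param config A `coord_config`.
#' @return Object of class `correlation_matrix`: list with `gene_ids`,
#'   `values` (symmetric matrix, unit diagonal for defined genes),
#'   `group` and `undefined_genes`.
#' @export
pairwise_correlation <- function(mat, genes, design, group,
                                 config = coord_config()) {
  unknown <- setdiff(genes, rownames(mat))
  if (length(unknown)) {
    stop("unknown gene identifier(s): ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  samples <- design_samples(design, group)
  if (length(samples) < 3L) {
    stop("group has fewer than 3 samples", call. = FALSE)
  }
  x <- apply_transform(mat[genes, samples, drop = FALSE], config$transform)
  defined <- rowSums((x - rowMeans(x))^2) > 0
  values <- matrix(NA_real_, length(genes), length(genes),
                   dimnames = list(genes, genes))
  if (any(defined)) {
    cc <- stats::cor(t(x[defined, , drop = FALSE]))
    cc <- pmin(pmax(cc, -1), 1)
    diag(cc) <- 1
    values[defined, defined] <- cc
  }
  structure(
    list(gene_ids = genes, values = values,
         group = if (group %in% c("reference", "condition"))
           switch(group, reference = design$reference,
                  condition = design$condition) else group,
         undefined_genes = genes[!defined]),
    class = "correlation_matrix"
  )
}

#' Summarise the coherence of a correlation matrix
#'
#' Off-diagonal summaries of a within-group correlation matrix: the mean R,
#' mean |R|, and the fraction of pairs with |R| above a threshold. Used to
#' quantify the "overall coordination" of a group and compare it between
#' groups.
#'
#' @param cm A `correlation_matrix`.
#' @param tau Threshold for `fraction_above` (default 0.5).
#' @return List with `mean_r`, `mean_abs_r`, `fraction_above`, `n_pairs`.
#' @export
coherence_summary <- function(cm, tau = 0.5) {
  v <- cm$values
  off <- v[upper.tri(v)]
  off <- off[!is.na(off)]
  if (!length(off)) {
    stop("all off-diagonal correlations undefined", call. = FALSE)
  }
  list(
    mean_r = mean(off),
    mean_abs_r = mean(abs(off)),
    fraction_above = mean(abs(off) > tau),
    n_pairs = length(off)
  )
}

#' Transcriptome-wide correlation profiles per seed gene and group
#'
#' For each seed gene, computes its vector of Pearson correlations against
#' every other gene of the matrix ("the transcriptome"), independently in
#' the reference and condition groups. The background is shared: it excludes
#' the seed itself and every gene with zero variance in either group, so the
#' two groups' profiles for one seed are index-aligned.
#'
#' @param mat Genes x samples matrix.
#' @param seed_genes Seed gene identifiers (duplicates dropped with a
#'   warning).
#' @param design A `sample_design`.
#' @param config A `coord_config`.
#' @return List with `seed_genes`, `background` (shared background before
#'   per-seed self-exclusion), and `reference` / `condition`: named lists of
#'   `correlation_profile` objects (fields `seed_gene`, `group`,
#'   `background_gene_ids`, `r_values`).
#' @export
transcriptome_profiles <- function(mat, seed_genes, design,
                                   config = coord_config()) {
  if (anyDuplicated(seed_genes)) {
    warning("duplicated seed genes dropped: ",
            paste(unique(seed_genes[duplicated(seed_genes)]), collapse = ", "),
            call. = FALSE)
    seed_genes <- unique(seed_genes)
  }
  unknown <- setdiff(seed_genes, rownames(mat))
  if (length(unknown)) {
    stop("seed gene(s) absent from matrix: ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  ref_s <- design_samples(design, "reference")
  cond_s <- design_samples(design, "condition")
  x_ref <- apply_transform(mat[, ref_s, drop = FALSE], config$transform)
  x_cond <- apply_transform(mat[, cond_s, drop = FALSE], config$transform)

  var0_ref <- rowSums((x_ref - rowMeans(x_ref))^2) == 0
  var0_cond <- rowSums((x_cond - rowMeans(x_cond))^2) == 0
  zero_var <- rownames(mat)[var0_ref | var0_cond]
  if (length(zero_var)) {
    message(length(zero_var),
            " gene(s) with zero variance in a group removed from the",
            " shared background")
  }
  background <- setdiff(rownames(mat), zero_var)

  profile_block <- function(x, group_label) {
    seeds_ok <- intersect(seed_genes, background)
    r <- matrix(NA_real_, length(seed_genes), length(background),
                dimnames = list(seed_genes, background))
    if (length(seeds_ok) && length(background)) {
      r[seeds_ok, ] <- stats::cor(t(x[seeds_ok, , drop = FALSE]),
                                  t(x[background, , drop = FALSE]))
    }
    pmin(pmax(r, -1), 1)
  }
  r_ref <- profile_block(x_ref, design$reference)
  r_cond <- profile_block(x_cond, design$condition)

  # integer indexing throughout: name-based matrix subsetting is O(n)
  # per seed and dominates runtime at transcriptome scale
  seed_pos <- match(seed_genes, background)
  make_profiles <- function(rmat, group_label) {
    dimnames(rmat) <- NULL
    out <- vector("list", length(seed_genes))
    for (i in seq_along(seed_genes)) {
      pos <- seed_pos[i]
      if (is.na(pos)) {
        bg <- background
        r <- rmat[i, ]
      } else {
        bg <- background[-pos]
        r <- rmat[i, -pos]
      }
      out[[i]] <- structure(
        list(seed_gene = seed_genes[i], group = group_label,
             background_gene_ids = bg, r_values = r),
        class = "correlation_profile"
      )
    }
    names(out) <- seed_genes
    out
  }
  list(
    seed_genes = seed_genes,
    background = background,
    reference = make_profiles(r_ref, design$reference),
    condition = make_profiles(r_cond, design$condition)
  )
}

#' Composite correlation (Pc) between a seed gene's two profiles
#'
#' Pc is the correlation between the seed gene's transcriptome R-profile in
#' the reference group and the same profile in the condition group, over the
#' background positions where both are defined. High Pc means the gene's
#' coordination with the transcriptome is retained across groups; low Pc
#' means it is lost.
#'
#' @param profile_ref,profile_cond `correlation_profile` objects for the
#'   same seed gene with index-aligned backgrounds.
#' @param config A `coord_config`; `pc_method` selects Pearson (default) or
#'   Spearman for the profile-vs-profile correlation.
#' @return Object of class `pc_record`: list with `seed_gene`, `pc`
#'   (`NA_real_` when undefined), `n_common_background`.
#' @export
composite_correlation <- function(profile_ref, profile_cond,
                                  config = coord_config()) {
  if (!identical(profile_ref$seed_gene, profile_cond$seed_gene)) {
    stop("mismatched seed genes: ", profile_ref$seed_gene, " vs ",
         profile_cond$seed_gene, call. = FALSE)
  }
  if (!identical(profile_ref$background_gene_ids,
                 profile_cond$background_gene_ids)) {
    stop("profiles are not index-aligned for seed ",
         profile_ref$seed_gene, call. = FALSE)
  }
  a <- profile_ref$r_values
  b <- profile_cond$r_values
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  pc <- NA_real_
  if (n >= 3L) {
    a <- a[ok]; b <- b[ok]
    if (stats::sd(a) > 0 && stats::sd(b) > 0) {
      pc <- stats::cor(a, b, method = config$pc_method)
      pc <- max(-1, min(1, pc))
    }
  }
  structure(
    list(seed_gene = profile_ref$seed_gene, pc = pc,
         n_common_background = as.integer(n)),
    class = "pc_record"
  )
}

#' Rank seed genes by ascending Pc
#'
#' Low Pc (lost coordination) ranks first. Ties break lexicographically by
#' gene identifier; records with undefined Pc are listed last and are never
#' selected into the bottom/top sets.
#'
#' @param records List of `pc_record` objects.
#' @param config A `coord_config` supplying `bottom_k` and `top_k`.
#' @return Object of class `pc_ranking`: list with `records` (data.frame
#'   `seed_gene`, `pc`, `n_common_background`, sorted), `bottom` and `top`
#'   (character vectors of selected seeds).
#' @export
rank_by_pc <- function(records, config = coord_config()) {
  if (!length(records)) stop("no Pc records supplied", call. = FALSE)
  df <- data.frame(
    seed_gene = vapply(records, `[[`, character(1L), "seed_gene"),
    pc = vapply(records, `[[`, numeric(1L), "pc"),
    n_common_background = vapply(records, `[[`, integer(1L),
                                 "n_common_background"),
    stringsAsFactors = FALSE
  )
  if (all(is.na(df$pc))) {
    stop("all Pc records are undefined", call. = FALSE)
  }
  # ascending pc, NA last, ties lexicographic by gene id (C collation)
  ord <- order(is.na(df$pc), df$pc, df$seed_gene, method = "radix")
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  defined <- df$seed_gene[!is.na(df$pc)]
  bottom <- utils::head(defined, min(config$bottom_k, length(defined)))
  top <- rev(utils::tail(defined, min(config$top_k, length(defined))))
  structure(list(records = df, bottom = bottom, top = top),
            class = "pc_ranking")
}

#' @export
print.pc_ranking <- function(x, ...) {
  cat("Pc ranking of", nrow(x$records), "seed genes\n")
  cat("  bottom:", paste(x$bottom, collapse = ", "), "\n")
  cat("  top:   ", paste(x$top, collapse = ", "), "\n")
  invisible(x)
}

#' Extract a seed gene's correlated set within one group
#'
#' Background genes whose correlation with the seed is strictly greater
#' than `config$r_cutoff` (the published cut-off is R > 0.5; the boundary
#' value itself is excluded). An empty set is allowed.
#'
#' @param profile A `correlation_profile`.
#' @param config A `coord_config`.
#' @return Object of class `gene_set`: list with `seed_gene`, `group`,
#'   `genes`, `r` (correlations of the members, same order).
#' @export
extract_correlated_set <- function(profile, config = coord_config()) {
  keep <- !is.na(profile$r_values) & profile$r_values > config$r_cutoff
  structure(
    list(seed_gene = profile$seed_gene, group = profile$group,
         genes = profile$background_gene_ids[keep],
         r = unname(profile$r_values[keep])),
    class = "gene_set"
  )
}
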