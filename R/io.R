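#' Validate a genes x samples expression matrix
#'
#' Enforces the contract every downstream stage relies on: unique gene and
#' sample identifiers, no missing cells, and non-negative values.
#'
#' @param values Numeric matrix with gene identifiers as rownames and sample
#'   identifiers as colnames.
#' @return The validated matrix (invisibly unchanged).
#' @export
expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  }
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || is.null(sid)) {
    stop("expression matrix must carry gene rownames and sample colnames",
         call. = FALSE)
  }
  if (anyDuplicated(gid)) {
    stop("duplicate gene identifiers: ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sid)) {
    stop("duplicate sample identifiers: ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "), call. = FALSE)
  }
  if (anyNA(values)) {
    stop("expression matrix contains missing cells", call. = FALSE)
  }
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative value at gene '%s', sample '%s'",
                 gid[bad[1L]], sid[bad[2L]]), call. = FALSE)
  }
  values
}

#' Read a genes x samples count matrix
#'
#' Reads a tab-separated expression table whose first column holds gene
#' identifiers and remaining columns hold one sample each. Two dialects are
#' supported: `plain_tsv` and `series_matrix`, the latter skipping GEO
#' series-matrix comment lines beginning with `!`.
#'
#' Missing cells are imputed as 0 with a warning (sparse exports omit
#' zeros); duplicate gene rows are collapsed by summation with a warning
#' (read counts are additive).
#'
#' @param path Path to the file.
#' @param dialect `"plain_tsv"` (default) or `"series_matrix"`.
#' @return A validated numeric matrix, genes x samples.
#' @export
read_counts <- function(path, dialect = c("plain_tsv", "series_matrix")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("counts file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (dialect == "series_matrix") {
    lines <- lines[!startsWith(lines, "!")]
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) {
    stop("counts file has no data rows: ", path, call. = FALSE)
  }
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L) {
    stop("malformed header (need gene column plus >=1 sample): ",
         lines[[1L]], call. = FALSE)
  }
  dt <- data.table::fread(text = lines, sep = "\t", header = TRUE,
                          colClasses = list(character = 1L))
  sample_ids <- colnames(dt)[-1L]
  gene_ids <- dt[[1L]]
  vals <- as.matrix(dt[, -1L, with = FALSE])
  if (!is.numeric(vals)) {
    bad <- colnames(vals)[!vapply(seq_len(ncol(vals)), function(j)
      is.numeric(dt[[j + 1L]]), logical(1L))][1L]
    stop("non-numeric values in sample column '", bad, "'", call. = FALSE)
  }
  if (anyNA(vals)) {
    warning(sum(is.na(vals)), " missing cell(s) imputed as 0", call. = FALSE)
    vals[is.na(vals)] <- 0
  }
  if (any(vals < 0)) {
    bad <- which(vals < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative value at gene '%s', sample '%s'",
                 gene_ids[bad[1L]], sample_ids[bad[2L]]), call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    dups <- unique(gene_ids[duplicated(gene_ids)])
    warning("collapsing ", length(dups),
            " duplicated gene identifier(s) by summation: ",
            paste(utils::head(dups, 5L), collapse = ", "), call. = FALSE)
    vals <- rowsum(vals, group = gene_ids, reorder = FALSE)
    gene_ids <- rownames(vals)
    # rowsum orders by first appearance with reorder = FALSE
  }
  rownames(vals) <- gene_ids
  colnames(vals) <- sample_ids
  expression_matrix(vals)
}

#' Write a count matrix as TSV
#'
#' Inverse of [read_counts()]; round-trips gene order, sample order and
#' values exactly.
#'
#' @param mat Genes x samples numeric matrix.
#' @param path Output path.
#' @param gene_col Name for the identifier column (default `"gene_id"`).
#' @export
write_counts <- function(mat, path, gene_col = "gene_id") {
  mat <- expression_matrix(mat)
  dt <- data.table::data.table(gene = rownames(mat))
  data.table::setnames(dt, "gene", gene_col)
  dt <- cbind(dt, data.table::as.data.table(mat))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Construct a two-group sample design
#'
#' @param assignments Named character vector mapping sample identifiers to
#'   group labels.
#' @param reference_label The label of the reference group (the published
#'   study's "NOR"); the other label becomes the condition group ("FRA").
#' @return An object of class `sample_design` with elements `assignments`,
#'   `reference`, `condition`.
#' @export
sample_design <- function(assignments, reference_label) {
  ids <- names(assignments)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("sample identifiers must be unique and named", call. = FALSE)
  }
  labels <- sort(unique(unname(assignments)))
  if (length(labels) != 2L) {
    stop("design must contain exactly 2 group labels, found ",
         length(labels), ": ", paste(labels, collapse = ", "), call. = FALSE)
  }
  if (!reference_label %in% labels) {
    stop("reference label '", reference_label,
         "' absent from design (labels: ",
         paste(labels, collapse = ", "), ")", call. = FALSE)
  }
  sizes <- table(assignments)
  if (any(sizes < 3L)) {
    small <- names(sizes)[sizes < 3L]
    stop("group(s) with fewer than 3 samples (Pearson R undefined): ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  structure(
    list(
      assignments = assignments,
      reference = reference_label,
      condition = setdiff(labels, reference_label)
    ),
    class = "sample_design"
  )
}

#' Sample identifiers belonging to one group of a design
#' @param design A `sample_design`.
#' @param group `"reference"` or `"condition"`, or an explicit group label.
#' @return Character vector of sample identifiers.
#' @export
design_samples <- function(design, group) {
  label <- switch(group,
                  reference = design$reference,
                  condition = design$condition,
                  group)
  if (!label %in% design$assignments) {
    stop("unknown group: ", group, call. = FALSE)
  }
  names(design$assignments)[design$assignments == label]
}

#' Read a two-column sample design table
#'
#' Expects a tab-separated file with columns sample_id, group_label; a
#' header row is detected and skipped if the first field is `sample_id`.
#'
#' @param path Path to the file.
#' @param reference_label Group label to treat as the reference group.
#' @return A `sample_design`.
#' @export
read_design <- function(path, reference_label) {
  if (!file.exists(path)) stop("design file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = "auto",
                          colClasses = "character")
  if (ncol(dt) != 2L) {
    stop("design table must have exactly 2 columns, found ", ncol(dt),
         call. = FALSE)
  }
  assignments <- dt[[2L]]
  names(assignments) <- dt[[1L]]
  sample_design(assignments, reference_label)
}

#' Write a sample design as a two-column TSV
#' @param design A `sample_design`.
#' @param path Output path.
#' @export
write_design <- function(design, path) {
  dt <- data.table::data.table(sample_id = names(design$assignments),
                               group_label = unname(design$assignments))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Construct an annotation collection
#'
#' @param terms Named list; each element a list with `description` (scalar
#'   character) and `genes` (character vector, de-duplicated here).
#' @return Object of class `annotation_collection` with `terms` and
#'   `universe` (union of all annotated genes).
#' @export
annotation_collection <- function(terms) {
  if (length(terms) && anyDuplicated(names(terms))) {
    stop("duplicate term identifiers in annotation", call. = FALSE)
  }
  terms <- lapply(terms, function(t) {
    genes <- unique(as.character(t$genes))
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("empty term gene set", call. = FALSE)
    list(description = as.character(t$description)[1L], genes = genes)
  })
  structure(
    list(terms = terms,
         universe = unique(unlist(lapply(terms, `[[`, "genes"),
                                  use.names = FALSE))),
    class = "annotation_collection"
  )
}

#' Read a GMT gene-set file
#'
#' One term per line: term_id, description, then one or more gene
#' identifiers, tab-separated. Member lists are de-duplicated per term.
#'
#' @param path Path to the GMT file.
#' @return An `annotation_collection`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty GMT file: ", path, call. = FALSE)
    return(annotation_collection(list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("GMT parse error at line ", which(nf < 3L)[1L],
         ": fewer than 3 tab-separated fields", call. = FALSE)
  }
  ids <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate term identifiers in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  terms <- lapply(fields, function(f) {
    list(description = f[[2L]], genes = unique(f[-c(1L, 2L)]))
  })
  names(terms) <- ids
  annotation_collection(terms)
}

#' Write an annotation collection as GMT
#' @param annotation An `annotation_collection`.
#' @param path Output path.
#' @export
write_gmt <- function(annotation, path) {
  lines <- vapply(names(annotation$terms), function(id) {
    t <- annotation$terms[[id]]
    paste(c(id, t$description, t$genes), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Write the ranked-Pc table, correlated-set tables and JSON run report
#'
#' Emits, under `out_dir`:
#' * `pc_ranking.tsv` — seed genes sorted by ascending Pc (undefined last,
#'   ties broken lexicographically), columns `gene_id`, `pc`,
#'   `n_profile_genes`;
#' * `sets/<seed>__<group>.tsv` — one file per seed gene per group with the
#'   members of its correlated set and their R values;
#' * `report.json` — configuration echo, group sizes, per-seed FRI/FAI, and
#'   the cross-gene common-term list.
#'
#' Outputs are byte-stable for a fixed input and configuration.
#'
#' @param ranking A `pc_ranking` from [rank_by_pc()].
#' @param comparisons List of `function_comparison` objects (may be empty).
#' @param out_dir Output directory (created if absent).
#' @param config The `coord_config` used for the run.
#' @param correlated_sets Optional list of gene sets from
#'   [extract_correlated_set()]; each becomes one TSV under `sets/`.
#' @param report_extra Named list merged into the JSON report (group sizes,
#'   coherence summaries, common terms, ...).
#' @return Invisibly, the path of the JSON report.
#' @export
write_outputs <- function(ranking, comparisons, out_dir,
                          config = coord_config(),
                          correlated_sets = list(),
                          report_extra = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }

  rank_tab <- data.table::data.table(
    gene_id = ranking$records$seed_gene,
    pc = ranking$records$pc,
    n_profile_genes = ranking$records$n_common_background
  )
  data.table::fwrite(rank_tab, file.path(out_dir, "pc_ranking.tsv"),
                     sep = "\t", quote = FALSE, na = "NA")

  if (length(correlated_sets)) {
    set_dir <- file.path(out_dir, "sets")
    dir.create(set_dir, showWarnings = FALSE)
    for (gs in correlated_sets) {
      tab <- data.table::data.table(gene_id = gs$genes, r = gs$r)
      data.table::fwrite(
        tab,
        file.path(set_dir, sprintf("%s__%s.tsv", gs$seed_gene, gs$group)),
        sep = "\t", quote = FALSE
      )
    }
  }

  fc <- lapply(comparisons, function(cmp) {
    list(
      seed_gene = cmp$seed_gene,
      n_terms_ref = length(cmp$terms_ref),
      n_terms_cond = length(cmp$terms_cond),
      n_common = length(cmp$common),
      n_acquired = length(cmp$acquired),
      n_lost = length(cmp$lost),
      fri = if (is.na(cmp$fri)) NULL else cmp$fri,
      fai = if (is.na(cmp$fai)) NULL else cmp$fai
    )
  })
  report <- c(
    list(
      package_version = as.character(utils::packageVersion("coordinatr")),
      config = unclass(config),
      function_comparison = fc
    ),
    report_extra
  )
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(report_path)
}
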