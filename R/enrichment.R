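#' Hypergeometric over-representation of annotation terms in a gene set
#'
#' A local, offline stand-in for a web GO platform: for each annotation
#' term, the upper-tail hypergeometric probability of observing at least
#' `k` query genes among the term's `K` background-restricted members, with
#' Benjamini-Hochberg adjustment across tested terms. Terms smaller than
#' `config$min_term_size` after intersection with the background are not
#' tested. Terms with `q < config$fdr_alpha` constitute the query's
#' "functions" set.
#'
#' @param query A `gene_set` from [extract_correlated_set()], or a character
#'   vector of gene identifiers. Must be a subset of `background`.
#' @param background Character vector: the gene universe against which
#'   enrichment is judged (typically the shared profile background).
#' @param annotation An `annotation_collection`.
#' @param config A `coord_config`.
#' @return A data.frame with one row per tested term: `term_id`,
#'   `description`, `k`, `K`, `n`, `N`, `p`, `q`, `significant`; sorted by
#'   ascending `p` (ties by `term_id`). Zero rows for an empty query.
#' @export
overrepresentation <- function(query, background, annotation,
                               config = coord_config()) {
  genes <- if (inherits(query, "gene_set")) query$genes else
    as.character(query)
  genes <- unique(genes)
  background <- unique(as.character(background))
  outside <- setdiff(genes, background)
  if (length(outside)) {
    stop("query gene(s) outside the background: ",
         paste(utils::head(outside, 5L), collapse = ", "), call. = FALSE)
  }
  empty <- data.frame(term_id = character(), description = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p = numeric(), q = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
  if (!length(genes)) {
    message("empty query gene set: no enrichment computed")
    return(empty)
  }
  if (!length(intersect(background, annotation$universe))) {
    stop("background and annotation universe are disjoint", call. = FALSE)
  }
  N <- length(background)
  n <- length(genes)
  rows <- lapply(names(annotation$terms), function(id) {
    term_genes <- intersect(annotation$terms[[id]]$genes, background)
    K <- length(term_genes)
    if (K < config$min_term_size) return(NULL)
    k <- length(intersect(term_genes, genes))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = id,
               description = annotation$terms[[id]]$description,
               k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) return(empty)
  res <- do.call(rbind, rows)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$q < config$fdr_alpha
  res <- res[order(res$p, res$term_id, method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Term identifiers forming a query's "functions" set
#' @param enrichment A data.frame from [overrepresentation()].
#' @return Character vector of significant term identifiers (sorted).
#' @export
significant_terms <- function(enrichment) {
  sort(enrichment$term_id[enrichment$significant])
}

#' Compare a seed gene's functional annotations between the two groups
#'
#' Computes the Function Retention Index and Function Acquisition Index
#' from the term sets attached to a seed gene's correlated sets:
#' FRI = |common| / |condition terms| (functions present in both groups,
#' as a fraction of all condition-group functions) and
#' FAI = |acquired| / |condition terms| (functions new to the condition
#' group). FRI + FAI = 1 whenever the condition set is nonempty; both are
#' `NA` (undefined) when it is empty. Terms found only in the reference
#' group are recorded as `lost` but carry no index.
#'
#' @param seed_gene Seed gene identifier.
#' @param terms_ref,terms_cond Character vectors of term identifiers for
#'   the reference and condition groups (either may be empty).
#' @return Object of class `function_comparison`: list with `seed_gene`,
#'   `terms_ref`, `terms_cond`, `common`, `acquired`, `lost`, `fri`, `fai`.
#' @export
compare_functions <- function(seed_gene, terms_ref, terms_cond) {
  terms_ref <- unique(as.character(terms_ref))
  terms_cond <- unique(as.character(terms_cond))
  common <- intersect(terms_ref, terms_cond)
  acquired <- setdiff(terms_cond, terms_ref)
  lost <- setdiff(terms_ref, terms_cond)
  if (length(terms_cond)) {
    fri <- length(common) / length(terms_cond)
    fai <- length(acquired) / length(terms_cond)
  } else {
    fri <- NA_real_
    fai <- NA_real_
  }
  structure(
    list(seed_gene = seed_gene, terms_ref = terms_ref,
         terms_cond = terms_cond, common = common, acquired = acquired,
         lost = lost, fri = fri, fai = fai),
    class = "function_comparison"
  )
}

#' Terms common to every seed gene within one group
#'
#' Intersection of the chosen group's term sets across all supplied seed
#' genes — the "functions shared by all low-Pc genes" summary.
#'
#' @param comparisons Nonempty list of `function_comparison` objects.
#' @param group `"ref"` or `"cond"`.
#' @param annotation Optional `annotation_collection` used to attach term
#'   descriptions.
#' @return A data.frame with columns `term_id`, `description` (possibly
#'   zero rows), sorted by `term_id`.
#' @export
common_terms_across_seeds <- function(comparisons, group = c("cond", "ref"),
                                      annotation = NULL) {
  group <- match.arg(group)
  if (!length(comparisons)) {
    stop("at least one function comparison required", call. = FALSE)
  }
  field <- if (group == "ref") "terms_ref" else "terms_cond"
  sets <- lapply(comparisons, `[[`, field)
  common <- Reduce(intersect, sets)
  common <- sort(common)
  desc <- rep(NA_character_, length(common))
  if (!is.null(annotation) && length(common)) {
    hit <- common %in% names(annotation$terms)
    desc[hit] <- vapply(annotation$terms[common[hit]], `[[`,
                        character(1L), "description")
  }
  data.frame(term_id = common, description = desc, stringsAsFactors = FALSE)
}
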