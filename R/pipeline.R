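#' Run the full coordination analysis
#'
#' Orchestrates, in order: read counts and design; high-expression filter in
#' the reference group; within-group pairwise correlation and coherence
#' summaries; transcriptome correlation profiles for the high-expression
#' seeds; composite correlation (Pc) per seed; Pc ranking with bottom/top
#' selection; correlated-set extraction per selected seed per group;
#' hypergeometric over-representation of each set against the GMT
#' annotation; FRI/FAI comparison per selected seed; and the cross-seed
#' common-term intersection. Every stage logs its input/output
#' cardinalities; any stage error aborts with the stage name.
#'
#' @param counts_path Path to a genes x samples TSV (see [read_counts()]).
#' @param design_path Path to a two-column design TSV (see [read_design()]).
#' @param gmt_path Path to a GMT annotation file; `NULL` disables the
#'   enrichment/FRI-FAI stages.
#' @param config A `coord_config`.
#' @param out_dir Output directory for tables, report and intermediates.
#' @param reference_label Group label of the reference group in the design
#'   file (default `"NOR"`).
#' @param counts_dialect Passed to [read_counts()].
#' @return Invisibly, an object of class `coord_report` with the
#'   configuration, stage cardinalities, coherence summaries, the
#'   `pc_ranking`, selected seeds, correlated sets, function comparisons,
#'   common terms and output paths.
#' @export
run_pipeline <- function(counts_path, design_path, gmt_path = NULL,
                         config = coord_config(), out_dir,
                         reference_label = "NOR",
                         counts_dialect = "plain_tsv") {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline aborted at stage '%s': %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  log_stage <- function(...) message("[", format(Sys.time(), "%H:%M:%S"),
                                     "] ", ...)

  mat <- stage("read_counts", read_counts(counts_path,
                                          dialect = counts_dialect))
  log_stage("read_counts: ", nrow(mat), " genes x ", ncol(mat), " samples")

  design <- stage("read_design", {
    d <- read_design(design_path, reference_label)
    absent <- setdiff(names(d$assignments), colnames(mat))
    if (length(absent)) {
      stop("design samples absent from counts: ",
           paste(absent, collapse = ", "))
    }
    d
  })
  n_ref <- length(design_samples(design, "reference"))
  n_cond <- length(design_samples(design, "condition"))
  log_stage("read_design: ", n_ref, " reference + ", n_cond,
            " condition samples")
  mat <- mat[, names(design$assignments), drop = FALSE]

  seeds <- stage("filter_high_expression",
                 filter_high_expression(mat, design, config))
  log_stage("filter_high_expression: ", length(seeds),
            " high-expression genes (min_reads = ", config$min_reads, ")")
  if (!length(seeds)) {
    stop("pipeline aborted at stage 'filter_high_expression': ",
         "no gene passes the filter", call. = FALSE)
  }

  corr <- stage("pairwise_correlation", list(
    reference = pairwise_correlation(mat, seeds, design, "reference", config),
    condition = pairwise_correlation(mat, seeds, design, "condition", config)
  ))
  coherence <- stage("coherence_summary", lapply(corr, coherence_summary))
  log_stage("coherence_summary: mean |R| reference = ",
            round(coherence$reference$mean_abs_r, 3), ", condition = ",
            round(coherence$condition$mean_abs_r, 3))

  profiles <- stage("transcriptome_profiles",
                    transcriptome_profiles(mat, seeds, design, config))
  log_stage("transcriptome_profiles: shared background of ",
            length(profiles$background), " genes")

  records <- stage("composite_correlation", lapply(seeds, function(s) {
    composite_correlation(profiles$reference[[s]], profiles$condition[[s]],
                          config)
  }))
  ranking <- stage("rank_by_pc", rank_by_pc(records, config))
  selected <- unique(c(ranking$bottom, ranking$top))
  log_stage("rank_by_pc: bottom = [",
            paste(ranking$bottom, collapse = ", "), "], top = [",
            paste(ranking$top, collapse = ", "), "]")

  sets <- stage("extract_correlated_set", {
    out <- list()
    for (s in selected) {
      out[[paste0(s, "::ref")]] <-
        extract_correlated_set(profiles$reference[[s]], config)
      out[[paste0(s, "::cond")]] <-
        extract_correlated_set(profiles$condition[[s]], config)
    }
    out
  })
  log_stage("extract_correlated_set: ",
            paste(vapply(sets, function(g) length(g$genes), integer(1L)),
                  collapse = "/"), " genes per set (R > ",
            config$r_cutoff, ")")

  comparisons <- list()
  common_bottom <- data.frame(term_id = character(),
                              description = character(),
                              stringsAsFactors = FALSE)
  annotation <- NULL
  if (!is.null(gmt_path)) {
    annotation <- stage("enrichment", read_gmt(gmt_path))
    comparisons <- stage("enrichment", {
      lapply(selected, function(s) {
        enr_ref <- overrepresentation(sets[[paste0(s, "::ref")]],
                                      profiles$background, annotation,
                                      config)
        enr_cond <- overrepresentation(sets[[paste0(s, "::cond")]],
                                       profiles$background, annotation,
                                       config)
        compare_functions(s, significant_terms(enr_ref),
                          significant_terms(enr_cond))
      })
    })
    names(comparisons) <- selected
    log_stage("enrichment: FRI/FAI computed for ", length(comparisons),
              " seed genes")
    if (length(ranking$bottom)) {
      common_bottom <- stage("common_terms_across_seeds",
                             common_terms_across_seeds(
                               comparisons[ranking$bottom],
                               group = "cond", annotation = annotation))
      log_stage("common_terms_across_seeds: ", nrow(common_bottom),
                " terms shared by all bottom seeds (condition group)")
    }
  }

  report_extra <- list(
    n_genes = nrow(mat),
    group_sizes = list(reference = n_ref, condition = n_cond),
    group_labels = list(reference = design$reference,
                        condition = design$condition),
    n_high_expression = length(seeds),
    n_background = length(profiles$background),
    coherence = coherence,
    bottom = as.list(ranking$bottom),
    top = as.list(ranking$top),
    common_terms_bottom_condition = as.list(common_bottom$term_id)
  )
  stage("write_outputs", {
    write_outputs(ranking, comparisons, out_dir, config,
                  correlated_sets = sets, report_extra = report_extra)
    write_intermediates(out_dir, corr, profiles, selected, comparisons)
  })
  log_stage("write_outputs: ", out_dir)

  invisible(structure(
    list(config = config, design = design,
         n_genes = nrow(mat), n_high_expression = length(seeds),
         seeds = seeds, coherence = coherence, corr = corr,
         profiles = profiles, ranking = ranking, selected = selected,
         sets = sets, comparisons = comparisons,
         common_terms_bottom_condition = common_bottom,
         out_dir = out_dir),
    class = "coord_report"
  ))
}

# Numeric twins of every figure: correlation matrices, per-selected-seed
# profile pairs, and the FRI/FAI table.
write_intermediates <- function(out_dir, corr, profiles, selected,
                                comparisons) {
  idir <- file.path(out_dir, "intermediates")
  dir.create(idir, showWarnings = FALSE, recursive = TRUE)
  for (grp in names(corr)) {
    v <- corr[[grp]]$values
    dt <- data.table::data.table(gene_id = rownames(v))
    dt <- cbind(dt, data.table::as.data.table(v))
    data.table::fwrite(dt, file.path(idir, sprintf("corr_%s.tsv", grp)),
                       sep = "\t", quote = FALSE, na = "NA")
  }
  for (s in selected) {
    p_ref <- profiles$reference[[s]]
    p_cond <- profiles$condition[[s]]
    dt <- data.table::data.table(gene_id = p_ref$background_gene_ids,
                                 r_ref = unname(p_ref$r_values),
                                 r_cond = unname(p_cond$r_values))
    data.table::fwrite(dt, file.path(idir, sprintf("profile_%s.tsv", s)),
                       sep = "\t", quote = FALSE, na = "NA")
  }
  if (length(comparisons)) {
    dt <- data.table::data.table(
      seed_gene = vapply(comparisons, `[[`, character(1L), "seed_gene"),
      fri = vapply(comparisons, `[[`, numeric(1L), "fri"),
      fai = vapply(comparisons, `[[`, numeric(1L), "fai")
    )
    data.table::fwrite(dt, file.path(idir, "fri_fai.tsv"),
                       sep = "\t", quote = FALSE, na = "NA")
  }
  invisible(idir)
}

#' Simulate a dataset and write it as pipeline-ready files
#'
#' Writes `counts.tsv` (both groups side by side), `design.tsv`,
#' `truth.json` (planted module assignments and rewired genes) and
#' `annotation.gmt` (module terms plus random background terms) under
#' `out_dir`. Reruns with the same configuration are byte-identical.
#'
#' @param config A `sim_config`, or a path to a JSON file whose fields are
#'   [sim_config()] arguments.
#' @param out_dir Output directory (created if absent).
#' @param n_background_terms Background terms for the planted annotation.
#' @return Invisibly, a named list of the four file paths plus the
#'   simulation result.
#' @export
simulate_command <- function(config, out_dir, n_background_terms = 50L) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("simulation config file not found: ", config, call. = FALSE)
    }
    args <- jsonlite::read_json(config, simplifyVector = TRUE)
    known <- names(formals(sim_config))
    bad <- setdiff(names(args), known)
    if (length(bad)) {
      stop("unknown simulation config field(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    config <- do.call(sim_config, args)
  }
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  sim <- simulate_dataset(config)
  design <- simulated_design(sim)
  annotation <- simulate_annotation(sim$truth, n_background_terms,
                                    rng_seed = config$rng_seed)

  paths <- list(
    counts = file.path(out_dir, "counts.tsv"),
    design = file.path(out_dir, "design.tsv"),
    truth = file.path(out_dir, "truth.json"),
    gmt = file.path(out_dir, "annotation.gmt")
  )
  write_counts(simulated_counts(sim), paths$counts)
  write_design(design, paths$design)
  jsonlite::write_json(
    list(config = unclass(config),
         module_of = as.list(sim$truth$module_of),
         module_of_cond = as.list(sim$truth$module_of_cond),
         seed_genes = sim$truth$seed_genes,
         rewired = sim$truth$rewired),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE,
    null = "null"
  )
  write_gmt(annotation, paths$gmt)
  invisible(c(paths, list(sim = sim)))
}

# Mirrored-density violin drawn with base graphics.
draw_violin <- function(values_list, labels, main) {
  vals <- unlist(values_list)
  vals <- vals[!is.na(vals)]
  ylim <- range(vals, finite = TRUE)
  plot(NULL, xlim = c(0.5, length(values_list) + 0.5), ylim = ylim,
       xaxt = "n", xlab = "", ylab = "R", main = main)
  graphics::axis(1, at = seq_along(values_list), labels = labels)
  for (i in seq_along(values_list)) {
    v <- values_list[[i]]
    v <- v[!is.na(v)]
    if (length(v) < 2L || stats::sd(v) == 0) {
      graphics::points(i, mean(v), pch = 19)
      next
    }
    d <- stats::density(v)
    w <- d$y / max(d$y) * 0.4
    graphics::polygon(c(i - w, rev(i + w)), c(d$x, rev(d$x)),
                      col = "grey80", border = "grey30")
    graphics::segments(i - 0.1, stats::median(v), i + 0.1,
                       stats::median(v), lwd = 2)
  }
}

#' Export basic figures from a pipeline report
#'
#' Writes, as PNG files under `out_dir`: one pairwise-correlation heatmap
#' per group, one violin panel per selected seed gene (its profile R values
#' in each group), and one FRI/FAI bar chart. The numeric data behind every
#' figure is already on disk as TSV (`intermediates/` of the pipeline
#' output), so no number exists only inside an image. Uses `pheatmap` for
#' heatmaps when installed, base graphics otherwise.
#'
#' @param report A `coord_report` from [run_pipeline()].
#' @param out_dir Output directory for images.
#' @return Invisibly, character vector of files written.
#' @export
export_figures <- function(report, out_dir) {
  stopifnot(inherits(report, "coord_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()

  for (grp in names(report$corr)) {
    v <- report$corr[[grp]]$values
    f <- file.path(out_dir, sprintf("heatmap_%s.png", grp))
    grDevices::png(f, width = 800, height = 800)
    if (requireNamespace("pheatmap", quietly = TRUE)) {
      vv <- v
      vv[is.na(vv)] <- 0
      pheatmap::pheatmap(vv, cluster_rows = FALSE, cluster_cols = FALSE,
                         show_rownames = nrow(vv) <= 60,
                         show_colnames = FALSE,
                         main = sprintf("pairwise R (%s)", grp))
    } else {
      graphics::image(v, main = sprintf("pairwise R (%s)", grp),
                      zlim = c(-1, 1))
    }
    grDevices::dev.off()
    written <- c(written, f)
  }

  if (length(report$selected)) {
    for (s in report$selected) {
      f <- file.path(out_dir, sprintf("violin_%s.png", s))
      grDevices::png(f, width = 500, height = 500)
      draw_violin(
        list(report$profiles$reference[[s]]$r_values,
             report$profiles$condition[[s]]$r_values),
        labels = c(report$design$reference, report$design$condition),
        main = sprintf("transcriptome R profile: %s", s)
      )
      grDevices::dev.off()
      written <- c(written, f)
    }
  } else {
    message("no selected seeds: no violin panels written")
  }

  if (length(report$comparisons)) {
    fri <- vapply(report$comparisons, `[[`, numeric(1L), "fri")
    fai <- vapply(report$comparisons, `[[`, numeric(1L), "fai")
    f <- file.path(out_dir, "fri_fai.png")
    grDevices::png(f, width = 600, height = 500)
    graphics::barplot(rbind(fri, fai), beside = TRUE,
                      names.arg = names(report$comparisons),
                      legend.text = c("FRI", "FAI"),
                      ylim = c(0, 1), ylab = "index")
    grDevices::dev.off()
    written <- c(written, f)
  }
  invisible(written)
}
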