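#' Simulation configuration
#'
#' Parameters of the two-group Gaussian-copula negative-binomial simulator.
#' The defaults describe the scale at which Pearson correlation profiles are
#' stable enough for recovery testing: 2,000 genes, 50 samples per group,
#' 10 co-expression modules of 50 genes with within-module latent
#' correlation 0.7, 100 designated seed genes of which 10 are rewired in the
#' condition group, and a mild (x1.15) global coherence amplification in the
#' condition group.
#'
#' @param n_genes Total number of genes.
#' @param n_samples_ref,n_samples_cond Samples per group.
#' @param n_modules,module_size Block co-expression structure;
#'   `n_modules * module_size <= n_genes`.
#' @param latent_rho Within-module latent correlation in the reference
#'   group, in (0, 1).
#' @param coherence_amplification Multiplier (>= 1) applied to `latent_rho`
#'   in the condition group, capped at 0.99.
#' @param n_seed_genes Number of designated seed genes (drawn from module
#'   members and forced into the top expression stratum so they pass the
#'   high-expression filter).
#' @param n_rewired Number of seed genes whose module assignment differs in
#'   the condition group (their planted "loss of coordination");
#'   `<= n_seed_genes`, and requires `n_modules >= 2` when positive.
#' @param nb_dispersion Negative-binomial dispersion (1/size); variance is
#'   `mu + dispersion * mu^2`.
#' @param mean_log_range Length-2 numeric: genes draw log-means uniformly
#'   from this range (default log(5) to log(500) reads).
#' @param rng_seed Integer; the simulation is fully determined by it.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L,
                       n_samples_ref = 50L,
                       n_samples_cond = 50L,
                       n_modules = 10L,
                       module_size = 50L,
                       latent_rho = 0.7,
                       coherence_amplification = 1.15,
                       n_seed_genes = 100L,
                       n_rewired = 10L,
                       nb_dispersion = 0.2,
                       mean_log_range = c(log(5), log(500)),
                       rng_seed = 1L) {
  stopifnot(
    n_genes >= 1, n_samples_ref >= 3, n_samples_cond >= 3,
    n_modules >= 0, module_size >= 1,
    latent_rho > 0, latent_rho < 1,
    coherence_amplification >= 1,
    n_seed_genes >= 1, n_rewired >= 0,
    nb_dispersion > 0,
    length(mean_log_range) == 2L, mean_log_range[1L] < mean_log_range[2L]
  )
  if (n_modules * module_size > n_genes) {
    stop("n_modules * module_size exceeds n_genes", call. = FALSE)
  }
  if (n_rewired > n_seed_genes) {
    stop("n_rewired exceeds n_seed_genes", call. = FALSE)
  }
  if (n_rewired > 0 && n_modules < 2L) {
    stop("rewiring requires at least 2 modules (n_modules = ",
         n_modules, ")", call. = FALSE)
  }
  if (n_seed_genes > n_modules * module_size) {
    stop("n_seed_genes exceeds the number of module genes", call. = FALSE)
  }
  structure(
    list(n_genes = as.integer(n_genes),
         n_samples_ref = as.integer(n_samples_ref),
         n_samples_cond = as.integer(n_samples_cond),
         n_modules = as.integer(n_modules),
         module_size = as.integer(module_size),
         latent_rho = latent_rho,
         coherence_amplification = coherence_amplification,
         n_seed_genes = as.integer(n_seed_genes),
         n_rewired = as.integer(n_rewired),
         nb_dispersion = nb_dispersion,
         mean_log_range = as.numeric(mean_log_range),
         rng_seed = as.integer(rng_seed)),
    class = "sim_config"
  )
}

# Latent normals with block (one-factor per module) correlation, mapped to
# negative-binomial counts through the Gaussian copula.
simulate_group_counts <- function(module_of, rho_by_gene, mu, size,
                                  n_samples, sample_prefix) {
  n_genes <- length(mu)
  f <- matrix(stats::rnorm(max(module_of, 0, na.rm = TRUE) * n_samples),
              ncol = n_samples)
  eps <- matrix(stats::rnorm(n_genes * n_samples), ncol = n_samples)
  z <- eps
  in_mod <- !is.na(module_of)
  if (any(in_mod)) {
    lam <- sqrt(rho_by_gene[in_mod])
    z[in_mod, ] <- lam * f[module_of[in_mod], , drop = FALSE] +
      sqrt(1 - rho_by_gene[in_mod]) * eps[in_mod, , drop = FALSE]
  }
  counts <- matrix(stats::qnbinom(stats::pnorm(z), size = size, mu = mu),
                   nrow = n_genes)
  rownames(counts) <- names(module_of)
  colnames(counts) <- sprintf("%s%02d", sample_prefix, seq_len(n_samples))
  counts
}

#' Simulate a two-group count dataset with planted coordination changes
#'
#' Each sample draws one latent factor per co-expression module plus
#' per-gene noise; a gene in module *m* has latent value
#' `sqrt(rho) * f_m + sqrt(1 - rho) * eps`, giving within-module latent
#' correlation exactly `rho` and zero between modules. Latents map to
#' counts by the Gaussian copula: the negative-binomial quantile (gene
#' mean drawn log-uniformly, shared between groups; fixed dispersion) of
#' the latent's normal CDF value. In the condition group the latent
#' correlation is amplified (`min(latent_rho * coherence_amplification,
#' 0.99)`) and each rewired seed gene is reassigned to a different,
#' randomly chosen module — decorrelating its transcriptome profile while
#' leaving its marginal distribution untouched (no differential-expression
#' confound).
#'
#' @param config A `sim_config`.
#' @return List with `ref` and `cond` (genes x samples count matrices,
#'   identical gene order), `truth` (class `synthetic_truth`: `module_of`,
#'   `module_of_cond`, `seed_genes`, `rewired`), the echoed `config`, and
#'   the copula's marginal targets `mu` (named per-gene NB means) and
#'   `nb_size` (shared NB size = 1/dispersion).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$rng_seed, {
    gene_ids <- sprintf("G%05d", seq_len(config$n_genes))
    module_of <- rep(NA_integer_, config$n_genes)
    n_mod_genes <- config$n_modules * config$module_size
    if (n_mod_genes > 0) {
      module_of[seq_len(n_mod_genes)] <-
        rep(seq_len(config$n_modules), each = config$module_size)
    }
    names(module_of) <- gene_ids

    lo <- config$mean_log_range[1L]
    hi <- config$mean_log_range[2L]
    log_mu <- stats::runif(config$n_genes, lo, hi)

    module_genes <- gene_ids[!is.na(module_of)]
    seed_genes <- sort(sample(module_genes, config$n_seed_genes))
    # top expression stratum: upper quarter of the log-mean range, so the
    # default >= 70-read filter keeps every seed
    seed_idx <- match(seed_genes, gene_ids)
    log_mu[seed_idx] <- stats::runif(config$n_seed_genes,
                                     lo + 0.75 * (hi - lo), hi)
    mu <- exp(log_mu)
    size <- 1 / config$nb_dispersion

    rewired <- character()
    module_of_cond <- module_of
    if (config$n_rewired > 0) {
      rewired <- sort(sample(seed_genes, config$n_rewired))
      for (g in rewired) {
        old <- module_of[[g]]
        module_of_cond[[g]] <-
          sample(setdiff(seq_len(config$n_modules), old), 1L)
      }
    }

    rho_ref <- ifelse(is.na(module_of), NA_real_, config$latent_rho)
    rho_amp <- min(config$latent_rho * config$coherence_amplification, 0.99)
    rho_cond <- ifelse(is.na(module_of_cond), NA_real_, rho_amp)

    ref <- simulate_group_counts(module_of, rho_ref, mu, size,
                                 config$n_samples_ref, "REF_S")
    cond <- simulate_group_counts(module_of_cond, rho_cond, mu, size,
                                  config$n_samples_cond, "CND_S")

    truth <- structure(
      list(module_of = module_of, module_of_cond = module_of_cond,
           seed_genes = seed_genes, rewired = rewired),
      class = "synthetic_truth"
    )
    list(ref = ref, cond = cond, truth = truth, config = config,
         mu = stats::setNames(mu, gene_ids), nb_size = size)
  })
}

#' Sample design matching a simulated dataset
#'
#' @param sim Result of [simulate_dataset()].
#' @param reference_label,condition_label Group labels (defaults "NOR" and
#'   "FRA", mirroring reference/condition).
#' @return A `sample_design`.
#' @export
simulated_design <- function(sim, reference_label = "NOR",
                             condition_label = "FRA") {
  assignments <- c(
    stats::setNames(rep(reference_label, ncol(sim$ref)), colnames(sim$ref)),
    stats::setNames(rep(condition_label, ncol(sim$cond)), colnames(sim$cond))
  )
  sample_design(assignments, reference_label)
}

#' Combine a simulated dataset's two groups into one matrix
#' @param sim Result of [simulate_dataset()].
#' @return Genes x samples matrix (reference samples first).
#' @export
simulated_counts <- function(sim) {
  expression_matrix(cbind(sim$ref, sim$cond))
}

#' Simulate a planted annotation matching the simulated modules
#'
#' One term per co-expression module containing exactly that module's genes
#' (by the reference-group assignment), plus random background terms of the
#' same size drawn from all genes.
#'
#' @param truth A `synthetic_truth`.
#' @param n_background_terms Number of random terms to add.
#' @param rng_seed Integer seed; the collection is deterministic given it.
#' @return An `annotation_collection`.
#' @export
simulate_annotation <- function(truth, n_background_terms = 50L,
                                rng_seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"), n_background_terms >= 0)
  with_seed(rng_seed, {
    gene_ids <- names(truth$module_of)
    mods <- sort(unique(truth$module_of[!is.na(truth$module_of)]))
    terms <- list()
    for (m in mods) {
      terms[[sprintf("MODULE_%02d", m)]] <- list(
        description = sprintf("planted co-expression module %d", m),
        genes = gene_ids[!is.na(truth$module_of) & truth$module_of == m]
      )
    }
    size <- if (length(mods)) {
      sum(!is.na(truth$module_of)) %/% length(mods)
    } else {
      max(5L, length(gene_ids) %/% 20L)
    }
    size <- min(size, length(gene_ids))
    for (b in seq_len(n_background_terms)) {
      terms[[sprintf("BG_%03d", b)]] <- list(
        description = sprintf("random background term %d", b),
        genes = sample(gene_ids, size)
      )
    }
    annotation_collection(terms)
  })
}

#' Score a Pc ranking against the planted truth
#'
#' `auc` is the probability that a randomly chosen rewired seed ranks below
#' (has lower Pc than) a randomly chosen unrewired seed, by exhaustive pair
#' counting with ties worth 0.5; seeds with undefined Pc count as ranked
#' last. `precision_at_k` is the fraction of the bottom `|rewired|` ranked
#' seeds that are truly rewired.
#'
#' @param ranking A `pc_ranking` covering every seed gene of `truth`.
#' @param truth A `synthetic_truth` (or any list with `seed_genes` and
#'   `rewired`) with at least one rewired gene.
#' @return List with `auc` and `precision_at_k`.
#' @export
evaluate_recovery <- function(ranking, truth) {
  seeds <- truth$seed_genes
  rewired <- truth$rewired
  if (!length(rewired)) {
    stop("no rewired genes: recovery is undefined", call. = FALSE)
  }
  rec <- ranking$records
  missing <- setdiff(seeds, rec$seed_gene)
  if (length(missing)) {
    stop("ranking does not cover seed gene(s): ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  pc <- rec$pc[match(seeds, rec$seed_gene)]
  pc[is.na(pc)] <- Inf
  is_rew <- seeds %in% rewired
  pos <- pc[is_rew]
  neg <- pc[!is_rew]
  if (!length(neg)) stop("no unrewired seeds to compare", call. = FALSE)
  cmp <- outer(pos, neg, FUN = function(a, b) (a < b) + 0.5 * (a == b))
  auc <- mean(cmp)
  k <- length(pos)
  ranked_seeds <- rec$seed_gene[rec$seed_gene %in% seeds]
  precision <- mean(utils::head(ranked_seeds, k) %in% rewired)
  list(auc = auc, precision_at_k = precision)
}
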