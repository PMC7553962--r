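#' Simulation configuration
#'
#' Describes a synthetic multi-region expression study with planted
#' region-specific co-expression modules over a log-normal noise
#' background, plus a companion somatic-mutation cohort with planted
#' elevated-rate gene sets.  Defaults describe the package's reference
#' study: 6 regions of 60 samples each, 300 genes, one 10-gene module
#' planted per region with factor loading 0.95, and a 2-type tumor cohort
#' of 100 tumors per type with a background per-gene mutation probability
#' of 0.01 and one 50-gene set mutated at 5x that rate.
#'
#' Expression model, on the log2 scale: every gene g has a baseline mean
#' `mu_g ~ N(baseline_log2_mean, baseline_log2_sd)`.  For a sample s of
#' region r and a gene in a module planted in region r,
#' `x = mu_g + region_shift + noise_sd * (lambda * f_s +
#' sqrt(1 - lambda^2) * e)`, with one shared latent factor
#' `f_s ~ N(0,1)` per module per sample; for background genes everywhere
#' `x = mu_g + noise_sd * e` with independent `e ~ N(0,1)`, and for a
#' module gene outside its planted region `x = mu_g - region_shift +
#' noise_sd * e`.  A planted gene is thus a marker of its region:
#' expressed at its natural level (and co-expressed) in-region, strongly
#' downregulated elsewhere — which is exactly the condition-specific
#' structure the per-pair mixture clustering deconvolves, while keeping
#' in-region module values interleaved with the background so that
#' quantile normalization preserves their rank variation.  The emitted
#' matrix is `2^x` (TPM-like), with zeros injected at `zero_prob` to
#' exercise downstream missing/negative-value handling.
#'
#' Mutations: per tumor and gene, presence ~ Bernoulli(rate) and
#' multiplicity ~ 1 + Poisson(0.3) given presence, where rate is
#' `background_rate` times the set's multiplier for genes of an enriched
#' set (in its designated tumor types).
#'
#' @param n_regions,samples_per_region,n_genes Study dimensions.
#' @param planted_modules List of modules, each a list with elements
#'   `region` (1-based region index or region name), `genes` (gene ids or
#'   1-based indices) and `lambda` (factor loading in `[0, 1)`).  The
#'   default plants one module of `module_size` consecutive genes per
#'   region at loading `lambda`.
#' @param module_size,lambda Used only to build the default
#'   `planted_modules`.
#' @param region_shift Mean log2 downregulation of a planted gene
#'   outside its region (default 3, i.e. 8-fold — a strong regional
#'   marker).
#' @param noise_sd Residual SD on the log2 scale.
#' @param baseline_log2_mean,baseline_log2_sd Background-gene baseline
#'   distribution.
#' @param module_baseline_log2_mean,module_baseline_log2_sd Baseline
#'   distribution for planted-module genes; the defaults make module
#'   genes clearly expressed, mirroring the observation that enriched
#'   network nodes sit well above the all-gene expression average.
#' @param zero_prob Probability that an emitted TPM value is zeroed.
#' @param gene_length_range Min/max bp; lengths drawn log-uniformly.
#' @param tumor_types,tumors_per_type,background_rate Mutation cohort.
#' @param enriched_sets List of lists with `genes`, `multiplier` and
#'   optional `tumor_types` (default: all types).  The default plants one
#'   50-gene set at multiplier 5.
#' @param seed Integer seed; all outputs are deterministic given the
#'   config (which includes the seed).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_regions = 6, samples_per_region = 60, n_genes = 300,
                       planted_modules = NULL, module_size = 10, lambda = 0.95,
                       region_shift = 3, noise_sd = 1, baseline_log2_mean = 3,
                       baseline_log2_sd = 2, module_baseline_log2_mean = 4.5,
                       module_baseline_log2_sd = 1, zero_prob = 0.02,
                       gene_length_range = c(200, 20000),
                       tumor_types = c("TUM_A", "TUM_B"),
                       tumors_per_type = 100, background_rate = 0.01,
                       enriched_sets = NULL, seed = 1L) {
  assert_that(n_regions >= 1 && samples_per_region >= 1 && n_genes >= 1,
              "all counts must be >= 1")
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  region_ids <- sprintf("region%02d", seq_len(n_regions))
  if (is.null(planted_modules)) {
    assert_that(module_size * n_regions <= n_genes,
                "not enough genes for the default planted modules")
    planted_modules <- lapply(seq_len(n_regions), function(r) {
      list(region = region_ids[r],
           genes = gene_ids[((r - 1) * module_size + 1):(r * module_size)],
           lambda = lambda)
    })
  }
  planted_modules <- lapply(planted_modules, function(m) {
    if (is.numeric(m$region)) m$region <- region_ids[m$region]
    if (is.numeric(m$genes)) m$genes <- gene_ids[m$genes]
    assert_that(m$region %in% region_ids, "planted module region unknown")
    assert_that(all(m$genes %in% gene_ids), "planted module gene unknown")
    assert_that(m$lambda >= 0 && m$lambda < 1,
                "factor loading lambda must be in [0, 1)")
    m
  })
  all_mod_genes <- unlist(lapply(planted_modules, `[[`, "genes"))
  assert_that(!anyDuplicated(all_mod_genes),
              "planted modules must have disjoint gene sets")
  if (is.null(enriched_sets)) {
    enriched_sets <- list(list(genes = gene_ids[seq_len(min(50, n_genes))],
                               multiplier = 5))
  }
  enriched_sets <- lapply(enriched_sets, function(s) {
    if (is.numeric(s$genes)) s$genes <- gene_ids[s$genes]
    s$tumor_types <- s$tumor_types %||% tumor_types
    assert_that(background_rate * s$multiplier <= 1,
                "background_rate * multiplier must be <= 1")
    s
  })
  structure(
    list(n_regions = n_regions, samples_per_region = samples_per_region,
         n_genes = n_genes, gene_ids = gene_ids, region_ids = region_ids,
         planted_modules = planted_modules, region_shift = region_shift,
         noise_sd = noise_sd,
         baseline_log2_mean = baseline_log2_mean,
         baseline_log2_sd = baseline_log2_sd,
         module_baseline_log2_mean = module_baseline_log2_mean,
         module_baseline_log2_sd = module_baseline_log2_sd,
         zero_prob = zero_prob,
         gene_length_range = gene_length_range, tumor_types = tumor_types,
         tumors_per_type = tumors_per_type, background_rate = background_rate,
         enriched_sets = enriched_sets, seed = as.integer(seed)),
    class = "sim_config")
}

#' Simulate a labeled gene expression matrix with planted modules
#'
#' @param config A [sim_config()].
#' @return A list with elements `gem` (a [gem] on the TPM-like scale with
#'   labels and gene lengths attached) and `truth`, a list holding
#'   `planted_edges` (tibble `gene_a < gene_b`, `region`),
#'   `informative_genes` (named list per region) and `enriched_mutation_sets`.
#' @export
simulate_gem <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_samples <- config$n_regions * config$samples_per_region
  sample_ids <- sprintf("S%04d", seq_len(n_samples))
  labels <- setNames(rep(config$region_ids, each = config$samples_per_region),
                     sample_ids)
  with_seed(derive_seed(config$seed, 101L), {
    mu <- rnorm(config$n_genes, config$baseline_log2_mean,
                config$baseline_log2_sd)
    mod_genes <- match(unlist(lapply(config$planted_modules, `[[`, "genes")),
                       config$gene_ids)
    if (length(mod_genes) > 0) {
      mu[mod_genes] <- rnorm(length(mod_genes),
                             config$module_baseline_log2_mean,
                             config$module_baseline_log2_sd)
    }
    x <- matrix(rnorm(config$n_genes * n_samples), config$n_genes, n_samples)
    for (m in config$planted_modules) {
      gi <- match(m$genes, config$gene_ids)
      si <- which(labels == m$region)
      f <- rnorm(length(si))
      x[gi, si] <- m$lambda * matrix(f, length(gi), length(si), byrow = TRUE) +
        sqrt(1 - m$lambda^2) * x[gi, si, drop = FALSE]
      x[gi, -si] <- x[gi, -si, drop = FALSE] -
        config$region_shift / config$noise_sd
    }
    x <- mu + config$noise_sd * x
    tpm <- 2^x
    if (config$zero_prob > 0) {
      z <- matrix(runif(length(tpm)) < config$zero_prob, nrow(tpm))
      tpm[z] <- 0
    }
    lr <- log(config$gene_length_range)
    lengths <- setNames(round(exp(runif(config$n_genes, lr[1], lr[2]))),
                        config$gene_ids)
    dimnames(tpm) <- list(config$gene_ids, sample_ids)
    g <- gem(tpm, labels = labels, gene_lengths = lengths, scale = "linear")
    planted_edges <- purrr::map_dfr(config$planted_modules, function(m) {
      if (length(m$genes) < 2) return(tibble::tibble())
      pr <- t(combn(sort(m$genes), 2))
      tibble::tibble(gene_a = pr[, 1], gene_b = pr[, 2], region = m$region)
    })
    informative <- split(
      unlist(lapply(config$planted_modules, `[[`, "genes")),
      unlist(lapply(config$planted_modules,
                    function(m) rep(m$region, length(m$genes)))))
    list(gem = g,
         truth = list(planted_edges = planted_edges,
                      informative_genes = informative,
                      enriched_mutation_sets = config$enriched_sets))
  })
}

#' Simulate a somatic-mutation table with planted enriched gene sets
#'
#' @param config A [sim_config()].
#' @return A list with `mutations` (tibble `tumor_id`, `tumor_type`,
#'   `gene`, one row per mutation event) and `truth` (the enriched sets).
#' @export
simulate_mutations <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 202L), {
    rows <- list()
    for (tt in config$tumor_types) {
      rate <- rep(config$background_rate, config$n_genes)
      names(rate) <- config$gene_ids
      for (s in config$enriched_sets) {
        if (tt %in% s$tumor_types) rate[s$genes] <- rate[s$genes] * s$multiplier
      }
      assert_that(all(rate <= 1),
                  "mutation presence probability exceeds 1")
      for (k in seq_len(config$tumors_per_type)) {
        tumor_id <- sprintf("%s_T%03d", tt, k)
        hit <- which(rbinom(config$n_genes, 1, rate) == 1)
        if (length(hit) == 0) next
        counts <- 1 + rpois(length(hit), 0.3)
        rows[[length(rows) + 1]] <- tibble::tibble(
          tumor_id = tumor_id, tumor_type = tt,
          gene = rep(config$gene_ids[hit], counts))
      }
    }
    mutations <- if (length(rows) > 0) dplyr::bind_rows(rows) else
      tibble::tibble(tumor_id = character(), tumor_type = character(),
                     gene = character())
    list(mutations = mutations,
         truth = list(enriched_mutation_sets = config$enriched_sets))
  })
}

#' Write the simulated study to TSV files
#'
#' Emits `gem.tsv`, `labels.tsv`, `gene_lengths.tsv` and `mutations.tsv`
#' under `dir`.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a character vector of the written paths.
#' @export
simulate_study <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- simulate_gem(config)
  mut <- simulate_mutations(config)
  paths <- c(
    gem = file.path(dir, "gem.tsv"),
    labels = file.path(dir, "labels.tsv"),
    gene_lengths = file.path(dir, "gene_lengths.tsv"),
    mutations = file.path(dir, "mutations.tsv"))
  write_gem(sim$gem, paths["gem"])
  write_labels(sim$gem$labels, paths["labels"])
  write_gene_lengths(sim$gem$gene_lengths, paths["gene_lengths"])
  readr::write_tsv(mut$mutations, paths["mutations"])
  invisible(paths)
}
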