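#' Configuration for the end-to-end pipeline
#'
#' Exactly one input source is required: either a `simulation` block (a
#' [simulation_config()]) or the three file paths of a real dataset
#' (`design_file`, `ct_file`, `behavior_file`, plus `directions_file`).
#'
#' @param simulation A [simulation_config()], or `NULL` when reading files.
#' @param design_file,ct_file,behavior_file,directions_file CSV inputs
#'   (design; long CT table `sample_id, gene, replicate, ct`; long behavior
#'   table; measure-direction map).
#' @param reference_genes The two qPCR reference genes.
#' @param comparison Comparison group for Z-scoring (named list of design
#'   column values).
#' @param categories Gene category table for FDR families.
#' @param fdr False discovery rate (default 0.05).
#' @param bh_family BH pooling mode for the ANOVA stage (`"per_term"` or
#'   `"pooled"`).
#' @param tau Network weight threshold (default 0).
#' @param n_perm Permutations for network comparisons (default 1000).
#' @param projection `"own"` exports each group's own network;
#'   `"male-reference"` additionally exports female-phenotype data projected
#'   onto the male-phenotype structure (and is what the exported female
#'   networks show).
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            design_file = NULL, ct_file = NULL,
                            behavior_file = NULL, directions_file = NULL,
                            reference_genes = c("Actb", "Gapdh"),
                            comparison = list(
                              sex_chromosome = "XX", hormone = "blank"
                            ),
                            categories = fcg_gene_panel(),
                            fdr = 0.05,
                            bh_family = c("per_term", "pooled"),
                            tau = 0, n_perm = 1000,
                            projection = c("own", "male-reference")) {
  bh_family <- match.arg(bh_family)
  projection <- match.arg(projection)
  files <- list(
    design_file = design_file, ct_file = ct_file,
    behavior_file = behavior_file, directions_file = directions_file
  )
  has_files <- any(!vapply(files, is.null, logical(1)))
  if (has_files && !is.null(simulation)) {
    abort("give either a simulation block or input files, not both",
      class = "fcg_invalid_config"
    )
  }
  if (!has_files && is.null(simulation)) {
    abort("one of simulation block or input files is required",
      class = "fcg_invalid_config"
    )
  }
  if (has_files && any(vapply(files[1:3], is.null, logical(1)))) {
    abort("design_file, ct_file and behavior_file are all required",
      class = "fcg_invalid_config"
    )
  }
  stopifnot(fdr > 0, fdr < 1, tau >= 0, tau < 1, n_perm >= 1)
  structure(
    c(
      list(simulation = simulation),
      files,
      list(
        reference_genes = reference_genes, comparison = comparison,
        categories = as_tibble(categories), fdr = fdr,
        bh_family = bh_family, tau = tau, n_perm = n_perm,
        projection = projection
      )
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Recognised keys mirror the [pipeline_config()] arguments; a `simulation`
#' sub-block is passed to [simulation_config()] (its `genes` and `behavior`
#' entries, if present, are coerced to tibbles).
#'
#' @param path A `.yaml`/`.yml` or `.json` file.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$simulation)) {
    sim <- raw$simulation
    for (tab in c("genes", "behavior")) {
      if (!is.null(sim[[tab]])) sim[[tab]] <- as_tibble(as.data.frame(sim[[tab]]))
    }
    for (beta in c("baseline_log2", "beta_chr", "beta_gon", "beta_act", "beta_gxa")) {
      if (!is.null(sim[[beta]]) && is.list(sim[[beta]])) {
        sim[[beta]] <- unlist(sim[[beta]])
      }
    }
    raw$simulation <- do.call(simulation_config, sim)
  }
  keep <- intersect(names(raw), names(formals(pipeline_config)))
  do.call(pipeline_config, raw[keep])
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> quantify -> emotionality scores -> per-gene
#' three-way ANOVA -> stratified gene-behavior correlations -> dimorphism
#' ratio matrix -> per-factor co-expression networks with permutation
#' comparisons -> exports. Writes every stage's tables plus `report.json`
#' (seeds, counts, warnings) into `out_dir`; a rerun with the same config
#' and seed is byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Top-level integer seed; all stage sub-seeds derive from it.
#' @return Invisibly, a list with every stage result and the report.
#' @export
#' @examples
#' \donttest{
#' cfg <- pipeline_config(
#'   simulation = simulation_config(n_per_group = 4), n_perm = 49
#' )
#' res <- run_pipeline(cfg, tempfile("fcg"), seed = 1)
#' names(res)
#' }
run_pipeline <- function(config, out_dir, seed = 1) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character()
  log_warning <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }

  # --- inputs ---------------------------------------------------------
  if (!is.null(config$simulation)) {
    sim <- simulate_study(config$simulation, seed = seed)
    design <- sim$design
    ct <- sim$ct
    behavior <- sim$behavior
    directions <- sim$directions
    write_simulation(sim, out_dir)
  } else {
    design <- readr::read_csv(config$design_file, show_col_types = FALSE)
    ct <- readr::read_csv(config$ct_file, show_col_types = FALSE)
    behavior <- readr::read_csv(config$behavior_file, show_col_types = FALSE)
    directions <- readr::read_csv(config$directions_file, show_col_types = FALSE)
    sim <- NULL
  }

  # --- quantification -------------------------------------------------
  ct_mean <- collapse_replicates(ct)
  withCallingHandlers(
    check_reference_stability(ct_mean, design, config$reference_genes),
    warning = log_warning
  )
  expression <- relative_expression(ct_mean, config$reference_genes)
  readr::write_csv(expression, file.path(out_dir, "expression.csv"))

  # --- emotionality ---------------------------------------------------
  emotionality <- emotionality_scores(
    behavior, design, directions,
    comparison = config$comparison
  )
  readr::write_csv(emotionality, file.path(out_dir, "emotionality.csv"))

  # --- per-gene ANOVA -------------------------------------------------
  anova_tbl <- withCallingHandlers(
    anova_expression(
      expression, design,
      categories = config$categories,
      fdr = config$fdr, bh_family = config$bh_family
    ),
    warning = log_warning
  )
  readr::write_csv(anova_tbl, file.path(out_dir, "anova_results.csv"))

  # --- correlations ---------------------------------------------------
  correlations <- stratified_correlations(
    expression, emotionality, design,
    categories = config$categories, fdr = config$fdr
  )
  readr::write_csv(correlations, file.path(out_dir, "correlations.csv"))
  signs <- sign_summary(correlations)
  writeLines(
    c(
      "# Genes correlated with anxiety-like behavior",
      "",
      sprintf(
        "- (%s) correlation in %s: %s",
        signs$direction, signs$stratum, signs$genes
      )
    ),
    file.path(out_dir, "sign_summary.md")
  )

  # --- dimorphism ratio matrix ----------------------------------------
  ratios <- ratio_matrix(expression, design, anova = anova_tbl)
  write_ratio_matrix(ratios, file.path(out_dir, "ratio_matrix.tsv"))

  # --- networks per main factor ---------------------------------------
  fl <- fcg_factors()
  net_dir <- file.path(out_dir, "networks")
  dir.create(net_dir, showWarnings = FALSE)
  networks <- list()
  comparisons <- list()
  prop_rows <- list()
  for (i in seq_len(nrow(fl))) {
    col <- fl$factor[i]
    ids_m <- design$sample_id[design[[col]] == fl$male_level[i]]
    ids_f <- design$sample_id[design[[col]] == fl$female_level[i]]
    net_m <- build_network(expression, ids_m,
      tau = config$tau,
      group = fl$male_level[i]
    )
    net_f <- build_network(expression, ids_f,
      tau = config$tau,
      group = fl$female_level[i]
    )
    cmp <- compare_networks(
      expression, ids_m, ids_f,
      n_perm = config$n_perm, tau = config$tau, seed = seed + i,
      labels = c(fl$male_level[i], fl$female_level[i])
    )
    networks[[col]] <- list(male = net_m, female = net_f)
    comparisons[[col]] <- cmp

    export_f <- if (config$projection == "male-reference") {
      project_reference(net_m, expression, ids_f, group = fl$female_level[i])
    } else {
      net_f
    }
    for (net in list(net_m, export_f)) {
      stem <- file.path(net_dir, paste0(col, "_", net$group))
      write_network_edges(net, paste0(stem, ".tsv"))
      write_network_graphml(net, paste0(stem, ".graphml"))
    }

    prop_rows[[col]] <- bind_rows(
      glance(net_m), glance(net_f)
    ) |>
      mutate(factor = col) |>
      left_join(
        tidy(cmp) |>
          select("property", "p") |>
          pivot_wider(
            names_from = "property", values_from = "p",
            names_prefix = "p_"
          ) |>
          mutate(factor = col),
        by = "factor"
      )
  }
  properties <- bind_rows(prop_rows)
  readr::write_csv(properties, file.path(out_dir, "network_properties.csv"))

  # --- report ---------------------------------------------------------
  report <- list(
    package = "fcgnet",
    version = as.character(utils::packageVersion("fcgnet")),
    seed = seed,
    sub_seeds = list(
      design = stage_seed(seed, "design"),
      expression = stage_seed(seed, "expression"),
      behavior = stage_seed(seed, "behavior"),
      permutation = stage_seed(seed, "permutation")
    ),
    n_samples = nrow(design),
    n_genes = length(setdiff(names(expression), "sample_id")),
    n_perm = config$n_perm,
    fdr = config$fdr,
    tau = config$tau,
    projection = config$projection,
    n_significant_anova = sum(anova_tbl$significant, na.rm = TRUE),
    n_significant_correlations = sum(correlations$significant, na.rm = TRUE),
    warnings = warnings_log,
    files = sort(list.files(out_dir, recursive = TRUE))
  )
  jsonlite::write_json(
    report, file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  invisible(list(
    simulation = sim, design = design, expression = expression,
    emotionality = emotionality, anova = anova_tbl,
    correlations = correlations, sign_summary = signs, ratios = ratios,
    networks = networks, comparisons = comparisons,
    network_properties = properties, report = report
  ))
}
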