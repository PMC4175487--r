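#' Configuration for the synthetic FCG study generator
#'
#' Builds and validates the parameter set from which synthetic Four Core
#' Genotypes (FCG) style datasets are generated: a 2 x 2 x 2 design (sex
#' chromosome complement x gonadal sex x adult hormone capsule), per-gene
#' additive log2 effects, a latent-factor co-expression module active only in
#' selected groups, qPCR cycle-threshold (CT) construction with technical
#' replicate noise, and behavioral measures linearly coupled to chosen genes.
#'
#' Effects are additive on the log2 scale so they carry fold-change semantics
#' through the `2^-dCT` quantification. CT values are constructed as
#' `CT_target = ct_ref_mean - latent + log2(10000)` so that quantification
#' recovers `2^latent` exactly when all noise terms are zero.
#'
#' @param n_per_group Mice per each of the 8 design cells (>= 2).
#' @param genes Gene table as from [fcg_gene_panel()]: columns `gene`,
#'   `category`, `is_reference`.
#' @param baseline_log2 Per-gene baseline log2 expression (arbitrary units);
#'   a scalar or a (possibly partial) named vector, default 10.
#' @param beta_chr,beta_gon,beta_act Additive log2 effects of the XY-,
#'   testes, and testosterone levels; scalar or partial named vectors.
#' @param beta_gxa Gonadal-sex x hormone interaction effect (added for
#'   testes + testosterone samples).
#' @param module_genes Genes sharing the latent co-expression factor.
#' @param module_groups Group labels (see [simulate_design()]) in which the
#'   module factor is active.
#' @param module_loading Loading of the latent factor, in `[0, 1)`.
#' @param noise_sd Residual log2 SD per sample x gene.
#' @param ct_ref_mean Mean CT of the two reference genes.
#' @param replicate_sd Technical CT SD across the quadruplicate wells.
#' @param behavior Behavioral coupling table: columns `test`, `measure`,
#'   `gene`, `intercept`, `slope`, `noise_sd`, `direction` (+1 if a larger
#'   raw value means more anxiety, -1 otherwise). `gene` may be `NA` for an
#'   uncoupled measure.
#' @return A validated list of class `"simulation_config"`.
#' @export
#' @examples
#' cfg <- simulation_config(n_per_group = 4)
#' names(cfg)
simulation_config <- function(n_per_group = 8,
                              genes = fcg_gene_panel(),
                              baseline_log2 = 10,
                              beta_chr = default_beta_chr(),
                              beta_gon = default_beta_gon(),
                              beta_act = default_beta_act(),
                              beta_gxa = default_beta_gxa(),
                              module_genes = fcg_core_module(),
                              module_groups = male_gonadal_groups(),
                              module_loading = 0.8,
                              noise_sd = 0.5,
                              ct_ref_mean = 20,
                              replicate_sd = 0.15,
                              behavior = default_behavior_coupling()) {
  genes <- as_tibble(genes)
  stopifnot(all(c("gene", "category", "is_reference") %in% names(genes)))
  targets <- genes$gene[!genes$is_reference]

  cfg <- structure(
    list(
      n_per_group = n_per_group,
      genes = genes,
      baseline_log2 = expand_per_gene(baseline_log2, targets, "baseline_log2"),
      beta_chr = expand_per_gene(beta_chr, targets, "beta_chr"),
      beta_gon = expand_per_gene(beta_gon, targets, "beta_gon"),
      beta_act = expand_per_gene(beta_act, targets, "beta_act"),
      beta_gxa = expand_per_gene(beta_gxa, targets, "beta_gxa"),
      module_genes = module_genes,
      module_groups = module_groups,
      module_loading = module_loading,
      noise_sd = noise_sd,
      ct_ref_mean = ct_ref_mean,
      replicate_sd = replicate_sd,
      behavior = as_tibble(behavior)
    ),
    class = "simulation_config"
  )
  validate_simulation_config(cfg)
}

validate_simulation_config <- function(cfg) {
  if (!is.numeric(cfg$n_per_group) || cfg$n_per_group < 2) {
    abort("n_per_group must be >= 2 (group variance undefined otherwise)",
      class = "fcg_invalid_config"
    )
  }
  if (sum(cfg$genes$is_reference) != 2) {
    abort("exactly 2 reference genes are required",
      class = "fcg_invalid_config"
    )
  }
  if (cfg$module_loading^2 >= 1 || cfg$module_loading < 0) {
    abort("module_loading must lie in [0, 1)", class = "fcg_invalid_config")
  }
  if (cfg$noise_sd < 0 || cfg$replicate_sd < 0) {
    abort("noise SDs must be >= 0", class = "fcg_invalid_config")
  }
  targets <- cfg$genes$gene[!cfg$genes$is_reference]
  missing_mod <- setdiff(cfg$module_genes, targets)
  if (length(missing_mod) > 0) {
    abort(
      paste0(
        "module genes not in gene list: ",
        paste(missing_mod, collapse = ", ")
      ),
      class = "fcg_invalid_config"
    )
  }
  coupled <- cfg$behavior$gene[!is.na(cfg$behavior$gene)]
  missing_beh <- setdiff(coupled, targets)
  if (length(missing_beh) > 0) {
    abort(
      paste0(
        "behavior coupling refers to unknown genes: ",
        paste(missing_beh, collapse = ", ")
      ),
      class = "fcg_invalid_config"
    )
  }
  needed <- c("test", "measure", "gene", "intercept", "slope", "noise_sd", "direction")
  stopifnot(all(needed %in% names(cfg$behavior)))
  cfg
}

expand_per_gene <- function(x, genes, what) {
  if (is.null(names(x))) {
    if (length(x) == 1) {
      return(setNames(rep(x, length(genes)), genes))
    }
    if (length(x) == length(genes)) {
      return(setNames(as.numeric(x), genes))
    }
    abort(paste0(what, " must be scalar, named, or one value per gene"),
      class = "fcg_invalid_config"
    )
  }
  unknown <- setdiff(names(x), genes)
  if (length(unknown) > 0) {
    abort(paste0(what, " names not in gene list: ", paste(unknown, collapse = ", ")),
      class = "fcg_invalid_config"
    )
  }
  out <- setNames(rep(0, length(genes)), genes)
  out[names(x)] <- x
  out
}

# default planted effects: genes for which the three sex-related factors
# showed main effects / gonadal x hormone interactions in frontal cortex
default_beta_chr <- function() {
  genes <- c(
    "Vip", "Calb1", "Gat1", "Trkb", "Sst", "Gad67", "Gad65",
    "Htr1a", "Htr2c", "Drd1a", "Adcy5", "Adcy7", "App"
  )
  setNames(rep(-0.35, length(genes)), genes)
}

default_beta_gon <- function() {
  setNames(rep(-0.25, 4), c("Htr2a", "Adcy1", "Akt2", "Akt3"))
}

default_beta_act <- function() {
  c(Calb1 = -0.3, Htr1a = 0.3, Adcy2 = -0.3, Akt1 = -0.2, Akt3 = -0.2)
}

default_beta_gxa <- function() {
  genes <- c(
    "Cst", "Calb1", "Bdnf", "Htr1a", "Drd1a", "Adcy5",
    "Akt1", "Akt3", "Cdk5"
  )
  setNames(rep(-0.4, length(genes)), genes)
}

#' @rdname simulation_config
#' @export
male_gonadal_groups <- function() {
  lv <- factor_levels()
  grid <- crossing(
    sex_chromosome = lv$sex_chromosome,
    hormone = lv$hormone
  )
  paste(grid$sex_chromosome, "testes", grid$hormone, sep = ".")
}

#' @rdname simulation_config
#' @export
default_behavior_coupling <- function() {
  tibble(
    test = c("EPM", "EPM", "OF", "OF"),
    measure = c(
      "time_open", "pct_crosses_open",
      "time_center", "pct_distance_center"
    ),
    gene = c("Trkb", "App", "Htr2c", "Adcy5"),
    intercept = c(60, 30, 40, 15),
    slope = c(6, 3, 5, 2),
    noise_sd = c(12, 8, 10, 5),
    direction = c(-1, -1, -1, -1)
  )
}

#' Generate the 2 x 2 x 2 sample design table
#'
#' Crosses sex chromosome complement (XX vs XY-), developmental gonadal sex
#' (ovaries vs testes), and adult hormone capsule (blank vs testosterone)
#' into 8 groups of `n_per_group` mice each. The layout is fully
#' deterministic; `seed` is accepted for interface symmetry with the other
#' generator stages.
#'
#' @param n_per_group Mice per group (>= 2).
#' @param seed Unused by this stage (the design carries no randomness).
#' @return Tibble with columns `sample_id`, `sex_chromosome`, `gonadal_sex`,
#'   `hormone`, and the derived `group` label
#'   (`<chromosome>.<gonads>.<hormone>`).
#' @export
#' @examples
#' simulate_design(2)
simulate_design <- function(n_per_group, seed = NULL) {
  if (!is.numeric(n_per_group) || n_per_group < 2) {
    abort("n_per_group must be >= 2", class = "fcg_invalid_config")
  }
  lv <- factor_levels()
  cells <- crossing(
    sex_chromosome = lv$sex_chromosome,
    gonadal_sex = lv$gonadal_sex,
    hormone = lv$hormone
  )
  design <- cells[rep(seq_len(nrow(cells)), each = n_per_group), ]
  design |>
    mutate(
      sample_id = sprintf("m%03d", seq_len(n())),
      group = paste(.data$sex_chromosome, .data$gonadal_sex, .data$hormone,
        sep = "."
      )
    ) |>
    select("sample_id", "sex_chromosome", "gonadal_sex", "hormone", "group")
}

#' Generate latent expression and raw qPCR CT values
#'
#' Latent log2 expression per sample x gene is
#' `baseline + beta_chr 1[XY-] + beta_gon 1[testes] + beta_act 1[testosterone]
#'  + beta_gxa 1[testes & testosterone] + loading * F_s * 1[module] + eps`
#' with `F_s` a per-sample standard-normal factor shared by the module genes
#' of module-active samples and `eps ~ N(0, noise_sd)`. CT values are then
#' laid out so that delta-Ct quantification against the two reference genes
#' is the exact inverse of the simulation at zero noise:
#' reference wells at `ct_ref_mean`, target wells at
#' `ct_ref_mean - latent + log2(10000)`, four replicates each with
#' `N(0, replicate_sd)` technical noise.
#'
#' @param design Design tibble from [simulate_design()].
#' @param config A [simulation_config()].
#' @param seed Integer seed for this stage.
#' @return List with `truth` (tibble `sample_id`, `gene`, `latent_log2`,
#'   `module_active`) and `ct` (long tibble `sample_id`, `gene`, `replicate`,
#'   `ct`).
#' @export
simulate_expression <- function(design, config, seed = 1) {
  config <- validate_simulation_config(config)
  set.seed(seed)
  targets <- config$genes$gene[!config$genes$is_reference]
  refs <- config$genes$gene[config$genes$is_reference]
  n <- nrow(design)

  is_xy <- design$sex_chromosome == "XY-"
  is_testes <- design$gonadal_sex == "testes"
  is_t <- design$hormone == "testosterone"
  module_sample <- design$group %in% config$module_groups

  fixed <- outer(rep(1, n), config$baseline_log2[targets]) +
    outer(is_xy, config$beta_chr[targets]) +
    outer(is_testes, config$beta_gon[targets]) +
    outer(is_t, config$beta_act[targets]) +
    outer(is_testes & is_t, config$beta_gxa[targets])

  f_s <- rnorm(n)
  module_term <- config$module_loading *
    outer(f_s * module_sample, as.numeric(targets %in% config$module_genes))
  eps <- matrix(rnorm(n * length(targets), sd = config$noise_sd),
    nrow = n
  )
  latent <- fixed + module_term + eps
  dimnames(latent) <- list(design$sample_id, targets)

  truth <- as_tibble(latent, rownames = "sample_id") |>
    pivot_longer(-"sample_id", names_to = "gene", values_to = "latent_log2") |>
    left_join(
      tibble(sample_id = design$sample_id, module_active = module_sample),
      by = "sample_id"
    ) |>
    mutate(
      module_active = .data$module_active & .data$gene %in% config$module_genes
    )

  n_rep <- 4L
  base_ct <- cbind(
    config$ct_ref_mean - latent + log2(10000),
    matrix(config$ct_ref_mean,
      nrow = n, ncol = length(refs),
      dimnames = list(design$sample_id, refs)
    )
  )
  ct <- crossing(
    sample_id = design$sample_id,
    gene = colnames(base_ct),
    replicate = seq_len(n_rep)
  ) |>
    mutate(
      ct = base_ct[cbind(.data$sample_id, .data$gene)] +
        rnorm(n(), sd = config$replicate_sd)
    )

  list(truth = truth, ct = ct)
}

#' Generate behavioral test measures coupled to latent expression
#'
#' Each raw measure is `intercept + slope * latent(coupled gene) + noise`
#' (uncoupled measures omit the gene term). The direction map (+1 if a
#' larger raw value means more anxiety) is carried in the coupling table and
#' returned as an attribute for downstream Z-scoring.
#'
#' @param design Design tibble from [simulate_design()].
#' @param truth `truth` tibble from [simulate_expression()].
#' @param config A [simulation_config()].
#' @param seed Integer seed for this stage.
#' @return Long tibble `sample_id`, `test`, `measure`, `value`; the
#'   measure-to-direction map is attached as attribute `"directions"`.
#' @export
simulate_behavior <- function(design, truth, config, seed = 1) {
  config <- validate_simulation_config(config)
  set.seed(seed)
  latent_wide <- truth |>
    select("sample_id", "gene", "latent_log2") |>
    pivot_wider(names_from = "gene", values_from = "latent_log2")

  rows <- map_dfr(seq_len(nrow(config$behavior)), function(i) {
    spec <- config$behavior[i, ]
    gene_part <- if (is.na(spec$gene)) {
      0
    } else {
      spec$slope * latent_wide[[spec$gene]]
    }
    tibble(
      sample_id = latent_wide$sample_id,
      test = spec$test,
      measure = spec$measure,
      value = spec$intercept + gene_part +
        rnorm(nrow(latent_wide), sd = spec$noise_sd)
    )
  })
  rows <- arrange(rows, .data$sample_id, .data$test, .data$measure)
  attr(rows, "directions") <- behavior_directions(config)
  rows
}

#' @rdname simulate_behavior
#' @export
behavior_directions <- function(config) {
  config$behavior |>
    select("measure", "direction") |>
    distinct()
}

#' Run the full synthetic study generator
#'
#' One call producing design, ground truth, CT table, and behavior table,
#' reproducible bit-for-bit from `(config, seed)`. Per-stage sub-seeds are
#' derived deterministically from the one top-level seed.
#'
#' @param config A [simulation_config()].
#' @param seed Top-level integer seed.
#' @return List of class `"fcg_simulation"` with elements `design`, `truth`,
#'   `ct`, `behavior`, `directions`, `config`, `seed`.
#' @export
#' @examples
#' sim <- simulate_study(simulation_config(n_per_group = 2), seed = 1)
#' nrow(sim$design)
simulate_study <- function(config = simulation_config(), seed = 1) {
  config <- validate_simulation_config(config)
  design <- simulate_design(config$n_per_group, stage_seed(seed, "design"))
  expr <- simulate_expression(design, config, stage_seed(seed, "expression"))
  behavior <- simulate_behavior(
    design, expr$truth, config,
    stage_seed(seed, "behavior")
  )
  structure(
    list(
      design = design,
      truth = expr$truth,
      ct = expr$ct,
      behavior = behavior,
      directions = attr(behavior, "directions"),
      config = config,
      seed = seed
    ),
    class = "fcg_simulation"
  )
}

#' Write a synthetic study to disk
#'
#' Writes `design.csv`, `ct_long.csv`, `behavior.csv`, `directions.csv`, and
#' `truth.json` (planted betas, module description, and latent expression)
#' into `dir`.
#'
#' @param sim An `"fcg_simulation"` from [simulate_study()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "fcg_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(sim$design, file.path(dir, "design.csv"))
  readr::write_csv(sim$ct, file.path(dir, "ct_long.csv"))
  readr::write_csv(sim$behavior, file.path(dir, "behavior.csv"))
  readr::write_csv(sim$directions, file.path(dir, "directions.csv"))
  truth <- list(
    seed = sim$seed,
    betas = list(
      chr = as.list(sim$config$beta_chr),
      gon = as.list(sim$config$beta_gon),
      act = as.list(sim$config$beta_act),
      gxa = as.list(sim$config$beta_gxa)
    ),
    module = list(
      genes = sim$config$module_genes,
      groups = sim$config$module_groups,
      loading = sim$config$module_loading
    ),
    latent_log2 = sim$truth
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "columns"
  )
  invisible(dir)
}
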