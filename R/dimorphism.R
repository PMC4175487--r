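#' Male/female phenotype expression-ratio matrix
#'
#' For each gene and each of the three sex-related factors, the ratio of
#' marginal mean expression in the "male" phenotype over the "female"
#' phenotype (sex chromosome complement XY-/XX; gonadal sex testes/ovaries;
#' activational testosterone/blank). Marginal means are unweighted means of
#' the design-cell means collapsed over the other two factors, which equals
#' the pooled sample mean for balanced designs but is robust to group-size
#' imbalance. Optional ANOVA annotations mark a significant main effect of
#' the factor (`main_effect`) and a significant interaction involving it
#' (`interaction`).
#'
#' @param expression Wide expression tibble (`sample_id` x genes).
#' @param design Design tibble.
#' @param anova Optional [anova_expression()] table supplying annotation
#'   flags.
#' @param use Which ANOVA flag drives the annotations: `"fdr"` (the BH
#'   `significant` column, default) or `"raw"` (`p < 0.05`).
#' @param gene_order Optional gene ordering for the output (e.g. the
#'   display order of a heatmap); default input order.
#' @return Tibble of class `"fcg_ratio_matrix"`: `gene`, `factor`,
#'   `male_mean`, `female_mean`, `ratio`, `log2_ratio`, `main_effect`,
#'   `interaction`, `undefined`.
#' @export
#' @examples
#' sim <- simulate_study(simulation_config(n_per_group = 4), seed = 1)
#' expr <- quantify_expression(sim$ct, c("Actb", "Gapdh"))
#' rm <- ratio_matrix(expr, sim$design)
#' head(rm)
ratio_matrix <- function(expression, design, anova = NULL,
                         use = c("fdr", "raw"), gene_order = NULL) {
  use <- match.arg(use)
  genes <- setdiff(names(expression), "sample_id")
  long <- expression |>
    pivot_longer(-"sample_id", names_to = "gene", values_to = "value") |>
    inner_join(design, by = "sample_id")

  cell_means <- long |>
    group_by(
      .data$gene, .data$sex_chromosome, .data$gonadal_sex, .data$hormone
    ) |>
    summarise(cell_mean = mean(.data$value, na.rm = TRUE), .groups = "drop")

  fl <- fcg_factors()
  out <- map_dfr(seq_len(nrow(fl)), function(i) {
    col <- fl$factor[i]
    cell_means |>
      group_by(.data$gene, level = .data[[col]]) |>
      summarise(marginal = mean(.data$cell_mean), .groups = "drop") |>
      pivot_wider(names_from = "level", values_from = "marginal") |>
      mutate(
        factor = col,
        male_mean = .data[[fl$male_level[i]]],
        female_mean = .data[[fl$female_level[i]]],
        .keep = "unused"
      )
  }) |>
    mutate(
      undefined = !is.finite(.data$female_mean) | .data$female_mean <= 0 |
        !is.finite(.data$male_mean),
      ratio = ifelse(.data$undefined, NA_real_,
        .data$male_mean / .data$female_mean
      ),
      log2_ratio = log2(.data$ratio)
    )

  flags <- ratio_annotations(anova, use)
  out <- left_join(out, flags, by = c("gene", "factor")) |>
    mutate(
      main_effect = .data$main_effect %in% TRUE,
      interaction = .data$interaction %in% TRUE
    )

  gene_order <- gene_order %||% genes
  out <- out |>
    arrange(
      factor(.data$gene, levels = gene_order),
      factor(.data$factor, levels = fl$factor)
    ) |>
    select(
      "gene", "factor", "male_mean", "female_mean", "ratio", "log2_ratio",
      "main_effect", "interaction", "undefined"
    )
  class(out) <- c("fcg_ratio_matrix", class(out))
  out
}

ratio_annotations <- function(anova, use) {
  empty <- tibble(
    gene = character(), factor = character(),
    main_effect = logical(), interaction = logical()
  )
  if (is.null(anova)) {
    return(empty)
  }
  sig <- if (use == "fdr") {
    anova$significant
  } else {
    !is.na(anova$p) & anova$p < 0.05
  }
  anova <- mutate(anova, sig = sig)
  factors <- fcg_factors()$factor
  map_dfr(factors, function(f) {
    anova |>
      filter(!is.na(.data$term)) |>
      group_by(.data$gene) |>
      summarise(
        main_effect = any(.data$sig[.data$term == f]),
        interaction = any(
          .data$sig[grepl(":", .data$term, fixed = TRUE) &
            grepl(f, .data$term, fixed = TRUE)]
        ),
        .groups = "drop"
      ) |>
      mutate(factor = f)
  })
}

#' Export a ratio matrix as the heatmap-style TSV
#'
#' Writes one row per gene with `chr_ratio`, `gon_ratio`, `act_ratio` and
#' matching `*_main`/`*_interaction` flag columns.
#'
#' @param ratios A [ratio_matrix()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ratio_matrix <- function(ratios, path) {
  short <- c(
    sex_chromosome = "chr", gonadal_sex = "gon", hormone = "act"
  )
  wide <- ratios |>
    mutate(factor = short[.data$factor]) |>
    select("gene", "factor", "ratio", "main_effect", "interaction") |>
    pivot_wider(
      names_from = "factor",
      values_from = c("ratio", "main_effect", "interaction"),
      names_glue = "{factor}_{.value}"
    ) |>
    rename_with(~ sub("_ratio$", "_ratio", .x)) |>
    select(
      "gene",
      "chr_ratio", "gon_ratio", "act_ratio",
      "chr_main_effect", "gon_main_effect", "act_main_effect",
      "chr_interaction", "gon_interaction", "act_interaction"
    )
  readr::write_tsv(wide, path)
  invisible(path)
}
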