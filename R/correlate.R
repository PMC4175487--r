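#' Pearson correlation between a gene and the emotionality score
#'
#' Standard product-moment correlation with a two-sided p-value from the t
#' transform `t = r sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of
#' freedom (as computed by `stats::cor.test`).
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`, each with nonzero
#'   variance.
#' @param what Label used in error messages.
#' @return Tibble `r`, `n`, `p`.
#' @export
#' @examples
#' pearson(1:5, c(2, 1, 4, 3, 5))
pearson <- function(x, y, what = "pair") {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) {
    abort(paste0("fewer than 3 complete pairs for ", what),
      class = "fcg_invalid_input"
    )
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort(paste0("zero variance; correlation undefined for ", what),
      class = "fcg_degenerate"
    )
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble(r = unname(ct$estimate), n = length(x), p = ct$p.value)
}

stratum_table <- function(design) {
  fl <- fcg_factors()
  bind_rows(
    tibble(stratum = "all", keep = list(design$sample_id)),
    map_dfr(seq_len(nrow(fl)), function(i) {
      col <- fl$factor[i]
      map_dfr(c(fl$female_level[i], fl$male_level[i]), function(lev) {
        tibble(
          stratum = stratum_label(col, lev),
          keep = list(design$sample_id[design[[col]] == lev])
        )
      })
    })
  )
}

stratum_label <- function(col, lev) {
  switch(col,
    sex_chromosome = lev,
    gonadal_sex = paste0("gonadal_", ifelse(lev == "testes", "male", "female")),
    hormone = ifelse(lev == "testosterone", "testosterone", "blank")
  )
}

#' Gene-behavior correlations overall and within sex-factor strata
#'
#' Correlates each gene's expression with the overall emotionality Z-score
#' in all mice and after splitting by each main sex-related factor (XX,
#' XY-, gonadal females, gonadal males, blank-treated,
#' testosterone-treated). Benjamini-Hochberg control at `fdr` is applied
#' separately per gene category within each stratum, against the declared
#' category sizes; a sign class (+ / - / ns) is assigned only to
#' BH-significant entries. Strata with fewer than 3 samples (or zero
#' variance) are flagged missing rather than scored.
#'
#' @param expression Wide expression tibble (`sample_id` x genes).
#' @param emotionality Output of [emotionality_scores()] (needs
#'   `sample_id`, `z_overall`).
#' @param design Design tibble.
#' @param categories Tibble `gene`, `category`.
#' @param fdr False discovery rate (default 0.05).
#' @param family_size Optional named vector of declared family sizes per
#'   category (e.g. `c(gaba = 16, monoamine = 14)`); defaults to the number
#'   of genes present per category.
#' @return Tibble: `gene`, `category`, `stratum`, `n`, `r`, `p`, `q`,
#'   `significant`, `sign_class`, `missing`.
#' @export
#' @examples
#' sim <- simulate_study(simulation_config(n_per_group = 4), seed = 1)
#' expr <- quantify_expression(sim$ct, c("Actb", "Gapdh"))
#' emo <- emotionality_scores(sim$behavior, sim$design, sim$directions)
#' cors <- stratified_correlations(expr, emo, sim$design)
#' head(cors)
stratified_correlations <- function(expression, emotionality, design,
                                    categories = fcg_gene_panel(),
                                    fdr = 0.05, family_size = NULL) {
  genes <- setdiff(names(expression), "sample_id")
  dat <- inner_join(
    expression,
    select(emotionality, "sample_id", "z_overall"),
    by = "sample_id"
  )
  strata <- stratum_table(design)

  res <- map_dfr(seq_len(nrow(strata)), function(i) {
    ids <- strata$keep[[i]]
    sub <- filter(dat, .data$sample_id %in% ids)
    map_dfr(genes, function(g) {
      cell <- tryCatch(
        pearson(sub[[g]], sub$z_overall, what = paste0(g, " in ", strata$stratum[i])),
        fcg_invalid_input = function(e) tibble(r = NA_real_, n = nrow(sub), p = NA_real_),
        fcg_degenerate = function(e) tibble(r = NA_real_, n = nrow(sub), p = NA_real_)
      )
      mutate(cell, gene = g, stratum = strata$stratum[i], .before = 1)
    })
  })

  cat_map <- select(as_tibble(categories), "gene", "category")
  res <- res |>
    left_join(cat_map, by = "gene") |>
    mutate(category = ifelse(is.na(.data$category), "uncategorised", .data$category))

  res <- res |>
    group_by(.data$stratum, .data$category) |>
    mutate(
      q = {
        ok <- !is.na(.data$p)
        m <- family_size[.data$category[1]] %||% sum(ok)
        if (is.na(m)) m <- sum(ok)
        out <- rep(NA_real_, length(.data$p))
        # numerically perfect correlations can print p = 0; clamp for BH
        if (any(ok)) {
          out[ok] <- bh_adjust(
            pmax(.data$p[ok], .Machine$double.xmin),
            fdr = fdr, m = m
          )$q
        }
        out
      }
    ) |>
    ungroup() |>
    mutate(
      significant = !is.na(.data$q) & .data$q <= fdr,
      sign_class = case_when(
        .data$significant & .data$r > 0 ~ "+",
        .data$significant & .data$r < 0 ~ "-",
        .default = "ns"
      ),
      missing = is.na(.data$r)
    ) |>
    select(
      "gene", "category", "stratum", "n", "r", "p", "q",
      "significant", "sign_class", "missing"
    )
  res
}

#' Summarise significant gene-behavior correlations per stratum
#'
#' Collapses a [stratified_correlations()] table into a per-stratum listing
#' of BH-significant positively and negatively correlated genes, with
#' `"None"` standing in for empty lists.
#'
#' @param correlations Output of [stratified_correlations()].
#' @return Tibble `stratum`, `direction` (`"+"`/`"-"`), `genes` (comma
#'   separated or `"None"`).
#' @export
sign_summary <- function(correlations) {
  strata <- unique(correlations$stratum)
  crossing(stratum = strata, direction = c("+", "-")) |>
    left_join(
      correlations |>
        filter(.data$sign_class != "ns") |>
        group_by(.data$stratum, direction = .data$sign_class) |>
        summarise(genes = paste(.data$gene, collapse = ", "), .groups = "drop"),
      by = c("stratum", "direction")
    ) |>
    mutate(genes = ifelse(is.na(.data$genes), "None", .data$genes)) |>
    arrange(factor(.data$stratum, levels = strata), desc(.data$direction))
}
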