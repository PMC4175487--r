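#' Three-way factorial ANOVA for one gene
#'
#' Fits the full-factorial linear model
#' `expression ~ chromosome * gonads * hormone` with sum-to-zero (effect)
#' coding and returns Type-III F tests per term, which coincide with the
#' classical balanced-design factorial sums of squares when cell sizes are
#' equal. Factors with a single observed level are dropped from the model
#' (with a message), so the same surface handles reduced designs (e.g. a
#' plain two-group comparison, where F equals the squared pooled t
#' statistic).
#'
#' @param expression Wide expression tibble (`sample_id` x genes), e.g. from
#'   [quantify_expression()].
#' @param design Design tibble with `sample_id`, `sex_chromosome`,
#'   `gonadal_sex`, `hormone`.
#' @param gene Gene (column) to test.
#' @return Object of class `"fcg_anova"`: list with `gene`, `fit` (the
#'   underlying `lm`), and `table` (tibble `term`, `df1`, `df2`, `F`, `p`).
#'   Use [tidy()] / [glance()] to extract tibbles.
#' @export
#' @examples
#' sim <- simulate_study(simulation_config(n_per_group = 4), seed = 1)
#' expr <- quantify_expression(sim$ct, c("Actb", "Gapdh"))
#' fit <- fit_threeway(expr, sim$design, "Sst")
#' tidy(fit)
fit_threeway <- function(expression, design, gene) {
  dat <- anova_frame(expression, design, gene)
  vars <- c("chr", "gon", "act")
  kept <- vars[map_lgl(vars, function(v) length(unique(dat[[v]])) > 1)]
  if (length(kept) == 0) {
    abort("no factor varies in the data", class = "fcg_degenerate")
  }
  if (length(kept) < length(vars)) {
    inform(paste0(
      "factor(s) with a single level dropped from the model for ", gene, ": ",
      paste(setdiff(vars, kept), collapse = ", ")
    ))
  }
  cells <- table(dat[kept])
  if (any(cells == 0)) {
    warn(paste0("empty design cell(s) for ", gene,
      "; terms estimated where estimable"))
  }
  if (any(cells == 1) && all(cells <= 1)) {
    abort(paste0("no residual degrees of freedom for ", gene),
      class = "fcg_degenerate"
    )
  }
  form <- as.formula(paste("value ~", paste(kept, collapse = " * ")))
  contr <- setNames(rep(list("contr.sum"), length(kept)), kept)
  fit <- lm(form, data = dat, contrasts = contr)
  sigma2 <- sum(fit$residuals^2) / df.residual(fit)
  scale <- mean(dat$value^2) + 1
  if (!is.finite(sigma2) || sigma2 < 1e-22 * scale) {
    abort(paste0("zero residual variance for ", gene, "; F undefined"),
      class = "fcg_degenerate"
    )
  }
  a3 <- car::Anova(fit, type = 3)
  rows <- rownames(a3)
  keep <- !rows %in% c("(Intercept)", "Residuals")
  tab <- tibble(
    term = rename_terms(rows[keep]),
    df1 = a3$Df[keep],
    df2 = df.residual(fit),
    F = a3$`F value`[keep],
    p = a3$`Pr(>F)`[keep]
  )
  structure(
    list(gene = gene, fit = fit, table = tab, n = nrow(dat)),
    class = "fcg_anova"
  )
}

anova_frame <- function(expression, design, gene) {
  if (!gene %in% names(expression)) {
    abort(paste0("gene '", gene, "' not in expression table"),
      class = "fcg_invalid_input"
    )
  }
  lv <- factor_levels()
  dat <- inner_join(
    select(expression, "sample_id", value = all_of(gene)),
    design,
    by = "sample_id"
  )
  dat$chr <- factor(dat$sex_chromosome, levels = lv$sex_chromosome)
  dat$gon <- factor(dat$gonadal_sex, levels = lv$gonadal_sex)
  dat$act <- factor(dat$hormone, levels = lv$hormone)
  dat <- dat[!is.na(dat$value), ]
  dat$chr <- droplevels(dat$chr)
  dat$gon <- droplevels(dat$gon)
  dat$act <- droplevels(dat$act)
  if (nrow(dat) < 3) {
    abort(paste0("too few observations for ", gene), class = "fcg_degenerate")
  }
  dat
}

rename_terms <- function(x) {
  map_chr_terms <- c(
    chr = "sex_chromosome", gon = "gonadal_sex", act = "hormone"
  )
  vapply(strsplit(x, ":", fixed = TRUE), function(parts) {
    paste(map_chr_terms[parts], collapse = ":")
  }, character(1))
}

#' @export
tidy.fcg_anova <- function(x, ...) {
  mutate(x$table, gene = x$gene, .before = 1)
}

#' @export
glance.fcg_anova <- function(x, ...) {
  s <- summary(x$fit)
  tibble(
    gene = x$gene,
    r.squared = s$r.squared,
    sigma = s$sigma,
    df.residual = df.residual(x$fit),
    nobs = x$n
  )
}

#' @export
print.fcg_anova <- function(x, ...) {
  cat("Three-way factorial ANOVA for", x$gene, "(n =", x$n, ")\n")
  print(x$table)
  invisible(x)
}

#' Three-way ANOVA across genes with per-category FDR control
#'
#' Runs [fit_threeway()] for every gene, then applies Benjamini-Hochberg
#' control at `fdr` within each gene category. The BH family is, per the
#' reporting convention mirrored here, the set of genes in a category; by
#' default each model term is corrected as its own family
#' (`bh_family = "per_term"`), with `"pooled"` pooling all terms of a
#' category into one family. The declared family size `m` may exceed the
#' number of genes actually present (tests counted but not listed).
#'
#' @inheritParams fit_threeway
#' @param genes Genes to test; default all non-`sample_id` columns.
#' @param categories Tibble `gene`, `category` (e.g. [fcg_gene_panel()]);
#'   genes absent from it form their own `"uncategorised"` family.
#' @param fdr False discovery rate (default 0.05).
#' @param bh_family `"per_term"` or `"pooled"` (see above).
#' @param family_size Optional named vector of declared family sizes per
#'   category, overriding the number of genes present.
#' @param trend_p Trend-level threshold reported as the `trend` flag
#'   (default 0.1).
#' @return Tibble: `gene`, `category`, `term`, `df1`, `df2`, `F`, `p`, `q`,
#'   `significant` (BH at `fdr`), `trend`, `degenerate`.
#' @export
anova_expression <- function(expression, design, genes = NULL,
                             categories = fcg_gene_panel(),
                             fdr = 0.05,
                             bh_family = c("per_term", "pooled"),
                             family_size = NULL,
                             trend_p = 0.1) {
  bh_family <- match.arg(bh_family)
  genes <- genes %||% setdiff(names(expression), "sample_id")
  results <- map_dfr(genes, function(g) {
    res <- tryCatch(
      tidy(fit_threeway(expression, design, g)),
      fcg_degenerate = function(e) {
        tibble(
          gene = g, term = NA_character_, df1 = NA_real_, df2 = NA_real_,
          F = NA_real_, p = NA_real_
        )
      }
    )
    mutate(res, degenerate = is.na(.data$p) & is.na(.data$term))
  })
  cat_map <- select(as_tibble(categories), "gene", "category")
  results <- results |>
    left_join(cat_map, by = "gene") |>
    mutate(category = ifelse(is.na(.data$category), "uncategorised", .data$category))

  n_genes <- results |>
    distinct(.data$gene, .data$category) |>
    count(.data$category, name = "n_genes")

  family_m <- function(category, n_tests, genes_in_cat) {
    m_genes <- family_size[category] %||% genes_in_cat
    if (is.na(m_genes)) m_genes <- genes_in_cat
    # pooled families count every term of every gene
    m_genes * n_tests / genes_in_cat
  }

  grouping <- if (bh_family == "per_term") {
    c("category", "term")
  } else {
    "category"
  }
  results <- results |>
    left_join(n_genes, by = "category") |>
    group_by(across(all_of(grouping))) |>
    mutate(
      q = if (all(is.na(.data$p))) {
        NA_real_
      } else {
        bh_adjust(
          pmax(.data$p[!is.na(.data$p)], .Machine$double.xmin),
          fdr = fdr,
          m = family_m(.data$category[1], sum(!is.na(.data$p)), .data$n_genes[1])
        )$q[match(seq_along(.data$p), which(!is.na(.data$p)))]
      }
    ) |>
    ungroup() |>
    mutate(
      significant = !is.na(.data$q) & .data$q <= fdr,
      trend = !is.na(.data$p) & .data$p < trend_p
    ) |>
    select(
      "gene", "category", "term", "df1", "df2", "F", "p", "q",
      "significant", "trend", "degenerate"
    )
  results
}

#' Benjamini-Hochberg step-up control with a declared family size
#'
#' Step-up procedure: order the p-values, find the largest rank `k` with
#' `p(k) <= fdr * k / m`, and reject the `k` smallest; `m` is the declared
#' number of tests in the family and may exceed the number of p-values
#' supplied (tests counted but not listed). Q-values use the standard
#' monotone cumulative-minimum transform (computed by
#' `stats::p.adjust(method = "BH", n = m)`).
#'
#' @param p Vector of p-values in (0, 1].
#' @param fdr Target false discovery rate.
#' @param m Declared family size; must be >= `length(p)`.
#' @return Tibble `p`, `q`, `reject` in the input order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.5), fdr = 0.05, m = 4)
bh_adjust <- function(p, fdr = 0.05, m = length(p)) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    abort("p-values must lie in (0, 1]", class = "fcg_invalid_input")
  }
  if (m < length(p)) {
    abort("declared family size m must be >= length(p)",
      class = "fcg_invalid_config"
    )
  }
  q <- p.adjust(p, method = "BH", n = m)
  tibble(p = p, q = q, reject = q <= fdr)
}

#' Tukey post hoc contrasts gated on the omnibus ANOVA
#'
#' Pairwise Tukey-Kramer comparisons among the four gonadal-sex x hormone
#' cells (the usual interaction follow-up) or among all eight design cells,
#' using the mean-square error and residual degrees of freedom of the full
#' three-way model and p-values from the studentized range distribution.
#' Following the omnibus gate, contrasts are only computed when some model
#' term is significant at `alpha`; otherwise an empty table is returned with
#' a message.
#'
#' @inheritParams fit_threeway
#' @param cells `"gonadal_hormone"` (4 cells) or `"full"` (8 cells).
#' @param alpha Omnibus gate level (default 0.05).
#' @param gate Apply the omnibus gate (default `TRUE`).
#' @return Tibble: `contrast`, `estimate` (difference of cell means),
#'   `se`, `q_stat`, `df`, `p`, `significant`.
#' @export
tukey_contrasts <- function(expression, design, gene,
                            cells = c("gonadal_hormone", "full"),
                            alpha = 0.05, gate = TRUE) {
  cells <- match.arg(cells)
  omni <- fit_threeway(expression, design, gene)
  if (gate && !any(omni$table$p < alpha, na.rm = TRUE)) {
    inform(paste0(
      "omnibus ANOVA not significant for ", gene,
      "; no contrasts computed"
    ))
    return(tibble(
      contrast = character(), estimate = double(), se = double(),
      q_stat = double(), df = double(), p = double(), significant = logical()
    ))
  }
  dat <- anova_frame(expression, design, gene)
  dat$cell <- if (cells == "gonadal_hormone") {
    paste(dat$gonadal_sex, dat$hormone, sep = ".")
  } else {
    dat$group %||% paste(dat$sex_chromosome, dat$gonadal_sex, dat$hormone,
      sep = "."
    )
  }
  mse <- sum(omni$fit$residuals^2) / df.residual(omni$fit)
  df_err <- df.residual(omni$fit)
  cm <- dat |>
    group_by(.data$cell) |>
    summarise(mean = mean(.data$value), n = n(), .groups = "drop")
  k <- nrow(cm)
  pairs <- utils::combn(seq_len(k), 2)
  map_dfr(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]
    i2 <- pairs[2, j]
    diff <- cm$mean[i1] - cm$mean[i2]
    se <- sqrt(mse / 2 * (1 / cm$n[i1] + 1 / cm$n[i2]))
    q_stat <- abs(diff) / se
    p <- ptukey(q_stat, nmeans = k, df = df_err, lower.tail = FALSE)
    tibble(
      contrast = paste(cm$cell[i1], "-", cm$cell[i2]),
      estimate = diff, se = se, q_stat = q_stat, df = df_err, p = p,
      significant = p < alpha
    )
  })
}
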