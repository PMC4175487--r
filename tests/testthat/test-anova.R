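balanced_fixture <- function(n_cell = 4, seed = 21, effects = TRUE) {
  design <- simulate_design(n_cell)
  set.seed(seed)
  value <- rnorm(nrow(design), sd = 1)
  if (effects) {
    value <- value +
      1.2 * (design$sex_chromosome == "XY-") +
      0.8 * (design$gonadal_sex == "testes") * (design$hormone == "testosterone")
  }
  list(
    design = design,
    expression = tibble::tibble(sample_id = design$sample_id, G = value)
  )
}

test_that("every term's F matches the textbook balanced sums-of-squares oracle", {
  fx <- balanced_fixture()
  fit <- fit_threeway(fx$expression, fx$design, "G")
  oracle <- oracle_threeway_F(
    fx$expression$G,
    fx$design$sex_chromosome, fx$design$gonadal_sex, fx$design$hormone
  )
  got <- setNames(fit$table$F, fit$table$term)
  want <- c(
    sex_chromosome = unname(oracle["A"]),
    gonadal_sex = unname(oracle["B"]),
    hormone = unname(oracle["C"]),
    `sex_chromosome:gonadal_sex` = unname(oracle["AB"]),
    `sex_chromosome:hormone` = unname(oracle["AC"]),
    `gonadal_sex:hormone` = unname(oracle["BC"]),
    `sex_chromosome:gonadal_sex:hormone` = unname(oracle["ABC"])
  )
  expect_equal(got[names(want)], want, tolerance = 1e-9)
  expect_true(all(fit$table$df1 == 1))
})

test_that("Type-III and sequential sums of squares coincide on balanced data", {
  fx <- balanced_fixture(seed = 4)
  fit <- fit_threeway(fx$expression, fx$design, "G")
  seq_tab <- anova(fit$fit)
  seq_F <- seq_tab$`F value`[seq_len(7)]
  expect_equal(unname(fit$table$F), unname(seq_F), tolerance = 1e-9)
})

test_that("constant expression is reported as degenerate, not fitted", {
  fx <- balanced_fixture()
  fx$expression$G <- 5
  expect_error(
    fit_threeway(fx$expression, fx$design, "G"),
    class = "fcg_degenerate"
  )
  tab <- anova_expression(fx$expression, fx$design, genes = "G")
  expect_true(all(tab$degenerate))
})

test_that("the two-group reduction reproduces F = t^2", {
  set.seed(7)
  design <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:12),
    sex_chromosome = rep(c("XX", "XY-"), each = 6),
    gonadal_sex = "ovaries",
    hormone = "blank"
  )
  expr <- tibble::tibble(
    sample_id = design$sample_id,
    G = rnorm(12) + (design$sex_chromosome == "XY-")
  )
  expect_message(
    fit <- fit_threeway(expr, design, "G"),
    "single level"
  )
  tt <- t.test(G ~ sex_chromosome,
    data = dplyr::inner_join(expr, design, by = "sample_id"),
    var.equal = TRUE
  )
  expect_equal(fit$table$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(fit$table$p, tt$p.value, tolerance = 1e-9)
})

test_that("BH step-up with declared family size matches the hand rule", {
  out <- bh_adjust(c(0.01, 0.02, 0.03, 0.5), fdr = 0.05, m = 4)
  expect_equal(out$reject, c(TRUE, TRUE, TRUE, FALSE)) # 0.03 <= 0.05*3/4
  expect_equal(bh_adjust(rep(1, 5), fdr = 0.05)$reject, rep(FALSE, 5))
  expect_true(bh_adjust(0.04, fdr = 0.05, m = 1)$reject)
  expect_false(bh_adjust(0.06, fdr = 0.05, m = 1)$reject)
  expect_error(bh_adjust(c(0.1, 0.2), m = 1), class = "fcg_invalid_config")
  expect_error(bh_adjust(c(0, 0.2)), class = "fcg_invalid_input")

  # declared m larger than the listed p-values tightens the rule
  p <- c(0.01, 0.02)
  expect_equal(
    bh_adjust(p, fdr = 0.05, m = 10)$reject,
    oracle_bh_reject(p, 0.05, 10)
  )
})

test_that("BH rejections are monotone in the FDR level and match the oracle", {
  set.seed(31)
  for (i in 1:50) {
    p <- runif(sample(3:12, 1))^sample(1:3, 1)
    m <- length(p) + sample(0:5, 1)
    for (fdr in c(0.01, 0.05, 0.1, 0.2)) {
      expect_equal(
        bh_adjust(p, fdr = fdr, m = m)$reject,
        oracle_bh_reject(p, fdr, m)
      )
    }
    r_low <- sum(bh_adjust(p, fdr = 0.01, m = m)$reject)
    r_high <- sum(bh_adjust(p, fdr = 0.2, m = m)$reject)
    expect_lte(r_low, r_high)
  }
})

test_that("per-category FDR control annotates the gene-level table", {
  sim <- simulate_study(tiny_config(), seed = 8)
  expr <- quantify_expression(sim$ct, c("Actb", "Gapdh"))
  tab <- anova_expression(expr, sim$design, fdr = 0.05)
  expect_setequal(unique(tab$category), c("gaba", "monoamine"))
  expect_true(all(tab$q >= tab$p, na.rm = TRUE))
  expect_true(all(tab$trend[!is.na(tab$p) & tab$p < 0.1]))
  # declared family larger than genes present can only lose rejections
  tab_m <- anova_expression(expr, sim$design,
    fdr = 0.05,
    family_size = c(gaba = 32, monoamine = 28)
  )
  expect_lte(sum(tab_m$significant), sum(tab$significant))
})

test_that("Tukey contrasts reduce to the pooled t-test for two cells", {
  set.seed(15)
  design <- simulate_design(6) |>
    dplyr::filter(sex_chromosome == "XX", gonadal_sex == "ovaries")
  expr <- tibble::tibble(
    sample_id = design$sample_id,
    G = rnorm(nrow(design)) + 2 * (design$hormone == "testosterone")
  )
  suppressMessages(
    tk <- tukey_contrasts(expr, design, "G", cells = "gonadal_hormone")
  )
  expect_equal(nrow(tk), 1)
  tt <- t.test(G ~ hormone,
    data = dplyr::inner_join(expr, design, by = "sample_id"),
    var.equal = TRUE
  )
  expect_equal(tk$p, tt$p.value, tolerance = 1e-6)
})

test_that("identical cell means give a Tukey p of 1 and the gate suppresses output", {
  design <- simulate_design(3)
  # strong chromosome effect opens the omnibus gate; gonadal x hormone cells equal
  expr <- tibble::tibble(
    sample_id = design$sample_id,
    G = rep(c(0, 10), each = 12) + rep(c(-0.5, 0, 0.5), 8)
  )
  tk <- tukey_contrasts(expr, design, "G", cells = "gonadal_hormone")
  expect_equal(nrow(tk), 6)
  expect_true(all(tk$p > 0.999))
  expect_true(all(abs(tk$estimate) < 1e-12))

  null_expr <- tibble::tibble(
    sample_id = design$sample_id,
    G = rep(c(-0.5, 0, 0.5), 8)
  )
  expect_message(
    empty <- tukey_contrasts(null_expr, design, "G"),
    "not significant"
  )
  expect_equal(nrow(empty), 0)
})
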