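test_that("pearson reproduces the hand-computed r and t-transform p", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 5)
  out <- pearson(x, y)
  expect_equal(out$r, 0.8, tolerance = 1e-12)
  t_stat <- 0.8 * sqrt(3) / sqrt(1 - 0.64)
  expect_equal(out$p, 2 * pt(t_stat, df = 3, lower.tail = FALSE),
    tolerance = 1e-12
  )
  expect_equal(pearson(x, 2 * x + 3)$r, 1)
  expect_equal(pearson(x, -x)$r, -1)
  expect_error(pearson(c(1, 2), c(3, 4)), class = "fcg_invalid_input")
  expect_error(pearson(x, rep(1, 5)), class = "fcg_degenerate")
})

test_that("r is affine-invariant up to the sign of the scale", {
  set.seed(5)
  x <- rnorm(20)
  y <- rnorm(20)
  r0 <- pearson(x, y)$r
  expect_equal(pearson(10 * x + 3, y)$r, r0, tolerance = 1e-12)
  expect_equal(pearson(-2 * x + 1, y)$r, -r0, tolerance = 1e-12)
})

strat_fixture <- function(n_per_group = 5, seed = 13) {
  # one anxiety-positive measure driven by Trkb with slope -1 (higher Trkb,
  # less anxiety) plus one uncoupled noisy measure in a second test
  beh <- tibble::tibble(
    test = c("EPM", "OF"),
    measure = c("anx_epm", "anx_of"),
    gene = c("Trkb", NA),
    intercept = c(10, 20),
    slope = c(-1, 0),
    noise_sd = c(0, 5),
    direction = c(1, 1)
  )
  cfg <- simulation_config(
    n_per_group = n_per_group, behavior = beh,
    module_loading = 0, replicate_sd = 0
  )
  sim <- simulate_study(cfg, seed = seed)
  expr <- quantify_expression(sim$ct, c("Actb", "Gapdh"))
  emo <- emotionality_scores(sim$behavior, sim$design, sim$directions)
  list(sim = sim, expr = expr, emo = emo)
}

test_that("a perfectly coupled gene is classed negative in every stratum", {
  # slope -1 on latent, direction -1 on the measure: higher Trkb -> more time
  # open -> lower anxiety z; expression is 2^latent (monotone), so the rank
  # relation is strong though not exactly -1
  fx <- strat_fixture()
  cors <- stratified_correlations(fx$expr, fx$emo, fx$sim$design)
  # the emotionality composite averages 2 tests; with only time_open coupled,
  # correlation with Trkb is strongly negative everywhere
  trkb <- dplyr::filter(cors, gene == "Trkb")
  expect_equal(nrow(trkb), 7)
  expect_true(all(trkb$r < 0))
})

test_that("strata partition the samples and carry their own BH families", {
  fx <- strat_fixture(n_per_group = 4, seed = 2)
  cors <- stratified_correlations(fx$expr, fx$emo, fx$sim$design)
  counts <- cors |>
    dplyr::distinct(stratum, n)
  n_all <- counts$n[counts$stratum == "all"]
  expect_equal(counts$n[counts$stratum == "XX"] +
    counts$n[counts$stratum == "XY-"], n_all)
  expect_equal(counts$n[counts$stratum == "gonadal_female"] +
    counts$n[counts$stratum == "gonadal_male"], n_all)
  expect_equal(counts$n[counts$stratum == "blank"] +
    counts$n[counts$stratum == "testosterone"], n_all)
  expect_true(all(abs(cors$r) <= 1, na.rm = TRUE))
})

test_that("small strata are flagged missing instead of scored", {
  fx <- strat_fixture(n_per_group = 4, seed = 3)
  keep <- fx$sim$design$sample_id[
    fx$sim$design$sex_chromosome == "XY-" |
      fx$sim$design$sample_id %in% fx$sim$design$sample_id[1:2]
  ]
  design <- dplyr::filter(fx$sim$design, sample_id %in% keep)
  expr <- dplyr::filter(fx$expr, sample_id %in% keep)
  emo <- dplyr::filter(fx$emo, sample_id %in% keep)
  cors <- stratified_correlations(expr, emo, design)
  xx <- dplyr::filter(cors, stratum == "XX")
  expect_true(all(xx$missing))
  expect_true(all(is.na(xx$p)))
  expect_true(all(xx$sign_class == "ns"))
})

test_that("sign summary lists significant genes by direction with None fallbacks", {
  cors <- tibble::tibble(
    gene = c("A", "B", "C", "A", "B", "C"),
    category = "gaba",
    stratum = rep(c("all", "XX"), each = 3),
    n = 10,
    r = c(0.9, -0.8, 0.1, 0.2, 0.1, -0.1),
    p = c(0.001, 0.002, 0.8, 0.5, 0.6, 0.7),
    q = c(0.003, 0.003, 0.9, 0.9, 0.9, 0.9),
    significant = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    sign_class = c("+", "-", "ns", "ns", "ns", "ns"),
    missing = FALSE
  )
  out <- sign_summary(cors)
  expect_equal(out$genes[out$stratum == "all" & out$direction == "+"], "A")
  expect_equal(out$genes[out$stratum == "all" & out$direction == "-"], "B")
  expect_true(all(out$genes[out$stratum == "XX"] == "None"))
})

test_that("Simpson-style disagreement between strata is handled without error", {
  # within-stratum slope positive, between-strata shift makes the pooled
  # correlation negative
  design <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:20),
    sex_chromosome = rep(c("XX", "XY-"), each = 10),
    gonadal_sex = "ovaries",
    hormone = "blank",
    group = paste(sex_chromosome, gonadal_sex, hormone, sep = ".")
  )
  set.seed(11)
  base <- rnorm(20, sd = 0.2)
  expr <- tibble::tibble(
    sample_id = design$sample_id,
    G = base + ifelse(design$sex_chromosome == "XX", 0, 5)
  )
  emo <- tibble::tibble(
    sample_id = design$sample_id,
    z_overall = base + ifelse(design$sex_chromosome == "XX", 5, 0)
  )
  cors <- stratified_correlations(expr, emo, design,
    categories = tibble::tibble(gene = "G", category = "gaba")
  )
  r_all <- cors$r[cors$stratum == "all"]
  r_xx <- cors$r[cors$stratum == "XX"]
  r_xy <- cors$r[cors$stratum == "XY-"]
  expect_lt(r_all, 0)
  expect_gt(r_xx, 0)
  expect_gt(r_xy, 0)
})
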