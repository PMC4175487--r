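#' Collapse qPCR replicate wells to one CT per sample and gene
#'
#' Quadruplicate (or any number of) wells are collapsed by the arithmetic
#' mean of their CT values; averaging CT is equivalent to a geometric mean
#' in intensity space, matching the geometric-mean quantification
#' convention. Sample x gene combinations with no wells are kept as
#' flagged-missing rows rather than dropped.
#'
#' @param ct Long tibble with columns `sample_id`, `gene`, `replicate`,
#'   `ct`.
#' @return Tibble `sample_id`, `gene`, `ct_mean`, `n_replicates`, `missing`.
#' @export
#' @examples
#' ct <- tibble::tibble(
#'   sample_id = "s1", gene = "Sst", replicate = 1:4, ct = c(20, 20, 20, 20)
#' )
#' collapse_replicates(ct)
collapse_replicates <- function(ct) {
  stopifnot(all(c("sample_id", "gene", "ct") %in% names(ct)))
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0)) {
    abort("CT values must be finite and > 0", class = "fcg_invalid_input")
  }
  ct |>
    group_by(.data$sample_id, .data$gene) |>
    summarise(
      ct_mean = mean(.data$ct),
      n_replicates = n(),
      .groups = "drop"
    ) |>
    complete(.data$sample_id, .data$gene) |>
    mutate(
      n_replicates = ifelse(is.na(.data$n_replicates), 0L, .data$n_replicates),
      missing = .data$n_replicates == 0L
    ) |>
    ungroup()
}

#' Relative expression from collapsed CT values
#'
#' For each target gene `g` the per-control relative intensity is
#' `2^-(CT_g - CT_c)`; the reported value is the geometric mean over the two
#' reference controls, scaled by 10,000 — algebraically identical to
#' `2^-(CT_g - mean(CT_c1, CT_c2)) * 10000`, which is how it is computed
#' here. Samples missing either reference gene are excluded with a message.
#'
#' @param ct_mean Output of [collapse_replicates()] (or any tibble with
#'   `sample_id`, `gene`, `ct_mean`).
#' @param reference_genes Character vector of exactly two reference genes.
#' @param scale Arbitrary-unit scale factor (default 10,000).
#' @return Wide tibble: `sample_id` plus one positive expression column per
#'   target gene.
#' @export
#' @examples
#' ct <- tibble::tibble(
#'   sample_id = "s1",
#'   gene = c("Sst", "Actb", "Gapdh"),
#'   ct_mean = c(25, 20, 22)
#' )
#' relative_expression(ct, c("Actb", "Gapdh")) # dCT = 4 -> 625
relative_expression <- function(ct_mean, reference_genes, scale = 10000) {
  stopifnot(all(c("sample_id", "gene", "ct_mean") %in% names(ct_mean)))
  if (length(reference_genes) != 2) {
    abort("exactly two reference genes are required",
      class = "fcg_invalid_input"
    )
  }
  refs <- ct_mean |>
    filter(.data$gene %in% reference_genes, !is.na(.data$ct_mean)) |>
    group_by(.data$sample_id) |>
    summarise(
      ref_ct = mean(.data$ct_mean),
      n_ref = n(),
      .groups = "drop"
    )
  bad <- refs$sample_id[refs$n_ref < 2]
  bad <- union(bad, setdiff(unique(ct_mean$sample_id), refs$sample_id))
  if (length(bad) > 0) {
    inform(paste0(
      "excluding samples missing a reference gene: ",
      paste(sort(bad), collapse = ", ")
    ))
  }
  out <- ct_mean |>
    filter(!.data$gene %in% reference_genes) |>
    inner_join(filter(refs, .data$n_ref == 2), by = "sample_id") |>
    mutate(expression = 2^-(.data$ct_mean - .data$ref_ct) * scale) |>
    select("sample_id", "gene", "expression") |>
    pivot_wider(names_from = "gene", values_from = "expression")
  out
}

#' Quantify a raw CT table in one step
#'
#' Convenience wrapper: [collapse_replicates()] then
#' [relative_expression()].
#'
#' @inheritParams collapse_replicates
#' @inheritParams relative_expression
#' @return Wide expression tibble (`sample_id` x genes), in arbitrary units.
#' @export
quantify_expression <- function(ct, reference_genes, scale = 10000) {
  relative_expression(collapse_replicates(ct), reference_genes, scale = scale)
}

#' QC check on reference-gene stability across design groups
#'
#' Reference genes are assumed not to respond to the sex-related factors; a
#' warning is emitted when the range of a reference gene's group-mean CT
#' (equivalently its log2 group-mean intensity range) exceeds
#' `max_log2_range`.
#'
#' @param ct_mean Output of [collapse_replicates()].
#' @param design Design tibble with `sample_id` and `group`.
#' @param reference_genes Two reference gene names.
#' @param max_log2_range Tolerated |log2| group-mean range (default 0.5).
#' @return Tibble `gene`, `log2_range`, `stable`, invisibly-warned.
#' @export
check_reference_stability <- function(ct_mean, design, reference_genes,
                                      max_log2_range = 0.5) {
  qc <- ct_mean |>
    filter(.data$gene %in% reference_genes) |>
    inner_join(select(design, "sample_id", "group"), by = "sample_id") |>
    group_by(.data$gene, .data$group) |>
    summarise(mean_ct = mean(.data$ct_mean, na.rm = TRUE), .groups = "drop_last") |>
    summarise(
      log2_range = max(.data$mean_ct) - min(.data$mean_ct),
      .groups = "drop"
    ) |>
    mutate(stable = .data$log2_range <= max_log2_range)
  if (any(!qc$stable)) {
    warn(paste0(
      "reference gene(s) vary across groups beyond ", max_log2_range,
      " log2 units: ",
      paste(qc$gene[!qc$stable], collapse = ", ")
    ))
  }
  qc
}
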