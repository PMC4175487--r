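#' Default mood-related gene panel
#'
#' The gene panel assayed in the frontal cortex of Four Core Genotypes mice:
#' 13 GABA-related genes assayed by qPCR plus three GABA markers (Sst, Gad67,
#' Gad65) carried over from a prior study of the same animals, 14
#' serotonin/dopamine-related genes (receptors, cAMP/PKA and AKT signal
#' transduction components, and other related genes), and the two reference
#' genes (beta-actin and Gapdh) used as internal qPCR controls.
#'
#' @param include_reference Keep the two reference genes in the table
#'   (default `TRUE`).
#' @return A tibble with columns `gene`, `category` (`"gaba"`,
#'   `"monoamine"` or `"reference"`), `is_reference`, and `assayed`
#'   (`FALSE` for the three genes quantified in the prior study).
#' @export
#' @examples
#' fcg_gene_panel()
fcg_gene_panel <- function(include_reference = TRUE) {
  gaba_assayed <- c(
    "Vip", "Calb1", "Cst", "Npy", "Cr", "Cck", "Pv",
    "Gat1", "Gabra1", "Gabra2", "Gabra5", "Bdnf", "Trkb"
  )
  gaba_prior <- c("Sst", "Gad67", "Gad65")
  monoamine <- c(
    "Htr1a", "Htr2a", "Htr2c", "Drd1a",
    "Adcy1", "Adcy2", "Adcy5", "Adcy7", "Cdk5",
    "Akt1", "Akt2", "Akt3", "App", "Pdyn"
  )
  reference <- c("Actb", "Gapdh")
  panel <- tibble(
    gene = c(gaba_assayed, gaba_prior, monoamine, reference),
    category = c(
      rep("gaba", length(gaba_assayed) + length(gaba_prior)),
      rep("monoamine", length(monoamine)),
      rep("reference", length(reference))
    ),
    is_reference = .data$category == "reference",
    assayed = !.data$gene %in% gaba_prior
  )
  if (!include_reference) {
    panel <- filter(panel, !.data$is_reference)
  }
  panel
}

#' The male-phenotype core co-expression module
#'
#' Signal-transduction genes forming the tightly co-expressed module observed
#' in the male-phenotype networks (XY-, gonadal male, testosterone-treated).
#'
#' @return Character vector of gene names.
#' @export
fcg_core_module <- function() {
  c("Akt1", "Akt2", "Akt3", "Adcy2", "Adcy5", "Pdyn", "Cdk5", "App")
}
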