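#' Build an |r|^3-weighted gene co-expression network
#'
#' Pairwise Pearson correlations `r_ij` are computed across the given
#' samples; the edge weight is `|r_ij|^3`, which boosts strong correlations
#' while shrinking the small ones random noise tends to introduce. The sign
#' of `r` is stored separately from the weight (it is used only for edge
#' annotation). Genes with zero variance within the group are excluded with
#' a warning. An optional threshold `tau` zeroes weights `w <= tau`; the
#' complete weighted graph (`tau = 0`) is the default.
#'
#' @param expression Wide expression tibble (`sample_id` x genes).
#' @param sample_ids Samples defining the group; default all rows.
#' @param genes Genes to include; default all non-`sample_id` columns.
#' @param tau Weight threshold in `[0, 1)`; weights `<= tau` are zeroed and
#'   the thresholded edge list also defines the assortativity edge set.
#' @param group Label carried on the network.
#' @return Object of class `"coexpr_network"`: list with `genes`, `r` and
#'   `w` (symmetric matrices, zero diagonal), `group`, `n_samples`, `tau`.
#'   [tidy()] yields the edge list, [glance()] the global properties.
#' @export
#' @examples
#' sim <- simulate_study(simulation_config(n_per_group = 4), seed = 1)
#' expr <- quantify_expression(sim$ct, c("Actb", "Gapdh"))
#' net <- build_network(expr, group = "all")
#' glance(net)
build_network <- function(expression, sample_ids = NULL, genes = NULL,
                          tau = 0, group = "network") {
  genes <- genes %||% setdiff(names(expression), "sample_id")
  if (!is.null(sample_ids)) {
    expression <- filter(expression, .data$sample_id %in% sample_ids)
  }
  x <- as.matrix(expression[, genes, drop = FALSE])
  if (nrow(x) < 3) {
    abort("at least 3 samples are required", class = "fcg_invalid_input")
  }
  if (ncol(x) < 3) {
    abort("at least 3 genes are required", class = "fcg_invalid_input")
  }
  sds <- apply(x, 2, sd)
  if (any(sds == 0 | is.na(sds))) {
    dropped <- genes[sds == 0 | is.na(sds)]
    warn(paste0(
      "excluding zero-variance gene(s): ", paste(dropped, collapse = ", ")
    ))
    x <- x[, !(genes %in% dropped), drop = FALSE]
    genes <- setdiff(genes, dropped)
    if (ncol(x) < 3) {
      abort("fewer than 3 genes with nonzero variance",
        class = "fcg_degenerate"
      )
    }
  }
  r <- cor(x)
  diag(r) <- 0
  new_coexpr_network(r, genes, group, nrow(x), tau)
}

new_coexpr_network <- function(r, genes, group, n_samples, tau) {
  w <- abs(r)^3
  if (tau > 0) w[w <= tau] <- 0
  diag(w) <- 0
  dimnames(r) <- dimnames(w) <- list(genes, genes)
  structure(
    list(
      genes = genes, r = r, w = w, group = group,
      n_samples = n_samples, tau = tau
    ),
    class = "coexpr_network"
  )
}

#' Construct a network directly from a weight matrix
#'
#' Mostly useful for worked examples and closed-form checks; `r` is taken
#' as `sign * w^(1/3)` so the stored correlation and weight stay
#' consistent.
#'
#' @param w Symmetric nonnegative weight matrix in `[0, 1]`.
#' @param genes Node names; default from `dimnames` or `g1..gn`.
#' @param signs Optional sign matrix (+1/-1); default all +1.
#' @param tau Weight threshold (see [build_network()]).
#' @param group Label.
#' @return A `"coexpr_network"`.
#' @export
network_from_weights <- function(w, genes = NULL, signs = NULL, tau = 0,
                                 group = "network") {
  w <- as.matrix(w)
  stopifnot(isSymmetric(unname(w)), all(w >= 0), all(w <= 1))
  genes <- genes %||% rownames(w) %||% paste0("g", seq_len(nrow(w)))
  signs <- signs %||% matrix(1, nrow(w), ncol(w))
  diag(w) <- 0
  net <- new_coexpr_network(signs * w^(1 / 3), genes, group,
    n_samples = NA_integer_, tau = tau
  )
  net$w <- w * (if (tau > 0) (w > tau) else 1)
  net
}

#' @export
print.coexpr_network <- function(x, ...) {
  cat(
    "Co-expression network '", x$group, "': ", length(x$genes),
    " genes, ", x$n_samples, " samples, tau = ", x$tau, "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.coexpr_network <- function(x, ...) {
  idx <- which(upper.tri(x$w), arr.ind = TRUE)
  tibble(
    gene_i = x$genes[idx[, 1]],
    gene_j = x$genes[idx[, 2]],
    r = x$r[idx],
    weight = x$w[idx],
    sign = ifelse(x$r[idx] > 0, "+", ifelse(x$r[idx] < 0, "-", "0"))
  )
}

#' @export
glance.coexpr_network <- function(x, ...) {
  network_properties(x)
}

#' Weighted degrees of a network
#'
#' `k_i = sum_j w_ij`, the sum of incident edge weights per node.
#'
#' @param network A `"coexpr_network"`.
#' @return Named numeric vector.
#' @export
weighted_degrees <- function(network) {
  rowSums(network$w)
}

#' Network density
#'
#' Mean weighted degree divided by `n - 1`: the fraction of the maximum
#' possible total edge weight realised; 1 for a complete unit-weight graph.
#'
#' @param network A `"coexpr_network"`.
#' @return Scalar in `[0, 1]`.
#' @export
network_density <- function(network) {
  n <- length(network$genes)
  if (n < 2) abort("density undefined for n < 2", class = "fcg_degenerate")
  mean(weighted_degrees(network)) / (n - 1)
}

#' Global weighted clustering coefficient
#'
#' Per node `i` the local coefficient is
#' `sum_{j != i} sum_{k != i,j} w_ij w_jk w_ki / ((sum_j w_ij)^2 -
#'  sum_j w_ij^2)` — the ordered double sum counts each triangle twice,
#' matching the symmetric denominator. The global value averages local
#' coefficients over nodes with a nonzero denominator; nodes whose
#' denominator is zero (fewer than two weighted neighbours) are excluded
#' from the mean and their count is attached as attribute `"n_excluded"`.
#'
#' @param network A `"coexpr_network"`.
#' @return Scalar; errors if every node is excluded.
#' @export
network_clustering <- function(network) {
  w <- network$w
  if (nrow(w) < 3) {
    abort("clustering undefined for n < 3", class = "fcg_degenerate")
  }
  k <- rowSums(w)
  numerator <- diag(w %*% w %*% w)
  denominator <- k^2 - rowSums(w^2)
  ok <- denominator > 1e-12
  if (!any(ok)) {
    abort("clustering undefined: no node has two weighted neighbours",
      class = "fcg_degenerate"
    )
  }
  out <- mean(numerator[ok] / denominator[ok])
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Degree assortativity over the thresholded edge list
#'
#' Newman's degree-correlation coefficient applied to the edge list
#' `{(i, j): w_ij > tau}` with endpoint values taken as the weighted
#' degrees `k_i`: with `M` edges whose endpoint degrees are `(j_e, k_e)`,
#' `r = [M^-1 sum j_e k_e - (M^-1 sum (j_e + k_e)/2)^2] /
#'      [M^-1 sum (j_e^2 + k_e^2)/2 - (M^-1 sum (j_e + k_e)/2)^2]`.
#' Positive values mean high-degree nodes preferentially attach to other
#' high-degree nodes; the value is undefined (returned as `NA` with
#' attribute `"undefined"`) when all endpoint degrees are equal, e.g. for a
#' perfectly regular graph.
#'
#' @param network A `"coexpr_network"`.
#' @return Scalar in `[-1, 1]`, or `NA` when undefined.
#' @export
network_assortativity <- function(network) {
  w <- network$w
  k <- rowSums(w)
  idx <- which(upper.tri(w) & w > network$tau, arr.ind = TRUE)
  m <- nrow(idx)
  if (m < 2) {
    abort("assortativity requires at least 2 edges", class = "fcg_degenerate")
  }
  je <- k[idx[, 1]]
  ke <- k[idx[, 2]]
  mean_jk <- mean(je * ke)
  mean_half_sum <- mean((je + ke) / 2)
  mean_half_sq <- mean((je^2 + ke^2) / 2)
  denominator <- mean_half_sq - mean_half_sum^2
  scale <- mean_half_sq + 1e-300
  if (denominator / scale < 1e-12) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  (mean_jk - mean_half_sum^2) / denominator
}

#' Global properties of a co-expression network
#'
#' @param network A `"coexpr_network"`.
#' @return One-row tibble: `group`, `n_genes`, `n_samples`, `density`,
#'   `clustering`, `assortativity` (NA when undefined).
#' @export
network_properties <- function(network) {
  assort <- tryCatch(
    as.numeric(network_assortativity(network)),
    fcg_degenerate = function(e) NA_real_
  )
  clus <- tryCatch(
    as.numeric(network_clustering(network)),
    fcg_degenerate = function(e) NA_real_
  )
  tibble(
    group = network$group,
    n_genes = length(network$genes),
    n_samples = network$n_samples,
    density = network_density(network),
    clustering = clus,
    assortativity = assort
  )
}

# fast path used by the permutation engine: all three properties straight
# from a samples x genes matrix, skipping object construction
properties_from_matrix <- function(x, tau = 0) {
  r <- suppressWarnings(cor(x))
  w <- abs(r)^3
  diag(w) <- 0
  w[is.na(w)] <- 0
  if (tau > 0) w[w <= tau] <- 0
  n <- ncol(w)
  k <- rowSums(w)
  density <- mean(k) / (n - 1)
  numerator <- diag(w %*% w %*% w)
  denominator <- k^2 - rowSums(w^2)
  ok <- denominator > 1e-12
  clustering <- if (any(ok)) mean(numerator[ok] / denominator[ok]) else NA_real_
  idx <- which(upper.tri(w) & w > tau, arr.ind = TRUE)
  assortativity <- NA_real_
  if (nrow(idx) >= 2) {
    je <- k[idx[, 1]]
    ke <- k[idx[, 2]]
    mhs <- mean((je + ke) / 2)
    den <- mean((je^2 + ke^2) / 2) - mhs^2
    if (den / (mean((je^2 + ke^2) / 2) + 1e-300) >= 1e-12) {
      assortativity <- (mean(je * ke) - mhs^2) / den
    }
  }
  c(density = density, clustering = clustering, assortativity = assortativity)
}

#' Permutation comparison of global network properties
#'
#' The observed difference `prop(A) - prop(B)` between the two groups'
#' networks is compared to a null built by repeatedly shuffling the pooled
#' sample labels (preserving group sizes), rebuilding both networks, and
#' recomputing the difference. The two-sided p-value uses add-one
#' smoothing, `p = (1 + #{|d_perm| >= |d_obs|}) / (n_valid + 1)`;
#' permutations where a property is undefined are excluded with an adjusted
#' denominator, and the result is flagged unreliable when more than 20% of
#' permutations are lost this way.
#'
#' @param expression Wide expression tibble (`sample_id` x genes).
#' @param ids_a,ids_b Sample ids of the two groups (>= 3 each).
#' @param properties Which properties to compare; default all three.
#' @param n_perm Number of permutations (default 1000).
#' @param tau Weight threshold.
#' @param seed Integer seed for the permutation stream.
#' @param genes Genes to include; default all.
#' @param labels Length-2 group labels used in the output.
#' @return Object of class `"network_comparison"`; [tidy()] gives a tibble
#'   with `property`, `observed_a`, `observed_b`, `delta`, `p`, `n_valid`,
#'   `unreliable`.
#' @export
#' @examples
#' sim <- simulate_study(simulation_config(n_per_group = 4), seed = 1)
#' expr <- quantify_expression(sim$ct, c("Actb", "Gapdh"))
#' ids_m <- sim$design$sample_id[sim$design$gonadal_sex == "testes"]
#' ids_f <- sim$design$sample_id[sim$design$gonadal_sex == "ovaries"]
#' cmp <- compare_networks(expr, ids_m, ids_f,
#'   properties = "density", n_perm = 99, seed = 1
#' )
#' tidy(cmp)
compare_networks <- function(expression, ids_a, ids_b,
                             properties = c(
                               "density", "clustering", "assortativity"
                             ),
                             n_perm = 1000, tau = 0, seed = 1,
                             genes = NULL, labels = c("A", "B")) {
  properties <- match.arg(properties, several.ok = TRUE)
  if (length(ids_a) < 3 || length(ids_b) < 3) {
    abort("both groups need at least 3 samples", class = "fcg_invalid_input")
  }
  genes <- genes %||% setdiff(names(expression), "sample_id")
  x <- as.matrix(expression[
    match(c(ids_a, ids_b), expression$sample_id), genes,
    drop = FALSE
  ])
  if (anyNA(x)) abort("missing expression values", class = "fcg_invalid_input")
  na <- length(ids_a)
  n_tot <- nrow(x)

  obs_a <- properties_from_matrix(x[seq_len(na), , drop = FALSE], tau)
  obs_b <- properties_from_matrix(x[(na + 1):n_tot, , drop = FALSE], tau)
  observed <- obs_a - obs_b

  set.seed(stage_seed(seed, "permutation"))
  null_delta <- matrix(NA_real_, nrow = n_perm, ncol = 3,
    dimnames = list(NULL, names(observed))
  )
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n_tot)
    pa <- properties_from_matrix(x[perm[seq_len(na)], , drop = FALSE], tau)
    pb <- properties_from_matrix(x[perm[(na + 1):n_tot], , drop = FALSE], tau)
    null_delta[b, ] <- pa - pb
  }

  res <- map_dfr(properties, function(prop) {
    nulls <- null_delta[, prop]
    valid <- !is.na(nulls)
    n_valid <- sum(valid)
    d_obs <- observed[[prop]]
    p <- if (is.na(d_obs) || n_valid == 0) {
      NA_real_
    } else {
      (1 + sum(abs(nulls[valid]) >= abs(d_obs))) / (n_valid + 1)
    }
    tibble(
      property = prop,
      observed_a = obs_a[[prop]],
      observed_b = obs_b[[prop]],
      delta = d_obs,
      p = p,
      n_valid = n_valid,
      unreliable = is.na(d_obs) | n_valid < 0.8 * n_perm
    )
  })
  structure(
    list(
      table = res, null_delta = null_delta[, properties, drop = FALSE],
      n_perm = n_perm, seed = seed, labels = labels, tau = tau
    ),
    class = "network_comparison"
  )
}

#' @export
tidy.network_comparison <- function(x, ...) {
  x$table
}

#' @export
glance.network_comparison <- function(x, ...) {
  tibble(
    n_perm = x$n_perm, seed = x$seed, tau = x$tau,
    group_a = x$labels[1], group_b = x$labels[2]
  )
}

#' @export
print.network_comparison <- function(x, ...) {
  cat(
    "Permutation comparison (", x$labels[1], " - ", x$labels[2], "), ",
    x$n_perm, " permutations\n",
    sep = ""
  )
  print(x$table)
  invisible(x)
}

#' Project another group's data onto a reference network structure
#'
#' Keeps the reference network's edge set (pairs with reference weight
#' `> tau`) fixed and recomputes correlations and weights from the other
#' group's samples — the device used to plot female-phenotype data on the
#' male-phenotype network structure. Intended for export and visual
#' comparison; group statistics should come from each group's own full
#' network.
#'
#' @param reference A `"coexpr_network"` defining the edge structure.
#' @param expression Wide expression tibble for the other group.
#' @param sample_ids Samples of the other group; default all rows.
#' @param group Label for the projected network.
#' @return A `"coexpr_network"` with edges restricted to the reference
#'   structure and attribute `"projected_from"` naming the reference group.
#' @export
project_reference <- function(reference, expression, sample_ids = NULL,
                              group = paste0(reference$group, "_projection")) {
  genes <- reference$genes
  missing <- setdiff(genes, names(expression))
  if (length(missing) > 0) {
    abort(
      paste0(
        "expression table lacks reference genes: ",
        paste(missing, collapse = ", ")
      ),
      class = "fcg_invalid_input"
    )
  }
  other <- build_network(expression, sample_ids,
    genes = genes, tau = 0,
    group = group
  )
  keep <- reference$w > reference$tau
  diag(keep) <- FALSE
  other$w[!keep] <- 0
  other$tau <- reference$tau
  attr(other, "projected_from") <- reference$group
  other
}

#' Export a network as an edge-list TSV
#'
#' Columns `gene_i`, `gene_j`, `r`, `weight`, `sign`.
#'
#' @param network A `"coexpr_network"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_edges <- function(network, path) {
  readr::write_tsv(tidy(network), path)
  invisible(path)
}

#' Export a network as GraphML
#'
#' Node attribute `degree` holds the weighted degree; edge attributes
#' `weight` (|r|^3) and `sign` are carried for styling in external viewers.
#'
#' @inheritParams write_network_edges
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path) {
  edges <- tidy(network)
  g <- igraph::graph_from_data_frame(
    filter(edges, .data$weight > 0),
    directed = FALSE,
    vertices = tibble(
      name = network$genes,
      degree = unname(weighted_degrees(network))
    )
  )
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
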