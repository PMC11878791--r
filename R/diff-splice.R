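#' Per-element PSI difference between two cell groups
#'
#' For every element, computes `delta`, the difference between the mean PSI
#' of group A and group B over unmasked cells. Elements of genes with fewer
#' than `min_cells` unmasked cells in either group are excluded (status
#' `"too_few_cells"`): too few cells make the group means unreliable.
#'
#' @param psi Long PSI tibble (`gene_id`, `element_id`, `cell_id`, `psi`,
#'   optionally `type`/`is_novel`), e.g. from [tidy.psi_fit()] or
#'   [quantify_dataset()].
#' @param groups Two-level grouping: named character vector or tibble with
#'   `cell_id`, `group`. Group A is the first level in sorted order.
#' @param min_cells Minimum unmasked cells per group and gene (default 5).
#' @return Tibble with `gene_id`, `element_id` (plus `type`/`is_novel` when
#'   present), `delta`, `n_A`, `n_B`, `status`.
#' @export
group_delta <- function(psi, groups, min_cells = 5L) {
  groups <- as_group_vector(groups)
  lv <- sort(unique(groups))
  if (length(lv) != 2L) {
    abort("exactly two group labels are required; run pairwise comparisons")
  }
  keep_cols <- intersect(c("type", "is_novel"), names(psi))
  d <- psi |>
    mutate(group = unname(groups[.data$cell_id])) |>
    filter(!is.na(.data$group))
  gene_n <- d |>
    filter(!is.na(.data$psi)) |>
    distinct(.data$gene_id, .data$cell_id, .data$group) |>
    count(.data$gene_id, .data$group) |>
    pivot_wider(names_from = "group", values_from = "n", values_fill = 0L)
  for (g in lv) if (!g %in% names(gene_n)) gene_n[[g]] <- 0L
  gene_n <- gene_n |>
    transmute(.data$gene_id, n_A = .data[[lv[1]]], n_B = .data[[lv[2]]])
  d |>
    group_by(across(all_of(c("gene_id", "element_id", keep_cols)))) |>
    summarise(
      delta = mean(.data$psi[.data$group == lv[1]], na.rm = TRUE) -
        mean(.data$psi[.data$group == lv[2]], na.rm = TRUE),
      .groups = "drop"
    ) |>
    left_join(gene_n, by = "gene_id") |>
    mutate(
      n_A = dplyr::coalesce(.data$n_A, 0L),
      n_B = dplyr::coalesce(.data$n_B, 0L),
      status = ifelse(.data$n_A < min_cells | .data$n_B < min_cells,
                      "too_few_cells", "tested"),
      delta = ifelse(.data$status == "tested", .data$delta, NA_real_)
    )
}

as_group_vector <- function(groups) {
  if (is.data.frame(groups)) groups <- setNames(groups$group, groups$cell_id)
  groups
}

#' Permutation-fitted normal null for the delta statistic
#'
#' Cells are randomly reassigned to two pseudo-groups of the original sizes;
#' since such groups no longer separate splice patterns, no differential
#' splicing is expected, and the resulting delta values form a background
#' distribution. Deltas from all elements of all genes across `n_perm`
#' reassignments are pooled and a normal distribution is fitted by sample
#' mean and standard deviation.
#'
#' @inheritParams group_delta
#' @param n_perm Number of random reassignments (default 10).
#' @param seed RNG seed governing the permutations (default 42).
#' @return A `null_model` list: `mu`, `sigma`, `n_permutations`, `n_deltas`.
#' @export
permutation_null <- function(psi, groups, n_perm = 10L, seed = 42L,
                             min_cells = 5L) {
  groups <- as_group_vector(groups)
  cells <- names(groups)
  pooled <- withr::with_seed(seed, {
    purrr::map(seq_len(n_perm), function(i) {
      perm <- setNames(sample(unname(groups)), cells)  # sizes preserved
      group_delta(psi, perm, min_cells = min_cells) |>
        filter(.data$status == "tested") |>
        pull(.data$delta)
    })
  }) |> unlist()
  pooled <- pooled[is.finite(pooled)]
  if (length(pooled) < 2L || sd(pooled) == 0) {
    abort("degenerate permutation null: all permuted deltas are equal")
  }
  structure(list(mu = mean(pooled), sigma = sd(pooled),
                 n_permutations = n_perm, n_deltas = length(pooled)),
            class = "null_model")
}

#' @export
print.null_model <- function(x, ...) {
  cat("<null_model> normal(mu = ", signif(x$mu, 3), ", sigma = ",
      signif(x$sigma, 3), ") from ", x$n_permutations,
      " permutations (", x$n_deltas, " deltas)\n", sep = "")
  invisible(x)
}

#' Call differentially spliced elements against a permutation null
#'
#' Two-sided normal p-values from the fitted null, Benjamini-Hochberg
#' corrected over all tested elements; an element is significant when its
#' adjusted p-value falls below `alpha`.
#'
#' @param deltas Tibble from [group_delta()].
#' @param null A `null_model` from [permutation_null()].
#' @param alpha Significance threshold on the BH-adjusted p-value
#'   (default 0.01).
#' @return `deltas` with `p_value`, `q_value` and `is_significant` columns
#'   (NA for excluded elements), of class `diff_splice_tbl`.
#' @export
call_differential <- function(deltas, null, alpha = 0.01) {
  tested <- deltas$status == "tested"
  p <- rep(NA_real_, nrow(deltas))
  p[tested] <- 2 * pnorm(-abs(deltas$delta[tested] - null$mu) / null$sigma)
  q <- rep(NA_real_, nrow(deltas))
  q[tested] <- p.adjust(p[tested], method = "BH")
  out <- deltas |>
    mutate(p_value = p, q_value = q,
           is_significant = !is.na(q) & q < alpha)
  attr(out, "null_model") <- null
  attr(out, "alpha") <- alpha
  class(out) <- c("diff_splice_tbl", class(out))
  out
}

#' Differential splicing between two cell groups
#'
#' Convenience wrapper: [group_delta()], [permutation_null()] and
#' [call_differential()] in one call.
#'
#' @inheritParams group_delta
#' @inheritParams permutation_null
#' @inheritParams call_differential
#' @return A `diff_splice_tbl` (see [call_differential()]).
#' @examples
#' sim <- simulate_dataset("allAnnot", n_genes = 3, n_cells_per_type = 20,
#'                         seed = 1)
#' res <- quantify_dataset(sim)
#' calls <- diff_splicing(res$psi, sim$cells[, c("cell_id", "group")])
#' dplyr::filter(calls, is_significant)
#' @export
diff_splicing <- function(psi, groups, min_cells = 5L, n_perm = 10L,
                          seed = 42L, alpha = 0.01) {
  deltas <- group_delta(psi, groups, min_cells = min_cells)
  null <- permutation_null(psi, groups, n_perm = n_perm, seed = seed,
                           min_cells = min_cells)
  call_differential(deltas, null, alpha = alpha)
}

#' @exportS3Method generics::glance
glance.diff_splice_tbl <- function(x, ...) {
  null <- attr(x, "null_model")
  tibble(n_elements = nrow(x),
         n_tested = sum(x$status == "tested"),
         n_significant = sum(x$is_significant),
         null_mu = null$mu, null_sigma = null$sigma,
         alpha = attr(x, "alpha"))
}

#' Volcano-style plot of differential splicing calls
#'
#' @param object A `diff_splice_tbl`.
#' @param ... Unused.
#' @return A ggplot object (delta versus -log10 adjusted p).
#' @exportS3Method ggplot2::autoplot
autoplot.diff_splice_tbl <- function(object, ...) {
  d <- object |> filter(.data$status == "tested")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$delta,
                                  y = -log10(pmax(.data$q_value, 1e-300)),
                                  colour = .data$is_significant)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = expression(Delta ~ "(mean PSI difference)"),
                  y = expression(-log[10] ~ "adjusted p"),
                  colour = "significant") +
    ggplot2::theme_minimal()
}

#' Base-pair-weighted absolute PSI error per gene
#'
#' For each cell, the mean absolute difference between estimated and true
#' exon PSI values, weighted by exon length (i.e. averaged over all bases
#' contained in the exons of the splice graph); errors are then averaged
#' over unmasked cells per gene. Base-pair weighting avoids inflating the
#' error of genes whose exons were subdivided into several short partial
#' exons.
#'
#' @param psi Long PSI tibble (estimates) with `gene_id`, `element_id`,
#'   `cell_id`, `psi`.
#' @param truth Long tibble of true PSI values with `gene_id`, `element_id`,
#'   `cell_id`, `psi_true`.
#' @param lengths Element lengths: tibble with `gene_id`, `element_id`,
#'   `length` (exon elements only).
#' @return Tibble with `gene_id`, `error` (mean over cells of the per-cell
#'   base-pair-weighted absolute error, in PSI fraction units) and
#'   `n_cells`.
#' @export
basepair_abs_error <- function(psi, truth, lengths) {
  psi |>
    inner_join(lengths, by = c("gene_id", "element_id")) |>
    inner_join(truth, by = c("gene_id", "element_id", "cell_id")) |>
    filter(!is.na(.data$psi)) |>
    group_by(.data$gene_id, .data$cell_id) |>
    summarise(err = sum(.data$length * abs(.data$psi - .data$psi_true)) /
                sum(.data$length), .groups = "drop") |>
    group_by(.data$gene_id) |>
    summarise(error = mean(.data$err), n_cells = dplyr::n(), .groups = "drop")
}

#' Correlation of PSI with pseudotime
#'
#' Spearman rank correlation of each element's PSI values with an externally
#' supplied pseudotime over unmasked cells. No significance threshold is
#' applied; ranking and thresholding are left to the user.
#'
#' @param psi Long PSI tibble.
#' @param pseudotime Named numeric vector (names = cell ids) or tibble with
#'   `cell_id`, `pseudotime`.
#' @param min_cells Minimum unmasked cells required (default 5; otherwise
#'   `NA`).
#' @return Tibble with `gene_id`, `element_id`, `rho`, `n_cells`.
#' @export
pseudotime_correlation <- function(psi, pseudotime, min_cells = 5L) {
  if (is.data.frame(pseudotime)) {
    pseudotime <- setNames(pseudotime$pseudotime, pseudotime$cell_id)
  }
  psi |>
    mutate(pt = unname(pseudotime[.data$cell_id])) |>
    filter(!is.na(.data$psi), !is.na(.data$pt)) |>
    group_by(.data$gene_id, .data$element_id) |>
    summarise(
      rho = if (dplyr::n() < min_cells || sd(.data$psi) == 0 ||
                sd(.data$pt) == 0) NA_real_
            else suppressWarnings(cor(.data$psi, .data$pt,
                                      method = "spearman")),
      n_cells = dplyr::n(), .groups = "drop"
    )
}
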