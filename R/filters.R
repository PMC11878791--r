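#' Gene-level exclusion rules
#'
#' A gene is kept for PSI estimation only when (i) at least one cell has an
#' initialization-style coverage proxy above 10, (ii) its simplified splice
#' graph is not entirely sequential (some node must offer an alternative
#' path, otherwise there is no splicing to quantify), and (iii) the graph has
#' at most `max_paths` source->sink paths (extremely complex graphs give
#' unreliable estimates and waste memory).
#'
#' @param graphs Named list of `splice_graph` objects (simplified).
#' @param coverages Named list of [coverage_table()] objects, same names.
#' @param min_coverage Retention threshold on the per-cell coverage proxy;
#'   a gene needs at least one cell strictly above it (default 10).
#' @param max_paths Path-count cap (default one million).
#' @param cfg An [em_config()] (controls the coverage-proxy definition).
#' @return A tibble with `gene_id`, `status` (`"kept"`,
#'   `"no_covered_cell"`, `"sequential_graph"`, `"too_many_paths"`) and
#'   `kept`.
#' @export
filter_genes <- function(graphs, coverages, min_coverage = 10,
                         max_paths = 1e6, cfg = em_config()) {
  purrr::imap(graphs, function(g, id) {
    status <- "kept"
    if (is.null(coverages[[id]])) {
      status <- "no_covered_cell"
    } else if (is_sequential_graph(g)) {
      status <- "sequential_graph"
    } else if (count_source_sink_paths(g, cap = max_paths) > max_paths) {
      status <- "too_many_paths"
    } else {
      alpha <- initialize_alpha(coverages[[id]], g, cfg)
      if (!any(alpha$alpha_E > min_coverage)) status <- "no_covered_cell"
    }
    tibble(gene_id = id, status = status, kept = status == "kept")
  }) |> bind_rows()
}

#' Cell-level exclusion rules for one gene
#'
#' A cell is kept only when at most `max_lowq` (10%) of its mapped gene
#' reads are low quality (MAPQ < 10), and its gene-coverage scalar is at
#' least `min_alpha` (10): cells below that lack the read coverage for a
#' reliable PSI estimate.
#'
#' @param cov A [coverage_table()].
#' @param alpha Tibble from [initialize_alpha()] (or converged alphas).
#' @param max_lowq Maximum tolerated low-quality read fraction (default 0.10).
#' @param min_alpha Minimum gene-coverage scalar (default 10; a cell with
#'   `alpha_E` exactly 10 is kept, removal applies to `alpha < 10`).
#' @return A tibble with `cell_id`, `status` (`"kept"`,
#'   `"low_quality_maps"`, `"low_alpha"`) and `kept`.
#' @export
filter_cells <- function(cov, alpha, max_lowq = 0.10, min_alpha = 10) {
  lowq <- cov$lowq[alpha$cell_id]
  lowq[is.na(lowq)] <- 0
  status <- dplyr::case_when(
    lowq > max_lowq ~ "low_quality_maps",
    alpha$alpha_E < min_alpha ~ "low_alpha",
    TRUE ~ "kept"
  )
  tibble(cell_id = alpha$cell_id, status = status, kept = status == "kept")
}
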