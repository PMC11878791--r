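#' Build, extend and simplify splice graphs for many genes
#'
#' For every gene in the annotation: build the reference graph, add
#' read-supported novel junctions, add read-supported novel exons, and
#' simplify. Genes whose graph construction fails are skipped with a warning
#' (quarantined), so one malformed gene cannot abort a run.
#'
#' @param annotation Exon tibble from [read_annotation()].
#' @param coverage Named list of [coverage_table()]s (one per gene).
#' @param min_reads,min_cells Novel-element support filter (defaults 5, 10).
#' @param simplify Drop unobserved elements (default `TRUE`).
#' @return Named list of `splice_graph` objects.
#' @export
build_graphs <- function(annotation, coverage, min_reads = 5L,
                         min_cells = 10L, simplify = TRUE) {
  out <- list()
  for (gid in unique(annotation$gene_id)) {
    res <- tryCatch({
      g <- build_splice_graph(annotation |> filter(.data$gene_id == gid))
      cov <- coverage[[gid]]
      if (!is.null(cov)) {
        g <- add_novel_junctions(g, cov$junction_count, min_reads, min_cells)
        g <- add_novel_exons(g, cov$junction_count, cov$exon_cov,
                             min_reads, min_cells)
        if (simplify) g <- simplify_graph(g, cov$exon_cov, cov$junction_count)
      }
      g
    }, error = function(e) {
      warn(paste0("gene ", gid, " quarantined: ", conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) out[[gid]] <- res
  }
  out
}

#' Quantify PSI values across a whole dataset
#'
#' Full pipeline over a simulated (or counts-mode) dataset: graph
#' construction and extension, gene filtering, neighbor finding and
#' per-gene PSI estimation.
#'
#' @param sim A dataset from [simulate_dataset()], or any list providing
#'   `annotation`, `coverage`, `expression` and `cells`.
#' @param cfg An [em_config()].
#' @param k Number of expression neighbors (default 100).
#' @param use_groups Restrict neighbors to cells of the same group label
#'   (default `TRUE`; uses `sim$cells$group`).
#' @param min_reads,min_cells Novel-element support filter.
#' @return A list with `psi` (long tibble over all kept genes), `fits`
#'   (named list of `psi_fit`), `graphs`, `gene_filter` (tibble) and
#'   `neighbors`.
#' @examples
#' sim <- simulate_dataset("allAnnot", n_genes = 4, n_cells_per_type = 20,
#'                         seed = 2)
#' res <- quantify_dataset(sim)
#' head(res$psi)
#' @export
quantify_dataset <- function(sim, cfg = em_config(), k = 100L,
                             use_groups = TRUE, min_reads = 5L,
                             min_cells = 10L) {
  graphs <- build_graphs(sim$annotation, sim$coverage,
                         min_reads = min_reads, min_cells = min_cells)
  flt <- filter_genes(graphs, sim$coverage, cfg = cfg)
  kept <- flt$gene_id[flt$kept]
  groups <- if (use_groups && !is.null(sim$cells$group)) {
    setNames(sim$cells$group, sim$cells$cell_id)
  } else NULL
  nb <- find_neighbors(sim$expression, k = k, groups = groups)
  fits <- purrr::map(kept, function(gid) {
    run_em(graphs[[gid]], sim$coverage[[gid]], neighbors = nb, cfg = cfg)
  })
  names(fits) <- kept
  psi <- purrr::map(fits, tidy) |> bind_rows()
  list(psi = psi, fits = fits, graphs = graphs, gene_filter = flt,
       neighbors = nb)
}

#' Run the full pipeline from files on disk
#'
#' File-level orchestration for counts-mode input (the simulator's native
#' layout, see [write_sim_dataset()]): reads the annotation, per-gene
#' coverage directories, expression matrix and optional group labels, runs
#' [quantify_dataset()], writes per-gene `psi.tsv`/`alpha.tsv`, graph node
#' and edge tables, a `filter_report.tsv` and (when groups are present) a
#' `diff_splice.tsv`, and returns a run manifest.
#'
#' @param input_dir Dataset directory (needs `annotation.gtf`,
#'   `coverage/<gene>/`, `expression.tsv`; optional `cells.tsv` with a
#'   `group` column).
#' @param output_dir Output directory (created).
#' @param cfg An [em_config()].
#' @param k,min_reads,min_cells See [quantify_dataset()].
#' @param diff Run the differential caller if two group labels are present
#'   (default `TRUE`).
#' @param seed Seed for the permutation null (default 42).
#' @return A manifest list: config, seed, per-gene status summary and the
#'   paths of every file written.
#' @export
run_pipeline <- function(input_dir, output_dir, cfg = em_config(), k = 100L,
                         min_reads = 5L, min_cells = 10L, diff = TRUE,
                         seed = 42L) {
  gtf <- file.path(input_dir, "annotation.gtf")
  if (!file.exists(gtf)) abort(paste0("stage build-graph: missing ", gtf))
  expr_f <- file.path(input_dir, "expression.tsv")
  if (!file.exists(expr_f)) abort(paste0("stage neighbors: missing ", expr_f))
  annotation <- read_annotation(gtf)
  cov_dirs <- list.dirs(file.path(input_dir, "coverage"), recursive = FALSE)
  coverage <- list()
  for (d in cov_dirs) {
    coverage[[basename(d)]] <- tryCatch(read_coverage_tsv(d),
      error = function(e) {
        warn(paste0("gene ", basename(d), " quarantined: ",
                    conditionMessage(e)))
        NULL
      })
  }
  coverage <- purrr::compact(coverage)
  expr_tbl <- readr::read_tsv(expr_f, show_col_types = FALSE)
  expression <- as.matrix(expr_tbl[, -1]); rownames(expression) <- expr_tbl[[1]]
  cells_f <- file.path(input_dir, "cells.tsv")
  cells <- if (file.exists(cells_f)) {
    readr::read_tsv(cells_f, show_col_types = FALSE)
  } else tibble(cell_id = rownames(expression))

  sim <- list(annotation = annotation, coverage = coverage,
              expression = expression, cells = cells)
  res <- quantify_dataset(sim, cfg = cfg, k = k,
                          use_groups = "group" %in% names(cells),
                          min_reads = min_reads, min_cells = min_cells)

  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (gid in names(res$fits)) {
    gd <- file.path(output_dir, "genes", gid)
    dir.create(gd, recursive = TRUE, showWarnings = FALSE)
    fit <- res$fits[[gid]]
    tidy(fit) |>
      pivot_wider(names_from = "cell_id", values_from = "psi") |>
      readr::write_tsv(file.path(gd, "psi.tsv"))
    fit$alpha |>
      mutate(converged = fit$converged, n_iter = fit$n_iter) |>
      readr::write_tsv(file.path(gd, "alpha.tsv"))
    gt <- graph_tables(res$graphs[[gid]])
    readr::write_tsv(gt$nodes, file.path(gd, "nodes.tsv"))
    readr::write_tsv(gt$edges, file.path(gd, "edges.tsv"))
    files <- c(files, file.path(gd, c("psi.tsv", "alpha.tsv", "nodes.tsv",
                                      "edges.tsv")))
  }
  readr::write_tsv(res$gene_filter, file.path(output_dir, "filter_report.tsv"))
  res$neighbors |>
    mutate(neighbors = purrr::map_chr(.data$neighbors, paste,
                                      collapse = ",")) |>
    readr::write_tsv(file.path(output_dir, "neighbors.tsv"))
  files <- c(files, file.path(output_dir, c("filter_report.tsv",
                                            "neighbors.tsv")))

  if (diff && "group" %in% names(cells) &&
      length(unique(cells$group)) == 2L && nrow(res$psi) > 0L) {
    calls <- diff_splicing(res$psi, cells |> select("cell_id", "group"),
                           seed = seed)
    readr::write_tsv(as_tibble(calls), file.path(output_dir, "diff_splice.tsv"))
    files <- c(files, file.path(output_dir, "diff_splice.tsv"))
  }

  manifest <- list(
    config = unclass(cfg), seed = seed, k = k,
    min_reads = min_reads, min_cells = min_cells,
    genes = res$gene_filter,
    files = tibble(path = files,
                   md5 = unname(tools::md5sum(files)))
  )
  manifest
}
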