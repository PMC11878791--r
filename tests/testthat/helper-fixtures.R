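# Shared fixtures, all built in code.

library(dplyr)
library(tibble)

# Gene with five exons and three transcripts; E4 and E5 are alternative last
# exons, E2 is a cassette exon and E1>E3 a skipping junction.
toy_gene <- function() {
  read_annotation(system.file("extdata", "toy.gtf", package = "psiflow"))
}

toy_graph <- function() build_splice_graph(toy_gene())

# Four-exon gene where one transcript skips E3, so the junction E2>E4 spans
# the cross section at E3 (and only that one).
skip_gene <- function() {
  ex <- tribble(
    ~transcript_id, ~start, ~end,
    "t1", 101, 200, "t1", 301, 400, "t1", 501, 600, "t1", 701, 800,
    "t2", 101, 200, "t2", 301, 400, "t2", 701, 800
  )
  ex |> mutate(gene_id = "SKIP1", chrom = "chr1", strand = "+",
               exon_rank = NA_integer_)
}

skip_graph <- function() build_splice_graph(skip_gene())

# coverage_table from per-element named vectors replicated across cells
cov_from_vectors <- function(graph, exon_depth, junc_count, cells = 20,
                             lowq = NULL) {
  real <- graph$nodes |> filter(!is_source, !is_sink)
  keys <- paste0(real$start, "-", real$end)
  e <- matrix(rep(exon_depth[real$node_id], each = cells), nrow = cells,
              dimnames = list(sprintf("c%02d", seq_len(cells)), keys))
  ed <- graph$edges |> filter(!touches_terminal)
  j <- matrix(rep(junc_count[ed$edge_id], each = cells), nrow = cells,
              dimnames = list(rownames(e), ed$key))
  if (is.null(lowq)) lowq <- setNames(numeric(cells), rownames(e))
  coverage_table(graph$gene_id, e, j, lowq)
}

# stacked weighted design built naively and independently of the package
# internals: loops over tibbles, no shared code with em_elements()
brute_design <- function(graph, cov, cell, alpha, prior = NULL,
                         cfg = em_config()) {
  nodes <- graph$nodes |> arrange(rank)
  edges <- graph$edges
  ids <- c(nodes$node_id, edges$edge_id)
  p <- length(ids)
  rows <- list(); ys <- c()
  add <- function(coef, y) {
    rows[[length(rows) + 1]] <<- coef
    ys <<- c(ys, y)
  }
  unit <- function(id, w = 1) { v <- numeric(p); v[match(id, ids)] <- w; v }
  # coverage rows
  for (i in seq_len(nrow(nodes))) {
    n <- nodes[i, ]
    if (n$is_source || n$is_sink) next
    key <- paste0(n$start, "-", n$end)
    a <- if (key %in% colnames(cov$exon_cov)) cov$exon_cov[cell, key] else 0
    add(unit(n$node_id), a / alpha[1])
  }
  for (i in seq_len(nrow(edges))) {
    e <- edges[i, ]
    if (e$touches_terminal) next
    if (e$is_containment && !(e$key %in% colnames(cov$junction_count))) next
    a <- if (!is.na(e$key) && e$key %in% colnames(cov$junction_count)) {
      cov$junction_count[cell, e$key]
    } else 0
    add(unit(e$edge_id), a / alpha[2])
  }
  # flow rows
  for (i in seq_len(nrow(nodes))) {
    n <- nodes[i, ]
    if (!n$is_source) {
      v <- unit(n$node_id)
      for (eid in edges$edge_id[edges$to == n$node_id]) v <- v - unit(eid)
      add(cfg$w_flow * v, 0)
    }
    if (!n$is_sink) {
      v <- unit(n$node_id)
      for (eid in edges$edge_id[edges$from == n$node_id]) v <- v - unit(eid)
      add(cfg$w_flow * v, 0)
    }
  }
  add(unit("source", cfg$w_ss), cfg$w_ss)
  add(unit("sink", cfg$w_ss), cfg$w_ss)
  if (!is.null(prior)) {
    for (id in ids) add(unit(id, cfg$w_sim), cfg$w_sim * prior[[id]])
  }
  list(A = do.call(rbind, rows), y = ys, ids = ids)
}

# tiny noise-free dataset: deterministic coverage, perfect junction detection
noiseless_sim <- function(n_genes = 3, n_cells = 12, seed = 5,
                          dataset = "allAnnot") {
  simulate_dataset(dataset, seed = seed, n_genes = n_genes,
                   n_cells_per_type = n_cells, cov_dispersion = 0,
                   junction_efficiency = 1, novel_site_efficiency = 1,
                   short_exon_factor = 1, lowq_contam_frac = 0,
                   poisson_junctions = FALSE,
                   cell_factor_sdlog = 0, gene_depth_meanlog = log(60),
                   gene_depth_sdlog = 0)
}
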