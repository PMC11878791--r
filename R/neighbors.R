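#' Find expression-similar neighbor cells
#'
#' Identifies, for each cell, the `k` most similar cells by gene expression.
#' The expression matrix is library-size normalized to counts per 10k,
#' log1p-transformed, gene-scaled, projected on the top principal
#' components, and neighbors are the `k` nearest cells by Euclidean distance
#' in that space (exact search). When group labels are given, candidate
#' neighbors are restricted to the cell's own group before taking the `k`
#' nearest — useful when a rare population would otherwise borrow splicing
#' information from a dominant one. Principal-component signs are fixed by
#' the largest-loading rule and distance ties are broken by cell id, so the
#' result is deterministic.
#'
#' @param expression Numeric matrix, cells in rows, genes in columns (raw
#'   counts or depth-like values), or a tibble with a `cell_id` first column.
#' @param k Number of neighbors (default 100). If fewer candidates exist,
#'   all of them are returned (with a warning when `k` is at least the
#'   number of cells).
#' @param groups Optional grouping: named character vector (names = cell
#'   ids) or tibble with `cell_id` and `group` columns.
#' @param n_pcs Number of principal components (default 20, capped by the
#'   matrix rank).
#' @return Tibble with `cell_id`, `group` and a `neighbors` list-column of
#'   ordered neighbor id vectors (nearest first; the cell itself excluded).
#' @export
find_neighbors <- function(expression, k = 100L, groups = NULL, n_pcs = 20L) {
  if (is.data.frame(expression)) {
    m <- as.matrix(expression[, -1, drop = FALSE])
    rownames(m) <- expression[[1]]
    expression <- m
  }
  stopifnot(nrow(expression) >= 2L, k >= 1L)
  cells <- rownames(expression)
  if (is.null(cells)) abort("expression matrix must have cell-id rownames")
  if (k >= nrow(expression)) {
    warn("k is not below the number of cells; returning all candidates")
  }
  if (is.data.frame(groups)) groups <- setNames(groups$group, groups$cell_id)

  lib <- rowSums(expression)
  lib[lib == 0] <- 1
  x <- log1p(sweep(expression, 1, lib, "/") * 1e4)
  sds <- apply(x, 2, sd)
  sds[sds == 0] <- 1      # constant genes carry no information
  x <- sweep(sweep(x, 2, colMeans(x)), 2, sds, "/")
  n_pcs <- min(n_pcs, nrow(x) - 1L, ncol(x))
  pc <- prcomp(x, center = FALSE, scale. = FALSE, rank. = n_pcs)
  # deterministic sign: largest-magnitude loading positive
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  emb <- sweep(pc$x, 2, flip, "*")

  d <- as.matrix(stats::dist(emb))
  res <- purrr::map(seq_along(cells), function(i) {
    cand <- setdiff(cells, cells[i])
    if (!is.null(groups)) {
      cand <- cand[groups[cand] == groups[[cells[i]]]]
    }
    if (length(cand) == 0L) return(character())
    dd <- d[cells[i], cand]
    cand[order(dd, cand)][seq_len(min(k, length(cand)))]
  })
  tibble(cell_id = cells,
         group = if (is.null(groups)) NA_character_ else unname(groups[cells]),
         neighbors = res)
}
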