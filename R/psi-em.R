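#' Configuration for the PSI estimation scheme
#'
#' Weights are relative to the observed-coverage equations, whose weight is
#' fixed to 1. PSI values are fractions in `[0, 1]` internally; the
#' convergence threshold `tol = 1e-4` corresponds to 0.01 percentage points.
#'
#' @param w_flow Weight of the conservation-of-flow equations (default 6).
#' @param w_ss Weight of the source/sink pinning equations (default 1).
#' @param w_sim Weight of the neighbor-similarity equations (default 4).
#' @param tol Convergence threshold on the maximum absolute PSI change
#'   between iterations (default `1e-4`).
#' @param alpha_tol Additional convergence requirement on the relative change
#'   of the coverage scalars (default `1e-4`), guarding against alpha
#'   oscillation.
#' @param max_iter Maximum number of EM iterations (default 100).
#' @param init_fraction Fraction of the longest annotated transcript length
#'   that the highest-covered exons must reach for alpha initialization
#'   (default 0.10).
#' @param psi_cap Upper clip applied to PSI values before the intermediate
#'   rescale (default 1.5); final output is clipped to `[0, 1]`.
#' @return An `em_config` list.
#' @export
em_config <- function(w_flow = 6, w_ss = 1, w_sim = 4, tol = 1e-4,
                      alpha_tol = 1e-4, max_iter = 100L,
                      init_fraction = 0.10, psi_cap = 1.5) {
  stopifnot(w_flow > 0, w_ss > 0, w_sim >= 0, tol > 0, tol < 1,
            max_iter >= 1, init_fraction > 0, psi_cap >= 1)
  structure(list(w_flow = w_flow, w_ss = w_ss, w_sim = w_sim, tol = tol,
                 alpha_tol = alpha_tol, max_iter = as.integer(max_iter),
                 init_fraction = init_fraction, psi_cap = psi_cap),
            class = "em_config")
}

# Static per-gene description of the estimation problem: element order,
# observation matrices, design blocks, cross sections.
em_elements <- function(graph, cov) {
  nodes <- graph$nodes |> arrange(.data$rank)
  edges <- graph$edges
  ids <- c(nodes$node_id, edges$edge_id)
  p <- length(ids)
  idx <- setNames(seq_len(p), ids)
  real <- nodes |> filter(!.data$is_source, !.data$is_sink)

  exon_keys <- paste0(real$start, "-", real$end)
  a_exon <- matrix(0, nrow(cov$exon_cov), nrow(real),
                   dimnames = list(rownames(cov$exon_cov), real$node_id))
  hit <- exon_keys %in% colnames(cov$exon_cov)
  a_exon[, hit] <- cov$exon_cov[, exon_keys[hit], drop = FALSE]

  # containment edges are only observable when contiguous reads over the
  # internal boundary were actually counted
  obs_e <- edges |>
    filter(!.data$touches_terminal,
           !.data$is_containment | .data$key %in% colnames(cov$junction_count))
  a_junc <- matrix(0, nrow(cov$junction_count), nrow(obs_e),
                   dimnames = list(rownames(cov$junction_count), obs_e$edge_id))
  hit <- obs_e$key %in% colnames(cov$junction_count)
  a_junc[, hit] <- cov$junction_count[, obs_e$key[hit], drop = FALSE]

  # design blocks -----------------------------------------------------------
  unit_rows <- function(cols) {
    m <- matrix(0, length(cols), p)
    m[cbind(seq_along(cols), idx[cols])] <- 1
    m
  }
  A_cov <- unit_rows(c(real$node_id, obs_e$edge_id))

  flow_in <- nodes |> filter(!.data$is_source)
  A_fin <- matrix(0, nrow(flow_in), p)
  for (i in seq_len(nrow(flow_in))) {
    A_fin[i, idx[flow_in$node_id[i]]] <- 1
    inc <- edges$edge_id[edges$to == flow_in$node_id[i]]
    A_fin[i, idx[inc]] <- -1
  }
  flow_out <- nodes |> filter(!.data$is_sink)
  A_fout <- matrix(0, nrow(flow_out), p)
  for (i in seq_len(nrow(flow_out))) {
    A_fout[i, idx[flow_out$node_id[i]]] <- 1
    out <- edges$edge_id[edges$from == flow_out$node_id[i]]
    A_fout[i, idx[out]] <- -1
  }
  A_ss <- unit_rows(c("source", "sink"))

  sections <- purrr::map(cross_sections(graph), function(s) unname(idx[s]))

  list(
    ids = ids, p = p, idx = idx,
    n_exon = nrow(real), n_junc = nrow(obs_e),
    exon_ids = real$node_id, junc_ids = obs_e$edge_id,
    exon_len = real$length,
    a_exon = a_exon, a_junc = a_junc,
    A_cov = A_cov, A_flow = rbind(A_fin, A_fout), A_ss = A_ss,
    sections = sections,
    element_meta = bind_rows(
      nodes |> transmute(element_id = .data$node_id,
                         type = "exon", .data$is_novel,
                         length = .data$length,
                         reported = !.data$is_source & !.data$is_sink),
      edges |> transmute(element_id = .data$edge_id,
                         type = "junction", .data$is_novel,
                         length = NA_integer_,
                         reported = !.data$is_containment)
    )
  )
}

weighted_design <- function(el, cfg, with_sim) {
  A <- rbind(el$A_cov,
             cfg$w_flow * el$A_flow,
             cfg$w_ss * el$A_ss)
  if (with_sim) A <- rbind(A, cfg$w_sim * diag(el$p))
  A
}

# right-hand sides for a block of cells: columns are cells
design_rhs <- function(el, cfg, alpha_E, alpha_J, priors = NULL) {
  n_cov <- el$n_exon + el$n_junc
  cells <- length(alpha_E)
  y_cov <- rbind(t(el$a_exon) / rep(alpha_E, each = el$n_exon),
                 if (el$n_junc > 0)
                   t(el$a_junc) / rep(alpha_J, each = el$n_junc))
  if (is.null(y_cov)) y_cov <- matrix(0, 0, cells)
  y <- rbind(y_cov,
             matrix(0, nrow(el$A_flow), cells),
             matrix(cfg$w_ss, 2, cells))
  if (!is.null(priors)) y <- rbind(y, cfg$w_sim * priors)
  y
}

# Solve the stacked WLS for a block of cells sharing one design. Negative
# solutions are re-solved with non-negativity enforced (active set NNLS).
solve_block <- function(A, Y) {
  M <- crossprod(A)
  R <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(R)) {
    abort("singular expectation system (isolated subgraph?)")
  }
  X <- backsolve(R, backsolve(R, crossprod(A, Y), transpose = TRUE))
  bad <- which(apply(X, 2, min) < -1e-8)
  for (c in bad) X[, c] <- nnls_solve(A, Y[, c])
  pmax(X, 0)
}

#' Initialize the per-cell gene-coverage scalar
#'
#' For each cell, exons are sorted by observed coverage (descending) and a
#' minimal prefix is taken whose combined lengths reach `init_fraction`
#' (default 10%) of the longest annotated transcript length. The initial
#' alpha (used for both the exon and the junction scalar) is the
#' length-weighted mean coverage of that prefix. Using several exons
#' prevents an extreme initial value caused by one short, highly covered
#' exon. Coverage ties are broken by exon id for determinism.
#'
#' @param cov A [coverage_table()].
#' @param graph The gene's `splice_graph`.
#' @param cfg An [em_config()].
#' @return A tibble with `cell_id`, `alpha_E`, `alpha_J` (equal at
#'   initialization; 0 for cells with no coverage).
#' @export
initialize_alpha <- function(cov, graph, cfg = em_config()) {
  el <- em_elements(graph, cov)
  target <- cfg$init_fraction * max(graph$transcript_lengths)
  a <- el$a_exon
  len <- el$exon_len
  ord_base <- order(el$exon_ids)   # deterministic tie-break
  alpha <- purrr::map_dbl(seq_len(nrow(a)), function(c) {
    o <- ord_base[order(-a[c, ord_base])]
    csum <- cumsum(len[o])
    take <- o[seq_len(which(csum >= min(target, sum(len)))[1])]
    sum(len[take] * a[c, take]) / sum(len[take])
  })
  tibble(cell_id = rownames(a), alpha_E = alpha, alpha_J = alpha)
}

#' One expectation step for a single cell
#'
#' Solves the stacked weighted-least-squares system for one cell: coverage
#' equations (weight 1) for observable elements, flow-conservation equations
#' (weight `w_flow`, one-sided at source/sink), source/sink pinning (weight
#' `w_ss`) and, when `prior` is given, neighbor-similarity equations (weight
#' `w_sim`). The solution is constrained to be non-negative.
#'
#' @param graph The gene's `splice_graph`.
#' @param cov A [coverage_table()].
#' @param cell Cell id (must be a row of the coverage matrices).
#' @param alpha Numeric of length 2, `c(alpha_E, alpha_J)`, both `> 0`.
#' @param prior Optional named numeric vector of neighbor-averaged PSI values
#'   for every element (the previous iteration's estimate, Eq.-(5)-style);
#'   `NULL` omits the similarity equations.
#' @param cfg An [em_config()].
#' @return Named numeric vector of PSI values for every element
#'   (exons incl. source/sink, then edges).
#' @export
expectation_step <- function(graph, cov, cell, alpha, prior = NULL,
                             cfg = em_config()) {
  stopifnot(all(alpha > 0))
  el <- em_elements(graph, cov)
  keep <- rownames(cov$exon_cov) == cell
  if (!any(keep)) abort(paste0("unknown cell: ", cell))
  el$a_exon <- el$a_exon[keep, , drop = FALSE]
  el$a_junc <- el$a_junc[keep, , drop = FALSE]
  with_sim <- !is.null(prior)
  A <- weighted_design(el, cfg, with_sim)
  if (with_sim && !is.null(names(prior))) prior <- prior[el$ids]
  P <- if (with_sim) matrix(prior, ncol = 1) else NULL
  Y <- design_rhs(el, cfg, alpha[1], alpha[2], P)
  x <- drop(solve_block(A, Y))
  setNames(x, el$ids)
}

#' Rescale PSI values so cross-section sums average to one
#'
#' Between the expectation and maximization steps, PSI values are divided by
#' the mean over observable exons of their cross-section sums. This imposes
#' global conservation of flow (average cross-section PSI equal to 100%) and
#' prevents a systematic drift where undershooting PSI values inflate alpha,
#' which would depress the next iteration's PSI values further.
#'
#' @param psi Named numeric vector over graph elements.
#' @param sections Cross sections as returned by [cross_sections()] (element
#'   ids, or integer indices into `psi`).
#' @return The rescaled vector; all-`NA` when the mean cross-section sum is
#'   zero (degenerate cell, to be masked by the caller).
#' @export
intermediate_rescale <- function(psi, sections) {
  m <- mean(purrr::map_dbl(sections, function(s) sum(psi[s])))
  if (!is.finite(m) || m <= 0) return(psi * NA_real_)
  psi / m
}

#' Closed-form maximization of the coverage scalars
#'
#' Given PSI values, the expected coverage of element `i` is
#' `psi_i * alpha`. The exon scalar minimizes the length-weighted squared
#' error `sum_e l_e (a_e - psi_e alpha_E)^2` and the junction scalar the
#' unweighted `sum_j (a_j - psi_j alpha_J)^2`, giving
#' `alpha_E = sum(l a psi) / sum(l psi^2)` over observable exons and
#' `alpha_J = sum(a psi) / sum(psi^2)` over observable junctions.
#'
#' @inheritParams expectation_step
#' @param psi Named numeric vector over graph elements (as returned by
#'   [expectation_step()]).
#' @return Numeric of length 2: `c(alpha_E, alpha_J)`. `NA` when all PSI
#'   values of the corresponding class are zero.
#' @export
maximization_step <- function(psi, graph, cov, cell) {
  el <- em_elements(graph, cov)
  row <- which(rownames(cov$exon_cov) == cell)
  pe <- psi[el$exon_ids]; ae <- el$a_exon[row, ]
  pj <- psi[el$junc_ids]; aj <- el$a_junc[row, ]
  den_e <- sum(el$exon_len * pe^2)
  den_j <- sum(pj^2)
  c(alpha_E = if (den_e > 0) sum(el$exon_len * ae * pe) / den_e else NA_real_,
    alpha_J = if (den_j > 0) sum(aj * pj) / den_j else NA_real_)
}

# column-normalized neighbor weight matrix over the kept cells of one gene;
# weights are the neighbors' alpha_E. Columns summing to zero mean the cell
# has no usable neighbor and falls back to the no-similarity design.
neighbor_weights <- function(cells, neighbors, alpha_E) {
  W <- matrix(0, length(cells), length(cells),
              dimnames = list(cells, cells))
  if (is.null(neighbors)) return(W)
  for (c in cells) {
    nb <- intersect(neighbors[[c]] %||% character(), cells)
    W[nb, c] <- alpha_E[nb]
  }
  cs <- colSums(W)
  ok <- cs > 0
  W[, ok] <- sweep(W[, ok, drop = FALSE], 2, cs[ok], "/")
  W
}

#' Estimate PSI values for one gene across all cells
#'
#' Runs the iterative estimation scheme: per cell, an expectation step (WLS
#' over coverage, flow and similarity equations), an intermediate
#' cross-section rescale, and a closed-form maximization of the coverage
#' scalars, until the largest PSI change over all cells and elements falls
#' below `cfg$tol` (and the relative alpha change below `cfg$alpha_tol`), or
#' `cfg$max_iter` is reached. The first iteration has no previous estimate,
#' so similarity equations are switched on from the second iteration onward.
#' Cells are processed independently within an iteration; results do not
#' depend on cell order.
#'
#' @param graph The gene's (extended, simplified) `splice_graph`.
#' @param cov A [coverage_table()] for the gene.
#' @param neighbors Neighbor sets from [find_neighbors()] (tibble or named
#'   list), or `NULL` to disable the similarity constraint.
#' @param cfg An [em_config()].
#' @param keep Optional logical vector (named by cell) of cells to estimate;
#'   by default [filter_cells()] is applied.
#' @return A `psi_fit` object: list with `gene_id`, `psi` (cells x elements
#'   matrix, `NA` rows for masked cells), `alpha` tibble (`cell_id`,
#'   `alpha_E`, `alpha_J`, `kept`), `elements` metadata tibble, `converged`
#'   flag and `n_iter`. See [tidy.psi_fit()].
#' @export
run_em <- function(graph, cov, neighbors = NULL, cfg = em_config(),
                   keep = NULL) {
  el <- em_elements(graph, cov)
  cells <- rownames(cov$exon_cov)
  init <- initialize_alpha(cov, graph, cfg)
  if (is.null(keep)) {
    keep <- setNames(filter_cells(cov, init)$kept, init$cell_id)
  }
  if (is.null(names(keep))) names(keep) <- cells
  neighbors <- as_neighbor_list(neighbors)

  kept <- cells[keep[cells]]
  out_psi <- matrix(NA_real_, length(cells), el$p,
                    dimnames = list(cells, el$ids))
  alpha_tbl <- tibble(cell_id = cells,
                      alpha_E = init$alpha_E[match(cells, init$cell_id)],
                      alpha_J = init$alpha_J[match(cells, init$cell_id)],
                      kept = unname(keep[cells]))
  fit <- structure(list(gene_id = graph$gene_id, psi = out_psi,
                        alpha = alpha_tbl, elements = el$element_meta,
                        converged = TRUE, n_iter = 0L),
                   class = "psi_fit")
  if (length(kept) == 0L) return(fit)

  aE <- setNames(alpha_tbl$alpha_E[match(kept, alpha_tbl$cell_id)], kept)
  aJ <- setNames(alpha_tbl$alpha_J[match(kept, alpha_tbl$cell_id)], kept)
  sub <- function(m) m[kept, , drop = FALSE]
  el$a_exon <- sub(el$a_exon); el$a_junc <- sub(el$a_junc)

  A_nosim <- weighted_design(el, cfg, with_sim = FALSE)
  A_sim <- weighted_design(el, cfg, with_sim = TRUE)

  psi <- NULL
  converged <- FALSE
  iter <- 0L
  while (iter < cfg$max_iter) {
    iter <- iter + 1L
    if (is.null(psi) || is.null(neighbors) || cfg$w_sim == 0) {
      priors <- NULL
      has_prior <- rep(FALSE, length(kept))
    } else {
      W <- neighbor_weights(kept, neighbors, aE)
      has_prior <- colSums(W) > 0
      priors <- psi %*% W
    }
    new_psi <- matrix(0, el$p, length(kept),
                      dimnames = list(el$ids, kept))
    sel <- function(m, j) m[, j, drop = FALSE]
    if (any(!has_prior)) {
      Y <- design_rhs(el_cells(el, !has_prior), cfg,
                      aE[!has_prior], aJ[!has_prior])
      new_psi[, !has_prior] <- solve_block(A_nosim, Y)
    }
    if (any(has_prior)) {
      Y <- design_rhs(el_cells(el, has_prior), cfg,
                      aE[has_prior], aJ[has_prior],
                      sel(priors, has_prior))
      new_psi[, has_prior] <- solve_block(A_sim, Y)
    }
    new_psi <- pmin(new_psi, cfg$psi_cap)

    # intermediate: global flow via cross-section average
    sec_sum <- matrix(0, length(el$sections), length(kept))
    for (s in seq_along(el$sections)) {
      sec_sum[s, ] <- colSums(new_psi[el$sections[[s]], , drop = FALSE])
    }
    scale <- colMeans(sec_sum)
    degenerate <- !is.finite(scale) | scale <= 0
    new_psi <- sweep(new_psi, 2, ifelse(degenerate, NA_real_, scale), "/")

    # maximization: closed-form alpha per cell
    pe <- new_psi[el$idx[el$exon_ids], , drop = FALSE]
    den_e <- colSums(el$exon_len * pe^2)
    num_e <- colSums(el$exon_len * t(el$a_exon) * pe)
    new_aE <- ifelse(den_e > 0, num_e / den_e, aE)
    if (el$n_junc > 0) {
      pj <- new_psi[el$idx[el$junc_ids], , drop = FALSE]
      den_j <- colSums(pj^2)
      new_aJ <- ifelse(den_j > 0, colSums(t(el$a_junc) * pj) / den_j, aJ)
    } else new_aJ <- aJ

    if (any(degenerate)) {
      drop_cells <- kept[degenerate]
      alpha_tbl$kept[alpha_tbl$cell_id %in% drop_cells] <- FALSE
      kept <- kept[!degenerate]
      if (length(kept) == 0L) {
        fit$alpha <- alpha_tbl
        fit$n_iter <- iter
        return(fit)
      }
      el$a_exon <- el$a_exon[!degenerate, , drop = FALSE]
      el$a_junc <- el$a_junc[!degenerate, , drop = FALSE]
      new_psi <- new_psi[, !degenerate, drop = FALSE]
      if (!is.null(psi)) psi <- psi[, !degenerate, drop = FALSE]
      new_aE <- new_aE[!degenerate]; new_aJ <- new_aJ[!degenerate]
      aE <- aE[!degenerate]; aJ <- aJ[!degenerate]
    }

    dpsi <- if (is.null(psi)) Inf else max(abs(new_psi - psi))
    dalpha <- max(abs(new_aE - aE) / pmax(aE, 1e-12),
                  abs(new_aJ - aJ) / pmax(aJ, 1e-12))
    psi <- new_psi
    aE <- setNames(new_aE, kept); aJ <- setNames(new_aJ, kept)
    if (dpsi < cfg$tol && dalpha < cfg$alpha_tol) { converged <- TRUE; break }
  }

  # final masking: cells whose converged alpha_E dropped below the
  # expression filter are not reported
  final_keep <- aE >= 10
  alpha_tbl$alpha_E[match(kept, alpha_tbl$cell_id)] <- unname(aE)
  alpha_tbl$alpha_J[match(kept, alpha_tbl$cell_id)] <- unname(aJ)
  alpha_tbl$kept[match(kept, alpha_tbl$cell_id)] <- unname(final_keep)
  good <- kept[final_keep]
  out_psi[good, ] <- t(pmin(pmax(psi[, final_keep, drop = FALSE], 0), 1))

  fit$psi <- out_psi
  fit$alpha <- alpha_tbl
  fit$converged <- converged
  fit$n_iter <- iter
  fit
}

# subset the observation matrices of an element description to a cell mask
el_cells <- function(el, mask) {
  el$a_exon <- el$a_exon[mask, , drop = FALSE]
  el$a_junc <- el$a_junc[mask, , drop = FALSE]
  el
}

as_neighbor_list <- function(neighbors) {
  if (is.null(neighbors)) return(NULL)
  if (is.data.frame(neighbors)) {
    return(setNames(neighbors$neighbors, neighbors$cell_id))
  }
  neighbors
}

#' @export
print.psi_fit <- function(x, ...) {
  cat("<psi_fit> ", x$gene_id, ": ", sum(x$alpha$kept), "/",
      nrow(x$alpha), " cells, ", ncol(x$psi), " elements, ",
      x$n_iter, " iterations (",
      if (x$converged) "converged" else "not converged", ")\n", sep = "")
  invisible(x)
}

#' Tidy a PSI fit into a long tibble
#'
#' @param x A `psi_fit` from [run_em()].
#' @param all_elements Keep source/sink nodes and containment edges too
#'   (default `FALSE`: only reportable exons and splice junctions).
#' @param ... Unused.
#' @return Tibble with `gene_id`, `element_id`, `type`, `is_novel`,
#'   `cell_id`, `psi` (`NA` for masked cells).
#' @exportS3Method generics::tidy
tidy.psi_fit <- function(x, all_elements = FALSE, ...) {
  meta <- x$elements
  if (!all_elements) meta <- meta |> filter(.data$reported)
  as_tibble(x$psi, rownames = "cell_id") |>
    pivot_longer(-"cell_id", names_to = "element_id", values_to = "psi") |>
    inner_join(meta |> select("element_id", "type", "is_novel"),
               by = "element_id") |>
    mutate(gene_id = x$gene_id) |>
    select("gene_id", "element_id", "type", "is_novel", "cell_id", "psi")
}

#' One-row summary of a PSI fit
#'
#' @param x A `psi_fit`.
#' @param ... Unused.
#' @return Tibble with gene id, cell counts, iteration count, convergence
#'   flag and median coverage scalars over kept cells.
#' @exportS3Method generics::glance
glance.psi_fit <- function(x, ...) {
  kept <- x$alpha |> filter(.data$kept)
  tibble(gene_id = x$gene_id,
         n_cells = nrow(x$alpha),
         n_kept = nrow(kept),
         n_elements = ncol(x$psi),
         n_iter = x$n_iter,
         converged = x$converged,
         median_alpha_E = median(kept$alpha_E),
         median_alpha_J = median(kept$alpha_J))
}

#' Plot a PSI fit as an element-by-cell heat map
#'
#' @param object A `psi_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.psi_fit <- function(object, ...) {
  d <- tidy.psi_fit(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cell_id, y = .data$element_id,
                                  fill = .data$psi)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey85") +
    ggplot2::labs(title = object$gene_id, x = "cell", y = NULL,
                  fill = "PSI") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
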