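#' Simulation configuration
#'
#' Defines the synthetic study: two homogeneous cell types of
#' `n_cells_per_type` cells each, expressing `n_genes` genes with three
#' annotated transcripts per gene, half of the genes differentially spliced
#' between the types. Depending on `novel`, each gene carries an extra
#' transcript with an unannotated skipping junction (`"junction"`), an
#' unannotated intronic exon with its two flanking junctions (`"exon"`), or
#' both extra transcripts (`"both"`). Novel elements are withheld from the
#' emitted annotation and must be rediscovered from the coverage evidence.
#'
#' Coverage is generated at the observation level rather than via raw reads:
#' mean exon depth is `depth * PSI` with multiplicative gamma noise and a
#' mapping-loss factor for short exons, junction counts are Poisson with
#' mean `depth * PSI * junction_efficiency` (the efficiency emulates the
#' read-overhang losses of splice-aware alignment).
#'
#' @param n_genes Number of genes (default 100).
#' @param n_cells_per_type Cells per type (default 100).
#' @param novel One of `"none"`, `"junction"`, `"exon"`, `"both"`.
#' @param frac_diff Fraction of genes with type-specific transcript
#'   proportions (default 0.5).
#' @param n_exons_range Range of exon counts per gene (default 4 to 8).
#' @param exon_len_meanlog,exon_len_sdlog,min_exon_len Log-normal exon
#'   length law (median ~150 bp, floor 25 bp).
#' @param intron_len_range Uniform intron length range in bp.
#' @param gene_depth_meanlog,gene_depth_sdlog Log-normal law of the per-gene
#'   base coverage (median 30x).
#' @param cell_factor_sdlog Spread of the cell-intrinsic depth scalar
#'   (cell size / library depth; log-normal, median 1).
#' @param cov_dispersion Coefficient of variation of the multiplicative
#'   gamma coverage noise (default 0.15).
#' @param junction_efficiency Detection efficiency in (0, 1] for junctions
#'   whose donor and acceptor are both annotated exon boundaries (default
#'   0.9; a skipping junction between two annotated exons is such a
#'   junction, even when the combination is unannotated).
#' @param novel_site_efficiency Detection efficiency for junctions with an
#'   unannotated splice site, i.e. the flanking junctions of an unannotated
#'   exon (default 0.45). Splice-aware aligners demand larger overhangs and
#'   more supporting reads at splice sites missing from their index, so
#'   these junctions are recovered far less efficiently than novel
#'   combinations of known sites.
#' @param short_exon_len,short_exon_factor Exons shorter than
#'   `short_exon_len` bp have their observed coverage shrunk by
#'   `short_exon_factor`, emulating the mapping loss on short exons.
#' @param poisson_junctions Draw junction counts from a Poisson law
#'   (default `TRUE`); `FALSE` emits the expected counts directly, giving a
#'   fully noise-free dataset when `cov_dispersion = 0`.
#' @param lowq_contam_frac Fraction of cells with a high low-MAPQ read
#'   fraction (drawn in 0.12-0.30; other cells are clean).
#' @param expr_type_frac,expr_type_fold Fraction of genes whose expression
#'   differs between the types, and the fold change applied, so that
#'   expression-based neighbor finding can separate the types.
#' @param dirichlet_alpha Concentration of the symmetric Dirichlet from
#'   which transcript proportions are drawn (default 1, i.e. uniform on the
#'   simplex).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 100L, n_cells_per_type = 100L,
                       novel = c("none", "junction", "exon", "both"),
                       frac_diff = 0.5,
                       n_exons_range = c(4L, 8L),
                       exon_len_meanlog = log(150), exon_len_sdlog = 0.45,
                       min_exon_len = 25L,
                       intron_len_range = c(300L, 2000L),
                       gene_depth_meanlog = log(30), gene_depth_sdlog = 0.7,
                       cell_factor_sdlog = 0.5,
                       cov_dispersion = 0.15,
                       junction_efficiency = 0.9,
                       novel_site_efficiency = 0.45,
                       short_exon_len = 50L, short_exon_factor = 0.5,
                       poisson_junctions = TRUE,
                       lowq_contam_frac = 0.02,
                       expr_type_frac = 0.3, expr_type_fold = 2,
                       dirichlet_alpha = 1) {
  novel <- match.arg(novel)
  stopifnot(n_genes >= 1, n_cells_per_type >= 1,
            frac_diff >= 0, frac_diff <= 1,
            cov_dispersion >= 0, junction_efficiency > 0,
            junction_efficiency <= 1, novel_site_efficiency > 0,
            novel_site_efficiency <= 1, lowq_contam_frac >= 0,
            lowq_contam_frac <= 1)
  structure(as.list(environment()), class = "sim_config")
}

rdirichlet1 <- function(k, alpha) {
  x <- rgamma(k, shape = alpha)
  x / sum(x)
}

sim_gene_id <- function(i) sprintf("G%03d", i)

# one gene's structure: exon table, transcript exon-index paths, novel labels
simulate_one_gene <- function(gene_id, cfg) {
  n <- sample(seq(cfg$n_exons_range[1], cfg$n_exons_range[2]), 1L)
  len <- pmax(cfg$min_exon_len,
              round(rlnorm(n, cfg$exon_len_meanlog, cfg$exon_len_sdlog)))
  gaps <- sample(seq(cfg$intron_len_range[1], cfg$intron_len_range[2]),
                 n - 1L, replace = TRUE)
  start <- cumsum(c(1001L, head(len, -1) + gaps))
  exons <- tibble(exon = seq_len(n), start = start,
                  end = start + len - 1L, length = len, is_novel = FALSE)

  internal <- 2:(n - 1)
  sk <- sample(internal, min(2L, length(internal)))
  if (length(sk) == 1L) sk <- c(sk, sk)
  tx <- list(t1 = seq_len(n),
             t2 = setdiff(seq_len(n), sk[1]),
             t3 = setdiff(seq_len(n), sk[2]))
  annot_pairs <- unique(do.call(rbind, purrr::map(tx, function(p) {
    cbind(head(p, -1), tail(p, -1))
  })))

  novel_junction <- NULL
  if (cfg$novel %in% c("junction", "both")) {
    cand <- expand.grid(i = seq_len(n - 2L), j = seq_len(n))
    cand <- cand[cand$j >= cand$i + 2L, , drop = FALSE]
    in_annot <- paste(cand$i, cand$j) %in% paste(annot_pairs[, 1], annot_pairs[, 2])
    cand <- cand[!in_annot, , drop = FALSE]
    pick <- cand[sample(nrow(cand), 1L), ]
    path <- c(seq_len(pick$i), seq(pick$j, n))
    tx$t_novelJ <- path
    novel_junction <- c(pick$i, pick$j)
  }

  novel_exon <- NULL
  if (cfg$novel %in% c("exon", "both")) {
    i <- sample(seq_len(n - 1L), 1L)
    gap_start <- exons$end[i] + 1L
    gap_end <- exons$start[i + 1L] - 1L
    avail <- gap_end - gap_start + 1L - 40L   # 20 bp margins
    elen <- max(cfg$min_exon_len,
                min(avail, round(rlnorm(1, cfg$exon_len_meanlog,
                                        cfg$exon_len_sdlog))))
    s <- gap_start + 20L
    exons <- bind_rows(exons,
                       tibble(exon = n + 1L, start = s, end = s + elen - 1L,
                              length = elen, is_novel = TRUE))
    tx$t_novelE <- append(seq_len(n), n + 1L, after = i)
    novel_exon <- c(i, n + 1L, i + 1L)
  }

  list(gene_id = gene_id, chrom = paste0("chr_", gene_id), exons = exons,
       transcripts = tx, novel_junction = novel_junction,
       novel_exon = novel_exon)
}

# canonical element ids shared with the graph module
gene_elements <- function(model) {
  ex <- model$exons
  nid <- node_id(ex$start, ex$end)
  paths <- purrr::map(model$transcripts, function(p) nid[match(p, ex$exon)])
  edges <- purrr::map(paths, function(p) {
    tibble(from = c("source", p), to = c(p, "sink"))
  }) |>
    bind_rows() |>
    distinct()
  membership_nodes <- purrr::map(paths, function(p) nid %in% p)
  edge_ids <- edge_id(edges$from, edges$to)
  membership_edges <- purrr::map(paths, function(p) {
    full <- c("source", p, "sink")
    edge_ids %in% edge_id(head(full, -1), tail(full, -1))
  })
  M <- rbind(do.call(cbind, membership_nodes),
             do.call(cbind, membership_edges))
  rownames(M) <- c(nid, edge_ids)
  tibble(
    element_id = rownames(M),
    type = rep(c("exon", "junction"), c(length(nid), length(edge_ids))),
    is_novel = c(ex$is_novel,
                 purrr::map_lgl(seq_len(nrow(edges)), function(i) {
                   !(edge_ids[i] %in% unlist(purrr::map(paths[1:3], function(p) {
                     full <- c("source", p, "sink")
                     edge_id(head(full, -1), tail(full, -1))
                   })))
                 })),
    length = c(ex$length, rep(NA_integer_, length(edge_ids)))
  ) |>
    mutate(membership = purrr::map(seq_len(nrow(M)), function(i) M[i, ]))
}

#' Simulate a synthetic splicing dataset with ground truth
#'
#' Generates gene models, per-type transcript proportions, per-cell depths,
#' observation-level coverage tables and an expression matrix, together with
#' full ground truth (true PSI per element and type, true delta, novel
#' element labels). The four canonical dataset styles are selected by
#' `dataset`: `allAnnot` (no novel events), `novelJ` (one unannotated
#' junction per gene), `novelE` (one unannotated exon per gene) and
#' `novelEJ` (both extra transcripts per gene).
#'
#' @param dataset One of `"allAnnot"`, `"novelJ"`, `"novelE"`, `"novelEJ"`.
#' @param seed RNG seed; identical seeds give identical datasets.
#' @param ... Overrides passed to [sim_config()] (e.g. `n_genes`,
#'   `n_cells_per_type`).
#' @return A list with `annotation` (exon tibble of annotated transcripts
#'   only, novel elements withheld), `cells` (tibble `cell_id`, `group`,
#'   `cell_factor`), `coverage` (named list of [coverage_table()]s),
#'   `expression` (cells x genes matrix), `truth` (list: `psi_group` true
#'   PSI per element and cell type, `delta` true deltas with novelty labels,
#'   `lengths` exon lengths, `models` raw gene structures) and `config`.
#' @examples
#' sim <- simulate_dataset("novelJ", n_genes = 5, n_cells_per_type = 15,
#'                         seed = 7)
#' sim$truth$delta
#' @export
simulate_dataset <- function(dataset = c("allAnnot", "novelJ", "novelE",
                                         "novelEJ"),
                             seed = 1L, ...) {
  dataset <- match.arg(dataset)
  novel <- switch(dataset, allAnnot = "none", novelJ = "junction",
                  novelE = "exon", novelEJ = "both")
  cfg <- sim_config(novel = novel, ...)
  withr::with_seed(seed, simulate_dataset_impl(dataset, cfg))
}

simulate_dataset_impl <- function(dataset, cfg) {
  genes <- purrr::map(seq_len(cfg$n_genes),
                      function(i) simulate_one_gene(sim_gene_id(i), cfg))
  names(genes) <- purrr::map_chr(genes, "gene_id")

  annotation <- purrr::map(genes, function(m) {
    purrr::imap(m$transcripts[c("t1", "t2", "t3")], function(p, tid) {
      ex <- m$exons[match(p, m$exons$exon), ]
      tibble(gene_id = m$gene_id,
             transcript_id = paste0(m$gene_id, "_", tid),
             chrom = m$chrom, strand = "+",
             start = ex$start, end = ex$end)
    }) |> bind_rows()
  }) |> bind_rows() |> sort_exons()

  n_type <- cfg$n_cells_per_type
  cells <- tibble(
    cell_id = sprintf("C%03d", seq_len(2L * n_type)),
    group = rep(c("typeA", "typeB"), each = n_type),
    cell_factor = rlnorm(2L * n_type, 0, cfg$cell_factor_sdlog)
  )

  diff_genes <- sample(names(genes), round(cfg$frac_diff * cfg$n_genes))
  gene_base <- setNames(rlnorm(cfg$n_genes, cfg$gene_depth_meanlog,
                               cfg$gene_depth_sdlog), names(genes))
  expr_genes <- sample(names(genes), round(cfg$expr_type_frac * cfg$n_genes))
  type_fold <- matrix(1, cfg$n_genes, 2,
                      dimnames = list(names(genes), c("typeA", "typeB")))
  type_fold[expr_genes, "typeB"] <-
    cfg$expr_type_fold ^ sample(c(-1, 1), length(expr_genes), replace = TRUE)

  contam <- sample(cells$cell_id,
                   round(cfg$lowq_contam_frac * nrow(cells)))
  lowq_all <- setNames(numeric(nrow(cells)), cells$cell_id)
  lowq_all[contam] <- runif(length(contam), 0.12, 0.30)

  truth_rows <- list(); cov_list <- list()
  expr <- matrix(0, nrow(cells), cfg$n_genes,
                 dimnames = list(cells$cell_id, names(genes)))
  for (gid in names(genes)) {
    m <- genes[[gid]]
    el <- gene_elements(m)
    K <- length(m$transcripts)
    prop_A <- rdirichlet1(K, cfg$dirichlet_alpha)
    prop_B <- if (gid %in% diff_genes) rdirichlet1(K, cfg$dirichlet_alpha)
              else prop_A
    M <- do.call(rbind, el$membership)
    psi_A <- drop(M %*% prop_A); psi_B <- drop(M %*% prop_B)
    truth_rows[[gid]] <- el |>
      select(-"membership") |>
      mutate(gene_id = gid, psi_typeA = psi_A, psi_typeB = psi_B,
             delta_true = psi_A - psi_B)

    depth <- gene_base[gid] * cells$cell_factor *
      type_fold[gid, ][cells$group]
    psi_cell <- function(idx) ifelse(cells$group == "typeA",
                                     psi_A[idx], psi_B[idx])

    ex_el <- which(el$type == "exon")
    short <- ifelse(el$length[ex_el] < cfg$short_exon_len,
                    cfg$short_exon_factor, 1)
    a_exon <- purrr::map(seq_along(ex_el), function(k) {
      mu <- depth * psi_cell(ex_el[k]) * short[k]
      noise <- if (cfg$cov_dispersion > 0) {
        rgamma(length(mu), shape = 1 / cfg$cov_dispersion^2,
               scale = cfg$cov_dispersion^2)
      } else 1
      mu * noise
    })
    a_exon <- do.call(cbind, a_exon)
    ex <- m$exons
    colnames(a_exon) <- paste0(ex$start, "-", ex$end)
    rownames(a_exon) <- cells$cell_id

    # non-terminal junctions: map element edge ids to genomic keys
    jn_el <- which(el$type == "junction" &
                     !grepl("source|sink", el$element_id))
    jn_key <- purrr::map_chr(el$element_id[jn_el], function(id) {
      p <- strsplit(id, ">", fixed = TRUE)[[1]]
      le <- as.integer(sub(".*-", "", sub("^E:", "", p[1])))
      rs <- as.integer(sub("-.*", "", sub("^E:", "", p[2])))
      junction_key(le, rs)
    })
    # junctions touching an unannotated exon have unannotated splice sites
    novel_nodes <- node_id(ex$start[ex$is_novel], ex$end[ex$is_novel])
    jn_eff <- purrr::map_dbl(el$element_id[jn_el], function(id) {
      p <- strsplit(id, ">", fixed = TRUE)[[1]]
      if (any(p %in% novel_nodes)) cfg$novel_site_efficiency
      else cfg$junction_efficiency
    })
    a_junc <- purrr::map(seq_along(jn_el), function(k) {
      mu <- depth * psi_cell(jn_el[k]) * jn_eff[k]
      if (cfg$poisson_junctions) rpois(nrow(cells), mu) else mu
    })
    a_junc <- do.call(cbind, a_junc)
    colnames(a_junc) <- jn_key
    rownames(a_junc) <- cells$cell_id

    cov_list[[gid]] <- coverage_table(gid, a_exon, a_junc, lowq_all)
    expr[, gid] <- depth * rlnorm(nrow(cells), 0, 0.3)
  }

  truth <- bind_rows(truth_rows) |>
    select("gene_id", "element_id", "type", "is_novel", "length",
           "psi_typeA", "psi_typeB", "delta_true")
  list(
    dataset = dataset,
    annotation = annotation,
    cells = cells,
    coverage = cov_list,
    expression = expr,
    truth = list(
      psi_group = truth |>
        select("gene_id", "element_id", "type", "is_novel",
               "psi_typeA", "psi_typeB") |>
        pivot_longer(c("psi_typeA", "psi_typeB"), names_to = "group",
                     values_to = "psi_true") |>
        mutate(group = sub("^psi_", "", .data$group)),
      delta = truth |>
        select("gene_id", "element_id", "type", "is_novel", "delta_true"),
      lengths = truth |>
        filter(.data$type == "exon") |>
        select("gene_id", "element_id", "length"),
      models = genes
    ),
    config = cfg
  )
}

#' Per-cell true PSI table for a simulated dataset
#'
#' Expands the per-type ground truth to one row per cell, for joining with
#' estimated PSI values (cells of a type share the true PSI exactly).
#'
#' @param sim A dataset from [simulate_dataset()].
#' @return Tibble with `gene_id`, `element_id`, `cell_id`, `psi_true`.
#' @export
truth_psi_per_cell <- function(sim) {
  sim$truth$psi_group |>
    inner_join(sim$cells |> select("cell_id", "group"), by = "group",
               relationship = "many-to-many") |>
    select("gene_id", "element_id", "cell_id", "psi_true")
}

#' Write a simulated dataset to plain-text files
#'
#' Writes `annotation.gtf`, `cells.tsv`, `expression.tsv`, `truth_psi.tsv`,
#' `truth_delta.tsv` and one coverage directory per gene (see
#' [write_coverage_tsv()]).
#'
#' @param sim A dataset from [simulate_dataset()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_annotation(sim$annotation, file.path(dir, "annotation.gtf"))
  readr::write_tsv(sim$cells, file.path(dir, "cells.tsv"))
  tibble::as_tibble(sim$expression, rownames = "cell_id") |>
    readr::write_tsv(file.path(dir, "expression.tsv"))
  readr::write_tsv(sim$truth$psi_group, file.path(dir, "truth_psi.tsv"))
  readr::write_tsv(sim$truth$delta, file.path(dir, "truth_delta.tsv"))
  for (gid in names(sim$coverage)) {
    write_coverage_tsv(sim$coverage[[gid]], file.path(dir, "coverage", gid))
  }
  invisible(dir)
}

#' Confusion metrics of differential-splicing calls against truth
#'
#' Joins calls with the simulated truth and computes precision and recall.
#' True elements absent from the calls (e.g. novel elements that were never
#' added to a graph, or elements of filtered genes) count as misses, so the
#' recall denominator is the full set of truly differential elements in the
#' truth table.
#'
#' @param calls A `diff_splice_tbl` from [diff_splicing()].
#' @param truth The `truth$delta` tibble of a simulated dataset.
#' @param types Element types to evaluate (default `"exon"`; Table-style
#'   exon-level metrics).
#' @param novel_only Restrict evaluation to elements absent from the
#'   annotation.
#' @param delta_tol Truth labeling threshold: an element is truly
#'   differential when `|delta_true| > delta_tol` (default 0).
#' @return One-row tibble with `tp`, `fp`, `fn`, `tn`, `precision`,
#'   `recall` (`NA` precision when nothing is called).
#' @export
evaluate_detection <- function(calls, truth, types = "exon",
                               novel_only = FALSE, delta_tol = 0) {
  truth <- truth |> filter(.data$type %in% types)
  if (novel_only) truth <- truth |> filter(.data$is_novel)
  d <- truth |>
    left_join(calls |>
                select("gene_id", "element_id", "is_significant"),
              by = c("gene_id", "element_id")) |>
    mutate(called = !is.na(.data$is_significant) & .data$is_significant,
           truly = abs(.data$delta_true) > delta_tol)
  tp <- sum(d$called & d$truly); fp <- sum(d$called & !d$truly)
  fn <- sum(!d$called & d$truly); tn <- sum(!d$called & !d$truly)
  tibble(tp = tp, fp = fp, fn = fn, tn = tn,
         precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
         recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

#' Count recovered novel elements in extended splice graphs
#'
#' @param graphs Named list of extended `splice_graph`s.
#' @param sim The simulated dataset the graphs were built from.
#' @return One-row tibble with `novel_junctions_true`,
#'   `novel_junctions_recovered`, `novel_exons_true`,
#'   `novel_exons_recovered`. Recovery of the simulated skipping junction
#'   and of the simulated intronic exon are counted separately; the two
#'   flanking junctions of a novel exon count toward the exon, not the
#'   junction, tally (matching how the dataset styles are defined).
#' @export
count_novel_recovery <- function(graphs, sim) {
  models <- sim$truth$models
  jt <- 0L; jr <- 0L; et <- 0L; er <- 0L
  for (gid in names(models)) {
    m <- models[[gid]]
    g <- graphs[[gid]]
    if (!is.null(m$novel_junction)) {
      jt <- jt + 1L
      i <- m$novel_junction[1]; j <- m$novel_junction[2]
      key <- junction_key(m$exons$end[m$exons$exon == i],
                          m$exons$start[m$exons$exon == j])
      if (!is.null(g) && key %in% g$edges$key[g$edges$is_novel]) jr <- jr + 1L
    }
    if (!is.null(m$novel_exon)) {
      et <- et + 1L
      ne <- m$exons |> filter(.data$is_novel)
      nid <- node_id(ne$start, ne$end)
      if (!is.null(g) &&
          nid %in% g$nodes$node_id[g$nodes$is_novel]) er <- er + 1L
    }
  }
  tibble(novel_junctions_true = jt, novel_junctions_recovered = jr,
         novel_exons_true = et, novel_exons_recovered = er)
}
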