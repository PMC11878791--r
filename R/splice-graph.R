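#' Disjoin overlapping exon variants into partial exons
#'
#' Alternative 3'/5' splice sites make annotated exons of one gene overlap
#' without being identical. This splits all exon intervals of a gene into
#' maximal non-overlapping "partial exons" such that every annotated exon is
#' an exact concatenation of consecutive partial exons.
#'
#' @param transcripts Exon tibble for a single gene, as one gene's rows of
#'   [read_annotation()].
#' @return A list with `exons`, a tibble of partial exons (`start`, `end`,
#'   `length`), and `paths`, a named list (one per transcript) of tibbles with
#'   the partial-exon path in transcript direction and a `new_exon` flag that
#'   is `FALSE` where a partial exon continues the same annotated exon as its
#'   predecessor (a containment adjacency, not a splice junction).
#' @export
disjoin_exons <- function(transcripts) {
  stopifnot(nrow(transcripts) > 0L)
  if (length(unique(transcripts$gene_id)) != 1L) {
    abort("disjoin_exons() expects exons of a single gene")
  }
  strand <- transcripts$strand[1]
  ir <- IRanges::IRanges(transcripts$start, transcripts$end)
  dj <- IRanges::disjoin(ir)
  pieces <- tibble(
    start  = IRanges::start(dj),
    end    = IRanges::end(dj),
    length = IRanges::width(dj)
  ) |> arrange(.data$start)

  # pieces contained in each annotated exon, walked in transcript direction
  paths <- transcripts |>
    group_by(.data$transcript_id) |>
    group_map(function(tx, key) {
      rows <- purrr::map(seq_len(nrow(tx)), function(i) {
        p <- pieces |>
          filter(.data$start >= tx$start[i], .data$end <= tx$end[i])
        if (strand == "-") p <- arrange(p, dplyr::desc(.data$start))
        p$new_exon <- c(TRUE, rep(FALSE, nrow(p) - 1L))
        p
      })
      bind_rows(rows)
    }, .keep = FALSE)
  names(paths) <- transcripts |>
    group_by(.data$transcript_id) |> group_keys() |> pull(.data$transcript_id)
  list(exons = pieces, paths = paths)
}

node_id <- function(start, end) paste0("E:", start, "-", end)
edge_id <- function(from, to) paste(from, to, sep = ">")

# genomic junction key: (last base of upstream-in-coordinates exon,
#  first base of downstream-in-coordinates exon)
junction_key <- function(left_end, right_start) {
  paste0(left_end, "-", right_start)
}

parse_junction_key <- function(key) {
  m <- do.call(rbind, strsplit(key, "-", fixed = TRUE))
  tibble(key = key,
         left_end = as.integer(m[, 1]),
         right_start = as.integer(m[, 2]))
}

#' Build the reference splice graph of a gene
#'
#' Creates one node per partial exon (after [disjoin_exons()]) plus artificial
#' source and sink nodes, and one edge per consecutive pair of partial exons
#' in any annotated transcript. The source connects to the first exon of each
#' transcript and the sink to the last (5'->3'; for minus-strand genes the
#' source therefore attaches at the genomic right end). Edges shared by
#' several transcripts are deduplicated. Adjacent partial exons of one
#' annotated exon are linked by "containment" edges, which behave as ordinary
#' edges for flow conservation but are not splice junctions.
#'
#' @param transcripts Exon tibble for one gene ([read_annotation()] rows).
#' @return A `splice_graph` object: a list with `gene_id`, `chrom`, `strand`,
#'   a `nodes` tibble (`node_id`, `start`, `end`, `length`, `rank`,
#'   `is_novel`, `is_source`, `is_sink`), an `edges` tibble (`edge_id`,
#'   `from`, `to`, `key`, `is_novel`, `is_containment`, `touches_terminal`),
#'   the annotated transcript paths, and annotated transcript lengths in bp.
#' @examples
#' gtf <- system.file("extdata", "toy.gtf", package = "psiflow")
#' ann <- read_annotation(gtf)
#' build_splice_graph(ann[ann$gene_id == ann$gene_id[1], ])
#' @export
build_splice_graph <- function(transcripts) {
  gene_id <- unique(transcripts$gene_id)
  if (length(gene_id) != 1L) abort("build_splice_graph() expects one gene")
  chrom  <- unique(transcripts$chrom)
  strand <- unique(transcripts$strand)
  if (length(chrom) != 1L) abort(paste0(gene_id, ": exons on multiple chromosomes"))
  if (length(strand) != 1L) abort(paste0(gene_id, ": exons on multiple strands"))

  dj <- disjoin_exons(transcripts)
  nodes <- dj$exons |>
    mutate(node_id = node_id(.data$start, .data$end),
           is_novel = FALSE, is_source = FALSE, is_sink = FALSE)

  tx_paths <- purrr::map(dj$paths, function(p) node_id(p$start, p$end))
  edges <- purrr::map(dj$paths, function(p) {
    ids <- node_id(p$start, p$end)
    n <- length(ids)
    if (n < 2L) return(NULL)
    tibble(from = ids[-n], to = ids[-1],
           is_containment = !p$new_exon[-1])
  }) |>
    bind_rows()

  term <- bind_rows(
    tibble(from = "source", to = purrr::map_chr(tx_paths, 1), is_containment = FALSE),
    tibble(from = purrr::map_chr(tx_paths, function(x) x[length(x)]),
           to = "sink", is_containment = FALSE)
  )
  edges <- bind_rows(edges, term) |> distinct(.data$from, .data$to, .keep_all = TRUE)
  if (any(edges$from == edges$to)) abort(paste0(gene_id, ": self-loop in transcript path"))

  g <- structure(list(
    gene_id = gene_id, chrom = chrom, strand = strand,
    nodes = nodes, edges = edges,
    transcripts = tx_paths,
    transcript_lengths = transcripts |>
      group_by(.data$transcript_id) |>
      summarise(len = sum(.data$end - .data$start + 1), .groups = "drop") |>
      (\(d) setNames(d$len, d$transcript_id))()
  ), class = "splice_graph")
  finalize_graph(g)
}

# add terminal pseudo-nodes, ranks and edge metadata; validate DAG structure
finalize_graph <- function(g) {
  real <- g$nodes |> filter(!.data$is_source, !.data$is_sink)
  ord <- if (g$strand == "-") order(-real$start) else order(real$start)
  real <- real[ord, , drop = FALSE]
  real$rank <- seq_len(nrow(real))
  terminals <- tibble(
    start = NA_integer_, end = NA_integer_, length = 0L,
    node_id = c("source", "sink"),
    is_novel = FALSE,
    is_source = c(TRUE, FALSE), is_sink = c(FALSE, TRUE),
    rank = c(0L, nrow(real) + 1L)
  )
  g$nodes <- bind_rows(terminals[1, ], real, terminals[2, ])

  ed <- g$edges
  ed$edge_id <- edge_id(ed$from, ed$to)
  ed$touches_terminal <- ed$from == "source" | ed$to == "sink"
  lookup <- setNames(seq_len(nrow(g$nodes)), g$nodes$node_id)
  if (anyNA(lookup[ed$from]) || anyNA(lookup[ed$to])) {
    abort(paste0(g$gene_id, ": edge references unknown node"))
  }
  fr <- g$nodes[lookup[ed$from], ]
  to <- g$nodes[lookup[ed$to], ]
  # genomic key: coordinates of the intervening gap, strand-agnostic
  le <- pmin(fr$end, to$end, na.rm = TRUE)
  rs <- pmax(fr$start, to$start, na.rm = TRUE)
  ed$key <- unname(ifelse(ed$touches_terminal, NA_character_,
                          junction_key(le, rs)))
  if (!"is_novel" %in% names(ed)) ed$is_novel <- FALSE
  ed$is_novel[is.na(ed$is_novel)] <- FALSE
  ed$from_rank <- fr$rank
  ed$to_rank <- to$rank
  g$edges <- ed |>
    select("edge_id", "from", "to", "key", "is_novel", "is_containment",
           "touches_terminal", "from_rank", "to_rank") |>
    arrange(.data$from_rank, .data$to_rank)
  validate_splice_graph(g)
  g
}

validate_splice_graph <- function(g) {
  n <- g$nodes
  e <- g$edges
  stopifnot(sum(n$is_source) == 1L, sum(n$is_sink) == 1L)
  real <- n |> filter(!.data$is_source, !.data$is_sink)
  stopifnot(all(real$length >= 1L), all(real$start <= real$end))
  if (any(e$from_rank >= e$to_rank)) {
    abort(paste0(g$gene_id, ": edge against transcript direction (cycle?)"))
  }
  reach <- reachable_nodes(g)
  orphan <- setdiff(real$node_id, reach)
  if (length(orphan) > 0L) {
    abort(paste0(g$gene_id, ": node(s) not on any source->sink path: ",
                 paste(orphan, collapse = ", ")))
  }
  invisible(g)
}

# node ids lying on at least one source->sink path
reachable_nodes <- function(g) {
  ids <- g$nodes$node_id
  fwd <- setNames(logical(length(ids)), ids)
  fwd["source"] <- TRUE
  for (i in order(g$edges$from_rank)) {     # edges in topological order
    ed <- g$edges[i, ]
    if (fwd[[ed$from]]) fwd[ed$to] <- TRUE
  }
  bwd <- setNames(logical(length(ids)), ids)
  bwd["sink"] <- TRUE
  for (i in rev(order(g$edges$to_rank))) {
    ed <- g$edges[i, ]
    if (bwd[[ed$to]]) bwd[ed$from] <- TRUE
  }
  ids[fwd[ids] & bwd[ids]]
}

#' @export
print.splice_graph <- function(x, ...) {
  nr <- sum(!x$nodes$is_source & !x$nodes$is_sink)
  cat("<splice_graph> ", x$gene_id, " (", x$chrom, x$strand, ")\n", sep = "")
  cat("  ", nr, " exons (", sum(x$nodes$is_novel), " novel), ",
      nrow(x$edges), " edges (", sum(x$edges$is_novel), " novel, ",
      sum(x$edges$is_containment), " containment), ",
      length(x$transcripts), " annotated transcripts\n", sep = "")
  invisible(x)
}

#' Extend a splice graph with read-supported novel junctions
#'
#' Candidate junctions observed in the reads (keyed by the genomic
#' coordinates of the last base of the donor exon and the first base of the
#' acceptor exon) are added to the graph when supported by at least
#' `min_reads` reads in at least `min_cells` cells, and when both endpoints
#' coincide with boundaries of existing partial exons. Junctions to or from
#' the artificial source/sink are never added, so first/last exon usage stays
#' limited to the annotation. Supported keys with an endpoint inside an
#' intron are kept aside as novel-exon evidence for [add_novel_exons()];
#' keys with an endpoint strictly inside an exon body are recorded in the
#' `"interior_junctions"` attribute but not added.
#'
#' @param graph A `splice_graph`.
#' @param junction_counts Numeric matrix of junction-spanning read counts,
#'   cells in rows, junction keys (`"<donorEnd>-<acceptorStart>"`) in columns.
#' @param min_reads,min_cells Support filter: a junction must reach
#'   `min_reads` reads in at least `min_cells` cells (defaults 5 and 10).
#' @return The extended `splice_graph`; accepted edges carry
#'   `is_novel = TRUE`. Idempotent.
#' @export
add_novel_junctions <- function(graph, junction_counts, min_reads = 5L,
                                min_cells = 10L) {
  keys <- supported_keys(junction_counts, min_reads, min_cells)
  cand <- setdiff(keys, stats::na.omit(graph$edges$key))
  if (length(cand) == 0L) return(graph)
  pk <- parse_junction_key(cand)
  real <- graph$nodes |> filter(!.data$is_source, !.data$is_sink)
  pk$left_node <- real$node_id[match(pk$left_end, real$end)]
  pk$right_node <- real$node_id[match(pk$right_start, real$start)]

  interior <- pk |>
    filter(purrr::map_lgl(seq_len(nrow(pk)), function(i) {
      (is.na(pk$left_node[i]) &&
         any(real$start <= pk$left_end[i] & pk$left_end[i] < real$end)) ||
      (is.na(pk$right_node[i]) &&
         any(real$start < pk$right_start[i] & pk$right_start[i] <= real$end))
    }))

  ok <- pk |>
    filter(!is.na(.data$left_node), !is.na(.data$right_node),
           .data$right_start > .data$left_end + 1L,
           .data$left_node != .data$right_node)
  if (nrow(ok) > 0L) {
    from <- if (graph$strand == "-") ok$right_node else ok$left_node
    to   <- if (graph$strand == "-") ok$left_node else ok$right_node
    new <- tibble(from = from, to = to, is_containment = FALSE, is_novel = TRUE)
    graph$edges <- bind_rows(
      graph$edges |> select("from", "to", "is_containment", "is_novel"),
      new
    ) |> distinct(.data$from, .data$to, .keep_all = TRUE)
    graph <- finalize_graph(graph)
  }
  attr(graph, "novel_candidates") <- pk |>
    filter(is.na(.data$left_node) | is.na(.data$right_node)) |>
    anti_join(interior, by = "key")
  attr(graph, "interior_junctions") <- interior
  graph
}

supported_keys <- function(junction_counts, min_reads, min_cells) {
  if (is.null(junction_counts) || ncol(junction_counts) == 0L) return(character())
  n_support <- colSums(junction_counts >= min_reads)
  colnames(junction_counts)[n_support >= min_cells]
}

#' Extend a splice graph with read-supported novel exons
#'
#' A novel exon is an unannotated interval inside an intron, connected to the
#' graph by two novel junctions (one incoming, one outgoing). It is added
#' only when *both* flanking junctions pass the `min_reads`/`min_cells`
#' support filter, the interval overlaps no existing exon, and the interval
#' shows nonzero read coverage in at least one cell; the exon and its two
#' junctions are added atomically, all flagged novel. Candidates supported on
#' one side only are recorded in the `"novel_exon_log"` attribute.
#'
#' @inheritParams add_novel_junctions
#' @param exon_cov Numeric matrix of mean per-base exon coverage, cells in
#'   rows, interval keys (`"<start>-<end>"`) in columns; used to check that a
#'   candidate interval is covered.
#' @return The extended `splice_graph`.
#' @export
add_novel_exons <- function(graph, junction_counts, exon_cov,
                            min_reads = 5L, min_cells = 10L) {
  keys <- supported_keys(junction_counts, min_reads, min_cells)
  known <- stats::na.omit(graph$edges$key)
  pk <- parse_junction_key(setdiff(keys, known))
  real <- graph$nodes |> filter(!.data$is_source, !.data$is_sink)
  if (nrow(pk) == 0L) return(graph)
  pk$left_node  <- real$node_id[match(pk$left_end, real$end)]
  pk$right_node <- real$node_id[match(pk$right_start, real$start)]

  # incoming junction: boundary-matched on the left, lands inside an intron
  inc <- pk |> filter(!is.na(.data$left_node), is.na(.data$right_node))
  # outgoing junction: starts inside an intron, boundary-matched on the right
  out <- pk |> filter(is.na(.data$left_node), !is.na(.data$right_node))
  log <- list()
  added <- FALSE
  if (nrow(inc) > 0L && nrow(out) > 0L) {
    for (i in seq_len(nrow(inc))) {
      s <- inc$right_start[i]
      hits <- out |> filter(.data$left_end >= s)
      if (nrow(hits) == 0L) next
      hits <- hits |> arrange(.data$left_end)
      for (h in seq_len(nrow(hits))) {
        e <- hits$left_end[h]
        if (any(real$start <= e & real$end >= s)) next   # overlaps an exon
        cov_key <- paste0(s, "-", e)
        covered <- cov_key %in% colnames(exon_cov) &&
          max(exon_cov[, cov_key]) > 0
        if (!covered) {
          log[[length(log) + 1L]] <- tibble(start = s, end = e,
                                            reason = "no_coverage")
          next
        }
        nid <- node_id(s, e)
        if (nid %in% graph$nodes$node_id) next
        graph$nodes <- bind_rows(
          graph$nodes,
          tibble(start = s, end = e, length = e - s + 1L, node_id = nid,
                 is_novel = TRUE, is_source = FALSE, is_sink = FALSE,
                 rank = NA_integer_)
        )
        u <- inc$left_node[i]; d <- hits$right_node[h]
        new <- if (graph$strand == "-") {
          tibble(from = c(nid, d), to = c(u, nid))
        } else {
          tibble(from = c(u, nid), to = c(nid, d))
        }
        new$is_containment <- FALSE
        new$is_novel <- TRUE
        graph$edges <- bind_rows(
          graph$edges |> select("from", "to", "is_containment", "is_novel"),
          new
        ) |> distinct(.data$from, .data$to, .keep_all = TRUE)
        added <- TRUE
        break
      }
    }
  }
  one_sided <- bind_rows(
    inc |> mutate(side = "incoming_only"),
    out |> mutate(side = "outgoing_only")
  )
  if (added) graph <- finalize_graph(graph)
  attr(graph, "novel_exon_log") <- bind_rows(log)
  attr(graph, "novel_exon_one_sided") <- one_sided
  graph
}

#' Simplify a splice graph by dropping unobserved elements
#'
#' Removes exons and junctions whose read coverage is below 1 in every cell,
#' unless they are required for graph connectivity. Elements are considered
#' greedily in ascending order of maximum coverage (ties broken by genomic
#' order); an element is retained whenever its removal would leave any
#' remaining exon off all source->sink paths. An exon is only removable when
#' all its incident edges are themselves unobserved; edges touching
#' source/sink are removed only together with their exon.
#'
#' @inheritParams add_novel_exons
#' @return A simplified `splice_graph`. Idempotent.
#' @export
simplify_graph <- function(graph, exon_cov, junction_counts) {
  node_cov <- function(n) {
    key <- paste0(n$start, "-", n$end)
    out <- numeric(length(key))
    hit <- key %in% colnames(exon_cov)
    if (any(hit)) out[hit] <- apply(exon_cov[, key[hit], drop = FALSE], 2, max)
    out
  }
  edge_cov <- function(e) {
    out <- numeric(nrow(e))
    hit <- !is.na(e$key) & e$key %in% colnames(junction_counts)
    if (any(hit)) out[hit] <- apply(junction_counts[, e$key[hit], drop = FALSE], 2, max)
    out
  }
  real <- graph$nodes |> filter(!.data$is_source, !.data$is_sink)
  ncov <- setNames(node_cov(real), real$node_id)
  ecov <- setNames(edge_cov(graph$edges), graph$edges$edge_id)

  # candidate table: uncovered elements, ascending coverage then genomic order
  cand <- bind_rows(
    tibble(id = real$node_id, type = "node", cov = unname(ncov[real$node_id]),
           ord = real$rank),
    graph$edges |>
      filter(!.data$touches_terminal) |>
      transmute(id = .data$edge_id, type = "edge",
                cov = unname(ecov[.data$edge_id]),
                ord = .data$from_rank + .data$to_rank / 1e6)
  ) |>
    filter(.data$cov < 1) |>
    arrange(.data$cov, .data$ord)

  for (i in seq_len(nrow(cand))) {
    id <- cand$id[i]
    if (cand$type[i] == "node") {
      if (!id %in% graph$nodes$node_id) next
      incident <- graph$edges |> filter(.data$from == id | .data$to == id)
      if (any(ecov[incident$edge_id[!incident$touches_terminal]] >= 1)) next
      trial <- graph
      trial$nodes <- trial$nodes |> filter(.data$node_id != id)
      trial$edges <- trial$edges |> filter(.data$from != id, .data$to != id)
    } else {
      if (!id %in% graph$edges$edge_id) next
      trial <- graph
      trial$edges <- trial$edges |> filter(.data$edge_id != id)
    }
    if (graph_connected(trial)) graph <- trial
  }
  finalize_graph(structure(
    list(gene_id = graph$gene_id, chrom = graph$chrom, strand = graph$strand,
         nodes = graph$nodes |> filter(!.data$is_source, !.data$is_sink),
         edges = graph$edges |>
           select("from", "to", "is_containment", "is_novel"),
         transcripts = graph$transcripts,
         transcript_lengths = graph$transcript_lengths),
    class = "splice_graph"
  ))
}

# TRUE iff every remaining real node lies on a source->sink path
graph_connected <- function(g) {
  real <- g$nodes |> filter(!.data$is_source, !.data$is_sink)
  if (nrow(real) == 0L) return(FALSE)
  on_path <- reachable_nodes(g)
  all(real$node_id %in% on_path) && "source" %in% on_path
}

#' Count source->sink paths of a splice graph
#'
#' Exact count by dynamic programming in topological order, saturating at
#' `cap + 1` to avoid overflow on combinatorially complex graphs.
#'
#' @param graph A `splice_graph`.
#' @param cap Saturation cap (default one million).
#' @return Number of distinct source->sink paths, or `cap + 1` if more.
#' @export
count_source_sink_paths <- function(graph, cap = 1e6) {
  ids <- graph$nodes$node_id[order(graph$nodes$rank)]
  npaths <- setNames(numeric(length(ids)), ids)
  npaths["source"] <- 1
  ed <- graph$edges |> arrange(.data$from_rank)
  for (id in ids[-1]) {
    inc <- ed |> filter(.data$to == id)
    npaths[id] <- min(sum(npaths[inc$from]), cap + 1)
  }
  unname(npaths["sink"])
}

#' Cross sections of a splice graph
#'
#' The cross section at exon `e` is the set containing `e` itself plus every
#' junction that starts before and ends after `e` in the graph's linear
#' (genomic) order. For true PSI values each cross-section sum equals 1,
#' which the intermediate EM step uses as a global flow constraint.
#'
#' @param graph A `splice_graph`.
#' @return Named list, one character vector of element ids per observable
#'   (non-terminal) exon.
#' @export
cross_sections <- function(graph) {
  real <- graph$nodes |> filter(!.data$is_source, !.data$is_sink)
  ed <- graph$edges
  out <- purrr::map(seq_len(nrow(real)), function(i) {
    r <- real$rank[i]
    spanning <- ed$edge_id[ed$from_rank < r & ed$to_rank > r]
    c(real$node_id[i], spanning)
  })
  setNames(out, real$node_id)
}

# TRUE when no node offers an alternative path (in/out degree all <= 1)
is_sequential_graph <- function(graph) {
  deg_out <- table(factor(graph$edges$from, levels = graph$nodes$node_id))
  deg_in <- table(factor(graph$edges$to, levels = graph$nodes$node_id))
  all(deg_out <= 1L) && all(deg_in <= 1L)
}

#' Tabulate a splice graph for serialization
#'
#' @param graph A `splice_graph`.
#' @return A list of two tibbles, `nodes` (id, chrom, start, end, is_novel)
#'   and `edges` (donor, acceptor, is_novel), matching the on-disk TSV layout
#'   written by [run_pipeline()].
#' @export
graph_tables <- function(graph) {
  list(
    nodes = graph$nodes |>
      filter(!.data$is_source, !.data$is_sink) |>
      transmute(id = .data$node_id, chrom = graph$chrom,
                .data$start, .data$end, .data$is_novel),
    edges = graph$edges |>
      transmute(donor = .data$from, acceptor = .data$to, .data$is_novel,
                .data$is_containment)
  )
}
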