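make_tx <- function(...) {
  # list of transcripts, each a 2-col matrix of (start, end)
  txs <- list(...)
  purrr::imap(txs, function(m, i) {
    tibble(gene_id = "G", transcript_id = paste0("t", i), chrom = "chr1",
           strand = "+", start = m[, 1], end = m[, 2])
  }) |> bind_rows() |> psiflow:::sort_exons()
}

test_that("disjoining splits overlapping exon variants at shared boundaries", {
  # identical exons: nothing to split
  tx <- make_tx(cbind(c(100, 300), c(200, 400)),
                cbind(c(100, 300), c(200, 400)))
  dj <- disjoin_exons(tx)
  expect_equal(dj$exons$start, c(100, 300))
  expect_equal(dj$exons$end, c(200, 400))

  # alternative 3' end forces a breakpoint at 200/201
  tx <- make_tx(cbind(100, 200), cbind(100, 250))
  dj <- disjoin_exons(tx)
  expect_equal(dj$exons$start, c(100, 201))
  expect_equal(dj$exons$end, c(200, 250))
  # the longer exon is the concatenation of both pieces, containment-linked
  p2 <- dj$paths$t2
  expect_equal(nrow(p2), 2L)
  expect_equal(p2$new_exon, c(TRUE, FALSE))
})

test_that("staggered 5' ends produce one partial exon per boundary segment", {
  # brute-force oracle: distinct segments between consecutive breakpoints
  # that are covered by at least one exon
  starts <- c(100, 130, 170); ends <- c(300, 300, 300)
  tx <- do.call(make_tx, purrr::map(seq_along(starts), function(i) {
    cbind(starts[i], ends[i])
  }))
  bounds <- sort(unique(c(starts, ends + 1)))
  segs <- tibble(start = head(bounds, -1), end = tail(bounds, -1) - 1)
  covered <- purrr::map_lgl(seq_len(nrow(segs)), function(i) {
    any(starts <= segs$start[i] & ends >= segs$end[i])
  })
  dj <- disjoin_exons(tx)
  expect_equal(dj$exons$start, segs$start[covered])
  expect_equal(dj$exons$end, segs$end[covered])

  # round trip: each transcript's base content is preserved exactly
  for (k in seq_along(starts)) {
    p <- dj$paths[[k]]
    bases <- unlist(purrr::map2(p$start, p$end, seq))
    expect_equal(sort(bases), seq(starts[k], ends[k]))
  }
})

test_that("reference graph links consecutive exons and both last exons to sink", {
  g <- toy_graph()
  # alternative last exons: both connected to the sink
  expect_true(all(c("E:701-800>sink", "E:901-1000>sink") %in% g$edges$edge_id))
  expect_equal(sum(g$edges$to == "sink"), 2L)
  # single first exon
  expect_equal(sum(g$edges$from == "source"), 1L)

  # pair-enumeration oracle: edges = distinct consecutive pairs over paths
  pairs <- unique(unlist(purrr::map(g$transcripts, function(p) {
    full <- c("source", p, "sink")
    paste(head(full, -1), tail(full, -1), sep = ">")
  })))
  expect_setequal(g$edges$edge_id, pairs)

  # two-exon single-transcript gene: a 3-edge path
  g2 <- build_splice_graph(make_tx(cbind(c(1, 101), c(50, 150))))
  expect_equal(nrow(g2$edges), 3L)
  expect_equal(count_source_sink_paths(g2), 1)
})

test_that("graphs are DAGs whose nodes all lie on source->sink paths", {
  for (g in list(toy_graph(), skip_graph())) {
    expect_true(all(g$edges$from_rank < g$edges$to_rank))
    real <- g$nodes$node_id[!g$nodes$is_source & !g$nodes$is_sink]
    expect_true(all(real %in% psiflow:::reachable_nodes(g)))
    expect_gte(count_source_sink_paths(g), length(g$transcripts))
  }
})

counts_matrix <- function(keys, reads, cells_with) {
  # cells_with cells at `reads` counts, remaining cells 0, 30 cells total
  m <- matrix(0, 30, length(keys), dimnames = list(sprintf("c%02d", 1:30), keys))
  for (j in seq_along(keys)) m[seq_len(cells_with[j]), j] <- reads[j]
  m
}

test_that("novel junctions obey the 5-read/10-cell support boundary", {
  g <- toy_graph()
  # E1>E2 exists; a novel skip E2>E5 (key 400-901) at exactly 5 reads in
  # exactly 10 cells is accepted, 5 reads in 9 cells is not
  jc <- counts_matrix("400-901", 5, 10)
  g1 <- add_novel_junctions(g, jc)
  expect_true("E:301-400>E:901-1000" %in% g1$edges$edge_id)
  expect_true(g1$edges$is_novel[g1$edges$edge_id == "E:301-400>E:901-1000"])

  jc9 <- counts_matrix("400-901", 5, 9)
  expect_identical(add_novel_junctions(g, jc9)$edges$edge_id, g$edges$edge_id)
  jc4 <- counts_matrix("400-901", 4, 30)
  expect_identical(add_novel_junctions(g, jc4)$edges$edge_id, g$edges$edge_id)

  # idempotence
  expect_identical(add_novel_junctions(g1, jc)$edges, g1$edges)
})

test_that("random junction candidates match a direct threshold oracle", {
  g <- toy_graph()
  real <- g$nodes |> filter(!is_source, !is_sink)
  withr::with_seed(99, {
    # candidate keys between random exon boundaries (non-adjacent pairs)
    combos <- t(combn(nrow(real), 2))
    keys <- unique(psiflow:::junction_key(real$end[combos[, 1]],
                                          real$start[combos[, 2]]))
    m <- matrix(rpois(30 * length(keys), 3), 30,
                dimnames = list(sprintf("c%02d", 1:30), keys))
    g2 <- add_novel_junctions(g, m)
    oracle <- colnames(m)[colSums(m >= 5) >= 10]
    expected <- union(stats::na.omit(g$edges$key),
                      setdiff(oracle, stats::na.omit(g$edges$key)))
    # every accepted non-terminal key is supported-or-annotated, and every
    # supported boundary-matching key not adjacent is present
    got <- stats::na.omit(g2$edges$key)
    adjacent <- purrr::map_lgl(oracle, function(k) {
      pk <- psiflow:::parse_junction_key(k)
      pk$right_start <= pk$left_end + 1
    })
    expect_setequal(got, union(stats::na.omit(g$edges$key),
                               oracle[!adjacent]))
  })
})

test_that("interior-endpoint junctions are logged, not added", {
  g <- toy_graph()
  jc <- counts_matrix("150-901", 50, 30)   # 150 is inside E1 (101-200)
  g1 <- add_novel_junctions(g, jc)
  expect_identical(g1$edges$edge_id, g$edges$edge_id)
  expect_equal(attr(g1, "interior_junctions")$key, "150-901")
})

test_that("novel exons need both flanking junctions and nonzero coverage", {
  g <- toy_graph()
  # novel exon 420-460 inside the E2..E3 intron (401..500)
  jin <- "400-420"; jout <- "460-501"
  exon_cov <- matrix(2, 30, 1, dimnames = list(sprintf("c%02d", 1:30),
                                               "420-460"))
  both <- counts_matrix(c(jin, jout), c(6, 6), c(12, 12))
  g1 <- add_novel_exons(g, both, exon_cov)
  expect_true("E:420-460" %in% g1$nodes$node_id)
  expect_true(g1$nodes$is_novel[g1$nodes$node_id == "E:420-460"])
  expect_true(all(c("E:301-400>E:420-460", "E:420-460>E:501-650") %in%
                    g1$edges$edge_id[g1$edges$is_novel]))
  # the graph stays valid and the exon lies on a source->sink path
  expect_true("E:420-460" %in% psiflow:::reachable_nodes(g1))

  # downstream junction failing the filter: nothing is added (atomicity)
  one <- counts_matrix(c(jin, jout), c(6, 6), c(12, 9))
  g2 <- add_novel_exons(g, one, exon_cov)
  expect_identical(g2$nodes$node_id, g$nodes$node_id)

  # no coverage on the interval: nothing added, reason logged
  dark <- matrix(0, 30, 1, dimnames = dimnames(exon_cov))
  g3 <- add_novel_exons(g, both, dark)
  expect_identical(g3$nodes$node_id, g$nodes$node_id)
  expect_equal(attr(g3, "novel_exon_log")$reason, "no_coverage")
})

test_that("simplification drops unobserved elements unless needed for connectivity", {
  g <- toy_graph()
  depth <- setNames(rep(10, 5), g$nodes$node_id[!g$nodes$is_source &
                                                  !g$nodes$is_sink])
  juncs <- setNames(rep(10, 5),
                    g$edges$edge_id[!g$edges$touches_terminal])
  # cassette exon E2 unobserved (with its two junctions): removable because
  # E1>E3 offers an alternative path
  d <- depth; d["E:301-400"] <- 0
  j <- juncs; j[c("E:101-200>E:301-400", "E:301-400>E:501-650")] <- 0
  cov <- cov_from_vectors(g, d, j)
  gs <- simplify_graph(g, cov$exon_cov, cov$junction_count)
  expect_false("E:301-400" %in% gs$nodes$node_id)
  expect_true(all(c("E:701-800", "E:901-1000") %in% gs$nodes$node_id))

  # E5's only edge from E3 unobserved but required for connectivity: retained
  j2 <- juncs; j2["E:501-650>E:901-1000"] <- 0
  cov2 <- cov_from_vectors(g, depth, j2)
  gs2 <- simplify_graph(g, cov2$exon_cov, cov2$junction_count)
  expect_true("E:501-650>E:901-1000" %in% gs2$edges$edge_id)

  # idempotence
  gss <- simplify_graph(gs, cov$exon_cov, cov$junction_count)
  expect_identical(gss$nodes$node_id, gs$nodes$node_id)
  expect_identical(gss$edges$edge_id, gs$edges$edge_id)
})

test_that("random zero patterns: simplified graphs satisfy the removal contract", {
  g <- toy_graph()
  real_ids <- g$nodes$node_id[!g$nodes$is_source & !g$nodes$is_sink]
  junc_ids <- g$edges$edge_id[!g$edges$touches_terminal]
  withr::with_seed(7, {
    for (rep in 1:20) {
      d <- setNames(sample(c(0, 10), 5, replace = TRUE), real_ids)
      j <- setNames(sample(c(0, 10), 5, replace = TRUE), junc_ids)
      cov <- cov_from_vectors(g, d, j)
      gs <- simplify_graph(g, cov$exon_cov, cov$junction_count)
      kept_nodes <- gs$nodes$node_id[!gs$nodes$is_source & !gs$nodes$is_sink]
      # every covered element survives
      expect_true(all(names(d)[d > 0] %in% kept_nodes))
      expect_true(all(names(j)[j > 0] %in% gs$edges$edge_id))
      # every kept node still on a source->sink path
      expect_true(all(kept_nodes %in% psiflow:::reachable_nodes(gs)))
      # removed elements were all unobserved
      dropped <- setdiff(real_ids, kept_nodes)
      expect_true(all(d[dropped] == 0))
    }
  })
})

test_that("path counting matches DFS enumeration and saturates at the cap", {
  # DFS oracle on the toy graph
  g <- toy_graph()
  adj <- split(g$edges$to, g$edges$from)
  dfs <- function(v) {
    if (v == "sink") return(1L)
    sum(vapply(adj[[v]], dfs, integer(1)))
  }
  expect_equal(count_source_sink_paths(g), dfs("source"))

  # chain of 4 exons: a single path
  chain <- build_splice_graph(
    make_tx(cbind(seq(1, 901, 300), seq(100, 1000, 300))))
  expect_equal(count_source_sink_paths(chain), 1)

  # 25 consecutive cassette diamonds: 2^25 paths saturate the default cap
  n <- 25
  const <- cbind(seq(1, by = 1000, length.out = n + 1),
                 seq(100, by = 1000, length.out = n + 1))
  skip <- cbind(const[seq_len(n), 1] + 500, const[seq_len(n), 1] + 580)
  t_full <- const
  inter <- rbind(const, skip)
  inter <- inter[order(inter[, 1]), ]
  g25 <- build_splice_graph(make_tx(inter, t_full))
  expect_equal(count_source_sink_paths(g25), 1e6 + 1)
  expect_equal(count_source_sink_paths(g25, cap = 100), 101)
})

test_that("cross sections contain the exon plus its spanning junctions", {
  # skipping gene: section at E3 contains the skip junction, others are
  # singletons aside from terminal-edge spans
  g <- skip_graph()
  cs <- cross_sections(g)
  expect_setequal(cs[["E:501-600"]], c("E:501-600", "E:301-400>E:701-800"))
  expect_equal(cs[["E:101-200"]], "E:101-200")
  expect_equal(cs[["E:301-400"]], "E:301-400")
  expect_equal(cs[["E:701-800"]], "E:701-800")

  # linear chain: all singletons
  chain <- build_splice_graph(
    make_tx(cbind(c(1, 201, 401), c(100, 300, 500))))
  expect_true(all(lengths(cross_sections(chain)) == 1))

  # pairwise-order oracle on the toy graph
  g <- toy_graph()
  cs <- cross_sections(g)
  ranks <- setNames(g$nodes$rank, g$nodes$node_id)
  for (e in names(cs)) {
    oracle <- g$edges$edge_id[ranks[g$edges$from] < ranks[e] &
                                ranks[g$edges$to] > ranks[e]]
    expect_setequal(cs[[e]], c(e, oracle))
  }
})

test_that("observability flags exclude exactly the terminal elements", {
  g <- toy_graph()
  term <- g$edges$edge_id[g$edges$from == "source" | g$edges$to == "sink"]
  expect_setequal(g$edges$edge_id[g$edges$touches_terminal], term)
  cov <- cov_from_vectors(
    g, setNames(rep(1, 5), g$nodes$node_id[!g$nodes$is_source &
                                             !g$nodes$is_sink]),
    setNames(rep(1, 5), g$edges$edge_id[!g$edges$touches_terminal]))
  el <- psiflow:::em_elements(g, cov)
  expect_setequal(el$exon_ids,
                  setdiff(g$nodes$node_id, c("source", "sink")))
  expect_setequal(el$junc_ids, setdiff(g$edges$edge_id, term))
})
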