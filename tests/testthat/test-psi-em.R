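test_that("alpha initialization takes top-covered exons up to 10% of transcript length", {
  # one exon covering the whole transcript at depth 20 -> alpha 20
  g1 <- build_splice_graph(
    tibble(gene_id = "G", transcript_id = c("t1", "t1", "t2"),
           chrom = "chr1", strand = "+",
           start = c(101, 301, 101), end = c(200, 400, 200)))
  cov <- cov_from_vectors(g1, c(`E:101-200` = 20, `E:301-400` = 20),
                          c(`E:101-200>E:301-400` = 20), cells = 1)
  expect_equal(initialize_alpha(cov, g1)$alpha_E, 20)

  # hand example: exon (50 bp, cov 100) alone misses the 10% target of a
  # 550 bp transcript, so the 500 bp exon joins -> length-weighted mean
  g2 <- build_splice_graph(
    tibble(gene_id = "G", transcript_id = c("t1", "t1", "t2"),
           chrom = "chr1", strand = "+",
           start = c(101, 301, 101), end = c(150, 800, 150)))
  cov2 <- cov_from_vectors(g2, c(`E:101-150` = 100, `E:301-800` = 10),
                           c(`E:101-150>E:301-800` = 5), cells = 1)
  expect_equal(initialize_alpha(cov2, g2)$alpha_E,
               (50 * 100 + 500 * 10) / 550)

  # ties in coverage resolve deterministically across runs
  covt <- cov_from_vectors(g1, c(`E:101-200` = 7, `E:301-400` = 7),
                           c(`E:101-200>E:301-400` = 7), cells = 3)
  expect_identical(initialize_alpha(covt, g1), initialize_alpha(covt, g1))
})

test_that("a consistent system yields PSI = 1 everywhere with zero residual", {
  g <- build_splice_graph(
    tibble(gene_id = "G", transcript_id = "t1", chrom = "chr1", strand = "+",
           start = c(101, 301, 501), end = c(200, 400, 600)))
  # linear chain is sequential (would be filtered), but the solver must
  # still treat it exactly
  ex <- setNames(rep(30, 3), g$nodes$node_id[2:4])
  jn <- setNames(rep(30, 2), g$edges$edge_id[!g$edges$touches_terminal])
  cov <- cov_from_vectors(g, ex, jn, cells = 1)
  psi <- expectation_step(g, cov, "c01", alpha = c(30, 30))
  expect_equal(unname(psi), rep(1, length(psi)), tolerance = 1e-8)
})

test_that("expectation solutions match a dense constrained-least-squares oracle", {
  skip_if_not_installed("pracma")
  cfg <- em_config()
  cases <- list(toy = toy_graph(), skip = skip_graph())
  withr::with_seed(31, {
    for (g in cases) {
      real <- g$nodes$node_id[!g$nodes$is_source & !g$nodes$is_sink]
      junc <- g$edges$edge_id[!g$edges$touches_terminal]
      for (rep in 1:5) {
        ex <- setNames(runif(length(real), 0, 40), real)
        jn <- setNames(rpois(length(junc), 12), junc)
        cov <- cov_from_vectors(g, ex, jn, cells = 1)
        alpha <- c(runif(1, 10, 40), runif(1, 10, 40))
        prior <- if (rep %% 2 == 0) {
          ids <- c(g$nodes$node_id[order(g$nodes$rank)], g$edges$edge_id)
          setNames(runif(length(ids)), ids)
        } else NULL
        psi <- expectation_step(g, cov, "c01", alpha, prior = prior,
                                cfg = cfg)
        bd <- brute_design(g, cov, "c01", alpha, prior = prior, cfg = cfg)
        oracle <- pracma::lsqnonneg(bd$A, bd$y)$x
        expect_equal(unname(psi[bd$ids]), oracle, tolerance = 1e-6)
      }
    }
  })
})

test_that("a dominating similarity weight pins the solution to a flow-consistent prior", {
  g <- skip_graph()
  ids <- c(g$nodes$node_id[order(g$nodes$rank)], g$edges$edge_id)
  # flow-consistent target: 70/30 split at the E3 cassette
  prior <- setNames(rep(1, length(ids)), ids)
  prior["E:501-600"] <- 0.7
  prior["E:301-400>E:501-600"] <- 0.7
  prior["E:501-600>E:701-800"] <- 0.7
  prior["E:301-400>E:701-800"] <- 0.3
  ex <- setNames(rep(10, 4), g$nodes$node_id[2:5])
  jn <- setNames(rep(10, 4), g$edges$edge_id[!g$edges$touches_terminal])
  cov <- cov_from_vectors(g, ex, jn, cells = 1)
  psi <- expectation_step(g, cov, "c01", alpha = c(10, 10), prior = prior,
                          cfg = em_config(w_sim = 1e6))
  expect_equal(unname(psi[ids]), unname(prior), tolerance = 1e-3)
})

test_that("the intermediate rescale makes cross-section sums average exactly one", {
  # all cross-section sums equal to 2 -> every value halves (linear chain,
  # where every cross section is a singleton exon)
  chain <- build_splice_graph(
    tibble(gene_id = "G", transcript_id = "t1", chrom = "chr1",
           strand = "+", start = c(1, 201, 401), end = c(100, 300, 500)))
  cids <- c(chain$nodes$node_id, chain$edges$edge_id)
  psi2 <- setNames(rep(2, length(cids)), cids)
  out <- intermediate_rescale(psi2, cross_sections(chain))
  expect_equal(unname(out), rep(1, length(cids)))

  g <- skip_graph()
  sections <- cross_sections(g)
  ids <- c(g$nodes$node_id, g$edges$edge_id)
  # a flow-consistent 60/40 split has sums (1,1,1,1): unchanged
  psi <- setNames(rep(1, length(ids)), ids)
  psi["E:501-600"] <- 0.6
  psi["E:301-400>E:501-600"] <- 0.6
  psi["E:501-600>E:701-800"] <- 0.6
  psi["E:301-400>E:701-800"] <- 0.4
  expect_equal(intermediate_rescale(psi, sections), psi)

  # random vectors: recompute the average cross-section sum directly
  withr::with_seed(8, {
    for (rep in 1:10) {
      p <- setNames(runif(length(ids), 0, 2), ids)
      r <- intermediate_rescale(p, sections)
      mean_sum <- mean(vapply(sections, function(s) sum(r[s]), numeric(1)))
      expect_equal(mean_sum, 1, tolerance = 1e-12)
    }
  })

  # degenerate all-zero vector is flagged by NA
  expect_true(all(is.na(intermediate_rescale(setNames(numeric(length(ids)),
                                                      ids), sections))))
})

test_that("closed-form maximization equals the stated minimization", {
  g <- build_splice_graph(
    tibble(gene_id = "G", transcript_id = c("t1", "t1", "t2"),
           chrom = "chr1", strand = "+",
           start = c(101, 301, 101), end = c(200, 400, 200)))
  ids <- c(g$nodes$node_id[order(g$nodes$rank)], g$edges$edge_id)

  # uniform coverage 30 at PSI 1 -> both alphas 30
  cov <- cov_from_vectors(g, c(`E:101-200` = 30, `E:301-400` = 30),
                          c(`E:101-200>E:301-400` = 30), cells = 1)
  psi <- setNames(rep(1, length(ids)), ids)
  expect_equal(unname(maximization_step(psi, g, cov, "c01")), c(30, 30))

  # hand computation with equal lengths: alpha_E = 10
  cov2 <- cov_from_vectors(g, c(`E:101-200` = 10, `E:301-400` = 5),
                           c(`E:101-200>E:301-400` = 5), cells = 1)
  psi2 <- psi; psi2["E:301-400"] <- 0.5
  a <- maximization_step(psi2, g, cov2, "c01")
  expect_equal(unname(a["alpha_E"]),
               (100 * 10 * 1 + 100 * 5 * 0.5) / (100 * 1 + 100 * 0.25))

  # random instances against a numeric 1-D minimizer
  withr::with_seed(13, {
    for (rep in 1:10) {
      ex <- setNames(runif(2, 0, 50),
                     c("E:101-200", "E:301-400"))
      jn <- setNames(rpois(1, 20), "E:101-200>E:301-400")
      cv <- cov_from_vectors(g, ex, jn, cells = 1)
      p <- setNames(runif(length(ids), 0.05, 1), ids)
      a <- maximization_step(p, g, cv, "c01")
      le <- c(100, 100)
      pe <- p[c("E:101-200", "E:301-400")]
      obj_e <- function(x) sum(le * (ex - pe * x)^2)
      pj <- p["E:101-200>E:301-400"]
      obj_j <- function(x) (jn - pj * x)^2
      expect_equal(unname(a["alpha_E"]),
                   optimize(obj_e, c(0, 2000))$minimum, tolerance = 1e-4)
      expect_equal(unname(a["alpha_J"]),
                   optimize(obj_j, c(0, 2000))$minimum, tolerance = 1e-4)
    }
  })
})

test_that("EM converges to the truth on noise-free simulated data", {
  sim <- noiseless_sim(n_genes = 3, n_cells = 10, seed = 41)
  res <- quantify_dataset(sim, k = 10)
  expect_gt(nrow(res$psi), 0)
  truth <- truth_psi_per_cell(sim)
  joined <- res$psi |>
    inner_join(truth, by = c("gene_id", "element_id", "cell_id")) |>
    filter(!is.na(psi))
  expect_gt(nrow(joined), 0)
  expect_lt(max(abs(joined$psi - joined$psi_true)), 0.05)

  # flow residual and source/sink pinning on the full element set
  for (gid in names(res$fits)) {
    fit <- res$fits[[gid]]
    g <- res$graphs[[gid]]
    psi <- fit$psi[which(fit$alpha$kept)[1], ]
    for (i in seq_len(nrow(g$nodes))) {
      n <- g$nodes[i, ]
      inc <- g$edges$edge_id[g$edges$to == n$node_id]
      out <- g$edges$edge_id[g$edges$from == n$node_id]
      if (!n$is_source) expect_lt(abs(psi[n$node_id] - sum(psi[inc])), 0.05)
      if (!n$is_sink) expect_lt(abs(psi[n$node_id] - sum(psi[out])), 0.05)
    }
    expect_lt(abs(psi["source"] - 1), 0.02)
    expect_lt(abs(psi["sink"] - 1), 0.02)
  }
})

test_that("PSI is invariant to a 10x depth scaling while alpha scales", {
  sim <- noiseless_sim(n_genes = 1, n_cells = 8, seed = 17)
  gid <- names(sim$coverage)[1]
  g <- build_graphs(sim$annotation, sim$coverage)[[gid]]
  cov <- sim$coverage[[gid]]
  fit1 <- run_em(g, cov)
  cov10 <- cov
  cell <- rownames(cov$exon_cov)[1]
  cov10$exon_cov[cell, ] <- 10 * cov10$exon_cov[cell, ]
  cov10$junction_count[cell, ] <- 10 * cov10$junction_count[cell, ]
  fit10 <- run_em(g, cov10)
  expect_equal(fit10$psi[cell, ], fit1$psi[cell, ], tolerance = 1e-3)
  a1 <- fit1$alpha |> filter(cell_id == cell)
  a10 <- fit10$alpha |> filter(cell_id == cell)
  expect_equal(a10$alpha_E, 10 * a1$alpha_E, tolerance = 1e-3)
  expect_equal(a10$alpha_J, 10 * a1$alpha_J, tolerance = 1e-3)
})

test_that("results do not depend on cell processing order", {
  sim <- simulate_dataset("allAnnot", n_genes = 1, n_cells_per_type = 10,
                          seed = 23)
  gid <- names(sim$coverage)[1]
  g <- build_graphs(sim$annotation, sim$coverage)[[gid]]
  cov <- sim$coverage[[gid]]
  perm <- rev(seq_len(nrow(cov$exon_cov)))
  cov_perm <- coverage_table(gid, cov$exon_cov[perm, ],
                             cov$junction_count[perm, ], cov$lowq[perm])
  f1 <- run_em(g, cov)
  f2 <- run_em(g, cov_perm)
  cells <- rownames(f1$psi)
  expect_identical(f1$psi[cells, ], f2$psi[cells, ])
})

test_that("neighbor similarity improves low-coverage cells over no similarity", {
  # two cell types with distinct splice patterns; a subset of cells gets
  # their depth scaled down so coverage evidence alone is weak
  sim <- simulate_dataset("allAnnot", n_genes = 4, n_cells_per_type = 25,
                          seed = 57, cov_dispersion = 0.6,
                          gene_depth_meanlog = log(20), gene_depth_sdlog = 0)
  truth <- truth_psi_per_cell(sim)
  err_for <- function(w_sim) {
    res <- quantify_dataset(sim, cfg = em_config(w_sim = w_sim), k = 24)
    basepair_abs_error(res$psi, truth, sim$truth$lengths)$error
  }
  e_sim <- err_for(4)
  e_none <- err_for(1e-9)
  expect_lt(mean(e_sim), mean(e_none))
})
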