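#' Per-cell coverage tables for a gene
#'
#' A coverage table holds, for one gene, the observed evidence used by the
#' PSI model: mean per-base exon depth, junction-spanning read counts, and
#' the per-cell fraction of low-quality (MAPQ < 10) gene reads.
#'
#' @param gene_id Gene identifier.
#' @param exon_cov Numeric matrix, cells x exon-interval keys
#'   (`"<start>-<end>"`), mean per-base read depth.
#' @param junction_count Numeric matrix, cells x junction keys
#'   (`"<donorEnd>-<acceptorStart>"`), junction-spanning read counts.
#' @param lowq Named numeric vector per cell, fraction of gene reads with
#'   MAPQ < 10 (0 when the cell has no reads).
#' @return A `coverage_table` object (list with the components above).
#' @export
coverage_table <- function(gene_id, exon_cov, junction_count, lowq) {
  stopifnot(is.matrix(exon_cov), is.matrix(junction_count),
            nrow(exon_cov) == nrow(junction_count),
            all(is.finite(exon_cov)), all(exon_cov >= 0),
            all(is.finite(junction_count)), all(junction_count >= 0))
  if (is.null(names(lowq))) names(lowq) <- rownames(exon_cov)
  structure(list(gene_id = gene_id, exon_cov = exon_cov,
                 junction_count = junction_count, lowq = lowq),
            class = "coverage_table")
}

#' @export
print.coverage_table <- function(x, ...) {
  cat("<coverage_table> ", x$gene_id, ": ", nrow(x$exon_cov), " cells, ",
      ncol(x$exon_cov), " exon intervals, ", ncol(x$junction_count),
      " junctions\n", sep = "")
  invisible(x)
}

read_cell_alignments <- function(bam, region) {
  param <- Rsamtools::ScanBamParam(
    which = region,
    what = c("mapq"),
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isDuplicate = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isUnmappedQuery = FALSE)
  )
  GenomicAlignments::readGAlignments(bam, param = param)
}

#' Mean per-base exon coverage from per-cell BAM files
#'
#' For every exon of the graph and every cell, computes the sum over exon
#' bases of aligned read depth divided by exon length. Spliced reads
#' contribute only their aligned blocks (CIGAR `N` gaps excluded). Reads with
#' MAPQ below `min_mapq`, secondary/supplementary alignments and duplicates
#' are excluded (low-MAPQ reads are only tracked by [lowq_fraction()]).
#'
#' @param bam_files Named character vector of coordinate-sorted, indexed BAM
#'   files, one per cell (names are cell ids).
#' @param graph A `splice_graph`.
#' @param min_mapq MAPQ threshold below which reads are ignored (default 10).
#' @return Numeric matrix, cells x exon-interval keys.
#' @export
exon_coverage <- function(bam_files, graph, min_mapq = 10L) {
  real <- graph$nodes |> filter(!.data$is_source, !.data$is_sink)
  span <- gene_span(graph)
  keys <- paste0(real$start, "-", real$end)
  out <- matrix(0, nrow = length(bam_files), ncol = nrow(real),
                dimnames = list(names(bam_files), keys))
  for (i in seq_along(bam_files)) {
    gal <- read_cell_alignments(bam_files[[i]], span)
    gal <- gal[!is.na(S4Vectors::mcols(gal)$mapq) &
                 S4Vectors::mcols(gal)$mapq >= min_mapq]
    if (length(gal) == 0L) next
    cov <- GenomicAlignments::coverage(gal)[[graph$chrom]]
    v <- as.numeric(cov)
    for (j in seq_len(nrow(real))) {
      s <- real$start[j]; e <- real$end[j]
      depth <- if (s > length(v)) 0 else sum(v[s:min(e, length(v))])
      out[i, j] <- depth / real$length[j]
    }
  }
  out
}

#' Junction-spanning read counts from per-cell BAM files
#'
#' A read supports a junction when it carries a CIGAR `N` gap whose
#' coordinates exactly match the junction's donor/acceptor sites; gaps off by
#' even one base are not counted. Reads aligned contiguously across the
#' internal boundary of a split (partial) exon are counted for the
#' corresponding containment edge.
#'
#' @inheritParams exon_coverage
#' @return Numeric matrix, cells x junction keys, covering every non-terminal
#'   edge of the graph plus any other observed gap (candidate novel
#'   junctions).
#' @export
junction_counts <- function(bam_files, graph, min_mapq = 10L) {
  span <- gene_span(graph)
  cont <- graph$edges |> filter(.data$is_containment)
  rows <- vector("list", length(bam_files))
  for (i in seq_along(bam_files)) {
    gal <- read_cell_alignments(bam_files[[i]], span)
    gal <- gal[!is.na(S4Vectors::mcols(gal)$mapq) &
                 S4Vectors::mcols(gal)$mapq >= min_mapq]
    counts <- list()
    if (length(gal) > 0L) {
      gaps <- GenomicAlignments::junctions(gal)
      flat <- unlist(gaps, use.names = FALSE)
      if (length(flat) > 0L) {
        key <- junction_key(GenomicRanges::start(flat) - 1L,
                            GenomicRanges::end(flat) + 1L)
        tab <- table(key)
        counts <- as.list(as.numeric(tab))
        names(counts) <- names(tab)
      }
      if (nrow(cont) > 0L) {
        blocks <- GenomicAlignments::grglist(gal)
        bl <- as.data.frame(blocks)   # one row per aligned block, with group
        for (k in seq_len(nrow(cont))) {
          bnd <- as.integer(sub("-.*", "", cont$key[k]))
          spans <- bl$start <= bnd & bl$end >= bnd + 1L
          counts[[cont$key[k]]] <- length(unique(bl$group[spans]))
        }
      }
    }
    rows[[i]] <- counts
  }
  all_keys <- sort(unique(unlist(purrr::map(rows, names))))
  out <- matrix(0, nrow = length(bam_files), ncol = length(all_keys),
                dimnames = list(names(bam_files), all_keys))
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) > 0L) {
      out[i, names(rows[[i]])] <- unlist(rows[[i]])
    }
  }
  out
}

#' Fraction of low-quality gene reads per cell
#'
#' Fraction of mapped reads overlapping the gene span that have MAPQ below
#' `min_mapq`; 0 for cells with no reads. Cells where this fraction exceeds
#' 10% are later excluded from PSI estimation ([filter_cells()]).
#'
#' @inheritParams exon_coverage
#' @return Named numeric vector, one fraction per cell.
#' @export
lowq_fraction <- function(bam_files, graph, min_mapq = 10L) {
  span <- gene_span(graph)
  out <- setNames(numeric(length(bam_files)), names(bam_files))
  for (i in seq_along(bam_files)) {
    gal <- read_cell_alignments(bam_files[[i]], span)
    if (length(gal) == 0L) next
    mapq <- S4Vectors::mcols(gal)$mapq
    out[i] <- mean(!is.na(mapq) & mapq < min_mapq)
  }
  out
}

gene_span <- function(graph) {
  real <- graph$nodes |> filter(!.data$is_source, !.data$is_sink)
  GenomicRanges::GRanges(graph$chrom,
                         IRanges::IRanges(min(real$start), max(real$end)))
}

#' Assemble a coverage table for a gene from per-cell BAM files
#'
#' Convenience wrapper around [exon_coverage()], [junction_counts()] and
#' [lowq_fraction()].
#'
#' @inheritParams exon_coverage
#' @return A [coverage_table()].
#' @export
coverage_from_bam <- function(bam_files, graph, min_mapq = 10L) {
  coverage_table(graph$gene_id,
                 exon_coverage(bam_files, graph, min_mapq),
                 junction_counts(bam_files, graph, min_mapq),
                 lowq_fraction(bam_files, graph, min_mapq))
}

#' Read and write coverage tables as TSV
#'
#' The on-disk layout is one directory per gene holding `exon_cov.tsv`
#' (rows = exon interval keys, columns = cells), `junction_counts.tsv`
#' (rows = junction keys) and `lowq.tsv` (cell, fraction). This is also the
#' simulator's native output, so the whole pipeline can run without BAMs.
#'
#' @param cov A `coverage_table` (for writing).
#' @param dir Directory for this gene's tables.
#' @param gene_id Gene identifier (for reading).
#' @return `write_coverage_tsv()` returns `dir` invisibly;
#'   `read_coverage_tsv()` returns a [coverage_table()].
#' @export
write_coverage_tsv <- function(cov, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(m, f) {
    tibble::as_tibble(t(m), rownames = "element") |>
      readr::write_tsv(file.path(dir, f))
  }
  wr(cov$exon_cov, "exon_cov.tsv")
  wr(cov$junction_count, "junction_counts.tsv")
  tibble(cell = names(cov$lowq), lowq = unname(cov$lowq)) |>
    readr::write_tsv(file.path(dir, "lowq.tsv"))
  invisible(dir)
}

#' @rdname write_coverage_tsv
#' @export
read_coverage_tsv <- function(dir, gene_id = basename(dir)) {
  rd <- function(f) {
    d <- readr::read_tsv(file.path(dir, f), show_col_types = FALSE)
    m <- t(as.matrix(d[, -1, drop = FALSE]))
    colnames(m) <- d$element
    m
  }
  lowq <- readr::read_tsv(file.path(dir, "lowq.tsv"), show_col_types = FALSE)
  coverage_table(gene_id, rd("exon_cov.tsv"), rd("junction_counts.tsv"),
                 setNames(lowq$lowq, lowq$cell))
}
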