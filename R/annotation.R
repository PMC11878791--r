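#' Read exon annotation from a GTF/GFF file
#'
#' Parses a GTF (or GFF) annotation and returns one row per exon, ordered
#' 5'->3' within each transcript. Only `exon` features are used; they must
#' carry `gene_id` and `transcript_id` attributes (Ensembl/GENCODE dialects).
#'
#' @param path Path to a GTF or GFF file (uncompressed or gzipped).
#' @return A tibble with columns `gene_id`, `transcript_id`, `chrom`,
#'   `strand` (`"+"` or `"-"`), `start`, `end` (1-based, inclusive) and
#'   `exon_rank` (position of the exon within the transcript, in transcript
#'   direction). Transcripts with zero exons are dropped with a warning.
#' @examples
#' gtf <- system.file("extdata", "toy.gtf", package = "psiflow")
#' read_annotation(gtf)
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[tolower(as.character(gr$type)) == "exon"]
  if (length(gr) == 0L) abort("no exon features found in annotation")
  need <- c("gene_id", "transcript_id")
  miss <- setdiff(need, names(S4Vectors::mcols(gr)))
  if (length(miss) > 0L) {
    abort(paste0("annotation lacks required attribute(s): ",
                 paste(miss, collapse = ", ")))
  }
  tbl <- tibble(
    gene_id       = as.character(gr$gene_id),
    transcript_id = as.character(gr$transcript_id),
    chrom         = as.character(GenomicRanges::seqnames(gr)),
    strand        = as.character(GenomicRanges::strand(gr)),
    start         = GenomicRanges::start(gr),
    end           = GenomicRanges::end(gr)
  )
  if (anyNA(tbl$gene_id) || anyNA(tbl$transcript_id)) {
    abort("exon feature with missing gene_id/transcript_id attribute")
  }
  tbl$strand[!tbl$strand %in% c("+", "-")] <- "+"
  multi <- tbl |>
    distinct(.data$gene_id, .data$chrom) |>
    count(.data$gene_id) |>
    filter(.data$n > 1L)
  if (nrow(multi) > 0L) {
    abort(paste0("gene annotated on multiple chromosomes: ",
                 paste(multi$gene_id, collapse = ", ")))
  }
  sort_exons(tbl)
}

# order exons 5'->3' within transcript and assign exon_rank
sort_exons <- function(tbl) {
  tbl |>
    group_by(.data$gene_id, .data$transcript_id) |>
    arrange(if (first(.data$strand) == "-") dplyr::desc(.data$start) else .data$start,
            .by_group = TRUE) |>
    mutate(exon_rank = dplyr::row_number()) |>
    ungroup() |>
    arrange(.data$gene_id, .data$transcript_id, .data$exon_rank)
}

#' Write an exon annotation tibble to GTF
#'
#' Inverse of [read_annotation()] for the columns psiflow uses. Written
#' features are `exon` rows with `gene_id` and `transcript_id` attributes.
#'
#' @param annotation Tibble as returned by [read_annotation()].
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges   = IRanges::IRanges(annotation$start, annotation$end),
    strand   = annotation$strand,
    type          = "exon",
    gene_id       = annotation$gene_id,
    transcript_id = annotation$transcript_id
  )
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}
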