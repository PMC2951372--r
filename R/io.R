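## feature_type <-> GFF3/SO type vocabulary
gff_type_map <- c(gene = "gene", pseudogene = "pseudogene",
                  TE = "transposable_element",
                  TEG = "transposable_element_gene")

#' Write an annotation as GFF3
#'
#' In-memory coordinates are 0-based half-open; on disk GFF3 is 1-based
#' inclusive, so `start + 1` is written.
#'
#' @param annotation annotation data.frame.
#' @param path output file.
#' @export
write_gff3 <- function(annotation, path) {
  gr <- as_granges(annotation)
  S4Vectors::mcols(gr)$source <- "tilemark"
  S4Vectors::mcols(gr)$type <- unname(gff_type_map[annotation$feature_type])
  S4Vectors::mcols(gr)$ID <- annotation$feature_id
  sf <- annotation$superfamily
  sf[sf == ""] <- NA_character_
  S4Vectors::mcols(gr)$superfamily <- sf
  GenomicRanges::strand(gr) <- annotation$strand
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 annotation
#'
#' Converts 1-based inclusive coordinates to the in-memory 0-based half-open
#' convention. Features whose type is outside the gene / pseudogene /
#' transposable-element vocabulary are skipped (count reported via message).
#'
#' @param path GFF3 file.
#' @return annotation data.frame (see [generate_annotation()]).
#' @export
read_gff3 <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stopf("malformed GFF3 '%s': %s", path,
                                           conditionMessage(e)))
  type <- as.character(S4Vectors::mcols(gr)$type)
  known <- type %in% gff_type_map
  n_skip <- sum(!known)
  if (n_skip > 0)
    message(sprintf("read_gff3: skipped %d feature(s) of unknown type",
                    n_skip))
  gr <- gr[known]
  type <- type[known]
  ids <- S4Vectors::mcols(gr)$ID
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stopf("GFF3 feature without an ID attribute in '%s'", path)
  sf <- S4Vectors::mcols(gr)$superfamily
  if (is.null(sf)) sf <- rep(NA_character_, length(gr))
  sf[is.na(sf)] <- ""
  rev_map <- stats::setNames(names(gff_type_map), gff_type_map)
  ann <- data.frame(
    feature_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    feature_type = unname(rev_map[type]),
    superfamily = as.character(sf),
    stringsAsFactors = FALSE)
  ann$strand[!ann$strand %in% c("+", "-")] <- "+"
  ann <- ann[order(ann$chrom, ann$start), , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

#' Write intervals as BED
#'
#' BED is natively 0-based half-open, matching the in-memory convention.
#' Scores are clamped to the BED range `[0, 1000]` on write.
#'
#' @param intervals data.frame with `chrom`, `start`, `end` and optionally
#'   `name` (or `region_id`) and `score` (or `region_score`).
#' @param path output file.
#' @export
write_bed <- function(intervals, path) {
  if (any(intervals$start < 0)) stopf("negative BED coordinates")
  nm <- if (!is.null(intervals$name)) intervals$name else intervals$region_id
  sc <- if (!is.null(intervals$score)) intervals$score else
    intervals$region_score
  cols <- data.frame(chrom = intervals$chrom, start = intervals$start,
                     end = intervals$end)
  if (!is.null(nm)) {
    cols$name <- nm
    cols$score <- if (is.null(sc)) 0 else pmin(pmax(sc, 0), 1000)
    cols$strand <- "."
  }
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3/BED6 file
#'
#' @param path BED file.
#' @param sorted sort by (chrom, start) (default); `FALSE` preserves file
#'   order.
#' @return data.frame `chrom`, `start`, `end` and, when present, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path, sorted = TRUE) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 6L) names(df)[4:6] <- c("name", "score", "strand")
  if (any(df$start < 0)) stopf("negative BED coordinates in '%s'", path)
  if (sorted) df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a score track as bedGraph
#'
#' @param scores score track data.frame (`chrom`, `start`, `end`, `score`).
#' @param path output file.
#' @export
write_bedgraph <- function(scores, path) {
  utils::write.table(scores[, c("chrom", "start", "end", "score")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph score track
#'
#' @param path bedGraph file.
#' @return score track data.frame sorted by (chrom, start).
#' @export
read_bedgraph <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "score"),
                          stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Tab-separated table I/O
#'
#' Thin wrappers fixing the dialect used by every table the pipeline writes:
#' header row, tab separator, no quoting, no row names.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `read_tsv()` returns a data.frame.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
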