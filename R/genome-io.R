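#' Read a BED file of intervals or aligned reads
#'
#' Parses 3- or 6-column BED. Coordinates in the file are 0-based
#' half-open and are converted to the 1-based closed convention used by
#' \code{GRanges}; \code{\link{writeBed}} reverses the conversion, so
#' round-trips preserve coordinates exactly. When a strand column
#' (column 6) is present it is kept, so aligned single-end reads can be
#' loaded with their orientation; name and score columns are ignored.
#'
#' @param path path to a tab- or whitespace-delimited BED file.
#' @param layout optional named vector of chromosome lengths; records on
#'   chromosomes absent from the layout raise an error.
#' @return a \code{GRanges}, in file order, with strand when column 6 is
#'   present and \code{*} otherwise.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t250\tr1\t0\t-", f)
#' readBed(f)
#' @export
readBed <- function(path, layout = NULL) {
  stopIfNot(file.exists(path), "no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(gr0(character(), integer(), integer(), layout = layout))
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf < 3L)
  if (length(bad))
    stop("BED parse error at line ", bad[1L], ": fewer than 3 columns")
  chrom <- vapply(fields, `[`, "", 1L)
  s <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  e <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(s) | is.na(e) | s != floor(s) | e != floor(e))
  if (length(bad))
    stop("BED parse error at line ", bad[1L], ": non-integer coordinates")
  bad <- which(e <= s | s < 0)
  if (length(bad))
    stop("BED parse error at line ", bad[1L],
         ": end must exceed start and start must be >= 0")
  strand <- rep("*", length(lines))
  has6 <- nf >= 6L
  if (any(has6)) {
    st <- vapply(fields[has6], `[`, "", 6L)
    bad <- which(!st %in% c("+", "-"))
    if (length(bad))
      stop("BED parse error at line ", which(has6)[bad[1L]],
           ": strand must be '+' or '-'")
    strand[has6] <- st
  }
  gr0(chrom, s, e, strand = strand, layout = layout)
}

#' Write intervals as BED
#'
#' Emits 3 columns, or 6 (with dot name and zero score) when any range is
#' stranded. Coordinates are written 0-based half-open.
#'
#' @param gr a \code{GRanges}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeBed <- function(gr, path) {
  stranded <- any(as.character(strand(gr)) != "*")
  if (length(gr) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  if (stranded) {
    out <- sprintf("%s\t%d\t%d\t.\t0\t%s",
                   as.character(seqnames(gr)), start0(gr), end0(gr),
                   as.character(strand(gr)))
  } else {
    out <- sprintf("%s\t%d\t%d",
                   as.character(seqnames(gr)), start0(gr), end0(gr))
  }
  writeLines(out, path)
  invisible(path)
}

#' Write a per-window signal track as bedGraph
#'
#' @param track \code{GRanges} with a numeric \code{score} metadata
#'   column; windows must be non-overlapping and sorted within each
#'   chromosome.
#' @param path output path.
#' @return the path, invisibly. Scores are written with 6 decimals, so a
#'   round-trip through \code{\link{readBedGraph}} reproduces them to
#'   that precision.
#' @export
writeBedGraph <- function(track, path) {
  if (length(track) > 0L) {
    stopIfNot(!is.null(mcols(track)$score),
              "track must carry a 'score' metadata column")
    bychr <- split(track, as.character(seqnames(track)))
    for (i in seq_along(bychr)) {
      gr <- bychr[[i]]
      if (length(gr) > 1L) {
        o <- order(start(gr))
        if (any(start(gr)[o][-1L] <= end(gr)[o][-length(gr)]))
          stop("bedGraph windows must be non-overlapping")
        if (is.unsorted(start(gr)))
          stop("bedGraph windows must be sorted within chromosome")
      }
    }
    out <- sprintf("%s\t%d\t%d\t%.6f",
                   as.character(seqnames(track)), start0(track),
                   end0(track), mcols(track)$score)
  } else out <- character()
  writeLines(out, path)
  invisible(path)
}

#' Read a bedGraph track
#'
#' @param path path to a 4-column bedGraph file.
#' @param layout optional named chromosome-length vector.
#' @return \code{GRanges} with a \code{score} metadata column.
#' @export
readBedGraph <- function(path, layout = NULL) {
  stopIfNot(file.exists(path), "no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    gr <- gr0(character(), integer(), integer(), layout = layout)
    mcols(gr)$score <- numeric()
    return(gr)
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(fields) < 4L)
  if (length(bad))
    stop("bedGraph parse error at line ", bad[1L], ": need 4 columns")
  gr <- gr0(vapply(fields, `[`, "", 1L),
            as.numeric(vapply(fields, `[`, "", 2L)),
            as.numeric(vapply(fields, `[`, "", 3L)),
            layout = layout)
  mcols(gr)$score <- as.numeric(vapply(fields, `[`, "", 4L))
  gr
}

#' Read a gene annotation table
#'
#' Expects 5 tab-separated columns without header: gene id, chromosome,
#' TSS, TES, strand. TSS and TES are 0-based base positions; the TSS is
#' the biological transcription start regardless of numeric order, so
#' minus-strand genes have TSS > TES. The gene body is the half-open span
#' from the smaller to the larger of the two.
#'
#' @param path path to the table.
#' @param layout optional named chromosome-length vector.
#' @return \code{GRanges} of gene bodies with strand and metadata columns
#'   \code{gene_id}, \code{tss}, \code{tes} (0-based positions).
#' @export
readGeneTable <- function(path, layout = NULL) {
  stopIfNot(file.exists(path), "no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(makeGeneTable(character(), character(),
                                                integer(), integer(),
                                                character(), layout))
  fields <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(fields) < 5L)
  if (length(bad))
    stop("gene table parse error at line ", bad[1L], ": need 5 columns")
  gene_id <- vapply(fields, `[`, "", 1L)
  chrom <- vapply(fields, `[`, "", 2L)
  tss <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  tes <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 4L)))
  st <- vapply(fields, `[`, "", 5L)
  bad <- which(is.na(tss) | is.na(tes))
  if (length(bad))
    stop("gene table parse error at line ", bad[1L],
         ": non-integer coordinates")
  bad <- which(!st %in% c("+", "-"))
  if (length(bad))
    stop("gene table parse error at line ", bad[1L],
         ": strand must be '+' or '-'")
  makeGeneTable(gene_id, chrom, tss, tes, st, layout)
}

#' Construct a gene table in memory
#'
#' @param gene_id,chrom,tss,tes,strand parallel vectors; see
#'   \code{\link{readGeneTable}} for conventions.
#' @param layout optional named chromosome-length vector.
#' @return \code{GRanges} of gene bodies (see \code{\link{readGeneTable}}).
#' @export
makeGeneTable <- function(gene_id, chrom, tss, tes, strand,
                          layout = NULL) {
  if (anyDuplicated(gene_id))
    stop("duplicate gene_id: ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  if (any(tss == tes)) stop("tss must differ from tes")
  lo <- pmin(tss, tes)
  hi <- pmax(tss, tes)
  gr <- gr0(chrom, lo, hi, strand = strand, layout = layout)
  mcols(gr)$gene_id <- gene_id
  mcols(gr)$tss <- tss
  mcols(gr)$tes <- tes
  gr
}

#' Write a gene table
#' @param genes gene \code{GRanges} from \code{\link{readGeneTable}} or
#'   \code{\link{makeGeneTable}}.
#' @param path output path.
#' @export
writeGeneTable <- function(genes, path) {
  out <- sprintf("%s\t%s\t%d\t%d\t%s",
                 mcols(genes)$gene_id, as.character(seqnames(genes)),
                 as.integer(mcols(genes)$tss),
                 as.integer(mcols(genes)$tes),
                 as.character(strand(genes)))
  writeLines(out, path)
  invisible(path)
}

#' Read a genome layout (chromosome lengths)
#'
#' @param path 2-column "chrom<TAB>length" file.
#' @return named numeric vector of chromosome lengths, in file order.
#' @export
readGenomeLayout <- function(path) {
  stopIfNot(file.exists(path), "no such file: ", path)
  tb <- utils::read.table(path, sep = "", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  if (anyDuplicated(tb$chrom)) stop("duplicate chromosome in layout")
  checkLayout(stats::setNames(tb$length, tb$chrom))
}

#' Write a genome layout
#' @param layout named chromosome-length vector.
#' @param path output path.
#' @export
writeGenomeLayout <- function(layout, path) {
  layout <- checkLayout(layout)
  writeLines(sprintf("%s\t%d", names(layout), as.integer(layout)), path)
  invisible(path)
}

#' Read a gene-expression table
#'
#' @param path 2-column "gene_id<TAB>expression" file, no header.
#' @return named numeric vector of expression values.
#' @export
readExpressionTable <- function(path) {
  stopIfNot(file.exists(path), "no such file: ", path)
  tb <- utils::read.table(path, sep = "", header = FALSE,
                          col.names = c("gene_id", "expression"),
                          colClasses = c("character", "numeric"))
  if (anyDuplicated(tb$gene_id)) stop("duplicate gene_id in expression table")
  stats::setNames(tb$expression, tb$gene_id)
}

#' Write a gene-expression table
#' @param expression named numeric vector.
#' @param path output path.
#' @export
writeExpressionTable <- function(expression, path) {
  writeLines(sprintf("%s\t%.10g", names(expression), expression), path)
  invisible(path)
}
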