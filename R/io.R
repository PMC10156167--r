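#' Read a Matrix Market count triplet directory
#'
#' Reads the CellRanger-style triplet `matrix.mtx` + `barcodes.tsv` +
#' `features.tsv` (one token per line, no header) into a [CountMatrix-class]
#' with cells as rows. The on-disk matrix is stored features-agnostically as
#' rows = cells, columns = features; 1-based Matrix Market indices are
#' converted internally.
#'
#' @param directory path containing `matrix.mtx`, `barcodes.tsv` and
#'   `features.tsv`.
#' @return A [CountMatrix-class].
#' @examples
#' scr <- simulateScreen(simulationConfig(nCells = 50, seed = 1))
#' d <- file.path(tempdir(), "trip")
#' writeFixture(scr, d)
#' m <- readCountTriplet(file.path(d, "expression"))
#' dim(m)
#' @export
readCountTriplet <- function(directory) {
    mtx <- file.path(directory, "matrix.mtx")
    bcf <- file.path(directory, "barcodes.tsv")
    ftf <- file.path(directory, "features.tsv")
    for (f in c(mtx, bcf, ftf))
        if (!file.exists(f)) stop("missing file: ", f)
    m <- Matrix::readMM(mtx)
    barcodes <- readLines(bcf)
    features <- readLines(ftf)
    if (nrow(m) != length(barcodes))
        stop(sprintf("%s: header declares %d rows but barcodes.tsv has %d lines",
                     mtx, nrow(m), length(barcodes)))
    if (ncol(m) != length(features))
        stop(sprintf("%s: header declares %d columns but features.tsv has %d lines",
                     mtx, ncol(m), length(features)))
    v <- if (inherits(m, "sparseMatrix")) m@x else as.numeric(m)
    if (length(v) && (any(v < 0) || any(v != floor(v))))
        stop(mtx, ": negative or non-integer values in count matrix")
    m <- as(as(as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
    dimnames(m) <- list(barcodes, features)
    new("CountMatrix", counts = m)
}

#' Write a CountMatrix as a Matrix Market triplet directory
#'
#' Emits `matrix.mtx` (general coordinate integer, entries sorted by
#' (column, row) for stable diffs), `barcodes.tsv` and `features.tsv`.
#' Output is bit-identical for identical input.
#'
#' @param x a [CountMatrix-class].
#' @param directory output directory (created if absent).
#' @return `directory`, invisibly.
#' @export
writeCountTriplet <- function(x, directory) {
    stopifnot(is(x, "CountMatrix"))
    dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(directory)) stop("cannot create directory: ", directory)
    m <- as(x@counts, "TsparseMatrix")
    ord <- order(m@j, m@i)
    lines <- c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(m), ncol(m), length(m@x)),
               if (length(m@x)) sprintf("%d %d %d", m@i[ord] + 1L,
                                        m@j[ord] + 1L, as.integer(m@x[ord])))
    writeLines(lines, file.path(directory, "matrix.mtx"))
    writeLines(as.character(barcodes(x)), file.path(directory, "barcodes.tsv"))
    writeLines(as.character(featureIds(x)), file.path(directory, "features.tsv"))
    invisible(directory)
}

#' Read a BED3/BED6 file into a GRanges
#'
#' BED convention (0-based half-open) is converted to the 1-based inclusive
#' convention of [GenomicRanges::GRanges] at the file boundary. Comment,
#' `track` and `browser` lines are skipped. Empty intervals
#' (start >= end) are rejected with the offending line number.
#'
#' @param path BED file path.
#' @return A `GRanges` with optional `name` and `score` metadata columns.
#' @export
readBed <- function(path) {
    raw <- readLines(path)
    keep <- !grepl("^(#|track\\b|browser\\b)", raw) & nzchar(trimws(raw))
    lineno <- which(keep)
    if (!length(lineno))
        return(GenomicRanges::GRanges())
    fields <- strsplit(raw[lineno], "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3))
        stop(sprintf("%s line %d: fewer than 3 BED fields", path,
                     lineno[which(nf < 3)[1]]))
    chrom <- vapply(fields, `[[`, "", 1L)
    start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
    end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
    if (anyNA(start) || anyNA(end))
        stop(sprintf("%s line %d: non-numeric coordinates", path,
                     lineno[which(is.na(start) | is.na(end))[1]]))
    bad <- which(start >= end)
    if (length(bad))
        stop(sprintf("%s line %d: empty or inverted interval (start >= end)",
                     path, lineno[bad[1]]))
    name <- ifelse(nf >= 4, vapply(fields, function(f) f[min(4, length(f))], ""),
                   NA_character_)
    score <- suppressWarnings(as.numeric(
        ifelse(nf >= 5, vapply(fields, function(f) f[min(5, length(f))], ""),
               NA_character_)))
    strand <- ifelse(nf >= 6, vapply(fields, function(f) f[min(6, length(f))], ""),
                     "*")
    strand[!strand %in% c("+", "-")] <- "*"
    gr <- GenomicRanges::GRanges(chrom,
                                 IRanges::IRanges(start + 1, end),
                                 strand = strand)
    S4Vectors::mcols(gr)$name <- name
    S4Vectors::mcols(gr)$score <- score
    gr
}

#' Write a GRanges as BED6
#'
#' Converts back to the BED 0-based half-open convention. `name` and
#' `score` metadata columns are used when present.
#'
#' @param gr a `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(gr, path) {
    mc <- S4Vectors::mcols(gr)
    name <- if ("name" %in% names(mc)) as.character(mc$name) else
        rep(NA_character_, length(gr))
    score <- if ("score" %in% names(mc)) mc$score else rep(NA_real_, length(gr))
    name[is.na(name)] <- "."
    scoretxt <- ifelse(is.na(score), "0", formatReal(score))
    strand <- as.character(GenomicRanges::strand(gr))
    strand[strand == "*"] <- "."
    writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                       as.character(GenomicRanges::seqnames(gr)),
                       GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
                       name, scoretxt, strand),
               path)
    invisible(path)
}

formatReal <- function(x) {
    out <- vapply(x, function(v) {
        if (is.na(v)) return("NA")
        if (is.numeric(v) && v == floor(v) && abs(v) < 1e15)
            return(sprintf("%d", as.integer(v)))
        sprintf("%.17g", v)
    }, "")
    out
}

#' Read / write tab-separated tables
#'
#' Tab-separated UTF-8 with a header row. Reals are serialized with 17
#' significant digits so that p-values down to the double-precision floor
#' survive a round trip. Ragged rows are rejected.
#'
#' @param path file path.
#' @return `readTsv`: a data.frame. `writeTsv`: `path`, invisibly.
#' @export
readTsv <- function(path) {
    raw <- readLines(path)
    if (!length(raw)) stop(path, ": empty file, expected a header row")
    fields <- strsplit(raw, "\t", fixed = TRUE)
    ncols <- length(fields[[1]])
    nf <- lengths(fields)
    # a trailing empty field is dropped by strsplit; tolerate NA-padding only
    bad <- which(nf != ncols & nf != ncols - 1L)
    if (length(bad))
        stop(sprintf("%s line %d: ragged row (%d fields, header has %d)",
                     path, bad[1], nf[bad[1]], ncols))
    utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                      stringsAsFactors = FALSE, check.names = FALSE,
                      colClasses = NA, na.strings = "NA",
                      comment.char = "")
}

#' @rdname readTsv
#' @param x a data.frame.
#' @export
writeTsv <- function(x, path) {
    y <- x
    for (j in seq_along(y)) {
        if (is.double(y[[j]])) y[[j]] <- formatReal(y[[j]])
    }
    utils::write.table(y, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = TRUE, na = "NA", fileEncoding = "UTF-8")
    invisible(path)
}

#' Read a YAML configuration file
#'
#' @param path YAML file mirroring [simulationConfig()] /
#'   [runPipeline()] field names.
#' @return A named list.
#' @export
readConfig <- function(path) yaml::read_yaml(path)

#' Write a JSON report deterministically
#'
#' @param x a named list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeJsonReport <- function(x, path) {
    json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                             null = "null", na = "null")
    writeLines(json, path)
    invisible(path)
}
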