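# Plain-text readers and writers for every pipeline table, MatrixMarket
# counts and GMT gene sets.

.writeTsv <- function(d, path)
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)

.readTsv <- function(path)
    utils::read.delim(path, stringsAsFactors = FALSE)

#' Read and write well tracks, index intensities, chimerism, colonies
#'
#' TSV round-trip for the tabular pipeline inputs/outputs. The writers take
#' the corresponding S4 container and emit its tables; the readers rebuild
#' the container (simulation truth is not serialized to these tables).
#'
#' @param x container to write.
#' @param dir directory for the file(s).
#' @return readers return the container; writers return the written paths,
#'   invisibly.
#' @name pipeline-io
NULL

#' @rdname pipeline-io
#' @export
writeWellTracks <- function(x, dir) {
    stopifnot(is(x, "WellTrackSet"))
    p1 <- file.path(dir, "welltracks.tsv")
    tr <- merge(wellTracks(x), wellData(x)[
        !grepl("^true_", names(wellData(x)))], by = "well_id", sort = FALSE)
    .writeTsv(tr[order(tr$well_id, tr$day),
                 c("well_id", "arm", "day", "cell_count",
                   setdiff(names(tr), c("well_id", "arm", "day",
                                        "cell_count")))], p1)
    paths <- p1
    if (nrow(indexData(x))) {
        p2 <- file.path(dir, "index.tsv")
        .writeTsv(indexData(x), p2)
        paths <- c(paths, p2)
    }
    invisible(paths)
}

#' @rdname pipeline-io
#' @export
readWellTracks <- function(dir) {
    tr <- .readTsv(file.path(dir, "welltracks.tsv"))
    wcols <- setdiff(names(tr), c("day", "cell_count"))
    wells <- unique(tr[wcols])
    ixp <- file.path(dir, "index.tsv")
    index <- if (file.exists(ixp)) .readTsv(ixp) else
        data.frame(well_id = character(), marker = character(),
                   intensity = numeric())
    WellTrackSet(wells = wells,
                 tracks = tr[c("well_id", "day", "cell_count")],
                 index = index)
}

#' @rdname pipeline-io
#' @export
writeChimerism <- function(x, dir) {
    p <- file.path(dir, "chimerism.tsv")
    .writeTsv(chimerismRecords(x), p)
    invisible(p)
}

#' @rdname pipeline-io
#' @export
readChimerism <- function(dir)
    ChimerismSet(.readTsv(file.path(dir, "chimerism.tsv")))

#' @rdname pipeline-io
#' @param threshold positivity threshold used when rebuilding a
#'   \code{ColonyFlowSet}.
#' @export
writeColonies <- function(x, dir) {
    p <- file.path(dir, "colonies.tsv")
    .writeTsv(colonyRecords(x), p)
    invisible(p)
}

#' @rdname pipeline-io
#' @export
readColonies <- function(dir, threshold = 0.01)
    ColonyFlowSet(.readTsv(file.path(dir, "colonies.tsv")), threshold)

#' Write and read counts as MatrixMarket + gene/cell TSVs
#'
#' \code{writeCounts} emits \code{counts.mtx}, \code{genes.tsv} and
#' \code{cells.tsv} (cell_id + condition); \code{readCounts} rebuilds a
#' \code{\linkS4class{HibExperiment}}.
#'
#' @param x a \code{\linkS4class{HibExperiment}}.
#' @param dir directory.
#' @return \code{readCounts}: a \code{HibExperiment}; \code{writeCounts}:
#'   the written paths, invisibly.
#' @export
writeCounts <- function(x, dir) {
    stopifnot(is(x, "HibExperiment"))
    m <- Matrix::Matrix(SummarizedExperiment::assay(x, "counts"),
                        sparse = TRUE)
    pm <- file.path(dir, "counts.mtx")
    Matrix::writeMM(m, pm)
    pg <- file.path(dir, "genes.tsv")
    writeLines(rownames(x), pg)
    pc <- file.path(dir, "cells.tsv")
    .writeTsv(data.frame(cell_id = colnames(x),
                         condition = as.character(cellCondition(x))), pc)
    invisible(c(pm, pg, pc))
}

#' @rdname writeCounts
#' @export
readCounts <- function(dir) {
    m <- as.matrix(Matrix::readMM(file.path(dir, "counts.mtx")))
    genes <- readLines(file.path(dir, "genes.tsv"))
    cells <- .readTsv(file.path(dir, "cells.tsv"))
    dimnames(m) <- list(genes, cells$cell_id)
    storage.mode(m) <- "integer"
    HibExperiment(m, cells$condition)
}

#' Read a GMT gene-set file
#'
#' Tab-delimited: set name, description, then member genes.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- lengths(parts) < 3
    if (any(bad))
        stop("input error: malformed GMT line(s): ",
             paste(which(bad), collapse = ", "))
    stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])),
                    vapply(parts, `[`, "", 1))
}

#' Write a GMT gene-set file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description field (recycled).
#' @return \code{path}, invisibly.
#' @export
writeGmt <- function(sets, path, description = "na") {
    description <- rep_len(description, length(sets))
    writeLines(vapply(seq_along(sets), function(i)
        paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"),
        ""), path)
    invisible(path)
}

#' Packaged default signatures
#'
#' The packaged HSC-identity (MolO-style) signature is a synthetic
#' reconstruction distributed with the package (see the methods vignette);
#' the proliferation signature is the union of the S and G2M marker lists
#' of the default gene map.
#'
#' @return named list of gene sets.
#' @export
defaultSignatures <- function() {
    readGmt(system.file("extdata", "signatures_synthetic.gmt",
                        package = "hibHSC", mustWork = TRUE))
}
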