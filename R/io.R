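## Tabular I/O: TSV count matrices, sample sheets, gene lengths, truth
## tables, GMT gene-group collections, and RPKM expression summaries.
## TSV dialect: tab-separated, UTF-8, '#' comment lines ignored, first
## column is the gene ID.

.readTsv <- function(path, ...) {
    if (!file.exists(path)) stop("file not found: ", path)
    utils::read.delim(path, comment.char = "#", check.names = FALSE,
                      stringsAsFactors = FALSE, ...)
}

#' Read a gene x sample count matrix from TSV
#'
#' @param path TSV file; first column gene IDs, remaining columns one per
#'   sample, header row of sample IDs.
#' @return Integer matrix with gene rownames and sample colnames.
#' @export
readCounts <- function(path) {
    df <- .readTsv(path)
    if (ncol(df) < 2) stop("count table needs a gene column and >= 1 sample")
    ids <- as.character(df[[1]])
    dup <- ids[duplicated(ids)]
    if (length(dup))
        stop("duplicate gene ID(s) in ", path, ": ",
             paste(unique(utils::head(dup, 5)), collapse = ", "))
    m <- as.matrix(df[, -1, drop = FALSE])
    if (anyDuplicated(colnames(m)))
        stop("duplicate sample ID(s) in ", path)
    suppressWarnings(storage.mode(m) <- "numeric")
    if (any(is.na(m))) {
        idx <- which(is.na(m), arr.ind = TRUE)[1, ]
        stop("non-numeric count for gene ", ids[idx[1]], ", sample ",
             colnames(m)[idx[2]])
    }
    if (any(m < 0)) {
        idx <- which(m < 0, arr.ind = TRUE)[1, ]
        stop("negative count for gene ", ids[idx[1]], ", sample ",
             colnames(m)[idx[2]])
    }
    rownames(m) <- ids
    m
}

#' Write a count matrix as TSV
#' @param counts matrix with gene rownames and sample colnames.
#' @param path output file.
#' @export
writeCounts <- function(counts, path) {
    df <- data.frame(gene_id = rownames(counts), counts,
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a sample sheet from TSV
#'
#' @param path TSV with columns \code{sample_id}, \code{strain},
#'   \code{treatment}, \code{cell_type}, \code{batch}, \code{replicate}.
#' @param counts optional count matrix to cross-check sample IDs against.
#' @return data.frame.
#' @export
readSampleSheet <- function(path, counts = NULL) {
    df <- .readTsv(path)
    need <- c("sample_id", "strain", "treatment", "cell_type", "batch",
              "replicate")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
    bad <- setdiff(unique(df$strain), .STRAINS)
    if (length(bad))
        stop("unknown strain label(s): ", paste(bad, collapse = ", "))
    bad <- setdiff(unique(df$treatment), .TREATMENTS)
    if (length(bad))
        stop("unknown treatment label(s): ", paste(bad, collapse = ", "))
    bad <- setdiff(unique(df$cell_type), .CELL_TYPES)
    if (length(bad))
        stop("unknown cell type label(s): ", paste(bad, collapse = ", "))
    if (anyDuplicated(df$sample_id))
        stop("duplicate sample_id in sample sheet")
    if (!is.null(counts)) {
        miss <- setdiff(df$sample_id, colnames(counts))
        if (length(miss))
            stop("sample(s) absent from count matrix: ",
                 paste(miss, collapse = ", "))
    }
    df
}

#' Write a sample sheet as TSV
#' @param sheet data.frame.
#' @param path output file.
#' @export
writeSampleSheet <- function(sheet, path) {
    utils::write.table(sheet, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read gene lengths from a two-column TSV
#'
#' @param path TSV with gene IDs in the first column and lengths in bp in
#'   the second.
#' @return Named numeric vector of lengths.
#' @export
readGeneLengths <- function(path) {
    df <- .readTsv(path)
    if (ncol(df) < 2) stop("gene length table needs two columns")
    if (anyDuplicated(df[[1]])) stop("duplicate gene IDs in ", path)
    len <- as.numeric(df[[2]])
    if (any(is.na(len) | len <= 0))
        stop("gene lengths must be positive numbers (gene ",
             df[[1]][which(is.na(len) | len <= 0)[1]], ")")
    stats::setNames(len, as.character(df[[1]]))
}

#' Write gene lengths as TSV
#' @param lengths named numeric vector.
#' @param path output file.
#' @export
writeGeneLengths <- function(lengths, path) {
    utils::write.table(
        data.frame(gene_id = names(lengths), length_bp = unname(lengths)),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read gene groups from a GMT file
#'
#' Each line is \code{name<TAB>description<TAB>gene1<TAB>gene2...}.
#'
#' @param path GMT file.
#' @return Named list of character vectors of gene IDs.
#' @examples
#' tf <- tempfile(fileext = ".gmt")
#' writeLines("setA\tdesc\tg1\tg2", tf)
#' readGMT(tf)
#' @export
readGMT <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
    if (!length(lines)) stop("empty GMT file: ", path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nm <- vapply(parts, `[[`, "", 1L)
    if (anyDuplicated(nm))
        stop("duplicate group name(s) in ", path, ": ",
             paste(unique(nm[duplicated(nm)]), collapse = ", "))
    groups <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
    empty <- lengths(groups) == 0 | lengths(parts) < 3
    if (any(empty))
        stop("GMT group(s) with empty gene list: ",
             paste(nm[empty], collapse = ", "))
    stats::setNames(groups, nm)
}

#' Write gene groups as GMT
#' @param groups named list of character vectors.
#' @param path output file.
#' @param descriptions optional character vector of descriptions.
#' @export
writeGMT <- function(groups, path, descriptions = NULL) {
    if (is.null(descriptions)) descriptions <- rep("na", length(groups))
    lines <- mapply(function(nm, d, g) paste(c(nm, d, g), collapse = "\t"),
                    names(groups), descriptions, groups)
    writeLines(lines, path)
    invisible(path)
}

#' RPKM expression values
#'
#' Reads per kilobase of gene per million mapped reads:
#' \code{rpkm[g, s] = count[g, s] / ((length_bp[g] / 1e3) *
#' (libsize[s] / 1e6))}, with the library size taken as the column sum of
#' the supplied count matrix.
#'
#' @param counts count matrix, genes in rows.
#' @param lengths named vector of gene lengths in bp covering all genes.
#' @return Numeric matrix of RPKM values with the same dimnames.
#' @examples
#' cnt <- matrix(c(10, 999990), 2, 1,
#'               dimnames = list(c("g1", "g2"), "s1"))
#' rpkm(cnt, c(g1 = 1000, g2 = 500))["g1", ]
#' @export
rpkm <- function(counts, lengths) {
    counts <- as.matrix(counts)
    miss <- setdiff(rownames(counts), names(lengths))
    if (length(miss))
        stop("gene length missing for: ",
             paste(utils::head(miss, 5), collapse = ", "))
    len <- lengths[rownames(counts)]
    if (any(len <= 0)) stop("gene lengths must be positive")
    lib <- colSums(counts)
    if (any(lib <= 0))
        stop("empty sample(s): ",
             paste(colnames(counts)[lib <= 0], collapse = ", "))
    counts / (outer(len / 1e3, lib / 1e6))
}

#' Gene lengths from a GFF3 file
#'
#' Sums the reduced (non-overlapping) exon widths per gene.  Requires the
#' rtracklayer and GenomicRanges packages.
#'
#' @param path GFF3 file with exon features carrying gene identifiers in
#'   \code{geneIdAttribute} (directly or via their Parent transcript).
#' @param geneIdAttribute attribute naming the gene; default
#'   \code{"gene_id"}, falling back to \code{Parent}.
#' @return Named numeric vector of summed exon lengths in bp.
#' @export
geneLengthsFromGFF <- function(path, geneIdAttribute = "gene_id") {
    for (pkg in c("rtracklayer", "GenomicRanges"))
        if (!requireNamespace(pkg, quietly = TRUE))
            stop("package '", pkg, "' is required for GFF3 ingestion")
    gr <- rtracklayer::import(path, format = "gff3")
    ex <- gr[tolower(as.character(gr$type)) == "exon"]
    if (!length(ex)) stop("no exon features in ", path)
    mc <- S4Vectors::mcols(ex)
    gid <- if (geneIdAttribute %in% colnames(mc))
        as.character(mc[[geneIdAttribute]])
    else if ("Parent" %in% colnames(mc))
        vapply(mc$Parent, function(p) as.character(p)[1], "")
    else stop("exons carry neither '", geneIdAttribute,
              "' nor 'Parent' attributes")
    byGene <- GenomicRanges::split(ex, gid)
    red <- GenomicRanges::reduce(byGene)
    lens <- sum(GenomicRanges::width(red))
    stats::setNames(as.numeric(lens), names(lens))
}

#' Write a SetSystem as TSV plus a JSON size sidecar
#'
#' The long TSV has one (gene_id, set_name) row per membership, plus rows
#' with set_name \code{"universe"} recording the condition's gene universe,
#' so the system round-trips through \code{\link{readSetSystem}}.
#'
#' @param system a \linkS4class{SetSystem}.
#' @param pathTsv long-format TSV (gene_id, set_name) output path.
#' @param pathJson optional JSON file of set sizes.
#' @export
writeSetSystem <- function(system, pathTsv, pathJson = NULL) {
    sets <- geneSets(system)
    df <- data.frame(
        gene_id = c(unlist(sets, use.names = FALSE), setUniverse(system)),
        set_name = c(rep(names(sets), lengths(sets)),
                     rep("universe", length(setUniverse(system)))),
        stringsAsFactors = FALSE)
    ## header comment preserves empty sets across the round trip
    writeLines(paste0("# sets: ", paste(names(sets), collapse = ",")),
               pathTsv)
    suppressWarnings(
        utils::write.table(df, pathTsv, sep = "\t", quote = FALSE,
                           row.names = FALSE, append = TRUE))
    if (!is.null(pathJson))
        jsonlite::write_json(
            list(condition = conditionLabel(system),
                 universe_size = length(setUniverse(system)),
                 sizes = as.list(setSizes(system))),
            pathJson, auto_unbox = TRUE, pretty = TRUE)
    invisible(pathTsv)
}

#' Read a SetSystem back from its long TSV
#' @param pathTsv file written by \code{\link{writeSetSystem}}.
#' @param condition condition label to store.
#' @return A \linkS4class{SetSystem}.
#' @export
readSetSystem <- function(pathTsv, condition = "") {
    df <- .readTsv(pathTsv)
    if (!all(c("gene_id", "set_name") %in% colnames(df)))
        stop("expected columns gene_id, set_name in ", pathTsv)
    universe <- unique(df$gene_id[df$set_name == "universe"])
    df <- df[df$set_name != "universe", , drop = FALSE]
    sets <- lapply(split(df$gene_id, df$set_name), unique)
    if (!length(universe)) universe <- unique(df$gene_id)
    header <- readLines(pathTsv, n = 1L)
    if (startsWith(header, "# sets: ")) {
        declared <- strsplit(sub("^# sets: ", "", header), ",")[[1]]
        for (nm in setdiff(declared, names(sets)))
            sets[[nm]] <- character()
        sets <- sets[declared]
    }
    new("SetSystem", sets = sets, condition = condition,
        universe = universe)
}

#' Write a differential-expression result table as TSV
#' @param de \code{DataFrame} from \code{\link{deTest}}.
#' @param path output file.
#' @export
writeDEResult <- function(de, path) {
    df <- as.data.frame(de)
    md <- S4Vectors::metadata(de)
    df$comparison <- md$comparison
    df$df <- md$df
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a differential-expression result table written by writeDEResult
#' @param path TSV file.
#' @return \code{DataFrame} with comparison label and t df restored into
#'   \code{metadata()}.
#' @export
readDEResult <- function(path) {
    df <- .readTsv(path)
    need <- c("gene_id", "log2fc", "p", "padj", "status")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("DE table ", path, " lacks column(s): ",
             paste(miss, collapse = ", "))
    md <- list(comparison = df$comparison[1], df = df$df[1])
    out <- S4Vectors::DataFrame(df[, setdiff(colnames(df),
                                             c("comparison", "df"))])
    S4Vectors::metadata(out) <- md
    out
}
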