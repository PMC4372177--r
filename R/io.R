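## Plain-text I/O: probe x sample matrices, probe annotation, probe lists
## and GMT gene-set collections.

#' Read / write a probe x sample matrix as TSV
#'
#' Probes as rows; the first column holds probe ids, the header the sample
#' ids.
#'
#' @param path file path.
#' @param x numeric matrix with dimnames.
#' @return \code{readMatrixTSV} a numeric matrix; \code{writeMatrixTSV} the
#'   path, invisibly.
#' @export
readMatrixTSV <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    storage.mode(m) <- "double"
    m
}

#' @rdname readMatrixTSV
#' @export
writeMatrixTSV <- function(x, path) {
    df <- data.frame(probe_id = rownames(x), x, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a probe annotation table
#'
#' TSV with header; requires columns \code{probe_id}, \code{chromosome},
#' \code{position} (1-based), and optionally \code{gene} and \code{region}.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readAnnotation <- function(path) {
    ann <- utils::read.delim(path, check.names = FALSE,
                             colClasses = c(chromosome = "character"))
    need <- c("probe_id", "chromosome", "position")
    if (!all(need %in% names(ann)))
        stop("annotation must have columns ", paste(need, collapse = ", "))
    if (any(ann$position <= 0)) stop("positions must be positive (1-based)")
    ann
}

#' Read a probe exclusion list
#'
#' One probe id per line; empty lines and \code{#} comments ignored. An
#' empty file is allowed.
#'
#' @param path file path.
#' @return character vector of probe ids.
#' @export
readProbeList <- function(path) {
    x <- readLines(path, warn = FALSE)
    x <- trimws(sub("#.*$", "", x))
    x[nzchar(x)]
}

#' Read gene sets in GMT format
#'
#' Each line: set name, description, then tab-separated gene symbols.
#'
#' @param path file path.
#' @return named list of character vectors of gene symbols.
#' @export
readGmt <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    sets <- lapply(lines, function(l) {
        f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
        if (length(f) < 3L)
            stop("malformed GMT line (need name, description, >= 1 gene): ",
                 substr(l, 1, 60))
        unique(f[-(1:2)])
    })
    names(sets) <- vapply(lines, function(l)
        strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1))
    if (any(lengths(sets) == 0L)) stop("empty gene set in GMT")
    sets
}
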