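## Pedigree file I/O and kinship-coefficient computation.
##
## The kinship coefficient phi_ij is the probability that one allele drawn
## at random from i and one from j are identical by descent; 2*phi_ij is the
## expected proportion of alleles shared IBD and is the weight used for the
## polygenic covariance in the mixed model.

#' Read a PED-like pedigree file
#'
#' Reads a whitespace- or tab-delimited file with columns
#' \code{FID IID FATHER MOTHER SEX} (no header, or a header starting with
#' \code{FID}). \code{"0"} or empty denotes a missing parent. Sex coding:
#' 1/\code{male} = male, 2/\code{female} = female, anything else = unknown.
#'
#' @param path path to the pedigree file.
#' @return a validated [Pedigree-class].
#' @export
readPedigree <- function(path) {
    if (!file.exists(path)) stop("pedigree file not found: ", path)
    df <- utils::read.table(path, header = FALSE, colClasses = "character",
                            col.names = c("family", "id", "father", "mother",
                                          "sex"),
                            comment.char = "#", fill = FALSE)
    if (nrow(df) && toupper(df$family[1L]) == "FID") df <- df[-1L, , drop = FALSE]
    df$sex <- c("1" = "male", "2" = "female",
                "male" = "male", "female" = "female")[tolower(df$sex)]
    df$sex[is.na(df$sex)] <- "unknown"
    Pedigree(df)
}

#' Write a pedigree to a PED-like file
#'
#' Tab-delimited \code{FID IID FATHER MOTHER SEX} with \code{0} for missing
#' parents and 1 = male / 2 = female / 0 = unknown, the format
#' [readPedigree()] consumes.
#'
#' @param ped a [Pedigree-class]
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writePedigree <- function(ped, path) {
    df <- pedMembers(ped)
    out <- data.frame(df$family, df$id,
                      ifelse(is.na(df$father), "0", df$father),
                      ifelse(is.na(df$mother), "0", df$mother),
                      c(male = "1", female = "2", unknown = "0")[df$sex])
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

## generation depth: founders 0, else 1 + max(parent depths)
.pedDepth <- function(df) {
    idx <- stats::setNames(seq_len(nrow(df)), df$id)
    depth <- rep(NA_integer_, nrow(df))
    f <- idx[df$father]; m <- idx[df$mother]
    depth[is.na(f) & is.na(m)] <- 0L
    while (anyNA(depth)) {
        todo <- which(is.na(depth))
        prog <- FALSE
        for (i in todo) {
            dp <- c(if (!is.na(f[i])) depth[f[i]] else 0L,
                    if (!is.na(m[i])) depth[m[i]] else 0L)
            if (!anyNA(dp)) {
                depth[i] <- max(dp) + 1L
                prog <- TRUE
            }
        }
        if (!prog) stop("pedigree contains a cycle")  # guarded by validity
    }
    stats::setNames(depth, df$id)
}

#' Kinship coefficient between two pedigree members
#'
#' Computes phi_ij by the standard recursion: founders are pairwise
#' unrelated with phi_ii = 1/2; for a non-founder i (taken as the
#' later-generation member of the pair), phi_ij = (phi_father(i),j +
#' phi_mother(i),j)/2, a missing parent contributing 0; and
#' phi_ii = 1/2 + phi_father(i),mother(i)/2, so inbreeding is supported.
#'
#' @param ped a [Pedigree-class]
#' @param i,j individual ids.
#' @return the kinship coefficient phi_ij (e.g. 1/4 for parent-offspring, so
#'   2*phi = 1/2).
#' @export
kinship <- function(ped, i, j) {
    df <- pedMembers(ped)
    if (!(i %in% df$id)) stop("id not in pedigree: ", i)
    if (!(j %in% df$id)) stop("id not in pedigree: ", j)
    phi <- kinshipMatrix(ped, unique(c(i, j)))
    unname(phi[i, j])
}

#' Kinship matrix over a set of samples
#'
#' Builds the symmetric matrix of pairwise kinship coefficients phi over the
#' requested samples, in the requested order, by one pass over the pedigree
#' in generation order. Members of different families have phi = 0. The
#' polygenic covariance used by the association model is \code{2 *
#' kinshipMatrix(...)}.
#'
#' @param ped a [Pedigree-class]
#' @param sampleIds ordered ids to include; default all members.
#' @return a symmetric numeric matrix of phi values with \code{sampleIds} as
#'   dimnames.
#' @export
kinshipMatrix <- function(ped, sampleIds = pedIds(ped)) {
    df <- pedMembers(ped)
    if (anyDuplicated(sampleIds))
        stop("duplicate sample ids: ",
             sampleIds[duplicated(sampleIds)][1L])
    missing <- setdiff(sampleIds, df$id)
    if (length(missing)) stop("id not in pedigree: ", missing[1L])

    ## restrict to the families containing requested ids, plus all their
    ## members (ancestors are needed by the recursion)
    fams <- unique(df$family[match(sampleIds, df$id)])
    df <- df[df$family %in% fams, , drop = FALSE]
    ord <- order(.pedDepth(df))
    df <- df[ord, , drop = FALSE]
    n <- nrow(df)
    idx <- stats::setNames(seq_len(n), df$id)
    f <- idx[df$father]; m <- idx[df$mother]
    phi <- matrix(0, n, n, dimnames = list(df$id, df$id))
    fam <- df$family
    for (k in seq_len(n)) {
        fk <- f[k]; mk <- m[k]
        phi[k, k] <- 0.5 + 0.5 * (if (!is.na(fk) && !is.na(mk))
            phi[fk, mk] else 0)
        if (k > 1L) {
            prev <- seq_len(k - 1L)
            prev <- prev[fam[prev] == fam[k]]
            if (length(prev)) {
                v <- 0.5 * ((if (!is.na(fk)) phi[fk, prev] else 0) +
                            (if (!is.na(mk)) phi[mk, prev] else 0))
                phi[k, prev] <- v
                phi[prev, k] <- v
            }
        }
    }
    phi[sampleIds, sampleIds, drop = FALSE]
}

#' Write / read a kinship matrix as TSV
#'
#' TSV with a leading id column and sample ids as header, suitable for
#' round-tripping the output of [kinshipMatrix()].
#'
#' @param phi square numeric matrix with dimnames.
#' @param path file path.
#' @return \code{writeKinship} returns \code{path} invisibly;
#'   \code{readKinship} the matrix.
#' @export
writeKinship <- function(phi, path) {
    df <- data.frame(id = rownames(phi), phi, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeKinship
#' @export
readKinship <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    m
}
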