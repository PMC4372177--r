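#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Pedigree of one or more families
#'
#' An S4 container for a validated pedigree: one row per individual with
#' family id, individual id, father id, mother id and sex. Parent ids are
#' \code{NA} for founders. The object is guaranteed acyclic and closed
#' (every referenced parent is itself a member).
#'
#' @slot members a \code{data.frame} with character columns \code{family},
#'   \code{id}, \code{father}, \code{mother} and \code{sex} (one of
#'   \code{"female"}, \code{"male"}, \code{"unknown"}).
#'
#' @seealso [readPedigree()], [kinship()], [kinshipMatrix()]
#' @export
setClass("Pedigree", representation(members = "data.frame"))

.checkPedigreeFrame <- function(df) {
    need <- c("family", "id", "father", "mother", "sex")
    if (!all(need %in% names(df)))
        return(paste("members must have columns", paste(need, collapse = ", ")))
    if (anyDuplicated(df$id))
        return(paste("duplicated individual id:",
                     df$id[duplicated(df$id)][1L]))
    if (!all(df$sex %in% c("female", "male", "unknown")))
        return("sex must be 'female', 'male' or 'unknown'")
    for (col in c("father", "mother")) {
        ref <- df[[col]]
        bad <- !is.na(ref) & !(ref %in% df$id)
        if (any(bad))
            return(sprintf("unknown %s id referenced: %s", col,
                           ref[bad][1L]))
    }
    ## same-family closure for parents
    fam <- stats::setNames(df$family, df$id)
    for (col in c("father", "mother")) {
        ref <- df[[col]]
        ok <- is.na(ref) | fam[ref] == df$family
        if (!all(ok))
            return(sprintf("parent %s of %s belongs to a different family",
                           ref[!ok][1L], df$id[!ok][1L]))
    }
    cyc <- .findPedigreeCycle(df)
    if (!is.null(cyc))
        return(paste("pedigree contains a cycle involving:",
                     paste(cyc, collapse = ", ")))
    TRUE
}

## Kahn's algorithm; returns NULL if acyclic, else the ids left in the cycle.
.findPedigreeCycle <- function(df) {
    ids <- df$id
    idx <- stats::setNames(seq_along(ids), ids)
    parents <- cbind(idx[df$father], idx[df$mother])
    indeg <- integer(length(ids))         # number of unresolved parents
    children <- vector("list", length(ids))
    for (i in seq_along(ids)) {
        for (p in parents[i, ]) {
            if (!is.na(p)) {
                indeg[i] <- indeg[i] + 1L
                children[[p]] <- c(children[[p]], i)
            }
        }
    }
    queue <- which(indeg == 0L)
    seen <- 0L
    while (length(queue)) {
        v <- queue[1L]; queue <- queue[-1L]; seen <- seen + 1L
        for (ch in children[[v]]) {
            indeg[ch] <- indeg[ch] - 1L
            if (indeg[ch] == 0L) queue <- c(queue, ch)
        }
    }
    if (seen == length(ids)) NULL else ids[indeg > 0L]
}

setValidity("Pedigree", function(object) .checkPedigreeFrame(object@members))

#' Construct a Pedigree from a data.frame
#'
#' @param members data.frame with columns \code{family}, \code{id},
#'   \code{father}, \code{mother}, \code{sex}. Parent entries \code{"0"},
#'   \code{""} or \code{NA} mean missing; a missing single parent is treated
#'   as an unobserved founder (this is how half-relationships are encoded).
#' @return a validated [Pedigree-class] object.
#' @examples
#' trio <- Pedigree(data.frame(
#'     family = "f1", id = c("F", "M", "C"),
#'     father = c(NA, NA, "F"), mother = c(NA, NA, "M"),
#'     sex = c("male", "female", "female")))
#' kinship(trio, "F", "C")
#' @export
Pedigree <- function(members) {
    members <- as.data.frame(members, stringsAsFactors = FALSE)
    for (col in c("family", "id", "father", "mother", "sex"))
        if (col %in% names(members))
            members[[col]] <- as.character(members[[col]])
    for (col in c("father", "mother")) {
        miss <- is.na(members[[col]]) | members[[col]] %in% c("0", "")
        members[[col]][miss] <- NA_character_
    }
    new("Pedigree", members = members)
}

#' @describeIn Pedigree number of individuals
#' @param x a Pedigree
#' @export
setMethod("length", "Pedigree", function(x) nrow(x@members))

setMethod("show", "Pedigree", function(object) {
    df <- object@members
    founders <- is.na(df$father) & is.na(df$mother)
    cat(sprintf("Pedigree: %d individuals in %d famil%s (%d founders)\n",
                nrow(df), length(unique(df$family)),
                if (length(unique(df$family)) == 1L) "y" else "ies",
                sum(founders)))
})

#' Accessors for Pedigree contents
#'
#' \code{pedMembers} returns the member table; \code{pedIds} the individual
#' ids; \code{pedFounders} the ids of individuals with both parents missing.
#'
#' @param ped a [Pedigree-class]
#' @return a data.frame (\code{pedMembers}) or character vector.
#' @export
pedMembers <- function(ped) {
    stopifnot(is(ped, "Pedigree"))
    ped@members
}

#' @rdname pedMembers
#' @export
pedIds <- function(ped) pedMembers(ped)$id

#' @rdname pedMembers
#' @export
pedFounders <- function(ped) {
    df <- pedMembers(ped)
    df$id[is.na(df$father) & is.na(df$mother)]
}
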