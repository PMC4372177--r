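## Gene-set over-representation of aDMC genes: one-sided Fisher's exact
## (hypergeometric tail) per set, with multiple-test adjustment across
## sets. A local, testable replacement for web-tool enrichment services.

#' One-sided Fisher's exact over-representation P value
#'
#' With \code{N} background genes of which \code{K} are in the set, and a
#' query of \code{n} genes of which \code{k} hit the set, returns
#' \code{P(X >= k)} for \code{X ~ Hypergeometric(N, K, n)} — the one-sided
#' Fisher's exact test of over-representation.
#'
#' @param k query genes in the set.
#' @param K background genes in the set.
#' @param n query size.
#' @param N background size.
#' @return P value in (0, 1\]; \code{k = 0} gives exactly 1.
#' @export
fisherOverrep <- function(k, K, n, N) {
    if (any(c(k, K, n, N) < 0) || k > min(K, n) || max(K, n) > N)
        stop("inconsistent counts: need 0 <= k <= min(K, n) <= N")
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Genes carried by clusters of one direction
#'
#' @param admcs [callADMC()] output.
#' @param direction \code{"positive"}, \code{"negative"} or
#'   \code{"varying"}.
#' @return character vector: union of the gene symbols of matching
#'   clusters.
#' @export
clusterGenes <- function(admcs, direction) {
    direction <- match.arg(direction, c("positive", "negative", "varying"))
    g <- unlist(strsplit(admcs$genes[admcs$direction == direction], ";",
                         fixed = TRUE))
    sort(unique(g[nzchar(g)]))
}

#' Gene-set over-representation of direction-specific cluster genes
#'
#' Tests the union of gene symbols from clusters of the requested direction
#' against each gene set, one-sided, with multiple-test adjustment across
#' sets. Query and sets are intersected with the background first (genes
#' outside the background are dropped and counted in the attached log).
#' The recommended background is the set of genes carrying at least one
#' post-QC probe, which controls for array coverage.
#'
#' @param admcs [callADMC()] output.
#' @param direction cluster direction whose genes form the query.
#' @param sets named list of gene-symbol vectors (e.g. [readGmt()]).
#' @param background character vector: the gene universe.
#' @param adjust \code{"BH"} (default) or \code{"bonferroni"}.
#' @param alpha adjusted-P significance level.
#' @return data.frame with one row per set: \code{set}, \code{k},
#'   \code{K}, \code{n}, \code{N}, \code{p}, \code{p_adjusted},
#'   \code{significant}, ordered by \code{p}.
#' @export
enrichClusters <- function(admcs, direction, sets, background,
                           adjust = c("BH", "bonferroni"), alpha = 0.05) {
    adjust <- match.arg(adjust)
    query <- clusterGenes(admcs, direction)
    background <- unique(background)
    dropped <- setdiff(query, background)
    query <- intersect(query, background)
    if (length(query) == 0L) {
        warning("empty query after intersecting with background")
        return(data.frame(set = character(), k = integer(), K = integer(),
                          n = integer(), N = integer(), p = numeric(),
                          p_adjusted = numeric(), significant = logical()))
    }
    N <- length(background)
    n <- length(query)
    rows <- lapply(names(sets), function(nm) {
        inBg <- intersect(sets[[nm]], background)
        K <- length(inBg)
        k <- length(intersect(query, inBg))
        data.frame(set = nm, k = k, K = K, n = n, N = N,
                   p = if (K > 0) fisherOverrep(k, K, n, N) else 1)
    })
    out <- do.call(rbind, rows)
    out$p_adjusted <- stats::p.adjust(out$p, method = adjust)
    out$significant <- out$p_adjusted < alpha
    out <- out[order(out$p), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "dropped_query_genes") <- dropped
    out
}
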