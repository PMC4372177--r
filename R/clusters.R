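## Age-associated differentially methylated cluster (aDMC) calling:
## positional gap-clustering of genome-wide significant probes, density
## filtering against the full post-QC probe set ("array bias" correction),
## and direction labeling.

#' Gap-cluster significant probes along the genome
#'
#' Partitions probes within each chromosome into maximal runs where every
#' consecutive pair is at most \code{maxGap} bp apart (distance exactly
#' \code{maxGap} still joins); chromosomes are clustered independently and
#' singletons are allowed at this stage. \code{method = "allpairs"} instead
#' requires every pair within a cluster to be within \code{maxGap}
#' (cluster diameter bound), the literal all-pairs reading; clusters are
#' then formed greedily left to right.
#'
#' @param probes data.frame with columns \code{probe_id},
#'   \code{chromosome}, \code{position} (1-based). Sorted internally.
#' @param maxGap maximum gap in bp (default 10,000).
#' @param method \code{"chain"} (default; consecutive-pair gaps) or
#'   \code{"allpairs"}.
#' @return the input rows, sorted by (chromosome, position), with an added
#'   integer \code{cluster} column.
#' @export
gapCluster <- function(probes, maxGap = 10000, method = c("chain",
                                                          "allpairs")) {
    method <- match.arg(method)
    stopifnot(maxGap > 0)
    probes <- probes[order(probes$chromosome, probes$position), ,
                     drop = FALSE]
    cl <- integer(nrow(probes))
    cur <- 0L
    lastChr <- ""
    lastPos <- NA_real_
    startPos <- NA_real_
    for (i in seq_len(nrow(probes))) {
        chr <- probes$chromosome[i]; pos <- probes$position[i]
        newClust <- chr != lastChr ||
            (method == "chain" && pos - lastPos > maxGap) ||
            (method == "allpairs" && pos - startPos > maxGap)
        if (newClust) {
            cur <- cur + 1L
            startPos <- pos
        }
        cl[i] <- cur
        lastChr <- chr; lastPos <- pos
    }
    probes$cluster <- cl
    rownames(probes) <- NULL
    probes
}

#' Direction label for a cluster's significant members
#'
#' \code{"positive"} iff all slopes are > 0, \code{"negative"} iff all are
#' < 0, otherwise \code{"varying"}. An exactly-zero slope counts as neither
#' sign (hence \code{"varying"}) with a warning.
#'
#' @param slopes numeric slopes of the genome-wide significant members.
#' @return one of \code{"positive"}, \code{"negative"}, \code{"varying"}.
#' @export
directionLabel <- function(slopes) {
    if (length(slopes) < 1L) stop("need at least one significant member")
    if (any(slopes == 0))
        warning("slope exactly zero counted as neither sign")
    if (all(slopes > 0)) "positive"
    else if (all(slopes < 0)) "negative"
    else "varying"
}

#' Filter candidate clusters into aDMCs
#'
#' For each candidate cluster of significant probes, counts how many
#' post-QC probes (significant or not) fall within the inclusive position
#' span of its members — correcting for array probe density — and retains
#' the cluster iff that count is at least \code{minProbes} and the
#' significant fraction is at least \code{minSigFraction}. Retained
#' clusters get a direction label from their significant members' slopes
#' and the gene symbols overlapped by any probe in the span.
#'
#' @param candidates output of [gapCluster()] run on the significant
#'   probes (columns \code{probe_id}, \code{chromosome}, \code{position},
#'   \code{cluster}).
#' @param allProbes post-QC probe annotation (columns \code{probe_id},
#'   \code{chromosome}, \code{position}, optional \code{gene}).
#' @param results association results with \code{probe_id} and
#'   \code{beta_age} (slopes of the significant members).
#' @param minProbes minimum post-QC probes in the span (default 10).
#' @param minSigFraction minimum significant fraction (default 0.5).
#' @return data.frame of aDMC records: \code{cluster_id},
#'   \code{chromosome}, \code{start}, \code{end}, \code{span_bp},
#'   \code{n_probes_in_span}, \code{n_significant}, \code{sig_fraction},
#'   \code{direction}, \code{genes} (semicolon-joined), \code{probe_ids}
#'   (semicolon-joined significant members).
#' @export
filterADMC <- function(candidates, allProbes, results, minProbes = 10,
                       minSigFraction = 0.5) {
    slope <- stats::setNames(results$beta_age, results$probe_id)
    recs <- lapply(split(candidates, candidates$cluster), function(cc) {
        lo <- min(cc$position); hi <- max(cc$position)
        chr <- cc$chromosome[1L]
        inSpan <- allProbes$chromosome == chr &
            allProbes$position >= lo & allProbes$position <= hi
        nIn <- sum(inSpan)
        nSig <- nrow(cc)
        if (nIn < minProbes || nSig / nIn < minSigFraction) return(NULL)
        genes <- if ("gene" %in% names(allProbes))
            sort(unique(allProbes$gene[inSpan & nzchar(allProbes$gene) &
                                       !is.na(allProbes$gene)]))
            else character()
        data.frame(chromosome = chr, start = lo, end = hi,
                   span_bp = hi - lo + 1L, n_probes_in_span = nIn,
                   n_significant = nSig, sig_fraction = nSig / nIn,
                   direction = directionLabel(unname(slope[cc$probe_id])),
                   genes = paste(genes, collapse = ";"),
                   probe_ids = paste(cc$probe_id, collapse = ";"))
    })
    recs <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
    if (is.null(recs))
        return(data.frame(cluster_id = integer(), chromosome = character(),
                          start = integer(), end = integer(),
                          span_bp = integer(), n_probes_in_span = integer(),
                          n_significant = integer(), sig_fraction = numeric(),
                          direction = character(), genes = character(),
                          probe_ids = character()))
    recs <- recs[order(recs$chromosome, recs$start), , drop = FALSE]
    data.frame(cluster_id = seq_len(nrow(recs)), recs, row.names = NULL)
}

#' Call aDMCs from an EWAS result table
#'
#' Convenience wrapper: selects the significant probes, gap-clusters them
#' ([gapCluster()]), and applies the density/fraction filter
#' ([filterADMC()]).
#'
#' @param results [runEwas()]-style table with \code{probe_id},
#'   \code{p_age}, \code{beta_age}, \code{significant}.
#' @param annotation post-QC probe annotation (\code{probe_id},
#'   \code{chromosome}, \code{position}, optional \code{gene}).
#' @param maxGap,method see [gapCluster()].
#' @param minProbes,minSigFraction see [filterADMC()].
#' @return aDMC record data.frame (see [filterADMC()]), with a
#'   direction-count summary attached as attribute \code{"summary"}.
#' @export
callADMC <- function(results, annotation, maxGap = 10000,
                     minProbes = 10, minSigFraction = 0.5,
                     method = c("chain", "allpairs")) {
    sig <- results$probe_id[results$significant %in% TRUE]
    ann <- annotation[annotation$probe_id %in% sig, , drop = FALSE]
    if (nrow(ann) == 0L)
        return(filterADMC(gapCluster(annotation[0, , drop = FALSE]),
                          annotation, results, minProbes, minSigFraction))
    cand <- gapCluster(ann, maxGap = maxGap, method = match.arg(method))
    recs <- filterADMC(cand, annotation, results, minProbes,
                       minSigFraction)
    attr(recs, "summary") <- admcSummary(recs)
    recs
}

#' Direction-count summary of an aDMC table
#'
#' @param admcs [filterADMC()] / [callADMC()] output.
#' @return list with \code{n_total}, \code{n_positive}, \code{n_negative},
#'   \code{n_varying}; the three direction counts always partition the
#'   total.
#' @export
admcSummary <- function(admcs) {
    list(n_total = nrow(admcs),
         n_positive = sum(admcs$direction == "positive"),
         n_negative = sum(admcs$direction == "negative"),
         n_varying = sum(admcs$direction == "varying"))
}

#' Write aDMCs as a BED-like file
#'
#' Columns: chrom, 0-based start, end, cluster id, n_probes_in_span,
#' n_significant, direction, genes (semicolon-joined).
#'
#' @param admcs [callADMC()] output.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeADMCBed <- function(admcs, path) {
    bed <- data.frame(chrom = admcs$chromosome, start = admcs$start - 1L,
                      end = admcs$end,
                      name = sprintf("aDMC%d", admcs$cluster_id),
                      admcs[, c("n_probes_in_span", "n_significant",
                                "direction", "genes")])
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}
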