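## QC / transform chain for 450K-style methylation matrices: intensity ->
## beta / M, detection-P filtering, exclusion lists, beta-range filtering,
## quantile normalization, and the beta <-> M logit2 transform pair.

#' Beta value from methylation intensities
#'
#' \code{beta = I_m / (I_u + I_m + alpha)}, the fraction of methylated
#' signal with a stabilizing offset.
#'
#' @param Im,Iu methylated / unmethylated fluorescence intensities (>= 0),
#'   vectorized.
#' @param alpha stabilizing offset constant; 100 is the platform convention.
#' @return beta values in \[0, 1).
#' @export
betaFromIntensities <- function(Im, Iu, alpha = 100) {
    if (any(Im < 0 | Iu < 0) || any(alpha < 0))
        stop("intensities and alpha must be non-negative")
    den <- Iu + Im + alpha
    if (any(den == 0))
        stop("undefined beta: I_m + I_u + alpha is zero")
    Im / den
}

#' M value from methylation intensities
#'
#' \code{M = log2((I_m + alpha) / (I_u + alpha))}. With \code{alpha = 0}
#' this equals \code{log2(beta/(1-beta))} of the matching beta value.
#'
#' @inheritParams betaFromIntensities
#' @return finite M values.
#' @export
mFromIntensities <- function(Im, Iu, alpha = 100) {
    if (any(Im + alpha <= 0) || any(Iu + alpha <= 0))
        stop("undefined M: shifted intensity is not positive")
    log2((Im + alpha) / (Iu + alpha))
}

#' Beta / M interconversion (logit2)
#'
#' \code{betaToM} computes \code{log2(beta/(1-beta))}; \code{mToBeta}
#' inverts it as \code{2^M/(2^M+1)}. Beta values of exactly 0 or 1 (possible
#' in degenerate synthetic input) are clamped to \[1e-6, 1-1e-6\] with a
#' warning to avoid infinite M.
#'
#' @param beta beta values in \[0, 1\] (vector or matrix).
#' @param m M values (vector or matrix).
#' @return M values, or beta values in (0, 1).
#' @export
betaToM <- function(beta) {
    if (any(beta < 0 | beta > 1, na.rm = TRUE))
        stop("beta values must lie in [0, 1]")
    eps <- 1e-6
    if (any(beta <= 0 | beta >= 1, na.rm = TRUE)) {
        warning("beta values at 0 or 1 clamped to [1e-6, 1 - 1e-6]")
        beta <- pmin(pmax(beta, eps), 1 - eps)
    }
    log2(beta / (1 - beta))
}

#' @rdname betaToM
#' @export
mToBeta <- function(m) {
    ## stable for large |M|
    b <- 1 / (1 + 2^(-m))
    b
}

#' Detection-P filter
#'
#' Retains a probe iff the fraction of samples in which its detection P
#' value is >= \code{threshold} does not exceed \code{maxFailFraction}
#' ("failing in more than 5\% of samples" removes the probe; exactly 5\% is
#' retained).
#'
#' @param detP probe x sample matrix of detection P values, rownames =
#'   probe ids.
#' @param threshold detection-P cutoff a sample must beat (default 0.01).
#' @param maxFailFraction tolerated failing-sample fraction (default 0.05).
#' @return character vector of retained probe ids.
#' @export
detectionFilter <- function(detP, threshold = 0.01, maxFailFraction = 0.05) {
    detP <- as.matrix(detP)
    if (is.null(rownames(detP))) stop("detP needs probe ids as rownames")
    failFrac <- rowMeans(detP >= threshold)
    rownames(detP)[failFrac <= maxFailFraction]
}

#' Beta-range filter
#'
#' Probes whose beta values range less than \code{minRange} across samples
#' carry no biologically meaningful variation at platform resolution and
#' are removed: retained iff \code{max(beta) - min(beta) >= minRange}
#' (boundary kept).
#'
#' @param beta probe x sample beta matrix, rownames = probe ids.
#' @param minRange minimum retained range (default 0.17).
#' @return character vector of retained probe ids.
#' @export
rangeFilter <- function(beta, minRange = 0.17) {
    beta <- as.matrix(beta)
    if (is.null(rownames(beta))) stop("beta needs probe ids as rownames")
    if (ncol(beta) < 2L)
        stop("range filter undefined with fewer than 2 samples")
    rng <- apply(beta, 1L, max) - apply(beta, 1L, min)
    rownames(beta)[rng >= minRange]
}

#' Quantile normalization across samples
#'
#' Forces every sample column onto the common distribution of across-sample
#' mean order statistics; ties share the mean of their spanned quantiles.
#' Thin wrapper over \code{limma::normalizeQuantiles}.
#'
#' @param x probe x sample numeric matrix (>= 2 samples).
#' @return matrix of the same shape and dimnames.
#' @export
quantileNormalize <- function(x) {
    x <- as.matrix(x)
    if (ncol(x) < 2L) stop("quantile normalization needs >= 2 samples")
    out <- limma::normalizeQuantiles(x, ties = TRUE)
    dimnames(out) <- dimnames(x)
    out
}

#' Run the full probe-QC chain
#'
#' Applies, in order: detection-P filter (if a detection matrix is given),
#' user exclusion list (cross-reactive / polymorphic probes), and the
#' beta-range filter. The retained set is order-independent because each
#' filter is a per-probe predicate.
#'
#' @param beta probe x sample beta matrix.
#' @param detP optional matching detection-P matrix.
#' @param exclude character vector of probe ids to drop (may be empty).
#' @param detectionThreshold,maxFailFraction see [detectionFilter()].
#' @param minRange see [rangeFilter()].
#' @return list with \code{retained} (probe ids, in input order) and
#'   \code{report} (data.frame of per-stage input/removed/retained counts).
#' @export
runQC <- function(beta, detP = NULL, exclude = character(),
                  detectionThreshold = 0.01, maxFailFraction = 0.05,
                  minRange = 0.17) {
    beta <- as.matrix(beta)
    probes <- rownames(beta)
    report <- data.frame(stage = character(), n_in = integer(),
                         n_removed = integer(), n_retained = integer())
    note <- function(stage, before, after) {
        report[nrow(report) + 1L, ] <<-
            list(stage, length(before), length(before) - length(after),
                 length(after))
    }
    keep <- probes
    if (!is.null(detP)) {
        if (!setequal(rownames(detP), probes) ||
            ncol(as.matrix(detP)) != ncol(beta))
            stop("detection-P matrix does not match the beta matrix")
        k <- intersect(keep, detectionFilter(as.matrix(detP)[probes, ,
                                                             drop = FALSE],
                                             detectionThreshold,
                                             maxFailFraction))
        note("detection_p", keep, k); keep <- k
    }
    k <- setdiff(keep, exclude)
    note("exclusion_list", keep, k); keep <- k
    k <- intersect(keep, rangeFilter(beta[keep, , drop = FALSE], minRange))
    note("beta_range", keep, k); keep <- k
    list(retained = keep, report = report)
}
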