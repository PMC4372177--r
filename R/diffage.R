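## Group-dependent methylation aging rates: does the per-year age slope
## (and the intercept) at a candidate CpG differ between adults with and
## without metabolic syndrome? Realized as likelihood-ratio tests of the
## age-by-group interaction (equal slopes) and of the group main effect in
## the no-interaction model (equal intercepts), inside the same
## kinship-aware mixed model used genome-wide; an unrelated-OLS mode
## (phi = I/2) is available for comparison.

#' Test differential aging at one probe
#'
#' Fits three nested kinship-aware models on adults with defined group
#' status: pooled (no group terms), equal-slopes (group intercept only) and
#' full (group intercept + age-by-group interaction). Reports the pooled
#' age slope, the two group slopes (reference-group slope and its sum with
#' the interaction), the equal-slopes LRT P and the equal-intercepts LRT P.
#'
#' @param y per-sample M values for one probe (all samples; non-adults and
#'   samples with missing group status are dropped internally).
#' @param pheno data.frame with rownames = sample ids and columns
#'   \code{age}, \code{sex}, and the 0/1 group column named by
#'   \code{group} (NA = undefined, e.g. children).
#' @param phi kinship matrix over all samples (subset internally).
#' @param covariates optional sample x k matrix of extra fixed effects
#'   (e.g. cell proportions).
#' @param group name of the 0/1 phenotype column (default \code{"mets"}).
#' @param minGroup minimum per-group sample count below which the result
#'   is flagged unreliable (default 5).
#' @param kinshipAware FALSE replaces phi by I/2, i.e. ordinary
#'   least-squares on unrelateds.
#' @return list with \code{beta_age_all}, \code{beta_age_ref} (group 0),
#'   \code{beta_age_group} (group 1), \code{p_diff_slope},
#'   \code{p_diff_intercept}, \code{opposite_signs}, \code{n_ref},
#'   \code{n_group}, \code{reliable}, \code{converged}.
#' @export
testDifferentialAging <- function(y, pheno, phi, covariates = NULL,
                                  group = "mets", minGroup = 5,
                                  kinshipAware = TRUE) {
    if (!(group %in% names(pheno))) stop("no phenotype column '", group, "'")
    ids <- rownames(pheno)
    names(y) <- ids
    g <- pheno[[group]]
    keep <- !is.na(g) & !is.na(pheno$age)
    if (!any(keep)) stop("no samples with defined group status")
    pheno <- pheno[keep, , drop = FALSE]
    g <- as.numeric(g[keep])
    ids <- ids[keep]
    if (length(unique(g)) < 2L)
        stop("group indicator is constant; both groups must be present")
    y <- y[ids]
    phi <- if (kinshipAware) as.matrix(phi)[ids, ids]
           else diag(0.5, length(ids))
    sexM <- if (is.numeric(pheno$sex)) pheno$sex
            else as.numeric(pheno$sex == "male")
    X <- cbind(age = pheno$age, male = sexM)
    if (!is.null(covariates))
        X <- cbind(X, as.matrix(covariates)[ids, , drop = FALSE])
    Xgrp <- cbind(X, group = g)
    Xfull <- cbind(Xgrp, age_x_group = pheno$age * g)

    ## pooled slope, interaction LRT, and intercept LRT
    pooled <- tryCatch(fitProbe(y, X, phi), error = function(e) NULL)
    slopeTest <- tryCatch(
        testFixedEffect(y, Xfull, phi, term = "age_x_group"),
        error = function(e) NULL)
    interceptTest <- tryCatch(
        testFixedEffect(y, Xgrp, phi, term = "group"),
        error = function(e) NULL)
    converged <- !is.null(pooled) && !is.null(slopeTest) &&
        !is.null(interceptTest) && pooled$converged &&
        slopeTest$converged && interceptTest$converged
    bRef <- bGrp <- NA_real_
    if (!is.null(slopeTest) && !is.null(slopeTest$fit)) {
        bRef <- unname(slopeTest$fit$coefficients["age"])
        bGrp <- bRef + unname(slopeTest$fit$coefficients["age_x_group"])
    }
    list(beta_age_all = if (!is.null(pooled))
             unname(pooled$coefficients["age"]) else NA_real_,
         beta_age_ref = bRef, beta_age_group = bGrp,
         p_diff_slope = if (!is.null(slopeTest)) slopeTest$p else NA_real_,
         p_diff_intercept = if (!is.null(interceptTest)) interceptTest$p
                            else NA_real_,
         opposite_signs = isTRUE(bRef * bGrp < 0),
         n_ref = sum(g == 0), n_group = sum(g == 1),
         reliable = min(sum(g == 0), sum(g == 1)) >= minGroup,
         converged = converged)
}

#' Screen EWAS results for significant probes in candidate genes
#'
#' Returns the probes whose annotated gene symbol is in the candidate list
#' and whose age-association P value beats the genome-wide threshold.
#'
#' @param results [runEwas()]-style table with \code{probe_id} and
#'   \code{p_age}.
#' @param annotation probe annotation with \code{probe_id} and \code{gene}.
#' @param geneList character vector of candidate gene symbols.
#' @param threshold P threshold; default the Bonferroni threshold over
#'   \code{nrow(results)}.
#' @return character vector of probe ids.
#' @export
candidateScreen <- function(results, annotation, geneList,
                            threshold = bonferroniThreshold(nrow(results))) {
    if (length(geneList) == 0L) {
        warning("empty candidate gene list")
        return(character())
    }
    gene <- stats::setNames(annotation$gene, annotation$probe_id)
    hit <- gene[results$probe_id] %in% geneList &
        !is.na(results$p_age) & results$p_age < threshold
    results$probe_id[hit]
}

#' Differential-aging scan over candidate probes
#'
#' Runs [testDifferentialAging()] for each listed probe and returns a
#' table mirroring the candidate-locus reporting format: per-probe P_age
#' (from the genome-wide scan), pooled and group-specific slopes, and the
#' slope/intercept difference P values, sorted by \code{p_diff_slope}.
#'
#' @param M probe x sample M-value matrix.
#' @param probes probe ids to test.
#' @param results genome-wide [runEwas()] table (for \code{p_age}).
#' @param annotation probe annotation (chromosome, position, gene, region).
#' @inheritParams testDifferentialAging
#' @return data.frame with one row per probe.
#' @export
diffAgingScan <- function(M, probes, results, annotation, pheno, phi,
                          covariates = NULL, group = "mets") {
    pAge <- stats::setNames(results$p_age, results$probe_id)
    rows <- lapply(probes, function(pb) {
        r <- tryCatch(
            testDifferentialAging(M[pb, ], pheno, phi, covariates, group),
            error = function(e) NULL)
        ann <- annotation[match(pb, annotation$probe_id), , drop = FALSE]
        data.frame(probe_id = pb, p_age = unname(pAge[pb]),
                   beta_age_all = if (is.null(r)) NA_real_ else r$beta_age_all,
                   beta_age_no_group = if (is.null(r)) NA_real_
                                       else r$beta_age_ref,
                   beta_age_group = if (is.null(r)) NA_real_
                                    else r$beta_age_group,
                   p_diff_slope = if (is.null(r)) NA_real_ else r$p_diff_slope,
                   p_diff_intercept = if (is.null(r)) NA_real_
                                      else r$p_diff_intercept,
                   opposite_signs = if (is.null(r)) NA else r$opposite_signs,
                   converged = if (is.null(r)) FALSE else r$converged,
                   chromosome = ann$chromosome, position = ann$position,
                   gene = if ("gene" %in% names(ann)) ann$gene else NA,
                   region = if ("region" %in% names(ann)) ann$region else NA)
    })
    out <- do.call(rbind, rows)
    out[order(out$p_diff_slope), , drop = FALSE]
}
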