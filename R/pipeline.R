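## End-to-end orchestration: QC -> cell deconvolution -> kinship-aware
## age EWAS -> aDMC calling -> differential aging -> enrichment, on a
## synthetic cohort or on user files. Each stage is an exported function;
## the pipeline itself is a thin, reproducible driver that collects the
## per-stage summary counts.

#' Load a cohort from user-supplied files
#'
#' Real-data entry point mirroring [writeCohort()]'s formats: a PED-like
#' pedigree, a phenotype TSV (columns \code{id}, \code{age}, \code{sex},
#' optional \code{mets}), a probe x sample beta- or M-value TSV and an
#' annotation TSV.
#'
#' @param pedigree,phenotypes,annotation file paths.
#' @param beta,M paths for the beta and/or M matrix (at least one).
#' @return list with \code{pedigree} ([Pedigree-class]), \code{pheno}
#'   (data.frame, rownames = ids), \code{beta}, \code{M} (matrices; the
#'   missing one is derived via the logit2 transform) and
#'   \code{annotation}.
#' @export
loadCohortFiles <- function(pedigree, phenotypes, annotation, beta = NULL,
                            M = NULL) {
    if (is.null(beta) && is.null(M))
        stop("provide at least one of beta= or M= matrix paths")
    ped <- readPedigree(pedigree)
    pheno <- utils::read.delim(phenotypes)
    if (!all(c("id", "age", "sex") %in% names(pheno)))
        stop("phenotype table needs columns id, age, sex")
    rownames(pheno) <- pheno$id
    B <- if (!is.null(beta)) readMatrixTSV(beta) else NULL
    Mm <- if (!is.null(M)) readMatrixTSV(M) else NULL
    if (is.null(B)) B <- mToBeta(Mm)
    if (is.null(Mm)) Mm <- betaToM(B)
    list(pedigree = ped, pheno = pheno, beta = B, M = Mm,
         annotation = readAnnotation(annotation))
}

#' Run the full analysis pipeline
#'
#' Executes QC ([runQC()]), cell-type deconvolution
#' ([estimateCellProportions()]), the kinship-aware age EWAS
#' ([runEwas()]), aDMC calling ([callADMC()]), and — when candidate genes
#' and/or gene sets are supplied — the differential-aging scan
#' ([diffAgingScan()]) and direction-specific enrichment
#' ([enrichClusters()]).
#'
#' @param cohort a [SynthCohort-class] or a [loadCohortFiles()] list.
#' @param cellReference probe x cell-type reference for deconvolution;
#'   NULL (with a [SynthCohort-class]) falls back to the cohort's true
#'   proportions when \code{useTrueCellProps} is TRUE, NULL otherwise
#'   skips cell covariates.
#' @param useTrueCellProps with a [SynthCohort-class] and no reference,
#'   whether to use the simulated true proportions as covariates.
#' @param detP optional detection-P matrix for QC.
#' @param excludeProbes probe ids to exclude during QC.
#' @param minRange beta-range filter threshold.
#' @param alpha family-wise level for the Bonferroni threshold.
#' @param maxGap,minProbes,minSigFraction aDMC criteria (see
#'   [callADMC()]).
#' @param candidateGenes gene symbols for the differential-aging screen;
#'   NULL skips the stage.
#' @param geneSets named list of gene sets for enrichment; NULL skips.
#' @param dropCellType cell type dropped from the covariates.
#' @param test association test, \code{"lrt"} or \code{"wald"}.
#' @param outDir if non-NULL, stage outputs are written there as TSV/BED.
#' @return list with elements \code{qc}, \code{cellProps}, \code{results},
#'   \code{admcs}, \code{diffAging}, \code{enrichment} (positive and
#'   negative), and \code{summary} (per-stage counts: probes retained per
#'   filter, significant sites, +/- counts and ratio, cluster counts by
#'   direction).
#' @export
runPipeline <- function(cohort, cellReference = NULL, detP = NULL,
                        excludeProbes = character(), minRange = 0.17,
                        alpha = 0.05, maxGap = 10000, minProbes = 10,
                        minSigFraction = 0.5, candidateGenes = NULL,
                        geneSets = NULL, dropCellType = "granulocytes",
                        test = "lrt", outDir = NULL,
                        useTrueCellProps = TRUE) {
    synth <- is(cohort, "SynthCohort")
    if (synth) {
        beta <- cohortBeta(cohort); M <- cohortM(cohort)
        pheno <- cohortPheno(cohort)
        ann <- cohortAnnotation(cohort)
        ped <- cohortPedigree(cohort)
    } else {
        beta <- cohort$beta; M <- cohort$M
        pheno <- cohort$pheno; ann <- cohort$annotation
        ped <- cohort$pedigree
    }
    phi <- kinshipMatrix(ped, colnames(M))

    ## QC
    qc <- runQC(beta, detP = detP, exclude = excludeProbes,
                minRange = minRange)
    keep <- qc$retained
    M <- M[keep, , drop = FALSE]
    beta <- beta[keep, , drop = FALSE]
    ann <- ann[ann$probe_id %in% keep, , drop = FALSE]

    ## cell composition
    if (!is.null(cellReference)) {
        props <- estimateCellProportions(beta, cellReference)
    } else if (synth && useTrueCellProps) {
        props <- cohortCellProps(cohort)
    } else {
        props <- NULL
    }
    cellCov <- if (!is.null(props)) covariateColumns(props, dropCellType)
               else NULL

    ## association scan
    results <- runEwas(M, pheno, phi, cellCovariates = cellCov,
                       alpha = alpha, test = test)
    ewasSum <- attr(results, "summary")

    ## clusters
    admcs <- callADMC(results, ann, maxGap = maxGap, minProbes = minProbes,
                      minSigFraction = minSigFraction)
    admcSum <- admcSummary(admcs)

    ## differential aging on candidates
    diffAging <- NULL
    if (!is.null(candidateGenes) && "mets" %in% names(pheno)) {
        cand <- candidateScreen(results, ann, candidateGenes,
                                threshold = attr(results, "threshold"))
        if (length(cand))
            diffAging <- diffAgingScan(M, cand, results, ann, pheno, phi,
                                       covariates = cellCov)
    }

    ## enrichment against the array-covered gene background
    enrichment <- NULL
    if (!is.null(geneSets)) {
        background <- sort(unique(ann$gene[nzchar(ann$gene) &
                                           !is.na(ann$gene)]))
        enrichment <- list(
            positive = enrichClusters(admcs, "positive", geneSets,
                                      background),
            negative = enrichClusters(admcs, "negative", geneSets,
                                      background))
    }

    summary <- list(qc = qc$report, n_probes_tested = nrow(results),
                    threshold = attr(results, "threshold"),
                    n_significant = ewasSum$n_significant,
                    n_positive = ewasSum$n_positive,
                    n_negative = ewasSum$n_negative,
                    ratio = ewasSum$ratio, admc = admcSum)

    out <- list(qc = qc, cellProps = props, results = results,
                admcs = admcs, diffAging = diffAging,
                enrichment = enrichment, summary = summary)
    if (!is.null(outDir)) .writePipelineOutputs(out, ann, outDir)
    out
}

.writePipelineOutputs <- function(out, ann, outDir) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(out$qc$report, file.path(outDir, "qc_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res <- merge(out$results,
                 ann[, intersect(c("probe_id", "chromosome", "position",
                                   "gene", "region"), names(ann))],
                 by = "probe_id", sort = FALSE)
    utils::write.table(res, file.path(outDir, "ewas_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(out$admcs, file.path(outDir, "admcs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeADMCBed(out$admcs, file.path(outDir, "admcs.bed"))
    if (!is.null(out$diffAging))
        utils::write.table(out$diffAging,
                           file.path(outDir, "differential_aging.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(out$enrichment)) {
        utils::write.table(out$enrichment$positive,
                           file.path(outDir, "enrichment_positive.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(out$enrichment$negative,
                           file.path(outDir, "enrichment_negative.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(outDir)
}
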