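## Synthetic cohort generator: multi-generation pedigrees, phenotypes,
## probe maps and M-value matrices with the covariance structure the
## association model assumes (polygenic 2*Phi*sigma2_g + iid residual),
## linear age effects of both signs, sex and cell-composition effects,
## clustered probe positions, and group-dependent aging slopes.

#' Simulation configuration
#'
#' Holds every knob of the synthetic cohort generator. Defaults emulate the
#' statistical structure of an obesity-prone extended-family cohort typed on
#' a 450K-style array: seven 4-generation families (~180 individuals, ages
#' 6-85), per-year age effects of magnitude 0.02-0.04 M-units with 64%
#' positive sign, metabolic-syndrome prevalence 24% among adults, and six
#' blood cell types mixed from a Dirichlet.
#'
#' @slot nFamilies number of independent families.
#' @slot generations generations per family (>= 2).
#' @slot offspringPerMating children per mating.
#' @slot nProbes total probes.
#' @slot nAgeProbes probes with a true age slope (includes clustered ones).
#' @slot ageEffectRange magnitude interval of true slopes, M-units/year.
#' @slot positiveFraction fraction of age probes with positive slope.
#' @slot heritability fraction of non-fixed variance that is polygenic
#'   (sigma2_g / (sigma2_g + sigma2_e)).
#' @slot residualSd residual standard deviation sigma_e, M-units.
#' @slot sexEffectSd sd of per-probe sex effects, M-units.
#' @slot cellEffectSd sd of per-probe cell-composition effects, M-units.
#' @slot nClusteredRegions number of planted dense age-associated regions.
#' @slot clusterSize probes per planted region.
#' @slot clusterProbeSpacing bp between consecutive probes of a region.
#' @slot metsPrevalence adult metabolic-syndrome prevalence.
#' @slot metsSlopeMultiplier slope in the affected group = multiplier x
#'   slope in the unaffected group, at designated interaction probes.
#' @slot nMetsProbes number of interaction probes (drawn from the
#'   non-clustered age probes).
#' @slot cellTypes the six blood cell-type labels.
#' @slot seed integer seed driving all stages.
#' @export
setClass("SimConfig", representation(
    nFamilies = "integer", generations = "integer",
    offspringPerMating = "integer",
    nProbes = "integer", nAgeProbes = "integer",
    ageEffectRange = "numeric", positiveFraction = "numeric",
    heritability = "numeric", residualSd = "numeric",
    sexEffectSd = "numeric", cellEffectSd = "numeric",
    nClusteredRegions = "integer", clusterSize = "integer",
    clusterProbeSpacing = "integer",
    metsPrevalence = "numeric", metsSlopeMultiplier = "numeric",
    nMetsProbes = "integer", cellTypes = "character", seed = "integer"))

setValidity("SimConfig", function(object) {
    if (object@generations < 2L) return("generations must be >= 2")
    if (object@heritability < 0 || object@heritability >= 1)
        return("heritability must be in [0, 1)")
    if (object@positiveFraction < 0 || object@positiveFraction > 1)
        return("positiveFraction must be in [0, 1]")
    if (object@nAgeProbes > object@nProbes)
        return("nAgeProbes must not exceed nProbes")
    if (object@nClusteredRegions * object@clusterSize > object@nAgeProbes)
        return("clustered probes exceed nAgeProbes")
    if (length(object@ageEffectRange) != 2L ||
        any(object@ageEffectRange < 0) || diff(object@ageEffectRange) < 0)
        return("ageEffectRange must be a non-decreasing pair of magnitudes")
    if (length(object@cellTypes) != 6L) return("exactly 6 cell types required")
    TRUE
})

#' @describeIn SimConfig constructor with cohort-emulating defaults.
#' @param nFamilies,generations,offspringPerMating,nProbes,nAgeProbes see slots.
#' @param ageEffectRange,positiveFraction,heritability,residualSd see slots.
#' @param sexEffectSd,cellEffectSd,nClusteredRegions,clusterSize see slots.
#' @param clusterProbeSpacing,metsPrevalence,metsSlopeMultiplier see slots.
#' @param nMetsProbes,cellTypes,seed see slots.
#' @export
SimConfig <- function(nFamilies = 7, generations = 4, offspringPerMating = 3,
                      nProbes = 2000, nAgeProbes = 60,
                      ageEffectRange = c(0.02, 0.04),
                      positiveFraction = 0.64, heritability = 0.5,
                      residualSd = 0.3, sexEffectSd = 0.1, cellEffectSd = 0.5,
                      nClusteredRegions = 3, clusterSize = 12,
                      clusterProbeSpacing = 1000,
                      metsPrevalence = 0.24, metsSlopeMultiplier = -0.37,
                      nMetsProbes = 4,
                      cellTypes = c("granulocytes", "CD4T", "CD8T",
                                    "monocytes", "NK", "B"),
                      seed = 1) {
    new("SimConfig",
        nFamilies = as.integer(nFamilies),
        generations = as.integer(generations),
        offspringPerMating = as.integer(offspringPerMating),
        nProbes = as.integer(nProbes), nAgeProbes = as.integer(nAgeProbes),
        ageEffectRange = as.numeric(ageEffectRange),
        positiveFraction = positiveFraction, heritability = heritability,
        residualSd = residualSd, sexEffectSd = sexEffectSd,
        cellEffectSd = cellEffectSd,
        nClusteredRegions = as.integer(nClusteredRegions),
        clusterSize = as.integer(clusterSize),
        clusterProbeSpacing = as.integer(clusterProbeSpacing),
        metsPrevalence = metsPrevalence,
        metsSlopeMultiplier = metsSlopeMultiplier,
        nMetsProbes = as.integer(nMetsProbes),
        cellTypes = cellTypes, seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
    cat(sprintf(paste0(
        "SimConfig: %d families x %d generations, %d probes ",
        "(%d age-associated, %d regions x %d clustered)\n",
        "  slope magnitude %.3f-%.3f M/yr, %d%% positive; h2 = %.2f, ",
        "sigma_e = %.2f; MetS prevalence %.2f; seed %d\n"),
        object@nFamilies, object@generations, object@nProbes,
        object@nAgeProbes, object@nClusteredRegions, object@clusterSize,
        object@ageEffectRange[1L], object@ageEffectRange[2L],
        round(100 * object@positiveFraction), object@heritability,
        object@residualSd, object@metsPrevalence, object@seed))
})

## stage-specific substream of the master seed (kept below 2^31)
.stageSeed <- function(cfg, stage) {
    (cfg@seed * 101L + stage * 7919L) %% .Machine$integer.max
}

#' Simulate a multi-generation pedigree
#'
#' Builds \code{nFamilies} independent families. Each family starts from a
#' founder couple; in every non-final generation the first two children of
#' each mating marry unrelated founder spouses and produce
#' \code{offspringPerMating} children. With >= 3 generations the pedigree
#' therefore contains parent-offspring, sibling, avuncular and (with >= 4)
#' first-cousin pairs. Sexes of children are random; spouses take the
#' opposite sex. Deterministic for a fixed config.
#'
#' @param cfg a [SimConfig-class].
#' @return a [Pedigree-class].
#' @export
simulatePedigree <- function(cfg) {
    stopifnot(is(cfg, "SimConfig"))
    set.seed(.stageSeed(cfg, 1L))
    rows <- vector("list", cfg@nFamilies)
    for (f in seq_len(cfg@nFamilies)) {
        fam <- sprintf("FAM%02d", f)
        nid <- 0L
        newId <- function() {
            nid <<- nid + 1L
            sprintf("%s_I%03d", fam, nid)
        }
        df <- data.frame(family = character(), id = character(),
                         father = character(), mother = character(),
                         sex = character(), generation = integer(),
                         stringsAsFactors = FALSE)
        addInd <- function(father, mother, sex, gen) {
            id <- newId()
            df[nrow(df) + 1L, ] <<- list(fam, id, father, mother, sex, gen)
            id
        }
        dad <- addInd(NA, NA, "male", 1L)
        mom <- addInd(NA, NA, "female", 1L)
        couples <- list(c(dad, mom))
        for (g in seq_len(cfg@generations - 1L) + 1L) {
            nextCouples <- list()
            for (cp in couples) {
                kids <- character(cfg@offspringPerMating)
                for (k in seq_len(cfg@offspringPerMating))
                    kids[k] <- addInd(cp[1L], cp[2L],
                                      sample(c("male", "female"), 1L), g)
                if (g < cfg@generations) {
                    for (k in seq_len(min(2L, length(kids)))) {
                        ksex <- df$sex[df$id == kids[k]]
                        spSex <- if (ksex == "male") "female" else "male"
                        sp <- addInd(NA, NA, spSex, g)
                        pair <- if (ksex == "male") c(kids[k], sp)
                                else c(sp, kids[k])
                        nextCouples[[length(nextCouples) + 1L]] <- pair
                    }
                }
            }
            couples <- nextCouples
        }
        rows[[f]] <- df
    }
    df <- do.call(rbind, rows)
    ped <- Pedigree(df[, c("family", "id", "father", "mother", "sex")])
    attr(ped@members, "generation") <- stats::setNames(df$generation, df$id)
    ped
}

## generation index for age assignment; recomputed when absent (e.g. after
## file round-trip): non-founders by depth, married-in founders join their
## partner's generation (min child depth - 1).
.pedGeneration <- function(ped) {
    gen <- attr(pedMembers(ped), "generation")
    df <- pedMembers(ped)
    if (!is.null(gen)) return(gen[df$id])
    depth <- .pedDepth(df)
    gen <- depth + 1L
    isFounder <- is.na(df$father) & is.na(df$mother)
    for (i in which(isFounder)) {
        kids <- df$father %in% df$id[i] | df$mother %in% df$id[i]
        if (any(kids)) gen[i] <- min(gen[which(kids)]) - 1L
    }
    stats::setNames(as.integer(gen), df$id)
}

#' Simulate a clustered probe map
#'
#' Emits \code{nClusteredRegions} dense regions of \code{clusterSize} probes
#' spaced \code{clusterProbeSpacing} bp apart, plus background probes spaced
#' 50 kb apart (never within 10 kb of one another or of a region). Autosomes
#' only, 1-based positions. Region probes carry a shared gene symbol
#' (\code{CLGENE<r>}); a third of background probes carry background gene
#' symbols, the rest are intergenic.
#'
#' @param cfg a [SimConfig-class].
#' @return a \code{data.frame} with columns \code{probe_id},
#'   \code{chromosome}, \code{position}, \code{gene}, \code{region} and
#'   \code{cluster_id} (\code{NA} for background probes).
#' @export
simulateProbeMap <- function(cfg) {
    stopifnot(is(cfg, "SimConfig"))
    set.seed(.stageSeed(cfg, 2L))
    regions <- c("TSS1500", "TSS200", "5'UTR", "First exon", "Body", "3'UTR")
    nClust <- cfg@nClusteredRegions * cfg@clusterSize
    nBg <- cfg@nProbes - nClust
    if (nBg < 0L) stop("nProbes too small for the requested clustered regions")
    out <- vector("list", cfg@nClusteredRegions + 1L)
    for (r in seq_len(cfg@nClusteredRegions)) {
        chr <- ((r - 1L) %% 22L) + 1L
        start <- 1e6 + (r - 1L) * 5e6
        pos <- as.integer(start + (seq_len(cfg@clusterSize) - 1L) *
                          cfg@clusterProbeSpacing)
        out[[r]] <- data.frame(
            chromosome = as.character(chr), position = pos,
            gene = sprintf("CLGENE%d", r),
            region = sample(regions, cfg@clusterSize, replace = TRUE),
            cluster_id = r)
    }
    if (nBg > 0L) {
        chr <- as.character(((seq_len(nBg) - 1L) %% 22L) + 1L)
        rank <- stats::ave(seq_len(nBg), chr, FUN = seq_along)
        pos <- as.integer(5e7 + (rank - 1L) * 5e4)
        gene <- ifelse(seq_len(nBg) %% 3L == 0L,
                       sprintf("BGGENE%d", seq_len(nBg)), "")
        out[[cfg@nClusteredRegions + 1L]] <- data.frame(
            chromosome = chr, position = pos, gene = gene,
            region = ifelse(gene == "", "intergenic",
                            sample(regions, nBg, replace = TRUE)),
            cluster_id = NA_integer_)
    }
    ann <- do.call(rbind, out)
    ann <- ann[order(as.integer(ann$chromosome), ann$position), ]
    ann <- data.frame(probe_id = sprintf("cg%08d", seq_len(nrow(ann))), ann,
                      row.names = NULL)
    ann
}

#' Simulate methylation for a pedigree
#'
#' For each probe p, \code{M_p = mu_p + b_p * age + s_p * male + C gamma_p +
#' g + e}, with \code{g ~ MVN(0, 2*Phi*sigma2_g)} drawn through the
#' symmetric eigendecomposition square root of 2*Phi, \code{e} iid normal
#' with sd \code{residualSd}, and \code{sigma2_g = h2/(1-h2) * residualSd^2}
#' so the polygenic fraction of non-fixed variance is \code{heritability}.
#' Ages are uniform within generation bands spanning 6-85 years (oldest
#' generation first); metabolic syndrome is assigned to adults (age >= 18)
#' at \code{metsPrevalence}; cell proportions come from a Dirichlet with
#' whole-blood-like means. Age probes comprise all clustered-region probes
#' (each region has one slope sign) plus scattered singletons; designated
#' interaction probes get slope \code{metsSlopeMultiplier * b_p} in the
#' affected group.
#'
#' @param ped a [Pedigree-class], typically from [simulatePedigree()].
#' @param cfg a [SimConfig-class].
#' @return a [SynthCohort-class].
#' @export
simulateMethylation <- function(ped, cfg) {
    stopifnot(is(ped, "Pedigree"), is(cfg, "SimConfig"))
    set.seed(.stageSeed(cfg, 3L))
    df <- pedMembers(ped)
    n <- nrow(df)
    ids <- df$id

    ## phenotypes
    gen <- .pedGeneration(ped)[ids]
    G <- max(gen)
    breaks <- seq(85, 6, length.out = G + 1L)
    age <- stats::runif(n, breaks[gen + 1L], breaks[gen])
    sexM <- as.numeric(df$sex == "male")
    mets <- ifelse(age >= 18, stats::rbinom(n, 1L, cfg@metsPrevalence),
                   NA_integer_)
    pheno <- data.frame(id = ids, age = age, sex = df$sex, mets = mets,
                        generation = gen, row.names = ids)

    ## cell proportions: Dirichlet with whole-blood-like means
    base <- c(granulocytes = 0.60, CD4T = 0.15, CD8T = 0.08,
              monocytes = 0.08, NK = 0.05, B = 0.04)
    alpha <- base[cfg@cellTypes] * 80
    C <- matrix(stats::rgamma(n * 6L, shape = rep(alpha, each = n)), n, 6L,
                dimnames = list(ids, cfg@cellTypes))
    C <- C / rowSums(C)

    ## probe map and true effects
    ann <- simulateProbeMap(cfg)
    P <- nrow(ann)
    isClust <- !is.na(ann$cluster_id)
    nScatter <- cfg@nAgeProbes - sum(isClust)
    scatterIdx <- sample(which(!isClust), nScatter)
    isAge <- isClust
    isAge[scatterIdx] <- TRUE
    mag <- stats::runif(P, cfg@ageEffectRange[1L], cfg@ageEffectRange[2L])
    sign <- ifelse(stats::rbinom(P, 1L, cfg@positiveFraction) == 1L, 1, -1)
    ## one direction per planted region
    for (r in unique(ann$cluster_id[isClust]))
        sign[which(ann$cluster_id %in% r)] <-
            sign[which(ann$cluster_id %in% r)][1L]
    slope <- ifelse(isAge, mag * sign, 0)
    metsIdx <- sample(scatterIdx, min(cfg@nMetsProbes, length(scatterIdx)))
    slopeMets <- slope
    slopeMets[metsIdx] <- cfg@metsSlopeMultiplier * slope[metsIdx]

    mu <- stats::runif(P, -3, 3)
    sexEff <- stats::rnorm(P, 0, cfg@sexEffectSd)
    gamma <- matrix(stats::rnorm(P * 6L, 0, cfg@cellEffectSd), P, 6L)

    ## polygenic + residual noise
    s2e <- cfg@residualSd^2
    s2g <- if (cfg@heritability > 0)
        cfg@heritability / (1 - cfg@heritability) * s2e else 0
    K2 <- 2 * kinshipMatrix(ped, ids)
    ee <- eigen(K2, symmetric = TRUE)
    if (min(ee$values) < -1e-8)
        stop("kinship matrix 2*Phi is not positive semidefinite")
    A <- ee$vectors %*% (sqrt(pmax(ee$values, 0)) * t(ee$vectors))

    metsNum <- ifelse(is.na(mets), 0, mets)  # children follow the unaffected slope
    slopeBySample <- outer(slope, 1 - metsNum) + outer(slopeMets, metsNum)
    M <- mu + slopeBySample * rep(age, each = P) +
        outer(sexEff, sexM) + gamma %*% t(C)
    if (s2g > 0)
        M <- M + sqrt(s2g) * t(A %*% matrix(stats::rnorm(n * P), n, P))
    if (s2e > 0)
        M <- M + matrix(stats::rnorm(P * n, 0, cfg@residualSd), P, n)
    dimnames(M) <- list(ann$probe_id, ids)

    truth <- data.frame(probe_id = ann$probe_id, is_age_probe = isAge,
                        slope = slope, slope_no_mets = slope,
                        slope_mets = slopeMets,
                        is_mets_probe = seq_len(P) %in% metsIdx,
                        cluster_id = ann$cluster_id)
    se <- SummarizedExperiment(
        assays = list(M = M, beta = mToBeta(M)),
        rowData = DataFrame(ann[, c("chromosome", "position", "gene",
                                    "region")], row.names = ann$probe_id),
        colData = DataFrame(pheno[, c("age", "sex", "mets", "generation")],
                            row.names = ids))
    metadata(se)$seed <- cfg@seed
    new("SynthCohort", se = se, pedigree = ped, truth = truth,
        cellProps = C, config = cfg)
}

#' Synthetic cohort container
#'
#' Bundles the simulated methylation experiment (a
#' \code{SummarizedExperiment} with \code{M} and \code{beta} assays, probe
#' annotation as rowData and phenotypes as colData) with the generating
#' pedigree, the per-probe truth table and the true cell proportions.
#'
#' @slot se the \code{SummarizedExperiment}.
#' @slot pedigree the generating [Pedigree-class].
#' @slot truth per-probe truth: slopes by group, age-probe and cluster flags.
#' @slot cellProps sample x cell-type matrix of true mixing proportions.
#' @slot config the [SimConfig-class] used.
#' @export
setClass("SynthCohort", representation(
    se = "SummarizedExperiment", pedigree = "Pedigree",
    truth = "data.frame", cellProps = "matrix", config = "SimConfig"))

setMethod("show", "SynthCohort", function(object) {
    cat(sprintf("SynthCohort: %d probes x %d samples (%d age probes)\n",
                nrow(object@se), ncol(object@se),
                sum(object@truth$is_age_probe)))
})

#' Accessors for SynthCohort pieces
#'
#' @param x a [SynthCohort-class]
#' @return \code{cohortSE} the \code{SummarizedExperiment}; \code{cohortM} /
#'   \code{cohortBeta} the assay matrices; \code{cohortPedigree} the
#'   pedigree; \code{cohortTruth} the truth table; \code{cohortPheno} the
#'   phenotype data.frame; \code{cohortCellProps} the true proportions.
#' @export
cohortSE <- function(x) { stopifnot(is(x, "SynthCohort")); x@se }

#' @rdname cohortSE
#' @export
cohortM <- function(x) assay(cohortSE(x), "M")

#' @rdname cohortSE
#' @export
cohortBeta <- function(x) assay(cohortSE(x), "beta")

#' @rdname cohortSE
#' @export
cohortPedigree <- function(x) { stopifnot(is(x, "SynthCohort")); x@pedigree }

#' @rdname cohortSE
#' @export
cohortTruth <- function(x) { stopifnot(is(x, "SynthCohort")); x@truth }

#' @rdname cohortSE
#' @export
cohortCellProps <- function(x) { stopifnot(is(x, "SynthCohort")); x@cellProps }

#' @rdname cohortSE
#' @export
cohortPheno <- function(x) {
    as.data.frame(colData(cohortSE(x)))
}

#' @rdname cohortSE
#' @export
cohortAnnotation <- function(x) {
    se <- cohortSE(x)
    data.frame(probe_id = rownames(se), as.data.frame(rowData(se)),
               row.names = NULL)
}

#' Simulate a full cohort in one call
#'
#' Convenience wrapper: [simulatePedigree()] then [simulateMethylation()].
#'
#' @param cfg a [SimConfig-class]; default [SimConfig()].
#' @return a [SynthCohort-class].
#' @examples
#' cohort <- simulateCohort(SimConfig(nFamilies = 1, nProbes = 50,
#'                                    nAgeProbes = 12, nClusteredRegions = 1))
#' cohort
#' @export
simulateCohort <- function(cfg = SimConfig()) {
    simulateMethylation(simulatePedigree(cfg), cfg)
}

#' Reference methylation profiles for cell-type deconvolution
#'
#' Builds a synthetic six-cell-type reference of discriminating probes: each
#' cell type gets a block of probes hypermethylated in that type and low in
#' the others, mirroring the structure of sorted-cell reference panels. Used
#' together with [mixCellSamples()] to exercise the deconvolution module;
#' real analyses supply their own reference.
#'
#' @param nPerType discriminating probes per cell type.
#' @param cellTypes the six labels.
#' @param seed integer seed.
#' @return probe x cell-type matrix of mean beta values in (0,1).
#' @export
syntheticCellReference <- function(nPerType = 10,
                                   cellTypes = c("granulocytes", "CD4T",
                                                 "CD8T", "monocytes", "NK",
                                                 "B"),
                                   seed = 1) {
    set.seed(seed %% .Machine$integer.max)
    k <- length(cellTypes)
    P <- nPerType * k
    ref <- matrix(stats::runif(P * k, 0.05, 0.25), P, k,
                  dimnames = list(sprintf("ref%03d", seq_len(P)), cellTypes))
    for (j in seq_len(k)) {
        idx <- (j - 1L) * nPerType + seq_len(nPerType)
        ref[idx, j] <- stats::runif(nPerType, 0.75, 0.95)
    }
    ref
}

#' Mix bulk samples from a cell-type reference
#'
#' Draws per-sample mixing weights from a Dirichlet and forms bulk beta
#' values as the weighted mixture of reference columns plus optional iid
#' noise (clamped to (0,1)).
#'
#' @param ref probe x cell-type reference matrix.
#' @param nSamples number of bulk samples.
#' @param alpha Dirichlet concentration vector (recycled to the number of
#'   cell types).
#' @param noiseSd sd of added beta-scale noise.
#' @param seed integer seed.
#' @return list with \code{beta} (probe x sample) and \code{weights}
#'   (sample x cell type, the truth).
#' @export
mixCellSamples <- function(ref, nSamples = 100, alpha = 4, noiseSd = 0,
                           seed = 1) {
    set.seed(seed %% .Machine$integer.max)
    k <- ncol(ref)
    alpha <- rep_len(alpha, k)
    W <- matrix(stats::rgamma(nSamples * k, shape = rep(alpha, each = nSamples)),
                nSamples, k)
    W <- W / rowSums(W)
    colnames(W) <- colnames(ref)
    rownames(W) <- sprintf("S%03d", seq_len(nSamples))
    beta <- ref %*% t(W)
    if (noiseSd > 0)
        beta <- beta + matrix(stats::rnorm(length(beta), 0, noiseSd),
                              nrow(beta), ncol(beta))
    beta <- pmin(pmax(beta, 1e-6), 1 - 1e-6)
    dimnames(beta) <- list(rownames(ref), rownames(W))
    list(beta = beta, weights = W)
}

#' Write a synthetic cohort to disk as plain-text files
#'
#' Emits exactly the formats the analysis reads back: \code{pedigree.ped},
#' \code{phenotypes.tsv}, \code{M.tsv}, \code{beta.tsv},
#' \code{annotation.tsv} and \code{truth.tsv} under \code{dir}.
#'
#' @param cohort a [SynthCohort-class].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writePedigree(cohortPedigree(cohort), file.path(dir, "pedigree.ped"))
    pheno <- cohortPheno(cohort)
    utils::write.table(data.frame(id = rownames(pheno), pheno),
                       file.path(dir, "phenotypes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeMatrixTSV(cohortM(cohort), file.path(dir, "M.tsv"))
    writeMatrixTSV(cohortBeta(cohort), file.path(dir, "beta.tsv"))
    utils::write.table(cohortAnnotation(cohort),
                       file.path(dir, "annotation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(cohortTruth(cohort), file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(dir)
}
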