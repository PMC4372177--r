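test_that("simulated pedigrees are deterministic and contain the expected
           relationship classes", {
    cfg <- SimConfig(nFamilies = 1, generations = 2, offspringPerMating = 2,
                     seed = 5)
    ped <- simulatePedigree(cfg)
    expect_length(ped, 4L)
    sibs <- setdiff(pedIds(ped), pedFounders(ped))
    expect_identical(2 * kinship(ped, sibs[1], sibs[2]), 1 / 2)

    ## same seed -> identical pedigree
    expect_identical(pedMembers(simulatePedigree(cfg)), pedMembers(ped))

    ## generations = 4 yields at least one first-cousin pair (2phi = 1/8)
    ped4 <- simulatePedigree(SimConfig(nFamilies = 1, generations = 4,
                                       seed = 5))
    km <- 2 * kinshipMatrix(ped4)
    diag(km) <- 0
    expect_true(any(abs(km - 1 / 8) < 1e-12))
    ## and parent-offspring, sibling/avuncular values are realized too
    expect_true(any(abs(km - 1 / 2) < 1e-12))
    expect_true(any(abs(km - 1 / 4) < 1e-12))
})

test_that("probe maps cluster below the gap and separate above it", {
    cfg <- SimConfig(nProbes = 60, nAgeProbes = 24, nClusteredRegions = 2,
                     clusterSize = 12, clusterProbeSpacing = 1000, seed = 2)
    ann <- simulateProbeMap(cfg)
    expect_identical(simulateProbeMap(cfg), ann)   # determinism
    expect_true(all(ann$position >= 1))
    expect_true(all(ann$chromosome %in% as.character(1:22)))

    ## clustered regions sit within 10 kb chains; background probes do not
    cl <- gapCluster(ann, maxGap = 10000)
    sizes <- table(cl$cluster)
    expect_identical(sum(sizes >= 10), 2L)
    expect_identical(sum(sizes == 1), 60L - 24L)

    ## spacing above the gap never clusters
    wide <- simulateProbeMap(SimConfig(nProbes = 24, nAgeProbes = 12,
                                       nClusteredRegions = 1,
                                       clusterSize = 12,
                                       clusterProbeSpacing = 10001,
                                       seed = 2))
    cl <- gapCluster(wide, maxGap = 10000)
    expect_identical(max(table(cl$cluster)), 1L)
})

test_that("noiseless simulation is an exact linear function of age", {
    cfg <- SimConfig(nFamilies = 1, generations = 3, offspringPerMating = 2,
                     nProbes = 40, nAgeProbes = 10, nClusteredRegions = 0,
                     clusterSize = 0, heritability = 0, residualSd = 0,
                     sexEffectSd = 0, cellEffectSd = 0, seed = 4)
    co <- simulateCohort(cfg)
    tr <- cohortTruth(co)
    age <- cohortPheno(co)$age
    M <- cohortM(co)
    for (i in which(tr$is_age_probe & !tr$is_mets_probe)) {
        b <- coef(lm(M[i, ] ~ age))[["age"]]
        expect_equal(b, tr$slope[i], tolerance = 1e-10)
    }
    ## truth slopes equal the generating parameters bit-exactly and
    ## non-age probes are flat
    expect_true(all(tr$slope[!tr$is_age_probe] == 0))
    expect_true(all(abs(tr$slope[tr$is_age_probe]) >= 0.02 - 1e-12 &
                    abs(tr$slope[tr$is_age_probe]) <= 0.04 + 1e-12))
})

test_that("beta and M assays are mutual logit2 transforms in (0,1)", {
    co <- simulateCohort(SimConfig(nFamilies = 1, generations = 2,
                                   nProbes = 50, nAgeProbes = 5,
                                   nClusteredRegions = 0, clusterSize = 0,
                                   seed = 9))
    B <- cohortBeta(co)
    expect_true(all(B > 0 & B < 1))
    expect_equal(betaToM(B), cohortM(co), tolerance = 1e-12)
    expect_equal(mToBeta(cohortM(co)), B, tolerance = 1e-12)
})

test_that("simulated covariance approaches h2 * 2Phi + (1 - h2) I", {
    cfg <- SimConfig(nFamilies = 1, generations = 3, offspringPerMating = 2,
                     nProbes = 3000, nAgeProbes = 0, nClusteredRegions = 0,
                     clusterSize = 0, heritability = 0.5, residualSd = 0.3,
                     sexEffectSd = 0, cellEffectSd = 0, seed = 10)
    ped <- simulatePedigree(cfg)
    co <- simulateMethylation(ped, cfg)
    M <- cohortM(co)
    ## remove the per-probe fixed part (intercept only; no effects here);
    ## compare against the covariance of the centered vector, C Sigma C'
    R <- M - rowMeans(M)
    emp <- crossprod(R) / nrow(M)      # average over probes
    s2 <- 0.3^2 / (1 - 0.5)            # total non-fixed variance
    n <- length(ped)
    theo <- s2 * (0.5 * 2 * kinshipMatrix(ped) + 0.5 * diag(n))
    C <- diag(n) - 1 / n
    theoC <- C %*% theo %*% C
    ## Monte-Carlo tolerance: ~5 sd of an entry averaged over 3000 probes
    expect_lt(max(abs(emp - theoC)), 5 * s2 * sqrt(2 / nrow(M)))
})

test_that("MetS assignment and group slopes follow the configuration", {
    cfg <- SimConfig(seed = 12)
    co <- simulateCohort(cfg)
    ph <- cohortPheno(co)
    expect_true(all(is.na(ph$mets[ph$age < 18])))
    expect_true(all(ph$mets[ph$age >= 18] %in% 0:1))
    adultFrac <- mean(ph$mets[ph$age >= 18])
    expect_gt(adultFrac, 0.10); expect_lt(adultFrac, 0.40)
    tr <- cohortTruth(co)
    mp <- tr[tr$is_mets_probe, ]
    expect_identical(nrow(mp), 4L)
    expect_equal(mp$slope_mets, -0.37 * mp$slope_no_mets, tolerance = 1e-12)
    same <- tr[!tr$is_mets_probe, ]
    expect_identical(same$slope_mets, same$slope_no_mets)
})

test_that("cohorts round-trip through the plain-text interchange files", {
    cfg <- SimConfig(nFamilies = 1, generations = 3, offspringPerMating = 2,
                     nProbes = 30, nAgeProbes = 4, nClusteredRegions = 0,
                     clusterSize = 0, seed = 13)
    co <- simulateCohort(cfg)
    d <- withr::local_tempdir()
    writeCohort(co, d)
    back <- loadCohortFiles(pedigree = file.path(d, "pedigree.ped"),
                            phenotypes = file.path(d, "phenotypes.tsv"),
                            annotation = file.path(d, "annotation.tsv"),
                            M = file.path(d, "M.tsv"))
    expect_equal(back$M, cohortM(co), tolerance = 1e-6)
    expect_identical(pedMembers(back$pedigree)[, 1:5],
                     pedMembers(cohortPedigree(co))[, 1:5])
    expect_equal(back$pheno[colnames(back$M), "age"],
                 cohortPheno(co)$age, tolerance = 1e-6)
})

test_that("same seed gives an identical cohort", {
    cfg <- SimConfig(nFamilies = 1, generations = 2, nProbes = 25,
                     nAgeProbes = 5, nClusteredRegions = 0, clusterSize = 0,
                     seed = 21)
    expect_identical(cohortM(simulateCohort(cfg)),
                     cohortM(simulateCohort(cfg)))
})
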