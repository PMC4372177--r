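test_that("Bonferroni threshold is alpha over the test count", {
    expect_identical(bonferroniThreshold(1), 0.05)
    expect_identical(bonferroniThreshold(10), 0.005)
    expect_equal(signif(bonferroniThreshold(137168), 3), 3.65e-7)
})

test_that("with unrelated samples the mixed model reduces to OLS", {
    u <- unrelatedCohort(80, seed = 15)
    y <- 1 + 0.02 * u$age - 0.1 * u$sex + rnorm(80, 0, 0.4)
    X <- cbind(age = u$age, male = u$sex)
    fit <- fitProbe(y, X, u$phi)
    ols <- lm(y ~ u$age + u$sex)
    expect_equal(unname(fit$coefficients),
                 unname(coef(ols)), tolerance = 1e-6)
    ## ML total variance is RSS/n
    expect_equal(fit$sigma2g + fit$sigma2e,
                 sum(resid(ols)^2) / 80, tolerance = 1e-6)
})

test_that("noiseless data are fitted exactly with vanishing residual variance", {
    u <- unrelatedCohort(40, seed = 16)
    y <- 0.03 * u$age
    fit <- fitProbe(y, cbind(age = u$age), u$phi)
    expect_equal(unname(fit$coefficients["age"]), 0.03, tolerance = 1e-10)
    expect_lt(fit$sigma2g + fit$sigma2e, 1e-12)
    tst <- testFixedEffect(y, cbind(age = u$age), u$phi)
    expect_lt(tst$p, 1e-20)
})

test_that("eigen-rotated likelihood equals dense MVN evaluation (n <= 50)", {
    for (seed in 1:3) {
        cfg <- SimConfig(nFamilies = 2, generations = 3,
                         offspringPerMating = 2, seed = seed)
        ped <- simulatePedigree(cfg)
        phi <- kinshipMatrix(ped)
        n <- nrow(phi)
        expect_lte(n, 50)
        set.seed(100 + seed)
        age <- runif(n, 6, 85)
        y <- 0.5 + 0.01 * age + drop(chol(2 * phi) %*% rnorm(n)) * 0.3 +
            rnorm(n, 0, 0.3)
        X <- cbind(age = age)
        fit <- fitProbe(y, X, phi)
        dense <- denseLogLik(y, cbind(1, X), fit$coefficients,
                             fit$sigma2g, fit$sigma2e, phi)
        expect_equal(fit$logLik, dense, tolerance = 1e-8)
    }
})

test_that("P values are invariant to affine rescaling of covariates", {
    cfg <- SimConfig(nFamilies = 1, generations = 3, seed = 17)
    ped <- simulatePedigree(cfg)
    phi <- kinshipMatrix(ped)
    n <- nrow(phi)
    set.seed(18)
    age <- runif(n, 6, 85); z <- rnorm(n)
    y <- 0.02 * age + 0.3 * z + rnorm(n, 0, 0.3)
    p1 <- testFixedEffect(y, cbind(age = age, z = z), phi)$p
    p2 <- testFixedEffect(y, cbind(age = age, z = 10 * z + 3), phi)$p
    expect_equal(p1, p2, tolerance = 1e-6)
    ## rescaling the tested column itself rescales beta but not p
    t3 <- testFixedEffect(y, cbind(age = age / 10, z = z), phi)
    expect_equal(t3$p, p1, tolerance = 1e-6)
})

test_that("degenerate designs are handled by convention or error", {
    u <- unrelatedCohort(30, seed = 19)
    y <- rnorm(30)
    ## constant age column: zero-LRT P of 1
    tst <- testFixedEffect(y, cbind(age = rep(42, 30)), u$phi)
    expect_identical(tst$p, 1)
    expect_identical(tst$lrt, 0)
    ## duplicated column: singular design
    expect_error(fitProbe(y, cbind(age = u$age, age2 = u$age), u$phi),
                 "singular")
})

test_that("LRT statistic is non-negative and grows with the planted effect", {
    u <- unrelatedCohort(120, seed = 20)
    X <- cbind(age = u$age)
    set.seed(21)
    lrts <- vapply(c(0, 0.005, 0.02), function(b) {
        mean(replicate(8, {
            y <- b * u$age + rnorm(120, 0, 0.3)
            testFixedEffect(y, X, u$phi)$lrt
        }))
    }, numeric(1))
    expect_true(all(lrts >= 0))
    expect_true(all(diff(lrts) > 0))
})

test_that("Wald cross-check agrees with the LRT for moderate effects", {
    u <- unrelatedCohort(150, seed = 22)
    set.seed(23)
    y <- 0.005 * u$age + rnorm(150, 0, 0.3)
    X <- cbind(age = u$age)
    lrt <- testFixedEffect(y, X, u$phi, test = "lrt")
    wald <- testFixedEffect(y, X, u$phi, test = "wald")
    expect_equal(lrt$beta, wald$beta, tolerance = 1e-8)
    ## chi-square(1) and squared-z agree to first order away from the
    ## saturation regime
    expect_equal(log10(lrt$p), log10(wald$p), tolerance = 0.3)
})

test_that("heritable traits yield calibrated estimates on pedigree data", {
    ## moderate replicate count here; the deeper recovery simulation runs
    ## in the acceptance suite
    cfg <- SimConfig(nFamilies = 4, generations = 3, offspringPerMating = 3,
                     seed = 24)
    ped <- simulatePedigree(cfg)
    phi <- kinshipMatrix(ped)
    n <- nrow(phi)
    A <- chol(2 * phi)
    set.seed(25)
    h2hat <- replicate(30, {
        y <- drop(rnorm(n) %*% A) * sqrt(0.5) + rnorm(n, 0, sqrt(0.5))
        fitProbe(y, NULL, phi)$h2
    })
    expect_lt(abs(mean(h2hat) - 0.5), 0.1)
})

test_that("the scan flags planted probes, reports direction counts and
           survives per-probe failure", {
    cfg <- SimConfig(nFamilies = 3, generations = 4, offspringPerMating = 3,
                     nProbes = 300, nAgeProbes = 30, nClusteredRegions = 1,
                     clusterSize = 10, seed = 26)
    co <- simulateCohort(cfg)
    phi <- kinshipMatrix(cohortPedigree(co))
    res <- runEwas(cohortM(co), cohortPheno(co), phi,
                   cellCovariates = covariateColumns(cohortCellProps(co)))
    tr <- cohortTruth(co)
    expect_identical(res$probe_id, tr$probe_id)
    ## all planted homogeneous-slope probes significant, no false
    ## positives expected (interaction probes have attenuated pooled
    ## slopes and are exercised in the differential-aging tests)
    expect_true(all(res$significant[tr$is_age_probe & !tr$is_mets_probe]))
    expect_lte(sum(res$significant & !tr$is_age_probe), 1)
    s <- attr(res, "summary")
    expect_identical(s$n_positive + s$n_negative, s$n_significant)
    expect_equal(attr(res, "threshold"), 0.05 / 300)
    ## slope estimates track the planted slopes
    hom <- tr$is_age_probe & !tr$is_mets_probe
    expect_gt(cor(res$beta_age[hom], tr$slope[hom]), 0.95)
})
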