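probesAt <- function(pos, chr = "1")
    data.frame(probe_id = sprintf("p%03d", seq_along(pos)),
               chromosome = chr, position = pos)

test_that("gap clustering follows the 10 kb chain rule with inclusive
           boundary", {
    cl <- gapCluster(probesAt(c(1000, 5000, 20000)))
    expect_identical(cl$cluster, c(1L, 1L, 2L))
    ## gap exactly 10,000 still joins
    cl <- gapCluster(probesAt(c(1000, 11000)))
    expect_identical(cl$cluster, c(1L, 1L))
    cl <- gapCluster(probesAt(c(1000, 11001)))
    expect_identical(cl$cluster, c(1L, 2L))
    ## chromosomes cluster independently
    two <- rbind(probesAt(c(1000, 2000), "1"), probesAt(c(1500), "2"))
    cl <- gapCluster(two)
    expect_identical(length(unique(cl$cluster)), 2L)
    ## unsorted input is sorted internally; duplicates allowed
    cl <- gapCluster(probesAt(c(9000, 1000, 9000)))
    expect_identical(cl$position, c(1000, 9000, 9000))
    expect_identical(cl$cluster, rep(1L, 3))
})

test_that("chain partition matches the brute-force transitive closure", {
    set.seed(27)
    for (rep in 1:10) {
        pos <- sort(sample(1:500000, sample(20:200, 1)))
        cl <- gapCluster(probesAt(pos), maxGap = 10000)
        comp <- bruteGapComponents(cl$position, 10000)
        ## identical partitions of the probe index set
        tab1 <- unname(split(seq_along(pos), cl$cluster))
        tab2 <- unname(split(seq_along(pos), comp))
        expect_setequal(lapply(tab1, unname), lapply(tab2, unname))
    }
})

test_that("all-pairs variant bounds the cluster diameter", {
    cl <- gapCluster(probesAt(c(0, 6000, 12000)), method = "allpairs")
    expect_identical(cl$cluster, c(1L, 1L, 2L))
    cl <- gapCluster(probesAt(c(0, 6000, 12000)), method = "chain")
    expect_identical(cl$cluster, rep(1L, 3))
})

test_that("direction labeling partitions clusters by slope signs", {
    expect_identical(directionLabel(c(0.02, 0.03)), "positive")
    expect_identical(directionLabel(c(-0.02, -0.4)), "negative")
    expect_identical(directionLabel(c(-0.02, 0.03)), "varying")
    expect_warning(lab <- directionLabel(c(0, 0.03)), "zero")
    expect_identical(lab, "varying")
    expect_error(directionLabel(numeric()), "at least one")
    ## category counts always partition the total on a labeled set
    set.seed(28)
    labs <- replicate(50, directionLabel(runif(3, -1, 1)))
    expect_identical(sum(labs == "positive") + sum(labs == "negative") +
                     sum(labs == "varying"), 50L)
})

test_that("aDMC filtering enforces the >=10-probe / >=50% criteria against
           the post-QC probe set", {
    ## 12 post-QC probes in the span, 7 significant -> retained; the
    ## significant members bracket the span so all 12 are counted
    all12 <- probesAt(seq(1000, 12000, by = 1000))
    all12$gene <- c(rep("GENEA", 6), rep("", 6))
    sig7 <- all12[c(1:6, 12), ]
    res <- data.frame(probe_id = sig7$probe_id, beta_age = rep(0.02, 7))
    rec <- filterADMC(gapCluster(sig7), all12, res)
    expect_identical(nrow(rec), 1L)
    expect_identical(rec$n_probes_in_span, 12L)
    expect_identical(rec$n_significant, 7L)
    expect_identical(rec$direction, "positive")
    expect_identical(rec$genes, "GENEA")
    expect_identical(rec$start, 1000)
    expect_identical(rec$end, 12000)

    ## 9 post-QC probes, all significant -> rejected (< 10 probes)
    all9 <- probesAt(seq(1000, 9000, by = 1000))
    res9 <- data.frame(probe_id = all9$probe_id, beta_age = rep(-0.02, 9))
    rec <- filterADMC(gapCluster(all9), all9, res9)
    expect_identical(nrow(rec), 0L)

    ## significant fraction below 50% -> rejected
    all20 <- probesAt(seq(1000, 20000, by = 1000))
    sig9 <- all20[1:9, ]      # 9 significant in a span of 20
    res <- data.frame(probe_id = sig9$probe_id, beta_age = rep(0.02, 9))
    rec <- filterADMC(gapCluster(sig9), all20, res)
    expect_identical(nrow(rec), 0L)
})

test_that("aDMC spans are disjoint, order-invariant, and refine as the gap
           shrinks", {
    set.seed(29)
    cfg <- SimConfig(nProbes = 400, nAgeProbes = 40, nClusteredRegions = 3,
                     clusterSize = 12, seed = 30)
    ann <- simulateProbeMap(cfg)
    sig <- ann[!is.na(ann$cluster_id) | seq_len(nrow(ann)) %% 37 == 0, ]
    res <- data.frame(probe_id = sig$probe_id,
                      beta_age = runif(nrow(sig), -0.04, 0.04),
                      p_age = 1e-9, significant = TRUE)
    cand <- gapCluster(sig)
    recs <- filterADMC(cand, ann, res)
    ## disjoint spans per chromosome
    for (chr in unique(recs$chromosome)) {
        r <- recs[recs$chromosome == chr, ]
        r <- r[order(r$start), ]
        if (nrow(r) > 1)
            expect_true(all(r$start[-1] > r$end[-nrow(r)]))
    }
    ## input order does not matter
    shuf <- sig[sample(nrow(sig)), ]
    recs2 <- filterADMC(gapCluster(shuf), ann, res)
    expect_equal(recs2, recs)
    ## shrinking the gap only refines the partition
    for (gap in c(10000, 5000, 1500)) {
        cl <- gapCluster(sig, maxGap = gap)
        if (gap == 10000) {
            prev <- cl$cluster
        } else {
            ## every new cluster is contained in one previous cluster
            expect_true(all(tapply(prev, cl$cluster,
                                   function(v) length(unique(v))) == 1L))
            prev <- cl$cluster
        }
    }
})
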