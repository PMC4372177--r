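## Shared fixtures and independent oracles.

## quick pedigree builder: rows of c(id, father, mother, sex)
makePed <- function(..., family = "f1") {
    rows <- list(...)
    df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(df) <- c("id", "father", "mother", "sex")
    df$family <- family
    Pedigree(df[, c("family", "id", "father", "mother", "sex")])
}
indiv <- function(id, father = NA, mother = NA, sex = "unknown")
    c(id, father, mother, sex)

## three generations down from a founder couple, two branches; enough to
## realize grandparent, avuncular, first-cousin and deeper classes
cousinPedigree <- function() {
    makePed(
        indiv("gf", sex = "male"), indiv("gm", sex = "female"),
        indiv("a", "gf", "gm", "male"), indiv("b", "gf", "gm", "female"),
        indiv("aw", sex = "female"), indiv("bh", sex = "male"),
        indiv("ac", "a", "aw", "male"), indiv("bc", "bh", "b", "female"),
        indiv("acw", sex = "female"), indiv("bch", sex = "male"),
        indiv("acc", "ac", "acw", "male"),
        indiv("bcc", "bch", "bc", "female"),
        indiv("accw", sex = "female"), indiv("bcch", sex = "male"),
        indiv("accc", "acc", "accw", "male"),
        indiv("bccc", "bcch", "bcc", "female"))
}

## dense multivariate-normal log-likelihood at given parameter values:
## the brute-force counterpart of the eigen-rotated computation
denseLogLik <- function(y, Xfull, b, sigma2g, sigma2e, phi) {
    n <- length(y)
    Sigma <- sigma2g * 2 * phi + diag(sigma2e, n)
    r <- y - Xfull %*% b
    ch <- chol(Sigma)
    -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) +
            sum(backsolve(ch, r, transpose = TRUE)^2))
}

## exhaustive hypergeometric upper tail P(X >= k) by enumerating all
## n-subsets of an N-element background with K marked elements
bruteHyperTail <- function(k, K, n, N) {
    subsets <- utils::combn(N, n)
    hits <- colSums(subsets <= K)   # elements 1..K are the marked ones
    mean(hits >= k)
}

## union-find connected components of the pairwise <= maxGap relation
bruteGapComponents <- function(pos, maxGap) {
    n <- length(pos)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
        if (abs(pos[i] - pos[j]) <= maxGap) {
            ri <- find(i); rj <- find(j)
            if (ri != rj) parent[ri] <- rj
        }
    vapply(seq_len(n), find, integer(1))
}

## small unrelated-cohort fixture for association tests
unrelatedCohort <- function(n, seed = 1) {
    set.seed(seed)
    ids <- sprintf("s%03d", seq_len(n))
    phi <- diag(0.5, n)
    dimnames(phi) <- list(ids, ids)
    list(ids = ids, phi = phi,
         age = stats::runif(n, 6, 85),
         sex = stats::rbinom(n, 1L, 0.5))
}
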