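## Reference-based blood cell-type deconvolution: per-sample non-negative
## least squares of bulk beta values on six cell-type mean profiles,
## rescaled to proportions; five of the six enter the association model as
## fixed-effect covariates.

## Lawson-Hanson active-set NNLS (tiny: <= 6 coefficients). Hand-rolled
## because no NNLS/QP package ships in this environment.
.nnls <- function(A, b, tol = 1e-10) {
    p <- ncol(A)
    x <- numeric(p)
    passive <- rep(FALSE, p)
    w <- crossprod(A, b - A %*% x)
    iter <- 0L
    while (any(!passive & w > tol) && iter < 30L * p) {
        iter <- iter + 1L
        j <- which.max(ifelse(passive, -Inf, w))
        passive[j] <- TRUE
        repeat {
            s <- numeric(p)
            s[passive] <- qr.solve(A[, passive, drop = FALSE], b)
            if (all(s[passive] > tol)) { x <- s; break }
            neg <- passive & s <= tol
            alpha <- min(x[neg] / (x[neg] - s[neg]))
            x <- x + alpha * (s - x)
            passive <- passive & (x > tol)
            x[!passive] <- 0
        }
        w <- crossprod(A, b - A %*% x)
    }
    x
}

#' Estimate blood cell-type proportions per sample
#'
#' For each sample, fits bulk beta values at discriminating probes as a
#' non-negative mixture of the reference cell-type profiles (non-negative
#' least squares), then rescales the weights to sum to 1. Requires at least
#' 6 overlapping probes between the matrix and the reference. A collinear
#' reference triggers a warning and a pseudo-inverse fallback (negative
#' weights clamped to zero).
#'
#' @param beta probe x sample beta matrix.
#' @param ref probe x cell-type reference matrix of mean beta values
#'   (6 cell types).
#' @return sample x cell-type matrix of proportions (rows sum to 1).
#' @seealso [syntheticCellReference()], [covariateColumns()]
#' @export
estimateCellProportions <- function(beta, ref) {
    beta <- as.matrix(beta); ref <- as.matrix(ref)
    common <- intersect(rownames(beta), rownames(ref))
    if (length(common) < 6L)
        stop("need >= 6 probes shared between beta matrix and reference, got ",
             length(common))
    A <- ref[common, , drop = FALSE]
    B <- beta[common, , drop = FALSE]
    degenerate <- qr(A)$rank < ncol(A)
    if (degenerate)
        warning("reference columns are collinear; using pseudo-inverse fit ",
                "with negative weights clamped to zero")
    est <- matrix(0, ncol(B), ncol(A),
                  dimnames = list(colnames(B), colnames(A)))
    for (s in seq_len(ncol(B))) {
        w <- if (degenerate) {
            sv <- svd(A)
            keep <- sv$d > 1e-8 * sv$d[1L]
            pmax(sv$v[, keep, drop = FALSE] %*%
                 ((1 / sv$d[keep]) * crossprod(sv$u[, keep, drop = FALSE],
                                               B[, s])), 0)
        } else .nnls(A, B[, s])
        tot <- sum(w)
        est[s, ] <- if (tot > 0) w / tot else rep(1 / ncol(A), ncol(A))
    }
    est
}

#' Covariate columns from cell proportions
#'
#' Drops one of the six proportions (they sum to 1, so all six would be
#' collinear with the intercept) and returns the remaining five aligned to
#' sample order, ready to enter the fixed-effect design. Granulocytes — the
#' largest blood fraction — are dropped by default.
#'
#' @param props sample x cell-type proportion matrix.
#' @param drop cell-type label to drop.
#' @return sample x 5 numeric matrix.
#' @export
covariateColumns <- function(props, drop = "granulocytes") {
    props <- as.matrix(props)
    if (!(drop %in% colnames(props)))
        stop("unknown cell type to drop: ", drop)
    props[, setdiff(colnames(props), drop), drop = FALSE]
}
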