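#' @include AllClasses.R
NULL

#' Build the heterogeneous transition matrix
#'
#' Assembles the row-stochastic transition matrix W of the random walk on
#' the heterogeneous circRNA-disease network from the fused circRNA
#' similarity SC (m x m), fused disease similarity SD (n x n) and the
#' association matrix Y (m x n). With jump probability `mu`:
#'
#' * within-circRNA: `W_cc[i, j] = SC[i, j] / rowsum` when circRNA i has no
#'   associations, else `(1 - mu) * SC[i, j] / rowsum`;
#' * circRNA to disease: `W_cd[i, j] = mu * Y[i, j] / rowsum(Y[i, ])` when
#'   circRNA i has associations, else 0;
#' * the disease-side blocks `W_dd` and `W_dc` are the mirror images using
#'   columns of Y.
#'
#' Similarity row sums are at least 1 whenever the fused matrices keep a
#' unit diagonal, so no division by zero can occur on the similarity
#' blocks. Rows of the assembled W sum to 1 exactly (up to roundoff). A
#' fully isolated node -- zero similarity to every node including itself
#' and no associations, possible only when plain matrices are supplied --
#' yields an all-zero row, never NaN.
#'
#' @param SC,SD fused [SimilarityMatrix-class] over circRNAs / diseases
#'   (plain symmetric nonnegative matrices are also accepted)
#' @param Y the [AssociationMatrix-class] (m x n)
#' @param mu inter-network jump probability in (0, 1)
#' @return a [TransitionMatrix-class] of size (m + n)
#' @examples
#' Y <- AssociationMatrix(matrix(1, 1, 1, dimnames = list("c1", "d1")))
#' SC <- SimilarityMatrix(matrix(1, 1, 1, dimnames = list("c1", "c1")))
#' SD <- SimilarityMatrix(matrix(1, 1, 1, dimnames = list("d1", "d1")))
#' as.matrix(buildTransitionMatrix(SC, SD, Y, mu = 0.6))
#' @export
buildTransitionMatrix <- function(SC, SD, Y, mu) {
    stopifnot(is(Y, "AssociationMatrix"),
              is.numeric(mu), length(mu) == 1L, mu > 0, mu < 1)
    yv <- Y@values
    m <- nrow(yv); n <- ncol(yv)
    if (is(SC, "SimilarityMatrix")) {
        if (!identical(simIds(SC), circIds(Y)))
            stop("SC identifiers do not match the circRNAs of Y")
        sc <- SC@values
    } else sc <- as.matrix(SC)
    if (is(SD, "SimilarityMatrix")) {
        if (!identical(simIds(SD), diseaseIds(Y)))
            stop("SD identifiers do not match the diseases of Y")
        sd <- SD@values
    } else sd <- as.matrix(SD)
    if (nrow(sc) != m || ncol(sc) != m || nrow(sd) != n || ncol(sd) != n)
        stop("similarity matrix dimensions do not match Y")
    if (any(sc < 0) || any(sd < 0))
        stop("similarity matrices must be nonnegative")
    if (any(rowSums(sc) == 0 & rowSums(yv) > 0) ||
        any(rowSums(sd) == 0 & colSums(yv) > 0))
        stop("a node with associations must have positive total similarity")

    cAssoc <- rowSums(yv)            # associations per circRNA
    dAssoc <- colSums(yv)            # associations per disease
    ## pmax(., 1) only rescues all-zero rows, whose numerator is 0 anyway
    scSum <- rowSums(sc)
    sdSum <- rowSums(sd)
    Wcc <- sc / ifelse(scSum > 0, scSum, 1)
    Wcc[cAssoc > 0, ] <- (1 - mu) * Wcc[cAssoc > 0, , drop = FALSE]
    Wcd <- matrix(0, m, n)
    has <- cAssoc > 0
    Wcd[has, ] <- mu * yv[has, , drop = FALSE] / cAssoc[has]

    Wdd <- sd / ifelse(sdSum > 0, sdSum, 1)
    Wdd[dAssoc > 0, ] <- (1 - mu) * Wdd[dAssoc > 0, , drop = FALSE]
    Wdc <- matrix(0, n, m)
    hasD <- dAssoc > 0
    Wdc[hasD, ] <- mu * t(yv)[hasD, , drop = FALSE] / dAssoc[hasD]

    W <- rbind(cbind(Wcc, Wcd), cbind(Wdc, Wdd))
    dimnames(W) <- NULL
    methods::new("TransitionMatrix", values = W,
                 nCirc = as.integer(m), nDisease = as.integer(n))
}

#' Initial probability vector for a seed disease
#'
#' Builds the restart distribution p0 for a query disease: a fraction
#' `lambda_` of the mass is spread uniformly over the m circRNA nodes
#' (lambda_ / m each) and the remaining (1 - lambda_) sits on the seed
#' disease; all other disease entries are 0. Total mass is 1.
#'
#' @param seedDisease index of the seed disease, 1-based in 1..n
#' @param m,n numbers of circRNA and disease nodes
#' @param lambda_ circRNA-side mass share in [0, 1]
#' @return numeric vector of length m + n (circRNAs first)
#' @export
initialProbability <- function(seedDisease, m, n, lambda_) {
    stopifnot(is.numeric(m), m >= 1, is.numeric(n), n >= 1,
              is.numeric(lambda_), lambda_ >= 0, lambda_ <= 1,
              is.numeric(seedDisease), length(seedDisease) == 1L)
    if (seedDisease < 1 || seedDisease > n)
        stop(sprintf("seed disease index %d outside 1..%d",
                     as.integer(seedDisease), as.integer(n)))
    p0 <- c(rep(lambda_ / m, m), rep(0, n))
    p0[m + seedDisease] <- 1 - lambda_
    p0
}

#' Random walk with restart
#'
#' Iterates p_{t+1} = beta * t(W) %*% p_t + (1 - beta) * p0 until the l1
#' change drops below `tol` or `maxIter` is reached. W is row-stochastic
#' (probability of moving from row-node to column-node), so the iteration
#' uses its transpose and the total probability mass is conserved when no
#' row of W is zero. The fixed point is the resolvent
#' (1 - beta) * solve(I - beta * t(W)) %*% p0.
#'
#' @param W a [TransitionMatrix-class] (or plain row-stochastic matrix)
#' @param p0 initial/restart distribution, length nrow(W), summing to 1
#' @param beta walk weight in (0, 1); the restart weight is 1 - beta
#' @param tol l1 convergence tolerance
#' @param maxIter maximum number of iterations; on non-convergence the
#'   current iterate is returned with a warning
#' @return numeric vector with attributes `"iterations"` (integer) and
#'   `"converged"` (logical)
#' @export
propagate <- function(W, p0, beta, tol = 1e-6, maxIter = 1000L) {
    wv <- if (is(W, "TransitionMatrix")) W@values else as.matrix(W)
    stopifnot(is.numeric(beta), length(beta) == 1L, beta > 0, beta < 1,
              length(p0) == nrow(wv), tol > 0, maxIter >= 1)
    if (abs(sum(p0) - 1) > 1e-9)
        stop("p0 must sum to 1")
    Wt <- t(wv)
    p <- p0
    restart <- (1 - beta) * p0
    converged <- FALSE
    iter <- 0L
    while (iter < maxIter) {
        iter <- iter + 1L
        pNew <- beta * (Wt %*% p)[, 1L] + restart
        if (sum(abs(pNew - p)) < tol) {
            p <- pNew
            converged <- TRUE
            break
        }
        p <- pNew
    }
    if (!converged)
        warning(sprintf("restart iteration did not converge in %d steps",
                        as.integer(maxIter)))
    attr(p, "iterations") <- iter
    attr(p, "converged") <- converged
    p
}

#' Random-walk score matrix P
#'
#' Runs the restart walk once per disease: disease j is the seed of the
#' initial distribution, the walk is propagated to its fixed point, and
#' column j of P collects the circRNA-block entries of the converged
#' vector. All seeds are propagated simultaneously as columns of one
#' matrix iteration, stopping when every column's l1 change is below
#' tolerance; each column converges to the same fixed point as a
#' one-seed-at-a-time run.
#'
#' @param SC,SD fused [SimilarityMatrix-class] over circRNAs / diseases
#' @param Y the [AssociationMatrix-class]
#' @param params a [cdaParams()] list (uses `mu`, `lambda_`, `beta`,
#'   `rwr_tol`, `rwr_max_iter`)
#' @return a [ScoreMatrix-class] (m x n)
#' @export
rwrScoreMatrix <- function(SC, SD, Y, params = cdaParams()) {
    W <- buildTransitionMatrix(SC, SD, Y, params$mu)
    m <- W@nCirc; n <- W@nDisease
    P0 <- vapply(seq_len(n),
                 function(j) initialProbability(j, m, n, params$lambda_),
                 numeric(m + n))
    Wt <- t(W@values)
    beta <- params$beta
    restart <- (1 - beta) * P0
    P <- P0
    for (iter in seq_len(params$rwr_max_iter)) {
        PNew <- beta * (Wt %*% P) + restart
        if (max(colSums(abs(PNew - P))) < params$rwr_tol) {
            P <- PNew
            break
        }
        P <- PNew
        if (iter == params$rwr_max_iter)
            warning("restart iteration did not converge for some seeds")
    }
    ScoreMatrix(P[seq_len(m), , drop = FALSE],
                circIds = circIds(Y), diseaseIds = diseaseIds(Y))
}
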