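## Independent oracles and small fixture builders shared across tests.
## Each oracle is a direct, unoptimized transcription of the quantity it
## checks, kept independent of the package's computation path.

## best-match average similarity between two disease index sets
bruteFunctionalSim <- function(Y, S) {
    m <- nrow(Y)
    bm <- function(Di, Dj) {
        if (length(Di) == 0L || length(Dj) == 0L) return(0)
        sum(vapply(Di, function(d) max(S[d, Dj]), numeric(1)))
    }
    out <- matrix(0, m, m)
    for (i in seq_len(m)) for (j in seq_len(m)) {
        if (i == j) { out[i, j] <- 1; next }
        Di <- which(Y[i, ] == 1)
        Dj <- which(Y[j, ] == 1)
        tot <- length(Di) + length(Dj)
        out[i, j] <- if (tot == 0) 0 else (bm(Di, Dj) + bm(Dj, Di)) / tot
    }
    out
}

## AUC by the O(P*N) double loop over (positive, negative) pairs
bruteAUC <- function(scores, testIJ, trainIJ = matrix(0L, 0, 2)) {
    lin <- function(ij) (ij[, 2] - 1L) * nrow(scores) + ij[, 1]
    iTest <- lin(testIJ)
    iTrain <- if (nrow(trainIJ)) lin(trainIJ) else integer(0)
    neg <- setdiff(seq_along(scores), c(iTest, iTrain))
    s <- as.vector(scores)
    tot <- 0
    for (p in iTest) for (q in neg)
        tot <- tot + (if (s[p] > s[q]) 1 else if (s[p] == s[q]) 0.5 else 0)
    tot / (length(iTest) * length(neg))
}

## fixed point of the restart iteration by dense linear solve
resolventFixedPoint <- function(W, p0, beta) {
    n <- nrow(W)
    as.vector((1 - beta) * solve(diag(n) - beta * t(W), p0))
}

## random small heterogeneous problem: similarity matrices with unit
## diagonal plus a random bipartite incidence
randomHetProblem <- function(m, n, density = 0.4) {
    rs <- function(k) {
        v <- matrix(runif(k * k), k, k)
        v <- (v + t(v)) / 2
        diag(v) <- 1
        v
    }
    Y <- matrix(rbinom(m * n, 1, density), m, n)
    if (sum(Y) == 0) Y[sample(m, 1), sample(n, 1)] <- 1
    cids <- paste0("c", seq_len(m))
    dids <- paste0("d", seq_len(n))
    dimnames(Y) <- list(cids, dids)
    list(Y = AssociationMatrix(Y),
         SC = SimilarityMatrix(rs(m), ids = cids),
         SD = SimilarityMatrix(rs(n), ids = dids))
}

## random symmetric positive-definite similarity with unit diagonal
randomSPDSim <- function(k) {
    A <- matrix(runif(k * k, -1, 1), k, k)
    v <- crossprod(A) + k * diag(k)
    d <- sqrt(diag(v))
    v <- v / tcrossprod(d)          # correlation-like: unit diagonal
    v <- (v + t(v)) / 2
    v[v < 0] <- 0
    diag(v) <- 1
    SimilarityMatrix(v, ids = paste0("n", seq_len(k)))
}
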