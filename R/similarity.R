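#' @include AllClasses.R
NULL

#' Gaussian association-profile similarity
#'
#' Computes the Gaussian interaction-profile kernel over the rows of a
#' binary profile matrix: S(i, j) = exp(-gamma * ||row_i - row_j||^2) with
#' the bandwidth gamma = gammaPrime / mean_k(||row_k||^2) scaled by the
#' average squared profile norm. Disease-side profile similarity is the
#' same computation on the transposed association matrix.
#'
#' When every profile is all-zero the bandwidth denominator vanishes; the
#' kernel is then uninformative and the identity matrix is returned with a
#' warning (self-similarity only). This arises under heavy masking during
#' cross-validation.
#'
#' @param profiles k x p binary matrix, one profile per row (e.g. the rows
#'   of an association matrix for circRNAs, its transpose for diseases)
#' @param gammaPrime positive bandwidth scale, default 1
#' @param ids node identifiers; default rownames of `profiles`
#' @return a [SimilarityMatrix-class] with attribute `"gamma"` holding the
#'   effective bandwidth (0 when the identity fallback triggered)
#' @examples
#' Y <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE)
#' as.matrix(profileSimilarity(Y, ids = c("a", "b")))[1, 2]  # exp(-2)
#' @export
profileSimilarity <- function(profiles, gammaPrime = 1,
                              ids = rownames(profiles)) {
    profiles <- as.matrix(profiles)
    if (anyNA(profiles) || !all(profiles == 0 | profiles == 1))
        stop("profiles must be binary (0/1)")
    if (is.null(ids))
        ids <- paste0("row", seq_len(nrow(profiles)))
    stopifnot(is.numeric(gammaPrime), length(gammaPrime) == 1L,
              gammaPrime > 0)
    sq <- rowSums(profiles^2)
    denom <- mean(sq)
    if (denom == 0) {
        warning("all profiles are zero; returning identity similarity")
        S <- diag(nrow(profiles))
        dimnames(S) <- list(ids, ids)
        out <- SimilarityMatrix(S)
        attr(out, "gamma") <- 0
        return(out)
    }
    gamma <- gammaPrime / denom
    ## squared Euclidean distances via the Gram matrix; exact for 0/1 data
    G <- tcrossprod(profiles)
    D2 <- outer(sq, sq, "+") - 2 * G
    D2[D2 < 0] <- 0
    S <- exp(-gamma * D2)
    S <- (S + t(S)) / 2
    diag(S) <- 1
    dimnames(S) <- list(ids, ids)
    out <- SimilarityMatrix(S)
    attr(out, "gamma") <- gamma
    out
}

#' circRNA functional similarity from disease semantic similarity
#'
#' Scores each circRNA pair by best-match averaging over the semantic
#' similarity of their associated disease sets D_i and D_j:
#' \deqn{S(c_i, c_j) = \frac{\sum_{d \in D_i} \max_{t \in D_j} sem(d, t)
#'   + \sum_{d \in D_j} \max_{t \in D_i} sem(d, t)}{|D_i| + |D_j|}}
#' The construction is symmetric; the diagonal is forced to 1. A circRNA
#' with no known diseases contributes an empty set: the max over an empty
#' set is 0, and a pair where both sets are empty gets off-diagonal
#' similarity 0 (no evidence).
#'
#' @param Y an [AssociationMatrix-class]
#' @param sem a [SimilarityMatrix-class] over diseases covering every
#'   disease id of `Y`
#' @return a [SimilarityMatrix-class] over the circRNAs of `Y`
#' @export
functionalSimilarity <- function(Y, sem) {
    stopifnot(is(Y, "AssociationMatrix"), is(sem, "SimilarityMatrix"))
    yv <- Y@values
    dids <- colnames(yv)
    missing <- setdiff(dids, simIds(sem))
    if (length(missing))
        stop("semantic similarity does not cover disease(s): ",
             paste(missing, collapse = ", "))
    sv <- sem@values[dids, dids, drop = FALSE]
    m <- nrow(yv)
    sizes <- rowSums(yv)
    ## bm[d, j] = max_{t in D_j} sem(d, t); 0 when D_j is empty
    bm <- matrix(0, ncol(yv), m)
    nonempty <- which(sizes > 0)
    for (j in nonempty) {
        cols <- sv[, yv[j, ] == 1, drop = FALSE]
        bm[, j] <- do.call(pmax, c(as.data.frame(cols), list(0)))
    }
    ## A[i, j] = sum_{d in D_i} bm[d, j]
    A <- yv %*% bm
    den <- outer(sizes, sizes, "+")
    S <- matrix(0, m, m)
    pos <- den > 0
    S[pos] <- (A + t(A))[pos] / den[pos]
    S <- (S + t(S)) / 2
    S[S > 1] <- 1          # guard against roundoff above 1
    diag(S) <- 1
    dimnames(S) <- list(rownames(yv), rownames(yv))
    SimilarityMatrix(S)
}

#' Fuse two similarity matrices
#'
#' Convex elementwise combination alpha * bio + (1 - alpha) * ap of a
#' biological similarity (functional or semantic) with the
#' association-profile similarity over the same nodes. Symmetry and the
#' unit diagonal are preserved.
#'
#' @param bio,ap [SimilarityMatrix-class] objects with identical ids in
#'   identical order
#' @param alpha fusion weight in [0, 1] on `bio`
#' @return a [SimilarityMatrix-class]
#' @export
fuseSimilarity <- function(bio, ap, alpha) {
    stopifnot(is(bio, "SimilarityMatrix"), is(ap, "SimilarityMatrix"),
              is.numeric(alpha), length(alpha) == 1L,
              alpha >= 0, alpha <= 1)
    if (!identical(simIds(bio), simIds(ap)))
        stop("fusion inputs have mismatched identifiers")
    SimilarityMatrix(alpha * bio@values + (1 - alpha) * ap@values,
                     ids = simIds(bio))
}

#' Build both fused similarity matrices from data
#'
#' Convenience wrapper running the full similarity stage: circRNA
#' association-profile similarity (rows of Y), disease profile similarity
#' (columns of Y), circRNA functional similarity from the disease semantic
#' matrix, and the two fusions. The semantic matrix is first aligned to
#' the diseases of `Y`; a disease absent from it is given semantic
#' similarity 0 to every other disease and 1 to itself (with a message),
#' mirroring the motivation for profile similarity: diseases without
#' ontology annotation still need a similarity row.
#'
#' @param Y an [AssociationMatrix-class]
#' @param sem disease semantic [SimilarityMatrix-class]
#' @param params a [cdaParams()] list
#' @return list with elements `SC` and `SD` ([SimilarityMatrix-class])
#' @export
buildSimilarities <- function(Y, sem, params = cdaParams()) {
    stopifnot(is(Y, "AssociationMatrix"))
    sem <- alignSemantic(sem, diseaseIds(Y))
    Scap <- profileSimilarity(Y@values, params$gamma_c_band,
                              ids = circIds(Y))
    Sdap <- profileSimilarity(t(Y@values), params$gamma_d_band,
                              ids = diseaseIds(Y))
    Sfun <- functionalSimilarity(Y, sem)
    list(SC = fuseSimilarity(Sfun, Scap, params$alpha_c),
         SD = fuseSimilarity(sem, Sdap, params$alpha_d))
}

#' Align a disease semantic similarity matrix to a disease id set
#'
#' Reorders (and if needed extends) a semantic similarity matrix to cover
#' exactly the given diseases, in the given order. Diseases missing from
#' the matrix get similarity 0 to all others and 1 to themselves; a
#' message reports them.
#'
#' @param sem a [SimilarityMatrix-class] over diseases
#' @param diseaseIds character vector of required disease ids
#' @return a [SimilarityMatrix-class] over exactly `diseaseIds`
#' @export
alignSemantic <- function(sem, diseaseIds) {
    stopifnot(is(sem, "SimilarityMatrix"), is.character(diseaseIds))
    have <- simIds(sem)
    missing <- setdiff(diseaseIds, have)
    if (length(missing) == 0L && identical(have, diseaseIds))
        return(sem)
    if (length(missing))
        message("disease(s) absent from semantic similarity, using ",
                "self-similarity only: ", paste(missing, collapse = ", "))
    n <- length(diseaseIds)
    v <- diag(n)
    dimnames(v) <- list(diseaseIds, diseaseIds)
    keep <- intersect(diseaseIds, have)
    v[keep, keep] <- sem@values[keep, keep]
    SimilarityMatrix(v)
}
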