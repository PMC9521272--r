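#' @include AllClasses.R
NULL

#' Soft-voting combination of the two score matrices
#'
#' Combines the random-walk scores P and the Laplacian RLS scores F into
#' the final association scores Ypre = P + theta * F, elementwise. The raw
#' matrices are added without normalization by default; set
#' `normalize = TRUE` to min-max scale each matrix to [0, 1] first (an
#' exploration option, off by default).
#'
#' @param P,F [ScoreMatrix-class] objects with identical identifiers
#' @param theta nonnegative soft-voting weight on `F`
#' @param normalize min-max scale each matrix before combining
#' @return a [ScoreMatrix-class]
#' @export
ensembleCombine <- function(P, F, theta, normalize = FALSE) {
    stopifnot(is(P, "ScoreMatrix"), is(F, "ScoreMatrix"),
              is.numeric(theta), length(theta) == 1L, theta >= 0)
    pv <- P@values; fv <- F@values
    if (!identical(dimnames(pv), dimnames(fv)))
        stop("P and F have mismatched identifiers")
    if (normalize) {
        mm <- function(x) {
            r <- range(x)
            if (r[1] == r[2]) x - r[1] else (x - r[1]) / (r[2] - r[1])
        }
        pv <- mm(pv); fv <- mm(fv)
    }
    ScoreMatrix(pv + theta * fv)
}

#' Rank candidate circRNAs for a disease
#'
#' Sorts the circRNAs of one disease column by descending score, breaking
#' ties lexicographically by circRNA id, and flags which candidates are
#' already known associations. Known associations are ranked too (set
#' `includeKnown = FALSE` to drop them and rank novel candidates only).
#'
#' @param Ypre a [ScoreMatrix-class]
#' @param Y the [AssociationMatrix-class] of known associations
#' @param diseaseId disease identifier to rank for
#' @param top number of rows to return, default 20
#' @param includeKnown keep known associations in the ranking
#' @return data.frame with columns rank, circRNA_id, score, known
#' @export
rankForDisease <- function(Ypre, Y, diseaseId, top = 20L,
                           includeKnown = TRUE) {
    stopifnot(is(Ypre, "ScoreMatrix"), is(Y, "AssociationMatrix"),
              is.character(diseaseId), length(diseaseId) == 1L,
              top >= 1)
    if (!identical(dimnames(Ypre@values), dimnames(Y@values)))
        stop("score and association matrices have mismatched identifiers")
    dids <- diseaseIds(Y)
    if (!diseaseId %in% dids) {
        near <- utils::head(agrep(diseaseId, dids, ignore.case = TRUE,
                                  value = TRUE, max.distance = 0.3), 5L)
        stop(sprintf("unknown disease '%s'%s", diseaseId,
                     if (length(near)) paste0("; nearest matches: ",
                                              paste(near, collapse = ", "))
                     else ""))
    }
    cids <- circIds(Y)
    df <- data.frame(circRNA_id = cids,
                     score = Ypre@values[, diseaseId],
                     known = as.integer(Y@values[, diseaseId]),
                     stringsAsFactors = FALSE, row.names = NULL)
    if (!includeKnown)
        df <- df[df$known == 0L, , drop = FALSE]
    df <- df[order(-df$score, df$circRNA_id, method = "radix"), ,
             drop = FALSE]
    df <- utils::head(df, top)
    data.frame(rank = seq_len(nrow(df)), df, row.names = NULL)
}

#' Rank-based AUC over held-out association pairs
#'
#' Computes the area under the ROC curve for a link-prediction evaluation:
#' the positives are the held-out test pairs, the negatives are every
#' remaining pair not in the training positives, and tied scores
#' contribute 1/2. Equivalent to the Mann-Whitney U statistic normalized
#' by |positives| * |negatives|, computed from midranks.
#'
#' @param scores a [ScoreMatrix-class] (or plain m x n matrix)
#' @param testPositives 2-column integer matrix of (row, col) indices of
#'   the held-out positive pairs
#' @param trainPositives 2-column integer matrix of (row, col) indices of
#'   the training positives, excluded from the evaluation population;
#'   may have zero rows
#' @return AUC in [0, 1]
#' @export
aucRanked <- function(scores, testPositives,
                      trainPositives = matrix(integer(0), 0, 2)) {
    sv <- if (is(scores, "ScoreMatrix")) scores@values else as.matrix(scores)
    testPositives <- matrix(as.integer(testPositives), ncol = 2)
    trainPositives <- matrix(as.integer(trainPositives), ncol = 2)
    lin <- function(ij) (ij[, 2] - 1L) * nrow(sv) + ij[, 1]
    iTest <- lin(testPositives)
    iTrain <- lin(trainPositives)
    if (length(intersect(iTest, iTrain)))
        stop("test and training positives overlap")
    if (length(iTest) == 0L)
        stop("no test positives: AUC undefined")
    keep <- setdiff(seq_along(sv), iTrain)
    s <- as.vector(sv)[keep]
    pos <- keep %in% iTest
    nPos <- sum(pos)
    nNeg <- length(s) - nPos
    if (nNeg == 0L)
        stop("no negatives: AUC undefined")
    r <- rank(s)                     # midranks handle ties as 1/2
    (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}
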