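#' @include AllClasses.R
NULL

#' Normalized graph Laplacian
#'
#' Computes L = D^(-1/2) (D - S) D^(-1/2) where D is the diagonal matrix
#' of row sums of the similarity matrix S. L is symmetric positive
#' semidefinite with eigenvalues in [0, 2]; its null space contains
#' D^(1/2) 1, so graph-smooth score vectors are not penalized.
#'
#' @param S a [SimilarityMatrix-class] (or plain symmetric nonnegative
#'   matrix) with strictly positive row sums
#' @return a plain k x k numeric matrix
#' @export
normalizedLaplacian <- function(S) {
    v <- if (is(S, "SimilarityMatrix")) S@values else as.matrix(S)
    if (nrow(v) != ncol(v))
        stop("similarity matrix must be square")
    if (any(v < 0))
        stop("similarity matrix must be nonnegative")
    d <- rowSums(v)
    if (any(d <= 0))
        stop("zero row sum: the normalized Laplacian is undefined")
    inv <- 1 / sqrt(d)
    L <- -v * tcrossprod(inv)      # off-diagonal part of D^-1/2 (D-S) D^-1/2
    diag(L) <- diag(L) + 1         # D^-1/2 D D^-1/2 = I
    (L + t(L)) / 2
}

#' Closed-form Laplacian regularized least squares
#'
#' Solves the graph-regularized reconstruction
#' min_F ||target - F||_F^2 + gamma * tr(t(F) L F)
#' in closed form as F = S (S + gamma * L S)^(-1) target, which for
#' invertible S equals (I + gamma L)^(-1) target. With gamma = 0 the
#' target is returned unchanged; increasing gamma smooths each column of
#' the solution over the similarity graph.
#'
#' The linear system is solved, never explicitly inverted. If the system
#' matrix is singular the minimum-norm least-squares solution
#' (pseudoinverse) is used with a warning.
#'
#' @param S a [SimilarityMatrix-class] or plain k x k matrix
#' @param L the k x k Laplacian from [normalizedLaplacian()]
#' @param target k x q numeric matrix of labels to reconstruct
#' @param gamma nonnegative regularization trade-off
#' @return a k x q numeric matrix
#' @export
lrlsSolve <- function(S, L, target, gamma) {
    sv <- if (is(S, "SimilarityMatrix")) S@values else as.matrix(S)
    target <- as.matrix(target)
    stopifnot(is.numeric(gamma), length(gamma) == 1L, gamma >= 0,
              nrow(sv) == ncol(sv), nrow(L) == nrow(sv),
              ncol(L) == nrow(sv), nrow(target) == nrow(sv))
    A <- sv + gamma * (L %*% sv)
    X <- tryCatch(solve(A, target),
                  error = function(e) {
                      warning("singular LRLS system; using least-squares ",
                              "pseudoinverse solution")
                      MASS::ginv(A) %*% target
                  })
    out <- sv %*% X
    dimnames(out) <- dimnames(target)
    out
}

#' Laplacian RLS score matrix F
#'
#' Runs the closed-form graph-regularized reconstruction in both spaces
#' and averages: F_c = S_C (S_C + gamma_c L_c S_C)^(-1) Y reconstructs the
#' association labels over the circRNA similarity graph (m x n), F_d does
#' the same for t(Y) over the disease graph (n x m), and the returned
#' score matrix is F = (F_c + t(F_d)) / 2.
#'
#' @param SC,SD fused [SimilarityMatrix-class] over circRNAs / diseases
#' @param Y the [AssociationMatrix-class]
#' @param params a [cdaParams()] list (uses `gamma_c_reg`, `gamma_d_reg`)
#' @return a [ScoreMatrix-class] (m x n)
#' @export
lrlsScoreMatrix <- function(SC, SD, Y, params = cdaParams()) {
    stopifnot(is(SC, "SimilarityMatrix"), is(SD, "SimilarityMatrix"),
              is(Y, "AssociationMatrix"))
    if (!identical(simIds(SC), circIds(Y)))
        stop("SC identifiers do not match the circRNAs of Y")
    if (!identical(simIds(SD), diseaseIds(Y)))
        stop("SD identifiers do not match the diseases of Y")
    yv <- Y@values
    Lc <- normalizedLaplacian(SC)
    Ld <- normalizedLaplacian(SD)
    Fc <- lrlsSolve(SC, Lc, yv, params$gamma_c_reg)
    Fd <- lrlsSolve(SD, Ld, t(yv), params$gamma_d_reg)
    ScoreMatrix((Fc + t(Fd)) / 2,
                circIds = circIds(Y), diseaseIds = diseaseIds(Y))
}
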