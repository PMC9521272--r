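## Central S4 containers. All matrices carry their identifiers as dimnames;
## every downstream operation indexes by identifier, never by position in an
## external file.

.checkIds <- function(ids, what) {
    if (!is.character(ids) || length(ids) == 0L)
        return(sprintf("%s must be a non-empty character vector", what))
    if (anyDuplicated(ids))
        return(sprintf("%s contains duplicated identifiers", what))
    if (anyNA(ids) || any(!nzchar(ids)))
        return(sprintf("%s contains NA or empty identifiers", what))
    NULL
}

#' Binary circRNA-disease association matrix
#'
#' An m x n incidence matrix Y over m circRNAs (rows) and n diseases
#' (columns); Y[i, j] = 1 when circRNA i is known to be associated with
#' disease j and 0 otherwise. Row and column identifiers are unique and
#' stable: every matrix computed downstream (similarities, transition
#' matrix, score matrices) is indexed by these identifiers.
#'
#' @slot values numeric matrix of 0/1 with circRNA ids as rownames and
#'   disease ids as colnames
#' @seealso [AssociationMatrix()], [readAssociationEdgelist()]
#' @exportClass AssociationMatrix
setClass("AssociationMatrix", representation(values = "matrix"))

setValidity("AssociationMatrix", function(object) {
    v <- object@values
    if (!is.numeric(v))
        return("values must be a numeric matrix")
    msg <- .checkIds(rownames(v), "circRNA ids (rownames)")
    if (!is.null(msg)) return(msg)
    msg <- .checkIds(colnames(v), "disease ids (colnames)")
    if (!is.null(msg)) return(msg)
    if (anyNA(v) || !all(v == 0 | v == 1))
        return("association values must all be exactly 0 or 1")
    TRUE
})

#' Construct an AssociationMatrix
#'
#' @param values numeric m x n matrix of 0/1
#' @param circIds,diseaseIds identifiers for rows / columns; taken from
#'   `dimnames(values)` when omitted
#' @return an [AssociationMatrix-class]
#' @export
AssociationMatrix <- function(values, circIds = rownames(values),
                              diseaseIds = colnames(values)) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    dimnames(values) <- list(as.character(circIds), as.character(diseaseIds))
    methods::new("AssociationMatrix", values = values)
}

#' Square symmetric similarity matrix
#'
#' A k x k similarity matrix over circRNAs or diseases with values in
#' [0, 1], unit diagonal, and symmetry within 1e-10. Holds the disease
#' semantic similarity, Gaussian association-profile similarities, circRNA
#' functional similarity, and the fused matrices SC and SD.
#'
#' @slot values numeric k x k matrix; ids as dimnames (identical rownames
#'   and colnames)
#' @seealso [SimilarityMatrix()], [readSimilarityMatrix()]
#' @exportClass SimilarityMatrix
setClass("SimilarityMatrix", representation(values = "matrix"))

setValidity("SimilarityMatrix", function(object) {
    v <- object@values
    if (!is.numeric(v) || nrow(v) != ncol(v))
        return("values must be a square numeric matrix")
    msg <- .checkIds(rownames(v), "ids (rownames)")
    if (!is.null(msg)) return(msg)
    if (!identical(rownames(v), colnames(v)))
        return("rownames and colnames must be identical, in the same order")
    if (anyNA(v))
        return("similarity values must not contain NA")
    if (any(v < 0) || any(v > 1))
        return("similarity values must lie in [0, 1]")
    if (max(abs(v - t(v))) > 1e-10)
        return("matrix is not symmetric within 1e-10")
    if (any(abs(diag(v) - 1) > 0))
        return("diagonal must equal 1 exactly")
    TRUE
})

#' Construct a SimilarityMatrix
#'
#' @param values square numeric matrix
#' @param ids node identifiers; taken from rownames when omitted
#' @return a [SimilarityMatrix-class]
#' @export
SimilarityMatrix <- function(values, ids = rownames(values)) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    dimnames(values) <- list(as.character(ids), as.character(ids))
    methods::new("SimilarityMatrix", values = values)
}

#' Real-valued association score matrix
#'
#' An m x n matrix of real association scores over the same circRNA /
#' disease identifiers as the [AssociationMatrix-class] it was computed
#' from. Holds the random-walk score matrix P, the Laplacian RLS score
#' matrix F, and the ensemble combination P + theta * F. All entries are
#' finite.
#'
#' @slot values numeric m x n matrix with circRNA / disease ids as dimnames
#' @exportClass ScoreMatrix
setClass("ScoreMatrix", representation(values = "matrix"))

setValidity("ScoreMatrix", function(object) {
    v <- object@values
    if (!is.numeric(v))
        return("values must be a numeric matrix")
    msg <- .checkIds(rownames(v), "circRNA ids (rownames)")
    if (!is.null(msg)) return(msg)
    msg <- .checkIds(colnames(v), "disease ids (colnames)")
    if (!is.null(msg)) return(msg)
    if (anyNA(v) || any(!is.finite(v)))
        return("score values must be finite (no NA/NaN/Inf)")
    TRUE
})

#' Construct a ScoreMatrix
#'
#' @param values numeric m x n matrix
#' @param circIds,diseaseIds identifiers for rows / columns; taken from
#'   `dimnames(values)` when omitted
#' @return a [ScoreMatrix-class]
#' @export
ScoreMatrix <- function(values, circIds = rownames(values),
                        diseaseIds = colnames(values)) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    dimnames(values) <- list(as.character(circIds), as.character(diseaseIds))
    methods::new("ScoreMatrix", values = values)
}

#' Row-stochastic transition matrix of the heterogeneous network
#'
#' The (m+n) x (m+n) transition matrix W of the random walk on the
#' heterogeneous circRNA-disease network, with circRNAs occupying rows and
#' columns 1..m and diseases m+1..m+n. W[i, j] is the probability of moving
#' from node i to node j, so every row sums to 1 -- or to 0 for a fully
#' isolated node (zero similarity to all others and no associations).
#'
#' @slot values numeric (m+n) x (m+n) matrix
#' @slot nCirc number of circRNA nodes (m)
#' @slot nDisease number of disease nodes (n)
#' @seealso [buildTransitionMatrix()]
#' @exportClass TransitionMatrix
setClass("TransitionMatrix",
         representation(values = "matrix", nCirc = "integer",
                        nDisease = "integer"))

setValidity("TransitionMatrix", function(object) {
    v <- object@values
    m <- object@nCirc
    n <- object@nDisease
    if (nrow(v) != ncol(v) || nrow(v) != m + n)
        return("values must be (nCirc + nDisease) square")
    if (anyNA(v) || any(v < 0) || any(v > 1))
        return("transition probabilities must lie in [0, 1]")
    rs <- rowSums(v)
    if (!all(abs(rs - 1) <= 1e-10 | rs == 0))
        return("every row must sum to 1 (or 0 for isolated nodes) within 1e-10")
    TRUE
})

#' Repeated k-fold cross-validation result
#'
#' Per-fold AUC values of a repeated k-fold link-prediction
#' cross-validation, their pooled mean, and the fold assignment used.
#' Folds partition the known positive pairs; a fold left with no
#' evaluable positives is recorded as NA and excluded from the mean.
#'
#' @slot foldAUCs repeats x k numeric matrix of per-fold AUCs
#' @slot meanAUC mean of `foldAUCs` (NA folds excluded)
#' @slot foldAssignment data.frame with columns circRNA_id, disease_id,
#'   rep, fold: the (repeat, fold) cell each known association was tested in
#' @slot seed the master integer seed the fold shuffles flowed from
#' @slot model which scorer was evaluated: "rwr", "lrls" or "ensemble"
#' @seealso [crossValidate()]
#' @exportClass CVResult
setClass("CVResult",
         representation(foldAUCs = "matrix", meanAUC = "numeric",
                        foldAssignment = "data.frame", seed = "integer",
                        model = "character"))

setValidity("CVResult", function(object) {
    a <- object@foldAUCs
    if (anyNA(object@meanAUC))
        return("meanAUC must not be NA")
    ok <- a[!is.na(a)]
    if (any(ok < 0 | ok > 1))
        return("fold AUCs must lie in [0, 1]")
    if (abs(object@meanAUC - mean(ok)) > 1e-12)
        return("meanAUC must equal the mean of the non-NA fold AUCs")
    need <- c("circRNA_id", "disease_id", "rep", "fold")
    if (!all(need %in% names(object@foldAssignment)))
        return("foldAssignment must have columns circRNA_id, disease_id, rep, fold")
    TRUE
})

## ---- show methods ----

setMethod("show", "AssociationMatrix", function(object) {
    v <- object@values
    cat(sprintf("AssociationMatrix: %d circRNAs x %d diseases, %d known associations\n",
                nrow(v), ncol(v), as.integer(sum(v))))
    cat(sprintf("  circRNAs: %s\n", .previewIds(rownames(v))))
    cat(sprintf("  diseases: %s\n", .previewIds(colnames(v))))
})

setMethod("show", "SimilarityMatrix", function(object) {
    v <- object@values
    off <- v[upper.tri(v)]
    cat(sprintf("SimilarityMatrix: %d x %d, off-diagonal range [%.4g, %.4g]\n",
                nrow(v), ncol(v),
                if (length(off)) min(off) else 1, if (length(off)) max(off) else 1))
    cat(sprintf("  ids: %s\n", .previewIds(rownames(v))))
})

setMethod("show", "ScoreMatrix", function(object) {
    v <- object@values
    cat(sprintf("ScoreMatrix: %d circRNAs x %d diseases, scores in [%.4g, %.4g]\n",
                nrow(v), ncol(v), min(v), max(v)))
})

setMethod("show", "TransitionMatrix", function(object) {
    zero <- sum(rowSums(object@values) == 0)
    cat(sprintf("TransitionMatrix: %d nodes (%d circRNAs + %d diseases), %d isolated\n",
                object@nCirc + object@nDisease, object@nCirc,
                object@nDisease, zero))
})

setMethod("show", "CVResult", function(object) {
    a <- object@foldAUCs
    cat(sprintf("CVResult (%s): %d repeats x %d folds, mean AUC %.4f\n",
                object@model, nrow(a), ncol(a), object@meanAUC))
    cat(sprintf("  per-repeat means: %s\n",
                paste(sprintf("%.4f", rowMeans(a, na.rm = TRUE)), collapse = ", ")))
    cat(sprintf("  seed: %d\n", object@seed))
})

.previewIds <- function(ids, k = 4L) {
    if (length(ids) <= k)
        paste(ids, collapse = ", ")
    else
        sprintf("%s, ... (%d total)", paste(ids[seq_len(k)], collapse = ", "),
                length(ids))
}
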