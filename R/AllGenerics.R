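#' @include AllClasses.R
NULL

#' Accessors for cdaNetFuse objects
#'
#' `circIds()` and `diseaseIds()` return the ordered circRNA / disease
#' identifiers of an [AssociationMatrix-class] or [ScoreMatrix-class];
#' `simIds()` returns the node identifiers of a [SimilarityMatrix-class].
#' `as.matrix()` on any of these classes returns the underlying numeric
#' matrix with identifiers as dimnames.
#'
#' @param x an object of one of the cdaNetFuse S4 classes
#' @return a character vector of identifiers
#' @name accessors
#' @aliases circIds diseaseIds simIds
#' @examples
#' Y <- AssociationMatrix(matrix(c(1, 0, 1, 1), 2, 2),
#'                        circIds = c("c1", "c2"),
#'                        diseaseIds = c("d1", "d2"))
#' circIds(Y)
#' diseaseIds(Y)
NULL

#' @rdname accessors
#' @export
setGeneric("circIds", function(x) standardGeneric("circIds"))

#' @rdname accessors
#' @export
setGeneric("diseaseIds", function(x) standardGeneric("diseaseIds"))

#' @rdname accessors
#' @export
setGeneric("simIds", function(x) standardGeneric("simIds"))

#' Cross-validation result accessors
#'
#' `foldAUCs()` returns the repeats-by-folds matrix of per-fold AUCs of a
#' [CVResult-class]; `meanAUC()` its pooled mean; `foldAssignment()` the
#' data.frame mapping every known association to its (repeat, fold) cell.
#'
#' @param x a [CVResult-class]
#' @name cv-accessors
#' @aliases foldAUCs meanAUC foldAssignment
NULL

#' @rdname cv-accessors
#' @export
setGeneric("foldAUCs", function(x) standardGeneric("foldAUCs"))

#' @rdname cv-accessors
#' @export
setGeneric("meanAUC", function(x) standardGeneric("meanAUC"))

#' @rdname cv-accessors
#' @export
setGeneric("foldAssignment", function(x) standardGeneric("foldAssignment"))
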