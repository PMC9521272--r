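#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname accessors
#' @export
setMethod("circIds", "AssociationMatrix", function(x) rownames(x@values))

#' @rdname accessors
#' @export
setMethod("circIds", "ScoreMatrix", function(x) rownames(x@values))

#' @rdname accessors
#' @export
setMethod("diseaseIds", "AssociationMatrix", function(x) colnames(x@values))

#' @rdname accessors
#' @export
setMethod("diseaseIds", "ScoreMatrix", function(x) colnames(x@values))

#' @rdname accessors
#' @export
setMethod("simIds", "SimilarityMatrix", function(x) rownames(x@values))

#' @rdname accessors
#' @param ... ignored
#' @export
setMethod("as.matrix", "AssociationMatrix", function(x, ...) x@values)

#' @rdname accessors
#' @export
setMethod("as.matrix", "SimilarityMatrix", function(x, ...) x@values)

#' @rdname accessors
#' @export
setMethod("as.matrix", "ScoreMatrix", function(x, ...) x@values)

#' @rdname accessors
#' @export
setMethod("as.matrix", "TransitionMatrix", function(x, ...) x@values)

#' @rdname accessors
#' @export
setMethod("dim", "AssociationMatrix", function(x) dim(x@values))

#' @rdname accessors
#' @export
setMethod("dim", "ScoreMatrix", function(x) dim(x@values))

#' @rdname accessors
#' @export
setMethod("dim", "SimilarityMatrix", function(x) dim(x@values))

#' @rdname cv-accessors
#' @export
setMethod("foldAUCs", "CVResult", function(x) x@foldAUCs)

#' @rdname cv-accessors
#' @export
setMethod("meanAUC", "CVResult", function(x) x@meanAUC)

#' @rdname cv-accessors
#' @export
setMethod("foldAssignment", "CVResult", function(x) x@foldAssignment)
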