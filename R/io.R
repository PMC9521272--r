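#' @include AllClasses.R
NULL

#' Read a bipartite association edge list
#'
#' Reads a delimited text file with one known circRNA-disease association
#' per line (circRNA id, disease id; extra columns ignored) and builds the
#' binary incidence matrix Y. Lines starting with `#` and blank lines are
#' skipped. Identifiers are ordered by first appearance in the file;
#' duplicated (circRNA, disease) lines collapse to a single 1 with a
#' warning, so Y stays binary.
#'
#' @param path path to the edge list file
#' @param delimiter field separator, default tab
#' @return an [AssociationMatrix-class]
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("c1\td1", "c1\td2", "c2\td2"), tf)
#' readAssociationEdgelist(tf)
#' @export
readAssociationEdgelist <- function(path, delimiter = "\t") {
    if (!file.exists(path))
        stop("edge list file not found: ", path)
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    keep <- !grepl("^\\s*(#|$)", lines)
    lineno <- which(keep)
    lines <- lines[keep]
    if (length(lines) == 0L)
        stop("edge list is empty: ", path)
    parts <- strsplit(lines, delimiter, fixed = TRUE)
    bad <- which(vapply(parts, length, 0L) < 2L)
    if (length(bad))
        stop(sprintf("malformed edge list line %d (need >= 2 fields): '%s'",
                     lineno[bad[1L]], lines[bad[1L]]))
    circ <- trimws(vapply(parts, `[[`, "", 1L))
    dis <- trimws(vapply(parts, `[[`, "", 2L))
    empty <- which(!nzchar(circ) | !nzchar(dis))
    if (length(empty))
        stop(sprintf("malformed edge list line %d (empty identifier)",
                     lineno[empty[1L]]))
    cids <- unique(circ)
    dids <- unique(dis)
    Y <- matrix(0, length(cids), length(dids), dimnames = list(cids, dids))
    if (anyDuplicated(paste0(circ, "\r", dis)))
        warning("duplicate associations in edge list collapsed to 1")
    Y[cbind(match(circ, cids), match(dis, dids))] <- 1
    AssociationMatrix(Y)
}

#' Read a labelled similarity matrix
#'
#' Reads a square numeric table (tab-separated; first row and first column
#' are node labels, which must match in order), validates it, and returns a
#' [SimilarityMatrix-class]. Tiny numeric asymmetries (at most 1e-6) are
#' repaired by averaging (v + t(v)) / 2; larger asymmetry is an error.
#' Values outside [0, 1] or a diagonal away from 1 by at most 1e-9 are
#' snapped back; larger violations are errors.
#'
#' @param path path to the TSV file
#' @return a [SimilarityMatrix-class]
#' @export
readSimilarityMatrix <- function(path) {
    if (!file.exists(path))
        stop("similarity matrix file not found: ", path)
    tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                             check.names = FALSE, comment.char = "#",
                             fileEncoding = "UTF-8")
    v <- as.matrix(tab)
    if (!is.numeric(v))
        stop("similarity matrix contains non-numeric entries")
    if (nrow(v) != ncol(v))
        stop(sprintf("similarity matrix is not square: %d rows, %d columns",
                     nrow(v), ncol(v)))
    if (!identical(rownames(v), colnames(v)))
        stop("row and column labels differ (or are ordered differently)")
    asym <- max(abs(v - t(v)))
    if (asym > 1e-6)
        stop(sprintf("matrix asymmetry %.3g exceeds tolerance 1e-6", asym))
    v <- (v + t(v)) / 2
    lo <- min(v); hi <- max(v)
    if (lo < -1e-9 || hi > 1 + 1e-9)
        stop(sprintf("similarity values outside [0, 1]: range [%.6g, %.6g]",
                     lo, hi))
    v[v < 0] <- 0
    v[v > 1] <- 1
    dmax <- max(abs(diag(v) - 1))
    if (dmax > 1e-9)
        stop(sprintf("diagonal departs from 1 by %.3g (> 1e-9)", dmax))
    diag(v) <- 1
    SimilarityMatrix(v)
}

#' Write a long-format score table
#'
#' Serializes a [ScoreMatrix-class] together with the known associations to
#' a long-format TSV with columns `circRNA_id`, `disease_id`, `score`,
#' `known` (0/1) and `rank_within_disease` (dense ranks by descending
#' score; tied scores share a rank). Rows are ordered by disease, then by
#' rank, then lexicographically by circRNA id. Scores are written with 17
#' significant digits so a round trip through [readScoreTable()]
#' reproduces them bit-exactly.
#'
#' @param scores a [ScoreMatrix-class]
#' @param known the [AssociationMatrix-class] of known associations, with
#'   identical identifiers
#' @param path output file path
#' @return invisibly, the data.frame written
#' @export
writeScoreTable <- function(scores, known, path) {
    stopifnot(is(scores, "ScoreMatrix"), is(known, "AssociationMatrix"))
    S <- scores@values
    K <- known@values
    if (!identical(dimnames(S), dimnames(K)))
        stop("scores and known associations have mismatched identifiers")
    df <- data.frame(
        circRNA_id = rep(rownames(S), times = ncol(S)),
        disease_id = rep(colnames(S), each = nrow(S)),
        score = as.vector(S),
        known = as.integer(K),
        stringsAsFactors = FALSE)
    ## dense rank within disease: ties share a rank, no gaps after ties
    df$rank_within_disease <- unlist(lapply(split(df$score, df$disease_id),
        function(s) match(s, sort(unique(s), decreasing = TRUE)))[colnames(S)],
        use.names = FALSE)
    df <- df[order(match(df$disease_id, colnames(S)),
                   df$rank_within_disease,
                   df$circRNA_id, method = "radix"), ]
    out <- df
    out$score <- sprintf("%.17g", out$score)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(df)
}

#' Read back a score table
#'
#' Inverse of [writeScoreTable()]: reconstructs the [ScoreMatrix-class] and
#' the known-association matrix from a long-format score TSV. Identifier
#' order follows first appearance in the file.
#'
#' @param path path to a TSV written by [writeScoreTable()]
#' @return a list with elements `scores` ([ScoreMatrix-class]) and
#'   `known` ([AssociationMatrix-class])
#' @export
readScoreTable <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, comment.char = "",
                            fileEncoding = "UTF-8",
                            colClasses = c(circRNA_id = "character",
                                           disease_id = "character"))
    need <- c("circRNA_id", "disease_id", "score", "known")
    if (!all(need %in% names(df)))
        stop("score table must have columns ", paste(need, collapse = ", "))
    cids <- unique(df$circRNA_id)
    dids <- unique(df$disease_id)
    S <- matrix(NA_real_, length(cids), length(dids),
                dimnames = list(cids, dids))
    K <- S
    idx <- cbind(match(df$circRNA_id, cids), match(df$disease_id, dids))
    S[idx] <- df$score
    K[idx] <- df$known
    if (anyNA(S))
        stop("score table does not cover the full circRNA x disease grid")
    list(scores = ScoreMatrix(S), known = AssociationMatrix(K))
}
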