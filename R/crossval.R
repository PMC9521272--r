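#' @include AllClasses.R
NULL

## Evaluate expr with a temporary RNG state seeded from `seed`, restoring
## whatever state the caller had. All randomness in the package flows
## through this helper; nothing touches the global stream.
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

#' Score every circRNA-disease pair
#'
#' Runs the full pipeline on a dataset: builds the fused similarity
#' matrices from the association matrix and the disease semantic
#' similarity, then scores all pairs with the requested model -- the
#' random walk with restart (`"rwr"`, matrix P), the Laplacian
#' regularized least squares (`"lrls"`, matrix F), or their soft-voting
#' ensemble (`"ensemble"`, P + theta * F, the default).
#'
#' @param Y an [AssociationMatrix-class]
#' @param sem disease semantic [SimilarityMatrix-class]
#' @param params a [cdaParams()] list
#' @param model which scorer to run
#' @param components also return the intermediate P, F, SC, SD
#' @return a [ScoreMatrix-class]; with `components = TRUE`, a list with
#'   elements `scores`, `P`, `F`, `SC`, `SD` (entries not computed for the
#'   chosen model are NULL)
#' @examples
#' sim <- generateSynthetic(syntheticConfig(m = 20, n = 8, seed = 3))
#' scores <- cdaScores(sim$associations, sim$diseaseSim)
#' rankForDisease(scores, sim$associations, diseaseIds(sim$associations)[1],
#'                top = 5)
#' @export
cdaScores <- function(Y, sem, params = cdaParams(),
                      model = c("ensemble", "rwr", "lrls"),
                      components = FALSE) {
    model <- match.arg(model)
    sims <- buildSimilarities(Y, sem, params)
    P <- if (model %in% c("rwr", "ensemble"))
        rwrScoreMatrix(sims$SC, sims$SD, Y, params) else NULL
    F <- if (model %in% c("lrls", "ensemble"))
        lrlsScoreMatrix(sims$SC, sims$SD, Y, params) else NULL
    scores <- switch(model,
                     rwr = P,
                     lrls = F,
                     ensemble = ensembleCombine(P, F, params$theta))
    if (components)
        list(scores = scores, P = P, F = F, SC = sims$SC, SD = sims$SD)
    else scores
}

## Shared CV engine. `scorers` is a named list of functions(P, F) returning
## a plain score matrix; P and F are only computed if some scorer needs
## them (declared via needP/needF). Fold assignments depend only on
## (seed, k, repeats, positives), so every scorer sees identical folds.
.cvCore <- function(Y, sem, params, k, repeats, seed, scorers,
                    needP, needF, details = FALSE) {
    stopifnot(is(Y, "AssociationMatrix"), k >= 2, repeats >= 1)
    yv <- Y@values
    posIdx <- which(yv == 1)
    nPos <- length(posIdx)
    if (nPos < k)
        stop(sprintf("need at least k = %d positives, have %d", k, nPos))
    sem <- alignSemantic(sem, diseaseIds(Y))
    aucs <- array(NA_real_, c(repeats, k, length(scorers)),
                  dimnames = list(NULL, NULL, names(scorers)))
    assign_ <- vector("list", repeats)
    det <- if (details) list() else NULL
    for (r in seq_len(repeats)) {
        perm <- .withSeed(seed + r, sample.int(nPos))
        foldOf <- integer(nPos)
        foldOf[perm] <- rep_len(seq_len(k), nPos)
        ij <- arrayInd(posIdx, dim(yv))
        assign_[[r]] <- data.frame(
            circRNA_id = rownames(yv)[ij[, 1]],
            disease_id = colnames(yv)[ij[, 2]],
            rep = r, fold = foldOf, stringsAsFactors = FALSE)
        for (f in seq_len(k)) {
            test <- posIdx[foldOf == f]
            yMask <- yv
            yMask[test] <- 0
            if (sum(yMask) == 0) {
                warning(sprintf(
                    "repeat %d fold %d: masked data has no positives left; fold skipped",
                    r, f))
                next
            }
            Ym <- AssociationMatrix(yMask)
            sims <- buildSimilarities(Ym, sem, params)
            P <- if (needP) rwrScoreMatrix(sims$SC, sims$SD, Ym, params)@values
                 else NULL
            F <- if (needF) lrlsScoreMatrix(sims$SC, sims$SD, Ym, params)@values
                 else NULL
            testIJ <- arrayInd(test, dim(yv))
            trainIJ <- arrayInd(setdiff(posIdx, test), dim(yv))
            foldScores <- lapply(scorers, function(sc) sc(P, F))
            for (s in seq_along(scorers))
                aucs[r, f, s] <- aucRanked(foldScores[[s]], testIJ, trainIJ)
            if (details)
                det[[sprintf("r%d_f%d", r, f)]] <-
                    list(rep = r, fold = f, testPairs = testIJ,
                         maskedY = yMask, P = P, F = F,
                         scores = foldScores)
        }
    }
    list(aucs = aucs, assignment = do.call(rbind, assign_), details = det)
}

#' Repeated k-fold cross-validation
#'
#' Evaluates a scorer by repeated k-fold cross-validation over the known
#' association pairs. Per repeat, the positive pairs are shuffled with a
#' repeat-specific seed (`seed + r`) and split into k folds; per fold, the
#' test positives are masked to 0 in Y, every similarity matrix
#' (profile and functional) is recomputed from the masked data so no test
#' label can leak into the model, the requested scorer is run, and the AUC
#' over the held-out positives versus all remaining unknown pairs is
#' recorded. The result is fully reproducible from `seed`.
#'
#' @param Y an [AssociationMatrix-class]
#' @param sem disease semantic [SimilarityMatrix-class]
#' @param params a [cdaParams()] list
#' @param k number of folds (>= 2), default 5
#' @param repeats number of repetitions, default 10
#' @param seed master integer seed
#' @param model scorer to evaluate
#' @param pooled if TRUE, report one AUC per repeat from the scores of all
#'   of its folds pooled together, instead of the default per-fold AUCs
#'   averaged
#' @param details if TRUE, also return per-fold internals (masked Y, test
#'   pairs, P, F, scores) for auditing
#' @return a [CVResult-class]; with `details = TRUE`, a list with elements
#'   `result` and `folds`
#' @examples
#' sim <- generateSynthetic(syntheticConfig(m = 20, n = 8, seed = 3))
#' cv <- crossValidate(sim$associations, sim$diseaseSim, k = 3,
#'                     repeats = 1, seed = 7, model = "lrls")
#' meanAUC(cv)
#' @export
crossValidate <- function(Y, sem, params = cdaParams(), k = 5L,
                          repeats = 10L, seed = 1L,
                          model = c("ensemble", "rwr", "lrls"),
                          pooled = FALSE, details = FALSE) {
    model <- match.arg(model)
    theta <- params$theta
    scorer <- switch(model,
                     rwr = function(P, F) P,
                     lrls = function(P, F) F,
                     ensemble = function(P, F) P + theta * F)
    core <- .cvCore(Y, sem, params, k, repeats, seed,
                    scorers = stats::setNames(list(scorer), model),
                    needP = model %in% c("rwr", "ensemble"),
                    needF = model %in% c("lrls", "ensemble"),
                    details = details || pooled)
    foldA <- core$aucs[, , 1, drop = FALSE]
    dim(foldA) <- c(repeats, k)
    if (pooled) {
        pooledA <- matrix(NA_real_, repeats, 1L)
        for (r in seq_len(repeats)) {
            sc <- NULL; lab <- NULL
            for (f in seq_len(k)) {
                d <- core$details[[sprintf("r%d_f%d", r, f)]]
                if (is.null(d)) next
                m <- d$scores[[1]]
                train <- which(d$maskedY == 1)
                keep <- setdiff(seq_along(m), train)
                sc <- c(sc, as.vector(m)[keep])
                lab <- c(lab, keep %in%
                             ((d$testPairs[, 2] - 1L) * nrow(m) +
                              d$testPairs[, 1]))
            }
            rk <- rank(sc)
            np <- sum(lab)
            pooledA[r, 1] <- (sum(rk[lab]) - np * (np + 1) / 2) /
                (np * (length(lab) - np))
        }
        foldA <- pooledA
    }
    res <- methods::new("CVResult", foldAUCs = foldA,
                        meanAUC = mean(foldA[!is.na(foldA)]),
                        foldAssignment = core$assignment,
                        seed = as.integer(seed), model = model)
    if (details) list(result = res, folds = core$details) else res
}

#' Sweep the soft-voting weight theta
#'
#' Runs one cross-validation per candidate theta with identical fold
#' assignments (all flow from the same master seed), so the resulting
#' mean-AUC curve is comparable across theta values. P and F are computed
#' once per fold and recombined per theta.
#'
#' @param Y an [AssociationMatrix-class]
#' @param sem disease semantic [SimilarityMatrix-class]
#' @param params a [cdaParams()] list (its `theta` is ignored in favour of
#'   `thetas`)
#' @param thetas numeric vector of candidate weights, default
#'   `seq(0.1, 0.9, by = 0.1)`
#' @param k,repeats,seed as in [crossValidate()]
#' @return data.frame with columns theta, mean_auc
#' @export
thetaSweep <- function(Y, sem, params = cdaParams(),
                       thetas = seq(0.1, 0.9, by = 0.1), k = 5L,
                       repeats = 10L, seed = 1L) {
    stopifnot(is.numeric(thetas), length(thetas) >= 1, all(thetas >= 0))
    scorers <- lapply(thetas, function(th) {
        force(th)
        function(P, F) P + th * F
    })
    names(scorers) <- sprintf("theta=%g", thetas)
    core <- .cvCore(Y, sem, params, k, repeats, seed, scorers,
                    needP = TRUE, needF = TRUE)
    data.frame(theta = thetas,
               mean_auc = apply(core$aucs, 3, mean, na.rm = TRUE),
               row.names = NULL)
}
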