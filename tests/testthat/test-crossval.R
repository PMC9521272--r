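smallSim <- function(seed = 3)
    generateSynthetic(syntheticConfig(m = 24, n = 8, nDiseaseClusters = 2,
                                      nCircClusters = 2, seed = seed))

test_that("cross-validation is bitwise reproducible from the master seed", {
    sim <- smallSim()
    run <- function() suppressWarnings(
        crossValidate(sim$associations, sim$diseaseSim, k = 3, repeats = 2,
                      seed = 11, model = "ensemble"))
    a <- run(); b <- run()
    expect_identical(foldAUCs(a), foldAUCs(b))
    expect_identical(foldAssignment(a), foldAssignment(b))
    expect_identical(meanAUC(a), meanAUC(b))
})

test_that("every known association is tested in exactly one fold per repeat", {
    sim <- smallSim()
    cv <- suppressWarnings(
        crossValidate(sim$associations, sim$diseaseSim, k = 4, repeats = 3,
                      seed = 5, model = "lrls"))
    fa <- foldAssignment(cv)
    yv <- as.matrix(sim$associations)
    nPos <- sum(yv)
    for (r in 1:3) {
        sub <- fa[fa$rep == r, ]
        expect_identical(nrow(sub), as.integer(nPos))
        expect_identical(anyDuplicated(paste(sub$circRNA_id,
                                             sub$disease_id)), 0L)
        expect_true(all(yv[cbind(sub$circRNA_id, sub$disease_id)] == 1))
        expect_true(all(sub$fold %in% 1:4))
    }
})

test_that("no fold consumes a test positive: fold internals rebuild from masked data", {
    ## leakage guard: recompute one fold end-to-end from its masked Y and
    ## require bitwise identity with what crossValidate used internally
    sim <- smallSim()
    p <- cdaParams()
    out <- suppressWarnings(
        crossValidate(sim$associations, sim$diseaseSim, p, k = 3,
                      repeats = 1, seed = 7, model = "ensemble",
                      details = TRUE))
    yv <- as.matrix(sim$associations)
    for (d in out$folds) {
        ## the masked matrix really has 0 at every test position
        expect_true(all(d$maskedY[d$testPairs] == 0))
        expect_identical(d$maskedY[-((d$testPairs[, 2] - 1) * nrow(yv) +
                                     d$testPairs[, 1])],
                         yv[-((d$testPairs[, 2] - 1) * nrow(yv) +
                              d$testPairs[, 1])])
        ## independent recomputation of the fold pipeline
        Ym <- AssociationMatrix(d$maskedY)
        sims <- buildSimilarities(Ym, sim$diseaseSim, p)
        P <- as.matrix(rwrScoreMatrix(sims$SC, sims$SD, Ym, p))
        F <- suppressWarnings(
            as.matrix(lrlsScoreMatrix(sims$SC, sims$SD, Ym, p)))
        expect_identical(d$P, P)
        expect_identical(d$F, F)
        expect_identical(d$scores[["ensemble"]], P + p$theta * F)
    }
})

test_that("sentinel scores prove the ensemble is combined inside each fold", {
    ## if the ensemble were combined from full-data P and F, its fold AUCs
    ## could not equal the combination of the fold-internal matrices
    sim <- smallSim()
    p <- cdaParams()
    out <- suppressWarnings(
        crossValidate(sim$associations, sim$diseaseSim, p, k = 3,
                      repeats = 1, seed = 7, model = "ensemble",
                      details = TRUE))
    full <- suppressWarnings(
        cdaScores(sim$associations, sim$diseaseSim, p, components = TRUE))
    cv <- suppressWarnings(
        crossValidate(sim$associations, sim$diseaseSim, p, k = 3,
                      repeats = 1, seed = 7, model = "ensemble"))
    for (f in seq_along(out$folds)) {
        d <- out$folds[[f]]
        trainIJ <- which(d$maskedY == 1, arr.ind = TRUE)
        inFold <- aucRanked(d$scores[["ensemble"]], d$testPairs, trainIJ)
        expect_identical(foldAUCs(cv)[1, f], inFold)
        ## the full-data matrices differ from the fold-internal ones
        expect_false(isTRUE(all.equal(as.matrix(full$P), d$P)))
    }
})

test_that("pooled AUC variant reports one value per repeat", {
    sim <- smallSim()
    cv <- suppressWarnings(
        crossValidate(sim$associations, sim$diseaseSim, k = 3, repeats = 2,
                      seed = 9, model = "rwr", pooled = TRUE))
    expect_identical(dim(foldAUCs(cv)), c(2L, 1L))
    expect_true(all(foldAUCs(cv) >= 0 & foldAUCs(cv) <= 1))
})

test_that("theta sweep shares folds across theta and brackets the models", {
    sim <- smallSim()
    sw <- suppressWarnings(
        thetaSweep(sim$associations, sim$diseaseSim,
                   thetas = seq(0.1, 0.9, by = 0.1), k = 3, repeats = 1,
                   seed = 13))
    expect_identical(nrow(sw), 9L)
    expect_identical(sw$theta, seq(0.1, 0.9, by = 0.1))
    sw2 <- suppressWarnings(
        thetaSweep(sim$associations, sim$diseaseSim,
                   thetas = seq(0.1, 0.9, by = 0.1), k = 3, repeats = 1,
                   seed = 13))
    expect_identical(sw, sw2)

    ## a single theta reduces to crossValidate with that theta
    p3 <- cdaParams(theta = 0.3)
    one <- suppressWarnings(
        thetaSweep(sim$associations, sim$diseaseSim, p3, thetas = 0.3,
                   k = 3, repeats = 1, seed = 13))
    cv <- suppressWarnings(
        crossValidate(sim$associations, sim$diseaseSim, p3, k = 3,
                      repeats = 1, seed = 13, model = "ensemble"))
    expect_equal(one$mean_auc, meanAUC(cv), tolerance = 1e-15)
})

test_that("theta boundaries recover the single-model rankings", {
    sim <- smallSim()
    ## theta -> 0: ensemble fold AUCs converge to the RWR-only AUCs
    tiny <- suppressWarnings(
        thetaSweep(sim$associations, sim$diseaseSim, thetas = 1e-12,
                   k = 3, repeats = 1, seed = 21))
    rwr <- suppressWarnings(
        crossValidate(sim$associations, sim$diseaseSim, k = 3, repeats = 1,
                      seed = 21, model = "rwr"))
    expect_equal(tiny$mean_auc, meanAUC(rwr), tolerance = 1e-6)
    ## large theta: ranking converges to the LRLS-only ranking
    big <- suppressWarnings(
        thetaSweep(sim$associations, sim$diseaseSim, thetas = 1e12,
                   k = 3, repeats = 1, seed = 21))
    lrls <- suppressWarnings(
        crossValidate(sim$associations, sim$diseaseSim, k = 3, repeats = 1,
                      seed = 21, model = "lrls"))
    expect_equal(big$mean_auc, meanAUC(lrls), tolerance = 1e-6)
})

test_that("cross-validation refuses fewer positives than folds", {
    cids <- paste0("c", 1:3); dids <- paste0("d", 1:2)
    Y <- AssociationMatrix(matrix(c(1, 0, 0, 0, 1, 0), 3, 2,
                                  dimnames = list(cids, dids)))
    sem <- SimilarityMatrix(diag(2), ids = dids)
    expect_error(crossValidate(Y, sem, k = 5, repeats = 1, seed = 1),
                 "at least k")
})
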