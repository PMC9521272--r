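#' @include AllClasses.R
NULL

#' Configuration for the planted-cluster generator
#'
#' Describes a synthetic circRNA-disease benchmark with planted block
#' structure: circRNAs and diseases are assigned round-robin to clusters,
#' matched cluster pairs are densely associated (probability `p_in`),
#' everything else sparsely (`p_out`), and the disease semantic similarity
#' has block value `sem_in` within disease clusters and `sem_out` across,
#' plus symmetric uniform jitter of half-width `sem_noise`.
#'
#' The default is the "small" preset: 60 circRNAs, 20 diseases, 4
#' clusters, p_in = 0.5, p_out = 0.02, sem_in = 0.8, sem_out = 0.1,
#' sem_noise = 0.05 -- strong but not noiseless signal in both the
#' association-profile and the semantic channel, so the similarity fusion
#' is genuinely exercised, and small enough that the full pipeline runs in
#' seconds. `preset = "extract-scale"` instead matches the scale of a
#' curated human circRNA-disease extract (585 circRNAs, 88 diseases,
#' association density 650 / (585 * 88) ~ 0.0126) for scale testing; its
#' planted structure remains synthetic.
#'
#' @param m,n number of circRNAs / diseases
#' @param nDiseaseClusters,nCircClusters number of planted clusters
#' @param pIn,pOut association probability within matched clusters /
#'   elsewhere; must satisfy pIn > pOut
#' @param semIn,semOut semantic similarity within / across disease
#'   clusters; semIn > semOut
#' @param semNoise half-width of the symmetric uniform jitter added to the
#'   semantic matrix; semIn + semNoise <= 1 and semOut - semNoise >= 0
#' @param holdout fraction of within-cluster associations held out of Y as
#'   recoverable ground truth, default 0.1
#' @param seed integer seed; the whole fixture is reproducible from it
#' @param preset "small" (the defaults) or "extract-scale"
#' @return a validated list of class `syntheticConfig`
#' @export
syntheticConfig <- function(m = 60L, n = 20L, nDiseaseClusters = 4L,
                            nCircClusters = 4L, pIn = 0.5, pOut = 0.02,
                            semIn = 0.8, semOut = 0.1, semNoise = 0.05,
                            holdout = 0.1, seed = 17L,
                            preset = c("custom", "small", "extract-scale")) {
    preset <- match.arg(preset)
    if (preset == "extract-scale") {
        m <- 585L; n <- 88L
        ## 650 expected associations at the extract's density
        target <- 650
        nDiseaseClusters <- nCircClusters <- 8L
        inMass <- (m / 8) * (n / 8) * 8       # cells in matched blocks
        pOut <- 0.002
        pIn <- (target - (m * n - inMass) * pOut) / inMass
    }
    cfg <- list(m = as.integer(m), n = as.integer(n),
                nDiseaseClusters = as.integer(nDiseaseClusters),
                nCircClusters = as.integer(nCircClusters),
                pIn = pIn, pOut = pOut, semIn = semIn, semOut = semOut,
                semNoise = semNoise, holdout = holdout,
                seed = as.integer(seed), preset = preset)
    with(cfg, {
        stopifnot(m >= 1, n >= 1, nDiseaseClusters >= 1, nCircClusters >= 1,
                  holdout >= 0, holdout <= 1)
        if (!(pIn > pOut))
            stop("pIn must exceed pOut")
        if (!(semIn > semOut))
            stop("semIn must exceed semOut")
        if (pIn < 0 || pIn > 1 || pOut < 0)
            stop("association probabilities must lie in [0, 1]")
        if (semIn + semNoise > 1)
            stop("semIn + semNoise must not exceed 1")
        if (semOut - semNoise < 0)
            stop("semOut - semNoise must be nonnegative")
    })
    class(cfg) <- "syntheticConfig"
    cfg
}

#' Generate a planted-cluster benchmark
#'
#' Draws a synthetic circRNA-disease dataset from a [syntheticConfig()]:
#' nodes are assigned to clusters round-robin; circRNA cluster g is
#' matched to disease cluster g (recycled when counts differ); each
#' association is an independent Bernoulli draw with probability `pIn` in
#' matched cluster blocks and `pOut` elsewhere. The disease semantic
#' similarity takes value `semIn` within disease clusters and `semOut`
#' across, plus symmetric uniform jitter, with unit diagonal. A fraction
#' `holdout` of the drawn within-cluster associations is removed from the
#' emitted Y and returned as ground truth -- the recoverable missing
#' links a predictor should rank highly.
#'
#' The generator is fully reproducible from `config$seed` and does not
#' perturb the caller's RNG state.
#'
#' @param config a [syntheticConfig()]
#' @return list with elements `associations` ([AssociationMatrix-class]),
#'   `diseaseSim` ([SimilarityMatrix-class]), `groundTruth` (data.frame
#'   circRNA_id, disease_id of held-out true pairs), and the cluster
#'   assignments `circClusters`, `diseaseClusters`
#' @examples
#' sim <- generateSynthetic(syntheticConfig(m = 12, n = 6, seed = 1))
#' sim$associations
#' @export
generateSynthetic <- function(config = syntheticConfig()) {
    stopifnot(inherits(config, "syntheticConfig"))
    .withSeed(config$seed, {
        m <- config$m; n <- config$n
        cids <- sprintf("circ%03d", seq_len(m))
        dids <- sprintf("disease%02d", seq_len(n))
        circCl <- rep_len(seq_len(config$nCircClusters), m)
        disCl <- rep_len(seq_len(config$nDiseaseClusters), n)
        ## matched blocks: circRNA cluster g <-> disease cluster g,
        ## recycled modulo the disease cluster count when counts differ
        matchedCl <- ((circCl - 1L) %% config$nDiseaseClusters) + 1L
        matched <- outer(matchedCl, disCl, "==")
        prob <- ifelse(matched, config$pIn, config$pOut)
        Y <- matrix(stats::rbinom(m * n, 1L, prob), m, n,
                    dimnames = list(cids, dids))

        ## hold out a fraction of the within-cluster (matched-block) hits
        inHits <- which(Y == 1 & matched)
        nHold <- floor(config$holdout * length(inHits))
        held <- if (nHold > 0) sort(sample(inHits, nHold)) else integer(0)
        Y[held] <- 0
        ij <- arrayInd(held, dim(Y))
        gt <- data.frame(circRNA_id = cids[ij[, 1]],
                         disease_id = dids[ij[, 2]],
                         stringsAsFactors = FALSE)

        ## block semantic similarity with symmetric jitter
        sem <- ifelse(outer(disCl, disCl, "=="), config$semIn, config$semOut)
        if (config$semNoise > 0) {
            jit <- matrix(stats::runif(n * n, -config$semNoise,
                                       config$semNoise), n, n)
            jit <- (jit + t(jit)) / 2
            sem <- sem + jit
        }
        sem[sem < 0] <- 0
        sem[sem > 1] <- 1
        diag(sem) <- 1
        dimnames(sem) <- list(dids, dids)

        list(associations = AssociationMatrix(Y),
             diseaseSim = SimilarityMatrix(sem),
             groundTruth = gt,
             circClusters = stats::setNames(circCl, cids),
             diseaseClusters = stats::setNames(disCl, dids))
    })
}

#' Write a synthetic fixture to disk
#'
#' Serializes a generated benchmark to three TSV files in `dir`:
#' `associations.tsv` (edge list), `disease_sem.tsv` (labelled semantic
#' similarity matrix) and `ground_truth.tsv` (held-out true pairs). The
#' files round-trip through [readAssociationEdgelist()] and
#' [readSimilarityMatrix()].
#'
#' @param sim output of [generateSynthetic()]
#' @param dir output directory, created if missing
#' @return invisibly, the paths written
#' @export
writeSyntheticFixture <- function(sim, dir) {
    if (!dir.exists(dir))
        dir.create(dir, recursive = TRUE)
    yv <- sim$associations@values
    ij <- which(yv == 1, arr.ind = TRUE)
    ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
    edge <- data.frame(circRNA_id = rownames(yv)[ij[, 1]],
                       disease_id = colnames(yv)[ij[, 2]])
    pA <- file.path(dir, "associations.tsv")
    utils::write.table(edge, pA, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    sv <- sim$diseaseSim@values
    pS <- file.path(dir, "disease_sem.tsv")
    df <- data.frame(id = rownames(sv),
                     formatC(sv, format = "g", digits = 17),
                     check.names = FALSE)
    names(df) <- c("id", colnames(sv))
    utils::write.table(df, pS, sep = "\t", quote = FALSE, row.names = FALSE)
    pG <- file.path(dir, "ground_truth.tsv")
    utils::write.table(sim$groundTruth, pG, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(c(associations = pA, diseaseSim = pS, groundTruth = pG))
}
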