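test_that("profile similarity matches hand-evaluated kernel values", {
    ## identical rows are maximally similar
    S <- as.matrix(profileSimilarity(rbind(c(1, 0), c(1, 0)),
                                     ids = c("a", "b")))
    expect_equal(S["a", "b"], 1)

    ## rows (1,0), (0,1): mean squared norm 1, gamma 1, ||delta||^2 = 2
    S <- as.matrix(profileSimilarity(rbind(c(1, 0), c(0, 1)),
                                     ids = c("a", "b")))
    expect_equal(S["a", "b"], exp(-2), tolerance = 1e-12)

    ## rows (1,1), (1,0): mean squared norm 1.5, gamma 2/3, ||delta||^2 = 1
    S <- as.matrix(profileSimilarity(rbind(c(1, 1), c(1, 0)),
                                     ids = c("a", "b")))
    expect_equal(S["a", "b"], exp(-2 / 3), tolerance = 1e-12)

    expect_error(profileSimilarity(rbind(c(0.5, 0), c(0, 1))), "binary")
})

test_that("profile similarity values lie in (0,1]; 1 iff identical rows", {
    set.seed(3)
    for (rep in 1:10) {
        prof <- matrix(rbinom(7 * 5, 1, 0.5), 7, 5)
        if (all(prof == 0)) prof[1, 1] <- 1
        S <- as.matrix(profileSimilarity(prof, ids = paste0("r", 1:7)))
        expect_true(all(S > 0 & S <= 1))
        same <- as.matrix(dist(prof))^2 < 1e-12
        expect_identical(unname(S == 1), unname(same))
    }
})

test_that("all-zero profiles fall back to the identity with a warning", {
    expect_warning(S <- profileSimilarity(matrix(0, 3, 4),
                                          ids = paste0("r", 1:3)),
                   "identity")
    expect_equal(unname(as.matrix(S)), diag(3))
    expect_equal(attr(S, "gamma"), 0)
})

test_that("functional similarity matches the worked 3-disease example", {
    Y <- AssociationMatrix(rbind(ci = c(1, 0, 0), cj = c(0, 1, 1)),
                           circIds = c("ci", "cj"),
                           diseaseIds = c("d1", "d2", "d3"))
    sem <- matrix(c(1, 0.8, 0.2,
                    0.8, 1, 0.5,
                    0.2, 0.5, 1), 3, 3,
                  dimnames = list(c("d1", "d2", "d3"), c("d1", "d2", "d3")))
    S <- as.matrix(functionalSimilarity(Y, SimilarityMatrix(sem)))
    ## (max(0.8, 0.2) + 0.8 + 0.2) / (1 + 2) = 0.6
    expect_equal(S["ci", "cj"], 0.6, tolerance = 1e-12)
})

test_that("functional similarity: identical sets give 1, disjoint zero-sim sets give 0", {
    dids <- paste0("d", 1:4)
    sem <- diag(4); dimnames(sem) <- list(dids, dids)
    Y <- AssociationMatrix(rbind(a = c(1, 1, 0, 0),
                                 b = c(1, 1, 0, 0),
                                 c = c(0, 0, 1, 1)),
                           circIds = c("a", "b", "c"), diseaseIds = dids)
    S <- as.matrix(functionalSimilarity(Y, SimilarityMatrix(sem)))
    expect_equal(S["a", "b"], 1)          # same nonempty sets, unit diagonal
    expect_equal(S["a", "c"], 0)          # disjoint sets, zero cross-similarity
})

test_that("functional similarity agrees with the brute-force oracle", {
    set.seed(19)
    for (rep in 1:25) {
        m <- 6; n <- 5
        yv <- matrix(rbinom(m * n, 1, 0.4), m, n,
                     dimnames = list(paste0("c", 1:m), paste0("d", 1:n)))
        sv <- matrix(runif(n * n), n, n)
        sv <- (sv + t(sv)) / 2
        diag(sv) <- 1
        dimnames(sv) <- list(colnames(yv), colnames(yv))
        got <- as.matrix(functionalSimilarity(AssociationMatrix(yv),
                                              SimilarityMatrix(sv)))
        expect_equal(unname(got), bruteFunctionalSim(yv, sv),
                     tolerance = 1e-12)
    }
})

test_that("functional similarity with identity semantics reduces to two-sided overlap", {
    set.seed(23)
    for (rep in 1:10) {
        yv <- matrix(rbinom(30, 1, 0.5), 6, 5,
                     dimnames = list(paste0("c", 1:6), paste0("d", 1:5)))
        sem <- diag(5); dimnames(sem) <- list(colnames(yv), colnames(yv))
        got <- as.matrix(functionalSimilarity(AssociationMatrix(yv),
                                              SimilarityMatrix(sem)))
        for (i in 1:6) for (j in 1:6) {
            if (i == j) next
            Di <- which(yv[i, ] == 1); Dj <- which(yv[j, ] == 1)
            tot <- length(Di) + length(Dj)
            expct <- if (tot == 0) 0 else 2 * length(intersect(Di, Dj)) / tot
            expect_equal(got[i, j], expct, tolerance = 1e-12)
        }
    }
})

test_that("similarity fusion: boundaries exact, interior convex, monotone", {
    ids <- c("a", "b", "c")
    set.seed(2)
    mk <- function() {
        v <- matrix(runif(9, 0, 0.9), 3, 3)
        v <- (v + t(v)) / 2; diag(v) <- 1
        SimilarityMatrix(v, ids = ids)
    }
    bio <- mk(); ap <- mk()
    expect_identical(as.matrix(fuseSimilarity(bio, ap, 1)), as.matrix(bio))
    expect_identical(as.matrix(fuseSimilarity(bio, ap, 0)), as.matrix(ap))
    f <- as.matrix(fuseSimilarity(bio, ap, 0.5))
    expect_equal(f, 0.5 * as.matrix(bio) + 0.5 * as.matrix(ap))

    ## monotone: raising one off-diagonal entry never lowers the fusion
    b2 <- as.matrix(bio)
    b2["a", "b"] <- b2["b", "a"] <- min(1, b2["a", "b"] + 0.05)
    f2 <- as.matrix(fuseSimilarity(SimilarityMatrix(b2, ids = ids), ap, 0.5))
    expect_true(all(f2 - f >= -1e-15))

    apBad <- SimilarityMatrix(diag(3), ids = c("x", "y", "z"))
    expect_error(fuseSimilarity(bio, apBad, 0.5), "mismatch")
})

test_that("semantic alignment fills missing diseases with self-similarity", {
    sem <- SimilarityMatrix(matrix(c(1, 0.4, 0.4, 1), 2, 2,
                                   dimnames = list(c("d1", "d2"),
                                                   c("d1", "d2"))))
    expect_message(al <- alignSemantic(sem, c("d2", "d1", "d3")), "d3")
    v <- as.matrix(al)
    expect_identical(rownames(v), c("d2", "d1", "d3"))
    expect_equal(v["d1", "d2"], 0.4)
    expect_equal(v["d3", "d3"], 1)
    expect_equal(v["d3", "d1"], 0)
})
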