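test_that("count score is the plain dosage sum with the 2M ceiling", {
    co <- makeCohort(matrix(c(2L, 1L, 0L, 1L, 2L), ncol = 1),
                     status = 1L, sex = 0L, age = 40)
    expect_identical(computeCGRS(co)$score, 6)

    zeros <- makeCohort(matrix(0L, nrow = 5, ncol = 3),
                        status = c(1L, 0L, 0L))
    expect_identical(computeCGRS(zeros)$score, rep(0, 3))

    maxed <- makeCohort(matrix(2L, nrow = 5, ncol = 2), status = c(1L, 0L))
    expect_identical(computeCGRS(maxed)$score, rep(10, 2))

    withNA <- makeCohort(matrix(c(1L, NA), ncol = 1), status = 1L,
                         sex = 0L, age = 40)
    expect_error(computeCGRS(withNA), "missing")
})

test_that("weighted score is the dosage-weight dot product", {
    w <- log(defaultTrueORs)
    co <- makeCohort(matrix(c(1L, 1L, 1L, 1L, 1L,
                              2L, 0L, 0L, 0L, 0L), ncol = 2),
                     status = c(1L, 0L))
    s <- computeWGRS(co, w)$score
    expect_equal(s[1], sum(w), tolerance = 1e-12)
    expect_equal(s[1], 3.156, tolerance = 1e-3)
    expect_equal(s[2], 2 * log(7.42), tolerance = 1e-12)
    expect_equal(s[2], 4.009, tolerance = 1e-3)

    expect_error(computeWGRS(co, w[1:3]), "weights")
    expect_error(computeWGRS(co, c(w[1:4], Inf)), "finite")
})

test_that("unit weights reduce the weighted score to the count score", {
    set.seed(21)
    co <- simulateCohort(simConfig(nCases = 40, nControls = 40,
                                   missingRate = 0))
    expect_identical(computeWGRS(co, rep(1, 5))$score,
                     as.numeric(computeCGRS(co)$score))
})

test_that("weighted score is linear in the weights and rank-stable", {
    set.seed(22)
    co <- simulateCohort(simConfig(nCases = 30, nControls = 30,
                                   missingRate = 0))
    w <- log(defaultTrueORs)
    s1 <- computeWGRS(co, w)$score
    s3 <- computeWGRS(co, 3 * w)$score
    expect_equal(s3, 3 * s1, tolerance = 1e-12)

    # Mann-Whitney p is invariant to positive rescaling of the score
    st <- caseStatus(co)
    p1 <- mannWhitneyTest(s1[st == 1], s1[st == 0])$p_value
    p3 <- mannWhitneyTest(s3[st == 1], s3[st == 0])$p_value
    expect_identical(p1, p3)
})

test_that("weights come from in-sample ORs on natural or base-10 log scale", {
    set.seed(23)
    co <- simulateCohort(simConfig(nCases = 100, nControls = 100,
                                   missingRate = 0))
    w <- grsWeights(co, method = "crude", correct = TRUE)
    ors <- vapply(rownames(co), function(m)
        oddsRatioWald(buildAlleleTable(co, m), correct = TRUE)$or,
        numeric(1))
    expect_equal(as.numeric(w), unname(log(ors)), tolerance = 1e-12)
    expect_identical(attr(w, "source"), "crude")

    w10 <- grsWeights(co, method = "crude", correct = TRUE, logBase = 10)
    expect_equal(as.numeric(w10), as.numeric(w) / log(10),
                 tolerance = 1e-12)

    wa <- grsWeights(co, method = "adjusted")
    expect_equal(as.numeric(wa), unname(log(logisticFit(co)$or)),
                 tolerance = 1e-12)

    wx <- grsWeights(or = c(a = 2, b = 4), logBase = 2)
    expect_equal(as.numeric(wx), c(1, 2))
    expect_identical(attr(wx, "source"), "external")
})

test_that("descriptive statistics follow the Tukey-hinge convention", {
    d <- describeScores(c(1, 2, 3, 4))
    expect_equal(d$mean, 2.5)
    expect_equal(d$median, 2.5)
    expect_equal(d$sd, 1.2910, tolerance = 1e-4)
    expect_equal(d$iqr, 2.0)

    const <- describeScores(rep(3.3, 10))
    expect_equal(const$sd, 0)
    expect_equal(const$iqr, 0)

    single <- describeScores(5)
    expect_equal(single$n, 1)
    expect_equal(single$sd, 0)
    expect_equal(single$mean, 5)

    expect_error(describeScores(numeric(0)), "empty")

    # alternative quantile rule is honoured
    d7 <- describeScores(c(1, 2, 3, 4), quantileType = 7)
    expect_equal(d7$iqr, diff(quantile(1:4, c(0.25, 0.75), names = FALSE)))
})

test_that("score vectors carry status for group-wise summaries", {
    co <- makeCohort(matrix(c(2L, 0L, 1L, 1L), nrow = 1),
                     status = c(1L, 1L, 0L, 0L))
    v <- computeCGRS(co)
    expect_equal(describeScores(v, "case")$mean, 1)
    expect_equal(describeScores(v, "control")$mean, 1)
    expect_identical(S4Vectors::metadata(v)$kind, "cGRS")
})

test_that("Mann-Whitney test: frozen small cases and enumeration oracle", {
    r <- mannWhitneyTest(c(3, 4), c(1, 2))
    expect_equal(r$u, 4)
    expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)
    expect_identical(r$method, "exact")

    tied <- mannWhitneyTest(c(1, 2), c(1, 2))
    expect_equal(tied$u, 2)
    expect_equal(tied$p_value, 1.0)
    expect_identical(tied$method, "normal-approximation")

    set.seed(31)
    for (i in 1:20) {
        n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
        v <- sample(1:50, n1 + n2)           # tie-free
        x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
        r <- mannWhitneyTest(x, y)
        expect_identical(r$method, "exact")
        expect_equal(r$p_value, mwOracle(x, y), tolerance = 1e-9)
        # symmetry in the two groups
        expect_equal(mannWhitneyTest(y, x)$p_value, r$p_value,
                     tolerance = 1e-12)
        expect_true(r$u >= 0 && r$u <= n1 * n2)
    }
})

test_that("tie-corrected normal approximation is sane on tied data", {
    set.seed(32)
    x <- sample(0:3, 40, TRUE)
    y <- sample(0:3, 40, TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
    r <- mannWhitneyTest(x, y)
    expect_identical(r$method, "normal-approximation")
    expect_true(r$p_value > 0 && r$p_value <= 1)
    # agrees with the tie-corrected z computed from first principles
    u <- mwUStat(x, y)
    n1 <- length(x); n2 <- length(y); n <- n1 + n2
    ties <- table(c(x, y))
    sig2 <- n1 * n2 / 12 * (n + 1 - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (u - n1 * n2 / 2) / sqrt(sig2)
    expect_equal(r$p_value, 2 * pnorm(-abs(z)), tolerance = 1e-9)
})
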