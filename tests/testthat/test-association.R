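test_that("allele tables count risk and other alleles per status group", {
    co <- makeCohort(matrix(c(2L, 1L, 0L, 1L), nrow = 1),
                     status = c(1L, 1L, 0L, 0L))
    tab <- buildAlleleTable(co, "m1")
    expect_identical(as.integer(tab), c(3L, 1L, 1L, 3L))

    zero <- makeCohort(matrix(0L, nrow = 1, ncol = 6),
                       status = rep(c(1L, 0L), 3))
    tz <- buildAlleleTable(zero, "m1")
    expect_identical(tz["case", "risk"], 0L)
    expect_identical(tz["case", "other"], 2L * 3L)

    # margins are twice the group sizes, whatever the dosages
    set.seed(7)
    big <- makeCohort(matrix(sample(0:2, 226, TRUE), nrow = 1),
                      status = rep(c(1L, 0L), c(126, 100)))
    tb <- buildAlleleTable(big, "m1")
    expect_identical(sum(tb["case", ]), 252L)
    expect_identical(sum(tb["control", ]), 200L)

    withNA <- makeCohort(matrix(c(2L, NA, 0L, 1L), nrow = 1),
                         status = c(1L, 1L, 0L, 0L))
    expect_error(buildAlleleTable(withNA, "m1"), "missing")
    expect_error(buildAlleleTable(co, "nope"), "not in the panel")
})

test_that("crude OR and Wald CI match the closed form", {
    r <- oddsRatioWald(c(20, 5, 10, 15))
    expect_equal(r$or, 6.0, tolerance = 1e-12)
    expect_equal(r$se_log, 0.6454972, tolerance = 1e-6)
    expect_equal(r$ci_low, 1.693180, tolerance = 1e-5)
    expect_equal(r$ci_high, 21.26177, tolerance = 1e-5)
    expect_true(r$ci_low <= r$or && r$or <= r$ci_high)

    # balanced table: OR 1, CI symmetric about 1 on the log scale
    b <- oddsRatioWald(c(10, 10, 10, 10))
    expect_equal(b$or, 1.0)
    expect_equal(log(b$ci_high), -log(b$ci_low), tolerance = 1e-12)
})

test_that("zero cells error unless the Haldane-Anscombe correction is asked for", {
    expect_error(oddsRatioWald(c(10, 0, 5, 15)), "zero cell")
    r <- oddsRatioWald(c(10, 0, 5, 15), correct = TRUE)
    expect_equal(r$or, 10.5 * 15.5 / (0.5 * 5.5), tolerance = 1e-12)
    expect_equal(r$or, 59.18, tolerance = 1e-4)
    expect_true(r$corrected)
})

test_that("OR obeys group-swap reciprocity and CI width shrinks with counts", {
    set.seed(11)
    for (i in 1:25) {
        x <- sample(1:40, 4, replace = TRUE)
        r <- oddsRatioWald(x)
        s <- oddsRatioWald(x[c(3, 4, 1, 2)])
        expect_equal(s$or, 1 / r$or, tolerance = 1e-12)
        expect_equal(s$ci_low, 1 / r$ci_high, tolerance = 1e-12)
        expect_equal(s$ci_high, 1 / r$ci_low, tolerance = 1e-12)
        expect_true(r$ci_low <= r$or && r$or <= r$ci_high)
        # scaling every cell up narrows the CI on the log scale
        big <- oddsRatioWald(x * 4)
        expect_lt(log(big$ci_high) - log(big$ci_low),
                  log(r$ci_high) - log(r$ci_low))
    }
})

test_that("logistic fit recovers analytic maximum-likelihood cases", {
    # intercept-only: logit of the case fraction
    co <- makeCohort(matrix(rep(c(0L, 1L), 10), nrow = 1),
                     status = rep(c(1L, 1L, 0L, 0L, 0L), 4))
    f0 <- logisticFit(co, markers = character(0), covariates = character(0))
    expect_equal(unname(f0$coefficients[1]), log(8 / 12), tolerance = 1e-8)

    # one binary exposure, no covariates: identical to the crude 2x2 log-OR
    set.seed(3)
    g <- rbinom(400, 1, 0.4)
    st <- rbinom(400, 1, plogis(-0.5 + 0.9 * g))
    co2 <- makeCohort(matrix(as.integer(g), nrow = 1), status = st)
    f1 <- logisticFit(co2, covariates = character(0))
    tab <- table(factor(st, 1:0), factor(g, 1:0))  # a,b,c,d layout
    crude <- oddsRatioWald(matrix(as.integer(tab), 2, byrow = FALSE))
    expect_equal(unname(f1$coefficients[2]), log(crude$or),
                 tolerance = 1e-6)
    expect_true(f1$converged)
})

test_that("logistic fit recovers a known dosage effect at n = 5000/5000", {
    panel1 <- S4Vectors::DataFrame(name = "m1", risk_allele = "A",
                                   marker_class = "SNP")
    cfg <- simConfig(freqs = 0.35, or = 2.26, nCases = 5000,
                     nControls = 5000, missingRate = 0, panel = panel1)
    set.seed(226)
    co <- simulateCohort(cfg)
    fit <- logisticFit(co)
    expect_true(fit$converged)
    expect_equal(unname(fit$coefficients[2]), log(2.26), tolerance = 0.1)
})

test_that("separation and rank deficiency are flagged, never silent", {
    g <- c(rep(2L, 10), rep(0L, 10))
    co <- makeCohort(matrix(g, nrow = 1), status = rep(c(1L, 0L), each = 10))
    f <- logisticFit(co, covariates = character(0))
    expect_false(f$converged)

    d2 <- rbind(m1 = g, m2 = g)  # duplicated column
    colnames(d2) <- paste0("s", 1:20)
    co2 <- GenotypeCohort(d2, status = rep(c(1L, 0L), each = 10),
                          sex = rep(0:1, 10), age = rep(40, 20))
    expect_error(logisticFit(co2, covariates = character(0)),
                 "rank deficient")
})

test_that("HWE exact test matches hand enumeration and handles degeneracy", {
    expect_equal(hweExactTest(1, 0, 1)$p_value, 1 / 3, tolerance = 1e-12)
    expect_equal(hweExactTest(25, 0, 0)$p_value, 1)   # monomorphic
    expect_error(hweExactTest(0, 0, 0), "at least one")

    set.seed(5)
    for (i in 1:50) {
        n <- sample(2:50, 1)
        nAA <- sample(0:n, 1)
        nAa <- sample(0:(n - nAA), 1)
        p <- hweExactTest(nAA, nAa, n - nAA - nAa)$p_value
        expect_equal(p, hweOracle(nAA, nAa, n - nAA - nAa),
                     tolerance = 1e-9)
        expect_true(p > 0 && p <= 1)
    }
})

test_that("Fisher exact 2x2 matches hypergeometric enumeration", {
    expect_equal(fisherExact2x2(matrix(c(3, 1, 1, 3), 2, byrow = TRUE)),
                 34 / 70, tolerance = 1e-9)
    expect_equal(fisherExact2x2(matrix(5, 2, 2)), 1.0)
    expect_error(fisherExact2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
                 "degenerate")

    set.seed(6)
    for (i in 1:40) {
        tab <- matrix(sample(1:10, 4, TRUE), 2)
        expect_equal(fisherExact2x2(tab), fisherOracle(tab),
                     tolerance = 1e-9)
    }
})

test_that("Wald CIs cover the true OR at close to nominal rate", {
    # moderate-size replicate check; the full calibration lives in the
    # acceptance suite
    set.seed(9)
    trueOR <- 2.26
    hits <- 0L
    B <- 200
    for (b in seq_len(B)) {
        g0 <- rbinom(150, 2, 0.35)
        g1 <- rbinom(150, 2, 0.35 * trueOR / (1 - 0.35 + 0.35 * trueOR))
        a <- sum(g1); c_ <- sum(g0)
        r <- oddsRatioWald(c(a, 300 - a, c_, 300 - c_), correct = TRUE)
        if (r$ci_low <= trueOR && trueOR <= r$ci_high) hits <- hits + 1L
    }
    expect_gt(hits / B, 0.90)
    expect_lt(hits / B, 0.99)
})

test_that("association table combines counts, ORs and HWE checks", {
    set.seed(42)
    co <- simulateCohort(simConfig(nCases = 80, nControls = 80,
                                   missingRate = 0))
    tab <- associationTable(co, correct = TRUE)
    expect_identical(nrow(tab), 5L)
    expect_identical(as.integer(tab$a + tab$b), rep(160L, 5))
    expect_identical(as.integer(tab$c + tab$d), rep(160L, 5))
    expect_true(all(tab$ci_low_crude <= tab$or_crude &
                    tab$or_crude <= tab$ci_high_crude))
    expect_true(all(tab$hwe_p_cases > 0 & tab$hwe_p_cases <= 1))
    expect_true(all(tab$hwe_p_controls > 0 & tab$hwe_p_controls <= 1))
})
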