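#' Allele-count 2x2 table for one marker
#'
#' Collapses additive dosages to allele counts: with \code{n1} complete-case
#' cases the risk-allele count in cases is \code{a = sum(dosage)} and the
#' other-allele count is \code{b = 2*n1 - a}; likewise \code{c}, \code{d} in
#' controls. This is the table underlying the allelic (per-allele) odds
#' ratio, as opposed to a genotypic contrast.
#'
#' @param cohort a [GenotypeCohort-class]; must be complete-case for
#'   \code{marker}.
#' @param marker marker name (a rowname of \code{cohort}).
#' @return integer 2x2 matrix with rows \code{case}/\code{control} and
#'   columns \code{risk}/\code{other}.
#' @examples
#' d <- matrix(c(2L, 1L, 0L, 1L), nrow = 1,
#'             dimnames = list("m1", paste0("s", 1:4)))
#' co <- GenotypeCohort(d, status = c(1L, 1L, 0L, 0L), sex = c(0L, 1L, 0L, 1L),
#'                      age = c(40, 50, 45, 55))
#' buildAlleleTable(co, "m1")   # a=3 b=1 c=1 d=3
#' @export
buildAlleleTable <- function(cohort, marker) {
    if (!marker %in% rownames(cohort))
        stop(sprintf("marker '%s' is not in the panel", marker))
    g <- dosages(cohort)[marker, ]
    if (anyNA(g))
        stop(sprintf("marker '%s' has missing dosages; apply completeCaseFilter first",
                     marker))
    st <- caseStatus(cohort)
    a <- sum(g[st == 1L])
    c_ <- sum(g[st == 0L])
    tab <- matrix(as.integer(c(a, 2L * sum(st == 1L) - a,
                               c_, 2L * sum(st == 0L) - c_)),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("case", "control"), c("risk", "other")))
    tab
}

#' Crude odds ratio with Wald confidence interval
#'
#' For the allele-count table (a, b; c, d) the point estimate is
#' \eqn{OR = ad/bc}, the log-scale standard error is
#' \eqn{\sqrt{1/a + 1/b + 1/c + 1/d}}, and the 95\% interval is
#' \eqn{\exp(\log OR \pm 1.96\,SE)}. A zero cell makes the estimate
#' degenerate; by default this is a hard error so that a published-style OR
#' can never change silently, and the Haldane-Anscombe +0.5 correction (added
#' to all four cells) is applied only when requested explicitly.
#'
#' @param table 2x2 numeric matrix as from [buildAlleleTable()]
#'   (rows: groups, columns: alleles), or a length-4 vector (a, b, c, d).
#' @param correct apply the +0.5 Haldane-Anscombe correction when any cell is
#'   zero (default \code{FALSE}: zero cells raise an error).
#' @param conf.level confidence level for the Wald interval.
#' @return named list: \code{or}, \code{ci_low}, \code{ci_high},
#'   \code{se_log}, \code{method} (\code{"crude"}), \code{corrected}.
#' @examples
#' oddsRatioWald(c(20, 5, 10, 15))        # OR 6.00, CI 1.69-21.3
#' @export
oddsRatioWald <- function(table, correct = FALSE, conf.level = 0.95) {
    x <- as.numeric(t(table))
    if (length(x) != 4 || any(x < 0))
        stop("table must be four non-negative counts")
    if (any(x == 0)) {
        if (!correct)
            stop("zero cell in 2x2 table; rerun with correct = TRUE for the Haldane-Anscombe +0.5 correction")
        x <- x + 0.5
    }
    a <- x[1]; b <- x[2]; c_ <- x[3]; d <- x[4]
    lor <- log(a) + log(d) - log(b) - log(c_)
    se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
    z <- stats::qnorm(1 - (1 - conf.level) / 2)
    list(or = exp(lor), ci_low = exp(lor - z * se), ci_high = exp(lor + z * se),
         se_log = se, method = "crude", corrected = any(as.numeric(t(table)) == 0))
}

#' Covariate-adjusted logistic regression of case status
#'
#' Fits \eqn{\mathrm{logit}\,P(\mathrm{case}) = \beta_0 + \sum_m \beta_m
#' g_m + \beta_{sex}\,sex + \beta_{age}\,age} by maximum likelihood
#' (iteratively reweighted least squares via [stats::glm()]), with Wald
#' standard errors from the inverse observed information. The adjusted
#' per-allele odds ratio of marker m is \eqn{e^{\beta_m}}.
#'
#' Non-convergence and (quasi-)separation are flagged, never silent: the
#' result carries \code{converged = FALSE} when the IRLS loop did not
#' converge, when the score vector at the optimum is not numerically zero, or
#' when a coefficient has diverged (|beta| > 15, the classical separation
#' signature).
#'
#' @param cohort a complete-case [GenotypeCohort-class].
#' @param markers marker names to include as additive dosage terms
#'   (default: the full panel).
#' @param covariates subset of \code{c("sex", "age")} to adjust for.
#' @param tol convergence tolerance on the IRLS deviance change and on the
#'   maximum absolute score component.
#' @param maxit maximum IRLS iterations.
#' @return named list: \code{coefficients}, \code{se}, \code{or} (exp of the
#'   marker coefficients), \code{vcov}, \code{converged},
#'   \code{log_likelihood}, \code{max_gradient}, \code{fit} (the underlying
#'   \code{glm} object).
#' @export
logisticFit <- function(cohort, markers = rownames(cohort),
                        covariates = c("sex", "age"),
                        tol = 1e-8, maxit = 100) {
    g <- t(dosages(cohort)[markers, , drop = FALSE])
    if (anyNA(g))
        stop("missing dosages present; apply completeCaseFilter first")
    df <- as.data.frame(g, check.names = FALSE)
    df$.status <- caseStatus(cohort)
    if ("sex" %in% covariates) df$sex <- sampleSex(cohort)
    if ("age" %in% covariates) df$age <- sampleAge(cohort)
    rhs <- c(sprintf("`%s`", markers), intersect(covariates, c("sex", "age")))
    if (!length(rhs)) rhs <- "1"
    fml <- stats::as.formula(paste(".status ~", paste(rhs, collapse = " + ")))
    X <- stats::model.matrix(fml, df)
    if (qr(X)$rank < ncol(X))
        stop("design matrix is rank deficient")
    fit <- suppressWarnings(
        stats::glm(fml, family = stats::binomial(), data = df,
                   control = stats::glm.control(epsilon = tol, maxit = maxit)))
    beta <- stats::coef(fit)
    p <- fit$fitted.values
    grad <- drop(crossprod(X, df$.status - p))
    maxgrad <- max(abs(grad))
    converged <- isTRUE(fit$converged) &&
        maxgrad < max(tol * nrow(X), 1e-4) &&
        all(abs(beta) < 15)
    se <- sqrt(diag(stats::vcov(fit)))
    or <- exp(beta[1 + seq_along(markers)])
    names(or) <- markers
    list(coefficients = beta, se = se, or = or,
         vcov = stats::vcov(fit), converged = converged,
         log_likelihood = as.numeric(stats::logLik(fit)),
         max_gradient = maxgrad, fit = fit)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test on the genotype counts of a biallelic marker.
#' Conditioning on the sample size n and the risk-allele count nA, the
#' probability of observing h heterozygotes is proportional to
#' \eqn{n! / (n_{AA}!\, n_{Aa}!\, n_{aa}!) \cdot 2^{n_{Aa}}}; the p-value
#' sums the probabilities of every attainable heterozygote count (same n,
#' same nA, matching parity) whose probability does not exceed that of the
#' observed count. Preferred over the chi-square approximation at the
#' sample sizes typical of single-centre case-control panels (n of order
#' 100-150), where expected rare-homozygote counts are small.
#'
#' @param n_hom_risk,n_het,n_hom_other genotype counts (risk homozygote,
#'   heterozygote, other homozygote).
#' @return named list: the three counts, \code{n}, and \code{p_value}.
#' @examples
#' hweExactTest(1, 0, 1)   # p = 1/3
#' @export
hweExactTest <- function(n_hom_risk, n_het, n_hom_other) {
    counts <- c(n_hom_risk, n_het, n_hom_other)
    if (any(counts < 0) || any(counts != round(counts)))
        stop("genotype counts must be non-negative integers")
    n <- sum(counts)
    if (n == 0) stop("at least one genotyped sample is required")
    nA <- 2 * n_hom_risk + n_het
    hets <- seq.int(nA %% 2, min(nA, 2 * n - nA), by = 2)
    # log of n!/(nAA! nAa! naa!) * 2^h, up to the shared normalising constant
    logw <- lfactorial(n) - lfactorial((nA - hets) / 2) - lfactorial(hets) -
        lfactorial(n - (nA + hets) / 2) + hets * log(2)
    w <- exp(logw - max(logw))
    probs <- w / sum(w)
    p_obs <- probs[hets == n_het]
    p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
    list(n_hom_risk = as.integer(n_hom_risk), n_het = as.integer(n_het),
         n_hom_other = as.integer(n_hom_other), n = as.integer(n),
         p_value = min(p, 1))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Probability-mass two-sided rule: with both margins fixed, sum the
#' hypergeometric probabilities of every table whose probability does not
#' exceed (up to relative tolerance 1e-7) that of the observed table. This is
#' the convention implemented by [stats::fisher.test()], which performs the
#' enumeration.
#'
#' @param table 2x2 matrix of non-negative integer counts; both row and both
#'   column margins must be positive.
#' @return two-sided p-value.
#' @examples
#' fisherExact2x2(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))  # 34/70
#' @export
fisherExact2x2 <- function(table) {
    tab <- as.matrix(table)
    if (!all(dim(tab) == c(2, 2)) || any(tab < 0) || any(tab != round(tab)))
        stop("table must be a 2x2 matrix of non-negative integer counts")
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
        stop("degenerate table: a margin is zero")
    stats::fisher.test(tab)$p.value
}

#' Per-marker association table
#'
#' One row per panel marker: allele counts, crude allelic OR with Wald CI,
#' covariate-adjusted OR with Wald CI from the joint logistic model, and the
#' exact Hardy-Weinberg p-value within cases and within controls (a
#' genotyping-quality check).
#'
#' @param cohort a complete-case [GenotypeCohort-class].
#' @param correct passed to [oddsRatioWald()].
#' @param covariates passed to [logisticFit()].
#' @return \code{DataFrame}, one row per marker.
#' @export
associationTable <- function(cohort, correct = FALSE,
                             covariates = c("sex", "age")) {
    markers <- rownames(cohort)
    fit <- logisticFit(cohort, covariates = covariates)
    st <- caseStatus(cohort)
    rows <- lapply(markers, function(m) {
        tab <- buildAlleleTable(cohort, m)
        crude <- oddsRatioWald(tab, correct = correct)
        i <- match(m, markers)
        beta <- fit$coefficients[1 + i]
        se <- fit$se[1 + i]
        g <- dosages(cohort)[m, ]
        hwe_ca <- hweExactTest(sum(g[st == 1] == 2), sum(g[st == 1] == 1),
                               sum(g[st == 1] == 0))$p_value
        hwe_co <- hweExactTest(sum(g[st == 0] == 2), sum(g[st == 0] == 1),
                               sum(g[st == 0] == 0))$p_value
        S4Vectors::DataFrame(
            marker = m, a = tab[1, 1], b = tab[1, 2],
            c = tab[2, 1], d = tab[2, 2],
            or_crude = crude$or, ci_low_crude = crude$ci_low,
            ci_high_crude = crude$ci_high,
            or_adj = exp(beta), ci_low_adj = exp(beta - 1.96 * se),
            ci_high_adj = exp(beta + 1.96 * se),
            hwe_p_cases = hwe_ca, hwe_p_controls = hwe_co)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- markers
    out
}
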