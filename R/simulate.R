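#' Default five-marker psoriasis susceptibility panel
#'
#' The panel the package's examples and simulator default to: the classical
#' HLA-C*06 presence allele, a late-cornified-envelope deletion allele
#' (LCE3C_LCE3B-del) and three SNPs (ERAP1 rs26653 G, CSTA rs17589 T, ZAP70
#' rs17695937 A), all coded as additive risk-allele dosages. Note the ZAP70
#' risk-allele label is reported inconsistently in the literature (A vs G);
#' the label is metadata only and never enters a computation.
#'
#' @return \code{DataFrame} with columns \code{name}, \code{risk_allele},
#'   \code{marker_class}.
#' @export
defaultPanel <- function() {
    S4Vectors::DataFrame(
        name = c("HLA-C*06", "rs26653", "LCE3C_LCE3B-del", "rs17589",
                 "rs17695937"),
        risk_allele = c("HLA-C*06", "G", "del", "T", "A"),
        marker_class = c("HLA-presence", "SNP", "deletion", "SNP", "SNP"))
}

#' Simulation configuration for synthetic case-control cohorts
#'
#' Defines the generative model: control-population risk-allele frequencies
#' per marker (Hardy-Weinberg genotypes, markers independent -- the default
#' panel's loci sit in different genomic regions, so no LD is modelled), a
#' logistic disease model \eqn{\mathrm{logit} P(case) = \beta_0 + \sum_m
#' \log(OR_m) g_m + \beta_{sex} sex + \beta_{age} age} whose intercept is
#' solved so the population prevalence matches \code{prevalence}, sex drawn
#' Bernoulli(\code{maleFraction}) and age from a normal truncated below at
#' \code{ageMin}, and independent per-marker genotyping dropout at rate
#' \code{missingRate}.
#'
#' Defaults describe a plausible single-centre psoriasis case-control study
#' from northern Europe: true per-allele odds ratios (7.42, 2.26, 1.19,
#' 1.12, 1.05) spanning one strong HLA effect and several weak ones,
#' prevalence 5\%, adult ages centred at 43 (SD 14, minimum 18), 55\% male,
#' and 5\% per-marker dropout (complete-case retention \eqn{0.95^5 \approx
#' 0.77}). The control allele frequencies are synthetic placeholders giving
#' realistic score ranges, not population estimates.
#'
#' @param freqs control-population risk-allele frequencies, strictly inside
#'   (0, 1), one per marker.
#' @param or true per-allele odds ratios, one per marker.
#' @param prevalence target population prevalence in (0, 1).
#' @param sexEffect,ageEffect log-odds per unit of the covariate.
#' @param ageMean,ageSD,ageMin age distribution (years).
#' @param maleFraction probability sex = 1.
#' @param nCases,nControls cohort sizes to sample.
#' @param missingRate per-marker dropout probability in [0, 1).
#' @param populationMultiplier the population simulated before case-control
#'   sampling has \code{populationMultiplier * (nCases + nControls)}
#'   individuals.
#' @param panel marker panel (see [defaultPanel()]).
#' @return named list of validated settings, class \code{"grs_sim_config"}.
#' @export
simConfig <- function(freqs = c(0.10, 0.35, 0.30, 0.25, 0.40),
                      or = c(7.42, 2.26, 1.19, 1.12, 1.05),
                      prevalence = 0.05,
                      sexEffect = 0, ageEffect = 0,
                      ageMean = 43, ageSD = 14, ageMin = 18,
                      maleFraction = 0.55,
                      nCases = 148, nControls = 146,
                      missingRate = 0.05,
                      populationMultiplier = 20,
                      panel = defaultPanel()) {
    if (length(or) != length(freqs))
        stop("freqs and or must have one entry per marker")
    if (any(freqs <= 0) || any(freqs >= 1))
        stop("allele frequencies must be strictly inside (0, 1)")
    if (any(or <= 0)) stop("odds ratios must be positive")
    if (prevalence <= 0 || prevalence >= 1)
        stop("prevalence must be in (0, 1)")
    if (missingRate < 0 || missingRate >= 1)
        stop("missingRate must be in [0, 1)")
    if (nCases < 1 || nControls < 1)
        stop("nCases and nControls must be at least 1")
    if (nrow(panel) != length(freqs))
        stop("panel must have one row per marker")
    structure(list(freqs = freqs, or = or, prevalence = prevalence,
                   sexEffect = sexEffect, ageEffect = ageEffect,
                   ageMean = ageMean, ageSD = ageSD, ageMin = ageMin,
                   maleFraction = maleFraction, nCases = nCases,
                   nControls = nControls, missingRate = missingRate,
                   populationMultiplier = populationMultiplier,
                   panel = panel),
              class = "grs_sim_config")
}

#' Simulate Hardy-Weinberg genotype dosages
#'
#' Each marker is drawn independently as dosage ~ Binomial(2, freq) per
#' individual, i.e. Hardy-Weinberg proportions in the source population.
#'
#' @param n number of individuals.
#' @param freqs risk-allele frequency per marker, strictly inside (0, 1).
#' @param markerNames optional row names for the returned matrix.
#' @return integer matrix, markers x individuals.
#' @export
simulateGenotypes <- function(n, freqs, markerNames = NULL) {
    if (any(freqs <= 0) || any(freqs >= 1))
        stop("allele frequencies must be strictly inside (0, 1)")
    M <- length(freqs)
    d <- matrix(stats::rbinom(n * M, 2L, rep(freqs, times = n)),
                nrow = M, ncol = n)
    storage.mode(d) <- "integer"
    rownames(d) <- markerNames
    d
}

.solve_intercept <- function(eta, prevalence) {
    # beta0 with mean(plogis(beta0 + eta)) == prevalence, to 1e-10
    f <- function(b0) mean(stats::plogis(b0 + eta)) - prevalence
    stats::uniroot(f, lower = -60, upper = 60, tol = 1e-10)$root
}

#' Assign case status under the logistic disease model
#'
#' \eqn{P(case) = \mathrm{logit}^{-1}(\beta_0 + \sum_m \log(OR_m) g_m +
#' \beta_{sex} sex + \beta_{age} age)}. The intercept is found
#' deterministically (root-finding to 1e-10) so that the mean case
#' probability over the supplied population equals the target prevalence.
#'
#' @param dosages integer matrix, markers x individuals.
#' @param sex,age covariate vectors, one per individual.
#' @param config a [simConfig()].
#' @return named list: \code{status} (binary vector), \code{beta0},
#'   \code{prob} (per-individual case probability).
#' @export
assignStatus <- function(dosages, sex, age, config) {
    eta <- drop(crossprod(dosages, log(config$or))) +
        config$sexEffect * sex + config$ageEffect * age
    beta0 <- .solve_intercept(eta, config$prevalence)
    prob <- stats::plogis(beta0 + eta)
    status <- stats::rbinom(length(prob), 1L, prob)
    list(status = as.integer(status), beta0 = beta0, prob = prob)
}

.rtruncnorm_min <- function(n, mean, sd, min) {
    out <- stats::rnorm(n, mean, sd)
    while (any(bad <- out < min))
        out[bad] <- stats::rnorm(sum(bad), mean, sd)
    out
}

#' Simulate a complete case-control cohort
#'
#' Simulates a source population of \code{populationMultiplier * (nCases +
#' nControls)} individuals (genotypes, sex, age, then disease status under
#' the logistic model), and samples the requested numbers of cases and
#' controls uniformly without replacement from their strata -- the
#' retrospective case-control design. Optionally injects independent
#' per-marker genotyping dropout.
#'
#' All randomness flows through R's global RNG stream; call
#' \code{set.seed()} first for reproducibility (identical seed and config
#' give an identical cohort).
#'
#' @param config a [simConfig()].
#' @return a [GenotypeCohort-class] with \code{nCases + nControls} samples
#'   (cases first); \code{metadata(.)$beta0} records the solved intercept.
#' @examples
#' set.seed(1)
#' co <- simulateCohort(simConfig(nCases = 30, nControls = 30,
#'                                missingRate = 0))
#' co
#' @export
simulateCohort <- function(config = simConfig()) {
    N <- config$populationMultiplier * (config$nCases + config$nControls)
    d <- simulateGenotypes(N, config$freqs,
                           markerNames = as.character(config$panel$name))
    sex <- stats::rbinom(N, 1L, config$maleFraction)
    age <- round(.rtruncnorm_min(N, config$ageMean, config$ageSD,
                                 config$ageMin))
    st <- assignStatus(d, sex, age, config)
    caseIdx <- which(st$status == 1L)
    ctrlIdx <- which(st$status == 0L)
    if (length(caseIdx) < config$nCases || length(ctrlIdx) < config$nControls)
        stop(sprintf(
            "population of %d yielded %d cases / %d controls but %d / %d were requested; increase populationMultiplier",
            N, length(caseIdx), length(ctrlIdx),
            config$nCases, config$nControls))
    pick <- c(sample(caseIdx, config$nCases),
              sample(ctrlIdx, config$nControls))
    d <- d[, pick, drop = FALSE]
    colnames(d) <- sprintf("S%04d", seq_along(pick))
    cohort <- GenotypeCohort(d, status = st$status[pick], sex = sex[pick],
                             age = age[pick], panel = config$panel)
    if (config$missingRate > 0)
        cohort <- injectMissingness(cohort, config$missingRate)
    S4Vectors::metadata(cohort)$beta0 <- st$beta0
    cohort
}

#' Inject per-marker genotyping dropout
#'
#' Sets each dosage to missing independently with the given rate, emulating
#' samples that fail to amplify at one or more markers; status and
#' covariates are untouched.
#'
#' @param cohort a [GenotypeCohort-class].
#' @param rate dropout probability per dosage, in [0, 1).
#' @return the cohort with missing entries injected.
#' @export
injectMissingness <- function(cohort, rate) {
    if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
    if (rate == 0) return(cohort)
    d <- dosages(cohort)
    drop <- matrix(stats::runif(length(d)) < rate, nrow = nrow(d))
    d[drop] <- NA_integer_
    SummarizedExperiment::assay(cohort, "dosage") <- d
    cohort
}
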