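#' Per-marker log-odds-ratio weights for the weighted score
#'
#' The weighted genetic risk score multiplies each risk-allele dosage by the
#' logarithm of that marker's odds ratio. Weights default to in-sample
#' estimates (crude allelic OR, or sex/age-adjusted OR from the joint
#' logistic model); externally estimated ORs can be supplied instead for
#' honest out-of-sample scoring. The natural logarithm is the default base;
#' base 10 merely rescales every score by a constant and leaves all rank
#' statistics (Mann-Whitney, ROC/AUC) unchanged.
#'
#' @param cohort a complete-case [GenotypeCohort-class] (ignored when
#'   \code{or} is supplied).
#' @param method \code{"crude"} or \code{"adjusted"} for in-sample
#'   estimation; ignored when \code{or} is given.
#' @param or optional named numeric of externally estimated odds ratios, one
#'   per panel marker.
#' @param logBase base of the logarithm (default \code{exp(1)}).
#' @param correct passed to [oddsRatioWald()] for crude weights.
#' @return named numeric of per-marker weights, with attributes
#'   \code{source} and \code{logBase}.
#' @examples
#' grsWeights(or = c(m1 = 7.42, m2 = 2.26))   # log(7.42), log(2.26)
#' @export
grsWeights <- function(cohort = NULL, method = c("crude", "adjusted"),
                       or = NULL, logBase = exp(1), correct = FALSE) {
    if (!is.null(or)) {
        w <- log(or, base = logBase)
        attr(w, "source") <- "external"
        attr(w, "logBase") <- logBase
        return(w)
    }
    method <- match.arg(method)
    if (is.null(cohort)) stop("either a cohort or external ORs are required")
    if (method == "crude") {
        ors <- vapply(rownames(cohort), function(m)
            oddsRatioWald(buildAlleleTable(cohort, m), correct = correct)$or,
            numeric(1))
    } else {
        ors <- logisticFit(cohort)$or
    }
    w <- log(ors, base = logBase)
    attr(w, "source") <- method
    attr(w, "logBase") <- logBase
    w
}

.grs_vector <- function(cohort, score, kind) {
    out <- S4Vectors::DataFrame(sample_id = colnames(cohort),
                                status = caseStatus(cohort),
                                score = unname(score))
    rownames(out) <- colnames(cohort)
    S4Vectors::metadata(out)$kind <- kind
    out
}

#' Count genetic risk score
#'
#' cGRS of a sample is the plain sum of its risk-allele dosages over the
#' panel: an integer in \eqn{[0, 2M]} for M markers, treating every risk
#' allele as equally important.
#'
#' @param cohort a complete-case [GenotypeCohort-class].
#' @return \code{DataFrame} with columns \code{sample_id}, \code{status},
#'   \code{score}; \code{metadata(.)$kind == "cGRS"}.
#' @export
computeCGRS <- function(cohort) {
    d <- dosages(cohort)
    if (anyNA(d))
        stop("missing dosages present; apply completeCaseFilter first")
    .grs_vector(cohort, colSums(d), "cGRS")
}

#' Weighted genetic risk score
#'
#' wGRS of a sample is the dot product of its dosage vector with the
#' per-marker log-OR weights: \eqn{\mathrm{wGRS}_i = \sum_m \log(OR_m)\,
#' g_{im}}. With all weights equal to 1 this reduces exactly to the count
#' score.
#'
#' @param cohort a complete-case [GenotypeCohort-class].
#' @param weights numeric weights, one per panel marker (e.g. from
#'   [grsWeights()]).
#' @return \code{DataFrame} as for [computeCGRS()], \code{kind == "wGRS"}.
#' @export
computeWGRS <- function(cohort, weights) {
    d <- dosages(cohort)
    if (anyNA(d))
        stop("missing dosages present; apply completeCaseFilter first")
    if (length(weights) != nrow(d))
        stop(sprintf("%d weights supplied for %d panel markers",
                     length(weights), nrow(d)))
    if (!is.null(names(weights)) && !identical(names(weights), rownames(d)))
        stop("weight names do not match the marker panel")
    if (any(!is.finite(weights))) stop("weights must be finite")
    .grs_vector(cohort, colSums(d * as.numeric(weights)), "wGRS")
}

#' Descriptive statistics of a score within a status group
#'
#' Sample mean, SD (n-1 denominator), median, and IQR. The IQR uses Tukey
#' hinges by default (the \code{fivenum} convention: hinges are medians of
#' the lower/upper halves including the overall median when n is odd);
#' commercial statistics packages differ in their quantile rule, so the rule
#' is configurable via \code{quantileType} (7 = the R default, as in
#' [stats::quantile()]).
#'
#' @param scores \code{DataFrame} from [computeCGRS()]/[computeWGRS()], or a
#'   plain numeric vector.
#' @param group \code{"case"}, \code{"control"} or \code{"all"} (ignored for
#'   plain vectors).
#' @param quantileType \code{"hinges"} (default) or an integer 1-9 passed to
#'   [stats::quantile()].
#' @return named list: \code{n}, \code{mean}, \code{sd}, \code{median},
#'   \code{iqr}. A singleton group reports \code{sd = 0} (flagged by
#'   \code{n = 1}).
#' @examples
#' describeScores(c(1, 2, 3, 4))  # mean 2.5, sd 1.291, IQR 2 (hinges)
#' @export
describeScores <- function(scores, group = c("all", "case", "control"),
                           quantileType = "hinges") {
    group <- match.arg(group)
    if (is.numeric(scores)) {
        x <- scores
    } else {
        x <- switch(group,
                    all = scores$score,
                    case = scores$score[scores$status == 1L],
                    control = scores$score[scores$status == 0L])
    }
    if (length(x) == 0) stop("empty group")
    if (identical(quantileType, "hinges")) {
        f <- stats::fivenum(x)
        iqr <- f[4] - f[2]
    } else {
        q <- stats::quantile(x, c(0.25, 0.75), type = quantileType,
                             names = FALSE)
        iqr <- q[2] - q[1]
    }
    list(n = length(x), mean = mean(x),
         sd = if (length(x) > 1) stats::sd(x) else 0,
         median = stats::median(x), iqr = iqr)
}

#' Two-sided Mann-Whitney U test
#'
#' Compares two score distributions without a normality assumption. The U
#' statistic is reported for the first group (number of pairs where x beats
#' y, ties counting one half). The p-value is exact by full enumeration when
#' \eqn{n_1 + n_2 \le 16} and the data are tie-free, and otherwise uses the
#' normal approximation with tie-corrected variance and no continuity
#' correction. Enumeration and approximation are delegated to
#' [stats::wilcox.test()], whose W statistic is exactly this U.
#'
#' @param x,y numeric score vectors for the two groups.
#' @param exactLimit largest \eqn{n_1 + n_2} for which the exact distribution
#'   is enumerated (ties always force the approximation).
#' @return named list: \code{u}, \code{p_value}, \code{method}
#'   (\code{"exact"} or \code{"normal-approximation"}).
#' @examples
#' mannWhitneyTest(c(3, 4), c(1, 2))   # U = 4, exact p = 1/3
#' @export
mannWhitneyTest <- function(x, y, exactLimit = 16) {
    if (!length(x) || !length(y)) stop("both groups must be non-empty")
    ties <- anyDuplicated(c(x, y)) > 0
    exact <- !ties && (length(x) + length(y)) <= exactLimit
    ht <- suppressWarnings(
        stats::wilcox.test(x, y, exact = exact, correct = FALSE))
    p <- ht$p.value
    if (is.na(p)) p <- 1    # zero-variance degenerate case (all values tied)
    list(u = unname(ht$statistic), p_value = min(p, 1),
         method = if (exact) "exact" else "normal-approximation")
}
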