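.check_roc_input <- function(scores, status) {
    if (length(scores) != length(status))
        stop("scores and status must have equal length")
    if (anyNA(scores) || anyNA(status))
        stop("missing values are not allowed in scores or status")
    if (!all(status %in% c(0, 1)))
        stop("status must be binary 0/1")
    if (!any(status == 1) || !any(status == 0))
        stop("both cases and controls are required")
}

#' Empirical ROC curve
#'
#' The empirical receiver operating characteristic of a score for separating
#' cases (status 1) from controls (status 0), with higher scores oriented
#' toward cases. One point is produced per distinct threshold (tied scores
#' share a point), plus the (0, 0) origin at threshold +Inf; at the smallest
#' threshold the curve reaches (1, 1). No automatic orientation flip is
#' performed: a score that ranks cases low yields a curve below the diagonal
#' and an AUC below 0.5, reported as-is.
#'
#' @param scores numeric predictor values, one per sample.
#' @param status binary vector, 1 = case, 0 = control.
#' @return \code{data.frame} with columns \code{threshold} (decreasing;
#'   \code{Inf} first), \code{fpr} (1 - specificity) and \code{tpr}
#'   (sensitivity), both non-decreasing from (0, 0) to (1, 1).
#' @examples
#' rocCurve(c(2, 3, 1, 2), c(1, 1, 0, 0))
#' @export
rocCurve <- function(scores, status) {
    .check_roc_input(scores, status)
    thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
    n1 <- sum(status == 1)
    n0 <- sum(status == 0)
    tpr <- vapply(thr, function(t) sum(scores >= t & status == 1) / n1,
                  numeric(1))
    fpr <- vapply(thr, function(t) sum(scores >= t & status == 0) / n0,
                  numeric(1))
    data.frame(threshold = thr, fpr = fpr, tpr = tpr)
}

#' Trapezoidal area under an ROC curve
#'
#' @param curve a \code{data.frame} from [rocCurve()].
#' @return the trapezoidal area under the curve.
#' @export
rocArea <- function(curve) {
    x <- curve$fpr
    y <- curve$tpr
    sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

.mw_kernel_matrix <- function(cases, controls) {
    # psi(case, control): 1 if case > control, 0.5 if tied, 0 otherwise
    d <- outer(cases, controls, "-")
    (d > 0) + 0.5 * (d == 0)
}

#' Nonparametric (Mann-Whitney) AUC with DeLong variance
#'
#' The AUC is the Mann-Whitney two-sample statistic: the probability that a
#' random case outscores a random control, ties counting one half,
#' \deqn{\hat A = \frac{1}{n_1 n_0} \sum_{i \in cases}\sum_{j \in controls}
#'   \psi(s_i, s_j),} with \eqn{\psi} = 1, 1/2, 0 for win, tie, loss. The
#' variance is the structural-component estimator
#' \eqn{\widehat{var} = S_{10}/n_1 + S_{01}/n_0}, where \eqn{S_{10}} and
#' \eqn{S_{01}} are the n-1 sample variances of the per-case and per-control
#' components of [delongComponents()].
#'
#' @inheritParams rocCurve
#' @return named list: \code{auc}, \code{variance}, \code{se},
#'   \code{n_cases}, \code{n_controls}.
#' @examples
#' aucMannWhitney(c(2, 3, 1, 2), c(1, 1, 0, 0))$auc   # 0.875
#' @export
aucMannWhitney <- function(scores, status) {
    comp <- delongComponents(scores, status)
    n1 <- length(comp$v10)
    n0 <- length(comp$v01)
    v <- (if (n1 > 1) stats::var(comp$v10) else 0) / n1 +
         (if (n0 > 1) stats::var(comp$v01) else 0) / n0
    list(auc = comp$auc, variance = v, se = sqrt(v),
         n_cases = n1, n_controls = n0)
}

#' DeLong structural components
#'
#' Per-case components \eqn{V^{10}_i} = mean of the win/tie kernel of case i
#' against every control, and per-control components \eqn{V^{01}_j} = mean of
#' the kernel of every case against control j. The mean of either vector is
#' the AUC; their sample covariances across predictors drive the correlated
#' AUC test of [delongPairedTest()].
#'
#' @inheritParams rocCurve
#' @return named list: \code{v10} (length n_cases), \code{v01}
#'   (length n_controls), \code{auc}.
#' @export
delongComponents <- function(scores, status) {
    .check_roc_input(scores, status)
    cases <- scores[status == 1]
    controls <- scores[status == 0]
    K <- .mw_kernel_matrix(cases, controls)
    v10 <- rowMeans(K)
    v01 <- colMeans(K)
    list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong paired test of two correlated AUCs
#'
#' Compares the AUCs of two predictors scored on the same samples. The
#' 2x2 covariance of \eqn{(\hat A_a, \hat A_b)} is
#' \eqn{S = S_{10}/n_1 + S_{01}/n_0} with \eqn{S_{10}}, \eqn{S_{01}} the
#' (n-1)-denominator sample covariance matrices of the paired per-case and
#' per-control structural components; then
#' \eqn{z = (\hat A_a - \hat A_b) / \sqrt{S_{11} + S_{22} - 2 S_{12}}} is
#' referred to the standard normal, two-sided. Identical predictors (zero
#' contrast variance) return z = 0, p = 1 by convention. Because the
#' statistic depends on the scores only through ranks, any strictly
#' increasing transform of either predictor leaves the result unchanged.
#'
#' @param scores_a,scores_b numeric predictor values, paired sample-wise on
#'   the identical cohort.
#' @param status binary vector, 1 = case, 0 = control.
#' @return named list: \code{auc_a}, \code{auc_b}, \code{delta}, \code{cov}
#'   (2x2 matrix), \code{z}, \code{p_value}, \code{n_cases},
#'   \code{n_controls}.
#' @examples
#' s <- c(2, 3, 1, 2); st <- c(1, 1, 0, 0)
#' delongPairedTest(s, s, st)$p_value   # 1: identical predictors
#' @export
delongPairedTest <- function(scores_a, scores_b, status) {
    if (length(scores_a) != length(scores_b))
        stop("predictors must be scored on identical samples")
    ca <- delongComponents(scores_a, status)
    cb <- delongComponents(scores_b, status)
    n1 <- length(ca$v10)
    n0 <- length(ca$v01)
    V10 <- cbind(ca$v10, cb$v10)
    V01 <- cbind(ca$v01, cb$v01)
    S10 <- if (n1 > 1) stats::cov(V10) else matrix(0, 2, 2)
    S01 <- if (n0 > 1) stats::cov(V01) else matrix(0, 2, 2)
    S <- S10 / n1 + S01 / n0
    delta <- ca$auc - cb$auc
    varDelta <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
    if (varDelta <= .Machine$double.eps) {
        z <- 0
        p <- 1
    } else {
        z <- delta / sqrt(varDelta)
        p <- 2 * stats::pnorm(-abs(z))
    }
    dimnames(S) <- list(c("a", "b"), c("a", "b"))
    list(auc_a = ca$auc, auc_b = cb$auc, delta = delta, cov = S,
         z = z, p_value = min(max(p, 0), 1), n_cases = n1, n_controls = n0)
}
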