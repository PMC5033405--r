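#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.MARKER_CLASSES <- c("SNP", "deletion", "HLA-presence")

#' GenotypeCohort: a case-control cohort of risk-allele dosages
#'
#' An S4 container for a case-control genotype cohort, extending
#' \linkS4class{SummarizedExperiment}. The single \code{"dosage"} assay holds
#' risk-allele dosages (markers as rows, samples as columns) coded additively:
#' 0, 1 or 2 copies of the designated risk allele, with \code{NA} for a failed
#' genotype. Dosage coding is uniform across marker classes -- a SNP, a
#' biallelic deletion (e.g. a late-cornified-envelope CNV) and an HLA
#' presence/absence allele are all counted the same way; the class label in
#' \code{rowData} is metadata only and never enters a computation.
#'
#' \code{colData} carries the per-sample covariates: \code{status} (1 = case,
#' 0 = control), \code{sex} (binary 0/1) and \code{age} (years).
#' \code{rowData} carries the marker panel: \code{risk_allele} (the counted
#' allele's label) and \code{marker_class}.
#'
#' @slot .. inherited from \code{SummarizedExperiment}; no additional slots.
#'
#' @seealso [GenotypeCohort()] for construction, [readDosageTable()] for file
#'   input, [completeCaseFilter()] for the pre-analysis filter.
#' @export
setClass("GenotypeCohort", contains = "SummarizedExperiment")

.validGenotypeCohort <- function(object) {
    msg <- character()
    if (!("dosage" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'dosage' is required")
    else {
        d <- SummarizedExperiment::assay(object, "dosage")
        bad <- !is.na(d) & !(d %in% c(0L, 1L, 2L))
        if (any(bad))
            msg <- c(msg, "dosages must be 0, 1, 2 or NA")
    }
    cd <- SummarizedExperiment::colData(object)
    for (col in c("status", "sex", "age"))
        if (!(col %in% colnames(cd)))
            msg <- c(msg, sprintf("colData column '%s' is required", col))
    if ("status" %in% colnames(cd) && !all(cd$status %in% c(0L, 1L)))
        msg <- c(msg, "status must be 0 (control) or 1 (case)")
    if ("sex" %in% colnames(cd) && !all(cd$sex %in% c(0L, 1L)))
        msg <- c(msg, "sex must be coded 0/1")
    if ("age" %in% colnames(cd) && any(!is.na(cd$age) & cd$age <= 0))
        msg <- c(msg, "age must be positive")
    if (is.null(colnames(object)) && ncol(object) > 0)
        msg <- c(msg, "sample identifiers (colnames) are required")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample identifiers must be unique")
    if (is.null(rownames(object)) && nrow(object) > 0)
        msg <- c(msg, "marker names (rownames) are required")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "marker names must be unique within the panel")
    rd <- SummarizedExperiment::rowData(object)
    if ("marker_class" %in% colnames(rd) &&
        !all(rd$marker_class %in% .MARKER_CLASSES))
        msg <- c(msg, sprintf("marker_class must be one of: %s",
                              paste(.MARKER_CLASSES, collapse = ", ")))
    if (length(msg)) msg else TRUE
}

setValidity("GenotypeCohort", .validGenotypeCohort)

#' Analysis report for a genetic risk score pipeline run
#'
#' Aggregates all results of [runFullAnalysis()]: baseline case/control
#' comparability tests, the per-marker association table (allele counts,
#' crude and adjusted odds ratios, Hardy-Weinberg p-values), group-wise
#' descriptive statistics of the count and weighted genetic risk scores with
#' their Mann-Whitney p-values, the per-predictor AUC table and all pairwise
#' DeLong comparisons, plus the stage log and run parameters.
#'
#' @slot baseline named list: Fisher exact p for sex-by-status and
#'   Mann-Whitney p for age, computed on the unfiltered cohort.
#' @slot markers \code{DataFrame}, one row per marker (allele counts, crude
#'   OR/CI, adjusted OR/CI, HWE p in cases and controls).
#' @slot weights named numeric, the per-marker log-OR weights used for the
#'   weighted score.
#' @slot grs \code{DataFrame} mirroring the classical summary-table layout:
#'   score kind x group x \{n, mean, sd, median, IQR\} plus the two-sided
#'   Mann-Whitney p per score kind.
#' @slot scores \code{DataFrame} of per-sample scores (sample_id, status,
#'   cGRS, wGRS) on the complete-case set.
#' @slot auc \code{DataFrame}, one row per predictor (each marker dosage, the
#'   count score, the weighted score): AUC and DeLong standard error.
#' @slot comparisons \code{DataFrame} of pairwise DeLong tests: predictor
#'   pair, both AUCs, z and two-sided p.
#' @slot log character vector of stage messages (sample counts at each
#'   stage, weight values used).
#' @slot params named list of run options (weight source, log base, seed if
#'   any).
#' @export
setClass("GRSReport",
    representation(
        baseline = "list",
        markers = "DataFrame",
        weights = "numeric",
        grs = "DataFrame",
        scores = "DataFrame",
        auc = "DataFrame",
        comparisons = "DataFrame",
        log = "character",
        params = "list"
    )
)
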