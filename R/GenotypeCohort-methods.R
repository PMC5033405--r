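#' Construct a GenotypeCohort
#'
#' @param dosage integer matrix of risk-allele dosages, markers as rows and
#'   samples as columns; entries in \{0, 1, 2\} or \code{NA}. Row and column
#'   names are required (marker names, sample ids).
#' @param status integer vector (1 = case, 0 = control), one per sample.
#' @param sex binary integer vector, one per sample.
#' @param age numeric vector of ages in years, one per sample.
#' @param panel marker panel: a \code{data.frame}/\code{DataFrame} with
#'   columns \code{name}, \code{risk_allele}, \code{marker_class}, or
#'   \code{NULL} to default every marker to an unlabelled SNP.
#'
#' @return A [GenotypeCohort-class] object.
#' @examples
#' d <- matrix(c(2L, 1L, 0L, 1L), nrow = 2,
#'             dimnames = list(c("m1", "m2"), c("s1", "s2")))
#' GenotypeCohort(d, status = c(1L, 0L), sex = c(0L, 1L), age = c(40, 50))
#' @export
GenotypeCohort <- function(dosage, status, sex, age, panel = NULL) {
    dosage <- as.matrix(dosage)
    storage.mode(dosage) <- "integer"
    if (is.null(panel)) {
        panel <- S4Vectors::DataFrame(
            name = rownames(dosage),
            risk_allele = rep(NA_character_, nrow(dosage)),
            marker_class = rep("SNP", nrow(dosage)))
    } else {
        panel <- S4Vectors::DataFrame(panel)
        need <- c("name", "risk_allele", "marker_class")
        if (!all(need %in% colnames(panel)))
            stop("panel must have columns name, risk_allele, marker_class")
        if (!identical(as.character(panel$name), rownames(dosage)))
            stop("panel marker names must match dosage rownames, in order")
    }
    rd <- panel[, c("risk_allele", "marker_class"), drop = FALSE]
    rownames(rd) <- panel$name
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(dosage = dosage),
        rowData = rd,
        colData = S4Vectors::DataFrame(
            status = as.integer(status),
            sex = as.integer(sex),
            age = as.numeric(age),
            row.names = colnames(dosage)))
    new("GenotypeCohort", se)
}

#' @describeIn GenotypeCohort-accessors dosage matrix (markers x samples)
#' @export
dosages <- function(x) SummarizedExperiment::assay(x, "dosage")

#' Accessors for GenotypeCohort
#'
#' Small accessors in place of slot access: the dosage matrix, the
#' case/control status vector, the covariates, the marker panel, and the
#' case/control sample counts.
#'
#' @param x a [GenotypeCohort-class]
#' @return \code{dosages}: integer matrix; \code{caseStatus}, \code{sampleSex}:
#'   integer vectors; \code{sampleAge}: numeric vector; \code{markerPanel}: a
#'   \code{DataFrame} with columns \code{name}, \code{risk_allele},
#'   \code{marker_class}; \code{nCases}/\code{nControls}: integer counts.
#' @name GenotypeCohort-accessors
NULL

#' @rdname GenotypeCohort-accessors
#' @export
caseStatus <- function(x) SummarizedExperiment::colData(x)$status

#' @rdname GenotypeCohort-accessors
#' @export
sampleSex <- function(x) SummarizedExperiment::colData(x)$sex

#' @rdname GenotypeCohort-accessors
#' @export
sampleAge <- function(x) SummarizedExperiment::colData(x)$age

#' @rdname GenotypeCohort-accessors
#' @export
markerPanel <- function(x) {
    rd <- SummarizedExperiment::rowData(x)
    S4Vectors::DataFrame(name = rownames(x),
                         risk_allele = rd$risk_allele,
                         marker_class = rd$marker_class)
}

#' @rdname GenotypeCohort-accessors
#' @export
nCases <- function(x) sum(caseStatus(x) == 1L)

#' @rdname GenotypeCohort-accessors
#' @export
nControls <- function(x) sum(caseStatus(x) == 0L)

setMethod("show", "GenotypeCohort", function(object) {
    d <- dosages(object)
    nmiss <- sum(is.na(d))
    cat(sprintf("GenotypeCohort: %d marker%s x %d sample%s\n",
                nrow(object), if (nrow(object) == 1) "" else "s",
                ncol(object), if (ncol(object) == 1) "" else "s"))
    cat(sprintf("  cases: %d  controls: %d\n",
                nCases(object), nControls(object)))
    cat(sprintf("  markers: %s\n",
                paste(utils::head(rownames(object), 6), collapse = ", ")))
    cat(sprintf("  missing dosages: %d (%.1f%%)\n", nmiss,
                if (length(d)) 100 * nmiss / length(d) else 0))
    excl <- S4Vectors::metadata(object)$excluded
    if (!is.null(excl))
        cat(sprintf("  complete-case filter removed: %d cases, %d controls\n",
                    excl[["cases"]], excl[["controls"]]))
    invisible(NULL)
})

setMethod("show", "GRSReport", function(object) {
    cat("GRSReport\n")
    cat(sprintf("  markers: %d  predictors in AUC table: %d  pairwise tests: %d\n",
                nrow(object@markers), nrow(object@auc),
                nrow(object@comparisons)))
    cat(sprintf("  complete-case samples scored: %d\n", nrow(object@scores)))
    gm <- object@grs
    for (k in unique(gm$kind)) {
        rows <- gm[gm$kind == k, , drop = FALSE]
        p <- rows$p_mw[1]
        cat(sprintf("  %s: case mean %.2f vs control mean %.2f (Mann-Whitney p = %.3g)\n",
                    k, rows$mean[rows$group == "case"],
                    rows$mean[rows$group == "control"], p))
    }
    invisible(NULL)
})
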