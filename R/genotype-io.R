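#' Read a marker panel file
#'
#' Tab-separated with a header row and columns \code{name},
#' \code{risk_allele}, \code{marker_class}.
#'
#' @param path file path.
#' @return \code{DataFrame} with one row per marker.
#' @export
readMarkerPanel <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            colClasses = "character", quote = "",
                            comment.char = "")
    need <- c("name", "risk_allele", "marker_class")
    missing <- setdiff(need, colnames(df))
    if (length(missing))
        stop(sprintf("marker panel file is missing column(s): %s",
                     paste(missing, collapse = ", ")))
    if (anyDuplicated(df$name))
        stop("marker names must be unique within the panel")
    bad <- setdiff(df$marker_class, .MARKER_CLASSES)
    if (length(bad))
        stop(sprintf("unknown marker_class: %s", paste(bad, collapse = ", ")))
    S4Vectors::DataFrame(df[, need])
}

#' Read a per-sample dosage table
#'
#' The expected dialect is tab-separated UTF-8 with header
#' \code{sample_id, status, sex, age, <marker1> ... <markerM>} where the
#' marker columns follow the panel order and each dosage is 0, 1, 2 or the
#' literal \code{NA} for a failed genotype.
#'
#' @param path file path.
#' @param panel marker panel (\code{DataFrame} or \code{data.frame} with a
#'   \code{name} column, e.g. from [readMarkerPanel()]); the file must carry
#'   exactly these marker columns in this order.
#' @return A [GenotypeCohort-class]. Row order of the file is preserved as
#'   sample (column) order.
#' @export
readDosageTable <- function(path, panel) {
    panel <- S4Vectors::DataFrame(panel)
    markers <- as.character(panel$name)
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            colClasses = "character", quote = "",
                            comment.char = "", na.strings = NULL,
                            check.names = FALSE)
    need <- c("sample_id", "status", "sex", "age", markers)
    missing <- setdiff(need, colnames(df))
    if (length(missing))
        stop(sprintf("dosage table is missing required column(s): %s",
                     paste(missing, collapse = ", ")))
    if (anyDuplicated(df$sample_id))
        stop(sprintf("duplicate sample_id: %s",
                     paste(unique(df$sample_id[duplicated(df$sample_id)]),
                           collapse = ", ")))
    n <- nrow(df)
    dos <- matrix(NA_integer_, nrow = length(markers), ncol = n,
                  dimnames = list(markers, df$sample_id))
    for (m in markers) {
        v <- df[[m]]
        ok <- v %in% c("0", "1", "2", "NA")
        if (!all(ok)) {
            i <- which(!ok)[1]
            stop(sprintf(
                "invalid dosage '%s' at row %d, marker '%s' (must be 0, 1, 2 or NA)",
                v[i], i, m))
        }
        parsed <- rep(NA_integer_, n)
        parsed[v != "NA"] <- as.integer(v[v != "NA"])
        dos[m, ] <- parsed
    }
    .parse_col <- function(col, allowed) {
        v <- df[[col]]
        if (!all(v %in% allowed))
            stop(sprintf("invalid value '%s' in column '%s'",
                         setdiff(v, allowed)[1], col))
        as.integer(v)
    }
    status <- .parse_col("status", c("0", "1"))
    sex <- .parse_col("sex", c("0", "1"))
    age <- suppressWarnings(as.numeric(df$age))
    if (anyNA(age))
        stop(sprintf("unparseable age '%s' at row %d",
                     df$age[which(is.na(age))[1]], which(is.na(age))[1]))
    GenotypeCohort(dos, status = status, sex = sex, age = age,
                   panel = if ("risk_allele" %in% colnames(panel)) panel
                           else NULL)
}

#' Write a cohort as a dosage table
#'
#' Emits the exact dialect [readDosageTable()] accepts (tab-separated,
#' missing dosages as \code{"NA"}); \code{write} then \code{read} is the
#' identity on valid cohorts, and \code{read} then \code{write} reproduces a
#' canonical-dialect file byte for byte.
#'
#' @param cohort a [GenotypeCohort-class].
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeDosageTable <- function(cohort, path) {
    d <- dosages(cohort)
    dtxt <- matrix(as.character(d), nrow = nrow(d))
    dtxt[is.na(dtxt)] <- "NA"
    ids <- colnames(cohort)
    if (is.null(ids)) ids <- character(0)
    out <- data.frame(sample_id = ids,
                      status = as.character(caseStatus(cohort)),
                      sex = as.character(sampleSex(cohort)),
                      age = as.character(sampleAge(cohort)),
                      stringsAsFactors = FALSE, check.names = FALSE)
    for (i in seq_len(nrow(d))) out[[rownames(d)[i]]] <- dtxt[i, ]
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' Write a marker panel file
#'
#' @param panel \code{DataFrame}/\code{data.frame} with columns \code{name},
#'   \code{risk_allele}, \code{marker_class}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeMarkerPanel <- function(panel, path) {
    df <- as.data.frame(panel)[, c("name", "risk_allele", "marker_class")]
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' Complete-case filter
#'
#' Drops every sample with at least one missing dosage across the marker
#' panel, the standard exclusion applied before any score is computed (a
#' sample whose genotyping failed at any marker cannot be scored). Sample
#' order is preserved; no retained value is altered. The number of removed
#' cases and controls is recorded in \code{metadata(result)$excluded}.
#'
#' @param cohort a [GenotypeCohort-class].
#' @return The filtered [GenotypeCohort-class] (possibly empty).
#' @examples
#' d <- matrix(c(2L, NA, 0L, 1L), nrow = 2,
#'             dimnames = list(c("m1", "m2"), c("s1", "s2")))
#' co <- GenotypeCohort(d, status = c(1L, 0L), sex = c(0L, 1L),
#'                      age = c(40, 50))
#' completeCaseFilter(co)   # keeps s2 only
#' @export
completeCaseFilter <- function(cohort) {
    keep <- colSums(is.na(dosages(cohort))) == 0L
    removed <- caseStatus(cohort)[!keep]
    prev <- S4Vectors::metadata(cohort)$excluded
    if (is.null(prev)) prev <- c(cases = 0L, controls = 0L)
    out <- cohort[, keep]
    S4Vectors::metadata(out)$excluded <-
        prev + c(cases = sum(removed == 1L), controls = sum(removed == 0L))
    out
}
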