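# Small cohort builders shared across test files.

makeCohort <- function(dosage, status, sex = NULL, age = NULL,
                       panel = NULL) {
    dosage <- as.matrix(dosage)
    if (is.null(rownames(dosage)))
        rownames(dosage) <- paste0("m", seq_len(nrow(dosage)))
    if (is.null(colnames(dosage)))
        colnames(dosage) <- paste0("s", seq_len(ncol(dosage)))
    n <- ncol(dosage)
    if (is.null(sex)) sex <- rep(0:1, length.out = n)
    if (is.null(age)) age <- seq(30, 60, length.out = n)
    GenotypeCohort(dosage, status = status, sex = sex, age = age,
                   panel = panel)
}

# A deterministic 10-sample, 3-marker cohort with two samples carrying NAs.
makeMissingCohort <- function() {
    d <- matrix(rep(c(0L, 1L, 2L), length.out = 30), nrow = 3)
    d[2, 4] <- NA_integer_
    d[1, 9] <- NA_integer_
    d[3, 9] <- NA_integer_
    makeCohort(d, status = rep(c(1L, 0L), each = 5))
}

# the simulator's default true per-allele odds ratios
defaultTrueORs <- c(7.42, 2.26, 1.19, 1.12, 1.05)
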