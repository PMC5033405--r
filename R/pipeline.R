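.fmt <- function(x, digits = 6) formatC(x, digits = digits, format = "g")

.write_tsv <- function(df, path) {
    utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

.predictor_scores <- function(cohort, weights) {
    d <- dosages(cohort)
    preds <- lapply(seq_len(nrow(d)), function(i) as.numeric(d[i, ]))
    names(preds) <- rownames(d)
    preds$cGRS <- computeCGRS(cohort)$score
    preds$wGRS <- computeWGRS(cohort, weights)$score
    preds
}

#' Run the full genetic risk score analysis
#'
#' Executes the whole pipeline on a cohort, in the order a case-control GRS
#' study proceeds: baseline case/control comparability (Fisher exact test on
#' sex, Mann-Whitney on age, computed before any exclusion), complete-case
#' filtering, per-marker Hardy-Weinberg checks and crude plus adjusted odds
#' ratios, log-OR weights, count and weighted scores with group descriptives
#' and Mann-Whitney comparisons, and finally ROC/AUC for every predictor
#' (each single marker, cGRS, wGRS) with all pairwise DeLong tests.
#'
#' @param cohort a [GenotypeCohort-class], or the path of a dosage table
#'   (then \code{panel} is required).
#' @param panel marker panel \code{DataFrame} or panel file path; only used
#'   when \code{cohort} is a path.
#' @param weightSource \code{"crude"} (default), \code{"adjusted"}, or a
#'   named numeric of external odds ratios.
#' @param logBase base for the log-OR weights (default natural log).
#' @param perMarker when \code{TRUE}, crude ORs and HWE use, for each
#'   marker, all samples genotyped at that marker; the default (\code{FALSE})
#'   computes everything on the complete-case set.
#' @param zeroCellCorrection passed to [oddsRatioWald()] as \code{correct}.
#' @param outDir optional directory; when given, all intermediate tables,
#'   a text report and a run manifest are written there.
#' @param seed optional integer recorded in the manifest (the analysis path
#'   itself is deterministic).
#' @return a [GRSReport-class].
#' @export
runFullAnalysis <- function(cohort, panel = NULL,
                            weightSource = "crude", logBase = exp(1),
                            perMarker = FALSE, zeroCellCorrection = FALSE,
                            outDir = NULL, seed = NULL) {
    log <- character()
    say <- function(...) {
        msg <- sprintf(...)
        log[[length(log) + 1]] <<- msg
        message(msg)
        invisible(NULL)
    }
    if (is.character(cohort)) {
        if (is.null(panel)) stop("panel is required when cohort is a file path")
        if (is.character(panel)) panel <- readMarkerPanel(panel)
        cohort <- readDosageTable(cohort, panel)
    }
    say("input: %d cases, %d controls, %d markers",
        nCases(cohort), nControls(cohort), nrow(cohort))

    sexTab <- table(factor(sampleSex(cohort), levels = 0:1),
                    factor(caseStatus(cohort), levels = 0:1))
    baseline <- list(
        sex_fisher_p = fisherExact2x2(matrix(as.integer(sexTab), 2, 2)),
        age_mw_p = mannWhitneyTest(sampleAge(cohort)[caseStatus(cohort) == 1],
                                   sampleAge(cohort)[caseStatus(cohort) == 0]
                                   )$p_value)
    say("baseline: sex Fisher p = %s, age Mann-Whitney p = %s",
        .fmt(baseline$sex_fisher_p), .fmt(baseline$age_mw_p))

    cc <- completeCaseFilter(cohort)
    excl <- S4Vectors::metadata(cc)$excluded
    say("complete-case filter: removed %d cases and %d controls; %d cases, %d controls retained",
        excl[["cases"]], excl[["controls"]], nCases(cc), nControls(cc))
    if (nCases(cc) == 0 || nControls(cc) == 0)
        stop("complete-case set lost an entire status group")

    assocCohort <- if (perMarker) cohort else cc
    markers <- .association_rows(assocCohort, cc, perMarker,
                                 zeroCellCorrection)
    say("association: crude ORs %s",
        paste(sprintf("%s=%.3g", markers$marker, markers$or_crude),
              collapse = ", "))

    if (is.numeric(weightSource)) {
        weights <- grsWeights(or = weightSource, logBase = logBase)
    } else {
        weights <- grsWeights(cc, method = weightSource, logBase = logBase,
                              correct = zeroCellCorrection)
    }
    say("weights (%s, log base %.4g): %s", attr(weights, "source"), logBase,
        paste(sprintf("%s=%.4f", rownames(cc), as.numeric(weights)),
              collapse = ", "))

    cg <- computeCGRS(cc)
    wg <- computeWGRS(cc, weights)
    grs <- .grs_summary(cg, wg)
    say("cGRS: case mean %.3f vs control mean %.3f (p = %s)",
        grs$mean[grs$kind == "cGRS" & grs$group == "case"],
        grs$mean[grs$kind == "cGRS" & grs$group == "control"],
        .fmt(grs$p_mw[grs$kind == "cGRS"][1]))
    say("wGRS: case mean %.3f vs control mean %.3f (p = %s)",
        grs$mean[grs$kind == "wGRS" & grs$group == "case"],
        grs$mean[grs$kind == "wGRS" & grs$group == "control"],
        .fmt(grs$p_mw[grs$kind == "wGRS"][1]))

    preds <- .predictor_scores(cc, weights)
    st <- caseStatus(cc)
    aucRows <- lapply(names(preds), function(nm) {
        a <- aucMannWhitney(preds[[nm]], st)
        S4Vectors::DataFrame(predictor = nm, auc = a$auc, se = a$se)
    })
    auc <- do.call(rbind, aucRows)
    say("AUC: %s", paste(sprintf("%s=%.3f", auc$predictor, auc$auc),
                         collapse = ", "))

    pairs <- utils::combn(names(preds), 2)
    cmpRows <- lapply(seq_len(ncol(pairs)), function(k) {
        a <- pairs[1, k]; b <- pairs[2, k]
        t <- delongPairedTest(preds[[a]], preds[[b]], st)
        S4Vectors::DataFrame(predictor_a = a, predictor_b = b,
                             auc_a = t$auc_a, auc_b = t$auc_b,
                             z = t$z, p_value = t$p_value)
    })
    comparisons <- do.call(rbind, cmpRows)

    scores <- S4Vectors::DataFrame(sample_id = cg$sample_id,
                                   status = cg$status,
                                   cGRS = cg$score, wGRS = wg$score)
    params <- list(weightSource = if (is.numeric(weightSource)) "external"
                                  else weightSource,
                   logBase = logBase, perMarker = perMarker,
                   zeroCellCorrection = zeroCellCorrection,
                   seed = seed)
    report <- new("GRSReport", baseline = baseline, markers = markers,
                  weights = structure(as.numeric(weights),
                                      names = rownames(cc)),
                  grs = grs, scores = scores, auc = auc,
                  comparisons = comparisons, log = log, params = params)
    if (!is.null(outDir)) writeReport(report, outDir)
    report
}

.association_rows <- function(assocCohort, cc, perMarker, correct) {
    if (!perMarker) return(associationTable(cc, correct = correct))
    fit <- logisticFit(cc)
    rows <- lapply(seq_len(nrow(assocCohort)), function(i) {
        m <- rownames(assocCohort)[i]
        sub <- assocCohort[, !is.na(dosages(assocCohort)[m, ])]
        tab <- buildAlleleTable(sub, m)
        crude <- oddsRatioWald(tab, correct = correct)
        beta <- fit$coefficients[1 + i]
        se <- fit$se[1 + i]
        st <- caseStatus(sub)
        g <- dosages(sub)[m, ]
        S4Vectors::DataFrame(
            marker = m, a = tab[1, 1], b = tab[1, 2], c = tab[2, 1],
            d = tab[2, 2],
            or_crude = crude$or, ci_low_crude = crude$ci_low,
            ci_high_crude = crude$ci_high,
            or_adj = exp(beta), ci_low_adj = exp(beta - 1.96 * se),
            ci_high_adj = exp(beta + 1.96 * se),
            hwe_p_cases = hweExactTest(sum(g[st == 1] == 2),
                                       sum(g[st == 1] == 1),
                                       sum(g[st == 1] == 0))$p_value,
            hwe_p_controls = hweExactTest(sum(g[st == 0] == 2),
                                          sum(g[st == 0] == 1),
                                          sum(g[st == 0] == 0))$p_value)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- out$marker
    out
}

.grs_summary <- function(cg, wg) {
    one <- function(v, kind) {
        p <- mannWhitneyTest(v$score[v$status == 1],
                             v$score[v$status == 0])$p_value
        rows <- lapply(c("case", "control"), function(gr) {
            d <- describeScores(v, group = gr)
            S4Vectors::DataFrame(kind = kind, group = gr, n = d$n,
                                 mean = d$mean, sd = d$sd,
                                 median = d$median, iqr = d$iqr, p_mw = p)
        })
        do.call(rbind, rows)
    }
    rbind(one(cg, "cGRS"), one(wg, "wGRS"))
}

#' Write all report artefacts of a pipeline run
#'
#' Writes tab-separated tables (association, per-sample scores, GRS summary,
#' AUC table, pairwise comparisons, per-predictor ROC coordinates), a
#' human-readable text summary and a run manifest into \code{outDir}. Output
#' is deterministic for a deterministic analysis path, so a rerun on the
#' same input reproduces every file byte for byte.
#'
#' @param report a [GRSReport-class].
#' @param outDir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
writeReport <- function(report, outDir) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
        association = .write_tsv(report@markers,
                                 file.path(outDir, "association.tsv")),
        scores = .write_tsv(report@scores, file.path(outDir, "scores.tsv")),
        grs_summary = .write_tsv(report@grs,
                                 file.path(outDir, "grs_summary.tsv")),
        auc = .write_tsv(report@auc, file.path(outDir, "auc.tsv")),
        comparisons = .write_tsv(report@comparisons,
                                 file.path(outDir, "comparisons.tsv")))
    summaryPath <- file.path(outDir, "report.txt")
    writeLines(reportText(report), summaryPath)
    manifest <- c(
        sprintf("package\tgrsroc %s",
                as.character(utils::packageVersion("grsroc"))),
        sprintf("seed\t%s", if (is.null(report@params$seed)) "none"
                            else report@params$seed),
        sprintf("weight_source\t%s", report@params$weightSource),
        sprintf("log_base\t%s", .fmt(report@params$logBase, 10)),
        sprintf("per_marker\t%s", report@params$perMarker),
        sprintf("zero_cell_correction\t%s",
                report@params$zeroCellCorrection),
        sprintf("weights\t%s",
                paste(sprintf("%s=%.10g", names(report@weights),
                              report@weights), collapse = ",")))
    writeLines(manifest, file.path(outDir, "manifest.tsv"))
    invisible(c(paths, report = summaryPath,
                manifest = file.path(outDir, "manifest.tsv")))
}

#' Render a GRSReport as a text summary
#'
#' @param report a [GRSReport-class].
#' @return character vector of report lines.
#' @export
reportText <- function(report) {
    m <- report@markers
    g <- report@grs
    a <- report@auc
    cmp <- report@comparisons
    c("Genetic risk score analysis",
      "",
      sprintf("Baseline: sex Fisher p = %s; age Mann-Whitney p = %s",
              .fmt(report@baseline$sex_fisher_p),
              .fmt(report@baseline$age_mw_p)),
      "",
      "Per-marker association (crude and sex/age-adjusted allelic OR):",
      sprintf("  %-18s OR %6.2f (%5.2f-%6.2f)  adj %6.2f (%5.2f-%6.2f)  HWE p ca/co %s/%s",
              m$marker, m$or_crude, m$ci_low_crude, m$ci_high_crude,
              m$or_adj, m$ci_low_adj, m$ci_high_adj,
              .fmt(m$hwe_p_cases, 3), .fmt(m$hwe_p_controls, 3)),
      "",
      "Genetic risk scores (complete-case set):",
      sprintf("  %s %-7s n=%-4d mean %6.3f sd %6.3f median %6.3f IQR %6.3f%s",
              g$kind, g$group, g$n, g$mean, g$sd, g$median, g$iqr,
              ifelse(g$group == "case",
                     sprintf("  (Mann-Whitney p = %s)", .fmt(g$p_mw)), "")),
      "",
      "AUC per predictor:",
      sprintf("  %-18s AUC %6.3f (DeLong SE %6.4f)", a$predictor, a$auc,
              a$se),
      "",
      "Pairwise DeLong comparisons:",
      sprintf("  %-18s vs %-18s  %6.3f vs %6.3f  z %7.3f  p = %s",
              cmp$predictor_a, cmp$predictor_b, cmp$auc_a, cmp$auc_b,
              cmp$z, .fmt(cmp$p_value)))
}

#' Simulate a cohort and write it as dosage-table files
#'
#' Thin wrapper over [simulateCohort()] + [writeDosageTable()]; the seed is
#' mandatory because reproducibility is the point of a written cohort.
#'
#' @param config a [simConfig()].
#' @param outPath path for the dosage table; the marker panel is written
#'   next to it with suffix \code{.panel.tsv}.
#' @param seed integer seed.
#' @return invisibly, the cohort.
#' @export
simulateDosageFile <- function(config, outPath, seed) {
    if (missing(seed) || is.null(seed)) stop("a seed is required")
    set.seed(seed)
    cohort <- simulateCohort(config)
    writeDosageTable(cohort, outPath)
    writeMarkerPanel(config$panel, paste0(outPath, ".panel.tsv"))
    invisible(cohort)
}
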