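#' Coefficient of variation (percent)
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation, matching
#' the spreadsheet convention used for assay-validation tables.
#'
#' @param values Numeric vector; at least 2 non-missing values with
#'   positive mean.
#' @return CV in percent.
#' @examples
#' cvPercent(c(8, 10, 12))  # 20
#' @export
cvPercent <- function(values) {
    x <- values[!is.na(values)]
    if (length(x) < 2L)
        stop("cvPercent needs at least 2 non-missing values", call. = FALSE)
    m <- mean(x)
    if (m <= 0)
        stop("cvPercent needs a positive mean", call. = FALSE)
    100 * stats::sd(x) / m
}

#' Dilution-series design
#'
#' @param levels Fold-dilutions, strictly increasing, all >= 1
#'   (default 1, 2, 4, 8, 16: a serial 2-fold dilution series).
#' @param replicates Replicates per level.
#' @param matrix Sample matrix the series was prepared in
#'   (`"buffer"`, `"serum"`, or both).
#' @return list of class `"DilutionDesign"`.
#' @export
dilutionDesign <- function(levels = c(1, 2, 4, 8, 16), replicates = 3L,
                           matrix = c("buffer", "serum")) {
    levels <- as.numeric(levels)
    if (any(levels < 1) || any(diff(levels) <= 0))
        stop("dilution levels must be >= 1 and strictly increasing",
             call. = FALSE)
    stopifnot(replicates >= 1L)
    structure(list(levels = levels, replicates = as.integer(replicates),
                   matrix = matrix), class = "DilutionDesign")
}

#' Dilution linearity (Pearson correlation)
#'
#' Correlation between the dilution axis and peak area.  By default the
#' x-axis is the relative concentration `1/fold` (so a perfectly
#' proportional series gives r = 1); `x_mode = "fold_dilution"` correlates
#' against the raw fold-dilution instead (the same data then give a
#' negative r), so the mode is part of the report metadata.  The
#' correlation is computed on per-level replicate means by default.
#'
#' @param areas Numeric vector of areas.
#' @param folds Fold-dilution of each area (same length).
#' @param x_mode `"relative_concentration"` (default) or `"fold_dilution"`.
#' @param level_means Average replicates within each level before
#'   correlating (default TRUE).
#' @return Pearson correlation coefficient.
#' @examples
#' dilutionLinearity(c(16, 8, 4, 2, 1), c(1, 2, 4, 8, 16))  # 1
#' @export
dilutionLinearity <- function(areas, folds,
                              x_mode = c("relative_concentration",
                                         "fold_dilution"),
                              level_means = TRUE) {
    x_mode <- match.arg(x_mode)
    stopifnot(length(areas) == length(folds))
    ok <- !is.na(areas) & !is.na(folds)
    areas <- areas[ok]; folds <- folds[ok]
    if (level_means) {
        m <- tapply(areas, folds, mean)
        folds <- as.numeric(names(m))
        areas <- as.numeric(m)
    }
    if (length(unique(folds)) < 3L)
        stop("dilution linearity needs >= 3 levels with non-missing areas",
             call. = FALSE)
    x <- if (x_mode == "relative_concentration") 1 / folds else folds
    if (stats::sd(x) == 0 || stats::sd(areas) == 0)
        stop("zero variance in x or areas", call. = FALSE)
    stats::cor(x, areas)
}

.fold_from_condition <- function(condition) {
    fold <- suppressWarnings(as.numeric(sub("^x", "", condition)))
    if (anyNA(fold))
        stop("cannot parse fold-dilution from condition label(s): ",
             paste(unique(condition[is.na(fold)]), collapse = ", "),
             call. = FALSE)
    fold
}

#' Dilution-series QC report
#'
#' Per species and matrix: the CV% of replicate areas at every dilution
#' level and the dilution-linearity correlation, flagged against the
#' thresholds (defaults: CV <= 30%, r >= 0.94).
#'
#' @param a An [AreaTable-class] whose `set_id` is the matrix and whose
#'   `condition` encodes the fold-dilution as `"x<fold>"` (the layout
#'   emitted by [simulateDilutionSeries()]), or a data.frame with columns
#'   `species`, `matrix`, `fold_dilution`, `replicate`, `area`.
#' @param design A [dilutionDesign()].
#' @param cv_max CV% threshold.
#' @param r_min Linearity threshold.
#' @inheritParams dilutionLinearity
#' @return A [QCReport-class].
#' @export
qcReport <- function(a, design, cv_max = 30, r_min = 0.94,
                     x_mode = c("relative_concentration", "fold_dilution")) {
    x_mode <- match.arg(x_mode)
    stopifnot(inherits(design, "DilutionDesign"))
    if (length(design$levels) < 3L)
        stop("qcReport needs a design with >= 3 dilution levels",
             call. = FALSE)
    if (is(a, "AreaTable")) {
        d <- areaData(a)
        d$matrix <- d$set_id
        d$fold_dilution <- .fold_from_condition(d$condition)
    } else {
        d <- as.data.frame(a)
        need <- c("species", "matrix", "fold_dilution", "replicate", "area")
        if (!all(need %in% names(d)))
            stop("qcReport needs columns: ", paste(need, collapse = ", "),
                 call. = FALSE)
    }
    missing_lv <- setdiff(design$levels, unique(d$fold_dilution))
    if (length(missing_lv))
        stop("design level(s) absent from the table: ",
             paste(missing_lv, collapse = ", "), call. = FALSE)
    d <- d[d$fold_dilution %in% design$levels, ]
    cv_rows <- list(); lin_rows <- list()
    for (g in split(d, interaction(d$species, d$matrix, drop = TRUE))) {
        for (lv in sort(unique(g$fold_dilution))) {
            x <- g$area[g$fold_dilution == lv]
            x <- x[!is.na(x)]
            cv <- if (length(x) >= 2L && mean(x) > 0) cvPercent(x)
                  else NA_real_
            cv_rows[[length(cv_rows) + 1L]] <- data.frame(
                species = g$species[1L], matrix = g$matrix[1L],
                fold_dilution = lv, n = length(x), cv_percent = cv,
                cv_pass = !is.na(cv) & cv <= cv_max,
                stringsAsFactors = FALSE)
        }
        r <- tryCatch(
            dilutionLinearity(g$area, g$fold_dilution, x_mode = x_mode),
            error = function(e) NA_real_)
        lin_rows[[length(lin_rows) + 1L]] <- data.frame(
            species = g$species[1L], matrix = g$matrix[1L],
            n_levels = length(unique(g$fold_dilution)), r = r,
            r_pass = !is.na(r) & r >= r_min, stringsAsFactors = FALSE)
    }
    new("QCReport",
        cv = do.call(rbind, cv_rows),
        linearity = do.call(rbind, lin_rows),
        thresholds = list(cv_max = cv_max, r_min = r_min),
        xMode = x_mode)
}

#' QCReport accessors
#'
#' @param x A [QCReport-class].
#' @return `qcCV()` the per-level CV table; `qcLinearity()` the per-species
#'   correlation table; `qcPassed()` TRUE when every flag passes.
#' @export
qcCV <- function(x) x@cv

#' @rdname qcCV
#' @export
qcLinearity <- function(x) x@linearity

#' @rdname qcCV
#' @export
qcPassed <- function(x) {
    all(x@cv$cv_pass, na.rm = FALSE) && all(x@linearity$r_pass)
}

setMethod("show", "QCReport", function(object) {
    cat(sprintf(
        "QCReport: %d CV cells (max %.1f%%), %d linearity values (min r %.3f), x = %s\n",
        nrow(object@cv), object@thresholds$cv_max,
        nrow(object@linearity), object@thresholds$r_min, object@xMode))
    nf <- sum(!object@cv$cv_pass, na.rm = TRUE) +
        sum(!object@linearity$r_pass, na.rm = TRUE)
    cat(if (nf == 0L) "all entries pass\n"
        else paste0(nf, " entr(ies) flagged\n"))
})

#' Write a QC report
#'
#' Writes the CV table, the linearity table and a short human-readable
#' summary.
#'
#' @param x A [QCReport-class].
#' @param prefix Output path prefix; writes `<prefix>_cv.csv`,
#'   `<prefix>_linearity.csv`, `<prefix>_summary.txt`.
#' @return Invisibly, the paths written.
#' @export
writeQCReport <- function(x, prefix) {
    paths <- c(cv = paste0(prefix, "_cv.csv"),
               linearity = paste0(prefix, "_linearity.csv"),
               summary = paste0(prefix, "_summary.txt"))
    utils::write.csv(qcCV(x), paths["cv"], row.names = FALSE, na = "")
    utils::write.csv(qcLinearity(x), paths["linearity"], row.names = FALSE,
                     na = "")
    lines <- c(
        sprintf("QC report (x = %s)", x@xMode),
        sprintf("thresholds: CV <= %.1f%%, r >= %.3f",
                x@thresholds$cv_max, x@thresholds$r_min),
        sprintf("CV cells: %d (range %.2f-%.2f%%)", nrow(qcCV(x)),
                min(qcCV(x)$cv_percent, na.rm = TRUE),
                max(qcCV(x)$cv_percent, na.rm = TRUE)),
        sprintf("linearity: %d species x matrix (range %.3f-%.3f)",
                nrow(qcLinearity(x)),
                min(qcLinearity(x)$r, na.rm = TRUE),
                max(qcLinearity(x)$r, na.rm = TRUE)),
        if (qcPassed(x)) "result: all pass" else "result: flags present")
    writeLines(lines, paths["summary"])
    invisible(paths)
}
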