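#' @import methods
NULL

#' ChemicalFormula class
#'
#' An elemental composition: a named integer vector of element counts.
#' Zero-count elements are never stored, so equality is plain element-wise
#' comparison and formula arithmetic is commutative and associative.
#'
#' @slot counts Named integer vector, element symbol -> count (> 0).
#' @seealso [parseFormula()], [formulaMass()], [combineFormulas()]
#' @export
setClass("ChemicalFormula", representation(counts = "integer"))

setValidity("ChemicalFormula", function(object) {
    cnt <- object@counts
    if (length(cnt) == 0L) return(TRUE)
    if (is.null(names(cnt)) || any(!nzchar(names(cnt))))
        return("all counts must be named by element symbol")
    if (anyDuplicated(names(cnt)))
        return("duplicate element symbols")
    if (any(is.na(cnt)) || any(cnt <= 0L))
        return("counts must be positive; zero-count elements must be absent")
    unknown <- setdiff(names(cnt), .element_masses$element)
    if (length(unknown))
        return(paste0("unknown element symbol(s): ",
                      paste(unknown, collapse = ", ")))
    TRUE
})

#' LipidSpecies class
#'
#' One targeted lipid: its display name, class, shorthand composition (for
#' the shorthand classes), molecular formula and the counts of TMT-labelable
#' sites (free carboxy groups and phosphate monoesters).  LPC, LPE and DAG
#' carry no labelable site and are routed to the native SRM method.
#'
#' @slot displayName Character, e.g. `"LPA(18:1)"` or `"12-HETE"`.
#' @slot lipidClass One of FA, OXYLIPIN, LPA, PA, LPC, LPE, DAG.
#' @slot carbons,doubleBonds Total acyl carbons / double bonds (NA for
#'   registry species whose formula is not shorthand-derived).
#' @slot formula A [ChemicalFormula-class] object.
#' @slot nCarboxy,nPhosphoMonoester Labelable-site counts (>= 0).
#' @export
setClass("LipidSpecies", representation(
    displayName       = "character",
    lipidClass        = "character",
    carbons           = "integer",
    doubleBonds       = "integer",
    formula           = "ChemicalFormula",
    nCarboxy          = "integer",
    nPhosphoMonoester = "integer"
))

.LIPID_CLASSES <- c("FA", "OXYLIPIN", "LPA", "PA", "LPC", "LPE", "DAG")

setValidity("LipidSpecies", function(object) {
    if (length(object@displayName) != 1L || !nzchar(object@displayName))
        return("displayName must be a single non-empty string")
    if (!(object@lipidClass %in% .LIPID_CLASSES))
        return(paste0("lipidClass must be one of ",
                      paste(.LIPID_CLASSES, collapse = ", ")))
    if (object@nCarboxy < 0L || object@nPhosphoMonoester < 0L)
        return("site counts must be >= 0")
    if (object@lipidClass %in% c("LPC", "LPE") &&
        (object@nCarboxy + object@nPhosphoMonoester) != 0L)
        return("LPC/LPE cannot carry labelable sites")
    TRUE
})

#' TransitionList class
#'
#' An ordered SRM transition table plus method metadata.  Columns:
#' `species`, `precursor_mz`, `charge`, `polarity`, `product_mz`,
#' `channel` (reporter label, NA for the native method) and
#' `collision_energy`.
#'
#' @slot transitions data.frame with the columns above.
#' @slot metadata list of method metadata (mode, acquisition settings,
#'   validation notes, source config hash).
#' @export
setClass("TransitionList", representation(
    transitions = "data.frame",
    metadata    = "list"
))

.TRANSITION_COLS <- c("species", "precursor_mz", "charge", "polarity",
                      "product_mz", "channel", "collision_energy")

setValidity("TransitionList", function(object) {
    tr <- object@transitions
    if (!identical(names(tr), .TRANSITION_COLS))
        return(paste0("transition columns must be exactly: ",
                      paste(.TRANSITION_COLS, collapse = ",")))
    if (nrow(tr)) {
        if (any(tr$precursor_mz <= 0) || any(tr$product_mz <= 0))
            return("precursor_mz and product_mz must be positive")
        if (any(!tr$polarity %in% c("positive", "negative")))
            return("polarity must be 'positive' or 'negative'")
        if (any(tr$charge < 1L))
            return("charge must be >= 1")
        key <- paste(tr$species, tr$channel, sep = "\r")
        if (anyDuplicated(key[!is.na(tr$channel)]))
            return("duplicate (species, channel) pairs")
        if (any(tr$polarity[!is.na(tr$channel)] != "positive"))
            return("TMT transitions must be positive polarity")
    }
    TRUE
})

#' AreaTable class
#'
#' Long-format reporter peak areas as produced by SRM peak integration:
#' one record per (set, species, channel, replicate) with design
#' annotations (condition, incubation time).  Missing areas are NA.
#'
#' @slot data data.frame with columns `set_id`, `species`, `channel_label`,
#'   `replicate`, `condition`, `time_h`, `area`.
#' @export
setClass("AreaTable", representation(data = "data.frame"))

.AREA_COLS <- c("set_id", "species", "channel_label", "replicate",
                "condition", "time_h", "area")

setValidity("AreaTable", function(object) {
    d <- object@data
    if (!all(.AREA_COLS %in% names(d)))
        return(paste0("area table needs columns: ",
                      paste(.AREA_COLS, collapse = ",")))
    if (nrow(d)) {
        key <- paste(d$set_id, d$species, d$channel_label, d$replicate,
                     sep = "\r")
        if (anyDuplicated(key))
            return("duplicate (set_id, species, channel_label, replicate) key")
        if (any(d$area < 0, na.rm = TRUE))
            return("negative areas are not allowed")
        if (any(d$replicate < 1L))
            return("replicate must be >= 1")
        if (any(d$time_h < 0, na.rm = TRUE))
            return("time_h must be >= 0")
    }
    TRUE
})

#' QCReport class
#'
#' Reproducibility report: per-species, per-matrix coefficient of variation
#' at every dilution level and the dilution-linearity correlation, with
#' pass/fail flags against the configured thresholds.
#'
#' @slot cv data.frame: species, matrix (set_id), fold_dilution, n,
#'   cv_percent, cv_pass.
#' @slot linearity data.frame: species, matrix, n_levels, r, r_pass.
#' @slot thresholds list(cv_max, r_min).
#' @slot xMode Character, how the dilution axis was coded for correlation.
#' @export
setClass("QCReport", representation(
    cv         = "data.frame",
    linearity  = "data.frame",
    thresholds = "list",
    xMode      = "character"
))

setValidity("QCReport", function(object) {
    if (nrow(object@cv) && any(object@cv$cv_percent < 0, na.rm = TRUE))
        return("CV% must be >= 0")
    if (nrow(object@linearity) &&
        any(abs(object@linearity$r) > 1 + 1e-12, na.rm = TRUE))
        return("correlations must lie in [-1, 1]")
    TRUE
})
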