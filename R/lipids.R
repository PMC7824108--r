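## Composition rules for the shorthand lipid classes.  (c, d) are total acyl
## carbons and double bonds.  Each rule returns element counts and the
## labelable-site counts for the class.
.SHORTHAND_RULES <- list(
    FA  = function(c, d) list(cnt = c(C = c,     H = 2 * c - 2 * d,      O = 2L),
                              nC = 1L, nP = 0L, max_chains = 1L),
    LPA = function(c, d) list(cnt = c(C = c + 3L, H = 2 * c + 7L - 2 * d, O = 7L, P = 1L),
                              nC = 0L, nP = 1L, max_chains = 1L),
    PA  = function(c, d) list(cnt = c(C = c + 3L, H = 2 * c + 5L - 2 * d, O = 8L, P = 1L),
                              nC = 0L, nP = 1L, max_chains = 2L),
    LPC = function(c, d) list(cnt = c(C = c + 8L, H = 2 * c + 18L - 2 * d, N = 1L, O = 7L, P = 1L),
                              nC = 0L, nP = 0L, max_chains = 1L),
    LPE = function(c, d) list(cnt = c(C = c + 5L, H = 2 * c + 12L - 2 * d, N = 1L, O = 7L, P = 1L),
                              nC = 0L, nP = 0L, max_chains = 1L),
    DAG = function(c, d) list(cnt = c(C = c + 3L, H = 2 * c + 4L - 2 * d, O = 5L),
                              nC = 0L, nP = 0L, max_chains = 2L)
)

#' Parse lipid shorthand nomenclature
#'
#' Accepts total-composition form `CLASS(c:d)` and per-chain form
#' `CLASS(c1:d1/c2:d2)`; per-chain compositions are summed (sn-position is
#' not modeled).  Supported classes: FA, LPA, PA, LPC, LPE, DAG.  Double
#' bond position and geometry are ignored.
#'
#' @param name Shorthand name, e.g. `"FA(20:4)"`, `"PA(18:1/18:1)"`.
#' @return A [LipidSpecies-class] with class-determined formula and
#'   labelable-site counts.
#' @examples
#' parseLipidShorthand("LPA(16:0)")   # C19H39O7P, one phosphate monoester
#' parseLipidShorthand("PA(36:2)")    # C39H73O8P
#' @export
parseLipidShorthand <- function(name) {
    stopifnot(is.character(name), length(name) == 1L)
    m <- regmatches(name, regexec(
        "^\\s*([A-Za-z]+)\\(\\s*([0-9]+\\s*:\\s*[0-9]+(?:\\s*/\\s*[0-9]+\\s*:\\s*[0-9]+)*)\\s*\\)\\s*$",
        name))[[1]]
    if (!length(m))
        stop("cannot parse lipid shorthand: ", sQuote(name), call. = FALSE)
    cls <- toupper(m[2])
    rule <- .SHORTHAND_RULES[[cls]]
    if (is.null(rule))
        stop("unknown lipid class ", sQuote(m[2]), " in ", sQuote(name),
             "; supported: ", paste(names(.SHORTHAND_RULES), collapse = ", "),
             call. = FALSE)
    chains <- strsplit(gsub("\\s", "", m[3]), "/", fixed = TRUE)[[1]]
    cd <- vapply(strsplit(chains, ":", fixed = TRUE), as.integer,
                 integer(2))
    carbons <- sum(cd[1, ]); dbonds <- sum(cd[2, ])
    if (any(cd[2, ] > pmax(cd[1, ] - 1L, 0L)))
        stop("double bonds exceed chain capacity in ", sQuote(name),
             call. = FALSE)
    spec <- rule(carbons, dbonds)
    if (length(chains) > spec$max_chains)
        stop(cls, " accepts at most ", spec$max_chains,
             " acyl chain(s): ", sQuote(name), call. = FALSE)
    if (any(spec$cnt < 0))
        stop("implausible composition in ", sQuote(name), call. = FALSE)
    new("LipidSpecies",
        displayName       = trimws(name),
        lipidClass        = cls,
        carbons           = carbons,
        doubleBonds       = dbonds,
        formula           = chemicalFormula(spec$cnt),
        nCarboxy          = spec$nC,
        nPhosphoMonoester = spec$nP)
}

#' @rdname formulaMass
#' @export
setMethod("formulaMass", "LipidSpecies", function(object, mode) {
    formulaMass(object@formula, mode)
})

#' LipidSpecies accessors
#'
#' @param x A [LipidSpecies-class].
#' @return `speciesName()` the display name; `lipidClass()` the class token;
#'   `chemFormula()` the [ChemicalFormula-class]; `nCarboxy()` /
#'   `nPhosphoMonoester()` labelable-site counts; `labelSites()` their sum.
#' @name lipid-accessors
#' @examples
#' labelSites(parseLipidShorthand("FA(20:4)"))  # 1
NULL

#' @rdname lipid-accessors
#' @export
speciesName <- function(x) x@displayName

#' @rdname lipid-accessors
#' @export
lipidClass <- function(x) x@lipidClass

#' @rdname lipid-accessors
#' @export
chemFormula <- function(x) x@formula

#' @rdname lipid-accessors
#' @export
nCarboxy <- function(x) x@nCarboxy

#' @rdname lipid-accessors
#' @export
nPhosphoMonoester <- function(x) x@nPhosphoMonoester

#' @rdname lipid-accessors
#' @export
labelSites <- function(x) x@nCarboxy + x@nPhosphoMonoester

setMethod("show", "LipidSpecies", function(object) {
    cat(sprintf(
        "LipidSpecies %s [%s] %s (monoisotopic %.4f Da), %d carboxy, %d phosphate-monoester site(s)\n",
        object@displayName, object@lipidClass, formulaString(object@formula),
        formulaMass(object), object@nCarboxy, object@nPhosphoMonoester))
})
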