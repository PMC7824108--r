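#' Construct a chemical formula from element counts
#'
#' @param counts Named integer-ish vector of element counts; zero counts are
#'   dropped.
#' @return A [ChemicalFormula-class] object.
#' @examples
#' chemicalFormula(c(C = 20, H = 32, O = 2))
#' @export
chemicalFormula <- function(counts = integer()) {
    if (length(counts)) {
        if (any(is.na(counts)) || any(counts < 0) ||
            any(counts != as.integer(counts)))
            stop("element counts must be non-negative integers",
                 call. = FALSE)
        counts <- counts[counts > 0]
    }
    cnt <- as.integer(counts)
    names(cnt) <- names(counts)
    ## canonical Hill order: C, H, then alphabetical
    if (length(cnt)) {
        hill <- c("C", "H", sort(setdiff(names(cnt), c("C", "H"))))
        cnt <- cnt[hill[hill %in% names(cnt)]]
    }
    new("ChemicalFormula", counts = cnt)
}

#' Parse a Hill-notation formula string
#'
#' @param text Formula string such as `"C20H32O2"` or `"H2O"`.
#' @return A [ChemicalFormula-class] object.
#' @examples
#' parseFormula("C20H32O2")
#' @export
parseFormula <- function(text) {
    stopifnot(is.character(text), length(text) == 1L)
    s <- trimws(text)
    if (!nzchar(s)) stop("empty formula string", call. = FALSE)
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s, perl = TRUE)[[1]]
    tokens <- regmatches(s, list(m))[[1]]
    if (sum(attr(m, "match.length")) != nchar(s))
        stop("malformed formula string: ", sQuote(s), call. = FALSE)
    elem <- sub("[0-9]*$", "", tokens)
    n <- sub("^[A-Z][a-z]?", "", tokens)
    n <- ifelse(nzchar(n), as.integer(n), 1L)
    unknown <- setdiff(elem, .element_masses$element)
    if (length(unknown))
        stop("unknown element ", paste(unknown, collapse = ", "),
             " in ", sQuote(s), call. = FALSE)
    counts <- tapply(n, elem, sum)
    chemicalFormula(counts[unique(elem)])
}

#' Element counts of a formula
#'
#' @param f A [ChemicalFormula-class].
#' @return Named integer vector.
#' @export
elementCounts <- function(f) {
    stopifnot(is(f, "ChemicalFormula"))
    f@counts
}

#' Render a formula as a Hill-notation string
#'
#' @param f A [ChemicalFormula-class].
#' @return Character scalar (empty formula renders as `""`).
#' @export
formulaString <- function(f) {
    cnt <- elementCounts(f)
    if (!length(cnt)) return("")
    paste0(names(cnt), ifelse(cnt == 1L, "", cnt), collapse = "")
}

#' Molecular mass of a formula or species
#'
#' Sum of element count times atomic mass, monoisotopic by default.
#'
#' @param object A [ChemicalFormula-class] or [LipidSpecies-class].
#' @param mode `"monoisotopic"` or `"average"`.
#' @return Mass in Da.
#' @examples
#' formulaMass(parseFormula("H2O"))  # 18.010565
#' @export
setGeneric("formulaMass", function(object, mode = "monoisotopic")
    standardGeneric("formulaMass"))

#' @rdname formulaMass
#' @export
setMethod("formulaMass", "ChemicalFormula", function(object, mode) {
    cnt <- object@counts
    if (!length(cnt)) return(0)
    sum(cnt * .mass_of(names(cnt), mode))
})

#' Add or subtract chemical formulas
#'
#' Element-wise sum or difference.  Subtraction that would yield a negative
#' count is an infeasible formula and raises an error.
#'
#' @param a,b [ChemicalFormula-class] objects.
#' @param op `"add"` or `"subtract"`.
#' @return A [ChemicalFormula-class].
#' @examples
#' g3p <- parseFormula("C3H9O6P")
#' palmitic <- parseFormula("C16H32O2")
#' combineFormulas(combineFormulas(g3p, palmitic), parseFormula("H2O"),
#'                 op = "subtract")  # LPA 16:0, C19H39O7P
#' @export
combineFormulas <- function(a, b, op = c("add", "subtract")) {
    op <- match.arg(op)
    stopifnot(is(a, "ChemicalFormula"), is(b, "ChemicalFormula"))
    elems <- union(names(a@counts), names(b@counts))
    ca <- a@counts[elems]; ca[is.na(ca)] <- 0L
    cb <- b@counts[elems]; cb[is.na(cb)] <- 0L
    res <- if (op == "add") ca + cb else ca - cb
    if (any(res < 0L))
        stop("infeasible formula: subtraction yields negative count for ",
             paste(elems[res < 0L], collapse = ", "), call. = FALSE)
    names(res) <- elems
    chemicalFormula(res)
}

#' @rdname combineFormulas
#' @param e1,e2 [ChemicalFormula-class] operands.
#' @export
setMethod("+", signature("ChemicalFormula", "ChemicalFormula"),
          function(e1, e2) combineFormulas(e1, e2, "add"))

#' @rdname combineFormulas
#' @export
setMethod("-", signature("ChemicalFormula", "ChemicalFormula"),
          function(e1, e2) combineFormulas(e1, e2, "subtract"))

setMethod("show", "ChemicalFormula", function(object) {
    cat("ChemicalFormula:", formulaString(object),
        sprintf("(monoisotopic %.6f Da)\n", formulaMass(object)))
})
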