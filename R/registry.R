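#' Built-in oxylipin/eicosanoid formula registry
#'
#' Ships the formulas and labelable-site counts for the standards used by
#' the sixplex panel: hydroxyeicosatetraenoic acids, prostaglandin E2,
#' thromboxane B2, arachidonic acid and the two-carboxy metabolites
#' 20-carboxy-LTB4 and tetranor-PGDM.  Positional isomers (12-HETE vs
#' 20-HETE) share a formula and are distinguished only by name.
#' tetranor-PGDM's formula is configurable via [readRegistry()]; the
#' pipeline relies only on its two carboxy groups.
#'
#' @param extra Optional data.frame in registry format (columns `name`,
#'   `formula`, `n_carboxy`, `n_phospho_monoester`, `synonyms`) appended to
#'   the built-ins; entries with a name already present override it.
#' @return data.frame in registry format.
#' @examples
#' oxylipinRegistry()
#' @export
oxylipinRegistry <- function(extra = NULL) {
    reg <- data.frame(
        name = c("12-HETE", "15-HETE", "18-HETE", "20-HETE", "PGE2",
                 "TXB2", "AA", "EPA", "DHA", "20-carboxy-LTB4",
                 "tetranor-PGDM"),
        formula = c("C20H32O3", "C20H32O3", "C20H32O3", "C20H32O3",
                    "C20H32O5", "C20H34O6", "C20H32O2", "C20H30O2",
                    "C22H32O2", "C20H30O6", "C16H24O7"),
        n_carboxy = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 2L, 2L),
        n_phospho_monoester = 0L,
        synonyms = c("12-hydroxyeicosatetraenoic acid",
                     "15-hydroxyeicosatetraenoic acid",
                     "18-hydroxyeicosatetraenoic acid",
                     "20-hydroxyeicosatetraenoic acid",
                     "prostaglandin E2", "thromboxane B2",
                     "arachidonic acid|FA(20:4)",
                     "eicosapentaenoic acid|FA(20:5)",
                     "docosahexaenoic acid|FA(22:6)",
                     "20-carboxy leukotriene B4", "tetranor PGDM"),
        stringsAsFactors = FALSE)
    if (!is.null(extra)) {
        extra <- .validate_registry(extra)
        reg <- rbind(reg[!reg$name %in% extra$name, ], extra)
    }
    reg
}

.validate_registry <- function(reg) {
    need <- c("name", "formula", "n_carboxy", "n_phospho_monoester")
    if (!all(need %in% names(reg)))
        stop("registry needs columns: ", paste(need, collapse = ", "),
             call. = FALSE)
    if (!"synonyms" %in% names(reg)) reg$synonyms <- ""
    reg$synonyms[is.na(reg$synonyms)] <- ""
    reg$n_carboxy <- as.integer(reg$n_carboxy)
    reg$n_phospho_monoester <- as.integer(reg$n_phospho_monoester)
    if (any(is.na(reg$n_carboxy)) || any(reg$n_carboxy < 0) ||
        any(is.na(reg$n_phospho_monoester)) ||
        any(reg$n_phospho_monoester < 0))
        stop("registry site counts must be non-negative integers",
             call. = FALSE)
    reg[c(need, "synonyms")]
}

#' Read a registry CSV
#'
#' @param path CSV with columns `name`, `formula`, `n_carboxy`,
#'   `n_phospho_monoester` and optional `synonyms` (pipe-separated).
#' @param builtin Prepend the built-in registry (default TRUE; file entries
#'   override built-ins of the same name).
#' @return data.frame in registry format.
#' @export
readRegistry <- function(path, builtin = TRUE) {
    reg <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (builtin) oxylipinRegistry(extra = reg) else .validate_registry(reg)
}

#' Look up a species in the formula registry
#'
#' @param name Registry name or synonym (case-insensitive).
#' @param registry Registry data.frame, default [oxylipinRegistry()].
#' @return A [LipidSpecies-class] of class `"OXYLIPIN"`.
#' @examples
#' registryLookup("20-carboxy-LTB4")  # two carboxy groups -> divalent TMT ion
#' @export
registryLookup <- function(name, registry = oxylipinRegistry()) {
    stopifnot(is.character(name), length(name) == 1L)
    key <- tolower(trimws(name))
    hit <- which(tolower(registry$name) == key)
    if (!length(hit)) {
        syn <- strsplit(registry$synonyms, "|", fixed = TRUE)
        hit <- which(vapply(syn, function(s) key %in% tolower(trimws(s)),
                            logical(1)))
    }
    if (!length(hit)) {
        dist <- utils::adist(key, tolower(registry$name))
        near <- registry$name[order(dist)][seq_len(min(3L, nrow(registry)))]
        stop(errorCondition(
            paste0("species ", sQuote(name), " not found in registry; ",
                   "nearest names: ", paste(near, collapse = ", ")),
            class = c("lipidTMT_lookup_error", "error", "condition")))
    }
    row <- registry[hit[1L], ]
    new("LipidSpecies",
        displayName       = row$name,
        lipidClass        = "OXYLIPIN",
        carbons           = NA_integer_,
        doubleBonds       = NA_integer_,
        formula           = parseFormula(row$formula),
        nCarboxy          = row$n_carboxy,
        nPhosphoMonoester = row$n_phospho_monoester)
}

#' Resolve a panel name to a LipidSpecies
#'
#' Shorthand names (`"FA(20:4)"`) are parsed by composition rules; anything
#' else is looked up in the registry.
#'
#' @param name Character name.
#' @inheritParams registryLookup
#' @return A [LipidSpecies-class].
#' @export
resolveSpecies <- function(name, registry = oxylipinRegistry()) {
    if (grepl("^\\s*[A-Za-z]+\\(", name)) parseLipidShorthand(name)
    else registryLookup(name, registry)
}

#' Default sixplex panels
#'
#' `lpaPaPanel()` returns the LPA/PA panel as printed in the method (five
#' LPA species and nine PA entries, one of which is a duplicate that the
#' transition builder deduplicates); `fattyAcidPanel()` the saturated and
#' common unsaturated free fatty acids with 12-24 acyl carbons targeted by
#' the sixplex method.
#'
#' @return Character vector of shorthand names.
#' @examples
#' lpaPaPanel()
#' @export
lpaPaPanel <- function() {
    c("LPA(16:0)", "LPA(18:0)", "LPA(18:1)", "LPA(18:2)", "LPA(20:4)",
      "PA(32:0)", "PA(34:1)", "PA(34:2)", "PA(36:0)", "PA(36:2)",
      "PA(36:3)", "PA(36:2)", "PA(36:4)", "PA(38:4)")
}

#' @rdname lpaPaPanel
#' @export
fattyAcidPanel <- function() {
    even <- seq(12L, 24L, by = 2L)
    sat <- sprintf("FA(%d:0)", even)
    unsat <- c("FA(16:1)", "FA(18:1)", "FA(18:2)", "FA(18:3)", "FA(20:1)",
               "FA(20:4)", "FA(20:5)", "FA(22:4)", "FA(22:6)", "FA(24:1)")
    c(sat, unsat)
}
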