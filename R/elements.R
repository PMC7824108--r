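#' Element mass table
#'
#' Monoisotopic (6 decimals) and average (3 decimals) atomic masses for the
#' elements handled by the package, following IUPAC recommended values.
#' Hard-coded so that every mass in the package is reproducible without an
#' external dependency.
#'
#' @return A data.frame with columns `element`, `monoisotopic`, `average`.
#' @examples
#' elementMassTable()
#' @export
elementMassTable <- function() {
    .element_masses
}

.element_masses <- data.frame(
    element      = c("H", "C", "N", "O", "P", "S", "Na", "K"),
    monoisotopic = c(1.007825, 12.000000, 14.003074, 15.994915,
                     30.973762, 31.972071, 22.989769, 38.963706),
    average      = c(1.008, 12.011, 14.007, 15.999,
                     30.974, 32.060, 22.990, 39.098),
    stringsAsFactors = FALSE
)

#' Physical mass constants (Da)
#'
#' Proton and electron masses used for charged-species m/z arithmetic.
#'
#' @return Named numeric vector with elements `proton` and `electron`.
#' @examples
#' massConstants()["proton"]
#' @export
massConstants <- function() {
    c(proton = 1.007276, electron = 0.000549)
}

.mass_of <- function(element, mode = c("monoisotopic", "average")) {
    mode <- match.arg(mode)
    i <- match(element, .element_masses$element)
    if (anyNA(i)) {
        stop("element(s) missing from mass table: ",
             paste(element[is.na(i)], collapse = ", "), call. = FALSE)
    }
    .element_masses[[mode]][i]
}

## Neutral-loss / fragment constants used by the native SRM rules.
## Phosphoethanolamine head-group neutral loss (C2H8NO4P) and the
## protonated phosphocholine fragment cation (C5H15NO4P+).
.PHOSPHOETHANOLAMINE_LOSS <- 141.0191
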