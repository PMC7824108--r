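## Hydrogen atom mass used by the nominal TMT precursor rule [M-H+303.25]+.
.H_ATOM <- 1.007825
.TMT_NOMINAL_TAG <- 303.25

#' Count TMT-labelable sites of a species
#'
#' The aminoxyTMT chemistry (EDC + DMTMM activation) derivatizes free
#' carboxy groups and phosphate monoesters; each site takes one tag and the
#' labeled precursor carries one charge per tag.  Phosphatidylcholine,
#' phosphatidylethanolamine and their lyso-forms (phosphate diesters)
#' cannot be labeled and raise a condition of class
#' `lipidTMT_not_labelable`.
#'
#' @param species A [LipidSpecies-class].
#' @return list with `k_labels` (int >= 1) and `site_types` (character
#'   multiset of `"carboxy"` / `"phospho_monoester"`).
#' @examples
#' countLabelSites(parseLipidShorthand("FA(20:4)"))$k_labels   # 1
#' countLabelSites(registryLookup("20-carboxy-LTB4"))$k_labels # 2
#' @export
countLabelSites <- function(species) {
    stopifnot(is(species, "LipidSpecies"))
    k <- labelSites(species)
    if (k < 1L)
        stop(errorCondition(
            paste0(speciesName(species),
                   " has no labelable site (no free carboxy or phosphate",
                   " monoester); route it to the native SRM method"),
            class = c("lipidTMT_not_labelable", "error", "condition")))
    list(k_labels = k,
         site_types = c(rep("carboxy", nCarboxy(species)),
                        rep("phospho_monoester", nPhosphoMonoester(species))))
}

#' TMT precursor m/z and charge
#'
#' A species with k labelable sites takes k tags and is observed as a
#' k-fold protonated-equivalent cation following the nominal rule
#' `[M - kH + k*303.25]^(k+)`, i.e. m/z = (M - k*1.007825 + k*tag)/k with
#' M the monoisotopic mass.  k = 1 gives the singly labeled rule printed
#' for the sixplex method; k = 2 the divalent, doubly labeled ion observed
#' for two-carboxy eicosanoid metabolites.  `rule_mode = "exact_tag"`
#' replaces the nominal 303.25 Da offset with a user-supplied exact tag
#' mass (never silently substituted).
#'
#' @param species A [LipidSpecies-class].
#' @param rule_mode `"paper_nominal"` (default) or `"exact_tag"`.
#' @param tag_mass Exact per-tag mass offset in Da; required for
#'   `"exact_tag"`.
#' @return list with `mz` (unrounded) and `charge` (= number of tags).
#' @examples
#' tmtPrecursor(parseLipidShorthand("FA(20:4)"))      # 606.48, 1+
#' tmtPrecursor(registryLookup("20-carboxy-LTB4"))    # 485.34, 2+
#' @export
tmtPrecursor <- function(species, rule_mode = c("paper_nominal", "exact_tag"),
                         tag_mass = NULL) {
    rule_mode <- match.arg(rule_mode)
    k <- countLabelSites(species)$k_labels
    tag <- if (rule_mode == "paper_nominal") {
        .TMT_NOMINAL_TAG
    } else {
        if (is.null(tag_mass))
            stop("exact_tag mode requires an explicit tag_mass", call. = FALSE)
        tag_mass
    }
    M <- formulaMass(species, "monoisotopic")
    list(mz = (M - k * .H_ATOM + k * tag) / k, charge = k)
}

.resolve_panel <- function(panel, registry = oxylipinRegistry()) {
    if (is(panel, "LipidSpecies")) panel <- list(panel)
    if (is.character(panel))
        panel <- lapply(panel, resolveSpecies, registry = registry)
    if (!length(panel) || !all(vapply(panel, is, logical(1), "LipidSpecies")))
        stop("panel must be a non-empty list of species or species names",
             call. = FALSE)
    panel
}

.species_identity <- function(sp) {
    if (is.na(sp@carbons)) paste0("OXY:", tolower(speciesName(sp)))
    else sprintf("%s(%d:%d)", lipidClass(sp), sp@carbons, sp@doubleBonds)
}

.dedup_panel <- function(panel) {
    ids <- vapply(panel, .species_identity, character(1))
    dup <- duplicated(ids)
    if (any(dup)) {
        warning("duplicate panel entries dropped: ",
                paste(vapply(panel[dup], speciesName, character(1)),
                      collapse = ", "), call. = FALSE)
        panel <- panel[!dup]
    }
    panel
}

.transition_list <- function(df, metadata = list()) {
    rownames(df) <- NULL
    new("TransitionList", transitions = df[.TRANSITION_COLS],
        metadata = metadata)
}

#' Build the sixplex TMT transition list
#'
#' For every labelable species, one SRM transition per reporter channel:
#' all six share the species' TMT precursor (isobaric tags give identical
#' precursor m/z across channels) and differ only in the reporter product
#' ion.  Unlabelable species (LPC/LPE/DAG) are skipped with a warning;
#' duplicate panel entries are deduplicated with a warning.  Emitted m/z
#' are rounded to 2 decimals.
#'
#' @param panel Character vector of names or list of
#'   [LipidSpecies-class] objects.
#' @param channels Channel design from [tmtChannels()].
#' @param collision_energy Collision energy in eV (method default 46).
#' @param rule_mode,tag_mass Passed to [tmtPrecursor()].
#' @param registry Formula registry for name resolution.
#' @return A [TransitionList-class]; ordering is species then channel.
#' @examples
#' tl <- buildSixplexTransitions("FA(20:4)")
#' transitionTable(tl)
#' @export
buildSixplexTransitions <- function(panel, channels = tmtChannels(),
                                    collision_energy = 46,
                                    rule_mode = c("paper_nominal", "exact_tag"),
                                    tag_mass = NULL,
                                    registry = oxylipinRegistry()) {
    rule_mode <- match.arg(rule_mode)
    if (anyDuplicated(channels$label))
        stop("duplicate channel labels", call. = FALSE)
    if (nrow(channels) < 1L || nrow(channels) > 6L)
        stop("1 to 6 channels required", call. = FALSE)
    panel <- .dedup_panel(.resolve_panel(panel, registry))
    rows <- list()
    skipped <- character()
    for (sp in panel) {
        if (labelSites(sp) < 1L) {
            skipped <- c(skipped, speciesName(sp))
            next
        }
        prec <- tmtPrecursor(sp, rule_mode, tag_mass)
        rows[[length(rows) + 1L]] <- data.frame(
            species = speciesName(sp),
            precursor_mz = round(prec$mz, 2),
            charge = prec$charge,
            polarity = "positive",
            product_mz = channels$reporter_mz,
            channel = channels$label,
            collision_energy = collision_energy,
            stringsAsFactors = FALSE)
    }
    if (length(skipped))
        warning("skipped unlabelable species: ",
                paste(skipped, collapse = ", "), call. = FALSE)
    if (!length(rows))
        stop("no labelable species in panel", call. = FALSE)
    .transition_list(do.call(rbind, rows), metadata = list(
        mode = "tmt", rule_mode = rule_mode,
        tag_mass = if (rule_mode == "exact_tag") tag_mass else .TMT_NOMINAL_TAG,
        collision_energy = collision_energy,
        skipped = skipped))
}

## Native (underivatized) SRM settings stored verbatim from the method:
## instrument-tuned Q1/Q3 values, not derivable from formulas to the last
## digit.  Matched on (class, total carbons, total double bonds).
.NATIVE_STORED <- data.frame(
    class = c("LPC", "LPE", "DAG", "LPA", "LPA", "PA"),
    carbons = c(16L, 18L, 36L, 16L, 18L, 36L),
    dbonds  = c(0L, 1L, 2L, 0L, 1L, 2L),
    q1 = c(496.35, 480.3, 636.6, 409.4, 435.4, 699.6),
    q3 = c(184.1, 339.3, 339.3, 153.1, 153.1, 153.1),
    polarity = c("positive", "positive", "positive",
                 "negative", "negative", "negative"),
    stringsAsFactors = FALSE)

#' Computed native SRM rule for lyso-phospholipids
#'
#' The computation path behind [buildNativeTransitions()] for species not
#' covered by the stored instrument settings.  LPC: Q1 is the protonated
#' molecule `[M+H]+` and Q3 the protonated phosphocholine head-group
#' fragment cation (C5H15NO4P+).  LPE: Q1 is `[M+H]+` and Q3 the neutral
#' loss of phosphoethanolamine (C2H8NO4P, 141.0191 Da).  Values are
#' returned unrounded.
#'
#' @param species A [LipidSpecies-class] of class LPC or LPE.
#' @return list with `q1`, `q3`, `polarity`.
#' @examples
#' r <- nativeSrmRule(parseLipidShorthand("LPE(18:1)"))
#' round(r$q1, 1)  # 480.3
#' round(r$q3, 1)  # 339.3
#' @export
nativeSrmRule <- function(species) {
    stopifnot(is(species, "LipidSpecies"))
    cls <- lipidClass(species)
    M <- formulaMass(species, "monoisotopic")
    proton <- massConstants()[["proton"]]
    q1 <- M + proton
    q3 <- switch(cls,
        LPC = phosphocholineFragmentMz(),
        LPE = q1 - .PHOSPHOETHANOLAMINE_LOSS,
        stop(errorCondition(
            paste0("no computed native SRM rule for class ", cls),
            class = c("lipidTMT_no_native_rule", "error", "condition"))))
    list(q1 = q1, q3 = q3, polarity = "positive")
}

#' Phosphocholine fragment cation m/z
#'
#' Monoisotopic m/z of the protonated phosphocholine head-group fragment
#' C5H15NO4P+ (the diagnostic product ion of choline phospholipids),
#' computed from element masses with the electron mass removed.
#'
#' @return m/z (unrounded; 184.07).
#' @export
phosphocholineFragmentMz <- function() {
    formulaMass(parseFormula("C5H15NO4P")) - massConstants()[["electron"]]
}

## Adduct-rule Q1 expected for a native (underivatized) species, used by
## validateTransitions(): [M+H]+ for LPC/LPE, [M+NH4]+ for DAG, [M-H]- for
## acidic classes.
.expected_native_q1 <- function(species) {
    M <- formulaMass(species, "monoisotopic")
    k <- massConstants()
    switch(lipidClass(species),
        LPC = ,
        LPE = M + k[["proton"]],
        DAG = M + formulaMass(parseFormula("NH4")) - k[["electron"]],
        M - .H_ATOM + k[["electron"]])
}

#' Build the native (non-labeled) SRM transition list
#'
#' Species covered by the stored instrument method (LPC(16:0), LPE(18:1),
#' DAG(18:1/18:1), LPA(16:0), LPA(18:1), PA(36:2)) get their Q1/Q3 emitted
#' verbatim.  Novel LPC/LPE species are computed via [nativeSrmRule()]
#' (Q1 rounded to 2 decimals; LPC Q3 to 1 decimal as in the stored method).
#' Any other uncovered species raises `lipidTMT_no_native_rule`.  A
#' validation note is attached (metadata `notes`) whenever the stored and
#' the adduct-rule computed Q1 differ by more than 0.3 m/z.
#'
#' @inheritParams buildSixplexTransitions
#' @return A [TransitionList-class] with `channel = NA` (native mode).
#' @examples
#' tl <- buildNativeTransitions(c("LPE(18:1)", "LPA(16:0)"))
#' transitionTable(tl)
#' @export
buildNativeTransitions <- function(panel, registry = oxylipinRegistry()) {
    panel <- .dedup_panel(.resolve_panel(panel, registry))
    rows <- list(); notes <- list()
    for (sp in panel) {
        cls <- lipidClass(sp)
        hit <- which(.NATIVE_STORED$class == cls &
                     .NATIVE_STORED$carbons == sp@carbons &
                     .NATIVE_STORED$dbonds == sp@doubleBonds)
        if (length(hit)) {
            st <- .NATIVE_STORED[hit[1L], ]
            q1 <- st$q1; q3 <- st$q3; pol <- st$polarity; src <- "stored"
        } else {
            r <- nativeSrmRule(sp)   # errors for classes without a rule
            q1 <- round(r$q1, 2)
            q3 <- if (cls == "LPC") round(r$q3, 1) else round(r$q3, 2)
            pol <- r$polarity; src <- "computed"
        }
        delta <- q1 - .expected_native_q1(sp)
        if (abs(delta) > 0.3)
            notes[[length(notes) + 1L]] <- sprintf(
                "%s: stored Q1 %.2f differs from adduct-rule Q1 %.2f by %.2f m/z",
                speciesName(sp), q1, .expected_native_q1(sp), delta)
        rows[[length(rows) + 1L]] <- data.frame(
            species = speciesName(sp), precursor_mz = q1, charge = 1L,
            polarity = pol, product_mz = q3, channel = NA_character_,
            collision_energy = NA_real_, source = src,
            stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    .transition_list(df, metadata = list(mode = "native",
                                         source = df$source,
                                         notes = unlist(notes)))
}

#' Transition table and size of a TransitionList
#'
#' @param tl A [TransitionList-class].
#' @return `transitionTable()` the transitions data.frame;
#'   `methodMetadata()` the metadata list.
#' @export
transitionTable <- function(tl) {
    stopifnot(is(tl, "TransitionList"))
    tl@transitions
}

#' @rdname transitionTable
#' @export
methodMetadata <- function(tl) tl@metadata

#' @rdname transitionTable
#' @param x A [TransitionList-class].
#' @export
setMethod("length", "TransitionList", function(x) nrow(x@transitions))

setMethod("show", "TransitionList", function(object) {
    tr <- object@transitions
    cat(sprintf("TransitionList (%s mode): %d transitions, %d species\n",
                if (is.null(object@metadata$mode)) "?" else object@metadata$mode,
                nrow(tr), length(unique(tr$species))))
    if (nrow(tr)) print(utils::head(tr, 8L))
    if (nrow(tr) > 8L) cat("... and", nrow(tr) - 8L, "more rows\n")
    if (length(object@metadata$notes))
        cat("notes:\n ", paste(object@metadata$notes, collapse = "\n  "), "\n")
})

#' Cross-check emitted precursors against formula arithmetic
#'
#' Recomputes every transition's precursor m/z from the species' molecular
#' formula (the TMT labeling rule for reporter transitions, the standard
#' adduct rules for native ones) and flags entries whose stored value
#' deviates by more than `tolerance`.  Never mutates the list; the stored
#' native LPA/PA/DAG values are instrument-tuned, so deviations there are
#' expected and reported, not errors.
#'
#' @param tl A [TransitionList-class].
#' @param tolerance Allowed |computed - stored| in m/z units (> 0).
#' @inheritParams buildSixplexTransitions
#' @return data.frame: species, channel, stored_mz, computed_mz, delta,
#'   flagged; attribute `"tolerance"`.
#' @export
validateTransitions <- function(tl, tolerance = 0.01,
                                registry = oxylipinRegistry()) {
    stopifnot(is(tl, "TransitionList"), tolerance > 0)
    tr <- transitionTable(tl)
    md <- methodMetadata(tl)
    sp_names <- unique(tr$species)
    species <- lapply(sp_names, resolveSpecies, registry = registry)
    names(species) <- sp_names
    computed <- vapply(seq_len(nrow(tr)), function(i) {
        sp <- species[[tr$species[i]]]
        if (!is.na(tr$channel[i])) {
            rule <- if (is.null(md$rule_mode)) "paper_nominal" else md$rule_mode
            tmtPrecursor(sp, rule, md$tag_mass)$mz
        } else {
            .expected_native_q1(sp)
        }
    }, numeric(1))
    out <- data.frame(species = tr$species, channel = tr$channel,
                      stored_mz = tr$precursor_mz,
                      computed_mz = computed,
                      delta = tr$precursor_mz - computed,
                      stringsAsFactors = FALSE)
    out$flagged <- abs(out$delta) > tolerance
    attr(out, "tolerance") <- tolerance
    out
}

#' Write / read a transition list CSV
#'
#' The on-disk format has exactly the columns
#' `species,precursor_mz,charge,polarity,product_mz,channel,collision_energy`;
#' the round trip is lossless.  A tab-separated export with identical
#' columns is available via `format = "tsv"`.
#'
#' @param tl A [TransitionList-class].
#' @param path Destination / source file.
#' @param format `"csv"` (default) or `"tsv"`.
#' @return `readTransitionList()` returns a [TransitionList-class].
#' @export
writeTransitionList <- function(tl, path, format = c("csv", "tsv")) {
    format <- match.arg(format)
    tr <- transitionTable(tl)
    if (!nrow(tr)) stop("refusing to write an empty transition list",
                        call. = FALSE)
    sep <- if (format == "csv") "," else "\t"
    utils::write.table(tr, path, sep = sep, row.names = FALSE,
                       col.names = TRUE, qmethod = "double", na = "")
    invisible(path)
}

#' @rdname writeTransitionList
#' @export
readTransitionList <- function(path, format = c("csv", "tsv")) {
    format <- match.arg(format)
    sep <- if (format == "csv") "," else "\t"
    raw <- utils::read.table(path, sep = sep, header = TRUE,
                             colClasses = "character",
                             stringsAsFactors = FALSE, na.strings = NULL)
    if (!identical(names(raw), .TRANSITION_COLS))
        stop("transition CSV header must be exactly: ",
             paste(.TRANSITION_COLS, collapse = ","), call. = FALSE)
    num <- function(col, integer = FALSE) {
        x <- raw[[col]]
        x[!nzchar(x)] <- NA
        v <- suppressWarnings(if (integer) as.integer(x) else as.numeric(x))
        bad <- which(!is.na(x) & is.na(v))
        if (length(bad))
            stop("malformed value in column ", sQuote(col), " at file line ",
                 bad[1L] + 1L, call. = FALSE)
        v
    }
    df <- data.frame(species = raw$species,
                     precursor_mz = num("precursor_mz"),
                     charge = num("charge", integer = TRUE),
                     polarity = raw$polarity,
                     product_mz = num("product_mz"),
                     channel = ifelse(nzchar(raw$channel), raw$channel,
                                      NA_character_),
                     collision_energy = num("collision_energy"),
                     stringsAsFactors = FALSE)
    .transition_list(df, metadata = list(
        mode = if (all(is.na(df$channel))) "native" else "tmt",
        source_file = path))
}
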