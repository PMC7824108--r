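test_that("label-site counting follows the derivatization chemistry", {
    expect_identical(countLabelSites(parseLipidShorthand("FA(20:4)")),
                     list(k_labels = 1L, site_types = "carboxy"))
    expect_identical(
        countLabelSites(parseLipidShorthand("LPA(18:1)"))$site_types,
        "phospho_monoester")
    expect_identical(
        countLabelSites(registryLookup("20-carboxy-LTB4"))$k_labels, 2L)
    expect_error(countLabelSites(parseLipidShorthand("LPC(16:0)")),
                 class = "lipidTMT_not_labelable")
})

test_that("TMT precursor rule reproduces the singly and doubly labeled ions", {
    p <- tmtPrecursor(parseLipidShorthand("FA(20:4)"))
    expect_equal(round(p$mz, 2), 606.48)
    expect_identical(p$charge, 1L)
    p <- tmtPrecursor(parseLipidShorthand("LPA(18:1)"))
    expect_equal(round(p$mz, 2), 738.50)
    p2 <- tmtPrecursor(registryLookup("20-carboxy-LTB4"))
    expect_equal(round(p2$mz, 2), 485.34)
    expect_identical(p2$charge, 2L)  # divalent, doubly labeled
    ## exact-tag mode never substitutes silently
    expect_error(tmtPrecursor(parseLipidShorthand("FA(20:4)"),
                              rule_mode = "exact_tag"), "tag_mass")
    pa <- tmtPrecursor(parseLipidShorthand("FA(20:4)"))
    pe <- tmtPrecursor(parseLipidShorthand("FA(20:4)"),
                       rule_mode = "exact_tag", tag_mass = 303.2512)
    expect_equal(pe$mz - pa$mz, 303.2512 - 303.25, tolerance = 1e-9)
})

test_that("sixplex builder emits one isobaric transition per channel", {
    tl <- buildSixplexTransitions("FA(20:4)")
    tr <- transitionTable(tl)
    expect_identical(nrow(tr), 6L)
    expect_true(all(tr$precursor_mz == 606.48))
    expect_equal(tr$product_mz, 126.15 + 0:5)
    expect_identical(tr$channel, as.character(126:131))
    expect_true(all(tr$polarity == "positive"))
    expect_true(all(tr$collision_energy == 46))
})

test_that("unlabelable species are skipped and duplicates deduplicated", {
    expect_warning(tl <- buildSixplexTransitions(c("FA(20:4)", "LPC(16:0)")),
                   "unlabelable")
    expect_identical(length(tl), 6L)
    expect_warning(tl2 <- buildSixplexTransitions(lpaPaPanel()),
                   "duplicate")
    expect_identical(length(tl2), 78L)  # 13 unique labelable species x 6
    expect_error(suppressWarnings(buildSixplexTransitions("LPC(16:0)")),
                 "no labelable")
    badch <- tmtChannels()
    badch$label[2] <- "126"
    expect_error(buildSixplexTransitions("FA(20:4)", channels = badch),
                 "duplicate channel")
})

test_that("precursor m/z increases with carbon number at fixed saturation", {
    for (cls in c("FA(%d:0)", "LPA(%d:0)", "PA(%d:2)")) {
        mz <- vapply(seq(14, 24, 2), function(c_)
            tmtPrecursor(parseLipidShorthand(sprintf(cls, c_)))$mz,
            numeric(1))
        expect_true(all(diff(mz) > 0))
    }
})

test_that("native builder reproduces the stored instrument method", {
    tl <- buildNativeTransitions(c("LPC(16:0)", "LPE(18:1)",
                                   "DAG(18:1/18:1)", "LPA(16:0)",
                                   "LPA(18:1)", "PA(36:2)"))
    tr <- transitionTable(tl)
    expect_identical(nrow(tr), 6L)
    row <- function(sp) tr[tr$species == sp, ]
    expect_equal(row("LPE(18:1)")$precursor_mz, 480.3)
    expect_equal(row("LPE(18:1)")$product_mz, 339.3)
    expect_identical(row("LPE(18:1)")$polarity, "positive")
    expect_equal(row("LPC(16:0)")$precursor_mz, 496.35)
    expect_equal(row("LPC(16:0)")$product_mz, 184.1)
    expect_equal(row("LPA(16:0)")$precursor_mz, 409.4)
    expect_equal(row("LPA(16:0)")$product_mz, 153.1)
    expect_identical(row("LPA(16:0)")$polarity, "negative")
    expect_equal(row("PA(36:2)")$precursor_mz, 699.6)
    expect_true(all(is.na(tr$channel)))
    ## DAG stored Q1 deviates from any computed adduct: flagged in notes
    expect_match(paste(methodMetadata(tl)$notes, collapse = " "),
                 "DAG\\(18:1/18:1\\)")
})

test_that("novel lyso-species are computed from formula rules", {
    tr <- transitionTable(buildNativeTransitions("LPE(18:0)"))
    expect_equal(tr$precursor_mz, 482.32)
    expect_equal(tr$product_mz, 341.31)
    tr2 <- transitionTable(buildNativeTransitions("LPC(18:1)"))
    expect_equal(tr2$product_mz, 184.1)
    expect_error(buildNativeTransitions("FA(18:0)"),
                 class = "lipidTMT_no_native_rule")
})

test_that("transition validation flags only instrument-tuned deviations", {
    six <- suppressWarnings(buildSixplexTransitions(lpaPaPanel()))
    v <- validateTransitions(six, tolerance = 0.01)
    expect_false(any(v$flagged))
    nat <- buildNativeTransitions(c("LPC(16:0)", "DAG(18:1/18:1)"))
    v2 <- validateTransitions(nat, tolerance = 0.3)
    expect_true(v2$flagged[v2$species == "DAG(18:1/18:1)"])
    expect_false(v2$flagged[v2$species == "LPC(16:0)"])
    ## computed [M+NH4]+ for the DAG is 638.57
    expect_equal(round(v2$computed_mz[v2$species == "DAG(18:1/18:1)"], 2),
                 638.57)
})

test_that("transition list CSV round trip is lossless", {
    tl <- suppressWarnings(buildSixplexTransitions(lpaPaPanel()))
    csv <- withr::local_tempfile(fileext = ".csv")
    writeTransitionList(tl, csv)
    expect_identical(length(readLines(csv)), 79L)  # header + 78 rows
    back <- readTransitionList(csv)
    expect_identical(transitionTable(back), transitionTable(tl))

    nat <- buildNativeTransitions(c("LPE(18:1)", "LPA(16:0)"))
    tsv <- withr::local_tempfile(fileext = ".tsv")
    writeTransitionList(nat, tsv, format = "tsv")
    expect_identical(transitionTable(readTransitionList(tsv, "tsv")),
                     transitionTable(nat))
})

test_that("malformed transition CSVs are rejected with a location", {
    csv <- withr::local_tempfile(fileext = ".csv")
    tl <- buildSixplexTransitions("FA(20:4)")
    tr <- transitionTable(tl)
    utils::write.csv(tr[setdiff(names(tr), "charge")], csv,
                     row.names = FALSE)
    expect_error(readTransitionList(csv), "header must be exactly")
    writeTransitionList(tl, csv)
    lines <- readLines(csv)
    lines[3] <- sub("606.48", "oops", lines[3], fixed = TRUE)
    writeLines(lines, csv)
    expect_error(readTransitionList(csv), "line 3")
})
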