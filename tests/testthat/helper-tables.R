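## Small hand-built fixtures used across quant/qc tests.

## One set, one species, six channels with bridge on "126".
manual_areas <- function(areas = c(10, 20, 40, 10, 30, 50),
                         set_id = "s1", species = "FA(20:4)",
                         replicate = 1L, condition = NULL, time_h = 0) {
    labels <- as.character(126:131)[seq_along(areas)]
    if (is.null(condition))
        condition <- c("QC", "A", "B", "C", "D", "E")[seq_along(areas)]
    areaTable(data.frame(
        set_id = set_id, species = species, channel_label = labels,
        replicate = replicate, condition = condition, time_h = time_h,
        area = areas, stringsAsFactors = FALSE))
}

sixplex_design <- function() tmtChannels(bridging = "126")

## Random Hill formulas over the supported elements for property tests.
random_formula <- function() {
    elems <- sample(c("C", "H", "N", "O", "P", "S"), sample(1:4, 1))
    chemicalFormula(stats::setNames(sample(1:40, length(elems),
                                           replace = TRUE), elems))
}
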