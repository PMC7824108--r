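#' Sixplex TMT channel design
#'
#' The six reporter channels of the sixplex TMT reagent set.  At the unit
#' resolution of a triple quadrupole the reporters are monitored at
#' 126.15-131.15, spaced by exactly 1.00; exact-mass reporters can be
#' supplied via `reporters`.  Exactly one channel per set plays the
#' bridging role: the pooled QC sample shared across sets against which
#' all quantities are expressed.
#'
#' @param bridging Label of the bridging channel (default `"126"`).
#' @param labels Channel labels (default `"126"`..`"131"`).
#' @param reporters Reporter product-ion m/z values, one per label.
#' @param conditions Optional condition name per channel (e.g. disease
#'   groups for the sample channels, `"QC"` for the bridge).
#' @return data.frame with columns `label`, `reporter_mz`, `role` and,
#'   if supplied, `condition`.
#' @examples
#' tmtChannels()
#' @export
tmtChannels <- function(bridging = "126",
                        labels = as.character(126:131),
                        reporters = 126.15 + seq_along(labels) - 1,
                        conditions = NULL) {
    if (anyDuplicated(labels))
        stop("duplicate channel labels", call. = FALSE)
    if (length(reporters) != length(labels))
        stop("one reporter m/z per channel label required", call. = FALSE)
    if (!bridging %in% labels)
        stop("bridging channel ", sQuote(bridging), " not among labels",
             call. = FALSE)
    ch <- data.frame(label = as.character(labels),
                     reporter_mz = as.numeric(reporters),
                     role = ifelse(labels == bridging, "bridging", "sample"),
                     stringsAsFactors = FALSE)
    if (!is.null(conditions)) {
        if (length(conditions) != nrow(ch))
            stop("one condition per channel required", call. = FALSE)
        ch$condition <- as.character(conditions)
    }
    ch
}

.check_channel_design <- function(design) {
    need <- c("label", "role")
    if (!is.data.frame(design) || !all(need %in% names(design)))
        stop("channel design needs columns label, role", call. = FALSE)
    if (anyDuplicated(design$label))
        stop("duplicate channel labels in design", call. = FALSE)
    nb <- sum(design$role == "bridging")
    if (nb != 1L)
        stop(errorCondition(
            sprintf("channel design must have exactly one bridging channel (found %d)", nb),
            class = c("lipidTMT_design_error", "error", "condition")))
    invisible(design)
}
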