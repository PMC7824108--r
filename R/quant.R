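#' Construct an AreaTable
#'
#' @param data data.frame with columns `set_id`, `species`,
#'   `channel_label`, `replicate`, `condition`, `time_h`, `area` (extra
#'   columns are preserved).
#' @return An [AreaTable-class].
#' @export
areaTable <- function(data) {
    d <- as.data.frame(data, stringsAsFactors = FALSE)
    miss <- setdiff(.AREA_COLS, names(d))
    if (length(miss))
        stop("area table missing column(s): ", paste(miss, collapse = ", "),
             call. = FALSE)
    d$set_id <- as.character(d$set_id)
    d$species <- as.character(d$species)
    d$channel_label <- as.character(d$channel_label)
    d$replicate <- as.integer(d$replicate)
    d$condition <- as.character(d$condition)
    d$time_h <- as.numeric(d$time_h)
    d$area <- as.numeric(d$area)
    rownames(d) <- NULL
    new("AreaTable", data = d)
}

#' Read a reporter-area CSV
#'
#' Long-format areas as exported by SRM peak-integration software.
#' Negative areas are rejected; blank area cells become missing values
#' with a warning.
#'
#' @param path CSV with header
#'   `set_id,species,channel,replicate,condition,time_h,area` (the column
#'   `channel` is accepted as an alias of `channel_label`).
#' @param design Optional channel design ([tmtChannels()]); if given,
#'   channel labels in the file are checked against it.
#' @return An [AreaTable-class].
#' @export
readAreaTable <- function(path, design = NULL) {
    d <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
    if ("channel" %in% names(d) && !"channel_label" %in% names(d))
        names(d)[names(d) == "channel"] <- "channel_label"
    miss <- setdiff(.AREA_COLS, names(d))
    if (length(miss))
        stop("area CSV missing column(s): ", paste(miss, collapse = ", "),
             call. = FALSE)
    if (any(d$area < 0, na.rm = TRUE))
        stop("negative area value(s) in ", path, call. = FALSE)
    if (anyNA(d$area))
        warning(sum(is.na(d$area)), " blank area cell(s) read as missing",
                call. = FALSE)
    if (!is.null(design)) {
        .check_channel_design(design)
        bad <- setdiff(unique(d$channel_label), design$label)
        if (length(bad))
            stop("channel label(s) not in design: ",
                 paste(bad, collapse = ", "), call. = FALSE)
    }
    areaTable(d)
}

#' AreaTable data accessor
#'
#' @param x An [AreaTable-class].
#' @return The underlying long-format data.frame.
#' @export
areaData <- function(x) {
    stopifnot(is(x, "AreaTable"))
    x@data
}

#' @rdname areaData
#' @export
writeAreaTable <- function(x, path) {
    utils::write.csv(areaData(x), path, row.names = FALSE, na = "")
    invisible(path)
}

setMethod("show", "AreaTable", function(object) {
    d <- object@data
    cat(sprintf(
        "AreaTable: %d records | %d set(s), %d species, %d channel(s), %d replicate level(s)\n",
        nrow(d), length(unique(d$set_id)), length(unique(d$species)),
        length(unique(d$channel_label)), length(unique(d$replicate))))
    if (nrow(d)) print(utils::head(d, 6L))
})

#' Bridging-channel normalization
#'
#' Divides every reporter area by the bridging-channel area of its own
#' (set, species, replicate) group: `ratio = area[channel] / area[bridge]`.
#' Because the bridging sample (pooled QC) is common to every set, the
#' resulting ratios are comparable across sets by construction - any
#' per-set scale factor (injection amount, instrument response drift)
#' cancels exactly.  Groups whose bridging area is missing or zero yield
#' missing ratios for all channels of that group, with a warning; they are
#' never imputed.
#'
#' @param a An [AreaTable-class].
#' @param design Channel design with columns `label`, `role`
#'   (one `"bridging"` row), e.g. from [tmtChannels()].
#' @return data.frame (RatioTable): the AreaTable keys and annotations
#'   plus `ratio_to_bridge`.  The bridging channel's own ratio is 1
#'   wherever defined.
#' @export
bridgeNormalize <- function(a, design) {
    .check_channel_design(design)
    d <- areaData(a)
    bridge <- design$label[design$role == "bridging"]
    grp <- paste(d$set_id, d$species, d$replicate, sep = "\r")
    is_bridge <- d$channel_label == bridge
    if (!all(grp %in% grp[is_bridge]))
        stop(errorCondition(
            "some (set, species, replicate) groups lack a bridging-channel record",
            class = c("lipidTMT_design_error", "error", "condition")))
    bridge_area <- d$area[is_bridge][match(grp, grp[is_bridge])]
    invalid <- is.na(bridge_area) | bridge_area == 0
    if (any(invalid))
        warning(length(unique(grp[invalid])),
                " group(s) with missing or zero bridging area; ",
                "their ratios are set to missing", call. = FALSE)
    ratio <- ifelse(invalid, NA_real_, d$area / bridge_area)
    out <- d[setdiff(names(d), "area")]
    out$ratio_to_bridge <- ratio
    rownames(out) <- NULL
    out
}

#' Fold change versus a reference condition/time
#'
#' Expresses each measurement relative to the per-species mean of the
#' reference cells (e.g. pooled QC serum with no incubation).  In
#' `"bridge"` mode the input is a RatioTable from [bridgeNormalize()] and
#' the computation is invariant to per-set scale factors.  In `"raw"` mode
#' areas are used directly; this reproduces a relative-to-0h construction
#' across separate runs but assumes cross-run response stability, which
#' bridging normalization exists to avoid - a caveat is messaged.
#'
#' @param data RatioTable (bridge mode) or [AreaTable-class] (raw mode).
#' @param reference list or vector with `condition` and `time_h` naming
#'   the reference cells.
#' @param mode `"bridge"` (default) or `"raw"`.
#' @return data.frame (FoldChangeTable): keys plus `fold_change`.  Species
#'   with no usable reference cell are dropped with a warning.  Missing
#'   input values propagate to missing fold changes.
#' @export
relativeToReference <- function(data, reference, mode = c("bridge", "raw")) {
    mode <- match.arg(mode)
    if (mode == "bridge") {
        if (is(data, "AreaTable"))
            stop("bridge mode expects a RatioTable from bridgeNormalize()",
                 call. = FALSE)
        d <- as.data.frame(data)
        if (!"ratio_to_bridge" %in% names(d))
            stop("bridge mode needs a ratio_to_bridge column", call. = FALSE)
        value <- d$ratio_to_bridge
    } else {
        d <- if (is(data, "AreaTable")) areaData(data) else as.data.frame(data)
        if (!"area" %in% names(d))
            stop("raw mode needs an area column", call. = FALSE)
        message("raw mode assumes cross-run response stability; ",
                "per-set scale factors do NOT cancel")
        value <- d$area
    }
    ref <- as.list(reference)
    if (is.null(ref$condition) || is.null(ref$time_h))
        stop("reference must supply condition and time_h", call. = FALSE)
    in_ref <- d$condition == ref$condition &
        abs(d$time_h - as.numeric(ref$time_h)) < 1e-9
    if (!any(in_ref))
        stop("no records match the reference (", ref$condition, ", ",
             ref$time_h, " h)", call. = FALSE)
    ref_mean <- tapply(value[in_ref], d$species[in_ref], mean, na.rm = TRUE)
    ref_mean[is.nan(ref_mean)] <- NA_real_
    denom <- ref_mean[d$species]
    dropped <- unique(d$species[is.na(denom)])
    if (length(dropped))
        warning("species without usable reference dropped: ",
                paste(dropped, collapse = ", "), call. = FALSE)
    keep <- !is.na(denom)
    out <- d[keep, intersect(c("set_id", "species", "channel_label",
                               "replicate", "condition", "time_h"),
                             names(d))]
    out$fold_change <- as.numeric(value[keep] / denom[keep])
    rownames(out) <- NULL
    out
}

#' Replicate summary of fold changes
#'
#' Per (species, condition, time): mean, standard error of the mean
#' (sd with n-1 denominator over sqrt(n); missing when n = 1) and the
#' number of non-missing replicates.
#'
#' @param f FoldChangeTable from [relativeToReference()].
#' @return data.frame: species, condition, time_h, n, mean_fold, sem.
#' @examples
#' # replicates {2,4,6} summarize to mean 4, SEM 2/sqrt(3)
#' @export
aggregateReplicates <- function(f) {
    d <- as.data.frame(f)
    stopifnot(all(c("species", "condition", "time_h", "fold_change")
                  %in% names(d)))
    key <- interaction(d$species, d$condition, d$time_h, drop = TRUE)
    pieces <- lapply(split(d, key), function(g) {
        x <- g$fold_change[!is.na(g$fold_change)]
        n <- length(x)
        data.frame(species = g$species[1L], condition = g$condition[1L],
                   time_h = g$time_h[1L], n = n,
                   mean_fold = if (n) mean(x) else NA_real_,
                   sem = if (n > 1L) stats::sd(x) / sqrt(n) else NA_real_,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, pieces)
    out <- out[order(out$species, out$condition, out$time_h), ]
    rownames(out) <- NULL
    out
}
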