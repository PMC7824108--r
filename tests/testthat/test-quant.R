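test_that("area CSVs are read, typed and validated", {
    csv <- withr::local_tempfile(fileext = ".csv")
    grid <- expand.grid(channel = as.character(126:131),
                        species = c("FA(20:4)", "LPA(18:1)"),
                        replicate = 1:3, stringsAsFactors = FALSE)
    grid$set_id <- "s1"
    grid$condition <- "QC"
    grid$time_h <- 0
    grid$area <- seq_len(nrow(grid)) * 10
    utils::write.csv(grid, csv, row.names = FALSE)
    a <- readAreaTable(csv, design = sixplex_design())
    expect_identical(nrow(areaData(a)), 36L)  # 1 set x 2 species x 6 x 3

    grid2 <- grid; grid2$area[5] <- NA
    utils::write.csv(grid2, csv, row.names = FALSE)
    expect_warning(a2 <- readAreaTable(csv), "missing")
    expect_identical(sum(is.na(areaData(a2)$area)), 1L)

    grid3 <- grid; grid3$area[1] <- -5
    utils::write.csv(grid3, csv, row.names = FALSE)
    expect_error(readAreaTable(csv), "negative")

    grid4 <- grid; grid4$channel[1] <- "999"
    utils::write.csv(grid4, csv, row.names = FALSE)
    expect_error(readAreaTable(csv, design = sixplex_design()),
                 "not in design")
})

test_that("duplicate (set, species, channel, replicate) keys are rejected", {
    d <- areaData(manual_areas())
    expect_error(areaTable(rbind(d, d[1, ])), "duplicate")
})

test_that("bridging normalization is ratio-to-bridge by definition", {
    r <- bridgeNormalize(manual_areas(c(10, 20, 40, 10, 30, 50)),
                         sixplex_design())
    expect_equal(r$ratio_to_bridge, c(1, 2, 4, 1, 3, 5))
    ## per-set scale factors cancel exactly
    r2 <- bridgeNormalize(manual_areas(c(10, 20, 40, 10, 30, 50) * 7.3),
                          sixplex_design())
    expect_equal(r2$ratio_to_bridge, r$ratio_to_bridge)
})

test_that("batch effects of any magnitude cancel to machine precision", {
    set.seed(42)
    base <- c(10, 20, 40, 10, 30, 50)
    ref <- bridgeNormalize(manual_areas(base), sixplex_design())
    for (i in 1:20) {
        k <- stats::runif(1, 0.1, 10) * 10^sample(-1:1, 1)  # spans > 100x
        r <- bridgeNormalize(manual_areas(base * k), sixplex_design())
        expect_equal(r$ratio_to_bridge, ref$ratio_to_bridge,
                     tolerance = 1e-12)
    }
})

test_that("missing or zero bridge areas invalidate the group, not the run", {
    a <- manual_areas(c(0, 20, 40, 10, 30, 50))
    expect_warning(r <- bridgeNormalize(a, sixplex_design()),
                   "zero bridging")
    expect_true(all(is.na(r$ratio_to_bridge)))
    ## a design without a bridging channel is unusable
    d <- sixplex_design(); d$role <- "sample"
    expect_error(bridgeNormalize(manual_areas(), d),
                 class = "lipidTMT_design_error")
    ## missing bridging record violates the contract
    a2 <- areaTable(areaData(manual_areas())[-1, ])
    expect_error(bridgeNormalize(a2, sixplex_design()),
                 class = "lipidTMT_design_error")
})

test_that("fold change versus reference behaves like a ratio of means", {
    ## reference replicates at ratio 1, sample at 2 -> fold 2
    d <- rbind(
        data.frame(set_id = paste0("s", 1:3), species = "X",
                   channel_label = "127", replicate = 1:3,
                   condition = "QC", time_h = 0,
                   ratio_to_bridge = 1),
        data.frame(set_id = "s4", species = "X", channel_label = "127",
                   replicate = 1L, condition = "disease", time_h = 20,
                   ratio_to_bridge = 2))
    fc <- relativeToReference(d, list(condition = "QC", time_h = 0))
    expect_equal(fc$fold_change[fc$condition == "disease"], 2)
    ## the reference itself maps to fold 1 on average
    expect_equal(mean(fc$fold_change[fc$condition == "QC"]), 1)
    ## missing ratios propagate, never fabricated
    d$ratio_to_bridge[4] <- NA
    fc2 <- relativeToReference(d, list(condition = "QC", time_h = 0))
    expect_true(is.na(fc2$fold_change[fc2$condition == "disease"]))
})

test_that("species without a usable reference are flagged and excluded", {
    d <- data.frame(set_id = "s1", species = c("X", "Y"),
                    channel_label = "127", replicate = 1L,
                    condition = c("QC", "disease"), time_h = 0,
                    ratio_to_bridge = c(1, 2))
    expect_warning(fc <- relativeToReference(
        d, list(condition = "QC", time_h = 0)), "without usable reference")
    expect_identical(unique(fc$species), "X")
})

test_that("bridge mode is set-scale invariant; raw mode is not", {
    sim <- simulateSixplex(simulationConfig(
        c("FA(20:4)", "TXB2"), times = c(0, 20), replicates = 2,
        set_effect_sigma = 1.0, channel_bias_sigma = 0, noise_sigma = 0,
        true_fold = data.frame(species = "FA(20:4)",
                               condition = "Stroke", time_h = 20,
                               fold = 2),
        seed = 9))
    ref <- list(condition = "QC", time_h = 0)
    ch <- simulationConfig("x", seed = 1)$channels
    fc_b <- relativeToReference(bridgeNormalize(sim$areas, ch), ref)
    expect_equal(
        fc_b$fold_change[fc_b$species == "FA(20:4)" &
                         fc_b$condition == "Stroke" & fc_b$time_h == 20],
        rep(2, 2), tolerance = 1e-12)
    ## raw mode inherits the per-set scale factors
    fc_r <- suppressMessages(suppressWarnings(
        relativeToReference(sim$areas, ref, mode = "raw")))
    raw_est <- fc_r$fold_change[fc_r$species == "FA(20:4)" &
                                fc_r$condition == "Stroke" &
                                fc_r$time_h == 20]
    expect_gt(max(abs(raw_est - 2)), 0.05)
})

test_that("replicate aggregation reports mean, SEM and n", {
    f <- data.frame(species = "X", condition = "c", time_h = 0,
                    replicate = 1:3, fold_change = c(2, 4, 6))
    s <- aggregateReplicates(f)
    expect_equal(s$mean_fold, 4)
    expect_equal(s$sem, 2 / sqrt(3), tolerance = 1e-6)
    expect_identical(s$n, 3L)
    s1 <- aggregateReplicates(f[1, ])
    expect_true(is.na(s1$sem))
    f$fold_change <- 1
    expect_equal(aggregateReplicates(f)$sem, 0)
})
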