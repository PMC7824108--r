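test_that("simulation is deterministic under its seed", {
    cfg <- simulationConfig(c("FA(20:4)", "TXB2"), seed = 42)
    s1 <- simulateSixplex(cfg)
    s2 <- simulateSixplex(cfg)
    expect_identical(areaData(s1$areas), areaData(s2$areas))
    expect_identical(s1$truth, s2$truth)
    s3 <- simulateSixplex(simulationConfig(c("FA(20:4)", "TXB2"),
                                           seed = 43))
    expect_false(identical(areaData(s1$areas), areaData(s3$areas)))
})

test_that("with all sigmas zero and unit folds, areas are constant per species", {
    sim <- simulateSixplex(simulationConfig(
        c("A", "B"), set_effect_sigma = 0, channel_bias_sigma = 0,
        noise_sigma = 0, baseline_log_sigma = 0.5, seed = 1))
    d <- areaData(sim$areas)
    per_species_sd <- tapply(d$area, d$species, stats::sd)
    expect_true(all(per_species_sd == 0))
})

test_that("bridge normalization recovers truth exactly when noise is zero", {
    tf <- data.frame(species = c("A", "A", "B"),
                     condition = c("Alzheimer", "Stroke", "Parkinson"),
                     time_h = c(0, 20, 20), fold = c(0.25, 4, 0.5))
    cfg <- simulationConfig(c("A", "B"), true_fold = tf,
                            set_effect_sigma = 1.0,
                            channel_bias_sigma = 0, noise_sigma = 0,
                            seed = 2)
    sim <- simulateSixplex(cfg)
    r <- bridgeNormalize(sim$areas, cfg$channels)
    expect_equal(r$ratio_to_bridge, sim$truth$true_fold, tolerance = 1e-12)
})

test_that("dilution simulator obeys the design and the analytic CV", {
    sim <- simulateDilutionSeries(sprintf("sp%d", 1:9),
                                  design = dilutionDesign(
                                      matrix = "serum", replicates = 3),
                                  noise_sigma = 0, seed = 4)
    expect_identical(nrow(areaData(sim$areas)), 135L)  # 9 x 5 x 3
    rep0 <- qcReport(sim$areas, dilutionDesign(matrix = "serum"))
    expect_equal(qcLinearity(rep0)$r, rep(1, 9), tolerance = 1e-12)

    ## lognormal sigma 0.05 has closed-form CV 100*sqrt(exp(s^2)-1) ~ 5.0%
    sig <- 0.05
    sim2 <- simulateDilutionSeries(sprintf("sp%d", 1:5),
                                   design = dilutionDesign(
                                       matrix = "serum", replicates = 200),
                                   noise_sigma = sig, seed = 5)
    rep2 <- qcReport(sim2$areas, dilutionDesign(matrix = "serum"))
    analytic <- 100 * sqrt(exp(sig^2) - 1)
    expect_equal(stats::median(qcCV(rep2)$cv_percent), analytic,
                 tolerance = 0.1)  # relative; Monte-Carlo slack
    ## separate noise per matrix
    sim3 <- simulateDilutionSeries("sp1", design = dilutionDesign(
        matrix = c("buffer", "serum"), replicates = 50),
        noise_sigma = c(buffer = 0.2, serum = 0.02), seed = 6)
    rep3 <- qcReport(sim3$areas, dilutionDesign(matrix = c("buffer",
                                                           "serum")))
    cvs <- tapply(qcCV(rep3)$cv_percent, qcCV(rep3)$matrix, stats::median)
    expect_gt(cvs[["buffer"]], cvs[["serum"]])
})

test_that("recovery metrics are exact under zero noise and reject bad keys", {
    tf <- data.frame(species = "A", condition = "Stroke", time_h = 20,
                     fold = 0.5)
    cfg <- simulationConfig(c("A", "B"), true_fold = tf,
                            set_effect_sigma = 0.7,
                            channel_bias_sigma = 0, noise_sigma = 0,
                            seed = 3)
    sim <- simulateSixplex(cfg)
    fc <- relativeToReference(bridgeNormalize(sim$areas, cfg$channels),
                              list(condition = "QC", time_h = 0))
    m <- recoveryMetrics(fc, sim$truth)
    expect_equal(m$rmse, c(0, 0), tolerance = 1e-12)
    expect_equal(m$max_abs_error, c(0, 0), tolerance = 1e-12)
    ## truth lacking keys present in the estimates is rejected
    bad <- sim$truth[sim$truth$condition != "Stroke", ]
    expect_error(recoveryMetrics(fc, bad), "missing from ground truth")
    ## and truth with conflicting folds for one key is rejected too
    clash <- sim$truth
    clash$species <- "Z"
    expect_error(recoveryMetrics(fc, clash), "conflicting")
})

test_that("estimates stay unbiased under measurement noise (Monte Carlo)", {
    set.seed(77)
    n_sp <- 200L
    species <- sprintf("sp%03d", seq_len(n_sp))
    conds <- c("Alzheimer", "Parkinson", "Depression", "Schizophrenia",
               "Stroke")
    tf <- expand.grid(species = species, condition = conds,
                      stringsAsFactors = FALSE)
    tf$time_h <- 0
    tf$fold <- stats::runif(nrow(tf), 0.25, 4)
    cfg <- simulationConfig(species, times = 0, replicates = 3,
                            true_fold = tf, set_effect_sigma = 0.5,
                            channel_bias_sigma = 0, noise_sigma = 0.1,
                            seed = 78)
    sim <- simulateSixplex(cfg)
    fc <- relativeToReference(bridgeNormalize(sim$areas, cfg$channels),
                              list(condition = "QC", time_h = 0))
    m <- recoveryMetrics(fc, sim$truth)
    expect_identical(nrow(m), n_sp)
    ## true folds span 0.25-4x, so the scale-free (relative) bias is the
    ## meaningful unbiasedness measure
    expect_lt(stats::median(abs(m$rel_bias)), 0.05)
})
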