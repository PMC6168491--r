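test_that("generators are fully determined by their seed", {
    expect_identical(peaks(makeApoPeakList(30, seed = 4)),
                     peaks(makeApoPeakList(30, seed = 4)))
    apo <- makeApoPeakList(30, seed = 4)
    sc <- tet1MutantScenario(seed = 8)
    s1 <- makeComplexSeries(apo, sc); s2 <- makeComplexSeries(apo, sc)
    expect_identical(lapply(s1$lists, peaks), lapply(s2$lists, peaks))
    expect_identical(s1$truth, s2$truth)
    g1 <- renderGrid(apo, noise_sigma = 5, seed = 2)
    g2 <- renderGrid(apo, noise_sigma = 5, seed = 2)
    expect_identical(gridIntensities(g1), gridIntensities(g2))
    expect_identical(makeSidAlignment(seed = 6), makeSidAlignment(seed = 6))
})

test_that("apo lists respect the ppm box and the separation constraint", {
    expect_equal(nPeaks(makeApoPeakList(0, seed = 1)), 0)
    pl <- makeApoPeakList(90, seed = 1)
    pk <- peaks(pl)
    expect_true(all(pk$h_ppm >= 6.5 & pk$h_ppm <= 10.5))
    expect_true(all(pk$n_ppm >= 103 & pk$n_ppm <= 133))
    d <- peak_dist(pl, pl)
    diag(d) <- Inf
    expect_gte(min(d), 0.05)
    expect_true(all(pk$kind == "backbone_amide"))
    ## an unsatisfiable packing request fails loudly
    expect_error(makeApoPeakList(50, seed = 1, h_range = c(8, 8.05),
                                 n_range = c(120, 120.1),
                                 min_separation = 0.05),
                 "could not place")
})

test_that("a zero multiplier with zero jitter reproduces the apo spectrum", {
    apo <- makeApoPeakList(40, seed = 2)
    ser <- makeComplexSeries(apo, perturbationScenario(
        effect_multipliers = c(null = 0), jitter_sigma = 0, seed = 3))
    expect_equal(peaks(ser$lists$null)$h_ppm, peaks(apo)$h_ppm)
    expect_equal(peaks(ser$lists$null)$n_ppm, peaks(apo)$n_ppm)
    expect_identical(deltaMin(minimalShiftSummary(ser$lists$apo,
                                                  ser$lists$null)), 0)
})

test_that("the apo-vs-complex shift scales with the planted effect", {
    dm_wt <- c(); dm_mut <- c()
    for (seed in 1:10) {
        apo <- makeApoPeakList(60, seed = seed)
        ser <- makeComplexSeries(apo, perturbationScenario(
            mean_shift = 0.2, effect_multipliers = c(WT = 1, mutA = 0.1),
            jitter_sigma = 0, seed = seed + 50))
        dm_wt <- c(dm_wt, deltaMin(minimalShiftSummary(ser$lists$apo,
                                                       ser$lists$WT)))
        dm_mut <- c(dm_mut, deltaMin(minimalShiftSummary(ser$lists$apo,
                                                         ser$lists$mutA)))
    }
    ## expectation by construction: interface_fraction x mean_shift = 0.06
    expect_equal(mean(dm_wt), 0.06, tolerance = 0.25)
    expect_true(all(dm_wt > dm_mut))
})

test_that("the minimal shift grows monotonically with the planted mean shift", {
    for (seed in 1:3) {
        apo <- makeApoPeakList(60, seed = seed)
        dm <- vapply(c(0.02, 0.05, 0.1, 0.2), function(S) {
            ser <- makeComplexSeries(apo, perturbationScenario(
                mean_shift = S, effect_multipliers = c(WT = 1),
                jitter_sigma = 0, seed = 1000 + seed))
            deltaMin(minimalShiftSummary(ser$lists$apo, ser$lists$WT))
        }, numeric(1))
        expect_true(all(diff(dm) > 0))
    }
})

test_that("with no jitter and small shifts, matching recovers the truth", {
    ## mean_shift well below half the minimum apo separation
    for (seed in 1:5) {
        apo <- makeApoPeakList(50, seed = seed, min_separation = 0.1)
        ser <- makeComplexSeries(apo, perturbationScenario(
            mean_shift = 0.02, effect_multipliers = c(WT = 1),
            jitter_sigma = 0, seed = seed + 20))
        ## truncate rare large Gamma draws by checking the planted shifts
        if (max(ser$truth$true_shift) >= 0.05) next
        mr <- matchPeaks(ser$lists$apo, ser$lists$WT)
        expect_true(all(matchedPairs(mr)$id_a == matchedPairs(mr)$id_b))
    }
})

test_that("rendered grids place peaks where the list says", {
    pl <- peakList(data.frame(id = "p1", h_ppm = 8.0, n_ppm = 120,
                              intensity = 100))
    g <- renderGrid(pl, grid_shape = c(64, 64))
    m <- gridIntensities(g)
    ix <- which(m == max(m), arr.ind = TRUE)
    ax <- gridAxes(g)
    expect_lt(abs(ax$h[ix[2]] - 8.0), diff(ax$h[1:2]) + 1e-12)
    expect_lt(abs(ax$n[ix[1]] - 120), diff(ax$n[1:2]) + 1e-12)
    expect_error(renderGrid(peakList()), "empty")
})

test_that("render -> pick round trip recovers well-separated peaks", {
    apo <- makeApoPeakList(20, seed = 13, min_separation = 0.3)
    pk <- peaks(apo); pk$intensity <- runif(20, 20, 60)
    pl <- peakList(pk)
    g <- renderGrid(pl, noise_sigma = 1, seed = 14)
    picked <- pickPeaks(g, threshold_factor = 5,
                        noise = new("NoiseEstimate", sigma = 1,
                                    method = "known"))
    expect_equal(nPeaks(picked), 20)
})

test_that("noise-only grids yield a small, bounded false-positive rate", {
    ## peaks with missing intensity contribute no signal
    pk <- peaks(makeApoPeakList(10, seed = 15))
    pk$intensity <- NA_real_
    g <- renderGrid(peakList(pk), noise_sigma = 1, seed = 16)
    picked <- pickPeaks(g, threshold_factor = 1.4,
                        noise = new("NoiseEstimate", sigma = 1,
                                    method = "known"))
    ## local maxima above 1.4 sigma arise from noise alone, at the rate
    ## P(X > 1.4 and X > its 8 neighbours) = int_{1.4}^inf phi(x) Phi(x)^8 dx
    ## ~= 5.9% of interior cells for Gaussian noise
    expect_lt(nPeaks(picked) / (254 * 254), 0.08)
    expect_gt(nPeaks(picked), 0)
})
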