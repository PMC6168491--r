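two_lists <- function() {
    list(a = peakList(data.frame(id = c("a1", "a2"),
                                 h_ppm = c(8.00, 8.50),
                                 n_ppm = c(120.00, 115.00))),
         b = peakList(data.frame(id = c("b1", "b2"),
                                 h_ppm = c(8.02, 8.48),
                                 n_ppm = c(120.10, 115.20))))
}

test_that("the weighted distance follows the 7:1 convention", {
    expect_equal(weightedDistance(0, 0), 0)
    expect_equal(weightedDistance(0.1, 0.7), sqrt(0.02))
    expect_equal(weightedDistance(0, 7), 1)
    expect_equal(weightedDistance(0.3, 1.5, n_weight = 5),
                 sqrt(0.09 + 0.09))
    expect_error(weightedDistance(0.1, 0.1, n_weight = 0), "positive")
})

test_that("optimal matching reproduces the enumerated two-peak solution", {
    tl <- two_lists()
    mr <- matchPeaks(tl$a, tl$b)
    expect_equal(matchedPairs(mr)$id_b[match(c("a1", "a2"),
                                             matchedPairs(mr)$id_a)],
                 c("b1", "b2"))
    ## hand-derived: sqrt(0.02^2 + (0.1/7)^2) and sqrt(0.02^2 + (0.2/7)^2)
    expect_equal(matchedPairs(mr)$delta, c(0.0245781, 0.0348759),
                 tolerance = 1e-5)
    s <- minimalShiftSummary(tl$a, tl$b)
    expect_equal(deltaMin(s), 0.0297270, tolerance = 1e-5)
    expect_equal(nMatched(s), 2L)
})

test_that("greedy and optimal modes differ on the classic swap case", {
    a <- peakList(data.frame(id = c("a1", "a2"), h_ppm = c(8.00, 8.10),
                             n_ppm = c(120, 120)))
    b <- peakList(data.frame(id = c("b1", "b2"), h_ppm = c(8.06, 8.20),
                             n_ppm = c(120, 120)))
    gr <- matchPeaks(a, b, mode = "greedy")
    expect_equal(gr@total_distance, 0.24, tolerance = 1e-10)
    expect_equal(matchedPairs(gr)$id_b[matchedPairs(gr)$id_a == "a2"], "b1")
    op <- matchPeaks(a, b, mode = "optimal")
    expect_equal(op@total_distance, 0.16, tolerance = 1e-10)
    expect_equal(matchedPairs(op)$id_b[matchedPairs(op)$id_a == "a1"], "b1")
})

test_that("a spectrum compared with itself has zero minimal shift, exactly", {
    set.seed(5)
    a <- random_peaklist(40)
    s <- minimalShiftSummary(a, a)
    expect_identical(deltaMin(s), 0)
    expect_equal(nMatched(s), 40L)
    expect_true(all(matchedPairs(matchPeaks(a, a))$delta == 0))
})

test_that("optimal matching is symmetric for equal-size lists", {
    set.seed(6)
    for (r in 1:5) {
        a <- random_peaklist(15, "a"); b <- random_peaklist(15, "b")
        expect_equal(deltaMin(minimalShiftSummary(a, b)),
                     deltaMin(minimalShiftSummary(b, a)), tolerance = 1e-10)
    }
})

test_that("optimal matching equals exhaustive enumeration on small lists", {
    set.seed(7)
    for (r in 1:25) {
        n <- sample(2:6, 1)
        a <- random_peaklist(n, "a"); b <- random_peaklist(n, "b")
        op <- matchPeaks(a, b, mode = "optimal")
        expect_equal(op@total_distance, brute_min_total(peak_dist(a, b)),
                     tolerance = 1e-12)
    }
})

test_that("optimal total distance never exceeds greedy total distance", {
    set.seed(8)
    for (r in 1:40) {
        n <- sample(2:9, 1)
        a <- random_peaklist(n, "a"); b <- random_peaklist(n, "b")
        expect_lte(matchPeaks(a, b, mode = "optimal")@total_distance,
                   matchPeaks(a, b, mode = "greedy")@total_distance + 1e-12)
    }
})

test_that("unequal list sizes match min(|A|,|B|) peaks and report the rest", {
    a <- peakList(data.frame(id = paste0("a", 1:3),
                             h_ppm = c(8.0, 8.5, 9.0),
                             n_ppm = c(120, 115, 125)))
    b <- peakList(data.frame(id = paste0("b", 1:2),
                             h_ppm = c(8.01, 8.51), n_ppm = c(120.1, 115.1)))
    s <- minimalShiftSummary(a, b)
    expect_equal(nMatched(s), 2L)
    mr <- matchPeaks(a, b)
    expect_equal(mr@unmatched_a, "a3")
    expect_length(mr@unmatched_b, 0)
    expect_error(matchPeaks(a, peakList()), "empty")
})

test_that("the optional distance gate drops distant pairs after matching", {
    tl <- two_lists()
    mr <- matchPeaks(tl$a, tl$b, max_distance = 0.03)
    expect_equal(nrow(matchedPairs(mr)), 1)
    expect_equal(matchedPairs(mr)$id_a, "a1")
    expect_setequal(mr@unmatched_a, "a2")
    expect_setequal(mr@unmatched_b, "b2")
})

test_that("matched optimal distance never overstates the true perturbation", {
    ## with known ground-truth correspondence (shared ids) and equal sizes,
    ## the optimal total is <= the true-correspondence total
    for (seed in 1:5) {
        apo <- makeApoPeakList(40, seed = seed)
        ser <- makeComplexSeries(apo, perturbationScenario(
            effect_multipliers = c(WT = 1), seed = seed + 100))
        a <- ser$lists$apo; b <- ser$lists$WT
        d <- peak_dist(a, b)
        ib <- match(peaks(a)$id, peaks(b)$id)  # true correspondence
        true_total <- sum(d[cbind(seq_len(nrow(d)), ib)])
        expect_lte(matchPeaks(a, b)@total_distance, true_total + 1e-12)
    }
})

test_that("compareSeries ranks comparisons and guards its labels", {
    apo <- makeApoPeakList(30, seed = 9)
    ser <- makeComplexSeries(apo, perturbationScenario(
        effect_multipliers = c(WT = 1, weak = 0.2), seed = 10))
    tab <- compareSeries(ser$lists$apo,
                         list(self = ser$lists$apo, WT = ser$lists$WT,
                              weak = ser$lists$weak))
    expect_equal(tab$label[tab$rank == 1], "WT")
    expect_lt(tab$delta_min[tab$label == "self"], 1e-12)
    expect_equal(tab$label, tab$label[order(tab$rank)])
    bad <- list(ser$lists$WT, ser$lists$weak)
    expect_error(compareSeries(ser$lists$apo, bad), "labels")
    names(bad) <- c("x", "x")
    expect_error(compareSeries(ser$lists$apo, bad), "labels")
})

test_that("labels with identical planted effects are exchangeable", {
    diffs <- vapply(1:30, function(seed) {
        apo <- makeApoPeakList(50, seed = seed)
        ser <- makeComplexSeries(apo, perturbationScenario(
            effect_multipliers = c(mutX = 0.5, mutY = 0.5),
            seed = seed + 500))
        deltaMin(minimalShiftSummary(ser$lists$apo, ser$lists$mutX)) -
            deltaMin(minimalShiftSummary(ser$lists$apo, ser$lists$mutY))
    }, numeric(1))
    expect_lt(abs(mean(diffs)), 2 * sd(diffs) / sqrt(length(diffs)))
})
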