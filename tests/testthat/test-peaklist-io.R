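test_that("CSV peak lists read back with ids and shifts preserved", {
    f <- tempfile(fileext = ".csv")
    writeLines(c("id,h_ppm,n_ppm,intensity",
                 "p1,8.1234,120.5678,1e5",
                 "p2,7.5000,115.0000,",
                 "p3,9.0001,130.2500,2e4"), f)
    pl <- readPeakList(f, "csv")
    expect_s4_class(pl, "PeakList")
    expect_equal(peaks(pl)$id, c("p1", "p2", "p3"))
    expect_equal(peaks(pl)$h_ppm, c(8.1234, 7.5, 9.0001))
    expect_true(is.na(peaks(pl)$intensity[2]))
    expect_equal(peakMeta(pl)$temperature, 303)
})

test_that("an empty data section yields a valid empty list", {
    f <- tempfile(fileext = ".csv")
    writeLines("id,h_ppm,n_ppm", f)
    expect_equal(nPeaks(readPeakList(f, "csv")), 0)
    g <- tempfile(fileext = ".list")
    writeLines("Assignment w1 w2", g)
    expect_equal(nPeaks(readPeakList(g, "sparky")), 0)
})

test_that("Sparky rows map w1 to 15N and w2 to 1H, with annotation kinds", {
    f <- tempfile(fileext = ".list")
    writeLines(c("Assignment w1 w2 Height",
                 "Q5N-H 115.20 8.31 1.0e5",
                 "N30ND2-HD21 112.80 7.10 5e4",
                 "?-? 125.00 9.20 8e4"), f)
    pl <- readPeakList(f, "sparky")
    pk <- peaks(pl)
    expect_equal(pk$n_ppm[1], 115.20)
    expect_equal(pk$h_ppm[1], 8.31)
    expect_equal(pk$kind, c("backbone_amide", "sidechain_nh2", "unknown"))
    expect_true(is.na(pk$assignment[3]))  # uninformative label, autonumbered id
    ## flipped axis convention
    pl2 <- readPeakList(f, "sparky", axis_order = "hn")
    expect_equal(peaks(pl2)$h_ppm[1], 115.20)
    expect_equal(peaks(pl2)$n_ppm[1], 8.31)
})

test_that("malformed input is rejected with a line number", {
    expect_error(readPeakList(tempfile(), "csv"), "not found")
    f <- tempfile(fileext = ".csv")
    writeLines(c("id,h_ppm,n_ppm", "p1,8.0,120.0", "p2,oops,121.0"), f)
    expect_error(readPeakList(f, "csv"), "line 3")
    g <- tempfile(fileext = ".csv")
    writeLines(c("id,h_ppm,n_ppm", "p1,8.0,120.0", "p1,8.1,121.0"), g)
    expect_error(readPeakList(g, "csv"), "duplicate")
    h <- tempfile(fileext = ".list")
    writeLines(c("Assignment w1 w2", "A5N-H bad 8.2"), h)
    expect_error(readPeakList(h, "sparky"), "line 2")
})

test_that("read/write round trip is the identity to 1e-4 ppm in both dialects", {
    set.seed(7)
    pl <- random_peaklist(80)
    pk <- peaks(pl)
    pk$intensity[seq(1, 80, by = 3)] <- NA  # missing intensities round-trip
    pk$intensity[2] <- 4.2e4
    pl <- peakList(pk, meta = list(label = "roundtrip"))
    for (fmt in c("csv", "sparky")) {
        f <- tempfile()
        writePeakList(pl, f, fmt)
        back <- readPeakList(f, fmt)
        expect_equal(peaks(back)$id, peaks(pl)$id)
        expect_equal(peaks(back)$h_ppm, peaks(pl)$h_ppm, tolerance = 1e-4)
        expect_equal(peaks(back)$n_ppm, peaks(pl)$n_ppm, tolerance = 1e-4)
        expect_equal(is.na(peaks(back)$intensity), is.na(peaks(pl)$intensity))
        ## empty list round trip
        f2 <- tempfile()
        writePeakList(peakList(), f2, fmt)
        expect_equal(nPeaks(readPeakList(f2, fmt)), 0)
    }
})

test_that("flagged NH2 side-chain peaks are excluded", {
    set.seed(1)
    pl <- makeApoPeakList(n = 8, seed = 3, nh2_pairs = 1)
    expect_equal(nPeaks(pl), 10)
    out <- excludeSidechainNH2(pl)
    expect_equal(nPeaks(out), 8)
    expect_true(all(peaks(out)$kind == "backbone_amide"))
    expect_setequal(peakMeta(out)$nh2_removed,
                    peaks(pl)$id[peaks(pl)$kind == "sidechain_nh2"])
})

test_that("the NH2 doublet heuristic removes co-located pairs only", {
    backbone <- data.frame(id = paste0("b", 1:5),
                           h_ppm = c(8.2, 8.6, 9.1, 7.9, 10.0),
                           n_ppm = c(118, 122, 126, 110, 130),
                           kind = "backbone_amide")
    nh2 <- data.frame(id = c("u1", "u2"),
                      h_ppm = c(7.05, 7.62), n_ppm = c(112.30, 112.35),
                      kind = "unknown")
    pl <- peakList(rbind(backbone, nh2))
    expect_equal(nPeaks(excludeSidechainNH2(pl, heuristic = FALSE)), 7)
    out <- excludeSidechainNH2(pl, heuristic = TRUE)
    expect_equal(sort(peaks(out)$id), paste0("b", 1:5))
    ## backbone-annotated peaks are immune even inside the NH2 window
    prot <- peakList(data.frame(id = c("x1", "x2"),
                                h_ppm = c(7.0, 7.5), n_ppm = c(112.0, 112.1),
                                kind = "backbone_amide"))
    expect_equal(nPeaks(excludeSidechainNH2(prot, heuristic = TRUE)), 2)
})

test_that("NH2 exclusion is idempotent", {
    pl <- makeApoPeakList(n = 12, seed = 5, nh2_pairs = 2)
    once <- excludeSidechainNH2(pl, heuristic = TRUE)
    twice <- excludeSidechainNH2(once, heuristic = TRUE)
    expect_equal(peaks(twice), peaks(once))
    expect_setequal(peakMeta(twice)$nh2_removed, peakMeta(once)$nh2_removed)
})

test_that("peaks can be deleted by id", {
    pl <- makeApoPeakList(n = 5, seed = 2)
    out <- removePeaks(pl, c("a002", "a004", "nosuch"))
    expect_equal(peaks(out)$id, c("a001", "a003", "a005"))
})
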