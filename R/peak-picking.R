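## Automatic peak picking of 2D intensity grids at a multiple of the
## robust noise level.

#' Estimate the noise level of a 2D spectrum
#'
#' The noise sigma is the scaled median absolute deviation (MAD, with the
#' usual 1.4826 Gaussian consistency constant) of all grid intensities
#' about their median. The MAD tolerates contamination by real signal, so
#' the estimate is dominated by baseline noise even on crowded spectra.
#'
#' @param grid a [SpectrumGrid-class]
#' @return A [NoiseEstimate-class] with `method = "mad"`.
#' @examples
#' g <- spectrumGrid(matrix(rnorm(100), 10), 1:10, 101:110)
#' noiseSigma(estimateNoise(g))
#' @export
estimateNoise <- function(grid) {
    stopifnot(is(grid, "SpectrumGrid"))
    v <- as.vector(grid@intensities)
    if (!length(v)) stop("empty grid")
    new("NoiseEstimate", sigma = stats::mad(v), method = "mad")
}

#' Pick peaks from a 2D spectrum grid
#'
#' Finds local maxima (strictly greater than their 8 neighbours; on exact
#' plateaus the lowest-index cell wins) whose intensity exceeds
#' `threshold_factor` times the noise sigma, the automatic picking step
#' applied to HSQC spectra before minimal-shift analysis. Border cells
#' lack a full neighbourhood and are never picked. Each apex position is
#' refined by 3-point parabolic interpolation along each axis, clipped to
#' half a grid step; no lineshape fitting is attempted.
#'
#' @param grid a [SpectrumGrid-class], at least 3x3
#' @param threshold_factor multiple of the noise sigma a peak must
#'   exceed; default 1.4, the factor used for automatic picking of the
#'   HSQC spectra this toolkit emulates
#' @param noise optional [NoiseEstimate-class]; computed from the grid
#'   via [estimateNoise()] when missing
#' @return A [PeakList-class] sorted by decreasing intensity, ids
#'   `pk001`, `pk002`, ... assigned in that order.
#' @export
pickPeaks <- function(grid, threshold_factor = 1.4, noise = NULL) {
    stopifnot(is(grid, "SpectrumGrid"))
    if (threshold_factor <= 0) stop("threshold_factor must be > 0")
    m <- grid@intensities
    nr <- nrow(m); nc <- ncol(m)
    if (nr < 3 || nc < 3) stop("grid must be at least 3x3")
    if (is.null(noise)) noise <- estimateNoise(grid)
    stopifnot(is(noise, "NoiseEstimate"))
    thr <- threshold_factor * noise@sigma

    inner_i <- 2:(nr - 1); inner_j <- 2:(nc - 1)
    core <- m[inner_i, inner_j, drop = FALSE]
    ismax <- core > thr
    ## neighbour offsets; a cell survives an exact tie only against
    ## neighbours with a higher column-major linear index
    for (dj in -1:1) for (di in -1:1) {
        if (di == 0 && dj == 0) next
        nb <- m[inner_i + di, inner_j + dj, drop = FALSE]
        lower_index <- dj < 0 || (dj == 0 && di < 0)
        ismax <- ismax & (if (lower_index) core > nb else core >= nb)
    }
    hits <- which(ismax, arr.ind = TRUE)
    if (!nrow(hits))
        return(peakList(meta = list(label = "picked",
                                    threshold_factor = threshold_factor,
                                    noise_sigma = noise@sigma)))
    i <- hits[, 1] + 1L; j <- hits[, 2] + 1L  # back to full-grid indices

    refine <- function(vm, v0, vp) {
        den <- vm - 2 * v0 + vp
        off <- ifelse(abs(den) > 0, 0.5 * (vm - vp) / den, 0)
        pmin(pmax(off, -0.5), 0.5)
    }
    off_n <- refine(m[cbind(i - 1L, j)], m[cbind(i, j)], m[cbind(i + 1L, j)])
    off_h <- refine(m[cbind(i, j - 1L)], m[cbind(i, j)], m[cbind(i, j + 1L)])
    step_n <- (grid@n_axis[i + 1L] - grid@n_axis[i - 1L]) / 2
    step_h <- (grid@h_axis[j + 1L] - grid@h_axis[j - 1L]) / 2
    pk <- data.frame(h_ppm = grid@h_axis[j] + off_h * step_h,
                     n_ppm = grid@n_axis[i] + off_n * step_n,
                     intensity = m[cbind(i, j)],
                     kind = "unknown", stringsAsFactors = FALSE)
    ## deterministic order: intensity desc, then position
    ord <- order(-pk$intensity, pk$n_ppm, pk$h_ppm)
    pk <- pk[ord, , drop = FALSE]
    pk$id <- sprintf("pk%03d", seq_len(nrow(pk)))
    peakList(pk, meta = list(label = "picked",
                             threshold_factor = threshold_factor,
                             noise_sigma = noise@sigma))
}
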