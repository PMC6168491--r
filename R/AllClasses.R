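#' @import methods
NULL

.PEAK_KINDS <- c("backbone_amide", "sidechain_nh2", "unknown")

.emptyPeakFrame <- function() {
    data.frame(id = character(), h_ppm = numeric(), n_ppm = numeric(),
               intensity = numeric(), kind = character(),
               assignment = character(), stringsAsFactors = FALSE)
}

#' PeakList: an annotated collection of 2D amide cross peaks
#'
#' A `PeakList` holds the cross peaks of one 15N-HSQC spectrum: one row per
#' peak with its 1H and 15N chemical shifts (ppm), an optional intensity,
#' a peak kind (`backbone_amide`, `sidechain_nh2` or `unknown`) and an
#' optional residue assignment, together with spectrum-level metadata
#' (label, temperature in K, field strength in MHz, free-text provenance).
#'
#' @slot peaks data.frame with columns `id`, `h_ppm`, `n_ppm`, `intensity`,
#'   `kind`, `assignment`; ids are unique, shifts finite.
#' @slot meta named list of spectrum metadata. `temperature` defaults to
#'   303 K, the condition the toolkit's synthetic spectra emulate.
#' @aliases PeakList
#' @exportClass PeakList
setClass("PeakList", representation(peaks = "data.frame", meta = "list"))

setValidity("PeakList", function(object) {
    pk <- object@peaks
    need <- c("id", "h_ppm", "n_ppm", "intensity", "kind", "assignment")
    if (!all(need %in% names(pk)))
        return(paste("peaks must have columns:", paste(need, collapse = ", ")))
    if (anyDuplicated(pk$id))
        return("peak ids must be unique within a list")
    if (nrow(pk) > 0 && (!all(is.finite(pk$h_ppm)) || !all(is.finite(pk$n_ppm))))
        return("h_ppm and n_ppm must be finite")
    if (!all(pk$kind %in% .PEAK_KINDS))
        return(paste("kind must be one of:", paste(.PEAK_KINDS, collapse = ", ")))
    TRUE
})

#' Construct a PeakList
#'
#' @param peaks data.frame with at least `h_ppm` and `n_ppm`; missing
#'   `id` (autonumbered `p1`, `p2`, ...), `intensity` (NA), `kind`
#'   (`"unknown"`) and `assignment` (NA) columns are filled in.
#' @param meta named list of spectrum metadata; `temperature` defaults to
#'   303 (K).
#' @return A [PeakList-class] object.
#' @examples
#' pl <- peakList(data.frame(h_ppm = c(8.0, 8.5), n_ppm = c(120, 115)))
#' nPeaks(pl)
#' @export
peakList <- function(peaks = .emptyPeakFrame(), meta = list()) {
    peaks <- as.data.frame(peaks, stringsAsFactors = FALSE)
    if (nrow(peaks) > 0 && is.null(peaks$id))
        peaks$id <- paste0("p", seq_len(nrow(peaks)))
    if (is.null(peaks$id)) peaks$id <- character()
    peaks$id <- as.character(peaks$id)
    if (is.null(peaks$intensity)) peaks$intensity <- rep(NA_real_, nrow(peaks))
    if (is.null(peaks$kind)) peaks$kind <- rep("unknown", nrow(peaks))
    if (is.null(peaks$assignment)) peaks$assignment <- rep(NA_character_, nrow(peaks))
    peaks$intensity <- as.numeric(peaks$intensity)
    peaks$kind <- as.character(peaks$kind)
    peaks$assignment <- as.character(peaks$assignment)
    peaks <- peaks[, c("id", "h_ppm", "n_ppm", "intensity", "kind", "assignment")]
    rownames(peaks) <- NULL
    if (is.null(meta$temperature)) meta$temperature <- 303
    new("PeakList", peaks = peaks, meta = meta)
}

#' @describeIn peakList Number of peaks in the list.
#' @param x,object a `PeakList`
#' @export
nPeaks <- function(x) nrow(x@peaks)

#' @describeIn peakList Peak table accessor (data.frame, one row per peak).
#' @export
peaks <- function(x) x@peaks

#' @describeIn peakList Spectrum metadata accessor.
#' @export
peakMeta <- function(x) x@meta

#' @describeIn peakList Remove peaks by id (manual curation of spurious
#'   peaks); unknown ids are ignored.
#' @param ids character vector of peak ids to drop
#' @export
removePeaks <- function(x, ids) {
    stopifnot(is(x, "PeakList"))
    keep <- !(x@peaks$id %in% ids)
    pk <- x@peaks[keep, , drop = FALSE]
    rownames(pk) <- NULL
    initialize(x, peaks = pk)
}

setMethod("show", "PeakList", function(object) {
    lab <- object@meta$label
    cat("PeakList", if (!is.null(lab)) paste0("'", lab, "'") else "",
        "with", nrow(object@peaks), "peaks\n")
    kinds <- table(object@peaks$kind)
    if (length(kinds))
        cat("  kinds:", paste(names(kinds), kinds, sep = "=", collapse = ", "), "\n")
    if (nrow(object@peaks)) {
        cat("  1H range:", paste(round(range(object@peaks$h_ppm), 2), collapse = " - "),
            "ppm; 15N range:",
            paste(round(range(object@peaks$n_ppm), 2), collapse = " - "), "ppm\n")
    }
})

#' SpectrumGrid: a processed 2D spectrum as an intensity matrix
#'
#' Rows follow the 15N axis, columns the 1H axis. Axes are stored strictly
#' increasing in ppm; input in the conventional decreasing-left-to-right
#' plotting order is flipped on construction.
#'
#' @slot intensities numeric matrix (rows = 15N, cols = 1H)
#' @slot h_axis,n_axis strictly increasing ppm coordinates matching the
#'   matrix dimensions
#' @aliases SpectrumGrid
#' @exportClass SpectrumGrid
setClass("SpectrumGrid", representation(intensities = "matrix",
                                        h_axis = "numeric", n_axis = "numeric"))

setValidity("SpectrumGrid", function(object) {
    if (nrow(object@intensities) != length(object@n_axis))
        return("nrow(intensities) must equal length(n_axis)")
    if (ncol(object@intensities) != length(object@h_axis))
        return("ncol(intensities) must equal length(h_axis)")
    if (length(object@h_axis) > 1 && any(diff(object@h_axis) <= 0))
        return("h_axis must be strictly increasing after normalisation")
    if (length(object@n_axis) > 1 && any(diff(object@n_axis) <= 0))
        return("n_axis must be strictly increasing after normalisation")
    TRUE
})

#' Construct a SpectrumGrid
#'
#' @param intensities numeric matrix, rows = 15N axis, cols = 1H axis
#' @param h_axis,n_axis strictly monotone ppm vectors; decreasing axes are
#'   accepted and normalised to increasing order (with the matrix flipped
#'   to match).
#' @return A [SpectrumGrid-class].
#' @export
spectrumGrid <- function(intensities, h_axis, n_axis) {
    intensities <- as.matrix(intensities)
    if (length(h_axis) > 1 && all(diff(h_axis) < 0)) {
        h_axis <- rev(h_axis)
        intensities <- intensities[, rev(seq_len(ncol(intensities))), drop = FALSE]
    }
    if (length(n_axis) > 1 && all(diff(n_axis) < 0)) {
        n_axis <- rev(n_axis)
        intensities <- intensities[rev(seq_len(nrow(intensities))), , drop = FALSE]
    }
    new("SpectrumGrid", intensities = intensities,
        h_axis = as.numeric(h_axis), n_axis = as.numeric(n_axis))
}

#' @describeIn spectrumGrid Intensity matrix accessor.
#' @param x a `SpectrumGrid`
#' @export
gridIntensities <- function(x) x@intensities

#' @describeIn spectrumGrid ppm axes accessor, `list(h = ..., n = ...)`.
#' @export
gridAxes <- function(x) list(h = x@h_axis, n = x@n_axis)

setMethod("show", "SpectrumGrid", function(object) {
    cat("SpectrumGrid", nrow(object@intensities), "x", ncol(object@intensities),
        "(15N x 1H)\n")
    cat("  1H:", round(min(object@h_axis), 2), "-", round(max(object@h_axis), 2),
        "ppm; 15N:", round(min(object@n_axis), 2), "-",
        round(max(object@n_axis), 2), "ppm\n")
})

#' NoiseEstimate: robust spectrum noise level
#'
#' @slot sigma non-negative noise standard deviation (intensity units)
#' @slot method label of the estimator used
#' @aliases NoiseEstimate
#' @exportClass NoiseEstimate
setClass("NoiseEstimate", representation(sigma = "numeric", method = "character"))

setValidity("NoiseEstimate", function(object) {
    if (length(object@sigma) != 1 || is.na(object@sigma) || object@sigma < 0)
        return("sigma must be a single non-negative number")
    TRUE
})

#' @describeIn estimateNoise Noise sigma accessor.
#' @param x a `NoiseEstimate`
#' @export
noiseSigma <- function(x) x@sigma

setMethod("show", "NoiseEstimate", function(object) {
    cat("NoiseEstimate: sigma =", signif(object@sigma, 4),
        paste0("(", object@method, ")\n"))
})

#' MatchResult: one-to-one peak correspondence between two lists
#'
#' @slot pairs data.frame `id_a`, `id_b`, `delta` (weighted ppm distance)
#' @slot unmatched_a,unmatched_b ids left unmatched in either list
#' @slot mode `"optimal"` (exact assignment) or `"greedy"`
#' @slot total_distance sum of pair distances (weighted ppm)
#' @slot n_weight the 15N divisor used
#' @aliases MatchResult
#' @exportClass MatchResult
setClass("MatchResult", representation(pairs = "data.frame",
                                       unmatched_a = "character",
                                       unmatched_b = "character",
                                       mode = "character",
                                       total_distance = "numeric",
                                       n_weight = "numeric"))

setValidity("MatchResult", function(object) {
    if (anyDuplicated(object@pairs$id_a) || anyDuplicated(object@pairs$id_b))
        return("each peak id may appear in at most one pair")
    TRUE
})

#' @describeIn matchPeaks Matched pair table accessor.
#' @export
matchedPairs <- function(x) x@pairs

setMethod("show", "MatchResult", function(object) {
    cat("MatchResult (", object@mode, "): ", nrow(object@pairs), " pairs, ",
        length(object@unmatched_a), "/", length(object@unmatched_b),
        " unmatched (A/B), total distance ",
        signif(object@total_distance, 5), " ppm\n", sep = "")
})

#' MinShiftSummary: the average minimal shift of a spectral comparison
#'
#' @slot delta_min average minimal shift (ppm): summed weighted distance
#'   over all matched peaks divided by the number of matched peaks
#' @slot n_matched number of matched peaks
#' @slot per_peak data.frame `id_a`, `id_b`, `delta` keyed by list-A ids
#' @slot mode matching mode that produced it
#' @aliases MinShiftSummary
#' @exportClass MinShiftSummary
setClass("MinShiftSummary", representation(delta_min = "numeric",
                                           n_matched = "integer",
                                           per_peak = "data.frame",
                                           mode = "character"))

setValidity("MinShiftSummary", function(object) {
    if (object@delta_min < 0) return("delta_min must be non-negative")
    if (object@n_matched > 0 &&
        abs(object@delta_min - sum(object@per_peak$delta) / object@n_matched) > 1e-9)
        return("delta_min must equal mean of per-peak shifts")
    TRUE
})

#' @describeIn minimalShiftSummary Average minimal shift accessor (ppm).
#' @export
deltaMin <- function(x) x@delta_min

#' @describeIn minimalShiftSummary Number of matched peaks.
#' @export
nMatched <- function(x) x@n_matched

setMethod("show", "MinShiftSummary", function(object) {
    cat("MinShiftSummary: delta_min = ", sprintf("%.3f", object@delta_min),
        " ppm over ", object@n_matched, " matched peaks (", object@mode,
        ")\n", sep = "")
})

#' PerturbationScenario: how a synthetic binding experiment perturbs peaks
#'
#' Describes a slow-exchange binding scenario: a fixed fraction of peaks
#' (the interface) moves on complex formation, each by a shared
#' displacement vector whose weighted magnitude is Gamma-distributed;
#' mutant complexes scale that displacement by a per-label multiplier;
#' every list carries isotropic measurement jitter.
#'
#' @slot interface_fraction fraction of peaks perturbed, in `[0, 1]`
#' @slot mean_shift mean weighted displacement magnitude of perturbed
#'   peaks for a multiplier of 1 (ppm)
#' @slot effect_multipliers named non-negative multipliers, one per label
#' @slot jitter_sigma isotropic weighted-space measurement noise (ppm)
#' @slot seed integer; the scenario is fully determined by it
#' @aliases PerturbationScenario
#' @exportClass PerturbationScenario
setClass("PerturbationScenario", representation(interface_fraction = "numeric",
                                                mean_shift = "numeric",
                                                effect_multipliers = "numeric",
                                                jitter_sigma = "numeric",
                                                seed = "integer"))

setValidity("PerturbationScenario", function(object) {
    if (object@interface_fraction < 0 || object@interface_fraction > 1)
        return("interface_fraction must be in [0, 1]")
    if (object@mean_shift < 0) return("mean_shift must be non-negative")
    if (any(object@effect_multipliers < 0))
        return("effect multipliers must be non-negative")
    if (is.null(names(object@effect_multipliers)) ||
        anyDuplicated(names(object@effect_multipliers)))
        return("effect_multipliers must have unique names")
    if (object@jitter_sigma < 0) return("jitter_sigma must be non-negative")
    TRUE
})

setMethod("show", "PerturbationScenario", function(object) {
    cat("PerturbationScenario: interface fraction ", object@interface_fraction,
        ", mean shift ", object@mean_shift, " ppm, jitter ",
        object@jitter_sigma, " ppm, seed ", object@seed, "\n  labels: ",
        paste(names(object@effect_multipliers),
              object@effect_multipliers, sep = "=", collapse = ", "),
        "\n", sep = "")
})

#' StructureModel: one model of a PDB entry plus its helix annotation
#'
#' @slot atoms data.frame `chain`, `resno`, `resid`, `elety`, `x`, `y`, `z`
#'   (coordinates in Angstrom), restricted to one model and to blank/'A'
#'   altlocs
#' @slot model_index which deposited model was read (1 = first member of
#'   an NMR ensemble)
#' @slot helices data.frame `chain`, `start`, `end` in author numbering,
#'   from the file's HELIX records (zero rows when absent)
#' @aliases StructureModel
#' @exportClass StructureModel
setClass("StructureModel", representation(atoms = "data.frame",
                                          model_index = "integer",
                                          helices = "data.frame"))

setValidity("StructureModel", function(object) {
    at <- object@atoms
    if (!all(c("chain", "resno", "resid", "elety", "x", "y", "z") %in% names(at)))
        return("atoms must have chain, resno, resid, elety, x, y, z")
    if (nrow(at) > 0 && !all(is.finite(c(at$x, at$y, at$z))))
        return("coordinates must be finite")
    h <- object@helices
    if (nrow(h) > 0) {
        if (any(h$start > h$end)) return("helix start must be <= end")
        for (ch in unique(h$chain)) {
            seg <- h[h$chain == ch, , drop = FALSE]
            seg <- seg[order(seg$start), , drop = FALSE]
            if (nrow(seg) > 1 && any(seg$start[-1] <= seg$end[-nrow(seg)]))
                return("helix segments must not overlap within a chain")
        }
    }
    TRUE
})

#' @describeIn readStructure Atom table accessor.
#' @export
structureAtoms <- function(x) x@atoms

#' @describeIn readStructure Helix segment accessor (`chain`, `start`,
#'   `end` in author numbering).
#' @export
helixSegments <- function(x) x@helices

setMethod("show", "StructureModel", function(object) {
    cat("StructureModel: model", object@model_index, "with",
        nrow(object@atoms), "atoms,",
        nrow(object@helices), "helix segments\n")
})
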