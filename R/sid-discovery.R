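## Sequence-based discovery of candidate Sin3-interaction domains:
## helical-wheel geometry, Eisenberg hydrophobic moment, hydrophobic-face
## detection, the short/long hydrophobic pair motif, and alignment
## conservation.

.SMALL_HYDROPHOBIC <- c("A", "G", "S", "C")
.LARGE_HYDROPHOBIC <- c("L", "I", "V", "M", "F")

#' Eisenberg consensus hydrophobicity scale
#'
#' The normalised consensus scale of Eisenberg and co-workers, the
#' default scale for hydrophobic-moment and face calculations. Values
#' are (very nearly) zero-mean over the 20 amino acids, so centring the
#' scale — which [hydrophobicMoment()] always does — leaves them
#' essentially unchanged.
#'
#' @return Named numeric vector over the 20 one-letter codes.
#' @export
eisenbergScale <- function() {
    c(A =  0.62, R = -2.53, N = -0.78, D = -0.90, C =  0.29,
      Q = -0.85, E = -0.74, G =  0.48, H = -0.40, I =  1.38,
      L =  1.06, K = -1.50, M =  0.64, F =  1.19, P =  0.12,
      S = -0.18, T = -0.05, W =  0.81, Y =  0.26, V =  1.08)
}

.splitResidues <- function(x) {
    if (is(x, "AAString") || is(x, "AAStringSet")) x <- as.character(x)[1]
    stopifnot(is.character(x), length(x) == 1, nzchar(x))
    res <- strsplit(toupper(x), "")[[1]]
    bad <- setdiff(res, c(names(eisenbergScale()), "X"))
    if (length(bad))
        stop("unknown residue code(s): ", paste(unique(bad), collapse = ", "))
    res
}

## centred scale values for a residue vector; X contributes the scale mean
.scaleValues <- function(res, scale) {
    h <- scale[res]
    h[res == "X"] <- mean(scale)
    unname(h - mean(scale))
}

#' Helical-wheel angles of a sequence window
#'
#' Projects residues onto an ideal alpha-helical wheel: 3.6 residues per
#' turn, i.e. 100 degrees per residue, with the first residue of the
#' window at 0 degrees. Angles depend only on the position within the
#' window, never on residue identity.
#'
#' @param window a one-letter amino-acid string (or `AAString`), or a
#'   single integer giving the window length
#' @return Numeric vector of angles in degrees, in `[0, 360)`.
#' @examples
#' wheelAngles(8)   # 0 100 200 300 40 140 240 340
#' @export
wheelAngles <- function(window) {
    n <- if (is.numeric(window)) as.integer(window)
         else length(.splitResidues(window))
    stopifnot(n >= 1)
    (100 * (seq_len(n) - 1)) %% 360
}

## minimal covering arc (degrees) of a set of wheel angles:
## 360 minus the largest circular gap between adjacent angles
.minimalArc <- function(angles) {
    if (length(angles) <= 1) return(0)
    a <- sort(angles %% 360)
    gaps <- c(diff(a), 360 - a[length(a)] + a[1])
    360 - max(gaps)
}

#' Eisenberg hydrophobic moment of a window
#'
#' The magnitude of the vector sum of per-residue hydrophobicities
#' placed at their helical-wheel angles, divided by the window length.
#' The scale is centred (mean over the 20 amino acids subtracted) before
#' summing, which makes the moment invariant under adding any constant
#' to the scale; `X` contributes the scale mean, i.e. zero after
#' centring. Large values flag amphipathic helices — hydrophobic
#' residues clustered on one face.
#'
#' @param window one-letter amino-acid string (or `AAString`)
#' @param scale named hydrophobicity scale; default [eisenbergScale()]
#' @return The moment per residue (scale units).
#' @export
hydrophobicMoment <- function(window, scale = eisenbergScale()) {
    res <- .splitResidues(window)
    h <- .scaleValues(res, scale)
    th <- wheelAngles(length(res)) * pi / 180
    sqrt(sum(h * cos(th))^2 + sum(h * sin(th))^2) / length(res)
}

#' Detect a coherent hydrophobic face on a helical wheel
#'
#' Collects the window's hydrophobic residues (centred scale value > 0)
#' and computes the minimal covering arc of their wheel angles. If that
#' arc is at most `max_arc` degrees the residues form one coherent face
#' — the geometry that lets a SID helix present its hydrophobics to the
#' PAH cleft — otherwise no face is reported.
#'
#' @inheritParams hydrophobicMoment
#' @param max_arc widest arc (degrees) still counted as one face;
#'   default 180
#' @param start residue number of the first window position, used to
#'   label face residues; default 1
#' @return List with `face` (residue numbers on the face; empty when no
#'   coherent face), `face_arc` (degrees, the minimal covering arc of
#'   the hydrophobic residues), and `coherent` (logical).
#' @export
hydrophobicFace <- function(window, scale = eisenbergScale(),
                            max_arc = 180, start = 1) {
    res <- .splitResidues(window)
    if (length(res) < 2) stop("window must have at least 2 residues")
    h <- .scaleValues(res, scale)
    hyd <- which(h > 0)
    if (!length(hyd))
        return(list(face = integer(0), face_arc = NA_real_, coherent = FALSE))
    arc <- .minimalArc(wheelAngles(length(res))[hyd])
    coherent <- arc <= max_arc
    list(face = if (coherent) start + hyd - 1L else integer(0),
         face_arc = arc, coherent = coherent)
}

#' Short/long hydrophobic pair motif
#'
#' Tests a window for the SID lock-and-key signature: a pair of short
#' hydrophobic side chains (A, G, S, C) at offsets `i` and `i + 3`
#' followed by a pair of long hydrophobic side chains (L, I, V, M, F) at
#' `i + 4` and `i + 7` — the arrangement the Tet1-SID realises as
#' A893/A896 plus L897/L900. On a helical wheel these four positions lie
#' on one face, stacking short against long side chains in the PAH
#' cleft.
#'
#' @param window one-letter amino-acid string of at least 8 residues
#' @return List with `match` (logical) and `anchor` (1-based window
#'   position of the first matching `i`, or `NA`).
#' @export
sidMotifMatch <- function(window) {
    res <- .splitResidues(window)
    if (length(res) < 8) stop("window must have at least 8 residues")
    for (i in seq_len(length(res) - 7)) {
        if (res[i] %in% .SMALL_HYDROPHOBIC &&
            res[i + 3] %in% .SMALL_HYDROPHOBIC &&
            res[i + 4] %in% .LARGE_HYDROPHOBIC &&
            res[i + 7] %in% .LARGE_HYDROPHOBIC)
            return(list(match = TRUE, anchor = i))
    }
    list(match = FALSE, anchor = NA_integer_)
}

.msaMatrix <- function(msa) {
    if (is(msa, "AAMultipleAlignment")) msa <- as(msa, "AAStringSet")
    if (is(msa, "AAStringSet") || is(msa, "BStringSet"))
        msa <- as.character(msa)
    stopifnot(is.character(msa), length(msa) >= 2)
    if (length(unique(nchar(msa))) != 1)
        stop("ragged alignment: all rows must have equal length")
    do.call(rbind, strsplit(toupper(msa), ""))
}

#' Per-column conservation of a multiple alignment
#'
#' Scores each column as `1 - H / log(21)` where `H` is the Shannon
#' entropy of the observed symbol frequencies over the 20 amino acids
#' plus the gap character as a 21st symbol. Identical columns score 1,
#' a column uniform over all 21 symbols scores 0. The score is
#' permutation-invariant across rows.
#'
#' @param msa aligned sequences: character vector, `AAStringSet` or
#'   `AAMultipleAlignment`, all rows of equal length, at least 2 rows
#' @return Numeric vector of per-column scores in `[0, 1]`.
#' @export
columnConservation <- function(msa) {
    m <- .msaMatrix(msa)
    apply(m, 2, function(col) {
        p <- table(col) / length(col)
        H <- -sum(p * log(p))
        1 - H / log(21)
    })
}

#' Scan a sequence for candidate Sin3-interaction domains
#'
#' Slides a window of `window_length` residues along the sequence and
#' scores each window by a weighted sum of its z-scored hydrophobic
#' moment, its z-scored mean alignment conservation (when an MSA is
#' supplied) and a bonus when the short/long hydrophobic pair motif is
#' present. Both continuous terms are z-scored across the scan's windows
#' so they compete on a common scale; a raw conservation term, bounded
#' in `[0, 1]`, would be swamped by moment outliers such as
#' charge-clustered windows. The raw mean conservation is still reported
#' per window. The
#' default window of 11 residues matches the length of the minimal SID
#' this toolkit was built around; moment-based helicity scoring stands
#' in for an external secondary-structure predictor.
#'
#' @param sequence one-letter amino-acid string, `AAString`, or a
#'   single-entry `AAStringSet` (e.g. from
#'   [Biostrings::readAAStringSet()]); when missing and `msa` is given,
#'   the degapped first alignment row is scanned
#' @param msa optional aligned set whose first row is the (gapped)
#'   scanned sequence; conservation is averaged over each window's
#'   columns
#' @param window_length window size in residues, default 11
#' @param scale hydrophobicity scale, default [eisenbergScale()]
#' @param weights named weights `moment`, `conservation`, `motif`
#'   combined as `w["moment"] * z(mu_h) + w["conservation"] * z(cons) +
#'   w["motif"] * motif`; default all 1
#' @param max_arc face coherence limit (degrees), default 180
#' @return data.frame ranked by decreasing combined score: `start`,
#'   `end`, `residues`, `mu_h`, `face_arc`, `n_face`, `motif`,
#'   `conservation`, `combined`, `rank`.
#' @export
scanSID <- function(sequence = NULL, msa = NULL, window_length = 11,
                    scale = eisenbergScale(),
                    weights = c(moment = 1, conservation = 1, motif = 1),
                    max_arc = 180) {
    stopifnot(window_length >= 8)
    colmap <- NULL
    cons_cols <- NULL
    if (!is.null(msa)) {
        m <- .msaMatrix(msa)
        cons_cols <- columnConservation(msa)
        row1 <- m[1, ]
        keep <- row1 != "-"
        seq_from_msa <- paste(row1[keep], collapse = "")
        colmap <- which(keep)  # sequence position -> alignment column
        if (is.null(sequence)) sequence <- seq_from_msa
        else if (paste(.splitResidues(sequence), collapse = "") != seq_from_msa)
            stop("'sequence' does not match the degapped first MSA row")
    }
    res <- .splitResidues(sequence)
    n <- length(res)
    if (n <= window_length)
        stop("sequence must be longer than window_length")
    starts <- seq_len(n - window_length + 1)
    win <- vapply(starts, function(s)
        paste(res[s:(s + window_length - 1)], collapse = ""), character(1))
    mu <- vapply(win, hydrophobicMoment, numeric(1), scale = scale,
                 USE.NAMES = FALSE)
    faces <- lapply(win, hydrophobicFace, scale = scale, max_arc = max_arc)
    motif <- vapply(win, function(w) sidMotifMatch(w)$match, logical(1),
                    USE.NAMES = FALSE)
    cons <- if (is.null(cons_cols)) rep(NA_real_, length(starts))
            else vapply(starts, function(s)
                mean(cons_cols[colmap[s:(s + window_length - 1)]]), numeric(1))
    zscore <- function(v) {
        if (length(v) > 1 && stats::sd(v) > 0) (v - mean(v)) / stats::sd(v)
        else rep(0, length(v))
    }
    combined <- weights[["moment"]] * zscore(mu) +
        (if (is.null(cons_cols)) 0
         else weights[["conservation"]] * zscore(cons)) +
        weights[["motif"]] * as.numeric(motif)
    out <- data.frame(start = starts, end = starts + window_length - 1,
                      residues = win,
                      mu_h = mu,
                      face_arc = vapply(faces, function(f) f$face_arc,
                                        numeric(1)),
                      n_face = vapply(faces, function(f) length(f$face),
                                      integer(1)),
                      motif = motif,
                      conservation = cons,
                      combined = combined,
                      stringsAsFactors = FALSE)
    out$rank <- rank(-out$combined, ties.method = "first")
    out <- out[order(out$rank), , drop = FALSE]
    rownames(out) <- NULL
    out
}
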