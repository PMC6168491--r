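## Minimal chemical-shift mapping: 7:1-weighted distances, minimal-distance
## peak matching (exact assignment or greedy), and the per-comparison
## average minimal shift.

#' Weighted 1H/15N chemical-shift distance
#'
#' The combined shift distance with the common 7:1 1H:15N weighting:
#' `sqrt(dh^2 + (dn / n_weight)^2)`. Scaling the 15N difference by 1/7
#' makes it commensurate with the 1H difference.
#'
#' @param dh 1H shift difference (ppm); vectorised
#' @param dn 15N shift difference (ppm); vectorised
#' @param n_weight positive divisor applied to `dn`; default 7
#' @return Weighted distance in ppm.
#' @examples
#' weightedDistance(0.1, 0.7)        # sqrt(0.01 + 0.01)
#' weightedDistance(0, 7)            # 1
#' @export
weightedDistance <- function(dh, dn, n_weight = 7) {
    if (!is.numeric(n_weight) || length(n_weight) != 1 || n_weight <= 0)
        stop("n_weight must be a single positive number")
    sqrt(dh^2 + (dn / n_weight)^2)
}

## Exact rectangular assignment by shortest augmenting paths
## (Jonker-Volgenant / Hungarian with potentials). Returns, for each row
## of the cost matrix, the column it is assigned to; requires
## nrow <= ncol (callers transpose). O(n^2 m) with vectorised inner loop,
## comfortably fast for the <=100-peak lists this package handles.
.solveAssignment <- function(cost) {
    n <- nrow(cost); m <- ncol(cost)
    stopifnot(n <= m, all(is.finite(cost)))
    u <- numeric(n + 1L)          # row potentials, index i+1 (0 = virtual)
    v <- numeric(m + 1L)          # column potentials, index j+1
    p <- integer(m + 1L)          # p[j+1]: row assigned to column j
    way <- integer(m + 1L)
    cols <- seq_len(m)
    for (i in seq_len(n)) {
        p[1L] <- i
        j0 <- 0L
        minv <- rep(Inf, m)
        used <- logical(m + 1L)
        repeat {
            used[j0 + 1L] <- TRUE
            i0 <- p[j0 + 1L]
            free <- cols[!used[cols + 1L]]
            cur <- cost[i0, free] - u[i0 + 1L] - v[free + 1L]
            upd <- cur < minv[free]
            if (any(upd)) {
                minv[free[upd]] <- cur[upd]
                way[free[upd] + 1L] <- j0
            }
            k <- which.min(minv[free])
            j1 <- free[k]
            delta <- minv[j1]
            usedc <- c(0L, cols[used[cols + 1L]])
            u[p[usedc + 1L] + 1L] <- u[p[usedc + 1L] + 1L] + delta
            v[usedc + 1L] <- v[usedc + 1L] - delta
            minv[free] <- minv[free] - delta
            j0 <- j1
            if (p[j0 + 1L] == 0L) break
        }
        repeat {
            j1 <- way[j0 + 1L]
            p[j0 + 1L] <- p[j1 + 1L]
            j0 <- j1
            if (j0 == 0L) break
        }
    }
    assignment <- integer(n)
    for (j in cols) if (p[j + 1L] > 0L) assignment[p[j + 1L]] <- j
    assignment
}

.peakCost <- function(a, b, n_weight) {
    outer(a$h_ppm, b$h_ppm, "-")^2 +
        (outer(a$n_ppm, b$n_ppm, "-") / n_weight)^2
}

#' Match peaks between two lists by minimal distance
#'
#' Establishes a one-to-one correspondence of size `min(|A|, |B|)`
#' between the peaks of two spectra using the weighted distance of
#' [weightedDistance()]. Two modes are provided because "minimal
#' distance" admits both readings:
#' \describe{
#'   \item{optimal}{the exact assignment-problem solution minimising the
#'     total weighted distance over all one-to-one matchings
#'     (Jonker-Volgenant shortest augmenting paths); the default.}
#'   \item{greedy}{repeatedly pairs the globally closest unmatched pair;
#'     exact-distance ties broken lexicographically by `(id_a, id_b)`.}
#' }
#' If `max_distance` is set, pairs farther apart than it are dropped
#' after matching and their peaks reported as unmatched; no gate is
#' applied by default.
#'
#' @param a,b [PeakList-class] objects (non-empty; NH2 exclusion, if
#'   wanted, is applied beforehand via [excludeSidechainNH2()])
#' @param n_weight 15N weighting divisor, default 7
#' @param mode `"optimal"` or `"greedy"`
#' @param max_distance optional gate (weighted ppm)
#' @return A [MatchResult-class].
#' @export
matchPeaks <- function(a, b, n_weight = 7, mode = c("optimal", "greedy"),
                       max_distance = NULL) {
    stopifnot(is(a, "PeakList"), is(b, "PeakList"))
    mode <- match.arg(mode)
    pa <- a@peaks; pb <- b@peaks
    if (!nrow(pa) || !nrow(pb)) stop("cannot match an empty peak list")
    if (!all(is.finite(c(pa$h_ppm, pa$n_ppm, pb$h_ppm, pb$n_ppm))))
        stop("non-finite chemical shifts")
    d <- sqrt(.peakCost(pa, pb, n_weight))  # weighted distances

    if (mode == "optimal") {
        ## the objective is the total (unsquared) weighted distance
        if (nrow(pa) <= nrow(pb)) {
            asg <- .solveAssignment(d)
            ia <- seq_len(nrow(pa)); ib <- asg
        } else {
            asg <- .solveAssignment(t(d))
            ib <- seq_len(nrow(pb)); ia <- asg
        }
    } else {
        ## greedy: global closest pair first, lexicographic id tie-break
        ri_all <- as.vector(row(d)); ci_all <- as.vector(col(d))
        ord <- order(d, pa$id[ri_all], pb$id[ci_all])
        used_a <- logical(nrow(pa)); used_b <- logical(nrow(pb))
        ia <- integer(0); ib <- integer(0)
        nmatch <- min(nrow(pa), nrow(pb))
        for (k in ord) {
            ri <- ri_all[k]; ci <- ci_all[k]
            if (!used_a[ri] && !used_b[ci]) {
                used_a[ri] <- TRUE; used_b[ci] <- TRUE
                ia <- c(ia, ri); ib <- c(ib, ci)
                if (length(ia) == nmatch) break
            }
        }
    }
    delta <- d[cbind(ia, ib)]
    keep <- if (is.null(max_distance)) rep(TRUE, length(delta))
            else delta <= max_distance
    pairs <- data.frame(id_a = pa$id[ia[keep]], id_b = pb$id[ib[keep]],
                        delta = delta[keep], stringsAsFactors = FALSE)
    new("MatchResult", pairs = pairs,
        unmatched_a = setdiff(pa$id, pairs$id_a),
        unmatched_b = setdiff(pb$id, pairs$id_b),
        mode = mode, total_distance = sum(pairs$delta),
        n_weight = n_weight)
}

#' Average minimal shift between two spectra
#'
#' The per-comparison statistic of minimal chemical-shift mapping: peaks
#' are matched by [matchPeaks()] and the average minimal shift is the
#' summed weighted distance over all matched peaks divided by the number
#' of matched peaks. With unequal list sizes only `min(|A|, |B|)` peaks
#' are matched; unmatched peaks never enter the average.
#'
#' @inheritParams matchPeaks
#' @return A [MinShiftSummary-class]; per-peak shifts are keyed by
#'   list-A ids.
#' @export
minimalShiftSummary <- function(a, b, n_weight = 7,
                                mode = c("optimal", "greedy"),
                                max_distance = NULL) {
    mode <- match.arg(mode)
    mr <- matchPeaks(a, b, n_weight = n_weight, mode = mode,
                     max_distance = max_distance)
    n <- nrow(mr@pairs)
    new("MinShiftSummary",
        delta_min = if (n) sum(mr@pairs$delta) / n else 0,
        n_matched = as.integer(n),
        per_peak = mr@pairs, mode = mode)
}

#' Compare a series of spectra against one reference
#'
#' Computes the average minimal shift of each labelled peak list against
#' a common reference and ranks the comparisons by decreasing shift.
#' Both conventions of a mutant-series analysis are covered by the
#' choice of reference: complexes against the apo spectrum (magnitude of
#' the binding effect) or mutant complexes against the wild-type complex
#' (importance of the mutated residue for complex formation).
#'
#' @param reference a [PeakList-class]
#' @param others named list of [PeakList-class] objects; names must be
#'   unique labels
#' @inheritParams matchPeaks
#' @return data.frame with columns `label`, `delta_min`, `n_matched`,
#'   `mode`, `rank` (1 = largest shift), ordered by rank.
#' @export
compareSeries <- function(reference, others, n_weight = 7,
                          mode = c("optimal", "greedy"),
                          max_distance = NULL) {
    mode <- match.arg(mode)
    stopifnot(is(reference, "PeakList"), is.list(others), length(others) > 0)
    labels <- names(others)
    if (is.null(labels) || any(!nzchar(labels)) || anyDuplicated(labels))
        stop("'others' must be a list with unique non-empty labels")
    rows <- lapply(labels, function(lb) {
        s <- minimalShiftSummary(reference, others[[lb]], n_weight = n_weight,
                                 mode = mode, max_distance = max_distance)
        data.frame(label = lb, delta_min = s@delta_min,
                   n_matched = s@n_matched, mode = mode,
                   stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$rank <- rank(-tab$delta_min, ties.method = "first")
    tab <- tab[order(tab$rank), , drop = FALSE]
    rownames(tab) <- NULL
    tab
}
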