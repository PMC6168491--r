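## Synthetic 15N-HSQC data with known ground truth: apo peak lists,
## slow-exchange complex series with per-label effect multipliers, grid
## rendering, and a planted-SID alignment generator. Everything is fully
## determined by its seed.

## run code under a temporary RNG state seeded with `seed`
.withSeed <- function(seed, code) {
    if (is.null(seed)) return(code)
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    code
}

#' Generate a synthetic apo 15N-HSQC peak list
#'
#' Draws `n` backbone-amide peaks uniformly over the amide region (1H
#' 6.5-10.5 ppm, 15N 103-133 ppm) subject to a minimum pairwise weighted
#' separation, by rejection sampling — a stand-in for the apo spectrum
#' of a well-dispersed, folded domain. Optionally appends flagged
#' Asn/Gln NH2 side-chain doublets (two 1H shifts sharing one 15N shift)
#' for exercising the NH2 exclusion step.
#'
#' @param n number of backbone peaks, default 90
#' @param seed integer; the list is fully determined by it
#' @param nh2_pairs number of side-chain NH2 doublets to append
#' @param h_range,n_range ppm boxes for 1H and 15N
#' @param min_separation minimum pairwise weighted distance (ppm),
#'   default 0.05
#' @param n_weight 15N weighting divisor used for the separation test
#' @return A [PeakList-class] with ids `a001`, `a002`, ...
#' @export
makeApoPeakList <- function(n = 90, seed = 1, nh2_pairs = 0,
                            h_range = c(6.5, 10.5), n_range = c(103, 133),
                            min_separation = 0.05, n_weight = 7) {
    stopifnot(n >= 0, nh2_pairs >= 0)
    .withSeed(seed, {
        h <- numeric(0); nn <- numeric(0)
        attempts <- 0L; max_attempts <- 2000L + 500L * n
        while (length(h) < n) {
            attempts <- attempts + 1L
            if (attempts > max_attempts)
                stop("could not place ", n, " peaks at separation ",
                     min_separation, " ppm within ", max_attempts,
                     " attempts")
            ch <- stats::runif(1, h_range[1], h_range[2])
            cn <- stats::runif(1, n_range[1], n_range[2])
            if (!length(h) ||
                all(weightedDistance(ch - h, cn - nn, n_weight) >=
                    min_separation)) {
                h <- c(h, ch); nn <- c(nn, cn)
            }
        }
        pk <- if (n > 0)
            data.frame(id = sprintf("a%03d", seq_len(n)), h_ppm = h,
                       n_ppm = nn,
                       intensity = stats::rlnorm(n, log(1e5), 0.3),
                       kind = "backbone_amide",
                       assignment = NA_character_,
                       stringsAsFactors = FALSE)
        else .emptyPeakFrame()
        if (nh2_pairs > 0) {
            nh_n <- stats::runif(nh2_pairs, 109, 113)
            nh_h1 <- stats::runif(nh2_pairs, 6.6, 7.1)
            nh_h2 <- nh_h1 + stats::runif(nh2_pairs, 0.4, 0.7)
            nh <- data.frame(id = c(sprintf("q%02da", seq_len(nh2_pairs)),
                                    sprintf("q%02db", seq_len(nh2_pairs))),
                             h_ppm = c(nh_h1, nh_h2),
                             n_ppm = c(nh_n, nh_n + stats::runif(nh2_pairs,
                                                                 -0.05, 0.05)),
                             intensity = stats::rlnorm(2 * nh2_pairs,
                                                       log(5e4), 0.3),
                             kind = "sidechain_nh2",
                             assignment = NA_character_,
                             stringsAsFactors = FALSE)
            pk <- rbind(pk, nh)
        }
        peakList(pk, meta = list(label = "apo", seed = seed))
    })
}

#' Describe a slow-exchange perturbation scenario
#'
#' @param interface_fraction fraction of apo peaks perturbed on complex
#'   formation; default 0.3
#' @param mean_shift mean weighted displacement magnitude (ppm) of a
#'   perturbed peak at multiplier 1; default 0.48 (calibrated once so the
#'   apo-vs-WT average minimal shift of the default scenario lands near
#'   0.127 ppm)
#' @param effect_multipliers named non-negative multipliers, one list
#'   per label; default `c(WT = 1)`
#' @param jitter_sigma isotropic weighted-space measurement noise (ppm)
#'   added to every peak of every generated list; default 0.005
#' @param seed integer seed fully determining the scenario
#' @return A [PerturbationScenario-class].
#' @export
perturbationScenario <- function(interface_fraction = 0.3, mean_shift = 0.48,
                                 effect_multipliers = c(WT = 1),
                                 jitter_sigma = 0.005, seed = 1) {
    new("PerturbationScenario",
        interface_fraction = interface_fraction, mean_shift = mean_shift,
        effect_multipliers = effect_multipliers,
        jitter_sigma = jitter_sigma, seed = as.integer(seed))
}

#' The built-in mutant-series scenario
#'
#' A six-label scenario (`WT`, `L897A`, `L900A`, `I894A`, `T898E`,
#' `T898A`) whose effect multipliers were fixed once so that the
#' mutant-vs-WT average minimal shifts are ordered
#' `L897A > L900A > I894A > T898E > T898A` — the residue-importance
#' ordering of the Tet1-SID mutant series this scenario emulates — and
#' the apo-vs-WT shift lands near the 0.127 ppm calibration anchor.
#' The multipliers are package choices, not measured quantities.
#'
#' @param seed integer seed
#' @param jitter_sigma measurement noise (ppm), default 0.005
#' @return A [PerturbationScenario-class].
#' @export
tet1MutantScenario <- function(seed = 1, jitter_sigma = 0.005) {
    perturbationScenario(
        interface_fraction = 0.3, mean_shift = 0.48,
        effect_multipliers = c(WT = 1, L897A = 0.07, L900A = 0.42,
                               I894A = 0.52, T898E = 0.70, T898A = 0.795),
        jitter_sigma = jitter_sigma, seed = seed)
}

#' Generate a labelled series of complex peak lists
#'
#' Emulates slow-exchange binding at 1:1 stoichiometry: every complex
#' peak sits at its fully bound position. A fixed subset of apo peaks
#' (the interface, chosen once per scenario and shared across labels) is
#' displaced; each interface peak carries one base displacement vector —
#' weighted magnitude Gamma-distributed (shape 2) with mean
#' `mean_shift`, direction uniform in weighted shift space — and each
#' label shifts by that vector scaled by its effect multiplier, so a
#' weaker-binding mutant moves the same peaks the same way, only less.
#' Isotropic jitter is then added to every peak of every list, including
#' a regenerated apo list.
#'
#' @param apo a [PeakList-class], e.g. from [makeApoPeakList()]
#' @param scenario a [PerturbationScenario-class]
#' @param n_weight 15N weighting divisor defining the weighted space
#' @return List with `lists` (named [PeakList-class] objects: `apo` plus
#'   one per multiplier label; ids are shared with the apo input, which
#'   is the ground-truth correspondence) and `truth` (data.frame
#'   `label`, `id`, `interface`, `true_shift` — the planted weighted
#'   displacement magnitude of every peak in every labelled list).
#' @export
makeComplexSeries <- function(apo, scenario, n_weight = 7) {
    stopifnot(is(apo, "PeakList"), is(scenario, "PerturbationScenario"))
    pk <- apo@peaks
    if (!nrow(pk)) stop("apo list is empty")
    .withSeed(scenario@seed, {
        n <- nrow(pk)
        n_int <- round(scenario@interface_fraction * n)
        interface <- sort(sample.int(n, n_int))
        mag <- stats::rgamma(n_int, shape = 2,
                             scale = scenario@mean_shift / 2)
        ang <- stats::runif(n_int, 0, 2 * pi)
        base_dh <- mag * cos(ang)
        base_dnw <- mag * sin(ang)      # weighted 15N component
        labels <- names(scenario@effect_multipliers)
        jit <- function() cbind(stats::rnorm(n, 0, scenario@jitter_sigma),
                                stats::rnorm(n, 0, scenario@jitter_sigma))
        lists <- list()
        truth <- list()
        ## regenerated apo: same true positions, fresh jitter
        j <- jit()
        ap <- pk
        ap$h_ppm <- ap$h_ppm + j[, 1]
        ap$n_ppm <- ap$n_ppm + j[, 2] * n_weight
        lists$apo <- peakList(ap, meta = list(label = "apo",
                                              seed = scenario@seed))
        for (lb in labels) {
            m <- scenario@effect_multipliers[[lb]]
            cp <- pk
            cp$h_ppm[interface] <- cp$h_ppm[interface] + m * base_dh
            cp$n_ppm[interface] <- cp$n_ppm[interface] +
                m * base_dnw * n_weight
            j <- jit()
            cp$h_ppm <- cp$h_ppm + j[, 1]
            cp$n_ppm <- cp$n_ppm + j[, 2] * n_weight
            lists[[lb]] <- peakList(cp, meta = list(label = lb,
                                                    seed = scenario@seed))
            ts <- numeric(n)
            ts[interface] <- m * mag
            truth[[lb]] <- data.frame(label = lb, id = pk$id,
                                      interface = seq_len(n) %in% interface,
                                      true_shift = ts,
                                      stringsAsFactors = FALSE)
        }
        list(lists = lists, truth = do.call(rbind, truth))
    })
}

#' Render a peak list as a 2D intensity grid
#'
#' Places a 2D Gaussian of the peak's intensity at each peak position
#' (widths given as Gaussian sigmas in ppm) and adds i.i.d. Gaussian
#' noise, bridging synthetic peak lists to the automatic picking step.
#' Axes cover the peak bounding box padded by 5 linewidths. Peaks with
#' missing intensity contribute no signal (they only extend the
#' bounding box), which gives a convenient noise-only control.
#'
#' @param pl a non-empty [PeakList-class]
#' @param linewidth_h,linewidth_n Gaussian widths (sigma, ppm) along the
#'   1H and 15N axes; defaults 0.015 and 0.12
#' @param grid_shape `c(n_rows, n_cols)` = (15N points, 1H points);
#'   default `c(256, 256)`
#' @param noise_sigma standard deviation of the added noise (intensity
#'   units); default 0
#' @param seed integer seed for the noise
#' @return A [SpectrumGrid-class].
#' @export
renderGrid <- function(pl, linewidth_h = 0.015, linewidth_n = 0.12,
                       grid_shape = c(256, 256), noise_sigma = 0, seed = 1) {
    stopifnot(is(pl, "PeakList"))
    pk <- pl@peaks
    if (!nrow(pk)) stop("cannot render an empty peak list")
    if (linewidth_h <= 0 || linewidth_n <= 0) stop("linewidths must be > 0")
    h_axis <- seq(min(pk$h_ppm) - 5 * linewidth_h,
                  max(pk$h_ppm) + 5 * linewidth_h, length.out = grid_shape[2])
    n_axis <- seq(min(pk$n_ppm) - 5 * linewidth_n,
                  max(pk$n_ppm) + 5 * linewidth_n, length.out = grid_shape[1])
    m <- matrix(0, nrow = grid_shape[1], ncol = grid_shape[2])
    for (k in seq_len(nrow(pk))) {
        amp <- pk$intensity[k]
        if (is.na(amp)) next
        gh <- exp(-(h_axis - pk$h_ppm[k])^2 / (2 * linewidth_h^2))
        gn <- exp(-(n_axis - pk$n_ppm[k])^2 / (2 * linewidth_n^2))
        m <- m + amp * (gn %o% gh)
    }
    if (noise_sigma > 0)
        m <- m + .withSeed(seed, matrix(stats::rnorm(length(m), 0,
                                                     noise_sigma),
                                        nrow = nrow(m)))
    spectrumGrid(m, h_axis, n_axis)
}

#' Generate an alignment with one planted SID-like window
#'
#' Builds a synthetic multiple alignment for plant-and-recover tests of
#' [scanSID()]: an ancestral random sequence is mutated independently in
#' every row and column (substitution probability `background_sub`),
#' except over one planted window that is kept identical in all rows —
#' a strongly conserved, amphipathic, motif-positive island
#' (`AIEALTELQES`: small hydrophobics at offsets 0 and 3, large at
#' 4 and 7, hydrophilic elsewhere) inside a weakly conserved background,
#' the sequence signature a SID scanner is meant to find.
#'
#' Background residues (ancestral and substituted) are drawn from a
#' disorder-like composition strongly enriched in polar, charged and
#' small residues and depleted of large hydrophobics, emulating the
#' low-complexity regions that flank short linear interaction motifs;
#' a uniform composition would scatter spuriously amphipathic windows
#' through the background, which real disordered sequence does not.
#'
#' @param n_rows alignment rows (species), default 6
#' @param length sequence length (no gaps are introduced), default 200
#' @param sid_start 1-based start of the planted window; drawn at random
#'   when `NULL`
#' @param background_sub per-row, per-column substitution probability
#'   outside the plant; default 0.5
#' @param seed integer seed
#' @return List with `msa` (character vector of aligned rows, first row
#'   is the reference), `sid_start`, and `sid_seq` (the planted 11-mer).
#' @export
makeSidAlignment <- function(n_rows = 6, length = 200, sid_start = NULL,
                             background_sub = 0.5, seed = 1) {
    ## disorder-promoting composition: polar/charged/small enriched,
    ## large hydrophobics rare
    freqs <- c(S = 0.11, E = 0.11, Q = 0.09, K = 0.09, P = 0.08, G = 0.08,
               T = 0.08, D = 0.07, A = 0.07, R = 0.06, N = 0.05, H = 0.02,
               L = 0.02, I = 0.015, V = 0.015, M = 0.01, F = 0.01,
               Y = 0.01, W = 0.005, C = 0.005)
    plant <- c("A", "I", "E", "A", "L", "T", "E", "L", "Q", "E", "S")
    stopifnot(length >= length(plant) + 2, n_rows >= 2)
    .withSeed(seed, {
        if (is.null(sid_start))
            sid_start <- sample.int(length - length(plant) + 1, 1)
        anc <- sample(names(freqs), length, replace = TRUE, prob = freqs)
        idx <- sid_start:(sid_start + length(plant) - 1)
        anc[idx] <- plant
        rows <- vapply(seq_len(n_rows), function(r) {
            s <- anc
            mut <- stats::runif(length) < background_sub
            mut[idx] <- FALSE
            s[mut] <- sample(names(freqs), sum(mut), replace = TRUE,
                             prob = freqs)
            paste(s, collapse = "")
        }, character(1))
        names(rows) <- c("ref", paste0("sp", seq_len(n_rows - 1)))
        list(msa = rows, sid_start = sid_start,
             sid_seq = paste(plant, collapse = ""))
    })
}
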