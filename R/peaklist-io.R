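## Peak-list I/O: Sparky .list and CSV dialects, plus the Asn/Gln NH2
## side-chain exclusion applied before any minimal-shift analysis.

.sparkyKind <- function(assignment) {
    ifelse(grepl("ND2|NE2", assignment), "sidechain_nh2",
           ifelse(grepl("N-H$", assignment), "backbone_amide", "unknown"))
}

#' Read a 2D peak list
#'
#' Reads an amide cross-peak list in one of two dialects:
#' \describe{
#'   \item{sparky}{whitespace-separated `Assignment w1 w2 [height]` with a
#'     single header line. By default `w1` is the 15N shift and `w2` the
#'     1H shift (the common convention for deposited amide lists); set
#'     `axis_order = "hn"` for lists written the other way around.
#'     Assignments ending in `N-H` are flagged `backbone_amide`, those
#'     containing `ND2`/`NE2` (Asn/Gln side chains) `sidechain_nh2`.}
#'   \item{csv}{columns `id,h_ppm,n_ppm[,intensity,kind[,assignment]]`.}
#' }
#' Lines starting with `#` (provenance comments) and blank lines are
#' skipped in both dialects.
#'
#' @param path path to the file
#' @param format `"sparky"` or `"csv"`
#' @param axis_order for the Sparky dialect: `"nh"` (w1 = 15N, w2 = 1H,
#'   default) or `"hn"`
#' @param meta extra metadata merged into the result's `meta`
#' @return A [PeakList-class].
#' @examples
#' f <- tempfile(fileext = ".list")
#' writeLines(c("Assignment w1 w2 Height", "Q5N-H 115.20 8.31 1.0e5"), f)
#' pl <- readPeakList(f, "sparky")
#' peaks(pl)
#' @export
readPeakList <- function(path, format = c("sparky", "csv"),
                         axis_order = c("nh", "hn"), meta = list()) {
    format <- match.arg(format)
    axis_order <- match.arg(axis_order)
    if (!file.exists(path)) stop("peak list file not found: ", path)
    meta$source <- path
    if (format == "csv") {
        lines <- readLines(path)
        keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
        if (!any(keep)) stop("no header line in CSV peak list: ", path)
        tab <- utils::read.csv(text = lines[keep], stringsAsFactors = FALSE,
                               colClasses = "character")
        if (!all(c("id", "h_ppm", "n_ppm") %in% names(tab)))
            stop("CSV peak list needs columns id, h_ppm, n_ppm")
        lineno <- which(keep)[-1]  # data rows in original numbering
        h <- suppressWarnings(as.numeric(tab$h_ppm))
        n <- suppressWarnings(as.numeric(tab$n_ppm))
        bad <- which(!is.finite(h) | !is.finite(n))
        if (length(bad))
            stop("non-numeric chemical shift at line ", lineno[bad[1]],
                 " of ", path)
        if (anyDuplicated(tab$id))
            stop("duplicate peak id in ", path, ": ",
                 tab$id[anyDuplicated(tab$id)])
        pk <- data.frame(id = tab$id, h_ppm = h, n_ppm = n,
                         stringsAsFactors = FALSE)
        pk$intensity <- if (!is.null(tab$intensity))
            suppressWarnings(as.numeric(tab$intensity))
        else rep(NA_real_, nrow(tab))
        pk$kind <- if (!is.null(tab$kind))
            ifelse(nzchar(tab$kind), tab$kind, "unknown")
        else rep("unknown", nrow(tab))
        if (!is.null(tab$assignment))
            pk$assignment <- ifelse(nzchar(tab$assignment), tab$assignment,
                                    NA_character_)
        return(peakList(pk, meta))
    }
    ## sparky dialect
    lines <- readLines(path)
    keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
    idx <- which(keep)
    if (!length(idx)) stop("no header line in Sparky peak list: ", path)
    data_idx <- idx[-1]  # first non-comment line is the header
    if (!length(data_idx))
        return(peakList(meta = meta))
    rows <- strsplit(trimws(lines[data_idx]), "\\s+")
    nf <- lengths(rows)
    if (any(nf < 3))
        stop("unparseable row at line ", data_idx[which(nf < 3)[1]],
             " of ", path, " (need at least 3 fields)")
    assignment <- vapply(rows, `[[`, "", 1L)
    w1 <- suppressWarnings(as.numeric(vapply(rows, `[[`, "", 2L)))
    w2 <- suppressWarnings(as.numeric(vapply(rows, `[[`, "", 3L)))
    bad <- which(!is.finite(w1) | !is.finite(w2))
    if (length(bad))
        stop("non-numeric chemical shift at line ", data_idx[bad[1]],
             " of ", path)
    height <- vapply(seq_along(rows), function(i)
        if (nf[i] >= 4) suppressWarnings(as.numeric(rows[[i]][4])) else NA_real_,
        numeric(1))
    if (axis_order == "nh") { n <- w1; h <- w2 } else { h <- w1; n <- w2 }
    informative <- !grepl("\\?", assignment)
    id <- assignment
    id[!informative] <- paste0("pk", which(!informative))
    if (anyDuplicated(id))
        stop("duplicate peak id in ", path, ": ", id[anyDuplicated(id)])
    peakList(data.frame(id = id, h_ppm = h, n_ppm = n, intensity = height,
                        kind = .sparkyKind(assignment),
                        assignment = ifelse(informative, assignment,
                                            NA_character_),
                        stringsAsFactors = FALSE), meta)
}

#' Write a 2D peak list
#'
#' Writes the Sparky or CSV dialect read by [readPeakList()]. A
#' provenance comment line (`# ...`) is emitted first; shifts are written
#' with 4 decimal places so that a read/write round trip reproduces
#' positions to 1e-4 ppm.
#'
#' @param pl a [PeakList-class]
#' @param path output path
#' @param format `"sparky"` or `"csv"`
#' @param axis_order Sparky axis convention, as in [readPeakList()]
#' @return `path`, invisibly.
#' @export
writePeakList <- function(pl, path, format = c("sparky", "csv"),
                          axis_order = c("nh", "hn")) {
    stopifnot(is(pl, "PeakList"))
    format <- match.arg(format)
    axis_order <- match.arg(axis_order)
    pk <- pl@peaks
    prov <- paste0("# CSPmap peak list; label=",
                   if (is.null(pl@meta$label)) "NA" else pl@meta$label,
                   "; temperature=", pl@meta$temperature, "K")
    con <- file(path, "w")
    on.exit(close(con))
    if (format == "csv") {
        writeLines(prov, con)
        writeLines("id,h_ppm,n_ppm,intensity,kind,assignment", con)
        if (nrow(pk))
            writeLines(sprintf("%s,%.4f,%.4f,%s,%s,%s", pk$id, pk$h_ppm,
                               pk$n_ppm,
                               ifelse(is.na(pk$intensity), "",
                                      sprintf("%g", pk$intensity)),
                               pk$kind,
                               ifelse(is.na(pk$assignment), "", pk$assignment)),
                       con)
    } else {
        writeLines(prov, con)
        writeLines("      Assignment         w1         w2   Height", con)
        lab <- ifelse(is.na(pk$assignment), pk$id, pk$assignment)
        w1 <- if (axis_order == "nh") pk$n_ppm else pk$h_ppm
        w2 <- if (axis_order == "nh") pk$h_ppm else pk$n_ppm
        if (nrow(pk))
            writeLines(sprintf("%16s %10.4f %10.4f %s", lab, w1, w2,
                               ifelse(is.na(pk$intensity), "",
                                      sprintf("%10.4g", pk$intensity))),
                       con)
    }
    invisible(path)
}

#' Exclude Asn/Gln NH2 side-chain peaks
#'
#' Removes side-chain NH2 cross peaks before minimal-shift analysis.
#' Peaks annotated `sidechain_nh2` are always removed; peaks annotated
#' `backbone_amide` are never removed. With `heuristic = TRUE`,
#' unannotated (`kind = "unknown"`) peaks are additionally removed when
#' they occur in pairs sharing their 15N shift within `n_tol` ppm with
#' both 1H shifts inside the NH2 window `h_window` — the geminal NH2
#' doublet signature.
#'
#' Removed ids are accumulated in `peakMeta(x)$nh2_removed`, so the
#' operation is idempotent.
#'
#' @param pl a [PeakList-class]
#' @param heuristic also apply the unannotated-doublet rule
#' @param n_tol 15N co-location tolerance (ppm), default 0.2
#' @param h_window 1H window for NH2 protons (ppm), default `c(6.4, 7.8)`
#' @return A new [PeakList-class] without the NH2 peaks.
#' @export
excludeSidechainNH2 <- function(pl, heuristic = FALSE, n_tol = 0.2,
                                h_window = c(6.4, 7.8)) {
    stopifnot(is(pl, "PeakList"))
    pk <- pl@peaks
    drop <- pk$kind == "sidechain_nh2"
    if (heuristic && nrow(pk) > 1) {
        cand <- which(pk$kind == "unknown" &
                      pk$h_ppm >= h_window[1] & pk$h_ppm <= h_window[2])
        if (length(cand) > 1) {
            for (a in seq_along(cand)[-length(cand)]) {
                for (b in (a + 1):length(cand)) {
                    i <- cand[a]; j <- cand[b]
                    if (abs(pk$n_ppm[i] - pk$n_ppm[j]) <= n_tol)
                        drop[c(i, j)] <- TRUE
                }
            }
        }
    }
    removed <- pk$id[drop]
    out <- pk[!drop, , drop = FALSE]
    rownames(out) <- NULL
    meta <- pl@meta
    meta$nh2_removed <- union(meta$nh2_removed, removed)
    initialize(pl, peaks = out, meta = meta)
}
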