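## Minimal structure comparison: read PDB coordinates and HELIX records,
## superpose selected atoms by Kabsch least squares, and report RMSD.

#' Read one model of a PDB file
#'
#' Parses a PDB file (via \pkg{bio3d}) and returns the atoms of the
#' requested model only — model 1, the first member of an NMR ensemble,
#' by default. Atoms with alternate-location indicator other than blank
#' or `'A'` are dropped. Helix segments are taken from the file's HELIX
#' records when present.
#'
#' @param path path to a PDB file
#' @param model 1-based model number, default 1
#' @return A [StructureModel-class].
#' @export
readStructure <- function(path, model = 1) {
    if (!file.exists(path)) stop("structure file not found: ", path)
    pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = TRUE, verbose = FALSE)
    nmodels <- nrow(pdb$xyz)
    if (is.null(nmodels)) nmodels <- 1L
    if (model < 1 || model > nmodels)
        stop("model ", model, " not present (file has ", nmodels, ")")
    xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[model, ] else pdb$xyz
    at <- pdb$atom
    keep <- at$type == "ATOM"
    co <- matrix(xyz, ncol = 3, byrow = TRUE)
    atoms <- data.frame(chain = at$chain[keep], resno = at$resno[keep],
                        resid = at$resid[keep], elety = at$elety[keep],
                        x = co[keep, 1], y = co[keep, 2], z = co[keep, 3],
                        stringsAsFactors = FALSE)
    if (!nrow(atoms)) stop("no ATOM coordinates in ", path)
    atoms$chain[is.na(atoms$chain)] <- " "
    helices <- if (!is.null(pdb$helix) && length(pdb$helix$start))
        data.frame(chain = as.character(pdb$helix$chain),
                   start = as.integer(pdb$helix$start),
                   end = as.integer(pdb$helix$end),
                   stringsAsFactors = FALSE)
    else data.frame(chain = character(), start = integer(), end = integer(),
                    stringsAsFactors = FALSE)
    rownames(atoms) <- NULL
    new("StructureModel", atoms = atoms, model_index = as.integer(model),
        helices = helices)
}

## Kabsch: optimal proper rotation of centred P onto centred Q
.kabschRmsd <- function(P, Q) {
    P0 <- sweep(P, 2, colMeans(P))
    Q0 <- sweep(Q, 2, colMeans(Q))
    s <- svd(crossprod(P0, Q0))          # t(P0) %*% Q0
    d <- sign(det(s$u %*% t(s$v)))
    R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
    diff <- P0 %*% R - Q0
    sqrt(sum(diff^2) / nrow(P0))
}

## atoms within helix segments, keyed for pairing:
## (segment order, residue offset within segment, atom name)
.helixSelection <- function(sm, segments, atom_set) {
    at <- sm@atoms
    out <- list()
    for (k in seq_len(nrow(segments))) {
        seg <- segments[k, ]
        sel <- at$chain == seg$chain & at$resno >= seg$start &
            at$resno <= seg$end & at$elety %in% atom_set
        sub <- at[sel, , drop = FALSE]
        if (!nrow(sub)) next
        sub$key <- paste(k, sub$resno - seg$start, sub$elety, sep = ":")
        out[[k]] <- sub
    }
    do.call(rbind, out)
}

#' Superpose two structures and report RMSD
#'
#' Performs a least-squares rigid (Kabsch) superposition of paired atoms
#' and returns the RMSD over those atoms. Atoms are restricted to the
#' given helix segments and atom set, and paired across structures by
#' (segment order, residue offset within segment, atom name); offsets
#' present in only one structure are dropped, so segments of unequal
#' length are compared over their common prefix.
#'
#' @param a,b [StructureModel-class] objects
#' @param segments_a,segments_b data.frames `chain`, `start`, `end`
#'   selecting the segments to compare, in matching order; default: each
#'   structure's own HELIX records
#' @param atoms backbone atom set, default `c("N", "CA", "C")` (add
#'   `"O"` for the 4-atom convention)
#' @return List with `rmsd` (Angstrom), `n_atoms` paired, and
#'   `selection` (the paired keys).
#' @export
superposeRmsd <- function(a, b, segments_a = helixSegments(a),
                          segments_b = helixSegments(b),
                          atoms = c("N", "CA", "C")) {
    stopifnot(is(a, "StructureModel"), is(b, "StructureModel"))
    if (!nrow(segments_a) || !nrow(segments_b))
        stop("no segments to superpose (no HELIX records and no explicit selection)")
    if (nrow(segments_a) != nrow(segments_b))
        stop("selections must have the same number of segments")
    sa <- .helixSelection(a, segments_a, atoms)
    sb <- .helixSelection(b, segments_b, atoms)
    if (is.null(sa) || is.null(sb)) stop("selection matches no atoms")
    common <- intersect(sa$key, sb$key)
    if (length(common) < 3)
        stop("fewer than 3 paired atoms in the selection")
    P <- as.matrix(sa[match(common, sa$key), c("x", "y", "z")])
    Q <- as.matrix(sb[match(common, sb$key), c("x", "y", "z")])
    list(rmsd = .kabschRmsd(P, Q), n_atoms = length(common),
         selection = common)
}

#' Backbone RMSD over the four PAH1 helices of two structures
#'
#' Convenience wrapper for comparing two PAH-domain structures (e.g. the
#' first members of two deposited NMR ensembles): reads both files,
#' keeps the HELIX records of the chain carrying the most helices (the
#' PAH chain, in a SID complex the peptide chain has at most one), pairs
#' the four helices in order and reports the backbone RMSD after Kabsch
#' superposition.
#'
#' @param ref_path,mov_path PDB file paths
#' @param model model number read from each file, default 1
#' @param atoms backbone atom set, default `c("N", "CA", "C")`
#' @return List with `rmsd`, `n_atoms`, `segments_ref`, `segments_mov`.
#' @export
comparePah1Helices <- function(ref_path, mov_path, model = 1,
                               atoms = c("N", "CA", "C")) {
    a <- readStructure(ref_path, model)
    b <- readStructure(mov_path, model)
    pick <- function(sm) {
        h <- helixSegments(sm)
        if (!nrow(h)) stop("no HELIX records")
        tab <- table(h$chain)
        h <- h[h$chain == names(tab)[which.max(tab)], , drop = FALSE]
        h[order(h$start), , drop = FALSE]
    }
    ha <- pick(a); hb <- pick(b)
    nseg <- min(nrow(ha), nrow(hb))
    ha <- ha[seq_len(nseg), , drop = FALSE]
    hb <- hb[seq_len(nseg), , drop = FALSE]
    sp <- superposeRmsd(a, b, ha, hb, atoms = atoms)
    list(rmsd = sp$rmsd, n_atoms = sp$n_atoms,
         segments_ref = ha, segments_mov = hb)
}
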