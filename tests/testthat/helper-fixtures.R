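## Shared fixtures and independent oracles, all built in code at test time.

## exhaustive minimal total matching distance over all permutations
## (independent oracle for the assignment solver; n <= ~7)
all_perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
        for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
}

brute_min_total <- function(cost) {
    n <- nrow(cost)
    stopifnot(n == ncol(cost))
    min(vapply(all_perms(seq_len(n)),
               function(p) sum(cost[cbind(seq_len(n), p)]), numeric(1)))
}

## weighted distance matrix between two peak lists
peak_dist <- function(a, b, n_weight = 7) {
    pa <- peaks(a); pb <- peaks(b)
    sqrt(outer(pa$h_ppm, pb$h_ppm, "-")^2 +
         (outer(pa$n_ppm, pb$n_ppm, "-") / n_weight)^2)
}

## quick random peak list (no separation constraint)
random_peaklist <- function(n, prefix = "p") {
    peakList(data.frame(id = paste0(prefix, seq_len(n)),
                        h_ppm = runif(n, 6.5, 10.5),
                        n_ppm = runif(n, 103, 133)))
}

## brute-force rigid-superposition RMSD oracle: numeric minimisation over
## Euler angles from many random starts (independent of the SVD route)
rmsd_oracle <- function(P, Q, starts = 25) {
    P0 <- sweep(P, 2, colMeans(P)); Q0 <- sweep(Q, 2, colMeans(Q))
    rotmat <- function(a) {
        cz <- cos(a[1]); sz <- sin(a[1])
        cy <- cos(a[2]); sy <- sin(a[2])
        cx <- cos(a[3]); sx <- sin(a[3])
        Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
        Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
        Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
        Rz %*% Ry %*% Rx
    }
    f <- function(a) sqrt(mean(rowSums((P0 %*% t(rotmat(a)) - Q0)^2)))
    best <- Inf
    for (s in seq_len(starts)) {
        r <- optim(runif(3, -pi, pi), f, method = "Nelder-Mead",
                   control = list(maxit = 5000, reltol = 1e-14))
        best <- min(best, r$value)
    }
    best
}

## ideal alpha-helix backbone coordinates (N, CA, C per residue):
## 100 deg/residue, 1.5 A rise, CA radius 2.3 A
helix_coords <- function(n_res, phase = 0) {
    out <- NULL
    for (k in seq_len(n_res) - 1) {
        phi <- (100 * k + phase) * pi / 180
        z <- 1.5 * k
        out <- rbind(out,
            c(1.6 * cos(phi - 26 * pi / 180), 1.6 * sin(phi - 26 * pi / 180), z - 0.9),
            c(2.3 * cos(phi), 2.3 * sin(phi), z),
            c(1.7 * cos(phi + 27 * pi / 180), 1.7 * sin(phi + 27 * pi / 180), z + 0.6))
    }
    out
}

pdb_atom_line <- function(serial, name, resno, xyz, chain = "A",
                          alt = " ", resid = "ALA") {
    name4 <- sprintf(" %-3s", name)
    sprintf("ATOM  %5d %4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
            serial, name4, alt, resid, chain, resno, xyz[1], xyz[2], xyz[3],
            1, 0)
}

pdb_helix_line <- function(ser, chain, start, end) {
    sprintf("HELIX  %3d %3s %3s %1s %4d%1s %3s %1s %4d%1s%2d%30s %5d",
            ser, paste0("H", ser), "ALA", chain, start, " ", "ALA", chain,
            end, " ", 1, "", end - start + 1)
}

## write a synthetic four-helix-bundle PDB (one chain, four 12-residue
## helices laid side by side), optionally perturbed by `distort` (A of
## isotropic coordinate noise) and rigidly moved; returns the path
write_bundle_pdb <- function(path, distort = 0, seed = 1, models = 1,
                             chain = "A") {
    set.seed(seed)
    offsets <- list(c(0, 0, 0), c(8, 0, 0), c(0, 8, 0), c(8, 8, 0))
    coords <- NULL; resno <- NULL
    res0 <- c(10, 40, 70, 100)
    for (hx in 1:4) {
        xyz <- helix_coords(12, phase = 37 * hx)
        if (hx %% 2 == 0) xyz[, 3] <- -xyz[, 3]   # antiparallel pairs
        xyz <- sweep(xyz, 2, unlist(offsets[hx]), "+")
        coords <- rbind(coords, xyz)
        resno <- c(resno, rep(res0[hx] + seq_len(12) - 1, each = 3))
    }
    if (distort > 0)
        coords <- coords + matrix(rnorm(length(coords), 0, distort),
                                  ncol = 3)
    lines <- vapply(1:4, function(hx)
        pdb_helix_line(hx, chain, res0[hx], res0[hx] + 11), character(1))
    names3 <- rep(c("N", "CA", "C"), nrow(coords) / 3)
    for (mdl in seq_len(models)) {
        if (models > 1) lines <- c(lines, sprintf("MODEL     %4d", mdl))
        cc <- if (mdl == 1) coords else coords + 2 * (mdl - 1)
        lines <- c(lines, vapply(seq_len(nrow(cc)), function(i)
            pdb_atom_line(i, names3[i], resno[i], cc[i, ], chain),
            character(1)))
        if (models > 1) lines <- c(lines, "ENDMDL")
    }
    writeLines(c(lines, "END"), path)
    path
}

## apply a random proper rigid transform to an atom table
rigid_transform <- function(atoms, seed = 1) {
    set.seed(seed)
    M <- matrix(rnorm(9), 3)
    R <- qr.Q(qr(M))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% R
    xyz <- sweep(xyz, 2, runif(3, -20, 20), "+")
    atoms[, c("x", "y", "z")] <- xyz
    atoms
}

## the Tet1-SID region, residues 889-903: the residues named in the
## analysis (A893, I894, A896, L897, T898, L900, E902) with neutral
## hydrophilic placeholders elsewhere
tet1_sid_889_903 <- function() {
    c("889" = "S", "890" = "E", "891" = "Q", "892" = "K",
      "893" = "A", "894" = "I", "895" = "Q", "896" = "A",
      "897" = "L", "898" = "T", "899" = "Q", "900" = "L",
      "901" = "S", "902" = "E", "903" = "K")
}
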