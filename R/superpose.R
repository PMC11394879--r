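# Rigid superposition (Kabsch) and ligand ARMSD.

#' Least-squares rigid superposition of two node sets
#'
#' Computes the proper rigid transform (rotation with determinant +1 plus
#' translation) that minimizes the RMSD of `mobile` onto `reference` over
#' a residue correspondence. When `correspondence` is not supplied, nodes
#' are matched chain-agnostically by residue number (intersection of the
#' two sets; duplicated residue numbers are dropped), which is the
#' protocol used for superposing the shared protein of a monomer and a
#' complex.
#'
#' @param mobile,reference `mcdpa_nodes` objects (or data frames with
#'   x/y/z columns).
#' @param correspondence Optional two-column integer matrix of row
#'   indices `(mobile, reference)`.
#' @return An `mcdpa_transform`: list with `rotation` (3x3),
#'   `translation` (length 3) and `fit_rmsd` (Angstrom). Applying it to
#'   the mobile points yields `rotation %*% p + translation`.
#' @export
superpose <- function(mobile, reference, correspondence = NULL) {
  if (is.null(correspondence)) {
    if (is.null(mobile$resno) || is.null(reference$resno))
      stop_mcdpa("no correspondence supplied and no residue numbers available",
                 class = "mcdpa_degenerate_fit")
    mr <- mobile$resno[!duplicated(mobile$resno)]
    rr <- reference$resno[!duplicated(reference$resno)]
    shared <- intersect(mr, rr)
    correspondence <- cbind(
      match(shared, mobile$resno),
      match(shared, reference$resno)
    )
  }
  correspondence <- as.matrix(correspondence)
  if (nrow(correspondence) < 3L)
    stop_mcdpa("need at least 3 correspondence pairs, got ",
               nrow(correspondence), class = "mcdpa_degenerate_fit")
  P <- coords_matrix(mobile)[correspondence[, 1L], , drop = FALSE]
  Q <- coords_matrix(reference)[correspondence[, 2L], , drop = FALSE]
  kabsch(P, Q)
}

# Kabsch fit of point set P (mobile) onto Q (reference), both n x 3.
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp); Qc <- sweep(Q, 2L, cq)
  s <- svd(crossprod(Pc, Qc))
  if (min(s$d) < 1e-10 && sum(s$d > 1e-10 * max(s$d)) < 2L)
    stop_mcdpa("degenerate (collinear) correspondence set",
               class = "mcdpa_degenerate_fit")
  d <- sign(det(tcrossprod(s$v, s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t_vec <- cq - as.vector(R %*% cp)
  fitted <- tcrossprod(Pc, R)
  rmsd <- sqrt(mean(rowSums((fitted - Qc)^2)))
  structure(list(rotation = R, translation = t_vec, fit_rmsd = rmsd,
                 n_pairs = nrow(P)),
            class = "mcdpa_transform")
}

#' Identity rigid transform
#' @return An `mcdpa_transform` that maps every point to itself.
#' @export
identity_transform <- function() {
  structure(list(rotation = diag(3), translation = c(0, 0, 0),
                 fit_rmsd = 0, n_pairs = NA_integer_),
            class = "mcdpa_transform")
}

#' Apply a rigid transform to coordinates
#' @param transform An `mcdpa_transform`.
#' @param coords An n x 3 matrix (or data frame with x/y/z columns).
#' @return The transformed n x 3 matrix.
#' @export
apply_transform <- function(transform, coords) {
  stopifnot(inherits(transform, "mcdpa_transform"))
  if (is.data.frame(coords)) coords <- coords_matrix(coords)
  sweep(tcrossprod(coords, transform$rotation), 2L, -transform$translation)
}

#' Invert a rigid transform
#' @param transform An `mcdpa_transform`.
#' @return The inverse `mcdpa_transform`.
#' @export
invert_transform <- function(transform) {
  R <- t(transform$rotation)
  structure(list(rotation = R,
                 translation = as.vector(-R %*% transform$translation),
                 fit_rmsd = transform$fit_rmsd, n_pairs = transform$n_pairs),
            class = "mcdpa_transform")
}

#' Ligand ARMSD after superposing the shared protein
#'
#' Measures how far a bound ligand moved between two structures of the
#' same protein (e.g. the monomer and the protein-protein complex). The
#' supplied transform must map the frame of `ligand_2`'s parent structure
#' onto that of `ligand_1` (typically from [superpose()] of the shared
#' protein).
#'
#' In `"atom_match"` mode atoms are paired by PDB atom name (within
#' residue units matched in order, for oligomeric ligands); unmatched
#' atoms are excluded from the average and reported. In
#' `"center_of_mass"` mode the value is the distance between the two
#' (unweighted) centroids, which is the appropriate measure when the two
#' ligands are chemically different.
#'
#' @param ligand_1 `mcdpa_ligand` in the reference frame.
#' @param ligand_2 `mcdpa_ligand` in the mobile frame.
#' @param transform `mcdpa_transform` mapping frame 2 onto frame 1.
#' @param mode `"atom_match"` (default) or `"center_of_mass"`.
#' @return An `mcdpa_armsd`: list with `value` (Angstrom),
#'   `n_matched_atoms`, `mode`, `unmatched_atoms`.
#' @export
compute_armsd <- function(ligand_1, ligand_2, transform = identity_transform(),
                          mode = c("atom_match", "center_of_mass")) {
  mode <- match.arg(mode)
  a1 <- ligand_1$atoms; a2 <- ligand_2$atoms
  x2 <- apply_transform(transform, coords_matrix(a2))
  if (mode == "center_of_mass") {
    value <- sqrt(sum((colMeans(coords_matrix(a1)) - colMeans(x2))^2))
    return(structure(list(value = value, n_matched_atoms = 0L,
                          mode = mode, unmatched_atoms = character()),
                     class = "mcdpa_armsd"))
  }
  # pair residue units in order, then atoms by name within each unit
  k1 <- match(paste(a1$chain, a1$resno, a1$insert, a1$resid, sep = "|"),
              ligand_unit_keys(a1))
  k2 <- match(paste(a2$chain, a2$resno, a2$insert, a2$resid, sep = "|"),
              ligand_unit_keys(a2))
  n_units <- min(max(k1), max(k2))
  idx1 <- integer(); idx2 <- integer(); unmatched <- character()
  for (u in seq_len(n_units)) {
    i1 <- which(k1 == u); i2 <- which(k2 == u)
    m <- match(a1$elety[i1], a2$elety[i2])
    hit <- !is.na(m)
    used2 <- i2[m[hit]]
    idx1 <- c(idx1, i1[hit]); idx2 <- c(idx2, used2)
    lost2 <- setdiff(i2, used2)
    unmatched <- c(unmatched,
                   paste0("1:", a1$resid[i1[!hit]], ":", a1$elety[i1[!hit]]),
                   paste0("2:", a2$resid[lost2], ":", a2$elety[lost2]))
  }
  if (max(k1) > n_units)
    unmatched <- c(unmatched, paste0("1:unit", (n_units + 1L):max(k1)))
  if (max(k2) > n_units)
    unmatched <- c(unmatched, paste0("2:unit", (n_units + 1L):max(k2)))
  if (length(idx1) == 0L)
    stop_mcdpa("no atom-name correspondence between ligands; ",
               "consider mode = 'center_of_mass'",
               class = "mcdpa_no_correspondence")
  d <- coords_matrix(a1)[idx1, , drop = FALSE] - x2[idx2, , drop = FALSE]
  structure(list(value = sqrt(mean(rowSums(d^2))),
                 n_matched_atoms = length(idx1),
                 mode = mode, unmatched_atoms = unique(unmatched)),
            class = "mcdpa_armsd")
}

ligand_unit_keys <- function(atoms) {
  unique(paste(atoms$chain, atoms$resno, atoms$insert, atoms$resid, sep = "|"))
}
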