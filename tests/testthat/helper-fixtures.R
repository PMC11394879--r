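# Small in-code fixtures shared across test files.

# A random connected node cloud: points drawn in a box scaled so the
# default (or given) cutoff keeps the network connected.
random_nodes <- function(n, seed = 1, box = 10) {
  with_seed <- get("with_seed", asNamespace("mcdpa"))
  xyz <- with_seed(seed, matrix(stats::runif(3 * n, 0, box), ncol = 3))
  nodes <- data.frame(label = paste0("A", seq_len(n)), chain = "A",
                      resno = seq_len(n),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  attr(nodes, "scheme") <- "calpha"
  class(nodes) <- c("mcdpa_nodes", "data.frame")
  nodes
}

random_rotation <- function(seed = 1) {
  with_seed <- get("with_seed", asNamespace("mcdpa"))
  M <- with_seed(seed, matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr(M))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Hand-written 3-atom PDB text (fixed literal coordinates).
mini_pdb_text <- function() {
  c("ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00 10.00           C",
    "ATOM      3  C   ALA A   1      10.938   7.062  -4.211  1.00 10.00           C",
    "END")
}

# Two altlocs for one atom plus one plain atom.
altloc_pdb_text <- function() {
  c("ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.60 10.00           C",
    "ATOM      2  CA BALA A   1       2.000   0.000   0.000  0.40 10.00           C",
    "ATOM      3  CA  GLY A   2       5.000   0.000   0.000  1.00 10.00           C",
    "END")
}

# A ligand object from raw coordinates (single residue unit).
make_ligand <- function(xyz, resid = "LIG", elety = NULL) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  atoms <- data.frame(
    type = "HETATM", eleno = seq_len(n),
    elety = elety %||% paste0("C", seq_len(n)),
    alt = "", resid = resid, chain = "L", resno = 900L, insert = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1, b = 0, elesy = "C",
    is_water = FALSE)
  structure(list(ligand_id = paste0(resid, "_L900"), atoms = atoms,
                 n_atoms = n, residues = paste0("L|900||", resid),
                 n_residues = 1L),
            class = "mcdpa_ligand")
}

# A cluster object from raw coordinates (all dx = 1 unless given).
make_cluster <- function(xyz, label = "O", dx = NULL) {
  xyz <- as.matrix(xyz)
  pts <- data.frame(id = seq_len(nrow(xyz)), x = xyz[, 1], y = xyz[, 2],
                    z = xyz[, 3], layer = 4,
                    dx = dx %||% rep(1, nrow(xyz)))
  list(label = label, points = pts, n = nrow(xyz), mean_dx = mean(pts$dx),
       centroid = colMeans(xyz))
}

make_cluster_set <- function(clusters, provenance = "monomer") {
  structure(list(clusters = clusters, provenance = provenance,
                 config = list(linkage_cutoff = 3.5, min_cluster_size = 1)),
            class = "mcdpa_clusters")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
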