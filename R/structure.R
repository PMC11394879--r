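# Structure input, chain selection, ligand extraction and coarse-graining.
#
# A `mcdpa_structure` is a thin wrapper around a bio3d-style atom table:
# one row per atom with columns type (ATOM/HETATM), eleno, elety, alt,
# resid, chain, resno, insert, x, y, z, o, b, elesy, plus a logical
# `is_water` flag. Only the first MODEL of a file is kept.

WATER_RESIDUES <- c("HOH", "WAT", "H2O", "DOD", "SOL", "TIP", "TIP3")
ION_RESIDUES <- c(
  "NA", "K", "CL", "MG", "CA", "ZN", "MN", "FE", "CU", "CO", "NI",
  "CD", "HG", "BR", "IOD", "F", "LI", "RB", "CS", "SR", "BA", "SO4", "PO4"
)

#' Read a structure from a PDB file
#'
#' Parses ATOM/HETATM records of the first model via [bio3d::read.pdb()],
#' resolves alternate locations (highest occupancy wins; ties go to the
#' first occurrence in the file) and flags water molecules.
#'
#' @param source Path to a PDB file.
#' @return An object of class `mcdpa_structure`: a list with element
#'   `atom` (the atom table) and `source` (the input path).
#' @export
read_structure <- function(source) {
  if (!is.character(source) || length(source) != 1L || !file.exists(source))
    stop_mcdpa("cannot read PDB source: ", source, class = "mcdpa_input_error")
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(source, multi = FALSE, verbose = FALSE)),
    error = function(e) stop_mcdpa("unreadable PDB source '", source, "': ",
                                   conditionMessage(e),
                                   class = "mcdpa_input_error")
  )
  atom <- pdb$atom
  if (is.null(atom) || nrow(atom) == 0L || !any(atom$type == "ATOM"))
    stop_mcdpa("no ATOM records in ", source, class = "mcdpa_empty_structure")
  atom <- resolve_altloc(atom)
  atom$chain[is.na(atom$chain)] <- " "
  atom$insert[is.na(atom$insert)] <- ""
  atom$is_water <- toupper(atom$resid) %in% WATER_RESIDUES
  bad <- !is.finite(atom$x) | !is.finite(atom$y) | !is.finite(atom$z)
  if (any(bad)) {
    warning(sum(bad), " atom(s) with non-finite coordinates skipped")
    atom <- atom[!bad, , drop = FALSE]
  }
  new_structure(atom, source = source)
}

new_structure <- function(atom, source = NA_character_) {
  rownames(atom) <- NULL
  structure(list(atom = atom, source = source), class = "mcdpa_structure")
}

#' @export
print.mcdpa_structure <- function(x, ...) {
  a <- x$atom
  cat("mcdpa_structure:", nrow(a), "atoms,",
      sum(a$type == "ATOM"), "polymer /", sum(a$type != "ATOM"), "hetero;",
      "chains:", paste(sort(unique(a$chain)), collapse = ","), "\n")
  invisible(x)
}

# Keep one atom per (chain, resno, insert, resid, elety): the altloc with
# the highest occupancy, ties broken by file order.
resolve_altloc <- function(atom) {
  alt <- atom$alt
  alt[is.na(alt)] <- ""
  if (all(alt == "")) return(atom)
  key <- paste(atom$chain, atom$resno, atom$insert, atom$resid, atom$elety,
               sep = "|")
  occ <- atom$o
  occ[is.na(occ)] <- 1
  ord <- order(key, -occ, seq_len(nrow(atom)))
  keep_first <- !duplicated(key[ord])
  keep <- sort(ord[keep_first])
  atom[keep, , drop = FALSE]
}

#' Select chains of a structure
#'
#' @param x An `mcdpa_structure`.
#' @param chain_ids Character vector of chain identifiers to keep.
#' @return An `mcdpa_structure` restricted to the requested chains
#'   (hetero records on those chains included).
#' @export
select_chains <- function(x, chain_ids) {
  stopifnot(inherits(x, "mcdpa_structure"))
  avail <- unique(x$atom$chain)
  missing <- setdiff(chain_ids, avail)
  if (length(missing) > 0L)
    stop_mcdpa("unknown chain id(s) ", paste(missing, collapse = ","),
               "; available chains: ", paste(sort(avail), collapse = ","),
               class = "mcdpa_lookup_error")
  new_structure(x$atom[x$atom$chain %in% chain_ids, , drop = FALSE],
                source = x$source)
}

#' Extract ligands from a structure
#'
#' Groups HETATM residues that are not waters or common ions into ligand
#' entities. Covalently linked hetero residues on the same chain (any
#' inter-residue atom pair closer than `bond_threshold`) are merged into
#' one oligomeric entity, so e.g. a poly-NAG glycan is returned as a
#' single ligand.
#'
#' @param x An `mcdpa_structure`.
#' @param exclude Residue names to discard (default: waters and common
#'   monoatomic/small ions).
#' @param bond_threshold Covalent-link distance in Angstrom (default 1.9).
#' @return A list of `mcdpa_ligand` objects, each with fields
#'   `ligand_id`, `atoms` (atom table), `n_atoms`, `residues`, and
#'   `n_residues`.
#' @export
extract_ligands <- function(x, exclude = c(WATER_RESIDUES, ION_RESIDUES),
                            bond_threshold = 1.9) {
  stopifnot(inherits(x, "mcdpa_structure"))
  het <- x$atom[x$atom$type == "HETATM" &
                  !(toupper(x$atom$resid) %in% toupper(exclude)), ,
                drop = FALSE]
  if (nrow(het) == 0L) return(list())
  res_key <- paste(het$chain, het$resno, het$insert, het$resid, sep = "|")
  res_ids <- unique(res_key)
  nres <- length(res_ids)
  grp <- seq_len(nres)
  if (nres > 1L) {
    # union-find over hetero residues linked by a covalent-range contact
    find <- function(i) { while (grp[i] != i) i <- grp[i] <- grp[grp[i]]; i }
    coords <- lapply(res_ids, function(k)
      coords_matrix(het[res_key == k, , drop = FALSE]))
    chains <- vapply(res_ids, function(k) het$chain[res_key == k][1L], "")
    for (i in seq_len(nres - 1L)) for (j in (i + 1L):nres) {
      if (chains[i] != chains[j]) next
      if (min(cross_dist(coords[[i]], coords[[j]])) < bond_threshold)
        grp[find(j)] <- find(i)
    }
    grp <- vapply(seq_len(nres), find, 0L)
  }
  lapply(unique(grp), function(g) {
    members <- res_ids[grp == g]
    atoms <- het[res_key %in% members, , drop = FALSE]
    rownames(atoms) <- NULL
    first <- atoms[1L, ]
    structure(list(
      ligand_id = paste0(first$resid, "_", first$chain, first$resno),
      atoms = atoms,
      n_atoms = nrow(atoms),
      residues = members,
      n_residues = length(members)
    ), class = "mcdpa_ligand")
  })
}

#' Coarse-grain a structure to elastic-network nodes
#'
#' @param x An `mcdpa_structure`.
#' @param scheme `"calpha"` (one node per residue at its CA position, the
#'   default) or `"heavy_atom"` (every non-hydrogen polymer atom).
#' @return An `mcdpa_nodes` data frame with columns `label`, `chain`,
#'   `resno`, `x`, `y`, `z` and attribute `scheme`.
#' @export
coarse_grain <- function(x, scheme = c("calpha", "heavy_atom")) {
  stopifnot(inherits(x, "mcdpa_structure"))
  scheme <- match.arg(scheme)
  poly <- x$atom[x$atom$type == "ATOM", , drop = FALSE]
  if (nrow(poly) == 0L)
    stop_mcdpa("structure has no polymer atoms", class = "mcdpa_empty_structure")
  if (scheme == "calpha") {
    res_key <- paste(poly$chain, poly$resno, poly$insert, sep = "|")
    ca <- poly[poly$elety == "CA", , drop = FALSE]
    n_res <- length(unique(res_key))
    ca <- ca[!duplicated(paste(ca$chain, ca$resno, ca$insert, sep = "|")), ,
             drop = FALSE]
    if (nrow(ca) < n_res)
      warning(n_res - nrow(ca), " residue(s) without a CA atom dropped")
    nodes <- data.frame(
      label = paste0(ca$chain, ca$resno, ca$insert),
      chain = ca$chain, resno = ca$resno,
      x = ca$x, y = ca$y, z = ca$z,
      stringsAsFactors = FALSE
    )
  } else {
    heavy <- poly[!(poly$elesy %in% c("H", "D")) &
                    !grepl("^[0-9]*H", poly$elety), , drop = FALSE]
    nodes <- data.frame(
      label = paste0(heavy$chain, heavy$resno, heavy$insert, ":", heavy$elety),
      chain = heavy$chain, resno = heavy$resno,
      x = heavy$x, y = heavy$y, z = heavy$z,
      stringsAsFactors = FALSE
    )
  }
  if (nrow(nodes) == 0L)
    stop_mcdpa("coarse-graining produced zero nodes",
               class = "mcdpa_empty_structure")
  rownames(nodes) <- NULL
  attr(nodes, "scheme") <- scheme
  class(nodes) <- c("mcdpa_nodes", "data.frame")
  nodes
}
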