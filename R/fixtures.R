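# Deterministic toy structures with known geometry: the no-download test
# substrate for every other module. All fixtures are CA-only
# pseudo-proteins (chemistry is irrelevant to the dynamics core) and are
# connected at the default elastic-network cutoff.

# Quasi-uniform points on a unit sphere (Fibonacci lattice), optionally
# jittered by a seeded generator to avoid pathological symmetry.
fibonacci_sphere <- function(n, jitter = 0, seed = NULL) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  pts <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  if (jitter > 0) {
    z <- if (is.null(seed)) matrix(stats::rnorm(3L * n), ncol = 3L)
         else with_seed(seed, matrix(stats::rnorm(3L * n), ncol = 3L))
    pts <- pts + jitter * z
    pts <- pts / sqrt(rowSums(pts^2))
  }
  pts
}

# Quasi-uniform solid ball: concentric Fibonacci shells with node counts
# proportional to shell area, plus a center node.
solid_ball <- function(n_surface, radius, shell_spacing = 5, jitter = 0.05,
                       seed = 1) {
  radii <- seq(radius, shell_spacing, by = -shell_spacing)
  pts <- NULL
  for (s in seq_along(radii)) {
    n_s <- max(8L, round(n_surface * (radii[s] / radius)^2))
    pts <- rbind(pts, fibonacci_sphere(n_s, jitter = jitter,
                                       seed = seed + s) * radii[s])
  }
  rbind(pts, c(0, 0, 0))
}

#' Solid toy structure with a carved surface pocket
#'
#' A quasi-uniform solid ball of pseudo-residues (CA-only, concentric
#' Fibonacci shells 4 Angstrom apart). When `pocket_depth > 0`, a
#' cylindrical channel of radius `pocket_radius` is carved into the +z
#' surface to the stated depth, leaving a deep, narrow pocket — the
#' deep-pocket versus convex-surface contrast the perturbation scores
#' must discriminate. The ground-truth pocket center (the midpoint of
#' the channel axis, where a ligand would sit) is attached as attribute
#' `pocket_center`.
#'
#' @param n_surface Node count of the outermost shell (default 200,
#'   minimum 40, giving roughly 4 Angstrom surface spacing at the
#'   default radius; inner shells scale with area).
#' @param radius Ball radius in Angstrom (default 16).
#' @param pocket_depth Channel depth in Angstrom (default 7; 0 gives a
#'   plain ball with no pocket annotation).
#' @param pocket_radius Channel radius in Angstrom (default 5.5, a
#'   ligand-sized mouth wide enough to admit probes of both default
#'   layers).
#' @param jitter Relative angular jitter of the shell lattices (default
#'   0.05).
#' @param seed RNG seed for the jitter.
#' @param with_ligand Plant a small rigid HETATM ligand at the pocket
#'   center (default FALSE), giving a ligand-in-pocket fixture for
#'   evaluation tests.
#' @return An `mcdpa_structure` with attribute `pocket_center` (NULL for
#'   a plain ball) and, when `with_ligand`, `ligand_center`.
#' @export
make_pocket_cage <- function(n_surface = 200, radius = 16, pocket_depth = 7,
                             pocket_radius = 5.5, jitter = 0.05, seed = 1,
                             with_ligand = FALSE) {
  if (n_surface < 40L)
    stop_mcdpa("need at least 40 surface nodes",
               class = "mcdpa_parameter_error")
  if (pocket_depth >= radius)
    stop_mcdpa("pocket depth must be smaller than the radius",
               class = "mcdpa_parameter_error")
  xyz <- solid_ball(n_surface, radius, shell_spacing = 4, jitter = jitter,
                    seed = seed)
  pocket_center <- NULL
  if (pocket_depth > 0) {
    lateral <- sqrt(xyz[, 1L]^2 + xyz[, 2L]^2)
    keep <- !(lateral < pocket_radius & xyz[, 3L] > radius - pocket_depth)
    xyz <- xyz[keep, , drop = FALSE]
    pocket_center <- c(0, 0, radius - pocket_depth / 2)
  }
  st <- ca_structure(xyz, chain = "A")
  if (with_ligand) {
    if (is.null(pocket_center))
      stop_mcdpa("a ligand needs a pocket (pocket_depth > 0)",
                 class = "mcdpa_parameter_error")
    st$atom <- rbind(st$atom, ligand_atoms(pocket_center))
    st$atom$eleno <- seq_len(nrow(st$atom))
    attr(st, "ligand_center") <- pocket_center
  }
  attr(st, "pocket_center") <- pocket_center
  st
}

#' Two-shell toy complex with a defined interface
#'
#' Chain A is a shell of radius `radius_A` centered at the origin; chain
#' B a shell of radius `radius_B` placed along +x so that the closest
#' approach of the two shells is `interface_gap`. Optionally plants a
#' small rigid HETATM ligand, either at the interface midpoint
#' (`ligand_site = "interface"`) or on the far side of chain A
#' (`"distal"`).
#'
#' @param n_nodes_A,n_nodes_B Nodes per shell (defaults 60 and 50).
#' @param radius_A,radius_B Shell radii in Angstrom (defaults 12 and 10).
#' @param interface_gap Closest shell-to-shell distance (default 4; must
#'   not exceed `cutoff` or no interface contacts can form).
#' @param ligand_site NULL (no ligand), `"interface"`, or `"distal"`.
#' @param cutoff Contact cutoff used for the interface feasibility check
#'   (default 13).
#' @param jitter,seed Lattice jitter and its seed.
#' @return An `mcdpa_structure` with attributes `ligand_center` (NULL if
#'   no ligand) and `interface_center`.
#' @export
make_two_chain_complex <- function(n_nodes_A = 60, n_nodes_B = 50,
                                   radius_A = 12, radius_B = 10,
                                   interface_gap = 4, ligand_site = NULL,
                                   cutoff = 13, jitter = 0.05, seed = 1) {
  if (interface_gap > cutoff)
    stop_mcdpa("interface gap ", interface_gap, " exceeds cutoff ", cutoff,
               ": no interface contacts possible",
               class = "mcdpa_no_interface")
  xa <- fibonacci_sphere(n_nodes_A, jitter = jitter, seed = seed) * radius_A
  xb <- fibonacci_sphere(n_nodes_B, jitter = jitter, seed = seed + 1L) *
    radius_B
  shift <- radius_A + radius_B + interface_gap
  xb[, 1L] <- xb[, 1L] + shift
  sa <- ca_structure(xa, chain = "A")
  sb <- ca_structure(xb, chain = "B", resno_offset = n_nodes_A)
  atom <- rbind(sa$atom, sb$atom)
  interface_center <- c(radius_A + interface_gap / 2, 0, 0)
  ligand_center <- NULL
  if (!is.null(ligand_site)) {
    ligand_center <- switch(match.arg(ligand_site, c("interface", "distal")),
                            interface = interface_center,
                            distal = c(-radius_A - 3, 0, 0))
    lig <- ligand_atoms(ligand_center)
    atom <- rbind(atom, lig)
  }
  atom$eleno <- seq_len(nrow(atom))
  st <- new_structure(atom, source = "synthetic:two_chain_complex")
  attr(st, "ligand_center") <- ligand_center
  attr(st, "interface_center") <- interface_center
  st
}

# Five-atom rigid cross: a minimal HETATM ligand.
ligand_atoms <- function(center, resid = "LIG", chain = "L", resno = 900L) {
  offs <- rbind(c(0, 0, 0), c(1.4, 0, 0), c(-1.4, 0, 0),
                c(0, 1.4, 0), c(0, -1.4, 0))
  xyz <- sweep(offs, 2L, center, "+")
  data.frame(
    type = "HETATM", eleno = NA_integer_,
    elety = c("C1", "C2", "C3", "O1", "O2"),
    alt = "", resid = resid, chain = chain, resno = resno, insert = "",
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    o = 1, b = 0, elesy = c("C", "C", "C", "O", "O"),
    is_water = FALSE, stringsAsFactors = FALSE
  )
}

ca_structure <- function(xyz, chain = "A", resno_offset = 0L) {
  n <- nrow(xyz)
  atom <- data.frame(
    type = "ATOM", eleno = seq_len(n) + resno_offset, elety = "CA",
    alt = "", resid = "GLY", chain = chain,
    resno = seq_len(n) + resno_offset, insert = "",
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    o = 1, b = 0, elesy = "C", is_water = FALSE,
    stringsAsFactors = FALSE
  )
  new_structure(atom, source = "synthetic:shell")
}

#' Write a structure as a fixed-column PDB file
#'
#' Coordinates are written at the format's 3-decimal precision; a
#' [read_structure()] round-trip preserves atom count and coordinates to
#' that precision. Ground-truth annotations attached to synthetic
#' fixtures (pocket center, ligand center) can be written to a JSON
#' sidecar with `sidecar = TRUE`.
#'
#' @param x An `mcdpa_structure`.
#' @param file Output path.
#' @param sidecar Also write `<file>.json` with the fixture's
#'   ground-truth attributes (default FALSE).
#' @export
write_structure <- function(x, file, sidecar = FALSE) {
  stopifnot(inherits(x, "mcdpa_structure"))
  a <- x$atom
  bio3d::write.pdb(file = file,
                   xyz = as.vector(t(coords_matrix(a))),
                   type = a$type, resno = a$resno, resid = a$resid,
                   chain = a$chain, insert = ifelse(a$insert == "", "",
                                                    a$insert),
                   elety = a$elety, o = a$o, b = a$b, elesy = a$elesy)
  if (sidecar) {
    truth <- list(pocket_center = attr(x, "pocket_center"),
                  ligand_center = attr(x, "ligand_center"),
                  interface_center = attr(x, "interface_center"))
    truth <- truth[!vapply(truth, is.null, TRUE)]
    if (length(truth) > 0)
      jsonlite::write_json(truth, paste0(file, ".json"),
                           auto_unbox = FALSE, digits = NA)
  }
  invisible(file)
}
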