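# Surface test points: randomly distributed, multi-layer, seeded.

#' Generate surface probe points around a node set
#'
#' Decorates the molecular surface with layers of randomly distributed
#' test points. For each layer offset `d`, candidate points are drawn
#' uniformly on spheres of radius `d` centered on every node (in node
#' order, from a seeded generator). A candidate survives iff (a) its
#' distance to the *nearest* node lies within `tol` of `d` — which
#' rejects points buried inside the body, because there a closer node
#' exists — and (b) it is at least `target_spacing` away from every
#' previously kept point (greedy Poisson-disk thinning in candidate
#' order). Regeneration with the same seed and nodes is bit-identical.
#'
#' @param nodes An `mcdpa_nodes` object.
#' @param layer_offsets Layer distances from the surface in Angstrom
#'   (default `c(4, 6)`, bracketing first-shell ligand-contact
#'   distances).
#' @param target_spacing Minimum spacing between kept points (default 2).
#' @param seed Integer RNG seed (required for reproducibility).
#' @param n_per_node Candidates drawn per node per layer (default 20).
#' @param tol Acceptance band around the layer offset (default 0.5).
#' @return An `mcdpa_probes` data frame with columns `id`, `x`, `y`,
#'   `z`, `layer`; attributes `seed` and `params`.
#' @export
generate_probes <- function(nodes, layer_offsets = c(4, 6),
                            target_spacing = 2, seed = 1,
                            n_per_node = 20, tol = 0.5) {
  X <- coords_matrix(nodes)
  n <- nrow(X)
  if (n < 1L) stop_mcdpa("no nodes", class = "mcdpa_generation_error")
  stopifnot(all(layer_offsets > 0), target_spacing >= 0)
  kept <- matrix(numeric(0), 0L, 3L)
  layer <- numeric(0)
  with_seed(seed, {
    for (d in layer_offsets) {
      # candidates: n_per_node uniform sphere points around each node
      z <- matrix(stats::rnorm(3L * n * n_per_node), ncol = 3L)
      z <- z / sqrt(rowSums(z^2))
      cand <- X[rep(seq_len(n), each = n_per_node), , drop = FALSE] + d * z
      nd <- apply(cross_dist(cand, X), 1L, min)
      cand <- cand[abs(nd - d) <= tol, , drop = FALSE]
      for (p in seq_len(nrow(cand))) {
        pt <- cand[p, ]
        if (nrow(kept) == 0L ||
            min(sqrt(colSums((t(kept) - pt)^2))) >= target_spacing) {
          kept <- rbind(kept, pt)
          layer <- c(layer, d)
        }
      }
    }
  })
  if (nrow(kept) == 0L)
    stop_mcdpa("no probe survived generation (pathological geometry)",
               class = "mcdpa_generation_error")
  probes <- data.frame(id = seq_len(nrow(kept)),
                       x = kept[, 1L], y = kept[, 2L], z = kept[, 3L],
                       layer = layer)
  rownames(probes) <- NULL
  attr(probes, "seed") <- seed
  attr(probes, "params") <- list(layer_offsets = layer_offsets,
                                 target_spacing = target_spacing,
                                 n_per_node = n_per_node, tol = tol)
  class(probes) <- c("mcdpa_probes", "data.frame")
  probes
}

#' Surface coverage of a probe set
#'
#' Fraction of surface-exposed nodes having at least one probe within
#' `max(layer_offsets) + tol`. Buried nodes (no probe could survive near
#' them) are excluded from the denominator: a node counts as surface-
#' exposed when the outermost probe layer band around it is not fully
#' blocked by closer nodes, estimated here by a spherical test-direction
#' scan.
#'
#' @param probes An `mcdpa_probes` object.
#' @param nodes The `mcdpa_nodes` the probes were generated on.
#' @param warn_below Emit a warning when coverage falls below this
#'   fraction (default 0.9).
#' @return List with `coverage`, `n_exposed`, `n_covered`.
#' @export
coverage_report <- function(probes, nodes, warn_below = 0.9) {
  X <- coords_matrix(nodes)
  P <- coords_matrix(probes)
  pars <- attr(probes, "params") %||% list(layer_offsets = c(4, 6), tol = 0.5)
  reach <- max(pars$layer_offsets) + pars$tol
  exposed <- vapply(seq_len(nrow(X)), function(i) {
    node_exposed(X, i, max(pars$layer_offsets), pars$tol)
  }, logical(1L))
  if (!any(exposed)) return(list(coverage = NA_real_, n_exposed = 0L,
                                 n_covered = 0L))
  dmin <- apply(cross_dist(X[exposed, , drop = FALSE], P), 1L, min)
  covered <- dmin <= reach
  cov <- mean(covered)
  if (cov < warn_below)
    warning(sprintf("probe coverage %.2f below %.2f", cov, warn_below))
  list(coverage = cov, n_exposed = sum(exposed), n_covered = sum(covered))
}

# Deterministic 26-direction scan: node i is exposed at layer d if some
# direction admits a point at distance d whose nearest node is node i
# (within tol) — the same acceptance rule probes face.
node_exposed <- function(X, i, d, tol) {
  dirs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  dirs <- dirs[rowSums(abs(dirs)) > 0, , drop = FALSE]
  dirs <- dirs / sqrt(rowSums(dirs^2))
  pts <- sweep(d * dirs, 2L, X[i, ], "+")
  nd <- apply(cross_dist(pts, X), 1L, min)
  any(abs(nd - d) <= tol)
}

#' Export probes (with optional scores) as a PDB of dummy atoms
#'
#' One chain per layer; the B-factor column carries the per-probe score
#' when `scores` is given, for coloring in molecular viewers.
#'
#' @param probes An `mcdpa_probes` object.
#' @param file Output path.
#' @param scores Optional numeric vector aligned with the probes.
#' @export
write_probes_pdb <- function(probes, file, scores = NULL) {
  layers <- sort(unique(probes$layer))
  chain <- LETTERS[match(probes$layer, layers)]
  b <- scores %||% rep(0, nrow(probes))
  bio3d::write.pdb(file = file,
                   xyz = as.vector(t(coords_matrix(probes))),
                   type = rep("HETATM", nrow(probes)),
                   resno = probes$id, resid = rep("PRB", nrow(probes)),
                   chain = chain, elety = rep("S", nrow(probes)),
                   b = round(b, 2))
  invisible(file)
}
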