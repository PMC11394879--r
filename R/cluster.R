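# Turning high-D_x probes into ranked, labeled binding-region predictions.

#' Select the high-scoring probes of a perturbation profile
#'
#' Keeps probes whose D_x reaches the value at rank
#' `ceiling(top_fraction * n)` of the descending-sorted profile; ties at
#' that threshold are all included, so the rule is deterministic.
#'
#' @param profile An `mcdpa_profile` from [score_all()].
#' @param top_fraction Fraction of probes to keep (default 0.10).
#' @return The selected rows of the profile (threshold in attribute
#'   `threshold`).
#' @export
select_high_dx <- function(profile, top_fraction = 0.10) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  if (all(profile$dx == 0)) {
    warning("all-zero perturbation profile: empty selection")
    out <- profile[integer(0), , drop = FALSE]
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  k <- ceiling(top_fraction * nrow(profile))
  thr <- sort(profile$dx, decreasing = TRUE)[k]
  out <- profile[profile$dx >= thr, , drop = FALSE]
  attr(out, "threshold") <- thr
  attr(out, "config") <- attr(profile, "config")
  out
}

#' Group selected probes into labeled clusters
#'
#' Single-linkage connected components: two probes belong to the same
#' cluster when they are joined by a chain of pairwise distances at most
#' `linkage_cutoff`. Components smaller than `min_cluster_size` are
#' discarded. Clusters are sorted by descending mean D_x (ties: larger
#' cluster first, then lexicographic centroid) and labeled alphabetically
#' from O (O, P, ..., Z, then OA, OB, ...), with primed labels (O', ...)
#' when `provenance = "complex"`.
#'
#' @param points A profile subset (rows carry x/y/z and dx), typically
#'   from [select_high_dx()].
#' @param linkage_cutoff Linkage distance in Angstrom (default 3.5,
#'   matching the overlap cutoff `r_cutoff`).
#' @param min_cluster_size Minimum surviving component size (default 5).
#' @param provenance `"monomer"` or `"complex"`.
#' @return An `mcdpa_clusters`: list with `clusters` (each a list with
#'   `label`, `points`, `n`, `mean_dx`, `centroid`) and `provenance`.
#' @export
cluster_probes <- function(points, linkage_cutoff = 3.5,
                           min_cluster_size = 5,
                           provenance = c("monomer", "complex")) {
  provenance <- match.arg(provenance)
  n <- nrow(points)
  if (n == 0L) {
    warning("no points to cluster")
    return(new_cluster_set(list(), provenance, linkage_cutoff,
                           min_cluster_size))
  }
  P <- coords_matrix(points)
  D <- cross_dist(P, P)
  adj <- which(D <= linkage_cutoff & upper.tri(D), arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(adj[, 1L]), to = as.character(adj[, 2L])),
    directed = FALSE, vertices = data.frame(name = as.character(seq_len(n))))
  memb <- igraph::components(g)$membership[as.character(seq_len(n))]
  comps <- split(seq_len(n), memb)
  comps <- comps[vapply(comps, length, 0L) >= min_cluster_size]
  if (length(comps) == 0L) {
    warning("no cluster of size >= ", min_cluster_size, " survived")
    return(new_cluster_set(list(), provenance, linkage_cutoff,
                           min_cluster_size))
  }
  clusters <- lapply(comps, function(idx) {
    pts <- points[idx, , drop = FALSE]
    rownames(pts) <- NULL
    list(points = pts, n = length(idx), mean_dx = mean(pts$dx),
         centroid = colMeans(coords_matrix(pts)))
  })
  ord <- order(
    -vapply(clusters, `[[`, 0, "mean_dx"),
    -vapply(clusters, `[[`, 0L, "n"),
    vapply(clusters, function(cl) cl$centroid[1L], 0),
    vapply(clusters, function(cl) cl$centroid[2L], 0),
    vapply(clusters, function(cl) cl$centroid[3L], 0)
  )
  clusters <- unname(clusters[ord])
  labels <- cluster_labels(length(clusters), primed = provenance == "complex")
  for (i in seq_along(clusters)) clusters[[i]]$label <- labels[i]
  new_cluster_set(clusters, provenance, linkage_cutoff, min_cluster_size)
}

new_cluster_set <- function(clusters, provenance, linkage_cutoff,
                            min_cluster_size) {
  structure(list(clusters = clusters, provenance = provenance,
                 config = list(linkage_cutoff = linkage_cutoff,
                               min_cluster_size = min_cluster_size)),
            class = "mcdpa_clusters")
}

#' @export
print.mcdpa_clusters <- function(x, ...) {
  cat("mcdpa_clusters (", x$provenance, "): ",
      length(x$clusters), " cluster(s)\n", sep = "")
  for (cl in x$clusters)
    cat(sprintf("  %-3s n=%-4d mean Dx=%.4g\n", cl$label, cl$n, cl$mean_dx))
  invisible(x)
}

# O, P, ..., Z, then OA, OB, ... ; primed variants get a trailing '.
cluster_labels <- function(n, primed = FALSE) {
  base <- LETTERS[15:26]
  if (n > length(base))
    base <- c(base, paste0("O", c(LETTERS, apply(
      expand.grid(LETTERS, LETTERS)[, 2:1], 1L, paste0, collapse = ""))))
  lab <- base[seq_len(n)]
  if (primed) paste0(lab, "'") else lab
}

#' Predict ligand-binding regions for a structure
#'
#' Runs the full pipeline: coarse-grain, build the elastic network
#' (adding inter-chain coupling springs when `chain_groups` names more
#' than one group), generate surface probes, score every probe by its
#' dynamic perturbation value, select the high-D_x subset and cluster it
#' into ranked regions.
#'
#' @param x An `mcdpa_structure`.
#' @param chain_groups NULL (treat all chains as one protein) or a list
#'   of chain-id vectors, e.g. `list(A = "A", B = "B")`; inter-group
#'   contacts get springs of constant `gamma_AB`.
#' @param cutoff,gamma,gamma_AB Elastic-network parameters (see
#'   [build_network()] and [couple_chains()]).
#' @param layer_offsets,target_spacing Probe-generation parameters.
#' @param config A [perturbation_config()].
#' @param top_fraction,linkage_cutoff,min_cluster_size Selection and
#'   clustering parameters.
#' @param seed RNG seed for probe generation.
#' @param scheme Coarse-graining scheme.
#' @return An `mcdpa_clusters` with the run configuration, profile and
#'   seed attached (`$run`).
#' @export
predict_regions <- function(x, chain_groups = NULL,
                            cutoff = 13, gamma = 1, gamma_AB = gamma,
                            layer_offsets = c(4, 6), target_spacing = 2,
                            config = perturbation_config(),
                            top_fraction = 0.10, linkage_cutoff = 3.5,
                            min_cluster_size = 5, seed = 1,
                            scheme = "calpha") {
  nodes <- coarse_grain(x, scheme = scheme)
  multi <- !is.null(chain_groups) && length(chain_groups) > 1L
  if (multi) {
    net <- build_network(nodes, cutoff = cutoff, gamma = gamma,
                         group_by_chain = TRUE)
    groups <- chain_groups
    for (i in seq_len(length(groups) - 1L)) for (j in (i + 1L):length(groups))
      net <- couple_chains(net, groups[[i]], groups[[j]],
                           gamma_AB = gamma_AB, cutoff_AB = cutoff)
  } else {
    net <- build_network(nodes, cutoff = cutoff, gamma = gamma)
  }
  probes <- generate_probes(nodes, layer_offsets = layer_offsets,
                            target_spacing = target_spacing, seed = seed)
  profile <- score_all(net, probes, config = config)
  sel <- select_high_dx(profile, top_fraction = top_fraction)
  cs <- cluster_probes(sel, linkage_cutoff = linkage_cutoff,
                       min_cluster_size = min_cluster_size,
                       provenance = if (multi) "complex" else "monomer")
  cs$run <- list(seed = seed, cutoff = cutoff, gamma = gamma,
                 gamma_AB = if (multi) gamma_AB else NA_real_,
                 layer_offsets = layer_offsets,
                 target_spacing = target_spacing,
                 gamma_s = config$gamma_s, r_int = config$r_int,
                 kl_direction = config$kl_direction,
                 top_fraction = top_fraction,
                 linkage_cutoff = linkage_cutoff,
                 min_cluster_size = min_cluster_size, scheme = scheme,
                 n_probes = nrow(probes))
  cs$profile <- profile
  cs
}

#' Export a cluster set as a PDB of dummy atoms
#'
#' One chain per cluster (first character of the label), D_x in the
#' B-factor column.
#'
#' @param clusters An `mcdpa_clusters`.
#' @param file Output path.
#' @export
write_clusters_pdb <- function(clusters, file) {
  pts <- do.call(rbind, lapply(clusters$clusters, function(cl) {
    data.frame(chain = substr(cl$label, 1L, 1L),
               x = cl$points$x, y = cl$points$y, z = cl$points$z,
               b = cl$points$dx)
  }))
  if (is.null(pts) || nrow(pts) == 0L) {
    writeLines("END", file)
    return(invisible(file))
  }
  bmax <- max(pts$b)
  bio3d::write.pdb(file = file,
                   xyz = as.vector(t(as.matrix(pts[, c("x", "y", "z")]))),
                   type = rep("HETATM", nrow(pts)),
                   resno = seq_len(nrow(pts)),
                   resid = rep("CLU", nrow(pts)), chain = pts$chain,
                   elety = rep("S", nrow(pts)),
                   b = round(99.99 * pts$b / max(bmax, 1e-12), 2))
  invisible(file)
}
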