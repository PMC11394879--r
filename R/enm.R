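# Elastic network models: spring lists, Hessians, rigid-mode-free spectra.
#
# The network is anisotropic (Cartesian 3N): each spring between nodes i,j
# contributes the 3x3 block -k * (d d^T) off-diagonal (d the unit bond
# vector) and its positive counterpart on the diagonal, i.e. the second
# derivative of the quadratic energy 1/2 sum k (r_ij - r_ij0)^2 evaluated
# at the build conformation (which is the energy minimum by construction).

#' Build an elastic network over a node set
#'
#' Connects every node pair within `cutoff` by a spring of force constant
#' `gamma`, with rest length equal to the current distance. When
#' `group_by_chain` is TRUE only intra-chain springs are created (the
#' inter-chain springs of a complex are then added by [couple_chains()]
#' with their own force constant).
#'
#' @param nodes An `mcdpa_nodes` object.
#' @param cutoff Contact cutoff in Angstrom (default 13, the conventional
#'   value for C-alpha anisotropic networks).
#' @param gamma Intra-protein spring force constant (arbitrary
#'   energy/Angstrom^2 units; only ratios of force constants matter for
#'   the perturbation scores).
#' @param group_by_chain If TRUE, omit springs that cross chains.
#' @param check_connected Assert that the spring graph is connected
#'   (default TRUE; skipped automatically when `group_by_chain` is TRUE,
#'   where per-chain connectivity is checked instead).
#' @return An `mcdpa_network`: list with `nodes`, `springs` (data frame
#'   i, j, r0, k with i < j), `gamma`, `gamma_AB` (NA until
#'   [couple_chains()]), `cutoff`.
#' @export
build_network <- function(nodes, cutoff = 13, gamma = 1,
                          group_by_chain = FALSE, check_connected = TRUE) {
  X <- coords_matrix(nodes)
  n <- nrow(X)
  if (n < 2L) stop_mcdpa("need at least 2 nodes", class = "mcdpa_model_error")
  D <- cross_dist(X, X)
  adj <- D <= cutoff
  adj[lower.tri(adj, diag = TRUE)] <- FALSE
  if (group_by_chain) {
    same <- outer(nodes$chain, nodes$chain, "==")
    adj <- adj & same
  }
  idx <- which(adj, arr.ind = TRUE)
  springs <- data.frame(i = idx[, 1L], j = idx[, 2L],
                        r0 = D[idx], k = gamma)
  springs <- springs[order(springs$i, springs$j), , drop = FALSE]
  rownames(springs) <- NULL
  net <- structure(list(nodes = nodes, springs = springs, gamma = gamma,
                        gamma_AB = NA_real_, cutoff = cutoff),
                   class = "mcdpa_network")
  if (check_connected) {
    if (group_by_chain) {
      for (ch in unique(nodes$chain)) {
        sub <- which(nodes$chain == ch)
        assert_connected(springs[springs$i %in% sub & springs$j %in% sub, ],
                         sub, what = paste0("chain ", ch))
      }
    } else {
      assert_connected(springs, seq_len(n), what = "network")
    }
  }
  net
}

assert_connected <- function(springs, node_idx, what = "network") {
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(springs$i), to = as.character(springs$j)),
    directed = FALSE,
    vertices = data.frame(name = as.character(node_idx))
  )
  comp <- igraph::components(g)
  if (comp$no > 1L)
    stop_mcdpa(what, " is disconnected at this cutoff (",
               comp$no, " components of sizes ",
               paste(comp$csize, collapse = ","), ")",
               class = "mcdpa_connectivity_error")
  invisible(TRUE)
}

#' Add inter-chain springs coupling two chain groups
#'
#' Implements the protein-protein interaction term of the model: an
#' additional harmonic energy `1/2 * sum gamma_AB (r_ij - r_ij0)^2` over
#' interface node pairs (i in chains_A, j in chains_B) within
#' `cutoff_AB`. With `gamma_AB = gamma` the coupled network is identical
#' to building a single network over all chains; `gamma_AB` is the
#' adjustable knob for protein-protein interactions of different
#' strengths, and `gamma_AB = 0` decouples the chains (no springs added).
#'
#' @param network An `mcdpa_network` (typically built with
#'   `group_by_chain = TRUE`).
#' @param chains_A,chains_B Chain id sets of the two sides.
#' @param gamma_AB Inter-chain force constant (default: the network's
#'   intra-chain `gamma`).
#' @param cutoff_AB Interface contact cutoff (default: the network's
#'   cutoff).
#' @return The network with cross-interface springs appended and
#'   `gamma_AB` recorded.
#' @export
couple_chains <- function(network, chains_A, chains_B,
                          gamma_AB = network$gamma,
                          cutoff_AB = network$cutoff) {
  stopifnot(inherits(network, "mcdpa_network"))
  nodes <- network$nodes
  ia <- which(nodes$chain %in% chains_A)
  ib <- which(nodes$chain %in% chains_B)
  if (length(ia) == 0L || length(ib) == 0L)
    stop_mcdpa("chain groups not found among node chains",
               class = "mcdpa_lookup_error")
  network$gamma_AB <- gamma_AB
  if (gamma_AB == 0) return(network)
  D <- cross_dist(coords_matrix(nodes)[ia, , drop = FALSE],
                  coords_matrix(nodes)[ib, , drop = FALSE])
  hit <- which(D <= cutoff_AB, arr.ind = TRUE)
  if (nrow(hit) == 0L) {
    warning("no cross-interface contacts within ", cutoff_AB,
            " Angstrom: complex is dynamically uncoupled")
    return(network)
  }
  ii <- ia[hit[, 1L]]; jj <- ib[hit[, 2L]]
  cross <- data.frame(i = pmin(ii, jj), j = pmax(ii, jj),
                      r0 = D[hit], k = gamma_AB)
  springs <- rbind(network$springs, cross)
  springs <- springs[!duplicated(springs[, c("i", "j")]), , drop = FALSE]
  springs <- springs[order(springs$i, springs$j), , drop = FALSE]
  rownames(springs) <- NULL
  network$springs <- springs
  network
}

#' Assemble and diagonalize the network Hessian
#'
#' Builds the 3N x 3N second-derivative matrix of the spring energy,
#' diagonalizes it, identifies the rigid-body (zero) modes by magnitude
#' and verifies them against the analytic translation/rotation
#' generators, and returns the non-rigid spectrum and eigenbasis used by
#' all downstream covariance and divergence computations. A connected
#' network has exactly 6 rigid modes; a deliberately decoupled complex
#' (`gamma_AB = 0`) has 6 per rigid body, and the count is asserted
#' against the spring-graph component structure.
#'
#' @param network An `mcdpa_network`.
#' @param rigid_tol Relative threshold separating rigid from internal
#'   modes (default 1e-8 of the largest eigenvalue).
#' @return An `mcdpa_hessian`: list with `hessian`, `basis` (3N x
#'   (3N - 6 n_bodies) orthonormal non-rigid eigenvectors),
#'   `eigenvalues` (ascending, non-rigid only), `log_pseudodet`,
#'   `n_nodes`, `n_bodies`.
#' @export
assemble_hessian <- function(network, rigid_tol = 1e-8) {
  stopifnot(inherits(network, "mcdpa_network"))
  X <- coords_matrix(network$nodes)
  n <- nrow(X)
  H <- matrix(0, 3L * n, 3L * n)
  sp <- network$springs
  for (s in seq_len(nrow(sp))) {
    i <- sp$i[s]; j <- sp$j[s]
    d <- X[j, ] - X[i, ]
    u <- d / sqrt(sum(d^2))
    K <- sp$k[s] * tcrossprod(u)
    bi <- (3L * i - 2L):(3L * i); bj <- (3L * j - 2L):(3L * j)
    H[bi, bi] <- H[bi, bi] + K
    H[bj, bj] <- H[bj, bj] + K
    H[bi, bj] <- H[bi, bj] - K
    H[bj, bi] <- H[bj, bi] - K
  }
  ev <- eigen(H, symmetric = TRUE)
  vals <- rev(ev$values)            # ascending
  vecs <- ev$vectors[, rev(seq_len(3L * n)), drop = FALSE]
  tol <- rigid_tol * max(vals)
  n_rigid <- sum(vals < tol)
  bodies <- spring_graph_components(sp, n)
  n_bodies <- max(bodies)
  if (n_rigid != 6L * n_bodies)
    stop_mcdpa("expected ", 6L * n_bodies, " rigid modes (", n_bodies,
               " rigid bodies), found ", n_rigid,
               " (geometry degenerate or network underconstrained)",
               class = "mcdpa_model_error")
  rigid_vecs <- vecs[, seq_len(n_rigid), drop = FALSE]
  gen <- do.call(cbind, lapply(seq_len(n_bodies), function(b) {
    G <- matrix(0, 3L * n, 6L)
    members <- which(bodies == b)
    rows <- as.vector(vapply(members, function(i) (3L * i - 2L):(3L * i),
                             integer(3L)))
    G[rows, ] <- rigid_generators(X[members, , drop = FALSE])
    G
  }))
  gen <- qr.Q(qr(gen))
  ov <- crossprod(gen, rigid_vecs)  # rigid space must match the generators
  if (min(svd(ov)$d) < 0.99)
    stop_mcdpa("near-zero modes do not span rigid-body motions",
               class = "mcdpa_model_error")
  nonrigid <- seq.int(n_rigid + 1L, 3L * n)
  structure(list(
    hessian = H,
    basis = vecs[, nonrigid, drop = FALSE],
    eigenvalues = vals[nonrigid],
    log_pseudodet = sum(log(vals[nonrigid])),
    n_nodes = n,
    n_bodies = n_bodies
  ), class = "mcdpa_hessian")
}

# Component labels of the spring graph (zero-constant springs ignored).
spring_graph_components <- function(springs, n) {
  live <- springs[springs$k > 0, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(live$i), to = as.character(live$j)),
    directed = FALSE, vertices = data.frame(name = as.character(seq_len(n))))
  as.integer(igraph::components(g)$membership[as.character(seq_len(n))])
}

# Orthonormal basis of the 6 rigid-body motions (3 translations + 3
# rotations about the centroid) of a non-collinear point set.
rigid_generators <- function(X) {
  n <- nrow(X)
  Xc <- sweep(X, 2L, colMeans(X))
  G <- matrix(0, 3L * n, 6L)
  for (a in 1:3) G[seq.int(a, 3L * n, by = 3L), a] <- 1
  for (i in seq_len(n)) {
    r <- Xc[i, ]
    G[(3L * i - 2L):(3L * i), 4L] <- c(0, -r[3L], r[2L])
    G[(3L * i - 2L):(3L * i), 5L] <- c(r[3L], 0, -r[1L])
    G[(3L * i - 2L):(3L * i), 6L] <- c(-r[2L], r[1L], 0)
  }
  qr.Q(qr(G))
}

#' Apply the Hessian pseudo-inverse within the internal-motion subspace
#'
#' Projects `v` onto the non-rigid eigenbasis, scales by the inverse
#' eigenvalues and reconstructs, i.e. returns `H^+ v`. Rigid-body
#' components of `v` map to zero.
#'
#' @param bundle An `mcdpa_hessian`.
#' @param v A length-3N vector or 3N x m matrix.
#' @return `H^+ v`, orthogonal to the rigid modes.
#' @export
quadratic_form_solve <- function(bundle, v) {
  stopifnot(inherits(bundle, "mcdpa_hessian"))
  v <- as.matrix(v)
  w <- crossprod(bundle$basis, v) / bundle$eigenvalues
  out <- bundle$basis %*% w
  if (ncol(out) == 1L) drop(out) else out
}
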