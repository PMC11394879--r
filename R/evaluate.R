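# Scoring predictions against ligands and classifying the changes that a
# protein-protein interaction induces in ligands and predicted regions.

#' Precision and recall of a predicted region against a ligand
#'
#' With cluster points C and ligand atoms L, the overlap sets are
#' `c = {s in C : d(s, L) < r_cutoff}` and
#' `l = {a in L : d(a, C) < r_cutoff}` (strict inequality), and
#' `P = |c|/|C|`, `R = |l|/|L|`.
#'
#' @param cluster A cluster (element of `mcdpa_clusters$clusters`) or any
#'   data frame of points with x/y/z.
#' @param ligand An `mcdpa_ligand` (same coordinate frame).
#' @param r_cutoff Overlap cutoff in Angstrom (default 3.5).
#' @return List with `precision`, `recall`, `n_cluster`, `n_ligand`,
#'   `overlap_points` (indices into the cluster), `covered_atoms`
#'   (indices into the ligand), `hit` (at least one covered ligand atom),
#'   `r_cutoff`.
#' @export
precision_recall <- function(cluster, ligand, r_cutoff = 3.5) {
  C <- cluster_coords(cluster)
  if (nrow(C) == 0L)
    stop_mcdpa("empty cluster: precision undefined",
               class = "mcdpa_empty_cluster")
  L <- coords_matrix(ligand$atoms)
  D <- cross_dist(C, L)
  overlap_points <- which(apply(D, 1L, min) < r_cutoff)
  covered_atoms <- which(apply(D, 2L, min) < r_cutoff)
  list(precision = length(overlap_points) / nrow(C),
       recall = length(covered_atoms) / nrow(L),
       n_cluster = nrow(C), n_ligand = nrow(L),
       overlap_points = overlap_points, covered_atoms = covered_atoms,
       hit = length(covered_atoms) >= 1L, r_cutoff = r_cutoff)
}

cluster_coords <- function(cluster) {
  if (is.list(cluster) && !is.null(cluster$points))
    coords_matrix(cluster$points)
  else coords_matrix(cluster)
}

#' Best predicted region per ligand
#'
#' For each ligand, selects the cluster maximizing recall (ties: higher
#' precision, then label order) and reports its precision/recall plus a
#' hit flag (at least one ligand atom within `r_cutoff` of the cluster).
#'
#' @param clusters An `mcdpa_clusters`.
#' @param ligands List of `mcdpa_ligand` objects.
#' @param r_cutoff Overlap cutoff (default 3.5).
#' @return Data frame with one row per ligand: `ligand_id`, `cluster`,
#'   `precision`, `recall`, `hit`.
#' @export
best_region_report <- function(clusters, ligands, r_cutoff = 3.5) {
  rows <- lapply(ligands, function(lig) {
    if (length(clusters$clusters) == 0L)
      return(data.frame(ligand_id = lig$ligand_id, cluster = NA_character_,
                        precision = 0, recall = 0, hit = FALSE))
    ev <- lapply(clusters$clusters, precision_recall, ligand = lig,
                 r_cutoff = r_cutoff)
    rec <- vapply(ev, `[[`, 0, "recall")
    prec <- vapply(ev, `[[`, 0, "precision")
    best <- order(-rec, -prec, seq_along(ev))[1L]
    data.frame(ligand_id = lig$ligand_id,
               cluster = clusters$clusters[[best]]$label,
               precision = prec[best], recall = rec[best],
               hit = ev[[best]]$hit)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify changes between monomer- and complex-based cluster sets
#'
#' After mapping the monomer-based predictions into the complex frame
#' (via the shared-protein superposition), computes for every cluster
#' pair (C, C') the two overlap fractions |{s in C: d(s,C') < r_cutoff}|
#' / |C| and |{s in C': d(s,C) < r_cutoff}| / |C'|. A bipartite link
#' exists when either fraction reaches `link_threshold`. Components of
#' the link graph are classified: isolated monomer cluster -> vanished;
#' isolated complex cluster -> created; 1-1 with both fractions >=
#' `strong_threshold` -> unchanged, otherwise shifted; 1-many -> split;
#' many-1 -> merged. Many-many components are first decomposed greedily
#' by descending link strength into star-shaped sub-components.
#'
#' @param mono `mcdpa_clusters` from the monomer.
#' @param complexed `mcdpa_clusters` from the complex.
#' @param transform `mcdpa_transform` mapping the monomer frame onto the
#'   complex frame (identity by default).
#' @param r_cutoff Overlap cutoff (default 3.5).
#' @param link_threshold Minimum overlap fraction for a link (default
#'   0.2).
#' @param strong_threshold Both-ways fraction above which a 1-1 link
#'   counts as unchanged (default 0.5).
#' @return List of `mcdpa_cluster_change` records (fields `kind`,
#'   `sources`, `targets`); every cluster appears in exactly one record.
#'   A frame-mismatch warning is attached as attribute `alignment_warning`
#'   when the transform's fit RMSD exceeds 10 Angstrom.
#' @export
compare_cluster_sets <- function(mono, complexed,
                                 transform = identity_transform(),
                                 r_cutoff = 3.5, link_threshold = 0.2,
                                 strong_threshold = 0.5) {
  mono_pts <- lapply(mono$clusters, function(cl)
    apply_transform(transform, cluster_coords(cl)))
  comp_pts <- lapply(complexed$clusters, cluster_coords)
  nm <- length(mono_pts); nc <- length(comp_pts)
  links <- NULL
  if (nm > 0L && nc > 0L) {
    for (i in seq_len(nm)) for (j in seq_len(nc)) {
      D <- cross_dist(mono_pts[[i]], comp_pts[[j]])
      f_mono <- mean(apply(D, 1L, min) < r_cutoff)
      f_comp <- mean(apply(D, 2L, min) < r_cutoff)
      if (max(f_mono, f_comp) >= link_threshold)
        links <- rbind(links, data.frame(i = i, j = j, f_mono = f_mono,
                                         f_comp = f_comp,
                                         strength = max(f_mono, f_comp)))
    }
  }
  changes <- list()
  linked_m <- integer(0); linked_c <- integer(0)
  if (!is.null(links)) {
    links <- links[order(-links$strength, links$i, links$j), , drop = FALSE]
    # Greedy decomposition into star components (1-1, 1-many, many-1),
    # strongest links first. A link is kept when at most one endpoint is
    # already linked, and that endpoint is not a leaf hanging off a hub
    # (degree 1 with a partner of degree > 1) - otherwise a many-many
    # component would form.
    deg_m <- integer(nm); deg_c <- integer(nc)
    keep <- logical(nrow(links))
    for (k in seq_len(nrow(links))) {
      i <- links$i[k]; j <- links$j[k]
      if (deg_m[i] > 0L && deg_c[j] > 0L) next
      if (deg_m[i] > 0L) {
        partners <- links$j[keep & links$i == i]
        if (any(deg_c[partners] > 1L)) next  # i is a leaf of a complex hub
      }
      if (deg_c[j] > 0L) {
        partners <- links$i[keep & links$j == j]
        if (any(deg_m[partners] > 1L)) next  # j is a leaf of a monomer hub
      }
      keep[k] <- TRUE
      deg_m[i] <- deg_m[i] + 1L
      deg_c[j] <- deg_c[j] + 1L
    }
    links <- links[keep, , drop = FALSE]
    linked_m <- unique(links$i); linked_c <- unique(links$j)
    # components of the kept (star-shaped) link graph
    seen_m <- logical(nm); seen_c <- logical(nc)
    for (i in linked_m) {
      if (seen_m[i]) next
      js <- links$j[links$i == i]
      is <- unique(links$i[links$i == i | links$j %in% js])
      js <- unique(links$j[links$i %in% is])
      seen_m[is] <- TRUE; seen_c[js] <- TRUE
      sub <- links[links$i %in% is & links$j %in% js, , drop = FALSE]
      kind <-
        if (length(is) == 1L && length(js) == 1L) {
          if (sub$f_mono[1L] >= strong_threshold &&
              sub$f_comp[1L] >= strong_threshold) "unchanged" else "shifted"
        } else if (length(is) == 1L) "split" else "merged"
      changes[[length(changes) + 1L]] <- new_cluster_change(
        kind,
        sources = vapply(is, function(ii) mono$clusters[[ii]]$label, ""),
        targets = vapply(js, function(jj) complexed$clusters[[jj]]$label, "")
      )
    }
  }
  for (i in setdiff(seq_len(nm), linked_m))
    changes[[length(changes) + 1L]] <- new_cluster_change(
      "vanished", sources = mono$clusters[[i]]$label, targets = character())
  for (j in setdiff(seq_len(nc), linked_c))
    changes[[length(changes) + 1L]] <- new_cluster_change(
      "created", sources = character(), targets = complexed$clusters[[j]]$label)
  if (is.finite(transform$fit_rmsd) && transform$fit_rmsd > 10)
    attr(changes, "alignment_warning") <-
      sprintf("shared-protein fit RMSD %.2f A exceeds sanity bound 10 A",
              transform$fit_rmsd)
  changes
}

new_cluster_change <- function(kind, sources, targets) {
  structure(list(kind = kind, sources = sources, targets = targets),
            class = "mcdpa_cluster_change")
}

#' @export
print.mcdpa_cluster_change <- function(x, ...) {
  src <- if (length(x$sources)) paste(x$sources, collapse = ",") else "0"
  tgt <- if (length(x$targets)) paste(x$targets, collapse = ",") else "0"
  cat(sprintf("%s: {%s} -> {%s}\n", x$kind, src, tgt))
  invisible(x)
}

#' Classify the change a protein-protein interaction induces in a ligand
#'
#' Matches the ligand inventories of a monomer structure (A-L1) and a
#' complex structure (B-A-L2) by residue name and pocket proximity
#' (centroids within `match_distance` after superposing the shared
#' protein), then classifies:
#' \itemize{
#'   \item matched, same size, ARMSD < 1 Angstrom: `unchanged`
#'   \item matched, same size, ARMSD >= 1 Angstrom: `shifted`
#'   \item monomer-only ligand: `disappeared`
#'   \item complex-only ligand: `new_ligand`
#'   \item more residue units on the complex side (monomer units
#'     recombined into an oligomer, or several monomer entities matching
#'     one complex entity): `fused`
#'   \item fewer residue units on the complex side: `split`
#' }
#'
#' @param mono_ligands,complex_ligands Lists of `mcdpa_ligand`.
#' @param transform `mcdpa_transform` mapping the complex frame onto the
#'   monomer frame.
#' @param match_distance Centroid matching distance (default 8).
#' @param armsd_threshold Unchanged/shifted boundary (default 1).
#' @return List of `mcdpa_ligand_change` records: `category`, `armsd`
#'   (an `mcdpa_armsd` or NULL), `mono_ids`, `complex_ids`.
#' @export
classify_ligand_change <- function(mono_ligands, complex_ligands,
                                   transform = identity_transform(),
                                   match_distance = 8,
                                   armsd_threshold = 1) {
  if (length(mono_ligands) == 0L && length(complex_ligands) == 0L)
    stop_mcdpa("no ligands on either side", class = "mcdpa_no_ligand")
  cen_m <- t(vapply(mono_ligands, function(l)
    colMeans(coords_matrix(l$atoms)), numeric(3L)))
  cen_c <- t(vapply(complex_ligands, function(l)
    colMeans(coords_matrix(l$atoms)), numeric(3L)))
  if (length(complex_ligands) > 0L)
    cen_c <- apply_transform(transform, cen_c)
  pairs <- NULL
  for (i in seq_along(mono_ligands)) for (j in seq_along(complex_ligands)) {
    share <- any(unique(toupper(mono_ligands[[i]]$atoms$resid)) %in%
                   unique(toupper(complex_ligands[[j]]$atoms$resid)))
    d <- sqrt(sum((cen_m[i, ] - cen_c[j, ])^2))
    if (share && d <= match_distance)
      pairs <- rbind(pairs, data.frame(i = i, j = j, d = d))
  }
  changes <- list()
  used_m <- integer(0); used_c <- integer(0)
  if (!is.null(pairs)) {
    pairs <- pairs[order(pairs$d), , drop = FALSE]
    # greedy star decomposition, nearest matches first
    deg_m <- integer(length(mono_ligands))
    deg_c <- integer(length(complex_ligands))
    keep <- logical(nrow(pairs))
    for (k in seq_len(nrow(pairs))) {
      if (deg_m[pairs$i[k]] > 0L && deg_c[pairs$j[k]] > 0L) next
      keep[k] <- TRUE
      deg_m[pairs$i[k]] <- deg_m[pairs$i[k]] + 1L
      deg_c[pairs$j[k]] <- deg_c[pairs$j[k]] + 1L
    }
    pairs <- pairs[keep, , drop = FALSE]
    seen <- logical(nrow(pairs))
    for (k in seq_len(nrow(pairs))) {
      if (seen[k]) next
      grp <- pairs$i == pairs$i[k] | pairs$j == pairs$j[k]
      seen[grp] <- TRUE
      is <- unique(pairs$i[grp]); js <- unique(pairs$j[grp])
      used_m <- c(used_m, is); used_c <- c(used_c, js)
      units_m <- sum(vapply(mono_ligands[is], function(l) as.numeric(l$n_residues), 0))
      units_c <- sum(vapply(complex_ligands[js], function(l) as.numeric(l$n_residues), 0))
      if (units_c > units_m) {
        category <- "fused"; armsd <- NULL
      } else if (units_c < units_m) {
        category <- "split"; armsd <- NULL
      } else {
        armsd <- tryCatch(
          compute_armsd(mono_ligands[[is[1L]]], complex_ligands[[js[1L]]],
                        transform, mode = "atom_match"),
          mcdpa_no_correspondence = function(e)
            compute_armsd(mono_ligands[[is[1L]]], complex_ligands[[js[1L]]],
                          transform, mode = "center_of_mass"))
        category <- if (armsd$value < armsd_threshold) "unchanged"
                    else "shifted"
      }
      changes[[length(changes) + 1L]] <- structure(
        list(category = category, armsd = armsd,
             mono_ids = vapply(mono_ligands[is], `[[`, "", "ligand_id"),
             complex_ids = vapply(complex_ligands[js], `[[`, "",
                                  "ligand_id")),
        class = "mcdpa_ligand_change")
    }
  }
  for (i in setdiff(seq_along(mono_ligands), used_m))
    changes[[length(changes) + 1L]] <- structure(
      list(category = "disappeared", armsd = NULL,
           mono_ids = mono_ligands[[i]]$ligand_id,
           complex_ids = character()),
      class = "mcdpa_ligand_change")
  for (j in setdiff(seq_along(complex_ligands), used_c))
    changes[[length(changes) + 1L]] <- structure(
      list(category = "new_ligand", armsd = NULL,
           mono_ids = character(),
           complex_ids = complex_ligands[[j]]$ligand_id),
      class = "mcdpa_ligand_change")
  changes
}

#' Tally a list of change records
#' @param changes List of `mcdpa_cluster_change` or `mcdpa_ligand_change`.
#' @return Named integer vector of counts per kind/category.
#' @export
change_summary <- function(changes) {
  kinds <- vapply(changes, function(x) x$kind %||% x$category, "")
  table(kinds)
}
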