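test_that("precision_recall matches brute-force counting with strict cutoff", {
  # full overlap
  C <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0), ncol = 3, byrow = TRUE)
  lig <- make_ligand(C + 0.5)
  res <- precision_recall(make_cluster(C), lig)
  expect_equal(res$precision, 1)
  expect_equal(res$recall, 1)
  expect_true(res$hit)

  # total miss at 50 A
  far <- make_ligand(C + 50)
  res0 <- precision_recall(make_cluster(C), far)
  expect_equal(res0$precision, 0)
  expect_equal(res0$recall, 0)
  expect_false(res0$hit)

  # random instances against the all-pairs oracle, including the strict
  # "<" rule at an exactly-realized distance
  with_seed <- get("with_seed", asNamespace("mcdpa"))
  for (seed in 1:25) {
    Cpts <- with_seed(seed, matrix(runif(3 * 12, 0, 12), ncol = 3))
    Lpts <- with_seed(seed + 100, matrix(runif(3 * 9, 0, 12), ncol = 3))
    res <- precision_recall(make_cluster(Cpts), make_ligand(Lpts),
                            r_cutoff = 3.5)
    orc <- oracle_precision_recall(Cpts, Lpts, 3.5)
    expect_identical(res$precision, unname(orc["precision"]))
    expect_identical(res$recall, unname(orc["recall"]))
  }
  # a point at exactly r_cutoff does not count (strict inequality)
  exact <- precision_recall(make_cluster(matrix(c(0, 0, 0), 1)),
                            make_ligand(matrix(c(3.5, 0, 0), 1)),
                            r_cutoff = 3.5)
  expect_equal(exact$precision, 0)

  empty_cl <- list(label = "O",
                   points = data.frame(x = numeric(0), y = numeric(0),
                                       z = numeric(0)))
  expect_error(precision_recall(empty_cl, lig),
               class = "mcdpa_empty_cluster")
})

test_that("precision and recall are non-decreasing in r_cutoff", {
  with_seed <- get("with_seed", asNamespace("mcdpa"))
  Cpts <- with_seed(7, matrix(runif(45, 0, 15), ncol = 3))
  Lpts <- with_seed(8, matrix(runif(30, 0, 15), ncol = 3))
  cl <- make_cluster(Cpts); lig <- make_ligand(Lpts)
  rs <- c(1, 2, 3.5, 5, 8)
  prec <- vapply(rs, function(r) precision_recall(cl, lig, r)$precision, 0)
  rec <- vapply(rs, function(r) precision_recall(cl, lig, r)$recall, 0)
  expect_true(all(diff(prec) >= 0))
  expect_true(all(diff(rec) >= 0))
})

test_that("best_region_report picks the highest-recall cluster per ligand", {
  near <- make_cluster(matrix(c(0, 0, 0, 1, 0, 0), ncol = 3, byrow = TRUE),
                       label = "O")
  far <- make_cluster(matrix(c(50, 0, 0, 51, 0, 0), ncol = 3, byrow = TRUE),
                      label = "P")
  lig <- make_ligand(matrix(c(0.5, 0, 0), 1))
  cs <- make_cluster_set(list(near, far))
  rep1 <- best_region_report(cs, list(lig))
  expect_equal(rep1$cluster, "O")
  expect_equal(rep1$recall, 1)

  # exhaustive enumeration on a 3-cluster / 2-ligand toy
  with_seed <- get("with_seed", asNamespace("mcdpa"))
  cls <- lapply(1:3, function(k)
    make_cluster(with_seed(k, matrix(runif(24, 0, 10), ncol = 3)),
                 label = c("O", "P", "Q")[k]))
  ligs <- lapply(1:2, function(k)
    make_ligand(with_seed(10 + k, matrix(runif(15, 0, 10), ncol = 3)),
                resid = paste0("L", k)))
  cs3 <- make_cluster_set(cls)
  rep3 <- best_region_report(cs3, ligs)
  for (li in 1:2) {
    evs <- lapply(cls, function(cl) precision_recall(cl, ligs[[li]]))
    recs <- vapply(evs, `[[`, 0, "recall")
    precs <- vapply(evs, `[[`, 0, "precision")
    best <- order(-recs, -precs)[1]
    expect_equal(rep3$cluster[li], cls[[best]]$label)
    expect_equal(rep3$recall[li], recs[best])
  }

  # empty cluster set: all-miss report
  rep0 <- best_region_report(make_cluster_set(list()), ligs)
  expect_true(all(!rep0$hit))
  expect_true(all(rep0$recall == 0))
})

test_that("cluster-change taxonomy classifies all six kinds", {
  blob <- function(center, label, n = 8) {
    with_seed <- get("with_seed", asNamespace("mcdpa"))
    make_cluster(sweep(with_seed(sum(utf8ToInt(label)),
                                 matrix(rnorm(3 * n, sd = 1.2), ncol = 3)),
                       2, center, "+"), label = label)
  }
  O <- blob(c(0, 0, 0), "O")
  P <- blob(c(30, 0, 0), "P")

  # identical sets -> all unchanged
  mono <- make_cluster_set(list(O, P))
  comp_same <- make_cluster_set(list(
    make_cluster(as.matrix(O$points[, c("x", "y", "z")]), "O'"),
    make_cluster(as.matrix(P$points[, c("x", "y", "z")]), "P'")),
    provenance = "complex")
  ch <- compare_cluster_sets(mono, comp_same)
  expect_setequal(vapply(ch, `[[`, "", "kind"),
                  "unchanged")
  expect_length(ch, 2L)

  # disjoint sets -> vanished + created
  comp_far <- make_cluster_set(list(blob(c(100, 0, 0), "O'")),
                               provenance = "complex")
  ch2 <- compare_cluster_sets(mono, comp_far)
  kinds2 <- sort(vapply(ch2, `[[`, "", "kind"))
  expect_equal(kinds2, c("created", "vanished", "vanished"))

  # partial 1-1 overlap below the strong threshold -> shifted:
  # 8 collinear points spaced 1 A, copy shifted by 9 A -> 2/8 = 0.25 of
  # each cluster lies within 3.5 A of the other (>= 0.2, < 0.5)
  line <- cbind(0:7, 0, 0)
  ch3 <- compare_cluster_sets(
    make_cluster_set(list(make_cluster(line, "O"))),
    make_cluster_set(list(make_cluster(sweep(line, 2, c(9, 0, 0), "+"),
                                       "O'")), "complex"))
  expect_equal(ch3[[1]]$kind, "shifted")

  # one mono cluster overlapping two complex clusters -> split
  left <- as.matrix(O$points[, c("x", "y", "z")])
  ch4 <- compare_cluster_sets(
    make_cluster_set(list(O)),
    make_cluster_set(list(make_cluster(left[1:4, ], "O'"),
                          make_cluster(left[5:8, ] + 0.2, "P'")),
                     "complex"))
  expect_equal(ch4[[1]]$kind, "split")
  expect_length(ch4[[1]]$targets, 2L)

  # two mono clusters overlapping one complex cluster -> merged
  ch5 <- compare_cluster_sets(
    make_cluster_set(list(make_cluster(left[1:4, ], "O"),
                          make_cluster(left[5:8, ] + 0.2, "P"))),
    make_cluster_set(list(O_shift <- make_cluster(left, "O'")), "complex"))
  expect_equal(ch5[[1]]$kind, "merged")
  expect_length(ch5[[1]]$sources, 2L)
})

test_that("cluster-change classification is invariant to relabeling and
           rigid motion, and partitions every cluster exactly once", {
  with_seed <- get("with_seed", asNamespace("mcdpa"))
  mk <- function(center, label)
    make_cluster(sweep(with_seed(sum(utf8ToInt(label)) + 3,
                                 matrix(rnorm(24, sd = 1.5), ncol = 3)),
                       2, center, "+"), label)
  mono <- make_cluster_set(list(mk(c(0, 0, 0), "O"), mk(c(25, 0, 0), "P"),
                                mk(c(0, 25, 0), "Q")))
  comp <- make_cluster_set(list(mk(c(0, 0, 1), "O'"), mk(c(60, 0, 0), "P'"),
                                mk(c(25, 1, 0), "Q'")), "complex")
  ch <- compare_cluster_sets(mono, comp)
  all_src <- unlist(lapply(ch, `[[`, "sources"))
  all_tgt <- unlist(lapply(ch, `[[`, "targets"))
  expect_setequal(all_src, c("O", "P", "Q"))
  expect_setequal(all_tgt, c("O'", "P'", "Q'"))
  expect_equal(anyDuplicated(all_src), 0L)
  expect_equal(anyDuplicated(all_tgt), 0L)

  # relabeling: reverse the cluster order on both sides
  mono_r <- make_cluster_set(rev(mono$clusters))
  comp_r <- make_cluster_set(rev(comp$clusters), "complex")
  ch_r <- compare_cluster_sets(mono_r, comp_r)
  key <- function(chs) sort(vapply(chs, function(x)
    paste(x$kind, paste(sort(x$sources), collapse = ","),
          paste(sort(x$targets), collapse = ",")), ""))
  expect_equal(key(ch_r), key(ch))

  # common rigid transform of both point sets
  R <- random_rotation(17); shift <- c(7, -4, 2)
  move_set <- function(cs) {
    cs$clusters <- lapply(cs$clusters, function(cl) {
      xyz <- sweep(tcrossprod(as.matrix(cl$points[, c("x", "y", "z")]), R),
                   2, -shift)
      make_cluster(xyz, cl$label)
    })
    cs
  }
  ch_m <- compare_cluster_sets(move_set(mono), move_set(comp))
  expect_equal(key(ch_m), key(ch))
})

test_that("ligand-change taxonomy classifies all six categories", {
  xyz <- rbind(c(0, 0, 0), c(1.4, 0, 0), c(0, 1.4, 0), c(0, 0, 1.4))
  gdp_mono <- make_ligand(xyz, resid = "GDP")

  # unchanged: same ligand, sub-Angstrom displacement
  gdp_near <- make_ligand(xyz + 0.3, resid = "GDP")
  ch_u <- classify_ligand_change(list(gdp_mono), list(gdp_near))
  expect_equal(ch_u[[1]]$category, "unchanged")
  expect_lt(ch_u[[1]]$armsd$value, 1)

  # shifted: displacement above 1 A
  gdp_shift <- make_ligand(sweep(xyz, 2, c(2.5, 0, 0), "+"), resid = "GDP")
  ch_s <- classify_ligand_change(list(gdp_mono), list(gdp_shift))
  expect_equal(ch_s[[1]]$category, "shifted")
  expect_equal(ch_s[[1]]$armsd$value, 2.5, tolerance = 1e-9)

  # disappeared / new ligand
  ch_d <- classify_ligand_change(list(gdp_mono), list())
  expect_equal(ch_d[[1]]$category, "disappeared")
  ch_n <- classify_ligand_change(list(), list(gdp_mono))
  expect_equal(ch_n[[1]]$category, "new_ligand")
  expect_error(classify_ligand_change(list(), list()),
               class = "mcdpa_no_ligand")

  # fused: one NAG in the monomer, linked tri-NAG oligomer in the complex
  nag1 <- make_ligand(xyz, resid = "NAG")
  tri <- nag1
  tri_atoms <- do.call(rbind, lapply(0:2, function(k) {
    a <- nag1$atoms
    a$resno <- 900L + k
    a$x <- a$x + 1.45 * k
    a
  }))
  tri$atoms <- tri_atoms
  tri$n_atoms <- nrow(tri_atoms)
  tri$residues <- paste0("L|", 900:902, "||NAG")
  tri$n_residues <- 3L
  ch_f <- classify_ligand_change(list(nag1), list(tri))
  expect_equal(ch_f[[1]]$category, "fused")
  # and the reverse direction is a split
  ch_sp <- classify_ligand_change(list(tri), list(nag1))
  expect_equal(ch_sp[[1]]$category, "split")
})

test_that("ligand matching respects the pocket-proximity radius", {
  xyz <- rbind(c(0, 0, 0), c(1.4, 0, 0), c(0, 1.4, 0))
  a <- make_ligand(xyz, resid = "ATP")
  b_near <- make_ligand(xyz + 2, resid = "ATP")
  b_far <- make_ligand(xyz + 30, resid = "ATP")
  ch <- classify_ligand_change(list(a), list(b_far))
  kinds <- sort(vapply(ch, `[[`, "", "category"))
  expect_equal(kinds, c("disappeared", "new_ligand"))
  ch2 <- classify_ligand_change(list(a), list(b_near))
  expect_length(ch2, 1L)
  expect_equal(ch2[[1]]$category, "shifted")
})
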