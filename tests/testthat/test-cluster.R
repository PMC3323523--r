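make_sig <- function(mean, t_rel = seq(-82, 40, 2)) {
  structure(list(t_rel = t_rel, mean = mean, sem = rep(0, length(t_rel)),
                 n = rep(10L, length(t_rel))),
            class = "recruitment_signature")
}

test_that("the pre-scission window has the expected grid", {
  sig <- make_sig(seq_along(seq(-82, 40, 2)))
  v <- prescission_window(sig, c(-82, 0))
  expect_length(v, 42)
  expect_equal(as.numeric(names(v)[1]), -82)
  expect_equal(as.numeric(names(v)[42]), 0)
  expect_error(prescission_window(sig, c(-100, 0)), "window")
})

test_that("windowing before or after the distance gives the same result", {
  set.seed(2)
  t_rel <- seq(-82, 40, 2)
  curves <- lapply(1:4, function(i) abs(rnorm(length(t_rel))) + 0.5)
  names(curves) <- letters[1:4]
  sigs <- lapply(curves, make_sig)
  pre <- lapply(sigs, prescission_window)
  d1 <- cosine_distance_matrix(signature_set(pre))
  full <- do.call(rbind, curves)
  win <- t_rel >= -82 & t_rel <= 0
  d2 <- cosine_distance_matrix(full[, win])
  expect_equal(unname(d1), unname(d2), tolerance = 1e-14)
})

test_that("cosine distances match first principles", {
  expect_equal(cosine_distance_matrix(rbind(a = c(1, 2, 3),
                                            b = c(2, 4, 6)))["a", "b"], 0,
               tolerance = 1e-14)
  expect_equal(cosine_distance_matrix(rbind(a = c(1, 0), b = c(0, 1)))["a", "b"],
               1)
  # brute-force double-loop oracle on random curves
  set.seed(5)
  m <- matrix(rnorm(5 * 42), 5, dimnames = list(paste0("c", 1:5), NULL))
  d <- cosine_distance_matrix(m)
  for (i in 1:5) for (j in 1:5) {
    ui <- m[i, ]; uj <- m[j, ]
    expect_equal(d[i, j],
                 if (i == j) 0 else
                 1 - sum(ui * uj) / sqrt(sum(ui^2) * sum(uj^2)),
                 tolerance = 1e-12)
  }
  expect_error(cosine_distance_matrix(rbind(a = c(0, 0), b = c(1, 1))), "a")
  # centred variant equals 1 - Pearson correlation
  dc <- cosine_distance_matrix(m, centered = TRUE)
  expect_equal(dc[1, 2], 1 - cor(m[1, ], m[2, ]), tolerance = 1e-12)
})

test_that("three-leaf UPGMA merges are forced by the distances", {
  d <- matrix(c(0, 0.1, 0.5, 0.1, 0, 0.5, 0.5, 0.5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- average_linkage(d)
  expect_equal(tree$height, c(0.1, 0.5))
  expect_equal(sort(tree$merge[1, ]), c(-2, -1))  # A and B first
})

test_that("UPGMA equals the reference agglomeration on random matrices", {
  set.seed(8)
  for (n in c(4, 5, 6)) {
    for (rep in 1:4) {
      m <- matrix(runif(n * 20), n,
                  dimnames = list(paste0("s", 1:n), NULL))
      d <- cosine_distance_matrix(m)
      mine <- average_linkage(d)
      ref <- stats::hclust(stats::as.dist(d), method = "average")
      expect_equal(sort(mine$height), sort(ref$height), tolerance = 1e-12)
      expect_equal(stats::cophenetic(mine), stats::cophenetic(ref),
                   tolerance = 1e-12)
      wm <- average_linkage(d, weighted = TRUE)
      wr <- stats::hclust(stats::as.dist(d), method = "mcquitty")
      expect_equal(sort(wm$height), sort(wr$height), tolerance = 1e-12)
    }
  }
})

test_that("permuting labels yields an isomorphic tree", {
  set.seed(12)
  m <- matrix(runif(5 * 30), 5, dimnames = list(paste0("s", 1:5), NULL))
  d <- cosine_distance_matrix(m)
  t1 <- average_linkage(d)
  p <- c(3, 1, 5, 2, 4)
  t2 <- average_linkage(d[p, p])
  expect_equal(sort(t1$height), sort(t2$height), tolerance = 1e-14)
  c1 <- stats::cophenetic(t1); c2 <- stats::cophenetic(t2)
  m1 <- as.matrix(c1); m2 <- as.matrix(c2)[labels(c1), labels(c1)]
  expect_equal(m1, m2, tolerance = 1e-14)
})

test_that("cophenetic correlation is exact on ultrametric input", {
  # an ultrametric matrix is reproduced exactly by UPGMA
  d <- matrix(c(0, 0.2, 0.6, 0.6,
                0.2, 0, 0.6, 0.6,
                0.6, 0.6, 0, 0.3,
                0.6, 0.6, 0.3, 0), 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tree <- average_linkage(d)
  expect_equal(cophenetic_correlation(tree, d), 1.0, tolerance = 1e-12)
})

test_that("cophenetic correlation matches an explicit LCA oracle", {
  set.seed(19)
  m <- matrix(runif(5 * 25), 5, dimnames = list(paste0("s", 1:5), NULL))
  d <- cosine_distance_matrix(m)
  tree <- average_linkage(d)
  # brute-force oracle via stats::cophenetic on the hclust object
  r_ref <- cor(d[upper.tri(d)],
               as.matrix(stats::cophenetic(tree))[rownames(d),
                                                  rownames(d)][upper.tri(d)])
  expect_equal(cophenetic_correlation(tree, d), r_ref, tolerance = 1e-12)
  # scale invariance
  expect_equal(cophenetic_correlation(average_linkage(d * 10), d * 10),
               cophenetic_correlation(tree, d), tolerance = 1e-12)
  expect_error(cophenetic_correlation(average_linkage(d[1:2, 1:2]),
                                      d[1:2, 1:2]), "3")
})

test_that("dendrograms export as parseable Newick", {
  d <- matrix(c(0, 0.1, 0.5, 0.1, 0, 0.5, 0.5, 0.5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- average_linkage(d)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, f)
  phy <- ape::read.tree(f)
  expect_setequal(phy$tip.label, c("A", "B", "C"))
})

test_that("synthetic kinetic classes cluster into their true partition", {
  classes <- c("wt", "slow_burst", "early_enriched")
  curves <- list()
  for (cl in classes) for (r in 1:2) {
    cfg <- sim_config(n_cycles = 250, field_size = 64,
                      nucleation_rate = 0.035, kinetic_class = cl)
    sim <- simulate_movie(cfg, seed = 500 + 10 * match(cl, classes) + r)
    ev <- truth_events(sim$truth, 250)
    tr <- extract_aligned_traces(sim$movie$reporter, ev, c(-82, 0), 2)
    sig <- ensemble_signature(tr)
    curves[[paste0(cl, "_", r)]] <- prescission_window(sig)
  }
  D <- cosine_distance_matrix(signature_set(curves))
  tree <- average_linkage(D)
  cl3 <- stats::cutree(tree, k = 3)
  expect_equal(adjusted_rand_index(cl3, rep(1:3, each = 2)), 1)
})
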