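test_that("generated connectomes are simple, symmetric, connected, on-density", {
  p <- gen_parcellation(20, 2, seed = 1)
  near_full <- gen_connectome(p, target_density = 0.97, seed = 1)
  expect_gt(sum(near_full$adjacency) / (20 * 19), 0.9)
  for (s in 1:4) {
    cn <- gen_connectome(fix_parc_small, target_density = 0.12, seed = s)
    a <- cn$adjacency
    expect_identical(a, t(a))
    expect_true(all(diag(a) == 0))
    expect_true(all(a %in% 0:1))
    g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    expect_equal(igraph::components(g)$no, 1)
    dens <- sum(a) / (nrow(a) * (nrow(a) - 1))
    expect_lt(abs(dens - 0.12) / 0.12, 0.2)
  }
  expect_error(gen_connectome(fix_parc_small, length_scale = -1), "positive")
})

test_that("shorter wiring length scale yields shorter mean edge lengths", {
  mean_len <- function(ls, s) {
    cn <- gen_connectome(fix_parc, target_density = 0.08, length_scale = ls,
                         seed = s)
    mean(cn$distance[upper.tri(cn$distance) & cn$adjacency == 1])
  }
  short <- vapply(1:50, function(s) mean_len(0.3, s), numeric(1))
  long <- vapply(1:50, function(s) mean_len(1.5, s), numeric(1))
  expect_lt(mean(short), mean(long))
})

test_that("consensus backbone reproduces unanimous individual networks", {
  cn <- gen_connectome(fix_parc_small, seed = 3)
  ind <- list(cn$adjacency, cn$adjacency, cn$adjacency)
  bb <- consensus_backbone(ind, parcellation = fix_parc_small)
  expect_identical(bb$adjacency, cn$adjacency)
})

test_that("backbone edge count equals the rounded mean individual count", {
  ind <- lapply(1:5, function(s)
    gen_connectome(fix_parc_small, target_density = 0.1 + 0.01 * s,
                   seed = s)$adjacency)
  bb <- consensus_backbone(ind, parcellation = fix_parc_small)
  expect_equal(sum(bb$adjacency) / 2,
               round(mean(vapply(ind, function(a) sum(a) / 2, numeric(1)))))
})

test_that("more frequent edges win the bin quota (hand-checkable toy)", {
  # 5 nodes, 1 bin, no hemispheres: edge (1,2) in 3/3 subjects, (1,3) in 2/3,
  # (2,3) in 1/3; mean count 2 -> quota 2 keeps (1,2) and (1,3)
  e <- function(pairs) {
    a <- matrix(0, 5, 5)
    for (pr in pairs) a[pr[1], pr[2]] <- a[pr[2], pr[1]] <- 1
    a
  }
  ind <- list(e(list(c(1, 2), c(1, 3))), e(list(c(1, 2), c(1, 3))),
              e(list(c(1, 2), c(2, 3))))
  d <- matrix(1, 5, 5); diag(d) <- 0
  bb <- consensus_backbone(ind, distances = d, n_bins = 1)
  expect_equal(bb$adjacency[1, 2], 1)
  expect_equal(bb$adjacency[1, 3], 1)
  expect_equal(bb$adjacency[2, 3], 0)
  expect_equal(sum(bb$adjacency) / 2, 2)
})

test_that("consensus backbone is permutation-equivariant", {
  ind <- lapply(1:4, function(s) gen_connectome(fix_parc_small, seed = s)$adjacency)
  d <- euclidean_distance_matrix(fix_parc_small)
  bb <- consensus_backbone(ind, distances = d, n_bins = 5)
  set.seed(7)
  perm <- sample(fix_parc_small$n)
  ind_p <- lapply(ind, function(a) a[perm, perm])
  bb_p <- consensus_backbone(ind_p, distances = d[perm, perm], n_bins = 5)
  expect_identical(bb_p$adjacency, bb$adjacency[perm, perm])
})

test_that("graph diameter matches hand-enumerated toys and errors when disconnected", {
  expect_identical(graph_diameter(toy_path4), 3L)
  expect_identical(graph_diameter(toy_k3), 1L)
  expect_identical(graph_diameter(toy_cycle6), 3L)
  disc <- as_connectome(rbind(c(0, 1, 0, 0), c(1, 0, 0, 0),
                              c(0, 0, 0, 1), c(0, 0, 1, 0)))
  expect_error(graph_diameter(disc), "disconnected.*component")
})

test_that("nodal efficiency matches closed-form toy values", {
  expect_equal(nodal_efficiency(toy_star4)[1], 1.0)
  expect_equal(nodal_efficiency(toy_path3)[1], (1 + 1 / 2) / 2)
  expect_equal(nodal_efficiency(toy_k3), rep(1, 3))
})

test_that("mean first passage time solves the first-step system on toys", {
  # K3: every pairwise hitting time is 2 (h = 1 + h/2)
  expect_equal(mean_first_passage_time(toy_k3), rep(2, 3))
  # path 1-2-3: h(2->1) = 3, h(3->1) = 4; ends symmetric; middle gets 1
  expect_equal(mean_first_passage_time(toy_path3), c(3.5, 1, 3.5))
})

test_that("mean first passage time agrees with a Monte-Carlo walk oracle", {
  set.seed(42)
  g <- igraph::sample_gnp(12, 0.35)
  while (igraph::components(g)$no > 1) g <- igraph::sample_gnp(12, 0.35)
  cn <- as_connectome(as.matrix(igraph::as_adjacency_matrix(g)))
  exact <- mean_first_passage_time(cn)
  for (target in c(1, 7)) {
    mc <- mc_mfpt_nodal(cn, target, n_walks = 1e5)
    expect_lt(abs(mc - exact[target]) / exact[target], 0.02)
  }
})

test_that("participation coefficient matches its definition and bounds", {
  sys2 <- c(1, 1, 2, 2)
  # all edges within own system -> 0
  within <- as_connectome(rbind(c(0, 1, 0, 0), c(1, 0, 0, 0),
                                c(0, 0, 0, 1), c(0, 0, 1, 0)))
  expect_equal(participation_coefficient(within, sys2), rep(0, 4))
  # degree-2 node with one edge into each system -> 1 - 2*(1/2)^2 = 0.5
  mixed <- as_connectome(rbind(c(0, 1, 1, 0), c(1, 0, 0, 0),
                               c(1, 0, 0, 1), c(0, 0, 1, 0)))
  expect_equal(participation_coefficient(mixed, sys2)[1], 0.5)
  pc <- participation_coefficient(fix_conn, fix_parc$system)
  k <- length(unique(fix_parc$system))
  expect_true(all(pc >= 0 & pc <= 1 - 1 / k + 1e-12))
})

test_that("euclidean distances form a metric with correct extremes", {
  d <- euclidean_distance_matrix(fix_parc_small)
  expect_true(all(diag(d) == 0))
  expect_identical(d, t(d))
  expect_equal(max(d), max(dist(fix_parc_small$centroids)))
  # triangle inequality on random triples
  set.seed(1)
  for (i in 1:50) {
    tri <- sample(fix_parc_small$n, 3)
    expect_lte(d[tri[1], tri[3]], d[tri[1], tri[2]] + d[tri[2], tri[3]] + 1e-12)
  }
  # antipodal unit vectors are 2 apart
  anti <- as.matrix(dist(rbind(c(0, 0, 1), c(0, 0, -1))))
  expect_equal(anti[1, 2], 2)
})
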