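test_that("perfect-LD components form clusters; remaining markers are singletons", {
  # 3 markers all pairwise r^2 = 1 -> one cluster, no singletons
  r2 <- matrix(1, 3, 3)
  cl <- build_clusters(as_ld_matrix(r2))
  expect_length(cl$clusters, 1)
  expect_equal(cl$clusters[[1]]$member_ids, c("m01", "m02", "m03"))
  expect_length(cl$singletons, 0)
  # two separate blocks of 2 with weak cross-LD
  r2b <- diag(4)
  r2b[1, 2] <- r2b[2, 1] <- 1
  r2b[3, 4] <- r2b[4, 3] <- 1
  r2b[r2b == 0] <- 0.2
  clb <- build_clusters(as_ld_matrix(r2b))
  expect_length(clb$clusters, 2)
  expect_equal(clb$clusters[[1]]$name, "m01")
  expect_equal(clb$clusters[[2]]$name, "m03")
})

test_that("clusters are named by their first (leftmost) member and sorted by span", {
  r2 <- diag(4)
  r2[2, 4] <- r2[4, 2] <- 1   # markers at pos 200 and 400 form a block
  r2[1, 3] <- r2[3, 1] <- 1   # markers at pos 100 and 300 form a block
  mk <- data.frame(id = sprintf("m%02d", 1:4), chrom = "9",
                   pos = c(100L, 200L, 300L, 400L))
  cl <- build_clusters(as_ld_matrix(r2), markers = mk)
  expect_equal(vapply(cl$clusters, `[[`, "", "name"), c("m01", "m02"))
  expect_equal(cl$clusters[[1]]$min_pos, 100L)
  expect_equal(cl$clusters[[1]]$max_pos, 300L)
  expect_equal(cl$clusters[[2]]$positions, c(200L, 400L))
})

test_that("components match the igraph oracle and clique flags match exhaustive checking", {
  set.seed(515)
  for (rep in 1:50) {
    k <- sample(4:10, 1)
    r2 <- random_symmetric_r2(k)
    ldm <- as_ld_matrix(r2 >= 0.6)  # pre-thresholded 0/1 matrix
    ldm$r2 <- (r2 >= 0.6) * 1
    cl <- suppressWarnings(build_clusters(ldm, epsilon = 1e-6))
    adj <- ldm$r2 >= 1 - 1e-6; diag(adj) <- FALSE
    memb <- oracle_components(adj)
    got <- membership_of(ldm$marker_ids, cl$clusters, cl$singletons)
    expect_equal(adjusted_rand_index(memb, got[ldm$marker_ids]), 1)
    # clique verification warnings agree with exhaustive pair checking
    non_clique <- any(vapply(split(seq_len(k), memb), function(g)
      length(g) >= 2 && !oracle_is_clique(adj, g), logical(1)))
    expect_identical(non_clique,
                     length(capture_warnings(build_clusters(ldm, epsilon = 1e-6))) > 0)
  }
})

test_that("cluster membership is invariant to marker input order", {
  sim <- simulate_panel(block_spec(n_snps = c(3, 2), maf = 0.3, n_samples = 60,
                                   seed = 9))
  p <- sim$panel
  cl1 <- build_clusters(r2_matrix(p), markers = p$markers)
  perm <- sample(ncol(p$geno))
  # re-sorting by position happens inside genotype_panel; feed shuffled ldm
  ldm <- r2_matrix(p, marker_subset = perm)
  cl2 <- build_clusters(ldm, markers = p$markers)
  ids <- p$markers$id
  m1 <- membership_of(ids, cl1$clusters, cl1$singletons)
  m2 <- membership_of(ids, cl2$clusters, cl2$singletons)
  expect_equal(adjusted_rand_index(m1, m2), 1)
})

test_that("cluster distance is 1 minus the mean defined cross-pair r^2", {
  r2 <- matrix(0.75, 4, 4); diag(r2) <- 1
  r2[1, 2] <- r2[2, 1] <- 1; r2[3, 4] <- r2[4, 3] <- 1
  ldm <- as_ld_matrix(r2)
  expect_equal(cluster_distance(ldm, c("m01", "m02"), c("m03", "m04")), 0.25)
  expect_equal(cluster_distance(ldm, c("m01", "m02"), c("m01", "m02")), 0)
  und <- as_ld_matrix(r2, defined = {
    d <- matrix(TRUE, 4, 4); d[1:2, 3:4] <- FALSE; d[3:4, 1:2] <- FALSE; d
  })
  expect_error(cluster_distance(und, c("m01", "m02"), c("m03", "m04")),
               "no defined cross-pair")
  expect_warning(d <- cluster_distance_matrix(und, list(c("m01", "m02"),
                                                        c("m03", "m04"))),
                 "maximal distance")
  expect_equal(d[1, 2], 1)
})

test_that("with exact perfect blocks the mean distance equals any representative pair", {
  sim <- simulate_panel(block_spec(n_snps = c(3, 4), maf = c(0.25, 0.35),
                                   n_samples = 200, cross_corr = 0.6, seed = 21))
  ldm <- r2_matrix(sim$panel)
  cl <- build_clusters(ldm, markers = sim$panel$markers)
  expect_length(cl$clusters, 2)
  a <- cl$clusters[[1]]$member_ids; b <- cl$clusters[[2]]$member_ids
  d_mean <- cluster_distance(ldm, a, b)
  d_rep <- 1 - ldm$r2[a[1], b[1]]
  expect_equal(d_mean, d_rep, tolerance = 1e-9)
})

test_that("UPGMA merges at average distances with deterministic tie-breaks", {
  # 2 items at distance 0.3 -> single merge at 0.3
  d2 <- matrix(c(0, 0.3, 0.3, 0), 2, 2)
  dg <- agglomerate(d2)
  expect_equal(dg$height, 0.3)
  expect_equal(nrow(dg$merge), 1)
  # 3 items: (1,2)@0.1 then ({1,2},3)@0.5
  d3 <- matrix(c(0, 0.1, 0.5,
                 0.1, 0, 0.5,
                 0.5, 0.5, 0), 3, 3)
  dg3 <- agglomerate(d3)
  expect_equal(dg3$height, c(0.1, 0.5))
  expect_equal(dendro_merge_sets(dg3), list(c(1L, 2L), c(1L, 2L, 3L)))
  expect_equal(leaf_order(dg3), c(1L, 2L, 3L))
  # all-equal distances merge at the common height throughout
  d_eq <- matrix(0.4, 4, 4); diag(d_eq) <- 0
  dg_eq <- agglomerate(d_eq)
  expect_equal(dg_eq$height, rep(0.4, 3))
  # contract errors
  expect_error(agglomerate(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  expect_error(agglomerate(matrix(c(0, -1, -1, 0), 2, 2)), "non-negative")
})

test_that("UPGMA matches the naive recompute-everything oracle on random matrices", {
  set.seed(626)
  for (rep in 1:25) {
    d <- matrix(0, 6, 6)
    d[upper.tri(d)] <- runif(15)
    d <- d + t(d)
    dg <- agglomerate(d)
    oracle <- oracle_upgma(d)
    expect_equal(dg$height, oracle$heights, tolerance = 1e-12)
    expect_equal(dendro_merge_sets(dg), oracle$sets)
    # merge heights are non-decreasing (no inversions under average linkage)
    expect_true(all(diff(dg$height) >= -1e-12))
  }
})

test_that("UPGMA heights agree with stats::hclust average linkage", {
  set.seed(727)
  for (rep in 1:10) {
    d <- matrix(0, 7, 7)
    d[upper.tri(d)] <- runif(21)
    d <- d + t(d)
    dg <- agglomerate(d)
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    expect_equal(dg$height, hc$height, tolerance = 1e-12)
  }
})

test_that("leaf order is a nesting-consistent permutation; subtrees are contiguous", {
  set.seed(828)
  for (rep in 1:20) {
    k <- sample(3:9, 1)
    d <- matrix(0, k, k)
    d[upper.tri(d)] <- runif(k * (k - 1) / 2)
    d <- d + t(d)
    dg <- agglomerate(d)
    ord <- leaf_order(dg)
    expect_setequal(ord, seq_len(k))
    for (set in dendro_merge_sets(dg)) {
      run <- range(match(set, ord))
      expect_equal(diff(run) + 1L, length(set))  # contiguous run
    }
  }
})

test_that("single-cluster dendrograms and Newick export work end to end", {
  dg1 <- agglomerate(matrix(0, 1, 1), labels = "solo")
  expect_equal(leaf_order(dg1), 1L)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(dg1, f)
  expect_equal(readLines(f), "solo;")
  d3 <- matrix(c(0, 0.2, 0.8, 0.2, 0, 0.8, 0.8, 0.8, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  write_dendrogram_newick(agglomerate(d3), f)
  tree <- ape::read.tree(f)
  expect_setequal(tree$tip.label, c("a", "b", "c"))
})

test_that("epsilon = 0 with exact duplicate genotype columns still clusters", {
  p <- duplicate_into_blocks(balanced_independent_pair(16))
  ldm <- r2_matrix(p)
  cl <- build_clusters(ldm, markers = p$markers, epsilon = 0)
  expect_length(cl$clusters, 2)
  expect_equal(cl$clusters[[1]]$member_ids, c("rsA", "rsA_dup"))
})
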