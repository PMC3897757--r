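# Independent oracles and fixture builders. Everything here recomputes
# results by routes the package itself never takes.

# ---- two-locus likelihood oracle -------------------------------------------

# Observed-data log-likelihood of a 3x3 dosage table, written out longhand
# (independent of the package's internals).
oracle_loglik <- function(pAB, pAb, paB, pab, tab) {
  P <- rbind(c(pAB^2, 2 * pAB * pAb, pAb^2),
             c(2 * pAB * paB, 2 * (pAB * pab + pAb * paB), 2 * pAb * pab),
             c(paB^2, 2 * paB * pab, pab^2))
  keep <- tab > 0
  if (any(P[keep] <= 0)) return(-Inf)
  sum(tab[keep] * log(P[keep]))
}

# Brute-force likelihood maximizer. For complete data the likelihood fixes
# both marginal allele frequencies at their sample values, so the search is
# a refined 1-D grid over p_AB on its Frechet interval (still a grid-search
# maximizer, independent of the EM path).
oracle_em_grid <- function(tab) {
  N <- sum(tab)
  pa <- sum(tab * matrix(0:2, 3, 3)) / (2 * N)            # minor at locus 1
  pb <- sum(tab * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * N)
  pA <- 1 - pa; pB <- 1 - pb
  lo <- max(0, pA + pB - 1); hi <- min(pA, pB)
  ll <- function(pAB) oracle_loglik(pAB, pA - pAB, pB - pAB, 1 - pA - pB + pAB, tab)
  width <- hi - lo
  center <- (lo + hi) / 2
  for (round in 1:8) {
    grid <- seq(max(lo, center - width / 2), min(hi, center + width / 2),
                length.out = 401L)
    vals <- vapply(grid, ll, numeric(1))
    center <- grid[which.max(vals)]
    width <- width / 100
  }
  pAB <- center
  c(AB = pAB, Ab = pA - pAB, aB = pB - pAB, ab = 1 - pA - pB + pAB)
}

# 3x3 dosage table straight from two dosage vectors (no package code).
oracle_pair_table <- function(g1, g2) {
  keep <- !is.na(g1) & !is.na(g2)
  table(factor(g1[keep], 0:2), factor(g2[keep], 0:2))
}

# ---- phased-haplotype fixtures ---------------------------------------------

# Panel built from explicit phased haplotype pairs. `haps` is a 2-column
# matrix of haplotype codes 1..4 = AB, Ab, aB, ab; rows are individuals.
panel_from_haplotypes <- function(haps, ids = c("rsL", "rsR"),
                                  positions = c(1000L, 2000L)) {
  dos1 <- c(0L, 0L, 1L, 1L)  # minor-allele dosage contributed at locus 1
  dos2 <- c(0L, 1L, 0L, 1L)  # and at locus 2, per haplotype code
  geno <- cbind(dos1[haps[, 1]] + dos1[haps[, 2]],
                dos2[haps[, 1]] + dos2[haps[, 2]])
  ldhier::genotype_panel(
    markers = data.frame(id = ids, chrom = "1", pos = positions,
                         stringsAsFactors = FALSE),
    samples = sprintf("I%03d", seq_len(nrow(haps))), geno = geno)
}

# Random complete-data panel with double heterozygotes, drawn from true
# haplotype frequencies; returns the panel plus the phased haplotype codes.
random_phased_panel <- function(n_samples, p = c(0.4, 0.2, 0.1, 0.3)) {
  codes <- sample.int(4L, 2L * n_samples, replace = TRUE, prob = p)
  haps <- matrix(codes, ncol = 2L)
  list(panel = panel_from_haplotypes(haps), haps = haps)
}

# Squared Pearson correlation of the two latent indicator vectors of a
# phased haplotype code matrix.
oracle_hap_r2 <- function(haps) {
  codes <- as.vector(haps)
  x <- as.integer(codes %in% c(3L, 4L))  # minor allele at locus 1
  y <- as.integer(codes %in% c(2L, 4L))  # minor allele at locus 2
  stats::cor(x, y)^2
}

# A panel with double heterozygotes whose phase composition makes the
# phased haplotype counts an exact fixed point of the EM: haplotype counts
# AB=8, Ab=4, aB=4, ab=8 (w = 0.8), 5 double heterozygotes of which 4 are
# AB/ab. 12 samples.
fixture_fixed_point_panel <- function() {
  haps <- rbind(
    matrix(c(1L, 4L), 4L, 2L, byrow = TRUE),  # 4 x AB/ab (double het)
    c(2L, 3L),                                # 1 x Ab/aB (double het)
    matrix(c(1L, 2L), 3L, 2L, byrow = TRUE),  # 3 x AB/Ab
    c(1L, 3L),                                # 1 x AB/aB
    matrix(c(3L, 4L), 2L, 2L, byrow = TRUE),  # 2 x aB/ab
    c(4L, 4L))                                # 1 x ab/ab
  list(panel = panel_from_haplotypes(haps), haps = haps)
}

# ---- clustering oracles -----------------------------------------------------

# Components of the thresholded graph via igraph (independent of the
# package's union-find), as a membership vector.
oracle_components <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  igraph::components(g)$membership
}

# Exhaustive clique check of a member subset under the thresholded graph.
oracle_is_clique <- function(adj, members) {
  if (length(members) < 2L) return(TRUE)
  sub <- adj[members, members, drop = FALSE]
  all(sub[upper.tri(sub)])
}

# Naive average-linkage oracle: recomputes every pairwise average distance
# from the original matrix at every step; ties broken by the smallest
# (i, j) position pair in the current cluster list, merged cluster
# replacing position i. Returns per-step heights and merged member sets.
oracle_upgma <- function(d) {
  k <- nrow(d)
  groups <- as.list(seq_len(k))
  heights <- numeric(0)
  merged_sets <- list()
  while (length(groups) > 1L) {
    n <- length(groups)
    best <- NULL; bestd <- Inf
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      avg <- mean(d[groups[[i]], groups[[j]]])
      if (avg < bestd) { bestd <- avg; best <- c(i, j) }
    }
    heights <- c(heights, bestd)
    newg <- c(groups[[best[1]]], groups[[best[2]]])
    merged_sets[[length(merged_sets) + 1L]] <- sort(newg)
    groups[[best[1]]] <- newg
    groups[[best[2]]] <- NULL
  }
  list(heights = heights, sets = merged_sets)
}

# Member sets at each merge of an ld_dendrogram, for comparison with the
# naive oracle.
dendro_merge_sets <- function(dg) {
  sets <- vector("list", nrow(dg$merge))
  leaves <- function(node) {
    if (node < 0L) return(-node)
    sets[[node]]
  }
  for (s in seq_len(nrow(dg$merge)))
    sets[[s]] <- sort(c(leaves(dg$merge[s, 1]), leaves(dg$merge[s, 2])))
  sets
}

# ---- partition comparison ---------------------------------------------------

# Adjusted Rand index between two label vectors.
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# Membership labels over a fixed id universe from a clustering result
# (clusters + singletons); singletons get unique labels.
membership_of <- function(ids, clusters, singletons) {
  lab <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  nxt <- 0L
  for (cl in clusters) {
    mem <- if (inherits(cl, "ld_cluster")) cl$member_ids else cl
    nxt <- nxt + 1L
    lab[mem] <- nxt
  }
  for (s in singletons) { nxt <- nxt + 1L; lab[s] <- nxt }
  lab
}

# Random symmetric matrix in [0, 1] with unit diagonal.
random_symmetric_r2 <- function(k) {
  m <- matrix(stats::runif(k * k), k, k)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 1
  m
}

# Wrap a plain r2 matrix as an ld_matrix-shaped object.
as_ld_matrix <- function(r2, ids = sprintf("m%02d", seq_len(nrow(r2))),
                         defined = NULL) {
  dimnames(r2) <- list(ids, ids)
  if (is.null(defined)) defined <- matrix(TRUE, nrow(r2), ncol(r2))
  dimnames(defined) <- dimnames(r2)
  structure(list(marker_ids = ids, r2 = r2, defined = defined),
            class = "ld_matrix")
}
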