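# Union-find with path compression; components of the perfect-LD graph.
.uf_components <- function(k, edges) {
  parent <- seq_len(k)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(edges)) for (e in seq_len(nrow(edges))) {
    ra <- find(edges[e, 1L]); rb <- find(edges[e, 2L])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  vapply(seq_len(k), find, integer(1))
}

#' Build perfect-LD clusters from an LD matrix
#'
#' Two markers are joined when their r-squared is defined and at least
#' `1 - epsilon`; clusters are the connected components of size >= 2 of that
#' graph. With complete data perfect correlation is transitive, so
#' components are automatically cliques; a verification pass warns about any
#' non-clique component, which can only arise through missing-data artifacts
#' or externally supplied r-squared tables. All remaining markers are
#' singletons.
#'
#' @param ldm an `ld_matrix` (see [r2_matrix()]).
#' @param markers optional data.frame with columns `id`, `chrom`, `pos` used
#'   to order members by genomic position and fill in cluster spans; without
#'   it, members keep their `ldm` order and spans are `NA`.
#' @param epsilon tolerance below exact 1 (default 1e-6) absorbing
#'   floating-point noise in EM-derived r-squared values.
#' @return List with `clusters` (list of `ld_cluster` objects: `member_ids`,
#'   `name` = id of the first/leftmost member, `chrom`, `min_pos`,
#'   `max_pos`, `positions`), sorted by `min_pos`, and `singletons`
#'   (character vector of marker ids).
#' @export
build_clusters <- function(ldm, markers = NULL, epsilon = 1e-6) {
  stopifnot(epsilon >= 0)
  ids <- ldm$marker_ids
  k <- length(ids)
  if (!k) return(list(clusters = list(), singletons = character()))
  thr <- 1 - epsilon
  adj <- ldm$defined & !is.na(ldm$r2) & ldm$r2 >= thr
  diag(adj) <- FALSE
  edges <- which(adj & upper.tri(adj), arr.ind = TRUE)
  comp <- .uf_components(k, edges)
  pos <- chrom <- NULL
  if (!is.null(markers)) {
    m <- match(ids, markers$id)
    if (anyNA(m)) stop("markers table is missing ids present in the LD matrix")
    pos <- markers$pos[m]
    chrom <- markers$chrom[m]
  }
  clusters <- list()
  singleton_idx <- integer()
  for (grp in split(seq_len(k), comp)) {
    if (length(grp) < 2L) { singleton_idx <- c(singleton_idx, grp); next }
    sub <- adj[grp, grp, drop = FALSE]
    if (!all(sub[upper.tri(sub)]))
      warning("perfect-LD component {", paste(ids[grp], collapse = ", "),
              "} is not a clique at r^2 >= ", format(thr),
              " (missing-data artifact); kept as one cluster")
    o <- if (is.null(pos)) order(grp) else order(pos[grp])
    grp <- grp[o]
    clusters[[length(clusters) + 1L]] <- structure(list(
      member_ids = ids[grp],
      name = ids[grp][1L],
      chrom = if (is.null(chrom)) NA_character_ else chrom[grp][1L],
      min_pos = if (is.null(pos)) NA_integer_ else min(pos[grp]),
      max_pos = if (is.null(pos)) NA_integer_ else max(pos[grp]),
      positions = if (is.null(pos)) rep(NA_integer_, length(grp)) else pos[grp]
    ), class = "ld_cluster")
  }
  if (length(clusters)) {
    key <- vapply(clusters, function(cl)
      if (is.na(cl$min_pos)) Inf else as.numeric(cl$min_pos), numeric(1))
    idx <- vapply(clusters, function(cl) match(cl$member_ids[1L], ids), integer(1))
    clusters <- clusters[order(key, idx)]
  }
  singles <- ids[singleton_idx]
  if (!is.null(pos)) singles <- singles[order(pos[singleton_idx])]
  list(clusters = clusters, singletons = singles)
}

#' @export
print.ld_cluster <- function(x, ...) {
  cat("cluster", x$name, "(", length(x$member_ids), "SNPs,",
      x$chrom, ":", x$min_pos, "-", x$max_pos, ")\n")
  invisible(x)
}

#' Distance between two clusters
#'
#' `1 - mean(r^2)` over all defined cross-pairs between members of the two
#' clusters. Under exact perfect LD within blocks every cross-pair is equal,
#' so the mean coincides with any single representative pair; the mean is
#' robust when epsilon-tolerant blocks make cross-pairs differ slightly.
#'
#' @param ldm an `ld_matrix`.
#' @param a_ids,b_ids member id vectors of the two clusters (or `ld_cluster`
#'   objects).
#' @return Distance in `[0, 1]`.
#' @export
cluster_distance <- function(ldm, a_ids, b_ids) {
  if (inherits(a_ids, "ld_cluster")) a_ids <- a_ids$member_ids
  if (inherits(b_ids, "ld_cluster")) b_ids <- b_ids$member_ids
  a <- match(a_ids, ldm$marker_ids); b <- match(b_ids, ldm$marker_ids)
  if (anyNA(a) || anyNA(b)) stop("cluster members absent from the LD matrix")
  if (!length(a) || !length(b)) stop("empty cluster")
  r2 <- ldm$r2[a, b, drop = FALSE]
  ok <- ldm$defined[a, b, drop = FALSE]
  if (!any(ok))
    stop("no defined cross-pair between clusters {",
         paste(a_ids, collapse = ","), "} and {", paste(b_ids, collapse = ","), "}")
  1 - mean(r2[ok])
}

#' Pairwise distance matrix over a list of clusters
#'
#' Applies [cluster_distance()] to every cluster pair. A pair with no
#' defined cross-pair (reachable only through sparse precomputed r-squared
#' tables) is assigned the maximal distance 1 with a warning.
#'
#' @param ldm an `ld_matrix`.
#' @param clusters list of `ld_cluster` objects (or plain id vectors).
#' @return Symmetric numeric matrix with zero diagonal, labelled by cluster
#'   names.
#' @export
cluster_distance_matrix <- function(ldm, clusters) {
  k <- length(clusters)
  nm <- vapply(seq_len(k), function(i) {
    cl <- clusters[[i]]
    if (inherits(cl, "ld_cluster")) cl$name else as.character(cl[[1L]])
  }, character(1))
  d <- matrix(0, k, k, dimnames = list(nm, nm))
  if (k >= 2L) for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    d[i, j] <- d[j, i] <- tryCatch(
      cluster_distance(ldm, clusters[[i]], clusters[[j]]),
      error = function(e) {
        warning("no defined cross-pair between clusters ", nm[i], " and ",
                nm[j], "; using maximal distance 1")
        1
      })
  }
  d
}

#' Average-linkage (UPGMA) agglomeration
#'
#' Repeatedly merges the pair of current nodes with minimal average
#' inter-member distance; the merge height is that average. Ties are broken
#' by the smallest (row, column) position pair in the current node list, so
#' the output is platform-independent. Average linkage admits no inversions
#' on a proper distance matrix, so merge heights are non-decreasing.
#'
#' @param d square symmetric non-negative distance matrix (zero diagonal),
#'   optionally labelled.
#' @param labels leaf labels (default: `d` dimnames or `1..k`).
#' @return Object of class `ld_dendrogram`: `merge` and `height` in
#'   `stats::hclust` convention, `order` (left-to-right leaf permutation,
#'   see [leaf_order()]), `labels`. A single item yields an empty merge
#'   list.
#' @export
agglomerate <- function(d, labels = NULL) {
  d <- as.matrix(d)
  k <- nrow(d)
  if (k == 0L) stop("empty distance matrix")
  if (ncol(d) != k || !isTRUE(all.equal(d, t(d), tolerance = 1e-12,
                                        check.attributes = FALSE)))
    stop("distance matrix must be square and symmetric")
  if (any(d < 0)) stop("distances must be non-negative")
  if (is.null(labels))
    labels <- if (!is.null(rownames(d))) rownames(d) else as.character(seq_len(k))
  # active nodes: id < 0 => leaf -id; id > 0 => merge row id (hclust style)
  nodes <- -seq_len(k)
  sizes <- rep(1L, k)
  cur <- d
  merge <- matrix(0L, max(k - 1L, 0L), 2L)
  height <- numeric(max(k - 1L, 0L))
  for (s in seq_len(k - 1L)) {
    n <- length(nodes)
    best <- c(NA_integer_, NA_integer_); bestd <- Inf
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (cur[i, j] < bestd) { bestd <- cur[i, j]; best <- c(i, j) }
    }
    i <- best[1L]; j <- best[2L]
    a <- nodes[i]; b <- nodes[j]
    merge[s, ] <- sort(c(a, b))
    height[s] <- bestd
    # Lance-Williams update for average linkage
    ni <- sizes[i]; nj <- sizes[j]
    newrow <- (ni * cur[i, ] + nj * cur[j, ]) / (ni + nj)
    cur[i, ] <- newrow; cur[, i] <- newrow; cur[i, i] <- 0
    cur <- cur[-j, -j, drop = FALSE]
    nodes[i] <- s; sizes[i] <- ni + nj
    nodes <- nodes[-j]; sizes <- sizes[-j]
  }
  dg <- structure(list(merge = merge, height = height, order = integer(),
                       labels = labels, method = "average"),
                  class = "ld_dendrogram")
  dg$order <- leaf_order(dg)
  dg
}

#' Left-to-right leaf order of a dendrogram
#'
#' Depth-first traversal; at each internal node the child whose own minimum
#' leaf index is smaller is traversed first, giving a deterministic,
#' nesting-consistent layout.
#'
#' @param dendro an `ld_dendrogram` (see [agglomerate()]).
#' @return Integer permutation of `1..k` (leaf indices).
#' @export
leaf_order <- function(dendro) {
  k <- length(dendro$labels)
  if (k == 1L) return(1L)
  merge <- dendro$merge
  leaves_of <- function(node) {
    if (node < 0L) return(-node)
    c(leaves_of(merge[node, 1L]), leaves_of(merge[node, 2L]))
  }
  walk <- function(node) {
    if (node < 0L) return(-node)
    l <- merge[node, 1L]; r <- merge[node, 2L]
    if (min(leaves_of(l)) <= min(leaves_of(r))) c(walk(l), walk(r))
    else c(walk(r), walk(l))
  }
  walk(nrow(merge))
}

#' Convert to a stats::hclust object
#'
#' Allows plotting with base graphics and conversion to `ape::phylo`.
#'
#' @param x an `ld_dendrogram`.
#' @param ... unused.
#' @return A `stats::hclust` object.
#' @export
as.hclust.ld_dendrogram <- function(x, ...) {
  if (!nrow(x$merge)) stop("cannot convert a single-leaf dendrogram to hclust")
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = "average",
                 dist.method = "1 - r^2", call = match.call()),
            class = "hclust")
}

#' Export a dendrogram as Newick text
#'
#' Branch lengths derive from the merge heights (ultrametric tree). A
#' single-leaf dendrogram is written as a trivial one-tip tree.
#'
#' @param dendro an `ld_dendrogram`.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
write_dendrogram_newick <- function(dendro, path) {
  if (length(dendro$labels) == 1L) {
    writeLines(paste0(dendro$labels, ";"), path)
    return(invisible(path))
  }
  phy <- ape::as.phylo(as.hclust(dendro))
  ape::write.tree(phy, file = path)
  invisible(path)
}
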