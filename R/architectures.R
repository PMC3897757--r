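# Round half up to `digits` decimals (track-name r^2 labels must not use
# round-half-to-even).
.round_half_up <- function(x, digits = 3L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

.fmt_r2 <- function(x) sprintf("%.3f", .round_half_up(x, 3L))

# Five-bin light-to-dark blue ramp on [0, 0.5] (bin width 0.1).
.MAF_RAMP <- matrix(c(239, 243, 255,
                      189, 215, 231,
                      107, 174, 214,
                      49, 130, 189,
                      8,  81, 156),
                    nrow = 5L, byrow = TRUE,
                    dimnames = list(NULL, c("r", "g", "b")))

#' Color for a minor allele frequency
#'
#' Five fixed bins of width 0.1 on `[0, 0.5]` mapped to a light-to-dark blue
#' ramp; a cluster is colored by the mean MAF of its members. MAF 0 falls in
#' the lightest bin, MAF 0.5 in the darkest.
#'
#' @param maf minor allele frequency in `[0, 0.5]`.
#' @return Named integer RGB triple (`r`, `g`, `b`), each in 0-255.
#' @export
maf_color <- function(maf) {
  if (!is.numeric(maf) || length(maf) != 1L || is.na(maf) || maf < 0 || maf > 0.5)
    stop("maf must be a single value in [0, 0.5], got ", maf)
  bin <- min(floor(maf / 0.1) + 1L, 5L)
  c(r = .MAF_RAMP[bin, "r"], g = .MAF_RAMP[bin, "g"], b = .MAF_RAMP[bin, "b"])
}

# One track item: a cluster or a lone SNP, with everything export needs.
.item <- function(type, ids, positions, chrom, mafs, name = ids[[1L]]) {
  list(type = type, ids = ids, positions = positions, chrom = chrom,
       mafs = mafs, name = name)
}

.cluster_item <- function(cl, maf_by_id) {
  .item("cluster", cl$member_ids, cl$positions, cl$chrom,
        unname(maf_by_id[cl$member_ids]), name = cl$name)
}

.snp_item <- function(id, panel, maf_by_id) {
  j <- match(id, panel$markers$id)
  .item("snp", id, panel$markers$pos[j], panel$markers$chrom[j],
        unname(maf_by_id[id]))
}

.track <- function(name, items, r2 = NULL) {
  list(name = name, items = items, r2 = r2)
}

.new_architecture <- function(kind, center, tracks, dendrogram, params) {
  structure(list(kind = kind, center = center, tracks = tracks,
                 dendrogram = dendrogram, params = params),
            class = "ld_architecture")
}

#' @export
print.ld_architecture <- function(x, ...) {
  cat("ld_architecture (", x$kind, "-centered on ", x$center, "): ",
      length(x$tracks), " tracks\n", sep = "")
  for (tr in x$tracks)
    cat("  ", tr$name, ": ", length(tr$items), " record(s)",
        if (!is.null(tr$r2)) sprintf(" [r^2 = %s]", .fmt_r2(tr$r2)) else "",
        "\n", sep = "")
  invisible(x)
}

# MAF lookup for a set of marker ids.
.maf_by_id <- function(panel, ids) {
  vapply(stats::setNames(ids, ids), function(id) compute_maf(panel, id), numeric(1))
}

# Names track: one record per displayed marker, position order.
.names_track <- function(panel, ids, maf_by_id) {
  pos <- panel$markers$pos[match(ids, panel$markers$id)]
  o <- order(pos)
  items <- lapply(ids[o], .snp_item, panel = panel, maf_by_id = maf_by_id)
  .track("SNP_names", items)
}

# Shared skeleton of gene-/region-centered architectures: clusters are built
# on the full MAF-filtered panel; `window` (NULL = whole panel) selects
# which clusters (>= 1 member inside) and singletons (inside) are shown.
.windowed_architecture <- function(panel, kind, center, window, maf_min,
                                   epsilon, include_singletons, hierarchical,
                                   color_by_maf, params_extra = list()) {
  ldm <- r2_matrix(panel, maf_min = maf_min)
  cl <- build_clusters(ldm, markers = panel$markers, epsilon = epsilon)
  in_window <- function(pos) {
    if (is.null(window)) rep(TRUE, length(pos))
    else pos >= window[1L] & pos <= window[2L]
  }
  keep <- vapply(cl$clusters, function(x) any(in_window(x$positions)), logical(1))
  clusters <- cl$clusters[keep]
  spos <- panel$markers$pos[match(cl$singletons, panel$markers$id)]
  singletons <- cl$singletons[in_window(spos)]
  shown <- c(unlist(lapply(clusters, `[[`, "member_ids")), singletons)
  params <- c(list(maf_min = maf_min, epsilon = epsilon,
                   include_singletons = include_singletons,
                   hierarchical = hierarchical, color_by_maf = color_by_maf),
              params_extra)
  if (!length(shown)) {
    warning(kind, "-centered architecture for ", center,
            ": no candidate markers after filtering")
    return(.new_architecture(kind, center, list(), NULL, params))
  }
  maf_by_id <- .maf_by_id(panel, shown)
  tracks <- list(.names_track(panel, shown, maf_by_id))
  dendro <- NULL
  if (length(clusters)) {
    if (hierarchical) {
      if (length(clusters) == 1L) {
        dendro <- structure(list(merge = matrix(0L, 0L, 2L), height = numeric(),
                                 order = 1L, labels = clusters[[1L]]$name,
                                 method = "average"),
                            class = "ld_dendrogram")
        ord <- 1L
      } else {
        d <- cluster_distance_matrix(ldm, clusters)
        dendro <- agglomerate(d)
        ord <- dendro$order
      }
      for (i in ord) {
        x <- clusters[[i]]
        tracks[[length(tracks) + 1L]] <-
          .track(paste0("cluster_", x$name), list(.cluster_item(x, maf_by_id)))
      }
    } else {
      items <- lapply(clusters, .cluster_item, maf_by_id = maf_by_id)
      tracks[[length(tracks) + 1L]] <- .track("clusters", items)
    }
  }
  if (include_singletons && length(singletons)) {
    items <- lapply(singletons, .snp_item, panel = panel, maf_by_id = maf_by_id)
    tracks[[length(tracks) + 1L]] <- .track("singletons", items)
  }
  .new_architecture(kind, center, tracks, dendro, params)
}

#' Gene-centered LD architecture
#'
#' Builds perfect-LD clusters on the whole (MAF-filtered) panel and keeps
#' those with at least one member inside the window
#' `[tx_start - flank_bp, tx_end + flank_bp]` (inclusive, 1-based); retained
#' clusters are displayed in full, including members outside the window.
#' The first track lists the names and positions of all displayed SNPs. In
#' hierarchical mode each cluster gets its own track, ordered as the
#' clusters appear in the average-linkage tree of their `1 - r^2` distances
#' (the dendrogram is attached); otherwise all clusters share one track.
#' In-window singletons get a final track when requested.
#'
#' @param panel a [genotype_panel()].
#' @param gene a one-row gene record (from [resolve_gene()] or
#'   [read_gene_table()]), or a query string if `gene_table` is supplied.
#' @param gene_table optional [read_gene_table()] result used to resolve a
#'   string query.
#' @param flank_bp maximum distance from the transcription start/end for a
#'   SNP to count as associated with the gene (default 10000).
#' @param maf_min minimum minor allele frequency (default 0).
#' @param epsilon perfect-LD tolerance (default 1e-6), see [build_clusters()].
#' @param include_singletons show SNPs that belong to no cluster (default
#'   TRUE).
#' @param hierarchical order cluster tracks by the dendrogram (default TRUE).
#' @param color_by_maf color records by minor allele frequency bins (default
#'   FALSE), see [maf_color()].
#' @return An `ld_architecture`.
#' @export
gene_centered <- function(panel, gene, gene_table = NULL, flank_bp = 10000,
                          maf_min = 0, epsilon = 1e-6,
                          include_singletons = TRUE, hierarchical = TRUE,
                          color_by_maf = FALSE) {
  stopifnot(flank_bp >= 0)
  if (is.character(gene)) {
    if (is.null(gene_table))
      stop("a gene_table is required to resolve the gene query '", gene, "'")
    gene <- resolve_gene(gene_table, gene)
  }
  if (gene$chrom != panel$markers$chrom[1L])
    stop("gene ", gene$symbol, " is on chromosome ", gene$chrom,
         " but the panel holds chromosome ", panel$markers$chrom[1L])
  center <- if (nzchar(gene$symbol)) gene$symbol
            else if (nzchar(gene$refseq_id)) gene$refseq_id else gene$entrez_id
  .windowed_architecture(
    panel, "gene", center,
    window = c(gene$tx_start - flank_bp, gene$tx_end + flank_bp),
    maf_min = maf_min, epsilon = epsilon,
    include_singletons = include_singletons, hierarchical = hierarchical,
    color_by_maf = color_by_maf, params_extra = list(flank_bp = flank_bp))
}

#' Region-centered LD architecture
#'
#' Identical to [gene_centered()] but the region of interest is the whole
#' genotype panel: every SNP in the imported dataset is a candidate.
#'
#' @inheritParams gene_centered
#' @return An `ld_architecture`.
#' @export
region_centered <- function(panel, maf_min = 0, epsilon = 1e-6,
                            include_singletons = TRUE, hierarchical = TRUE,
                            color_by_maf = FALSE) {
  center <- sprintf("%s:%d-%d", panel$markers$chrom[1L],
                    min(panel$markers$pos), max(panel$markers$pos))
  .windowed_architecture(
    panel, "region", center, window = NULL, maf_min = maf_min,
    epsilon = epsilon, include_singletons = include_singletons,
    hierarchical = hierarchical, color_by_maf = color_by_maf)
}

#' Chromosome-centered LD architecture
#'
#' One names track, one track holding every cluster on the chromosome, and
#' (when requested) one track holding all singletons. No dendrogram.
#'
#' @inheritParams gene_centered
#' @return An `ld_architecture`.
#' @export
chromosome_centered <- function(panel, maf_min = 0, epsilon = 1e-6,
                                include_singletons = TRUE,
                                color_by_maf = FALSE) {
  arch <- .windowed_architecture(
    panel, "chromosome", panel$markers$chrom[1L], window = NULL,
    maf_min = maf_min, epsilon = epsilon,
    include_singletons = include_singletons, hierarchical = FALSE,
    color_by_maf = color_by_maf)
  arch$dendrogram <- NULL
  arch
}

#' SNP-centered LD architecture
#'
#' Keeps every marker whose r-squared with the reference SNP is defined and
#' at least `r2_min` (default 0.5) and builds perfect-LD clusters on them.
#' Track 1 lists SNP names; track 2 holds the reference SNP together with
#' all its perfectly linked SNPs (r-squared >= 1 - epsilon). Every remaining
#' cluster gets its own track annotated with its r-squared to the reference
#' (taken from the cluster's first member — all members tie under exact
#' perfect LD), and singletons are added as tracks at their own r-squared
#' when requested; these tracks are ordered by decreasing r-squared, ties
#' broken by the genomic position of the track's first SNP. The r-squared is
#' embedded in the track name with three decimals.
#'
#' @inheritParams gene_centered
#' @param ref_snp_id marker id of the reference (index) SNP; must be present
#'   and polymorphic. The reference is kept even if its own MAF is below
#'   `maf_min`.
#' @param r2_min minimum r-squared with the reference for a variant to be
#'   considered (default 0.5).
#' @return An `ld_architecture`.
#' @export
snp_centered <- function(panel, ref_snp_id, maf_min = 0, epsilon = 1e-6,
                         r2_min = 0.5, include_singletons = TRUE,
                         color_by_maf = FALSE) {
  jref <- match(ref_snp_id, panel$markers$id)
  if (is.na(jref)) stop("reference SNP not found: ", ref_snp_id)
  gref <- panel$geno[, jref]
  if (all(is.na(gref)) || compute_maf(panel, jref) == 0)
    stop("LD with reference SNP ", ref_snp_id,
         " is undefined: the marker is monomorphic")
  ids <- panel$markers$id
  # r^2 of every MAF-passing marker to the reference (reference always kept)
  r2ref <- stats::setNames(rep(NA_real_, length(ids)), ids)
  r2ref[ref_snp_id] <- 1
  for (j in seq_along(ids)) {
    if (j == jref) next
    g <- panel$geno[, j]
    if (all(is.na(g))) next
    maf <- compute_maf(panel, j)
    if (maf == 0 || maf < maf_min) next
    r2ref[j] <- tryCatch(
      r2_pair(.em_from_counts(.pair_counts(gref, g))),
      error = function(e) NA_real_)
  }
  cand <- ids[!is.na(r2ref) & r2ref >= r2_min]
  params <- list(maf_min = maf_min, epsilon = epsilon, r2_min = r2_min,
                 include_singletons = include_singletons,
                 color_by_maf = color_by_maf)
  # clusters over the candidate set (reference included)
  ldm <- r2_matrix(panel, marker_subset = match(cand, ids), maf_min = 0)
  cl <- build_clusters(ldm, markers = panel$markers, epsilon = epsilon)
  perfect <- ids[!is.na(r2ref) & r2ref >= 1 - epsilon]
  perfect <- union(ref_snp_id, perfect)
  shown <- unique(c(unlist(lapply(cl$clusters, `[[`, "member_ids")),
                    if (include_singletons) cl$singletons else
                      intersect(cl$singletons, perfect)))
  shown <- union(shown, ref_snp_id)
  maf_by_id <- .maf_by_id(panel, shown)
  tracks <- list(.names_track(panel, shown, maf_by_id))
  # track 2: reference + perfectly linked SNPs, as one record
  ppos <- panel$markers$pos[match(perfect, ids)]
  perfect <- perfect[order(ppos)]
  ref_item <- if (length(perfect) >= 2L)
    .item("cluster", perfect, sort(ppos), panel$markers$chrom[jref],
          unname(maf_by_id[perfect]), name = perfect[1L])
  else .snp_item(ref_snp_id, panel, maf_by_id)
  tracks[[2L]] <- .track(paste0("reference_", ref_snp_id, "_r2_", .fmt_r2(1)),
                         list(ref_item), r2 = 1)
  # remaining clusters and singletons, by decreasing r^2 to the reference
  rest_clusters <- Filter(function(x) !(ref_snp_id %in% x$member_ids), cl$clusters)
  entries <- lapply(rest_clusters, function(x)
    list(item = .cluster_item(x, maf_by_id), r2 = unname(r2ref[x$member_ids[1L]]),
         pos = x$min_pos, label = paste0("cluster_", x$name)))
  if (include_singletons) {
    singles <- setdiff(cl$singletons, perfect)
    entries <- c(entries, lapply(singles, function(id)
      list(item = .snp_item(id, panel, maf_by_id), r2 = unname(r2ref[id]),
           pos = panel$markers$pos[match(id, ids)], label = paste0("snp_", id))))
  }
  if (length(entries)) {
    o <- order(-vapply(entries, `[[`, numeric(1), "r2"),
               vapply(entries, `[[`, numeric(1), "pos"))
    for (e in entries[o])
      tracks[[length(tracks) + 1L]] <-
        .track(paste0(e$label, "_r2_", .fmt_r2(e$r2)), list(e$item), r2 = e$r2)
  }
  .new_architecture("snp", ref_snp_id, tracks, NULL, params)
}
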