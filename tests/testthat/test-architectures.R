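# Shared fixture: three planted blocks (3 + 2 SNPs and one singleton) at
# moderate mutual LD, no missing data, plus a gene table whose first gene
# covers the leading markers.
fixture_arch <- function(seed = 33) {
  sim <- simulate_panel(block_spec(n_snps = c(3, 2, 1), maf = c(0.3, 0.25, 0.4),
                                   cross_corr = 0.5, n_samples = 150,
                                   seed = seed))
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("entrez_id\trefseq_id\tsymbol\tchrom\ttx_start\ttx_end\tstrand",
               "100\tNM_0001\tGENE1\t1\t10500\t13500\t+",
               "200\tNM_0002\tGENE2\t1\t40000\t45000\t+"), tsv)
  list(sim = sim, genes = read_gene_table(tsv))
}

track_names <- function(arch) vapply(arch$tracks, `[[`, "", "name")

test_that("gene-centered architectures keep clusters with >= 1 member in the window", {
  fx <- fixture_arch()
  p <- fx$sim$panel
  # GENE1 spans 10500-13500: covers block-1 SNPs at 10001-12001 partially
  # (rs01_02, rs01_03 in window) and block-2 SNP rs02_01 at 13001
  arch <- gene_centered(p, "GENE1", gene_table = fx$genes, flank_bp = 0)
  nm <- track_names(arch)
  expect_equal(nm[1], "SNP_names")
  expect_setequal(nm[-1], c("cluster_rs01_01", "cluster_rs02_01"))
  # retained clusters are displayed in full, including members outside it
  cl1 <- arch$tracks[[which(nm == "cluster_rs01_01")]]$items[[1]]
  expect_equal(cl1$ids, c("rs01_01", "rs01_02", "rs01_03"))
  expect_false(is.null(arch$dendrogram))
  # the singleton at 16001 is out of window: no singleton track
  expect_false("singletons" %in% nm)
})

test_that("gene window + flank controls candidate markers; empty windows warn", {
  fx <- fixture_arch()
  p <- fx$sim$panel
  # large flank brings the singleton rs03_01 (pos 16001) into GENE1's window
  arch <- gene_centered(p, "GENE1", gene_table = fx$genes, flank_bp = 5000)
  expect_true("singletons" %in% track_names(arch))
  expect_warning(empty <- gene_centered(p, "GENE2", gene_table = fx$genes,
                                        flank_bp = 0),
                 "no candidate markers")
  expect_length(empty$tracks, 0)
})

test_that("the same gene queried by Entrez, RefSeq and symbol gives one architecture", {
  fx <- fixture_arch()
  p <- fx$sim$panel
  a1 <- gene_centered(p, "100", gene_table = fx$genes)
  a2 <- gene_centered(p, "NM_0001", gene_table = fx$genes)
  a3 <- gene_centered(p, "GENE1", gene_table = fx$genes)
  a2$center <- a3$center <- a1$center
  expect_equal(a1$tracks, a2$tracks)
  expect_equal(a1$tracks, a3$tracks)
})

test_that("hierarchical mode orders cluster tracks by the dendrogram leaf order", {
  sim <- simulate_panel(block_spec(
    n_snps = c(2, 2, 2), maf = 0.3, n_samples = 400,
    cross_corr = rbind(c(1, 0.8, 0.1), c(0.8, 1, 0.1), c(0.1, 0.1, 1)),
    seed = 55))
  arch <- region_centered(sim$panel)
  expect_length(arch$tracks, 3 + 1)
  ord <- arch$dendrogram$order
  labs <- arch$dendrogram$labels[ord]
  expect_equal(track_names(arch)[-1], paste0("cluster_", labs))
  # blocks 1 and 2 are the tight pair: adjacent in the leaf order
  pos12 <- match(c("rs01_01", "rs02_01"), labs)
  expect_equal(abs(diff(pos12)), 1L)
  flat <- region_centered(sim$panel, hierarchical = FALSE)
  expect_equal(track_names(flat)[2], "clusters")
  expect_length(flat$tracks[[2]]$items, 3)
  expect_null(flat$dendrogram)
})

test_that("region-centered equals gene-centered when the window covers the panel", {
  fx <- fixture_arch()
  p <- fx$sim$panel
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("entrez_id\trefseq_id\tsymbol\tchrom\ttx_start\ttx_end\tstrand",
               sprintf("900\tNM_0900\tWIDE\t1\t%d\t%d\t+",
                       min(p$markers$pos), max(p$markers$pos))), tsv)
  wide <- gene_centered(p, "WIDE", gene_table = read_gene_table(tsv),
                        flank_bp = 0)
  reg <- region_centered(p)
  expect_equal(wide$tracks, reg$tracks)
  expect_equal(wide$dendrogram, reg$dendrogram)
})

test_that("chromosome-centered puts every cluster in one track, singletons in another", {
  fx <- fixture_arch()
  arch <- chromosome_centered(fx$sim$panel)
  nm <- track_names(arch)
  expect_equal(nm, c("SNP_names", "clusters", "singletons"))
  expect_length(arch$tracks[[2]]$items, 2)
  expect_null(arch$dendrogram)
  # record count in the all-clusters track equals build_clusters output
  cl <- build_clusters(r2_matrix(fx$sim$panel), markers = fx$sim$panel$markers)
  expect_length(arch$tracks[[2]]$items, length(cl$clusters))
  nos <- chromosome_centered(fx$sim$panel, include_singletons = FALSE)
  expect_equal(track_names(nos), c("SNP_names", "clusters"))
})

test_that("snp-centered keeps r^2 >= r2_min, orders tracks by decreasing r^2", {
  # one-factor correlation structure: r^2 targets to the reference block
  targets <- c(0.9, 0.75, 0.6, 0.3)      # block 1 = reference block
  sim <- simulate_panel(block_spec(n_snps = c(2, 2, 1, 1, 1), maf = 0.35,
                                   n_samples = 2000,
                                   corr_to_first = sqrt(targets), seed = 77))
  p <- sim$panel
  ref <- "rs01_01"
  arch <- snp_centered(p, ref)
  nm <- track_names(arch)
  expect_equal(nm[1], "SNP_names")
  expect_match(nm[2], "^reference_rs01_01_r2_1\\.000$")
  # reference track holds the reference and its perfect partners
  expect_setequal(arch$tracks[[2]]$items[[1]]$ids, c("rs01_01", "rs01_02"))
  # following tracks carry non-increasing r^2 annotations embedded in names
  r2s <- vapply(arch$tracks[-(1:2)], `[[`, numeric(1), "r2")
  expect_true(all(diff(r2s) <= 0))
  expect_match(nm[3], "_r2_0\\.\\d{3}$")
  # brute-force scan oracle: retained set = markers with pairwise r^2 >= 0.5
  shown <- unique(unlist(lapply(arch$tracks, function(tr)
    unlist(lapply(tr$items, `[[`, "ids")))))
  scan <- vapply(p$markers$id, function(id)
    if (id == ref) 1 else
      tryCatch(r2_pair(em_haplotype_freqs(p, ref, id)), error = function(e) NA_real_),
    numeric(1))
  expect_setequal(shown, p$markers$id[!is.na(scan) & scan >= 0.5])
  expect_gte(min(scan[shown], na.rm = TRUE), 0.5)
})

test_that("snp-centered handles a reference with no linked markers", {
  sim <- simulate_panel(block_spec(n_snps = c(1, 1, 1), maf = 0.3,
                                   n_samples = 100, cross_corr = 0, seed = 88))
  arch <- snp_centered(sim$panel, "rs02_01")
  nm <- track_names(arch)
  expect_equal(nm[1], "SNP_names")
  expect_match(nm[2], "^reference_rs02_01")
  expect_length(arch$tracks, 2)
  expect_error(snp_centered(sim$panel, "rs99_01"), "not found")
  mono <- sim$panel
  mono$geno[, "rs01_01"] <- 0L
  expect_error(snp_centered(mono, "rs01_01"), "monomorphic")
})

test_that("every MAF-passing marker lands in exactly one displayed place", {
  sim <- simulate_panel(block_spec(n_snps = c(3, 2, 1, 1), maf = 0.3,
                                   n_samples = 120, cross_corr = 0.4, seed = 99))
  p <- sim$panel
  arch <- region_centered(p, maf_min = 0, include_singletons = TRUE)
  per_track <- lapply(arch$tracks[-1], function(tr)
    unlist(lapply(tr$items, `[[`, "ids")))
  all_ids <- unlist(per_track)
  expect_false(any(duplicated(all_ids)))
  poly <- p$markers$id[vapply(seq_len(ncol(p$geno)),
                              function(j) compute_maf(p, j) > 0, logical(1))]
  expect_setequal(all_ids, poly)
})

test_that("maf_color bins [0, 0.5] into five ramp steps", {
  light <- maf_color(0)
  dark <- maf_color(0.5)
  expect_equal(unname(light), c(239, 243, 255))
  expect_equal(unname(dark), c(8, 81, 156))
  expect_equal(maf_color(0.11), maf_color(0.19))   # same bin, same color
  expect_false(identical(maf_color(0.09), maf_color(0.11)))
  expect_error(maf_color(0.6), "\\[0, 0.5\\]")
  expect_error(maf_color(-0.1), "\\[0, 0.5\\]")
})
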