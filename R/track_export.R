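# One BED12 record from 1-based SNP positions: chromStart = min(pos) - 1,
# chromEnd = max(pos), one 1-bp block per SNP. BED is 0-based half-open;
# panel coordinates are 1-based — the conversion is pos - 1 at the start
# and pos at the end, stated here once and tested everywhere.
.bed12_record <- function(chrom, positions, name, rgb = "0,0,0") {
  positions <- as.integer(positions)
  if (anyDuplicated(positions)) {
    warning("duplicate positions in record '", name, "' collapsed to one block")
    positions <- unique(positions)
  }
  positions <- sort(positions)
  start <- positions[1L] - 1L
  end <- positions[length(positions)]
  offs <- positions - positions[1L]
  data.frame(
    chrom = chrom, chromStart = start, chromEnd = end, name = name,
    score = 0L, strand = "+", thickStart = start, thickEnd = end,
    itemRgb = rgb, blockCount = length(positions),
    blockSizes = paste0(paste(rep("1", length(positions)), collapse = ","), ","),
    blockStarts = paste0(paste(offs, collapse = ","), ","),
    stringsAsFactors = FALSE)
}

.item_rgb <- function(item, color_by_maf) {
  if (!color_by_maf) return("0,0,0")
  paste(maf_color(mean(item$mafs)), collapse = ",")
}

#' BED12 record for a perfect-LD cluster
#'
#' The record spans the cluster (`[min_pos - 1, max_pos)` in 0-based
#' half-open coordinates) with one 1-bp block per member SNP; the record's
#' intron-style connecting line between blocks is the horizontal line that
#' joins perfectly linked SNPs in the browser. The record is named after the
#' cluster (its first SNP).
#'
#' @param cluster an `ld_cluster` (see [build_clusters()]) with >= 2 members
#'   and known positions.
#' @param color RGB string `"r,g,b"` (default black).
#' @return One-row data.frame with the 12 BED columns.
#' @export
cluster_to_bed <- function(cluster, color = "0,0,0") {
  if (length(cluster$member_ids) < 2L)
    stop("a cluster record needs >= 2 members; got ", length(cluster$member_ids))
  if (anyNA(cluster$positions))
    stop("cluster ", cluster$name, " has members with unknown positions")
  .bed12_record(cluster$chrom, cluster$positions, cluster$name, color)
}

#' BED records for the SNP-names track
#'
#' One 1-bp single-block BED12 record per marker, named by marker id.
#'
#' @param markers data.frame with columns `id`, `chrom`, `pos` (1-based).
#' @return data.frame of BED12 rows (zero rows for an empty input).
#' @export
snp_names_track <- function(markers) {
  if (!nrow(markers)) return(.bed12_record("x", 1L, "x")[0L, ])
  do.call(rbind, lapply(seq_len(nrow(markers)), function(i)
    .bed12_record(markers$chrom[i], markers$pos[i], markers$id[i])))
}

.bed_line <- function(rec) {
  paste(rec$chrom, rec$chromStart, rec$chromEnd, rec$name, rec$score,
        rec$strand, rec$thickStart, rec$thickEnd, rec$itemRgb,
        rec$blockCount, rec$blockSizes, rec$blockStarts, sep = "\t")
}

#' Write an architecture as a UCSC custom-track BED file
#'
#' One file per architecture, one `track` header line per track (name,
#' description, `itemRgb=On` when coloring by MAF, visibility), tracks in
#' architecture order and records sorted by chromStart within each track.
#' Always 12-column BED; singleton records are single-block BED12. Output is
#' UTF-8 with Unix newlines and is byte-identical across runs with the same
#' inputs.
#'
#' @param arch an `ld_architecture`.
#' @param out_path output BED file path.
#' @param newick_path optional path for a Newick sidecar of the dendrogram
#'   (hierarchical gene-/region-centered architectures only).
#' @return Invisibly, `out_path`.
#' @export
write_architecture <- function(arch, out_path, newick_path = NULL) {
  color_by_maf <- isTRUE(arch$params$color_by_maf)
  lines <- character()
  for (tr in arch$tracks) {
    hdr <- sprintf('track name="%s" description="%s-centered LD architecture (%s)"%s visibility=2',
                   tr$name, arch$kind, arch$center,
                   if (color_by_maf) ' itemRgb="On"' else "")
    recs <- do.call(rbind, lapply(tr$items, function(it)
      .bed12_record(it$chrom, it$positions, it$name, .item_rgb(it, color_by_maf))))
    recs <- recs[order(recs$chromStart), , drop = FALSE]
    lines <- c(lines, hdr, vapply(seq_len(nrow(recs)), function(i)
      .bed_line(recs[i, ]), character(1)))
  }
  con <- file(out_path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  if (!is.null(newick_path) && !is.null(arch$dendrogram))
    write_dendrogram_newick(arch$dendrogram, newick_path)
  invisible(out_path)
}

#' Export per-cluster SNP id lists
#'
#' One plain-text file per cluster, named `<cluster_name>.txt`, one marker
#' id per line in position order. Path separators in cluster names are
#' sanitized to underscores.
#'
#' @param arch an `ld_architecture`.
#' @param out_dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
export_cluster_ids <- function(arch, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character()
  for (tr in arch$tracks) for (it in tr$items) {
    if (it$type != "cluster") next
    fname <- paste0(gsub("[/\\\\]", "_", it$name), ".txt")
    p <- file.path(out_dir, fname)
    writeLines(it$ids[order(it$positions)], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Strict BED12 validator
#'
#' Checks every non-header line of a custom-track BED file: 12 tab-separated
#' fields; `chromStart < chromEnd`; `thickStart`/`thickEnd` matching;
#' blockCount agreeing with blockSizes/blockStarts; blockStarts strictly
#' increasing starting at 0; every blockSize >= 1; the last block ending
#' exactly at `chromEnd - chromStart`; itemRgb a valid `r,g,b` triple.
#'
#' @param path path to a BED file.
#' @return Character vector of violation messages; `character(0)` means the
#'   file is valid.
#' @export
check_bed12 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  problems <- character()
  say <- function(i, msg) problems <<- c(problems, sprintf("line %d: %s", i, msg))
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^(track|browser)\\b", ln) || !nzchar(ln)) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) != 12L) { say(i, paste("expected 12 fields, found", length(f))); next }
    start <- suppressWarnings(as.integer(f[2L]))
    end <- suppressWarnings(as.integer(f[3L]))
    if (is.na(start) || is.na(end) || start < 0L || start >= end) {
      say(i, "invalid chromStart/chromEnd"); next
    }
    if (!(f[6L] %in% c("+", "-", "."))) say(i, "invalid strand")
    if (suppressWarnings(as.integer(f[7L])) != start ||
        suppressWarnings(as.integer(f[8L])) != end)
      say(i, "thickStart/thickEnd do not match chromStart/chromEnd")
    if (!grepl("^\\d{1,3},\\d{1,3},\\d{1,3}$", f[9L]) &&
        f[9L] != "0") say(i, "invalid itemRgb")
    count <- suppressWarnings(as.integer(f[10L]))
    sizes <- suppressWarnings(as.integer(strsplit(f[11L], ",")[[1L]]))
    starts <- suppressWarnings(as.integer(strsplit(f[12L], ",")[[1L]]))
    if (is.na(count) || count < 1L || length(sizes) != count ||
        length(starts) != count) { say(i, "blockCount mismatch"); next }
    if (anyNA(sizes) || any(sizes < 1L)) say(i, "blockSizes must be >= 1")
    if (anyNA(starts) || starts[1L] != 0L ||
        (count > 1L && any(diff(starts) <= 0L)))
      say(i, "blockStarts must start at 0 and be strictly increasing")
    else if (starts[count] + sizes[count] != end - start)
      say(i, "last block does not end at chromEnd")
    else if (any(starts + sizes > end - start))
      say(i, "block extends past chromEnd")
  }
  problems
}

#' Recover member positions from an emitted BED12 record line
#'
#' Parse-back helper (round-trip oracle): 1-based positions are
#' `chromStart + blockStarts + 1`.
#'
#' @param line one 12-field BED line.
#' @return Integer vector of 1-based positions.
#' @export
bed12_positions <- function(line) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  stopifnot(length(f) == 12L)
  start <- as.integer(f[2L])
  offs <- as.integer(strsplit(f[12L], ",")[[1L]])
  start + offs + 1L
}
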