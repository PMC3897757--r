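.MISSING_ALLELES <- c("0", "N", "-")

#' Construct a genotype panel
#'
#' A genotype panel holds a set of biallelic markers on one chromosome
#' together with an unphased diploid genotype matrix coded as minor-allele
#' dosage (0, 1, 2) with `NA` for missing calls.
#'
#' @param markers data.frame with columns `id`, `chrom`, `pos` and optionally
#'   `major`, `minor` (allele symbols; `minor` is `NA` for monomorphic
#'   markers). Positions are 1-based. Rows must be strictly increasing in
#'   `pos`; ties are an input error.
#' @param samples character vector of sample identifiers.
#' @param geno integer matrix, samples x markers, entries in `{0, 1, 2, NA}`.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(markers, samples, geno) {
  stopifnot(is.data.frame(markers), all(c("id", "chrom", "pos") %in% names(markers)))
  if (!("major" %in% names(markers))) markers$major <- NA_character_
  if (!("minor" %in% names(markers))) markers$minor <- NA_character_
  markers$id <- as.character(markers$id)
  markers$chrom <- as.character(markers$chrom)
  markers$pos <- as.integer(markers$pos)
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(markers) != ncol(geno))
    stop("marker count (", nrow(markers), ") does not match genotype columns (",
         ncol(geno), ")")
  if (length(samples) != nrow(geno))
    stop("sample count does not match genotype rows")
  if (anyDuplicated(markers$id))
    stop("duplicate marker id: ",
         paste(unique(markers$id[duplicated(markers$id)]), collapse = ", "))
  if (length(unique(markers$chrom)) > 1L)
    stop("a panel must contain exactly one chromosome, found: ",
         paste(unique(markers$chrom), collapse = ", "))
  if (any(markers$pos < 1L)) stop("marker positions must be >= 1")
  if (is.unsorted(markers$pos)) {
    o <- order(markers$pos)
    markers <- markers[o, , drop = FALSE]
    geno <- geno[, o, drop = FALSE]
  }
  if (anyDuplicated(markers$pos))
    stop("tied marker positions are an input error: pos ",
         paste(unique(markers$pos[duplicated(markers$pos)]), collapse = ", "))
  bad <- geno[!is.na(geno)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("genotype codes must be 0, 1, 2 or NA")
  rownames(markers) <- NULL
  dimnames(geno) <- list(samples, markers$id)
  structure(list(markers = markers, samples = as.character(samples), geno = geno),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", length(x$samples), "samples x", nrow(x$markers),
      "markers on chromosome", x$markers$chrom[1L], "\n")
  cat("  positions", min(x$markers$pos), "-", max(x$markers$pos),
      "; missing calls:", sum(is.na(x$geno)), "\n")
  invisible(x)
}

.read_table_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  list(fields = strsplit(trimws(lines[keep]), "\\s+"), lineno = which(keep))
}

#' Read a linkage-format genotype panel
#'
#' Reads pedigree genotype data (PED: six leading columns family, individual,
#' father, mother, sex, phenotype followed by two allele columns per marker)
#' plus a marker file, either 4-column MAP (chrom, id, genetic distance, pos)
#' or 2-column INFO (id, pos). The dialect is auto-detected from the column
#' count; the INFO dialect carries no chromosome so `chrom_override` is
#' required. Allele symbols `0`, `N` and `-` denote missing; a genotype is
#' missing if either allele is. Genotypes are recoded to minor-allele dosage
#' after a first pass establishes allele frequencies (exact 0.5/0.5 ties are
#' broken lexicographically: the alphabetically first symbol is called
#' major). Family structure, sex and phenotype are parsed and discarded: all
#' individuals are treated as unrelated. Markers are re-sorted by position
#' with the genotype matrix permuted in lockstep.
#'
#' @param ped_path path to the PED file.
#' @param marker_path path to the MAP or INFO file.
#' @param chrom_override chromosome name; required for 2-column INFO files,
#'   optional override otherwise.
#' @return A [genotype_panel()].
#' @export
read_linkage <- function(ped_path, marker_path, chrom_override = NULL) {
  mk <- .read_table_lines(marker_path)
  if (!length(mk$fields)) stop("marker file is empty: ", marker_path)
  ncols <- lengths(mk$fields)
  if (all(ncols == 4L)) {
    chrom <- vapply(mk$fields, `[`, "", 1L)
    ids <- vapply(mk$fields, `[`, "", 2L)
    pos <- vapply(mk$fields, `[`, "", 4L)
    if (!is.null(chrom_override)) chrom <- rep(chrom_override, length(ids))
  } else if (all(ncols == 2L)) {
    if (is.null(chrom_override))
      stop("2-column INFO marker file carries no chromosome; chrom_override is required")
    ids <- vapply(mk$fields, `[`, "", 1L)
    pos <- vapply(mk$fields, `[`, "", 2L)
    chrom <- rep(chrom_override, length(ids))
  } else {
    bad <- mk$lineno[which(!(ncols %in% c(2L, 4L)))[1L]]
    stop("marker file line ", bad,
         ": expected 4 columns (MAP) or 2 columns (INFO), found ",
         ncols[which(!(ncols %in% c(2L, 4L)))[1L]])
  }
  pos_n <- suppressWarnings(as.integer(pos))
  if (anyNA(pos_n))
    stop("marker file line ", mk$lineno[which(is.na(pos_n))[1L]],
         ": malformed position '", pos[which(is.na(pos_n))[1L]], "'")
  if (anyDuplicated(ids))
    stop("duplicate marker id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- length(ids)

  pd <- .read_table_lines(ped_path)
  if (!length(pd$fields)) stop("PED file is empty: ", ped_path)
  expected <- 6L + 2L * m
  nc <- lengths(pd$fields)
  if (any(nc != expected))
    stop("PED line ", pd$lineno[which(nc != expected)[1L]], ": expected ",
         expected, " columns for ", m, " markers, found ", nc[which(nc != expected)[1L]])
  ped <- do.call(rbind, pd$fields)
  samples <- ped[, 2L]
  if (anyDuplicated(samples))
    samples <- paste(ped[, 1L], ped[, 2L], sep = "_")

  n <- nrow(ped)
  geno <- matrix(NA_integer_, n, m)
  major <- minor <- character(m)
  for (j in seq_len(m)) {
    a1 <- ped[, 5L + 2L * j]
    a2 <- ped[, 6L + 2L * j]
    miss <- a1 %in% .MISSING_ALLELES | a2 %in% .MISSING_ALLELES
    obs <- c(a1[!miss], a2[!miss])
    if (!length(obs)) {
      major[j] <- NA_character_; minor[j] <- NA_character_
      next
    }
    tab <- sort(table(obs), decreasing = TRUE)
    if (length(tab) > 2L)
      stop("marker ", ids[j], ": more than 2 distinct non-missing alleles (",
           paste(names(tab), collapse = ", "), ")")
    if (length(tab) == 1L) {
      major[j] <- names(tab); minor[j] <- NA_character_
      geno[!miss, j] <- 0L
    } else {
      if (tab[1L] == tab[2L]) tab <- tab[order(names(tab))]  # tie: major = first alphabetically
      major[j] <- names(tab)[1L]; minor[j] <- names(tab)[2L]
      geno[!miss, j] <- (a1[!miss] == minor[j]) + (a2[!miss] == minor[j])
    }
  }
  genotype_panel(
    markers = data.frame(id = ids, chrom = chrom, pos = pos_n,
                         major = major, minor = minor, stringsAsFactors = FALSE),
    samples = samples, geno = geno)
}

#' Write a panel back to PED/MAP
#'
#' Fixture helper exercised by the round-trip tests: emits the panel in the
#' 4-column MAP dialect with placeholder pedigree columns (all individuals
#' unrelated, sex and phenotype 0). Markers with no recorded allele symbols
#' are written with symbolic alleles `A` (major) and `B` (minor).
#'
#' @param panel a [genotype_panel()].
#' @param ped_path,map_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_linkage <- function(panel, ped_path, map_path) {
  mk <- panel$markers
  major <- ifelse(is.na(mk$major), "A", mk$major)
  minor <- ifelse(is.na(mk$minor), "B", mk$minor)
  map <- sprintf("%s\t%s\t0\t%d", mk$chrom, mk$id, mk$pos)
  writeLines(map, map_path)
  n <- length(panel$samples)
  rows <- character(n)
  for (i in seq_len(n)) {
    g <- panel$geno[i, ]
    a1 <- ifelse(is.na(g), "0", ifelse(g >= 1L, minor, major))
    a2 <- ifelse(is.na(g), "0", ifelse(g == 2L, minor, major))
    rows[i] <- paste(c(sprintf("FAM%d", i), panel$samples[i], "0", "0", "0", "0",
                       as.vector(rbind(a1, a2))), collapse = "\t")
  }
  writeLines(rows, ped_path)
  invisible(c(ped_path, map_path))
}

#' Read a gene annotation table
#'
#' Plain TSV with a header row naming at least `entrez_id`, `refseq_id`,
#' `symbol`, `chrom`, `tx_start`, `tx_end`, `strand`; optional `exon_starts`
#' and `exon_ends` columns hold comma-separated integer lists (display only).
#' Coordinates are 1-based and `tx_end` is inclusive. Rows with malformed or
#' inverted coordinates are rejected with their line numbers.
#'
#' @param tsv_path path to the TSV file.
#' @return A data.frame of gene records (class `gene_table`).
#' @export
read_gene_table <- function(tsv_path) {
  df <- utils::read.delim(tsv_path, stringsAsFactors = FALSE,
                          colClasses = "character", comment.char = "#")
  required <- c("entrez_id", "refseq_id", "symbol", "chrom",
                "tx_start", "tx_end", "strand")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("gene table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  tx_start <- suppressWarnings(as.integer(df$tx_start))
  tx_end <- suppressWarnings(as.integer(df$tx_end))
  bad <- which(is.na(tx_start) | is.na(tx_end) | tx_start > tx_end |
                 tx_start < 1L | !(df$strand %in% c("+", "-")))
  if (length(bad))
    stop("gene table: malformed record(s) at line(s) ",
         paste(bad + 1L, collapse = ", "),
         " (coordinates must be integers with 1 <= tx_start <= tx_end",
         ", strand '+' or '-')")
  no_id <- which(df$entrez_id == "" & df$refseq_id == "" & df$symbol == "")
  if (length(no_id))
    stop("gene table: record(s) with no identifier at line(s) ",
         paste(no_id + 1L, collapse = ", "))
  df$tx_start <- tx_start
  df$tx_end <- tx_end
  if (!("exon_starts" %in% names(df))) df$exon_starts <- NA_character_
  if (!("exon_ends" %in% names(df))) df$exon_ends <- NA_character_
  class(df) <- c("gene_table", "data.frame")
  df
}

#' Resolve a gene query against a gene table
#'
#' Matching is attempted against `entrez_id` first, then `refseq_id`, then
#' `symbol` (case-insensitive for symbols); the first identifier type with
#' any match wins, and exactly one record must remain.
#'
#' @param gene_table a [read_gene_table()] result.
#' @param query gene identifier (Entrez ID, RefSeq ID, or gene symbol).
#' @return A one-row data.frame (the matching gene record).
#' @export
resolve_gene <- function(gene_table, query) {
  query <- as.character(query)
  hit <- which(gene_table$entrez_id == query)
  if (!length(hit)) hit <- which(gene_table$refseq_id == query)
  if (!length(hit)) hit <- which(toupper(gene_table$symbol) == toupper(query))
  if (!length(hit))
    stop("gene not found by Entrez ID, RefSeq ID or symbol: '", query, "'")
  if (length(hit) > 1L)
    stop("ambiguous gene query '", query, "': matches ",
         paste(sprintf("%s/%s/%s", gene_table$entrez_id[hit],
                       gene_table$refseq_id[hit], gene_table$symbol[hit]),
               collapse = "; "))
  gene_table[hit, , drop = FALSE]
}
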