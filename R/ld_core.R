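#' Minor allele frequency of one marker
#'
#' Counts the coded (minor) allele over non-missing genotypes and folds the
#' frequency onto `[0, 0.5]`; in a finite sample the allele coded at load
#' time can drift above 0.5, and the minor allele is by definition the less
#' frequent one. Monomorphic markers return 0.
#'
#' @param panel a [genotype_panel()].
#' @param marker marker id or column index.
#' @return Frequency in `[0, 0.5]`.
#' @export
compute_maf <- function(panel, marker) {
  j <- if (is.character(marker)) match(marker, panel$markers$id) else as.integer(marker)
  if (is.na(j) || j < 1L || j > ncol(panel$geno))
    stop("marker not found: ", marker)
  g <- panel$geno[, j]
  g <- g[!is.na(g)]
  if (!length(g))
    stop("MAF undefined for marker ", panel$markers$id[j], ": all genotypes missing")
  f <- sum(g) / (2 * length(g))
  min(f, 1 - f)
}

# 3x3 genotype count table (dosage 0/1/2 at each locus) from two dosage
# vectors, pairwise-complete.
.pair_counts <- function(g1, g2) {
  keep <- !is.na(g1) & !is.na(g2)
  g1 <- g1[keep]; g2 <- g2[keep]
  tab <- matrix(0, 3L, 3L)
  for (a in 0:2) for (b in 0:2) tab[a + 1L, b + 1L] <- sum(g1 == a & g2 == b)
  tab
}

# Observed-data log-likelihood of a 3x3 dosage table under haplotype
# frequencies p = (AB, Ab, aB, ab); A/B major, a/b minor alleles.
.two_locus_loglik <- function(p, tab) {
  P <- matrix(c(p[1]^2,        2 * p[1] * p[2],                 p[2]^2,
                2 * p[1] * p[3], 2 * (p[1] * p[4] + p[2] * p[3]), 2 * p[2] * p[4],
                p[3]^2,        2 * p[3] * p[4],                 p[4]^2),
              3L, 3L, byrow = TRUE)
  keep <- tab > 0
  sum(tab[keep] * log(P[keep]))
}

#' Two-locus EM haplotype frequency estimation
#'
#' Estimates the four two-locus haplotype frequencies from unphased diploid
#' genotypes by expectation-maximization over the 3x3 genotype table.
#' Only the double-heterozygote class is phase-ambiguous; each E-step splits
#' it between AB/ab and Ab/aB in proportion to the current haplotype-product
#' weights. The EM is initialized at linkage equilibrium (products of the
#' sample allele frequencies) and is fully deterministic. Missing data are
#' handled by pairwise-complete deletion.
#'
#' @param panel a [genotype_panel()].
#' @param i,j marker ids or column indices.
#' @param tol stop when the largest absolute frequency change drops below
#'   this (default 1e-10).
#' @param max_iter iteration cap (default 1000); hitting it sets
#'   `converged = FALSE` rather than raising an error.
#' @return Object of class `haplotype_freqs`: list with `p` (named frequencies
#'   `AB`, `Ab`, `aB`, `ab`; A/B = major alleles), `n_eff`, `loglik`,
#'   `iterations`, `converged`.
#' @export
em_haplotype_freqs <- function(panel, i, j, tol = 1e-10, max_iter = 1000L) {
  ii <- if (is.character(i)) match(i, panel$markers$id) else as.integer(i)
  jj <- if (is.character(j)) match(j, panel$markers$id) else as.integer(j)
  if (is.na(ii) || is.na(jj)) stop("marker not found")
  tab <- .pair_counts(panel$geno[, ii], panel$geno[, jj])
  out <- .em_from_counts(tab, tol = tol, max_iter = max_iter)
  out$marker_ids <- panel$markers$id[c(ii, jj)]
  out
}

# Core EM on a 3x3 dosage count table. Rows: dosage at locus 1 (0/1/2 copies
# of minor allele a); columns: locus 2.
.em_from_counts <- function(tab, tol = 1e-10, max_iter = 1000L) {
  stopifnot(tol > 0)
  N <- sum(tab)
  if (N == 0)
    stop("LD undefined: no sample is non-missing at both loci")
  # allele counts of the minor alleles a, b
  ca <- sum(tab * matrix(0:2, 3L, 3L)) # rowwise dosage
  cb <- sum(tab * matrix(0:2, 3L, 3L, byrow = TRUE))
  pa <- ca / (2 * N); pb <- cb / (2 * N)
  if (pa <= 0 || pa >= 1 || pb <= 0 || pb >= 1)
    stop("LD undefined: a locus is monomorphic in the pairwise-complete subsample")
  # phase-known haplotype count contributions
  cAB <- 2 * tab[1, 1] + tab[1, 2] + tab[2, 1]
  cAb <- tab[1, 2] + 2 * tab[1, 3] + tab[2, 3]
  caB <- tab[2, 1] + 2 * tab[3, 1] + tab[3, 2]
  cab <- tab[2, 3] + tab[3, 2] + 2 * tab[3, 3]
  ndh <- tab[2, 2]
  p <- c(AB = (1 - pa) * (1 - pb), Ab = (1 - pa) * pb,
         aB = pa * (1 - pb), ab = pa * pb)
  ll <- .two_locus_loglik(p, tab)
  trace <- ll
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    denom <- p["AB"] * p["ab"] + p["Ab"] * p["aB"]
    w <- if (denom > 0) (p["AB"] * p["ab"]) / denom else 0.5
    newp <- c(cAB + w * ndh, cAb + (1 - w) * ndh,
              caB + (1 - w) * ndh, cab + w * ndh) / (2 * N)
    names(newp) <- names(p)
    delta <- max(abs(newp - p))
    p <- newp
    ll <- .two_locus_loglik(p, tab)
    trace <- c(trace, ll)
    if (delta < tol) { converged <- TRUE; break }
  }
  # Boundary snap: EM converges onto a Frechet endpoint of p_AB (e.g. for a
  # duplicated marker) only asymptotically. If the solution sits within 1e-8
  # of an endpoint and the endpoint does not lower the observed-data
  # likelihood, return the endpoint exactly. Interior stationary points
  # (all-double-heterozygote tables) are untouched.
  pA <- p[["AB"]] + p[["Ab"]]; pB <- p[["AB"]] + p[["aB"]]
  for (edge in c(max(0, pA + pB - 1), min(pA, pB))) {
    if (abs(p[["AB"]] - edge) < 1e-8 && p[["AB"]] != edge) {
      cand <- c(AB = edge, Ab = pA - edge, aB = pB - edge,
                ab = 1 - pA - pB + edge)
      cand_ll <- .two_locus_loglik(cand, tab)
      if (cand_ll >= ll) {
        p <- cand; ll <- cand_ll; trace <- c(trace, ll)
      }
    }
  }
  structure(list(p = p, n_eff = N, loglik = ll, loglik_trace = trace,
                 iterations = iter, converged = converged),
            class = "haplotype_freqs")
}

#' @export
print.haplotype_freqs <- function(x, ...) {
  cat("two-locus haplotype frequencies (n_eff =", x$n_eff, "):\n")
  print(round(x$p, 6))
  cat("loglik", format(x$loglik), "after", x$iterations, "iterations",
      if (!x$converged) "(NOT converged)" else "", "\n")
  invisible(x)
}

#' Pairwise r-squared from haplotype frequencies
#'
#' `D = p_AB - p_A * p_B`; `r^2 = D^2 / (p_A (1 - p_A) p_B (1 - p_B))`,
#' clamped to `[0, 1]` against floating-point overshoot.
#'
#' @param freqs a `haplotype_freqs` object (see [em_haplotype_freqs()]).
#' @return r-squared in `[0, 1]`.
#' @export
r2_pair <- function(freqs) {
  p <- freqs$p
  # Algebraically D = p_AB - p_A p_B and den = p_A q_A p_B q_B; these
  # product forms (and their grouping) share roundings so that perfect LD
  # (p_Ab = p_aB = 0) yields exactly 1 in floating point.
  den <- ((p[["AB"]] + p[["Ab"]]) * (p[["aB"]] + p[["ab"]])) *
         ((p[["AB"]] + p[["aB"]]) * (p[["Ab"]] + p[["ab"]]))
  if (den <= 0)
    stop("r^2 undefined: monomorphic locus (zero variance)")
  D <- p[["AB"]] * p[["ab"]] - p[["Ab"]] * p[["aB"]]
  min(max(D^2 / den, 0), 1)
}

#' Pairwise r-squared matrix over a marker subset
#'
#' Markers that are monomorphic or below the MAF threshold are dropped
#' before any pairwise computation ("exclude rare SNPs from the analysis");
#' every remaining pair is estimated by two-locus EM on the
#' pairwise-complete samples. Pairs whose LD is undefined (e.g. a locus
#' monomorphic within the pairwise-complete subsample) are masked in
#' `defined`, never silently set to 0.
#'
#' @param panel a [genotype_panel()].
#' @param marker_subset marker ids or indices (default: all markers).
#' @param maf_min minimum minor allele frequency (default 0: drop only
#'   monomorphic markers).
#' @param tol,max_iter EM controls, see [em_haplotype_freqs()].
#' @return Object of class `ld_matrix`: list with `marker_ids`, `r2`
#'   (symmetric numeric matrix, diagonal 1), `defined` (symmetric logical
#'   mask).
#' @export
r2_matrix <- function(panel, marker_subset = NULL, maf_min = 0,
                      tol = 1e-10, max_iter = 1000L) {
  ids <- panel$markers$id
  if (is.null(marker_subset)) {
    sel <- seq_along(ids)
  } else if (is.character(marker_subset)) {
    sel <- match(marker_subset, ids)
    if (anyNA(sel))
      stop("marker not found: ", paste(marker_subset[is.na(sel)], collapse = ", "))
  } else sel <- as.integer(marker_subset)
  maf <- vapply(sel, function(j) {
    g <- panel$geno[, j]
    if (all(is.na(g))) return(NA_real_)
    compute_maf(panel, j)
  }, numeric(1))
  keep <- !is.na(maf) & maf > 0 & maf >= maf_min
  sel <- sel[keep]
  k <- length(sel)
  r2 <- matrix(NA_real_, k, k, dimnames = list(ids[sel], ids[sel]))
  defined <- matrix(FALSE, k, k, dimnames = dimnames(r2))
  if (k) { diag(r2) <- 1; diag(defined) <- TRUE }
  if (k >= 2L) {
    for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
      val <- tryCatch({
        f <- .em_from_counts(.pair_counts(panel$geno[, sel[a]], panel$geno[, sel[b]]),
                             tol = tol, max_iter = max_iter)
        r2_pair(f)
      }, error = function(e) NA_real_)
      if (!is.na(val)) {
        r2[a, b] <- r2[b, a] <- val
        defined[a, b] <- defined[b, a] <- TRUE
      }
    }
  }
  structure(list(marker_ids = ids[sel], r2 = r2, defined = defined),
            class = "ld_matrix")
}

#' Load a precomputed pairwise r-squared table
#'
#' Reproduces the workflow in which pairwise LD is computed upstream (e.g.
#' by Haploview) and only cluster building happens here. Whitespace-
#' delimited text with three columns: `marker_id_1 marker_id_2 r2`.
#' Unlisted pairs are treated as undefined; diagonal entries are 1.
#'
#' @param path path to the table.
#' @param marker_ids ordered marker ids of the matrix (default: ids in
#'   first-appearance order from the file).
#' @return An `ld_matrix` (see [r2_matrix()]).
#' @export
read_ld_table <- function(path, marker_ids = NULL) {
  tl <- .read_table_lines(path)
  if (length(tl$fields) && any(lengths(tl$fields) != 3L))
    stop("LD table line ", tl$lineno[which(lengths(tl$fields) != 3L)[1L]],
         ": expected 3 columns (id1, id2, r2)")
  id1 <- vapply(tl$fields, `[`, "", 1L)
  id2 <- vapply(tl$fields, `[`, "", 2L)
  val <- suppressWarnings(as.numeric(vapply(tl$fields, `[`, "", 3L)))
  if (anyNA(val))
    stop("LD table line ", tl$lineno[which(is.na(val))[1L]], ": malformed r2 value")
  if (any(val < 0 | val > 1))
    stop("LD table: r2 values must lie in [0, 1]")
  if (is.null(marker_ids)) marker_ids <- unique(c(rbind(id1, id2)))
  k <- length(marker_ids)
  r2 <- matrix(NA_real_, k, k, dimnames = list(marker_ids, marker_ids))
  defined <- matrix(FALSE, k, k, dimnames = dimnames(r2))
  if (k) { diag(r2) <- 1; diag(defined) <- TRUE }
  a <- match(id1, marker_ids); b <- match(id2, marker_ids)
  if (anyNA(a) || anyNA(b))
    stop("LD table references marker ids absent from marker_ids")
  for (t in seq_along(val)) {
    r2[a[t], b[t]] <- r2[b[t], a[t]] <- val[t]
    defined[a[t], b[t]] <- defined[b[t], a[t]] <- TRUE
  }
  structure(list(marker_ids = marker_ids, r2 = r2, defined = defined),
            class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  k <- length(x$marker_ids)
  cat("ld_matrix:", k, "markers,",
      sum(x$defined[upper.tri(x$defined)]), "of", choose(k, 2),
      "pairs defined\n")
  invisible(x)
}
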