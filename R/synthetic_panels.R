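# P(Z1 > a1, Z2 > a2) for standard bivariate normal with correlation rho,
# by 1-D numerical integration (no bivariate-normal CDF dependency):
# integral over x > a1 of phi(x) * P(Z2 > a2 | Z1 = x).
.bvn_upper <- function(a1, a2, rho) {
  if (abs(rho) >= 1) {
    if (rho >= 1) return(stats::pnorm(max(a1, a2), lower.tail = FALSE))
    return(max(0, 1 - stats::pnorm(a1) - stats::pnorm(a2)))
  }
  s <- sqrt(1 - rho^2)
  stats::integrate(function(x)
    stats::dnorm(x) * stats::pnorm((a2 - rho * x) / s, lower.tail = FALSE),
    lower = a1, upper = Inf, rel.tol = 1e-10, abs.tol = 1e-12)$value
}

# Latent Gaussian correlation that yields binary correlation `target`
# between threshold indicators with success probabilities p1, p2.
.latent_rho <- function(target, p1, p2) {
  if (target == 0) return(0)
  a1 <- stats::qnorm(1 - p1); a2 <- stats::qnorm(1 - p2)
  sd12 <- sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  corr_at <- function(rho) (.bvn_upper(a1, a2, rho) - p1 * p2) / sd12
  lo <- corr_at(-0.999999); hi <- corr_at(0.999999)
  if (target < lo - 1e-9 || target > hi + 1e-9)
    stop("infeasible correlation target ", target, " for frequencies ",
         p1, " and ", p2, " (achievable range ", signif(lo, 4), " to ",
         signif(hi, 4), ")")
  stats::uniroot(function(r) corr_at(r) - target,
                 lower = -0.999999, upper = 0.999999, tol = 1e-10)$root
}

#' Specification of a synthetic panel with planted LD blocks
#'
#' Describes a panel in which every SNP of a block carries an identical
#' latent haplotype indicator (perfect LD by construction) and blocks are
#' mutually correlated at the haplotype level through a Gaussian copula.
#'
#' @param n_snps integer vector: number of SNPs per block (a block of 1 is a
#'   planted singleton).
#' @param maf minor allele frequency per block, each in `(0, 0.5]` (recycled).
#' @param n_samples number of diploid samples.
#' @param cross_corr target haplotype-indicator correlation between blocks:
#'   a scalar applied to every pair, or a symmetric matrix (unit diagonal).
#'   Infeasible targets fail before any sampling. Ignored when
#'   `corr_to_first` is given.
#' @param corr_to_first alternative one-factor specification: a vector of
#'   target correlations between each block's indicator and block 1's
#'   (length `B` with leading 1, or `B - 1` for blocks `2..B`). The latent
#'   Gaussian follows a single-factor model, so the joint specification is
#'   always consistent; only the block-to-block-1 correlations are
#'   controlled.
#' @param missing_rate i.i.d. per-genotype missingness in `[0, 1)`.
#' @param positions optional 1-based positions for all SNPs; defaults to
#'   `spacing` apart starting at `start`.
#' @param spacing,start position defaults (1 kb spacing from 10001).
#' @param chrom chromosome label (default "1").
#' @param seed mandatory integer seed; all randomness flows from it.
#' @return Object of class `block_spec`.
#' @export
block_spec <- function(n_snps, maf = 0.3, n_samples = 100L, cross_corr = 0,
                       corr_to_first = NULL, missing_rate = 0,
                       positions = NULL, spacing = 1000L,
                       start = 10001L, chrom = "1", seed) {
  if (missing(seed)) stop("a seed is mandatory")
  n_snps <- as.integer(n_snps)
  stopifnot(length(n_snps) >= 1L, all(n_snps >= 1L), n_samples >= 2L,
            missing_rate >= 0, missing_rate < 1)
  B <- length(n_snps)
  maf <- rep_len(maf, B)
  if (any(maf <= 0 | maf > 0.5)) stop("block MAFs must lie in (0, 0.5]")
  if (is.matrix(cross_corr)) {
    stopifnot(nrow(cross_corr) == B, ncol(cross_corr) == B)
    if (!isTRUE(all.equal(cross_corr, t(cross_corr))))
      stop("cross_corr matrix must be symmetric")
    cc <- cross_corr
  } else {
    cc <- matrix(cross_corr, B, B)
  }
  diag(cc) <- 1
  if (any(cc < -1 | cc > 1)) stop("correlation targets must lie in [-1, 1]")
  if (!is.null(corr_to_first)) {
    if (length(corr_to_first) == B - 1L) corr_to_first <- c(1, corr_to_first)
    if (length(corr_to_first) != B || corr_to_first[1L] != 1)
      stop("corr_to_first must give one target per block (leading entry 1)")
    if (any(corr_to_first < -1 | corr_to_first > 1))
      stop("correlation targets must lie in [-1, 1]")
  }
  m <- sum(n_snps)
  if (is.null(positions)) positions <- start + spacing * (seq_len(m) - 1L)
  if (length(positions) != m) stop("positions must have one entry per SNP")
  structure(list(n_snps = n_snps, maf = maf, n_samples = as.integer(n_samples),
                 cross_corr = cc, corr_to_first = corr_to_first,
                 missing_rate = missing_rate,
                 positions = as.integer(positions), chrom = chrom,
                 seed = as.integer(seed)),
            class = "block_spec")
}

#' Simulate a genotype panel with planted perfect-LD blocks
#'
#' For each block one latent binary haplotype indicator is drawn per
#' chromosome (2 x n_samples) at the block's allele frequency; every SNP in
#' the block copies its block's indicator, so within-block r-squared is
#' exactly 1 whenever no data are missing. Between-block correlation is
#' induced by thresholding a multivariate Gaussian whose latent correlations
#' are solved numerically so the binary indicators hit the target
#' correlation in expectation; an infeasible specification (outside the
#' Frechet bounds, or a non-positive-definite latent matrix) fails before
#' any sampling. Chromosomes are paired randomly into diploid unphased
#' genotypes and missingness is applied i.i.d.
#'
#' @param spec a [block_spec()].
#' @return List with `panel` (a [genotype_panel()]) and `truth`: the planted
#'   partition as `clusters` (list of member-id vectors for blocks with
#'   >= 2 SNPs), `singletons` (ids of 1-SNP blocks), and `assignment`
#'   (named block index per marker).
#' @export
simulate_panel <- function(spec) {
  stopifnot(inherits(spec, "block_spec"))
  B <- length(spec$n_snps)
  if (!is.null(spec$corr_to_first)) {
    # single-factor latent model: loading of block 1 is 1, block j's loading
    # is the tetrachoric solution of its target to block 1, so the latent
    # matrix lambda lambda' + diag(1 - lambda^2) is consistent by
    # construction
    lam <- c(1, vapply(seq_len(B)[-1L], function(j)
      .latent_rho(spec$corr_to_first[j], spec$maf[1L], spec$maf[j]),
      numeric(1)))
    L <- outer(lam, lam)
    diag(L) <- 1
  } else {
    L <- matrix(0, B, B)
    for (i in seq_len(B)) for (j in seq_len(B)) {
      L[i, j] <- if (i == j) 1 else
        .latent_rho(spec$cross_corr[i, j], spec$maf[i], spec$maf[j])
    }
  }
  # The per-pair tetrachoric transform of a positive semidefinite binary
  # target can be marginally indefinite; take an eigendecomposition square
  # root, clipping only numerically-zero negative eigenvalues.
  ev <- eigen(L, symmetric = TRUE)
  if (any(ev$values < -1e-8 * max(1, abs(ev$values))))
    stop("infeasible correlation specification: latent matrix is not ",
         "positive definite")
  A <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), B)
  set.seed(spec$seed)
  nh <- 2L * spec$n_samples
  Z <- matrix(stats::rnorm(nh * B), nh, B) %*% t(A)
  thr <- stats::qnorm(1 - spec$maf)
  X <- sweep(Z, 2L, thr, `>`) + 0L  # haplotype indicators, one column per block
  # random pairing of chromosomes into diploids
  perm <- sample.int(nh)
  G_block <- X[perm[seq(1L, nh, by = 2L)], , drop = FALSE] +
             X[perm[seq(2L, nh, by = 2L)], , drop = FALSE]
  block_of <- rep(seq_len(B), spec$n_snps)
  geno <- G_block[, block_of, drop = FALSE]
  if (spec$missing_rate > 0) {
    miss <- matrix(stats::runif(length(geno)) < spec$missing_rate,
                   nrow(geno), ncol(geno))
    geno[miss] <- NA_integer_
  }
  m <- sum(spec$n_snps)
  ids <- sprintf("rs%02d_%02d", block_of,
                 unlist(lapply(spec$n_snps, seq_len)))
  panel <- genotype_panel(
    markers = data.frame(id = ids, chrom = spec$chrom, pos = spec$positions,
                         stringsAsFactors = FALSE),
    samples = sprintf("S%04d", seq_len(spec$n_samples)),
    geno = geno)
  assignment <- stats::setNames(block_of, ids)
  clusters <- lapply(which(spec$n_snps >= 2L), function(b) ids[block_of == b])
  singles <- ids[block_of %in% which(spec$n_snps == 1L)]
  list(panel = panel,
       truth = list(clusters = clusters, singletons = singles,
                    assignment = assignment))
}

#' Two markers with exactly zero sample LD
#'
#' Balanced construction: the four two-locus haplotypes AB, Ab, aB, ab occur
#' in exactly equal counts (`n_haplotypes / 4` each) and are paired into
#' diploids with no double heterozygotes, so phase is unambiguous and the
#' sample r-squared is exactly 0 (D = 0 by construction). The EM converges
#' in a single iteration because the linkage-equilibrium start is already
#' the maximizer.
#'
#' @param n_haplotypes total haplotype count, divisible by 4.
#' @param positions positions of the two markers (default 10001, 11001).
#' @param chrom chromosome label.
#' @param ids marker ids.
#' @return A [genotype_panel()] with two markers and `n_haplotypes / 2`
#'   samples.
#' @export
balanced_independent_pair <- function(n_haplotypes, positions = c(10001L, 11001L),
                                      chrom = "1", ids = c("rsA", "rsB")) {
  if (n_haplotypes %% 4L != 0L || n_haplotypes < 4L)
    stop("n_haplotypes must be a positive multiple of 4")
  m <- n_haplotypes %/% 4L
  # u individuals AB/Ab and u individuals aB/ab (heterozygous at locus 2),
  # v individuals AB/aB and v individuals Ab/ab (heterozygous at locus 1):
  # each haplotype occurs u + v = m times, no individual is doubly
  # heterozygous, and (for m >= 2) both loci carry homozygote classes.
  u <- (m + 1L) %/% 2L; v <- m - u
  geno <- cbind(c(rep(0L, u), rep(2L, u), rep(1L, 2L * v)),
                c(rep(1L, 2L * u), rep(0L, v), rep(2L, v)))
  genotype_panel(
    markers = data.frame(id = ids, chrom = chrom, pos = positions,
                         stringsAsFactors = FALSE),
    samples = sprintf("S%03d", seq_len(2L * m)),
    geno = geno)
}

#' Duplicate each marker of a two-marker panel into a 2-SNP block
#'
#' Convenience for constructing two perfect-LD blocks with a prescribed
#' between-block LD: each input marker is copied once at `offset_bp`
#' downstream, yielding blocks of exact duplicate genotype columns.
#'
#' @param panel a two-marker [genotype_panel()].
#' @param offset_bp distance between a marker and its copy (default 100).
#' @return A four-marker [genotype_panel()]; copies are named `<id>_dup`.
#' @export
duplicate_into_blocks <- function(panel, offset_bp = 100L) {
  stopifnot(ncol(panel$geno) == 2L)
  mk <- panel$markers
  markers <- data.frame(
    id = c(mk$id[1L], paste0(mk$id[1L], "_dup"),
           mk$id[2L], paste0(mk$id[2L], "_dup")),
    chrom = mk$chrom[1L],
    pos = c(mk$pos[1L], mk$pos[1L] + offset_bp,
            mk$pos[2L], mk$pos[2L] + offset_bp),
    stringsAsFactors = FALSE)
  genotype_panel(markers, panel$samples,
                 panel$geno[, c(1L, 1L, 2L, 2L), drop = FALSE])
}
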