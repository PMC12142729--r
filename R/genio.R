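#' Construct a dosage matrix
#'
#' The universal genetic input of the package: an individuals x loci matrix of
#' alternate-allele counts (0, 1, 2) at biallelic SNPs, with `NA` marking
#' missing genotypes. Dosage is defined as the count of the ALT allele (not
#' the minor allele) so values are stable under subsetting of the dataset.
#'
#' @param values integer matrix, individuals x loci; entries in {0,1,2} or NA.
#' @param sample_ids character vector of row identifiers.
#' @param locus_ids character vector of locus identifiers ("chrom:pos").
#' @return An object of class `dosage_matrix`.
#' @export
dosage_matrix <- function(values, sample_ids = rownames(values),
                          locus_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(sample_ids)) sample_ids <- paste0("ind", seq_len(nrow(values)))
  if (is.null(locus_ids)) locus_ids <- paste0("locus", seq_len(ncol(values)))
  stopifnot(length(sample_ids) == nrow(values),
            length(locus_ids) == ncol(values))
  ok <- values[!is.na(values)]
  if (length(ok) && !all(ok %in% c(0, 1, 2)))
    stop("dosage values must be 0, 1 or 2 (or NA for missing)")
  storage.mode(values) <- "integer"
  dimnames(values) <- list(sample_ids, locus_ids)
  structure(list(values = values,
                 sample_ids = as.character(sample_ids),
                 locus_ids = as.character(locus_ids)),
            class = "dosage_matrix")
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("<dosage_matrix> %d individuals x %d loci (%.1f%% missing)\n",
              nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.dosage_matrix <- function(x) dim(x$values)

#' Missingness mask of a dosage matrix
#' @param g a `dosage_matrix`.
#' @return logical matrix, TRUE where the genotype is missing.
#' @export
missing_mask <- function(g) is.na(g$values)

#' Read a VCF file into a dosage matrix
#'
#' Only biallelic SNP records are kept (single-base REF and ALT); multiallelic
#' and non-SNP records are dropped with a message reporting the count. The
#' dosage of a genotype is the number of ALT alleles in the GT field; missing
#' genotypes ("./.") become `NA`. Locus identifiers are "CHROM:POS" with the
#' 1-based VCF position. Gzip-compressed files are handled transparently.
#'
#' @param path path to a VCF 4.x file (optionally gzipped).
#' @return A [dosage_matrix()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("cannot read VCF file: ", path)
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("cannot parse VCF file: ",
                                           conditionMessage(e)))
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  is_snp <- !is.na(ref) & !is.na(alt) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_drop <- sum(!is_snp)
  if (n_drop > 0)
    message(sprintf("read_vcf: dropped %d non-biallelic-SNP record(s)", n_drop))
  if (!any(is_snp)) stop("no biallelic SNPs remain after filtering")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field")
  gt <- gt[is_snp, , drop = FALSE]
  locus_ids <- paste0(fix[is_snp, "CHROM"], ":", fix[is_snp, "POS"])
  # dosage = count of "1" alleles; any missing allele -> NA
  miss <- is.na(gt) | grepl(".", gt, fixed = TRUE)
  ones <- nchar(gsub("[^1]", "", gt))
  dose <- ifelse(miss, NA_integer_, ones)
  dim(dose) <- dim(gt)
  dosage_matrix(t(dose), sample_ids = colnames(gt), locus_ids = locus_ids)
}

maf <- function(col) {
  p <- mean(col, na.rm = TRUE) / 2
  min(p, 1 - p)
}

#' Prune loci in linkage disequilibrium
#'
#' Greedy sliding-window LD pruning. Windows are defined in locus-index units
#' (a window of `window_size` consecutive loci advanced by `window_step`).
#' Within each window, for every pair of retained loci whose squared Pearson
#' correlation of dosages (pairwise-complete observations) exceeds
#' `r2_threshold`, the locus with the lower minor-allele frequency is removed
#' (ties remove the higher column index). Monomorphic loci have undefined r2,
#' which is treated as 0 (never removed on correlation grounds); a warning is
#' issued when any are present.
#'
#' @param g a `dosage_matrix`.
#' @param window_size window length in loci.
#' @param window_step step between window starts, in loci.
#' @param r2_threshold squared-correlation threshold in (0, 1].
#' @return The pruned `dosage_matrix`.
#' @export
ld_prune <- function(g, window_size = 50, window_step = 5, r2_threshold = 0.2) {
  stopifnot(inherits(g, "dosage_matrix"),
            window_step <= window_size, window_step >= 1,
            r2_threshold > 0, r2_threshold <= 1)
  x <- g$values
  n_loci <- ncol(x)
  vars <- apply(x, 2, stats::var, na.rm = TRUE)
  if (any(!is.na(vars) & vars == 0))
    warning("monomorphic loci present: r2 undefined, treated as 0")
  keep <- rep(TRUE, n_loci)
  mafs <- apply(x, 2, maf)
  starts <- seq(1, max(1, n_loci - 1), by = window_step)
  for (s in starts) {
    idx <- s:min(s + window_size - 1, n_loci)
    idx <- idx[keep[idx]]
    if (length(idx) < 2) next
    cc <- suppressWarnings(stats::cor(x[, idx, drop = FALSE],
                                      use = "pairwise.complete.obs"))
    cc[is.na(cc)] <- 0
    for (a in seq_along(idx)) {
      ia <- idx[a]
      if (!keep[ia]) next
      for (b in seq_along(idx)) {
        if (b <= a) next
        ib <- idx[b]
        if (!keep[ib]) next
        if (cc[a, b]^2 > r2_threshold) {
          drop <- if (mafs[ia] < mafs[ib]) ia
                  else if (mafs[ib] < mafs[ia]) ib
                  else max(ia, ib)
          keep[drop] <- FALSE
          if (drop == ia) break
        }
      }
    }
    if (s + window_size - 1 >= n_loci) break
  }
  dosage_matrix(x[, keep, drop = FALSE], g$sample_ids, g$locus_ids[keep])
}

#' Impute missing genotypes by the per-locus median
#'
#' Each missing cell is replaced by the median of the non-missing dosages at
#' that locus, rounded to the nearest integer with 0.5 rounding up, so the
#' result stays in {0, 1, 2}.
#'
#' @param g a `dosage_matrix`.
#' @return A complete `dosage_matrix`.
#' @export
impute_median <- function(g) {
  stopifnot(inherits(g, "dosage_matrix"))
  x <- g$values
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (!any(miss)) next
    if (all(miss)) stop("locus entirely missing: ", g$locus_ids[j])
    m <- stats::median(x[!miss, j])
    x[miss, j] <- as.integer(floor(m + 0.5))  # .5 rounds up
  }
  dosage_matrix(x, g$sample_ids, g$locus_ids)
}

one_hot_genotypes <- function(x) {
  # n x (3L) indicator encoding; missing rows are all-zero (masked in loss)
  n <- nrow(x); L <- ncol(x)
  v <- matrix(0, n, 3L * L)
  obs <- matrix(FALSE, n, 3L * L)
  for (cls in 0:2) {
    cols <- seq(cls + 1L, 3L * L, by = 3L)
    v[, cols] <- (!is.na(x)) & (x == cls)
    obs[, cols] <- !is.na(x)
  }
  list(v = v, obs = obs)
}

nmf_multiplicative <- function(v, mask, k, seed, max_iter = 200, tol = 1e-6) {
  # weighted NMF: minimize || mask * (v - w h) ||_F^2, multiplicative updates
  set.seed(seed)
  n <- nrow(v); m <- ncol(v)
  w <- matrix(stats::runif(n * k, 0.1, 1), n, k)
  h <- matrix(stats::runif(k * m, 0.1, 1), k, m)
  eps <- 1e-12
  mv <- mask * v
  loss_old <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    wh <- w %*% h
    w <- w * ((mv %*% t(h)) / ((mask * wh) %*% t(h) + eps))
    wh <- w %*% h
    h <- h * ((t(w) %*% mv) / (t(w) %*% (mask * wh) + eps))
    loss <- sum((mask * (v - w %*% h))^2)
    if (is.finite(loss_old) &&
        abs(loss_old - loss) <= tol * max(loss_old, eps)) {
      converged <- TRUE
      loss_old <- loss
      break
    }
    loss_old <- loss
  }
  if (!converged)
    warning("NMF did not converge within ", max_iter,
            " iterations; best iterate used")
  list(w = w, h = h, loss = loss_old)
}

#' Impute missing genotypes from population structure
#'
#' Fits a rank-k non-negative matrix factorization of the one-hot-encoded
#' genotype matrix using only observed cells (missing cells carry zero weight
#' in the loss), then replaces each missing dosage by the genotype class with
#' the largest reconstructed probability. Deterministic for a fixed seed.
#'
#' @param g a `dosage_matrix`.
#' @param k factorization rank (number of latent clusters), >= 1.
#' @param seed integer seed for the factorization initialization.
#' @return A complete `dosage_matrix`; non-missing cells are never altered.
#' @export
impute_structure <- function(g, k = 2, seed = 1) {
  stopifnot(inherits(g, "dosage_matrix"), k >= 1)
  x <- g$values
  if (!anyNA(x)) return(g)
  if (mean(is.na(x)) >= 0.5) stop("missing fraction must be below 50%")
  enc <- one_hot_genotypes(x)
  fit <- nmf_multiplicative(enc$v, enc$obs, k = k, seed = seed)
  recon <- fit$w %*% fit$h
  miss <- which(is.na(x), arr.ind = TRUE)
  for (r in seq_len(nrow(miss))) {
    i <- miss[r, 1]; j <- miss[r, 2]
    probs <- recon[i, (3L * (j - 1L) + 1L):(3L * j)]
    x[i, j] <- which.max(probs) - 1L
  }
  dosage_matrix(x, g$sample_ids, g$locus_ids)
}

#' Write a dosage matrix to CSV
#'
#' Samples x loci table with an `id` column; missing genotypes are written as
#' empty cells.
#' @param g a `dosage_matrix`.
#' @param path output file path.
#' @export
write_dosage_csv <- function(g, path) {
  df <- data.frame(id = g$sample_ids, g$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a dosage matrix from CSV written by [write_dosage_csv()]
#' @param path input file path.
#' @return A [dosage_matrix()].
#' @export
read_dosage_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "integer"
  dosage_matrix(vals, sample_ids = df$id, locus_ids = colnames(df)[-1])
}
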