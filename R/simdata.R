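# Synthetic landscapes, coordinates and genotypes with known structure:
# spatially autocorrelated environmental layers, demes occupying contiguous
# longitudinal blocks with Balding-Nichols-style drift, a distance-decaying
# neutral spatial signal (isolation by distance), and environment-associated
# adaptive loci. Every output is deterministic for a fixed seed and the truth
# record is sufficient to score downstream recovery tests.

#' Configuration for the synthetic-data generator
#'
#' @param seed integer seed; all outputs are deterministic given it.
#' @param n_individuals,n_loci dataset dimensions.
#' @param n_demes number of demes (contiguous longitudinal blocks).
#' @param deme_divergence drift intensity in [0, 1] (Balding-Nichols F).
#' @param ibd_strength scale of the distance-decaying neutral spatial signal
#'   on the logit allele-frequency scale (0 disables IBD).
#' @param n_adaptive_loci,adaptive_effect count and logit-scale effect size
#'   of environment-associated loci (associated with the first layer).
#' @param missing_rate MCAR missing-genotype rate in [0, 1).
#' @param grid_nrow,grid_ncol landscape grid dimensions (>= 10).
#' @param n_env_layers number of environmental layers.
#' @param env_range autocorrelation range of the layers, in cell units (the
#'   distance at which spatial correlation decays to 0.05).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 42, n_individuals = 60, n_loci = 500,
                       n_demes = 2, deme_divergence = 0.3,
                       ibd_strength = 0.5, n_adaptive_loci = 10,
                       adaptive_effect = 1.5, missing_rate = 0,
                       grid_nrow = 20, grid_ncol = 20, n_env_layers = 2,
                       env_range = 6) {
  stopifnot(n_adaptive_loci <= n_loci,
            deme_divergence >= 0, deme_divergence <= 1,
            ibd_strength >= 0, adaptive_effect >= 0,
            missing_rate >= 0, missing_rate < 1,
            grid_nrow >= 10, grid_ncol >= 10)
  structure(list(seed = seed, n_individuals = n_individuals, n_loci = n_loci,
                 n_demes = n_demes, deme_divergence = deme_divergence,
                 ibd_strength = ibd_strength,
                 n_adaptive_loci = n_adaptive_loci,
                 adaptive_effect = adaptive_effect,
                 missing_rate = missing_rate,
                 grid_nrow = grid_nrow, grid_ncol = grid_ncol,
                 n_env_layers = n_env_layers, env_range = env_range),
            class = "sim_config")
}

gaussian_field <- function(nr, nc, range_cells) {
  # kernel-smoothed white noise; the smoothing kernel sd is chosen so the
  # field's Gaussian autocorrelation drops to 0.05 at `range_cells`
  sigma <- max(range_cells / (2 * sqrt(log(1 / 0.05))), 1e-6)
  pad <- ceiling(3 * sigma)
  noise <- matrix(stats::rnorm((nr + 2 * pad) * (nc + 2 * pad)),
                  nr + 2 * pad, nc + 2 * pad)
  if (sigma < 0.05) {
    sm <- noise
  } else {
    ks <- seq(-pad, pad)
    kern <- exp(-ks^2 / (2 * sigma^2))
    kern <- kern / sum(kern)
    sm <- apply(noise, 2, function(col) stats::filter(col, kern, sides = 2))
    sm <- t(apply(sm, 1, function(row) stats::filter(row, kern, sides = 2)))
  }
  out <- sm[(pad + 1):(pad + nr), (pad + 1):(pad + nc)]
  (out - mean(out)) / stats::sd(out)
}

#' Simulate spatially autocorrelated environmental layers
#'
#' Gaussian random fields built by Gaussian-kernel smoothing of white noise,
#' standardized to zero mean and unit variance, on a unit-degree grid with
#' 0.1-degree cells starting at (0, 0).
#'
#' @param cfg a [sim_config()].
#' @return list of `grid_surface` layers (`env1`, `env2`, ...).
#' @export
simulate_landscape <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  lapply(seq_len(cfg$n_env_layers), function(i)
    grid_surface(gaussian_field(cfg$grid_nrow, cfg$grid_ncol, cfg$env_range),
                 xmin = 0, ymax = cfg$grid_nrow * 0.1, xres = 0.1,
                 name = paste0("env", i)))
}

#' Simulate sampling coordinates inside the landscape extent
#'
#' Uniform random points over the grid extent (with a half-cell inset so
#' every point falls strictly inside a cell).
#'
#' @param cfg a [sim_config()].
#' @return A [sample_coords()] table.
#' @export
simulate_coords <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1)
  w <- cfg$grid_ncol * 0.1
  h <- cfg$grid_nrow * 0.1
  sample_coords(sprintf("ind%03d", seq_len(cfg$n_individuals)),
                lon = stats::runif(cfg$n_individuals, 0.05, w - 0.05),
                lat = stats::runif(cfg$n_individuals, 0.05, h - 0.05))
}

logistic <- function(x) 1 / (1 + exp(-x))
logit <- function(p) log(p / (1 - p))

#' Simulate genotypes with deme structure, IBD and adaptive loci
#'
#' Ancestral allele frequencies are Uniform(0.1, 0.9); each deme (a
#' contiguous longitudinal block of the landscape) drifts them by a
#' Balding-Nichols Beta draw with `F = deme_divergence`. A low-rank
#' distance-decaying spatial field perturbs individual-level logit
#' frequencies (isolation by distance, scaled by `ibd_strength`), and the
#' first `n_adaptive_loci` loci receive a logit shift of
#' `adaptive_effect x` the standardized first environmental layer at the
#' individual's location. Genotypes are Binomial(2, p) (Hardy-Weinberg
#' within locality); missing calls are MCAR at `missing_rate`.
#'
#' @param cfg a [sim_config()].
#' @param coords a [sample_coords()] table (defaults to [simulate_coords()]).
#' @param env optional layer list from [simulate_landscape()].
#' @return list with `genotypes` (a `dosage_matrix`), `coords`, `env_layers`,
#'   and `truth` (deme labels, adaptive locus indices, complete dosages and
#'   masked-cell indices).
#' @export
simulate_genotypes <- function(cfg, coords = NULL, env = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(env)) env <- simulate_landscape(cfg)
  if (is.null(coords)) coords <- simulate_coords(cfg)
  set.seed(cfg$seed + 2)
  n <- cfg$n_individuals; l <- cfg$n_loci
  # demes: contiguous longitudinal blocks
  breaks <- stats::quantile(coords$lon,
                            probs = seq(0, 1, length.out = cfg$n_demes + 1))
  breaks[1] <- -Inf; breaks[length(breaks)] <- Inf
  deme <- as.integer(cut(coords$lon, breaks, labels = FALSE,
                         include.lowest = TRUE))
  p_anc <- stats::runif(l, 0.1, 0.9)
  f <- cfg$deme_divergence
  deme_freq <- matrix(p_anc, cfg$n_demes, l, byrow = TRUE)
  if (f > 0 && cfg$n_demes > 1) {
    a <- p_anc * (1 - f) / f
    b <- (1 - p_anc) * (1 - f) / f
    for (dd in seq_len(cfg$n_demes))
      deme_freq[dd, ] <- stats::rbeta(l, a, b)
  }
  eta <- logit(pmin(pmax(deme_freq[deme, , drop = FALSE], 1e-4), 1 - 1e-4))
  if (cfg$ibd_strength > 0) {
    # low-rank spatial signal: a few smooth basis fields with random
    # per-locus weights give a distance-decaying genetic covariance
    n_basis <- 8
    basis <- sapply(seq_len(n_basis), function(b) {
      fl <- gaussian_field(cfg$grid_nrow, cfg$grid_ncol, cfg$env_range)
      gs <- grid_surface(fl, 0, cfg$grid_nrow * 0.1, 0.1)
      extract_env(gs, coords)[, 1]
    })
    wts <- matrix(stats::rnorm(n_basis * l), n_basis, l) / sqrt(n_basis)
    eta <- eta + cfg$ibd_strength * (basis %*% wts)
  }
  adaptive_idx <- integer(0)
  if (cfg$n_adaptive_loci > 0 && cfg$adaptive_effect > 0) {
    adaptive_idx <- seq_len(cfg$n_adaptive_loci)
    ev <- extract_env(env[[1]], coords)[, 1]
    ev <- (ev - mean(ev)) / stats::sd(ev)
    eta[, adaptive_idx] <- eta[, adaptive_idx] +
      cfg$adaptive_effect * matrix(ev, n, length(adaptive_idx))
  }
  p_ind <- pmin(pmax(logistic(eta), 1e-4), 1 - 1e-4)
  dose <- matrix(stats::rbinom(n * l, 2, p_ind), n, l)
  complete <- dose
  masked <- matrix(FALSE, n, l)
  if (cfg$missing_rate > 0) {
    masked <- matrix(stats::runif(n * l) < cfg$missing_rate, n, l)
    dose[masked] <- NA_integer_
  }
  gm <- dosage_matrix(dose, sample_ids = coords$id,
                      locus_ids = paste0("1:", seq_len(l)))
  list(genotypes = gm, coords = coords, env_layers = env,
       truth = list(deme = deme, adaptive_idx = adaptive_idx,
                    complete = complete, masked = masked,
                    deme_freq = deme_freq))
}

#' Write a dosage matrix as a minimal VCF 4.2 file
#'
#' One biallelic SNP record per locus (REF=A, ALT=T), diploid GT genotypes,
#' missing as "./.". Locus ids of the form "chrom:pos" set CHROM and POS.
#'
#' @param g a `dosage_matrix`.
#' @param path output path.
#' @export
write_vcf <- function(g, path) {
  ids <- strsplit(g$locus_ids, ":", fixed = TRUE)
  chrom <- vapply(ids, `[`, character(1), 1)
  pos <- vapply(ids, function(v) if (length(v) > 1) v[2] else "1",
                character(1))
  gt_map <- c("0/0", "0/1", "1/1")
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", g$sample_ids), collapse = "\t"))
  rows <- vapply(seq_along(g$locus_ids), function(j) {
    d <- g$values[, j]
    gt <- ifelse(is.na(d), "./.", gt_map[d + 1])
    paste(c(chrom[j], pos[j], g$locus_ids[j], "A", "T", ".", "PASS", ".",
            "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write all simulation outputs to a directory
#'
#' Emits VCF genotypes, a coordinates CSV, environmental layers as ESRI
#' ASCII grids, and the truth record as JSON.
#'
#' @param sim output of [simulate_genotypes()].
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of files written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    vcf = file.path(dir, "genotypes.vcf"),
    coords = file.path(dir, "coords.csv"),
    truth = file.path(dir, "truth.json"))
  write_vcf(sim$genotypes, files["vcf"])
  utils::write.csv(sim$coords, files["coords"], row.names = FALSE)
  for (i in seq_along(sim$env_layers)) {
    f <- file.path(dir, paste0(sim$env_layers[[i]]$name, ".asc"))
    write_gridsurface(sim$env_layers[[i]], f)
    files <- c(files, f)
  }
  jsonlite::write_json(
    list(deme = sim$truth$deme, adaptive_idx = sim$truth$adaptive_idx,
         n_masked = sum(sim$truth$masked)),
    files["truth"], auto_unbox = TRUE)
  invisible(files)
}
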