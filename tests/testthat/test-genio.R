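test_that("read_vcf converts genotypes to ALT-allele dosages", {
  path <- write_fixture_vcf(c(
    vcf_header(),
    vcf_record("1", 100, "A", "T", c("0/0", "0/1", "1/1"))))
  g <- read_vcf(path)
  expect_equal(unname(g$values[, 1]), c(0L, 1L, 2L))
  expect_equal(g$locus_ids, "1:100")
  expect_equal(g$sample_ids, c("s1", "s2", "s3"))
})

test_that("read_vcf keeps loci with missing genotypes and marks them NA", {
  path <- write_fixture_vcf(c(
    vcf_header(),
    vcf_record("1", 100, "A", "T", c("0/0", "./.", "1/1")),
    vcf_record("1", 200, "G", "C", c("0/1", "0/1", "0/0"))))
  g <- read_vcf(path)
  expect_equal(ncol(g$values), 2L)
  expect_true(is.na(g$values[2, 1]))
  expect_equal(unname(g$values[, 2]), c(1L, 1L, 0L))
})

test_that("read_vcf drops non-biallelic-SNP records and reports the count", {
  path <- write_fixture_vcf(c(
    vcf_header(),
    vcf_record("1", 100, "A", "T", c("0/0", "0/1", "1/1")),
    vcf_record("1", 150, "A", "T,G", c("0/1", "0/2", "1/2")),
    vcf_record("1", 200, "G", "C", c("0/0", "0/0", "0/1"))))
  expect_message(g <- read_vcf(path), "dropped 1")
  expect_equal(g$locus_ids, c("1:100", "1:200"))
  expect_error(read_vcf(write_fixture_vcf(c(
    vcf_header(), vcf_record("1", 1, "A", "AT", c("0/0", "0/1", "1/1"))))),
    "no biallelic SNPs")
})

test_that("a synthetic VCF written and re-read round-trips dosages exactly", {
  sim <- small_sim(seed = 4, n = 25, l = 60, miss = 0.1)
  path <- tempfile(fileext = ".vcf")
  write_vcf(sim$genotypes, path)
  g2 <- read_vcf(path)
  expect_identical(unname(g2$values), unname(sim$genotypes$values))
  expect_identical(g2$sample_ids, sim$genotypes$sample_ids)
})

test_that("ld_prune removes one of two identical columns and keeps independent ones", {
  set.seed(7)
  a <- rbinom(50, 2, 0.5)
  # identical pair: r2 = 1 > 0.2 -> one survivor
  g <- dosage_matrix(cbind(l1 = a, l2 = a))
  pruned <- ld_prune(g, window_size = 10, window_step = 5,
                     r2_threshold = 0.2)
  expect_equal(ncol(pruned$values), 1L)
  # independent pair below threshold -> both retained
  repeat {
    b <- rbinom(50, 2, 0.5)
    if (cor(a, b)^2 < 0.2) break
  }
  g2 <- dosage_matrix(cbind(l1 = a, l2 = b))
  expect_equal(ncol(ld_prune(g2, 10, 5, 0.2)$values), 2L)
})

test_that("ld_prune at threshold 1 returns imperfectly correlated input unchanged", {
  set.seed(8)
  x <- matrix(rbinom(40 * 6, 2, 0.4), 40, 6)
  g <- dosage_matrix(x)
  expect_identical(ld_prune(g, 6, 3, 1.0)$values, g$values)
})

test_that("ld_prune survivors pass a brute-force within-window r2 post-check", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 60; l <- 40
    base <- matrix(rbinom(n * l, 2, runif(l, 0.2, 0.8)), n, l, byrow = FALSE)
    # plant correlated runs
    base[, 10] <- base[, 9]
    base[, 25] <- pmin(2, base[, 24] + rbinom(n, 1, 0.05))
    g <- dosage_matrix(base)
    window <- 15; thr <- 0.3
    pruned <- ld_prune(g, window, 5, thr)
    keep_idx <- match(pruned$locus_ids, g$locus_ids)
    for (s in seq(1, l, by = 5)) {
      w <- keep_idx[keep_idx >= s & keep_idx <= s + window - 1]
      if (length(w) < 2) next
      cc <- suppressWarnings(cor(base[, w, drop = FALSE]))
      cc[is.na(cc)] <- 0
      diag(cc) <- 0
      expect_lte(max(cc^2), thr)
    }
  }
})

test_that("ld_prune warns on monomorphic loci and never removes them for correlation", {
  x <- cbind(mono = rep(1L, 30), poly = rbinom(30, 2, 0.5))
  g <- dosage_matrix(x)
  expect_warning(pruned <- ld_prune(g, 10, 5, 0.2), "monomorphic")
  expect_true("mono" %in% pruned$locus_ids)
})

test_that("impute_median fills with the rounded per-locus median", {
  g <- dosage_matrix(cbind(a = c(0L, 2L, NA, 0L),
                           b = c(0L, 0L, 2L, NA),
                           c = c(1L, 1L, 1L, NA)))
  out <- impute_median(g)
  expect_equal(unname(out$values[3, "a"]), 0L)  # median of {0,2,0} = 0
  expect_equal(unname(out$values[4, "b"]), 0L)  # median of {0,0,2} = 0
  expect_equal(unname(out$values[4, "c"]), 1L)  # median of {1,1,1} = 1
  expect_false(anyNA(out$values))
})

test_that("impute_median on a two-value locus takes the midpoint rounded up", {
  g <- dosage_matrix(cbind(a = c(0L, 2L, NA)))
  expect_equal(unname(impute_median(g)$values[3, 1]), 1L)
  g2 <- dosage_matrix(cbind(a = c(1L, 2L, NA, NA)))  # median 1.5 rounds up
  expect_equal(unname(impute_median(g2)$values[3, 1]), 2L)
})

test_that("impute_median errors with the locus name when a locus is all-missing", {
  g <- dosage_matrix(cbind(ok = c(0L, 1L), bad = c(NA, NA)))
  expect_error(impute_median(g), "bad")
})

test_that("imputation never alters observed genotypes", {
  sim <- small_sim(seed = 5, n = 30, l = 80, miss = 0.1)
  obs <- !is.na(sim$genotypes$values)
  m1 <- impute_median(sim$genotypes)
  m2 <- impute_structure(sim$genotypes, k = 2, seed = 3)
  expect_identical(m1$values[obs], sim$genotypes$values[obs])
  expect_identical(m2$values[obs], sim$genotypes$values[obs])
})

test_that("impute_structure is the identity on complete data and seed-reproducible", {
  sim <- small_sim(seed = 6, n = 20, l = 40, miss = 0)
  expect_identical(impute_structure(sim$genotypes, 2, 1)$values,
                   sim$genotypes$values)
  simm <- small_sim(seed = 6, n = 20, l = 40, miss = 0.1)
  a <- impute_structure(simm$genotypes, k = 2, seed = 9)
  b <- impute_structure(simm$genotypes, k = 2, seed = 9)
  expect_identical(a$values, b$values)
})

test_that("rank-1 structure imputation recovers the modal genotype on homogeneous data", {
  set.seed(2)
  n <- 40; l <- 30
  p <- runif(l, 0.1, 0.9)
  x <- sapply(p, function(pp) rbinom(n, 2, pp))
  x_miss <- x
  hide <- cbind(sample(n, l, replace = TRUE), seq_len(l))
  x_miss[hide] <- NA
  g <- dosage_matrix(x_miss)
  out <- impute_structure(g, k = 1, seed = 3)
  modal <- apply(x_miss, 2, function(col) {
    tab <- table(col)
    as.integer(names(tab)[which.max(tab)])
  })
  agree <- mean(out$values[hide] == modal)
  expect_gte(agree, 0.9)
})

test_that("dosage CSV export round-trips including missing cells", {
  sim <- small_sim(seed = 7, n = 10, l = 15, miss = 0.15)
  path <- tempfile(fileext = ".csv")
  write_dosage_csv(sim$genotypes, path)
  g2 <- read_dosage_csv(path)
  expect_identical(g2$values, sim$genotypes$values)
})
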