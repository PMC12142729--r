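test_that("rarefied richness matches exhaustive subset enumeration", {
  # closed example: counts (3,1), g=2 -> 1.5
  expect_equal(rarefied_richness(3, 1, 2), 1.5)
  expect_equal(rarefied_richness(5, 0, 3), 1.0)   # single allele
  expect_equal(rarefied_richness(4, 2, 6), 2.0)   # g = N: observed count
  enum_oracle <- function(c0, c1, g) {
    pool <- c(rep(0, c0), rep(1, c1))
    subsets <- utils::combn(length(pool), g)
    mean(apply(subsets, 2, function(ix) length(unique(pool[ix]))))
  }
  set.seed(1)
  for (rep in 1:20) {
    n <- sample(2:12, 1)
    c0 <- sample(0:n, 1); c1 <- n - c0
    g <- sample(seq_len(n), 1)
    expect_equal(rarefied_richness(c0, c1, g), enum_oracle(c0, c1, g),
                 tolerance = 1e-12)
  }
  expect_error(rarefied_richness(2, 1, 5), "exceeds")
})

test_that("window statistics reproduce closed-form examples", {
  grid <- grid_surface(matrix(NA_real_, 3, 3), 0, 3, 1)
  co <- sample_coords(c("a", "b"), lon = c(1.5, 1.5), lat = c(1.5, 1.4))
  # both individuals in the center cell
  g_het <- dosage_matrix(rbind(a = c(1L, 1L), b = c(1L, 1L)))
  wd <- window_diversity(g_het, co, grid, diversity_config("het", 3, 2))
  expect_equal(wd$surface$values[2, 2], 1.0)
  # pi for dosages (0,2) at one locus: 4 copies, 2/3
  g_pi <- dosage_matrix(rbind(a = 0L, b = 2L))
  wp <- window_diversity(g_pi, co, grid, diversity_config("pi", 3, 2))
  expect_equal(wp$surface$values[2, 2], 2 / 3)
  # monomorphic data: richness 1 everywhere defined
  g_mono <- dosage_matrix(rbind(a = c(2L, 2L), b = c(2L, 2L)))
  wr <- window_diversity(g_mono, co, grid,
                         diversity_config("allelic_richness", 3, 2))
  vals <- wr$surface$values
  expect_true(all(vals[!is.na(vals)] == 1.0))
  # windows that never reach min_n are an error with advice
  far <- sample_coords(c("a", "b"), lon = c(0.5, 2.5), lat = c(0.5, 2.5))
  expect_error(window_diversity(g_het, far, grid,
                                diversity_config("het", 1, 2)), "wdim")
})

test_that("window_diversity equals a brute-force per-window oracle on a 5x5 grid", {
  sim <- small_sim(seed = 21, n = 30, l = 40, miss = 0.1)
  grid <- make_grid(sim$coords, resolution = diff(range(sim$coords$lon)) / 5,
                    buffer = 0.01)
  cells <- cell_of_point(grid, sim$coords)
  for (stat in c("het", "pi", "allelic_richness")) {
    cfg <- diversity_config(stat, wdim = 3, min_n = 2, rarefy = FALSE)
    wd <- window_diversity(sim$genotypes, sim$coords, grid, cfg)
    x <- sim$genotypes$values
    for (r in seq_len(nrow(grid$values))) for (cl in seq_len(ncol(grid$values))) {
      pool <- which(abs(cells$row - r) <= 1 & abs(cells$col - cl) <= 1)
      expect_equal(wd$counts$values[r, cl], length(pool))
      if (length(pool) < 2) {
        expect_true(is.na(wd$surface$values[r, cl]))
        next
      }
      sub <- x[pool, , drop = FALSE]
      oracle <- switch(stat,
        het = mean(sub[!is.na(sub)] == 1),
        pi = {
          per <- apply(sub, 2, function(col) {
            col <- col[!is.na(col)]
            m <- 2 * length(col)
            if (m < 2) return(NA_real_)
            2 * sum(col) * (m - sum(col)) / (m * (m - 1))
          })
          mean(per, na.rm = TRUE)
        },
        allelic_richness = {
          per <- apply(sub, 2, function(col) {
            col <- col[!is.na(col)]
            if (!length(col)) return(NA_real_)
            sum(any(col < 2), any(col > 0))  # ref seen, alt seen
          })
          mean(per, na.rm = TRUE)
        })
      expect_equal(wd$surface$values[r, cl], oracle, tolerance = 1e-12)
    }
  }
})

test_that("diversity statistics stay in their theoretical ranges and count every individual", {
  sim <- small_sim(seed = 22, n = 25, l = 60, miss = 0.05)
  grid <- make_grid(sim$coords, resolution = diff(range(sim$coords$lon)) / 6,
                    buffer = 0.05)
  het <- window_diversity(sim$genotypes, sim$coords, grid,
                          diversity_config("het", 3, 2))
  pi <- window_diversity(sim$genotypes, sim$coords, grid,
                         diversity_config("pi", 3, 2))
  ar <- window_diversity(sim$genotypes, sim$coords, grid,
                         diversity_config("allelic_richness", 3, 2,
                                          rarefy = TRUE, g = 4))
  rng <- function(s) range(s$surface$values, na.rm = TRUE)
  expect_true(all(rng(het) >= 0 & rng(het) <= 1))
  expect_true(all(rng(pi) >= 0 & rng(pi) <= 1))
  expect_true(all(rng(ar) >= 1 & rng(ar) <= 2))
  expect_gte(sum(het$counts$values), nrow(sim$coords))
})

test_that("interpolation fills nodata, preserves constants and masks to the hull", {
  grid <- grid_surface(matrix(NA_real_, 6, 6), 0, 6, 1)
  filled <- grid
  set.seed(3)
  filled$values[] <- 2.5
  filled$values[sample(36, 10)] <- NA
  out <- interpolate_surface(filled, method = "idw")
  expect_equal(out$values, matrix(2.5, 6, 6), tolerance = 1e-6)
  # fully defined input returned unchanged
  full <- grid; full$values[] <- rnorm(36)
  expect_equal(interpolate_surface(full, "idw")$values, full$values)
  # fewer than 5 defined cells: kriging falls back to IDW with a warning
  sparse <- grid; sparse$values[1, 1:3] <- 1
  expect_warning(interpolate_surface(sparse, "krige"), "IDW")
  # convex hull mask: point-in-polygon oracle on a known square hull
  co <- sample_coords(paste0("s", 1:4), lon = c(1.2, 4.8, 4.8, 1.2),
                      lat = c(1.2, 1.2, 4.8, 4.8))
  masked <- interpolate_surface(full, "idw", mask_to = "convex_hull",
                                coords = co)
  centers <- cell_centers(grid)
  inside_oracle <- centers$lon >= 1.2 & centers$lon <= 4.8 &
    centers$lat >= 1.2 & centers$lat <= 4.8
  got <- !is.na(masked$values[cbind(centers$row, centers$col)])
  expect_equal(got, inside_oracle)
})
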