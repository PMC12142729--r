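# Fixtures built in code: tiny VCF files, small simulated datasets and
# shared oracles used across test files.

write_fixture_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

vcf_header <- function(samples = c("s1", "s2", "s3")) {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

vcf_record <- function(chrom, pos, ref, alt, gts) {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

small_sim <- function(seed = 11, n = 50, l = 300, demes = 2, div = 0.5,
                      miss = 0, ...) {
  simulate_genotypes(sim_config(seed = seed, n_individuals = n, n_loci = l,
                                n_demes = demes, deme_divergence = div,
                                missing_rate = miss, ...))
}

# independent BH step-up oracle (direct formula)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# dense Laplacian-pseudoinverse commute-distance oracle for a tiny surface
commute_oracle <- function(resistance, coords) {
  surf <- resistance
  v <- surf$values
  nr <- nrow(v); nc <- ncol(v)
  idx <- matrix(seq_len(nr * nc), nr, nc)
  cond <- 1 / v
  lap <- matrix(0, nr * nc, nr * nc)
  add_edge <- function(a, b, w) {
    lap[a, b] <<- lap[a, b] - w; lap[b, a] <<- lap[b, a] - w
    lap[a, a] <<- lap[a, a] + w; lap[b, b] <<- lap[b, b] + w
  }
  total <- 0
  for (r in seq_len(nr)) for (cl in seq_len(nc)) {
    for (d in list(c(0, 1, 1), c(1, 0, 1), c(1, 1, 1 / sqrt(2)),
                   c(1, -1, 1 / sqrt(2)))) {
      r2 <- r + d[1]; c2 <- cl + d[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      w <- d[3] * (cond[r, cl] + cond[r2, c2]) / 2
      add_edge(idx[r, cl], idx[r2, c2], w)
      total <- total + w
    }
  }
  lplus <- MASS::ginv(lap)
  cells <- cell_of_point(surf, coords)
  nodes <- idx[cbind(cells$row, cells$col)]
  n <- length(nodes)
  out <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- nodes[i]; b <- nodes[j]
    if (a == b) next
    reff <- lplus[a, a] + lplus[b, b] - 2 * lplus[a, b]
    out[i, j] <- out[j, i] <- 2 * total * reff
  }
  out
}
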