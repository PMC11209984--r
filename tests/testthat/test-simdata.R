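test_that("layout and parameter validation rejects inconsistent inputs", {
  expect_error(genome_layout(data.frame(name = character(), length = numeric())),
               "at least one chromosome")
  expect_error(genome_layout(c(chr1 = 1e5),
                             sdr = list(chrom = "chr1", start = 9e4, end = 2e5)),
               "out of bounds")
  expect_error(genome_layout(c(chr1 = 1e6),
                             sdr = list(chrom = "chr1", start = 0, end = 1e5),
                             y_insertion = list(chrom = "chr1", start = 5e4,
                                                end = 1.5e5)),
               "overlap")
  expect_error(sim_params(background_snp_rate = 1.2), "\\[0, 1\\]")
  expect_error(sim_params(rad_sex_linked_count = 5, rad_marker_count = 2),
               "exceeds")
  expect_error(sim_params(pool_depth = -1), "pool_depth")
})

test_that("simulation is deterministic under a fixed seed", {
  lay <- genome_layout(c(chr1 = 5e4),
                       sdr = list(chrom = "chr1", start = 1e4, end = 3e4))
  p <- sim_params(seed = 42, rad_marker_count = 50)
  expect_identical(simulate_pools(lay, p), simulate_pools(lay, p))
  expect_identical(simulate_rad(lay, p), simulate_rad(lay, p))
  expect_identical(simulate_genotype_table(p), simulate_genotype_table(p))
})

test_that("zero pool depth yields zero counts everywhere", {
  lay <- genome_layout(c(chr1 = 2e4))
  s <- simulate_pools(lay, sim_params(seed = 1, pool_depth = 0))
  cnt <- as.matrix(s[, grep("^[mf]_", names(s)), with = FALSE])
  expect_true(all(cnt == 0L))
  expect_gt(nrow(s), 0L)
})

test_that("X/Y-divergent sites show a male-pool alternate frequency near 0.5 and fixed females", {
  lay <- genome_layout(c(chr1 = 3e5),
                       sdr = list(chrom = "chr1", start = 5e4, end = 2.5e5))
  p <- sim_params(seed = 11, seq_error_rate = 0, background_snp_rate = 0,
                  pool_depth = 40)
  s <- simulate_pools(lay, p, dense_step = NA)
  div <- s[s$site_type == "xy_divergent", ]
  expect_gte(nrow(div), 100L)
  fq <- pool_frequencies(div, scan_params())
  maf <- fq$m_minor_freq[fq$m_depth > 0]
  # analytic binomial expectation: sd of minor freq at depth ~40 is
  # sqrt(0.25/40) per site, but minor freq is folded at 0.5, so check the
  # unfolded alternate-read fraction instead
  alt_frac <- 1 - ifelse(div$ref == "A", div$m_A,
                         ifelse(div$ref == "C", div$m_C,
                                ifelse(div$ref == "G", div$m_G, div$m_T))) /
    fq$m_depth
  se <- sqrt(0.25 / 40 / length(alt_frac))
  expect_lt(abs(mean(alt_frac) - 0.5), 3 * se)
  expect_true(all(fq$f_major_freq[fq$f_depth > 0] == 1))
})

test_that("Y-limited insertion gives haploid male coverage and zero female coverage", {
  lay <- genome_layout(c(chr1 = 4e5),
                       y_insertion = list(chrom = "chr1", start = 1e5, end = 3e5))
  p <- sim_params(seed = 3, seq_error_rate = 0, pool_depth = 40)
  s <- simulate_pools(lay, p)
  inside <- s$pos >= 1e5 & s$pos < 3e5
  dm <- rowSums(s[inside, grep("^m_", names(s)), with = FALSE])
  df <- rowSums(s[inside, grep("^f_", names(s)), with = FALSE])
  expect_lt(abs(mean(dm) - 20), 3 * sqrt(20 / length(dm)))
  expect_true(all(df == 0))
  outside <- !inside
  dmo <- rowSums(s[outside, grep("^m_", names(s)), with = FALSE])
  expect_lt(abs(mean(dmo) - 40), 3 * sqrt(40 / length(dmo)))
})

test_that("per-site depth means match the Poisson parameters over >= 1000 sites", {
  lay <- genome_layout(c(chr1 = 1e6))
  p <- sim_params(seed = 9, pool_depth = 25, seq_error_rate = 0)
  s <- simulate_pools(lay, p)
  expect_gte(nrow(s), 1000L)
  for (pool in c("m", "f")) {
    d <- rowSums(s[, grep(paste0("^", pool, "_"), names(s)), with = FALSE])
    expect_lt(abs(mean(d) - 25), 3 * sqrt(25 / length(d)))
  }
})

test_that("sex-linked RAD markers are male-limited and dropout follows its rate", {
  lay <- genome_layout(c(chr1 = 1e5))
  p <- sim_params(seed = 5, n_males = 35, n_females = 34,
                  rad_marker_count = 200, rad_sex_linked_count = 1,
                  rad_dropout_rate = 0)
  rad <- simulate_rad(lay, p)
  pres <- rad_presence(rad, 1)
  linked <- rad$sex_linked
  expect_length(linked, 1L)
  expect_equal(sum(pres[linked, rad$sex == "M"]), 35)
  expect_equal(sum(pres[linked, rad$sex == "F"]), 0)

  # binomial expectation for presence under dropout: 40 * 0.9 per marker
  p2 <- sim_params(seed = 6, n_males = 20, n_females = 20,
                   rad_marker_count = 1000, rad_sex_linked_count = 0,
                   rad_dropout_rate = 0.1)
  rad2 <- simulate_rad(lay, p2)
  pres2 <- rad_presence(rad2, 1)
  per_marker <- rowSums(pres2)
  se <- sqrt(40 * 0.9 * 0.1 / 1000)
  expect_lt(abs(mean(per_marker) - 36), 3 * se)
  # no marker is male-limited beyond dropout noise
  male_limited <- rowSums(pres2[, rad2$sex == "F"]) == 0 &
    rowSums(pres2[, rad2$sex == "M"]) == 20
  expect_false(any(male_limited))
})

test_that("genotype tables follow the XY expectation and noise rates", {
  p0 <- sim_params(seed = 2, n_males = 48, n_females = 48,
                   geno_error_rate = 0, geno_missing_rate = 0)
  g <- simulate_genotype_table(p0, xy_linked = TRUE)
  expect_equal(unlist(g[, c("male_ho", "male_he", "male_u")]),
               c(male_ho = 0L, male_he = 48L, male_u = 0L))
  expect_equal(unlist(g[, c("female_ho", "female_he", "female_u")]),
               c(female_ho = 48L, female_he = 0L, female_u = 0L))

  # female-only missingness at 0.125: expected 6 of 48 uncalled
  u <- vapply(1:40, function(sd) {
    p <- sim_params(seed = sd, n_males = 48, n_females = 48,
                    geno_error_rate = 0, geno_missing_rate = 0.125)
    g <- simulate_genotype_table(p, xy_linked = TRUE,
                                 missing_rates = c(male = 0))
    c(g$female_u, g$male_u)
  }, numeric(2))
  expect_true(all(u[2, ] == 0))
  se <- sqrt(48 * 0.125 * 0.875 / 40)
  expect_lt(abs(mean(u[1, ]) - 6), 3 * se)

  # counts always sum to n per sex
  p <- sim_params(seed = 8, n_males = 31, n_females = 27)
  g <- simulate_genotype_table(p, xy_linked = FALSE)
  expect_equal(g$n_males, 31L)
  expect_equal(g$n_females, 27L)
})
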