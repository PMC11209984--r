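test_that("pool frequencies use A/C/G/T counts only and honour min_depth", {
  s <- make_sites(c(100, 200, 300),
                  male = c("A15 T15", "A19 T1", "A5 N20"),
                  female = c("A30", "A30", "A30"))
  fq <- pool_frequencies(s, scan_params(min_depth = 10, hom_min_major = 0.98))
  expect_equal(fq$m_major_freq, c(0.5, 0.95, 1))
  expect_equal(fq$f_major_freq, c(1, 1, 1))
  expect_equal(fq$m_depth, c(30, 20, 5))  # N excluded from the denominator
  expect_equal(fq$m_pass, c(TRUE, TRUE, FALSE))
  expect_false(fq$m_major_freq[2] >= 0.98)
})

test_that("site classification matches the heterozygous/homozygous rule", {
  s <- make_sites(c(10, 20, 30, 40),
                  male = c("A20 G20", "A40", "A40", "A4 G4"),
                  female = c("A40", "A40", "A20 G20", "A40"))
  cls <- classify_sites(s, scan_params(min_depth = 10))
  expect_equal(as.character(cls$status),
               c("male_specific", "none", "female_specific", "low_depth"))
})

test_that("classification agrees with a brute-force re-evaluation of the frequency rules", {
  # exhaustive two-base compositions at depth 12 for the male pool crossed
  # with a grid of female compositions, plus random four-base sites
  params <- scan_params(min_depth = 10, het_delta = 0.1, hom_min_major = 0.98)
  grid <- expand.grid(a = 0:12, c = 0:12)
  s <- make_sites(seq_len(nrow(grid)) * 10,
                  male = sprintf("A%d G%d", grid$a, 12 - grid$a),
                  female = sprintf("A%d T%d", grid$c, 12 - grid$c))
  set.seed(99)
  rnd <- matrix(sample(0:12, 8 * 300, replace = TRUE), ncol = 8)
  s2 <- make_sites(seq_len(300) * 10 + 1e5,
                   male = sprintf("A%d C%d G%d T%d", rnd[, 1], rnd[, 2],
                                  rnd[, 3], rnd[, 4]),
                   female = sprintf("A%d C%d G%d T%d", rnd[, 5], rnd[, 6],
                                    rnd[, 7], rnd[, 8]))
  s <- rbind(s, s2)
  cls <- classify_sites(s, params)

  brute <- apply(as.matrix(s[, c(paste0("m_", c("A", "C", "G", "T")),
                                 paste0("f_", c("A", "C", "G", "T"))),
                             with = FALSE]),
                 1, function(v) {
    m <- sort(v[1:4], decreasing = TRUE); f <- sort(v[5:8], decreasing = TRUE)
    if (sum(m) < 10 || sum(f) < 10) return("low_depth")
    het <- function(x) abs(x[2] / sum(x) - 0.5) <= 0.1
    hom <- function(x) x[1] / sum(x) >= 0.98
    if (het(m) && hom(f)) "male_specific"
    else if (het(f) && hom(m)) "female_specific"
    else "none"
  })
  expect_equal(as.character(cls$status), unname(brute))
})

test_that("a single SNV lands in exactly the sliding windows covering it", {
  s <- make_sites(4500, male = "A20 G20", female = "A40")
  tr <- window_scan(s, scan_params(), chrom_lengths = c(chr1 = 10000))
  hit <- tr$start[tr$male_specific_snvs == 1]
  expect_equal(hit, c(0, 1000, 2000, 3000, 4000))
  expect_true(all(tr$male_specific_snvs[!tr$start %in% hit] == 0))
  expect_equal(nrow(tr), 10)
})

test_that("window scan rejects unsorted input with the offending position", {
  s <- make_sites(c(5000, 1000), male = c("A40", "A40"), female = c("A40", "A40"))
  expect_error(window_scan(s, scan_params()), "row 2.*chr1:1000")
})

test_that("an empty chromosome yields an all-zero track", {
  s <- make_sites(100, male = "A40", female = "A40")
  tr <- window_scan(s, scan_params(), chrom_lengths = c(chr1 = 5e4, chr2 = 2e4))
  tr2 <- tr[tr$chrom == "chr2", ]
  expect_equal(nrow(tr2), 20)
  expect_true(all(tr2$male_specific_snvs == 0) && all(is.na(tr2$depth_m)))
})

test_that("non-overlapping bins conserve totals and match interval arithmetic", {
  s <- make_sites(c(10, 49999, 50000),
                  male = rep("A20 G20", 3), female = rep("A40", 3))
  bins <- manhattan_bins(s, scan_params(), chrom_lengths = c(chr1 = 1e5))
  expect_equal(bins$start, c(0, 50000))
  expect_equal(bins$male_specific_snvs, c(2, 1))
  expect_equal(sum(bins$male_specific_snvs), 3)

  # conservation on a simulated genome: bin totals equal classified totals,
  # and each interior SNV appears in window_size / output_resolution windows
  lay <- genome_layout(c(chr1 = 2e5),
                       sdr = list(chrom = "chr1", start = 5e4, end = 1.5e5))
  sim <- simulate_pools(lay, sim_params(seed = 4))
  params <- scan_params()
  cls <- classify_sites(sim, params)
  bins <- manhattan_bins(sim, params, chrom_lengths = lay)
  expect_equal(sum(bins$male_specific_snvs), sum(cls$status == "male_specific"))
  expect_equal(sum(bins$female_specific_snvs), sum(cls$status == "female_specific"))
  tr <- window_scan(sim, params, chrom_lengths = lay)
  interior <- cls$status == "male_specific" & cls$pos >= params$window_size
  expect_equal(sum(tr$male_specific_snvs),
               sum(cls$status == "male_specific") * 5 -
                 sum((params$window_size - 1 - cls$pos[cls$status == "male_specific" &
                                                         cls$pos < params$window_size - 1]) %/%
                       params$output_resolution))
})

test_that("swapping pool labels swaps male- and female-specific output exactly", {
  lay <- genome_layout(c(chr1 = 1e5),
                       sdr = list(chrom = "chr1", start = 2e4, end = 8e4))
  sim <- simulate_pools(lay, sim_params(seed = 13))
  params <- scan_params()
  cls <- classify_sites(sim, params)
  cls_sw <- classify_sites(swap_pools(sim), params)
  expect_equal(as.character(cls_sw$status),
               c(male_specific = "female_specific",
                 female_specific = "male_specific",
                 none = "none", low_depth = "low_depth")[as.character(cls$status)],
               ignore_attr = TRUE)
  tr <- window_scan(sim, params, chrom_lengths = lay)
  tr_sw <- window_scan(swap_pools(sim), params, chrom_lengths = lay)
  expect_equal(tr$male_specific_snvs, tr_sw$female_specific_snvs)
  expect_equal(tr$depth_m, tr_sw$depth_f)
  expect_equal(call_sdr(tr, sex = "male"), call_sdr(tr_sw, sex = "female"))
})

test_that("stricter depth and homozygosity thresholds never add sex-specific SNVs", {
  lay <- genome_layout(c(chr1 = 2e5),
                       sdr = list(chrom = "chr1", start = 5e4, end = 1.5e5))
  sim <- simulate_pools(lay, sim_params(seed = 21, pool_depth = 30))
  n_specific <- function(params) {
    cls <- classify_sites(sim, params)
    sum(cls$status %in% c("male_specific", "female_specific"))
  }
  for (par in list(list(a = scan_params(min_depth = 5), b = scan_params(min_depth = 15)),
                   list(a = scan_params(hom_min_major = 0.9),
                        b = scan_params(hom_min_major = 0.99)))) {
    expect_gte(n_specific(par$a), n_specific(par$b))
  }
})

test_that("region calling equals an independent run-length scanner on random tracks", {
  set.seed(7)
  for (rep in 1:200) {
    counts <- stats::rpois(60, 1.2) * stats::rbinom(60, 1, 0.4)
    min_count <- sample(1:3, 1)
    max_gap <- sample(0:4, 1)
    min_windows <- sample(1:4, 1)
    tr <- make_track(counts, window_size = 5000L, step = 1000L)
    got <- call_sdr(tr, min_count = min_count, min_windows = min_windows,
                    max_gap = max_gap)
    runs <- oracle_runs(counts >= min_count, max_gap)
    runs <- Filter(function(r) sum(counts[r[1]:r[2]] >= min_count) >= min_windows,
                   runs)
    expect_equal(nrow(got), length(runs))
    if (length(runs)) {
      want <- data.table::data.table(
        start = vapply(runs, function(r) (r[1] - 1) * 1000, 0),
        end = vapply(runs, function(r) (r[2] - 1) * 1000 + 5000, 0))
      data.table::setorderv(want, "start")
      gs <- data.table::copy(got)[order(start)]
      expect_equal(gs$start, want$start)
      expect_equal(gs$end, want$end)
    }
  }
  expect_error(call_sdr(make_track(c(1, 2)), min_count = 0), "min_count")
})

test_that("one qualifying run of 96 window steps yields a single 100-kb region", {
  counts <- c(rep(0L, 50), rep(6L, 96), rep(0L, 50))
  tr <- make_track(counts)
  calls <- call_sdr(tr, min_count = 5, min_windows = 10, max_gap = 2)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$end - calls$start, 100e3)
  expect_equal(calls$n_windows, 96L)
})

test_that("coverage region detection matches a brute-force threshold scan", {
  # equal-depth genome: nothing to call
  tr0 <- make_track(rep(0L, 100), depth_m = rep(40, 100), depth_f = rep(40, 100))
  expect_equal(nrow(coverage_regions(tr0)), 0L)

  set.seed(31)
  for (rep in 1:50) {
    n <- 80
    dm <- stats::runif(n, 0, 50)
    df <- stats::runif(n, 0, 50)
    tr <- make_track(rep(0L, n), depth_m = dm, depth_f = df)
    f_frac <- stats::runif(1, 0.05, 0.3)
    lo <- stats::runif(1, 0.2, 0.45); hi <- stats::runif(1, 0.55, 0.9)
    max_gap <- sample(0:3, 1)
    got <- coverage_regions(tr, f_max_frac = f_frac, m_range = c(lo, hi),
                            min_windows = 1, max_gap = max_gap)
    qual <- df <= f_frac * stats::median(df) &
      dm >= lo * stats::median(dm) & dm <= hi * stats::median(dm)
    runs <- oracle_runs(qual, max_gap)
    expect_equal(nrow(got), length(runs))
    if (length(runs)) {
      gs <- data.table::copy(got)[order(start)]
      expect_equal(gs$start, vapply(runs, function(r) (r[1] - 1) * 1000, 0))
      expect_equal(gs$end, vapply(runs, function(r) (r[2] - 1) * 1000 + 5000, 0))
    }
  }
  expect_error(coverage_regions(make_track(c(0L, 0L), depth_f = c(0, 0))),
               "median depth is zero")
})

test_that("simulated Y-insertion is recovered with haploid male coverage", {
  lay <- example_layout()
  sim <- simulate_pools(lay, sim_params(seed = 17))
  tr <- window_scan(sim, scan_params(), chrom_lengths = lay)
  cov <- coverage_regions(tr)
  expect_gte(nrow(cov), 1L)
  top <- cov[1, ]
  expect_equal(top$chrom, "chr3")
  expect_lt(top$start, 1053e3)
  expect_gt(top$end, 1e6)
  expect_lt(abs(top$mean_depth_m - 20), 2)
  expect_lte(top$mean_depth_f, 1)
})

test_that("gene annotation overlap matches brute-force interval comparison", {
  lay <- example_layout()
  region <- list(chrom = "chr2", start = 950e3, end = 1050e3)
  expect_equal(annotate_region(region, lay$genes),
               c("c18h1orf198", "cx32.2", "gja13.2", "cx32.7", "hsdl1",
                 "tbc1d32"))
  expect_equal(annotate_region(list(chrom = "chr1", start = 0, end = 1e4),
                               lay$genes), character(0))

  set.seed(5)
  for (rep in 1:50) {
    genes <- data.frame(chrom = sample(c("c1", "c2"), 30, replace = TRUE),
                        start = sample(0:1000, 30), strand = "+",
                        name = paste0("g", 1:30))
    genes$end <- genes$start + sample(1:200, 30)
    region <- list(chrom = "c1", start = 300, end = 600)
    brute <- genes[genes$chrom == "c1" & genes$start < 600 & genes$end > 300, ]
    brute <- brute$name[order(brute$start)]
    expect_equal(annotate_region(region, genes), brute)
  }
})
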