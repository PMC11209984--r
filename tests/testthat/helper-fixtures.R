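# Small builders shared across test files.

# One site's pooled counts from two base:count strings like "A15 T15".
make_sites <- function(pos, male, female, chrom = "chr1", ref = "A") {
  parse_counts <- function(s) {
    v <- stats::setNames(rep(0L, 6L), c("A", "C", "G", "T", "N", "del"))
    if (nzchar(s)) {
      for (tok in strsplit(s, " ", fixed = TRUE)[[1]]) {
        base <- sub("[0-9]+$", "", tok)
        v[base] <- as.integer(sub("^[A-Za-z]+", "", tok))
      }
    }
    v
  }
  rows <- lapply(seq_along(pos), function(i) {
    m <- parse_counts(male[[i]])
    f <- parse_counts(female[[i]])
    dt <- data.table::data.table(chrom = chrom, pos = as.integer(pos[i]),
                                 ref = ref)
    dt[, (paste0("m_", names(m))) := as.list(m)]
    dt[, (paste0("f_", names(f))) := as.list(f)]
    dt
  })
  out <- data.table::rbindlist(rows)
  data.table::setattr(out, "class",
                      c("pooled_sites", class(data.table::data.table())))
  out[]
}

# Exchange the male and female pool columns.
swap_pools <- function(sites) {
  out <- data.table::copy(sites)
  mcols <- grep("^m_", names(sites), value = TRUE)
  fcols <- sub("^m_", "f_", mcols)
  data.table::setnames(out, c(mcols, fcols), c(fcols, mcols))
  data.table::setcolorder(out, names(sites))
  out
}

# A window_track built directly from per-window counts (single chromosome).
make_track <- function(male_counts, female_counts = rep(0L, length(male_counts)),
                       depth_m = rep(40, length(male_counts)),
                       depth_f = rep(40, length(male_counts)),
                       window_size = 5000L, step = 1000L, chrom = "chr1") {
  n <- length(male_counts)
  out <- data.table::data.table(
    chrom = chrom, start = step * (seq_len(n) - 1L),
    n_sites = rep(5L, n),
    male_specific_snvs = as.integer(male_counts),
    female_specific_snvs = as.integer(female_counts),
    depth_m = depth_m, depth_f = depth_f)
  data.table::setattr(out, "window_size", window_size)
  data.table::setattr(out, "output_resolution", step)
  data.table::setattr(out, "class",
                      c("window_track", class(data.table::data.table())))
  out[]
}

# Independent run-merging oracle: a left-to-right state machine over windows,
# counting consecutive sub-threshold windows, structurally unlike the
# index-diff implementation in the package.
oracle_runs <- function(qualifying, max_gap) {
  regions <- list()
  open <- FALSE
  first <- last <- NA_integer_
  misses <- 0L
  for (i in seq_along(qualifying)) {
    if (qualifying[i]) {
      if (!open) { open <- TRUE; first <- i }
      last <- i
      misses <- 0L
    } else if (open) {
      misses <- misses + 1L
      if (misses > max_gap) {
        regions[[length(regions) + 1L]] <- c(first, last)
        open <- FALSE
        misses <- 0L
      }
    }
  }
  if (open) regions[[length(regions) + 1L]] <- c(first, last)
  regions
}

# Closed-form Yates chi-square for a 2x2 table plus the df=1 upper tail via
# the normal distribution (erfc identity), independent of pchisq and of the
# cell-wise expected-count formula used in the package.
oracle_yates <- function(a, b, c, d) {
  n <- a + b + c + d
  dev <- max(abs(a * d - b * c) - n / 2, 0)
  chi2 <- n * dev^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  list(chi2 = chi2, p = 2 * stats::pnorm(sqrt(chi2), lower.tail = FALSE))
}

oracle_pearson <- function(a, b, c, d) {
  n <- a + b + c + d
  chi2 <- n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  list(chi2 = chi2, p = 2 * stats::pnorm(sqrt(chi2), lower.tail = FALSE))
}
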