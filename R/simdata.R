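BASES <- c("A", "C", "G", "T")
COUNT_COLS <- c(paste0("m_", c(BASES, "N", "del")),
                paste0("f_", c(BASES, "N", "del")))

#' Simulate pooled allele counts along an XY genome
#'
#' Generates per-site nucleotide counts for a male pool and a female pool with
#' the structure a pooled-sequencing sex scan assumes:
#' \itemize{
#'   \item background polymorphic sites everywhere, whose population allele
#'     frequency is drawn once per site from Beta(0.7, 0.7) and shared by the
#'     sexes, so both pools sample reads from the same binomial;
#'   \item X/Y-divergent sites inside the SDR, where every male carries one X
#'     (reference) and one Y (alternate) haplotype: expected male-pool
#'     alternate frequency 0.5, female pool fixed for the reference;
#'   \item inside a Y-limited insertion, female depth is exactly zero and male
#'     depth halves (one haploid copy per male), mirroring the half-coverage
#'     signature of a hemizygous region;
#'   \item per-site pool depths are Poisson(`pool_depth`); each read is
#'     independently miscalled to a uniformly chosen other base with
#'     probability `seq_error_rate`.
#' }
#' A dense record of monomorphic sites every `dense_step` bp carries depth
#' information between variant sites so that coverage tracks do not depend on
#' SNV density.
#'
#' @param layout a [genome_layout()].
#' @param params a [sim_params()].
#' @param dense_step spacing (bp) of monomorphic depth records; `NA` disables
#'   them.
#' @return a `data.table` of class `pooled_sites`, sorted by (chrom, pos), with
#'   columns `chrom`, `pos` (0-based), `ref`, twelve count columns
#'   (`m_A` ... `m_del`, `f_A` ... `f_del`) and `site_type` (the simulation
#'   truth: `background`, `xy_divergent` or `depth_record`).
#' @seealso [classify_sites()], [window_scan()], [write_sync()]
#' @export
simulate_pools <- function(layout, params, dense_step = 1000) {
  stopifnot(inherits(layout, "genome_layout"), inherits(params, "sim_params"))
  with_seed(params$seed, {
    per_chrom <- lapply(seq_len(nrow(layout$chromosomes)), function(i) {
      sim_pools_chrom(layout$chromosomes$name[i], layout$chromosomes$length[i],
                      layout, params, dense_step)
    })
  })
  out <- data.table::rbindlist(per_chrom)
  data.table::setattr(out, "class",
                      c("pooled_sites", class(data.table::data.table())))
  out[]
}

sim_pools_chrom <- function(chrom, len, layout, params, dense_step) {
  # site positions by type; divergent sites take precedence on collision
  n_bg <- stats::rbinom(1L, len, params$background_snp_rate)
  pos_bg <- sort(sample.int(len, n_bg)) - 1L
  pos_div <- integer(0)
  sdr <- layout$sdr
  if (!is.null(sdr) && sdr$chrom == chrom) {
    span <- sdr$end - sdr$start
    n_div <- stats::rbinom(1L, span, params$xy_divergent_rate)
    pos_div <- sdr$start + sort(sample.int(span, n_div)) - 1L
  }
  pos_bg <- setdiff(pos_bg, pos_div)
  pos_dense <- if (is.na(dense_step)) integer(0) else
    setdiff(seq.int(0L, len - 1L, by = dense_step), c(pos_bg, pos_div))

  pos <- c(pos_bg, pos_div, pos_dense)
  type <- rep(c("background", "xy_divergent", "depth_record"),
              c(length(pos_bg), length(pos_div), length(pos_dense)))
  o <- order(pos)
  pos <- pos[o]; type <- type[o]
  n <- length(pos)
  if (n == 0L) return(empty_sites())

  ref_idx <- sample.int(4L, n, replace = TRUE)
  alt_idx <- (ref_idx - 1L + sample.int(3L, n, replace = TRUE)) %% 4L + 1L

  # Poisson depths; hemizygous insertion: male haploid, female zero
  lam_m <- rep(params$pool_depth, n)
  lam_f <- rep(params$pool_depth, n)
  yi <- layout$y_insertion
  if (!is.null(yi) && yi$chrom == chrom) {
    inside <- pos >= yi$start & pos < yi$end
    lam_m[inside] <- params$pool_depth / 2
    lam_f[inside] <- 0
  }
  depth_m <- stats::rpois(n, lam_m)
  depth_f <- stats::rpois(n, lam_f)

  # true alternate-allele frequency per pool
  p_shared <- numeric(n)
  is_bg <- type == "background"
  p_shared[is_bg] <- stats::rbeta(sum(is_bg), 0.7, 0.7)
  p_m <- p_shared; p_f <- p_shared
  is_div <- type == "xy_divergent"
  p_m[is_div] <- 0.5
  p_f[is_div] <- 0

  alt_m <- stats::rbinom(n, depth_m, p_m)
  alt_f <- stats::rbinom(n, depth_f, p_f)

  cm <- base_count_matrix(n, ref_idx, alt_idx, depth_m, alt_m)
  cf <- base_count_matrix(n, ref_idx, alt_idx, depth_f, alt_f)
  cm <- add_read_errors(cm, params$seq_error_rate)
  cf <- add_read_errors(cf, params$seq_error_rate)

  dt <- data.table::data.table(chrom = chrom, pos = as.integer(pos),
                               ref = BASES[ref_idx])
  dt[, (COUNT_COLS) := c(split_cols(cm), list(0L, 0L),
                         split_cols(cf), list(0L, 0L))]
  dt[, "site_type" := type]
  dt
}

empty_sites <- function() {
  dt <- data.table::data.table(chrom = character(), pos = integer(),
                               ref = character())
  dt[, (COUNT_COLS) := integer()]
  dt[, "site_type" := character()]
  dt
}

base_count_matrix <- function(n, ref_idx, alt_idx, depth, alt) {
  m <- matrix(0L, n, 4L)
  m[cbind(seq_len(n), ref_idx)] <- depth - alt
  m[cbind(seq_len(n), alt_idx)] <- m[cbind(seq_len(n), alt_idx)] + alt
  m
}

split_cols <- function(m) lapply(seq_len(ncol(m)), function(j) m[, j])

# Miscall each read independently with probability e to a uniform other base.
add_read_errors <- function(m, e) {
  if (e == 0) return(m)
  n <- nrow(m)
  err <- matrix(stats::rbinom(length(m), as.vector(m), e), n, 4L)
  k <- sum(err)
  if (k == 0L) return(m)
  idx <- which(err > 0L, arr.ind = TRUE)
  times <- err[idx]
  row_id <- rep(idx[, 1L], times)
  from <- rep(idx[, 2L], times)
  dest <- (from - 1L + sample.int(3L, k, replace = TRUE)) %% 4L + 1L
  inc <- tabulate((row_id - 1L) * 4L + dest, nbins = n * 4L)
  m - err + matrix(inc, n, 4L, byrow = TRUE)
}

#' Simulate a RAD-seq marker depth matrix with sex-linked markers
#'
#' Produces a marker-by-individual read-depth matrix in which
#' `rad_sex_linked_count` randomly chosen markers sit on the Y haplotype and
#' therefore have nonzero depth only in males, while the remaining markers are
#' shared by all individuals. Depths are Poisson with mean
#' `pool_depth` scaled by a per-individual library-size factor
#' (lognormal, sdlog 0.2); independent dropout zeroes each marker-individual
#' cell with probability `rad_dropout_rate`.
#'
#' @param layout a [genome_layout()] (markers are not placed on the genome;
#'   accepted for interface symmetry with [simulate_pools()]).
#' @param params a [sim_params()].
#' @return an object of class `rad_matrix`: list with `depth` (integer matrix,
#'   markers x individuals), `sex` (named vector of "M"/"F") and
#'   `sex_linked` (ids of the truly male-limited markers).
#' @export
simulate_rad <- function(layout, params) {
  stopifnot(inherits(params, "sim_params"))
  if (params$n_males + params$n_females == 0L)
    stop("at least one individual is required")
  with_seed(params$seed, {
    n_ind <- params$n_males + params$n_females
    ids <- c(sprintf("M%03d", seq_len(params$n_males)),
             sprintf("F%03d", seq_len(params$n_females)))
    sex <- stats::setNames(rep(c("M", "F"), c(params$n_males, params$n_females)),
                           ids)
    markers <- sprintf("RAD%06d", seq_len(params$rad_marker_count))
    size_factor <- exp(stats::rnorm(n_ind, 0, 0.2))
    lam <- outer(rep(params$pool_depth, params$rad_marker_count), size_factor)
    depth <- matrix(stats::rpois(length(lam), lam),
                    nrow = params$rad_marker_count,
                    dimnames = list(markers, ids))
    linked <- sort(sample.int(params$rad_marker_count,
                              params$rad_sex_linked_count))
    depth[linked, sex == "F"] <- 0L
    if (params$rad_dropout_rate > 0) {
      drop <- matrix(stats::runif(length(depth)) < params$rad_dropout_rate,
                     nrow = nrow(depth))
      depth[drop] <- 0L
    }
  })
  structure(list(depth = depth, sex = sex, sex_linked = markers[linked]),
            class = "rad_matrix")
}

#' @export
print.rad_matrix <- function(x, ...) {
  cat("rad_matrix:", nrow(x$depth), "markers x", ncol(x$depth),
      "individuals (", sum(x$sex == "M"), "M /", sum(x$sex == "F"), "F )\n")
  invisible(x)
}

#' Simulate a genotyping-assay count table
#'
#' Emulates an allele-specific PCR assay scored on phenotypically sexed
#' individuals. Under XY linkage the true genotype is heterozygous in every
#' male and homozygous in every female; genotyping error flips Ho and He with
#' probability `geno_error_rate` and each individual is uncalled with
#' probability `geno_missing_rate`. With `xy_linked = FALSE` the genotype is
#' independent of sex (He with probability 1/2).
#'
#' @param params a [sim_params()] (uses `n_males`, `n_females`,
#'   `geno_error_rate`, `geno_missing_rate`, `seed`).
#' @param xy_linked is the assayed variant on the Y haplotype?
#' @param assay_id label for the output row.
#' @param missing_rates optional length-2 named vector
#'   `c(male =, female =)` overriding `geno_missing_rate` per sex.
#' @return a one-row [genotype_counts()] table.
#' @export
simulate_genotype_table <- function(params, xy_linked = TRUE,
                                    assay_id = "assay1",
                                    missing_rates = NULL) {
  stopifnot(inherits(params, "sim_params"))
  miss <- c(male = params$geno_missing_rate, female = params$geno_missing_rate)
  if (!is.null(missing_rates)) {
    if (any(missing_rates < 0 | missing_rates > 1))
      stop("missing rates must lie in [0, 1]")
    miss[names(missing_rates)] <- missing_rates
  }
  with_seed(params$seed, {
    call_sex <- function(n, true_he, p_miss) {
      u <- stats::runif(n) < p_miss
      he <- if (is.na(true_he)) stats::runif(n) < 0.5 else {
        flip <- stats::runif(n) < params$geno_error_rate
        xor(rep(true_he, n), flip)
      }
      c(ho = sum(!u & !he), he = sum(!u & he), u = sum(u))
    }
    m <- call_sex(params$n_males, if (xy_linked) TRUE else NA, miss["male"])
    f <- call_sex(params$n_females, if (xy_linked) FALSE else NA, miss["female"])
  })
  genotype_counts(assay_id, m["ho"], m["he"], m["u"], f["ho"], f["he"], f["u"])
}
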