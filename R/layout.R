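#' Describe a genome layout for simulation and scanning
#'
#' A `genome_layout` holds the chromosome table and the intervals that give a
#' synthetic XY genome its sex-linked structure: an optional allelic
#' sex-determining region (SDR) in which males are X/Y heterozygous, an
#' optional Y-limited insertion that is hemizygous in males and absent from
#' females, and a gene annotation set used for region annotation.
#'
#' All coordinates are 0-based half-open internally; user-facing writers
#' convert to the convention of each file format.
#'
#' @param chromosomes a data.frame with columns `name` and `length` (bp), or a
#'   named numeric vector of chromosome lengths.
#' @param sdr optional allelic SDR interval as `list(chrom =, start =, end =)`
#'   (0-based half-open).
#' @param y_insertion optional Y-limited insertion interval, same form.
#' @param genes optional gene annotation: data.frame with columns `chrom`,
#'   `start`, `end`, `strand`, `name` (0-based half-open).
#' @return an object of class `genome_layout`.
#' @examples
#' genome_layout(c(chr1 = 1e6), sdr = list(chrom = "chr1", start = 4e5, end = 5e5))
#' @export
genome_layout <- function(chromosomes, sdr = NULL, y_insertion = NULL,
                          genes = NULL) {
  if (is.numeric(chromosomes)) {
    if (is.null(names(chromosomes)) || anyDuplicated(names(chromosomes)))
      stop("chromosome vector must have unique names")
    chromosomes <- data.frame(name = names(chromosomes),
                              length = as.numeric(chromosomes))
  }
  chromosomes <- as.data.frame(chromosomes)
  if (!all(c("name", "length") %in% names(chromosomes)))
    stop("chromosomes needs 'name' and 'length' columns")
  if (nrow(chromosomes) == 0L) stop("layout must contain at least one chromosome")
  if (any(chromosomes$length <= 0)) stop("chromosome lengths must be positive")
  if (anyDuplicated(chromosomes$name)) stop("duplicated chromosome names")

  check_interval <- function(iv, what) {
    if (is.null(iv)) return(NULL)
    iv <- as.list(iv)
    if (!all(c("chrom", "start", "end") %in% names(iv)))
      stop(what, " needs chrom, start, end")
    i <- match(iv$chrom, chromosomes$name)
    if (is.na(i)) stop(what, " chromosome '", iv$chrom, "' not in layout")
    if (iv$start < 0 || iv$end > chromosomes$length[i] || iv$end <= iv$start)
      stop(what, " interval out of bounds or empty")
    iv[c("chrom", "start", "end")]
  }
  sdr <- check_interval(sdr, "sdr")
  y_insertion <- check_interval(y_insertion, "y_insertion")
  if (!is.null(sdr) && !is.null(y_insertion) &&
      sdr$chrom == y_insertion$chrom &&
      sdr$start < y_insertion$end && y_insertion$start < sdr$end)
    stop("sdr and y_insertion intervals overlap")

  if (!is.null(genes)) {
    genes <- as.data.frame(genes)
    need <- c("chrom", "start", "end", "strand", "name")
    if (!all(need %in% names(genes))) stop("genes needs columns: ",
                                           paste(need, collapse = ", "))
    i <- match(genes$chrom, chromosomes$name)
    if (anyNA(i)) stop("gene on unknown chromosome: ",
                       genes$chrom[which(is.na(i))[1]])
    bad <- genes$start < 0 | genes$end > chromosomes$length[i] |
      genes$end <= genes$start
    if (any(bad)) stop("invalid gene interval: ", genes$name[which(bad)[1]])
    genes <- genes[order(i, genes$start), , drop = FALSE]
    rownames(genes) <- NULL
  }

  structure(list(chromosomes = chromosomes, sdr = sdr,
                 y_insertion = y_insertion, genes = genes),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", nrow(x$chromosomes), "chromosome(s),",
      format(sum(x$chromosomes$length), big.mark = ","), "bp total\n")
  fmt_iv <- function(iv) sprintf("%s:%s-%s (%.1f kb)", iv$chrom,
                                 format(iv$start, big.mark = ","),
                                 format(iv$end, big.mark = ","),
                                 (iv$end - iv$start) / 1e3)
  if (!is.null(x$sdr)) cat("  allelic SDR:      ", fmt_iv(x$sdr), "\n")
  if (!is.null(x$y_insertion)) cat("  Y-limited region: ", fmt_iv(x$y_insertion), "\n")
  if (!is.null(x$genes)) cat("  genes:            ", nrow(x$genes), "\n")
  invisible(x)
}

#' Demonstration XY genome layout
#'
#' Three 2-Mb chromosomes; a 100-kb allelic SDR on chr2 containing six genes
#' (a C1orf198 homolog, three gap-junction connexins, an inactive
#' hydroxysteroid dehydrogenase-like gene and a TBC1 domain gene, the gene
#' content typical of a young percid sex locus); and a 53-kb Y-limited
#' insertion on chr3.
#'
#' @param sdr_len SDR length in bp.
#' @param insertion_len Y-limited insertion length in bp.
#' @return a [genome_layout()].
#' @export
example_layout <- function(sdr_len = 100e3, insertion_len = 53e3) {
  chroms <- data.frame(name = c("chr1", "chr2", "chr3"), length = 2e6)
  sdr_start <- 950e3
  genes <- data.frame(
    chrom  = "chr2",
    start  = sdr_start + c(2e3, 18e3, 33e3, 48e3, 63e3, 80e3),
    end    = sdr_start + c(14e3, 30e3, 44e3, 59e3, 76e3, 97e3),
    strand = c("+", "-", "+", "+", "-", "+"),
    name   = c("c18h1orf198", "cx32.2", "gja13.2", "cx32.7", "hsdl1", "tbc1d32")
  )
  genes$end <- pmin(genes$end, sdr_start + sdr_len - 1e3)
  genome_layout(chroms,
                sdr = list(chrom = "chr2", start = sdr_start,
                           end = sdr_start + sdr_len),
                y_insertion = list(chrom = "chr3", start = 1e6,
                                   end = 1e6 + insertion_len),
                genes = genes)
}

#' Simulation parameters for a synthetic XY population
#'
#' Bundles every rate and size of the synthetic data generator. Defaults are
#' the study conditions the package's analyses are designed around: ~40x pool
#' sequencing of 35 males and 34 females, one X/Y-differentiated site per kb
#' inside the SDR, Illumina-scale base error, and a RAD panel of 10,000
#' markers with a single perfectly sex-linked one.
#'
#' @param n_males,n_females numbers of individuals per sex.
#' @param pool_depth mean reads per site per pool (Poisson).
#' @param background_snp_rate shared (sex-independent) polymorphic sites per bp.
#' @param xy_divergent_rate X/Y-differentiated sites per bp inside the SDR.
#' @param seq_error_rate per-read substitution error probability.
#' @param rad_marker_count,rad_sex_linked_count RAD panel size and number of
#'   male-limited markers within it.
#' @param rad_dropout_rate per-marker, per-individual probability of dropout
#'   (depth forced to zero).
#' @param geno_error_rate,geno_missing_rate genotyping assay error (Ho/He flip)
#'   and no-call probabilities.
#' @param seed integer seed; identical seed and parameters give byte-identical
#'   output.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(n_males = 35, n_females = 34, pool_depth = 40,
                       background_snp_rate = 1e-3, xy_divergent_rate = 1e-3,
                       seq_error_rate = 1e-3, rad_marker_count = 10000,
                       rad_sex_linked_count = 1, rad_dropout_rate = 0.05,
                       geno_error_rate = 0.02, geno_missing_rate = 0.05,
                       seed = 1L) {
  p <- list(n_males = n_males, n_females = n_females, pool_depth = pool_depth,
            background_snp_rate = background_snp_rate,
            xy_divergent_rate = xy_divergent_rate,
            seq_error_rate = seq_error_rate,
            rad_marker_count = rad_marker_count,
            rad_sex_linked_count = rad_sex_linked_count,
            rad_dropout_rate = rad_dropout_rate,
            geno_error_rate = geno_error_rate,
            geno_missing_rate = geno_missing_rate,
            seed = as.integer(seed))
  rates <- c("background_snp_rate", "xy_divergent_rate", "seq_error_rate",
             "rad_dropout_rate", "geno_error_rate", "geno_missing_rate")
  for (r in rates)
    if (p[[r]] < 0 || p[[r]] > 1) stop(r, " must lie in [0, 1]")
  counts <- c("n_males", "n_females", "rad_marker_count",
              "rad_sex_linked_count")
  for (k in counts)
    if (p[[k]] < 0 || p[[k]] != round(p[[k]])) stop(k, " must be a non-negative count")
  if (p$pool_depth < 0) stop("pool_depth must be >= 0")
  if (p$rad_sex_linked_count > p$rad_marker_count)
    stop("rad_sex_linked_count exceeds rad_marker_count")
  if (is.na(p$seed)) stop("seed must be an integer")
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("sim_params:\n")
  for (k in names(x)) cat(sprintf("  %-22s %s\n", k, format(x[[k]])))
  invisible(x)
}

# Run expr under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
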