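#' Parameters for the pooled-sequencing sex scan
#'
#' @param min_depth minimum A/C/G/T read depth per pool for a site to enter
#'   classification.
#' @param het_delta half-width of the heterozygosity band: a pool is called
#'   heterozygous when its minor-allele frequency lies within
#'   `0.5 +/- het_delta`.
#' @param hom_min_major minimum major-allele frequency for a pool to be called
#'   homozygous.
#' @param window_size sliding window size in bp.
#' @param output_resolution window step in bp (must not exceed `window_size`).
#' @param manhattan_bin non-overlapping bin size (bp) for genome-wide plots.
#' @return an object of class `scan_params`.
#' @export
scan_params <- function(min_depth = 10, het_delta = 0.1, hom_min_major = 0.98,
                        window_size = 5000, output_resolution = 1000,
                        manhattan_bin = 50000) {
  if (min_depth < 1) stop("min_depth must be >= 1")
  if (het_delta <= 0 || het_delta >= 0.5) stop("het_delta must lie in (0, 0.5)")
  if (hom_min_major <= 0.5 || hom_min_major > 1)
    stop("hom_min_major must lie in (0.5, 1]")
  if (window_size < 1 || output_resolution < 1 || manhattan_bin < 1)
    stop("window sizes must be positive")
  if (output_resolution > window_size)
    stop("output_resolution must not exceed window_size")
  structure(list(min_depth = min_depth, het_delta = het_delta,
                 hom_min_major = hom_min_major, window_size = window_size,
                 output_resolution = output_resolution,
                 manhattan_bin = manhattan_bin),
            class = "scan_params")
}

pool_matrix <- function(sites, prefix) {
  as.matrix(sites[, paste0(prefix, "_", BASES), with = FALSE])
}

top2 <- function(m) {
  # per-row largest and second-largest of the four base counts
  mx <- pmax(m[, 1], m[, 2], m[, 3], m[, 4])
  major_idx <- max.col(m, ties.method = "first")
  m2 <- m
  m2[cbind(seq_len(nrow(m)), major_idx)] <- -1L
  second <- pmax(m2[, 1], m2[, 2], m2[, 3], m2[, 4])
  list(major_idx = major_idx, major = mx, second = second,
       depth = rowSums(m))
}

#' Per-pool allele frequencies at each site
#'
#' Computes, for the male and the female pool, the major base, the
#' major-allele frequency and the second-allele (minor) frequency from the
#' A/C/G/T counts only; N and deletion counts never enter the denominator.
#' Pools whose A/C/G/T depth is below `min_depth` are flagged as failing and
#' are excluded from classification by [classify_sites()].
#'
#' @param sites a `pooled_sites` table (see [simulate_pools()], [read_sync()]).
#' @param params a [scan_params()].
#' @return a `data.table` with per-pool columns `*_major_base`, `*_major_freq`,
#'   `*_minor_freq`, `*_depth` and logical `*_pass`.
#' @export
pool_frequencies <- function(sites, params = scan_params()) {
  stopifnot(inherits(params, "scan_params"))
  out <- data.table::data.table(chrom = sites$chrom, pos = sites$pos)
  for (p in c("m", "f")) {
    t2 <- top2(pool_matrix(sites, p))
    freq_major <- ifelse(t2$depth > 0, t2$major / t2$depth, NA_real_)
    freq_minor <- ifelse(t2$depth > 0, t2$second / t2$depth, NA_real_)
    out[, paste0(p, "_major_base") := ifelse(t2$depth > 0,
                                             BASES[t2$major_idx], NA_character_)]
    out[, paste0(p, "_major_freq") := freq_major]
    out[, paste0(p, "_minor_freq") := freq_minor]
    out[, paste0(p, "_depth") := t2$depth]
    out[, paste0(p, "_pass") := t2$depth >= params$min_depth]
  }
  out[]
}

#' Classify sites as male-specific, female-specific or neither
#'
#' A site is a male-specific SNV when the male pool is heterozygous (minor
#' frequency within `0.5 +/- het_delta`) while the female pool is homozygous
#' (major frequency `>= hom_min_major`); female-specific is the mirror image.
#' Sites where either pool fails `min_depth` are excluded (`low_depth`).
#'
#' @inheritParams pool_frequencies
#' @return a `data.table` with `chrom`, `pos`, per-pool depths and a `status`
#'   factor with levels `male_specific`, `female_specific`, `none`,
#'   `low_depth`.
#' @export
classify_sites <- function(sites, params = scan_params()) {
  fq <- pool_frequencies(sites, params)
  het <- function(p) !is.na(fq[[paste0(p, "_minor_freq")]]) &
    abs(fq[[paste0(p, "_minor_freq")]] - 0.5) <= params$het_delta
  hom <- function(p) !is.na(fq[[paste0(p, "_major_freq")]]) &
    fq[[paste0(p, "_major_freq")]] >= params$hom_min_major
  pass <- fq$m_pass & fq$f_pass
  status <- rep("none", nrow(fq))
  status[het("m") & hom("f")] <- "male_specific"
  status[het("f") & hom("m")] <- "female_specific"
  status[!pass] <- "low_depth"
  data.table::data.table(
    chrom = fq$chrom, pos = fq$pos,
    depth_m = fq$m_depth, depth_f = fq$f_depth,
    status = factor(status, levels = c("male_specific", "female_specific",
                                       "none", "low_depth")))
}

check_sorted <- function(sites) {
  if (nrow(sites) < 2L) return(invisible())
  new_chrom <- sites$chrom[-1L] != sites$chrom[-nrow(sites)]
  backwards <- !new_chrom & diff(sites$pos) < 0
  if (any(backwards)) {
    i <- which(backwards)[1L] + 1L
    stop("sites not sorted by position: row ", i, " (", sites$chrom[i], ":",
         sites$pos[i], ")")
  }
  if (anyDuplicated(rle(sites$chrom)$values))
    stop("sites not grouped by chromosome")
  invisible()
}

chrom_length_map <- function(sites, chrom_lengths) {
  chroms <- unique(sites$chrom)
  if (inherits(chrom_lengths, "genome_layout"))
    chrom_lengths <- stats::setNames(chrom_lengths$chromosomes$length,
                                     chrom_lengths$chromosomes$name)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(chroms, function(cc)
      max(sites$pos[sites$chrom == cc]) + 1, numeric(1))
  }
  missing <- setdiff(chroms, names(chrom_lengths))
  if (length(missing))
    stop("no length given for chromosome(s): ", paste(missing, collapse = ", "))
  chrom_lengths
}

#' Sliding-window track of sex-specific SNV density and pool depth
#'
#' Places windows of `window_size` bp every `output_resolution` bp along each
#' chromosome (half-open `[start, start + window_size)`) and reports, per
#' window, the number of male- and female-specific SNVs and the mean total
#' read depth of each pool over all recorded sites in the window (SNVs,
#' background sites and dense depth records alike). Windows without recorded
#' sites report zero counts and `NA` depths.
#'
#' @inheritParams pool_frequencies
#' @param chrom_lengths named vector of chromosome lengths, or a
#'   [genome_layout()]; when `NULL`, lengths are taken from the last recorded
#'   site of each chromosome.
#' @return a `data.table` of class `window_track` with columns `chrom`,
#'   `start`, `n_sites`, `male_specific_snvs`, `female_specific_snvs`,
#'   `depth_m`, `depth_f`; attributes record `window_size` and
#'   `output_resolution`.
#' @export
window_scan <- function(sites, params = scan_params(), chrom_lengths = NULL) {
  stopifnot(inherits(params, "scan_params"))
  check_sorted(sites)
  lens <- chrom_length_map(sites, chrom_lengths)
  cls <- classify_sites(sites, params)
  w <- params$window_size
  step <- params$output_resolution

  tracks <- lapply(names(lens), function(cc) {
    idx <- which(cls$chrom == cc)
    starts <- seq.int(0L, max(0L, lens[[cc]] - 1L), by = step)
    # counts over [start, start + w) via cumulative counts at sorted positions
    count_in <- function(pos) {
      findInterval(starts + w - 1L, pos) - findInterval(starts - 1L, pos)
    }
    sum_in <- function(pos, val) {
      cs <- c(0, cumsum(val))
      cs[findInterval(starts + w - 1L, pos) + 1L] -
        cs[findInterval(starts - 1L, pos) + 1L]
    }
    pos_all <- cls$pos[idx]
    n_sites <- count_in(pos_all)
    dm <- sum_in(pos_all, cls$depth_m[idx])
    df <- sum_in(pos_all, cls$depth_f[idx])
    data.table::data.table(
      chrom = cc, start = starts, n_sites = n_sites,
      male_specific_snvs = count_in(cls$pos[idx][cls$status[idx] == "male_specific"]),
      female_specific_snvs = count_in(cls$pos[idx][cls$status[idx] == "female_specific"]),
      depth_m = ifelse(n_sites > 0, dm / n_sites, NA_real_),
      depth_f = ifelse(n_sites > 0, df / n_sites, NA_real_))
  })
  out <- data.table::rbindlist(tracks)
  data.table::setattr(out, "window_size", w)
  data.table::setattr(out, "output_resolution", step)
  data.table::setattr(out, "class",
                      c("window_track", class(data.table::data.table())))
  out[]
}

#' Non-overlapping genome-wide bins of sex-specific SNV counts
#'
#' Counts classified sex-specific SNVs in consecutive non-overlapping bins of
#' `manhattan_bin` bp, the summary used for genome-wide Manhattan-style plots.
#'
#' @inheritParams window_scan
#' @return a `data.table` with `chrom`, `start`, `male_specific_snvs`,
#'   `female_specific_snvs` covering every bin of every chromosome.
#' @export
manhattan_bins <- function(sites, params = scan_params(), chrom_lengths = NULL) {
  stopifnot(inherits(params, "scan_params"))
  check_sorted(sites)
  lens <- chrom_length_map(sites, chrom_lengths)
  cls <- classify_sites(sites, params)
  b <- params$manhattan_bin
  out <- lapply(names(lens), function(cc) {
    starts <- seq.int(0L, max(0L, lens[[cc]] - 1L), by = b)
    sub <- cls[cls$chrom == cc & cls$status %in%
                 c("male_specific", "female_specific"), ]
    bin <- sub$pos %/% b
    data.table::data.table(
      chrom = cc, start = starts,
      male_specific_snvs = tabulate(bin[sub$status == "male_specific"] + 1L,
                                    nbins = length(starts)),
      female_specific_snvs = tabulate(bin[sub$status == "female_specific"] + 1L,
                                      nbins = length(starts)))
  })
  data.table::rbindlist(out)[]
}

# Merge indices of qualifying windows into runs allowing <= max_gap
# consecutive sub-threshold windows inside a run.
merge_runs <- function(qual_idx, max_gap) {
  if (length(qual_idx) == 0L) return(list())
  brk <- which(diff(qual_idx) > max_gap + 1L)
  first <- qual_idx[c(1L, brk + 1L)]
  last <- qual_idx[c(brk, length(qual_idx))]
  Map(c, first, last)
}

region_track_attrs <- function(track) {
  w <- attr(track, "window_size")
  if (is.null(w)) stop("track lacks a window_size attribute; ",
                       "build it with window_scan()")
  w
}

#' Call candidate sex-determining regions from a window track
#'
#' Finds maximal runs of windows whose sex-specific SNV count reaches
#' `min_count`, allowing up to `max_gap` consecutive sub-threshold windows
#' inside a run. A region spans from the first qualifying window start to the
#' last qualifying window start plus the window size. Runs with fewer than
#' `min_windows` qualifying windows are dropped. Calls are returned ranked by
#' total SNV count (ties broken by leftmost start), so the first row is the
#' top candidate.
#'
#' The defaults reflect how cleanly the classifier separates signal from
#' noise: under the pool heterozygosity/homozygosity thresholds, background
#' polymorphism essentially never produces a sex-specific call, so a single
#' SNV qualifies a window (`min_count = 1`) and false regions are controlled
#' by requiring `min_windows = 10` qualifying windows. `max_gap = 5` — one
#' window-length of steps at the default 5000/1000 geometry — tolerates a
#' sparse stretch the size of one window without splitting a region.
#'
#' @param track a `window_track` from [window_scan()].
#' @param min_count minimum sex-specific SNVs per window to qualify.
#' @param min_windows minimum qualifying windows per region.
#' @param max_gap maximum run of sub-threshold windows tolerated inside a
#'   region.
#' @param sex which SNV class defines the region: `"male"` scans for an XY
#'   male-heterozygous SDR, `"female"` for the ZW mirror image.
#' @return a `data.table` of class `region_calls`: `chrom`, `start`, `end`,
#'   `n_windows`, `peak_density`, `total_snvs`, `kind = "allelic_sdr"`.
#' @export
call_sdr <- function(track, min_count = 1, min_windows = 10, max_gap = 5,
                     sex = c("male", "female")) {
  sex <- match.arg(sex)
  if (min_count < 1) stop("min_count must be >= 1")
  w <- region_track_attrs(track)
  col <- paste0(sex, "_specific_snvs")
  calls <- lapply(unique(track$chrom), function(cc) {
    tr <- track[track$chrom == cc, ]
    cnt <- tr[[col]]
    runs <- merge_runs(which(cnt >= min_count), max_gap)
    rows <- lapply(runs, function(r) {
      span <- seq.int(r[1], r[2])
      nq <- sum(cnt[span] >= min_count)
      if (nq < min_windows) return(NULL)
      data.table::data.table(chrom = cc, start = tr$start[r[1]],
                             end = tr$start[r[2]] + w, n_windows = nq,
                             peak_density = max(cnt[span]),
                             total_snvs = sum(cnt[span]))
    })
    data.table::rbindlist(rows)
  })
  out <- data.table::rbindlist(calls)
  if (nrow(out) == 0L)
    out <- data.table::data.table(chrom = character(), start = numeric(),
                                  end = numeric(), n_windows = integer(),
                                  peak_density = numeric(),
                                  total_snvs = numeric())
  out[, "kind" := rep("allelic_sdr", nrow(out))]
  data.table::setorderv(out, c("total_snvs", "chrom", "start"),
                        order = c(-1L, 1L, 1L))
  data.table::setattr(out, "class",
                      c("region_calls", class(data.table::data.table())))
  out[]
}

#' Detect Y-limited (male-hemizygous) regions from coverage
#'
#' Flags runs of windows where the female pool has lost essentially all
#' coverage while the male pool retains about half of its genome-wide depth —
#' the signature of a sequence present on the Y haplotype only (one copy per
#' male, none per female). Thresholds are relative to the genome-median window
#' depth of each pool.
#'
#' @param track a `window_track` with depth columns.
#' @param f_max_frac female window depth must be at most this fraction of the
#'   genome-median female depth.
#' @param m_range male window depth must fall inside this fraction range of
#'   the genome-median male depth (haploid expectation 0.5).
#' @param min_windows,max_gap run-merging parameters as in [call_sdr()].
#' @return a `data.table` of class `region_calls`: `chrom`, `start`, `end`,
#'   `n_windows`, `mean_depth_m`, `mean_depth_f`, `ratio_m`, `ratio_f`,
#'   `kind = "male_limited_insertion"`, ranked by span length.
#' @export
coverage_regions <- function(track, f_max_frac = 0.1,
                             m_range = c(0.35, 0.65), min_windows = 10,
                             max_gap = 2) {
  region_track_attrs(track)
  w <- attr(track, "window_size")
  ok <- track$n_sites > 0 & !is.na(track$depth_m) & !is.na(track$depth_f)
  med_m <- stats::median(track$depth_m[ok])
  med_f <- stats::median(track$depth_f[ok])
  if (!length(med_m) || is.na(med_m) || med_m == 0 || is.na(med_f) || med_f == 0)
    stop("genome-median depth is zero; coverage ratios are undefined")
  calls <- lapply(unique(track$chrom), function(cc) {
    tr <- track[track$chrom == cc, ]
    qual <- !is.na(tr$depth_m) & !is.na(tr$depth_f) &
      tr$depth_f <= f_max_frac * med_f &
      tr$depth_m >= m_range[1] * med_m & tr$depth_m <= m_range[2] * med_m
    runs <- merge_runs(which(qual), max_gap)
    rows <- lapply(runs, function(r) {
      span <- seq.int(r[1], r[2])
      qspan <- span[qual[span]]
      if (length(qspan) < min_windows) return(NULL)
      data.table::data.table(chrom = cc, start = tr$start[r[1]],
                             end = tr$start[r[2]] + w,
                             n_windows = length(qspan),
                             mean_depth_m = mean(tr$depth_m[qspan]),
                             mean_depth_f = mean(tr$depth_f[qspan]),
                             ratio_m = mean(tr$depth_m[qspan]) / med_m,
                             ratio_f = mean(tr$depth_f[qspan]) / med_f)
    })
    data.table::rbindlist(rows)
  })
  out <- data.table::rbindlist(calls)
  if (nrow(out) == 0L)
    out <- data.table::data.table(chrom = character(), start = numeric(),
                                  end = numeric(), n_windows = integer(),
                                  mean_depth_m = numeric(),
                                  mean_depth_f = numeric(),
                                  ratio_m = numeric(), ratio_f = numeric())
  out[, "kind" := rep("male_limited_insertion", nrow(out))]
  data.table::setorderv(out, c("n_windows", "chrom", "start"),
                        order = c(-1L, 1L, 1L))
  data.table::setattr(out, "class",
                      c("region_calls", class(data.table::data.table())))
  out[]
}

#' Genes overlapping a called region
#'
#' Returns, in genomic order, the names of annotated genes overlapping a
#' region call by at least one bp (half-open interval logic).
#'
#' @param region a one-row region call (or `list(chrom =, start =, end =)`,
#'   0-based half-open).
#' @param genes gene intervals: the `genes` table of a [genome_layout()], a
#'   `GRanges`, or a path to a BED/GFF3 file (see [read_annotation()]).
#' @return character vector of gene names.
#' @export
annotate_region <- function(region, genes) {
  region <- as.list(region)[c("chrom", "start", "end")]
  if (region$end <= region$start) stop("region must have end > start")
  if (is.character(genes) && length(genes) == 1L)
    genes <- read_annotation(genes)
  gr <- if (inherits(genes, "GRanges")) genes else {
    genes <- as.data.frame(genes)
    GenomicRanges::GRanges(genes$chrom,
                           IRanges::IRanges(genes$start + 1, genes$end),
                           name = genes$name)
  }
  if (!region$chrom %in% as.character(unique(GenomicRanges::seqnames(gr))))
    return(character(0))
  q <- GenomicRanges::GRanges(region$chrom,
                              IRanges::IRanges(region$start + 1, region$end))
  hits <- gr[S4Vectors::queryHits(GenomicRanges::findOverlaps(gr, q))]
  hits <- hits[order(GenomicRanges::start(hits))]
  as.character(S4Vectors::mcols(hits)$name)
}
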