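#' Presence/absence of RAD markers at a depth threshold
#'
#' A marker is present in an individual when its read depth is at least `d`.
#'
#' @param rad a `rad_matrix` (see [simulate_rad()], [read_rad_depths()]) or a
#'   numeric depth matrix.
#' @param d minimum read depth (>= 1).
#' @return logical marker-by-individual matrix.
#' @export
rad_presence <- function(rad, d = 1) {
  if (d < 1) stop("d must be >= 1")
  depth <- if (inherits(rad, "rad_matrix")) rad$depth else rad
  depth >= d
}

#' Tile matrix of marker distribution across sexes
#'
#' Counts, for every combination (m, f), the markers present in exactly m
#' males and f females at depth threshold `d` — the tile-plot summary used to
#' screen RAD panels for sex-limited sequence. The cell sums over all (m, f)
#' equal the number of markers.
#'
#' @param rad a `rad_matrix`, or a logical presence matrix (then `sex` is
#'   required).
#' @param d minimum read depth.
#' @param sex named vector of "M"/"F" per individual (taken from `rad` when it
#'   is a `rad_matrix`).
#' @return an integer matrix of class `tile_matrix` with rows m = 0..n_males
#'   and columns f = 0..n_females; attributes `n_males`, `n_females`,
#'   `min_depth`.
#' @export
tile_matrix <- function(rad, d = 1, sex = NULL) {
  if (inherits(rad, "rad_matrix")) {
    sex <- rad$sex
    pres <- rad_presence(rad, d)
  } else {
    if (is.null(sex)) stop("sex labels are required with a plain matrix")
    pres <- if (is.logical(rad)) rad else rad >= d
  }
  if (!all(sex %in% c("M", "F"))) stop("sex labels must be 'M' or 'F'")
  if (ncol(pres) != length(sex)) stop("one sex label per individual required")
  n_m <- sum(sex == "M"); n_f <- sum(sex == "F")
  m_cnt <- as.integer(rowSums(pres[, sex == "M", drop = FALSE]))
  f_cnt <- as.integer(rowSums(pres[, sex == "F", drop = FALSE]))
  tiles <- matrix(0L, n_m + 1L, n_f + 1L, dimnames = list(0:n_m, 0:n_f))
  inc <- tabulate(m_cnt * (n_f + 1L) + f_cnt + 1L,
                  nbins = (n_m + 1L) * (n_f + 1L))
  tiles[] <- matrix(inc, n_m + 1L, n_f + 1L, byrow = TRUE)
  structure(tiles, class = c("tile_matrix", "matrix", "array"),
            n_males = n_m, n_females = n_f, min_depth = d)
}

#' Sex-associated tile cells by Bonferroni-corrected chi-square
#'
#' For every non-empty cell (m, f) — markers present in m of `n_males` males
#' and f of `n_females` females — tests the 2x2 table
#' `[[m, n_males - m], [f, n_females - f]]` with Pearson's chi-square
#' (1 df, no continuity correction, matching the RAD screening convention) and
#' flags cells with `p < alpha / n_cells`, where `n_cells` is the number of
#' non-empty cells tested. The all-absent cell (0, 0) is excluded from testing
#' and from the Bonferroni denominator; cells whose 2x2 table has a zero
#' column margin have an undefined statistic and are never flagged.
#'
#' @param tiles a [tile_matrix()].
#' @param alpha family-wise significance level before Bonferroni division.
#' @return a `data.table` with one row per tested cell: `m`, `f`,
#'   `n_markers`, `chi2`, `p`, `n_tests`, `significant`.
#' @export
significant_cells <- function(tiles, alpha = 0.05) {
  stopifnot(inherits(tiles, "tile_matrix"))
  n_m <- attr(tiles, "n_males"); n_f <- attr(tiles, "n_females")
  if (n_m == 0L || n_f == 0L) stop("both sexes must have individuals")
  idx <- which(tiles > 0L, arr.ind = TRUE)
  m <- idx[, 1L] - 1L; f <- idx[, 2L] - 1L
  keep <- !(m == 0L & f == 0L)
  m <- m[keep]; f <- f[keep]
  n_tests <- length(m)
  res <- chisq22(m, n_m - m, f, n_f - f, correct = FALSE)
  out <- data.table::data.table(
    m = m, f = f, n_markers = tiles[cbind(m + 1L, f + 1L)],
    chi2 = res$chi2, p = res$p, n_tests = n_tests,
    significant = !is.na(res$p) & res$p < alpha / max(n_tests, 1L))
  data.table::setorderv(out, c("m", "f"))
  out[]
}

#' Sex-linked markers from a RAD depth matrix
#'
#' End-to-end RAD screen: presence at depth `d`, tile matrix, per-cell
#' chi-square with Bonferroni correction, and marker-level results inherited
#' from each marker's cell.
#'
#' @inheritParams tile_matrix
#' @param alpha family-wise significance level.
#' @return a list with `tiles` (the [tile_matrix()]), `cells` (the
#'   [significant_cells()] table) and `markers` (a `data.table` of marker id,
#'   males/females present, `p` and `significant`, restricted to markers in
#'   significant cells).
#' @export
rad_sex_markers <- function(rad, d = 1, alpha = 0.05) {
  stopifnot(inherits(rad, "rad_matrix"))
  pres <- rad_presence(rad, d)
  tiles <- tile_matrix(rad, d)
  cells <- significant_cells(tiles, alpha)
  m_cnt <- rowSums(pres[, rad$sex == "M", drop = FALSE])
  f_cnt <- rowSums(pres[, rad$sex == "F", drop = FALSE])
  sig <- cells[cells$significant, ]
  hit <- paste(m_cnt, f_cnt) %in% paste(sig$m, sig$f)
  markers <- data.table::data.table(
    marker = rownames(pres)[hit],
    males_present = as.integer(m_cnt[hit]),
    females_present = as.integer(f_cnt[hit]))
  markers <- merge(markers,
                   cells[, c("m", "f", "p"), with = FALSE],
                   by.x = c("males_present", "females_present"),
                   by.y = c("m", "f"), all.x = TRUE, sort = FALSE)
  data.table::setcolorder(markers, c("marker", "males_present",
                                     "females_present", "p"))
  list(tiles = tiles, cells = cells, markers = markers[order(markers$p), ])
}
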