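#' Write pooled counts as a popoolation2-style sync file
#'
#' Tab-separated: chromosome, position (1-based), reference base, then one
#' "A:C:G:T:N:del" count field per pool (male pool first). Header comment
#' lines (leading `#`) state the coordinate convention and, when available,
#' the simulation seed.
#'
#' @param sites a `pooled_sites` table.
#' @param path output file.
#' @param seed optional seed to record in the header.
#' @return `path`, invisibly.
#' @export
write_sync <- function(sites, path, seed = NULL) {
  m <- do.call(paste, c(lapply(paste0("m_", c(BASES, "N", "del")),
                               function(cc) sites[[cc]]), sep = ":"))
  f <- do.call(paste, c(lapply(paste0("f_", c(BASES, "N", "del")),
                               function(cc) sites[[cc]]), sep = ":"))
  hdr <- c("# sync: chrom\tpos(1-based)\tref\tmale_pool\tfemale_pool",
           "# pool count fields are A:C:G:T:N:del",
           if (!is.null(seed)) paste0("# seed: ", seed))
  writeLines(hdr, path)
  data.table::fwrite(data.table::data.table(sites$chrom, sites$pos + 1L,
                                            sites$ref, m, f),
                     path, sep = "\t", col.names = FALSE, append = TRUE)
  invisible(path)
}

parse_pool_field <- function(x, line_no, what) {
  parts <- data.table::tstrsplit(x, ":", fixed = TRUE)
  if (length(parts) != 6L) {
    bad <- which(lengths(regmatches(x, gregexpr(":", x, fixed = TRUE))) != 5L)
    stop("malformed ", what, " count field at line ",
         line_no[if (length(bad)) bad[1] else 1L],
         " (expected A:C:G:T:N:del)")
  }
  counts <- lapply(parts, function(p) suppressWarnings(as.integer(p)))
  bad <- Reduce(`|`, lapply(counts, function(cc) is.na(cc) | cc < 0))
  if (any(bad))
    stop("non-numeric or negative ", what, " count at line ",
         line_no[which(bad)[1]])
  counts
}

#' Read a sync file of pooled counts
#'
#' Parses the dialect written by [write_sync()] (and popoolation2-compatible
#' files with two pools): 1-based positions are converted to the package's
#' internal 0-based convention; malformed lines are rejected with their line
#' number; positions must be sorted within each chromosome.
#'
#' @param path sync file with male and female pool columns.
#' @return a `pooled_sites` `data.table`.
#' @export
read_sync <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(empty_sites()[, !"site_type"])
  fields <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  if (length(fields) != 5L) {
    nf <- lengths(regmatches(lines, gregexpr("\t", lines, fixed = TRUE))) + 1L
    stop("expected 5 tab-separated columns, got ", length(fields),
         " (first offending line: ", line_no[which(nf != 5L)[1]], ")")
  }
  pos1 <- suppressWarnings(as.integer(fields[[2]]))
  if (anyNA(pos1) || any(pos1 < 1L))
    stop("invalid position at line ", line_no[which(is.na(pos1) | pos1 < 1L)[1]])
  out <- data.table::data.table(chrom = fields[[1]], pos = pos1 - 1L,
                                ref = fields[[3]])
  out[, (paste0("m_", c(BASES, "N", "del"))) :=
        parse_pool_field(fields[[4]], line_no, "male pool")]
  out[, (paste0("f_", c(BASES, "N", "del"))) :=
        parse_pool_field(fields[[5]], line_no, "female pool")]
  same <- out$chrom[-1L] == out$chrom[-nrow(out)]
  if (nrow(out) > 1L && any(same & diff(out$pos) <= 0L)) {
    i <- which(same & diff(out$pos) <= 0L)[1L] + 1L
    stop("positions not strictly increasing at line ", line_no[i])
  }
  data.table::setattr(out, "class",
                      c("pooled_sites", class(data.table::data.table())))
  out[]
}

#' Write / read a RAD depth matrix and its sex map
#'
#' The depth matrix is a TSV with a `marker` column and one column per
#' individual; the sex map is a two-column TSV (`individual`, `sex`).
#'
#' @param rad a `rad_matrix`.
#' @param depth_path,sex_path output/input files.
#' @return `write_rad` returns the paths invisibly; `read_rad_depths` returns
#'   a `rad_matrix`.
#' @export
write_rad <- function(rad, depth_path, sex_path) {
  stopifnot(inherits(rad, "rad_matrix"))
  dt <- data.table::data.table(marker = rownames(rad$depth))
  dt <- cbind(dt, data.table::as.data.table(rad$depth))
  data.table::fwrite(dt, depth_path, sep = "\t")
  data.table::fwrite(data.table::data.table(individual = names(rad$sex),
                                            sex = unname(rad$sex)),
                     sex_path, sep = "\t")
  invisible(c(depth_path, sex_path))
}

#' @rdname write_rad
#' @export
read_rad_depths <- function(depth_path, sex_path) {
  dt <- data.table::fread(depth_path, sep = "\t")
  if (names(dt)[1] != "marker") stop("first column must be 'marker'")
  depth <- as.matrix(dt[, -1L])
  rownames(depth) <- dt$marker
  storage.mode(depth) <- "integer"
  if (any(depth < 0)) stop("negative depths in ", depth_path)
  sm <- data.table::fread(sex_path, sep = "\t")
  sex <- stats::setNames(as.character(sm[[2]]), as.character(sm[[1]]))
  if (!all(colnames(depth) %in% names(sex)))
    stop("individuals missing from sex map: ",
         paste(setdiff(colnames(depth), names(sex)), collapse = ", "))
  sex <- sex[colnames(depth)]
  if (!all(sex %in% c("M", "F"))) stop("sex labels must be 'M' or 'F'")
  structure(list(depth = depth, sex = sex, sex_linked = character()),
            class = "rad_matrix")
}

#' Read / write genotyping-assay count tables
#'
#' TSV with columns `assay_id`, `male_ho`, `male_he`, `male_u`, `female_ho`,
#' `female_he`, `female_u`.
#'
#' @param path assay table file.
#' @param assays a `data.frame` of assay counts.
#' @return `read_assays` returns a `data.table`; `write_assays` returns `path`
#'   invisibly.
#' @export
read_assays <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  need <- c("assay_id", "male_ho", "male_he", "male_u", "female_ho",
            "female_he", "female_u")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("assay table lacks columns: ",
                         paste(miss, collapse = ", "))
  cnt <- as.matrix(dt[, need[-1], with = FALSE])
  if (any(cnt < 0)) stop("negative genotype counts")
  dt[]
}

#' @rdname read_assays
#' @export
write_assays <- function(assays, path) {
  data.table::fwrite(data.table::as.data.table(assays), path, sep = "\t")
  invisible(path)
}

validate_annotation_lines <- function(lines, format) {
  keep <- nzchar(lines) & !startsWith(lines, "#") &
    !startsWith(lines, "track") & !startsWith(lines, "browser")
  for (i in which(keep)) {
    fld <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (format == "bed") {
      if (length(fld) < 4L || length(fld) > 12L)
        stop("malformed BED line ", i, ": expected 4-12 tab-separated fields")
      s <- suppressWarnings(as.numeric(fld[2]))
      e <- suppressWarnings(as.numeric(fld[3]))
      if (is.na(s) || is.na(e) || e < s)
        stop("malformed BED line ", i, ": bad coordinates")
    } else {
      if (length(fld) != 9L)
        stop("malformed GFF3 line ", i, ": expected 9 tab-separated fields")
      s <- suppressWarnings(as.numeric(fld[4]))
      e <- suppressWarnings(as.numeric(fld[5]))
      if (is.na(s) || is.na(e) || e < s)
        stop("malformed GFF3 line ", i, ": bad coordinates")
    }
  }
}

#' Read gene annotation from BED or GFF3
#'
#' Returns gene intervals normalized to the internal 0-based half-open
#' convention. BED input is taken as-is (column 4 is the gene name); GFF3
#' input is restricted to `gene`-type records, named from the `Name`, `ID` or
#' `gene_id` attribute. The format is inferred from the file extension unless
#' given.
#'
#' @param path annotation file.
#' @param format `"bed"` or `"gff3"`; default inferred from extension.
#' @return a `data.frame` with columns `chrom`, `start`, `end`, `strand`,
#'   `name` (0-based half-open).
#' @export
read_annotation <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, bed = "bed", gff = "gff3", gff3 = "gff3",
                     stop("cannot infer annotation format from extension '",
                          ext, "'; pass format="))
  }
  format <- match.arg(format, c("bed", "gff3"))
  validate_annotation_lines(readLines(path), format)
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  if (format == "gff3") {
    md <- S4Vectors::mcols(gr)
    if ("type" %in% names(md)) gr <- gr[as.character(md$type) == "gene"]
    md <- S4Vectors::mcols(gr)
    nm <- rep(NA_character_, length(gr))
    for (k in c("gene_id", "ID", "Name"))
      if (k %in% names(md)) {
        v <- as.character(md[[k]])
        nm[!is.na(v)] <- v[!is.na(v)]
      }
    name <- nm
  } else {
    name <- as.character(S4Vectors::mcols(gr)$name)
  }
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             name = name)[order(as.character(GenomicRanges::seqnames(gr)),
                                GenomicRanges::start(gr)), ]
}

#' Write gene annotation as BED (0-based half-open) or GFF3 (1-based)
#'
#' @param genes gene table (`chrom`, `start`, `end`, `strand`, `name`,
#'   internal 0-based half-open).
#' @param path output file; format from extension (`.bed`, `.gff3`/`.gff`).
#' @return `path`, invisibly.
#' @export
write_annotation <- function(genes, path) {
  ext <- tolower(tools::file_ext(path))
  genes <- as.data.frame(genes)
  if (ext == "bed") {
    data.table::fwrite(data.table::data.table(
      genes$chrom, as.integer(genes$start), as.integer(genes$end),
      genes$name, 0L, genes$strand),
      path, sep = "\t", col.names = FALSE)
  } else if (ext %in% c("gff", "gff3")) {
    lines <- c("##gff-version 3",
               sprintf("%s\tsdrscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                       genes$chrom, as.integer(genes$start) + 1L,
                       as.integer(genes$end), genes$strand, genes$name,
                       genes$name))
    writeLines(lines, path)
  } else stop("unsupported annotation extension: ", ext)
  invisible(path)
}

#' Write a window track / region calls with 1-based inclusive coordinates
#'
#' User-facing TSV reports use 1-based inclusive coordinates (stated in the
#' header); the optional BED export of regions uses the BED standard 0-based
#' half-open convention.
#'
#' @param track a `window_track`.
#' @param calls a `region_calls` table.
#' @param path,tsv_path,bed_path output files.
#' @param seed optional seed recorded in the header.
#' @return the path(s), invisibly.
#' @export
write_track <- function(track, path, seed = NULL) {
  w <- attr(track, "window_size")
  hdr <- c("# window track; coordinates 1-based inclusive",
           paste0("# window_size: ", w, "; output_resolution: ",
                  attr(track, "output_resolution")),
           if (!is.null(seed)) paste0("# seed: ", seed))
  out <- data.table::copy(track)
  out[, "start" := out$start + 1L]
  out[, "end" := out$start + w - 1L]
  data.table::setcolorder(out, c("chrom", "start", "end"))
  writeLines(c(hdr, paste(names(out), collapse = "\t")), path)
  data.table::fwrite(out, path, sep = "\t", append = TRUE, col.names = FALSE)
  invisible(path)
}

#' Read a window track written by [write_track()]
#'
#' @param path track TSV.
#' @return a `window_track` with internal 0-based starts.
#' @export
read_track <- function(path) {
  hdr <- grep("^#", readLines(path, n = 10L), value = TRUE)
  meta <- regmatches(hdr, regexec("window_size: ([0-9]+); output_resolution: ([0-9]+)",
                                  hdr))
  meta <- meta[lengths(meta) == 3][[1]]
  out <- data.table::fread(path, sep = "\t", skip = "chrom")
  out[, "start" := out$start - 1L]
  out[, "end" := NULL]
  data.table::setattr(out, "window_size", as.integer(meta[2]))
  data.table::setattr(out, "output_resolution", as.integer(meta[3]))
  data.table::setattr(out, "class",
                      c("window_track", class(data.table::data.table())))
  out[]
}

#' @rdname write_track
#' @export
write_regions <- function(calls, tsv_path, bed_path = NULL, seed = NULL) {
  out <- data.table::copy(calls)
  out[, "start" := out$start + 1L]
  writeLines(c("# region calls; coordinates 1-based inclusive",
               if (!is.null(seed)) paste0("# seed: ", seed),
               paste(names(out), collapse = "\t")), tsv_path)
  data.table::fwrite(out, tsv_path, sep = "\t", append = TRUE,
                     col.names = FALSE)
  if (!is.null(bed_path)) {
    data.table::fwrite(data.table::data.table(
      calls$chrom, as.integer(calls$start), as.integer(calls$end),
      calls$kind),
      bed_path, sep = "\t", col.names = FALSE)
  }
  invisible(c(tsv_path, bed_path))
}

#' Read / write a flat key-value pipeline configuration
#'
#' Lines of the form `key = value`; `#` starts a comment. Keys use a
#' `section.name` convention mirroring the module the value belongs to
#' (`sim.`, `scan.`, `rad.`, `link.`). Values are auto-typed (numeric,
#' TRUE/FALSE, or character).
#'
#' @param path config file.
#' @param config named list.
#' @return `read_config` returns a named list; `write_config` returns `path`
#'   invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- which(lengths(kv) != 3L)
  if (length(bad)) stop("malformed config line: '", lines[bad[1]], "'")
  keys <- trimws(vapply(kv, `[`, "", 2L))
  vals <- trimws(vapply(kv, `[`, "", 3L))
  typed <- lapply(vals, function(v) {
    if (toupper(v) %in% c("TRUE", "FALSE")) return(as.logical(v))
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else v
  })
  stats::setNames(typed, keys)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, function(v) format(v, scientific = FALSE),
                            "")),
             path)
  invisible(path)
}
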