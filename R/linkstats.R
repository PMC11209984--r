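# Vectorised 2x2 chi-square. Rows (a, b) and (c, d); Yates continuity
# correction subtracts 0.5 from |O - E| in each cell, clamped at zero so
# near-independent tables cannot contribute negatively. Tables with a zero
# row or column margin have no defined test: chi2 and p are NA.
chisq22 <- function(a, b, c, d, correct = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative")
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  ok <- r1 > 0 & r2 > 0 & c1 > 0 & c2 > 0
  chi2 <- rep(NA_real_, length(a))
  ea <- r1 * c1 / n
  adj <- if (correct) 0.5 else 0
  # |O - E| is equal in all four cells of a 2x2 table
  dev <- pmax(abs(a - ea) - adj, 0)
  chi2[ok] <- (dev^2 * (1 / (r1 * c1 / n) + 1 / (r1 * c2 / n) +
                          1 / (r2 * c1 / n) + 1 / (r2 * c2 / n)))[ok]
  p <- ifelse(is.na(chi2), NA_real_,
              stats::pchisq(chi2, df = 1, lower.tail = FALSE))
  list(chi2 = chi2, p = p)
}

#' Yates-corrected chi-square test of a 2x2 table
#'
#' Pearson's chi-square with Yates' continuity correction on the table
#' `[[a, b], [c, d]]`: each cell contributes `(max(|O - E| - 0.5, 0))^2 / E`
#' with expectations from the margins; the p-value is the upper tail of the
#' chi-square distribution with 1 df.
#'
#' @param a,b top-row counts.
#' @param c,d bottom-row counts.
#' @return list with `chi2` and `p`.
#' @examples
#' yates_chi2(10, 0, 0, 9)   # p = 9.667e-05
#' @export
yates_chi2 <- function(a, b, c, d) {
  res <- chisq22(a, b, c, d, correct = TRUE)
  if (is.na(res$chi2))
    stop("chi-square undefined: a row or column margin is zero")
  list(chi2 = res$chi2, p = res$p)
}

#' Format a p-value the way linkage reports print it
#'
#' Values below the double-precision floor 2.22e-16 print as "< 2.2e-16";
#' otherwise four significant digits.
#'
#' @param p numeric p-value(s).
#' @return character vector.
#' @export
format_pvalue <- function(p) {
  ifelse(is.na(p), "NA",
         ifelse(p < 2.22e-16, "< 2.2e-16", format(signif(p, 4))))
}

#' Genotype-call count table for sex-linkage testing
#'
#' One row per assay: numbers of homozygote (Ho), heterozygote (He) and
#' uncalled (U) genotypes among phenotypic males and females. Per-sex totals
#' are Ho + He + U.
#'
#' @param assay_id assay label.
#' @param male_ho,male_he,male_u male genotype counts.
#' @param female_ho,female_he,female_u female genotype counts.
#' @return a one-row `data.table` of class `genotype_counts` with derived
#'   columns `n_males`, `n_females`.
#' @export
genotype_counts <- function(assay_id, male_ho, male_he, male_u,
                            female_ho, female_he, female_u) {
  cnt <- c(male_ho, male_he, male_u, female_ho, female_he, female_u)
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stop("genotype counts must be non-negative integers")
  out <- data.table::data.table(
    assay_id = as.character(assay_id),
    male_ho = as.integer(male_ho), male_he = as.integer(male_he),
    male_u = as.integer(male_u),
    female_ho = as.integer(female_ho), female_he = as.integer(female_he),
    female_u = as.integer(female_u))
  out[, "n_males" := out$male_ho + out$male_he + out$male_u]
  out[, "n_females" := out$female_ho + out$female_he + out$female_u]
  data.table::setattr(out, "class",
                      c("genotype_counts", class(data.table::data.table())))
  out[]
}

new_linkage_result <- function(chi2, p, pct_genotyped, pct_assigned, table_used,
                               note = NULL) {
  structure(list(chi2 = chi2, p = p, p_formatted = format_pvalue(p),
                 pct_genotyped = pct_genotyped, pct_assigned = pct_assigned,
                 table_used = table_used, note = note),
            class = "linkage_result")
}

#' @export
print.linkage_result <- function(x, ...) {
  cat(sprintf("linkage_result: chi2 = %.4g, p = %s\n", x$chi2, x$p_formatted))
  cat(sprintf("  %% genotyped = %.1f, %% assigned = %.1f\n",
              x$pct_genotyped, x$pct_assigned))
  print(x$table_used)
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Sex linkage of a presence/absence marker
#'
#' Yates-corrected chi-square on the 2x2 table of positive/negative
#' individuals by sex, `[[pos_m, n_m - pos_m], [pos_f, n_f - pos_f]]`. For a
#' male-limited marker the correct assignment is a positive male or a negative
#' female.
#'
#' @param pos_m,n_m positive and total males.
#' @param pos_f,n_f positive and total females.
#' @return a `linkage_result`; with a degenerate margin (e.g. no positive
#'   individual at all) the test is undefined and an error is raised.
#' @examples
#' marker_presence_test(10, 10, 0, 9)   # p = 9.667e-05
#' @export
marker_presence_test <- function(pos_m, n_m, pos_f, n_f) {
  if (pos_m > n_m || pos_f > n_f) stop("positives exceed totals")
  tab <- matrix(c(pos_m, n_m - pos_m, pos_f, n_f - pos_f), 2, byrow = TRUE,
                dimnames = list(c("male", "female"),
                                c("positive", "negative")))
  res <- yates_chi2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
  note <- if (n_m + n_f < 10)
    "small sample: continuity-corrected chi-square is conservative" else NULL
  new_linkage_result(res$chi2, res$p,
                     pct_genotyped = 100,
                     pct_assigned = 100 * (pos_m + (n_f - pos_f)) / (n_m + n_f),
                     table_used = tab, note = note)
}

#' Sex linkage of a genotyping assay
#'
#' Tests association between sex and called genotype with a Yates-corrected
#' chi-square on `[[male_he, male_ho], [female_he, female_ho]]`; uncalled
#' genotypes are excluded from the table. Correct assignments are
#' heterozygous males and homozygous females (the XY expectation for a
#' Y-allele assay). `pct_assigned` divides correct assignments by the assayed
#' total (Ho + He + U over both sexes); `pct_genotyped` divides the assayed
#' total by the recruited cohort size.
#'
#' @param counts a [genotype_counts()] row (or a list with the same fields).
#' @param cohort_size recruited individuals the assay was attempted on;
#'   defaults to the assayed total.
#' @return a `linkage_result`.
#' @examples
#' snv2 <- genotype_counts("SNV2", 8, 37, 3, 34, 2, 12)
#' genotype_linkage(snv2, cohort_size = 96)  # p = 3.175e-11, %As = 74.0
#' @export
genotype_linkage <- function(counts, cohort_size = NULL) {
  counts <- as.list(counts)
  need <- c("male_ho", "male_he", "male_u", "female_ho", "female_he",
            "female_u")
  if (!all(need %in% names(counts)))
    stop("counts must provide: ", paste(need, collapse = ", "))
  n_m <- counts$male_ho + counts$male_he + counts$male_u
  n_f <- counts$female_ho + counts$female_he + counts$female_u
  n_assayed <- n_m + n_f
  if (is.null(cohort_size)) cohort_size <- n_assayed
  if (cohort_size < n_assayed) stop("cohort_size below assayed total")
  tab <- matrix(c(counts$male_he, counts$male_ho,
                  counts$female_he, counts$female_ho), 2, byrow = TRUE,
                dimnames = list(c("male", "female"), c("He", "Ho")))
  if (sum(tab) == 0) stop("no called genotypes: test undefined")
  res <- yates_chi2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
  new_linkage_result(res$chi2, res$p,
                     pct_genotyped = 100 * n_assayed / cohort_size,
                     pct_assigned = 100 * (counts$male_he + counts$female_ho) /
                       n_assayed,
                     table_used = tab)
}

#' Linkage statistics for a table of assays
#'
#' Applies [genotype_linkage()] to every row of an assay count table and
#' returns the per-assay report: chi-square, raw and formatted p, percentage
#' of genotyped individuals (%N) and of correctly assigned genotypes (%As),
#' both rounded to one decimal as in printed reports.
#'
#' @param assays a `data.frame`/`data.table` with columns `assay_id`,
#'   `male_ho`, `male_he`, `male_u`, `female_ho`, `female_he`, `female_u`
#'   (see [read_assays()]).
#' @param cohort_size recruited cohort size shared by all assays.
#' @return a `data.table` with one row per assay.
#' @export
linkage_table <- function(assays, cohort_size = NULL) {
  assays <- data.table::as.data.table(assays)
  rows <- lapply(seq_len(nrow(assays)), function(i) {
    r <- genotype_linkage(assays[i, ], cohort_size)
    data.table::data.table(
      assay_id = assays$assay_id[i], chi2 = r$chi2, p = r$p,
      p_formatted = r$p_formatted,
      pct_genotyped = round(r$pct_genotyped, 1),
      pct_assigned = round(r$pct_assigned, 1))
  })
  data.table::rbindlist(rows)[]
}
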