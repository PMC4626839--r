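#' Per-specimen brain compartment study table
#'
#' Container for per-specimen, per-region volume and surface records (the
#' shape of a compartment morphometry table: prosencephalon, mesencephalon,
#' rhombencephalon rows per specimen). Specimen totals, when printed
#' separately in a source table, are themselves rounded, so they are kept
#' alongside the records and checked against the region sums with a
#' <= 1 (mm^3 / mm^2) rounding tolerance.
#'
#' @param records data.frame with columns `specimen`, `sex` ("male"/"female"),
#'   `age_class` ("adult"/"juvenile"), `region`, `volume_mm3`, `surface_mm2`.
#' @param totals optional data.frame with columns `specimen`,
#'   `total_volume_mm3`, `total_surface_mm2` (stated totals); defaults to the
#'   per-specimen region sums.
#' @return object of class `study_table` with elements `records` and `totals`.
#' @export
study_table <- function(records, totals = NULL) {
  req <- c("specimen", "sex", "age_class", "region", "volume_mm3", "surface_mm2")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("records missing columns: ", paste(miss, collapse = ", "))
  if (any(records$volume_mm3 <= 0) || any(records$surface_mm2 <= 0))
    stop("volumes and surfaces must be positive")
  bad_sex <- setdiff(unique(records$sex), c("male", "female"))
  if (length(bad_sex)) stop("unknown sex values: ", paste(bad_sex, collapse = ", "))
  bad_age <- setdiff(unique(records$age_class), c("adult", "juvenile"))
  if (length(bad_age)) stop("unknown age_class values: ", paste(bad_age, collapse = ", "))

  sums <- aggregate(cbind(volume_mm3, surface_mm2) ~ specimen, records, sum)
  names(sums) <- c("specimen", "sum_volume_mm3", "sum_surface_mm2")
  if (is.null(totals)) {
    totals <- data.frame(specimen = sums$specimen,
                         total_volume_mm3 = sums$sum_volume_mm3,
                         total_surface_mm2 = sums$sum_surface_mm2)
  } else {
    m <- merge(totals, sums, by = "specimen")
    dv <- abs(m$total_volume_mm3 - m$sum_volume_mm3)
    ds <- abs(m$total_surface_mm2 - m$sum_surface_mm2)
    if (any(dv > 1 + 1e-9) || any(ds > 1 + 1e-9))
      stop("stated totals deviate from region sums by more than 1 for: ",
           paste(m$specimen[dv > 1 | ds > 1], collapse = ", "))
  }
  structure(list(records = records, totals = totals), class = "study_table")
}

#' @export
print.study_table <- function(x, ...) {
  cat(sprintf("<study_table> %d specimens, %d records\n",
              nrow(x$totals), nrow(x$records)))
  invisible(x)
}

# round half away from zero at `digits` decimals (display convention of the
# source tables; base round() rounds half to even)
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Compartment fractions of total brain volume and surface
#'
#' Per-specimen fraction of each region relative to the specimen's whole
#' brain. The denominator is the sum of the specimen's region values (not a
#' separately rounded "total" column, whose own rounding error would
#' propagate into the fractions). Fractions are returned at full precision
#' with 2-decimal display columns rounded half away from zero.
#'
#' @param table a [study_table()].
#' @return data.frame with columns `specimen`, `sex`, `age_class`, `region`,
#'   `volume_fraction`, `surface_fraction` and their `_2dp` display versions.
#' @export
fractions <- function(table) {
  stopifnot(inherits(table, "study_table"))
  rec <- table$records
  sv <- tapply(rec$volume_mm3, rec$specimen, sum)
  ss <- tapply(rec$surface_mm2, rec$specimen, sum)
  if (any(sv <= 0) || any(ss <= 0)) stop("zero specimen total")
  out <- rec[, c("specimen", "sex", "age_class", "region")]
  out$volume_fraction <- as.numeric(rec$volume_mm3 / sv[rec$specimen])
  out$surface_fraction <- as.numeric(rec$surface_mm2 / ss[rec$specimen])
  out$volume_fraction_2dp <- round_half_away(out$volume_fraction, 2)
  out$surface_fraction_2dp <- round_half_away(out$surface_fraction, 2)
  rownames(out) <- NULL
  out
}

#' Mean and sample SD of a group of measurements
#'
#' @param values numeric vector (n >= 1). The SD uses the n-1 denominator;
#'   with a single value the SD is reported as 0 and flagged.
#' @return object of class `group_summary`: `mean`, `sd`, `n`,
#'   `single_value` flag.
#' @export
group_summary <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 1 || anyNA(values)) stop("need at least one non-NA value")
  n <- length(values)
  structure(list(mean = mean(values),
                 sd = if (n == 1) 0 else sd(values),
                 n = n, single_value = n == 1),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, digits = 1, ...) {
  cat(sprintf("%s +/- %s (n = %d%s)\n",
              format(round_half_away(x$mean, digits)),
              format(round_half_away(x$sd, digits)), x$n,
              if (x$single_value) ", single value" else ""))
  invisible(x)
}

#' Sexual-dimorphism contrast of total brain measures
#'
#' Percent difference of male versus female mean totals,
#' `(mean_male - mean_female) / mean_female * 100`, with a two-sided
#' Welch unequal-variance two-sample p-value.
#'
#' @param table a [study_table()].
#' @param measure `"volume"` or `"surface"`.
#' @param age_class which age class to contrast (default `"adult"`).
#' @return list with `percent_difference`, `p_value`, `mean_male`,
#'   `mean_female`, and the per-sex values.
#' @export
dimorphism_contrast <- function(table, measure = c("volume", "surface"),
                                age_class = "adult") {
  stopifnot(inherits(table, "study_table"))
  measure <- match.arg(measure)
  rec <- unique(table$records[, c("specimen", "sex", "age_class")])
  rec <- merge(rec, table$totals, by = "specimen")
  rec <- rec[rec$age_class == age_class, ]
  col <- if (measure == "volume") "total_volume_mm3" else "total_surface_mm2"
  males <- rec[[col]][rec$sex == "male"]
  females <- rec[[col]][rec$sex == "female"]
  if (!length(males) || !length(females))
    stop("both sexes must be present in age class \"", age_class, "\"")
  pct <- (mean(males) - mean(females)) / mean(females) * 100
  p <- if (isTRUE(all.equal(var(c(males, females)), 0)) ||
           (length(males) == 1 && length(females) == 1)) {
    if (mean(males) == mean(females)) 1 else 0
  } else {
    tryCatch(t.test(males, females)$p.value,
             error = function(e) if (mean(males) == mean(females)) 1 else 0)
  }
  list(percent_difference = pct, p_value = p,
       mean_male = mean(males), mean_female = mean(females),
       males = males, females = females, measure = measure)
}

#' Method-agreement statistic over paired measurements
#'
#' Per pair, the signed percent deviation of the comparison method from the
#' reference, `(comparison - reference) / reference * 100`, summarized as
#' mean +/- sample SD. Used to compare e.g. manual delineation against the
#' Fakir probe, or MR-based against CT-based measures.
#'
#' @param reference,comparison numeric vectors of equal length (reference
#'   values nonzero).
#' @return a [group_summary()] of the signed percent differences, with the
#'   per-pair deviations attached as attribute `"deviations"`.
#' @export
method_agreement <- function(reference, comparison) {
  if (length(reference) != length(comparison) || !length(reference))
    stop("need equal-length nonempty vectors")
  if (any(reference == 0)) stop("zero reference value")
  dev <- (comparison - reference) / reference * 100
  gs <- group_summary(dev)
  attr(gs, "deviations") <- dev
  gs
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return the correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need equal lengths >= 3")
  if (var(x) == 0 || var(y) == 0) stop("zero variance")
  cor(x, y)
}

#' Read / write a study table as CSV
#'
#' The CSV schema is `specimen,sex,age_class,region,volume_mm3,surface_mm2`
#' (UTF-8, comma separator, "." decimal, header required). A malformed row
#' fails with an error naming its line.
#'
#' @param path CSV file path.
#' @param totals_path optional CSV of stated totals
#'   (`specimen,total_volume_mm3,total_surface_mm2`).
#' @return a [study_table()].
#' @export
read_study_table <- function(path, totals_path = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  req <- c("specimen", "sex", "age_class", "region", "volume_mm3", "surface_mm2")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing columns in ", path, ": ",
                         paste(miss, collapse = ", "))
  for (col in c("volume_mm3", "surface_mm2")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("malformed value in column %s at line %d of %s",
                   col, bad[1] + 1L, path))  # +1 for the header line
    df[[col]] <- v
  }
  totals <- NULL
  if (!is.null(totals_path)) {
    totals <- read.csv(totals_path, stringsAsFactors = FALSE)
  }
  study_table(df, totals)
}

#' @rdname read_study_table
#' @param table a [study_table()] to write.
#' @export
write_study_table <- function(table, path, totals_path = NULL) {
  stopifnot(inherits(table, "study_table"))
  write.csv(table$records, path, row.names = FALSE)
  if (!is.null(totals_path)) write.csv(table$totals, totals_path, row.names = FALSE)
  invisible(path)
}

#' Bundled pheasant brain morphometry tables
#'
#' Loads the bundled reference dataset: per-specimen brain compartment
#' volumes and surface areas of ten Ring-necked pheasants (six adults, four
#' juveniles; MR imaging measured with an enhanced Fakir probe), their
#' stated whole-brain totals, the published per-method group summaries
#' (manual MR delineation, MR + Fakir probe, CT + watershed), and the
#' published 2-decimal compartment fractions.
#'
#' @return list with elements `compartments` (a [study_table()]),
#'   `methods` (data.frame of per-method group means and SDs) and
#'   `fractions_2dp` (data.frame of published rounded fractions).
#' @export
pheasant_tables <- function() {
  ext <- function(f) system.file("extdata", f, package = "fakir3d", mustWork = TRUE)
  comp <- read_study_table(ext("pheasant_compartments.csv"),
                           ext("pheasant_totals.csv"))
  methods <- read.csv(ext("pheasant_method_summaries.csv"),
                      stringsAsFactors = FALSE)
  fr <- read.csv(ext("pheasant_fractions_2dp.csv"), stringsAsFactors = FALSE)
  list(compartments = comp, methods = methods, fractions_2dp = fr)
}
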