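#' Per-band isotope datasets (band tables)
#'
#' A *band table* is the package's canonical container: a data frame with one
#' row per vertebral-band measurement, carrying the individual's metadata on
#' every row. It is an ordinary `data.frame` with class `"band_table"` so all
#' base tooling keeps working.
#'
#' Columns (fixed names, comma-separated UTF-8 files with a mandatory header):
#' \describe{
#'   \item{individual_id}{character, unique per shark}
#'   \item{sex}{`"male"` or `"female"`}
#'   \item{total_length_cm}{numeric total length}
#'   \item{age}{integer age in years (annulus count at capture)}
#'   \item{maturity}{`"mature"` or `"immature"`}
#'   \item{band_index}{integer growth-band (annulus) number; band 1 is the
#'     first annulus after the birth ring. An optional band-0 row holds the
#'     birth-ring measurement itself; it is excluded from age-class
#'     statistics but used as the enrichment reference.}
#'   \item{d13C, d15N}{delta values in per-mil vs vPDB / AIR. May be `NA` only
#'     when the raw-ratio columns are supplied.}
#'   \item{cn_ratio}{collagen mass C/N ratio (demineralization QC)}
#'   \item{r13C12C, r15N14N}{optional raw heavy-to-light atomic ratios}
#' }
#'
#' @name band_table
NULL

.band_cols <- c("individual_id", "sex", "total_length_cm", "age", "maturity",
                "band_index", "d13C", "d15N", "cn_ratio", "r13C12C", "r15N14N")
.mandatory_cols <- c("individual_id", "sex", "total_length_cm", "age",
                     "maturity", "band_index")

#' Construct a band table from per-sample vectors
#'
#' @param individual_id,sex,total_length_cm,age,maturity,band_index,d13C,d15N,cn_ratio,r13C12C,r15N14N
#'   column vectors, recycled to a common length; see [band_table].
#' @param validate if `TRUE` (default) reject tables with invariant
#'   violations (see [validate_band_table()]).
#' @return a `band_table` data frame sorted by individual and band.
#' @export
band_table <- function(individual_id, sex, total_length_cm, age, maturity,
                       band_index, d13C = NA_real_, d15N = NA_real_,
                       cn_ratio = NA_real_, r13C12C = NA_real_,
                       r15N14N = NA_real_, validate = TRUE) {
  x <- data.frame(individual_id = as.character(individual_id),
                  sex = as.character(sex),
                  total_length_cm = as.numeric(total_length_cm),
                  age = as.integer(age),
                  maturity = as.character(maturity),
                  band_index = as.integer(band_index),
                  d13C = as.numeric(d13C), d15N = as.numeric(d15N),
                  cn_ratio = as.numeric(cn_ratio),
                  r13C12C = as.numeric(r13C12C),
                  r15N14N = as.numeric(r15N14N),
                  stringsAsFactors = FALSE)
  x <- x[order(x$individual_id, x$band_index), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("band_table", "data.frame")
  if (validate) {
    v <- validate_band_table(x)
    if (nrow(v) > 0L)
      stop("invalid band table: ", nrow(v), " violation(s); first: ",
           v$rule[1L], " (", v$individual_id[1L], ", band ", v$band_index[1L],
           "). Run validate_band_table() for the full report.", call. = FALSE)
  }
  x
}

#' Read a band-table CSV
#'
#' Reads the documented comma-separated dialect, groups rows by individual,
#' sorts bands within individual and enforces all dataset invariants.
#'
#' @param path path to an existing CSV file.
#' @return a validated [band_table].
#' @export
read_band_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(.mandatory_cols, names(raw))
  if (length(missing_cols) > 0L)
    stop("band-table format error: missing mandatory column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  has_delta <- all(c("d13C", "d15N") %in% names(raw))
  has_raw <- all(c("r13C12C", "r15N14N") %in% names(raw))
  if (!has_delta && !has_raw)
    stop("band-table format error: need columns d13C,d15N or r13C12C,r15N14N",
         call. = FALSE)
  num <- function(col) {
    if (!col %in% names(raw)) return(rep(NA_real_, nrow(raw)))
    v <- raw[[col]]
    v[!nzchar(trimws(v))] <- NA
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad) > 0L)
      stop("band-table parse error: non-numeric value ", dQuote(v[bad[1L]]),
           " in column ", col, ", data row ", bad[1L], call. = FALSE)
    out
  }
  band_table(individual_id = raw$individual_id, sex = raw$sex,
             total_length_cm = num("total_length_cm"), age = num("age"),
             maturity = raw$maturity, band_index = num("band_index"),
             d13C = num("d13C"), d15N = num("d15N"),
             cn_ratio = num("cn_ratio"),
             r13C12C = num("r13C12C"), r15N14N = num("r15N14N"))
}

#' Write a band table to CSV
#'
#' Emits the fixed documented column order; the round trip
#' `read_band_table(write_band_table(x, f))` is lossless.
#'
#' @param x a [band_table] (or compatible data frame).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_band_table <- function(x, path) {
  x <- as.data.frame(x)
  for (col in setdiff(.band_cols, names(x))) x[[col]] <- NA
  utils::write.csv(x[, .band_cols, drop = FALSE], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Validate a band table
#'
#' A reporting operation: it never raises on malformed-but-parseable content.
#' Returns one row per violated rule with enough context to locate the
#' offending sample.
#'
#' @param x a data frame with band-table columns.
#' @return a data frame with columns `individual_id`, `band_index`, `rule`,
#'   `detail`; zero rows iff all invariants hold.
#' @export
validate_band_table <- function(x) {
  v <- list()
  bad <- function(id, band, rule, detail = "") {
    v[[length(v) + 1L]] <<- data.frame(individual_id = as.character(id),
                                       band_index = as.integer(band),
                                       rule = rule, detail = detail,
                                       stringsAsFactors = FALSE)
  }
  x <- as.data.frame(x)
  if (nrow(x) == 0L) {
    bad(NA, NA, "empty dataset", "no samples")
    return(do.call(rbind, v))
  }
  for (i in seq_len(nrow(x))) {
    r <- x[i, ]
    if (is.na(r$band_index) || r$band_index < 0)
      bad(r$individual_id, r$band_index, "band_index >= 0",
          "band index missing or negative (band 0 = birth ring)")
    if (!is.na(r$cn_ratio) && r$cn_ratio <= 0)
      bad(r$individual_id, r$band_index, "cn_ratio > 0", "")
    if ((!is.na(r$r13C12C) && r$r13C12C <= 0) ||
        (!is.na(r$r15N14N) && r$r15N14N <= 0))
      bad(r$individual_id, r$band_index, "raw ratios > 0", "")
    if (is.na(r$d13C) && is.na(r$d15N) &&
        (is.na(r$r13C12C) || is.na(r$r15N14N)))
      bad(r$individual_id, r$band_index, "isotope values present",
          "need d13C/d15N or both raw ratios")
    if (!r$sex %in% c("male", "female"))
      bad(r$individual_id, r$band_index, "sex in {male, female}",
          as.character(r$sex))
    if (!r$maturity %in% c("mature", "immature"))
      bad(r$individual_id, r$band_index, "maturity in {mature, immature}",
          as.character(r$maturity))
  }
  for (id in unique(x$individual_id)) {
    g <- x[x$individual_id == id, ]
    bands <- g$band_index[!is.na(g$band_index)]
    if (anyDuplicated(bands))
      bad(id, bands[duplicated(bands)][1L], "band_index unique",
          "duplicate band for individual")
    age <- g$age[1L]
    if (is.na(age) || age < 1) {
      bad(id, NA, "age >= 1", "")
    } else if (length(bands) > 0L && max(bands) > age) {
      bad(id, max(bands), "band exceeds age",
          sprintf("band %d on age-%d individual", max(bands), age))
    }
    if (length(unique(g$age)) > 1L || length(unique(g$sex)) > 1L)
      bad(id, NA, "consistent metadata",
          "age/sex differ across rows of one individual")
  }
  if (length(v) == 0L)
    return(data.frame(individual_id = character(), band_index = integer(),
                      rule = character(), detail = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, v)
  rownames(out) <- NULL
  out
}

#' @export
print.band_table <- function(x, ...) {
  cat(sprintf("band_table: %d samples, %d individuals (%d male, %d female)\n",
              nrow(x), length(unique(x$individual_id)),
              length(unique(x$individual_id[x$sex == "male"])),
              length(unique(x$individual_id[x$sex == "female"]))))
  NextMethod()
}

#' Number of individuals and samples in a band table
#'
#' @param x a [band_table].
#' @return named integer vector with `individuals`, `males`, `females`,
#'   `samples`.
#' @export
band_table_counts <- function(x) {
  c(individuals = length(unique(x$individual_id)),
    males = length(unique(x$individual_id[x$sex == "male"])),
    females = length(unique(x$individual_id[x$sex == "female"])),
    samples = nrow(x))
}
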