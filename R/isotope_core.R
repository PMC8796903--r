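#' Reference standards for delta notation
#'
#' Conventional heavy-to-light atomic ratios of the international reference
#' materials: Vienna Pee Dee Belemnite for carbon (13C/12C = 0.0112372) and
#' atmospheric N2 for nitrogen (15N/14N = 0.0036765). The constants are
#' arguments, not hard-wired, so alternative calibrations can be supplied.
#'
#' @param name `"vPDB_carbon"` or `"AIR_nitrogen"`.
#' @param ratio reference atomic ratio; defaults to the conventional value
#'   for `name`.
#' @return a list with `name` and `ratio`.
#' @export
delta_standard <- function(name = c("vPDB_carbon", "AIR_nitrogen"),
                           ratio = NULL) {
  name <- match.arg(name)
  ratio <- ratio %||% switch(name, vPDB_carbon = 0.0112372,
                             AIR_nitrogen = 0.0036765)
  if (!is.numeric(ratio) || ratio <= 0)
    stop("reference ratio must be positive", call. = FALSE)
  list(name = name, ratio = ratio)
}

#' Delta value from a raw isotope ratio
#'
#' delta = (R_sample / R_standard - 1) x 1000, in per-mil. The map is affine
#' and strictly increasing in the sample ratio, and exactly 0 at the
#' standard.
#'
#' @param r_sample positive heavy-to-light atomic ratio(s) of the sample.
#' @param standard a [delta_standard()].
#' @return delta value(s) in per-mil.
#' @export
delta_from_ratio <- function(r_sample, standard) {
  if (any(!is.finite(r_sample)) || any(r_sample <= 0))
    stop("sample ratio must be positive and finite", call. = FALSE)
  (r_sample / standard$ratio - 1) * 1000
}

#' Fill delta columns from raw ratios
#'
#' Computes `d13C`/`d15N` from `r13C12C`/`r15N14N` wherever the delta value
#' is missing but the raw ratio is present.
#'
#' @param x a [band_table].
#' @param carbon,nitrogen reference standards ([delta_standard()]).
#' @return `x` with delta columns completed.
#' @export
compute_deltas <- function(x, carbon = delta_standard("vPDB_carbon"),
                           nitrogen = delta_standard("AIR_nitrogen")) {
  i <- is.na(x$d13C) & !is.na(x$r13C12C)
  x$d13C[i] <- delta_from_ratio(x$r13C12C[i], carbon)
  j <- is.na(x$d15N) & !is.na(x$r15N14N)
  x$d15N[j] <- delta_from_ratio(x$r15N14N[j], nitrogen)
  x
}

#' Demineralization quality control on collagen C/N
#'
#' Splits a band table on the collagen C/N criterion: a mass C/N ratio at or
#' below the threshold indicates effective demineralization and the sample
#' is retained. Samples without a C/N value cannot be judged and are
#' rejected with reason `"missing"`. Retained and rejected rows partition
#' the input in its original order, so the filter is idempotent.
#'
#' @param x a [band_table].
#' @param threshold inclusive C/N cutoff; default 3.5.
#' @return list with `retained` (a band table) and `rejected` (the rejected
#'   rows plus a `reason` column: `"cn_ratio > threshold"` or `"missing"`).
#' @export
cn_qc_filter <- function(x, threshold = 3.5) {
  stopifnot(is.numeric(threshold), threshold > 0)
  x <- as.data.frame(x)
  keep <- !is.na(x$cn_ratio) & x$cn_ratio <= threshold
  rejected <- x[!keep, , drop = FALSE]
  if (nrow(rejected) > 0L)
    rejected$reason <- ifelse(is.na(rejected$cn_ratio), "missing",
                              sprintf("cn_ratio > %g", threshold))
  else rejected$reason <- character(0)
  retained <- x[keep, , drop = FALSE]
  class(retained) <- c("band_table", "data.frame")
  rownames(retained) <- rownames(rejected) <- NULL
  list(retained = retained, rejected = rejected)
}

#' Band sampling plan for a given age
#'
#' Micro-drill sampling scheme along a vertebral centrum: every annulus
#' through the eighth, then every second band (the outer-edge bands are too
#' densely spaced to drill individually).
#'
#' @param age integer age in years (>= 1).
#' @return strictly increasing integer vector of band indices:
#'   `1..min(age, 8)` followed by `10, 12, ...` up to `age`.
#' @export
band_sampling_plan <- function(age) {
  if (!is.numeric(age) || length(age) != 1L || is.na(age) || age < 1)
    stop("age must be a single integer >= 1", call. = FALSE)
  age <- as.integer(age)
  c(seq_len(min(age, 8L)),
    if (age > 9L) seq(10L, age, by = 2L) else integer(0))
}

.age_class_levels <- c("1", "2", "3", "4", "5", "6", "7", "adult")

#' Assign growth bands to age classes
#'
#' Bands 1-7 form seven yearly classes; band 8 and beyond are pooled as
#' `"adult"` (both sexes mature at about 8.6-8.8 years). Band index is
#' equated with the age-in-years the band records.
#'
#' @param band_index integer vector of band indices (>= 1).
#' @return factor with levels `1`..`7`, `adult`.
#' @export
assign_age_class <- function(band_index) {
  if (any(is.na(band_index)) || any(band_index < 1))
    stop("band_index must be >= 1 (band 0, the birth ring, has no age class)",
         call. = FALSE)
  factor(ifelse(band_index >= 8, "adult", as.character(as.integer(band_index))),
         levels = .age_class_levels)
}

#' Grouped isotope and trophic-position summary table
#'
#' Builds the classic chronology summary: for each sex (male, female,
#' combined) crossed with each age class plus an overall row, the sample
#' count and mean, standard error, minimum and maximum of d13C, d15N and of
#' the per-sample trophic positions. Statistics for TP are computed on
#' per-sample TP values (mean of TPs, not TP of the mean d15N). Band-0
#' birth-ring rows are excluded. Empty groups are omitted with a warning;
#' singleton groups get SE 0 by convention.
#'
#' @param x a QC-filtered [band_table] with complete `d15N`.
#' @param params trophic-position model constants, see [tp_params()].
#' @return data frame with one row per non-empty (sex, age_class) cell.
#' @export
group_summary <- function(x, params = tp_params()) {
  x <- as.data.frame(x)
  x <- x[x$band_index >= 1, , drop = FALSE]
  if (nrow(x) == 0L) stop("no analysable samples (band >= 1)", call. = FALSE)
  x$age_class <- assign_age_class(x$band_index)
  x$tp <- trophic_position(x$d15N, params)
  cells <- expand.grid(sex = c("male", "female", "combined"),
                       age_class = c(.age_class_levels, "overall"),
                       stringsAsFactors = FALSE)
  stat3 <- function(v, prefix) {
    out <- c(mean(v), se_mean(v), min(v), max(v))
    names(out) <- paste0(c("mean_", "se_", "min_", "max_"), prefix)
    out
  }
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sx <- cells$sex[i]; ac <- cells$age_class[i]
    g <- x[(sx == "combined" | x$sex == sx) &
             (ac == "overall" | x$age_class == ac), , drop = FALSE]
    if (nrow(g) == 0L) return(NULL)
    data.frame(sex = sx, age_class = ac, n = nrow(g),
               t(c(stat3(g$d13C, "d13C"), stat3(g$d15N, "d15N"),
                   stat3(g$tp, "TP"))),
               stringsAsFactors = FALSE)
  })
  empty <- vapply(rows, is.null, logical(1))
  if (any(empty))
    warning(sum(empty), " empty (sex, age_class) cell(s) omitted from summary",
            call. = FALSE)
  singletons <- vapply(rows[!empty], function(r) r$n == 1L, logical(1))
  if (any(singletons))
    warning(sum(singletons),
            " singleton group(s): SE reported as 0 by convention",
            call. = FALSE)
  out <- do.call(rbind, rows[!empty])
  rownames(out) <- NULL
  out
}
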