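# Initial-rate cleavage kinetics from densitometric time courses:
# ordinary least-squares slope of fraction-cleaved versus time, normalized
# for enzyme amount, then expressed relative to a reference.

#' Fraction of substrate cleaved in one gel lane
#'
#' `sum(products) / (substrate + sum(products))`, clamped to `[0, 1]`.
#' Invariant to rescaling all intensities in the lane by a constant.
#'
#' @param substrate_band Densitometric intensity of the uncleaved substrate.
#' @param product_bands Intensities of the product bands.
#' @return Proportion cleaved.
#' @export
fraction_cleaved <- function(substrate_band, product_bands) {
  stopifnot(substrate_band >= 0, all(product_bands >= 0))
  total <- substrate_band + sum(product_bands)
  if (total <= 0) stop("total lane intensity must be positive")
  min(1, max(0, sum(product_bands) / total))
}

#' Construct a cleavage time course
#'
#' @param substrate_id,enzyme_id Labels.
#' @param enzyme_amount Enzyme amount (e.g. uM); must be positive.
#' @param times Time points (minutes), strictly increasing, length >= 2.
#' @param fractions Fractions cleaved in `[0, 1]`, same length as `times`.
#' @return A `time_course`.
#' @export
time_course <- function(substrate_id, enzyme_id, enzyme_amount,
                        times, fractions) {
  stopifnot(length(times) >= 2L, length(times) == length(fractions),
            all(diff(times) > 0), all(fractions >= 0), all(fractions <= 1),
            enzyme_amount > 0)
  structure(
    list(substrate_id = substrate_id, enzyme_id = enzyme_id,
         enzyme_amount = enzyme_amount,
         points = data.frame(time_min = times, fraction = fractions)),
    class = "time_course"
  )
}

#' Initial cleavage rate by linear regression
#'
#' Ordinary least squares of fraction cleaved versus time. The fit includes
#' an intercept by default (gels have time-zero backgrounds);
#' `through_origin = TRUE` forces the line through zero. The slope is also
#' normalized for the enzyme amount. Time courses containing fractions
#' above 0.5 trigger a warning that the linear initial-rate assumption may
#' be strained.
#'
#' @param tc A [time_course()].
#' @param through_origin Omit the intercept.
#' @return A `rate_estimate`: `substrate_id`, `enzyme_id`, `slope`
#'   (fraction min^-1), `slope_se`, `normalized_rate`
#'   (= slope / enzyme_amount), `enzyme_amount`.
#' @export
initial_rate <- function(tc, through_origin = FALSE) {
  stopifnot(inherits(tc, "time_course"))
  if (any(tc$points$fraction > 0.5)) {
    warning(sprintf(
      "time course %s/%s has fractions > 0.5; the linear initial-rate assumption may be violated",
      tc$substrate_id, tc$enzyme_id
    ))
  }
  fit <- if (through_origin) {
    stats::lm(fraction ~ 0 + time_min, data = tc$points)
  } else {
    stats::lm(fraction ~ time_min, data = tc$points)
  }
  # exact lines are legitimate inputs; silence summary.lm's perfect-fit note
  co <- suppressWarnings(summary(fit))$coefficients
  slope <- co["time_min", "Estimate"]
  se <- co["time_min", "Std. Error"]
  structure(
    list(substrate_id = tc$substrate_id, enzyme_id = tc$enzyme_id,
         slope = unname(slope), slope_se = unname(se),
         normalized_rate = unname(slope) / tc$enzyme_amount,
         enzyme_amount = tc$enzyme_amount),
    class = "rate_estimate"
  )
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf(
    "<rate_estimate> %s/%s: slope %.4g +/- %.2g min^-1, normalized %.4g min^-1 per unit enzyme\n",
    x$substrate_id, x$enzyme_id, x$slope, x$slope_se, x$normalized_rate
  ))
  invisible(x)
}

.estimates_df <- function(estimates) {
  if (is.data.frame(estimates)) return(estimates)
  if (inherits(estimates, "rate_estimate")) estimates <- list(estimates)
  do.call(rbind, lapply(estimates, function(e) {
    data.frame(substrate_id = e$substrate_id, enzyme_id = e$enzyme_id,
               normalized_rate = e$normalized_rate, stringsAsFactors = FALSE)
  }))
}

#' Rates relative to a reference substrate or enzyme
#'
#' Divides every normalized rate by the reference's; the reference maps to
#' exactly 1. A ratio of 0.38 is reported as a 62% reduction.
#'
#' @param estimates List of `rate_estimate`s, or a data frame with columns
#'   `substrate_id`, `enzyme_id`, `normalized_rate`.
#' @param reference_id Reference id, matched against `by`.
#' @param by `"substrate_id"` or `"enzyme_id"` (default substrate).
#' @return Data frame: ids, `normalized_rate`, `relative_rate`,
#'   `percent_change` (negative = slower than the reference).
#' @export
relative_rates <- function(estimates, reference_id, by = "substrate_id") {
  df <- .estimates_df(estimates)
  by <- match.arg(by, c("substrate_id", "enzyme_id"))
  ref <- df$normalized_rate[df[[by]] == reference_id]
  if (length(ref) == 0L) stop(sprintf("reference '%s' absent", reference_id))
  if (length(ref) > 1L) stop(sprintf("reference '%s' is ambiguous", reference_id))
  if (ref == 0) stop(sprintf("reference '%s' has zero rate", reference_id))
  df$relative_rate <- df$normalized_rate / ref
  df$percent_change <- 100 * (df$relative_rate - 1)
  df
}

#' Per-enzyme substrate-preference profile
#'
#' Within each enzyme, every substrate's normalized rate is divided by that
#' same enzyme's rate on the reference substrate, giving comparable
#' preference profiles across enzyme variants. Missing substrate/enzyme
#' combinations are explicit `NA`s, never silent zeros.
#'
#' @param estimates As in [relative_rates()].
#' @param reference_substrate Substrate id used as each enzyme's reference.
#' @return Numeric matrix, enzymes x substrates, of preference ratios.
#' @export
preference_profile <- function(estimates, reference_substrate) {
  df <- .estimates_df(estimates)
  enzymes <- unique(df$enzyme_id)
  substrates <- unique(df$substrate_id)
  if (!(reference_substrate %in% substrates)) {
    stop(sprintf("reference substrate '%s' absent", reference_substrate))
  }
  m <- matrix(NA_real_, nrow = length(enzymes), ncol = length(substrates),
              dimnames = list(enzymes, substrates))
  for (r in seq_len(nrow(df))) {
    m[df$enzyme_id[r], df$substrate_id[r]] <- df$normalized_rate[r]
  }
  for (e in enzymes) {
    ref <- m[e, reference_substrate]
    if (is.na(ref) || ref == 0) {
      stop(sprintf("enzyme '%s' lacks a usable rate on reference substrate '%s'",
                   e, reference_substrate))
    }
    m[e, ] <- m[e, ] / ref
  }
  m
}

#' Read a time-course TSV into [time_course()] objects
#'
#' Expected columns: `substrate_id`, `enzyme_id`, `enzyme_amount`,
#' `time_min`, `fraction`; one time course per (substrate, enzyme) pair.
#'
#' @param path TSV file (as written by [write_tsv_table()] or
#'   [simulate_timecourse()] saved with it).
#' @return Named list of `time_course` objects.
#' @export
read_timecourse_tsv <- function(path) {
  df <- read_tsv_table(path)
  need <- c("substrate_id", "enzyme_id", "enzyme_amount", "time_min", "fraction")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing column(s) %s", path, paste(missing, collapse = ", ")))
  }
  keys <- unique(df[, c("substrate_id", "enzyme_id")])
  out <- lapply(seq_len(nrow(keys)), function(k) {
    sub <- df[df$substrate_id == keys$substrate_id[k] &
                df$enzyme_id == keys$enzyme_id[k], , drop = FALSE]
    sub <- sub[order(sub$time_min), , drop = FALSE]
    time_course(keys$substrate_id[k], keys$enzyme_id[k],
                sub$enzyme_amount[1L], sub$time_min, sub$fraction)
  })
  names(out) <- paste(keys$substrate_id, keys$enzyme_id, sep = "/")
  out
}
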