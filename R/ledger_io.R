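# Feed/biomass accounting and the comparative arithmetic used to evaluate
# feeding strategies (savings, percent increases, average feed rates).

#' Feed ledger
#'
#' Records initial nutrient charges and every per-interval feed event.
#' Cumulative totals use compensated (Kahan) summation so long schedules do
#' not accumulate floating-point drift.
#'
#' @param initial named numeric, initial medium charges (mg/L) per nutrient.
#' @return a `feed_ledger`.
#' @export
feed_ledger <- function(initial = numeric()) {
  structure(list(initial = initial,
                 feeds = data.frame(nutrient = character(),
                                    time_h = numeric(),
                                    feed_mg_L = numeric())),
            class = "feed_ledger")
}

#' Record a feed event
#'
#' @param ledger a [feed_ledger()].
#' @param nutrient nutrient name.
#' @param time_h feed time (h).
#' @param feed_mg_L mass concentration added (mg/L), non-negative.
#' @return the updated ledger.
#' @export
add_feed <- function(ledger, nutrient, time_h, feed_mg_L) {
  stopifnot(inherits(ledger, "feed_ledger"))
  if (feed_mg_L < 0) stop("feed mass must be non-negative")
  ledger$feeds <- rbind(ledger$feeds,
                        data.frame(nutrient = nutrient, time_h = time_h,
                                   feed_mg_L = feed_mg_L))
  ledger
}

kahan_sum <- function(x) {
  s <- 0; c <- 0
  for (v in x) {
    y <- v - c
    t <- s + y
    c <- (t - s) - y
    s <- t
  }
  s
}

#' Cumulative nutrient total
#'
#' @param ledger a [feed_ledger()].
#' @param nutrient nutrient name.
#' @param include_initial include the initial charge (default `TRUE`).
#' @return total mg/L (initial charge + sum of feeds).
#' @export
cumulative_total <- function(ledger, nutrient, include_initial = TRUE) {
  stopifnot(inherits(ledger, "feed_ledger"))
  init <- if (include_initial) {
    if (nutrient %in% names(ledger$initial)) ledger$initial[[nutrient]] else 0
  } else 0
  init + kahan_sum(ledger$feeds$feed_mg_L[ledger$feeds$nutrient == nutrient])
}

#' @export
print.feed_ledger <- function(x, ...) {
  cat("<feed_ledger>\n")
  for (nm in union(names(x$initial), unique(x$feeds$nutrient))) {
    cat(sprintf("  %s: initial %.4g + %d feeds = %.6g mg/L\n", nm,
                if (nm %in% names(x$initial)) x$initial[[nm]] else 0,
                sum(x$feeds$nutrient == nm), cumulative_total(x, nm)))
  }
  invisible(x)
}

#' Percent nutrient saving of a controlled culture vs a reference
#'
#' `100 * (reference - mmc) / reference`. The unrounded value is returned;
#' [report_percent()] renders the integer-rounded form used in reporting.
#'
#' @param reference_total reference (e.g. bulk-fed) total, mg/L; must be > 0.
#' @param mmc_total controlled-culture total, mg/L.
#' @return unrounded percent saving.
#' @export
savings_percent <- function(reference_total, mmc_total) {
  if (reference_total <= 0) stop("reference_total must be positive")
  100 * (reference_total - mmc_total) / reference_total
}

#' Percent increase of a quantity over a baseline
#'
#' `100 * (new - base) / base`, unrounded.
#'
#' @param base baseline value, > 0.
#' @param new new value.
#' @return unrounded percent increase.
#' @export
percent_increase <- function(base, new) {
  if (base <= 0) stop("base must be positive")
  100 * (new - base) / base
}

#' Render a percentage rounded to the nearest integer
#'
#' @param x unrounded percent value.
#' @return character like `"18%"`.
#' @export
report_percent <- function(x) sprintf("%d%%", as.integer(round(x)))

#' Average feed rate over a time window
#'
#' Cumulative mass fed inside `[t_start, t_end]` divided by the window
#' length (mg/L/h). Initial charges are excluded by default (they are not
#' feed events); pass `include_initial = TRUE` to count them when the window
#' starts at or before 0.
#'
#' @param ledger a [feed_ledger()].
#' @param nutrient nutrient name.
#' @param t_start,t_end window (h), `t_end > t_start`.
#' @param include_initial count the initial charge if `t_start <= 0`.
#' @return mg/L/h.
#' @export
average_feed_rate <- function(ledger, nutrient, t_start, t_end,
                              include_initial = FALSE) {
  stopifnot(inherits(ledger, "feed_ledger"))
  if (t_end <= t_start) stop("empty window: t_end must exceed t_start")
  sel <- ledger$feeds$nutrient == nutrient &
    ledger$feeds$time_h >= t_start & ledger$feeds$time_h <= t_end
  total <- kahan_sum(ledger$feeds$feed_mg_L[sel])
  if (include_initial && t_start <= 0 && nutrient %in% names(ledger$initial)) {
    total <- total + ledger$initial[[nutrient]]
  }
  total / (t_end - t_start)
}

#' Yield record for one culture condition and time point
#'
#' @param condition label (e.g. `"MMC-10%AA"`).
#' @param time_h sampling time.
#' @param biomass_mg_L dry biomass concentration.
#' @param yields_mg_L named numeric of product yields (mg/L).
#' @param contents_pct named numeric of contents (% of dry weight). When a
#'   product appears in both, `content * biomass / 100` must agree with the
#'   yield within 1% (rounding in source tables).
#' @return a `yield_record`.
#' @export
yield_record <- function(condition, time_h, biomass_mg_L,
                         yields_mg_L = numeric(), contents_pct = numeric()) {
  if (any(yields_mg_L < 0) || any(contents_pct < 0) || biomass_mg_L < 0) {
    stop("yields, contents and biomass must be non-negative")
  }
  both <- intersect(names(yields_mg_L), names(contents_pct))
  for (nm in both) {
    implied <- contents_pct[[nm]] * biomass_mg_L / 100
    if (abs(implied - yields_mg_L[[nm]]) >
        0.01 * max(implied, yields_mg_L[[nm]], 1)) {
      stop("content and yield inconsistent for '", nm, "': content implies ",
           format(implied, digits = 4), " mg/L vs yield ",
           yields_mg_L[[nm]])
    }
  }
  structure(list(condition = condition, time_h = time_h,
                 biomass_mg_L = biomass_mg_L, yields_mg_L = yields_mg_L,
                 contents_pct = contents_pct),
            class = "yield_record")
}
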