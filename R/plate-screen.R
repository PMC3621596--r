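# Plate-screen statistics: butanol sensitivity index (BSI), sensitivity
# classification, apparent growth-rate fitting, and the deletion-screen
# triage bookkeeping.

#' Butanol Sensitivity Index
#'
#' BSI is the ratio of the 48-h OD660 of the culture grown without butanol
#' over the culture grown with 1% butanol. A denominator floor keeps
#' non-growing cultures finite and sortable.
#'
#' @param od_control final OD660 without butanol (> 0); vectorized.
#' @param od_butanol final OD660 with 1% butanol; vectorized.
#' @param floor denominator floor in OD units (default 0.01).
#' @return numeric vector of BSI values.
#' @examples
#' compute_bsi(1.0, 0.5) # 2
#' compute_bsi(1.0, 0.0) # 100 (floored denominator)
#' @export
compute_bsi <- function(od_control, od_butanol, floor = 0.01) {
  check_that(is_number(floor) && floor > 0, "floor must be a positive number")
  if (any(!is.finite(od_control)) || any(od_control <= 0)) {
    stop("od_control must be positive: a zero/negative control OD indicates ",
         "a dead or failed control well", call. = FALSE)
  }
  check_that(all(od_butanol >= 0), "od_butanol must be non-negative")
  od_control / pmax(od_butanol, floor)
}

#' Classify a strain's butanol sensitivity from BSI and final OD
#'
#' Applies the screening bands: hypersensitive strains have BSI > 10 and are
#' unable to grow at 1% butanol (final OD < 0.08); sensitive strains have
#' 2 < BSI <= 10 and still grow (final OD > 0.1); reference-like strains sit
#' in a band around BSI 2 (the reference strain's value); tolerant strains
#' have BSI in [1, 2). Records falling in none of these bands — e.g. final
#' OD inside the deliberately unassigned (0.08, 0.1] gap with a large BSI —
#' are `indeterminate` rather than silently binned.
#'
#' Bands overlap around BSI 2: the reference band takes precedence over the
#' sensitive and tolerant bands so that a reference strain whose measured BSI
#' lands marginally above or below 2 is not mis-binned.
#'
#' @param bsi BSI from replicate-mean ODs; vectorized.
#' @param od_butanol final OD660 at 1% butanol; vectorized.
#' @param ref_band_delta half-width of the reference-like band around BSI 2
#'   (default 0.25).
#' @return factor with levels `tolerant`, `reference_like`, `sensitive`,
#'   `hypersensitive`, `indeterminate`.
#' @export
classify_strain <- function(bsi, od_butanol, ref_band_delta = 0.25) {
  check_that(is_number(ref_band_delta) && ref_band_delta >= 0 &&
               ref_band_delta < 1, "ref_band_delta must be in [0, 1)")
  check_that(length(bsi) == length(od_butanol),
             "bsi and od_butanol must have equal length")
  out <- rep("indeterminate", length(bsi))
  ref <- bsi >= 2 - ref_band_delta & bsi <= 2 + ref_band_delta
  out[bsi > 10 & od_butanol < 0.08] <- "hypersensitive"
  out[ref & out == "indeterminate"] <- "reference_like"
  out[bsi > 2 & bsi <= 10 & od_butanol > 0.1 &
        out == "indeterminate"] <- "sensitive"
  out[bsi >= 1 & bsi < 2 & out == "indeterminate"] <- "tolerant"
  factor(out, levels = sensitivity_classes())
}

#' @rdname classify_strain
#' @export
sensitivity_classes <- function() {
  c("tolerant", "reference_like", "sensitive", "hypersensitive",
    "indeterminate")
}

#' Fit the apparent specific growth rate of a curve
#'
#' Slides a window of `window_points` consecutive readings over ln(OD),
#' restricted to readings above a detection OD, and reports the maximal
#' least-squares slope as the apparent specific growth rate, with the R^2 of
#' that window's linear fit. Curves that never clear the detection OD over a
#' full window are flagged as non-growers with mu = 0.
#'
#' @param curve a [growth_curve()] (any data frame with `time_h`, `od660`).
#' @param window_points readings per window (default 8, i.e. 4 h at
#'   half-hourly sampling).
#' @param detection_od minimum OD considered above background (default 0.05).
#' @return list of class `growth_fit`: `mu` (per hour), `window` (hours),
#'   `r2`, `non_grower`.
#' @export
fit_growth_rate <- function(curve, window_points = 8, detection_od = 0.05) {
  check_that(is_number(window_points) && window_points >= 3,
             "window_points must be at least 3")
  t <- curve$time_h
  od <- curve$od660
  ok <- is.finite(od) & od > detection_od
  # candidate window starts: all readings in the window above detection
  n <- length(t)
  best <- list(mu = 0, window = c(NA_real_, NA_real_), r2 = NA_real_,
               non_grower = TRUE)
  if (n >= window_points) {
    for (s in seq_len(n - window_points + 1L)) {
      idx <- s:(s + window_points - 1L)
      if (!all(ok[idx])) next
      x <- t[idx]
      y <- log(od[idx])
      fit <- stats::lm.fit(cbind(1, x), y)
      slope <- fit$coefficients[2L]
      if (is.finite(slope) && (best$non_grower || slope > best$mu)) {
        ss_res <- sum(fit$residuals^2)
        ss_tot <- sum((y - mean(y))^2)
        best <- list(mu = max(0, unname(slope)),
                     window = c(x[1L], x[window_points]),
                     r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
                     non_grower = FALSE)
      }
    }
  }
  structure(best, class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  if (x$non_grower) {
    cat("Growth fit: non-grower (no window above detection OD); mu = 0\n")
  } else {
    cat(sprintf("Growth fit: mu = %.4f h^-1 over [%.1f, %.1f] h (R2 = %.4f)\n",
                x$mu, x$window[1], x$window[2], x$r2))
  }
  invisible(x)
}

#' Summarize a plate screen into per-strain records
#'
#' Aggregates long-format plate data (one row per strain/well/time point) to
#' one record per strain: replicate-mean final ODs at 0% and 1% butanol, BSI
#' computed from those mean ODs (not the mean of per-replicate BSIs), and the
#' sensitivity class. Wells whose control OD never exceeds `failed_control_od`
#' are treated as failed and dropped before averaging.
#'
#' @param plate data frame with columns `strain`, `well`, `concentration`,
#'   `time_h`, `od660` (the long-format plate layout written by
#'   [write_plate_tsv()]).
#' @param final_time the time point (hours) defining "final" OD; default the
#'   maximum shared time.
#' @param floor BSI denominator floor (see [compute_bsi()]).
#' @param ref_band_delta passed to [classify_strain()].
#' @param failed_control_od control wells never exceeding this OD are treated
#'   as failed and discarded (default 0.02).
#' @return data frame with one row per strain: `strain`, `od_control`,
#'   `od_butanol`, `bsi`, `sensitivity_class`, `n_replicates`.
#' @export
summarize_screen <- function(plate, final_time = NULL, floor = 0.01,
                             ref_band_delta = 0.25,
                             failed_control_od = 0.02) {
  need <- c("strain", "well", "concentration", "time_h", "od660")
  check_that(all(need %in% names(plate)),
             paste("plate is missing columns:",
                   paste(setdiff(need, names(plate)), collapse = ", ")))
  if (is.null(final_time)) final_time <- max(plate$time_h)
  fin <- plate[plate$time_h == final_time, , drop = FALSE]
  check_that(nrow(fin) > 0, "no readings at the requested final time")

  ctrl <- fin[fin$concentration == 0, , drop = FALSE]
  but <- fin[fin$concentration > 0, , drop = FALSE]
  # drop failed control wells before averaging
  ctrl <- ctrl[ctrl$od660 > failed_control_od, , drop = FALSE]

  mean_by <- function(d) {
    agg <- stats::aggregate(od660 ~ strain, data = d, FUN = mean)
    n <- stats::aggregate(od660 ~ strain, data = d, FUN = length)
    names(agg)[2] <- "od"
    agg$n <- n$od660
    agg
  }
  mc <- mean_by(ctrl)
  mb <- mean_by(but)
  rec <- merge(mc, mb, by = "strain", suffixes = c("_control", "_butanol"))
  bsi <- compute_bsi(rec$od_control, rec$od_butanol, floor = floor)
  data.frame(
    strain = rec$strain,
    od_control = rec$od_control,
    od_butanol = rec$od_butanol,
    bsi = bsi,
    sensitivity_class = classify_strain(bsi, rec$od_butanol,
                                        ref_band_delta = ref_band_delta),
    n_replicates = pmin(rec$n_control, rec$n_butanol),
    stringsAsFactors = FALSE
  )
}

#' Triage bookkeeping from hypersensitive hits to confirmed genes
#'
#' Reproduces the screening follow-up arithmetic: hypersensitive hits minus
#' dubious open reading frames plus arbitrarily added extra picks gives the
#' deletions re-tested in a second genetic background; subtracting deletions
#' that yielded no transformants gives the viable set; intersecting the
#' independently confirmed sensitive list with the viable set gives the
#' confirmed genes.
#'
#' @param hits character vector of hypersensitive hit genes.
#' @param dubious_orfs genes excluded as dubious ORFs; must be a subset of
#'   `hits`.
#' @param extra_picks genes added for testing; must not overlap `hits`.
#' @param transformation_failures genes whose deletion yielded no
#'   transformants.
#' @param confirmed genes confirmed sensitive in the second background.
#' @return list of class `triage_summary` with the derived sets and counts
#'   `n_hits`, `n_tested`, `n_viable`, `n_confirmed`.
#' @export
triage_screen <- function(hits, dubious_orfs = character(),
                          extra_picks = character(),
                          transformation_failures = character(),
                          confirmed = character()) {
  hits <- unique(as.character(hits))
  dubious_orfs <- unique(as.character(dubious_orfs))
  extra_picks <- unique(as.character(extra_picks))
  transformation_failures <- unique(as.character(transformation_failures))
  confirmed <- unique(as.character(confirmed))

  check_that(all(dubious_orfs %in% hits),
             "dubious_orfs must be a subset of hits")
  if (length(intersect(extra_picks, hits)) > 0) {
    stop("extra_picks must not overlap hits: ",
         paste(intersect(extra_picks, hits), collapse = ", "), call. = FALSE)
  }
  tested <- union(setdiff(hits, dubious_orfs), extra_picks)
  viable <- setdiff(tested, transformation_failures)
  conf <- intersect(confirmed, viable)
  structure(list(
    hits = hits, dubious_orfs = dubious_orfs, extra_picks = extra_picks,
    transformation_failures = transformation_failures,
    tested = tested, viable = viable, confirmed = conf,
    n_hits = length(hits), n_tested = length(tested),
    n_viable = length(viable), n_confirmed = length(conf)
  ), class = "triage_summary")
}

#' @export
print.triage_summary <- function(x, ...) {
  cat("Screen triage summary\n")
  cat(sprintf("  hypersensitive hits : %d\n", x$n_hits))
  cat(sprintf("  - dubious ORFs      : %d\n", length(x$dubious_orfs)))
  cat(sprintf("  + extra picks       : %d\n", length(x$extra_picks)))
  cat(sprintf("  = tested deletions  : %d\n", x$n_tested))
  cat(sprintf("  - no transformants  : %d\n",
              length(x$transformation_failures)))
  cat(sprintf("  = viable deletions  : %d\n", x$n_viable))
  cat(sprintf("  confirmed sensitive : %d\n", x$n_confirmed))
  invisible(x)
}
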