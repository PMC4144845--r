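#' Estimate the maximum specific growth rate from an OD time series
#'
#' Computes the maximum slope of `ln(od - blank)` over any contiguous window
#' of `window_points` readings (sliding-window log-linear fit), converted to
#' per-hour units.  This is the classic plate-reader estimator of the maximum
#' specific growth rate: during the exponential phase `ln(OD)` is linear in
#' time with slope equal to the rate.
#'
#' @param time_min numeric vector of measurement times in minutes since
#'   inoculation; strictly increasing.
#' @param od numeric vector of optical-density readings (OD600), same length
#'   as `time_min`, at least 10 readings.
#' @param blank baseline OD of the well (medium without growth).  If `NULL`
#'   the first reading is used as the blank, which is a biased approximation:
#'   supply the true blank whenever it is known.
#' @param window_points number of consecutive readings per window (>= 3).
#'
#' @return A list with elements
#'   \describe{
#'     \item{rate}{maximum specific growth rate per hour (`NA` on failure);}
#'     \item{ok}{logical quality flag, `FALSE` when the culture never grew
#'       (maximum OD does not exceed twice the blank) or no window of
#'       positive blank-corrected readings exists;}
#'     \item{note}{short explanation when `ok` is `FALSE`.}
#'   }
#'   A failed well is flagged, never an error: plate-scale pipelines must
#'   survive empty or contaminated wells.
#'
#' @examples
#' t <- seq(0, 600, by = 20)
#' od <- 0.02 * exp(0.3 * t / 60)
#' estimate_growth_rate(t, od, blank = 0)$rate  # 0.3
#' @export
estimate_growth_rate <- function(time_min, od, blank = NULL,
                                 window_points = 5) {
  stopifnot(is.numeric(time_min), is.numeric(od),
            length(time_min) == length(od))
  if (length(time_min) < 10)
    stop("need at least 10 OD readings")
  if (any(diff(time_min) <= 0))
    stop("measurement times must be strictly increasing")
  if (any(od < 0))
    stop("OD readings must be non-negative")
  if (window_points < 3)
    stop("window_points must be >= 3")
  if (is.null(blank))
    blank <- od[1L]

  corrected <- od - blank
  if (all(corrected <= 0))
    return(list(rate = NA_real_, ok = FALSE, note = "no reading above blank"))

  th <- time_min / 60
  y <- ifelse(corrected > 0, log(corrected), NA_real_)
  n <- length(y)
  w <- min(window_points, n)
  best <- -Inf
  for (i in seq_len(n - w + 1L)) {
    idx <- i:(i + w - 1L)
    yi <- y[idx]
    if (anyNA(yi)) next
    ti <- th[idx]
    slope <- sum((ti - mean(ti)) * (yi - mean(yi))) / sum((ti - mean(ti))^2)
    if (slope > best) best <- slope
  }
  if (!is.finite(best))
    return(list(rate = NA_real_, ok = FALSE,
                note = "no full window of readings above blank"))

  grew <- blank <= 0 || max(od) > 2 * blank
  list(rate = best, ok = grew,
       note = if (grew) "" else "maximum OD never exceeded 2x blank")
}

#' Estimate growth rates for every well of an OD table
#'
#' Applies [estimate_growth_rate()] to each (plate, well) series of a
#' long-format OD table.
#'
#' @param od_table data frame with columns `plate`, `row`, `col`, `time_min`,
#'   `od`, and optionally `blank` (per-well baseline).
#' @param window_points passed to [estimate_growth_rate()].
#'
#' @return data frame with one row per well: `plate`, `row`, `col`, `rate`,
#'   `ok`.
#' @export
estimate_plate_rates <- function(od_table, window_points = 5) {
  need <- c("plate", "row", "col", "time_min", "od")
  if (!all(need %in% names(od_table)))
    stop("od_table must have columns ", paste(need, collapse = ", "))
  key <- interaction(od_table$plate, od_table$row, od_table$col, drop = TRUE)
  out <- lapply(split(od_table, key), function(d) {
    d <- d[order(d$time_min), , drop = FALSE]
    blank <- if ("blank" %in% names(d)) d$blank[1L] else NULL
    fit <- estimate_growth_rate(d$time_min, d$od, blank = blank,
                                window_points = window_points)
    data.frame(plate = d$plate[1L], row = d$row[1L], col = d$col[1L],
               rate = fit$rate, ok = fit$ok, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Normalize well growth rates by neighboring reference wells
#'
#' Divides each well's growth rate by the median rate of reference wells
#' within a Manhattan-distance neighborhood on the same plate, cancelling
#' smooth within-plate biases (edge effects, temperature and evaporation
#' gradients).  The default radius of 1 uses the four orthogonally adjacent
#' wells, matching an interleaved reference layout.
#'
#' @param rates data frame with columns `plate`, `row`, `col`, `rate`
#'   (0-based row/column indices).
#' @param layout data frame with columns `plate`, `row`, `col`, `strain`,
#'   `role` where `role` is one of `"sample"`, `"reference"`, `"empty"`.
#' @param radius neighborhood radius in Manhattan distance (default 1).
#'
#' @return `rates` with added columns `strain`, `role` and
#'   `normalized_rate`; wells with no reference in range are normalized by
#'   the plate-wide reference median (with a warning).  The neighborhood
#'   definition is recorded in the `"neighborhood"` attribute.
#' @export
normalize_by_neighbors <- function(rates, layout, radius = 1) {
  need <- c("plate", "row", "col")
  stopifnot(all(c(need, "rate") %in% names(rates)),
            all(c(need, "strain", "role") %in% names(layout)))
  d <- merge(rates, layout, by = need, sort = FALSE)
  if (!any(d$role == "reference"))
    stop("no reference wells in layout")
  d$normalized_rate <- NA_real_
  fallback <- 0L
  for (p in unique(d$plate)) {
    on_plate <- d$plate == p
    ref <- d[on_plate & d$role == "reference" & !is.na(d$rate), , drop = FALSE]
    if (nrow(ref) == 0L)
      stop("plate ", p, " has no usable reference wells")
    plate_med <- median(ref$rate)
    for (i in which(on_plate & d$role != "empty")) {
      dist <- abs(ref$row - d$row[i]) + abs(ref$col - d$col[i])
      near <- ref$rate[dist <= radius]
      if (length(near) == 0L) {
        fallback <- fallback + 1L
        near <- plate_med
      }
      d$normalized_rate[i] <- d$rate[i] / median(near)
    }
  }
  if (fallback > 0L)
    warning(fallback, " well(s) had no reference within radius ", radius,
            "; plate-wide reference median used")
  attr(d, "neighborhood") <- list(metric = "manhattan", radius = radius)
  d
}

#' Compute per-line relative fitness from replicate normalized growth rates
#'
#' Relative fitness of a strain at a timepoint is the median of the
#' normalized growth rates of its technical replicates divided by the median
#' normalized rate of the wild-type controls at the same timepoint.  At day
#' 0 the replicates of all isogenic lines of a genotype are pooled, because
#' the lines share their full history up to the start of the evolution
#' experiment.  Strain-timepoints with fewer than `min_replicates` retained
#' replicates are excluded (quality-control rule; a message reports the
#' exclusions).
#'
#' @param records data frame of replicate-level measurements with columns
#'   `strain`, `line`, `day`, `rate` (normalized growth rates).
#' @param wt_records data frame of wild-type control replicate measurements
#'   with columns `day`, `rate`.
#' @param min_replicates minimum retained technical replicates (default 4).
#' @param pool_day0 pool replicates across lines of a strain at day 0
#'   (default `TRUE`).
#'
#' @return data frame with columns `strain`, `line`, `day`, `fitness`,
#'   `n_replicates`, and a list-column `replicate_rates` holding the
#'   normalized replicate rates (each divided by the wild-type median, so
#'   their median equals `fitness`).
#' @export
relative_fitness <- function(records, wt_records, min_replicates = 4,
                             pool_day0 = TRUE) {
  stopifnot(all(c("strain", "line", "day", "rate") %in% names(records)),
            all(c("day", "rate") %in% names(wt_records)))
  if (nrow(wt_records) == 0L)
    stop("empty wild-type record set")
  wt_med <- tapply(wt_records$rate, wt_records$day, median)

  rows <- list()
  dropped <- 0L
  for (s in unique(records$strain)) {
    rs <- records[records$strain == s, , drop = FALSE]
    for (d in unique(rs$day)) {
      rd <- rs[rs$day == d, , drop = FALSE]
      wm <- wt_med[as.character(d)]
      if (is.na(wm))
        stop("no wild-type records at day ", d)
      pooled <- pool_day0 && d == 0
      for (ln in unique(rd$line)) {
        reps <- if (pooled) rd$rate else rd$rate[rd$line == ln]
        reps <- reps[!is.na(reps)]
        if (length(reps) < min_replicates) {
          dropped <- dropped + 1L
          next
        }
        rows[[length(rows) + 1L]] <- data.frame(
          strain = s, line = ln, day = d,
          fitness = median(reps) / wm,
          n_replicates = length(reps), stringsAsFactors = FALSE)
        rows[[length(rows)]]$replicate_rates <- I(list(reps / wm))
      }
    }
  }
  if (dropped > 0L)
    message(dropped, " strain-line-timepoint(s) excluded (<",
            min_replicates, " replicates)")
  if (length(rows) == 0L)
    stop("no strain-timepoint passed the replicate threshold")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify slow-growing genotypes at the start of the experiment
#'
#' A genotype enters the evolution panel only if its initial fitness defect
#' is both substantial and statistically supported: relative fitness at most
#' 0.9 (a minimum 10% fitness drop) and a one-tailed Wilcoxon rank-sum test
#' of its replicate rates against the wild-type replicates, Benjamini-
#' Hochberg corrected across genotypes at the given false-discovery rate.
#'
#' @param day0_records data frame with columns `strain`, `rate`
#'   (replicate-level normalized rates at day 0, lines pooled).
#' @param wt_rates numeric vector of wild-type replicate normalized rates.
#' @param fdr false-discovery rate (default 0.05).
#' @param max_fitness maximum relative fitness retained (default 0.9).
#'
#' @return data frame with columns `strain`, `fitness`, `p`, `q`,
#'   `slow_grower`.
#' @export
classify_slow_growers <- function(day0_records, wt_rates, fdr = 0.05,
                                  max_fitness = 0.9) {
  stopifnot(all(c("strain", "rate") %in% names(day0_records)))
  if (length(wt_rates) == 0L)
    stop("empty wild-type rate set")
  wt_med <- median(wt_rates)
  strains <- unique(day0_records$strain)
  fit <- p <- numeric(length(strains))
  for (i in seq_along(strains)) {
    r <- day0_records$rate[day0_records$strain == strains[i]]
    fit[i] <- median(r) / wt_med
    p[i] <- suppressWarnings(
      wilcox.test(r, wt_rates, alternative = "less")$p.value)
  }
  q <- p.adjust(p, method = "BH")
  data.frame(strain = strains, fitness = fit, p = p, q = q,
             slow_grower = fit <= max_fitness & q <= fdr,
             stringsAsFactors = FALSE)
}

#' Convert A1-style well labels to 0-based (row, col) indices
#'
#' @param well character vector of labels such as `"A1"`, `"P24"`.
#' @return data frame with 0-based integer columns `row`, `col`.
#' @export
parse_well <- function(well) {
  m <- regmatches(well, regexec("^([A-Za-z]+)([0-9]+)$", well))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop("malformed well label(s): ", paste(well[bad], collapse = ", "))
  letters_part <- toupper(vapply(m, `[`, "", 2L))
  row <- vapply(strsplit(letters_part, ""), function(ch)
    sum((match(ch, LETTERS)) * 26^(rev(seq_along(ch)) - 1L)) - 1L, 1)
  col <- as.integer(vapply(m, `[`, "", 3L)) - 1L
  data.frame(row = as.integer(row), col = col)
}

#' Read a long-format OD table
#'
#' Expects tab-separated columns `plate`, `well` (A1-style) or `row`/`col`
#' (0-based), `time_min`, `od`, and optionally `blank`.
#'
#' @param path file path.
#' @return data frame with columns `plate`, `row`, `col`, `time_min`, `od`
#'   (and `blank` if present).
#' @export
read_od_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if ("well" %in% names(d) && !all(c("row", "col") %in% names(d)))
    d <- cbind(d[setdiff(names(d), c("row", "col"))], parse_well(d$well))
  need <- c("plate", "row", "col", "time_min", "od")
  if (!all(need %in% names(d)))
    stop("OD table must provide columns ", paste(need, collapse = ", "))
  d
}

#' Read a plate-layout table
#'
#' Expects tab-separated columns `plate`, `well` (A1-style) or `row`/`col`
#' (0-based), `strain`, `role` (`sample`/`reference`/`empty`).
#'
#' @param path file path.
#' @return data frame with columns `plate`, `row`, `col`, `strain`, `role`.
#' @export
read_layout <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if ("well" %in% names(d) && !all(c("row", "col") %in% names(d)))
    d <- cbind(d[setdiff(names(d), c("row", "col"))], parse_well(d$well))
  need <- c("plate", "row", "col", "strain", "role")
  if (!all(need %in% names(d)))
    stop("layout must provide columns ", paste(need, collapse = ", "))
  if (!all(d$role %in% c("sample", "reference", "empty")))
    stop("role must be sample, reference or empty")
  d
}

#' Write a fitness table to TSV
#'
#' Replicate rates are packed into a comma-separated column so the table
#' stays rectangular; [read_fitness_table()] unpacks them.
#'
#' @param fitness data frame from [relative_fitness()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fitness_table <- function(fitness, path) {
  d <- fitness
  if ("replicate_rates" %in% names(d)) {
    d$replicate_rates <- vapply(
      d$replicate_rates, function(x) paste(sprintf("%.17g", x), collapse = ","), "")
  }
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a fitness table written by [write_fitness_table()]
#'
#' @param path file path.
#' @return data frame with the packed `replicate_rates` column restored to a
#'   list of numeric vectors.
#' @export
read_fitness_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if ("replicate_rates" %in% names(d))
    d$replicate_rates <- I(lapply(strsplit(as.character(d$replicate_rates), ","),
                                  as.numeric))
  d
}
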