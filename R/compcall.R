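#' Relative fitness improvement of an evolving line
#'
#' RFI = evolved fitness / initial fitness - 1: the fractional fitness gain
#' of one line over the course of the evolution experiment.  Negative values
#' indicate decline.
#'
#' @param initial initial (pre-evolution) relative fitness; must be > 0.
#' @param evolved evolved (post-evolution) relative fitness.
#' @return numeric RFI, vectorized over its arguments.
#' @export
rfi <- function(initial, evolved) {
  if (any(initial <= 0))
    stop("initial fitness must be positive")
  evolved / initial - 1
}

#' Relative compensation index
#'
#' The fraction of a knock-out's initial fitness deficit, measured against
#' the evolving wild-type controls, that was recovered by the end of the
#' experiment:
#' `RC = (delta_end - delta_start) / (wt_end - delta_start)`.
#' RC = 1 means the knock-out reached the fitness of the evolving wild-type
#' controls; RC = 0 means no improvement at all.
#'
#' @param delta_start,delta_end median normalized fitness of the knock-out
#'   line before and after evolution.
#' @param wt_end median normalized fitness of the evolving wild-type
#'   controls at the end of the experiment.
#' @return numeric RC, vectorized; `NA` (with a warning) where
#'   `wt_end == delta_start`, for which the index is undefined.
#' @export
relative_compensation <- function(delta_start, delta_end, wt_end) {
  stopifnot(all(delta_start > 0), all(delta_end > 0), all(wt_end > 0))
  denom <- wt_end - delta_start
  undef <- denom == 0
  if (any(undef))
    warning(sum(undef), " line(s) with wt_end == delta_start: RC undefined")
  out <- (delta_end - delta_start) / denom
  out[undef] <- NA_real_
  out
}

#' Fitness-improvement cutoff from the evolving-control null
#'
#' Fits a normal distribution (maximum likelihood: sample mean and ML
#' standard deviation) to the RFIs of the evolving wild-type control lines
#' and returns the improvement value that a control line would exceed with
#' probability `alpha`.  A knock-out line whose improvement exceeds this
#' cutoff improved disproportionally relative to general adaptation to the
#' medium.
#'
#' @param control_rfis numeric vector of control-line RFIs (>= 3 values).
#' @param alpha upper-tail probability (default 0.05).
#' @return the cutoff `mu + z[1-alpha] * sigma`.
#' @export
control_improvement_cutoff <- function(control_rfis, alpha = 0.05) {
  control_rfis <- control_rfis[!is.na(control_rfis)]
  if (length(control_rfis) < 3)
    stop("need at least 3 control RFI values")
  stopifnot(alpha > 0, alpha < 1)
  mu <- mean(control_rfis)
  sigma <- sqrt(mean((control_rfis - mu)^2))  # ML estimate
  if (sigma == 0) {
    warning("control RFIs have zero variance; cutoff set to their mean")
    return(mu)
  }
  mu + qnorm(1 - alpha) * sigma
}

#' Call compensated lines and genotypes
#'
#' A line is called compensated when both criteria hold: (i) its fitness
#' improvement is significant (one-tailed Wilcoxon rank-sum test of end
#' versus start replicate fitness, Benjamini-Hochberg corrected across lines
#' at the given FDR) and (ii) its RFI exceeds the evolving-control cutoff
#' (see [control_improvement_cutoff()]), i.e. the gain is disproportionally
#' larger than general adaptation.  A genotype shows evidence of
#' compensatory evolution when at least one of its lines is compensated.
#'
#' @param lines data frame with columns `genotype`, `line` and list-columns
#'   `start_rates`, `end_rates` holding replicate-level normalized fitness
#'   at the start and end of the experiment.
#' @param cutoff RFI cutoff from [control_improvement_cutoff()].
#' @param fdr false-discovery rate for the improvement test (default 0.05).
#' @param wt_end optional median end fitness of the evolving controls; when
#'   supplied, a relative-compensation (`rc`) column is added.
#'
#' @return list with elements
#'   \describe{
#'     \item{calls}{per-line data frame: `genotype`, `line`, `start`, `end`
#'       (medians), `rfi`, `p`, `q`, `compensated` (and `rc`);}
#'     \item{genotypes}{per-genotype data frame: `genotype`, `n_lines`,
#'       `n_compensated`, `compensated`;}
#'     \item{cutoff}{the cutoff used.}
#'   }
#'   Lines with missing start or end replicates are skipped with a message.
#' @export
call_compensation <- function(lines, cutoff, fdr = 0.05, wt_end = NULL) {
  stopifnot(all(c("genotype", "line", "start_rates", "end_rates") %in%
                  names(lines)))
  keep <- vapply(seq_len(nrow(lines)), function(i) {
    length(lines$start_rates[[i]]) > 0 && length(lines$end_rates[[i]]) > 0 &&
      !anyNA(lines$start_rates[[i]]) && !anyNA(lines$end_rates[[i]])
  }, TRUE)
  if (any(!keep))
    message(sum(!keep), " line(s) skipped: missing start or end measurements")
  lines <- lines[keep, , drop = FALSE]
  if (nrow(lines) == 0L)
    stop("no line with complete start and end measurements")

  start_med <- vapply(lines$start_rates, median, 1)
  end_med <- vapply(lines$end_rates, median, 1)
  line_rfi <- rfi(start_med, end_med)
  p <- vapply(seq_len(nrow(lines)), function(i) {
    suppressWarnings(wilcox.test(lines$end_rates[[i]], lines$start_rates[[i]],
                                 alternative = "greater")$p.value)
  }, 1)
  q <- p.adjust(p, method = "BH")
  calls <- data.frame(genotype = lines$genotype, line = lines$line,
                      start = start_med, end = end_med, rfi = line_rfi,
                      p = p, q = q,
                      compensated = q <= fdr & line_rfi > cutoff,
                      stringsAsFactors = FALSE)
  if (!is.null(wt_end))
    calls$rc <- relative_compensation(start_med, end_med, wt_end)

  n_comp <- tapply(calls$compensated, calls$genotype, sum)
  genotypes <- data.frame(genotype = names(n_comp),
                          n_lines = as.integer(table(calls$genotype)[names(n_comp)]),
                          n_compensated = as.integer(n_comp),
                          compensated = as.integer(n_comp) > 0L,
                          stringsAsFactors = FALSE)
  rownames(genotypes) <- NULL
  list(calls = calls, genotypes = genotypes, cutoff = cutoff)
}

#' End-to-end compensation analysis from fitness tables
#'
#' Convenience wrapper: derives control RFIs and the improvement cutoff from
#' the evolving-control fitness table, assembles per-line start/end
#' replicate sets from a fitness table (as produced by [relative_fitness()])
#' and runs [call_compensation()].
#'
#' @param fitness fitness table for the deletion lines: columns `strain`,
#'   `line`, `day`, `fitness`, list-column `replicate_rates`.
#' @param control_fitness same-format table for the evolving wild-type
#'   control lines.
#' @param start_day,end_day days defining the start and end of the
#'   experiment (defaults: minimum and maximum day present).
#' @param fdr FDR for the improvement test (default 0.05).
#' @param alpha upper-tail probability for the control cutoff (default
#'   0.05).
#' @return as [call_compensation()], with added elements `control_rfis` and
#'   `wt_end`.
#' @export
compensation_analysis <- function(fitness, control_fitness,
                                  start_day = NULL, end_day = NULL,
                                  fdr = 0.05, alpha = 0.05) {
  days <- sort(unique(c(fitness$day, control_fitness$day)))
  if (is.null(start_day)) start_day <- days[1L]
  if (is.null(end_day)) end_day <- days[length(days)]

  ctl_start <- control_fitness[control_fitness$day == start_day, ]
  ctl_end <- control_fitness[control_fitness$day == end_day, ]
  key <- function(d) paste(d$strain, d$line, sep = "\r")
  shared <- intersect(key(ctl_start), key(ctl_end))
  if (length(shared) < 3)
    stop("need at least 3 control lines measured at both endpoints")
  control_rfis <- rfi(ctl_start$fitness[match(shared, key(ctl_start))],
                      ctl_end$fitness[match(shared, key(ctl_end))])
  cutoff <- control_improvement_cutoff(control_rfis, alpha = alpha)
  wt_end <- median(ctl_end$fitness)

  f_start <- fitness[fitness$day == start_day, ]
  f_end <- fitness[fitness$day == end_day, ]
  shared <- intersect(key(f_start), key(f_end))
  i0 <- match(shared, key(f_start)); i1 <- match(shared, key(f_end))
  lines <- data.frame(genotype = f_start$strain[i0], line = f_start$line[i0],
                      stringsAsFactors = FALSE)
  lines$start_rates <- I(f_start$replicate_rates[i0])
  lines$end_rates <- I(f_end$replicate_rates[i1])

  out <- call_compensation(lines, cutoff, fdr = fdr, wt_end = wt_end)
  out$control_rfis <- control_rfis
  out$wt_end <- wt_end
  out
}

#' Test for a trend in compensation across initial-fitness bins
#'
#' Cochran-Armitage chi-squared test for trend in the proportion of
#' compensated lines across ordered initial-fitness bins (equally spaced
#' scores).  Empty bins are merged with their lower neighbor, with a
#' warning.
#'
#' @param initial_fitness numeric vector, one value per line.
#' @param compensated logical vector, one flag per line.
#' @param bin_edges ordered break points defining the bins (passed to
#'   [cut()] with `include.lowest = TRUE`).
#' @return list with `statistic`, `df`, `p`, and a `bins` data frame
#'   (`bin`, `n`, `n_compensated`, `proportion`).
#' @export
trend_test <- function(initial_fitness, compensated, bin_edges) {
  stopifnot(length(initial_fitness) == length(compensated),
            length(bin_edges) >= 3)
  bin <- cut(initial_fitness, breaks = bin_edges, include.lowest = TRUE)
  if (anyNA(bin))
    stop("initial fitness values outside the bin range")
  n <- tabulate(bin, nbins = nlevels(bin))
  x <- vapply(seq_len(nlevels(bin)),
              function(b) sum(compensated[as.integer(bin) == b]), 1L)
  if (any(n == 0L)) {
    warning("empty bin(s) merged with lower neighbor")
    keep <- n > 0L
    grp <- cumsum(keep)[keep]  # collapse indices
    n2 <- tapply(n[keep], grp, sum); x2 <- tapply(x[keep], grp, sum)
    n <- as.integer(n2); x <- as.integer(x2)
    labs <- levels(bin)[keep]
  } else labs <- levels(bin)
  if (length(n) < 2)
    stop("need at least 2 non-empty bins")
  tt <- suppressWarnings(prop.trend.test(x, n))
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value,
       bins = data.frame(bin = labs, n = n, n_compensated = x,
                         proportion = x / n, stringsAsFactors = FALSE))
}

#' One-way ANOVA of fitness gains across genotypes
#'
#' Tests whether the per-line fitness gain differs across deletion
#' genotypes (genotype as a fixed factor).
#'
#' @param gains data frame with columns `genotype` and `gain` (one row per
#'   line).
#' @return list with `F`, `df` (numerator, denominator) and `p`.
#' @export
genotype_effect_anova <- function(gains) {
  stopifnot(all(c("genotype", "gain") %in% names(gains)))
  tab <- table(gains$genotype)
  if (length(tab) < 2)
    stop("need at least 2 genotypes")
  if (all(tab < 2))
    stop("all genotypes have a single line; no within-group variance")
  # detect degenerate decompositions exactly before delegating to aov,
  # whose QR fit leaves ~1e-30 residues in the sums of squares
  gm <- tapply(gains$gain, gains$genotype, mean)
  ss_w <- sum((gains$gain - gm[as.character(gains$genotype)])^2)
  ss_b <- sum((gm[as.character(gains$genotype)] - mean(gains$gain))^2)
  df <- c(length(tab) - 1L, nrow(gains) - length(tab))
  if (ss_b == 0)
    return(list(F = 0, df = df, p = 1))
  if (ss_w == 0)
    return(list(F = Inf, df = df, p = 0))
  a <- anova(aov(gain ~ factor(genotype), data = gains))
  list(F = a[1, "F value"], df = c(a[1, "Df"], a[2, "Df"]),
       p = a[1, "Pr(>F)"])
}

.genotype_categories <- function(flags, genotype) {
  per <- tapply(flags, genotype, function(x) mean(x))
  cat <- ifelse(per == 0, "none", ifelse(per == 1, "all", "mixed"))
  c(none = sum(cat == "none"), mixed = sum(cat == "mixed"),
    all = sum(cat == "all"))
}

#' Genotype specificity of compensation by randomization
#'
#' Classifies each genotype as `none`, `mixed` or `all` according to how
#' many of its replicate lines were called compensated, then compares the
#' observed category counts with the distribution obtained by shuffling the
#' compensated flags across all lines (preserving the total number of
#' compensated lines) `n_shuffles` times.  Strong enrichment of `none` and
#' `all` at the expense of `mixed` indicates that the propensity for
#' compensation is a property of the genotype.  A chi-squared goodness-of-
#' fit statistic compares observed counts with the mean null counts.
#' Restrict `calls` to an initial-fitness stratum before calling to test
#' within similar fitness defects.
#'
#' @param calls data frame with columns `genotype`, `line`, `compensated`;
#'   every genotype must have at least 2 lines, and at least 2 genotypes
#'   are required.
#' @param n_shuffles number of random shuffles (default 1000; a warning is
#'   issued below 100).
#' @param seed RNG seed for reproducibility.
#' @return list with `observed` (named counts), `null_mean`, `null_counts`
#'   (`n_shuffles` x 3 matrix), `statistic`, `df`, `p`.
#' @export
genotype_specificity_randomization <- function(calls, n_shuffles = 1000,
                                               seed = NULL) {
  stopifnot(all(c("genotype", "compensated") %in% names(calls)))
  tab <- table(calls$genotype)
  if (length(tab) < 2)
    stop("need at least 2 genotypes")
  if (any(tab < 2))
    stop("every genotype needs at least 2 lines")
  if (n_shuffles < 100)
    warning("fewer than 100 shuffles gives a coarse null")
  if (!is.null(seed)) set.seed(seed)

  flags <- as.logical(calls$compensated)
  genotype <- as.character(calls$genotype)
  observed <- .genotype_categories(flags, genotype)
  null_counts <- t(vapply(seq_len(n_shuffles), function(i)
    .genotype_categories(sample(flags), genotype), observed))
  null_mean <- colMeans(null_counts)

  use <- null_mean > 0
  statistic <- sum((observed[use] - null_mean[use])^2 / null_mean[use])
  df <- max(sum(use) - 1L, 1L)
  p <- pchisq(statistic, df = df, lower.tail = FALSE)
  list(observed = observed, null_mean = null_mean,
       null_counts = null_counts, statistic = statistic, df = df, p = p)
}

#' Depletion test for late fitness improvements
#'
#' Among lines that showed exactly one significant fitness improvement over
#' the consecutive time intervals of the experiment, tests whether the
#' final interval is depleted relative to a uniform assignment of the
#' improvement across intervals (expected `n / n_intervals`).  One-degree-
#' of-freedom chi-squared test of (final, non-final) counts.
#'
#' @param final_count number of single-improvement lines whose improvement
#'   fell in the final interval.
#' @param n total number of single-improvement lines.
#' @param n_intervals number of intervals (default 4).
#' @return list with `observed`, `expected`, `statistic`, `p`.
#' @export
saturation_depletion_test <- function(final_count, n, n_intervals = 4) {
  stopifnot(final_count >= 0, n >= final_count, n_intervals >= 2)
  expected <- n / n_intervals
  obs <- c(final_count, n - final_count)
  exp <- c(expected, n - expected)
  statistic <- sum((obs - exp)^2 / exp)
  list(observed = final_count, expected = expected, statistic = statistic,
       p = pchisq(statistic, df = 1, lower.tail = FALSE))
}

#' Per-interval improvement calls and saturation of fitness trajectories
#'
#' For each line and each consecutive pair of measured timepoints, tests
#' for a fitness improvement (one-sided Wilcoxon rank-sum on replicate
#' fitness, Benjamini-Hochberg corrected across all line-interval tests).
#' Among lines with exactly one significant interval, applies
#' [saturation_depletion_test()] to the final interval: saturating
#' compensatory evolution leaves the last interval depleted.
#'
#' @param fitness fitness table with columns `strain`, `line`, `day` and
#'   list-column `replicate_rates` (as from [relative_fitness()]); each
#'   line should be measured at every timepoint, intervals are derived from
#'   the days actually present per line.
#' @param fdr FDR for the per-interval improvement tests (default 0.05).
#' @return list with `intervals` (per line-interval data frame: `strain`,
#'   `line`, `from_day`, `to_day`, `p`, `q`, `improved`), `single` (per-line
#'   data frame of single-improvement lines with `final_interval` flag), and
#'   `depletion` (result of [saturation_depletion_test()], or `NULL` when no
#'   line qualifies).
#' @export
trajectory_saturation <- function(fitness, fdr = 0.05) {
  stopifnot(all(c("strain", "line", "day", "replicate_rates") %in%
                  names(fitness)))
  all_days <- sort(unique(fitness$day))
  n_int_full <- length(all_days) - 1L
  if (n_int_full < 2)
    stop("need at least 3 timepoints")

  key <- interaction(fitness$strain, fitness$line, drop = TRUE)
  rows <- list()
  for (d in split(fitness, key)) {
    d <- d[order(d$day), , drop = FALSE]
    if (nrow(d) < 2) next
    if (nrow(d) < length(all_days))
      message("line ", d$strain[1], "/", d$line[1],
              ": intervals derived from ", nrow(d), " available days")
    for (i in seq_len(nrow(d) - 1L)) {
      p <- suppressWarnings(
        wilcox.test(d$replicate_rates[[i + 1L]], d$replicate_rates[[i]],
                    alternative = "greater")$p.value)
      rows[[length(rows) + 1L]] <- data.frame(
        strain = d$strain[1L], line = d$line[1L],
        from_day = d$day[i], to_day = d$day[i + 1L], p = p,
        stringsAsFactors = FALSE)
    }
  }
  intervals <- do.call(rbind, rows)
  intervals$q <- p.adjust(intervals$p, method = "BH")
  intervals$improved <- intervals$q <= fdr

  lk <- paste(intervals$strain, intervals$line, sep = "\r")
  n_sig <- tapply(intervals$improved, lk, sum)
  singles <- names(n_sig)[n_sig == 1L]
  final_day <- all_days[length(all_days)]
  single <- NULL
  depletion <- NULL
  if (length(singles) > 0) {
    hit <- intervals[intervals$improved & lk %in% singles, , drop = FALSE]
    single <- data.frame(strain = hit$strain, line = hit$line,
                         interval_to = hit$to_day,
                         final_interval = hit$to_day == final_day,
                         stringsAsFactors = FALSE)
    depletion <- saturation_depletion_test(sum(single$final_interval),
                                           nrow(single),
                                           n_intervals = n_int_full)
  }
  list(intervals = intervals, single = single, depletion = depletion)
}
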