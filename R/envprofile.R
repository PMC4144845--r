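#' Normalize colony sizes for within-plate spatial bias
#'
#' Estimates a smooth positional bias surface per plate from reference
#' colonies by additive row/column median polish on log sizes, divides
#' every colony by the fitted bias, and rescales so the median normalized
#' reference colony equals 1.  Plates without reference colonies are left
#' spatially uncorrected (scaled by the batch-wide reference median, with
#' a warning); plates whose colonies are all zero (failed pinning) are
#' flagged and excluded.
#'
#' @param records data frame with columns `plate`, `row`, `col`, `strain`,
#'   `size` (and any others, carried through).
#' @param reference_strain strain id of the reference colonies.
#' @return `records` with added columns `normalized_size` and `excluded`.
#' @export
normalize_colony_sizes <- function(records, reference_strain = "reference") {
  need <- c("plate", "row", "col", "strain", "size")
  stopifnot(all(need %in% names(records)))
  if (any(records$size < 0))
    stop("colony sizes must be non-negative")
  records$normalized_size <- NA_real_
  records$excluded <- FALSE
  all_ref <- records$strain == reference_strain & records$size > 0
  if (!any(all_ref))
    stop("no reference colonies found for strain ", reference_strain)
  batch_med <- median(records$size[all_ref])

  uncorrected <- character()
  for (p in unique(records$plate)) {
    on <- records$plate == p
    if (all(records$size[on] == 0)) {
      records$excluded[on] <- TRUE
      next
    }
    ref <- records[on & all_ref, , drop = FALSE]
    if (nrow(ref) == 0) {
      uncorrected <- c(uncorrected, as.character(p))
      records$normalized_size[on] <- records$size[on] / batch_med
      next
    }
    nr <- max(records$row[on]) + 1L
    nc <- max(records$col[on]) + 1L
    m <- matrix(NA_real_, nr, nc)
    m[cbind(ref$row + 1L, ref$col + 1L)] <- log(ref$size)
    mp <- medpolish(m, na.rm = TRUE, trace.iter = FALSE, maxiter = 20)
    roweff <- mp$row; roweff[is.na(roweff)] <- 0
    coleff <- mp$col; coleff[is.na(coleff)] <- 0
    bias <- exp(mp$overall + roweff[records$row[on] + 1L] +
                  coleff[records$col[on] + 1L])
    norm <- records$size[on] / bias
    # rescale so the median normalized reference colony is exactly 1
    ref_norm <- norm[records$strain[on] == reference_strain &
                       records$size[on] > 0]
    records$normalized_size[on] <- norm / median(ref_norm)
  }
  if (length(uncorrected) > 0)
    warning("no reference colonies on plate(s) ",
            paste(uncorrected, collapse = ", "),
            "; spatial correction skipped")
  records
}

#' Per-environment fitness calls of evolved lines against their ancestors
#'
#' For each line and environment, compares evolved (end-day) and ancestral
#' (day-0) replicate colony sizes by a two-sided Wilcoxon rank-sum test,
#' Benjamini-Hochberg corrected within each environment; significant
#' differences are called `improved` or `declined` by the direction of the
#' median change, everything else `equal`.  Pairs with fewer than
#' `min_replicates` colonies on either day get no call.
#'
#' @param records data frame with columns `line`, `environment`, `day` and
#'   `normalized_size` (use [normalize_colony_sizes()] first).
#' @param start_day,end_day days compared (defaults: minimum and maximum
#'   day present).
#' @param fdr false-discovery rate per environment (default 0.05).
#' @param min_replicates minimum replicate colonies per day (default 3).
#' @return list with `calls` (data frame `line`, `environment`,
#'   `median_start`, `median_end`, `p`, `q`, `call`) and `fractions`
#'   (named vector: fraction of called pairs improved / equal / declined).
#' @export
environment_fitness_calls <- function(records, start_day = NULL,
                                      end_day = NULL, fdr = 0.05,
                                      min_replicates = 3) {
  need <- c("line", "environment", "day", "normalized_size")
  stopifnot(all(need %in% names(records)))
  records <- records[!is.na(records$day) & !is.na(records$normalized_size), ]
  days <- sort(unique(records$day))
  if (is.null(start_day)) start_day <- days[1]
  if (is.null(end_day)) end_day <- days[length(days)]

  rows <- list()
  skipped <- 0L
  for (env in unique(records$environment)) {
    re <- records[records$environment == env, ]
    for (ln in unique(re$line)) {
      s <- re$normalized_size[re$line == ln & re$day == start_day]
      e <- re$normalized_size[re$line == ln & re$day == end_day]
      if (length(s) < min_replicates || length(e) < min_replicates) {
        skipped <- skipped + 1L
        next
      }
      p <- suppressWarnings(wilcox.test(e, s)$p.value)
      rows[[length(rows) + 1L]] <- data.frame(
        line = ln, environment = env, median_start = median(s),
        median_end = median(e), p = p, stringsAsFactors = FALSE)
    }
  }
  if (skipped > 0L)
    message(skipped, " line-environment pair(s) skipped (<",
            min_replicates, " replicates)")
  if (length(rows) == 0L)
    stop("no line-environment pair with enough replicates")
  calls <- do.call(rbind, rows)
  calls$q <- NA_real_
  for (env in unique(calls$environment)) {
    i <- calls$environment == env
    calls$q[i] <- p.adjust(calls$p[i], method = "BH")
  }
  calls$call <- ifelse(calls$q > fdr, "equal",
                       ifelse(calls$median_end > calls$median_start,
                              "improved", "declined"))
  fr <- table(factor(calls$call, levels = c("improved", "equal", "declined")))
  fractions <- setNames(as.vector(fr) / nrow(calls), names(fr))
  list(calls = calls, fractions = fractions)
}

#' Z-test comparing two coefficients of variation
#'
#' Large-sample test on log CVs with delta-method variances
#' `Var(log CV) ~ (0.5 + CV^2) / n`.
#'
#' @param cv1,cv2 the two coefficients of variation.
#' @param n1,n2 number of observations behind each CV.
#' @return list with `z` and two-sided `p`.
#' @export
cv_z_test <- function(cv1, n1, cv2, n2) {
  stopifnot(cv1 > 0, cv2 > 0, n1 > 1, n2 > 1)
  v1 <- (0.5 + cv1^2) / n1   # delta-method Var(log CV)
  v2 <- (0.5 + cv2^2) / n2
  z <- (log(cv1) - log(cv2)) / sqrt(v1 + v2)
  list(z = z, p = 2 * pnorm(abs(z), lower.tail = FALSE))
}

#' Dispersion of evolved fitness across replicate lines and environments
#'
#' For each genotype and environment, the coefficient of variation
#' (sd/mean) of fitness across its replicate evolved lines.  Compares the
#' CV in the medium of selection with the mean CV across the other
#' environments (Wilcoxon test across genotypes; pooled CVs additionally
#' by [cv_z_test()]), and correlates the per-genotype mean fitness gain
#' with the mean other-media CV (Spearman).  High dispersion outside the
#' selection medium with low dispersion inside it is the signature of
#' hidden pleiotropic variation among independently evolved lines.
#'
#' @param fitness data frame with columns `genotype`, `line`,
#'   `environment`, `fitness` (one value per replicate line and
#'   environment).
#' @param selection_env id of the medium of selection.
#' @param gains optional data frame `genotype`, `gain` (mean fitness gain
#'   of the genotype's lines during evolution) for the Spearman analysis.
#' @param min_lines minimum replicate lines per genotype (default 3).
#' @param paired use a paired Wilcoxon signed-rank test across genotypes
#'   instead of the rank-sum test (default `FALSE`).
#' @return list with `per_genotype` (data frame `genotype`, `cv_selection`,
#'   `cv_other_mean`), `wilcoxon_p`, `z_test` (pooled-CV comparison) and
#'   `spearman` (`rho`, `p`; `NULL` without `gains`).
#' @export
cv_analysis <- function(fitness, selection_env, gains = NULL,
                        min_lines = 3, paired = FALSE) {
  need <- c("genotype", "line", "environment", "fitness")
  stopifnot(all(need %in% names(fitness)))
  if (!selection_env %in% fitness$environment)
    stop("selection environment ", selection_env, " not in data")

  cv_one <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < min_lines || mean(x) == 0) return(NA_real_)
    sd(x) / mean(x)
  }
  rows <- list()
  for (g in unique(fitness$genotype)) {
    fg <- fitness[fitness$genotype == g, ]
    cvs <- tapply(fg$fitness, fg$environment, cv_one)
    sel <- cvs[[selection_env]]
    oth <- cvs[names(cvs) != selection_env]
    rows[[length(rows) + 1L]] <- data.frame(
      genotype = g, cv_selection = sel,
      cv_other_mean = mean(unlist(oth), na.rm = TRUE),
      stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, rows)
  ok <- complete.cases(per[c("cv_selection", "cv_other_mean")])
  if (sum(ok) < 2)
    stop("fewer than 2 genotypes with defined CVs")
  wp <- suppressWarnings(
    wilcox.test(per$cv_selection[ok], per$cv_other_mean[ok],
                paired = paired)$p.value)
  n_ok <- sum(ok)
  zt <- cv_z_test(mean(per$cv_selection[ok]), n_ok,
                  mean(per$cv_other_mean[ok]), n_ok)
  sp <- NULL
  if (!is.null(gains)) {
    m <- merge(per[ok, ], gains, by = "genotype")
    ct <- suppressWarnings(cor.test(m$gain, m$cv_other_mean,
                                    method = "spearman"))
    sp <- list(rho = unname(ct$estimate), p = ct$p.value)
  }
  list(per_genotype = per, wilcoxon_p = wp, z_test = zt, spearman = sp)
}
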