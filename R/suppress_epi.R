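#' Flag suppression interactions in a genetic-interaction table
#'
#' Deletion of gene B suppresses deletion of gene A when `F_A < F_B` and
#' `F_AB > F_A + sigma_A`: the double mutant is fitter than the sicker
#' single mutant beyond its measurement noise.  Also returns the per-gene
#' suppressor fraction, with the denominator being either all partners
#' tested for that gene or (when an `interaction` column marks genetic
#' interactions) only its genetic interactions.
#'
#' @param records data frame with columns `geneA`, `geneB`, `F_A`, `F_B`,
#'   `F_AB`, `sigma_A`; optionally a logical `interaction` column.
#' @param denominator `"tested"` (all partners) or `"interactions"`.
#' @return list with `records` (input plus `suppressor` flag; rows with
#'   missing `sigma_A` are dropped with a message) and `per_gene` (data
#'   frame `gene`, `fitness`, `n`, `n_suppressors`, `fraction`).
#' @export
find_suppressors <- function(records,
                             denominator = c("tested", "interactions")) {
  denominator <- match.arg(denominator)
  need <- c("geneA", "geneB", "F_A", "F_B", "F_AB", "sigma_A")
  stopifnot(all(need %in% names(records)))
  bad <- is.na(records$sigma_A)
  if (any(bad)) {
    message(sum(bad), " record(s) skipped: missing sigma_A")
    records <- records[!bad, , drop = FALSE]
  }
  records$suppressor <- records$F_A < records$F_B &
    records$F_AB > records$F_A + records$sigma_A
  denom_ok <- if (denominator == "interactions") {
    if (!"interaction" %in% names(records))
      stop("denominator = 'interactions' needs an 'interaction' column")
    records$interaction
  } else rep(TRUE, nrow(records))

  genes <- unique(records$geneA)
  n <- tapply(denom_ok, records$geneA, sum)[genes]
  k <- tapply(records$suppressor & denom_ok, records$geneA, sum)[genes]
  f <- tapply(records$F_A, records$geneA, function(x) x[1])[genes]
  per_gene <- data.frame(gene = genes, fitness = as.numeric(f),
                         n = as.integer(n), n_suppressors = as.integer(k),
                         fraction = ifelse(n > 0, k / n, NA_real_),
                         stringsAsFactors = FALSE)
  rownames(per_gene) <- NULL
  list(records = records, per_gene = per_gene)
}

#' Correlation between single-deletion fitness and suppressor fraction
#'
#' Spearman rank correlation between a gene's single-deletion fitness and
#' the fraction of other genes whose deletion suppresses it, with
#' quartile-binned medians for boxplot-style reporting.  A strong negative
#' correlation means strongly deleterious deletions can be suppressed by
#' many loss-of-function mutations elsewhere.
#'
#' @param per_gene data frame with columns `fitness` and `fraction` (as
#'   from [find_suppressors()]; >= 10 genes).
#' @return list with `rho`, `p` (both `NA` when the fractions are
#'   constant) and `bins` (quartile bins of fitness with median fraction).
#' @export
suppression_fitness_correlation <- function(per_gene) {
  stopifnot(all(c("fitness", "fraction") %in% names(per_gene)))
  d <- per_gene[complete.cases(per_gene[c("fitness", "fraction")]), ]
  if (nrow(d) < 10)
    stop("need at least 10 genes")
  q <- quantile(d$fitness, probs = seq(0, 1, 0.25))
  bin <- cut(d$fitness, breaks = unique(q), include.lowest = TRUE)
  bins <- data.frame(bin = levels(bin),
                     n = as.integer(table(bin)),
                     median_fraction = as.numeric(
                       tapply(d$fraction, bin, median)),
                     stringsAsFactors = FALSE)
  if (length(unique(d$fraction)) == 1L)
    return(list(rho = NA_real_, p = NA_real_, bins = bins))
  ct <- suppressWarnings(cor.test(d$fitness, d$fraction,
                                  method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, bins = bins)
}

#' Epistasis between two mutations from single- and double-mutant fitness
#'
#' Fitness values are rescaled so the wild type is 1; epistasis is the
#' deviation from the multiplicative expectation,
#' `epsilon = F_ab - F_a * F_b`.  Sign epistasis is called when one
#' mutation's fitness effect changes sign between backgrounds (e.g.
#' deleterious alone, beneficial in the other mutant's background);
#' reciprocal sign epistasis when both do; magnitude epistasis when
#' `epsilon` exceeds `tol` without any sign change.
#'
#' @param f_a,f_b,f_ab relative fitness of the two single mutants and the
#'   double mutant.
#' @param f_wt wild-type fitness (> 0; inputs are divided by it).
#' @param tol minimal absolute effect / epsilon treated as different from
#'   zero (default 1e-12; supply a propagated measurement error for real
#'   data).
#' @return list with `epsilon`, `classification` (`none`, `magnitude`,
#'   `sign`, `reciprocal_sign`) and `effects` (each mutation's effect in
#'   each background).
#' @export
epistasis <- function(f_a, f_b, f_ab, f_wt = 1, tol = 1e-12) {
  if (f_wt <= 0)
    stop("wild-type fitness must be positive")
  a <- f_a / f_wt; b <- f_b / f_wt; ab <- f_ab / f_wt
  eps <- ab - a * b
  eff <- c(a_alone = a - 1, a_in_b = ab - b,
           b_alone = b - 1, b_in_a = ab - a)
  sgn <- function(x) if (abs(x) <= tol) 0 else sign(x)
  flip_a <- sgn(eff["a_alone"]) != 0 && sgn(eff["a_in_b"]) != 0 &&
    sgn(eff["a_alone"]) != sgn(eff["a_in_b"])
  flip_b <- sgn(eff["b_alone"]) != 0 && sgn(eff["b_in_a"]) != 0 &&
    sgn(eff["b_alone"]) != sgn(eff["b_in_a"])
  classification <- if (flip_a && flip_b) "reciprocal_sign"
    else if (flip_a || flip_b) "sign"
    else if (abs(eps) > tol) "magnitude"
    else "none"
  list(epsilon = eps, classification = classification, effects = eff)
}

#' Bootstrap significance of a sign-epistasis call
#'
#' Resamples replicate fitness measurements of the four genotypes and
#' reports the percentile confidence interval of the focal mutation's
#' effect in the other mutant's background; sign epistasis is supported
#' when the interval excludes 0 with sign opposite to the effect alone.
#' A Wilcoxon rank-sum test of the double mutant against the background
#' single mutant is reported alongside.
#'
#' @param wt,a,b,ab numeric vectors of replicate fitness measurements
#'   (e.g. colony sizes) for wild type, singles and double.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @param level confidence level (default 0.95).
#' @return list with `effect_b_in_a` (point estimate of the b effect in
#'   the a background, means rescaled by wild type), `ci`, `sign_supported`
#'   and `wilcoxon_p`.
#' @export
sign_epistasis_bootstrap <- function(wt, a, b, ab, n_boot = 1000,
                                     seed = NULL, level = 0.95) {
  stopifnot(length(wt) > 1, length(a) > 1, length(b) > 1, length(ab) > 1)
  if (!is.null(seed)) set.seed(seed)
  est <- function(wt, a, b, ab) (mean(ab) - mean(a)) / mean(wt)
  point <- est(wt, a, b, ab)
  boot <- vapply(seq_len(n_boot), function(i)
    est(sample(wt, replace = TRUE), sample(a, replace = TRUE),
        sample(b, replace = TRUE), sample(ab, replace = TRUE)), 1)
  alpha <- (1 - level) / 2
  ci <- quantile(boot, c(alpha, 1 - alpha), names = FALSE)
  b_alone <- (mean(b) - mean(wt)) / mean(wt)
  supported <- (ci[1] > 0 || ci[2] < 0) && sign(point) != sign(b_alone)
  list(effect_b_in_a = point, ci = ci, sign_supported = supported,
       wilcoxon_p = suppressWarnings(wilcox.test(ab, a)$p.value))
}

#' Consistency of two genotypes' fitness profiles across environments
#'
#' Spearman correlation of two normalized fitness vectors over shared
#' environments (at least 5).  Used to ask whether a reconstructed mutant
#' phenocopies an evolved line across conditions.
#'
#' @param x,y numeric fitness vectors; if named, they are matched on
#'   shared environment names, otherwise positionally.
#' @return list with `rho`, `p` and `n_environments`.
#' @export
cross_environment_consistency <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    shared <- intersect(names(x), names(y))
    x <- x[shared]; y <- y[shared]
  } else if (length(x) != length(y))
    stop("unnamed vectors must have equal length")
  if (length(x) < 5)
    stop("need at least 5 shared environments")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n_environments = length(x))
}
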