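#' Differential-expression configuration
#'
#' @param fc_threshold fold-change threshold (> 1; default 1.7).
#' @param p_threshold p-value threshold (default 0.05).
#' @param exclude character vector of genes to drop before analysis
#'   (stochastic, CNV-affected, aneuploidy-responsive or growth-rate-
#'   correlated transcripts).
#' @return list of class `de_config`.
#' @export
de_config <- function(fc_threshold = 1.7, p_threshold = 0.05,
                      exclude = character()) {
  if (fc_threshold <= 1)
    stop("fc_threshold must be > 1")
  structure(list(fc_threshold = fc_threshold, p_threshold = p_threshold,
                 exclude = exclude), class = "de_config")
}

#' Average technical replicates within biological replicates
#'
#' @param mat genes x replicates matrix of log2 ratios.
#' @param bio vector of biological-replicate labels, one per column.
#' @return genes x biological-replicates matrix.
#' @export
collapse_technical <- function(mat, bio) {
  stopifnot(ncol(mat) == length(bio))
  groups <- unique(bio)
  out <- vapply(groups, function(b)
    rowMeans(mat[, bio == b, drop = FALSE]), numeric(nrow(mat)))
  dimnames(out) <- list(rownames(mat), paste0("bio", groups))
  out
}

# Vectorized equal-variance two-sample t-test on matrix rows.
.row_t_p <- function(x, y) {
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2); vy <- rowSums((y - my)^2)
  df <- nx + ny - 2
  sp2 <- (vx + vy) / df
  se <- sqrt(sp2 * (1 / nx + 1 / ny))
  tstat <- (mx - my) / se
  p <- 2 * pt(abs(tstat), df = df, lower.tail = FALSE)
  # degenerate rows: zero variance in both groups
  zero <- se == 0
  p[zero & mx == my] <- 1
  p[zero & mx != my] <- 0
  p
}

#' Call differential expression between two strains
#'
#' A gene is differentially expressed when its mean log2 difference
#' exceeds `log2(fc_threshold)` in absolute value and a two-sample t-test
#' on the (biological-)replicate log ratios gives p below `p_threshold`.
#' When `bio` labels are supplied, technical replicates are averaged
#' within biological replicate first, so the test sees independent units.
#'
#' @param x,y genes x replicates matrices of log2 ratios for the two
#'   strains (same genes, same row order; >= 2 replicates each).
#' @param config a [de_config()].
#' @param bio optional biological-replicate labels for the columns of both
#'   matrices.
#' @return data frame `gene`, `log2fc` (x minus y), `p`, `de`.
#' @export
call_de <- function(x, y, config = de_config(), bio = NULL) {
  stopifnot(nrow(x) == nrow(y))
  if (!is.null(config$exclude) && length(config$exclude) > 0) {
    keep <- !(rownames(x) %in% config$exclude)
    x <- x[keep, , drop = FALSE]; y <- y[keep, , drop = FALSE]
  }
  if (!is.null(bio)) {
    x <- collapse_technical(x, bio)
    y <- collapse_technical(y, bio)
  }
  if (ncol(x) < 2 || ncol(y) < 2)
    stop("need at least 2 replicates per strain")
  lfc <- rowMeans(x) - rowMeans(y)
  p <- .row_t_p(x, y)
  data.frame(gene = rownames(x), log2fc = lfc, p = p,
             de = abs(lfc) >= log2(config$fc_threshold) &
               p < config$p_threshold,
             stringsAsFactors = FALSE)
}

#' Normalized expression-distance triangle of a WT/ancestor/evolved triplet
#'
#' Computes Euclidean distances between the mean log2 profiles of wild
#' type, ancestor and evolved strain over the genes differentially
#' expressed in at least one of the three pairwise comparisons, each
#' normalized to the ancestor-wild-type distance.  A small evolved-WT
#' distance relative to evolved-ancestor indicates restoration of the
#' wild-type expression state; the opposite indicates further divergence.
#' Replicate-noise radii (distance between the two biological-replicate
#' mean profiles of each strain, same gene set, same normalization) gauge
#' how much of each distance is measurement noise.
#'
#' @param wt,anc,evo genes x replicates matrices of log2 ratios.
#' @param config a [de_config()].
#' @param bio biological-replicate labels for the columns (default
#'   `c(1, 1, 2, 2)` for 2 biological x 2 technical replicates).
#' @return list with `distances` (named: `anc_wt` = 1, `evo_wt`,
#'   `evo_anc`), `raw_distances` (unnormalized), `radii` (per strain),
#'   `n_genes` (size of the DE union set) and `genes`.
#' @export
distance_triangle <- function(wt, anc, evo, config = de_config(),
                              bio = c(1, 1, 2, 2)) {
  stopifnot(nrow(wt) == nrow(anc), nrow(anc) == nrow(evo))
  d1 <- call_de(anc, wt, config, bio = bio)
  d2 <- call_de(evo, wt, config, bio = bio)
  d3 <- call_de(evo, anc, config, bio = bio)
  de_union <- unique(c(d1$gene[d1$de], d2$gene[d2$de], d3$gene[d3$de]))
  if (length(de_union) == 0)
    stop("no gene differentially expressed in any pairwise comparison")
  sel <- rownames(wt) %in% de_union
  euc <- function(a, b) sqrt(sum((a - b)^2))
  mw <- rowMeans(wt[sel, , drop = FALSE])
  ma <- rowMeans(anc[sel, , drop = FALSE])
  me <- rowMeans(evo[sel, , drop = FALSE])
  d_anc_wt <- euc(ma, mw)
  if (d_anc_wt == 0) {
    warning("ancestor-wild-type distance is 0; triangle undefined")
    return(list(distances = c(anc_wt = NA, evo_wt = NA, evo_anc = NA),
                raw_distances = c(anc_wt = 0, evo_wt = euc(me, mw),
                                  evo_anc = euc(me, ma)),
                radii = NULL, n_genes = sum(sel), genes = de_union))
  }
  raw <- c(anc_wt = d_anc_wt, evo_wt = euc(me, mw), evo_anc = euc(me, ma))
  radius <- function(m) {
    b <- collapse_technical(m[sel, , drop = FALSE], bio)
    if (ncol(b) < 2) return(NA_real_)
    euc(b[, 1], b[, 2]) / d_anc_wt
  }
  list(distances = raw / d_anc_wt, raw_distances = raw,
       radii = c(wt = radius(wt), anc = radius(anc), evo = radius(evo)),
       n_genes = sum(sel), genes = de_union)
}

#' Fraction of deletion-responsive genes restored during evolution
#'
#' Among the genes differentially expressed in the ancestor relative to
#' wild type (the deletion's expression signature), a gene is `restored`
#' when it is also differentially expressed in the evolved line relative
#' to the ancestor with the opposite sign -- a significant move back
#' toward the wild-type level passing the full fold-change threshold.
#' The remainder are `unrestored`; genes without an ancestral change are
#' `other`.
#'
#' @param wt,anc,evo genes x replicates matrices of log2 ratios.
#' @param config a [de_config()].
#' @param bio biological-replicate labels (default 2 x 2).
#' @return list with `fractions` (named `restored`, `unrestored`; `NA`
#'   when no gene is ancestor-DE), `n_ancestor_de` and `labels` (per-gene
#'   data frame).
#' @export
restoration_fractions <- function(wt, anc, evo, config = de_config(),
                                  bio = c(1, 1, 2, 2)) {
  anc_wt <- call_de(anc, wt, config, bio = bio)
  evo_anc <- call_de(evo, anc, config, bio = bio)
  stopifnot(identical(anc_wt$gene, evo_anc$gene))
  anc_de <- anc_wt$de
  restored <- anc_de & evo_anc$de &
    sign(evo_anc$log2fc) == -sign(anc_wt$log2fc)
  label <- ifelse(!anc_de, "other",
                  ifelse(restored, "restored", "unrestored"))
  n <- sum(anc_de)
  fractions <- if (n == 0) {
    warning("no ancestor-DE gene; restoration fractions undefined")
    c(restored = NA_real_, unrestored = NA_real_)
  } else {
    c(restored = sum(restored) / n, unrestored = 1 - sum(restored) / n)
  }
  list(fractions = fractions, n_ancestor_de = n,
       labels = data.frame(gene = anc_wt$gene, label = label,
                           anc_log2fc = anc_wt$log2fc,
                           evo_log2fc = evo_anc$log2fc,
                           stringsAsFactors = FALSE))
}

#' Drop excluded genes from a WT/ancestor/evolved triplet
#'
#' Robustness filter: removes genes whose expression change could be a
#' by-product rather than a signal of interest -- genes amplified by copy-
#' number changes in the evolved line, aneuploidy-responsive genes,
#' growth-rate-correlated genes, and transcripts with stochastic wild-type
#' variation -- so downstream distances and restoration fractions can be
#' recomputed on the filtered set and compared with the unfiltered
#' results.
#'
#' @param triplet list with genes x replicates matrices `wt`, `anc`, `evo`
#'   (shared rownames).
#' @param exclude_lists list (or single character vector) of gene ids to
#'   exclude; the union is removed.
#' @return the triplet with excluded genes dropped; errors if nothing
#'   remains.
#' @export
robustness_filter <- function(triplet, exclude_lists) {
  stopifnot(all(c("wt", "anc", "evo") %in% names(triplet)))
  drop <- unique(unlist(exclude_lists))
  keep <- !(rownames(triplet$wt) %in% drop)
  if (!any(keep))
    stop("exclusion lists remove every gene")
  out <- triplet
  for (nm in c("wt", "anc", "evo"))
    out[[nm]] <- triplet[[nm]][keep, , drop = FALSE]
  out
}
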