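#' Classify evolved-line variants as de novo, inherited or background
#'
#' A variant observed in an evolved clone is `de_novo` when it is absent
#' from every ancestor strain; `secondary_ancestor` when it is present in
#' the clone's own ancestor and in no other ancestral strain (a private
#' mutation that arose before the evolution experiment); `background` when
#' it is present in its own ancestor and at least one other (a strain-
#' library variant); and `ambiguous` when it is found in other ancestors
#' but not the clone's own (excluded from de novo counts).
#'
#' @param evolved data frame of evolved-clone variants with columns `line`,
#'   `ancestor` (id of the clone's ancestor strain), `chrom`, `pos`, `ref`,
#'   `alt`.
#' @param ancestor_variants data frame of ancestor-strain variants with
#'   columns `ancestor`, `chrom`, `pos`, `ref`, `alt`.
#' @return `evolved` with an added `status` factor
#'   (`de_novo`/`secondary_ancestor`/`background`/`ambiguous`).
#' @export
classify_mutation_status <- function(evolved, ancestor_variants) {
  stopifnot(all(c("line", "ancestor", "chrom", "pos", "ref", "alt") %in%
                  names(evolved)),
            all(c("ancestor", "chrom", "pos", "ref", "alt") %in%
                  names(ancestor_variants)))
  vkey <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = "\r")
  anc_key <- vkey(ancestor_variants)
  carriers <- split(as.character(ancestor_variants$ancestor), anc_key)

  ek <- vkey(evolved)
  status <- character(nrow(evolved))
  for (i in seq_len(nrow(evolved))) {
    who <- carriers[[ek[i]]]
    own <- as.character(evolved$ancestor[i])
    status[i] <- if (is.null(who)) "de_novo"
      else if (own %in% who && length(who) == 1L) "secondary_ancestor"
      else if (own %in% who) "background"
      else "ambiguous"
  }
  evolved$status <- factor(status, levels = c("de_novo", "secondary_ancestor",
                                              "background", "ambiguous"))
  evolved
}

.check_orfs <- function(orfs) {
  if (length(orfs) == 0L)
    stop("empty ORF set")
  orfs <- toupper(orfs)
  nc <- nchar(orfs)
  if (any(nc %% 3 != 0))
    stop("ORF length(s) not divisible by 3")
  code <- Biostrings::GENETIC_CODE
  for (s in orfs) {
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    aa <- code[codons]
    if (anyNA(aa))
      stop("ORF contains non-ACGT codon(s)")
    if (any(aa[-length(aa)] == "*"))
      stop("ORF contains internal stop codon(s)")
  }
  orfs
}

#' Probability that a given substitution is nonsynonymous
#'
#' Over all coding positions of the ORF set carrying base `ref`, the
#' fraction where substituting `alt` changes the encoded amino acid.
#' Stop-gains count as nonsynonymous.  This is the site-averaged
#' probability that the observed substitution type would be nonsynonymous
#' had it occurred at a random coding position.
#'
#' @param ref,alt single upper-case bases (`A`/`C`/`G`/`T`), `ref != alt`.
#' @param orfs character vector of coding sequences (length divisible by
#'   3, no internal stop codons).
#' @return probability in `[0, 1]`.
#' @export
ns_site_probability <- function(ref, alt, orfs) {
  stopifnot(ref %in% c("A", "C", "G", "T"), alt %in% c("A", "C", "G", "T"),
            ref != alt)
  orfs <- .check_orfs(orfs)
  code <- Biostrings::GENETIC_CODE
  total <- 0L
  ns <- 0L
  for (s in orfs) {
    chars <- strsplit(s, "")[[1L]]
    pos <- which(chars == ref)
    if (length(pos) == 0L) next
    codon_start <- ((pos - 1L) %/% 3L) * 3L + 1L
    within <- (pos - 1L) %% 3L + 1L
    orig <- substring(s, codon_start, codon_start + 2L)
    mut <- orig
    substr(mut, within, within) <- alt
    total <- total + length(pos)
    ns <- ns + sum(code[orig] != code[mut])
  }
  if (total == 0L)
    stop("reference base ", ref, " absent from the ORF set")
  ns / total
}

#' Poisson-binomial upper-tail probability
#'
#' Exact `P(X >= k)` for `X` a sum of independent Bernoulli variables with
#' success probabilities `probs`, computed by dynamic programming over the
#' exact probability mass function.
#'
#' @param k threshold count.
#' @param probs numeric vector of success probabilities in `[0, 1]`.
#' @return tail probability.
#' @export
poisson_binomial_tail <- function(k, probs) {
  stopifnot(all(probs >= 0), all(probs <= 1), k >= 0)
  n <- length(probs)
  if (n == 0L) stop("no probabilities supplied")
  pmf <- c(1, numeric(n))
  for (p in probs) {
    pmf <- c(pmf[1L] * (1 - p),
             pmf[-1L] * (1 - p) + pmf[-(n + 1L)] * p)
  }
  if (k > n) return(0)
  sum(pmf[(k + 1L):(n + 1L)])
}

#' Test for an excess of nonsynonymous coding substitutions
#'
#' For each observed coding SNP, computes the site-averaged probability
#' that its substitution type would be nonsynonymous at a random coding
#' position ([ns_site_probability()]); the tail probability that at least
#' the observed number of SNPs would be nonsynonymous is then the Poisson-
#' binomial upper tail over those per-SNP probabilities.  A small tail
#' probability indicates that the accumulation of the observed mutations
#' was driven by selection on protein sequence rather than neutral drift.
#'
#' @param snps data frame with columns `ref`, `alt` and either a logical
#'   `nonsynonymous` or an `effect` column (values `synonymous`,
#'   `nonsynonymous`, `nonsense`; nonsense counts as nonsynonymous).
#' @param orfs character vector of coding sequences (the mutational target
#'   set).
#' @return list with `n` (SNPs tested), `observed_ns`, `ns_fraction`,
#'   `expected_ns` (sum of per-SNP probabilities), `p` (upper-tail
#'   probability) and `site_probs`.
#' @export
ns_excess_test <- function(snps, orfs) {
  if (nrow(snps) == 0L)
    stop("no observed SNPs")
  if ("nonsynonymous" %in% names(snps)) {
    obs_flag <- as.logical(snps$nonsynonymous)
  } else if ("effect" %in% names(snps)) {
    obs_flag <- snps$effect %in% c("nonsynonymous", "nonsense")
  } else stop("snps needs a 'nonsynonymous' or 'effect' column")

  sub_types <- unique(snps[c("ref", "alt")])
  type_p <- mapply(function(r, a) ns_site_probability(r, a, orfs),
                   sub_types$ref, sub_types$alt)
  names(type_p) <- paste(sub_types$ref, sub_types$alt, sep = ">")
  probs <- type_p[paste(snps$ref, snps$alt, sep = ">")]

  k <- sum(obs_flag)
  list(n = nrow(snps), observed_ns = k, ns_fraction = k / nrow(snps),
       expected_ns = sum(probs), p = poisson_binomial_tail(k, probs),
       site_probs = unname(probs))
}

#' Parallelism of mutated-gene sets across lines
#'
#' For every pair of lines, the shared fraction of mutated genes (Jaccard
#' index by default: intersection over union); reports the mean over pairs
#' of lines founded from the same genotype and over pairs from different
#' genotypes.  Parallel evolution at the gene level inflates the
#' within-genotype mean relative to the between-genotype mean.
#'
#' @param gene_sets list of character vectors: the de novo mutated genes of
#'   each line.
#' @param genotype character vector of genotype labels, one per line.
#' @param metric `"jaccard"` (intersection/union) or `"min"`
#'   (intersection / size of the smaller set).
#' @return list with `within`, `between` (mean shared fractions; `NaN` when
#'   no pair exists) and `pairs` (per-pair data frame).  Pairs where both
#'   sets are empty are excluded (with a message); pairs with one empty set
#'   contribute 0.
#' @export
parallelism <- function(gene_sets, genotype, metric = c("jaccard", "min")) {
  metric <- match.arg(metric)
  stopifnot(length(gene_sets) == length(genotype))
  n <- length(gene_sets)
  if (n < 2) stop("need at least 2 lines")
  rows <- list()
  excluded <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- unique(gene_sets[[i]]); b <- unique(gene_sets[[j]])
    if (length(a) == 0L && length(b) == 0L) { excluded <- excluded + 1L; next }
    inter <- length(intersect(a, b))
    denom <- if (metric == "jaccard") length(union(a, b))
             else max(min(length(a), length(b)), 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      i = i, j = j, shared = inter / denom,
      same_genotype = genotype[i] == genotype[j])
  }
  if (excluded > 0L)
    message(excluded, " pair(s) of empty gene sets excluded")
  pairs <- do.call(rbind, rows)
  list(within = mean(pairs$shared[pairs$same_genotype]),
       between = mean(pairs$shared[!pairs$same_genotype]),
       pairs = pairs)
}

#' Bundle functional-relatedness annotation tables
#'
#' @param complexes data frame (`gene`, `complex`): stable protein-complex
#'   membership, one row per gene-complex assignment.
#' @param categories data frame (`gene`, `category`): functional-category
#'   membership.
#' @param gi_similarity data frame (`gene1`, `gene2`, `r`): genetic-
#'   interaction profile similarity (Pearson r), symmetric pairs.
#' @param coexpression data frame (`gene1`, `gene2`, `r`): co-expression
#'   (Pearson r), symmetric pairs.
#' @return object of class `relatedness_annotation`.
#' @export
relatedness_annotation <- function(complexes = NULL, categories = NULL,
                                   gi_similarity = NULL, coexpression = NULL) {
  out <- list(complexes = complexes, categories = categories,
              gi_similarity = gi_similarity, coexpression = coexpression)
  structure(out, class = "relatedness_annotation")
}

.pair_value_fun <- function(annotation, measure) {
  if (measure %in% c("co_complex", "co_category")) {
    tbl <- if (measure == "co_complex") annotation$complexes
           else annotation$categories
    if (is.null(tbl) || nrow(tbl) == 0L)
      stop("no annotation coverage for measure ", measure)
    ids <- split(as.character(tbl[[2L]]), as.character(tbl[[1L]]))
    function(g1, g2) {
      a <- ids[[g1]]; b <- ids[[g2]]
      if (is.null(a) || is.null(b)) 0 else as.numeric(length(intersect(a, b)) > 0)
    }
  } else {
    tbl <- if (measure == "gi_profile_similarity") annotation$gi_similarity
           else annotation$coexpression
    if (is.null(tbl) || nrow(tbl) == 0L)
      stop("no annotation coverage for measure ", measure)
    key <- paste(pmin(as.character(tbl$gene1), as.character(tbl$gene2)),
                 pmax(as.character(tbl$gene1), as.character(tbl$gene2)),
                 sep = "\r")
    val <- setNames(tbl$r, key)
    function(g1, g2) {
      v <- val[paste(min(g1, g2), max(g1, g2), sep = "\r")]
      if (is.na(v)) NA_real_ else unname(v)
    }
  }
}

#' Permutation test for functional relatedness of de novo mutations
#'
#' Tests whether de novo mutations preferentially hit genes functionally
#' related to the line's deleted gene.  The observed statistic is the
#' fraction of (knock-out gene, mutated gene) pairs that are co-annotated
#' (binary measures: co-complex, co-category) or the mean pairwise
#' similarity (continuous measures: genetic-interaction profile similarity,
#' co-expression).  The null reassigns the whole per-line mutated-gene
#' lists to the knock-out genotypes uniformly at random (a permutation of
#' the knock-out labels across lines), preserving each line's mutational
#' burden.  The enrichment ratio is observed over mean null; the p-value
#' uses the add-one permutation estimator.
#'
#' @param ko character vector: the deleted (knock-out) gene of each line.
#' @param gene_lists list of character vectors: each line's de novo mutated
#'   genes.
#' @param annotation a [relatedness_annotation()] object.
#' @param measure one of `"co_complex"`, `"co_category"`,
#'   `"gi_profile_similarity"`, `"co_expression"`.
#' @param n_shuffles number of permutations (default 1000).
#' @param seed RNG seed.
#' @return list with `observed`, `null_mean`, `enrichment`, `p`, `null`
#'   (vector of permuted statistics) and `n_pairs`.
#' @export
functional_relatedness_test <- function(ko, gene_lists, annotation,
                                        measure = c("co_complex",
                                                    "co_category",
                                                    "gi_profile_similarity",
                                                    "co_expression"),
                                        n_shuffles = 1000, seed = NULL) {
  measure <- match.arg(measure)
  stopifnot(length(ko) == length(gene_lists))
  if (!is.null(seed)) set.seed(seed)
  pair_value <- .pair_value_fun(annotation, measure)

  kos <- unique(as.character(ko))
  if (length(kos) < 2) {
    warning("single genotype: shuffling is the identity, p = 1")
  }
  n_lines <- length(ko)
  # Precompute per-line sums/counts against every candidate knock-out gene,
  # so each permutation is a table lookup.
  V <- matrix(0, n_lines, length(kos), dimnames = list(NULL, kos))
  N <- matrix(0L, n_lines, length(kos), dimnames = list(NULL, kos))
  for (i in seq_len(n_lines)) {
    genes <- setdiff(unique(as.character(gene_lists[[i]])), NA)
    for (k in kos) {
      vals <- vapply(genes, function(g) pair_value(k, g), 1)
      vals <- vals[!is.na(vals)]
      V[i, k] <- sum(vals)
      N[i, k] <- length(vals)
    }
  }
  stat <- function(assign) {
    idx <- cbind(seq_len(n_lines), match(assign, kos))
    num <- sum(V[idx]); den <- sum(N[idx])
    if (den == 0L) NA_real_ else num / den
  }
  observed <- stat(as.character(ko))
  if (is.na(observed))
    stop("no annotated (knock-out, mutated gene) pair for measure ", measure)
  null <- vapply(seq_len(n_shuffles), function(b)
    stat(sample(as.character(ko))), 1)
  null_mean <- mean(null, na.rm = TRUE)
  list(observed = observed, null_mean = null_mean,
       enrichment = observed / null_mean,
       p = (1 + sum(null >= observed, na.rm = TRUE)) / (1 + n_shuffles),
       null = null, n_pairs = sum(N[cbind(seq_len(n_lines),
                                          match(as.character(ko), kos))]))
}

#' Fraction of the genome covered by putative promoter windows
#'
#' Promoter windows are taken `window` bp upstream of each ORF start
#' (strand-aware), clipped to the chromosome, and merged where they
#' overlap.
#'
#' @param genes data frame with columns `chrom`, `start`, `end` (1-based,
#'   inclusive) and `strand` (`"+"`/`"-"`).
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param window promoter window length in bp (default 500).
#' @return fraction of the total genome length covered by promoter windows.
#' @export
promoter_fraction <- function(genes, chrom_lengths, window = 500) {
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(genes)),
            window > 0)
  total_bp <- 0
  for (ch in names(chrom_lengths)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0L) next
    up_start <- ifelse(g$strand == "+", g$start - window, g$end + 1)
    up_end <- ifelse(g$strand == "+", g$start - 1, g$end + window)
    up_start <- pmax(up_start, 1)
    up_end <- pmin(up_end, chrom_lengths[[ch]])
    keep <- up_end >= up_start
    if (!any(keep)) next
    ir <- IRanges::reduce(IRanges::IRanges(up_start[keep], up_end[keep]))
    total_bp <- total_bp + sum(IRanges::width(ir))
  }
  total_bp / sum(chrom_lengths)
}

#' Binomial test for promoter-mutation enrichment
#'
#' Two-sided exact binomial test of the number of mutations falling in
#' putative promoter windows against the expectation that mutations land
#' uniformly on the mutable genome.
#'
#' @param in_promoter logical vector: one flag per mutation.
#' @param prom_fraction expected promoter fraction of the mutable genome
#'   (e.g. from [promoter_fraction()]).
#' @return list with `n`, `observed`, `expected`, `p`.
#' @export
promoter_enrichment <- function(in_promoter, prom_fraction) {
  stopifnot(prom_fraction > 0, prom_fraction < 1)
  n <- length(in_promoter)
  if (n == 0L)
    stop("no mutations supplied")
  k <- sum(in_promoter)
  bt <- binom.test(k, n, p = prom_fraction, alternative = "two.sided")
  list(n = n, observed = k, expected = n * prom_fraction, p = bt$p.value)
}

#' Filter sequence-similarity records down to paralog pairs
#'
#' A gene pair is called a paralog pair when the alignment satisfies all
#' of: E-value < 1e-8, alignment length > 100 residues, sequence similarity
#' > 30%, and neither gene is part of a transposon.  Records with missing
#' fields are rejected (with a message).
#'
#' @param records data frame with columns `gene1`, `gene2`, `evalue`,
#'   `aln_length`, `similarity` (percent), `transposon1`, `transposon2`.
#' @param max_evalue,min_length,min_similarity rule thresholds.
#' @return the subset of `records` called paralog pairs.
#' @export
paralog_filter <- function(records, max_evalue = 1e-8, min_length = 100,
                           min_similarity = 30) {
  need <- c("gene1", "gene2", "evalue", "aln_length", "similarity",
            "transposon1", "transposon2")
  stopifnot(all(need %in% names(records)))
  complete <- complete.cases(records[need])
  if (any(!complete))
    message(sum(!complete), " record(s) rejected: missing fields")
  r <- records[complete, , drop = FALSE]
  keep <- r$evalue < max_evalue & r$aln_length > min_length &
    r$similarity > min_similarity & !r$transposon1 & !r$transposon2
  r[keep, , drop = FALSE]
}
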