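test_that("mutation status separates de novo, inherited and background variants", {
  anc <- data.frame(ancestor = c("a1", "a1", "a2", "a1", "a2", "a3"),
                    chrom = "chr1",
                    pos = c(100, 200, 200, 300, 300, 300),
                    ref = "A", alt = "T")
  evo <- data.frame(line = "L1", ancestor = "a1", chrom = "chr1",
                    pos = c(50, 100, 300, 400, 200),
                    ref = "A", alt = "T")
  out <- classify_mutation_status(evo, anc)
  got <- setNames(as.character(out$status), out$pos)
  expect_equal(got[["50"]], "de_novo")                # nowhere ancestral
  expect_equal(got[["100"]], "secondary_ancestor")    # private to own ancestor
  expect_equal(got[["300"]], "background")            # own + other ancestors
  expect_equal(got[["400"]], "de_novo")
  expect_equal(got[["200"]], "background")            # own + a2
})

test_that("variants found only in foreign ancestors are ambiguous", {
  anc <- data.frame(ancestor = "a2", chrom = "chr1", pos = 100,
                    ref = "G", alt = "C")
  evo <- data.frame(line = "L1", ancestor = "a1", chrom = "chr1",
                    pos = 100, ref = "G", alt = "C")
  out <- classify_mutation_status(evo, anc)
  expect_equal(as.character(out$status), "ambiguous")
})

test_that("nonsynonymous site probability matches codon arithmetic", {
  # single codon TTT, T->C: position 3 synonymous (TTC = Phe),
  # positions 1 and 2 nonsynonymous (CTT = Leu, TCT = Ser)
  expect_equal(ns_site_probability("T", "C", "TTT"), 2 / 3)
  # repeated GGG, G->A: GGA synonymous, AGG/GAG nonsynonymous
  expect_equal(ns_site_probability("G", "A", strrep("GGG", 10)), 2 / 3)
  expect_error(ns_site_probability("A", "C", "GGG"), "absent")
  expect_error(ns_site_probability("A", "C", "GGGA"), "divisible")
  expect_error(ns_site_probability("A", "C", "TAAGGG"), "stop")
})

test_that("site probability equals exhaustive per-site enumeration", {
  sim <- simulate_mutation_tables(n_lines = 2, n_orfs = 10,
                                  orf_length = 300, seed = 9)
  orfs <- sim$orfs
  for (sub in list(c("A", "G"), c("C", "T"), c("G", "C"), c("T", "A"))) {
    expect_identical(ns_site_probability(sub[1], sub[2], orfs),
                     oracle_ns_site_probability(sub[1], sub[2], orfs))
  }
})

test_that("Poisson-binomial tail is exact", {
  expect_equal(poisson_binomial_tail(2, c(0.75, 0.75)), 0.5625)
  expect_equal(poisson_binomial_tail(1, c(0.75, 0.75)), 0.9375)
  expect_equal(poisson_binomial_tail(0, c(0.2, 0.9)), 1)
  # equal probabilities reduce to the binomial tail
  expect_equal(poisson_binomial_tail(7, rep(0.3, 20)),
               pbinom(6, 20, 0.3, lower.tail = FALSE))
  # heterogeneous case against direct enumeration over all 2^n outcomes
  p <- c(0.1, 0.5, 0.8, 0.33)
  outcomes <- expand.grid(rep(list(0:1), 4))
  probs <- apply(outcomes, 1, function(o) prod(ifelse(o == 1, p, 1 - p)))
  for (k in 0:4)
    expect_equal(poisson_binomial_tail(k, p),
                 sum(probs[rowSums(outcomes) >= k]))
})

test_that("nonsynonymous excess test uses observed substitution types", {
  sim <- simulate_mutation_tables(n_lines = 20, n_orfs = 30,
                                  orf_length = 600, seed = 2)
  snps <- sim$mutations[sim$mutations$class == "snp", ]
  out <- ns_excess_test(snps, sim$orfs)
  expect_equal(out$n, nrow(snps))
  expect_equal(out$ns_fraction, mean(snps$effect != "synonymous"))
  expect_true(out$p >= 0 && out$p <= 1)
  # all-synonymous observations make the tail certain
  syn <- snps
  syn$effect <- "synonymous"
  expect_equal(ns_excess_test(syn, sim$orfs)$p, 1)
  expect_error(ns_excess_test(snps[0, ], sim$orfs), "no observed")
})

test_that("parallelism is the Jaccard share of mutated genes", {
  sets <- list(c("a", "b", "c"), c("b", "c", "d"),
               c("a", "b", "c"), c("x", "y"))
  out <- parallelism(sets[1:2], c("g1", "g1"))
  expect_equal(out$within, 0.5)
  expect_equal(parallelism(sets[c(1, 3)], c("g1", "g1"))$within, 1)
  expect_equal(parallelism(sets[c(1, 4)], c("g1", "g1"))$within, 0)
  # symmetry under relabeling; values bounded in [0, 1]
  a <- parallelism(sets, c("g1", "g1", "g2", "g2"))
  b <- parallelism(rev(sets), c("g2", "g2", "g1", "g1"))
  expect_equal(sort(a$pairs$shared), sort(b$pairs$shared))
  expect_true(all(a$pairs$shared >= 0 & a$pairs$shared <= 1))
  # one empty set contributes zero; both-empty pairs are dropped
  expect_message(
    z <- parallelism(list(character(), character(), "a"),
                     c("g1", "g1", "g1")), "excluded")
  expect_equal(nrow(z$pairs), 2L)
  expect_equal(z$within, 0)
})

test_that("functional relatedness test finds constructed co-complex bias", {
  # universe of 100 genes in 25 complexes of 4; knock-outs always hit
  # complex mates, so the observed co-complex rate is 1
  genes <- sprintf("g%03d", 1:100)
  complexes <- data.frame(gene = genes, complex = rep(1:25, each = 4))
  ann <- relatedness_annotation(complexes = complexes)
  ko <- genes[seq(1, 80, by = 4)]          # first member of 20 complexes
  lists <- lapply(seq_along(ko), function(i) genes[(i - 1) * 4 + 2:3])
  out <- functional_relatedness_test(ko, lists, ann, "co_complex",
                                     n_shuffles = 1000, seed = 1)
  expect_equal(out$observed, 1)
  expect_equal(out$p, 1 / 1001)
  expect_gt(out$enrichment, 10)

  # single genotype: shuffling is the identity
  expect_warning(
    one <- functional_relatedness_test("g001", lists[1], ann, "co_complex",
                                       n_shuffles = 50, seed = 1),
    "single genotype")
  expect_equal(one$p, 1)
})

test_that("continuous relatedness measures average pairwise similarity", {
  pairs <- expand.grid(gene1 = c("k1", "k2"), gene2 = c("m1", "m2"),
                       stringsAsFactors = FALSE)
  pairs$r <- c(0.9, 0.1, 0.9, 0.1)   # k1 similar to both targets
  ann <- relatedness_annotation(gi_similarity = pairs)
  out <- functional_relatedness_test(c("k1", "k2"),
                                     list("m1", "m2"), ann,
                                     "gi_profile_similarity",
                                     n_shuffles = 100, seed = 2)
  expect_equal(out$observed, mean(c(0.9, 0.1)))
  # an empty annotation table for the requested measure is an error
  expect_error(functional_relatedness_test(
    c("k1", "k2"), list("m1", "m2"), relatedness_annotation(),
    "co_complex"), "coverage")
})

test_that("promoter windows and the enrichment binomial test", {
  genes <- data.frame(chrom = "c1",
                      start = c(1000, 1400, 5000),
                      end = c(1200, 1600, 5300),
                      strand = c("+", "+", "-"))
  # windows: [500,999], [900,1399] (overlap merges to [500,1399]: 900 bp),
  # minus-strand gene: [5301,5800]: 500 bp => 1400 bp of 10000
  fr <- promoter_fraction(genes, c(c1 = 10000), window = 500)
  expect_equal(fr, 1400 / 10000)

  out <- promoter_enrichment(rep(c(TRUE, FALSE), c(10, 90)), 0.1)
  expect_gt(out$p, 0.99)
  expect_lt(promoter_enrichment(rep(FALSE, 100), 0.1)$p, 1e-4)
  all_in <- promoter_enrichment(rep(TRUE, 100), 0.5)
  expect_equal(all_in$p, min(1, 2 * 0.5^100), tolerance = 1e-6)
  expect_error(promoter_enrichment(logical(0), 0.1), "no mutations")
})

test_that("paralog rule requires all four alignment criteria", {
  rec <- data.frame(
    gene1 = c("RPL6A", "p2", "p3", "p4", "p5"),
    gene2 = c("RPL6B", "q2", "q3", "q4", "q5"),
    evalue = c(1e-9, 1e-9, 1e-7, 1e-9, 1e-9),
    aln_length = c(150, 90, 200, 200, 200),
    similarity = c(94, 50, 50, 20, 50),
    transposon1 = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    transposon2 = FALSE)
  out <- paralog_filter(rec)
  # only the ribosomal-duplicate-style pair survives: high identity,
  # long alignment, strong E-value, no transposon
  expect_equal(out$gene1, "RPL6A")

  rec$evalue[2] <- NA
  expect_message(out2 <- paralog_filter(rec), "rejected")
  expect_equal(nrow(out2), 1L)
})
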