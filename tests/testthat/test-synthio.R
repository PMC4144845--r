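test_that("generators are pure functions of parameters and seed", {
  p <- evolution_sim_params(n_genotypes = 6, n_controls = 5, seed = 99)
  expect_identical(simulate_evolution_experiment(p),
                   simulate_evolution_experiment(p))

  lay <- data.frame(plate = "p", row = 0:1, col = 0, strain = c("a", "b"),
                    role = "sample")
  expect_identical(simulate_growth_plate(lay, c(a = 0.3, b = 0.2),
                                         noise_sd = 0.05, seed = 4),
                   simulate_growth_plate(lay, c(a = 0.3, b = 0.2),
                                         noise_sd = 0.05, seed = 4))

  expect_identical(simulate_mutation_tables(5, seed = 3, n_orfs = 20,
                                            orf_length = 300),
                   simulate_mutation_tables(5, seed = 3, n_orfs = 20,
                                            orf_length = 300))

  expect_identical(simulate_expression_triplets(n_genes = 100, n_de = 10,
                                                seed = 5),
                   simulate_expression_triplets(n_genes = 100, n_de = 10,
                                                seed = 5))

  gi_args <- list(n_genes = 60, partners_per_gene = 10, seed = 6)
  expect_identical(do.call(simulate_gi_map, gi_args),
                   do.call(simulate_gi_map, gi_args))
})

test_that("parameter validation rejects impossible experiments", {
  expect_error(evolution_sim_params(initial_fitness_range = c(0, 0.9)),
               "0 < low")
  expect_error(evolution_sim_params(initial_fitness_range = c(0.9, 0.5)),
               "0 < low")
  expect_error(evolution_sim_params(replicates = 3), ">= 4")
  expect_error(evolution_sim_params(timepoints_days = c(26, 104)),
               "start at 0")
  expect_error(evolution_sim_params(compensable_fraction = 1.2), "\\[0, 1\\]")
})

test_that("noise-free compensable lines reach their constructed final fitness", {
  p <- evolution_sim_params(n_genotypes = 3, lines_per_genotype = 2,
                            n_controls = 4,
                            initial_fitness_range = c(0.7, 0.7),
                            compensable_fraction = 1,
                            compensation_effect = c(0.3, 0),
                            replicate_noise_sd = 0, line_drift_sd = 0,
                            seed = 1)
  sim <- simulate_evolution_experiment(p)
  final <- sim$fitness[sim$fitness$role == "deletion" &
                         sim$fitness$day == 104, ]
  expect_true(all(final$fitness == 1.0))
  day0 <- sim$fitness[sim$fitness$role == "deletion" & sim$fitness$day == 0, ]
  expect_true(all(day0$fitness == 0.7))
  # trajectory is monotone and saturating: per-interval gains decrease
  tr <- sim$truth$trajectories
  one <- tr[tr$strain == "g0001" & tr$line == "l1", ]
  gains <- diff(one$true_fitness[order(one$day)])
  expect_true(all(gains > 0))
  expect_true(all(diff(gains) < 0))
})

test_that("ground truth and emitted tables agree when noise is zero", {
  p <- evolution_sim_params(n_genotypes = 4, n_controls = 4,
                            replicate_noise_sd = 0, seed = 21)
  sim <- simulate_evolution_experiment(p)
  m <- merge(sim$fitness, sim$truth$trajectories,
             by = c("strain", "line", "role", "day"))
  expect_equal(m$fitness, m$true_fitness)
})

test_that("growth plates emit one logistic curve per inoculated well", {
  lay <- expand.grid(row = 0:15, col = 0:23)
  lay$plate <- "P1"
  lay$role <- "sample"
  lay$role[c(1, 100, 200, 384)] <- "empty"
  lay$strain <- ifelse(lay$role == "empty", NA, "s1")
  od <- simulate_growth_plate(lay, c(s1 = 0.3), noise_sd = 0, seed = 1)
  wells <- unique(od[c("row", "col")])
  expect_equal(nrow(wells), 380L)

  # noise-free default curve: the estimator recovers the rate within 1%
  one <- simulate_growth_plate(
    data.frame(plate = "p", row = 0, col = 0, strain = "s", role = "sample"),
    c(s = 0.42), noise_sd = 0)
  fit <- estimate_growth_rate(one$time_min, one$od, blank = one$blank[1])
  expect_lt(abs(fit$rate - 0.42) / 0.42, 0.01)

  expect_error(simulate_growth_plate(
    data.frame(plate = "p", row = 0, col = 0, strain = "s", role = "sample"),
    c(s = -0.1)), "negative")
})

test_that("simulated plates flow through normalization to known fitness", {
  lay <- expand.grid(row = 0:3, col = 0:3)
  lay$plate <- "p"
  lay$role <- ifelse(lay$col %% 2 == 0, "reference", "sample")
  lay$strain <- ifelse(lay$role == "reference", "wt_ref", "mut")
  od <- simulate_growth_plate(lay, c(wt_ref = 0.35, mut = 0.28),
                              noise_sd = 0, seed = 2)
  rates <- estimate_plate_rates(od)
  norm <- normalize_by_neighbors(rates, lay)
  got <- norm$normalized_rate[norm$role == "sample"]
  expect_equal(mean(got), 0.8, tolerance = 0.01)
})

test_that("mutation counts follow their Poisson means", {
  sim <- simulate_mutation_tables(n_lines = 400, n_orfs = 30,
                                  orf_length = 300, seed = 8)
  per_line <- table(factor(sim$mutations$line[sim$mutations$class == "snp"],
                           levels = sim$genotypes$line))
  expect_equal(mean(per_line), 6, tolerance = 3 * sqrt(6 / 400) / 6)
  indels <- table(factor(sim$mutations$line[sim$mutations$class == "indel"],
                         levels = sim$genotypes$line))
  expect_lt(abs(mean(indels) - 0.5), 3 * sqrt(0.5 / 400))
  # SNP records are single-base; coding effects come from the codon table
  snps <- sim$mutations[sim$mutations$class == "snp", ]
  expect_true(all(nchar(snps$ref) == 1 & nchar(snps$alt) == 1))
  expect_true(all(snps$effect %in% c("synonymous", "nonsynonymous",
                                     "nonsense")))
  # recomputing one effect from the ORF agrees with the table
  s1 <- snps[1, ]
  orf <- sim$orfs[[s1$gene]]
  off <- s1$pos - sim$genes$start[sim$genes$gene == s1$gene] + 1
  expect_equal(substr(orf, off, off), s1$ref)
})

test_that("functional bias lands mutations in related genes", {
  unbiased <- simulate_mutation_tables(n_lines = 60, n_orfs = 60,
                                       functional_bias = 0, seed = 10)
  biased <- simulate_mutation_tables(n_lines = 60, n_orfs = 60,
                                     functional_bias = 0.8, seed = 10)
  hit_rate <- function(sim) {
    snps <- sim$mutations[sim$mutations$class == "snp", ]
    rel <- mapply(function(g, ko) g %in% sim$related_sets[[ko]],
                  snps$gene, snps$genotype)
    mean(rel)
  }
  expect_gt(hit_rate(biased), hit_rate(unbiased) + 0.4)
})

test_that("expression triplets encode the requested restoration", {
  full <- simulate_expression_triplets(n_genes = 500, n_de = 50,
                                       restoration_fraction = 1,
                                       replicate_sd = 1e-4, seed = 11)
  out <- restoration_fractions(full$wt, full$anc, full$evo, bio = full$bio)
  expect_equal(unname(out$fractions["restored"]), 1)

  none <- simulate_expression_triplets(n_genes = 500, n_de = 50,
                                       restoration_fraction = 0,
                                       replicate_sd = 1e-4, seed = 12)
  out0 <- restoration_fractions(none$wt, none$anc, none$evo, bio = none$bio)
  expect_equal(unname(out0$fractions["restored"]), 0)

  # full restoration means the evolved profile sits on the wild type
  tri <- distance_triangle(full$wt, full$anc, full$evo, bio = full$bio)
  expect_lt(tri$distances["evo_wt"], 0.01)

  expect_error(simulate_expression_triplets(restoration_fraction = 1.5),
               "\\[0, 1\\]")
  expect_error(simulate_expression_triplets(n_genes = 10, n_de = 20),
               "n_de")
})

test_that("colony plates carry the requested replicate structure", {
  strains <- data.frame(strain = c("g1", "g1"), line = c("L1", "L1"),
                        day = c(0, 104))
  cp <- simulate_colony_plates(strains, c("YPD", "E1"),
                               matrix(1, 2, 2), seed = 13)
  counts <- table(cp$colonies$strain, cp$colonies$environment,
                  cp$colonies$day)
  expect_true(all(counts["g1", , ] == 4))
  # noise and gradient off: normalized sizes equal the true effects
  cp2 <- simulate_colony_plates(strains, "YPD", matrix(c(1.3, 0.7), 2, 1),
                                noise_sd = 0, seed = 14)
  nc <- normalize_colony_sizes(cp2$colonies)
  expect_equal(unique(nc$normalized_size[nc$day %in% 0]), 1.3,
               tolerance = 1e-9)
  expect_equal(unique(nc$normalized_size[nc$day %in% 104]), 0.7,
               tolerance = 1e-9)
})

test_that("the GI generator plants exactly the suppression rule", {
  gi <- simulate_gi_map(n_genes = 300, partners_per_gene = 40, seed = 15)
  out <- find_suppressors(gi$records)
  expect_identical(out$records$suppressor, gi$truth$pairs$suppressor)

  # constant link: suppressor fraction unrelated to fitness
  flat <- simulate_gi_map(n_genes = 800, partners_per_gene = 100,
                          suppression_link = function(f) rep(0.1, length(f)),
                          seed = 16)
  sc <- suppression_fitness_correlation(find_suppressors(flat$records)$per_gene)
  expect_lt(abs(sc$rho), 0.1)
})

test_that("OD tables round-trip through the readers", {
  lay <- data.frame(plate = "p", row = c(0, 0), col = c(0, 1),
                    strain = c("wt", "m"), role = c("reference", "sample"))
  od <- simulate_growth_plate(lay, c(wt = 0.3, m = 0.25), noise_sd = 0.01,
                              seed = 17)
  f_od <- withr::local_tempfile(fileext = ".tsv")
  f_lay <- withr::local_tempfile(fileext = ".tsv")
  write.table(od[c("plate", "row", "col", "time_min", "od", "blank")],
              f_od, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(lay, f_lay, sep = "\t", quote = FALSE, row.names = FALSE)
  od2 <- read_od_table(f_od)
  lay2 <- read_layout(f_lay)
  expect_equal(od2$od, od$od, tolerance = 1e-9)
  expect_identical(lay2$role, lay$role)
  # A1-style labels are accepted too
  lay_a1 <- data.frame(plate = "p", well = c("A1", "A2"),
                       strain = c("wt", "m"), role = c("reference", "sample"))
  write.table(lay_a1, f_lay, sep = "\t", quote = FALSE, row.names = FALSE)
  lay3 <- read_layout(f_lay)
  expect_equal(lay3$row, c(0L, 0L))
  expect_equal(lay3$col, c(0L, 1L))
})
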