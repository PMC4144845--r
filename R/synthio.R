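#' Parameters for a simulated compensatory-evolution experiment
#'
#' Defaults emulate the structure of the laboratory evolution study the
#' pipeline targets: 187 slow-growing deletion genotypes with 4
#' independently evolving replicate lines each, 22 evolving wild-type
#' control lineages, fitness measured at days 0/26/52/78/104 with 6
#' technical replicates.  Fitness gains decompose into a medium-adaptation
#' ("drift") component drawn once per genotype or control lineage, and a
#' compensation component for compensable genotypes.  Drawing the drift at
#' the lineage level (rather than per line) makes null genotypes
#' exchangeable with single control lineages, so the control-derived
#' improvement cutoff retains its nominal error rate at the genotype level;
#' it also reproduces the strong all-or-none genotype specificity seen in
#' such experiments.
#'
#' @param n_genotypes number of deletion genotypes.
#' @param lines_per_genotype independently evolving lines per genotype.
#' @param n_controls evolving wild-type control lineages.
#' @param timepoints_days measurement days; must start at 0 and include a
#'   final day.
#' @param initial_fitness_range `(low, high)` of the uniform distribution
#'   of initial relative fitness of deletion genotypes; `0 < low <= high
#'   < 1`.
#' @param control_drift mean total fitness improvement of control lineages
#'   (fraction; the medium-adaptation gain).
#' @param control_drift_sd between-lineage SD of the drift gain.
#' @param line_drift_sd extra per-line SD of the drift gain within a
#'   genotype.
#' @param compensable_fraction probability that a genotype is compensable.
#' @param compensable_link optional function mapping initial fitness to the
#'   probability of being compensable (overrides `compensable_fraction`);
#'   use a decreasing function to emulate the observed excess of
#'   compensation among strongly deleterious deletions.
#' @param compensation_effect `(mean, sd)` of the total absolute fitness
#'   recovery of each line of a compensable genotype.
#' @param replicate_noise_sd SD of technical-replicate noise on observed
#'   fitness.
#' @param replicates technical replicates per line per timepoint (>= 4).
#' @param seed RNG seed.
#' @return validated parameter list of class `evolution_sim_params`.
#' @export
evolution_sim_params <- function(n_genotypes = 187, lines_per_genotype = 4,
                                 n_controls = 22,
                                 timepoints_days = c(0, 26, 52, 78, 104),
                                 initial_fitness_range = c(0.5, 0.9),
                                 control_drift = 0.05,
                                 control_drift_sd = 0.02,
                                 line_drift_sd = 0.005,
                                 compensable_fraction = 0.68,
                                 compensable_link = NULL,
                                 compensation_effect = c(0.22, 0.08),
                                 replicate_noise_sd = 0.02,
                                 replicates = 6, seed = 1) {
  if (!(initial_fitness_range[1] > 0 &&
        initial_fitness_range[1] <= initial_fitness_range[2] &&
        initial_fitness_range[2] < 1))
    stop("initial_fitness_range must satisfy 0 < low <= high < 1")
  if (replicates < 4)
    stop("replicates must be >= 4")
  if (timepoints_days[1] != 0 || length(timepoints_days) < 2)
    stop("timepoints_days must start at 0 and include a final day")
  if (compensable_fraction < 0 || compensable_fraction > 1)
    stop("compensable_fraction must be in [0, 1]")
  if (replicate_noise_sd < 0 || control_drift_sd < 0 || line_drift_sd < 0)
    stop("standard deviations must be non-negative")
  structure(list(n_genotypes = n_genotypes,
                 lines_per_genotype = lines_per_genotype,
                 n_controls = n_controls,
                 timepoints_days = sort(timepoints_days),
                 initial_fitness_range = initial_fitness_range,
                 control_drift = control_drift,
                 control_drift_sd = control_drift_sd,
                 line_drift_sd = line_drift_sd,
                 compensable_fraction = compensable_fraction,
                 compensable_link = compensable_link,
                 compensation_effect = compensation_effect,
                 replicate_noise_sd = replicate_noise_sd,
                 replicates = replicates, seed = seed),
            class = "evolution_sim_params")
}

# Saturating approach to the line's final gain: ~95% of the gain is realized
# by the final day's scale, normalized so the full gain is reached exactly at
# the final day.
.trajectory <- function(f0, gain, days) {
  T <- days[length(days)]
  f0 + gain * (1 - exp(-3 * days / T)) / (1 - exp(-3))
}

#' Simulate a compensatory-evolution experiment
#'
#' Emits replicate-level relative-fitness observations for every line and
#' timepoint of a simulated experiment, alongside the ground truth.
#' Control lineages gain their medium-adaptation drift; lines of
#' compensable genotypes additionally recover `compensation_effect` of
#' absolute fitness by the final day; all trajectories approach their final
#' value along a saturating curve.
#'
#' @param params an [evolution_sim_params()] object.
#' @return list with
#'   \describe{
#'     \item{fitness}{data frame `strain`, `line`, `role`
#'       (`deletion`/`control`), `day`, `replicate`, `fitness`;}
#'     \item{truth}{list with `genotypes` (per-genotype `f0`, `compensable`,
#'       `drift`), `lines` (per-line total `gain`) and `trajectories`
#'       (per-line true fitness per day).}
#'   }
#' @export
simulate_evolution_experiment <- function(params) {
  stopifnot(inherits(params, "evolution_sim_params"))
  p <- params
  set.seed(p$seed)
  days <- p$timepoints_days

  gid <- sprintf("g%04d", seq_len(p$n_genotypes))
  f0 <- runif(p$n_genotypes, p$initial_fitness_range[1],
              p$initial_fitness_range[2])
  p_comp <- if (is.null(p$compensable_link)) p$compensable_fraction
            else pmin(pmax(p$compensable_link(f0), 0), 1)
  compensable <- runif(p$n_genotypes) < p_comp
  drift_g <- rnorm(p$n_genotypes, p$control_drift, p$control_drift_sd)

  lines <- expand.grid(line = sprintf("l%d", seq_len(p$lines_per_genotype)),
                       genotype = gid, stringsAsFactors = FALSE)[, 2:1]
  gi <- match(lines$genotype, gid)
  # drift is a fractional improvement, so the absolute gain scales with the
  # line's initial fitness; the compensation effect is an absolute recovery
  gain <- ifelse(compensable[gi],
                 rnorm(nrow(lines), p$compensation_effect[1],
                       p$compensation_effect[2]),
                 f0[gi] * (drift_g[gi] + rnorm(nrow(lines), 0, p$line_drift_sd)))
  lines$gain <- gain
  lines$f0 <- f0[gi]
  lines$compensable <- compensable[gi]

  ctl <- data.frame(line = sprintf("c%02d", seq_len(p$n_controls)),
                    stringsAsFactors = FALSE)
  ctl$gain <- rnorm(p$n_controls, p$control_drift, p$control_drift_sd)

  traj_del <- do.call(rbind, lapply(seq_len(nrow(lines)), function(i)
    data.frame(strain = lines$genotype[i], line = lines$line[i],
               role = "deletion", day = days,
               true_fitness = .trajectory(lines$f0[i], lines$gain[i], days),
               stringsAsFactors = FALSE)))
  traj_ctl <- do.call(rbind, lapply(seq_len(nrow(ctl)), function(i)
    data.frame(strain = "evolving_WT", line = ctl$line[i], role = "control",
               day = days,
               true_fitness = .trajectory(1, ctl$gain[i], days),
               stringsAsFactors = FALSE)))
  traj <- rbind(traj_del, traj_ctl)

  obs <- traj[rep(seq_len(nrow(traj)), each = p$replicates), ]
  obs$replicate <- rep(seq_len(p$replicates), nrow(traj))
  obs$fitness <- obs$true_fitness +
    rnorm(nrow(obs), 0, p$replicate_noise_sd)
  obs$true_fitness <- NULL
  rownames(obs) <- NULL

  list(fitness = obs,
       truth = list(genotypes = data.frame(genotype = gid, f0 = f0,
                                           compensable = compensable,
                                           drift = drift_g,
                                           stringsAsFactors = FALSE),
                    lines = lines, controls = ctl, trajectories = traj))
}

#' Collapse simulated replicate observations into fitness tables
#'
#' Builds the deletion and control fitness tables consumed by
#' [compensation_analysis()] from the replicate-level output of
#' [simulate_evolution_experiment()], using [relative_fitness()] (values
#' are already normalized, so the wild-type denominator is 1; day-0
#' replicates are pooled within genotype).
#'
#' @param sim output of [simulate_evolution_experiment()].
#' @return list with `fitness` (deletion lines) and `control` tables.
#' @export
sim_fitness_tables <- function(sim) {
  obs <- sim$fitness
  unit_wt <- data.frame(day = unique(obs$day), rate = 1)
  del <- obs[obs$role == "deletion", c("strain", "line", "day", "fitness")]
  ctl <- obs[obs$role == "control", c("strain", "line", "day", "fitness")]
  names(del)[4] <- names(ctl)[4] <- "rate"
  list(fitness = relative_fitness(del, unit_wt),
       control = relative_fitness(ctl, unit_wt))
}

#' Simulate plate-reader OD growth curves
#'
#' Each non-empty well follows a logistic growth curve with the well's true
#' rate, on top of a blank offset, with multiplicative measurement noise.
#' Wells with role `empty` carry no culture and are not emitted (set
#' `include_empty = TRUE` to emit them at blank level).
#'
#' @param layout data frame `plate`, `row`, `col`, `strain`, `role`
#'   (`sample`/`reference`/`empty`).
#' @param true_rates named numeric vector of per-hour growth rates by
#'   strain, or a numeric vector aligned with `layout` rows; all positive.
#' @param noise_sd SD of multiplicative (log-scale) OD noise.
#' @param seed RNG seed.
#' @param times_min measurement times in minutes.
#' @param od0 inoculum density (blank-corrected OD); small relative to `K`
#'   so the early phase is exponential.
#' @param K carrying capacity (OD units).
#' @param blank baseline OD of medium without cells.
#' @param include_empty emit flat blank-level series for empty wells.
#' @return long data frame `plate`, `row`, `col`, `strain`, `role`,
#'   `time_min`, `od`, `blank`.
#' @export
simulate_growth_plate <- function(layout, true_rates, noise_sd = 0,
                                  seed = 1,
                                  times_min = seq(0, 1440, by = 20),
                                  od0 = 0.005, K = 1.5, blank = 0.05,
                                  include_empty = FALSE) {
  stopifnot(all(c("plate", "row", "col", "strain", "role") %in%
                  names(layout)))
  set.seed(seed)
  wells <- if (include_empty) layout
           else layout[layout$role != "empty", , drop = FALSE]
  if (is.null(names(true_rates)) && length(true_rates) == nrow(layout))
    names(true_rates) <- paste(layout$plate, layout$row, layout$col,
                               sep = "\r")
  out <- vector("list", nrow(wells))
  for (i in seq_len(nrow(wells))) {
    w <- wells[i, ]
    if (w$role == "empty") {
      od <- rep(blank, length(times_min))
    } else {
      r <- if (!is.null(names(true_rates)) &&
               w$strain %in% names(true_rates)) true_rates[[w$strain]]
           else true_rates[[paste(w$plate, w$row, w$col, sep = "\r")]]
      if (is.null(r) || is.na(r))
        stop("no true rate for strain ", w$strain)
      if (r < 0)
        stop("negative growth rate for strain ", w$strain)
      th <- times_min / 60
      n <- K * od0 * exp(r * th) / (K + od0 * (exp(r * th) - 1))
      if (noise_sd > 0)
        n <- n * exp(rnorm(length(n), 0, noise_sd))
      od <- blank + n
    }
    out[[i]] <- data.frame(plate = w$plate, row = w$row, col = w$col,
                           strain = w$strain, role = w$role,
                           time_min = times_min, od = od, blank = blank,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.random_orf <- function(n_codons, codons) {
  paste(sample(codons, n_codons, replace = TRUE), collapse = "")
}

#' Simulate per-line mutation tables over a synthetic ORF set
#'
#' Generates synthetic ORFs (uniform-random non-stop codons), a complex and
#' a functional-category annotation, a deleted gene per genotype, and per
#' line a Poisson number of point mutations and small indels.  With
#' probability `functional_bias` a point mutation targets a gene
#' functionally related to the line's deleted gene (sharing a complex or
#' category); otherwise the target gene is uniform over all genes other
#' than the deletion.  Coding effects are annotated by translating the
#' affected codon.
#'
#' @param n_lines number of evolved lines.
#' @param lines_per_genotype replicate lines per deletion genotype.
#' @param n_orfs number of synthetic genes.
#' @param orf_length ORF length in bp (rounded to a codon multiple).
#' @param snp_mean,indel_mean Poisson means of point mutations and indels
#'   per line.
#' @param functional_bias excess probability that a point mutation lands in
#'   a functionally related gene (0 = uniform).
#' @param complex_size,category_size genes per complex / category.
#' @param seed RNG seed.
#' @return list with `mutations` (data frame `line`, `genotype`, `chrom`,
#'   `pos`, `ref`, `alt`, `class`, `gene`, `effect`), `orfs` (named
#'   character vector), `genes` (coordinate table `gene`, `chrom`, `start`,
#'   `end`, `strand`), `annotation` (a [relatedness_annotation()]),
#'   `genotypes` (line to deleted gene) and `chrom_lengths`.
#' @export
simulate_mutation_tables <- function(n_lines, lines_per_genotype = 1,
                                     n_orfs = 200, orf_length = 900,
                                     snp_mean = 6, indel_mean = 0.5,
                                     functional_bias = 0,
                                     complex_size = 4, category_size = 8,
                                     seed = 1) {
  if (n_orfs < 2) stop("empty or degenerate ORF set")
  if (functional_bias < 0 || functional_bias > 1)
    stop("functional_bias must be in [0, 1]")
  set.seed(seed)
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)[code != "*"]
  n_codons <- max(orf_length %/% 3, 2)
  genes <- sprintf("g%04d", seq_len(n_orfs))
  orfs <- setNames(vapply(seq_len(n_orfs), function(i)
    .random_orf(n_codons, codons), ""), genes)

  spacing <- 200
  len <- n_codons * 3L
  starts <- spacing + (seq_len(n_orfs) - 1L) * (len + spacing) + 1L
  gene_tbl <- data.frame(gene = genes, chrom = "chrS", start = starts,
                         end = starts + len - 1L, strand = "+",
                         stringsAsFactors = FALSE)
  chrom_lengths <- c(chrS = max(gene_tbl$end) + spacing)

  complexes <- data.frame(gene = genes,
                          complex = paste0("cpx",
                                           (seq_len(n_orfs) - 1L) %/% complex_size),
                          stringsAsFactors = FALSE)
  # categories use an interleaved assignment so they cut across complexes
  n_cat <- max(n_orfs %/% category_size, 1L)
  categories <- data.frame(gene = genes,
                           category = paste0("cat",
                                             (seq_len(n_orfs) - 1L) %% n_cat),
                           stringsAsFactors = FALSE)
  ann <- relatedness_annotation(complexes = complexes,
                                categories = categories)
  related_sets <- lapply(seq_len(n_orfs), function(i) {
    same_cpx <- complexes$gene[complexes$complex == complexes$complex[i]]
    same_cat <- categories$gene[categories$category == categories$category[i]]
    setdiff(union(same_cpx, same_cat), genes[i])
  })
  names(related_sets) <- genes

  n_genotypes <- ceiling(n_lines / lines_per_genotype)
  ko <- sample(genes, n_genotypes, replace = n_genotypes > n_orfs)
  line_ids <- sprintf("L%03d", seq_len(n_lines))
  line_ko <- ko[((seq_len(n_lines) - 1L) %/% lines_per_genotype) + 1L]

  bases <- c("A", "C", "G", "T")
  gene_start <- setNames(gene_tbl$start, gene_tbl$gene)
  acc <- list(line = character(), genotype = character(), pos = integer(),
              ref = character(), alt = character(), class = character(),
              gene = character(), effect = character())
  add <- function(line, koi, pos, ref, alt, cls, gene, eff) {
    n <- length(acc$line) + 1L
    acc$line[n] <<- line; acc$genotype[n] <<- koi; acc$pos[n] <<- pos
    acc$ref[n] <<- ref; acc$alt[n] <<- alt; acc$class[n] <<- cls
    acc$gene[n] <<- gene; acc$effect[n] <<- eff
  }
  for (i in seq_len(n_lines)) {
    n_snp <- rpois(1, snp_mean)
    n_indel <- rpois(1, indel_mean)
    koi <- line_ko[i]
    pool <- setdiff(genes, koi)
    rel <- related_sets[[koi]]
    for (m in seq_len(n_snp + n_indel)) {
      is_snp <- m <= n_snp
      target <- if (is_snp && length(rel) > 0 &&
                    runif(1) < functional_bias) sample(rel, 1)
                else sample(pool, 1)
      s <- orfs[[target]]
      off <- sample.int(nchar(s), 1)
      refb <- substr(s, off, off)
      gpos <- gene_start[[target]] + off - 1L
      if (is_snp) {
        altb <- sample(setdiff(bases, refb), 1)
        cs <- ((off - 1L) %/% 3L) * 3L + 1L
        orig <- substr(s, cs, cs + 2L)
        mut <- orig
        substr(mut, (off - 1L) %% 3L + 1L, (off - 1L) %% 3L + 1L) <- altb
        aa0 <- code[[orig]]; aa1 <- code[[mut]]
        eff <- if (aa0 == aa1) "synonymous"
               else if (aa1 == "*") "nonsense" else "nonsynonymous"
        add(line_ids[i], koi, gpos, refb, altb, "snp", target, eff)
      } else {
        ins <- runif(1) < 0.5
        alt <- if (ins) paste0(refb, paste(sample(bases, 2, TRUE),
                                           collapse = ""))
               else substr(refb, 1, 1)
        ref <- if (ins) refb else paste0(refb, substr(s, off + 1L,
                                                      min(off + 2L, nchar(s))))
        add(line_ids[i], koi, gpos, ref, alt, "indel", target, "frameshift")
      }
    }
  }
  mutations <- data.frame(line = acc$line, genotype = acc$genotype,
                          chrom = rep("chrS", length(acc$line)),
                          pos = acc$pos, ref = acc$ref, alt = acc$alt,
                          class = acc$class, gene = acc$gene,
                          effect = acc$effect, stringsAsFactors = FALSE)
  list(mutations = mutations, orfs = orfs, genes = gene_tbl,
       annotation = ann,
       genotypes = data.frame(line = line_ids, ko = line_ko,
                              stringsAsFactors = FALSE),
       chrom_lengths = chrom_lengths, related_sets = related_sets)
}

#' Simulate wild-type / ancestor / evolved expression triplets
#'
#' The ancestor differs from wild type at `n_de` genes by `effect_log2`
#' (random sign); in the evolved profile a `restoration_fraction` of those
#' genes revert fully to the wild-type level, the rest stay at the ancestor
#' level.  Observed matrices add i.i.d. replicate noise; columns are
#' organized as 2 biological x `n_replicates/2` technical replicates.
#'
#' @param n_genes total genes.
#' @param n_de ancestor-DE genes (`n_de <= n_genes`).
#' @param effect_log2 absolute log2 effect of the ancestral change.
#' @param restoration_fraction fraction of ancestor-DE genes reverting in
#'   the evolved line, in `[0, 1]`.
#' @param replicate_sd replicate noise SD (log2 units).
#' @param n_replicates replicates per strain (>= 2; even values split into
#'   2 biological replicates).
#' @param seed RNG seed.
#' @return list with matrices `wt`, `anc`, `evo` (genes x replicates),
#'   `bio` (biological-replicate labels per column) and `truth` (per-gene
#'   `de`, `sign`, `restored`).
#' @export
simulate_expression_triplets <- function(n_genes = 6000, n_de = 300,
                                         effect_log2 = 2,
                                         restoration_fraction = 0.2,
                                         replicate_sd = 0.1,
                                         n_replicates = 4, seed = 1) {
  if (n_de > n_genes) stop("n_de must be <= n_genes")
  if (n_replicates < 2) stop("need at least 2 replicates per strain")
  if (restoration_fraction < 0 || restoration_fraction > 1)
    stop("restoration_fraction must be in [0, 1]")
  set.seed(seed)
  gene <- sprintf("y%05d", seq_len(n_genes))
  de <- seq_len(n_genes) <= n_de  # which genes respond to the deletion
  sgn <- ifelse(de, sample(c(-1, 1), n_genes, replace = TRUE), 0)
  n_restored <- round(restoration_fraction * n_de)
  restored <- de & seq_len(n_genes) <= n_restored

  mu_wt <- rep(0, n_genes)
  mu_anc <- sgn * effect_log2
  mu_evo <- ifelse(restored, 0, mu_anc)

  mk <- function(mu) {
    m <- matrix(rnorm(n_genes * n_replicates, mean = mu, sd = replicate_sd),
                n_genes, n_replicates)
    dimnames(m) <- list(gene, sprintf("rep%d", seq_len(n_replicates)))
    m
  }
  bio <- rep(1:2, each = ceiling(n_replicates / 2))[seq_len(n_replicates)]
  list(wt = mk(mu_wt), anc = mk(mu_anc), evo = mk(mu_evo), bio = bio,
       truth = data.frame(gene = gene, de = de, sign = sgn,
                          restored = restored, stringsAsFactors = FALSE))
}

#' Simulate colony-size plates across environments
#'
#' One 24 x 32 (768-position) plate per environment.  A reference strain
#' occupies a regular diagonal grid (every fourth position, spanning every
#' row and every column, as spatial correction requires); the remaining
#' positions carry `replicates` technical replicate colonies of each
#' strain-line-day entry, randomly placed, so ancestor and evolved
#' replicates of a genotype share the plate.  Colony size is the
#' strain-by-environment effect times a smooth positional bias
#' (exponential in the row/column coordinate) times lognormal noise.
#'
#' @param strains data frame with columns `strain`, `line`, `day`.
#' @param environments character vector of environment ids.
#' @param env_effects matrix of true relative sizes, `nrow(strains)` x
#'   `length(environments)`.
#' @param spatial_gradient named vector `c(row=, col=)`: total log-fold
#'   bias across the plate in each direction.
#' @param noise_sd lognormal noise SD.
#' @param replicates technical replicate colonies per entry (default 4).
#' @param reference_strain id given to reference colonies.
#' @param seed RNG seed.
#' @return list with `colonies` (data frame `plate`, `row`, `col`,
#'   `strain`, `line`, `day`, `environment`, `size`) and `truth`
#'   (`env_effects` as given).
#' @export
simulate_colony_plates <- function(strains, environments, env_effects,
                                   spatial_gradient = c(row = 0, col = 0),
                                   noise_sd = 0.1, replicates = 4,
                                   reference_strain = "reference",
                                   seed = 1) {
  stopifnot(all(c("strain", "line", "day") %in% names(strains)),
            nrow(env_effects) == nrow(strains),
            ncol(env_effects) == length(environments))
  set.seed(seed)
  nr <- 24L; nc <- 32L
  grid <- expand.grid(row = 0:(nr - 1L), col = 0:(nc - 1L))
  # diagonal reference grid: every 4th position, covering every row and column
  is_ref <- (grid$row + grid$col) %% 4L == 0L
  free <- which(!is_ref)
  need <- nrow(strains) * replicates
  if (need > length(free))
    stop("plate capacity exceeded: ", need, " colonies for ",
         length(free), " free positions")
  gr <- spatial_gradient[["row"]]; gc <- spatial_gradient[["col"]]
  bias <- function(row, col)
    exp(gr * (row / (nr - 1) - 0.5) + gc * (col / (nc - 1) - 0.5))

  out <- vector("list", length(environments))
  for (e in seq_along(environments)) {
    env <- environments[e]
    ref_idx <- which(is_ref)
    slots <- sample(free, need)
    entry <- rep(seq_len(nrow(strains)), each = replicates)
    rows <- c(grid$row[ref_idx], grid$row[slots])
    cols <- c(grid$col[ref_idx], grid$col[slots])
    strain <- c(rep(reference_strain, length(ref_idx)),
                strains$strain[entry])
    line <- c(rep(NA_character_, length(ref_idx)),
              as.character(strains$line[entry]))
    day <- c(rep(NA, length(ref_idx)), strains$day[entry])
    eff <- c(rep(1, length(ref_idx)), env_effects[entry, e])
    size <- eff * bias(rows, cols) *
      exp(rnorm(length(eff), 0, noise_sd))
    out[[e]] <- data.frame(plate = paste0("plate_", env), row = rows,
                           col = cols, strain = strain, line = line,
                           day = day, environment = env, size = size,
                           stringsAsFactors = FALSE)
  }
  list(colonies = do.call(rbind, out), truth = list(env_effects = env_effects))
}

#' Simulate a genetic-interaction map with planted suppression
#'
#' Single-deletion fitness values are uniform on `fitness_range`; each gene
#' A is paired with `partners_per_gene` other genes, and each pair is a
#' suppression interaction with probability `suppression_link(F_A)`.
#' Suppressor pairs are constructed to satisfy the suppression rule
#' (`F_A < F_B` and `F_AB > F_A + sigma_A`): the partner is drawn among
#' genes fitter than A and the double-mutant fitness is placed above the
#' threshold.  Non-suppressor pairs get multiplicative double-mutant
#' fitness, truncated below the threshold, so they never satisfy the rule.
#' A gene with no fitter partner available cannot be suppressed and the
#' planted flag is forced off.
#'
#' @param n_genes number of genes (the study's map covers 3880).
#' @param fitness_range `(low, high)` of single-deletion fitness.
#' @param suppression_link function mapping `F_A` to the per-pair
#'   suppression probability; must return values in `[0, 1]`.
#' @param partners_per_gene partners tested per gene.
#' @param seed RNG seed.
#' @return list with `records` (data frame `geneA`, `geneB`, `F_A`, `F_B`,
#'   `F_AB`, `sigma_A`, usable by [find_suppressors()]) and `truth`
#'   (per-pair planted `suppressor` flag, per-gene fitness and planted
#'   probability).
#' @export
simulate_gi_map <- function(n_genes = 3880, fitness_range = c(0.2, 1),
                            suppression_link = function(f) 0.01 + 0.4 * (1 - f)^2,
                            partners_per_gene = 400, seed = 1) {
  set.seed(seed)
  gene <- sprintf("G%04d", seq_len(n_genes))
  f <- runif(n_genes, fitness_range[1], fitness_range[2])
  sig <- runif(n_genes, 0.03, 0.05)
  ord <- order(f)        # ranks: fitness-sorted gene indices
  rank_of <- integer(n_genes); rank_of[ord] <- seq_len(n_genes)

  m <- partners_per_gene
  idxA <- rep(seq_len(n_genes), each = m)
  # partner sampled uniformly among the other genes
  idxB <- unlist(lapply(seq_len(n_genes), function(i) {
    b <- sample.int(n_genes - 1L, m, replace = m > n_genes - 1L)
    b + (b >= i)
  }))
  p_pair <- suppression_link(f[idxA])
  if (any(p_pair < 0 | p_pair > 1))
    stop("suppression_link must return probabilities in [0, 1]")
  supp <- runif(length(idxA)) < p_pair
  # suppressor pairs need a partner fitter than A
  n_higher <- n_genes - rank_of[idxA]
  supp[n_higher == 0L] <- FALSE
  if (any(supp)) {
    pick <- rank_of[idxA[supp]] +
      ceiling(runif(sum(supp)) * n_higher[supp])
    idxB[supp] <- ord[pick]
  }
  F_A <- f[idxA]; F_B <- f[idxB]; sigma_A <- sig[idxA]
  F_AB <- numeric(length(idxA))
  F_AB[supp] <- F_A[supp] + sigma_A[supp] + 0.02 +
    abs(rnorm(sum(supp), 0, sigma_A[supp]))
  ns <- !supp
  F_AB[ns] <- pmin(F_A[ns] * F_B[ns] + rnorm(sum(ns), 0, sigma_A[ns] / 2),
                   F_A[ns] + 0.5 * sigma_A[ns])
  F_AB <- pmax(F_AB, 0)

  list(records = data.frame(geneA = gene[idxA], geneB = gene[idxB],
                            F_A = F_A, F_B = F_B, F_AB = F_AB,
                            sigma_A = sigma_A, stringsAsFactors = FALSE),
       truth = list(pairs = data.frame(geneA = gene[idxA],
                                       geneB = gene[idxB],
                                       suppressor = supp,
                                       stringsAsFactors = FALSE),
                    genes = data.frame(gene = gene, fitness = f,
                                       sigma = sig,
                                       p_suppression = suppression_link(f),
                                       stringsAsFactors = FALSE)))
}
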