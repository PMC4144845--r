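# Small fixtures shared across test files; everything is generated in code.

# replicate-level fitness table rows in the relative_fitness() output format
make_fitness_row <- function(strain, line, day, reps) {
  d <- data.frame(strain = strain, line = line, day = day,
                  fitness = median(reps), n_replicates = length(reps),
                  stringsAsFactors = FALSE)
  d$replicate_rates <- I(list(reps))
  d
}

make_fitness_table <- function(...) {
  do.call(rbind, list(...))
}

# a line table for call_compensation()
make_line_tbl <- function(genotype, line, start, end) {
  d <- data.frame(genotype = genotype, line = line,
                  stringsAsFactors = FALSE)
  d$start_rates <- I(start)
  d$end_rates <- I(end)
  d
}

# naive per-site oracle for the nonsynonymous site probability: translate
# every codon before and after substitution, one site at a time
oracle_ns_site_probability <- function(ref, alt, orfs) {
  code <- Biostrings::GENETIC_CODE
  ns <- 0L; total <- 0L
  for (s in orfs) {
    s <- toupper(s)
    for (pos in seq_len(nchar(s))) {
      if (substr(s, pos, pos) != ref) next
      total <- total + 1L
      cs <- ((pos - 1) %/% 3) * 3 + 1
      codon <- substr(s, cs, cs + 2)
      mutated <- codon
      substr(mutated, (pos - 1) %% 3 + 1, (pos - 1) %% 3 + 1) <- alt
      if (code[[codon]] != code[[mutated]]) ns <- ns + 1L
    }
  }
  ns / total
}
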