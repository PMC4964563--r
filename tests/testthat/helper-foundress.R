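# Shared helpers for the test suite.

# small, fast parameter set for unit tests; dots override the defaults
tiny_params <- function(...) {
  args <- list(n_side = 20L, m = 40L, n_generations = 10L,
               r_cluster = 2, r_territory = 2)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(model_params, args)
}

# a fully suitable landscape (deterministic)
flat_landscape <- function(n_side = 10L) {
  generate_landscape(n_side, 1.0, seed = 1L)
}

# hand-built queen tibble on one cell
group_of <- function(phenotypes, row = 1L, col = 1L) {
  tibble::tibble(
    id = seq_along(phenotypes),
    phenotype = phenotypes,
    row = row, col = col,
    alive = TRUE
  )
}

# hand-built foundress records
make_records <- function(n, death_day, cause,
                         treatment = "pure_group",
                         population = "pleometrotic",
                         phenotype = "tolerant",
                         group_id = 1L) {
  tibble::tibble(
    queen_id = seq_len(n),
    group_id = rep_len(group_id, n),
    treatment = rep_len(treatment, n),
    population = rep_len(population, n),
    phenotype = rep_len(phenotype, n),
    death_day = rep_len(death_day, n),
    cause = rep_len(cause, n)
  )
}
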