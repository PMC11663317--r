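# cached simulated cohorts shared across test files (built once per run)
.c9_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.c9_cache[[name]])) assign(name, force(expr), envir = .c9_cache)
  .c9_cache[[name]]
}

# small six-individual cohort with explicit modal lengths, fast to analyse
small_config <- function(seed = 42, ...) {
  sim_config(
    n_individuals = 6,
    expanded_modal_length = c(80, 150, 300, 500, 900, 1400),
    reads_per_allele_range = c(6L, 10L),
    seed = seed,
    ...
  )
}

small_cohort <- function() cached("small", simulate_cohort(small_config()))

# the default study-scale cohort used by the acceptance checks
default_cohort <- function() {
  cached("default", simulate_cohort(sim_config(seed = 107)))
}

default_pipeline <- function() {
  cached("default_pipeline", {
    dir <- file.path(tempdir(), "c9methyl-default-pipeline")
    suppressMessages(run_pipeline(default_cohort(), dir, seed = 107))
  })
}

random_reads_table <- function(n, seed = 1) {
  set.seed(seed)
  lens <- sample(5:60, n, replace = TRUE) # straddles the 10 bp minimum
  lens[sample.int(n, max(1L, n %/% 200L))] <- 100001L + sample(-2:2, max(1L, n %/% 200L), replace = TRUE) # straddles the 100 kb maximum
  tibble::tibble(
    read_id = sprintf("r%05d", seq_len(n)),
    sequence = strrep("A", lens),
    n_passes = sample(0:15, n, replace = TRUE),
    predicted_accuracy = round(runif(n, 0.7, 1), 4),
    spans_left_flank = sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(.8, .2)),
    spans_right_flank = sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(.8, .2))
  )
}
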