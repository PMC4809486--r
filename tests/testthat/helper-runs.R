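# Shared Monte Carlo runs, computed once per test session. The heavier
# accuracy checks and the distributional property checks read the same
# runs, so the suite pays for each condition only once.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- fn()
  .run_cache[[key]]
}

# DRR, artificial dichotomy, the selection ratios of the tabulated accuracy
# cells (1000 iterations)
drr_artificial_cells <- function() {
  cached("drr_art_1000", function() {
    run_condition("DRR", "artificial", iterations = 1000L,
                  sr_grid = c(0.1, 0.4, 0.5), seed = 42L)
  })
}

# DRR, natural dichotomy, the high-selection-ratio precision cell
drr_natural_sr9 <- function() {
  cached("drr_nat_1000", function() {
    run_condition("DRR", "natural", iterations = 1000L, sr_grid = 0.9,
                  seed = 43L)
  })
}

# imputation-count study, natural dichotomy, 50% missing
prelim_half_missing <- function() {
  cached("prelim_1000", function() {
    preliminary_m_study("natural", missing_rates = 0.5,
                        m_values = c(5L, 20L, 50L), iterations = 1000L,
                        seed = 44L)
  })
}

# full selection-ratio grids at reduced repetitions, one per condition
condition_grid <- function(scenario, kind) {
  seeds <- c(DRR.artificial = 51L, DRR.natural = 52L,
             IRR.artificial = 53L, IRR.natural = 54L)
  key <- paste(scenario, kind, sep = ".")
  cached(key, function() {
    run_condition(scenario, kind, iterations = 500L, seed = seeds[[key]])
  })
}

accuracy_cell <- function(run, sr_val, method_val, estimator_val) {
  out <- dplyr::filter(run$accuracy, sr == sr_val, method == method_val,
                       estimator == estimator_val)
  stopifnot(nrow(out) == 1L)
  out
}
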