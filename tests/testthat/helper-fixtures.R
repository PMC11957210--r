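# Shared fixtures, built in code.

# tiny proteomics_matrix builder; single plate unless plate labels given
make_pm <- function(values, plate = NULL, scale_factor = NULL, lod = NULL) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("S%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("A%02d", seq_len(ncol(values)))
  if (is.null(plate)) plate <- rep("P1", nrow(values))
  proteomics_matrix(values, stats::setNames(plate, rownames(values)),
                    scale_factor = scale_factor, lod = lod)
}

# small simulated cohort shared across test files (computed once per run)
.fixture_env <- new.env()
tiny_cohort <- function() {
  if (is.null(.fixture_env$tc)) {
    cf <- sim_config(n_co = 150, n_ad = 100, n_analytes = 60, n_plates = 2,
                     fraction_nonnull = 0.05, effect_size_sd = 0.4, seed = 42)
    sim <- simulate_cohort(cf)
    z <- zscore_normalize(sim$matrix,
                          stats::setNames(sim$samples$dataset_cluster,
                                          sim$samples$sample_id))
    sim$z <- z
    .fixture_env$tc <- sim
  }
  .fixture_env$tc
}

# simple metadata table builder
make_samples <- function(n, status, age = NULL, sex = NULL, cohort = "C1",
                         cluster = "cl1") {
  data.frame(sample_id = sprintf("S%02d", seq_len(n)),
             age_at_draw = if (is.null(age)) rep(70, n) else age,
             sex = if (is.null(sex)) rep(c("female", "male"), length.out = n) else sex,
             cohort = cohort, dataset_cluster = cluster,
             clinical_status = status, stringsAsFactors = FALSE)
}
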