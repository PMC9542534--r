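# Shared fixtures, built in code.

# small 3-taxon count table with two runs and one blank-correctable run
toy_counts <- function() {
  m <- rbind(s1 = c(A = 100L, B = 10L, C = 500L),
             s2 = c(A = 60L,  B = 0L,  C = 300L),
             s3 = c(A = 80L,  B = 40L, C = 250L))
  lin <- data.frame(taxon = c("A", "B", "C"),
                    class = c("Ca", "Ca", "Cb"),
                    order = c("Oa", "Oa", "Ob"),
                    family = c("Fa", "Fa", "Fb"),
                    genus = c("A", "B", "C"), stringsAsFactors = FALSE)
  smp <- data.frame(sample_id = c("s1", "s2", "s3"),
                    run = c("run1", "run1", "run2"),
                    cohort = "HELMi", stringsAsFactors = FALSE)
  count_table(m, lin, smp)
}

toy_blanks <- function() {
  m <- rbind(b1 = c(A = 20L, B = 30L, C = 0L),
             b2 = c(A = 40L, B = 30L, C = 0L))
  lin <- toy_counts()$lineage
  smp <- data.frame(sample_id = c("b1", "b2"), run = "run1",
                    cohort = "HELMi", stringsAsFactors = FALSE)
  count_table(m, lin, smp)
}

# small simulated cohort reused across tests (two timepoints for speed)
small_sim <- function(seed = 11) {
  simulate_cohort(sim_config(
    n_infants_per_group = c(VD = 10, "VD-cep" = 4, "VD-pen" = 5,
                            "CS-cep" = 10, "CS-other" = 5),
    timepoints = c(4, 12), seed = seed))
}

# two-group cross-sectional design straight from a data.frame
flat_design <- function(df, exposure = "group") {
  df$age_weeks <- 1
  build_design(df, 1, exposure = exposure, covariates = character(0))
}
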