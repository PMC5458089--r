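# Shared fixtures. Expensive simulations are computed once per test run and
# cached; every consumer sees the identical object.

.tf_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .tf_cache, inherits = FALSE))
    assign(key, expr, envir = .tf_cache)
  get(key, envir = .tf_cache, inherits = FALSE)
}

default_model <- function(glucose_mM = 500) {
  m <- cached("model_limonene_500", build_full_system("limonene", glucose_mM = 500))
  if (glucose_mM != 500) m <- set_initial(m, "Glc", glucose_mM)
  m
}

# the long 500 mM batch run driven to completion
completion_run <- function() {
  cached("tc_500_completion",
         simulate_timecourse(default_model(), t_end = 5.5e5, n_out = 151))
}

# day-scale 200 mM ground truth reused by the synthetic-data tests
day_scale_truth <- function() {
  cached("tc_200_days",
         simulate_timecourse(set_initial(default_model(), "Glc", 200),
                             times = (0:5) * 86400))
}

# independent element/moiety bookkeeping straight from the shipped tables,
# bypassing the package's stoichiometric-matrix machinery
raw_tables <- function() {
  cached("raw_tables", {
    sp <- utils::read.csv(system.file("extdata", "species.csv",
                                      package = "terpflux"))
    rx <- utils::read.csv(system.file("extdata", "reactions.csv",
                                      package = "terpflux"))
    list(species = sp, reactions = rx)
  })
}

# parse one equation side-by-side with plain string handling (oracle use)
oracle_parse_side <- function(side) {
  out <- c()
  for (tm in trimws(strsplit(side, "+", fixed = TRUE)[[1]])) {
    bits <- strsplit(tm, " ")[[1]]
    if (length(bits) == 2) out[bits[2]] <- as.numeric(bits[1])
    else out[bits] <- 1
  }
  out
}
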