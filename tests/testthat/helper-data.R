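# shared fixtures, computed once per test session

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache, inherits = FALSE)
}

# the reference synthetic study: 6 regions x 60 samples, 300 genes,
# one 10-gene module per region at loading 0.95
ref_sim <- function() cached("ref_sim", simulate_gem(sim_config()))

ref_gem <- function() cached("ref_gem", preprocess_gem(ref_sim()$gem)$gem)

ref_scan <- function() cached("ref_scan", similarity_scan(ref_gem(), seed = 1))

ref_informative <- function() sort(unlist(ref_sim()$truth$informative_genes))

ref_background <- function() {
  setdiff(rownames(ref_gem()$values), ref_informative())
}

# a small study for fast unit tests: 3 regions x 40 samples, 60 genes,
# one 6-gene module per region
small_config <- function() {
  sim_config(n_regions = 3, samples_per_region = 40, n_genes = 60,
             module_size = 6, tumors_per_type = 40,
             enriched_sets = list(list(genes = 1:18, multiplier = 5)),
             seed = 42L)
}

small_sim <- function() cached("small_sim", simulate_gem(small_config()))

small_gem <- function() cached("small_gem", preprocess_gem(small_sim()$gem)$gem)

small_informative <- function() sort(unlist(small_sim()$truth$informative_genes))
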