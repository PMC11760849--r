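# Shared fixtures, built once per test run and memoised. The default
# simulation spec defines the study conditions; the bundle runs the whole
# pipeline on it (with a shortened LD scan to keep the run brisk).

.shared <- new.env(parent = emptyenv())

shared_spec <- function() sim_spec()

shared_reference <- function() {
  if (is.null(.shared$reference))
    .shared$reference <- generate_reference(shared_spec())
  .shared$reference
}

shared_candidates <- function() {
  if (is.null(.shared$candidates))
    .shared$candidates <- enumerate_coding_candidates(shared_reference())
  .shared$candidates
}

shared_bundle <- function() {
  if (is.null(.shared$bundle)) {
    cfg <- pipeline_config(spec = shared_spec(),
                           ld_max_dist = 50000L, ld_bin_width = 5000L)
    .shared$bundle <- run_pipeline(cfg, reference = shared_reference(),
                                   candidates = shared_candidates())
  }
  .shared$bundle
}

## Rebuild a sim_spec with field overrides (validation re-applied).
spec_with <- function(...) {
  args <- list(...)
  spec <- shared_spec()
  for (nm in names(args)) spec[[nm]] <- args[[nm]]
  class(spec) <- "sim_spec"
  rohload:::validate_sim_spec(spec)
  spec
}

null_effects <- function() list(lof_daf_mult = 1, hom_missense_boost = 0,
                                roh_missense_boost = 1)
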