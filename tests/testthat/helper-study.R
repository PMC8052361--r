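# The desk-scale training study is expensive (minutes), so the two acceptance
# tests that need it share one memoised run under a fixed seed.
study_cache <- new.env(parent = emptyenv())

get_desk_study <- function() {
  if (is.null(study_cache$run)) {
    study_cache$run <- run_desk_study(seed = 1L, verbose = FALSE)
  }
  study_cache$run
}
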