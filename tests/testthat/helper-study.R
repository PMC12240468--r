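# Lazily computed planted-signature benchmark shared by the acceptance
# tests (training Model 1 once and attacking it in both swarm modes is the
# expensive part; the correlation checks reuse the same result).

.study_cache <- new.env(parent = emptyenv())

get_benchmark <- function() {
  if (is.null(.study_cache$res)) {
    .study_cache$res <- run_planted_benchmark(seed = 1L)
  }
  .study_cache$res
}
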