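# Shared cache for the expensive developmental-learning runs: the body-map
# experiment trains one cortex per (seed, condition); the multimodal
# experiment probes the same trained networks.
the_cache <- new.env(parent = emptyenv())

bodymap_cached <- function() {
  if (is.null(the_cache$bodymap)) {
    the_cache$bodymap <- run_bodymap_experiment(
      seeds = 1:10, duration = 100, visual = TRUE, return_nets = TRUE)
  }
  the_cache$bodymap
}

trained_nets_cached <- function() {
  rep <- bodymap_cached()
  lapply(rep$per_seed, function(p)
    list(intra = p$intra$net, extra = p$extra$net))
}
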