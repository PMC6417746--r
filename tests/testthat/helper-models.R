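# The three named coupling configurations examined throughout, plus their
# reference sodium conductances (computed once per test run and cached).

weak_model   <- function(...) two_cpt_model(coupling(0.3, 0.2), ...)
fwd_model    <- function(...) two_cpt_model(coupling(0.8, 0.2), ...)
strong_model <- function(...) two_cpt_model(coupling(0.8, 0.7), ...)

.gna_ref_cache <- new.env(parent = emptyenv())

cached_gna_ref <- function(model) {
  key <- paste(model$coupling$kfwd, model$coupling$kback,
               model$klt_placement, model$klt_mode, model$klt_fraction,
               sep = "_")
  if (is.null(.gna_ref_cache[[key]]))
    .gna_ref_cache[[key]] <- find_gna_ref(model)
  .gna_ref_cache[[key]]
}
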