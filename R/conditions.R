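# Structured conditions used across the package. Each helper both constructs
# and signals the condition so call sites stay one-liners.

stop_synfuse <- function(class, message, call = sys.call(-1), ...) {
  cond <- structure(
    class = c(class, "synfuse_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
  stop(cond)
}

warn_synfuse <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "synfuse_warning", "warning", "condition"),
    list(message = message, call = NULL, ...)
  )
  warning(cond)
}

stop_invalid_smiles <- function(smiles, detail = NULL) {
  msg <- sprintf("invalid SMILES: %s", paste(smiles, collapse = ", "))
  if (!is.null(detail)) msg <- paste0(msg, " (", detail, ")")
  stop_synfuse("invalid_smiles_error", msg, smiles = smiles)
}

stop_domain <- function(message) stop_synfuse("domain_error", message)

stop_shape <- function(message) stop_synfuse("shape_error", message)

stop_empty_intersection <- function(message) {
  stop_synfuse("empty_intersection_error", message)
}

stop_insufficient_entities <- function(message) {
  stop_synfuse("insufficient_entities_error", message)
}

stop_data_coverage <- function(message) stop_synfuse("data_coverage_error", message)

stop_degenerate_input <- function(message) {
  stop_synfuse("degenerate_input_error", message)
}

stop_unknown_variant <- function(variant) {
  stop_synfuse("unknown_variant_error",
               sprintf("unknown ablation variant '%s'", variant))
}

stop_vocabulary_exhausted <- function(requested, available) {
  stop_synfuse("vocabulary_exhausted_error",
               sprintf("requested %d drugs but the vocabulary holds %d",
                       requested, available))
}

warn_degenerate_molecule <- function(message) {
  warn_synfuse("degenerate_molecule_warning", message)
}
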