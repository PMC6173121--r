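# Shared fixtures: all built in code, nothing read from outside the
# package's own bundled data.

# a deliberately tiny schema for unit tests that should not depend on
# the full bundled catalogue
mini_schema <- function() {
  load_schema(list(
    version = "1.0.0",
    fields = list(
      list(name = "sequence_id", category = "input", kind = "text",
           required = TRUE),
      list(name = "sequence", category = "input", kind = "nt_sequence",
           required = TRUE),
      list(name = "rev_comp", category = "primary_annotations",
           kind = "boolean", required = FALSE),
      list(name = "junction", category = "primary_annotations",
           kind = "nt_sequence", required = FALSE),
      list(name = "junction_length", category = "junction_lengths",
           kind = "integer", required = FALSE),
      list(name = "v_sequence_start", category = "alignment_positions",
           required = FALSE),
      list(name = "v_sequence_end", category = "alignment_positions",
           required = FALSE),
      list(name = "v_score", category = "alignment_annotations",
           required = FALSE)
    )))
}

write_tsv_lines <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  con <- file(f, "wb")
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  close(con)
  f
}

# deterministic small simulated dataset, cached per options
sim_cache <- new.env()
cached_sim <- function(n, seed, chain = "heavy", mu = 0.01) {
  key <- paste(n, seed, chain, mu, sep = "_")
  if (is.null(sim_cache[[key]])) {
    sim_cache[[key]] <- simulate_dataset(
      n, toy_germline_set(chain), recombination_model(mu = mu), seed = seed)
  }
  sim_cache[[key]]
}

# a model with no stochastic modification at all
degenerate_model <- function() {
  recombination_model(
    trim_prob = 1,
    max_trim = c(v3 = 0L, d5 = 0L, d3 = 0L, j5 = 0L),
    np_lambda = c(np1 = 0, np2 = 0),
    mu = 0)
}
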