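# Shared fixtures: a small plate geometry for image-level tests (fast to
# render) and constructors for common synthetic inputs.

spec_small <- function() plate_spec(n_rows = 8L, n_cols = 12L,
                                    pitch_px = 20, margin_px = 20)

spec_full <- function() plate_spec()

# A small single-plate screen: map + truth + measurement tables.
small_screen <- function(seed = 1L, n_replicates = 1L, ...) {
  spec <- spec_full()
  map <- generate_plate_map(spec, n_strains = 1200L, n_duplicates = 150L,
                            n_plates = 1L, seed = seed)
  truth <- screen_truth(map, seed = seed, ...)
  sim <- simulate_screen(map, spec, truth, n_replicates = n_replicates,
                         seed = seed)
  list(spec = spec, map = map, truth = truth, sim = sim)
}

# Distance to the nearest plate edge for a record table.
rec_edge_distance <- function(rec, spec) {
  pmin(rec$row - 1L, spec$n_rows - rec$row,
       rec$col - 1L, spec$n_cols - rec$col)
}

# Minimal expression-index table for hit-calling tests.
index_table <- function(index, ids = sprintf("s%04d", seq_along(index))) {
  structure(data.frame(strain_id = ids, index = index,
                       stringsAsFactors = FALSE),
            class = c("expression_index", "data.frame"))
}
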