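# One-call wrapper: simulate a group of cells and return the per-cell table.
analyze_cells_of <- function(seed, enrichment, n) {
  sim <- simulate_cells(cell_sim_params(n_cells = n, enrichment = enrichment,
                                        seed = seed))
  analyze_cells(sim$gfp, sim$mask)$cells
}
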