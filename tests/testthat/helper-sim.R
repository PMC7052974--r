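# small, fast parameter sets used across tests; dots override defaults
tiny_params <- function(...) {
  args <- utils::modifyList(
    list(n_sgrnas = 800, n_sgrnas_per_gene = 4, n_repl_sel = 2,
         n_repl_pcr = 1, n_repl_lib_pcr = 1, n_splittings = 2,
         rng_seed = 101),
    list(...))
  do.call(sim_params, args)
}

small_params <- function(...) {
  args <- utils::modifyList(
    list(n_sgrnas = 4000, n_sgrnas_per_gene = 4, n_repl_sel = 2,
         n_repl_pcr = 1, n_repl_lib_pcr = 1, n_splittings = 3,
         rng_seed = 202),
    list(...))
  do.call(sim_params, args)
}

quiet_sim <- function(params, ...) {
  suppressMessages(simulate_screen(params, ...))
}
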