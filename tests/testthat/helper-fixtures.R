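# Small shared fixtures, built once per test run and cached in an
# environment so individual test files stay fast.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

make_cds_fixture <- function(n_codons) bchrom:::make_cds(n_codons)

tiny_world <- function() {
  fixture("tiny_world", function() {
    lib <- make_repeat_library(seed = 11)
    genome <- make_genome(default_blueprint(1.2e5), lib,
                          n_a_chromosomes = 2, a_length = 30000,
                          n_transposed_genes = 4, seed = 12)
    scaffolds <- fragment_scaffolds(genome, n_scaffolds = 8,
                                    min_len = 5000, seed = 13)
    panel <- make_line_panel(genome, n_terminal = 5, n_mini = 1, seed = 14)
    list(lib = lib, genome = genome, scaffolds = scaffolds, panel = panel)
  })
}
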