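# Shared small synthetic fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, make) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- make()
  .fixture_cache[[key]]
}

test_ref <- function() memo("ref2mb", function()
  generate_reference(n_chrom = 1, chrom_length = 2e6, gc_fraction = 0.4,
                     seed = 42))

test_germline <- function() memo("germ2mb", function()
  generate_germline(test_ref(), het_density = 0.67, seed = 43))

# one diploid cell at the default study conditions
test_diploid_cell <- function() memo("cell2", function()
  simulate_cell(test_ref(), test_germline(), age = 75, ploidy = 2, seed = 7))

# one tetraploid cell
test_tetraploid_cell <- function() memo("cell4", function()
  simulate_cell(test_ref(), test_germline(), age = 75, ploidy = 4, seed = 8))

default_caller_model <- function(cell, ploidy = 2) {
  g <- cell$evidence$depth[cell$evidence$kind == "germline"]
  calibrate_threshold(depth = stats::median(g),
                      allele_fraction = 1 / ploidy)
}
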