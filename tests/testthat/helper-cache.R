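# Expensive shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

table1_preset <- function() cached("preset", make_table1_preset())

# Full-scale registry at the published stratum sizes (~260k records plus
# contamination); used by the descriptive-replication and sampling-error
# tests.
full_registry <- function() cached("full_registry",
                                   generate_registry(table1_preset(), seed = 20260919))
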