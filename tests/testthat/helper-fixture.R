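# Shared fast-converging fixture, built once per test run.
.fixture_cache <- new.env(parent = emptyenv())

get_fixture <- function() {
  if (is.null(.fixture_cache$fx))
    .fixture_cache$fx <- generate_fixture(seed = 42, n_baseline = 150)
  .fixture_cache$fx
}

# combined z-score of a difference given two standard errors
zdiff <- function(a, b, se_a, se_b) abs(a - b) / sqrt(se_a^2 + se_b^2)
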