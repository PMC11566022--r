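# Shared fixtures, built in code. The default synthetic world is generated
# once per test run and reused.

.fixture_env <- new.env(parent = emptyenv())

default_world <- function() {
  if (is.null(.fixture_env$world))
    .fixture_env$world <- generate_world(sim_config(seed = 1))
  .fixture_env$world
}

default_report <- function() {
  if (is.null(.fixture_env$report))
    .fixture_env$report <- run_all(default_world())
  .fixture_env$report
}

# independent random-sequence helper for fixtures
rand_dna_fixture <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# build a transcript carrying a perfect 30-nt duplex for `guide` with the
# cleavage position at `p` (0-based); returns list(transcript, guide, p)
make_perfect_site <- function(seed = 42, p = 30L, tx_len = 80L) {
  set.seed(seed)
  tx <- paste(sample(c("A", "C", "G", "T"), tx_len, replace = TRUE),
              collapse = "")
  window <- substr(tx, p - 19L, p + 10L)   # 1-based [p-20, p+10) 0-based
  guide <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(window)))
  list(transcript = tx, guide = guide, p = p)
}

# mutate the transcript base paired to guide position k into a mismatch
# (set it equal to the guide base, which can never pair)
break_pair_at <- function(site, k) {
  idx <- site$p + 11L - k
  g <- substr(site$guide, k, k)
  substr(site$transcript, idx, idx) <- g
  site
}
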