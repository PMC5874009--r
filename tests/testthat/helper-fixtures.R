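# shared fixture helpers: everything is built in code or read from the
# packaged printed-table transcriptions

fixture_path <- function(name) np_extdata(name)

load_isotopes <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- read_isotope_table(fixture_path("table2_isotopes.csv"))
    cache
  }
})

load_frequencies <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressWarnings(
        read_trait_frequencies(fixture_path("table4_frequencies.csv"))
      )
    }
    cache
  }
})

load_individuals <- function() {
  read.csv(fixture_path("table1_individuals.csv"), stringsAsFactors = FALSE)
}

paper_range <- function() local_range(0.7086, 0.7090)

# the thirteen Italic comparison groups
italic_groups <- c("LAA", "LAB", "LAC", "ETB", "ETC", "PCB", "PCC",
                   "CAA", "CAB", "CAC", "SUL", "SAM", "MON")

# a small deterministic binary matrix with row/col names
toy_binary <- function(n, p, prob = 0.4, seed = 42) {
  set.seed(seed)
  m <- matrix(rbinom(n * p, 1, prob), n, p,
              dimnames = list(sprintf("i%02d", seq_len(n)),
                              sprintf("g%02d", seq_len(p))))
  m
}
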