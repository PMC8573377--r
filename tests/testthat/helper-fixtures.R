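# compact builders for hand-sized repertoires used across the suite

# a repertoire from named counts; keys k1, k2, ... map to distinct clones
toy_repertoire <- function(counts, ...) {
  n <- length(counts)
  nts <- c("A", "C", "G", "T")
  cdr3 <- vapply(seq_len(n), function(i) {
    paste0("TGT", paste0(rep(nts[(i - 1) %% 4 + 1], 3), collapse = ""),
           paste0(nts[(i - 1) %/% 4 %% 4 + 1], "GC"), "TTT")
  }, character(1))
  make_repertoire(
    data.frame(
      v = paste0("TRBV", (seq_len(n) - 1) %% 5 + 1),
      j = paste0("TRBJ1-", (seq_len(n) - 1) %% 3 + 1),
      cdr3nt = cdr3,
      count = as.numeric(counts)
    ),
    ...
  )
}

# repertoire over an explicit shared key table (for overlap fixtures)
keyed_repertoire <- function(keys, counts, ...) {
  make_repertoire(
    data.frame(v = keys$v, j = keys$j, cdr3nt = keys$cdr3nt,
               count = as.numeric(counts)),
    ...
  )
}

toy_keys <- function(n) {
  codons <- c("AAC", "AAG", "ACA", "ACC", "ACG", "ACT", "AGA", "AGC",
              "AGG", "ATA", "ATC", "ATG", "CAA", "CAC", "CAG", "CAT",
              "CCA", "CCC", "CCG", "CCT", "CGA", "CGC", "CGG", "CGT",
              "CTA", "CTC")
  stopifnot(n <= length(codons))
  data.frame(
    v = paste0("TRBV", (seq_len(n) - 1) %% 7 + 1),
    j = paste0("TRBJ2-", (seq_len(n) - 1) %% 4 + 1),
    cdr3nt = paste0("TGTAGC", codons[seq_len(n)], "TTC")
  )
}

# random repertoire with reproducible keys, for property-style loops
random_repertoire <- function(n_clones, seed, total = 1000, ...) {
  with_seed(seed, {
    cfg <- synthetic_config()
    keys <- generate_clone_keys(n_clones, cfg)
    counts <- as.numeric(rmultinom(1, total, rexp(n_clones))[, 1])
    keys$count <- counts
    make_repertoire(keys[counts > 0, ], ...)
  })
}

# small 2-mouse synthetic config so pipeline tests stay fast
small_config <- function(seed = 11, ...) {
  base <- list(
    n_mice = 2L, n_reactive_clones = 120L,
    n_bystander_dln_clones = 1500L, n_bystander_tumor_clones = 400L,
    cells_per_tumor_sample = 800L, cells_per_dln_sample = 800L,
    seed = seed
  )
  do.call(synthetic_config, utils::modifyList(base, list(...)))
}
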