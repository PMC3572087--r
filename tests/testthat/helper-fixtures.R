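# shared fixtures and independent oracles for the test suite

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# random standard-alphabet windows (odd width w), seeded
random_windows <- function(n, w = 15, seed = 1, center_c = TRUE) {
  withr_seed(seed)
  vapply(seq_len(n), function(i) {
    chars <- sample(AA, w, replace = TRUE)
    if (center_c) chars[(w + 1) / 2] <- "C"
    paste(chars, collapse = "")
  }, character(1))
}

# minimal local set.seed wrapper (tests may freely clobber the RNG)
withr_seed <- function(seed) set.seed(seed)

# independent k-mer counting oracle: table of contiguous k-mers
count_kmers <- function(peptide, k) {
  w <- nchar(peptide)
  kms <- substring(peptide, seq_len(w - k + 1), seq_len(w - k + 1) + k - 1)
  table(kms)
}

# independent AUC oracle: pairwise Mann-Whitney with half-credit ties
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == "positive"]
  neg <- scores[labels == "negative"]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# mechanical PROSITE -> regex translation (independent of the scanner)
prosite_to_regex <- function(pattern) {
  parts <- vapply(pattern$elements, function(e) {
    core <- switch(e$type,
      exact = e$residues,
      wildcard = ".",
      set = paste0("[", paste(e$residues, collapse = ""), "]"),
      exclusion = paste0("[^", paste(e$residues, collapse = ""), "]"))
    if (e$min == 1 && e$max == 1) core
    else paste0("(?:", core, "){", e$min, ",", e$max, "}")
  }, character(1))
  paste(parts, collapse = "")
}

# all match start positions under the regex oracle
regex_match_starts <- function(pattern, sequence) {
  rx <- prosite_to_regex(pattern)
  starts <- integer(0)
  for (s in seq_len(nchar(sequence))) {
    tail <- substring(sequence, s)
    m <- regexpr(paste0("^(?:", rx, ")"), tail, perl = TRUE)
    if (m != -1L) starts <- c(starts, s)
  }
  starts
}

# a small synthetic dataset with strong signal, windows extracted at w
signal_windows <- function(seed = 1, w = 15, n_proteins = 39,
                           n_positive = 75, signal = strong_signal()) {
  cfg <- synth_config(n_proteins = n_proteins,
                      n_positive_sites = n_positive,
                      signal = signal, seed = seed)
  ds <- generate_dataset(cfg)
  suppressWarnings(
    extract_windows(ds$proteins, validate_sites(ds$sites, ds$proteins), w))
}
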