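#' Reduced amino acid alphabets
#'
#' Grouping of the 20 amino acids into 3 physicochemical classes (polar /
#' neutral / hydrophobic) and 7 classes (aliphatic / acid / base / aromatic /
#' amide / small hydroxyl / sulfur-containing), as used by the
#' reduced-alphabet composition encoder.
#'
#' @return A list with elements `classes3` and `classes7`, each a named list
#'   of residue character vectors.
#' @export
reduced_alphabets <- function() {
  list(
    classes3 = list(
      polar       = c("R", "K", "E", "D", "Q", "N"),
      neutral     = c("G", "A", "S", "T", "P", "H", "Y"),
      hydrophobic = c("C", "V", "L", "I", "M", "F", "W")),
    classes7 = list(
      aliphatic      = c("A", "I", "L", "V", "G", "P"),
      acid           = c("D", "E"),
      base           = c("H", "K", "R"),
      aromatic       = c("F", "W", "Y"),
      amide          = c("N", "Q"),
      small_hydroxyl = c("S", "T"),
      sulfur         = c("C", "M")))
}

#' Single amino acid composition (20 dimensions)
#'
#' Occurrence frequency of each of the 20 amino acids within the window;
#' entries sum to 1.
#'
#' @param peptide Window string over the standard alphabet.
#' @return Named 20-vector in fixed alphabetical order (A, C, D, ..., Y).
#' @examples
#' encode_single("HLGYVLTCPSNLGTG")
#' @export
encode_single <- function(peptide) {
  stop_if_nonstandard(peptide)
  tab <- table(factor(pep_chars(peptide), levels = AA20))
  v <- as.vector(tab) / nchar(peptide)
  names(v) <- AA20
  v
}

#' Reduced amino acid composition (10 dimensions)
#'
#' Class frequencies under the 3-class alphabet (polar, neutral, hydrophobic)
#' followed by the 7-class alphabet (aliphatic, acid, base, aromatic, amide,
#' small hydroxyl, sulfur-containing); each block sums to 1.
#'
#' @inheritParams encode_single
#' @return Named 10-vector (3-class block then 7-class block).
#' @export
encode_reduced_comp <- function(peptide) {
  stop_if_nonstandard(peptide)
  chars <- pep_chars(peptide)
  ra <- reduced_alphabets()
  block <- function(classes) {
    v <- vapply(classes, function(members) sum(chars %in% members) /
                  length(chars), numeric(1))
    v
  }
  c(block(ra$classes3), block(ra$classes7))
}

#' Pairwise amino acid composition (400 dimensions)
#'
#' Frequencies of the `w - 1` contiguous ordered dipeptides in the window,
#' normalized by `w - 1`; entries sum to 1.
#'
#' @inheritParams encode_single
#' @return Named 400-vector; names are dipeptides "AA", "AC", ... in
#'   lexicographic order.
#' @export
encode_pair <- function(peptide) {
  stop_if_nonstandard(peptide)
  w <- nchar(peptide)
  pairs <- substring(peptide, seq_len(w - 1L), seq_len(w - 1L) + 1L)
  lev <- kmer_names(2L)
  tab <- table(factor(pairs, levels = lev))
  v <- as.vector(tab) / (w - 1L)
  names(v) <- lev
  v
}

#' Triplet amino acid composition (8000 dimensions)
#'
#' Raw counts of the `w - 2` contiguous ordered tripeptides in the window
#' (counts, not frequencies: the vector sums to `w - 2`, i.e. 13 for the
#' default window of 15).
#'
#' @inheritParams encode_single
#' @return Named 8000-vector of counts.
#' @export
encode_triplet <- function(peptide) {
  stop_if_nonstandard(peptide)
  w <- nchar(peptide)
  trip <- substring(peptide, seq_len(w - 2L), seq_len(w - 2L) + 2L)
  lev <- kmer_names(3L)
  tab <- table(factor(trip, levels = lev))
  v <- as.vector(tab)
  names(v) <- lev
  v
}

#' Reversal-merged triplet composition (4200 dimensions)
#'
#' Triplet counts in which a tripeptide and its reversal are collapsed into
#' one feature class ("ABD" and "DBA" increment the same feature): the local
#' neighborhood of the cysteine is treated as direction-free. Each triplet is
#' mapped to its canonical form, the lexicographic minimum of the triplet and
#' its reversal. The 8000 ordered triplets collapse to
#' (8000 - 400) / 2 + 400 = 4200 classes (the 400 palindromic-endpoint
#' triplets are their own reversal); the class count is derived by
#' enumeration at first use, not hard-coded. The vector sums to `w - 2`.
#'
#' @inheritParams encode_single
#' @return Named vector of counts over the canonical triplet classes.
#' @export
encode_reduced_triplet <- function(peptide) {
  stop_if_nonstandard(peptide)
  w <- nchar(peptide)
  trip <- substring(peptide, seq_len(w - 2L), seq_len(w - 2L) + 2L)
  canon <- canonical_triplet_map()
  tab <- table(factor(unname(canon[trip]), levels = canonical_triplet_classes()))
  v <- as.vector(tab)
  names(v) <- canonical_triplet_classes()
  v
}

# all ordered k-mers over AA20, lexicographic
kmer_names <- function(k) {
  key <- paste0("kmer", k)
  if (is.null(.glutapred_cache[[key]])) {
    grid <- do.call(expand.grid,
                    c(rep(list(AA20), k), stringsAsFactors = FALSE))
    # expand.grid varies the first column fastest; reverse for lexicographic
    nm <- do.call(paste0, rev(grid))
    .glutapred_cache[[key]] <- sort(nm)
  }
  .glutapred_cache[[key]]
}

#' Canonical map from ordered triplets to reversal-merged classes
#'
#' @return Named character vector: for every ordered triplet, the
#'   lexicographic minimum of the triplet and its reversal.
#' @export
canonical_triplet_map <- function() {
  if (is.null(.glutapred_cache$canon3)) {
    trip <- kmer_names(3L)
    rev3 <- paste0(substr(trip, 3, 3), substr(trip, 2, 2), substr(trip, 1, 1))
    canon <- ifelse(trip <= rev3, trip, rev3)
    names(canon) <- trip
    .glutapred_cache$canon3 <- canon
    .glutapred_cache$canon3_classes <- sort(unique(unname(canon)))
  }
  .glutapred_cache$canon3
}

#' Canonical triplet class names (reversal-merged)
#' @return Sorted character vector of canonical triplet classes.
#' @export
canonical_triplet_classes <- function() {
  canonical_triplet_map()
  .glutapred_cache$canon3_classes
}

#' Binary one-hot profile (20 x w dimensions)
#'
#' Each window position is encoded as a 20-dimensional one-hot vector in
#' fixed alphabetical order (A = 10000000000000000000, C = 01000...,
#' ..., Y = ...0001); the window is the concatenation of its `w` blocks, so
#' exactly `w` entries are 1.
#'
#' @inheritParams encode_single
#' @return Named `20 * w` 0/1 vector; names are "pos<i>.<residue>".
#' @export
encode_binary <- function(peptide) {
  stop_if_nonstandard(peptide)
  chars <- pep_chars(peptide)
  w <- length(chars)
  m <- matrix(0, nrow = w, ncol = 20L, dimnames = list(NULL, AA20))
  m[cbind(seq_len(w), match(chars, AA20))] <- 1
  v <- as.vector(t(m))
  names(v) <- paste0("pos", rep(seq_len(w), each = 20L), ".", rep(AA20, w))
  v
}

#' Fit a bi-profile Bayes position-frequency matrix
#'
#' From the positive and negative training windows separately, estimates the
#' per-position occurrence frequency of each amino acid: a `w` x 20 matrix
#' for each class (together the 20 x 2w posterior matrix of the bi-profile
#' Bayes encoding). Must be fitted on training windows only — fitting on
#' pooled data leaks test labels into the features.
#'
#' @param peptides Character vector of equal-length training windows.
#' @param labels Character vector, `"positive"` / `"negative"`, parallel to
#'   `peptides`; both classes must be present.
#' @param pseudocount Non-negative smoothing count added per residue cell
#'   (default 0, plain occurrence frequencies).
#' @return An object of class `biprofile`: list with `w`, `pos_freq`,
#'   `neg_freq` (each `w` x 20, rows summing to 1), `pseudocount`.
#' @export
fit_biprofile <- function(peptides, labels, pseudocount = 0) {
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  stopifnot(length(peptides) == length(labels))
  w <- unique(nchar(peptides))
  if (length(w) != 1L) stop("windows differ in length", call. = FALSE)
  for (p in peptides) stop_if_nonstandard(p)
  count_class <- function(cls) {
    sel <- peptides[labels == cls]
    if (length(sel) == 0L) {
      stop("no ", cls, " windows in the training set", call. = FALSE)
    }
    chars <- matrix(unlist(strsplit(sel, "", fixed = TRUE)),
                    ncol = w, byrow = TRUE)
    counts <- t(apply(chars, 2, function(col)
      table(factor(col, levels = AA20))))
    (counts + pseudocount) / (length(sel) + 20 * pseudocount)
  }
  structure(list(w = as.integer(w),
                 pos_freq = count_class("positive"),
                 neg_freq = count_class("negative"),
                 pseudocount = pseudocount),
            class = "biprofile")
}

#' Bi-profile Bayes encoding (2 x w dimensions)
#'
#' Entries 1..w are the positive-class frequency of the window's residue at
#' each position; entries w+1..2w the negative-class frequency (30
#' dimensions for the default window of 15).
#'
#' @inheritParams encode_single
#' @param profile A fitted [fit_biprofile()] object.
#' @return Named `2 * w` vector with entries in \[0, 1\].
#' @export
encode_biprofile <- function(peptide, profile) {
  stopifnot(inherits(profile, "biprofile"))
  stop_if_nonstandard(peptide)
  if (nchar(peptide) != profile$w) {
    stop("window length ", nchar(peptide), " does not match profile (",
         profile$w, ")", call. = FALSE)
  }
  idx <- match(pep_chars(peptide), AA20)
  pos <- profile$pos_freq[cbind(seq_len(profile$w), idx)]
  neg <- profile$neg_freq[cbind(seq_len(profile$w), idx)]
  v <- c(pos, neg)
  names(v) <- c(paste0("pos_freq", seq_len(profile$w)),
                paste0("neg_freq", seq_len(profile$w)))
  v
}

#' Load the packaged physicochemical property table
#'
#' Twenty amino acids by ten properties: number of atoms, net electrostatic
#' charge, hydrogen-bonding capacity, hydrophobicity, hydrophilicity, burial
#' propensity, isoelectric point, mass, expected contacts within a 14
#' angstrom sphere, and electron-ion interaction potential. The packaged TSV
#' (see its header for provenance) is the source of truth and may be replaced
#' by any table with the same shape.
#'
#' @param path Path to a property TSV; defaults to the packaged table.
#' @return A 20 x 10 numeric matrix with residue rownames.
#' @export
load_property_table <- function(path = system.file("extdata",
                                                   "physchem_properties.tsv",
                                                   package = "glutapred")) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(tab) != 20L || ncol(tab) != 11L || anyNA(tab)) {
    stop("property table must be 20 rows x (residue + 10 properties), ",
         "no missing values", call. = FALSE)
  }
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab$amino_acid
  if (!setequal(rownames(m), AA20)) {
    stop("property table must cover exactly the 20 standard residues",
         call. = FALSE)
  }
  m[AA20, , drop = FALSE]
}

#' Summed physicochemical property encoding (10 dimensions)
#'
#' For each of the ten properties, sums the per-residue values over the whole
#' window. The encoding is order-free (any permutation of the window gives
#' the same vector).
#'
#' @inheritParams encode_single
#' @param table 20 x 10 property matrix, as from [load_property_table()].
#' @return Named 10-vector of property sums.
#' @export
encode_physchem <- function(peptide, table = load_property_table()) {
  stop_if_nonstandard(peptide)
  idx <- match(pep_chars(peptide), rownames(table))
  if (anyNA(idx)) stop("residue missing from property table", call. = FALSE)
  colSums(table[idx, , drop = FALSE])
}

#' The eight encoding schemes and their dimensionalities
#'
#' @param w Window width (needed for the profile schemes).
#' @return Named integer vector of feature-space dimensionalities per scheme.
#' @export
scheme_dimensions <- function(w = 15) {
  w <- check_window_size(w)
  c(single_aa = 20L,
    reduced_comp = 10L,
    pair_aa = 400L,
    triplet_aa = 8000L,
    reduced_triplet_aa = length(canonical_triplet_classes()),
    binary_profile = 20L * w,
    biprofile_bayes = 2L * w,
    physchem = 10L)
}

#' Reference number of selected features per scheme
#'
#' The t-test feature-selection depths used as packaged defaults for each
#' scheme (tunable; sweep them under cross-validation for a new dataset).
#'
#' @return Named integer vector, parallel to [scheme_dimensions()].
#' @export
default_selected_k <- function() {
  c(single_aa = 3L, reduced_comp = 6L, pair_aa = 21L, triplet_aa = 76L,
    reduced_triplet_aa = 71L, binary_profile = 12L, biprofile_bayes = 18L,
    physchem = 3L)
}

#' Encode a set of windows into a feature matrix
#'
#' Applies one of the eight encoding schemes to every window, producing a
#' samples x features numeric matrix with scheme metadata. For the
#' `biprofile_bayes` scheme a fitted profile must be supplied (fit it on
#' training windows only).
#'
#' @param windows Data frame from [extract_windows()] (columns `protein_id`,
#'   `center`, `peptide`, `label`), or a character vector of peptides.
#' @param scheme One of `"single_aa"`, `"reduced_comp"`, `"pair_aa"`,
#'   `"triplet_aa"`, `"reduced_triplet_aa"`, `"binary_profile"`,
#'   `"biprofile_bayes"`, `"physchem"`.
#' @param profile [fit_biprofile()] object (biprofile_bayes scheme only).
#' @param properties Property matrix (physchem scheme only); defaults to the
#'   packaged table.
#' @return An object of class `feature_matrix`: list with `scheme`, `w`,
#'   `features` (numeric matrix), `labels`, `meta` (protein_id / center).
#' @export
encode_windows <- function(windows, scheme, profile = NULL,
                           properties = NULL) {
  if (is.character(windows)) {
    windows <- data.frame(protein_id = NA_character_, center = NA_integer_,
                          peptide = windows, label = NA_character_,
                          stringsAsFactors = FALSE)
  }
  scheme <- match.arg(scheme, names(scheme_dimensions(15)))
  peps <- windows$peptide
  w <- unique(nchar(peps))
  if (length(w) > 1L) stop("windows differ in length", call. = FALSE)
  if (length(w) == 0L) w <- if (!is.null(profile)) profile$w else 15L
  enc <- switch(scheme,
    single_aa = encode_single,
    reduced_comp = encode_reduced_comp,
    pair_aa = encode_pair,
    triplet_aa = encode_triplet,
    reduced_triplet_aa = encode_reduced_triplet,
    binary_profile = encode_binary,
    biprofile_bayes = {
      if (is.null(profile)) {
        stop("biprofile_bayes needs a fitted profile", call. = FALSE)
      }
      function(p) encode_biprofile(p, profile)
    },
    physchem = {
      if (is.null(properties)) properties <- load_property_table()
      function(p) encode_physchem(p, properties)
    })
  template <- enc(strrep("A", w))
  if (length(peps) == 0L) {
    mat <- matrix(numeric(0), nrow = 0, ncol = length(template),
                  dimnames = list(NULL, names(template)))
  } else {
    mat <- t(vapply(peps, enc, template))
    rownames(mat) <- NULL
    colnames(mat) <- names(template)
  }
  structure(list(scheme = scheme, w = as.integer(w), features = mat,
                 labels = windows$label,
                 meta = windows[, c("protein_id", "center"), drop = FALSE]),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix:", nrow(x$features), "samples x", ncol(x$features),
      "features (scheme:", x$scheme, ", window:", x$w, ")\n")
  if (!all(is.na(x$labels))) {
    cat("  labels:", sum(x$labels == "positive"), "positive /",
        sum(x$labels == "negative"), "negative\n")
  }
  invisible(x)
}

#' Write a feature matrix as TSV
#'
#' Columns: `protein_id`, `center`, `label`, then one column per feature.
#'
#' @param fm A `feature_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  out <- data.frame(protein_id = fm$meta$protein_id,
                    center = fm$meta$center, label = fm$labels,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(fm$features))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
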