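#' Read protein sequences from a FASTA file
#'
#' Sequences are upper-cased on read. Letters outside the 20 standard amino
#' acids (B, J, O, U, X, Z, ...) are retained but reported with a warning so
#' that downstream window filtering can exclude them explicitly.
#'
#' @param path Path to a FASTA file. Multi-line sequences are allowed. An
#'   empty file yields an empty (zero-length) result.
#' @return A named character vector of protein sequences; names are the FASTA
#'   identifiers (first whitespace-delimited token of each header).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "HLGYVLTCPSNLGTG"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    return(structure(character(0), names = character(0)))
  }
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop("malformed FASTA: line ", nonblank[1],
         " contains sequence data before any '>' header", call. = FALSE)
  }
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             seqonly = FALSE)
  ids <- vapply(seqs, function(s) attr(s, "name"), character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  out <- toupper(vapply(seqs, function(s) as.character(s[1]), character(1)))
  names(out) <- ids
  if (any(!nzchar(out))) {
    stop("malformed FASTA: empty sequence for entry ",
         paste(ids[!nzchar(out)], collapse = ", "), call. = FALSE)
  }
  bad <- vapply(out, function(s) !is_standard(s), logical(1))
  if (any(bad)) {
    warning("non-standard residues in: ", paste(ids[bad], collapse = ", "),
            call. = FALSE)
  }
  out
}

#' Write protein sequences to a FASTA file
#'
#' @param proteins Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  seqinr::write.fasta(as.list(unname(proteins)), names = names(proteins),
                      file.out = path, as.string = TRUE, nbchar = 60)
  invisible(path)
}

#' Read and validate a cysteine site annotation table
#'
#' The table is TSV with a header and columns `protein_id`, `position`
#' (1-based) and `label` (`positive` or `negative`). Each row is validated
#' against the supplied proteins: the id must be known, the position in
#' bounds, and the residue at that position must be a cysteine. Invalid rows
#' are dropped with a warning; the rejected rows (with a `reason` column) are
#' attached as attribute `"rejected"`.
#'
#' @param path Path to the TSV file.
#' @param proteins Named character vector of sequences, as from
#'   [read_fasta()].
#' @return A data frame with columns `protein_id`, `position`, `label`.
#' @export
read_site_table <- function(path, proteins) {
  if (!file.exists(path)) stop("site table not found: ", path, call. = FALSE)
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  validate_sites(tab, proteins)
}

#' Validate site annotations against protein sequences
#'
#' @param sites Data frame with columns `protein_id`, `position`, `label`.
#' @inheritParams read_site_table
#' @return The valid rows; rejected rows in attribute `"rejected"`.
#' @export
validate_sites <- function(sites, proteins) {
  need <- c("protein_id", "position", "label")
  if (!all(need %in% names(sites))) {
    stop("site table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  sites$protein_id <- as.character(sites$protein_id)
  sites$position <- as.integer(sites$position)
  sites$label <- as.character(sites$label)
  reason <- rep(NA_character_, nrow(sites))
  reason[!sites$label %in% c("positive", "negative")] <- "bad label"
  unknown <- !sites$protein_id %in% names(proteins)
  reason[is.na(reason) & unknown] <- "unknown protein"
  ok <- is.na(reason)
  inb <- ok & sites$position >= 1L &
    sites$position <= nchar(proteins)[match(sites$protein_id, names(proteins))]
  reason[ok & !inb] <- "position out of bounds"
  res <- ifelse(inb, substr(proteins[match(sites$protein_id, names(proteins))],
                            sites$position, sites$position), "")
  reason[inb & res != "C"] <- paste0("residue is '", res[inb & res != "C"],
                                     "', not 'C'")
  keep <- is.na(reason)
  if (any(!keep)) {
    warning(sum(!keep), " of ", nrow(sites),
            " annotation row(s) rejected", call. = FALSE)
  }
  out <- sites[keep, need, drop = FALSE]
  rownames(out) <- NULL
  rej <- sites[!keep, need, drop = FALSE]
  rej$reason <- reason[!keep]
  rownames(rej) <- NULL
  attr(out, "rejected") <- rej
  out
}

#' Extract the cysteine-centered window around one position
#'
#' Returns the exact substring covering `(w - 1) / 2` residues on each side
#' of the cysteine. No padding is ever applied: when the window would extend
#' past either terminus, `NA_character_` is returned as a discard signal (the
#' site is dropped from the dataset rather than padded, because every encoder
#' assumes a full-length window).
#'
#' @param sequence A protein sequence string.
#' @param position 1-based position of a cysteine in `sequence`.
#' @param w Odd window width, at least 3.
#' @return The length-`w` peptide, or `NA_character_` if the window runs past
#'   a terminus.
#' @examples
#' extract_window("XXHLGYVLTCPSNLGTGXX", 10, 15)
#' @export
extract_window <- function(sequence, position, w) {
  check_window_size(w)
  position <- as.integer(position)
  if (position < 1L || position > nchar(sequence)) {
    stop("position ", position, " out of bounds", call. = FALSE)
  }
  if (substr(sequence, position, position) != "C") {
    stop("residue at position ", position, " is '",
         substr(sequence, position, position), "', not 'C'", call. = FALSE)
  }
  half <- (w - 1L) %/% 2L
  if (position - half < 1L || position + half > nchar(sequence)) {
    return(NA_character_)
  }
  substr(sequence, position - half, position + half)
}

check_window_size <- function(w) {
  if (length(w) != 1L || is.na(w) || w %% 2L != 1L || w < 3L) {
    stop("window size must be a single odd integer >= 3, got ", w,
         call. = FALSE)
  }
  invisible(as.integer(w))
}

#' Extract windows for a whole annotation table
#'
#' Applies [extract_window()] to every annotated site and drops (with a
#' warning) sites whose window crosses a terminus, plus — optionally —
#' windows containing non-standard residues, which the composition and
#' profile encoders cannot represent.
#'
#' @inheritParams read_site_table
#' @param sites Validated annotation data frame (`protein_id`, `position`,
#'   `label`).
#' @param w Odd window width.
#' @param drop_nonstandard Drop windows containing letters outside the 20
#'   standard amino acids (default `TRUE`).
#' @return Data frame with columns `protein_id`, `center`, `peptide`,
#'   `label`; discarded rows (with a `reason`) in attribute `"discarded"`.
#' @export
extract_windows <- function(proteins, sites, w = 15,
                            drop_nonstandard = TRUE) {
  w <- check_window_size(w)
  peps <- vapply(seq_len(nrow(sites)), function(i) {
    extract_window(proteins[[sites$protein_id[i]]], sites$position[i], w)
  }, character(1))
  reason <- rep(NA_character_, nrow(sites))
  reason[is.na(peps)] <- "terminal window"
  if (drop_nonstandard) {
    ns <- !is.na(peps) & !vapply(ifelse(is.na(peps), "A", peps),
                                 is_standard, logical(1))
    reason[ns] <- "non-standard residue"
  }
  keep <- is.na(reason)
  if (any(!keep)) {
    warning(sum(!keep), " window(s) discarded (",
            paste(unique(reason[!keep]), collapse = "; "), ")",
            call. = FALSE)
  }
  out <- data.frame(protein_id = sites$protein_id[keep],
                    center = sites$position[keep],
                    peptide = peps[keep],
                    label = sites$label[keep],
                    stringsAsFactors = FALSE)
  disc <- data.frame(protein_id = sites$protein_id[!keep],
                     center = sites$position[!keep],
                     reason = reason[!keep], stringsAsFactors = FALSE)
  attr(out, "discarded") <- disc
  out
}

#' Sample negative cysteines from one protein
#'
#' Candidate negatives are every cysteine in the sequence that is not an
#' annotated positive and whose window of width `w` lies fully inside the
#' sequence. At most `ratio` negatives per positive are drawn uniformly
#' without replacement, keeping the class imbalance bounded (default: at most
#' three negatives per positive, per protein).
#'
#' @param sequence Protein sequence string.
#' @param positives Integer vector of 1-based positive cysteine positions.
#' @param ratio Maximum negatives per positive (default 3).
#' @param w Odd window width used for the eligibility check.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return Sorted integer vector of sampled negative positions.
#' @export
sample_negatives <- function(sequence, positives, ratio = 3, w = 15,
                             seed = 1) {
  if (ratio < 1) stop("ratio must be >= 1", call. = FALSE)
  w <- check_window_size(w)
  cys <- which(pep_chars(sequence) == "C")
  cand <- setdiff(cys, as.integer(positives))
  half <- (w - 1L) %/% 2L
  cand <- cand[cand - half >= 1L & cand + half <= nchar(sequence)]
  n_take <- min(length(cand), ratio * length(positives))
  if (n_take == 0L) return(integer(0))
  with_seed(seed, sort(sample(cand, n_take)))
}
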