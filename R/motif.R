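#' Parse a PROSITE-style pattern
#'
#' Supports the core PROSITE pattern dialect: dash-separated elements, each
#' an exact residue (`C`), the wildcard `x` (any amino acid), an allowed set
#' `[ST]` (either S or T), or a forbidden set `{FWY}` (any residue except F,
#' W, Y); any element may carry a repetition suffix `(n)` (exactly n times)
#' or `(n,m)` (n to m times). Anchors (`<`, `>`) are not part of this dialect
#' and are rejected explicitly.
#'
#' @param text Pattern string, e.g. `"C-P-x(0,1)-[ST]-N-[ILV]-G-T"`. A
#'   trailing period (PROSITE database style) is tolerated.
#' @param id Optional pattern identifier (e.g. `"PS00112"`).
#' @return An object of class `prosite_pattern`: list with `id`, `text`, and
#'   `elements` — each element a list with `type` (`"exact"`, `"wildcard"`,
#'   `"set"`, `"exclusion"`), `residues`, `min`, `max`.
#' @examples
#' parse_prosite("C-P-x(0,1)-[ST]-N-[ILV]-G-T", id = "PS00112")
#' @export
parse_prosite <- function(text, id = "") {
  raw <- sub("\\.$", "", trimws(text))
  if (!nzchar(raw)) stop("empty pattern", call. = FALSE)
  if (grepl("[<>]", raw)) {
    stop("PROSITE anchors '<'/'>' are not supported by this dialect",
         call. = FALSE)
  }
  tokens <- strsplit(raw, "-", fixed = TRUE)[[1]]
  elements <- lapply(seq_along(tokens), function(i) {
    tok <- trimws(tokens[i])
    if (!nzchar(tok)) stop("empty element at position ", i, call. = FALSE)
    m <- regmatches(tok, regexec(
      "^([A-Z]|x|\\[[A-Z]+\\]|\\{[A-Z]+\\})(?:\\((\\d+)(?:,(\\d+))?\\))?$",
      tok))[[1]]
    if (length(m) == 0L) {
      stop("cannot parse element ", i, ": '", tok, "'", call. = FALSE)
    }
    core <- m[2]
    lo <- if (nzchar(m[3])) as.integer(m[3]) else 1L
    hi <- if (nzchar(m[4])) as.integer(m[4]) else lo
    if (lo > hi) stop("element ", i, ": min repetition ", lo,
                      " exceeds max ", hi, call. = FALSE)
    if (core == "x") {
      list(type = "wildcard", residues = AA20, min = lo, max = hi)
    } else if (startsWith(core, "[")) {
      res <- pep_chars(substr(core, 2, nchar(core) - 1L))
      list(type = "set", residues = unique(res), min = lo, max = hi)
    } else if (startsWith(core, "{")) {
      res <- pep_chars(substr(core, 2, nchar(core) - 1L))
      list(type = "exclusion", residues = unique(res), min = lo, max = hi)
    } else {
      list(type = "exact", residues = core, min = lo, max = hi)
    }
  })
  structure(list(id = id, text = raw, elements = elements),
            class = "prosite_pattern")
}

#' Render a parsed pattern back to PROSITE syntax
#'
#' @param pattern A [parse_prosite()] object.
#' @return The pattern string; `parse_prosite(unparse_prosite(p))` gives an
#'   element list identical to `p`'s.
#' @export
unparse_prosite <- function(pattern) {
  stopifnot(inherits(pattern, "prosite_pattern"))
  toks <- vapply(pattern$elements, function(e) {
    core <- switch(e$type,
      exact = e$residues,
      wildcard = "x",
      set = paste0("[", paste(e$residues, collapse = ""), "]"),
      exclusion = paste0("{", paste(e$residues, collapse = ""), "}"))
    rep <- if (e$min == 1L && e$max == 1L) {
      ""
    } else if (e$min == e$max) {
      paste0("(", e$min, ")")
    } else {
      paste0("(", e$min, ",", e$max, ")")
    }
    paste0(core, rep)
  }, character(1))
  paste(toks, collapse = "-")
}

#' @export
print.prosite_pattern <- function(x, ...) {
  cat("prosite_pattern", if (nzchar(x$id)) paste0("[", x$id, "]") else "",
      ":", unparse_prosite(x), "\n")
  invisible(x)
}

# does residue ch satisfy element e?
element_matches <- function(e, ch) {
  switch(e$type,
         exact = ch == e$residues,
         wildcard = TRUE,
         set = ch %in% e$residues,
         exclusion = !(ch %in% e$residues))
}

# all end offsets (number of residues consumed) of matches of
# elements[idx..] starting at position pos; full backtracking over
# repetition counts so the shortest span can be chosen
match_spans <- function(elements, idx, chars, pos) {
  if (idx > length(elements)) return(0L)
  e <- elements[[idx]]
  spans <- integer(0)
  for (reps in e$min:e$max) {
    if (reps > 0L) {
      seg <- pos + seq_len(reps) - 1L
      if (max(seg) > length(chars)) break
      if (!all(vapply(chars[seg], function(ch) element_matches(e, ch),
                      logical(1)))) {
        next
      }
    }
    rest <- match_spans(elements, idx + 1L, chars, pos + reps)
    spans <- c(spans, reps + rest)
  }
  unique(spans)
}

#' Scan a sequence with a PROSITE pattern
#'
#' Reports every distinct start position at which the pattern matches,
#' backtracking over variable repetition bounds. Overlapping matches at
#' different starts are all reported; at each start the shortest satisfying
#' span is given. Matching is case-insensitive in the sequence.
#'
#' @param pattern A [parse_prosite()] object.
#' @param sequence Protein sequence string.
#' @param sequence_id Identifier recorded in the result.
#' @return Data frame with columns `pattern_id`, `sequence_id`, `start`
#'   (1-based), `match` (the matched span); zero rows when there is no
#'   match.
#' @examples
#' ps <- parse_prosite("C-P-x(0,1)-[ST]-N-[ILV]-G-T", id = "PS00112")
#' scan_prosite(ps, "HLGYVLTCPSNLGTG", "creatine_kinase")
#' @export
scan_prosite <- function(pattern, sequence, sequence_id = "") {
  stopifnot(inherits(pattern, "prosite_pattern"))
  chars <- pep_chars(toupper(sequence))
  starts <- integer(0); spans <- integer(0)
  for (s in seq_along(chars)) {
    hit <- match_spans(pattern$elements, 1L, chars, s)
    if (length(hit) > 0L) {
      starts <- c(starts, s)
      spans <- c(spans, min(hit))
    }
  }
  if (length(starts) == 0L) {
    return(data.frame(pattern_id = character(0), sequence_id = character(0),
                      start = integer(0), match = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(pattern_id = rep(pattern$id, length(starts)),
             sequence_id = rep(sequence_id, length(starts)),
             start = starts,
             match = substring(paste(chars, collapse = ""), starts,
                               starts + spans - 1L),
             stringsAsFactors = FALSE)
}

#' Count motif occurrences in positive and negative windows
#'
#' For each pattern, counts how many windows of each label contain at least
#' one match — the motif-analysis summary for a window set.
#'
#' @param patterns List of [parse_prosite()] objects.
#' @param windows Window data frame (`peptide`, `label`).
#' @return Data frame with columns `pattern_id`,
#'   `n_matching_positive_windows`, `n_matching_negative_windows`.
#' @export
motif_report <- function(patterns, windows) {
  rows <- lapply(patterns, function(p) {
    hit <- vapply(seq_len(nrow(windows)), function(i) {
      nrow(scan_prosite(p, windows$peptide[i])) > 0L
    }, logical(1))
    if (nrow(windows) == 0L) hit <- logical(0)
    data.frame(pattern_id = p$id,
               n_matching_positive_windows =
                 sum(hit & windows$label == "positive"),
               n_matching_negative_windows =
                 sum(hit & windows$label == "negative"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' The four motif patterns used in the worked example
#'
#' Phosphagen kinase active site (PS00112), glyceraldehyde 3-phosphate
#' dehydrogenase active site (PS00071), NF-kB/Rel/dorsal domain signature
#' (PS01204), and the eukaryotic thiol protease cysteine active site
#' (PS00139) — motifs recovered around known S-glutathionylation sites.
#'
#' @return Named list of `prosite_pattern` objects.
#' @export
worked_example_patterns <- function() {
  specs <- c(
    PS00112 = "C-P-x(0,1)-[ST]-N-[ILV]-G-T",
    PS00071 = "[ASV]-S-C-[NT]-T-{S}-x-[LIM]",
    PS01204 = "F-R-Y-x-C-E-G",
    PS00139 = "Q-{V}-x-{DE}-[GE]-{F}-C-[YW]-{DN}-x-[STAGC]-[STAGCV]")
  out <- lapply(names(specs), function(id) parse_prosite(specs[[id]], id))
  names(out) <- names(specs)
  out
}
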