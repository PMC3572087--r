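#' Configuration for the synthetic dataset generator
#'
#' The defaults mirror the shape of a realistic curated S-glutathionylation
#' corpus: 39 proteins, 75 positive cysteines in total (so roughly two per
#' protein), at most three sampled negatives per positive per protein, and
#' protein lengths around 300 residues. Sequences are drawn residue-wise
#' from `background` (uniform 1/20 by default); the learnable signal is a
#' set of single-residue enrichments at fixed offsets from the positive
#' cysteine.
#'
#' @param n_proteins Number of proteins.
#' @param length_mean,length_sd Protein length distribution (normal,
#'   truncated below at `2 * margin + 20`).
#' @param n_positive_sites Total positive cysteines across all proteins.
#' @param negative_ratio Per-protein cap on negatives per positive.
#' @param signal `NULL` (no signal) or a data frame with columns `offset`
#'   (in -7..7, never 0 — the center is always the cysteine itself),
#'   `residue`, `enrichment` (probability that the residue is placed at that
#'   offset in a positive window).
#' @param background Length-20 residue probability vector in the fixed
#'   alphabet order (sums to 1).
#' @param window Window width used for negative-eligibility filtering.
#' @param margin Minimum distance of planted sites from either terminus
#'   (default 10, so windows up to width 21 survive extraction).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_proteins = 39, length_mean = 300,
                         length_sd = 60, n_positive_sites = 75,
                         negative_ratio = 3, signal = NULL,
                         background = rep(1 / 20, 20), window = 15,
                         margin = 10, seed = 1) {
  if (length(background) != 20L || any(background < 0) ||
      abs(sum(background) - 1) > 1e-8) {
    stop("background must be 20 non-negative probabilities summing to 1",
         call. = FALSE)
  }
  if (!is.null(signal)) {
    stopifnot(all(c("offset", "residue", "enrichment") %in% names(signal)))
    if (any(signal$offset == 0) || any(abs(signal$offset) > 7)) {
      stop("signal offsets must be in -7..7, excluding 0", call. = FALSE)
    }
    if (any(signal$enrichment < 0 | signal$enrichment > 1)) {
      stop("enrichment must be a probability", call. = FALSE)
    }
    if (!all(signal$residue %in% AA20)) {
      stop("signal residues must be standard amino acids", call. = FALSE)
    }
  }
  if (negative_ratio < 1) stop("negative_ratio must be >= 1", call. = FALSE)
  structure(list(n_proteins = as.integer(n_proteins),
                 length_mean = length_mean, length_sd = length_sd,
                 n_positive_sites = as.integer(n_positive_sites),
                 negative_ratio = as.integer(negative_ratio),
                 signal = signal, background = background,
                 window = check_window_size(window),
                 margin = as.integer(margin), seed = as.integer(seed)),
            class = "synth_config")
}

#' The strong planted-flank signal used for calibration
#'
#' Three single-residue enrichments at contiguous offsets (K at offset -2,
#' E at -1, W at +1), each placed with probability 0.9 in positive windows.
#' The offsets are deliberately contiguous with the central cysteine so the
#' enriched residues form deterministic tripeptides (KEC, ECW): contiguous
#' k-mer encoders can then provably recover the signal. Signal placed at
#' isolated offsets is spread across a wildcard position and diluted
#' twenty-fold per tripeptide feature, which defeats univariate feature
#' selection at realistic sample sizes (see the methods vignette).
#'
#' @return Signal data frame for [synth_config()].
#' @export
strong_signal <- function() {
  data.frame(offset = c(-2L, -1L, 1L), residue = c("K", "E", "W"),
             enrichment = 0.9)
}

#' Generate a synthetic protein dataset with plantable flank signal
#'
#' Draws protein sequences residue-wise from the background distribution,
#' plants positive cysteines at random interior positions (each protein gets
#' at least one while supply lasts), rewrites the flanks of positive sites
#' per the signal specification, and samples negatives from the remaining
#' cysteines at most `negative_ratio` per positive per protein
#' ([sample_negatives()]). Deterministic given `config$seed`: the same seed
#' reproduces the dataset byte for byte.
#'
#' @param config A [synth_config()].
#' @return List with `proteins` (named character vector) and `sites`
#'   (annotation data frame: `protein_id`, `position`, `label`).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(config) {
  min_len <- 2L * config$margin + 20L
  lens <- pmax(min_len,
               round(rnorm(config$n_proteins, config$length_mean,
                           config$length_sd)))
  ids <- sprintf("synthP%03d", seq_len(config$n_proteins))
  # distribute positives: one per protein while supply lasts, rest at random
  n_pos <- config$n_positive_sites
  alloc <- if (n_pos >= config$n_proteins) {
    rep(1L, config$n_proteins)
  } else {
    as.integer(seq_len(config$n_proteins) %in%
                 sample(config$n_proteins, n_pos))
  }
  extra <- n_pos - sum(alloc)
  if (extra > 0L) {
    # cap sites per protein at a third of the interior, keeping windows
    # mostly non-overlapping
    room <- pmax(0L, (lens - 2L * config$margin) %/% 3L - alloc)
    if (extra > sum(room)) {
      stop("infeasible config: too many positive sites (", n_pos,
           ") for ", config$n_proteins, " proteins of mean length ",
           config$length_mean, call. = FALSE)
    }
    pool <- rep(seq_len(config$n_proteins), room)
    pick <- pool[sample.int(length(pool), extra)]
    alloc <- alloc + tabulate(pick, nbins = config$n_proteins)
  }
  proteins <- character(config$n_proteins)
  names(proteins) <- ids
  sites <- list()
  for (i in seq_len(config$n_proteins)) {
    len <- lens[i]
    chars <- sample(AA20, len, replace = TRUE, prob = config$background)
    interior <- seq.int(config$margin + 1L, len - config$margin)
    if (alloc[i] > length(interior)) {
      stop("protein ", ids[i], " too short for ", alloc[i],
           " positive sites; increase length_mean or n_proteins",
           call. = FALSE)
    }
    pos_sites <- sort(sample(interior, alloc[i]))
    chars[pos_sites] <- "C"
    if (!is.null(config$signal)) {
      for (p in pos_sites) {
        for (j in seq_len(nrow(config$signal))) {
          tgt <- p + config$signal$offset[j]
          if (runif(1) <= config$signal$enrichment[j] &&
              !(tgt %in% pos_sites)) {
            chars[tgt] <- config$signal$residue[j]
          }
        }
      }
    }
    seq_str <- paste(chars, collapse = "")
    proteins[i] <- seq_str
    neg <- sample_negatives(seq_str, pos_sites,
                            ratio = config$negative_ratio,
                            w = config$window,
                            seed = sample.int(.Machine$integer.max, 1))
    sites[[i]] <- data.frame(
      protein_id = ids[i],
      position = c(pos_sites, neg),
      label = c(rep("positive", length(pos_sites)),
                rep("negative", length(neg))),
      stringsAsFactors = FALSE)
  }
  list(proteins = proteins, sites = do.call(rbind, sites))
}

#' Write a generated dataset to FASTA + site TSV
#'
#' @param dataset A [generate_dataset()] result.
#' @param fasta_path,sites_path Output paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_dataset <- function(dataset, fasta_path, sites_path) {
  write_fasta(dataset$proteins, fasta_path)
  write.table(dataset$sites, sites_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(fasta = fasta_path, sites = sites_path))
}

#' Five worked-example positive windows
#'
#' Fifteen-residue windows around known S-glutathionylated cysteines of
#' creatine kinase, GAPDH, the NF-kB subunits p50 and p65, and papain. All
#' have the modified cysteine at window position 8 (papain's window contains
#' two cysteines; the second is the center). Used to demonstrate the motif
#' scanner and encoders on real sequence context.
#'
#' @return Window data frame (`protein_id`, `center`, `peptide`, `label`);
#'   `center` is `NA` because only the windows, not full-length parents, are
#'   bundled.
#' @export
worked_example_windows <- function() {
  data.frame(
    protein_id = c("creatine_kinase", "gapdh", "nfkb_p50", "nfkb_p65",
                   "papain"),
    center = NA_integer_,
    peptide = c("HLGYVLTCPSNLGTG", "KIVSNASCTTNCLAP", "GMRFRYKCEGRSAGS",
                "GFRFRYVCEGPSHGG", "NQGSCGSCWAFSAVV"),
    label = "positive",
    stringsAsFactors = FALSE)
}
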