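## Sequence-level characterization: nucleotide composition, A/G-rich
## window scanning, kmer enrichment, and (optional) structure metrics.

#' Per-sequence nucleotide composition
#'
#' Fractions of A, C, G and U/T (U is normalized to T on input) over
#' unambiguous bases; ambiguous bases are excluded from the denominator.
#'
#' @param sequences named character vector or `DNAStringSet`.
#' @return data.frame with `sequence_id`, `frac_a`, `frac_c`, `frac_g`,
#'   `frac_t`, `frac_ag`.
#' @export
composition <- function(sequences) {
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- setNames(as.character(sequences), names(sequences))
  sequences <- normalize_seq(sequences)
  ids <- names(sequences) %||% as.character(seq_along(sequences))
  freq <- Biostrings::alphabetFrequency(Biostrings::DNAStringSet(sequences))
  tot <- rowSums(freq[, DNA_BASES, drop = FALSE])
  data.frame(sequence_id = ids,
             frac_a = freq[, "A"] / tot, frac_c = freq[, "C"] / tot,
             frac_g = freq[, "G"] / tot, frac_t = freq[, "T"] / tot,
             frac_ag = (freq[, "A"] + freq[, "G"]) / tot,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare composition between sequence classes
#'
#' Wilcoxon rank-sum tests of each base fraction (and A+G) between every
#' pair of classes.
#'
#' @param comp a [composition()] data.frame.
#' @param classes factor/character of class labels, one per row.
#' @return data.frame with `metric`, `class_a`, `class_b`, `p_value`.
#' @export
compare_composition <- function(comp, classes) {
  stopifnot(length(classes) == nrow(comp))
  metrics <- c("frac_a", "frac_c", "frac_g", "frac_t", "frac_ag")
  lv <- unique(as.character(classes))
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  do.call(rbind, lapply(metrics, function(m) {
    do.call(rbind, lapply(pairs, function(pr) {
      p <- suppressWarnings(
        wilcox.test(comp[[m]][classes == pr[1]],
                    comp[[m]][classes == pr[2]])$p.value)
      data.frame(metric = m, class_a = pr[1], class_b = pr[2], p_value = p,
                 stringsAsFactors = FALSE)
    }))
  }))
}

#' Most A/G-rich fixed-length window of each sequence
#'
#' Exhaustive scan at step 1 via a sliding sum; ties resolve to the
#' 5'-most start. Sequences shorter than `window` are scored as one
#' whole-sequence window and flagged.
#'
#' @param sequences named character vector or `DNAStringSet`.
#' @param window window length in nt.
#' @param threshold A+G fraction for `passes_threshold` (inclusive).
#' @return data.frame with `sequence_id`, `window_length`,
#'   `max_ag_fraction`, `max_window_start` (0-based), `passes_threshold`,
#'   `whole_sequence`.
#' @export
max_ag_window <- function(sequences, window = 100L, threshold = 0.75) {
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- setNames(as.character(sequences), names(sequences))
  sequences <- normalize_seq(sequences)
  ids <- names(sequences) %||% as.character(seq_along(sequences))
  res <- lapply(sequences, function(s) {
    is_ag <- strsplit(s, "", fixed = TRUE)[[1]] %in% c("A", "G")
    n <- length(is_ag)
    if (n < window) {
      list(frac = mean(is_ag), start = 0L, wlen = n, whole = TRUE)
    } else {
      cs <- c(0, cumsum(is_ag))
      sums <- cs[(window + 1L):(n + 1L)] - cs[1:(n - window + 1L)]
      i <- which.max(sums)                     # 5'-most maximum
      list(frac = sums[i] / window, start = i - 1L, wlen = as.integer(window),
           whole = FALSE)
    }
  })
  data.frame(sequence_id = ids,
             window_length = vapply(res, `[[`, 0L, "wlen"),
             max_ag_fraction = vapply(res, `[[`, 0, "frac"),
             max_window_start = vapply(res, `[[`, 0L, "start"),
             passes_threshold = vapply(res, `[[`, 0, "frac") >= threshold,
             whole_sequence = vapply(res, `[[`, TRUE, "whole"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Association between A/G-rich windows and localization class
#'
#' Flags each UTR for containing a `window`-nt stretch with at least
#' `threshold` A+G content (inclusive) and crosses that flag with a
#' localization classification (e.g. the median-Z >= 2 rule from
#' [zscore_datasets()]), reporting the contingency table, odds ratio and
#' Fisher exact p-value.
#'
#' @param utr_seqs named character vector / `DNAStringSet` of UTRs.
#' @param localized logical vector (same order) of localization calls.
#' @param window,threshold window definition as in [max_ag_window()].
#' @return list with `has_window`, `table`, `odds_ratio`, `p_value`.
#' @export
classify_ag_rich <- function(utr_seqs, localized, window = 100L,
                             threshold = 0.75) {
  scan <- max_ag_window(utr_seqs, window, threshold)
  stopifnot(length(localized) == nrow(scan))
  has <- scan$passes_threshold
  tab <- table(factor(localized, c(FALSE, TRUE)),
               factor(has, c(FALSE, TRUE)),
               dnn = c("localized", "ag_window"))
  ft <- fisher.test(tab)
  list(has_window = setNames(has, scan$sequence_id), table = tab,
       odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}

#' Kmer enrichment between two sequence sets
#'
#' Kmers are counted on the given (RNA-sense) strand only. Enrichment is
#' the log2 ratio of pseudocounted kmer frequencies in foreground vs
#' background (symmetric: swapping sets negates it); significance is a
#' two-sided binomial test of the foreground count against the background
#' frequency, BH-adjusted across all 4^k kmers.
#'
#' @param fg,bg character vectors / `DNAStringSet` of foreground and
#'   background sequences.
#' @param k kmer length.
#' @return data.frame with `kmer`, `fg_count`, `bg_count`, `log2_enrichment`,
#'   `pvalue`, `fdr`, ordered by decreasing enrichment.
#' @export
kmer_enrichment <- function(fg, bg, k = 6L) {
  count_kmers <- function(x) {
    if (!methods::is(x, "DNAStringSet"))
      x <- Biostrings::DNAStringSet(normalize_seq(x))
    if (any(Biostrings::width(x) < k))
      stop("k exceeds the shortest sequence", call. = FALSE)
    colSums(Biostrings::oligonucleotideFrequency(x, width = k))
  }
  fgc <- count_kmers(fg); bgc <- count_kmers(bg)
  ftot <- sum(fgc); btot <- sum(bgc)
  nk <- length(fgc)
  ffreq <- (fgc + 0.5) / (ftot + 0.5 * nk)
  bfreq <- (bgc + 0.5) / (btot + 0.5 * nk)
  p0 <- pmin(pmax(bfreq, 1e-12), 1 - 1e-12)
  pv <- vapply(seq_len(nk), function(i)
    binom.test(fgc[i], ftot, p0[i])$p.value, 0)
  out <- data.frame(kmer = names(fgc), fg_count = as.integer(fgc),
                    bg_count = as.integer(bgc),
                    log2_enrichment = log2(ffreq / bfreq),
                    pvalue = pv, fdr = p.adjust(pv, "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$log2_enrichment), ]
}

## G-quadruplex regex fallback: four runs of >= 3 G separated by loops of
## 1-7 bases.
QUADRUPLEX_REGEX <- "G{3,}[ACGTU]{1,7}G{3,}[ACGTU]{1,7}G{3,}[ACGTU]{1,7}G{3,}"

#' Windowed RNA folding profile
#'
#' Slides an 80-nt window 5 nt at a time, folds each window with an
#' external `RNAfold` binary when `backend = "external"` (the median
#' window MFE summarizes the sequence; the backend's `-g` mode flags
#' predicted G-quadruplexes), and otherwise reports `NA` energies with a
#' regex-based quadruplex flag (four G>=3 runs with 1-7 nt loops).
#' Sequences shorter than the window are folded as one whole-sequence
#' window.
#'
#' @param sequences named character vector / `DNAStringSet`.
#' @param backend `"none"` (regex quadruplex flag only) or `"external"`
#'   (requires `RNAfold` on PATH; missing binary is an error, never a
#'   silent fallback).
#' @param window,slide window geometry in nt.
#' @return data.frame with `sequence_id`, `n_windows`, `median_mfe`,
#'   `quadruplex_predicted`; attribute `window_mfe` holds the per-window
#'   energies.
#' @export
fold_profile <- function(sequences, backend = c("none", "external"),
                         window = 80L, slide = 5L) {
  backend <- match.arg(backend)
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- setNames(as.character(sequences), names(sequences))
  sequences <- normalize_seq(sequences)
  ids <- names(sequences) %||% as.character(seq_along(sequences))
  if (backend == "external" && Sys.which("RNAfold") == "")
    stop("backend='external' but RNAfold is not on PATH", call. = FALSE)
  win_list <- lapply(sequences, function(s) {
    n <- nchar(s)
    if (n <= window) return(s)
    starts <- seq.int(1L, n - window + 1L, by = slide)
    substring(s, starts, starts + window - 1L)
  })
  mfe_list <- lapply(win_list, function(w) {
    if (backend == "none") return(rep(NA_real_, length(w)))
    rnafold_mfe(w)
  })
  quad <- if (backend == "external") {
    vapply(sequences, function(s) rnafold_quadruplex(s), TRUE)
  } else {
    grepl(QUADRUPLEX_REGEX, sequences, perl = TRUE)
  }
  out <- data.frame(sequence_id = ids,
                    n_windows = vapply(win_list, length, 0L),
                    median_mfe = vapply(mfe_list, function(x)
                      if (all(is.na(x))) NA_real_ else median(x), 0),
                    quadruplex_predicted = unname(quad),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "window_mfe") <- mfe_list
  out
}

## Fold a batch of windows with RNAfold, returning MFEs (kcal/mol).
rnafold_mfe <- function(seqs) {
  out <- system2("RNAfold", c("--noPS"), input = seqs, stdout = TRUE)
  struct_lines <- grep("\\(\\s*-?[0-9.]+\\s*\\)\\s*$", out, value = TRUE)
  as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$", "\\1", struct_lines))
}

## Quadruplex prediction via RNAfold -g: the structure string contains '+'
## runs when a quadruplex is part of the MFE structure.
rnafold_quadruplex <- function(seq) {
  out <- system2("RNAfold", c("--noPS", "-g"), input = seq, stdout = TRUE)
  any(grepl("\\+", out[-1]))
}
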