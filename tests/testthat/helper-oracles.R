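## Independent oracles. These deliberately take different algorithmic
## routes from the package implementations they check.

## Union-calling oracle: run-length formulation of the x/y/x+2y rule.
## Enriched runs R1, G1, R2, G2, ... (runs/gaps from rle): a gap of length
## y between two enriched runs is bridged iff the next enriched run has
## length >= y (the y oligos after the gap are then all enriched, and the
## traversal resumes inside or just after that run with a fresh x/y). A
## trailing gap can never be bridged. Windows are maximal chains of
## bridge-connected runs.
oracle_unions <- function(enriched) {
  if (!any(enriched)) return(list())
  r <- rle(enriched)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)                  # indices into rle of enriched runs
  spans <- list()
  cur_start <- starts[runs[1]]
  cur_end <- ends[runs[1]]
  if (length(runs) > 1) {
    for (i in seq_len(length(runs) - 1L)) {
      this_run <- runs[i]; next_run <- runs[i + 1L]
      gap_len <- starts[next_run] - ends[this_run] - 1L
      if (gap_len <= r$lengths[next_run] && next_run == this_run + 2L) {
        cur_end <- ends[next_run]          # bridge: absorb gap + next run
      } else {
        spans[[length(spans) + 1L]] <- c(cur_start, cur_end)
        cur_start <- starts[next_run]
        cur_end <- ends[next_run]
      }
    }
  }
  spans[[length(spans) + 1L]] <- c(cur_start, cur_end)
  spans
}

## Brute-force maximum A/G window: recompute the fraction of every start
## by substring counting (O(n*w)).
oracle_max_ag <- function(seq, window) {
  n <- nchar(seq)
  if (n < window) {
    ch <- strsplit(seq, "")[[1]]
    return(list(frac = mean(ch %in% c("A", "G")), start = 0L))
  }
  best <- -1; best_start <- 0L
  for (s in 0:(n - window)) {
    w <- substr(seq, s + 1L, s + window)
    f <- sum(strsplit(w, "")[[1]] %in% c("A", "G")) / window
    if (f > best + 1e-15) { best <- f; best_start <- s }
  }
  list(frac = best, start = best_start)
}

## Exact-match read-assignment oracle for error-free reads: dictionary
## lookup of the forward+reverse sequence pair.
oracle_exact_assign <- function(fwd_seq, rev_bio_seq, pool, fwd_len, rev_len) {
  key_ref <- paste0(substr(pool$insert_sequence, 1, fwd_len), "|",
                    substr(as.character(Biostrings::reverseComplement(
                      Biostrings::DNAStringSet(pool$insert_sequence))),
                      1, rev_len))
  lut <- setNames(pool$oligo_id, key_ref)
  unname(lut[paste0(fwd_seq, "|", rev_bio_seq)])
}

## Brute-force per-position oligo coverage of a tiled pool.
oracle_coverage <- function(pool, positions, oligo_length) {
  vapply(positions, function(p)
    sum(pool$offset <= p & pool$offset + oligo_length > p), 0L)
}

random_enrichment_vector <- function(len, density) {
  runif(len) < density
}
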