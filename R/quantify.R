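## Reads -> per-oligo UMI counts: adapter trimming, read-to-oligo
## assignment (builtin seed-and-score aligner or external SAM), UMI
## deduplication.

#' Adapter trimming specification
#'
#' @param fwd_adapter,rev_adapter adapter sequences expected at the 5' ends
#'   of forward and reverse reads.
#' @param max_mismatch_fraction tolerated mismatch fraction within the
#'   adapter match.
#' @return an object of class `trim_spec`.
#' @export
trim_spec <- function(
    fwd_adapter = "GGCGGAAAGATCGCCGTGTAAGTTTGCTTCGATATCCGCATGCTA",
    rev_adapter = "CTGATCAGCGGGTTTCACTAGTGCGACCGCAAGAG",
    max_mismatch_fraction = 0.1) {
  stopifnot(nzchar(fwd_adapter), nzchar(rev_adapter))
  assert_scalar_num(max_mismatch_fraction, "max_mismatch_fraction", 0, 1)
  structure(list(fwd_adapter = normalize_seq(fwd_adapter),
                 rev_adapter = normalize_seq(rev_adapter),
                 max_mismatch_fraction = max_mismatch_fraction),
            class = "trim_spec")
}

## Number of mismatches between each read's prefix and `adapter`.
prefix_mismatches <- function(seqs, adapter) {
  L <- nchar(adapter)
  a <- strsplit(adapter, "", fixed = TRUE)[[1]]
  short <- nchar(seqs) < L
  mm <- rep.int(L, length(seqs))          # too-short reads: treated as all-mm
  if (any(!short)) {
    m <- str_to_mat(substr(seqs[!short], 1L, L))
    mm[!short] <- rowSums(m != matrix(a, nrow(m), L, byrow = TRUE))
  }
  mm
}

#' Trim 5' adapters from a read pair
#'
#' Pairs whose forward or reverse read lacks the expected adapter (more
#' than `max_mismatch_fraction` mismatches over the adapter length) are
#' dropped and counted in the report.
#'
#' @param fwd,rev data.frames with columns `name`, `seq` (as from
#'   [read_fastq()] or [simulate_reads()]).
#' @param spec a [trim_spec()].
#' @return list with trimmed `fwd`, `rev`, and `report` (`n_input`,
#'   `n_kept`, `n_dropped`, `fraction_retained`).
#' @export
trim_adapters <- function(fwd, rev, spec = trim_spec()) {
  stopifnot(nrow(fwd) == nrow(rev), all(fwd$name == rev$name))
  mm_f <- prefix_mismatches(fwd$seq, spec$fwd_adapter)
  mm_r <- prefix_mismatches(rev$seq, spec$rev_adapter)
  ok <- (mm_f <= spec$max_mismatch_fraction * nchar(spec$fwd_adapter)) &
    (mm_r <= spec$max_mismatch_fraction * nchar(spec$rev_adapter))
  out_f <- fwd[ok, , drop = FALSE]
  out_r <- rev[ok, , drop = FALSE]
  out_f$seq <- substr(out_f$seq, nchar(spec$fwd_adapter) + 1L, 1e9L)
  out_r$seq <- substr(out_r$seq, nchar(spec$rev_adapter) + 1L, 1e9L)
  list(fwd = out_f, rev = out_r,
       report = list(n_input = nrow(fwd), n_kept = sum(ok),
                     n_dropped = sum(!ok),
                     fraction_retained = if (nrow(fwd)) mean(ok) else NA_real_))
}

#' Assign read pairs to pool oligos
#'
#' The builtin assigner nominates candidate oligos by exact k-mer seeds at
#' fixed offsets of the end-anchored templates (forward read vs oligo 5'
#' end, reverse read vs reverse-complemented 3' end) and scores candidates
#' with a banded start-anchored edit distance on both mates; the single
#' best-scoring oligo is taken, score ties are left unassigned. `effort`
#' mirrors the seed-extension effort knob of end-to-end aligners:
#' `"default"` probes one seed per mate, `"high"` probes every
#' non-overlapping seed and falls back to an exhaustive scan when seeding
#' fails, which is what makes 100% correct assignment attainable on dense
#' (2-nt step) libraries.
#'
#' The UMI is captured as the first `umi_len` nt of the reverse read before
#' assignment; the remainder of the reverse read is the biological part.
#'
#' @param fwd,rev read data.frames (`name`, `seq`); reverse reads carry the
#'   UMI prefix.
#' @param pool an `oligo_pool`.
#' @param effort `"default"` or `"high"`.
#' @param umi_len UMI length at the reverse read 5' end (0 = none).
#' @param seed_k seed k-mer length.
#' @param band band half-width of the edit-distance DP (max indel shift).
#' @param max_dist maximum per-mate edit distance for a valid assignment.
#' @return data.frame of assignment records: `read_name`, `oligo_id`
#'   (`NA` = unassigned), `mapping_quality` (distance margin to the
#'   second-best candidate), `umi`.
#' @export
assign_reads <- function(fwd, rev, pool, effort = c("default", "high"),
                         umi_len = 8L, seed_k = 16L, band = 4L,
                         max_dist = 20L) {
  effort <- match.arg(effort)
  stopifnot(nrow(fwd) == nrow(rev))
  umi <- substr(rev$seq, 1L, umi_len)
  rev_bio <- substr(rev$seq, umi_len + 1L, 1e9L)
  fwd_len <- max(nchar(fwd$seq)); rev_len <- max(nchar(rev_bio))
  insert <- normalize_seq(pool$insert_sequence)
  fwd_tpl <- substr(insert, 1L, fwd_len + band)
  rc <- revcomp(insert)
  rev_tpl <- substr(rc, 1L, rev_len + band)
  n_seed_f <- if (effort == "high") max(1L, fwd_len %/% seed_k) else 1L
  n_seed_r <- if (effort == "high") max(1L, rev_len %/% seed_k) else 1L
  res <- assign_reads_cpp(fwd$seq, rev_bio, fwd_tpl, rev_tpl,
                          as.integer(seed_k), n_seed_f, n_seed_r,
                          effort == "high", as.integer(band),
                          as.integer(max_dist))
  data.frame(read_name = fwd$name,
             oligo_id = pool$oligo_id[res$assignment],
             mapping_quality = res$margin,
             umi = umi, stringsAsFactors = FALSE)
}

#' Ingest assignments from an external aligner's SAM output
#'
#' Any SAM-emitting end-to-end aligner (run with flags equivalent to
#' `-q --end-to-end --fr --no-discordant --no-unal`, plus `-D 150` for high
#' effort in the bowtie2 dialect) can substitute for the builtin assigner.
#' Primary, properly-paired first-mate records are converted to assignment
#' records.
#'
#' @param path SAM file.
#' @param umis optional named character vector mapping read name to UMI
#'   (captured from the raw reverse reads before alignment).
#' @return assignment record data.frame as in [assign_reads()].
#' @export
read_sam_assignments <- function(path, umis = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L)
    return(data.frame(read_name = character(), oligo_id = character(),
                      mapping_quality = integer(), umi = character(),
                      stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  qname <- vapply(f, `[[`, "", 1L)
  flag <- as.integer(vapply(f, `[[`, "", 2L))
  rname <- vapply(f, `[[`, "", 3L)
  mapq <- as.integer(vapply(f, `[[`, "", 5L))
  primary_first <- bitwAnd(flag, 0x100L) == 0L & bitwAnd(flag, 0x40L) != 0L
  keep <- primary_first
  mapped <- bitwAnd(flag[keep], 0x4L) == 0L & bitwAnd(flag[keep], 0x2L) != 0L
  oligo <- ifelse(mapped, rname[keep], NA_character_)
  data.frame(read_name = qname[keep], oligo_id = oligo,
             mapping_quality = ifelse(mapped, mapq[keep], NA_integer_),
             umi = if (is.null(umis)) NA_character_ else
               unname(umis[qname[keep]]),
             stringsAsFactors = FALSE)
}

#' Collapse assignments to per-oligo unique-UMI counts
#'
#' `count[oligo, sample]` is the number of distinct UMI strings among reads
#' assigned to that oligo in that sample (exact-match deduplication; no
#' Hamming clustering). Oligos with no reads keep a zero row so the
#' differential stage sees the full pool.
#'
#' @param assignments a single assignment data.frame (one sample) or a
#'   named list of them (one per sample).
#' @param pool an `oligo_pool` defining the row universe.
#' @param samples sample sheet data.frame (`sample`, `compartment`,
#'   `replicate`); defaults to a single nameless sample when `assignments`
#'   is a lone data.frame.
#' @param dedup count distinct UMIs (`TRUE`, default) or raw assigned reads
#'   (`FALSE`).
#' @return a `count_matrix`.
#' @export
count_umis <- function(assignments, pool, samples = NULL, dedup = TRUE) {
  if (is.data.frame(assignments)) assignments <- list(sample1 = assignments)
  if (is.null(samples))
    samples <- data.frame(sample = names(assignments),
                          compartment = rep("soma", length(assignments)),
                          replicate = seq_along(assignments),
                          stringsAsFactors = FALSE)
  stopifnot(all(samples$sample %in% names(assignments)))
  counts <- matrix(0L, nrow(pool), nrow(samples),
                   dimnames = list(pool$oligo_id, samples$sample))
  for (s in samples$sample) {
    a <- assignments[[s]]
    a <- a[!is.na(a$oligo_id), , drop = FALSE]
    if (!all(a$oligo_id %in% pool$oligo_id))
      stop("assignment references oligo not in pool", call. = FALSE)
    if (nrow(a)) {
      tab <- if (dedup)
        tapply(a$umi, a$oligo_id, function(u) length(unique(u))) else
          tapply(a$umi, a$oligo_id, length)
      counts[names(tab), s] <- as.integer(tab)
    }
  }
  count_matrix(counts, samples)
}
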