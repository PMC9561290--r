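## File formats: pool FASTA/manifest, counts TSV, sample sheets, FASTQ,
## windows BED, GTF transcript models. FASTA is handled by Biostrings; GTF
## by rtracklayer; FASTQ by a minimal 4-line reader/writer (gzip-aware via
## R connections) because reads carry package-specific name/UMI structure.

#' Read transcript models from a GTF/GFF file
#'
#' Imports `three_prime_UTR` (or `3UTR`) features and turns them into
#' [transcript_model()] objects, one per transcript (multi-exon UTRs are
#' spanned). Annotation `tag` attributes are preserved so that the
#' not-found-end filter in [merge_utrs()] can act on them.
#'
#' @param path GTF/GFF3 file.
#' @return named list of `transcript_model` lists, one entry per gene.
#' @export
read_transcript_models <- function(path) {
  gr <- rtracklayer::import(path)
  type <- tolower(as.character(gr$type))
  gr <- gr[type %in% c("three_prime_utr", "3utr", "utr3")]
  if (length(gr) == 0L) stop("no three_prime_UTR features in ", path,
                             call. = FALSE)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # GTF is 1-based inclusive
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    transcript_id = gr$transcript_id, gene_id = gr$gene_id,
    stringsAsFactors = FALSE)
  tags <- if ("tag" %in% names(S4Vectors::mcols(gr))) gr$tag else
    rep(list(character()), length(gr))
  if (!is.list(tags)) tags <- as.list(as.character(tags))
  models <- lapply(split(seq_len(nrow(df)), df$transcript_id), function(ix) {
    tag_set <- unique(unlist(tags[ix]))
    tag_set <- tag_set[!is.na(tag_set)]
    transcript_model(
      transcript_id = df$transcript_id[ix[1]], gene_id = df$gene_id[ix[1]],
      chrom = df$chrom[ix[1]], start = min(df$start[ix]),
      end = max(df$end[ix]), strand = df$strand[ix[1]], tags = tag_set)
  })
  split(unname(models), vapply(models, `[[`, "", "gene_id"))
}

#' Write an oligo pool as FASTA plus manifest TSV
#'
#' FASTA ids are `oligo_id` with a description carrying `gene_id` and
#' `offset`; the manifest TSV has columns `oligo_id`, `gene_id`, `offset`,
#' `insert_sequence`. Output is deterministic (byte-identical for identical
#' pools).
#'
#' @param pool an `oligo_pool`.
#' @param prefix output path prefix; writes `<prefix>.fasta` and
#'   `<prefix>_manifest.tsv`.
#' @param full use `full_sequence` (with handles) in the FASTA instead of
#'   the insert.
#' @return invisibly, the two paths.
#' @export
write_pool <- function(pool, prefix, full = FALSE) {
  fa <- paste0(prefix, ".fasta"); tsv <- paste0(prefix, "_manifest.tsv")
  seqs <- Biostrings::DNAStringSet(
    if (full) pool$full_sequence else pool$insert_sequence)
  names(seqs) <- sprintf("%s %s offset=%d", pool$oligo_id, pool$gene_id,
                         pool$offset)
  Biostrings::writeXStringSet(seqs, fa)
  write.table(pool[, c("oligo_id", "gene_id", "offset", "insert_sequence")],
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fa, manifest = tsv))
}

#' Read a pool manifest TSV
#' @param path manifest written by [write_pool()].
#' @return an `oligo_pool` data.frame (without `full_sequence`).
#' @export
read_manifest <- function(path) {
  pool <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  class(pool) <- c("oligo_pool", "data.frame")
  pool
}

#' Construct a count matrix with sample metadata
#'
#' @param counts non-negative integer matrix, rows = oligos, columns =
#'   samples.
#' @param samples data.frame with columns `sample`, `compartment`
#'   (`soma`/`neurite`) and `replicate`, one row per count column.
#' @return an object of class `count_matrix`.
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == nrow(samples),
            all(c("sample", "compartment", "replicate") %in% names(samples)),
            !anyDuplicated(samples$sample),
            all(samples$compartment %in% c("soma", "neurite")))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  colnames(counts) <- samples$sample
  structure(list(counts = counts, samples = as.data.frame(samples)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d oligos x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(table(x$samples$compartment), collapse = " soma/neurite ")))
  invisible(x)
}

#' Write / read a count matrix as TSV pair
#'
#' `<prefix>_counts.tsv` holds the oligo x sample matrix (first column
#' `oligo_id`), `<prefix>_samples.tsv` the sample sheet.
#'
#' @param cm a `count_matrix`.
#' @param prefix output prefix.
#' @return invisibly, the two paths.
#' @export
write_counts <- function(cm, prefix) {
  cpath <- paste0(prefix, "_counts.tsv"); spath <- paste0(prefix, "_samples.tsv")
  df <- data.frame(oligo_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, cpath, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cm$samples, spath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(counts = cpath, samples = spath))
}

#' @rdname write_counts
#' @param counts_path,samples_path the two TSVs.
#' @export
read_counts <- function(counts_path, samples_path) {
  df <- read.table(counts_path, header = TRUE, sep = "\t",
                   check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  samples <- read.table(samples_path, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
  count_matrix(m, samples)
}

#' Write reads to FASTQ (gzip-aware)
#'
#' @param names,seqs character vectors of read names and sequences.
#' @param path output path; `.gz` suffix triggers gzip compression.
#' @param qual constant quality character (reads carry no quality model).
#' @return invisibly, `path`.
#' @export
write_fastq <- function(names, seqs, path, qual = "I") {
  stopifnot(length(names) == length(seqs))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  rec <- paste0("@", names, "\n", seqs, "\n+\n",
                strrep(qual, nchar(seqs)))
  writeLines(rec, con)
  invisible(path)
}

#' Read a FASTQ file into names and sequences
#'
#' @param path FASTQ path (`.gz` supported).
#' @return data.frame with columns `name` and `seq`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  if (length(lines) %% 4L != 0L)
    stop(sprintf("truncated FASTQ '%s' at record %d", path,
                 length(lines) %/% 4L + 1L), call. = FALSE)
  idx <- seq(1L, length(lines), by = 4L)
  data.frame(name = sub("^@", "", sub("\\s.*$", "", lines[idx])),
             seq = lines[idx + 1L], stringsAsFactors = FALSE)
}

#' Write called windows as BED6 plus a detail TSV
#'
#' BED intervals are the union intervals in UTR coordinates (0-based,
#' end-exclusive); score is the peak oligo's log2 fold change.
#'
#' @param windows data.frame from [call_unions()].
#' @param prefix output prefix; writes `<prefix>_windows.bed` and
#'   `<prefix>_windows.tsv`.
#' @return invisibly, the two paths.
#' @export
write_windows <- function(windows, prefix) {
  bed <- paste0(prefix, "_windows.bed"); tsv <- paste0(prefix, "_windows.tsv")
  if (nrow(windows) == 0L) {
    file.create(bed)
    hdr <- setdiff(names(windows), "member_oligos")
    writeLines(paste(c(hdr, "member_oligos"), collapse = "\t"), tsv)
    return(invisible(c(bed = bed, detail = tsv)))
  }
  bed_df <- data.frame(windows$gene_id, windows$union_start,
                       windows$union_end,
                       paste0(windows$gene_id, ":window",
                              seq_len(nrow(windows))),
                       round(windows$peak_log2fc, 4),
                       rep("+", nrow(windows)))
  write.table(bed_df, bed, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  out <- windows
  out$member_oligos <- vapply(windows$member_oligos, paste, "",
                              collapse = ",")
  write.table(out, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(bed = bed, detail = tsv))
}
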