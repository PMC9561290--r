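## Oligo pool design: meta-UTR assembly, inclusion filters, dense tiling.
##
## Coordinates are 0-based, end-exclusive throughout (BED convention).
## Oligo offsets are relative to meta-UTR position 0; negative offsets lie
## in the upstream flank.

#' Transcript model
#'
#' Minimal description of one transcript's 3' UTR used by the designer.
#'
#' @param transcript_id,gene_id identifiers.
#' @param chrom chromosome / sequence name (must exist in the genome used
#'   for [merge_utrs()]).
#' @param start,end 0-based end-exclusive genomic interval of the 3' UTR.
#' @param strand "+" or "-".
#' @param tags character vector of annotation tags. Transcripts tagged
#'   `cds_end_NF` or `mRNA_end_NF` (not-found 3' ends) are excluded from
#'   meta-UTR assembly.
#' @param polya_site genomic position of the polyA site; defaults to the
#'   3'-most UTR coordinate.
#' @return an object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, start, end,
                             strand = c("+", "-"), tags = character(),
                             polya_site = NULL) {
  strand <- match.arg(strand)
  stopifnot(end > start, start >= 0)
  if (is.null(polya_site))
    polya_site <- if (strand == "+") end else start
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, start = as.integer(start),
                 end = as.integer(end), strand = strand,
                 tags = as.character(tags),
                 polya_site = as.integer(polya_site)),
            class = "transcript_model")
}

## Tags marking transcripts whose 3' end is not confidently defined.
INCOMPLETE_END_TAGS <- c("cds_end_NF", "mRNA_end_NF")

#' Meta-UTR container
#'
#' The positional merge of all filter-passing 3' UTR isoforms of one gene,
#' with genomic flanks of the configured length on each side: the tiling
#' substrate.
#'
#' @param gene_id gene identifier.
#' @param sequence UTR sequence (5'->3' in transcript orientation, no
#'   flanks).
#' @param upstream_flank,downstream_flank flanking sequence in transcript
#'   orientation.
#' @param source_transcripts transcript ids merged into this meta-UTR.
#' @param chrom,strand,utr_start,utr_end,polya_site genomic anchors
#'   (optional for purely synthetic meta-UTRs).
#' @return an object of class `meta_utr`.
#' @export
meta_utr <- function(gene_id, sequence, upstream_flank = "",
                     downstream_flank = "", source_transcripts = character(),
                     chrom = NA_character_, strand = NA_character_,
                     utr_start = NA_integer_, utr_end = NA_integer_,
                     polya_site = NA_integer_) {
  structure(list(gene_id = gene_id, sequence = normalize_seq(sequence),
                 upstream_flank = normalize_seq(upstream_flank),
                 downstream_flank = normalize_seq(downstream_flank),
                 source_transcripts = source_transcripts,
                 chrom = chrom, strand = strand,
                 utr_start = utr_start, utr_end = utr_end,
                 polya_site = polya_site),
            class = "meta_utr")
}

#' @export
print.meta_utr <- function(x, ...) {
  cat(sprintf("<meta_utr> %s: %d nt UTR, flanks %d/%d nt, %d transcript(s)\n",
              x$gene_id, nchar(x$sequence), nchar(x$upstream_flank),
              nchar(x$downstream_flank), length(x$source_transcripts)))
  invisible(x)
}

## Extract genomic [start, end) (0-based, end-exclusive) from a genome
## (named character vector or DNAStringSet), padding with N out of range.
extract_genomic <- function(genome, chrom, start, end) {
  if (methods::is(genome, "DNAStringSet")) {
    seqs <- as.character(genome)
  } else seqs <- genome
  if (!chrom %in% names(seqs))
    stop("chromosome not in genome: ", chrom, call. = FALSE)
  s <- seqs[[chrom]]
  L <- nchar(s)
  lo <- max(start, 0L); hi <- min(end, L)
  core <- if (hi > lo) substr(s, lo + 1L, hi) else ""
  paste0(strrep("N", max(0L, -start)), core, strrep("N", max(0L, end - L)))
}

#' Merge a gene's 3' UTR isoforms into a meta-UTR
#'
#' Transcripts whose 3' ends are flagged as not-found (`cds_end_NF` /
#' `mRNA_end_NF` tags) are excluded before merging. The meta-UTR spans the
#' union of the remaining transcripts' UTR intervals in genomic coordinates
#' (reported 5'->3' in transcript orientation), and carries genomic flanks
#' of `params$flank_extension` nt on each side.
#'
#' @param models list of [transcript_model()] objects, all for one gene.
#' @param genome named character vector or `Biostrings::DNAStringSet`.
#' @param params a [design_params()] object.
#' @return a `meta_utr`, or `NULL` (with a `reason` attribute) when the gene
#'   must be rejected (mixed strand/chromosome, or no tag-passing
#'   transcript).
#' @export
merge_utrs <- function(models, genome, params = design_params()) {
  stopifnot(length(models) >= 1L)
  gene_id <- unique(vapply(models, `[[`, "", "gene_id"))
  if (length(gene_id) != 1L)
    stop("all models must share one gene_id", call. = FALSE)
  keep <- vapply(models, function(m) !any(m$tags %in% INCOMPLETE_END_TAGS),
                 logical(1))
  models <- models[keep]
  reject <- function(why) {
    message("gene ", gene_id, " rejected: ", why)
    NULL
  }
  if (length(models) == 0L)
    return(reject("no transcript with a well-defined 3' end"))
  chrom <- unique(vapply(models, `[[`, "", "chrom"))
  strand <- unique(vapply(models, `[[`, "", "strand"))
  if (length(chrom) != 1L) return(reject("transcripts on multiple chromosomes"))
  if (length(strand) != 1L) return(reject("transcripts on mixed strands"))
  start <- min(vapply(models, `[[`, 0L, "start"))
  end <- max(vapply(models, `[[`, 0L, "end"))
  fl <- params$flank_extension
  utr <- extract_genomic(genome, chrom, start, end)
  left <- extract_genomic(genome, chrom, start - fl, start)
  right <- extract_genomic(genome, chrom, end, end + fl)
  if (strand == "-") {
    utr <- revcomp(utr)
    tmp <- revcomp(left); left <- revcomp(right); right <- tmp
  }
  polya <- if (strand == "+") end else start
  meta_utr(gene_id = gene_id, sequence = utr,
           upstream_flank = left, downstream_flank = right,
           source_transcripts = vapply(models, `[[`, "", "transcript_id"),
           chrom = chrom, strand = strand, utr_start = start, utr_end = end,
           polya_site = polya)
}

#' Apply gene-level inclusion filters
#'
#' Retains genes whose meta-UTR is at most `params$max_utr_length` nt long
#' and whose polyA site lies within 200 nt of a conserved polyA site.
#' Conservation is consumed as a precomputed site list (e.g. lifted over
#' from another genome); the liftOver itself is out of scope here.
#'
#' @param metas list of `meta_utr` objects (NULL entries are dropped).
#' @param conserved_polya data.frame with columns `chrom` and `pos`
#'   (0-based positions), or a numeric vector of positions when chromosomes
#'   are not tracked. `NULL` disables the conservation filter (synthetic
#'   designs).
#' @param params a [design_params()] object.
#' @param max_polya_distance maximum distance (nt) to a conserved site.
#' @return the retained `meta_utr` list; attribute `audit` is a data.frame
#'   of per-gene filter outcomes (genes are never silently dropped).
#' @export
filter_genes <- function(metas, conserved_polya = NULL,
                         params = design_params(),
                         max_polya_distance = 200L) {
  metas <- Filter(Negate(is.null), metas)
  status <- character(length(metas)); reason <- character(length(metas))
  keep <- logical(length(metas))
  for (i in seq_along(metas)) {
    m <- metas[[i]]
    if (nchar(m$sequence) > params$max_utr_length) {
      status[i] <- "removed"
      reason[i] <- sprintf("UTR length %d > %d", nchar(m$sequence),
                           params$max_utr_length)
      next
    }
    if (!is.null(conserved_polya) && !is.na(m$polya_site)) {
      if (is.data.frame(conserved_polya)) {
        pos <- conserved_polya$pos[is.na(m$chrom) |
                                     conserved_polya$chrom == m$chrom]
      } else pos <- conserved_polya
      d <- if (length(pos)) min(abs(pos - m$polya_site)) else Inf
      if (d > max_polya_distance) {
        status[i] <- "removed"
        reason[i] <- sprintf("no conserved polyA site within %d nt (min %s)",
                             max_polya_distance,
                             if (is.finite(d)) d else "Inf")
        next
      }
    }
    status[i] <- "retained"; reason[i] <- ""
    keep[i] <- TRUE
  }
  out <- metas[keep]
  attr(out, "audit") <- data.frame(
    gene_id = vapply(metas, `[[`, "", "gene_id"),
    status = status, reason = reason, stringsAsFactors = FALSE)
  out
}

#' Tile a meta-UTR into an oligo pool
#'
#' The design sequence is `upstream_flank + UTR + downstream_flank`. Oligos
#' of `params$oligo_length` nt start at every `params$step` multiple from 0
#' to `len(design) - oligo_length`; when that end position is not itself a
#' step multiple, a final oligo is anchored there so the 3' end is always
#' fully covered. With default parameters every interior UTR nucleotide is
#' contained in exactly `oligo_length / step = 65` oligos.
#'
#' @param meta a `meta_utr` (flanks shorter than `flank_extension` are
#'   N-padded with a message).
#' @param params a [design_params()] object.
#' @return a data.frame (class `oligo_pool`) with columns `oligo_id`,
#'   `gene_id`, `offset` (oligo start relative to UTR position 0; negative
#'   in the upstream flank), `insert_sequence` and `full_sequence` (insert
#'   with PCR handles).
#' @export
tile_oligos <- function(meta, params = design_params()) {
  stopifnot(inherits(meta, "meta_utr"))
  fl <- params$flank_extension
  up <- meta$upstream_flank; down <- meta$downstream_flank
  if (nchar(up) < fl) {
    message("gene ", meta$gene_id, ": upstream flank padded with N")
    up <- paste0(strrep("N", fl - nchar(up)), up)
  }
  if (nchar(down) < fl) {
    message("gene ", meta$gene_id, ": downstream flank padded with N")
    down <- paste0(down, strrep("N", fl - nchar(down)))
  }
  up <- substr(up, nchar(up) - fl + 1L, nchar(up))
  down <- substr(down, 1L, fl)
  design <- paste0(up, meta$sequence, down)
  L <- nchar(design); olen <- params$oligo_length
  if (L < olen)
    stop(sprintf("design sequence (%d nt) shorter than oligo length (%d nt)",
                 L, olen), call. = FALSE)
  starts <- seq.int(0L, L - olen, by = params$step)
  if ((L - olen) %% params$step != 0L) starts <- c(starts, L - olen)
  inserts <- substring(design, starts + 1L, starts + olen)
  ids <- sprintf("%s|%05d", meta$gene_id, seq_along(starts) - 1L)
  pool <- data.frame(
    oligo_id = ids, gene_id = meta$gene_id,
    offset = as.integer(starts - fl),
    insert_sequence = inserts,
    full_sequence = paste0(params$handle_5p, inserts, params$handle_3p),
    stringsAsFactors = FALSE)
  class(pool) <- c("oligo_pool", "data.frame")
  attr(pool, "params") <- params
  pool
}

## rbind oligo_pool pieces, preserving class/params and checking id unicity.
bind_pools <- function(...) {
  pieces <- list(...)
  pieces <- Filter(function(p) !is.null(p) && nrow(p) > 0, pieces)
  out <- do.call(rbind, lapply(pieces, as.data.frame))
  if (anyDuplicated(out$oligo_id))
    stop("duplicate oligo_id in pool", call. = FALSE)
  class(out) <- c("oligo_pool", "data.frame")
  attr(out, "params") <- attr(pieces[[1]], "params")
  out
}

#' Design a full oligo pool for a list of meta-UTRs
#'
#' Convenience wrapper: [filter_genes()] then [tile_oligos()] per gene,
#' concatenated. The filter audit is carried through as attribute `audit`.
#'
#' @inheritParams filter_genes
#' @return an `oligo_pool` data.frame.
#' @export
design_pool <- function(metas, conserved_polya = NULL,
                        params = design_params()) {
  kept <- filter_genes(metas, conserved_polya, params)
  pool <- do.call(bind_pools, lapply(kept, tile_oligos, params = params))
  attr(pool, "audit") <- attr(kept, "audit")
  pool
}

#' Append control oligos to a pool
#'
#' Control sequences enter a distinguishing `ctrl:` gene namespace. Two
#' modes: `"whole"` places a short control sequence (at most one oligo
#' long) at `n_placements` evenly spaced positions within an oligo-length
#' insert, padding with reproducible random sequence; `"tile"` tiles longer
#' controls exactly like UTRs (flanks empty, N-padding suppressed by tiling
#' the bare sequence).
#'
#' @param pool an `oligo_pool`.
#' @param control_seqs named character vector (or `DNAStringSet`) of control
#'   sequences.
#' @param mode `"whole"` or `"tile"`.
#' @param n_placements placements per control in `"whole"` mode.
#' @param params a [design_params()] object.
#' @return the pool with control oligos appended.
#' @export
add_controls <- function(pool, control_seqs, mode = c("whole", "tile"),
                         n_placements = 3L, params = design_params()) {
  mode <- match.arg(mode)
  if (methods::is(control_seqs, "DNAStringSet"))
    control_seqs <- setNames(as.character(control_seqs), names(control_seqs))
  if (length(control_seqs) == 0L) return(pool)
  if (is.null(names(control_seqs)) || any(!nzchar(names(control_seqs))))
    stop("control sequences must be named", call. = FALSE)
  olen <- params$oligo_length
  ctrl_pools <- lapply(names(control_seqs), function(nm) {
    s <- normalize_seq(control_seqs[[nm]])
    gid <- paste0("ctrl:", nm)
    if (mode == "tile") {
      m <- meta_utr(gid, s)
      p <- tile_oligos(m, params)
      return(p)
    }
    if (nchar(s) > olen)
      stop("control '", nm, "' longer than oligo_length; use mode='tile'",
           call. = FALSE)
    pad_total <- olen - nchar(s)
    offs <- if (n_placements == 1L) pad_total %/% 2L else
      as.integer(round(pad_total * (seq_len(n_placements) - 1L) /
                         (n_placements - 1L)))
    # reproducible padding: seeded from the control name
    pad_seed <- sum(utf8ToInt(nm)) %% 2147483646L
    inserts <- with_seed(pad_seed, {
      pad <- random_dna(pad_total + olen)  # one pad pool reused per placement
      vapply(offs, function(o)
        paste0(substr(pad, 1L, o), s,
               substr(pad, o + 1L, pad_total)), "")
    })
    data.frame(
      oligo_id = sprintf("%s|%05d", gid, seq_along(offs) - 1L),
      gene_id = gid, offset = offs, insert_sequence = inserts,
      full_sequence = paste0(params$handle_5p, inserts, params$handle_3p),
      stringsAsFactors = FALSE)
  })
  do.call(bind_pools, c(list(pool), ctrl_pools))
}
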