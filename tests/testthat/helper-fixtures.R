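## Fixtures built in code (no binary files).

rand_seq <- function(n, seed = NULL) {
  f <- function() paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  if (is.null(seed)) f() else withr::with_seed(seed, f())
}

## A tiny two-chromosome genome with known sequence.
test_genome <- function(seed = 42L, len = 2000L) {
  withr::with_seed(seed, c(
    chr1 = paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""),
    chr2 = paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")))
}

## A synthetic meta-UTR plus its tiled pool.
test_pool <- function(utr_len = 1000L, seed = 7L,
                      params = design_params()) {
  withr::with_seed(seed, {
    m <- meta_utr("gene1",
                  rand_seq(utr_len),
                  upstream_flank = rand_seq(params$flank_extension),
                  downstream_flank = rand_seq(params$flank_extension))
    tile_oligos(m, params)
  })
}

## Enrichment records with prescribed significance for window tests:
## sig[i] gives oligo i (in offset order) fdr 0.001 / log2fc 1, others
## fdr 0.9 / log2fc 0 (overridable).
enrichment_from_sig <- function(pool, sig, log2fc = NULL) {
  stopifnot(length(sig) == nrow(pool))
  if (is.null(log2fc)) log2fc <- ifelse(sig, 1, 0)
  out <- data.frame(oligo_id = pool$oligo_id, log2fc = log2fc,
                    se = 0.1, pvalue = ifelse(sig, 1e-4, 0.9),
                    fdr = ifelse(sig, 1e-3, 0.9),
                    mean_count = 500, stringsAsFactors = FALSE)
  class(out) <- c("enrichment_records", "data.frame")
  out
}

## Minimal manifest-style pool without sequences (for window tests):
## n oligos at step-nt spacing.
index_pool <- function(n, step = 4L, gene = "g", oligo_length = 260L) {
  pool <- data.frame(
    oligo_id = sprintf("%s|%05d", gene, seq_len(n) - 1L),
    gene_id = gene,
    offset = as.integer((seq_len(n) - 1L) * step),
    insert_sequence = strrep("A", oligo_length),
    stringsAsFactors = FALSE)
  class(pool) <- c("oligo_pool", "data.frame")
  pool
}
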