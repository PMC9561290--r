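test_that("merge_utrs unions isoform intervals and respects strand", {
  genome <- test_genome()
  p <- design_params(oligo_length = 20L, step = 4L, flank_extension = 20L)
  t1 <- transcript_model("tx1", "gA", "chr1", 100, 400, "+")
  t2 <- transcript_model("tx2", "gA", "chr1", 100, 600, "+")

  # idempotent union: identical intervals give the plain UTR
  m_same <- merge_utrs(list(t1, t1), genome, p)
  expect_identical(m_same$sequence, substr(genome[["chr1"]], 101, 400))
  expect_identical(nchar(m_same$sequence), 300L)

  # interval-union oracle: [100,400) u [100,600) = [100,600), length 500
  m <- merge_utrs(list(t1, t2), genome, p)
  expect_identical(nchar(m$sequence), 500L)
  expect_identical(m$sequence, substr(genome[["chr1"]], 101, 600))
  expect_identical(m$upstream_flank, substr(genome[["chr1"]], 81, 100))
  expect_identical(m$downstream_flank, substr(genome[["chr1"]], 601, 620))
  expect_identical(m$polya_site, 600L)

  # minus strand: reverse complement, flanks swap sides
  tm <- transcript_model("tx3", "gB", "chr1", 100, 400, "-")
  mm <- merge_utrs(list(tm), genome, p)
  rc <- function(s) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s)))
  expect_identical(mm$sequence, rc(substr(genome[["chr1"]], 101, 400)))
  expect_identical(mm$upstream_flank, rc(substr(genome[["chr1"]], 401, 420)))
  expect_identical(mm$polya_site, 100L)
})

test_that("merge_utrs excludes not-found-end transcripts and rejects mixed input", {
  genome <- test_genome()
  p <- design_params(20L, 4L, 20L)
  good <- transcript_model("tx1", "gA", "chr1", 100, 400, "+")
  nf <- transcript_model("tx2", "gA", "chr1", 100, 900, "+",
                         tags = c("basic", "mRNA_end_NF"))
  m <- suppressMessages(merge_utrs(list(good, nf), genome, p))
  expect_identical(nchar(m$sequence), 300L)  # NF isoform did not extend it

  expect_null(suppressMessages(
    merge_utrs(list(transcript_model("t", "g", "chr1", 1, 50, "+",
                                     tags = "cds_end_NF")), genome, p)))
  mixed <- list(good, transcript_model("tx3", "gA", "chr1", 100, 500, "-"))
  expect_message(res <- merge_utrs(mixed, genome, p), "mixed strands")
  expect_null(res)
})

test_that("filter_genes applies length and polyA-conservation rules with audit", {
  p <- design_params()
  mk <- function(id, len, polya) {
    m <- meta_utr(id, strrep("A", len))
    m$polya_site <- polya; m$chrom <- "chr1"
    m
  }
  metas <- list(mk("short", 100L, 1000L),
                mk("long", 10001L, 1000L),
                mk("edge", 200L, 1000L),
                mk("far", 200L, 5000L))
  cons <- data.frame(chrom = "chr1", pos = c(1200L, 4500L))
  out <- filter_genes(metas, cons, p)
  aud <- attr(out, "audit")
  # polyA 1000 vs conserved 1200: distance 200 <= 200 -> retained
  expect_setequal(vapply(out, `[[`, "", "gene_id"), c("short", "edge"))
  expect_identical(aud$status[aud$gene_id == "long"], "removed")
  expect_match(aud$reason[aud$gene_id == "long"], "10001")
  # polyA 5000 vs conserved 4500: distance 500 -> removed
  expect_identical(aud$status[aud$gene_id == "far"], "removed")
  # boundary + 1: conserved at 1201 -> distance 201 -> removed
  out2 <- filter_genes(list(mk("b", 200L, 1000L)),
                       data.frame(chrom = "chr1", pos = 1201L), p)
  expect_length(out2, 0L)
  # empty input is not an error
  expect_length(filter_genes(list(), cons, p), 0L)
})

test_that("tile_oligos produces the documented tiling", {
  # single-tile case: UTR 260, no flanks, one oligo at offset 0
  m <- meta_utr("g", rand_seq(260, seed = 1))
  p0 <- design_params(flank_extension = 0L)
  pool1 <- tile_oligos(m, p0)
  expect_identical(nrow(pool1), 1L)
  expect_identical(pool1$offset, 0L)
  expect_identical(pool1$insert_sequence, m$sequence)

  # UTR 1000 with defaults: 316 oligos, offsets -260 ... 1000 step 4
  pool <- test_pool(1000L)
  expect_identical(nrow(pool), 316L)
  expect_identical(pool$offset, seq(-260L, 1000L, by = 4L))
  # handles present on full_sequence
  expect_true(all(startsWith(pool$full_sequence, design_params()$handle_5p)))
  expect_true(all(nchar(pool$insert_sequence) == 260L))
})

test_that("coverage and reconstruction invariants hold, incl. anchored final oligo", {
  p <- design_params()
  for (utr_len in c(1000L, 1003L)) {   # 1003: end not a step multiple
    pool <- test_pool(utr_len, seed = utr_len)
    cov <- oracle_coverage(pool, 0:(utr_len - 1L), p$oligo_length)
    expect_true(all(cov == p$oligo_length / p$step))
    # reconstruction: first `step` nt of each oligo + tail of final oligo
    steps <- diff(c(pool$offset, pool$offset[nrow(pool)] + p$oligo_length))
    pieces <- substring(pool$insert_sequence, 1L, steps)
    m <- withr::with_seed(utr_len, meta_utr(
      "gene1", rand_seq(utr_len),
      upstream_flank = rand_seq(p$flank_extension),
      downstream_flank = rand_seq(p$flank_extension)))
    design <- paste0(m$upstream_flank, m$sequence, m$downstream_flank)
    expect_identical(paste(pieces, collapse = ""), design)
  }
  expect_error(tile_oligos(meta_utr("g", "ACGT"),
                           design_params(flank_extension = 0L)),
               "shorter than oligo")
})

test_that("pool FASTA output is deterministic", {
  pool <- test_pool(500L)
  f1 <- tempfile(); f2 <- tempfile()
  write_pool(pool, f1); write_pool(pool, f2)
  expect_identical(unname(tools::md5sum(paste0(f1, ".fasta"))),
                   unname(tools::md5sum(paste0(f2, ".fasta"))))
  back <- read_manifest(paste0(f1, "_manifest.tsv"))
  expect_identical(back$oligo_id, pool$oligo_id)
  expect_identical(back$offset, pool$offset)
})

test_that("add_controls places controls in a ctrl namespace", {
  pool <- test_pool(500L)
  expect_identical(add_controls(pool, character()), pool)

  # 150-nt control, whole-sequence mode, 3 placements -> 3 oligos
  bc1 <- rand_seq(150, seed = 9)
  out <- add_controls(pool, c(BC1 = bc1), mode = "whole", n_placements = 3L)
  ctrl <- out[out$gene_id == "ctrl:BC1", ]
  expect_identical(nrow(ctrl), 3L)
  expect_true(all(nchar(ctrl$insert_sequence) == 260L))
  expect_true(all(vapply(ctrl$insert_sequence, grepl, TRUE,
                         pattern = bc1, fixed = TRUE)))
  # placements cover start / middle / end
  expect_identical(ctrl$offset, c(0L, 55L, 110L))

  # tiling mode obeys the tile_oligos contract
  ctrl_utr <- rand_seq(600, seed = 10)
  out2 <- add_controls(pool, c(neg1 = ctrl_utr), mode = "tile")
  tiled <- out2[out2$gene_id == "ctrl:neg1", ]
  ref <- tile_oligos(meta_utr("ctrl:neg1", ctrl_utr), design_params())
  expect_identical(tiled$insert_sequence, ref$insert_sequence)

  expect_error(add_controls(out, c(BC1 = bc1)), "duplicate")
})

test_that("read_transcript_models parses GTF three_prime_UTR features", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste0('chr1\ttest\tthree_prime_UTR\t101\t400\t.\t+\t.\t',
           'gene_id "gA"; transcript_id "tx1"; tag "basic";'),
    paste0('chr1\ttest\tthree_prime_UTR\t101\t600\t.\t+\t.\t',
           'gene_id "gA"; transcript_id "tx2"; tag "mRNA_end_NF";')),
    gtf)
  models <- read_transcript_models(gtf)
  expect_named(models, "gA")
  tx <- models$gA
  byid <- setNames(tx, vapply(tx, `[[`, "", "transcript_id"))
  expect_identical(byid$tx1$start, 100L)    # GTF 1-based -> 0-based
  expect_identical(byid$tx1$end, 400L)
  expect_true("mRNA_end_NF" %in% byid$tx2$tags)
})
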