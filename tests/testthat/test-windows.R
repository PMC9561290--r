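test_that("call_unions matches the spec walkthroughs", {
  pool <- index_pool(10L)
  # enriched indices (0-based) {0,1,2,5,6,7}: gap of 2 bridged -> one window
  sig <- seq_len(10) %in% c(1, 2, 3, 6, 7, 8)
  w <- call_unions(enrichment_from_sig(pool, sig), pool)
  expect_identical(nrow(w), 1L)
  expect_identical(w$member_oligos[[1]], pool$oligo_id[1:8])
  expect_identical(w$first_offset, 0L)
  expect_identical(w$last_offset, 28L)
  # enriched {0,1,2,6}: bridge test fails -> windows 0-2 and 6 alone
  sig2 <- seq_len(10) %in% c(1, 2, 3, 7)
  w2 <- call_unions(enrichment_from_sig(pool, sig2), pool)
  expect_identical(nrow(w2), 2L)
  expect_identical(w2$member_oligos[[1]], pool$oligo_id[1:3])
  expect_identical(w2$member_oligos[[2]], pool$oligo_id[7])
  # no enriched oligos -> no windows
  w0 <- call_unions(enrichment_from_sig(pool, rep(FALSE, 10)), pool)
  expect_identical(nrow(w0), 0L)
})

test_that("call_unions agrees with the run-length oracle on random vectors", {
  withr::with_seed(99, {
    for (i in 1:2000) {
      len <- sample(5:200, 1)
      enr <- random_enrichment_vector(len, runif(1, 0.05, 0.9))
      got <- utrtile:::union_spans(enr)
      want <- oracle_unions(enr)
      expect_identical(got, want)
    }
  })
})

test_that("window membership invariants hold on random cases", {
  withr::with_seed(123, {
    for (i in 1:50) {
      n <- sample(20:120, 1)
      pool <- index_pool(n)
      sig <- random_enrichment_vector(n, runif(1, 0.1, 0.6))
      w <- call_unions(enrichment_from_sig(pool, sig), pool)
      members <- unlist(w$member_oligos)
      # every significant oligo is in exactly one window
      expect_true(all(pool$oligo_id[sig] %in% members))
      expect_identical(anyDuplicated(members), 0L)
      # non-significant members only inside bridged gaps (never at edges)
      for (j in seq_len(nrow(w))) {
        ids <- w$member_oligos[[j]]
        s <- sig[match(ids, pool$oligo_id)]
        expect_true(s[1] && s[length(s)])
      }
      # intersection-length identity on every called window
      span <- w$last_offset - w$first_offset
      ilen <- ifelse(is.na(w$intersection_start), 0L,
                     w$intersection_end - w$intersection_start)
      expect_identical(ilen[span < 260], 260L - span[span < 260])
    }
  })
})

test_that("derive_intersection follows the interval formula", {
  expect_identical(derive_intersection(list(first_offset = 0L,
                                            last_offset = 0L), 260L),
                   c(0L, 260L))                     # single oligo: full 260
  expect_identical(derive_intersection(list(first_offset = 0L,
                                            last_offset = 8L), 260L),
                   c(8L, 260L))                     # members 0,4,8 -> len 252
  expect_null(derive_intersection(list(first_offset = 0L,
                                       last_offset = 260L), 260L))
  expect_null(derive_intersection(list(first_offset = 0L,
                                       last_offset = 400L), 260L))
})

test_that("pick_peak maximizes log2fc with documented tie-breaks", {
  pool <- index_pool(9L)
  # monotone ramp: 3'-most significant member wins
  sig <- rep(TRUE, 9)
  enr <- enrichment_from_sig(pool, sig, log2fc = seq(0.1, 0.9, by = 0.1))
  w <- call_unions(enr, pool)
  expect_identical(w$peak_oligo_id, pool$oligo_id[9])
  expect_identical(pick_peak(w[1, ], enr, pool), pool$oligo_id[9])
  # two equal maxima flanking the midpoint symmetrically: 5'-most returned
  lfc <- c(0.1, 0.1, 0.9, 0.1, 0.1, 0.1, 0.9, 0.1, 0.1)
  w2 <- call_unions(enrichment_from_sig(pool, sig, log2fc = lfc), pool)
  expect_identical(w2$peak_oligo_id, pool$oligo_id[3])
  # single member window
  sig3 <- seq_len(9) == 5
  w3 <- call_unions(enrichment_from_sig(pool, sig3), pool)
  expect_identical(w3$peak_oligo_id, pool$oligo_id[5])
})

test_that("call_unions validates ordering and tiling", {
  pool <- index_pool(10L)
  gap <- pool[-4, ]                       # hole in the tiling
  expect_error(call_unions(enrichment_from_sig(pool, rep(TRUE, 10)), gap),
               "do not cover|irregular")
  enr <- enrichment_from_sig(gap, rep(TRUE, 9))
  expect_error(call_unions(enr, gap), "gapped or irregular")
  # a 3'-anchored final oligo (short last step) is legal tiling
  anch <- index_pool(10L)
  anch$offset[10] <- anch$offset[9] + 3L
  w <- call_unions(enrichment_from_sig(anch, rep(TRUE, 10)), anch)
  expect_identical(nrow(w), 1L)
  expect_identical(w$last_offset, anch$offset[10])
})

test_that("neighbor_similarity_test detects positional coherence", {
  # constant profile: all differences 0 under any shuffle, p = 1
  df0 <- data.frame(gene_id = "g", offset = (0:19) * 4, log2fc = 1)
  out0 <- neighbor_similarity_test(df0, n_shuffles = 50L, seed = 1)
  expect_equal(out0$p_value, 1)
  # smooth sinusoid over 65 oligos: observed |diff| << shuffled, p < 0.01
  df <- data.frame(gene_id = "g", offset = (0:64) * 4,
                   log2fc = sin((0:64) / 6))
  out <- neighbor_similarity_test(df, n_shuffles = 200L, seed = 2)
  expect_lt(out$p_value, 0.01)
  expect_lt(median(out$observed), median(out$shuffled))
  # determinism under a fixed seed
  out2 <- neighbor_similarity_test(df, n_shuffles = 200L, seed = 2)
  expect_identical(out$p_value, out2$p_value)
  expect_error(neighbor_similarity_test(df[1:2, ]), ">= 3 oligos")
})

test_that("smooth_profile has exact edge and closed-form behavior", {
  df <- data.frame(offset = (0:19) * 4, log2fc = 2)
  sm <- smooth_profile(df, k = 8L)
  expect_equal(sm$mean, rep(2, 20))
  expect_equal(sm$sd, rep(0, 20))
  # k = 1 is the identity
  ramp <- data.frame(offset = (0:19) * 4, log2fc = 0:19)
  expect_equal(smooth_profile(ramp, k = 1L)$mean, 0:19)
  # linear ramp: interior sliding mean is the ramp at the window center
  sm8 <- smooth_profile(ramp, k = 8L)
  interior <- 4:16                      # full windows i-3 ... i+4
  expect_equal(sm8$mean[interior], (interior - 1) + 0.5)
})
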