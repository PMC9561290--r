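samples_4x4 <- function() {
  data.frame(sample = c(paste0("soma_rep", 1:4), paste0("neurite_rep", 1:4)),
             compartment = rep(c("soma", "neurite"), each = 4),
             replicate = rep(1:4, 2), stringsAsFactors = FALSE)
}

test_that("normalize_counts is median-of-ratios with scaling invariance", {
  m <- withr::with_seed(1, matrix(rnbinom(400, mu = 100, size = 10), 100, 4))
  rownames(m) <- sprintf("o%03d", 1:100)
  # sample 2 = 2 x sample 1: size-factor ratio 2, normalized equal
  m2 <- cbind(m[, 1], m[, 1] * 2L, m[, 3:4])
  nz <- normalize_counts(m2)
  expect_equal(nz$size_factors[[2]] / nz$size_factors[[1]], 2)
  expect_equal(nz$normalized[, 1], nz$normalized[, 2],
               ignore_attr = TRUE)
  # identical columns: all size factors 1
  nz2 <- normalize_counts(m[, c(1, 1, 1)])
  expect_equal(unname(nz2$size_factors), rep(1, 3))
  # random NB matrix: factors within 5% of true library-size ratios
  true_sf <- c(1, 0.5, 2, 1.5)
  m3 <- withr::with_seed(2, sapply(true_sf, function(s)
    rnbinom(2000, mu = s * 200, size = 20)))
  nz3 <- normalize_counts(m3)
  rel <- nz3$size_factors / (true_sf / exp(mean(log(true_sf))))
  expect_true(all(abs(rel - 1) < 0.05))
  # all-zero-containing rows only: falls back to totals with warning
  mz <- rbind(c(0L, 5L), c(7L, 0L))
  expect_warning(normalize_counts(mz), "total-count")
})

test_that("test_enrichment handles nulls, filters, and planted effects", {
  # identical compartment counts -> log2fc 0, p ~ 1
  base <- withr::with_seed(3, matrix(rnbinom(400, mu = 200, size = 20), 100, 4))
  cm_same <- count_matrix(cbind(base, base), samples_4x4())
  rownames(cm_same$counts) <- sprintf("o%03d", 1:100)
  enr <- test_enrichment(cm_same)
  expect_equal(enr$log2fc, rep(0, 100))
  expect_true(all(enr$pvalue > 0.99))

  # low-count filter: pooled < 20 in either compartment -> fdr NA
  cm <- cm_same
  cm$counts[1, 1:4] <- c(4L, 4L, 4L, 4L)   # soma pooled 16 < 20
  enr2 <- test_enrichment(cm)
  expect_true(is.na(enr2$fdr[1]))
  expect_false(anyNA(enr2$fdr[-1]))

  # planted 4-fold effect at mean ~500: recovered within +/-0.25, fdr < 0.01
  sim <- withr::with_seed(4, {
    mu <- rep(500, 400)
    eff <- rep(c(4, 1), c(40, 360))
    soma <- sapply(1:4, function(i) rnbinom(400, mu = mu, size = 1 / 0.02))
    neur <- sapply(1:4, function(i) rnbinom(400, mu = mu * eff, size = 1 / 0.02))
    cbind(soma, neur)
  })
  rownames(sim) <- sprintf("o%03d", 1:400)
  enr3 <- test_enrichment(count_matrix(sim, samples_4x4()))
  expect_lt(abs(mean(enr3$log2fc[1:40]) - 2), 0.25)
  expect_true(all(enr3$fdr[1:40] < 0.01))
  expect_lt(mean(enr3$fdr[41:400] < 0.01), 0.02)

  # single replicate is an explicit error
  s1 <- data.frame(sample = c("s", "n"), compartment = c("soma", "neurite"),
                   replicate = 1L)
  expect_error(test_enrichment(count_matrix(sim[, c(1, 5)], s1)),
               ">= 2 replicates")
})

test_that("label swap negates log2fc and preserves p-values (symmetry)", {
  m <- withr::with_seed(5, matrix(rnbinom(800, mu = 300, size = 15), 100, 8))
  rownames(m) <- sprintf("o%03d", 1:100)
  s <- samples_4x4()
  enr_a <- test_enrichment(count_matrix(m, s))
  s_sw <- s; s_sw$compartment <- rev(s_sw$compartment)
  enr_b <- test_enrichment(count_matrix(m, s_sw))
  expect_equal(enr_a$log2fc, -enr_b$log2fc)
  expect_equal(enr_a$pvalue, enr_b$pvalue)
  # BH monotonicity in p-value rank
  ord <- order(enr_a$pvalue)
  expect_true(all(diff(enr_a$fdr[ord]) >= -1e-12))
  expect_true(all(enr_a$fdr >= enr_a$pvalue - 1e-12))
})

test_that("zscore_datasets matches the closed form and classifies inclusively", {
  m1 <- matrix(c(2, 0, -2), ncol = 1, dimnames = list(c("a", "b", "c"), "d1"))
  z <- zscore_datasets(m1)
  expect_equal(unname(z$z[, 1]), c(1.2247, 0, -1.2247), tolerance = 1e-4)

  # inclusive threshold: top gene of c(1,0,0,0,0) has z = sqrt(n-1) = 2.0
  m2 <- cbind(d1 = c(1, 0, 0, 0, 0), d2 = c(1, 0, 0, 0, 0))
  z2 <- zscore_datasets(m2)
  expect_equal(z2$median_z[[1]], 2)
  expect_true(z2$localized[[1]])            # median_z == 2 -> localized
  expect_false(any(z2$localized[-1]))

  expect_warning(z3 <- zscore_datasets(matrix(1, 3, 1)), "constant")
  expect_equal(unname(z3$z[, 1]), rep(0, 3))

  # NA-aware median across datasets
  m4 <- cbind(c(2, 0, -2), c(NA, 0, -1))
  z4 <- suppressWarnings(zscore_datasets(m4))
  expect_false(anyNA(z4$median_z))
})

test_that("qpcr_fold_enrichment implements the ratio of ratios", {
  mk <- function(rep_s, rep_n, ctl_s, ctl_n) {
    data.frame(target = rep(c("reporter", "control"), each = 2),
               compartment = rep(c("soma", "neurite"), 2),
               replicate = 1L, ct = c(rep_s, rep_n, ctl_s, ctl_n))
  }
  expect_equal(qpcr_fold_enrichment(mk(20, 20, 20, 20))$mean, 1)
  # ddCt = -1 -> fold 2
  expect_equal(qpcr_fold_enrichment(mk(20, 19, 20, 20))$mean, 2)
  # ddCt = 3.32 -> fold ~ 0.1
  expect_equal(qpcr_fold_enrichment(mk(20, 23.32, 20, 20))$mean,
               2^-3.32, tolerance = 1e-12)
  expect_equal(2^-3.32, 0.1, tolerance = 0.01)
  bad <- mk(20, 20, 20, 20); bad <- bad[bad$compartment != "neurite", ]
  expect_error(qpcr_fold_enrichment(bad), "compartment")
  # replicate spread is reported
  ct3 <- do.call(rbind, lapply(1:3, function(r) {
    d <- mk(20, 19 + 0.1 * r, 20, 20); d$replicate <- r; d
  }))
  out <- qpcr_fold_enrichment(ct3)
  expect_length(out$fold, 3L)
  expect_gt(out$sd, 0)
})

test_that("read_de_table adapts external DE output", {
  f <- tempfile()
  write.table(data.frame(oligo_id = c("a", "b"), log2FoldChange = c(1, -1),
                         padj = c(0.001, 0.5)),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  de <- read_de_table(f)
  expect_s3_class(de, "enrichment_records")
  expect_identical(de$log2fc, c(1, -1))
  expect_identical(de$fdr, c(0.001, 0.5))
})
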