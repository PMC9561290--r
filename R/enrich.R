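## Per-oligo neurite-vs-soma enrichment: median-of-ratios normalization, a
## negative-binomial Wald test with trend-shrunk dispersions, cross-dataset
## Z-score utilities, and the delta-delta-Ct qPCR helper.

#' Median-of-ratios normalization
#'
#' Size factor per sample = median across oligos of count / geometric mean
#' of the oligo's row, computed over rows with no zero counts. When no such
#' row exists the function falls back to total-count scaling with a
#' warning.
#'
#' @param cm a `count_matrix` or plain count matrix.
#' @return list with `size_factors` (named numeric) and `normalized`
#'   (matrix of counts divided by size factors).
#' @export
normalize_counts <- function(cm) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  allpos <- rowSums(counts == 0) == 0
  if (!any(allpos)) {
    warning("no all-nonzero rows; falling back to total-count scaling")
    sf <- colSums(counts) / mean(colSums(counts))
  } else {
    lg <- rowMeans(log(counts[allpos, , drop = FALSE]))
    sf <- apply(counts[allpos, , drop = FALSE], 2,
                function(col) median(exp(log(col) - lg)))
  }
  sf <- sf / exp(mean(log(sf)))           # geometric-mean-centered
  list(size_factors = sf,
       normalized = sweep(counts, 2, sf, "/"))
}

## Parametric dispersion trend alpha(mu) = a0 + a1/mu, fit by linear
## regression of method-of-moments dispersions on 1/mu; coefficients are
## clamped at >= 0 and the fit degrades to the median dispersion when the
## regression is degenerate.
fit_dispersion_trend <- function(mu, alpha) {
  ok <- is.finite(mu) & is.finite(alpha) & mu > 0 & alpha > 0
  fallback <- max(1e-8, median(alpha[ok]), na.rm = TRUE)
  if (sum(ok) < 10) return(function(m) rep(fallback, length(m)))
  fit <- tryCatch(lm(alpha[ok] ~ I(1 / mu[ok])), error = function(e) NULL)
  if (is.null(fit)) return(function(m) rep(fallback, length(m)))
  a0 <- max(0, coef(fit)[1]); a1 <- max(0, coef(fit)[2])
  if (a0 == 0 && a1 == 0) return(function(m) rep(fallback, length(m)))
  function(m) pmax(1e-8, a0 + a1 / m)
}

#' Per-oligo neurite-vs-soma differential enrichment
#'
#' Counts are normalized by median-of-ratios; oligos with fewer than
#' `min_count` pooled counts in either compartment are not tested
#' (`fdr = NA`). For tested oligos a negative-binomial Wald test is
#' applied: group means are estimated from normalized counts, per-oligo
#' method-of-moments dispersions are shrunk toward a parametric
#' mean-dispersion trend (`alpha = a0 + a1/mu`) with `prior_df` prior
#' degrees of freedom, and the variance of the log ratio follows the NB
#' delta method. P-values are Benjamini-Hochberg adjusted over tested
#' rows. Sign convention: `log2fc > 0` means neurite-enriched.
#'
#' @param cm a `count_matrix` with >= 2 replicates per compartment.
#' @param min_count minimum pooled raw count per compartment for testing.
#' @param prior_df prior degrees of freedom for dispersion shrinkage.
#' @param pseudocount added to group means only for the descriptive
#'   `log2fc` of untested/zero rows; the test uses raw estimates.
#' @return data.frame (class `enrichment_records`): `oligo_id`, `log2fc`,
#'   `se`, `pvalue`, `fdr`, `mean_count`.
#' @export
test_enrichment <- function(cm, min_count = 20L, prior_df = 6,
                            pseudocount = 0.5) {
  stopifnot(inherits(cm, "count_matrix"))
  soma <- cm$samples$compartment == "soma"
  neur <- cm$samples$compartment == "neurite"
  if (sum(soma) < 2 || sum(neur) < 2)
    stop("need >= 2 replicates per compartment; ",
         "use descriptive log2 ratios for single-replicate designs",
         call. = FALSE)
  nz <- normalize_counts(cm)
  norm <- nz$normalized; sf <- nz$size_factors
  counts <- cm$counts
  pooled_s <- rowSums(counts[, soma, drop = FALSE])
  pooled_n <- rowSums(counts[, neur, drop = FALSE])
  tested <- pooled_s >= min_count & pooled_n >= min_count

  mu_s <- rowMeans(norm[, soma, drop = FALSE])
  mu_n <- rowMeans(norm[, neur, drop = FALSE])
  mu <- (mu_s + mu_n) / 2

  # method-of-moments dispersion on normalized counts, within-group
  v_s <- apply(norm[, soma, drop = FALSE], 1, var)
  v_n <- apply(norm[, neur, drop = FALSE], 1, var)
  xim <- mean(1 / sf)
  v_w <- (v_s + v_n) / 2
  alpha_mom <- pmax(1e-8, (v_w - xim * mu) / mu^2)
  trend <- fit_dispersion_trend(mu[tested], alpha_mom[tested])
  alpha_tr <- trend(mu)
  d <- sum(soma) + sum(neur) - 2
  alpha <- exp((d * log(alpha_mom) + prior_df * log(alpha_tr)) /
                 (d + prior_df))

  # NB delta-method variance of log group means
  vlog <- function(mu_g, cols, a) {
    inv_s <- 1 / sf[cols]
    n_g <- length(inv_s)
    (vapply(mu_g, function(m) sum(inv_s / m), 0) / n_g^2 + a / n_g)
  }
  V <- vlog(pmax(mu_n, 1e-8), which(neur), alpha) +
    vlog(pmax(mu_s, 1e-8), which(soma), alpha)
  log2fc <- ifelse(mu_s > 0 & mu_n > 0, log2(mu_n / mu_s),
                   log2((mu_n + pseudocount) / (mu_s + pseudocount)))
  se <- sqrt(V) / log(2)
  z <- log2fc / se
  pvalue <- 2 * pnorm(-abs(z))
  pvalue[!tested] <- NA_real_
  fdr <- rep(NA_real_, length(pvalue))
  fdr[tested] <- p.adjust(pvalue[tested], method = "BH")
  out <- data.frame(oligo_id = rownames(counts), log2fc = log2fc, se = se,
                    pvalue = pvalue, fdr = fdr,
                    mean_count = rowMeans(norm), stringsAsFactors = FALSE)
  class(out) <- c("enrichment_records", "data.frame")
  out
}

#' Adapter for an externally produced differential-expression table
#'
#' Lets any DE engine substitute for the builtin test: a TSV with columns
#' `oligo_id`, `log2fc` (or `log2FoldChange`) and `padj` is converted to
#' enrichment records.
#'
#' @param path TSV path.
#' @return an `enrichment_records` data.frame.
#' @export
read_de_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if ("log2FoldChange" %in% names(df)) df$log2fc <- df$log2FoldChange
  need <- c("oligo_id", "log2fc", "padj")
  if (!all(need %in% names(df)))
    stop("DE table needs columns oligo_id, log2fc (or log2FoldChange), padj",
         call. = FALSE)
  out <- data.frame(oligo_id = df$oligo_id, log2fc = as.numeric(df$log2fc),
                    se = df$lfcSE %||% NA_real_,
                    pvalue = df$pvalue %||% NA_real_, fdr = df$padj,
                    mean_count = df$baseMean %||% NA_real_,
                    stringsAsFactors = FALSE)
  class(out) <- c("enrichment_records", "data.frame")
  out
}

#' Z-normalize per-dataset gene enrichments and rank genes
#'
#' Neurite enrichments from multiple datasets are made comparable by
#' Z-normalizing within each dataset (population standard deviation, so
#' e.g. values 2, 0, -2 map to 1.22, 0, -1.22); each gene is summarized by
#' its NA-aware median Z-score across datasets, and genes with a median
#' Z-score of at least `threshold` (inclusive) are classified localized.
#'
#' @param mat genes x datasets numeric matrix of neurite enrichments.
#' @param threshold median-Z classification threshold.
#' @return list (class `dataset_enrichment`): `z` matrix, `median_z`,
#'   `localized` logical, `ranking` (gene ids by decreasing median Z).
#' @export
zscore_datasets <- function(mat, threshold = 2) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) stop("need >= 2 genes per dataset", call. = FALSE)
  z <- apply(mat, 2, function(x) {
    mu <- mean(x, na.rm = TRUE)
    s <- sqrt(mean((x - mu)^2, na.rm = TRUE))   # population sd
    if (!is.finite(s) || s == 0) {
      warning("constant dataset column; Z-scores set to 0")
      return(rep(0, length(x)))
    }
    (x - mu) / s
  })
  z <- matrix(z, nrow = nrow(mat), dimnames = dimnames(mat))
  med <- apply(z, 1, median, na.rm = TRUE)
  ord <- order(med, decreasing = TRUE)
  structure(list(z = z, median_z = med, localized = med >= threshold,
                 ranking = rownames(mat)[ord] %||% ord),
            class = "dataset_enrichment")
}

#' Fold enrichment from Ct values (delta-delta-Ct)
#'
#' Computes, per replicate, `fold = 2^-[(Ct_rep - Ct_ctrl)_neurite -
#' (Ct_rep - Ct_ctrl)_soma]`: the neurite/soma ratio of reporter/control
#' ratios measured by RT-qPCR.
#'
#' @param ct data.frame with columns `target` (`reporter`/`control`),
#'   `compartment` (`soma`/`neurite`), `replicate`, `ct` (positive).
#' @return list with per-replicate `fold`, `mean` and `sd`.
#' @export
qpcr_fold_enrichment <- function(ct) {
  need <- c("target", "compartment", "replicate", "ct")
  stopifnot(all(need %in% names(ct)), all(ct$ct > 0))
  if (!all(c("soma", "neurite") %in% ct$compartment))
    stop("both compartments required", call. = FALSE)
  if (!all(c("reporter", "control") %in% ct$target))
    stop("both reporter and control targets required", call. = FALSE)
  reps <- sort(unique(ct$replicate))
  fold <- vapply(reps, function(r) {
    get1 <- function(tg, cp) {
      v <- ct$ct[ct$target == tg & ct$compartment == cp & ct$replicate == r]
      if (length(v) == 0) stop("missing Ct for ", tg, "/", cp,
                               " replicate ", r, call. = FALSE)
      mean(v)
    }
    ddct <- (get1("reporter", "neurite") - get1("control", "neurite")) -
      (get1("reporter", "soma") - get1("control", "soma"))
    2^(-ddct)
  }, 0)
  list(fold = setNames(fold, reps), mean = mean(fold),
       sd = if (length(fold) > 1) sd(fold) else NA_real_)
}
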