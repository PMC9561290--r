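## Active-window ("oligonucleotide union") calling: contiguous runs of
## neurite-enriched oligos, optionally bridged across short non-enriched
## gaps by the x/y/x+2y rule, plus intersections, peak oligos, and
## positional QC statistics.

## Core traversal on a logical enrichment vector (oligo-index units).
## Opens a window at the first enriched oligo and extends while enriched.
## At the first non-enriched oligo (position x) it measures the distance y
## to the next enriched oligo; if every oligo in [x+y, x+2y) is enriched
## the window is extended through x+2y-1 and scanning resumes at x+2y
## (the rule re-applies iteratively with a fresh x/y); otherwise the
## window closes at its last enriched member. A bridge that would run past
## the end of the tiling is not attempted. Returns a list of c(start, end)
## index pairs (1-based, inclusive); gap oligos inside successful bridges
## are members.
union_spans <- function(enriched) {
  n <- length(enriched)
  spans <- list()
  i <- 1L
  while (i <= n) {
    if (!enriched[i]) { i <- i + 1L; next }
    s <- i; j <- i; e <- NA_integer_
    repeat {
      while (j <= n && enriched[j]) j <- j + 1L
      if (j > n) { e <- n; i <- j; break }
      x <- j
      k <- x
      while (k <= n && !enriched[k]) k <- k + 1L
      if (k > n) { e <- j - 1L; i <- k; break }
      y <- k - x
      bridge_end <- x + 2L * y - 1L
      if (bridge_end <= n && all(enriched[(x + y):bridge_end])) {
        j <- x + 2L * y
      } else {
        e <- j - 1L
        i <- k
        break
      }
    }
    spans[[length(spans) + 1L]] <- c(s, e)
  }
  spans
}

#' Call oligonucleotide unions (active windows)
#'
#' Joins enrichment records to the pool manifest, orders each gene's
#' oligos by offset, marks an oligo significant when `fdr < fdr_cutoff`
#' and its fold change points in `direction`, and segments each gene with
#' the x/y/x+2y traversal rule (see [union_spans()] internals): a window
#' of enriched oligos may absorb a non-enriched gap of length `y` when the
#' following `y` oligos are all enriched.
#'
#' @param enrichment an `enrichment_records` data.frame.
#' @param pool an `oligo_pool` (or manifest) supplying `gene_id` and
#'   `offset` per oligo; tiling must be complete and regularly stepped.
#' @param fdr_cutoff significance cutoff (0.01 by default; 0.05 matches
#'   figure-level displays).
#' @param direction `"neurite"` (log2fc > 0) or `"soma"` (log2fc < 0).
#' @param oligo_length insert length; inferred from the pool when absent.
#' @return data.frame (class `active_windows`): one row per window with
#'   `gene_id`, `first_offset`, `last_offset`, `union_start`, `union_end`,
#'   `intersection_start`, `intersection_end` (NA when empty), `n_members`,
#'   `peak_oligo_id`, `peak_log2fc`, and list-column `member_oligos`.
#' @export
call_unions <- function(enrichment, pool, fdr_cutoff = 0.01,
                        direction = c("neurite", "soma"),
                        oligo_length = NULL) {
  direction <- match.arg(direction)
  if (is.null(oligo_length)) {
    oligo_length <- if (!is.null(pool$insert_sequence))
      nchar(pool$insert_sequence[1]) else
        attr(pool, "params")$oligo_length %||%
      stop("oligo_length cannot be inferred from pool", call. = FALSE)
  }
  df <- merge(pool[, c("oligo_id", "gene_id", "offset")], enrichment,
              by = "oligo_id")
  if (nrow(df) != nrow(pool))
    stop("enrichment records do not cover the pool", call. = FALSE)
  out <- list()
  for (g in unique(df$gene_id)) {
    gd <- df[df$gene_id == g, , drop = FALSE]
    gd <- gd[order(gd$offset), , drop = FALSE]
    steps <- diff(gd$offset)
    if (length(steps)) {
      step <- steps[1]
      # uniform steps; the 3'-anchored final oligo may sit closer
      if (any(steps[-length(steps)] != step) || steps[length(steps)] > step)
        stop("gapped or irregular tiling for gene ", g, call. = FALSE)
    }
    sig <- !is.na(gd$fdr) & gd$fdr < fdr_cutoff &
      (if (direction == "neurite") gd$log2fc > 0 else gd$log2fc < 0)
    for (sp in union_spans(sig)) {
      members <- gd[sp[1]:sp[2], , drop = FALSE]
      first_off <- members$offset[1]
      last_off <- members$offset[nrow(members)]
      inter <- derive_intersection(list(first_offset = first_off,
                                        last_offset = last_off),
                                   oligo_length)
      peak <- pick_peak_members(members, sig[sp[1]:sp[2]], first_off,
                                last_off, oligo_length)
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g, first_offset = first_off, last_offset = last_off,
        union_start = first_off, union_end = last_off + oligo_length,
        intersection_start = if (is.null(inter)) NA_integer_ else inter[1],
        intersection_end = if (is.null(inter)) NA_integer_ else inter[2],
        n_members = nrow(members),
        peak_oligo_id = peak$oligo_id, peak_log2fc = peak$log2fc,
        stringsAsFactors = FALSE)
      out[[length(out)]]$member_oligos <- list(members$oligo_id)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(gene_id = character(), first_offset = integer(),
               last_offset = integer(), union_start = integer(),
               union_end = integer(), intersection_start = integer(),
               intersection_end = integer(), n_members = integer(),
               peak_oligo_id = character(), peak_log2fc = numeric(),
               member_oligos = I(list()), stringsAsFactors = FALSE)
  class(res) <- c("active_windows", "data.frame")
  attr(res, "oligo_length") <- oligo_length
  res
}

#' Intersection interval of a window
#'
#' The subsequence common to every member oligo: from the last member's
#' start to the first member's end, `[last_offset, first_offset +
#' oligo_length)`. Empty (NULL) when the member starts span more than one
#' oligo length.
#'
#' @param window list or one-row data.frame with `first_offset` and
#'   `last_offset`.
#' @param oligo_length insert length in nt.
#' @return integer `c(start, end)` in UTR coordinates, or `NULL`.
#' @export
derive_intersection <- function(window, oligo_length = 260L) {
  start <- window$last_offset
  end <- window$first_offset + oligo_length
  if (start >= end) return(NULL)
  c(as.integer(start), as.integer(end))
}

## Peak among significant members: maximal log2fc; ties broken by
## proximity to the union midpoint, then 5'-most.
pick_peak_members <- function(members, sig, first_off, last_off,
                              oligo_length) {
  cand <- if (any(sig)) members[sig, , drop = FALSE] else members
  best <- which(cand$log2fc == max(cand$log2fc))
  if (length(best) > 1L) {
    mid <- (first_off + last_off + oligo_length) / 2
    center <- cand$offset[best] + oligo_length / 2
    best <- best[order(abs(center - mid), cand$offset[best])]
  }
  list(oligo_id = cand$oligo_id[best[1]], log2fc = cand$log2fc[best[1]])
}

#' Peak oligo of a called window
#'
#' @param window one row of a [call_unions()] result.
#' @param records the `enrichment_records` used for calling.
#' @param pool the `oligo_pool` (for offsets).
#' @param fdr_cutoff significance cutoff used to restrict candidates.
#' @return the peak `oligo_id`.
#' @export
pick_peak <- function(window, records, pool, fdr_cutoff = 0.01) {
  ids <- window$member_oligos[[1]]
  m <- merge(data.frame(oligo_id = ids, stringsAsFactors = FALSE),
             merge(records, pool[, c("oligo_id", "offset")], by = "oligo_id"),
             by = "oligo_id")
  m <- m[order(m$offset), , drop = FALSE]
  olen <- window$union_end - window$last_offset
  sig <- !is.na(m$fdr) & m$fdr < fdr_cutoff & m$log2fc > 0
  pick_peak_members(m, sig, window$first_offset, window$last_offset,
                    olen)$oligo_id
}

#' Positional-coherence shuffle test for neighboring oligos
#'
#' Neighboring oligos share almost all of their sequence, so a real signal
#' makes adjacent enrichment values similar. The observed absolute
#' differences between adjacent oligos (within each gene) are compared to
#' differences recomputed after randomly shuffling oligo positions within
#' the gene, with a two-sided Wilcoxon rank-sum test.
#'
#' @param df data.frame with columns `gene_id`, `offset`, `log2fc`.
#' @param n_shuffles number of within-gene position shuffles.
#' @param seed integer seed for the shuffles.
#' @return list with `observed` and `shuffled` absolute-difference vectors
#'   and `p_value`.
#' @export
neighbor_similarity_test <- function(df, n_shuffles = 1000L, seed = NULL) {
  stopifnot(all(c("gene_id", "offset", "log2fc") %in% names(df)))
  genes <- split(df, df$gene_id)
  genes <- lapply(genes, function(g) g[order(g$offset), , drop = FALSE])
  if (any(vapply(genes, nrow, 0L) < 3L))
    stop("need >= 3 oligos per gene", call. = FALSE)
  observed <- unlist(lapply(genes, function(g) abs(diff(g$log2fc))))
  shuffled <- with_seed(seed, {
    unlist(lapply(seq_len(n_shuffles), function(i) {
      unlist(lapply(genes, function(g) abs(diff(sample(g$log2fc)))))
    }))
  })
  p <- if (all(observed == 0) && all(shuffled == 0)) 1 else
    suppressWarnings(wilcox.test(observed, shuffled)$p.value)
  list(observed = observed, shuffled = shuffled, p_value = p)
}

#' Sliding mean and standard deviation of an enrichment profile
#'
#' Centered window of `k` oligos (for even `k` the window covers
#' `i - (k-1) %/% 2 ... i + k %/% 2`), shrunk at the profile edges.
#'
#' @param df data.frame with `offset` and `log2fc`, one gene, ordered or
#'   orderable by offset.
#' @param k window size in oligos.
#' @return data.frame `offset`, `mean`, `sd` (sd is 0 for single-point
#'   windows).
#' @export
smooth_profile <- function(df, k = 8L) {
  stopifnot(k >= 1L)
  df <- df[order(df$offset), , drop = FALSE]
  x <- df$log2fc; n <- length(x)
  lo_off <- (k - 1L) %/% 2L; hi_off <- k %/% 2L
  m <- numeric(n); s <- numeric(n)
  for (i in seq_len(n)) {
    w <- x[max(1L, i - lo_off):min(n, i + hi_off)]
    m[i] <- mean(w)
    s[i] <- if (length(w) > 1L) sd(w) else 0
  }
  data.frame(offset = df$offset, mean = m, sd = s)
}
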