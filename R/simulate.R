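## Synthetic-data generators: UTRs with planted A/G-rich localization
## elements, ground-truth count matrices, and error-bearing paired-end
## reads. Every generator records a complete truth object so downstream
## recovery can be scored.

#' Simulate meta-UTRs with planted localization elements
#'
#' UTR lengths are uniform in `params$utr_len_range` (default 500-5000 nt);
#' background sequence is random with 50% G+C and 50% A+G. Planted elements
#' are rewritten base by base so that each position is A or G with
#' probability `params$ag_target` (default 0.8), emulating the A/G-rich
#' character of neurite-localization elements. Flanking sequence of
#' `flank_len` nt is generated so the pool designer can tile with full end
#' coverage.
#'
#' @param params a [count_sim_params()] object; its `element_spec` places
#'   the elements.
#' @param flank_len flank length to generate (nt).
#' @param seed overrides `params$seed`.
#' @return list of `meta_utr` objects; attribute `truth` is a data.frame
#'   with the realized element coordinates and effects.
#' @export
simulate_utrs <- function(params = count_sim_params(), flank_len = 260L,
                          seed = params$seed) {
  n <- params$n_genes
  if (n == 0L) {
    out <- list(); attr(out, "truth") <- empty_element_truth(); return(out)
  }
  es <- params$element_spec
  with_seed(seed, {
    span <- params$utr_len_range[2] - params$utr_len_range[1] + 1L
    lens <- params$utr_len_range[1] + sample.int(span, n, replace = TRUE) - 1L
    gene_ids <- sprintf("simgene%03d", seq_len(n))
    metas <- vector("list", n)
    for (i in seq_len(n)) {
      s <- random_dna(lens[i])
      if (!is.null(es)) {
        for (j in which(es$gene_id == gene_ids[i])) {
          a <- es$element_start[j]; b <- es$element_end[j]
          if (b > lens[i] || a < 0)
            stop(sprintf("element [%d,%d) outside UTR of length %d",
                         a, b, lens[i]), call. = FALSE)
          # per-base: A/G with prob ag_target, C/T otherwise (uniform within)
          p <- params$ag_target / 2
          elem <- random_dna(b - a, prob = c(p, 0.5 - p, p, 0.5 - p))
          substr(s, a + 1L, b) <- elem
        }
      }
      metas[[i]] <- meta_utr(gene_ids[i], s,
                             upstream_flank = random_dna(flank_len),
                             downstream_flank = random_dna(flank_len))
    }
    truth <- if (is.null(es)) empty_element_truth() else
      data.frame(gene_id = es$gene_id, element_start = es$element_start,
                 element_end = es$element_end,
                 log2_effect = es$log2_effect, stringsAsFactors = FALSE)
    names(metas) <- gene_ids
    attr(metas, "truth") <- truth
    metas
  })
}

empty_element_truth <- function() {
  data.frame(gene_id = character(), element_start = integer(),
             element_end = integer(), log2_effect = numeric(),
             stringsAsFactors = FALSE)
}

#' Place one random element per gene
#'
#' Convenience builder for `element_spec`: a single element per gene with a
#' uniformly placed start.
#'
#' @param utr_lens named integer vector of UTR lengths (names = gene ids).
#' @param element_len element length (nt).
#' @param log2_effect planted neurite effect (log2).
#' @param seed integer seed.
#' @return an `element_spec` data.frame.
#' @export
random_element_spec <- function(utr_lens, element_len = 200L,
                                log2_effect = 2, seed = NULL) {
  with_seed(seed, {
    starts <- vapply(utr_lens, function(L) {
      if (L < element_len) stop("UTR shorter than element", call. = FALSE)
      sample.int(L - element_len + 1L, 1L) - 1L
    }, 0L)
    data.frame(gene_id = names(utr_lens), element_start = as.integer(starts),
               element_end = as.integer(starts + element_len),
               log2_effect = log2_effect, stringsAsFactors = FALSE)
  })
}

## Oligo/element overlap in nt; offsets are UTR coordinates.
oligo_element_overlap <- function(offset, oligo_len, e_start, e_end) {
  pmax(0L, pmin(offset + oligo_len, e_end) - pmax(offset, e_start))
}

#' Simulate per-oligo UMI count matrices with planted effects
#'
#' Baseline relative abundances are log-normal (sdlog
#' `params$abundance_sdlog`) and shared across samples. An oligo that
#' overlaps a planted element by at least `params$overlap_frac` of the
#' element's length receives the element's `log2_effect` in neurite
#' samples. Counts are negative binomial with mean `abundance x library
#' size` and dispersion `params$dispersion` (Poisson at dispersion 0);
#' library sizes are uniform in `params$library_size_range`.
#'
#' @param pool an `oligo_pool` tiled from the simulated UTRs.
#' @param element_truth data.frame as produced by [simulate_utrs()]
#'   (attribute `truth`); `NULL` means no effects.
#' @param params a [count_sim_params()] object.
#' @param seed overrides `params$seed`.
#' @return a `count_matrix`; attribute `truth` is a list with per-oligo
#'   baseline abundance, true log2 effect, and the per-sample library
#'   sizes.
#' @export
simulate_counts <- function(pool, element_truth = NULL,
                            params = count_sim_params(),
                            seed = params$seed) {
  olen <- nchar(pool$insert_sequence[1] %||% "")
  if (is.na(olen) || olen == 0) olen <- 260L
  n_oligo <- nrow(pool)
  nrep <- params$n_replicates
  samples <- data.frame(
    sample = c(sprintf("soma_rep%d", seq_len(nrep)),
               sprintf("neurite_rep%d", seq_len(nrep))),
    compartment = rep(c("soma", "neurite"), each = nrep),
    replicate = rep(seq_len(nrep), 2L), stringsAsFactors = FALSE)
  with_seed(seed, {
    base <- rlnorm(n_oligo, meanlog = 0, sdlog = params$abundance_sdlog)
    effect <- numeric(n_oligo)
    if (!is.null(element_truth) && nrow(element_truth) > 0) {
      for (j in seq_len(nrow(element_truth))) {
        gi <- pool$gene_id == element_truth$gene_id[j]
        ov <- oligo_element_overlap(pool$offset, olen,
                                    element_truth$element_start[j],
                                    element_truth$element_end[j])
        elen <- element_truth$element_end[j] - element_truth$element_start[j]
        hit <- gi & (ov >= params$overlap_frac * elen)
        effect[hit] <- effect[hit] + element_truth$log2_effect[j]
      }
    }
    soma_ab <- base / sum(base)
    neu_raw <- base * 2^effect
    neu_ab <- neu_raw / sum(neu_raw)
    lib <- runif(nrow(samples), params$library_size_range[1],
                 params$library_size_range[2])
    counts <- matrix(0L, n_oligo, nrow(samples))
    for (j in seq_len(nrow(samples))) {
      mu <- lib[j] * (if (samples$compartment[j] == "soma") soma_ab else neu_ab)
      counts[, j] <- if (params$dispersion <= 0) rpois(n_oligo, mu) else
        rnbinom(n_oligo, mu = mu, size = 1 / params$dispersion)
    }
    rownames(counts) <- pool$oligo_id
    cm <- count_matrix(counts, samples)
    attr(cm, "truth") <- list(
      abundance = setNames(soma_ab, pool$oligo_id),
      log2_effect = setNames(effect, pool$oligo_id),
      library_sizes = setNames(lib, samples$sample))
    cm
  })
}

## Apply `ndel` deletions at uniform template positions, then extend from
## the template to `out_len`. `tpl` must be at least out_len + ndel long.
apply_deletions <- function(tpl, ndel, out_len) {
  keep <- sort(sample.int(out_len + ndel, out_len))
  paste(strsplit(tpl, "", fixed = TRUE)[[1]][keep], collapse = "")
}

#' Simulate error-bearing paired-end MPRA reads
#'
#' Source oligos are drawn by relative abundance. The forward read is the
#' first `fwd_len` nt of the oligo insert; the reverse read is the
#' reverse complement of the last `rev_len` nt, prefixed by a random
#' `umi_len`-nt UMI. Deletions are applied first (a deleted base is skipped
#' and the read extended from the template so reads always have full
#' declared length), then substitutions (uniform among the other three
#' bases). Qualities are constant.
#'
#' @param pool an `oligo_pool`.
#' @param abundances per-oligo relative abundances (recycled uniform when
#'   `NULL`); normalized internally.
#' @param params a [read_sim_params()] object.
#' @param seed overrides `params$seed`.
#' @return list with `fwd`/`rev` data.frames (`name`, `seq`) and `truth`
#'   (data.frame `name`, `oligo_id`, `n_del_fwd`, `n_del_rev`).
#' @export
simulate_reads <- function(pool, abundances = NULL,
                           params = read_sim_params(), seed = params$seed) {
  olen <- nchar(pool$insert_sequence[1])
  if (params$fwd_len > olen || params$rev_len > olen)
    stop("requested read longer than oligo", call. = FALSE)
  n <- params$n_reads
  if (is.null(abundances)) abundances <- rep(1, nrow(pool))
  stopifnot(length(abundances) == nrow(pool))
  abundances <- abundances / sum(abundances)
  with_seed(seed, {
    src <- sample.int(nrow(pool), n, replace = TRUE, prob = abundances)
    names_out <- sprintf("read%07d", seq_len(n))
    # forward template: oligo 5' end; reverse template: revcomp of 3' end
    fwd_tpl_full <- pool$insert_sequence
    rev_tpl_full <- revcomp(pool$insert_sequence)
    fwd <- substr(fwd_tpl_full[src], 1L, params$fwd_len)
    rev <- substr(rev_tpl_full[src], 1L, params$rev_len)
    # deletions (rare): rebuild affected reads from an extended template
    ndel_f <- rbinom(n, params$fwd_len, params$deletion_rate)
    ndel_r <- rbinom(n, params$rev_len, params$deletion_rate)
    for (i in which(ndel_f > 0L)) {
      tpl <- substr(fwd_tpl_full[src[i]], 1L, params$fwd_len + ndel_f[i])
      fwd[i] <- apply_deletions(tpl, ndel_f[i], params$fwd_len)
    }
    for (i in which(ndel_r > 0L)) {
      tpl <- substr(rev_tpl_full[src[i]], 1L, params$rev_len + ndel_r[i])
      rev[i] <- apply_deletions(tpl, ndel_r[i], params$rev_len)
    }
    fwd <- mutate_bases(fwd, params$mutation_rate)
    rev <- mutate_bases(rev, params$mutation_rate)
    umi_mat <- matrix(sample(DNA_BASES, n * params$umi_len, replace = TRUE),
                      nrow = n)
    umi <- do.call(paste0, as.data.frame(umi_mat, stringsAsFactors = FALSE))
    truth <- data.frame(name = names_out, oligo_id = pool$oligo_id[src],
                        n_del_fwd = ndel_f, n_del_rev = ndel_r,
                        stringsAsFactors = FALSE)
    list(fwd = data.frame(name = names_out, seq = fwd,
                          stringsAsFactors = FALSE),
         rev = data.frame(name = names_out, seq = paste0(umi, rev),
                          stringsAsFactors = FALSE),
         truth = truth)
  })
}

## Vectorized per-base substitution at `rate`; substitutes uniformly among
## the other three bases. Uses the current RNG stream.
mutate_bases <- function(reads, rate) {
  if (rate <= 0) return(reads)
  lens <- nchar(reads)
  total <- sum(lens)
  nmut <- rbinom(1L, total, rate)
  if (nmut == 0L) return(reads)
  pos <- sample.int(total, nmut)           # global base coordinates
  ends <- cumsum(lens)
  read_idx <- findInterval(pos - 1L, ends) + 1L
  within <- pos - c(0L, ends)[read_idx]
  shift <- sample.int(3L, nmut, replace = TRUE)  # 1..3 away from original
  for (k in seq_len(nmut)) {
    i <- read_idx[k]; p <- within[k]
    old <- substr(reads[i], p, p)
    oi <- match(old, DNA_BASES)
    if (is.na(oi)) next                    # leave N untouched
    new <- DNA_BASES[((oi - 1L + shift[k]) %% 4L) + 1L]
    substr(reads[i], p, p) <- new
  }
  reads
}
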