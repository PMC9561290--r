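#' Oligo pool design parameters
#'
#' Defaults reproduce the dense-tiling design: 260-nt oligos stepped 4 nt
#' apart, a 260-nt flank extension on each side of the UTR so that the UTR
#' ends are covered at full depth, 20-nt PCR handles, and exclusion of UTRs
#' longer than 10 kb. With these defaults every interior UTR nucleotide is
#' contained in exactly `oligo_length / step = 65` oligos.
#'
#' @param oligo_length insert length in nt.
#' @param step distance between neighboring oligo starts in nt; must divide
#'   `oligo_length` so that coverage is uniform.
#' @param flank_extension nt of genomic sequence added on each side of the
#'   meta-UTR before tiling. Defaults to `oligo_length`.
#' @param handle_5p,handle_3p 20-nt PCR handles added to each insert. The
#'   defaults are placeholders; set your own for synthesis.
#' @param max_utr_length UTRs longer than this are excluded.
#' @return an object of class `design_params`.
#' @export
design_params <- function(oligo_length = 260L, step = 4L,
                          flank_extension = oligo_length,
                          handle_5p = "ACTGGCCGCTTCACTGGTAC",
                          handle_3p = "GTACTCGAGGATCCAGCGGC",
                          max_utr_length = 10000L) {
  assert_scalar_num(oligo_length, "oligo_length", 1)
  assert_scalar_num(step, "step", 1)
  assert_scalar_num(flank_extension, "flank_extension", 0)
  assert_scalar_num(max_utr_length, "max_utr_length", 1)
  if (oligo_length %% step != 0)
    stop("oligo_length must be divisible by step (uniform coverage)",
         call. = FALSE)
  for (h in list(handle_5p, handle_3p)) {
    if (nzchar(h) && nchar(h) != 20L)
      stop("PCR handles must be exactly 20 nt (or empty)", call. = FALSE)
  }
  structure(list(oligo_length = as.integer(oligo_length),
                 step = as.integer(step),
                 flank_extension = as.integer(flank_extension),
                 handle_5p = normalize_seq(handle_5p),
                 handle_3p = normalize_seq(handle_3p),
                 max_utr_length = as.integer(max_utr_length)),
            class = "design_params")
}

#' Paired-end read simulation parameters
#'
#' The read geometry mimics targeted MPRA sequencing after adapter removal:
#' the forward read carries the first 97 nt of the oligo insert and the
#' reverse read carries the last 91 nt (reverse-complemented), prefixed by an
#' 8-nt random UMI. Synthesis and sequencing errors are modeled as per-base
#' substitutions at rate 0.002 and deletions at rate 0.0001.
#'
#' @param n_reads number of read pairs.
#' @param fwd_len,rev_len biological read lengths in nt.
#' @param mutation_rate per-base substitution probability.
#' @param deletion_rate per-base deletion probability.
#' @param umi_len UMI length in nt.
#' @param seed integer seed; all randomness in [simulate_reads()] flows from
#'   it.
#' @return an object of class `read_sim_params`.
#' @export
read_sim_params <- function(n_reads = 1e5, fwd_len = 97L, rev_len = 91L,
                            mutation_rate = 0.002, deletion_rate = 1e-4,
                            umi_len = 8L, seed = NULL) {
  assert_scalar_num(n_reads, "n_reads", 0)
  assert_scalar_num(fwd_len, "fwd_len", 1)
  assert_scalar_num(rev_len, "rev_len", 1)
  assert_scalar_num(mutation_rate, "mutation_rate", 0, 1)
  assert_scalar_num(deletion_rate, "deletion_rate", 0, 1)
  assert_scalar_num(umi_len, "umi_len", 1)
  structure(list(n_reads = as.integer(n_reads), fwd_len = as.integer(fwd_len),
                 rev_len = as.integer(rev_len),
                 mutation_rate = mutation_rate, deletion_rate = deletion_rate,
                 umi_len = as.integer(umi_len), seed = seed),
            class = "read_sim_params")
}

#' Count-simulation parameters
#'
#' Describes the world the enrichment stage assumes: synthetic UTRs of
#' random length 500-5000 nt, log-normal baseline oligo abundances,
#' replicate soma/neurite libraries, negative-binomial counting noise, and
#' localization effects concentrated in contiguous element-overlapping
#' oligos.
#'
#' @param n_genes number of synthetic genes.
#' @param utr_len_range length-2 range of UTR lengths (nt), sampled
#'   uniformly.
#' @param n_replicates replicates per compartment.
#' @param element_spec `NULL` or a data.frame with columns `gene_id`,
#'   `element_start`, `element_end` (0-based, end-exclusive, UTR
#'   coordinates) and `log2_effect`.
#' @param dispersion negative-binomial dispersion (`0` gives Poisson
#'   counts).
#' @param library_size_range length-2 range of per-sample library sizes.
#' @param ag_target A+G fraction inside planted elements (background 0.5).
#' @param overlap_frac minimum fraction of the element an oligo must overlap
#'   to receive its effect.
#' @param abundance_sdlog sdlog of the log-normal baseline abundances.
#' @param seed integer seed.
#' @return an object of class `count_sim_params`.
#' @export
count_sim_params <- function(n_genes = 1L,
                             utr_len_range = c(500L, 5000L),
                             n_replicates = 4L,
                             element_spec = NULL,
                             dispersion = 0.05,
                             library_size_range = c(5e5, 2e6),
                             ag_target = 0.8,
                             overlap_frac = 0.5,
                             abundance_sdlog = 0.5,
                             seed = NULL) {
  assert_scalar_num(n_genes, "n_genes", 0)
  stopifnot(length(utr_len_range) == 2L, utr_len_range[1] <= utr_len_range[2])
  assert_scalar_num(n_replicates, "n_replicates", 1)
  assert_scalar_num(dispersion, "dispersion", 0)
  stopifnot(length(library_size_range) == 2L)
  assert_scalar_num(ag_target, "ag_target", 0, 1)
  assert_scalar_num(overlap_frac, "overlap_frac", 0, 1)
  if (!is.null(element_spec)) {
    need <- c("gene_id", "element_start", "element_end", "log2_effect")
    if (!all(need %in% names(element_spec)))
      stop("element_spec needs columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    if (any(!is.finite(element_spec$log2_effect)))
      stop("log2_effect must be finite", call. = FALSE)
    if (any(element_spec$element_end <= element_spec$element_start))
      stop("element_end must exceed element_start", call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes),
                 utr_len_range = as.integer(utr_len_range),
                 n_replicates = as.integer(n_replicates),
                 element_spec = element_spec,
                 dispersion = dispersion,
                 library_size_range = as.numeric(library_size_range),
                 ag_target = ag_target,
                 overlap_frac = overlap_frac,
                 abundance_sdlog = abundance_sdlog,
                 seed = seed),
            class = "count_sim_params")
}
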