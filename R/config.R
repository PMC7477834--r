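#' Pipeline configuration
#'
#' Assembles the tunable parameters of the caller. The platform preset selects
#' the length-partition weight (alpha) and the major-allele support fraction
#' (mu) appropriate for high-error reads (PacBio CLR, ONT) or low-error reads
#' (PacBio CCS): alpha is 0.2 (CLR/ONT) or 0.65 (CCS) for insertion clusters
#' and 0.3 for deletion clusters regardless of platform; mu is 0.6/0.65 for
#' insertions and 0.7/0.35 for deletions. Duplication/inversion refinement
#' always uses mu = 1/3, breakend refinement mu = 0.6 with a halved support
#' floor.
#'
#' @param platform one of "clr", "ont", "ccs".
#' @param min_support minimum number of supporting reads for an SV allele
#'   (SR_min).
#' @param min_size minimum SV signature size in bp considered at extraction;
#'   also the final call-size filter.
#' @param min_mapq records below this mapping quality are ignored.
#' @param max_cluster_bias_DEL,max_cluster_bias_INS,max_cluster_bias_DUP,max_cluster_bias_INV,max_cluster_bias_BND
#'   per-type position-clustering thresholds (TH) in bp.
#' @param sig_dis_DEL,sig_dis_INS maximum gap for merging fragmented CIGAR
#'   indels of one read.
#' @param diff_ratio_merging_INS override for alpha of insertion clusters
#'   (NULL = platform preset).
#' @param diff_ratio_filtering_INS,diff_ratio_filtering_DEL overrides for mu
#'   (NULL = platform preset).
#' @param epsilon per-read zygosity mis-assignment probability of the
#'   genotype likelihood model.
#' @param gt_flank half-width in bp of the window a reference-supporting read
#'   must fully span.
#' @param gq_cap ceiling for the conditional genotype quality.
#' @param block_size genome block length in bp for parallel processing.
#' @param block_pad extra margin read groups are shared across block borders
#'   so clusters never straddle a cut.
#' @return a named list of parameters.
#' @export
svConfig <- function(platform = c("clr", "ccs", "ont"),
                     min_support = 10L,
                     min_size = 30L,
                     min_mapq = 20L,
                     max_cluster_bias_DEL = 200,
                     max_cluster_bias_INS = 200,
                     max_cluster_bias_DUP = 500,
                     max_cluster_bias_INV = 500,
                     max_cluster_bias_BND = 50,
                     sig_dis_DEL = 200,
                     sig_dis_INS = 500,
                     diff_ratio_merging_INS = NULL,
                     diff_ratio_filtering_INS = NULL,
                     diff_ratio_filtering_DEL = NULL,
                     epsilon = 0.1,
                     gt_flank = 500,
                     gq_cap = 100,
                     block_size = 1e7,
                     block_pad = 5e4) {
  platform <- match.arg(platform)
  ccs <- platform == "ccs"
  stopifnot(min_size >= 1, min_support >= 1)
  list(
    platform = platform,
    min_support = as.integer(min_support),
    min_size = as.integer(min_size),
    # the 30-bp constants in the split-pair geometry move with min_size when
    # a smaller threshold is requested
    pair_thr = min(30L, as.integer(min_size)),
    min_mapq = as.integer(min_mapq),
    th = c(DEL = max_cluster_bias_DEL, INS = max_cluster_bias_INS,
           DUP = max_cluster_bias_DUP, INV = max_cluster_bias_INV,
           BND = max_cluster_bias_BND),
    sig_dis = c(DEL = sig_dis_DEL, INS = sig_dis_INS),
    alpha = c(INS = if (is.null(diff_ratio_merging_INS)) {
                 if (ccs) 0.65 else 0.2
               } else diff_ratio_merging_INS,
              DEL = 0.3),
    mu = c(INS = if (is.null(diff_ratio_filtering_INS)) {
              if (ccs) 0.65 else 0.6
            } else diff_ratio_filtering_INS,
           DEL = if (is.null(diff_ratio_filtering_DEL)) {
              if (ccs) 0.35 else 0.7
            } else diff_ratio_filtering_DEL,
           DUPINV = 1 / 3,
           BND = 0.6),
    bnd_read_gap = 100,
    dupinv_refine_dist = 500,
    bnd_refine_dist = 50,
    cluster_floor = 2L,
    epsilon = epsilon,
    gt_flank = gt_flank,
    gq_cap = gq_cap,
    block_size = block_size,
    block_pad = block_pad
  )
}
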