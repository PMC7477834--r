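# cluster + refine + summarize the signatures of one block/file
.callFromSignatures <- function(sigs, config) {
  out <- list()
  for (type in SV_TYPES) {
    st <- sigs[sigs$sv_type == type, , drop = FALSE]
    if (!nrow(st)) next
    key <- if (type == "BND") paste(st$chrom1, st$chrom2) else st$chrom1
    for (idx in split(seq_len(nrow(st)), key)) {
      sub <- st[idx, , drop = FALSE]
      clusters <- clusterByPosition(sub, config$th[[type]],
                                    min_reads = config$cluster_floor)
      for (cl in clusters) {
        ref <- switch(type,
          DEL = ,
          INS = refineDelIns(cl, config$alpha[[type]], config$min_support,
                             config$mu[[type]]),
          DUP = ,
          INV = refineDupInv(cl, config$min_support,
                             max_dist = config$dupinv_refine_dist,
                             mu = config$mu[["DUPINV"]]),
          BND = refineBnd(cl, config$min_support,
                          max_dist = config$bnd_refine_dist,
                          mu = config$mu[["BND"]]))
        keep <- which(ref$roles %in% c("major", "minor"))
        for (k in keep) {
          call <- summarizeAllele(ref$subclusters[[k]],
                                  min_size = config$min_size)
          if (!is.null(call)) out[[length(out) + 1]] <- call
        }
      }
    }
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.genotypeCalls <- function(calls, records, config) {
  n <- nrow(calls)
  spans <- records[, c("qname", "chrom", "pos0", "ref_end")]
  names(spans) <- c("qname", "chrom", "ref_start", "ref_end")
  sr_ref <- integer(n)
  for (i in seq_len(n)) {
    alt <- strsplit(calls$read_names[i], ",", fixed = TRUE)[[1]]
    sr_ref[i] <- countReferenceReads(spans, calls$chrom[i], calls$pos0[i],
                                     alt, flank = config$gt_flank)
  }
  g <- genotypeLikelihoods(sr_ref, calls$support, epsilon = config$epsilon,
                           gq_cap = config$gq_cap)
  calls$gt <- g$gt
  calls$dr <- sr_ref
  calls$dv <- calls$support
  calls$gl_00 <- g$gl_00; calls$gl_01 <- g$gl_01; calls$gl_11 <- g$gl_11
  calls$gq <- g$gq
  calls$qual <- g$qual
  calls
}

.callBlock <- function(records, block, config, genotype) {
  sub <- records[records$qname %in% block$use_qnames, , drop = FALSE]
  if (!nrow(sub)) return(NULL)
  sigs <- .signaturesFromRecords(sub, config)
  calls <- .callFromSignatures(sigs, config)
  if (is.null(calls)) return(NULL)
  own <- calls$chrom == block$chrom & calls$pos0 >= block$start &
    calls$pos0 < block$end
  calls <- calls[own, , drop = FALSE]
  if (!nrow(calls)) return(NULL)
  if (genotype) {
    calls <- .genotypeCalls(calls, sub, config)
  } else {
    calls$gt <- "./."
    calls$dr <- NA_integer_; calls$dv <- calls$support
    calls$gl_00 <- NA_real_; calls$gl_01 <- NA_real_; calls$gl_11 <- NA_real_
    calls$gq <- NA_real_; calls$qual <- NA_real_
  }
  calls
}

#' Call structural variants from long-read alignments
#'
#' Full pipeline: stream the alignment file, extract per-read SV signatures,
#' cluster and refine them into allele sub-clusters, summarize each allele
#' into a call and (optionally) genotype it under the bi-allelic likelihood
#' model. The genome is partitioned into blocks that are processed
#' independently (optionally in parallel); each read group is owned by
#' exactly one block and blocks share a padding margin, so the output is
#' identical for any thread count.
#'
#' @param file coordinate-sorted SAM/BAM path.
#' @param config configuration from \code{\link{svConfig}}.
#' @param sample sample name for the VCF column.
#' @param genotype logical; skip the genotyping stage with FALSE (genotypes
#'   are then reported as "./.").
#' @param threads number of worker processes for block processing.
#' @param include_chroms optional contig restriction.
#' @return an \code{\linkS4class{SVCallSet}}.
#' @export
callSVs <- function(file, config = svConfig(), sample = "SAMPLE",
                    genotype = TRUE, threads = 1L, include_chroms = NULL) {
  if (!file.exists(file)) stop("input alignment file not found: ", file)
  aln <- readAlignments(file, min_mapq = config$min_mapq,
                        include_chroms = include_chroms)
  records <- aln$records
  contigs <- aln$contigs
  if (!is.null(include_chroms))
    contigs <- contigs[contigs$name %in% include_chroms, , drop = FALSE]
  blocks <- streamBlocks(records, contigs, config$block_size,
                         config$block_pad)
  blocks <- blocks[vapply(blocks, function(b) length(b$use_qnames) > 0,
                          logical(1))]
  worker <- function(b) .callBlock(records, b, config, genotype)
  res <- if (threads > 1) {
    parallel::mclapply(blocks, worker, mc.cores = threads)
  } else {
    lapply(blocks, worker)
  }
  err <- vapply(res, inherits, logical(1), what = "try-error")
  if (any(err)) stop("block worker failed: ", res[[which(err)[1]]])
  calls <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (!is.null(calls) && nrow(calls)) {
    ord <- order(match(calls$chrom, contigs$name), calls$pos0, calls$sv_type,
                 calls$svlen, calls$pos2)
    calls <- calls[ord, , drop = FALSE]
    rownames(calls) <- NULL
  }
  .newSVCallSet(calls, contigs, sample = sample, genotyped = genotype)
}
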