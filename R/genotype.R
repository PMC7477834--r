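#' Summarize an allele sub-cluster into call coordinates
#'
#' The call breakpoint(s) and size are the (unweighted) arithmetic means of
#' the member signatures' positions and sizes, rounded to integers; each read
#' contributes once. Calls smaller than \code{min_size} bp are rejected.
#'
#' @param sub signature data.frame of one allele sub-cluster.
#' @param min_size final size filter in bp (default 30).
#' @return one-row data.frame (chrom, pos0, end0, svlen, sv_type, support,
#'   chrom2, pos2, orientation, read_names) or NULL when filtered out.
#' @export
summarizeAllele <- function(sub, min_size = 30) {
  type <- sub$sv_type[1]
  reads <- unique(sub$read_id)
  pos <- round(mean(sub$pos1))
  if (type %in% c("DEL", "INS")) {
    svlen <- round(mean(sub$length))
    if (svlen < min_size) return(NULL)
    end <- if (type == "DEL") pos + svlen else pos
    svlen_signed <- if (type == "DEL") -svlen else svlen
    return(data.frame(chrom = sub$chrom1[1], pos0 = pos, end0 = end,
                      svlen = svlen_signed, sv_type = type,
                      support = length(reads), chrom2 = sub$chrom1[1],
                      pos2 = NA_real_, orientation = NA_character_,
                      read_names = paste(reads, collapse = ","),
                      stringsAsFactors = FALSE))
  }
  if (type %in% c("DUP", "INV")) {
    end <- round(mean(sub$pos2))
    svlen <- end - pos
    if (svlen < min_size) return(NULL)
    orient <- if (type == "INV") {
      names(sort(table(sub$orientation), decreasing = TRUE))[1]
    } else NA_character_
    return(data.frame(chrom = sub$chrom1[1], pos0 = pos, end0 = end,
                      svlen = svlen, sv_type = type,
                      support = length(reads), chrom2 = sub$chrom1[1],
                      pos2 = NA_real_, orientation = orient,
                      read_names = paste(reads, collapse = ","),
                      stringsAsFactors = FALSE))
  }
  # breakend: mate position is the second breakpoint; no size filter
  data.frame(chrom = sub$chrom1[1], pos0 = pos, end0 = pos,
             svlen = NA_real_, sv_type = "BND",
             support = length(reads), chrom2 = sub$chrom2[1],
             pos2 = round(mean(sub$pos2)),
             orientation = sub$orientation[1],
             read_names = paste(reads, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Count reference-supporting reads around a breakpoint
#'
#' A read supports the reference allele when one of its alignment records
#' fully spans the window \code{[pos - flank, pos + flank]} and the read is
#' not among the SV-supporting read names.
#'
#' @param spans data.frame of record spans (qname, chrom, ref_start, ref_end).
#' @param chrom,pos breakpoint (0-based).
#' @param alt_read_names character vector of SV-supporting reads.
#' @param flank half-window in bp (default 500).
#' @return integer count of distinct reference-supporting reads.
#' @export
countReferenceReads <- function(spans, chrom, pos, alt_read_names,
                                flank = 500) {
  hit <- spans$chrom == chrom & spans$ref_start <= pos - flank &
    spans$ref_end >= pos + flank
  length(setdiff(unique(spans$qname[hit]), alt_read_names))
}

#' Bi-allelic genotype likelihoods from supporting-read counts
#'
#' Under a diploid model with a flat 1/3 genotype prior and a constant
#' per-read mis-assignment probability \code{epsilon}, the likelihoods of the
#' three zygosities given \code{sr_ref} reference-supporting and
#' \code{sr_alt} SV-supporting reads are
#' \deqn{L(0/0) = 1/3 (1-\epsilon)^{ref} \epsilon^{alt},\quad
#'       L(0/1) = 1/3 \, 0.5^{ref+alt},\quad
#'       L(1/1) = 1/3 (1-\epsilon)^{alt} \epsilon^{ref}.}
#' Computation is in log space; posteriors are normalized by
#' log-sum-exp. The genotype is the posterior argmax; GL are the log10
#' posteriors, GQ the (capped) phred gap between best and second-best, and
#' QUAL the phred-scaled posterior that the site is homozygous reference
#' (for a 0/0 call, that it is not).
#'
#' @param sr_ref,sr_alt supporting-read counts (vectorized).
#' @param epsilon per-read error probability (0 < epsilon < 1).
#' @param gq_cap GQ ceiling (default 100).
#' @return data.frame (gt, gl_00, gl_01, gl_11, gq, qual); gt is "./." when
#'   both counts are zero.
#' @export
genotypeLikelihoods <- function(sr_ref, sr_alt, epsilon = 0.1, gq_cap = 100) {
  stopifnot(epsilon > 0, epsilon < 1, length(sr_ref) == length(sr_alt))
  lp <- log(1 / 3)
  l00 <- lp + sr_ref * log1p(-epsilon) + sr_alt * log(epsilon)
  l01 <- lp + (sr_ref + sr_alt) * log(0.5)
  l11 <- lp + sr_alt * log1p(-epsilon) + sr_ref * log(epsilon)
  m <- pmax(l00, l01, l11)
  norm <- m + log(exp(l00 - m) + exp(l01 - m) + exp(l11 - m))
  gl <- cbind(l00 - norm, l01 - norm, l11 - norm) / log(10)
  idx <- max.col(gl, ties.method = "last")
  gt <- c("0/0", "0/1", "1/1")[idx]
  second <- vapply(seq_len(nrow(gl)), function(i) {
    max(gl[i, -idx[i]])
  }, numeric(1))
  best <- gl[cbind(seq_len(nrow(gl)), idx)]
  gq <- pmin(gq_cap, round(10 * (best - second)))
  p00 <- 10^gl[, 1]
  qual <- ifelse(gt == "0/0",
                 -10 * log10(pmax(1e-300, 1 - p00)),
                 -10 * (gl[, 1]))
  qual <- round(pmin(qual, 10 * 300), 1)
  none <- sr_ref + sr_alt == 0
  gt[none] <- "./."
  gq[none] <- NA_real_
  qual[none] <- NA_real_
  data.frame(gt = gt, gl_00 = gl[, 1], gl_01 = gl[, 2], gl_11 = gl[, 3],
             gq = gq, qual = qual, stringsAsFactors = FALSE)
}
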