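#' Interval-SV match predicate
#'
#' A prediction (comp) matches a truth record (base) of the DEL/INS/DUP/INV
#' classes when (i) the comp interval padded by 1 kbp on each side intersects
#' the base interval, (ii) the reciprocal size similarity
#' min(L)/max(L) is at least 0.7, and (iii) the SV classes agree. Insertions
#' use end = start + length.
#'
#' @param comp,base one-row data.frames with chrom, pos, end, size, sv_type.
#' @param window padding in bp applied to the comp side (default 1000).
#' @param min_size_ratio reciprocal size-similarity floor (default 0.7).
#' @return logical.
#' @export
matchInterval <- function(comp, base, window = 1000, min_size_ratio = 0.7) {
  if (comp$chrom != base$chrom) return(FALSE)
  if (comp$sv_type != base$sv_type) return(FALSE)
  if (is.na(comp$size) || is.na(base$size) ||
      comp$size == 0 || base$size == 0) return(FALSE)
  if (max(comp$pos - window, base$pos) > min(comp$end + window, base$end))
    return(FALSE)
  min(comp$size, base$size) / max(comp$size, base$size) >= min_size_ratio
}

#' Translocation match predicate
#'
#' At breakpoint level two breakend records match when both breakpoints are
#' within 1 kbp and the chromosome pair agrees; at breakend level the strand
#' connectivity class must additionally be identical.
#'
#' @param comp,base one-row data.frames with chrom, pos, chrom2, pos2,
#'   orientation.
#' @param level "breakpoint" or "breakend".
#' @param window breakpoint tolerance in bp (default 1000).
#' @return logical.
#' @export
matchTranslocation <- function(comp, base,
                               level = c("breakpoint", "breakend"),
                               window = 1000) {
  level <- match.arg(level)
  ok <- comp$chrom == base$chrom && comp$chrom2 == base$chrom2 &&
    abs(comp$pos - base$pos) <= window &&
    abs(comp$pos2 - base$pos2) <= window
  if (!ok) return(FALSE)
  if (level == "breakend") {
    return(!is.na(comp$orientation) && !is.na(base$orientation) &&
             comp$orientation == base$orientation)
  }
  TRUE
}

#' Precision, recall and F1 from match counts
#'
#' precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F1 = 2PR/(P+R); any 0/0 ratio is defined as 0.
#'
#' @param tp,fp,fn non-negative counts.
#' @return list(precision, recall, f1, tp, fp, fn).
#' @export
svMetrics <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  list(precision = p, recall = r, f1 = f1, tp = tp, fp = fp, fn = fn)
}

#' Convert duplication records to insertions
#'
#' Benchmark preprocessing used when a truth set represents tandem
#' duplications as inserted sequence: the class becomes INS and the end
#' coordinate follows the insertion convention.
#'
#' @param df SV table as from \code{\link{readSVVcf}}.
#' @return the transformed table.
#' @export
dupAsIns <- function(df) {
  i <- df$sv_type == "DUP" & !is.na(df$sv_type)
  df$sv_type[i] <- "INS"
  df$end[i] <- df$pos[i] + df$size[i]
  df
}

# greedy 1:1 assignment: comp records in position order claim the first
# eligible unmatched base record, ties broken by smallest breakpoint distance
.matchSets <- function(comp, base, level = "breakpoint", window = 1000,
                       min_size_ratio = 0.7) {
  comp_match <- rep(NA_integer_, nrow(comp))
  base_taken <- rep(FALSE, nrow(base))
  if (nrow(comp) && nrow(base)) {
    ord <- order(comp$chrom, comp$pos)
    for (i in ord) {
      ci <- comp[i, ]
      if (is.na(ci$sv_type)) next
      cand <- which(!base_taken & base$sv_type ==
                      (if (ci$sv_type == "BND") "BND" else ci$sv_type))
      if (!length(cand)) next
      ok <- vapply(cand, function(j) {
        if (ci$sv_type == "BND") {
          matchTranslocation(ci, base[j, ], level = level, window = window)
        } else {
          matchInterval(ci, base[j, ], window = window,
                        min_size_ratio = min_size_ratio)
        }
      }, logical(1))
      cand <- cand[ok]
      if (!length(cand)) next
      d <- abs(base$pos[cand] - ci$pos)
      j <- cand[which.min(d)]
      comp_match[i] <- j
      base_taken[j] <- TRUE
    }
  }
  comp_match
}

#' Benchmark a call set against a truth set
#'
#' Greedy one-to-one matching of predictions against truth records using the
#' interval predicate for DEL/INS/DUP/INV and the translocation predicate for
#' breakends, followed by precision/recall/F1 and their genotype-aware
#' variants (a matched prediction whose genotype differs from the truth
#' counts against the GT-aware statistics).
#'
#' @param comp,base SV tables (\code{\link{readSVVcf}} output) or VCF paths.
#' @param level breakend comparison level for BND records.
#' @param dup_as_ins transform DUP records to INS on both sides first.
#' @param window,min_size_ratio predicate parameters.
#' @return list(metrics, metrics_gt, matches) where matches is a data.frame
#'   with one row per comp record (base_idx, status).
#' @export
benchmarkCallsets <- function(comp, base, level = c("breakpoint", "breakend"),
                              dup_as_ins = FALSE, window = 1000,
                              min_size_ratio = 0.7) {
  level <- match.arg(level)
  if (is.character(comp)) comp <- readSVVcf(comp)
  if (is.character(base)) base <- readSVVcf(base)
  if (dup_as_ins) {
    comp <- dupAsIns(comp)
    base <- dupAsIns(base)
  }
  m <- .matchSets(comp, base, level = level, window = window,
                  min_size_ratio = min_size_ratio)
  tp <- sum(!is.na(m))
  fp <- nrow(comp) - tp
  fn <- nrow(base) - tp
  gt_ok <- !is.na(m) & !is.na(comp$gt) & !is.na(base$gt[m]) &
    comp$gt == base$gt[m]
  tp_gt <- sum(gt_ok, na.rm = TRUE)
  status <- ifelse(is.na(m), "FP", ifelse(gt_ok, "TP_GT", "TP"))
  list(
    metrics = svMetrics(tp, fp, fn),
    metrics_gt = svMetrics(tp_gt, fp + (tp - tp_gt), fn + (tp - tp_gt)),
    matches = data.frame(base_idx = m, status = status,
                         stringsAsFactors = FALSE))
}

# does any record of `set` match `rec` (no 1:1 constraint)
.anyMatch <- function(rec, set, window = 1000, min_size_ratio = 0.7) {
  if (is.na(rec$sv_type)) return(FALSE)
  cand <- which(set$sv_type == rec$sv_type |
                  (rec$sv_type == "BND" & set$sv_type == "BND"))
  for (j in cand) {
    hit <- if (rec$sv_type == "BND") {
      matchTranslocation(rec, set[j, ], level = "breakpoint", window = window)
    } else {
      matchInterval(rec, set[j, ], window = window,
                    min_size_ratio = min_size_ratio)
    }
    if (hit) return(TRUE)
  }
  FALSE
}

#' Trio concordance statistics
#'
#' Two family-based consistency measures: the trio recall is the fraction of
#' homozygous parental SVs re-identified in the offspring call set, and the
#' Mendelian discordance rate (MDR) is the fraction of offspring SVs not
#' re-identified in either parent's full call set. Parental records without
#' a genotype are excluded from the trio-recall denominator.
#'
#' @param offspring,father,mother SV tables or VCF paths.
#' @param window,min_size_ratio match-predicate parameters.
#' @return list(recall_trio, mdr, n_hom_parental, n_offspring).
#' @export
trioMetrics <- function(offspring, father, mother, window = 1000,
                        min_size_ratio = 0.7) {
  if (is.character(offspring)) offspring <- readSVVcf(offspring)
  if (is.character(father)) father <- readSVVcf(father)
  if (is.character(mother)) mother <- readSVVcf(mother)
  parents <- rbind(father, mother)
  hom <- parents[!is.na(parents$gt) & parents$gt %in% c("1/1", "1|1"), ,
                 drop = FALSE]
  found <- vapply(seq_len(nrow(hom)), function(i) {
    .anyMatch(hom[i, ], offspring, window, min_size_ratio)
  }, logical(1))
  recall_trio <- if (nrow(hom) == 0) 0 else sum(found) / nrow(hom)
  unmatched <- vapply(seq_len(nrow(offspring)), function(i) {
    !.anyMatch(offspring[i, ], parents, window, min_size_ratio)
  }, logical(1))
  mdr <- if (nrow(offspring) == 0) 0 else sum(unmatched) / nrow(offspring)
  list(recall_trio = recall_trio, mdr = mdr,
       n_hom_parental = nrow(hom), n_offspring = nrow(offspring))
}
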