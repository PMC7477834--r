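#' Extract large CIGAR indels as raw signatures
#'
#' Walks the CIGAR of each record and emits one raw indel signature per I/D
#' operation at least \code{min_size} bp long. The reference cursor advances
#' on M/=/X/D/N, the read cursor on M/=/X/I/S. A deletion is positioned where
#' the D operation begins; an insertion at the reference coordinate of the
#' insertion point. N operations advance the reference but never yield
#' deletion signatures (they encode splicing, not SVs).
#'
#' @param cigar character vector of CIGAR strings.
#' @param pos0 numeric vector of 0-based record start positions.
#' @param chrom character vector of contig names.
#' @param read_id character vector of read names.
#' @param min_size minimum indel length in bp (default 30).
#' @return data.frame (chrom, ref_start, length, kind, read_id), one row per
#'   qualifying I/D operation, in record/operation order.
#' @export
cigarSignatures <- function(cigar, pos0, chrom, read_id, min_size = 30) {
  stopifnot(min_size >= 1)
  ok <- grepl(CIGAR_RE, cigar)
  if (any(!ok)) {
    warning(sum(!ok), " malformed CIGAR(s) rejected")
    cigar <- cigar[ok]; pos0 <- pos0[ok]
    chrom <- chrom[ok]; read_id <- read_id[ok]
  }
  out <- list()
  if (!length(cigar)) {
    return(data.frame(chrom = character(0), ref_start = numeric(0),
                      length = numeric(0), kind = character(0),
                      read_id = character(0), stringsAsFactors = FALSE))
  }
  ops <- GenomicAlignments::explodeCigarOps(cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)
  for (i in seq_along(cigar)) {
    o <- ops[[i]]; l <- lens[[i]]
    hit <- (o == "D" | o == "I") & l >= min_size
    if (!any(hit)) next
    ref_adv <- l * (o %in% c("M", "=", "X", "D", "N"))
    ref_before <- cumsum(c(0, ref_adv))[seq_along(o)]
    w <- which(hit)
    out[[length(out) + 1]] <- data.frame(
      chrom = chrom[i], ref_start = pos0[i] + ref_before[w],
      length = l[w], kind = ifelse(o[w] == "D", "DEL", "INS"),
      read_id = read_id[i], stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), ref_start = numeric(0),
                      length = numeric(0), kind = character(0),
                      read_id = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Merge fragmented CIGAR indel signatures of one read
#'
#' Read aligners often represent one long insertion or deletion as a run of
#' smaller indel operations separated by short matches. Scanning a read's raw
#' indel signatures of one kind left to right, two consecutive signatures are
#' merged when their distance is at most \code{sig_dis}: for insertions the
#' distance is between the start coordinates, for deletions between the end
#' of the first (start + length) and the start of the second. The merged
#' record keeps the first start and sums the lengths; merging applies
#' transitively.
#'
#' @param sigs data.frame as from \code{\link{cigarSignatures}}, one read and
#'   one kind per chromosome.
#' @param sig_dis maximum merge distance in bp.
#' @return data.frame of the same shape with merged rows.
#' @export
mergeCigarSignatures <- function(sigs, sig_dis) {
  if (!nrow(sigs)) return(sigs)
  stopifnot(length(unique(sigs$kind)) == 1)
  sigs <- sigs[order(sigs$ref_start), , drop = FALSE]
  kind <- sigs$kind[1]
  start <- sigs$ref_start[1]; len <- sigs$length[1]
  out_s <- numeric(0); out_l <- numeric(0)
  for (i in seq_len(nrow(sigs))[-1]) {
    gap <- if (kind == "INS") sigs$ref_start[i] - start
           else sigs$ref_start[i] - (start + len)
    if (gap <= sig_dis) {
      len <- len + sigs$length[i]
    } else {
      out_s <- c(out_s, start); out_l <- c(out_l, len)
      start <- sigs$ref_start[i]; len <- sigs$length[i]
    }
  }
  out_s <- c(out_s, start); out_l <- c(out_l, len)
  data.frame(chrom = sigs$chrom[1], ref_start = out_s, length = out_l,
             kind = kind, read_id = sigs$read_id[1], stringsAsFactors = FALSE)
}

.sigRow <- function(sv_type, chrom1, pos1, chrom2 = chrom1, pos2 = NA_real_,
                    length = NA_real_, orientation = NA_character_, read_id) {
  data.frame(sv_type = sv_type, chrom1 = chrom1, pos1 = pos1,
             chrom2 = chrom2, pos2 = pos2, length = length,
             orientation = orientation, read_id = read_id,
             stringsAsFactors = FALSE)
}

#' Classify a read-adjacent segment pair into an SV signature
#'
#' For two segments adjacent on the read, the pair's geometry determines the
#' SV type. With both segments on one chromosome and strand, let
#' \code{diff_dis = (ref2_start - ref1_end) - (read2_start - read1_end)} (the
#' reference gap in excess of the read gap) and
#' \code{diff_olp = ref1_end - ref2_start} (the reference overlap):
#' \itemize{
#'   \item \code{diff_olp < thr} and \code{diff_dis >= thr}: deletion at
#'     ref1_end of length diff_dis;
#'   \item \code{diff_olp < thr} and \code{diff_dis <= -thr}: insertion at the
#'     (floored) midpoint of ref1_end and ref2_start, of length -diff_dis;
#'   \item \code{diff_olp >= thr}: duplication spanning ref2_start..ref1_end.
#' }
#' Opposite strands on one chromosome give an inversion: a head-to-head
#' junction (from the segment ends) when the first segment is forward, a
#' tail-to-tail junction (from the starts) otherwise. Different chromosomes
#' with a read gap below 100 bp give a breakend whose two sides take the
#' reference end of a forward first segment / start of a reverse one, and the
#' start of a forward second segment / end of a reverse one; the
#' alphabetically smaller chromosome is stored first.
#'
#' @param seg1,seg2 single-row segment data.frames (seg1 first on the read).
#' @param min_size threshold in bp for the deletion/insertion/duplication
#'   conditions (the classical 30-bp constant; tied to min_size when smaller).
#' @return one-row signature data.frame, or NULL when the pair is unremarkable.
#' @export
classifySegmentPair <- function(seg1, seg2, min_size = 30) {
  thr <- min(30, min_size)
  rid <- seg1$read_id
  if (seg1$chrom == seg2$chrom && seg1$strand == seg2$strand) {
    read_gap <- seg2$read_start - seg1$read_end
    if (seg1$strand == "-") {
      # a reverse-complement read presents the pair mirrored; evaluate the
      # geometry on the canonical forward orientation
      tmp <- seg1; seg1 <- seg2; seg2 <- tmp
    }
    diff_dis <- (seg2$ref_start - seg1$ref_end) - read_gap
    diff_olp <- seg1$ref_end - seg2$ref_start
    if (diff_olp < thr && diff_dis >= thr) {
      return(.sigRow("DEL", seg1$chrom, seg1$ref_end, length = diff_dis,
                     read_id = rid))
    }
    if (diff_olp < thr && diff_dis <= -thr) {
      mid <- floor((seg1$ref_end + seg2$ref_start) / 2)
      return(.sigRow("INS", seg1$chrom, mid, length = -diff_dis,
                     read_id = rid))
    }
    if (diff_olp >= thr) {
      return(.sigRow("DUP", seg1$chrom, seg2$ref_start,
                     pos2 = seg1$ref_end,
                     length = seg1$ref_end - seg2$ref_start, read_id = rid))
    }
    return(NULL)
  }
  if (seg1$chrom == seg2$chrom) {   # opposite strands: inversion junction
    if (seg1$strand == "+") {
      p <- sort(c(seg1$ref_end, seg2$ref_end))
      return(.sigRow("INV", seg1$chrom, p[1], pos2 = p[2],
                     length = p[2] - p[1], orientation = "INV_hh",
                     read_id = rid))
    }
    p <- sort(c(seg1$ref_start, seg2$ref_start))
    return(.sigRow("INV", seg1$chrom, p[1], pos2 = p[2],
                   length = p[2] - p[1], orientation = "INV_tt",
                   read_id = rid))
  }
  # different chromosomes: breakend, if the segments are close on the read
  if (seg2$read_start - seg1$read_end >= 100) return(NULL)
  bk1 <- if (seg1$strand == "+") seg1$ref_end else seg1$ref_start
  bk2 <- if (seg2$strand == "+") seg2$ref_start else seg2$ref_end
  orient <- paste0(seg1$strand, seg2$strand)
  if (seg1$chrom <= seg2$chrom) {
    .sigRow("BND", seg1$chrom, bk1, chrom2 = seg2$chrom, pos2 = bk2,
            length = 0, orientation = orient, read_id = rid)
  } else {
    .sigRow("BND", seg2$chrom, bk2, chrom2 = seg1$chrom, pos2 = bk1,
            length = 0, orientation = orient, read_id = rid)
  }
}

#' Detect the duplication-with-mobile-insertion triple pattern
#'
#' A read whose segment chain contains a triple (A, X, A') where A and A' map
#' to overlapping positions on one chromosome (duplication geometry) while X
#' maps elsewhere indicates an inserted mobile sequence between two copies of
#' a local duplication. The pattern yields the duplication signature of
#' (A, A'), the two breakend signatures linking X, and an insertion signature
#' at min(A_ref_end, A'_ref_start) whose length is the read-gap excess
#' between A and A'.
#'
#' @param segments segment chain of one read (sorted by read_start).
#' @param min_size threshold for the duplication-geometry test.
#' @return signature data.frame (possibly empty).
#' @export
detectComplexDupIns <- function(segments, min_size = 30) {
  out <- emptySignatures()
  n <- nrow(segments)
  if (is.null(segments) || n < 3) return(out)
  thr <- min(30, min_size)
  for (i in seq_len(n - 2)) {
    a <- segments[i, ]; x <- segments[i + 1, ]; a2 <- segments[i + 2, ]
    if (a$chrom != a2$chrom || a$strand != a2$strand) next
    if (x$chrom == a$chrom) next
    bnd1 <- classifySegmentPair(a, x, min_size)
    bnd2 <- classifySegmentPair(x, a2, min_size)
    read_gap <- a2$read_start - a$read_end
    if (a$strand == "-") {
      tmp <- a; a <- a2; a2 <- tmp     # mirrored on a reverse read
    }
    diff_olp <- a$ref_end - a2$ref_start
    if (diff_olp < thr) next
    diff_dis <- (a2$ref_start - a$ref_end) - read_gap
    dup <- .sigRow("DUP", a$chrom, a2$ref_start, pos2 = a$ref_end,
                   length = diff_olp, read_id = a$read_id)
    ins <- .sigRow("INS", a$chrom, min(a$ref_end, a2$ref_start),
                   length = -diff_dis, read_id = a$read_id)
    out <- rbind(out, dup, ins,
                 if (!is.null(bnd1) && bnd1$sv_type == "BND") bnd1,
                 if (!is.null(bnd2) && bnd2$sv_type == "BND") bnd2)
  }
  out
}

#' Extract all SV signatures of one read
#'
#' Combines the merged CIGAR indel signatures of all of the read's records
#' with the signatures classified from read-adjacent split-segment pairs and
#' the duplication-with-insertion triple pattern, de-duplicated on identical
#' (type, coordinates, orientation).
#'
#' @param records record rows of one read.
#' @param config configuration list from \code{\link{svConfig}}.
#' @return signature data.frame (possibly empty).
#' @export
extractSignatures <- function(records, config = svConfig()) {
  out <- emptySignatures()
  raw <- cigarSignatures(records$cigar, records$pos0, records$chrom,
                         records$qname, config$min_size)
  if (nrow(raw)) {
    for (kind in unique(raw$kind)) {
      for (ch in unique(raw$chrom[raw$kind == kind])) {
        sub <- raw[raw$kind == kind & raw$chrom == ch, , drop = FALSE]
        merged <- mergeCigarSignatures(sub, config$sig_dis[[kind]])
        out <- rbind(out, .sigRow(merged$kind, merged$chrom, merged$ref_start,
                                  length = merged$length,
                                  read_id = merged$read_id))
      }
    }
  }
  if (nrow(records) > 1 ||
      (nrow(records) == 1 && !is.na(records$sa[1]) && nzchar(records$sa[1]))) {
    segs <- splitSegments(records)
    if (!is.null(segs) && nrow(segs) > 1) {
      for (i in seq_len(nrow(segs) - 1)) {
        sig <- classifySegmentPair(segs[i, ], segs[i + 1, ], config$min_size)
        if (!is.null(sig)) out <- rbind(out, sig)
      }
      out <- rbind(out, detectComplexDupIns(segs, config$min_size))
    }
  }
  if (nrow(out) > 1) {
    key <- paste(out$sv_type, out$chrom1, out$pos1, out$chrom2, out$pos2,
                 out$length, out$orientation, out$read_id)
    out <- out[!duplicated(key), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Scan an alignment file for SV signatures
#'
#' Runs signature extraction over every read group of a SAM/BAM file and
#' returns the pooled result as an \code{\linkS4class{SVSignatureSet}}.
#'
#' @param file SAM/BAM path.
#' @param config configuration list from \code{\link{svConfig}}.
#' @return an SVSignatureSet.
#' @export
scanSignatures <- function(file, config = svConfig()) {
  aln <- readAlignments(file, min_mapq = config$min_mapq)
  sig <- .signaturesFromRecords(aln$records, config)
  new("SVSignatureSet", signatures = sig, source = file)
}

# batch version of extractSignatures over a whole record table: one pass of
# the vectorized CIGAR walk, then per-read work only where there is evidence
.signaturesFromRecords <- function(records, config) {
  if (!nrow(records)) return(emptySignatures())
  out <- list()
  raw <- cigarSignatures(records$cigar, records$pos0, records$chrom,
                         records$qname, config$min_size)
  if (nrow(raw)) {
    key <- paste(raw$read_id, raw$kind, raw$chrom)
    for (idx in split(seq_len(nrow(raw)), key)) {
      m <- mergeCigarSignatures(raw[idx, , drop = FALSE],
                                config$sig_dis[[raw$kind[idx[1]]]])
      out[[length(out) + 1]] <-
        .sigRow(m$kind, m$chrom, m$ref_start, length = m$length,
                read_id = m$read_id)
    }
  }
  multi <- records$qname[duplicated(records$qname)]
  has_sa <- records$qname[!is.na(records$sa) & nzchar(records$sa) &
                            records$is_primary]
  split_reads <- unique(c(multi, has_sa))
  if (length(split_reads)) {
    sub <- records[records$qname %in% split_reads, , drop = FALSE]
    for (idx in split(seq_len(nrow(sub)), sub$qname)) {
      segs <- splitSegments(sub[idx, , drop = FALSE])
      if (is.null(segs) || nrow(segs) < 2) next
      for (i in seq_len(nrow(segs) - 1)) {
        sig <- classifySegmentPair(segs[i, ], segs[i + 1, ], config$min_size)
        if (!is.null(sig)) out[[length(out) + 1]] <- sig
      }
      cx <- detectComplexDupIns(segs, config$min_size)
      if (nrow(cx)) out[[length(out) + 1]] <- cx
    }
  }
  if (!length(out)) return(emptySignatures())
  res <- do.call(rbind, out)
  key <- paste(res$sv_type, res$chrom1, res$pos1, res$chrom2, res$pos2,
               res$length, res$orientation, res$read_id)
  res <- res[!duplicated(key), , drop = FALSE]
  rownames(res) <- NULL
  res
}
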