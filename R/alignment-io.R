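CIGAR_RE <- "^([0-9]+[MIDNSHP=X])+$"

.flag <- function(flag, bit) bitwAnd(flag, bit) != 0L

# Ensure we have an indexed, coordinate-sorted BAM; SAM input is converted on
# the fly (text fixtures stay text, tooling works on BAM).
.asIndexedBam <- function(file) {
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    dest <- tempfile(fileext = ".bam")
    bam <- Rsamtools::asBam(file, sub("\\.bam$", "", dest),
                            overwrite = TRUE, indexDestination = TRUE)
    return(bam)
  }
  if (!file.exists(paste0(file, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", file))) {
    tryCatch(Rsamtools::indexBam(file), error = function(e) NULL)
  }
  file
}

#' Read alignment records into a flat table
#'
#' Streams a SAM/BAM file (SAM is converted internally) and returns one row
#' per usable alignment record with the clip-inclusive read-coordinate
#' bookkeeping needed for split-segment reconstruction. Secondary alignments,
#' unmapped records, records below the mapping-quality floor and records with
#' malformed CIGARs (dropped with a warning) are excluded.
#'
#' All coordinates are 0-based half-open.
#'
#' @param file path to a coordinate-sorted SAM or BAM file.
#' @param region optional "chrom:start-end" restriction (requires an index;
#'   an unindexed file with a region requested is a hard error).
#' @param min_mapq mapping-quality floor (default 20).
#' @param include_chroms optional character vector restricting contigs.
#' @return list with elements \code{records} (data.frame: qname, flag, chrom,
#'   pos0, mapq, strand, cigar, ref_end, clip_left, clip_right, qwidth,
#'   read_len, is_primary, sa) and \code{contigs} (data.frame name, length).
#' @export
readAlignments <- function(file, region = NULL, min_mapq = 20,
                           include_chroms = NULL) {
  bam <- .asIndexedBam(file)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  contigs <- data.frame(name = names(hdr), length = unname(hdr),
                        stringsAsFactors = FALSE)
  what <- c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar")
  if (is.null(region)) {
    param <- Rsamtools::ScanBamParam(what = what, tag = "SA")
  } else {
    gr <- as(region, "GRanges")
    if (!file.exists(paste0(bam, ".bai")) &&
        !file.exists(sub("\\.bam$", ".bai", bam)))
      stop("region queries require a coordinate-sorted, indexed BAM")
    param <- Rsamtools::ScanBamParam(what = what, tag = "SA", which = gr)
  }
  res <- Rsamtools::scanBam(bam, param = param)
  qname <- unlist(lapply(res, `[[`, "qname"), use.names = FALSE)
  if (length(qname) == 0) {
    return(list(records = .emptyRecords(), contigs = contigs))
  }
  flag <- unlist(lapply(res, `[[`, "flag"), use.names = FALSE)
  rname <- as.character(unlist(lapply(res, `[[`, "rname"), use.names = FALSE))
  strand <- as.character(unlist(lapply(res, `[[`, "strand"),
                                use.names = FALSE))
  pos <- unlist(lapply(res, `[[`, "pos"), use.names = FALSE)
  mapq <- unlist(lapply(res, `[[`, "mapq"), use.names = FALSE)
  cigar <- unlist(lapply(res, `[[`, "cigar"), use.names = FALSE)
  sa <- unlist(lapply(res, function(x) {
    s <- x$tag$SA
    if (is.null(s)) rep(NA_character_, length(x$qname)) else as.character(s)
  }), use.names = FALSE)

  keep <- !.flag(flag, 0x4) & !.flag(flag, 0x100) & !is.na(pos) &
    !is.na(cigar)
  keep <- keep & (is.na(mapq) | mapq >= min_mapq)
  if (!is.null(include_chroms)) keep <- keep & rname %in% include_chroms
  bad <- keep & !grepl(CIGAR_RE, cigar)
  if (any(bad)) {
    warning(sum(bad), " record(s) with malformed CIGAR skipped")
    keep <- keep & !bad
  }
  qname <- qname[keep]; flag <- flag[keep]; rname <- rname[keep]
  strand <- strand[keep]; pos <- pos[keep]; mapq <- mapq[keep]
  cigar <- cigar[keep]; sa <- sa[keep]
  if (!length(qname)) return(list(records = .emptyRecords(), contigs = contigs))

  geo <- .cigarGeometry(cigar)
  records <- data.frame(
    qname = qname, flag = flag, chrom = rname,
    pos0 = pos - 1, mapq = mapq, strand = strand, cigar = cigar,
    ref_end = pos - 1 + geo$ref_width,
    clip_left = geo$clip_left, clip_right = geo$clip_right,
    qwidth = geo$qwidth,
    read_len = geo$clip_left + geo$qwidth + geo$clip_right,
    is_primary = !.flag(flag, 0x800) & !.flag(flag, 0x100),
    sa = sa, stringsAsFactors = FALSE)
  list(records = records, contigs = contigs)
}

.emptyRecords <- function() {
  data.frame(qname = character(0), flag = integer(0), chrom = character(0),
             pos0 = numeric(0), mapq = integer(0), strand = character(0),
             cigar = character(0), ref_end = numeric(0),
             clip_left = numeric(0), clip_right = numeric(0),
             qwidth = numeric(0), read_len = numeric(0),
             is_primary = logical(0), sa = character(0),
             stringsAsFactors = FALSE)
}

# vectorized clip/width bookkeeping for a character vector of CIGARs
.cigarGeometry <- function(cigar) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)
  clip_left <- vapply(seq_along(ops), function(i) {
    o <- ops[[i]]; l <- lens[[i]]
    n <- 0; k <- 0
    while (k < length(o) && o[k + 1] %in% c("S", "H")) {
      k <- k + 1; n <- n + l[k]
    }
    n
  }, numeric(1))
  clip_right <- vapply(seq_along(ops), function(i) {
    o <- ops[[i]]; l <- lens[[i]]
    n <- 0; k <- length(o)
    while (k >= 1 && o[k] %in% c("S", "H")) {
      n <- n + l[k]; k <- k - 1
    }
    n
  }, numeric(1))
  qwidth <- GenomicAlignments::cigarWidthAlongQuerySpace(
    cigar, after.soft.clipping = TRUE)
  ref_width <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
  list(clip_left = clip_left, clip_right = clip_right,
       qwidth = qwidth, ref_width = ref_width)
}

#' Reconstruct the split-segment chain of one read
#'
#' Converts the primary + supplementary records of a single read into aligned
#' segments on the coordinates of the full (clip-inclusive) read, so segment
#' adjacency on the read can be assessed across records. Soft and hard clips
#' both count towards the read offsets, which makes the coordinates agree
#' between records regardless of the clip encoding. For a reverse-strand
#' record the offsets are flipped onto the original read orientation using
#' the implied total read length.
#'
#' When only a primary record is present but it carries an SA tag, the
#' supplementary segments are reconstructed from the tag as a fallback.
#'
#' @param records data.frame rows of one read (as from
#'   \code{\link{readAlignments}}).
#' @return data.frame of segments sorted by read_start (read_id, chrom,
#'   read_start, read_end, ref_start, ref_end, strand, is_primary), or NULL
#'   when the read has no primary alignment or inconsistent implied read
#'   lengths.
#' @export
splitSegments <- function(records) {
  if (!nrow(records)) return(NULL)
  if (!any(records$is_primary)) return(NULL)
  if (nrow(records) == 1 && !is.na(records$sa[1]) && nzchar(records$sa[1])) {
    records <- rbind(records[, setdiff(names(records), character(0))],
                     .saRecords(records[1, ]))
  }
  L <- unique(records$read_len)
  if (length(L) > 1) {
    warning("read ", records$qname[1],
            ": inconsistent implied read lengths across records; skipped")
    return(NULL)
  }
  fwd <- records$strand == "+"
  read_start <- ifelse(fwd, records$clip_left, records$clip_right)
  seg <- data.frame(
    read_id = records$qname,
    chrom = records$chrom,
    read_start = read_start,
    read_end = read_start + records$qwidth,
    ref_start = records$pos0,
    ref_end = records$ref_end,
    strand = records$strand,
    is_primary = records$is_primary,
    stringsAsFactors = FALSE)
  seg <- seg[order(seg$read_start, seg$ref_start), , drop = FALSE]
  dup <- duplicated(seg[, c("chrom", "read_start", "read_end",
                            "ref_start", "ref_end", "strand")])
  seg <- seg[!dup, , drop = FALSE]
  rownames(seg) <- NULL
  seg
}

# expand an SA tag ("rname,pos,strand,CIGAR,mapQ,NM;...") into pseudo-records
.saRecords <- function(primary) {
  parts <- strsplit(primary$sa, ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  if (!length(parts)) return(primary[0, , drop = FALSE])
  fields <- do.call(rbind, strsplit(parts, ",", fixed = TRUE))
  cigar <- fields[, 4]
  ok <- grepl(CIGAR_RE, cigar)
  fields <- fields[ok, , drop = FALSE]; cigar <- cigar[ok]
  if (!nrow(fields)) return(primary[0, , drop = FALSE])
  geo <- .cigarGeometry(cigar)
  data.frame(
    qname = primary$qname, flag = 2048L, chrom = fields[, 1],
    pos0 = as.numeric(fields[, 2]) - 1, mapq = as.integer(fields[, 5]),
    strand = fields[, 3], cigar = cigar,
    ref_end = as.numeric(fields[, 2]) - 1 + geo$ref_width,
    clip_left = geo$clip_left, clip_right = geo$clip_right,
    qwidth = geo$qwidth,
    read_len = geo$clip_left + geo$qwidth + geo$clip_right,
    is_primary = FALSE, sa = NA_character_, stringsAsFactors = FALSE)
}

#' Partition reads into genome blocks
#'
#' Supports block-parallel processing with deterministic output: every read
#' group is owned by exactly one block (the block containing its primary
#' alignment start), while blocks additionally process reads from a padding
#' margin on both sides so signature clusters near a block border are seen
#' whole. Calls are later kept only by the owning block.
#'
#' @param records record table (from \code{\link{readAlignments}}).
#' @param contigs contig table (name, length).
#' @param block_size block length in bp.
#' @param pad margin in bp shared between neighbouring blocks; should exceed
#'   the read length plus twice the largest clustering threshold.
#' @return list of blocks; each is a list(chrom, start, end, own_qnames,
#'   use_qnames).
#' @export
streamBlocks <- function(records, contigs, block_size = 1e7, pad = 5e4) {
  blocks <- list()
  prim <- records[records$is_primary, , drop = FALSE]
  for (i in seq_len(nrow(contigs))) {
    ch <- contigs$name[i]; len <- contigs$length[i]
    starts <- seq(0, max(0, len - 1), by = block_size)
    for (s in starts) {
      e <- min(s + block_size, len)
      p <- prim[prim$chrom == ch, , drop = FALSE]
      own <- unique(p$qname[p$pos0 >= s & p$pos0 < e])
      # a block must see every read group with any alignment in its padded
      # range (a breakend read's primary may sit on the mate chromosome)
      use <- unique(records$qname[records$chrom == ch &
                                    records$pos0 < e + pad &
                                    records$ref_end > s - pad])
      blocks[[length(blocks) + 1]] <-
        list(chrom = ch, start = s, end = e,
             own_qnames = own, use_qnames = use)
    }
  }
  blocks
}
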