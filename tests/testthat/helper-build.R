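# shared constructors for tests: hand-built segments, SAM snippets, SV tables

seg_row <- function(chrom, ref_start, ref_end, read_start, read_end,
                    strand = "+", read_id = "r1", is_primary = TRUE) {
  data.frame(read_id = read_id, chrom = chrom,
             read_start = read_start, read_end = read_end,
             ref_start = ref_start, ref_end = ref_end,
             strand = strand, is_primary = is_primary,
             stringsAsFactors = FALSE)
}

sig_row <- function(sv_type, chrom1, pos1, length = NA_real_,
                    chrom2 = chrom1, pos2 = NA_real_,
                    orientation = NA_character_, read_id = "r1") {
  data.frame(sv_type = sv_type, chrom1 = chrom1, pos1 = pos1,
             chrom2 = chrom2, pos2 = pos2, length = length,
             orientation = orientation, read_id = read_id,
             stringsAsFactors = FALSE)
}

# write a SAM with a simple two-contig header and parse it back; body rows are
# c(qname, flag, rname, pos1based, mapq, cigar) with optional SA tag
write_sam <- function(rows, contigs = c(chr1 = 1e7, chr2 = 1e7),
                      file = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), as.integer(contigs)))
  body <- vapply(rows, function(r) {
    line <- paste(r$qname, r$flag, r$rname, as.integer(r$pos), r$mapq,
                  r$cigar, "*", 0, 0, "*", "*", sep = "\t")
    if (!is.null(r$sa)) line <- paste0(line, "\tSA:Z:", r$sa)
    line
  }, character(1))
  ord <- order(match(vapply(rows, `[[`, "", "rname"), names(contigs)),
               vapply(rows, function(r) as.numeric(r$pos), numeric(1)))
  writeLines(c(hdr, body[ord]), file)
  file
}

read_sam_records <- function(rows, ...) {
  readAlignments(write_sam(rows, ...))$records
}

# raw bi-allelic likelihoods, straight from the closed form (test oracle)
raw_gt_likelihoods <- function(sr_ref, sr_alt, eps = 0.1) {
  c(l00 = (1 / 3) * (1 - eps)^sr_ref * eps^sr_alt,
    l01 = (1 / 3) * 0.5^(sr_ref + sr_alt),
    l11 = (1 / 3) * (1 - eps)^sr_alt * eps^sr_ref)
}

# SV table rows for eval tests (readSVVcf-shaped)
eval_row <- function(chrom, pos, end, size, sv_type, gt = NA_character_,
                     chrom2 = NA_character_, pos2 = NA_real_,
                     orientation = NA_character_) {
  data.frame(chrom = chrom, pos = pos, end = end, svlen = size, size = size,
             sv_type = sv_type, chrom2 = chrom2, pos2 = pos2,
             orientation = orientation, gt = gt, stringsAsFactors = FALSE)
}
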