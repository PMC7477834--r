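SV_TYPES <- c("DEL", "INS", "DUP", "INV", "BND")

.sig_columns <- c("sv_type", "chrom1", "pos1", "chrom2", "pos2",
                  "length", "orientation", "read_id")

.call_columns <- c("chrom", "pos0", "end0", "svlen", "sv_type", "support",
                   "chrom2", "pos2", "orientation", "gt", "dr", "dv",
                   "gl_00", "gl_01", "gl_11", "gq", "qual", "read_names")

#' Empty signature table
#'
#' Returns a zero-row data.frame with the canonical signature columns. All
#' coordinates are 0-based half-open; conversion to 1-based happens only at
#' VCF serialization.
#' @return data.frame with columns sv_type, chrom1, pos1, chrom2, pos2,
#'   length, orientation, read_id.
#' @export
emptySignatures <- function() {
  data.frame(sv_type = character(0), chrom1 = character(0),
             pos1 = numeric(0), chrom2 = character(0), pos2 = numeric(0),
             length = numeric(0), orientation = character(0),
             read_id = character(0), stringsAsFactors = FALSE)
}

.emptyCalls <- function() {
  df <- data.frame(chrom = character(0), pos0 = numeric(0), end0 = numeric(0),
                   svlen = numeric(0), sv_type = character(0),
                   support = integer(0), chrom2 = character(0),
                   pos2 = numeric(0), orientation = character(0),
                   gt = character(0), dr = integer(0), dv = integer(0),
                   gl_00 = numeric(0), gl_01 = numeric(0), gl_11 = numeric(0),
                   gq = numeric(0), qual = numeric(0),
                   read_names = character(0), stringsAsFactors = FALSE)
  df
}

#' SVSignatureSet: per-read SV evidence
#'
#' Container for the SV signatures extracted from one alignment file. Each row
#' of the signature table is one read's evidence for one candidate SV: type,
#' breakpoint coordinate(s), length (for deletions/insertions), junction
#' orientation (inversions/breakends) and the supporting read name.
#'
#' @slot signatures data.frame of signatures (0-based coordinates).
#' @slot source character, path of the alignment file the set came from.
#' @exportClass SVSignatureSet
setClass("SVSignatureSet",
         representation(signatures = "data.frame", source = "character"))

setValidity("SVSignatureSet", function(object) {
  sig <- object@signatures
  if (!all(.sig_columns %in% names(sig)))
    return("signature table lacks canonical columns")
  if (nrow(sig) && !all(sig$sv_type %in% SV_TYPES))
    return("unknown sv_type in signature table")
  bad <- sig$sv_type %in% c("DUP", "INV") & sig$pos1 > sig$pos2
  if (any(bad)) return("DUP/INV signatures must have pos1 <= pos2")
  TRUE
})

#' @describeIn SVSignatureSet-class accessor for the signature table
#' @param x an SVSignatureSet
#' @param ... unused
#' @export
setMethod("signatures", "SVSignatureSet", function(x, ...) x@signatures)

setMethod("show", "SVSignatureSet", function(object) {
  sig <- object@signatures
  cat("SVSignatureSet with", nrow(sig), "signatures from",
      length(unique(sig$read_id)), "reads\n")
  if (nrow(sig)) {
    print(table(factor(sig$sv_type, levels = SV_TYPES)))
  }
  invisible(NULL)
})

#' SVCallSet: genotyped structural variant calls
#'
#' Result container of \code{\link{callSVs}}. Holds one row per called SV
#' allele with breakpoints (0-based), signed length, supporting read count,
#' genotype and likelihood-derived qualities, plus the contig table used for
#' VCF header generation.
#'
#' @slot calls data.frame of calls.
#' @slot contigs data.frame with columns name, length.
#' @slot sample character scalar, sample name for the VCF column.
#' @slot genotyped logical, whether the genotyping stage was run.
#' @exportClass SVCallSet
setClass("SVCallSet",
         representation(calls = "data.frame", contigs = "data.frame",
                        sample = "character", genotyped = "logical"))

setValidity("SVCallSet", function(object) {
  calls <- object@calls
  if (!all(.call_columns %in% names(calls)))
    return("call table lacks canonical columns")
  if (nrow(calls)) {
    if (!all(calls$sv_type %in% SV_TYPES)) return("unknown sv_type")
    if (any(calls$pos0 < 0)) return("negative call position")
  }
  TRUE
})

#' @describeIn SVCallSet-class accessor for the call table
#' @param x an SVCallSet
#' @param ... unused
#' @export
setMethod("svCalls", "SVCallSet", function(x, ...) x@calls)

#' @describeIn SVCallSet-class sample name used in the VCF
#' @export
setMethod("sampleName", "SVCallSet", function(x) x@sample)

#' @describeIn SVCallSet-class contig table (name, length)
#' @export
setMethod("contigTable", "SVCallSet", function(x) x@contigs)

#' @describeIn SVCallSet-class number of calls
#' @export
setMethod("length", "SVCallSet", function(x) nrow(x@calls))

setMethod("show", "SVCallSet", function(object) {
  calls <- object@calls
  cat("SVCallSet:", nrow(calls), "calls, sample", object@sample,
      if (object@genotyped) "(genotyped)" else "(ungenotyped)", "\n")
  if (nrow(calls)) {
    print(table(factor(calls$sv_type, levels = SV_TYPES)))
  }
  invisible(NULL)
})

.newSVCallSet <- function(calls, contigs, sample = "SAMPLE",
                          genotyped = FALSE) {
  if (is.null(calls) || !nrow(calls)) calls <- .emptyCalls()
  new("SVCallSet", calls = calls, contigs = contigs, sample = sample,
      genotyped = genotyped)
}

#' FixtureSpec: study conditions for the synthetic-alignment generator
#'
#' Describes a toy diploid genome: contig lengths, a table of implanted SVs
#' with zygosities, sequencing depth and read length, and how faithfully the
#' emulated aligner represents large indels (clean single records vs
#' fragmented CIGAR runs).
#'
#' @slot refLengths named numeric, contig lengths in bp.
#' @slot svTable data.frame of implants: type, chrom, pos, len, chrom2, pos2,
#'   zygosity (hom/het1/het2).
#' @slot coverage numeric fold coverage.
#' @slot readLength numeric mean read length in bp.
#' @slot fragmentation "clean" or "fragmented".
#' @slot hapMode "alternate" (deterministic 50/50 per locus) or "random".
#' @slot jitterPos numeric, +/- bp breakpoint jitter per read.
#' @slot jitterLen numeric, fractional indel-size jitter per read.
#' @slot seed integer RNG seed.
#' @slot reads optional explicit read layout (data.frame chrom,start,length,hap)
#'   overriding coverage-based sampling.
#' @exportClass FixtureSpec
setClass("FixtureSpec",
         representation(refLengths = "numeric", svTable = "data.frame",
                        coverage = "numeric", readLength = "numeric",
                        fragmentation = "character", hapMode = "character",
                        jitterPos = "numeric", jitterLen = "numeric",
                        seed = "integer", reads = "ANY"))

setValidity("FixtureSpec", function(object) {
  if (is.null(names(object@refLengths)) || any(object@refLengths < 1))
    return("refLengths must be a named vector of positive lengths")
  if (object@coverage < 1) return("coverage must be >= 1")
  if (!object@fragmentation %in% c("clean", "fragmented"))
    return("fragmentation must be 'clean' or 'fragmented'")
  if (!object@hapMode %in% c("alternate", "random"))
    return("hapMode must be 'alternate' or 'random'")
  sv <- object@svTable
  if (nrow(sv)) {
    if (!all(sv$type %in% SV_TYPES)) return("unknown implant type")
    if (!all(sv$zygosity %in% c("hom", "het1", "het2")))
      return("zygosity must be hom/het1/het2")
    if (!all(sv$chrom %in% names(object@refLengths)))
      return("implant chrom not in refLengths")
    # implants on one haplotype must not overlap; shared loci are only
    # allowed as het1/het2 pairs (multi-allelic sites)
    for (hap in 1:2) {
      zy <- if (hap == 1) c("hom", "het1") else c("hom", "het2")
      svh <- sv[sv$zygosity %in% zy, , drop = FALSE]
      for (ch in unique(svh$chrom)) {
        s <- svh[svh$chrom == ch, , drop = FALSE]
        s <- s[order(s$pos), , drop = FALSE]
        if (nrow(s) > 1) {
          span_end <- s$pos + ifelse(s$type %in% c("DEL", "DUP", "INV"),
                                     s$len, 0)
          if (any(s$pos[-1] < span_end[-nrow(s)]))
            return("implants overlap on one haplotype")
        }
      }
    }
  }
  TRUE
})

setMethod("show", "FixtureSpec", function(object) {
  cat("FixtureSpec:", length(object@refLengths), "contigs (",
      sum(object@refLengths), "bp ),", nrow(object@svTable), "implants,",
      object@coverage, "x coverage,", object@fragmentation, "alignments\n")
  invisible(NULL)
})
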