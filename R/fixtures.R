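#' Construct a FixtureSpec
#'
#' @param refLengths named numeric vector of contig lengths.
#' @param svTable implant table: type, chrom, pos, len, chrom2, pos2,
#'   zygosity ("hom", "het" = "het1", or "het2"). Positions 0-based.
#' @param coverage fold coverage (default 20).
#' @param readLength mean read length (default 10000).
#' @param fragmentation "clean" or "fragmented".
#' @param hapMode "alternate" (reads alternate haplotypes in position order,
#'   realizing exact half coverage per haplotype at every locus) or "random".
#' @param jitterPos,jitterLen optional per-read breakpoint (bp) and size
#'   (fraction) jitter to exercise clustering tolerance.
#' @param seed RNG seed.
#' @param reads optional explicit read layout (data.frame chrom, start,
#'   length, hap) overriding coverage-based sampling.
#' @return a \code{\linkS4class{FixtureSpec}}.
#' @export
fixtureSpec <- function(refLengths, svTable = NULL, coverage = 20,
                        readLength = 10000,
                        fragmentation = c("clean", "fragmented"),
                        hapMode = c("alternate", "random"),
                        jitterPos = 0, jitterLen = 0, seed = 1L,
                        reads = NULL) {
  fragmentation <- match.arg(fragmentation)
  hapMode <- match.arg(hapMode)
  if (is.null(svTable) || !nrow(svTable)) {
    svTable <- data.frame(type = character(0), chrom = character(0),
                          pos = numeric(0), len = numeric(0),
                          chrom2 = character(0), pos2 = numeric(0),
                          zygosity = character(0), stringsAsFactors = FALSE)
  } else {
    if (is.null(svTable$chrom2)) svTable$chrom2 <- NA_character_
    if (is.null(svTable$pos2)) svTable$pos2 <- NA_real_
    svTable$zygosity[svTable$zygosity == "het"] <- "het1"
  }
  new("FixtureSpec", refLengths = refLengths, svTable = svTable,
      coverage = coverage, readLength = readLength,
      fragmentation = fragmentation, hapMode = hapMode,
      jitterPos = jitterPos, jitterLen = jitterLen,
      seed = as.integer(seed), reads = reads)
}

#' Random non-overlapping implant table
#'
#' Places SVs on a regular grid of candidate loci (keeping a safety margin
#' from contig ends and a spacing larger than any read, so every read crosses
#' at most one implant), with sizes drawn from type-typical ranges and
#' zygosities alternating hom/het. Breakends pair loci on different contigs.
#'
#' @param counts named vector, number of implants per type.
#' @param refLengths named contig lengths.
#' @param seed RNG seed.
#' @param spacing candidate-locus spacing in bp (default 25000).
#' @param edge_margin bp kept free at contig ends (default 30000).
#' @param size_ranges list of c(min, max) per type.
#' @return implant data.frame usable as \code{svTable}.
#' @export
randomSVTable <- function(counts = c(DEL = 60, INS = 60, DUP = 30, INV = 30,
                                     BND = 20),
                          refLengths, seed = 1L, spacing = 25000,
                          edge_margin = 30000,
                          size_ranges = list(DEL = c(50, 2000),
                                             INS = c(50, 900),
                                             DUP = c(100, 450),
                                             INV = c(300, 5000))) {
  set.seed(seed)
  slots <- do.call(rbind, lapply(names(refLengths), function(ch) {
    p <- seq(edge_margin, refLengths[[ch]] - edge_margin, by = spacing)
    data.frame(chrom = ch, pos = p, stringsAsFactors = FALSE)
  }))
  need <- sum(counts) + if ("BND" %in% names(counts)) counts[["BND"]] else 0
  if (nrow(slots) < need)
    stop("reference too small for the requested implant count")
  slots <- slots[sample(nrow(slots)), , drop = FALSE]
  out <- list(); k <- 0
  for (ty in names(counts)) {
    n <- counts[[ty]]
    if (n == 0) next
    zyg <- rep(c("hom", "het1"), length.out = n)
    if (ty == "BND") {
      for (i in seq_len(n)) {
        a <- slots[k + 1, ]; b <- slots[k + 2, ]; k <- k + 2
        # mate pair must live on two different contigs
        tries <- 0
        while (a$chrom == b$chrom && k < nrow(slots) && tries < 50) {
          b <- slots[k + 1, ]; k <- k + 1; tries <- tries + 1
        }
        first <- if (a$chrom <= b$chrom) a else b
        second <- if (a$chrom <= b$chrom) b else a
        out[[length(out) + 1]] <- data.frame(
          type = "BND", chrom = first$chrom, pos = first$pos, len = NA_real_,
          chrom2 = second$chrom, pos2 = second$pos, zygosity = zyg[i],
          stringsAsFactors = FALSE)
      }
    } else {
      r <- size_ranges[[ty]]
      for (i in seq_len(n)) {
        k <- k + 1
        out[[length(out) + 1]] <- data.frame(
          type = ty, chrom = slots$chrom[k], pos = slots$pos[k],
          len = round(runif(1, r[1], r[2])), chrom2 = NA_character_,
          pos2 = NA_real_, zygosity = zyg[i], stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write the fixture reference genome
#'
#' Deterministic uniform-random nucleotide sequence per contig; the same seed
#' yields byte-identical FASTA output.
#'
#' @param spec a FixtureSpec.
#' @param file output FASTA path.
#' @return invisibly the path.
#' @export
buildReference <- function(spec, file) {
  stopifnot(all(spec@refLengths >= 1))
  set.seed(spec@seed)
  seqs <- Biostrings::DNAStringSet(vapply(names(spec@refLengths), function(ch) {
    paste(sample(c("A", "C", "G", "T"), spec@refLengths[[ch]],
                 replace = TRUE), collapse = "")
  }, character(1)))
  names(seqs) <- names(spec@refLengths)
  Biostrings::writeXStringSet(seqs, file)
  invisible(file)
}

# sample the read layout (or take the explicit one from the spec)
.fixtureReads <- function(spec) {
  if (!is.null(spec@reads)) {
    rd <- spec@reads
    rd <- rd[order(match(rd$chrom, names(spec@refLengths)), rd$start), ,
             drop = FALSE]
    rd$name <- sprintf("r%s_%05d", rd$chrom, seq_len(nrow(rd)))
    return(rd)
  }
  rl <- spec@readLength
  out <- list()
  for (ch in names(spec@refLengths)) {
    len <- spec@refLengths[[ch]]
    n <- max(1L, round(spec@coverage * len / rl))
    start <- floor(runif(n, 0, max(1, len - rl / 2)))
    rlen <- round(pmin(pmax(rnorm(n, rl, rl * 0.08), rl * 0.5), rl * 1.4))
    rlen <- pmin(rlen, len - start)
    rd <- data.frame(chrom = ch, start = start, length = rlen,
                     stringsAsFactors = FALSE)
    rd <- rd[order(rd$start), , drop = FALSE]
    rd$hap <- if (spec@hapMode == "alternate") {
      rep(c(1L, 2L), length.out = n)
    } else {
      sample(1:2, n, replace = TRUE)
    }
    rd$name <- sprintf("r%s_%05d", ch, seq_len(n))
    out[[length(out) + 1]] <- rd
  }
  do.call(rbind, out)
}

# one aligned piece of a read: read-interval [rs, re) on the original read,
# mapped to refpos on chrom with strand; body is the CIGAR between the clips
.piece <- function(rs, re, chrom, refpos, strand, body = NULL) {
  list(rs = rs, re = re, chrom = chrom, refpos = refpos, strand = strand,
       body = if (is.null(body)) paste0(re - rs, "M") else body)
}

# CIGAR of a piece within a read of total length L (soft clips; SAM strand
# orientation flips the clips for reverse records)
.pieceCigar <- function(p, L) {
  c1 <- if (p$strand == "+") p$rs else L - p$re
  c2 <- if (p$strand == "+") L - p$re else p$rs
  paste0(if (c1 > 0) paste0(c1, "S"), p$body, if (c2 > 0) paste0(c2, "S"))
}

# records emulating the aligner's representation of one read (list of pieces)
.emitRead <- function(read, sv, spec, margin = 200, split_threshold = 1000) {
  s <- read$start; L <- read$length; ch <- read$chrom
  plain <- list(.piece(0, L, ch, s, "+"))
  if (is.null(sv)) return(plain)
  frag <- spec@fragmentation == "fragmented"
  jp <- if (spec@jitterPos > 0)
    round(runif(1, -spec@jitterPos, spec@jitterPos)) else 0
  jl <- if (spec@jitterLen > 0) 1 + runif(1, -spec@jitterLen, spec@jitterLen)
    else 1
  type <- sv$type
  if (type == "DEL") {
    p <- sv$pos + jp; d <- max(30, round(sv$len * jl))
    if (s >= p) s <- s + d          # read drawn beyond the deleted interval
    b1 <- p - s
    if (b1 <= 0 || b1 >= L) return(list(.piece(0, L, ch, s, "+")))
    b2 <- L - b1
    if (b1 < margin) return(list(.piece(b1, L, ch, p + d, "+")))
    if (b2 < margin) return(list(.piece(0, b1, ch, s, "+")))
    if (d > split_threshold) {
      return(list(.piece(0, b1, ch, s, "+"),
                  .piece(b1, L, ch, p + d, "+")))
    }
    body <- if (frag && d >= 60 && b2 > margin) {
      d1 <- floor(d * 0.55); d2 <- d - d1
      paste0(b1, "M", d1, "D", 10, "M", d2, "D", b2 - 10, "M")
    } else {
      paste0(b1, "M", d, "D", b2, "M")
    }
    return(list(.piece(0, L, ch, s, "+", body)))
  }
  if (type == "INS") {
    p <- sv$pos + jp; i <- max(30, round(sv$len * jl))
    b1 <- p - s
    if (b1 <= 0 || b1 >= L) return(plain)
    b2 <- L - b1 - i
    if (b1 < margin) {
      if (b2 < margin) return(list())   # read swallowed by the insertion
      return(list(.piece(b1 + i, L, ch, p, "+")))
    }
    if (b2 < margin) return(list(.piece(0, b1, ch, s, "+")))
    if (i > split_threshold) {
      return(list(.piece(0, b1, ch, s, "+"),
                  .piece(b1 + i, L, ch, p, "+")))
    }
    body <- if (frag && i >= 60 && b2 > margin + 10) {
      i1 <- floor(i * 0.55); i2 <- i - i1
      paste0(b1, "M", i1, "I", 10, "M", i2, "I", b2 - 10, "M")
    } else {
      paste0(b1, "M", i, "I", b2, "M")
    }
    return(list(.piece(0, L, ch, s, "+", body)))
  }
  if (type == "DUP") {
    p1 <- sv$pos; p2 <- sv$pos + sv$len   # junction: copy1 end -> copy2 start
    b1 <- p2 - s
    if (b1 <= 0 || b1 >= L) return(plain)
    b2 <- L - b1
    if (b1 < margin) return(list(.piece(b1, L, ch, p1, "+")))
    if (b2 < margin) return(list(.piece(0, b1, ch, s, "+")))
    return(list(.piece(0, b1, ch, s, "+"),
                .piece(b1, L, ch, p1, "+")))
  }
  if (type == "INV") {
    p1 <- sv$pos; p2 <- sv$pos + sv$len
    if (s < p1) {                       # enters through the left junction
      b1 <- p1 - s
      if (b1 >= L) return(plain)
      if (s + L <= p2) {                # ends inside the inversion
        b2 <- L - b1
        if (b1 < margin) return(list(.piece(b1, L, ch, p2 - b2, "-")))
        if (b2 < margin) return(list(.piece(0, b1, ch, s, "+")))
        return(list(.piece(0, b1, ch, s, "+"),
                    .piece(b1, L, ch, p2 - b2, "-")))
      }
      binv <- p2 - p1; b3 <- L - b1 - binv   # spans the whole inversion
      pieces <- list()
      if (b1 >= margin) pieces <- c(pieces, list(.piece(0, b1, ch, s, "+")))
      pieces <- c(pieces, list(.piece(b1, b1 + binv, ch, p1, "-")))
      if (b3 >= margin)
        pieces <- c(pieces, list(.piece(b1 + binv, L, ch, p2, "+")))
      return(pieces)
    }
    if (s < p2) {                       # starts inside, exits to the right
      b1 <- p2 - s
      if (b1 >= L) {                    # fully inside: maps reversed, intact
        return(list(.piece(0, L, ch, p1 + (p2 - s - L), "-")))
      }
      b2 <- L - b1
      if (b1 < margin) return(list(.piece(b1, L, ch, p2, "+")))
      if (b2 < margin) return(list(.piece(0, b1, ch, p1, "-")))
      return(list(.piece(0, b1, ch, p1, "-"),
                  .piece(b1, L, ch, p2, "+")))
    }
    return(plain)
  }
  if (type == "BND") {
    p1 <- sv$pos; p2 <- sv$pos2; ch2 <- sv$chrom2
    b1 <- p1 - s
    if (b1 <= 0 || b1 >= L) return(plain)
    b2 <- L - b1
    if (b1 < margin) return(list(.piece(b1, L, ch2, p2, "+")))
    if (b2 < margin) return(list(.piece(0, b1, ch, s, "+")))
    return(list(.piece(0, b1, ch, s, "+"),
                .piece(b1, L, ch2, p2, "+")))
  }
  plain
}

#' Emit fixture alignments as sorted SAM
#'
#' Simulates the alignment-level footprint of reads over the implant table:
#' deletions/insertions below the split threshold appear as D/I CIGAR
#' operations (optionally fragmented into sub-threshold-spaced pieces), large
#' indels and all duplication/inversion/breakend implants appear as primary +
#' supplementary record pairs with consistent SA tags and the canonical
#' split geometry of each type. Heterozygous implants are carried only by
#' reads of their haplotype. Reads overlapping a breakpoint with too little
#' anchor on one side are soft-clipped at the breakpoint, as an aligner
#' would. Base sequences are not modelled (SEQ "*").
#'
#' @param spec a FixtureSpec.
#' @param file output SAM path.
#' @param margin minimum anchor length in bp for a breakpoint-crossing
#'   alignment piece (default 200).
#' @param split_threshold indel size above which a split representation is
#'   used instead of a CIGAR operation (default 1000).
#' @return invisibly the path.
#' @export
emitAlignments <- function(spec, file, margin = 200, split_threshold = 1000) {
  set.seed(spec@seed + 1L)
  reads <- .fixtureReads(spec)
  sv <- spec@svTable
  lines <- character(0)
  rec <- list()
  for (i in seq_len(nrow(reads))) {
    rd <- reads[i, ]
    hap <- rd$hap
    zy_ok <- c("hom", if (hap == 1) "het1" else "het2")
    this_sv <- NULL
    if (nrow(sv)) {
      cand <- sv[sv$chrom == rd$chrom & sv$zygosity %in% zy_ok, ,
                 drop = FALSE]
      if (nrow(cand)) {
        bp2 <- ifelse(cand$type %in% c("DUP", "INV"),
                      cand$pos + cand$len, cand$pos)
        hit <- (cand$pos > rd$start & cand$pos < rd$start + rd$length) |
          (bp2 > rd$start & bp2 < rd$start + rd$length)
        if (any(hit)) this_sv <- cand[which(hit)[1], ]
      }
    }
    pieces <- .emitRead(rd, this_sv, spec,
                        margin = margin, split_threshold = split_threshold)
    if (!length(pieces)) next
    alen <- vapply(pieces, function(p) p$re - p$rs, numeric(1))
    primary <- which.max(alen)
    L <- rd$length
    for (k in seq_along(pieces)) {
      p <- pieces[[k]]
      flag <- 0L
      if (p$strand == "-") flag <- flag + 16L
      if (k != primary) flag <- flag + 2048L
      sa <- ""
      if (length(pieces) > 1) {
        others <- setdiff(seq_along(pieces), k)
        sa <- paste0("\tSA:Z:", paste(vapply(others, function(j) {
          q <- pieces[[j]]
          paste(q$chrom, as.integer(q$refpos + 1),
                q$strand, .pieceCigar(q, L), 60, 0, sep = ",")
        }, character(1)), collapse = ";"), ";")
      }
      rec[[length(rec) + 1]] <- data.frame(
        qname = rd$name, flag = flag, chrom = p$chrom,
        pos1 = as.integer(p$refpos + 1),
        cigar = .pieceCigar(p, L), sa = sa, stringsAsFactors = FALSE)
    }
  }
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(spec@refLengths),
                   as.integer(spec@refLengths)))
  if (length(rec)) {
    recs <- do.call(rbind, rec)
    recs <- recs[order(match(recs$chrom, names(spec@refLengths)),
                       recs$pos1, recs$qname, recs$flag), , drop = FALSE]
    body <- paste0(recs$qname, "\t", recs$flag, "\t", recs$chrom, "\t",
                   recs$pos1, "\t60\t", recs$cigar, "\t*\t0\t0\t*\t*",
                   recs$sa)
    writeLines(c(hdr, body), file)
  } else {
    writeLines(hdr, file)
  }
  invisible(file)
}

#' Write the fixture ground-truth VCF
#'
#' One record per implant with the zygosity as genotype (hom 1/1,
#' heterozygous 0/1); byte-stable for a given spec.
#'
#' @param spec a FixtureSpec.
#' @param file output VCF path.
#' @return invisibly the path.
#' @export
truthTable <- function(spec, file) {
  sv <- spec@svTable
  contigs <- data.frame(name = names(spec@refLengths),
                        length = unname(spec@refLengths),
                        stringsAsFactors = FALSE)
  if (!nrow(sv)) {
    cs <- .newSVCallSet(NULL, contigs, sample = "TRUTH", genotyped = TRUE)
    return(invisible(writeSVVcf(cs, file)))
  }
  calls <- data.frame(
    chrom = sv$chrom, pos0 = sv$pos,
    end0 = ifelse(sv$type %in% c("DEL", "DUP", "INV"), sv$pos + sv$len,
                  sv$pos),
    svlen = ifelse(sv$type == "DEL", -sv$len, sv$len),
    sv_type = sv$type, support = 0L,
    chrom2 = ifelse(is.na(sv$chrom2), sv$chrom, sv$chrom2),
    pos2 = sv$pos2,
    orientation = ifelse(sv$type == "BND", "++", NA_character_),
    gt = ifelse(sv$zygosity == "hom", "1/1", "0/1"),
    dr = NA_integer_, dv = NA_integer_,
    gl_00 = NA_real_, gl_01 = NA_real_, gl_11 = NA_real_,
    gq = NA_real_, qual = NA_real_,
    read_names = "", stringsAsFactors = FALSE)
  cs <- .newSVCallSet(calls, contigs, sample = "TRUTH", genotyped = TRUE)
  invisible(writeSVVcf(cs, file))
}

#' Materialize a fixture on disk
#'
#' Writes the reference FASTA, the sorted SAM alignments, the truth VCF and a
#' JSON echo of the spec into a directory.
#'
#' @param spec a FixtureSpec.
#' @param dir output directory (created if missing).
#' @return named list of file paths.
#' @export
simulateFixture <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(fasta = file.path(dir, "ref.fa"),
                sam = file.path(dir, "alignments.sam"),
                truth = file.path(dir, "truth.vcf"),
                spec = file.path(dir, "spec.json"))
  buildReference(spec, paths$fasta)
  emitAlignments(spec, paths$sam)
  truthTable(spec, paths$truth)
  echo <- list(refLengths = as.list(spec@refLengths),
               coverage = spec@coverage, readLength = spec@readLength,
               fragmentation = spec@fragmentation, hapMode = spec@hapMode,
               seed = spec@seed, svTable = spec@svTable)
  jsonlite::write_json(echo, paths$spec, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
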