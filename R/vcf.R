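# breakend ALT bracket notation: the first strand decides whether the local
# breakend extends right (t...) or left (...t) of POS, the second whether the
# mate contributes its end (]p]) or start ([p[)
.bndAlt <- function(chrom2, pos2_1based, orientation) {
  m <- paste0(chrom2, ":", pos2_1based)
  switch(orientation,
         "++" = paste0("N]", m, "]"),
         "+-" = paste0("N[", m, "["),
         "-+" = paste0("]", m, "]N"),
         "--" = paste0("[", m, "[N"),
         paste0("N]", m, "]"))
}

.parseBndAlt <- function(alt) {
  m <- regmatches(alt, regexec("([\\]\\[])([^\\]\\[:]+):([0-9]+)([\\]\\[])",
                               alt, perl = TRUE))[[1]]
  if (length(m) < 5) return(NULL)
  chrom2 <- m[3]; pos2 <- as.numeric(m[4])
  leading_n <- grepl("^[A-Za-z.]", alt)
  bracket <- m[2]
  s1 <- if (leading_n) "+" else "-"
  s2 <- if (bracket == "]") "+" else "-"
  list(chrom2 = chrom2, pos2 = pos2, orientation = paste0(s1, s2))
}

#' Write an SVCallSet as VCF 4.2
#'
#' Serializes calls to a VCF with symbolic ALT alleles (<DEL>, <INS>, <DUP>,
#' <INV>) and bracketed breakend notation for BND records. INFO carries
#' SVTYPE, SVLEN, END, RE (supporting reads), CHR2 for breakends and
#' optionally RNAMES; the per-sample FORMAT is GT:DR:DV:GQ:PL. Positions are
#' converted from the internal 0-based convention to 1-based here, at the
#' single serialization point. Calls are sorted by (contig order, position)
#' before writing.
#'
#' @param x an \code{\linkS4class{SVCallSet}}.
#' @param file output path.
#' @param rnames logical, include supporting read names in INFO.
#' @return invisibly, the file path.
#' @export
writeSVVcf <- function(x, file, rnames = FALSE) {
  stopifnot(is(x, "SVCallSet"))
  calls <- x@calls
  contigs <- x@contigs
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=svsigcall",
    sprintf("##contig=<ID=%s,length=%d>", contigs$name,
            as.integer(contigs$length)),
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=INS,Description=\"Insertion\">",
    "##ALT=<ID=DUP,Description=\"Duplication\">",
    "##ALT=<ID=INV,Description=\"Inversion\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Signed length of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of structural variant\">",
    "##INFO=<ID=RE,Number=1,Type=Integer,Description=\"Number of supporting reads\">",
    "##INFO=<ID=CHR2,Number=1,Type=String,Description=\"Mate chromosome of a breakend\">",
    if (rnames) "##INFO=<ID=RNAMES,Number=.,Type=String,Description=\"Supporting read names\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DR,Number=1,Type=Integer,Description=\"Reads supporting the reference allele\">",
    "##FORMAT=<ID=DV,Number=1,Type=Integer,Description=\"Reads supporting the variant allele\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Conditional genotype quality\">",
    "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"Phred-scaled genotype likelihoods\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", x@sample, sep = "\t"))
  hdr <- hdr[!vapply(hdr, is.null, logical(1))]
  if (!nrow(calls)) {
    writeLines(hdr, file)
    return(invisible(file))
  }
  ord <- order(match(calls$chrom, contigs$name), calls$pos0, calls$sv_type,
               calls$svlen)
  calls <- calls[ord, , drop = FALSE]
  pos1 <- as.integer(calls$pos0) + 1L
  alt <- character(nrow(calls))
  info <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    if (calls$sv_type[i] == "BND") {
      alt[i] <- .bndAlt(calls$chrom2[i], as.integer(calls$pos2[i]) + 1L,
                        calls$orientation[i])
      info[i] <- sprintf("SVTYPE=BND;CHR2=%s;RE=%d", calls$chrom2[i],
                         as.integer(calls$support[i]))
    } else {
      alt[i] <- paste0("<", calls$sv_type[i], ">")
      info[i] <- sprintf("SVTYPE=%s;SVLEN=%d;END=%d;RE=%d",
                         calls$sv_type[i], as.integer(calls$svlen[i]),
                         as.integer(calls$end0[i]) + 1L,
                         as.integer(calls$support[i]))
    }
    if (rnames) info[i] <- paste0(info[i], ";RNAMES=", calls$read_names[i])
  }
  pl <- rep(".", nrow(calls))
  has_gl <- !is.na(calls$gl_00)
  if (any(has_gl)) {
    glm <- as.matrix(calls[, c("gl_00", "gl_01", "gl_11")])
    plm <- round(-10 * (glm - apply(glm, 1, max)))
    pl[has_gl] <- paste(plm[has_gl, 1], plm[has_gl, 2], plm[has_gl, 3],
                        sep = ",")
  }
  fmt <- paste(
    calls$gt,
    ifelse(is.na(calls$dr), ".", calls$dr),
    ifelse(is.na(calls$dv), ".", calls$dv),
    ifelse(is.na(calls$gq), ".", calls$gq),
    pl, sep = ":")
  qual <- ifelse(is.na(calls$qual), ".", format(calls$qual, trim = TRUE))
  lines <- paste(calls$chrom, pos1,
                 sprintf("svsigcall.%s.%d", calls$sv_type,
                         seq_len(nrow(calls))),
                 "N", alt, qual, "PASS", info, "GT:DR:DV:GQ:PL", fmt,
                 sep = "\t")
  writeLines(c(hdr, lines), file)
  invisible(file)
}

.info1 <- function(info, key) {
  m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
         character(1))
}

#' Read structural variant records from a VCF
#'
#' Parses a VCF (as produced by \code{\link{writeSVVcf}}, a truth-set writer,
#' or any caller emitting SVTYPE/SVLEN/END INFO keys and bracketed breakends)
#' into a flat table for benchmarking. Coordinates stay 1-based as in the
#' file.
#'
#' @param file VCF path.
#' @return data.frame (chrom, pos, end, svlen, size, sv_type, chrom2, pos2,
#'   orientation, gt). \code{size} is the absolute SV length with the
#'   insertion convention end = pos + size applied for the \code{end} column.
#' @export
readSVVcf <- function(file) {
  empty <- data.frame(chrom = character(0), pos = numeric(0),
                      end = numeric(0), svlen = numeric(0), size = numeric(0),
                      sv_type = character(0), chrom2 = character(0),
                      pos2 = numeric(0), orientation = character(0),
                      gt = character(0), stringsAsFactors = FALSE)
  n_records <- tryCatch(
    sum(!startsWith(readLines(file), "#")),
    error = function(e) 0)
  if (n_records == 0) return(empty)
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(nrow(fix))) fix <- matrix(fix, nrow = 1,
                                        dimnames = list(NULL, names(fix)))
  info <- fix[, "INFO"]
  type <- .info1(info, "SVTYPE")
  svlen <- suppressWarnings(as.numeric(.info1(info, "SVLEN")))
  end <- suppressWarnings(as.numeric(.info1(info, "END")))
  pos <- as.numeric(fix[, "POS"])
  alt <- fix[, "ALT"]
  chrom2 <- .info1(info, "CHR2")
  pos2 <- rep(NA_real_, length(pos))
  orientation <- rep(NA_character_, length(pos))
  for (i in which(type == "BND")) {
    b <- .parseBndAlt(alt[i])
    if (!is.null(b)) {
      if (is.na(chrom2[i])) chrom2[i] <- b$chrom2
      pos2[i] <- b$pos2
      orientation[i] <- b$orientation
    }
  }
  size <- abs(svlen)
  size[is.na(size) & !is.na(end)] <-
    (end - pos)[is.na(size) & !is.na(end)]
  end_out <- ifelse(!is.na(type) & type == "INS", pos + size, end)
  end_out[is.na(end_out)] <- (pos + ifelse(is.na(size), 0, size))[is.na(end_out)]
  gt <- rep(NA_character_, length(pos))
  if (!is.null(v@gt) && ncol(v@gt) >= 2) {
    raw <- v@gt[, 2]
    fmt <- v@gt[, 1]
    gt <- vapply(seq_along(raw), function(i) {
      keys <- strsplit(fmt[i], ":", fixed = TRUE)[[1]]
      vals <- strsplit(raw[i], ":", fixed = TRUE)[[1]]
      k <- match("GT", keys)
      if (is.na(k) || k > length(vals)) NA_character_ else vals[k]
    }, character(1))
  }
  data.frame(chrom = fix[, "CHROM"], pos = pos, end = end_out, svlen = svlen,
             size = size, sv_type = type, chrom2 = chrom2, pos2 = pos2,
             orientation = orientation, gt = gt, stringsAsFactors = FALSE)
}
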