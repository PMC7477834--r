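test_that("fragmented CIGAR indels merge by the distance rule", {
  del <- data.frame(chrom = "chr1", ref_start = c(100, 160),
                    length = c(50, 40), kind = "DEL", read_id = "r1",
                    stringsAsFactors = FALSE)
  m <- mergeCigarSignatures(del, sig_dis = 200)   # gap 160-150 = 10 <= 200
  expect_equal(nrow(m), 1)
  expect_equal(m$ref_start, 100)
  expect_equal(m$length, 90)

  ins <- data.frame(chrom = "chr1", ref_start = c(100, 400),
                    length = c(50, 40), kind = "INS", read_id = "r1",
                    stringsAsFactors = FALSE)
  m <- mergeCigarSignatures(ins, sig_dis = 200)   # 400-100 = 300 > 200
  expect_equal(nrow(m), 2)

  one <- ins[1, ]
  expect_equal(mergeCigarSignatures(one, 200), one)
})

test_that("merging conserves total indel length per read and kind", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(1:8, 1)
    kind <- sample(c("DEL", "INS"), 1)
    sigs <- data.frame(chrom = "chr1",
                       ref_start = sort(sample(1:5000, n)),
                       length = sample(30:300, n, replace = TRUE),
                       kind = kind, read_id = "r1", stringsAsFactors = FALSE)
    m <- mergeCigarSignatures(sigs, sig_dis = sample(c(0, 100, 500, 1e5), 1))
    expect_equal(sum(m$length), sum(sigs$length))
  }
})

test_that("segment-pair geometry classifies deletions, insertions, duplications", {
  s1 <- seg_row("chr1", 5000, 6000, 0, 1000)
  del <- classifySegmentPair(s1, seg_row("chr1", 6500, 7500, 1010, 2010))
  expect_equal(del$sv_type, "DEL")        # diff_dis = 500 - 10 = 490
  expect_equal(del$pos1, 6000)
  expect_equal(del$length, 490)

  ins <- classifySegmentPair(s1, seg_row("chr1", 6010, 7010, 1510, 2510))
  expect_equal(ins$sv_type, "INS")        # diff_dis = 10 - 510 = -500
  expect_equal(ins$pos1, 6005)            # floor((6000 + 6010)/2)
  expect_equal(ins$length, 500)

  dup <- classifySegmentPair(s1, seg_row("chr1", 5900, 6800, 1010, 1910))
  expect_equal(dup$sv_type, "DUP")        # diff_olp = 100 >= 30
  expect_equal(dup$pos1, 5900)
  expect_equal(dup$pos2, 6000)

  none <- classifySegmentPair(s1, seg_row("chr1", 6010, 7010, 1010, 2010))
  expect_null(none)                       # diff_dis = 0, diff_olp = -10
})

test_that("opposite strands give inversion junction signatures", {
  inv <- classifySegmentPair(seg_row("chr1", 5000, 6000, 0, 1000, "+"),
                             seg_row("chr1", 6400, 6950, 1010, 1560, "-"))
  expect_equal(inv$sv_type, "INV")
  expect_equal(inv$orientation, "INV_hh")
  expect_equal(c(inv$pos1, inv$pos2), c(6000, 6950))

  inv <- classifySegmentPair(seg_row("chr1", 5000, 6000, 0, 1000, "-"),
                             seg_row("chr1", 6400, 6950, 1010, 1560, "+"))
  expect_equal(inv$orientation, "INV_tt")
  expect_equal(c(inv$pos1, inv$pos2), c(5000, 6400))
})

test_that("cross-chromosome pairs give canonically ordered breakends", {
  bnd <- classifySegmentPair(seg_row("chr1", 999000, 1000000, 0, 1000, "+"),
                             seg_row("chr2", 2000000, 2001000, 1020, 2020, "+"))
  expect_equal(bnd$sv_type, "BND")
  expect_equal(bnd$chrom1, "chr1")
  expect_equal(bnd$pos1, 1000000)
  expect_equal(bnd$chrom2, "chr2")
  expect_equal(bnd$pos2, 2000000)
  expect_equal(bnd$orientation, "++")

  # alphabetically larger chromosome first on the read: sides swap
  bnd <- classifySegmentPair(seg_row("chr2", 2000000, 2001000, 0, 1000, "+"),
                             seg_row("chr1", 999000, 1000000, 1020, 2020, "+"))
  expect_equal(bnd$chrom1, "chr1")
  expect_equal(bnd$pos1, 999000)   # second segment's start (its + side)
  expect_equal(bnd$pos2, 2001000)

  # distant on the read: no breakend
  expect_null(
    classifySegmentPair(seg_row("chr1", 999000, 1000000, 0, 1000, "+"),
                        seg_row("chr2", 2000000, 2001000, 1200, 2200, "+")))
})

test_that("pair classification is exhaustive and mutually exclusive", {
  # brute-force sweep over same-chrom same-strand geometries: every pair maps
  # to exactly one of DEL/INS/DUP/none, consistent with the defining
  # inequalities
  s1 <- seg_row("chr1", 5000, 6000, 0, 1000)
  for (ref2s in seq(5500, 7200, by = 37)) {
    for (gap in c(0, 20, 200, 700)) {
      s2 <- seg_row("chr1", ref2s, ref2s + 800, 1000 + gap, 1800 + gap)
      out <- classifySegmentPair(s1, s2)
      diff_dis <- (ref2s - 6000) - gap
      diff_olp <- 6000 - ref2s
      expected <-
        if (diff_olp < 30 && diff_dis >= 30) "DEL"
        else if (diff_olp < 30 && diff_dis <= -30) "INS"
        else if (diff_olp >= 30) "DUP"
        else "none"
      got <- if (is.null(out)) "none" else out$sv_type
      expect_equal(got, expected)
    }
  }
})

test_that("signatures are strand-symmetric in reference coordinates", {
  # reversing a read's segment chain (the reverse-complement read) flips
  # strands, read offsets and order, but reference coordinates and SV types
  # must not move
  revchain <- function(segs) {
    L <- max(segs$read_end)
    segs$strand <- ifelse(segs$strand == "+", "-", "+")
    rs <- L - segs$read_end
    segs$read_end <- L - segs$read_start
    segs$read_start <- rs
    segs <- segs[order(segs$read_start), , drop = FALSE]
    rownames(segs) <- NULL
    segs
  }
  chains <- list(
    rbind(seg_row("chr1", 5000, 6000, 0, 1000),
          seg_row("chr1", 6500, 7500, 1010, 2010)),           # DEL
    rbind(seg_row("chr1", 5000, 6000, 0, 1000),
          seg_row("chr1", 6010, 7010, 1510, 2510)),           # INS
    rbind(seg_row("chr1", 5000, 6000, 0, 1000),
          seg_row("chr1", 5900, 6800, 1010, 1910)),           # DUP
    rbind(seg_row("chr1", 5000, 6000, 0, 1000, "+"),
          seg_row("chr1", 6400, 6950, 1010, 1560, "-")))      # INV
  for (segs in chains) {
    fwd <- classifySegmentPair(segs[1, ], segs[2, ])
    rc <- revchain(segs)
    rev <- classifySegmentPair(rc[1, ], rc[2, ])
    expect_equal(rev$sv_type, fwd$sv_type)
    expect_equal(rev$pos1, fwd$pos1)
    if (!is.na(fwd$pos2)) expect_equal(rev$pos2, fwd$pos2)
    if (!is.na(fwd$length)) expect_equal(rev$length, fwd$length)
  }
})

test_that("the duplication-with-mobile-insertion triple is recognized", {
  segs <- rbind(
    seg_row("chr1", 1000, 2000, 0, 1000),
    seg_row("chrX", 5000, 5600, 1005, 1605),
    seg_row("chr1", 1000, 2000, 1610, 2610))
  out <- detectComplexDupIns(segs)
  expect_setequal(out$sv_type, c("DUP", "INS", "BND"))
  expect_equal(sum(out$sv_type == "BND"), 2)
  dup <- out[out$sv_type == "DUP", ]
  expect_equal(c(dup$pos1, dup$pos2), c(1000, 2000))
  ins <- out[out$sv_type == "INS", ]
  # diff_dis(A, A') = (1000 - 2000) - (1610 - 1000) = -1610
  expect_equal(ins$length, 1610)
  expect_equal(ins$pos1, 1000)

  # no cross-chromosome middle segment: nothing
  segs2 <- rbind(
    seg_row("chr1", 1000, 2000, 0, 1000),
    seg_row("chr1", 5000, 5600, 1005, 1605),
    seg_row("chr1", 1000, 2000, 1610, 2610))
  expect_equal(nrow(detectComplexDupIns(segs2)), 0)
  expect_equal(nrow(detectComplexDupIns(segs2[1:2, ])), 0)
})

test_that("per-read extraction unifies CIGAR and split evidence", {
  # clean read, no large indels: nothing
  rec <- read_sam_records(list(
    list(qname = "r1", flag = 0, rname = "chr1", pos = 1001, mapq = 60,
         cigar = "5000M")))
  expect_equal(nrow(extractSignatures(rec)), 0)

  # a 272 bp insertion fragmented into three I runs merges into one signature
  rec <- read_sam_records(list(
    list(qname = "r1", flag = 0, rname = "chr1", pos = 1001, mapq = 60,
         cigar = "1000M100I200M100I200M72I1000M")))
  sig <- extractSignatures(rec)
  expect_equal(nrow(sig), 1)
  expect_equal(sig$sv_type, "INS")
  expect_equal(sig$length, 272)
  expect_equal(sig$pos1, 2000)

  # one 50 bp D op plus a split deletion of 490 bp: two DEL signatures
  rec <- read_sam_records(list(
    list(qname = "r1", flag = 0, rname = "chr1", pos = 1001, mapq = 60,
         cigar = "1000M50D1000M2000S"),
    list(qname = "r1", flag = 2048, rname = "chr1", pos = 3551, mapq = 60,
         cigar = "2010S1990M")))
  sig <- extractSignatures(rec)
  expect_equal(sort(sig$length), c(50, 490))
  expect_equal(sig$sv_type, c("DEL", "DEL"))
  expect_equal(sort(sig$pos1), c(2000, 3050))
})
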