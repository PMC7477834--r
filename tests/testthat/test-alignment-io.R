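test_that("CIGAR walk extracts large indels at the right reference positions", {
  s <- cigarSignatures("100M50D100M", 1000, "chr1", "r1", min_size = 30)
  expect_equal(nrow(s), 1)
  expect_equal(s$kind, "DEL")
  expect_equal(s$ref_start, 1100)
  expect_equal(s$length, 50)

  s <- cigarSignatures("100M40I100M", 1000, "chr1", "r1", min_size = 30)
  expect_equal(s$kind, "INS")
  expect_equal(s$ref_start, 1100)
  expect_equal(s$length, 40)

  expect_equal(nrow(cigarSignatures("100M20D100M", 1000, "chr1", "r1", 30)), 0)

  # N advances the reference but is never an SV deletion
  s <- cigarSignatures("100M5000N100M60D100M", 1000, "chr1", "r1", 30)
  expect_equal(nrow(s), 1)
  expect_equal(s$ref_start, 1000 + 100 + 5000 + 100)

  # soft clips advance the read, not the reference
  s <- cigarSignatures("500S100M50D100M", 1000, "chr1", "r1", 30)
  expect_equal(s$ref_start, 1100)
})

test_that("malformed CIGARs are rejected with a warning, stream continues", {
  expect_warning(
    s <- cigarSignatures(c("100M50D100M", "10Q"), c(1000, 2000),
                         c("chr1", "chr1"), c("r1", "r2"), 30),
    "malformed")
  expect_equal(nrow(s), 1)
  expect_equal(s$read_id, "r1")
})

test_that("split segments use clip-inclusive read coordinates", {
  rec <- read_sam_records(list(
    list(qname = "r1", flag = 0, rname = "chr1", pos = 5001, mapq = 60,
         cigar = "500S1000M500S")))
  seg <- splitSegments(rec)
  expect_equal(seg$read_start, 500)
  expect_equal(seg$read_end, 1500)
  expect_equal(seg$ref_start, 5000)
  expect_equal(seg$ref_end, 6000)
  expect_equal(seg$strand, "+")
})

test_that("reverse-strand segments are flipped onto the original read", {
  # primary covers read 0..500 of a 2000 bp read; the supplementary is stored
  # reverse-complemented with a 1500 hard clip
  rec <- read_sam_records(list(
    list(qname = "r1", flag = 0, rname = "chr1", pos = 101, mapq = 60,
         cigar = "600M1400S"),
    list(qname = "r1", flag = 2064, rname = "chr1", pos = 8001, mapq = 60,
         cigar = "1500H500M")))
  seg <- splitSegments(rec)
  expect_equal(nrow(seg), 2)
  sup <- seg[seg$strand == "-", ]
  expect_equal(sup$read_start, 0)
  expect_equal(sup$read_end, 500)
  expect_equal(sup$ref_start, 8000)
  expect_equal(sup$ref_end, 8500)
})

test_that("single unsplit primary yields one segment", {
  rec <- read_sam_records(list(
    list(qname = "r1", flag = 0, rname = "chr1", pos = 1001, mapq = 60,
         cigar = "1000M")))
  seg <- splitSegments(rec)
  expect_equal(nrow(seg), 1)
  expect_true(seg$is_primary)
})

test_that("reads with no primary or inconsistent lengths are skipped", {
  rec <- read_sam_records(list(
    list(qname = "r1", flag = 2048, rname = "chr1", pos = 1001, mapq = 60,
         cigar = "1000M")))
  expect_null(splitSegments(rec))

  rec <- read_sam_records(list(
    list(qname = "r1", flag = 0, rname = "chr1", pos = 1001, mapq = 60,
         cigar = "500M1500S"),
    list(qname = "r1", flag = 2048, rname = "chr1", pos = 9001, mapq = 60,
         cigar = "100S500M")))
  expect_warning(out <- splitSegments(rec), "inconsistent")
  expect_null(out)
})

test_that("SA tags reconstruct supplementary segments when records are absent", {
  rec <- read_sam_records(list(
    list(qname = "r1", flag = 0, rname = "chr1", pos = 1001, mapq = 60,
         cigar = "500M1500S", sa = "chr1,9001,+,500S1500M,60,0;")))
  seg <- splitSegments(rec)
  expect_equal(nrow(seg), 2)
  expect_equal(seg$ref_start[2], 9000)
  expect_equal(seg$read_start[2], 500)
})

test_that("secondary and low-MAPQ records are filtered at read-in", {
  rec <- read_sam_records(list(
    list(qname = "r1", flag = 0, rname = "chr1", pos = 1001, mapq = 60,
         cigar = "1000M"),
    list(qname = "r2", flag = 256, rname = "chr1", pos = 2001, mapq = 60,
         cigar = "1000M"),
    list(qname = "r3", flag = 0, rname = "chr1", pos = 3001, mapq = 5,
         cigar = "1000M")))
  expect_equal(rec$qname, "r1")
})

test_that("every read group is owned by exactly one block", {
  rows <- lapply(seq_len(40), function(i) {
    list(qname = paste0("r", i), flag = 0, rname = "chr1",
         pos = i * 200000, mapq = 60, cigar = "1000M")
  })
  # one read with its primary in the first block, supplementary in another
  rows <- c(rows, list(
    list(qname = "split1", flag = 0, rname = "chr1", pos = 100,
         mapq = 60, cigar = "500M500S"),
    list(qname = "split1", flag = 2048, rname = "chr1", pos = 9000001,
         mapq = 60, cigar = "500S500M")))
  aln <- readAlignments(write_sam(rows))
  blocks <- streamBlocks(aln$records, aln$contigs, block_size = 2e6, pad = 0)
  own <- lapply(blocks, `[[`, "own_qnames")
  expect_equal(sort(unique(unlist(own))), sort(unique(aln$records$qname)))
  expect_equal(sum(lengths(own)), length(unique(aln$records$qname)))
  first_chr1 <- which(vapply(blocks, function(b)
    b$chrom == "chr1" && b$start == 0, logical(1)))
  expect_true("split1" %in% blocks[[first_chr1]]$own_qnames)
})

test_that("empty alignment input yields empty records and an intact header", {
  aln <- readAlignments(write_sam(list()))
  expect_equal(nrow(aln$records), 0)
  expect_equal(aln$contigs$name, c("chr1", "chr2"))
})

test_that("implied read length is conserved across a read's records", {
  refl <- c(chrA = 3e5)
  sv <- data.frame(type = c("DEL", "INV"), chrom = "chrA",
                   pos = c(5e4, 15e4), len = c(1500, 2000),
                   chrom2 = NA, pos2 = NA, zygosity = "hom")
  fx <- fixtureSpec(refl, sv, coverage = 8, seed = 11)
  sam <- tempfile(fileext = ".sam")
  emitAlignments(fx, sam)
  rec <- readAlignments(sam)$records
  rl <- tapply(rec$read_len, rec$qname, function(x) length(unique(x)))
  expect_true(all(rl == 1))
  # segments reconstruct contiguously on the read for split reads
  for (qn in unique(rec$qname[duplicated(rec$qname)])) {
    seg <- splitSegments(rec[rec$qname == qn, ])
    expect_false(is.null(seg))
    expect_true(all(diff(seg$read_start) > 0))
  }
})
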