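test_that("position clustering links signatures through either coordinate", {
  sigs <- rbind(sig_row("DEL", "chr1", 1000, 50, read_id = "a"),
                sig_row("DEL", "chr1", 1100, 60, read_id = "b"))
  cl <- clusterByPosition(sigs, th_type = 200, min_reads = 1)
  expect_length(cl, 1)                       # 100 <= 200

  sigs <- rbind(sigs, sig_row("DEL", "chr1", 2000, 50, read_id = "c"))
  cl <- clusterByPosition(sigs, th_type = 200, min_reads = 1)
  expect_length(cl, 2)                       # 900 > 200 on both conditions

  expect_length(clusterByPosition(emptySignatures(), 200), 0)
})

test_that("clustering equals connected components of the linkage predicate", {
  skip_if_not_installed("igraph")
  # independent oracle: explicit pairwise predicate graph
  oracle <- function(pos, len, th) {
    n <- length(pos)
    end <- pos + len
    edges <- c()
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i < j && (abs(pos[i] - pos[j]) <= th || abs(end[i] - end[j]) <= th))
        edges <- c(edges, i, j)
    }
    g <- igraph::make_graph(edges, n = n, directed = FALSE)
    igraph::components(g)$membership
  }
  set.seed(99)
  for (rep in 1:60) {
    n <- sample(1:20, 1)
    pos <- sort(sample(0:5000, n, replace = TRUE))
    len <- sample(30:1500, n, replace = TRUE)
    th <- sample(c(50, 200, 500), 1)
    sigs <- sig_row("DEL", "chr1", pos[1], len[1], read_id = "r1")[0, ]
    for (i in seq_len(n)) {
      sigs <- rbind(sigs, sig_row("DEL", "chr1", pos[i], len[i],
                                  read_id = paste0("r", i)))
    }
    got <- clusterByPosition(sigs, th, min_reads = 1)
    memb <- oracle(pos, len, th)
    # same partition: each reported cluster is exactly one oracle component
    expect_equal(length(got), length(unique(memb)))
    for (cl in got) {
      ids <- as.integer(sub("r", "", cl$read_id))
      expect_length(unique(memb[ids]), 1)
    }
  }
})

test_that("length tolerance scales with the mean signature size", {
  expect_equal(computeBiasL(c(100, 100, 100, 100), 0.3), 30)
  expect_equal(computeBiasL(50, 0.2), 10)
  expect_equal(computeBiasL(c(80, 120), 0), 0)
})

test_that("length partition follows the chained-gap rule", {
  sigs <- do.call(rbind, lapply(seq_along(c(100, 98, 95, 40, 38)),
    function(i) sig_row("DEL", "chr1", 1000,
                        c(100, 98, 95, 40, 38)[i],
                        read_id = paste0("r", i))))
  subs <- partitionByLength(sigs, bias_l = 22.26)
  expect_length(subs, 2)
  expect_setequal(subs[[1]]$length, c(100, 98, 95))
  expect_setequal(subs[[2]]$length, c(40, 38))

  same <- do.call(rbind, lapply(1:4, function(i)
    sig_row("INS", "chr1", 1000, 70, read_id = paste0("r", i))))
  expect_length(partitionByLength(same, 5), 1)
  expect_length(partitionByLength(sigs, 1e9), 1)
  # zero tolerance: every distinct length its own sub-cluster
  expect_length(partitionByLength(sigs, 0), 5)
})

test_that("major/minor allele selection follows the support rules", {
  mk <- function(sizes, n, tag) do.call(rbind, lapply(seq_len(n), function(i)
    sig_row("DEL", "chr1", 1000, sizes, read_id = paste0(tag, i))))
  # major + minor: supports {8, 2}, |Group| = 10, mu 0.7, SR_min 2
  sel <- selectAlleles(list(mk(100, 8, "a"), mk(40, 2, "b")),
                       group_size = 10, sr_min = 2, mu = 0.7)
  expect_equal(sel$roles, c("major", "minor"))

  # two-allele rescue: supports {5, 5}, SR_min 5: 5 in [5,7], 5 in [4,5],
  # 10 >= 9.5
  sel <- selectAlleles(list(mk(100, 5, "a"), mk(40, 5, "b")),
                       group_size = 10, sr_min = 5, mu = 0.7)
  expect_equal(sel$roles, c("major", "minor"))

  # below the floor: discarded
  sel <- selectAlleles(list(mk(100, 1, "a")), group_size = 1, sr_min = 2,
                       mu = 0.7)
  expect_equal(sel$roles, "discarded")
})

test_that("the two-allele rescue is exactly as printed (incl. upper bound)", {
  mk <- function(n, tag) do.call(rbind, lapply(seq_len(n), function(i)
    sig_row("INS", "chr1", 1000, 100, read_id = paste0(tag, i))))
  # SR_second must not exceed SR_min: supports {10, 10} in a group of 20
  # fail at SR_min 5 but qualify at SR_min 10
  low <- selectAlleles(list(mk(10, "a"), mk(10, "b")), 20, sr_min = 5,
                       mu = 0.6)
  expect_equal(low$roles, c("discarded", "discarded"))
  high <- selectAlleles(list(mk(10, "a"), mk(10, "b")), 20, sr_min = 10,
                        mu = 0.6)
  expect_equal(high$roles, c("major", "minor"))
})

test_that("allele count via the major-allele path never grows with SR_min", {
  set.seed(7)
  for (rep in 1:30) {
    supports <- sample(1:15, sample(1:4, 1), replace = TRUE)
    subs <- lapply(seq_along(supports), function(k) {
      do.call(rbind, lapply(seq_len(supports[k]), function(i)
        sig_row("DEL", "chr1", 1000, 50 + 40 * k,
                read_id = paste0("s", k, "_", i))))
    })
    g <- sum(supports)
    prev <- Inf
    for (srmin in 1:12) {
      sel <- selectAlleles(subs, g, srmin, mu = 0.7)
      if (sel$roles[1] == "major") {
        n_alleles <- sum(sel$roles != "discarded")
        expect_lte(n_alleles, prev)
        prev <- n_alleles
      }
    }
  }
})

test_that("every signature lands in exactly one cluster and sub-cluster", {
  set.seed(13)
  sigs <- do.call(rbind, lapply(1:40, function(i)
    sig_row("INS", "chr1", sample(0:20000, 1), sample(30:400, 1),
            read_id = paste0("r", i))))
  clusters <- clusterByPosition(sigs, 200, min_reads = 1)
  seen <- unlist(lapply(clusters, function(cl) cl$read_id))
  expect_setequal(seen, sigs$read_id)
  expect_equal(length(seen), nrow(sigs))
  for (cl in clusters) {
    subs <- partitionByLength(cl, computeBiasL(cl$length, 0.2))
    ids <- unname(unlist(lapply(subs, `[[`, "read_id")))
    expect_equal(length(ids), nrow(cl))
    expect_setequal(ids, cl$read_id)
  }
})

test_that("duplication/inversion refinement separates distant breakpoints", {
  inv <- rbind(
    do.call(rbind, lapply(1:4, function(i)
      sig_row("INV", "chr1", 6000, 950, pos2 = 6950, orientation = "INV_hh",
              read_id = paste0("a", i)))),
    do.call(rbind, lapply(1:2, function(i)
      sig_row("INV", "chr1", 6400, 900, pos2 = 7300, orientation = "INV_hh",
              read_id = paste0("b", i)))))
  ref <- refineDupInv(inv, sr_min = 2)
  expect_length(ref$subclusters, 2)    # summed breakpoint spread 750 > 500
  # mu = 1/3: the 4-read sub-cluster is the major allele (4 > 6/3)
  expect_equal(ref$roles[1], "major")

  same <- do.call(rbind, lapply(1:6, function(i)
    sig_row("INV", "chr1", 6000, 950, pos2 = 6950, orientation = "INV_hh",
            read_id = paste0("r", i))))
  expect_length(refineDupInv(same, 2)$subclusters, 1)
})

test_that("breakend refinement halves the support floor and splits classes", {
  bnd <- do.call(rbind, lapply(1:4, function(i)
    sig_row("BND", "chr1", 1000, 0, chrom2 = "chr2", pos2 = 5000,
            orientation = "++", read_id = paste0("r", i))))
  ref <- refineBnd(bnd, sr_min = 4)   # effective floor 2; 4 > 0.6*4
  expect_equal(ref$roles[1], "major")

  mixed <- rbind(bnd,
                 do.call(rbind, lapply(1:4, function(i)
                   sig_row("BND", "chr1", 1000, 0, chrom2 = "chr2",
                           pos2 = 5000, orientation = "+-",
                           read_id = paste0("q", i)))))
  ref <- refineBnd(mixed, sr_min = 4)
  expect_length(ref$subclusters, 2)   # orientation classes stay separate

  single <- bnd[1, ]
  ref <- refineBnd(single, sr_min = 4)
  expect_equal(ref$roles, "discarded")
})
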