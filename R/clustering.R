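#' Cluster signatures of one type by genomic position
#'
#' Groups position-sorted signatures of one SV type (and chromosome, or
#' chromosome pair for breakends) into per-locus clusters. Two signatures are
#' linked when either their positions or their end coordinates
#' (position + length) are within the per-type threshold; clusters are the
#' connected components of this linkage. Because the linkage is an interval
#' condition on sorted coordinates, components are computed exactly by
#' union-find over consecutive position gaps and consecutive end-coordinate
#' gaps, which is equivalent to the full pairwise predicate graph.
#'
#' Clusters supported by fewer than \code{min_reads} distinct reads are
#' dropped.
#'
#' @param sigs signature data.frame of one sv_type (DUP/INV lengths are the
#'   breakpoint spans, breakends use length 0).
#' @param th_type clustering threshold in bp.
#' @param min_reads discard floor on distinct supporting reads (default 2).
#' @return list of signature data.frames, each sorted by pos1; list ordered by
#'   first member position.
#' @export
clusterByPosition <- function(sigs, th_type, min_reads = 2L) {
  if (!nrow(sigs)) return(list())
  len <- ifelse(is.na(sigs$length), 0, sigs$length)
  pos <- sigs$pos1
  end <- pos + len
  n <- nrow(sigs)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  op <- order(pos)
  if (n > 1) {
    for (k in seq_len(n - 1)) {
      if (pos[op[k + 1]] - pos[op[k]] <= th_type) unite(op[k], op[k + 1])
    }
    oe <- order(end)
    for (k in seq_len(n - 1)) {
      if (end[oe[k + 1]] - end[oe[k]] <= th_type) unite(oe[k], oe[k + 1])
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), comp)
  first_pos <- vapply(groups, function(ix) min(pos[ix]), numeric(1))
  groups <- groups[order(first_pos)]
  out <- lapply(groups, function(ix) {
    cl <- sigs[ix[order(pos[ix])], , drop = FALSE]
    rownames(cl) <- NULL
    cl
  })
  names(out) <- NULL
  keep <- vapply(out, function(cl) length(unique(cl$read_id)) >= min_reads,
                 logical(1))
  out[keep]
}

#' Adaptive length tolerance of a deletion/insertion cluster
#'
#' The tolerance used to partition a cluster into allele sub-clusters scales
#' with the mean signature length: \code{alpha * mean(lengths)}.
#'
#' @param lengths signature lengths of the cluster.
#' @param alpha weighting parameter (platform/type dependent; see
#'   \code{\link{svConfig}}).
#' @return numeric tolerance in bp.
#' @export
computeBiasL <- function(lengths, alpha) {
  stopifnot(length(lengths) >= 1)
  alpha * mean(lengths)
}

#' Partition a cluster into length-homogeneous sub-clusters
#'
#' Signatures are scanned from largest to smallest; a signature joins the open
#' sub-cluster iff its size differs from the last signature added by less
#' than \code{bias_l}, otherwise a new sub-cluster opens (chained-gap rule).
#'
#' @param sigs signature data.frame (DEL or INS cluster).
#' @param bias_l length tolerance from \code{\link{computeBiasL}}.
#' @return list of data.frames, largest-size sub-cluster first.
#' @export
partitionByLength <- function(sigs, bias_l) {
  if (!nrow(sigs)) return(list())
  ord <- order(-sigs$length, sigs$pos1)
  s <- sigs[ord, , drop = FALSE]
  breaks <- c(TRUE, diff(-s$length) >= bias_l)  # sizes descending
  grp <- cumsum(breaks)
  lapply(split(seq_len(nrow(s)), grp), function(ix) {
    sub <- s[ix, , drop = FALSE]
    rownames(sub) <- NULL
    sub
  })
}

.support <- function(sub) length(unique(sub$read_id))

#' Assign major/minor allele roles to sub-clusters
#'
#' The sub-cluster with the most support becomes the major allele when its
#' distinct-read support SR satisfies \code{SR >= sr_min} and
#' \code{SR > mu * group_size}; the remaining sub-clusters with at least
#' \code{sr_min} signatures become minor alleles. When no major allele
#' exists, a two-allele rescue applies to the two largest sub-clusters:
#' \code{sr_min <= SR_first <= mu * group_size},
#' \code{0.4 * group_size <= SR_second <= sr_min} and
#' \code{SR_first + SR_second >= 0.95 * group_size} makes both alleles
#' (the larger one major). Everything else is discarded.
#'
#' Ties on support are broken by larger mean length, then smaller position.
#'
#' @param subclusters list of signature data.frames.
#' @param group_size total number of signatures in the parent cluster.
#' @param sr_min minimum supporting reads.
#' @param mu major-allele support fraction.
#' @return list(subclusters = reordered list, roles = character vector with
#'   values major/minor/discarded).
#' @export
selectAlleles <- function(subclusters, group_size, sr_min, mu) {
  if (!length(subclusters)) {
    return(list(subclusters = subclusters, roles = character(0)))
  }
  sr <- vapply(subclusters, .support, numeric(1))
  mlen <- vapply(subclusters, function(s) {
    if (all(is.na(s$length))) 0 else mean(s$length, na.rm = TRUE)
  }, numeric(1))
  mpos <- vapply(subclusters, function(s) min(s$pos1), numeric(1))
  ord <- order(-sr, -mlen, mpos)
  subclusters <- subclusters[ord]
  sr <- sr[ord]
  nsig <- vapply(subclusters, nrow, numeric(1))
  roles <- rep("discarded", length(subclusters))
  if (sr[1] >= sr_min && sr[1] > mu * group_size) {
    roles[1] <- "major"
    if (length(subclusters) > 1) {
      roles[-1][nsig[-1] >= sr_min] <- "minor"
    }
  } else if (length(subclusters) >= 2) {
    sr1 <- sr[1]; sr2 <- sr[2]
    if (sr_min <= sr1 && sr1 <= mu * group_size &&
        0.4 * group_size <= sr2 && sr2 <= sr_min &&
        sr1 + sr2 >= 0.95 * group_size) {
      roles[1] <- "major"; roles[2] <- "minor"
    }
  }
  list(subclusters = subclusters, roles = roles)
}

#' Refine a deletion/insertion cluster into allele sub-clusters
#'
#' Partitions the cluster by length with the adaptive tolerance and assigns
#' allele roles.
#'
#' @param cluster signature data.frame (one DEL or INS cluster).
#' @param alpha weighting parameter for the length tolerance.
#' @param sr_min minimum supporting reads.
#' @param mu major-allele support fraction.
#' @return list(subclusters, roles, bias_l).
#' @export
refineDelIns <- function(cluster, alpha, sr_min, mu) {
  bias_l <- computeBiasL(cluster$length, alpha)
  subs <- partitionByLength(cluster, bias_l)
  sel <- selectAlleles(subs, nrow(cluster), sr_min, mu)
  c(sel, list(bias_l = bias_l))
}

# greedy grouping on (pos1, pos2): a sub-cluster's total breakpoint
# discrepancy (pos1 spread + pos2 spread) must stay within max_dist
.diameterGroups <- function(sigs, max_dist) {
  sigs <- sigs[order(sigs$pos1, sigs$pos2), , drop = FALSE]
  out <- list()
  cur <- integer(0)
  min1 <- max1 <- min2 <- max2 <- NULL
  for (i in seq_len(nrow(sigs))) {
    p1 <- sigs$pos1[i]; p2 <- sigs$pos2[i]
    if (!length(cur)) {
      cur <- i; min1 <- max1 <- p1; min2 <- max2 <- p2
      next
    }
    if ((max(max1, p1) - min(min1, p1)) +
        (max(max2, p2) - min(min2, p2)) <= max_dist) {
      cur <- c(cur, i)
      min1 <- min(min1, p1); max1 <- max(max1, p1)
      min2 <- min(min2, p2); max2 <- max(max2, p2)
    } else {
      out[[length(out) + 1]] <- cur
      cur <- i; min1 <- max1 <- p1; min2 <- max2 <- p2
    }
  }
  if (length(cur)) out[[length(out) + 1]] <- cur
  lapply(out, function(ix) {
    sub <- sigs[ix, , drop = FALSE]
    rownames(sub) <- NULL
    sub
  })
}

#' Refine a duplication/inversion cluster
#'
#' Sub-clusters are formed so that the breakpoints of all members lie within
#' 500 bp of each other, measured as the summed spread of the two breakpoint
#' coordinates; allele selection then applies with mu = 1/3.
#'
#' @param cluster signature data.frame (DUP or INV).
#' @param sr_min minimum supporting reads.
#' @param max_dist breakpoint diameter bound (default 500 bp).
#' @param mu support fraction (default 1/3).
#' @return list(subclusters, roles).
#' @export
refineDupInv <- function(cluster, sr_min, max_dist = 500, mu = 1 / 3) {
  subs <- .diameterGroups(cluster, max_dist)
  selectAlleles(subs, nrow(cluster), sr_min, mu)
}

#' Refine a breakend cluster
#'
#' Members are first separated by orientation class and mate chromosome, then
#' sub-clustered so both mates lie within 50 bp; allele selection applies
#' with mu = 0.6 and the support floor halved (rounded up), which accounts
#' for the diversity of chromosome/orientation combinations of translocation
#' evidence.
#'
#' @param cluster signature data.frame (BND).
#' @param sr_min minimum supporting reads before halving.
#' @param max_dist mate diameter bound (default 50 bp).
#' @param mu support fraction (default 0.6).
#' @return list(subclusters, roles).
#' @export
refineBnd <- function(cluster, sr_min, max_dist = 50, mu = 0.6) {
  sr_eff <- ceiling(sr_min / 2)
  subs <- list()
  key <- paste(cluster$orientation, cluster$chrom2)
  for (k in unique(key)) {
    part <- cluster[key == k, , drop = FALSE]
    subs <- c(subs, .diameterGroups(part, max_dist))
  }
  selectAlleles(subs, nrow(cluster), sr_eff, mu)
}
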