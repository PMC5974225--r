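## Order-based ensemble likelihoods on branched trees.
##
## Every likelihood is assembled from explicit placements: within-segment
## placements (one per admissible start position, as on a single segment, but
## with gap zones that extend across open segment ends onto the adjacent
## segments) and branch-point placements (one per way of splitting the
## ensemble over the two or three segments meeting at a bifurcation). The
## placement sums reduce to the printed closed forms (end-correction sums,
## 3(M-1) two-segment and (M-1)(M-2)/2 three-segment placement counts) when
## all segments are long enough, and remain exact otherwise, which is what
## the enumeration oracle checks.

## global spine ids: segment i occupies offset[i] + 1 .. offset[i] + N_i
seg_offsets <- function(tree) {
  n <- vapply(tree@segments, nSpines, 0)
  c(0, cumsum(n))[seq_along(n)]
}

other_end <- function(end) if (end == "proximal") "distal" else "proximal"

## segments adjacent to `end` of segment x, with the end through which the
## gap enters each of them
adjacent_branches <- function(tree, x, end) {
  if (end == "distal") {
    ch <- childSegments(tree, x)
    if (!length(ch)) return(NULL)
    lapply(ch, function(s) list(seg = s, entry = "proximal"))
  } else {
    p <- tree@parent[x]
    if (is.na(p)) return(NULL)
    sibs <- setdiff(childSegments(tree, p), x)
    c(list(list(seg = p, entry = "distal")),
      lapply(sibs, function(s) list(seg = s, entry = "proximal")))
  }
}

## spine ids covered by a gap of r spines extending beyond `end` of segment
## x. At a closed end the gap is truncated by the tree itself (the standard
## end-correction); at an open end it covers the r spines nearest the branch
## point on EVERY adjacent segment. mode "recursive" distributes any residual
## over the segments beyond (splitting again at further branch points); mode
## "upper_bound" stops at the directly adjacent segments and flags the
## result, matching the printed treatment that yields an upper likelihood
## estimate.
gap_beyond <- function(tree, x, end, r, mode = "recursive") {
  ids <- integer(0); truncated <- FALSE
  if (r <= 0) return(list(ids = ids, truncated = truncated))
  br <- adjacent_branches(tree, x, end)
  if (is.null(br)) return(list(ids = ids, truncated = FALSE))
  off <- seg_offsets(tree)
  for (b in br) {
    Na <- nSpines(tree@segments[[b$seg]])
    t <- min(Na, r)
    if (t > 0) {
      idx <- if (b$entry == "proximal") seq_len(t) else (Na - t + 1):Na
      ids <- c(ids, off[b$seg] + idx)
    }
    if (r > Na) {
      if (mode == "recursive") {
        sub <- gap_beyond(tree, b$seg, other_end(b$entry), r - Na, mode)
        ids <- c(ids, sub$ids)
        truncated <- truncated || sub$truncated
      } else {
        truncated <- TRUE
      }
    }
  }
  list(ids = ids, truncated = truncated)
}

## all within-segment placements of an M-spine ensemble on segment x
segment_placements <- function(tree, x, M, g, mode = "recursive") {
  lay <- tree@segments[[x]]
  Nx <- nSpines(lay)
  if (Nx < M) return(list())
  off <- seg_offsets(tree)[x]
  out <- vector("list", Nx - M + 1)
  for (s in seq_len(Nx - M + 1)) {
    b <- s - 1L                       # spines before the ensemble
    a <- Nx - M - b                   # spines after
    gl <- min(g, b); gr <- min(g, a)
    gaps <- integer(0)
    if (gl > 0) gaps <- c(gaps, off + (s - gl):(s - 1))
    if (gr > 0) gaps <- c(gaps, off + (s + M):(s + M + gr - 1))
    truncated <- FALSE
    if (g - gl > 0) {
      bey <- gap_beyond(tree, x, "proximal", g - gl, mode)
      gaps <- c(gaps, bey$ids); truncated <- truncated || bey$truncated
    }
    if (g - gr > 0) {
      bey <- gap_beyond(tree, x, "distal", g - gr, mode)
      gaps <- c(gaps, bey$ids); truncated <- truncated || bey$truncated
    }
    win <- off + s:(s + M - 1)
    out[[s]] <- list(window = win, ends = c(win[1], win[M]), delta = 2L,
                     gaps = unique(gaps), truncated = truncated)
  }
  out
}

## all placements of an M-spine ensemble across the branch point where
## segments y and z arise from x; each placement is a split (kx, ky, kz)
## with at least two occupied arms
branchpoint_placements <- function(tree, x, y, z, M, g, mode = "recursive") {
  off <- seg_offsets(tree)
  Nx <- nSpines(tree@segments[[x]])
  Ny <- nSpines(tree@segments[[y]])
  Nz <- nSpines(tree@segments[[z]])
  out <- list()
  for (kx in 0:min(M, Nx)) {
    for (ky in 0:min(M - kx, Ny)) {
      kz <- M - kx - ky
      if (kz < 0 || kz > Nz) next
      if (sum(c(kx, ky, kz) > 0) < 2) next  # single-arm cases are segment placements
      window <- integer(0); ends <- integer(0)
      if (kx > 0) {
        window <- c(window, off[x] + (Nx - kx + 1):Nx)
        ends <- c(ends, off[x] + Nx - kx + 1)     # far (proximal) end of the x arm
      }
      if (ky > 0) {
        window <- c(window, off[y] + seq_len(ky))
        ends <- c(ends, off[y] + ky)              # far (distal) end of the y arm
      }
      if (kz > 0) {
        window <- c(window, off[z] + seq_len(kz))
        ends <- c(ends, off[z] + kz)
      }
      gaps <- integer(0); truncated <- FALSE
      arm <- list(list(seg = x, k = kx, far = "proximal"),
                  list(seg = y, k = ky, far = "distal"),
                  list(seg = z, k = kz, far = "distal"))
      for (aa in arm) {
        Ns <- nSpines(tree@segments[[aa$seg]])
        avail <- Ns - aa$k
        gin <- min(g, avail)
        if (gin > 0) {
          idx <- if (aa$far == "proximal") (avail - gin + 1):avail
                 else (aa$k + 1):(aa$k + gin)
          gaps <- c(gaps, off[aa$seg] + idx)
        }
        if (g - gin > 0) {
          bey <- gap_beyond(tree, aa$seg, aa$far, g - gin, mode)
          gaps <- c(gaps, bey$ids); truncated <- truncated || bey$truncated
        }
      }
      out[[length(out) + 1]] <- list(window = window, ends = ends,
                                     delta = sum(c(kx, ky, kz) > 0),
                                     gaps = unique(gaps),
                                     truncated = truncated)
    }
  }
  out
}

tree_placements <- function(tree, M, g, mode = "recursive",
                            segments = seq_len(nSegments(tree)),
                            branchpoints = TRUE) {
  out <- list()
  for (x in segments) out <- c(out, segment_placements(tree, x, M, g, mode))
  if (branchpoints) {
    bp <- branchPoints(tree)
    for (r in seq_len(nrow(bp))) {
      out <- c(out, branchpoint_placements(tree, bp$x[r], bp$y[r], bp$z[r],
                                           M, g, mode))
    }
  }
  out
}

## exact numerator contribution of a placement list for exactly m inputs
placements_numerator <- function(placements, Ntot, ntot, M, m) {
  num <- bi_new(0); truncated <- FALSE
  for (p in placements) {
    if (m < p$delta) next
    free <- Ntot - M - length(p$gaps)
    term <- bi_mul(bi_choose(M - p$delta, m - p$delta),
                   bi_choose(free, ntot - m))
    num <- bi_add(num, term)
    truncated <- truncated || p$truncated
  }
  list(num = num, truncated = truncated)
}

#' Two-segment placements of an ensemble at a branch point
#'
#' Number of ways an ensemble of M spines can span exactly two of the three
#' segments meeting at a bifurcation: 3 (M - 1).
#'
#' @param M ensemble size (>= 2).
#' @return Integer count.
#' @export
branchpointTwoSegmentPlacements <- function(M) {
  check_count(M, "M")
  if (M < 2) stop("M must be at least 2")
  3L * (M - 1L)
}

#' Three-segment placements of an ensemble at a branch point
#'
#' Number of ways an ensemble of M spines can span all three segments at a
#' bifurcation (compositions of M into three positive parts):
#' (M - 1)(M - 2) / 2.
#'
#' @param M ensemble size (>= 3).
#' @return Integer count.
#' @export
branchpointThreeSegmentPlacements <- function(M) {
  check_count(M, "M")
  if (M < 3) stop("M must be at least 3")
  as.integer((M - 1) * (M - 2) / 2)
}

#' Within-segment ensemble likelihood on a tree
#'
#' Likelihood of an (M, m, g) ensemble lying within segment x of a branched
#' tree, with the remaining inputs distributed over the whole tree. Gap
#' zones extend across open segment ends onto the adjacent segments;
#' \code{gapExtension = "recursive"} (default) distributes any residual gap
#' over all segments reachable beyond, while \code{"upper_bound"} stops at
#' the directly adjacent segments and flags the returned value as an upper
#' estimate when they are shorter than the gap.
#'
#' @param tree a \code{\linkS4class{DendriteTree}}.
#' @param x segment index.
#' @param M,m,g ensemble type parameters.
#' @param gapExtension \code{"recursive"} or \code{"upper_bound"}.
#' @return A \code{\linkS4class{LikelihoodValue}}.
#' @export
segmentEnsembleProbabilityTree <- function(tree, x, M, m, g,
                                           gapExtension = c("recursive",
                                                            "upper_bound")) {
  gapExtension <- match.arg(gapExtension)
  stopifnot(is(tree, "DendriteTree"))
  if (x < 1 || x > nSegments(tree)) stop("no such segment: ", x)
  check_count(M, "M"); check_count(m, "m"); check_count(g, "g")
  if (m < 2 || m > M) stop("need 2 <= m <= M")
  tt <- treeTotals(tree)
  if (m > tt["n"]) stop("m must not exceed the total input count")
  pl <- segment_placements(tree, x, M, g, gapExtension)
  r <- placements_numerator(pl, tt["N"], tt["n"], M, m)
  lk_new(r$num, bi_choose(tt["N"], tt["n"]), upperBound = r$truncated)
}

#' Branch-point ensemble likelihood
#'
#' Likelihood of an (M, m, g) ensemble spanning two or all three segments at
#' the bifurcation where segments y and z arise from segment x. Two-arm
#' spans require both far ends labeled, three-arm spans all three (so the
#' three-segment term vanishes for m = 2); each arm is delimited by a gap on
#' its segment, and the third segment carries a gap from the branch point
#' even when unoccupied.
#'
#' @inheritParams segmentEnsembleProbabilityTree
#' @param bp row of \code{\link{branchPoints}} or the parent segment index.
#' @return A \code{\linkS4class{LikelihoodValue}}.
#' @export
branchpointEnsembleProbability <- function(tree, bp, M, m, g,
                                           gapExtension = c("recursive",
                                                            "upper_bound")) {
  gapExtension <- match.arg(gapExtension)
  stopifnot(is(tree, "DendriteTree"))
  bps <- branchPoints(tree)
  if (is.data.frame(bp)) bp <- bp$x[1]
  row <- which(bps$x == bp)
  if (!length(row)) stop("segment ", bp, " is not a branch point")
  check_count(M, "M"); check_count(m, "m"); check_count(g, "g")
  if (m < 2 || m > M) stop("need 2 <= m <= M")
  tt <- treeTotals(tree)
  pl <- branchpoint_placements(tree, bps$x[row], bps$y[row], bps$z[row],
                               M, g, gapExtension)
  r <- placements_numerator(pl, tt["N"], tt["n"], M, m)
  lk_new(r$num, bi_choose(tt["N"], tt["n"]), upperBound = r$truncated)
}

#' Tree-wide ensemble likelihood
#'
#' Likelihood of finding an (M, m, g) ensemble anywhere on the tree: the sum
#' of the within-segment likelihoods over all segments and of the
#' branch-point likelihoods over all bifurcations.
#'
#' @inheritParams segmentEnsembleProbabilityTree
#' @return A \code{\linkS4class{LikelihoodValue}}.
#' @export
treeEnsembleProbability <- function(tree, M, m, g,
                                    gapExtension = c("recursive",
                                                     "upper_bound")) {
  gapExtension <- match.arg(gapExtension)
  stopifnot(is(tree, "DendriteTree"))
  check_count(M, "M"); check_count(m, "m"); check_count(g, "g")
  if (m < 2 || m > M) stop("need 2 <= m <= M")
  tt <- treeTotals(tree)
  pl <- tree_placements(tree, M, g, gapExtension)
  r <- placements_numerator(pl, tt["N"], tt["n"], M, m)
  lk_new(r$num, bi_choose(tt["N"], tt["n"]), upperBound = r$truncated)
}

#' Tree-wide specific ensemble likelihood
#'
#' SEL of the ensemble type (M spines, at least m labeled, gap g) on a
#' branched tree: \code{\link{treeEnsembleProbability}} summed over
#' m, m + 1, ..., min(n_tot, M) inputs.
#'
#' @inheritParams segmentEnsembleProbabilityTree
#' @return A \code{\linkS4class{LikelihoodValue}}.
#' @export
treeSpecificEnsembleLikelihood <- function(tree, M, m, g,
                                           gapExtension = c("recursive",
                                                            "upper_bound")) {
  gapExtension <- match.arg(gapExtension)
  stopifnot(is(tree, "DendriteTree"))
  check_count(M, "M"); check_count(m, "m"); check_count(g, "g")
  tt <- treeTotals(tree)
  if (m > min(tt["n"], M)) stop("m must not exceed min(n_tot, M)")
  pl <- tree_placements(tree, M, g, gapExtension)
  num <- bi_new(0); truncated <- FALSE
  for (i in m:min(tt["n"], M)) {
    r <- placements_numerator(pl, tt["N"], tt["n"], M, i)
    num <- bi_add(num, r$num)
    truncated <- truncated || r$truncated
  }
  lk_new(num, bi_choose(tt["N"], tt["n"]), upperBound = truncated)
}

## printed closed forms (for validation in the test suite)
open_end_closed_form <- function(Ntot, ntot, Nx, M, m, g, nClosedEnds, nOpenEnds,
                        open_top_3g = TRUE) {
  s <- bi_new(0)
  for (i in 0:(g - 1)) {
    s <- bi_add(s, bi_mul_small(bi_choose(Ntot - M - g - i, ntot - m),
                                nClosedEnds))
    top <- if (open_top_3g) Ntot - M - 3 * g + i else Ntot - M - 2 * g + i
    s <- bi_add(s, bi_mul_small(bi_choose(top, ntot - m), nOpenEnds))
  }
  interior <- Nx - M - 2 * g + 1
  if (interior > 0)
    s <- bi_add(s, bi_mul_small(bi_choose(Ntot - M - 2 * g, ntot - m),
                                interior))
  lk_new(bi_mul(bi_choose(M - 2, m - 2), s), bi_choose(Ntot, ntot))
}

branchpoint_closed_form <- function(Ntot, ntot, M, m, g) {
  num <- bi_add(
    bi_mul_small(bi_choose(M - 2, m - 2), 3 * (M - 1)),
    bi_mul_small(bi_choose(M - 3, m - 3), (M - 1) * (M - 2) / 2))
  lk_new(bi_mul(num, bi_choose(Ntot - M - 3 * g, ntot - m)),
         bi_choose(Ntot, ntot))
}

#' Full-enumeration oracle on a tree
#'
#' Enumerates every assignment of the tree's n_tot inputs to its N_tot
#' spines, tests each against every within-segment and branch-point
#' placement of the (M, m, g) type, and returns total window counts (matched
#' exactly by the closed-form counting) and assignment hit counts.
#'
#' @inheritParams segmentEnsembleProbabilityTree
#' @param guard refuse when C(N_tot, n_tot) exceeds this.
#' @return List as in \code{\link{enumerateAssignmentsOracle}}.
#' @export
enumerateTreeOracle <- function(tree, M, m, g,
                                gapExtension = c("recursive", "upper_bound"),
                                guard = 1e6) {
  gapExtension <- match.arg(gapExtension)
  tt <- treeTotals(tree)
  Ntot <- tt[["N"]]; ntot <- tt[["n"]]
  total <- choose(Ntot, ntot)
  if (total > guard) stop("enumeration guard exceeded")
  pl <- tree_placements(tree, M, g, gapExtension)
  pl <- Filter(function(p) m >= p$delta, pl)
  windows <- 0; hits <- 0; multiples <- 0
  if (ntot >= m && length(pl)) {
    combs <- utils::combn(Ntot, ntot)
    lab <- logical(Ntot)
    for (ci in seq_len(ncol(combs))) {
      lab[] <- FALSE; lab[combs[, ci]] <- TRUE
      cnt <- 0
      for (p in pl) {
        if (!all(lab[p$ends])) next
        if (sum(lab[p$window]) != m) next
        if (any(lab[p$gaps])) next
        cnt <- cnt + 1
      }
      windows <- windows + cnt
      if (cnt >= 1) hits <- hits + 1
      if (cnt >= 2) multiples <- multiples + 1
    }
  }
  list(windows = windows, hits = hits, total = total,
       windowProbability = windows / total, hitProbability = hits / total,
       multiples = multiples)
}
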