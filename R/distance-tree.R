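## Distance-based ensemble likelihoods on branched trees.
##
## The segment windows of the single-segment treatment are extended with
## open-end gap handling (the part of a gap that does not fit on the segment
## continues, by path length, onto the segments beyond the branch point),
## and ensembles whose extent crosses a branch point are covered by explicit
## arm placements: a choice of end spine on two or all three adjacent
## segments whose summed distances from the branch point stay within l_M.
## All zones use the "exclusive" interval convention.

## spine ids within path length r beyond `end` of segment x; recursion and
## truncation as in the order-based gap machinery
gap_beyond_length <- function(tree, x, end, r, mode = "recursive") {
  ids <- integer(0); truncated <- FALSE
  if (r <= .DIST_TOL) return(list(ids = ids, truncated = FALSE))
  br <- adjacent_branches(tree, x, end)
  if (is.null(br)) return(list(ids = ids, truncated = FALSE))
  off <- seg_offsets(tree)
  for (b in br) {
    lay <- tree@segments[[b$seg]]
    L <- segmentLength(lay); p <- lay@positions
    sel <- if (b$entry == "proximal") which(p <= r + .DIST_TOL)
           else which(p >= L - r - .DIST_TOL)
    if (length(sel)) ids <- c(ids, off[b$seg] + sel)
    if (r > L + .DIST_TOL) {
      if (mode == "recursive") {
        sub <- gap_beyond_length(tree, b$seg, other_end(b$entry), r - L, mode)
        ids <- c(ids, sub$ids)
        truncated <- truncated || sub$truncated
      } else {
        truncated <- TRUE
      }
    }
  }
  list(ids = ids, truncated = truncated)
}

seg_end_open <- function(tree, x, end) {
  if (end == "distal") length(childSegments(tree, x)) > 0
  else !is.na(tree@parent[x])
}

## sliding-window zones for ensembles lying within segment x of a tree
distance_tree_segment_zones <- function(tree, x, lM, lg, mode = "recursive") {
  lay <- tree@segments[[x]]
  p <- lay@positions
  if (length(p) < 2) return(list())
  off <- seg_offsets(tree)[x]
  Lx <- segmentLength(lay); dN <- p[length(p)]
  dist_open <- seg_end_open(tree, x, "distal")
  prox_open <- seg_end_open(tree, x, "proximal")
  fit_limit <- if (dist_open) Lx else dN
  out <- list()
  for (i in seq_along(p)) {
    di <- p[i]
    if (di + lM > fit_limit + .DIST_TOL) next
    win <- which(p >= di - .DIST_TOL & p <= di + lM + .DIST_TOL)
    if (length(win) < 2) next
    gaps <- integer(0); truncated <- FALSE
    trail <- which(p >= di - lg - .DIST_TOL & p < di - .DIST_TOL)
    gaps <- c(gaps, off + trail)
    if (prox_open && di < lg - .DIST_TOL) {
      bey <- gap_beyond_length(tree, x, "proximal", lg - di, mode)
      gaps <- c(gaps, bey$ids); truncated <- truncated || bey$truncated
    }
    lead <- which(p > di + lM + .DIST_TOL & p <= di + lM + lg + .DIST_TOL)
    gaps <- c(gaps, off + lead)
    if (dist_open && di + lM + lg > Lx + .DIST_TOL) {
      bey <- gap_beyond_length(tree, x, "distal", di + lM + lg - Lx, mode)
      gaps <- c(gaps, bey$ids); truncated <- truncated || bey$truncated
    }
    out[[length(out) + 1]] <- list(
      window = off + win, Mi = length(win),
      ends = off + c(win[1], win[length(win)]), delta = 2L,
      gaps = unique(gaps), truncated = truncated)
  }
  out
}

## arm placements for ensembles crossing the branch point x -> (y, z)
distance_bp_zones <- function(tree, x, y, z, lM, lg, mode = "recursive") {
  off <- seg_offsets(tree)
  segs <- c(x, y, z)
  lays <- tree@segments[segs]
  ## distances of each spine from the branch point, per adjacent segment
  dprime <- list(
    segmentLength(lays[[1]]) - lays[[1]]@positions,   # parent: distal end
    lays[[2]]@positions,
    lays[[3]]@positions)
  ## candidate arm end spines: 0 = arm empty, otherwise local spine index
  cand <- lapply(dprime, function(d) c(0L, which(d <= lM + .DIST_TOL)))
  out <- list()
  for (ia in cand[[1]]) for (ja in cand[[2]]) for (ka in cand[[3]]) {
    arms <- c(ia, ja, ka)
    if (sum(arms > 0) < 2) next
    dv <- c(if (ia > 0) dprime[[1]][ia] else 0,
            if (ja > 0) dprime[[2]][ja] else 0,
            if (ka > 0) dprime[[3]][ka] else 0)
    if (sum(dv) > lM + .DIST_TOL) next
    window <- integer(0); ends <- integer(0)
    gaps <- integer(0); truncated <- FALSE
    ok <- TRUE
    for (s in 1:3) {
      d <- dprime[[s]]
      lay <- lays[[s]]; L <- segmentLength(lay)
      if (arms[s] > 0) {
        sel <- which(d <= dv[s] + .DIST_TOL)
        ## the chosen spine must be the farthest within the arm
        if (max(d[sel]) > d[arms[s]] + .DIST_TOL) { ok <- FALSE; break }
        window <- c(window, off[segs[s]] + sel)
        ends <- c(ends, off[segs[s]] + arms[s])
      }
      gsel <- which(d > dv[s] + .DIST_TOL & d <= dv[s] + lg + .DIST_TOL)
      gaps <- c(gaps, off[segs[s]] + gsel)
      if (dv[s] + lg > L + .DIST_TOL) {
        far <- if (s == 1) "proximal" else "distal"
        bey <- gap_beyond_length(tree, segs[s], far, dv[s] + lg - L, mode)
        gaps <- c(gaps, bey$ids); truncated <- truncated || bey$truncated
      }
    }
    if (!ok) next
    window <- unique(window)
    if (length(window) < 2) next
    out[[length(out) + 1]] <- list(
      window = window, Mi = length(window), ends = unique(ends),
      delta = sum(arms > 0), gaps = unique(setdiff(gaps, window)),
      truncated = truncated)
  }
  out
}

distance_tree_zones <- function(tree, lM, lg, mode = "recursive",
                                segments = seq_len(nSegments(tree)),
                                branchpoints = TRUE) {
  out <- list()
  for (x in segments)
    out <- c(out, distance_tree_segment_zones(tree, x, lM, lg, mode))
  if (branchpoints) {
    bp <- branchPoints(tree)
    for (r in seq_len(nrow(bp)))
      out <- c(out, distance_bp_zones(tree, bp$x[r], bp$y[r], bp$z[r],
                                      lM, lg, mode))
  }
  out
}

## exact numerator over a zone list for exactly m inputs
zones_numerator <- function(zones, Ntot, ntot, m) {
  num <- bi_new(0); truncated <- FALSE
  for (z in zones) {
    if (m < z$delta || z$Mi < m) next
    free <- Ntot - z$Mi - length(z$gaps)
    num <- bi_add(num, bi_mul(bi_choose(z$Mi - z$delta, m - z$delta),
                              bi_choose(free, ntot - m)))
    truncated <- truncated || z$truncated
  }
  list(num = num, truncated = truncated)
}

#' Distance-based within-segment likelihood on a tree
#'
#' Distance analogue of \code{\link{segmentEnsembleProbabilityTree}}: sliding
#' windows of length lM within segment x, with gap stretches that continue
#' onto the adjacent segments across open segment ends.
#'
#' @param tree a \code{\linkS4class{DendriteTree}}.
#' @param x segment index.
#' @param lM,m,lg ensemble type (length um, inputs, gap length um).
#' @param gapExtension \code{"recursive"} or \code{"upper_bound"}.
#' @return A \code{\linkS4class{LikelihoodValue}}.
#' @export
segmentProbabilityDistanceTree <- function(tree, x, lM, m, lg,
                                           gapExtension = c("recursive",
                                                            "upper_bound")) {
  gapExtension <- match.arg(gapExtension)
  stopifnot(is(tree, "DendriteTree"))
  if (x < 1 || x > nSegments(tree)) stop("no such segment: ", x)
  if (m < 2) stop("m must be at least 2")
  tt <- treeTotals(tree)
  zones <- distance_tree_segment_zones(tree, x, lM, lg, gapExtension)
  r <- zones_numerator(zones, tt[["N"]], tt[["n"]], m)
  lk_new(r$num, bi_choose(tt[["N"]], tt[["n"]]), upperBound = r$truncated)
}

#' Distance-based branch-point likelihood
#'
#' Likelihood of an ensemble crossing the bifurcation where segments y and z
#' arise from segment x: arm end spines are chosen on two or all three
#' segments with summed branch-point distances within lM; the arm ends must
#' be labeled (two or three of them), and each segment carries a gap of
#' length lg beyond its arm.
#'
#' @inheritParams segmentProbabilityDistanceTree
#' @param bp parent segment index of the bifurcation.
#' @return A \code{\linkS4class{LikelihoodValue}}.
#' @export
branchpointProbabilityDistance <- function(tree, bp, lM, m, lg,
                                           gapExtension = c("recursive",
                                                            "upper_bound")) {
  gapExtension <- match.arg(gapExtension)
  stopifnot(is(tree, "DendriteTree"))
  bps <- branchPoints(tree)
  row <- which(bps$x == bp)
  if (!length(row)) stop("segment ", bp, " is not a branch point")
  if (m < 2) stop("m must be at least 2")
  tt <- treeTotals(tree)
  zones <- distance_bp_zones(tree, bps$x[row], bps$y[row], bps$z[row],
                             lM, lg, gapExtension)
  r <- zones_numerator(zones, tt[["N"]], tt[["n"]], m)
  lk_new(r$num, bi_choose(tt[["N"]], tt[["n"]]), upperBound = r$truncated)
}

#' Distance-based tree-wide ensemble likelihood and SEL
#'
#' Sum of the within-segment and branch-point distance likelihoods over the
#' whole tree; the SEL additionally sums over m, m + 1, ..., n_tot inputs.
#'
#' @inheritParams segmentProbabilityDistanceTree
#' @return A \code{\linkS4class{LikelihoodValue}}.
#' @export
treeProbabilityDistance <- function(tree, lM, m, lg,
                                    gapExtension = c("recursive",
                                                     "upper_bound")) {
  gapExtension <- match.arg(gapExtension)
  stopifnot(is(tree, "DendriteTree"))
  if (m < 2) stop("m must be at least 2")
  tt <- treeTotals(tree)
  zones <- distance_tree_zones(tree, lM, lg, gapExtension)
  r <- zones_numerator(zones, tt[["N"]], tt[["n"]], m)
  lk_new(r$num, bi_choose(tt[["N"]], tt[["n"]]), upperBound = r$truncated)
}

#' @rdname treeProbabilityDistance
#' @export
treeSELDistance <- function(tree, lM, m, lg,
                            gapExtension = c("recursive", "upper_bound")) {
  gapExtension <- match.arg(gapExtension)
  stopifnot(is(tree, "DendriteTree"))
  tt <- treeTotals(tree)
  if (m < 2 || m > tt[["n"]]) stop("need 2 <= m <= n_tot")
  zones <- distance_tree_zones(tree, lM, lg, gapExtension)
  num <- bi_new(0); truncated <- FALSE
  for (i in m:tt[["n"]]) {
    r <- zones_numerator(zones, tt[["N"]], tt[["n"]], i)
    num <- bi_add(num, r$num)
    truncated <- truncated || r$truncated
  }
  lk_new(num, bi_choose(tt[["N"]], tt[["n"]]), upperBound = truncated)
}

#' Full-enumeration oracle for the distance-based tree likelihood
#'
#' @inheritParams treeProbabilityDistance
#' @param guard refuse when C(N_tot, n_tot) exceeds this.
#' @return List as in \code{\link{enumerateAssignmentsOracle}}.
#' @export
enumerateDistanceTreeOracle <- function(tree, lM, m, lg,
                                        gapExtension = c("recursive",
                                                         "upper_bound"),
                                        guard = 1e6) {
  gapExtension <- match.arg(gapExtension)
  tt <- treeTotals(tree)
  Ntot <- tt[["N"]]; ntot <- tt[["n"]]
  total <- choose(Ntot, ntot)
  if (total > guard) stop("enumeration guard exceeded")
  zones <- Filter(function(z) z$Mi >= m && m >= z$delta,
                  distance_tree_zones(tree, lM, lg, gapExtension))
  windows <- 0; hits <- 0; multiples <- 0
  if (ntot >= m && length(zones)) {
    combs <- utils::combn(Ntot, ntot)
    lab <- logical(Ntot)
    for (ci in seq_len(ncol(combs))) {
      lab[] <- FALSE; lab[combs[, ci]] <- TRUE
      cnt <- 0
      for (z in zones) {
        if (!all(lab[z$ends])) next
        if (sum(lab[z$window]) != m) next
        if (any(lab[z$gaps])) next
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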