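## Distance-based ensemble likelihoods on a single segment.
##
## Spines sit at real path distances (um); an ensemble type is (l_M, m, l_g):
## ensembles of length at most l_M holding at least m labeled spines,
## delimited by gap stretches of length l_g free of the specific input. The
## likelihood slides a window of length l_M from spine to spine: the window
## starting at spine i contributes the arrangements in which spine i and the
## last spine inside the window are labeled, exactly m window spines are
## labeled, and no label falls into the flanking gap intervals.
##
## Two interval conventions are provided:
##   "exclusive" (default): windows are closed intervals, both gap intervals
##     exclude the window's own boundary spines, and a window must fit the
##     segment (d_i + l_M <= d_N). Under this convention the counting on a
##     unit-spacing layout with l_M = M - 1, l_g = g coincides exactly with
##     the order-based treatment, and the enumeration oracle reproduces it.
##   "published": the leading-gap interval is the closed interval
##     [d_i + l_M, d_i + l_M + l_g] exactly as the piecewise definitions
##     print it (so a spine sitting exactly at the window end is counted in
##     both window and gap), and the window slides across every start spine,
##     clipped at the distal segment end. This reproduces the published
##     worked-example table (see publishedWorkedExample()).

.DIST_TOL <- 1e-9

#' Spines inside a sliding ensemble window
#'
#' Number of spines in the closed window [d_i, d_i + lM], or 0 when fewer
#' than m (such windows cannot host the ensemble type and contribute
#' nothing).
#'
#' @param layout a \code{\linkS4class{SpineLayout}}.
#' @param i start spine index (1-based).
#' @param lM window length (um).
#' @param m minimum labeled spines of the type.
#' @return Integer spine count (possibly 0).
#' @export
windowSpineCount <- function(layout, i, lM, m) {
  stopifnot(is(layout, "SpineLayout"))
  p <- layout@positions
  if (i < 1 || i > length(p)) stop("spine index out of range")
  cnt <- sum(p >= p[i] - .DIST_TOL & p <= p[i] + lM + .DIST_TOL)
  if (cnt >= m) cnt else 0L
}

#' Spines inside the flanking gap intervals
#'
#' Counts of spines in the trailing gap (the lg-long stretch before the
#' window start) and in the leading gap (after the window end), truncated at
#' the segment ends per the piecewise definitions.
#'
#' @inheritParams windowSpineCount
#' @param lg gap length (um).
#' @param convention \code{"exclusive"} or \code{"published"} (see the
#'   module description above).
#' @return Named integer vector \code{c(g = ..., h = ...)}.
#' @export
gapSpineCounts <- function(layout, i, lM, lg,
                           convention = c("exclusive", "published")) {
  convention <- match.arg(convention)
  stopifnot(is(layout, "SpineLayout"))
  p <- layout@positions
  if (i < 1 || i > length(p)) stop("spine index out of range")
  di <- p[i]; dN <- p[length(p)]
  g <- sum(p >= di - lg - .DIST_TOL & p < di - .DIST_TOL)
  hi_end <- if (di + lM + lg >= dN - .DIST_TOL) dN else di + lM + lg
  h <- if (convention == "published") {
    sum(p >= di + lM - .DIST_TOL & p <= hi_end + .DIST_TOL)
  } else {
    sum(p > di + lM + .DIST_TOL & p <= hi_end + .DIST_TOL)
  }
  c(g = as.integer(g), h = as.integer(h))
}

## per-start-spine window descriptors shared by the closed form, the
## enumeration oracle and the reshuffling hit test
distance_zones <- function(layout, lM, lg,
                           convention = c("exclusive", "published")) {
  convention <- match.arg(convention)
  p <- layout@positions
  N <- length(p)
  if (!N) return(list())
  dN <- p[N]
  out <- list()
  for (i in seq_len(N)) {
    di <- p[i]
    if (convention == "exclusive" && di + lM > dN + .DIST_TOL) next
    win <- which(p >= di - .DIST_TOL & p <= di + lM + .DIST_TOL)
    if (length(win) < 2) next
    gh <- gapSpineCounts(layout, i, lM, lg, convention)
    trail <- which(p >= di - lg - .DIST_TOL & p < di - .DIST_TOL)
    hi_end <- if (di + lM + lg >= dN - .DIST_TOL) dN else di + lM + lg
    lead <- which(p > di + lM + .DIST_TOL & p <= hi_end + .DIST_TOL)
    out[[length(out) + 1]] <- list(
      start = i, window = win, Mi = length(win),
      ends = c(win[1], win[length(win)]),
      gaps = c(trail, lead),          # actual gap spines (window excluded)
      gcount = gh[["g"]], hcount = gh[["h"]])
  }
  out
}

#' Distance-based ensemble likelihood
#'
#' Probability, under uniform random assignment of the layout's n inputs to
#' its N spines, of an ensemble of length lM with exactly m inputs flanked
#' by clean gaps of length lg, summed over all admissible window start
#' spines. Each qualifying spine set has a unique leftmost labeled spine, so
#' window start positions do not double-count it.
#'
#' @param layout a \code{\linkS4class{SpineLayout}}.
#' @param lM ensemble length (um).
#' @param m labeled spines (exactly m for this probability; >= 2).
#' @param lg gap length (um); equals the nearest-neighbour criterion.
#' @param convention interval convention, see \code{\link{gapSpineCounts}}.
#' @return A \code{\linkS4class{LikelihoodValue}}.
#' @export
ensembleProbabilityDistance <- function(layout, lM, m, lg,
                                        convention = c("exclusive",
                                                       "published")) {
  convention <- match.arg(convention)
  stopifnot(is(layout, "SpineLayout"))
  if (m < 2) stop("m must be at least 2")
  if (lM <= 0 || lg <= 0) stop("lM and lg must be positive")
  N <- nSpines(layout); n <- nInputs(layout)
  if (N < 2) stop("need at least 2 spines")
  zones <- distance_zones(layout, lM, lg, convention)
  num <- bi_new(0)
  for (z in zones) {
    if (z$Mi < m) next
    free <- N - z$Mi - z$gcount - z$hcount
    num <- bi_add(num, bi_mul(bi_choose(z$Mi - 2, m - 2),
                              bi_choose(free, n - m)))
  }
  lk_new(num, bi_choose(N, n))
}

#' Distance-based specific ensemble likelihood
#'
#' SEL of the (lM, m, lg) type: \code{\link{ensembleProbabilityDistance}}
#' summed over m, m + 1, ... inputs (terms beyond the window capacity
#' vanish).
#'
#' @inheritParams ensembleProbabilityDistance
#' @return A \code{\linkS4class{LikelihoodValue}}.
#' @export
specificEnsembleLikelihoodDistance <- function(layout, lM, m, lg,
                                               convention = c("exclusive",
                                                              "published")) {
  convention <- match.arg(convention)
  stopifnot(is(layout, "SpineLayout"))
  if (m < 2) stop("m must be at least 2")
  N <- nSpines(layout); n <- nInputs(layout)
  if (m > n) stop("m must not exceed the layout's input count")
  zones <- distance_zones(layout, lM, lg, convention)
  num <- bi_new(0)
  for (i in m:n) {
    for (z in zones) {
      if (z$Mi < i) next
      free <- N - z$Mi - z$gcount - z$hcount
      num <- bi_add(num, bi_mul(bi_choose(z$Mi - 2, i - 2),
                                bi_choose(free, n - i)))
    }
  }
  lk_new(num, bi_choose(N, n))
}

#' Full-enumeration oracle for the distance-based likelihood
#'
#' Enumerates every assignment of the layout's inputs, detects qualifying
#' windows geometrically (start and last window spine labeled, exactly m
#' labels inside, gap intervals free of labels), and returns window and hit
#' counts. Applies to the \code{"exclusive"} convention, whose closed form
#' counts exactly these windows.
#'
#' @inheritParams ensembleProbabilityDistance
#' @param guard refuse when C(N, n) exceeds this.
#' @return List as in \code{\link{enumerateAssignmentsOracle}}.
#' @export
enumerateDistanceOracle <- function(layout, lM, m, lg, guard = 1e6) {
  stopifnot(is(layout, "SpineLayout"))
  N <- nSpines(layout); n <- nInputs(layout)
  total <- choose(N, n)
  if (total > guard) stop("enumeration guard exceeded")
  zones <- Filter(function(z) z$Mi >= m,
                  distance_zones(layout, lM, lg, "exclusive"))
  windows <- 0; hits <- 0; multiples <- 0
  if (n >= m && length(zones)) {
    combs <- utils::combn(N, n)
    lab <- logical(N)
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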