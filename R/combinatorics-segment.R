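## Order-based ensemble combinatorics on a single unbranched segment.
##
## Spines are counted by rank along the dendrite (the special case of uniform
## nearest-neighbour spacing); an ensemble of type (M, m, g) occupies M
## consecutive spines, its first and last spine are labeled, exactly m of its
## spines are labeled, and it is flanked on both sides by g spines free of the
## specific input (truncated where the segment ends).

#' Total number of input arrangements
#'
#' Number of ways to assign n labeled spines to N spine positions, C(N, n) —
#' the denominator of every order-based likelihood.
#'
#' @param N total spines on the segment.
#' @param n labeled spines.
#' @return Exact integer of class \code{"exactint"}.
#' @examples
#' as.numeric(totalArrangements(30, 5))  # 142506
#' @export
totalArrangements <- function(N, n) {
  check_count(N, "N"); check_count(n, "n")
  if (n > N) stop("n must not exceed N")
  bi_choose(N, n)
}

#' Packing-ratio threshold equivalent to a distance criterion
#'
#' The lowest packing ratio (labeled over total spines in an ensemble)
#' reached by m inputs spaced at the maximum distance satisfying the
#' nearest-neighbour criterion: m / (m * deltaCrit + 1). Approaches
#' 1/deltaCrit for large m, tying the packing-ratio criterion to the
#' distance criterion.
#'
#' @param m number of inputs in the ensemble (>= 1).
#' @param deltaCrit nearest-neighbour distance criterion (gap size, >= 1).
#' @return Numeric ratio in (0, 1).
#' @examples
#' packingRatioThreshold(1, 1)  # 0.5
#' @export
packingRatioThreshold <- function(m, deltaCrit) {
  if (any(m < 1) || any(deltaCrit < 1)) stop("m and deltaCrit must be >= 1")
  m / (m * deltaCrit + 1)
}

#' Maximal ensemble size for a given input count
#'
#' The largest ensemble realizable with n inputs under gap criterion g:
#' (n - 1) * g + 1 spines, reached when consecutive inputs are spaced at the
#' maximum admissible distance. Upper limit of the ensemble-size sum in the
#' overall cluster likelihood.
#'
#' @param n total inputs (>= 2).
#' @param g gap / nearest-neighbour criterion in spines (>= 1).
#' @return Integer spine count.
#' @examples
#' maxEnsembleSize(5, 2)  # 9
#' @export
maxEnsembleSize <- function(n, g) {
  check_count(n, "n"); check_count(g, "g")
  if (n < 2) stop("n must be at least 2")
  if (g < 1) stop("g must be at least 1")
  as.integer((n - 1) * g + 1)
}

#' Internal arrangements of inputs within an ensemble
#'
#' Ways to place m labeled spines in an ensemble of M spines whose first and
#' last spine must both be labeled: C(M - 2, m - 2). With \code{strict =
#' TRUE} the count is restricted to arrangements whose internal labeled
#' spines also satisfy the gap criterion (no stretch of g or more unlabeled
#' spines between consecutive inputs); the published counting does not impose
#' this restriction and \code{strict = FALSE} is the default.
#'
#' @param M ensemble size in spines.
#' @param m labeled spines in the ensemble (2 <= m <= M).
#' @param g gap criterion; only used when \code{strict = TRUE}.
#' @param strict enforce the internal nearest-neighbour criterion.
#' @return Exact integer of class \code{"exactint"}.
#' @examples
#' as.numeric(internalArrangements(6, 4))  # 6
#' @export
internalArrangements <- function(M, m, g = NULL, strict = FALSE) {
  check_count(M, "M"); check_count(m, "m")
  if (m < 2) stop("m must be at least 2: both ensemble ends must be labeled")
  if (m > M) stop("m must not exceed M")
  if (!strict) return(bi_choose(M - 2, m - 2))
  if (is.null(g)) stop("strict internal counting requires g")
  check_count(g, "g")
  ## unlabeled spines distributed over the m - 1 stretches between
  ## consecutive inputs, each stretch at most g - 1 spines long
  slots <- m - 1L
  total <- M - m
  if (total > slots * (g - 1L)) return(bi_new(0))
  ## bounded-composition count by dynamic programming (additions only,
  ## keeping every intermediate exact)
  dp <- c(list(bi_from_num(1)), rep(list(bi_new(0)), total))
  for (s in seq_len(slots)) {
    ndp <- rep(list(bi_new(0)), total + 1L)
    for (j in 0:total) {
      if (bi_is_zero(dp[[j + 1L]])) next
      for (add in 0:min(g - 1L, total - j)) {
        ndp[[j + add + 1L]] <- bi_add(ndp[[j + add + 1L]], dp[[j + 1L]])
      }
    }
    dp <- ndp
  }
  dp[[total + 1L]]
}

## Placement sum over ensemble start positions: for each placement the
## leading/trailing gap is truncated by the segment end, and the remaining
## n - m inputs are assigned to the spines outside ensemble and gaps. Equals
## the two-term closed form (end-correction sum plus interior term) whenever
## N - M >= 2 g, and remains correct for shorter segments, where the closed
## form's impossible-coefficient convention undercounts.
external_count <- function(N, n, M, m, g) {
  total <- bi_new(0)
  if (M > N) return(total)
  for (s in 0:(N - M)) {            # spines before the ensemble
    after <- N - M - s
    free <- max(0, s - g) + max(0, after - g)
    total <- bi_add(total, bi_choose(free, n - m))
  }
  total
}

## the closed form as printed (valid for N - M >= 2 g); kept for tests
external_count_closed <- function(N, n, M, m, g) {
  total <- bi_new(0)
  if (g > 0) {
    for (i in 0:(g - 1)) {
      total <- bi_add(total, bi_mul_small(bi_choose(N - M - g - i, n - m), 2))
    }
  }
  interior <- N - M - 2 * g + 1
  if (interior > 0) {
    total <- bi_add(total,
                    bi_mul_small(bi_choose(N - M - 2 * g, n - m), interior))
  }
  total
}

#' Arrangements of the remaining inputs outside an ensemble
#'
#' For every admissible position of an (M, m, g) ensemble on a segment of N
#' spines, counts the assignments of the remaining n - m inputs to the spines
#' outside ensemble and flanking gaps; gaps are truncated where the segment
#' ends. The total over all positions is returned.
#'
#' @param N,n segment totals (spines, labeled spines).
#' @param M,m ensemble size and labeled count.
#' @param g flanking gap in spines (g = 0 gives the naive placement count
#'   (N - M + 1) * C(N - M, n - m)).
#' @return Exact integer of class \code{"exactint"}.
#' @examples
#' as.numeric(externalArrangements(30, 5, 6, 5, 2))
#' @export
externalArrangements <- function(N, n, M, m, g) {
  check_count(N, "N"); check_count(n, "n")
  check_count(M, "M"); check_count(m, "m")
  check_count(g, "g", min = 0)
  if (M > N) stop("M must not exceed N")
  if (m > n) stop("m must not exceed n")
  external_count(N, n, M, m, g)
}

#' Likelihood of a specific ensemble arrangement
#'
#' Probability, under uniform random assignment of n inputs to N spines, of
#' observing an ensemble of M spines containing exactly m inputs with
#' flanking gaps of g spines: internal times external arrangements over the
#' total C(N, n). Arrangements containing two disjoint ensembles of the
#' identical type are counted once per ensemble (see the package vignette for
#' the disclosed overcount; it cannot occur when 2 m > n).
#'
#' @inheritParams externalArrangements
#' @param strict restrict internal arrangements to those satisfying the gap
#'   criterion inside the ensemble (not part of the published counting).
#' @return A \code{\linkS4class{LikelihoodValue}}.
#' @examples
#' likelihoodValue(ensembleProbability(30, 5, 5, 5, 2))  # 1.8e-4
#' @export
ensembleProbability <- function(N, n, M, m, g, strict = FALSE) {
  check_count(N, "N"); check_count(n, "n")
  check_count(M, "M"); check_count(m, "m"); check_count(g, "g", min = 0)
  if (n > N) stop("n must not exceed N")
  if (M > N) stop("M must not exceed N")
  if (m > n) stop("m must not exceed n")
  if (m < 2) stop("m must be at least 2")
  if (m > M) stop("m must not exceed M")
  num <- bi_mul(internalArrangements(M, m, g, strict = strict),
                external_count(N, n, M, m, g))
  lk_new(num, bi_choose(N, n))
}

#' Specific ensemble likelihood (SEL)
#'
#' Likelihood of the ensemble type (M spines, at least m of them labeled,
#' gap g): the sum of \code{\link{ensembleProbability}} over m, m + 1, ...,
#' min(n, M) inputs. Non-increasing in m for fixed N, n, M, g.
#'
#' @inheritParams ensembleProbability
#' @return A \code{\linkS4class{LikelihoodValue}}.
#' @examples
#' likelihoodValue(specificEnsembleLikelihood(30, 5, 9, 5, 2))
#' @export
specificEnsembleLikelihood <- function(N, n, M, m, g, strict = FALSE) {
  check_count(N, "N"); check_count(n, "n")
  check_count(M, "M"); check_count(m, "m"); check_count(g, "g", min = 0)
  if (n > N) stop("n must not exceed N")
  if (m < 2) stop("m must be at least 2")
  if (m > min(n, M)) stop("m must not exceed min(n, M)")
  num <- bi_new(0)
  for (i in m:min(n, M)) {
    num <- bi_add(num, bi_mul(internalArrangements(M, i, g, strict = strict),
                              external_count(N, n, M, i, g)))
  }
  lk_new(num, bi_choose(N, n))
}

## ---- full-enumeration oracle -------------------------------------------

## For one arrangement (sorted labeled positions p on spines 1..N), find all
## qualifying ensemble windows: every labeled pair (p[i], p[j]), i < j, spans
## a window of M = p[j] - p[i] + 1 spines with m = j - i + 1 inputs; the
## window qualifies when no other input lies within g spines of either end.
## Optionally windows must also satisfy the internal gap criterion.
arrangement_windows <- function(p, N, g, strict = FALSE) {
  k <- length(p)
  if (k < 2) return(NULL)
  out <- NULL
  for (i in 1:(k - 1)) {
    for (j in (i + 1):k) {
      clean_left <- i == 1 || (p[i] - p[i - 1]) > g
      clean_right <- j == k || (p[j + 1] - p[j]) > g
      if (!clean_left || !clean_right) next
      if (strict && any(diff(p[i:j]) > g)) next
      out <- rbind(out, c(M = p[j] - p[i] + 1, m = j - i + 1))
    }
  }
  out
}

#' Full-enumeration oracle for order-based ensemble likelihoods
#'
#' Iterates every assignment of n inputs to N spines, detects the qualifying
#' (M, m, g) ensemble windows in each, and returns both the total window
#' count (which the closed-form counting reproduces exactly) and the number
#' of assignments containing at least one window (which differs exactly by
#' the assignments holding two disjoint same-type ensembles). Guarded
#' against runaway enumeration.
#'
#' @inheritParams ensembleProbability
#' @param guard refuse when C(N, n) exceeds this.
#' @return List with \code{windows}, \code{hits}, \code{total},
#'   \code{windowProbability} (= windows / total, the closed-form quantity),
#'   \code{hitProbability} and \code{multiples} (assignments with more than
#'   one same-type window).
#' @export
enumerateAssignmentsOracle <- function(N, n, M, m, g, strict = FALSE,
                                       guard = 1e7) {
  check_count(N, "N"); check_count(n, "n")
  total <- choose(N, n)
  if (total > guard) stop("enumeration guard exceeded: C(N, n) = ", total)
  windows <- 0; hits <- 0; multiples <- 0
  if (n >= max(2, m)) {
    combs <- utils::combn(N, n)
    for (ci in seq_len(ncol(combs))) {
      w <- arrangement_windows(combs[, ci], N, g, strict = strict)
      if (is.null(w)) next
      cnt <- sum(w[, "M"] == M & w[, "m"] == m)
      windows <- windows + cnt
      if (cnt >= 1) hits <- hits + 1
      if (cnt >= 2) multiples <- multiples + 1
    }
  }
  list(windows = windows, hits = hits, total = total,
       windowProbability = windows / total, hitProbability = hits / total,
       multiples = multiples)
}

## One-pass oracle over all (M, m) types for a given (N, n, g): returns
## matrices of window counts and hit counts indexed [M, m]. Used by the
## equivalence sweeps so each arrangement is enumerated once.
oracle_sweep <- function(N, n, g, strict = FALSE) {
  windows <- matrix(0, N, n, dimnames = list(M = 1:N, m = 1:n))
  hits <- matrix(0, N, n, dimnames = list(M = 1:N, m = 1:n))
  total <- choose(N, n)
  if (n >= 2) {
    combs <- utils::combn(N, n)
    for (ci in seq_len(ncol(combs))) {
      w <- arrangement_windows(combs[, ci], N, g, strict = strict)
      if (is.null(w)) next
      for (r in seq_len(nrow(w))) {
        windows[w[r, 1], w[r, 2]] <- windows[w[r, 1], w[r, 2]] + 1
      }
      u <- unique(w)
      for (r in seq_len(nrow(u))) {
        hits[u[r, 1], u[r, 2]] <- hits[u[r, 1], u[r, 2]] + 1
      }
    }
  }
  list(windows = windows, hits = hits, total = total)
}

## shared argument checking
check_count <- function(x, name, min = 0) {
  if (length(x) != 1L || !is.finite(x) || x != floor(x) || x < min)
    stop(sprintf("'%s' must be a single integer >= %d", name, min))
  invisible(TRUE)
}
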