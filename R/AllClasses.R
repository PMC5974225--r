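#' @import methods
NULL

#' Exact likelihood value
#'
#' An ensemble likelihood under the random-assignment null, carried as an
#' exact rational number (arrangement count over total arrangements) together
#' with its floating-point value. Probabilities of rare input arrangements are
#' far below the resolution of simulation-based estimates, which is why the
#' exact counts are retained.
#'
#' @slot value numeric ratio in [0, 1].
#' @slot numerator exact decimal digits of the qualifying-arrangement count.
#' @slot denominator exact decimal digits of the total arrangement count.
#' @slot upperBound TRUE when the value is a documented upper estimate
#'   (gap zones truncated at short adjacent segments instead of extended).
#' @export
setClass("LikelihoodValue",
  representation(value = "numeric", numerator = "character",
                 denominator = "character", upperBound = "logical"),
  prototype(value = 0, numerator = "0", denominator = "1",
            upperBound = FALSE))

setValidity("LikelihoodValue", function(object) {
  if (length(object@value) != 1L || !is.finite(object@value))
    return("value must be a single finite number")
  if (object@value < -1e-12) return("value must be non-negative")
  if (!object@upperBound && object@value > 1 + 1e-9)
    return("value above 1 for a non-upper-bound likelihood")
  TRUE
})

## internal constructor from big integers
lk_new <- function(num, den, upperBound = FALSE) {
  new("LikelihoodValue",
      value = bi_ratio(num, den),
      numerator = bi_to_string(num),
      denominator = bi_to_string(den),
      upperBound = upperBound)
}

#' @describeIn LikelihoodValue the floating-point ratio.
#' @param x,object a \code{LikelihoodValue}.
#' @export
likelihoodValue <- function(x) {
  stopifnot(is(x, "LikelihoodValue"))
  x@value
}

#' @describeIn LikelihoodValue exact numerator digits.
#' @export
numeratorCount <- function(x) x@numerator

#' @describeIn LikelihoodValue exact denominator digits.
#' @export
denominatorCount <- function(x) x@denominator

#' @describeIn LikelihoodValue TRUE when the value is an upper estimate.
#' @export
isUpperBound <- function(x) x@upperBound

setMethod("show", "LikelihoodValue", function(object) {
  cat(sprintf("LikelihoodValue: %s%s  (= %s / %s)\n",
              signif(object@value, 2),
              if (object@upperBound) " (upper bound)" else "",
              object@numerator, object@denominator))
})

#' Spine layout of one unbranched dendritic stretch
#'
#' Positions are path distances (micrometres) from the proximal (soma-side)
#' end of the segment; \code{labeled} flags the spines receiving the specific
#' presynaptic input. Order-based analyses use only the spine ranks; the
#' distance-based analyses use the positions themselves.
#'
#' @slot positions sorted non-negative numeric, one entry per spine (um).
#' @slot labeled logical, same length.
#' @slot segmentId character identifier.
#' @slot length segment length in um (at least \code{max(positions)}).
#' @export
setClass("SpineLayout",
  representation(positions = "numeric", labeled = "logical",
                 segmentId = "character", length = "numeric"))

setValidity("SpineLayout", function(object) {
  p <- object@positions
  if (length(p) != length(object@labeled))
    return("positions and labeled differ in length")
  if (length(p) && any(!is.finite(p))) return("non-finite positions")
  if (length(p) && any(p < 0)) return("negative positions")
  if (is.unsorted(p)) return("positions must be sorted")
  if (length(object@length) != 1L || !is.finite(object@length))
    return("length must be a single finite number")
  if (length(p) && object@length < max(p) - 1e-9)
    return("segment length shorter than the most distal spine")
  if (anyNA(object@labeled)) return("labeled must not contain NA")
  TRUE
})

#' @param positions,labeled,segmentId,length see slots.
#' @rdname SpineLayout-class
#' @export
SpineLayout <- function(positions, labeled, segmentId = "seg1",
                        length = NA_real_) {
  o <- order(positions)
  positions <- as.numeric(positions)[o]
  labeled <- as.logical(labeled)[o]
  if (is.na(length)) length <- if (base::length(positions)) max(positions) else 0
  new("SpineLayout", positions = positions, labeled = labeled,
      segmentId = as.character(segmentId), length = as.numeric(length))
}

#' Evenly spaced layout for order-based analysis
#'
#' Places \code{N} spines at unit spacing and labels the spines in
#' \code{labeledIdx}. This is the geometry under which the distance-based
#' treatment coincides with the order-based one.
#'
#' @param N spine count.
#' @param labeledIdx integer indices of labeled spines.
#' @param segmentId identifier.
#' @return A \code{\linkS4class{SpineLayout}}.
#' @export
uniformLayout <- function(N, labeledIdx = integer(0), segmentId = "seg1") {
  lab <- logical(N)
  lab[labeledIdx] <- TRUE
  SpineLayout(seq_len(N) - 1, lab, segmentId = segmentId)
}

#' @describeIn SpineLayout-class number of spines.
#' @param x,object a \code{SpineLayout}.
#' @export
nSpines <- function(x) length(x@positions)

#' @describeIn SpineLayout-class number of labeled spines.
#' @export
nInputs <- function(x) sum(x@labeled)

#' @describeIn SpineLayout-class spine positions (um from proximal end).
#' @export
spinePositions <- function(x) x@positions

#' @describeIn SpineLayout-class logical vector of input labels.
#' @export
inputLabels <- function(x) x@labeled

#' @describeIn SpineLayout-class segment length in um.
#' @export
segmentLength <- function(x) x@length

setMethod("show", "SpineLayout", function(object) {
  cat(sprintf("SpineLayout '%s': %d spines (%d labeled) on %.3g um\n",
              object@segmentId, nSpines(object), nInputs(object),
              object@length))
})

#' Branched dendritic tree of spine layouts
#'
#' Segments wired by a parent relation into a rooted tree. The proximal end
#' of the root segment is the soma; a branch point exists at the distal end
#' of every segment with two children. Segment ends with no spines beyond
#' them (the soma end and distal tips) are \emph{closed}; ends at branch
#' points are \emph{open} and gap zones extend across them.
#'
#' @slot segments list of \code{\linkS4class{SpineLayout}}.
#' @slot parent integer, parent segment index per segment (NA for the root).
#' @slot rootClosed classification of the root's proximal end; with no
#'   segments beyond the root this only affects bookkeeping, not counts.
#' @export
setClass("DendriteTree",
  representation(segments = "list", parent = "integer",
                 rootClosed = "logical"))

setValidity("DendriteTree", function(object) {
  segs <- object@segments
  if (!all(vapply(segs, is, TRUE, "SpineLayout")))
    return("segments must be SpineLayout objects")
  p <- object@parent
  if (length(p) != length(segs)) return("parent length mismatch")
  if (sum(is.na(p)) != 1L) return("exactly one root segment required")
  ok <- is.na(p) | (p >= 1 & p <= length(segs))
  if (!all(ok)) return("parent indices out of range")
  ## acyclic: walking up from each node must reach the root
  for (i in seq_along(p)) {
    seen <- logical(length(p)); j <- i
    while (!is.na(p[j])) {
      if (seen[j]) return("cycle in parent relation")
      seen[j] <- TRUE; j <- p[j]
    }
  }
  nchild <- tabulate(p[!is.na(p)], nbins = length(segs))
  if (any(nchild > 2))
    return("branch points of degree > 3 are not supported (bifurcations only)")
  TRUE
})

#' @param segments,parent,rootClosed see slots.
#' @rdname DendriteTree-class
#' @export
DendriteTree <- function(segments, parent, rootClosed = TRUE) {
  if (is(segments, "SpineLayout")) segments <- list(segments)
  new("DendriteTree", segments = segments, parent = as.integer(parent),
      rootClosed = rootClosed)
}

#' @describeIn DendriteTree-class number of segments.
#' @param x,object a \code{DendriteTree}.
#' @export
nSegments <- function(x) length(x@segments)

#' @describeIn DendriteTree-class list of segment layouts.
#' @export
treeSegments <- function(x) x@segments

#' @describeIn DendriteTree-class indices of the children of segment i.
#' @param i segment index.
#' @export
childSegments <- function(x, i) which(!is.na(x@parent) & x@parent == i)

#' Total spine and input counts of a tree
#'
#' Sums spine and labeled-spine counts over all segments.
#'
#' @param tree a \code{\linkS4class{DendriteTree}}.
#' @return Named numeric \code{c(N = ..., n = ...)}.
#' @export
treeTotals <- function(tree) {
  stopifnot(is(tree, "DendriteTree"))
  c(N = sum(vapply(tree@segments, nSpines, 0)),
    n = sum(vapply(tree@segments, nInputs, 0)))
}

#' Branch points of a tree
#'
#' @param tree a \code{\linkS4class{DendriteTree}}.
#' @return data.frame with columns \code{x} (parent segment), \code{y},
#'   \code{z} (the two children) — one row per bifurcation.
#' @export
branchPoints <- function(tree) {
  stopifnot(is(tree, "DendriteTree"))
  out <- data.frame(x = integer(0), y = integer(0), z = integer(0))
  for (i in seq_len(nSegments(tree))) {
    ch <- childSegments(tree, i)
    if (length(ch) == 2L)
      out <- rbind(out, data.frame(x = i, y = ch[1], z = ch[2]))
  }
  out
}

setMethod("show", "DendriteTree", function(object) {
  tt <- treeTotals(object)
  cat(sprintf("DendriteTree: %d segments, %d spines (%d labeled), %d branch point(s)\n",
              nSegments(object), tt["N"], tt["n"], nrow(branchPoints(object))))
})

#' Order-based ensemble type
#'
#' The (M, m, g) signature of an input ensemble: M spines in total, delimited
#' by labeled spines at both ends, m of them labeled, flanked by gaps of g
#' spines free of the specific input. The gap equals the nearest-neighbour
#' distance criterion expressed in spine counts.
#'
#' @slot M,m,g integers; m >= 2 (both ensemble ends must be labeled),
#'   m <= M, g >= 1.
#' @export
setClass("EnsembleType",
  representation(M = "integer", m = "integer", g = "integer"))

setValidity("EnsembleType", function(object) {
  if (object@m < 2L) return("m must be at least 2 (both ends labeled)")
  if (object@m > object@M) return("m must not exceed M")
  if (object@g < 1L) return("g must be at least 1")
  TRUE
})

#' @param M,m,g see slots.
#' @rdname EnsembleType-class
#' @export
EnsembleType <- function(M, m, g) {
  new("EnsembleType", M = as.integer(M), m = as.integer(m), g = as.integer(g))
}

setMethod("show", "EnsembleType", function(object) {
  cat(sprintf("EnsembleType: M = %d, m = %d, gap = %d\n",
              object@M, object@m, object@g))
})

#' Distance-based ensemble type
#'
#' The (l_M, m, l_g) signature: ensembles of length at most \code{lM} um
#' containing at least \code{m} labeled spines, delimited by gap stretches of
#' length \code{lg} um free of the specific input. The gap length equals the
#' nearest-neighbour distance criterion.
#'
#' @slot lM ensemble length (um), positive.
#' @slot m minimum labeled spines, at least 2.
#' @slot lg gap length (um), positive.
#' @export
setClass("DistanceEnsembleType",
  representation(lM = "numeric", m = "integer", lg = "numeric"))

setValidity("DistanceEnsembleType", function(object) {
  if (object@lM <= 0) return("lM must be positive")
  if (object@lg <= 0) return("lg must be positive")
  if (object@m < 2L) return("m must be at least 2")
  TRUE
})

#' @param lM,m,lg see slots.
#' @rdname DistanceEnsembleType-class
#' @export
DistanceEnsembleType <- function(lM, m, lg) {
  new("DistanceEnsembleType", lM = as.numeric(lM), m = as.integer(m),
      lg = as.numeric(lg))
}

setMethod("show", "DistanceEnsembleType", function(object) {
  cat(sprintf("DistanceEnsembleType: lM = %g um, m = %d, lg = %g um\n",
              object@lM, object@m, object@lg))
})

#' Dataset-level cluster test result
#'
#' @slot S segments/trees analyzed.
#' @slot c segments/trees containing at least one classified cluster.
#' @slot OCLmax maximum overall cluster likelihood in the data set.
#' @slot P binomial tail probability of observing at least c positives.
#' @slot rankedP tail probabilities for the sorted-OCL variant.
#' @export
setClass("DatasetTestResult",
  representation(S = "integer", c = "integer", OCLmax = "numeric",
                 P = "numeric", rankedP = "numeric"))

setValidity("DatasetTestResult", function(object) {
  if (object@c < 0 || object@c > object@S) return("need 0 <= c <= S")
  if (object@P < 0 || object@P > 1) return("P outside [0, 1]")
  if (length(object@rankedP) > object@S) return("rankedP longer than S")
  TRUE
})

setMethod("show", "DatasetTestResult", function(object) {
  cat(sprintf(
    "DatasetTestResult: %d of %d segments/trees with a cluster; OCLmax = %s; P = %s\n",
    object@c, object@S, signif(object@OCLmax, 2), signif(object@P, 3)))
})

#' Monte-Carlo reshuffling estimate
#'
#' @slot rounds reshuffling rounds performed.
#' @slot hits rounds in which the target ensemble type occurred.
#' @slot estimate hits / rounds.
#' @slot predictedCV analytic coefficient of variation of the estimate.
#' @slot seed RNG seed used.
#' @slot exact the exact likelihood when available (NA otherwise).
#' @slot zScore (estimate - exact) / (exact * predictedCV), NA without exact.
#' @export
setClass("ReshuffleResult",
  representation(rounds = "numeric", hits = "numeric", estimate = "numeric",
                 predictedCV = "numeric", seed = "integer", exact = "numeric",
                 zScore = "numeric"))

setMethod("show", "ReshuffleResult", function(object) {
  cat(sprintf(
    "ReshuffleResult: %d hits / %g rounds = %s (predicted CV %s%s)\n",
    object@hits, object@rounds, signif(object@estimate, 4),
    signif(object@predictedCV, 3),
    if (is.finite(object@exact))
      sprintf("; exact %s, z = %s", signif(object@exact, 4),
              signif(object@zScore, 3)) else ""))
})
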