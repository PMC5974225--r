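## Synthetic spine layouts with recorded ground truth.
##
## The generators emulate the two organizations of interest: uniformly
## random input placement (the null of the combinatorial analysis) and
## layouts with a planted input cluster. Spines are placed either on a
## regular grid (the order-based geometry) or as a Poisson process along
## the segment. Ground truth is attached as the "groundTruth" attribute.

#' Generate a random spine layout
#'
#' Places spines on one segment and assigns the inputs uniformly at random
#' without replacement — the null model of the analysis. Ground truth
#' records that no structure was planted.
#'
#' @param nSpines spine count (grid mode), or NULL to draw it in
#'   \code{"poisson"} mode.
#' @param nInputs labeled spines.
#' @param placement \code{"grid"} (unit spacing times \code{spacing}) or
#'   \code{"poisson"} (rate \code{rate} spines/um over \code{length} um).
#' @param spacing grid spacing in um.
#' @param rate,length Poisson intensity and segment length.
#' @param seed RNG seed.
#' @param segmentId identifier.
#' @return A \code{\linkS4class{SpineLayout}} with a \code{groundTruth}
#'   attribute.
#' @export
generateRandomLayout <- function(nSpines = NULL, nInputs,
                                 placement = c("grid", "poisson"),
                                 spacing = 1, rate = 1, length = NULL,
                                 seed = NULL, segmentId = "seg1") {
  placement <- match.arg(placement)
  if (!is.null(seed)) set.seed(seed)
  if (placement == "grid") {
    if (is.null(nSpines)) stop("grid placement needs nSpines")
    pos <- (seq_len(nSpines) - 1) * spacing
    len <- (nSpines - 1) * spacing
  } else {
    if (is.null(length)) stop("poisson placement needs a segment length")
    if (is.null(nSpines)) nSpines <- stats::rpois(1, rate * length)
    pos <- sort(stats::runif(nSpines, 0, length))
    len <- length
  }
  if (nInputs > nSpines)
    stop("infeasible: more inputs (", nInputs, ") than spines (", nSpines, ")")
  lab <- logical(nSpines)
  lab[sample.int(nSpines, nInputs)] <- TRUE
  out <- SpineLayout(pos, lab, segmentId = segmentId, length = len)
  attr(out, "groundTruth") <- list(planted = NULL)
  out
}

## random member pattern for a planted (M, m, g) cluster: ends fixed,
## consecutive member gaps at most g (so detection at deltaCrit = g
## recovers exactly this member set)
planted_member_offsets <- function(M, m, g) {
  if (M - 1 > (m - 1) * g)
    stop("unsatisfiable cluster: M exceeds (m - 1) g + 1")
  if (M < m) stop("unsatisfiable cluster: M below m")
  diffs <- rep(1L, m - 1L)
  extra <- M - 1L - sum(diffs)
  while (extra > 0) {
    i <- sample(which(diffs < g), 1)
    diffs[i] <- diffs[i] + 1L
    extra <- extra - 1L
  }
  cumsum(c(0L, diffs))
}

#' Generate a layout with a planted input cluster
#'
#' Places a cluster of the given (M, m, g) type on a unit-spacing segment:
#' m member inputs within an M-spine window, both window ends labeled and
#' consecutive members within the gap criterion, flanked by input-free gap
#' zones; the remaining inputs are placed uniformly outside cluster and
#' gaps. Ground truth lists the member spines.
#'
#' @param nSpines,nInputs segment totals.
#' @param M,m,g planted cluster type.
#' @param position window start spine (1-based), or NULL for random
#'   placement.
#' @param seed RNG seed.
#' @param segmentId identifier.
#' @return A \code{\linkS4class{SpineLayout}} with a \code{groundTruth}
#'   attribute listing \code{members}, \code{M}, \code{m}, \code{g}.
#' @export
generatePlantedClusterLayout <- function(nSpines, nInputs, M, m, g,
                                         position = NULL, seed = NULL,
                                         segmentId = "seg1") {
  if (!is.null(seed)) set.seed(seed)
  if (m > nInputs) stop("unsatisfiable: cluster needs more inputs than available")
  if (M > nSpines) stop("unsatisfiable: cluster larger than the segment")
  if (is.null(position)) {
    position <- sample.int(nSpines - M + 1, 1)
  }
  if (position < 1 || position + M - 1 > nSpines)
    stop("cluster window outside the segment")
  members <- position + planted_member_offsets(M, m, g)
  ## spines barred for the remaining inputs: window plus flanking gaps
  barred <- max(1, position - g):min(nSpines, position + M - 1 + g)
  freeSpines <- setdiff(seq_len(nSpines), barred)
  rest <- nInputs - m
  if (rest > length(freeSpines))
    stop("unsatisfiable: not enough spines outside cluster and gaps")
  lab <- logical(nSpines)
  lab[members] <- TRUE
  if (rest > 0) lab[freeSpines[sample.int(length(freeSpines), rest)]] <- TRUE
  out <- SpineLayout(seq_len(nSpines) - 1, lab, segmentId = segmentId,
                     length = nSpines - 1)
  attr(out, "groundTruth") <- list(
    planted = list(members = as.integer(members), M = as.integer(M),
                   m = as.integer(m), g = as.integer(g)))
  out
}

#' Generate a random dendritic tree layout
#'
#' Builds a tree from a parent vector, places spines per segment (grid or
#' Poisson) and assigns the inputs uniformly over all spines of the tree.
#'
#' @param parent integer parent vector (NA for the root), one entry per
#'   segment; every segment must have 0, 1 or 2 children.
#' @param nSpines integer vector of per-segment spine counts.
#' @param nInputs total labeled spines on the tree.
#' @param spacing grid spacing in um.
#' @param seed RNG seed.
#' @return A \code{\linkS4class{DendriteTree}} with a \code{groundTruth}
#'   attribute.
#' @export
generateRandomTree <- function(parent, nSpines, nInputs, spacing = 1,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(parent) == length(nSpines))
  Ntot <- sum(nSpines)
  if (nInputs > Ntot) stop("infeasible: more inputs than spines")
  lab_global <- logical(Ntot)
  lab_global[sample.int(Ntot, nInputs)] <- TRUE
  off <- c(0, cumsum(nSpines))[seq_along(nSpines)]
  segs <- lapply(seq_along(nSpines), function(i) {
    SpineLayout((seq_len(nSpines[i]) - 1) * spacing,
                lab_global[off[i] + seq_len(nSpines[i])],
                segmentId = paste0("seg", i),
                length = max(nSpines[i] - 1, 0) * spacing)
  })
  out <- DendriteTree(segs, as.integer(parent))
  attr(out, "groundTruth") <- list(planted = NULL)
  out
}
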