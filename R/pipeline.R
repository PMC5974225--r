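## Steps 2-6 of the cluster analysis workflow: specific ensemble likelihoods
## for detected ensembles, cluster classification, overall cluster
## likelihood, dataset-level binomial tests and cluster characterization.

## add LikelihoodValues sharing one exact denominator
lk_sum <- function(lks) {
  stopifnot(length(lks) >= 1)
  den <- lks[[1]]@denominator
  num <- bi_new(0); ub <- FALSE
  for (l in lks) {
    stopifnot(l@denominator == den)
    num <- bi_add(num, str_to_bi(l@numerator))
    ub <- ub || l@upperBound
  }
  lk_new(num, str_to_bi(den), upperBound = ub)
}

## parse decimal digits back into limbs (inverse of bi_to_string)
str_to_bi <- function(s) {
  d <- nchar(s)
  limbs <- numeric(0)
  while (d > 0) {
    lo <- max(1, d - 5)
    limbs <- c(limbs, as.numeric(substr(s, lo, d)))
    d <- lo - 1
  }
  bi_norm(limbs)
}

#' Specific ensemble likelihoods for detected ensembles
#'
#' Computes the SEL of every detected ensemble with at least two labeled
#' members, in the order-based (\code{mode = "order"}: M spanned spines, m
#' inputs, gap in spines) or distance-based treatment (\code{mode =
#' "distance"}: the ensemble's span as l_M, the distance criterion as l_g).
#'
#' @param ensembles detection data.frame from \code{\link{detectEnsembles}}.
#' @param x the \code{\linkS4class{SpineLayout}} or
#'   \code{\linkS4class{DendriteTree}} the ensembles were detected on.
#' @param gap gap criterion: spines (order) or um (distance).
#' @param mode \code{"order"} or \code{"distance"}.
#' @param convention interval convention for the distance mode.
#' @return The input data.frame with an added numeric \code{SEL} column
#'   (NA for singletons).
#' @export
ensembleLikelihoods <- function(ensembles, x, gap,
                                mode = c("order", "distance"),
                                convention = "exclusive") {
  mode <- match.arg(mode)
  sel <- rep(NA_real_, nrow(ensembles))
  if (is(x, "SpineLayout")) {
    N <- nSpines(x); n <- nInputs(x)
    for (r in seq_len(nrow(ensembles))) {
      if (ensembles$m[r] < 2) next
      sel[r] <- if (mode == "order") {
        likelihoodValue(specificEnsembleLikelihood(
          N, n, ensembles$M[r], ensembles$m[r], gap))
      } else {
        likelihoodValue(specificEnsembleLikelihoodDistance(
          x, max(ensembles$span[r], .DIST_TOL), ensembles$m[r], gap,
          convention = convention))
      }
    }
  } else if (is(x, "DendriteTree")) {
    for (r in seq_len(nrow(ensembles))) {
      if (ensembles$m[r] < 2) next
      sel[r] <- if (mode == "order") {
        likelihoodValue(treeSpecificEnsembleLikelihood(
          x, ensembles$M[r], ensembles$m[r], gap))
      } else {
        likelihoodValue(treeSELDistance(
          x, max(ensembles$span[r], .DIST_TOL), ensembles$m[r], gap))
      }
    }
  } else stop("x must be a SpineLayout or DendriteTree")
  ensembles$SEL <- sel
  ensembles
}

#' Step 3: classify ensembles as clusters
#'
#' An ensemble is classified as a cluster when its specific ensemble
#' likelihood is at or below \code{selThreshold}, it contains at least
#' \code{minInputs} inputs, and (optionally) it does not encompass the
#' whole segment: ensembles with N >= M >= N - 2 g and m = n (or the
#' distance analogue with spans) are apparent clusters forced by the
#' segment borders and are excluded. Ensembles whose SEL sits exactly at
#' the threshold are flagged in \code{atThreshold}.
#'
#' @param ensembles data.frame with an \code{SEL} column
#'   (\code{\link{ensembleLikelihoods}}).
#' @param x the layout or tree analyzed.
#' @param gap gap criterion used (spines or um, per mode).
#' @param selThreshold upper SEL threshold (default 1 percent).
#' @param minInputs minimum inputs for a cluster.
#' @param excludeWholeSegment drop whole-segment ensembles.
#' @param mode \code{"order"} or \code{"distance"}.
#' @return The data.frame with logical \code{cluster}, \code{atThreshold}
#'   and character \code{exclusionReason} columns.
#' @export
classifyClusters <- function(ensembles, x, gap, selThreshold = 0.01,
                             minInputs = 2, excludeWholeSegment = TRUE,
                             mode = c("order", "distance")) {
  mode <- match.arg(mode)
  n_tot <- if (is(x, "SpineLayout")) nInputs(x) else treeTotals(x)[["n"]]
  cluster <- logical(nrow(ensembles))
  reason <- character(nrow(ensembles))
  at <- logical(nrow(ensembles))
  for (r in seq_len(nrow(ensembles))) {
    s <- ensembles$SEL[r]
    if (is.na(s)) { reason[r] <- "single input"; next }
    at[r] <- isTRUE(all.equal(s, selThreshold, tolerance = 1e-9))
    if (s > selThreshold + 1e-12) { reason[r] <- "SEL above threshold"; next }
    if (ensembles$m[r] < minInputs) { reason[r] <- "too few inputs"; next }
    if (excludeWholeSegment && is(x, "SpineLayout")) {
      whole <- if (mode == "order") {
        N <- nSpines(x)
        N >= ensembles$M[r] && ensembles$M[r] >= N - 2 * gap &&
          ensembles$m[r] == n_tot
      } else {
        ext <- diff(range(spinePositions(x)))
        ext >= ensembles$span[r] - .DIST_TOL &&
          ensembles$span[r] >= ext - 2 * gap - .DIST_TOL &&
          ensembles$m[r] == n_tot
      }
      if (whole) { reason[r] <- "encompasses whole segment"; next }
    }
    cluster[r] <- TRUE
  }
  ensembles$cluster <- cluster
  ensembles$atThreshold <- at
  ensembles$exclusionReason <- reason
  ensembles
}

## delta rule of the overall cluster likelihood: among the types of one
## ensemble size, keep only the smallest input count whose SEL is at or
## below the reference SEL
ocl_pick <- function(sel_by_m, refVal) {
  for (m in seq_along(sel_by_m)) {
    if (!is.null(sel_by_m[[m]]) &&
        likelihoodValue(sel_by_m[[m]]) <= refVal + 1e-12) return(m)
  }
  NULL
}

#' Step 4: overall cluster likelihood (order-based segment)
#'
#' Likelihood of observing any ensemble type at least as unlikely as the
#' reference cluster (refM, refm) on a segment of N spines with n inputs:
#' for every ensemble size M = 2 ... (n-1) g + 1 the SEL of the smallest
#' input count whose SEL is at or below SEL(refM, refm) is added (each
#' arrangement counted once per size, since for fixed M the SEL of larger m
#' is contained in that of smaller m).
#'
#' @param N,n,g segment totals and gap criterion.
#' @param refM,refm reference cluster type.
#' @return A \code{\linkS4class{LikelihoodValue}}.
#' @examples
#' likelihoodValue(overallClusterLikelihood(30, 5, 2, 5, 4))
#' @export
overallClusterLikelihood <- function(N, n, g, refM, refm) {
  refSEL <- specificEnsembleLikelihood(N, n, refM, refm, g)
  refVal <- likelihoodValue(refSEL)
  terms <- list()
  for (M in 2:maxEnsembleSize(n, g)) {
    sel_by_m <- vector("list", min(n, M))
    for (m in 2:min(n, M))
      sel_by_m[[m]] <- specificEnsembleLikelihood(N, n, M, m, g)
    pick <- ocl_pick(sel_by_m, refVal)
    if (!is.null(pick)) terms[[length(terms) + 1]] <- sel_by_m[[pick]]
  }
  if (!length(terms)) stop("reference type qualifies no ensemble size")
  lk_sum(terms)
}

#' Overall cluster likelihood on a tree (order-based)
#'
#' @param tree a \code{\linkS4class{DendriteTree}}.
#' @inheritParams overallClusterLikelihood
#' @return A \code{\linkS4class{LikelihoodValue}}.
#' @export
overallClusterLikelihoodTree <- function(tree, g, refM, refm) {
  tt <- treeTotals(tree)
  refVal <- likelihoodValue(treeSpecificEnsembleLikelihood(tree, refM, refm, g))
  terms <- list()
  for (M in 2:maxEnsembleSize(tt[["n"]], g)) {
    sel_by_m <- vector("list", min(tt[["n"]], M))
    for (m in 2:min(tt[["n"]], M))
      sel_by_m[[m]] <- treeSpecificEnsembleLikelihood(tree, M, m, g)
    pick <- ocl_pick(sel_by_m, refVal)
    if (!is.null(pick)) terms[[length(terms) + 1]] <- sel_by_m[[pick]]
  }
  if (!length(terms)) stop("reference type qualifies no ensemble size")
  lk_sum(terms)
}

#' Overall cluster likelihood (distance-based)
#'
#' Distance analogue of \code{\link{overallClusterLikelihood}}: the outer
#' sum runs over candidate ensemble lengths generated from the pairwise
#' spine spans of the layout (every realizable ensemble length is a span
#' between two spines), de-duplicated by the window sets they produce so
#' that a set of spines in an interval satisfying several lengths is
#' counted once; lengths are capped at (n - 1) l_g, the largest admissible
#' ensemble extent.
#'
#' @param layout a \code{\linkS4class{SpineLayout}}.
#' @param lg gap length (um).
#' @param refLM,refm reference cluster (length um, inputs).
#' @param convention interval convention.
#' @return A \code{\linkS4class{LikelihoodValue}}.
#' @export
overallClusterLikelihoodDistance <- function(layout, lg, refLM, refm,
                                             convention = "exclusive") {
  stopifnot(is(layout, "SpineLayout"))
  n <- nInputs(layout)
  refVal <- likelihoodValue(specificEnsembleLikelihoodDistance(
    layout, refLM, refm, lg, convention = convention))
  p <- spinePositions(layout)
  spans <- unique(round(as.numeric(stats::dist(p)), 9))
  spans <- sort(spans[spans > .DIST_TOL & spans <= (n - 1) * lg + .DIST_TOL])
  ## de-duplicate candidate lengths by the window sets they generate
  seen <- character(0); terms <- list()
  for (lM in spans) {
    zones <- distance_zones(layout, lM, lg, convention)
    sig <- paste(vapply(zones, function(z)
      paste(z$window, collapse = ","), ""), collapse = ";")
    if (sig %in% seen) next
    seen <- c(seen, sig)
    sel_by_m <- vector("list", n)
    for (m in 2:n)
      sel_by_m[[m]] <- specificEnsembleLikelihoodDistance(
        layout, lM, m, lg, convention = convention)
    pick <- ocl_pick(sel_by_m, refVal)
    if (!is.null(pick)) terms[[length(terms) + 1]] <- sel_by_m[[pick]]
  }
  if (!length(terms)) stop("reference type qualifies no ensemble length")
  lk_sum(terms)
}

#' Step 5: binomial test on the number of segments with a cluster
#'
#' Probability of observing at least c segments/trees containing a cluster
#' among S analyzed, when each contains one with probability OCLmax (the
#' maximum overall cluster likelihood of the data set): the binomial tail
#' sum. This is the P value of the test that the number of segments with a
#' cluster arises from a random input distribution.
#'
#' @param S segments/trees analyzed.
#' @param c segments/trees containing at least one cluster.
#' @param OCLmax maximum overall cluster likelihood, in [0, 1].
#' @param oclValues optional vector of per-segment OCL values; when given,
#'   the sorted-OCL tail probabilities (\code{\link{rankedClusterTest}})
#'   are included in the result.
#' @return A \code{\linkS4class{DatasetTestResult}}.
#' @examples
#' datasetClusterTest(10, 2, 0.025)
#' @export
datasetClusterTest <- function(S, c, OCLmax, oclValues = numeric(0)) {
  check_count(S, "S"); check_count(c, "c")
  if (c > S) stop("c must not exceed S")
  if (OCLmax < 0 || OCLmax > 1) stop("OCLmax must lie in [0, 1]")
  P <- stats::pbinom(c - 1, S, OCLmax, lower.tail = FALSE)
  ranked <- if (length(oclValues)) rankedClusterTest(oclValues, S) else numeric(0)
  new("DatasetTestResult", S = as.integer(S), c = as.integer(c),
      OCLmax = OCLmax, P = P, rankedP = ranked)
}

#' Sorted-OCL variant of the dataset test
#'
#' For heterogeneous overall cluster likelihoods: the OCL values are sorted
#' ascending and, for every c, the probability of at least c segments with
#' a cluster of OCL at most the c-th value is computed. Plotting these
#' against c shows how many segments with a cluster lie below the
#' significance level.
#'
#' @param oclValues per-segment OCL values sorted in ascending order.
#' @param S total segments/trees analyzed (at least
#'   \code{length(oclValues)}).
#' @return Numeric vector of tail probabilities, one per c.
#' @export
rankedClusterTest <- function(oclValues, S) {
  check_count(S, "S")
  if (length(oclValues) > S) stop("more OCL values than segments")
  if (is.unsorted(oclValues)) stop("oclValues must be sorted ascending")
  if (length(oclValues) && (min(oclValues) < 0 || max(oclValues) > 1))
    stop("OCL values must lie in [0, 1]")
  vapply(seq_along(oclValues), function(c)
    stats::pbinom(c - 1, S, oclValues[c], lower.tail = FALSE), 0)
}

#' Step 6: characterize classified clusters
#'
#' Reports, for every cluster row, the input count, total spines, dendritic
#' span between the outermost inputs, distance of the cluster midpoint from
#' the soma, spine density inside versus outside the cluster and the
#' packing ratio.
#'
#' @param clusters classified data.frame (rows with \code{cluster = TRUE}
#'   are characterized).
#' @param x the \code{\linkS4class{SpineLayout}} or
#'   \code{\linkS4class{DendriteTree}} analyzed.
#' @return data.frame with one row per cluster.
#' @export
characterizeClusters <- function(clusters, x) {
  rows <- which(clusters$cluster)
  if (is(x, "SpineLayout")) {
    L <- segmentLength(x); N <- nSpines(x)
  } else {
    L <- sum(vapply(x@segments, segmentLength, 0))
    N <- treeTotals(x)[["N"]]
  }
  out <- lapply(rows, function(r) {
    span <- clusters$span[r]
    M <- clusters$M[r]
    data.frame(
      segmentId = clusters$segmentId[r],
      inputs = clusters$m[r],
      totalSpines = M,
      span = span,
      distanceFromSoma = (clusters$firstPos[r] + clusters$lastPos[r]) / 2,
      insideDensity = if (span > 0) M / span else NA_real_,
      outsideDensity = if (L - span > 0) (N - M) / (L - span) else NA_real_,
      packingRatio = clusters$m[r] / M)
  })
  if (!length(out)) return(data.frame(
    segmentId = character(0), inputs = integer(0), totalSpines = integer(0),
    span = numeric(0), distanceFromSoma = numeric(0),
    insideDensity = numeric(0), outsideDensity = numeric(0),
    packingRatio = numeric(0)))
  do.call(rbind, out)
}

#' Run the full cluster analysis on one segment or tree
#'
#' Steps 1-4 in one call: detection under the nearest-neighbour criterion,
#' SEL computation, cluster classification, and the overall cluster
#' likelihood of the most significant cluster (reference cluster = lowest
#' SEL among the classified clusters).
#'
#' @param x a \code{\linkS4class{SpineLayout}} or
#'   \code{\linkS4class{DendriteTree}}.
#' @param deltaCrit nearest-neighbour criterion (spines for order mode at
#'   unit spacing, um otherwise).
#' @param mode \code{"order"} or \code{"distance"}.
#' @param selThreshold,minInputs,excludeWholeSegment see
#'   \code{\link{classifyClusters}}.
#' @param convention interval convention for the distance mode.
#' @return List with \code{ensembles} (annotated data.frame), \code{ocl}
#'   (\code{\linkS4class{LikelihoodValue}} or NULL when no cluster) and
#'   \code{characterization}.
#' @export
analyzeClusters <- function(x, deltaCrit, mode = c("order", "distance"),
                            selThreshold = 0.01, minInputs = 2,
                            excludeWholeSegment = TRUE,
                            convention = "exclusive") {
  mode <- match.arg(mode)
  ens <- detectEnsembles(x, "nn_distance", deltaCrit = deltaCrit)
  ens <- ensembleLikelihoods(ens, x, deltaCrit, mode = mode,
                             convention = convention)
  ens <- classifyClusters(ens, x, deltaCrit, selThreshold = selThreshold,
                          minInputs = minInputs,
                          excludeWholeSegment = excludeWholeSegment,
                          mode = mode)
  ocl <- NULL
  cl <- which(ens$cluster)
  if (length(cl)) {
    ref <- cl[which.min(ens$SEL[cl])]
    ocl <- if (is(x, "SpineLayout")) {
      if (mode == "order") {
        overallClusterLikelihood(nSpines(x), nInputs(x), deltaCrit,
                                 ens$M[ref], ens$m[ref])
      } else {
        overallClusterLikelihoodDistance(x, deltaCrit,
                                         max(ens$span[ref], .DIST_TOL),
                                         ens$m[ref],
                                         convention = convention)
      }
    } else {
      if (mode == "order") {
        overallClusterLikelihoodTree(x, deltaCrit, ens$M[ref], ens$m[ref])
      } else {
        stop("tree-wide distance OCL: compute per reference via treeSELDistance")
      }
    }
  }
  list(ensembles = ens, ocl = ocl,
       characterization = characterizeClusters(ens, x))
}

#' Write analysis results as TSV / JSON reports
#'
#' \code{writeClusterTable} writes one row per ensemble (location, M, m,
#' span, SEL, cluster flag) as TSV, with probabilities both at full
#' precision and rounded to the 2-significant-figure display convention;
#' \code{writeDatasetReport} writes the dataset-level quantities (S, c,
#' OCLmax, P, ranked P values) as JSON.
#'
#' @param ensembles annotated data.frame.
#' @param result a \code{\linkS4class{DatasetTestResult}}.
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeClusterTable <- function(ensembles, path) {
  df <- ensembles
  df$members <- vapply(df$members, paste, "", collapse = ",")
  if (!is.null(df$SEL)) df$SEL_display <- signif(df$SEL, 2)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeClusterTable
#' @export
writeDatasetReport <- function(result, path) {
  stopifnot(is(result, "DatasetTestResult"))
  jsonlite::write_json(
    list(S = result@S, c = result@c, OCLmax = result@OCLmax,
         OCLmax_display = signif(result@OCLmax, 2), P = result@P,
         rankedP = result@rankedP),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
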