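## Step 1: detection of input ensembles.
##
## Criteria: (i) "continuous" runs of directly neighbouring labeled spines;
## (ii) nearest-neighbour distance: maximal groups in which every labeled
## spine is within deltaCrit of its nearest labeled neighbour; (iii) packing
## ratio: maximal stretches whose labeled/total spine ratio stays at or
## above prCrit. Criterion (ii) is the working criterion of the analysis;
## ensembles are delimited by labeled spines at both ends and are maximal
## and non-overlapping within a criterion.

#' Detect input ensembles
#'
#' Finds the maximal input ensembles of a spine layout or dendritic tree
#' under one of the three spatial criteria. Distances are path lengths in
#' the units of the spine positions; for order-based analysis place spines
#' at unit spacing (\code{\link{uniformLayout}}) and give \code{deltaCrit}
#' as the gap criterion in spines.
#'
#' @param x a \code{\linkS4class{SpineLayout}} or
#'   \code{\linkS4class{DendriteTree}}.
#' @param criterion \code{"nn_distance"} (default), \code{"continuous"} or
#'   \code{"packing_ratio"}.
#' @param deltaCrit nearest-neighbour distance criterion (same units as the
#'   positions) for \code{"nn_distance"}.
#' @param prCrit packing-ratio threshold in (0, 1] for
#'   \code{"packing_ratio"}.
#' @return data.frame with one row per ensemble: \code{segmentId},
#'   \code{members} (list column of global spine indices), \code{m} (labeled
#'   members), \code{M} (total spines spanned), \code{span} (um between the
#'   outermost members), \code{firstPos}, \code{lastPos}. Singletons
#'   (\code{m = 1}) are reported but carry no likelihood.
#' @export
setGeneric("detectEnsembles", function(x, criterion = c("nn_distance",
                                                        "continuous",
                                                        "packing_ratio"),
                                       deltaCrit = NULL, prCrit = NULL)
  standardGeneric("detectEnsembles"))

empty_detection <- function() {
  data.frame(segmentId = character(0), m = integer(0), M = integer(0),
             span = numeric(0), firstPos = numeric(0), lastPos = numeric(0),
             members = I(list()))
}

detect_groups_segment <- function(layout, criterion, deltaCrit, prCrit) {
  p <- layout@positions
  lab <- which(layout@labeled)
  if (!length(lab)) return(list())
  if (criterion == "nn_distance") {
    if (is.null(deltaCrit) || deltaCrit <= 0)
      stop("criterion 'nn_distance' needs a positive deltaCrit")
    brk <- which(diff(p[lab]) > deltaCrit + .DIST_TOL)
    grp <- split(lab, cumsum(c(0, seq_along(lab)[-1] %in% (brk + 1))))
  } else if (criterion == "continuous") {
    brk <- which(diff(lab) > 1)
    grp <- split(lab, cumsum(c(0, seq_along(lab)[-1] %in% (brk + 1))))
  } else if (criterion == "packing_ratio") {
    if (is.null(prCrit) || prCrit <= 0 || prCrit > 1)
      stop("criterion 'packing_ratio' needs prCrit in (0, 1]")
    ## greedy proximal-to-distal: from each unclaimed labeled spine take the
    ## longest stretch keeping the packing ratio at or above threshold; a
    ## boundary spine reachable from two stretches is claimed by the
    ## proximal one
    grp <- list(); i <- 1
    while (i <= length(lab)) {
      best <- i
      for (j in seq(i, length(lab))) {
        Mspan <- lab[j] - lab[i] + 1
        if ((j - i + 1) / Mspan >= prCrit - 1e-12) best <- j
      }
      grp[[length(grp) + 1]] <- lab[i:best]
      i <- best + 1
    }
  } else stop("unknown criterion: ", criterion)
  unname(grp)
}

groups_to_df <- function(groups, layout, offset = 0L) {
  if (!length(groups)) return(empty_detection())
  p <- layout@positions
  do.call(rbind, lapply(groups, function(g) {
    data.frame(segmentId = layout@segmentId, m = length(g),
               M = g[length(g)] - g[1] + 1L,
               span = p[g[length(g)]] - p[g[1]],
               firstPos = p[g[1]], lastPos = p[g[length(g)]],
               members = I(list(as.integer(g + offset))))
  }))
}

#' @rdname detectEnsembles
#' @export
setMethod("detectEnsembles", "SpineLayout",
  function(x, criterion = c("nn_distance", "continuous", "packing_ratio"),
           deltaCrit = NULL, prCrit = NULL) {
    criterion <- match.arg(criterion)
    groups_to_df(detect_groups_segment(x, criterion, deltaCrit, prCrit), x)
  })

## distance of every spine from the soma along the path
spine_soma_depths <- function(tree) {
  depth <- numeric(nSegments(tree))
  ord <- order(vapply(seq_len(nSegments(tree)), function(i) {
    d <- 0; j <- i
    while (!is.na(tree@parent[j])) { d <- d + 1; j <- tree@parent[j] }
    d
  }, 0))
  for (i in ord) {
    p <- tree@parent[i]
    depth[i] <- if (is.na(p)) 0 else depth[p] + segmentLength(tree@segments[[p]])
  }
  unlist(lapply(seq_len(nSegments(tree)), function(i)
    depth[i] + tree@segments[[i]]@positions))
}

## full pairwise path-distance matrix between spines of a tree
spine_path_distances <- function(tree) {
  ns <- vapply(tree@segments, nSpines, 0)
  segOf <- rep(seq_len(nSegments(tree)), ns)
  D <- spine_soma_depths(tree)
  anc <- lapply(seq_len(nSegments(tree)), function(i) {
    a <- i
    while (!is.na(tree@parent[a[length(a)]])) a <- c(a, tree@parent[a[length(a)]])
    a
  })
  depth_prox <- vapply(seq_len(nSegments(tree)), function(i) {
    p <- tree@parent[i]
    d <- 0
    while (!is.na(p)) { d <- d + segmentLength(tree@segments[[p]]); p <- tree@parent[p] }
    d
  }, 0)
  Ntot <- sum(ns)
  out <- matrix(0, Ntot, Ntot)
  for (a in seq_len(Ntot)) for (b in seq_len(Ntot)) {
    if (a >= b) next
    sa <- segOf[a]; sb <- segOf[b]
    if (sa == sb || sa %in% anc[[sb]] || sb %in% anc[[sa]]) {
      d <- abs(D[a] - D[b])
    } else {
      common <- intersect(anc[[sa]], anc[[sb]])
      l <- common[1]                       # nearest common ancestor segment
      meet <- depth_prox[l] + segmentLength(tree@segments[[l]])
      d <- (D[a] - meet) + (D[b] - meet)
    }
    out[a, b] <- out[b, a] <- d
  }
  out
}

#' @rdname detectEnsembles
#' @export
setMethod("detectEnsembles", "DendriteTree",
  function(x, criterion = c("nn_distance", "continuous", "packing_ratio"),
           deltaCrit = NULL, prCrit = NULL) {
    criterion <- match.arg(criterion)
    if (criterion != "nn_distance")
      stop("tree-wide detection supports the nn_distance criterion")
    if (is.null(deltaCrit) || deltaCrit <= 0)
      stop("criterion 'nn_distance' needs a positive deltaCrit")
    ns <- vapply(x@segments, nSpines, 0)
    lab <- which(unlist(lapply(x@segments, inputLabels)))
    if (!length(lab)) return(empty_detection())
    pd <- spine_path_distances(x)
    ## single-linkage components under the distance criterion
    comp <- seq_along(lab)
    repeat {
      changed <- FALSE
      for (i in seq_along(lab)) for (j in seq_along(lab)) {
        if (comp[i] != comp[j] &&
            pd[lab[i], lab[j]] <= deltaCrit + .DIST_TOL) {
          comp[comp == comp[j]] <- comp[i]; changed <- TRUE
        }
      }
      if (!changed) break
    }
    segOf <- rep(seq_len(nSegments(x)), ns)
    D <- spine_soma_depths(x)
    rows <- lapply(unique(comp), function(cc) {
      mem <- lab[comp == cc]
      ## spanned spines: those on a path between two members
      span_set <- mem
      if (length(mem) >= 2) {
        for (s in seq_len(sum(ns))) {
          if (s %in% span_set) next
          on_path <- FALSE
          for (a in mem) for (b in mem) {
            if (a < b && pd[a, s] + pd[s, b] <= pd[a, b] + 1e-6) {
              on_path <- TRUE; break
            }
          }
          if (on_path) span_set <- c(span_set, s)
        }
      }
      segIds <- unique(vapply(x@segments[unique(segOf[mem])],
                              function(s) s@segmentId, ""))
      data.frame(segmentId = paste(segIds, collapse = "+"),
                 m = length(mem), M = length(span_set),
                 span = if (length(mem) >= 2) max(pd[mem, mem]) else 0,
                 firstPos = min(D[mem]), lastPos = max(D[mem]),
                 members = I(list(sort(as.integer(mem)))))
    })
    df <- do.call(rbind, rows)
    df[order(df$firstPos), , drop = FALSE]
  })
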