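## The fully specified worked example: one segment with N = 30 spines,
## n = 5 inputs, gap / nearest-neighbour criterion 2.
##
## The published table of specific ensemble likelihoods for this
## configuration corresponds to the distance-based sliding-window
## computation on the unit-spacing layout under the "published" interval
## convention (leading-gap interval closed as printed, windows slid across
## every start spine and clipped at the distal end); the order-based closed
## form gives slightly different values in the cells affected by the
## interval overlap and the clipped windows (see the methods vignette for
## the full comparison). Both are available here.

#' Specific ensemble likelihood table of the worked example
#'
#' Computes the SEL of every admissible ensemble type (M, m) for a single
#' segment with N spines and n inputs under gap criterion g, plus the
#' overall cluster likelihood obtained from it by the count-once rule with
#' the given reference cluster.
#'
#' @param N,n,g configuration (defaults: the 30-spine worked example).
#' @param engine \code{"published"}: distance-based computation on the
#'   unit-spacing layout under the published interval convention (matches
#'   the published table of this example); \code{"order"}: the order-based
#'   closed form.
#' @param refM,refm reference cluster type for the overall cluster
#'   likelihood (default (5, 4), the least unlikely type classified as a
#'   cluster at the 1 percent threshold in this example).
#' @return List with \code{table} (matrix of SEL values, rows m, columns
#'   M; NA for unrealizable types), \code{display} (the same rounded to 2
#'   significant figures), \code{qualifying} (logical matrix of the types
#'   entering the OCL sum) and \code{ocl}
#'   (\code{\linkS4class{LikelihoodValue}}).
#' @examples
#' ex <- publishedWorkedExample()
#' ex$display
#' likelihoodValue(ex$ocl)
#' @export
publishedWorkedExample <- function(N = 30, n = 5, g = 2,
                                   engine = c("published", "order"),
                                   refM = 5, refm = 4) {
  engine <- match.arg(engine)
  maxM <- maxEnsembleSize(n, g)
  lay <- uniformLayout(N, seq_len(n))   # labels only set the input count
  sel <- function(M, m) {
    if (engine == "order") {
      specificEnsembleLikelihood(N, n, M, m, g)
    } else {
      specificEnsembleLikelihoodDistance(lay, M - 1, m, g,
                                         convention = "published")
    }
  }
  tab <- matrix(NA_real_, nrow = n - 1, ncol = maxM - 1,
                dimnames = list(m = 2:n, M = 2:maxM))
  lks <- vector("list", maxM)
  for (M in 2:maxM) {
    lks[[M]] <- vector("list", min(n, M))
    for (m in 2:min(n, M)) {
      if (M > (m - 1) * g + 1) next    # unrealizable type: dash in the table
      lk <- sel(M, m)
      lks[[M]][[m]] <- lk
      tab[as.character(m), as.character(M)] <- likelihoodValue(lk)
    }
  }
  refVal <- tab[as.character(refm), as.character(refM)]
  if (is.na(refVal)) stop("reference type is unrealizable")
  qualifying <- !is.na(tab) & tab <= refVal + 1e-12
  ## count-once rule: per ensemble size keep the smallest qualifying m
  terms <- list()
  for (M in 2:maxM) {
    col <- as.character(M)
    ms <- which(qualifying[, col])
    if (!length(ms)) next
    keep <- ms[1]
    qualifying[, col] <- FALSE
    qualifying[keep, col] <- TRUE
    terms[[length(terms) + 1]] <- lks[[M]][[as.integer(rownames(tab)[keep])]]
  }
  list(table = tab, display = signif(tab, 2), qualifying = qualifying,
       ocl = lk_sum(terms))
}
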