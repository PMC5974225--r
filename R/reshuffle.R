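## Monte-Carlo reshuffling baseline.
##
## Labels are repeatedly re-assigned uniformly at random to the fixed spine
## positions; each round records whether an ensemble of the target type
## (same size, m or more labels, same gap rule — the SEL event) occurs. The
## binomial error model gives the expected accuracy analytically, which is
## how many rounds a reshuffling analysis needs for a given precision — and
## why the exact combinatorics are preferable for the small likelihoods of
## interest.

#' Variance of the hit count in reshuffling
#'
#' For a pattern of probability p observed over a number of reshuffling
#' rounds, the hit count is binomial with variance rounds * p * (1 - p).
#'
#' @param p pattern probability in [0, 1].
#' @param rounds reshuffling rounds (>= 1).
#' @return Numeric variance.
#' @examples
#' reshuffleVariance(0.5, 100)  # 25
#' @export
reshuffleVariance <- function(p, rounds) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  if (any(rounds < 1)) stop("rounds must be at least 1")
  rounds * p * (1 - p)
}

#' Coefficient of variation of a reshuffling estimate
#'
#' CV of the likelihood estimate from a number of reshuffling rounds:
#' sqrt((1 - p) / (rounds * p)). One million rounds are needed to reach a
#' 1 percent expected error for a pattern of probability 0.01; the CV
#' halves when the rounds quadruple.
#'
#' @inheritParams reshuffleVariance
#' @return Numeric CV.
#' @examples
#' reshuffleCV(0.01, 1e6)  # ~0.995 percent
#' @export
reshuffleCV <- function(p, rounds) {
  if (any(p <= 0 | p > 1)) stop("p must lie in (0, 1]")
  if (any(rounds < 1)) stop("rounds must be at least 1")
  sqrt((1 - p) / (rounds * p))
}

## hit-test zones for a target type on a layout or tree
reshuffle_zones <- function(x, target, convention = "exclusive") {
  if (is(x, "SpineLayout") && is(target, "EnsembleType")) {
    tree <- DendriteTree(list(x), NA_integer_)
    zones <- segment_placements(tree, 1, target@M, target@g)
    lapply(zones, function(z)
      list(window = z$window, ends = z$ends, gaps = z$gaps))
  } else if (is(x, "SpineLayout") && is(target, "DistanceEnsembleType")) {
    zones <- distance_zones(x, target@lM, target@lg, convention)
    lapply(Filter(function(z) z$Mi >= target@m, zones), function(z)
      list(window = z$window, ends = z$ends, gaps = z$gaps))
  } else if (is(x, "DendriteTree") && is(target, "EnsembleType")) {
    zones <- tree_placements(x, target@M, target@g)
    lapply(Filter(function(z) target@m >= z$delta, zones), function(z)
      list(window = z$window, ends = z$ends, gaps = z$gaps))
  } else if (is(x, "DendriteTree") && is(target, "DistanceEnsembleType")) {
    zones <- distance_tree_zones(x, target@lM, target@lg)
    lapply(Filter(function(z) z$Mi >= target@m && target@m >= z$delta, zones),
           function(z) list(window = z$window, ends = z$ends, gaps = z$gaps))
  } else stop("unsupported layout/target combination")
}

#' Monte-Carlo reshuffling estimate of an ensemble likelihood
#'
#' Re-assigns the n labels uniformly among the N spine positions for the
#' given number of rounds and counts the rounds containing an ensemble of
#' the target type (its size with m or more labels, delimited by clean
#' gaps — the event whose exact probability the SEL gives). The analytic
#' error model supplies the predicted CV; when the exact likelihood is
#' available a z score of the estimate against it is included.
#'
#' @param x a \code{\linkS4class{SpineLayout}} or
#'   \code{\linkS4class{DendriteTree}} (spine positions are kept fixed).
#' @param target an \code{\linkS4class{EnsembleType}} or
#'   \code{\linkS4class{DistanceEnsembleType}}.
#' @param rounds reshuffling rounds.
#' @param seed RNG seed (required, for reproducibility).
#' @param exact exact likelihood of the event when known; used for the
#'   predicted CV and z score (defaults to NA: the CV is computed from the
#'   estimate itself).
#' @param convention interval convention for distance targets.
#' @return A \code{\linkS4class{ReshuffleResult}}.
#' @export
reshuffleLikelihoodEstimate <- function(x, target, rounds, seed,
                                        exact = NA_real_,
                                        convention = "exclusive") {
  check_count(rounds, "rounds", min = 1)
  check_count(seed, "seed")
  N <- if (is(x, "SpineLayout")) nSpines(x) else treeTotals(x)[["N"]]
  n <- if (is(x, "SpineLayout")) nInputs(x) else treeTotals(x)[["n"]]
  if (N < 1 || n < 1) stop("degenerate layout: no spines or no inputs")
  m <- target@m
  hits <- 0
  if (m <= n) {
    zones <- reshuffle_zones(x, target, convention)
    if (length(zones)) {
      set.seed(seed)
      chunk <- 20000L
      done <- 0
      while (done < rounds) {
        k <- min(chunk, rounds - done)
        lab <- matrix(FALSE, k, N)
        for (r in seq_len(k)) lab[r, sample.int(N, n)] <- TRUE
        hit <- logical(k)
        for (z in zones) {
          idx <- which(!hit)
          if (!length(idx)) break
          ok <- rowSums(lab[idx, z$ends, drop = FALSE]) == length(z$ends)
          if (any(ok)) {
            sub <- idx[ok]
            cnt <- rowSums(lab[sub, z$window, drop = FALSE])
            ok2 <- cnt >= m
            if (length(z$gaps) && any(ok2)) {
              ok2[ok2] <- rowSums(lab[sub[ok2], z$gaps, drop = FALSE]) == 0
            }
            hit[sub[ok2]] <- TRUE
          }
        }
        hits <- hits + sum(hit)
        done <- done + k
      }
    }
  }
  est <- hits / rounds
  pref <- if (is.finite(exact) && exact > 0) exact else est
  cv <- if (pref > 0) reshuffleCV(pref, rounds) else NA_real_
  z <- if (is.finite(exact) && exact > 0 && is.finite(cv) && cv > 0)
    (est - exact) / (exact * cv) else NA_real_
  new("ReshuffleResult", rounds = as.numeric(rounds), hits = as.numeric(hits),
      estimate = est, predictedCV = cv, seed = as.integer(seed),
      exact = as.numeric(exact), zScore = z)
}
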