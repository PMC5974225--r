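## shared fixtures built in code

## the worked-example configuration: 30 spines, 5 inputs, gap 2
worked_layout <- function(labels = c(1, 5, 9, 20, 27)) {
  uniformLayout(30, labels)
}

## printed SEL table of the worked example (rows m = 2..5, columns M = 2..9)
printed_table1 <- function() {
  cells <- rbind(
    c(2, 2, 0.37),   c(3, 2, 0.38),
    c(3, 3, 0.046),  c(4, 3, 0.088),  c(5, 3, 0.12),
    c(4, 4, 0.0040), c(5, 4, 0.01),   c(6, 4, 0.021), c(7, 4, 0.034),
    c(5, 5, 1.8e-4), c(6, 5, 7.0e-4), c(7, 5, 0.0017),
    c(8, 5, 0.0033), c(9, 5, 0.0056))
  data.frame(M = cells[, 1], m = cells[, 2], sel = cells[, 3])
}

## unit-spacing segments wired into a small tree; lab gives global labeled ids
small_tree <- function(nspines, parent, labeled = integer(0), spacing = 1) {
  off <- c(0, cumsum(nspines))[seq_along(nspines)]
  segs <- lapply(seq_along(nspines), function(i) {
    lab <- (off[i] + seq_len(nspines[i])) %in% labeled
    SpineLayout((seq_len(nspines[i]) - 1) * spacing, lab,
                segmentId = paste0("seg", i),
                length = max(nspines[i] - 1, 0) * spacing)
  })
  DendriteTree(segs, as.integer(parent))
}

## numeric value of an exact count
cnt <- function(x) as.numeric(x)

## independent maximal-ensemble detector on ranks (nearest-neighbour
## criterion g), used to cross-check detection and for calibration truth
detect_types_ranks <- function(p, g) {
  if (!length(p)) return(NULL)
  brk <- which(diff(p) > g)
  grp <- split(p, cumsum(c(0, seq_along(p)[-1] %in% (brk + 1))))
  t(vapply(grp, function(x) c(M = x[length(x)] - x[1] + 1, m = length(x)),
           c(M = 0, m = 0)))
}
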