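#' Define the active-site gate
#'
#' The gate at the pocket entrance is formed by a lower pair of charged
#' residues (ASP33/ARG37 by default) and an upper pair (GLU241/ARG243); its
#' state is read off the separation between the two sides. Which atoms carry
#' the distance is explicit configuration: `min_sidechain_heavy` takes the
#' minimum distance between side-chain heavy atoms of the two sides,
#' `centroid_sidechain` the distance between the side-chain-heavy centroids.
#' A residue without side-chain heavy atoms (one-bead fixtures) falls back to
#' all its heavy atoms.
#'
#' @param lower residue indices of the lower gate side (default c(33, 37)).
#' @param upper residue indices of the upper side (default c(241, 243)).
#' @param mode "min_sidechain_heavy" (default) or "centroid_sidechain".
#' @return a GateDefinition (list).
#' @export
gateDefinition <- function(lower = c(33, 37), upper = c(241, 243),
                           mode = c("min_sidechain_heavy",
                                    "centroid_sidechain")) {
  mode <- match.arg(mode)
  if (length(intersect(lower, upper)))
    stop("lower and upper gate residues must be disjoint", call. = FALSE)
  structure(list(lower = lower, upper = upper, mode = mode),
            class = "GateDefinition")
}

# side-chain heavy atom rows of one residue key within a chain, with
# all-heavy fallback
.sidechainRows <- function(system, resid, chain) {
  a <- system@atoms
  rows <- which(a$chain == chain & a$resid == resid)
  if (!length(rows))
    stop("gate residue ", resid, " not found in chain ", chain, call. = FALSE)
  heavy <- rows[toupper(a$element[rows]) != "H"]
  if (!length(heavy))
    stop("gate residue ", resid, " in chain ", chain,
         " has no heavy atoms", call. = FALSE)
  sc <- heavy[!(a$name[heavy] %in% BACKBONE_NAMES)]
  if (length(sc)) sc else heavy
}

#' Gate-distance time series
#'
#' Per-frame distance between the lower and upper gate sides of one subunit,
#' by the gate's distance mode.
#'
#' @param traj a [Trajectory-class].
#' @param gate a [gateDefinition()].
#' @param chain subunit chain ID.
#' @return numeric vector (nm), one value per frame.
#' @export
gateDistanceSeries <- function(traj, gate = gateDefinition(), chain) {
  sys <- traj@system
  lowerRows <- unlist(lapply(gate$lower, .sidechainRows, system = sys,
                             chain = chain))
  upperRows <- unlist(lapply(gate$upper, .sidechainRows, system = sys,
                             chain = chain))
  co <- traj@coords
  nf <- dim(co)[1]
  if (gate$mode == "centroid_sidechain") {
    cl <- apply(co[, lowerRows, , drop = FALSE], c(1, 3), mean)
    cu <- apply(co[, upperRows, , drop = FALSE], c(1, 3), mean)
    return(sqrt(rowSums((cl - cu)^2)))
  }
  best <- rep(Inf, nf)
  for (i in lowerRows) for (j in upperRows) {
    d2 <- (co[, i, 1] - co[, j, 1])^2 + (co[, i, 2] - co[, j, 2])^2 +
      (co[, i, 3] - co[, j, 3])^2
    best <- pmin(best, d2)
  }
  sqrt(best)
}

#' Band occupancy of a gate-distance series
#'
#' Fraction of frames in each conformational band: closed [0, 0.4) nm,
#' open [0.4, 0.7] nm, wide-open (0.7, Inf) nm by default (0.4 and 0.7 are
#' owned by the open band, matching peaks "less than 0.4" and "exceeding
#' 0.7"). The merged open + wide-open fraction is attached as attribute
#' `open_or_wide`.
#'
#' @param series numeric distances (nm).
#' @param bands c(closed/open boundary, open/wide boundary), nm.
#' @return named numeric c(closed, open, wide_open) summing to 1.
#' @export
stateOccupancy <- function(series, bands = c(0.4, 0.7)) {
  if (!length(series)) stop("empty series", call. = FALSE)
  closed <- mean(series < bands[1])
  open <- mean(series >= bands[1] & series <= bands[2])
  wide <- mean(series > bands[2])
  structure(c(closed = closed, open = open, wide_open = wide),
            open_or_wide = open + wide)
}

#' Classify a gate-distance distribution
#'
#' A Gaussian kernel density estimate (Silverman's rule-of-thumb bandwidth)
#' is computed over the series; peaks are local maxima whose height exceeds
#' `peakFraction` of the global maximum. A single peak below 0.4 nm is
#' "closed", in [0.4, 0.7] "open", above 0.7 "wide_open"; peaks in both the
#' closed and the open band give the alternating "open_closed" label. Any
#' other multi-band pattern is labeled by the band of the highest peak.
#'
#' @param series numeric distances (nm); a warning is issued below 100
#'   frames.
#' @param bands band boundaries, nm (default c(0.4, 0.7)).
#' @param peakFraction minimum relative peak height (default 0.1).
#' @param bw density bandwidth rule (default "nrd0", Silverman).
#' @return list with `label`, `peaks` (data.frame(position, height)) and
#'   `occupancy` (see [stateOccupancy()]).
#' @export
classifyGate <- function(series, bands = c(0.4, 0.7), peakFraction = 0.1,
                         bw = "nrd0") {
  if (!length(series)) stop("empty series", call. = FALSE)
  if (length(series) < 100L)
    warning("fewer than 100 frames; classification may be under-sampled")
  if (stats::sd(series) < 1e-12) {
    peaks <- data.frame(position = series[1], height = Inf)
  } else {
    d <- stats::density(series, bw = bw)
    y <- d$y; n <- length(y)
    isMax <- c(y[1] > y[2], y[2:(n - 1)] > y[1:(n - 2)] &
                 y[2:(n - 1)] >= y[3:n], y[n] > y[n - 1])
    isMax <- isMax & y >= peakFraction * max(y)
    peaks <- data.frame(position = d$x[isMax], height = y[isMax])
  }
  band <- function(p) ifelse(p < bands[1], "closed",
                             ifelse(p <= bands[2], "open", "wide_open"))
  pb <- band(peaks$position)
  label <- if (all(c("closed", "open") %in% pb)) "open_closed"
  else if (length(unique(pb)) == 1L) unique(pb)
  else band(peaks$position[which.max(peaks$height)])
  list(label = label, peaks = peaks,
       occupancy = stateOccupancy(series, bands))
}
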