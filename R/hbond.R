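#' Geometric hydrogen-bond criteria
#'
#' The default criteria: donor-acceptor distance at most 0.35 nm (3.5
#' Angstrom) and deviation-from-linearity at most 30 degrees, measured as
#' the hydrogen-donor-acceptor angle at the donor vertex.
#'
#' @param distance donor-acceptor cutoff, nm (default 0.35).
#' @param angle deviation-from-linearity cutoff, degrees in (0, 90]
#'   (default 30).
#' @return an HBondCriteria (list).
#' @export
hbondCriteria <- function(distance = 0.35, angle = 30) {
  if (distance <= 0) stop("distance cutoff must be positive", call. = FALSE)
  if (angle <= 0 || angle > 90)
    stop("angle cutoff must be in (0, 90] degrees", call. = FALSE)
  structure(list(distance = distance, angle = angle),
            class = "HBondCriteria")
}

#' Detect hydrogen bonds in one frame
#'
#' A bond is recorded for a (donor, hydrogen, acceptor) triple iff the
#' donor-acceptor distance is within the cutoff and the angle between the
#' donor->hydrogen and donor->acceptor directions is within the angle
#' cutoff. Backbone and side-chain atoms are equally eligible; the covalent
#' donor-hydrogen mapping must be supplied and is checked geometrically
#' (H within 0.15 nm of its donor).
#'
#' @param frame n x 3 coordinate matrix (nm) for the whole system.
#' @param donors data.frame(donor, hydrogen): atom row indices of each
#'   donor heavy atom and its covalent hydrogen.
#' @param acceptors atom row indices of acceptor heavy atoms.
#' @param criteria an [hbondCriteria()].
#' @return data.frame(donor, hydrogen, acceptor) of qualifying triples.
#' @export
detectHbonds <- function(frame, donors, acceptors,
                         criteria = hbondCriteria()) {
  frame <- as.matrix(frame)
  out <- list()
  for (r in seq_len(nrow(donors))) {
    d <- donors$donor[r]; h <- donors$hydrogen[r]
    dh <- frame[h, ] - frame[d, ]
    if (sqrt(sum(dh^2)) > 0.15)
      stop("hydrogen ", h, " is not bonded to donor ", d,
           " (D-H distance > 0.15 nm)", call. = FALSE)
    for (a in setdiff(acceptors, c(d, h))) {
      da <- frame[a, ] - frame[d, ]
      rda <- sqrt(sum(da^2))
      if (rda > criteria$distance) next
      cosang <- sum(dh * da) / (sqrt(sum(dh^2)) * rda)
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      if (ang <= criteria$angle)
        out[[length(out) + 1L]] <- c(d, h, a)
    }
  }
  if (!length(out))
    return(data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer()))
  m <- do.call(rbind, out)
  data.frame(donor = m[, 1], hydrogen = m[, 2], acceptor = m[, 3])
}

# polar heavy atoms (N/O) of a residue, and their covalent hydrogens
# assigned by proximity (<= 0.12 nm) in the reference frame
.residuePolarSites <- function(system, key, chain, refFrame) {
  a <- system@atoms
  k <- .parseResidueKey(key)
  ch <- if (!is.na(k$chain)) k$chain else chain
  rows <- which(a$resid == k$resid & (is.na(ch) | a$chain == ch))
  if (!length(rows))
    stop("cannot resolve residue '", key, "'", call. = FALSE)
  polar <- rows[toupper(a$element[rows]) %in% c("N", "O")]
  hyd <- rows[toupper(a$element[rows]) == "H"]
  donors <- list()
  for (h in hyd) {
    if (!length(polar)) break
    d2 <- rowSums(sweep(refFrame[polar, , drop = FALSE], 2, refFrame[h, ])^2)
    if (min(d2) <= 0.12^2)
      donors[[length(donors) + 1L]] <- c(polar[which.min(d2)], h)
  }
  donors <- if (length(donors)) {
    m <- do.call(rbind, donors)
    data.frame(donor = m[, 1], hydrogen = m[, 2])
  } else data.frame(donor = integer(), hydrogen = integer())
  list(donors = donors, acceptors = polar)
}

#' Hydrogen-bond occupancy of a residue pair
#'
#' Fraction of pooled frames (all replicas) in which at least one
#' qualifying hydrogen bond exists between the two residues, counting every
#' donor/acceptor combination in either direction. Donor and acceptor sites
#' are the N/O atoms of each residue; hydrogens are assigned to their donor
#' by covalent proximity in the first frame.
#'
#' @param pair character(2) residue keys (e.g. `c("33", "243")` or
#'   chain-qualified `c("A:33", "A:243")`).
#' @param trajectories a [Trajectory-class] or list of replicas.
#' @param criteria an [hbondCriteria()].
#' @param chain default chain for unqualified keys (NA = any chain, keys
#'   must then resolve uniquely).
#' @return occupancy fraction in [0, 1].
#' @export
hbondOccupancy <- function(pair, trajectories, criteria = hbondCriteria(),
                           chain = NA) {
  if (is(trajectories, "Trajectory")) trajectories <- list(trajectories)
  bonded <- 0L; total <- 0L
  for (tr in trajectories) {
    ref <- matrix(tr@coords[1, , ], ncol = 3L)
    s1 <- .residuePolarSites(tr@system, pair[1], chain, ref)
    s2 <- .residuePolarSites(tr@system, pair[2], chain, ref)
    if (!nrow(s1$donors) && !nrow(s2$donors))
      stop("neither residue of the pair has a polar hydrogen to donate",
           call. = FALSE)
    for (f in seq_len(nFrames(tr))) {
      fr <- matrix(tr@coords[f, , ], ncol = 3L)
      hit <- nrow(detectHbonds(fr, s1$donors, s2$acceptors, criteria)) > 0 ||
        nrow(detectHbonds(fr, s2$donors, s1$acceptors, criteria)) > 0
      bonded <- bonded + hit
      total <- total + 1L
    }
  }
  bonded / total
}
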