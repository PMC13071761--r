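#' Dynamic cross-correlation matrix of Calpha fluctuations
#'
#' C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>), with dr the deviation
#' of the Calpha position from its time mean after removal of overall
#' translation and rotation (per-replica iterated-mean superposition).
#' Replicas are pooled by concatenation after alignment. Residues with zero
#' positional fluctuation get 0-valued off-diagonal entries and are flagged.
#'
#' @param trajectories a [Trajectory-class] or list of replicas.
#' @param selection selection label or residue keys ("" = all residues).
#' @param fit superpose frames before measuring (default TRUE).
#' @return a [DCCMatrix-class].
#' @export
dccMatrix <- function(trajectories, selection = "", fit = TRUE) {
  pooled <- .pooledFluctCoords(trajectories, selection, fit)
  X <- pooled$X
  if (nrow(X) < 2L) stop("DCCM needs at least 2 frames", call. = FALSE)
  m <- nrow(pooled$residues)
  if (m < 2L) stop("DCCM needs at least 2 residues", call. = FALSE)
  D <- sweep(X, 2, colMeans(X))
  cols <- function(k) seq(k, 3L * m, by = 3L)
  raw <- crossprod(D[, cols(1)]) + crossprod(D[, cols(2)]) +
    crossprod(D[, cols(3)])
  raw <- raw / nrow(D)
  amp <- diag(raw)
  zero <- amp <= 1e-24
  denom <- sqrt(pmax(amp, 1e-300))
  C <- raw / outer(denom, denom)
  C[zero, ] <- 0; C[, zero] <- 0
  diag(C) <- 1
  C <- (C + t(C)) / 2
  C[C > 1] <- 1; C[C < -1] <- -1
  dimnames(C) <- list(pooled$residues$label, pooled$residues$label)
  new("DCCMatrix", values = C,
      zeroFluctuation = pooled$residues$label[zero])
}

#' Construct a DCCMatrix from a plain matrix
#'
#' @param values symmetric matrix in [-1, 1] with unit diagonal; residue
#'   labels taken from dimnames (or "1", "2", ... if absent).
#' @param zeroFluctuation labels of flagged zero-fluctuation residues.
#' @return a validated [DCCMatrix-class].
#' @export
newDCCMatrix <- function(values, zeroFluctuation = character()) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    dimnames(values) <- list(as.character(seq_len(nrow(values))),
                             as.character(seq_len(ncol(values))))
  new("DCCMatrix", values = values,
      zeroFluctuation = as.character(zeroFluctuation))
}

#' Per-residue strong-coupling fractions
#'
#' For each residue, the fraction of partner residues (diagonal excluded,
#' denominator n - 1) whose correlation exceeds the strong-coupling
#' threshold: f_plus with C_ij > threshold, f_minus with C_ij < -threshold
#' (strict inequalities), and the directional balance f_plus - f_minus.
#'
#' @param x a [DCCMatrix-class] or square correlation matrix.
#' @param threshold strong-correlation threshold in (0, 1); default 0.2.
#' @return data.frame(label, f_plus, f_minus, directional).
#' @export
couplingFractions <- function(x, threshold = 0.2) {
  if (is(x, "DCCMatrix")) x <- x@values
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 residues", call. = FALSE)
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)", call. = FALSE)
  labs <- rownames(x)
  if (is.null(labs)) labs <- as.character(seq_len(n))
  off <- row(x) != col(x)
  fp <- rowSums(x > threshold & off) / (n - 1L)
  fm <- rowSums(x < -threshold & off) / (n - 1L)
  data.frame(label = labs, f_plus = fp, f_minus = fm,
             directional = fp - fm, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' PTM correlation-redistribution score
#'
#' For each residue, the change between the PTMed and reduced states in the
#' balance of strongly correlated versus strongly anti-correlated partners:
#' score_i = (f_plus - f_minus)_PTM - (f_plus - f_minus)_reduced. Positive
#' scores mean net enrichment of correlated interactions upon PTM, negative
#' scores relative enrichment of anti-correlated interactions.
#'
#' @param reduced [DCCMatrix-class] of the reduced state.
#' @param ptm [DCCMatrix-class] of the PTMed state, same residue labels.
#' @param threshold strong-correlation threshold (default 0.2).
#' @return data.frame(label, directional_reduced, directional_ptm, score),
#'   score in [-2, 2].
#' @export
redistributionScore <- function(reduced, ptm, threshold = 0.2) {
  fr <- couplingFractions(reduced, threshold)
  fp <- couplingFractions(ptm, threshold)
  if (!identical(fr$label, fp$label)) {
    bad <- c(setdiff(fr$label, fp$label), setdiff(fp$label, fr$label))
    stop("residue labels differ between states: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  data.frame(label = fr$label,
             directional_reduced = fr$directional,
             directional_ptm = fp$directional,
             score = fp$directional - fr$directional,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a correlation matrix as CSV (square) and long TSV
#'
#' @param x a [DCCMatrix-class].
#' @param csvPath path for the labeled square CSV (optional).
#' @param longPath path for the long-format TSV (res_i, res_j, C_ij)
#'   (optional).
#' @return invisibly, the matrix values.
#' @export
writeDCCM <- function(x, csvPath = NULL, longPath = NULL) {
  v <- x@values
  if (!is.null(csvPath))
    utils::write.csv(v, csvPath, row.names = TRUE)
  if (!is.null(longPath)) {
    idx <- which(upper.tri(v, diag = FALSE), arr.ind = TRUE)
    long <- data.frame(res_i = rownames(v)[idx[, 1]],
                       res_j = colnames(v)[idx[, 2]],
                       C_ij = v[idx])
    utils::write.table(long, longPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(v)
}
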