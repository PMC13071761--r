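#' Bennett acceptance ratio free-energy estimate
#'
#' Maximum-likelihood free-energy difference from forward and reverse work
#' samples. The estimate solves the Bennett self-consistency condition
#'
#'   sum_F f(M + w_F - x) = sum_R f(-M + w_R + x),  f(t) = 1/(1 + e^t),
#'
#' with works and x in kT units and M = ln(nF/nR). The left side is
#' monotone increasing in x, so the root is bracketed from the sample range
#' and solved with Brent's method to `tolerance`. The standard error is
#' Bennett's asymptotic variance estimate,
#' var = 1 / sum_all 1/(2 + 2 cosh(t)) - 1/nF - 1/nR (t the Fermi
#' arguments at the solution), which vanishes in the reversible limit and
#' diverges when the forward and negated-reverse work distributions do not
#' overlap; that case is flagged as non-converged.
#'
#' Sign convention: `forward` holds reduced-to-PTM work measured in the
#' reduced ensemble, `reverse` PTM-to-reduced work in the PTMed ensemble
#' (so in the reversible limit forward = -reverse = dG).
#'
#' @param samples list with numeric `forward` and `reverse` work vectors,
#'   e.g. from [sampleCrooksWork()], in units of `kT`.
#' @param kT thermal energy in the desired output unit (default 1, i.e.
#'   results in kT; use 0.5924849 for kcal/mol at 300 K).
#' @param tolerance root tolerance in kT (default 1e-10).
#' @param maxIter maximum bracket-expansion iterations.
#' @return list with `dg`, `stderr` (both in `kT` units), `iterations`,
#'   `converged`.
#' @export
barEstimate <- function(samples, kT = 1, tolerance = 1e-10,
                        maxIter = 10000L) {
  wF <- as.numeric(samples$forward) / kT
  wR <- as.numeric(samples$reverse) / kT
  if (!length(wF) || !length(wR))
    stop("both forward and reverse samples are required", call. = FALSE)
  nF <- length(wF); nR <- length(wR)
  M <- log(nF / nR)
  fermi <- function(t) stats::plogis(-t)
  g <- function(x) sum(fermi(M + wF - x)) - sum(fermi(-M + wR + x))
  mid <- (mean(wF) - mean(wR)) / 2
  half <- max(1, diff(range(c(wF, -wR)))) ; it <- 0L
  lo <- mid - half; hi <- mid + half
  while (g(lo) > 0 && it < maxIter) { lo <- lo - half; half <- half * 2; it <- it + 1L }
  while (g(hi) < 0 && it < maxIter) { hi <- hi + half; half <- half * 2; it <- it + 1L }
  root <- stats::uniroot(g, c(lo, hi), tol = tolerance, maxiter = maxIter)
  x <- root$root
  t_all <- c(M + wF - x, -M + wR + x)
  h <- 1 / (2 + 2 * cosh(pmin(abs(t_all), 700)))
  overlap <- mean(h)
  v <- max(1 / sum(h) - 1 / nF - 1 / nR, 0)
  converged <- is.finite(v) && overlap > 1e-10
  if (!converged)
    warning("forward/reverse work distributions do not overlap; ",
            "variance estimate diverges")
  list(dg = x * kT,
       stderr = if (converged) sqrt(v) * kT else NA_real_,
       iterations = root$iter + it, converged = converged)
}

#' Chain per-window free energies across the schedule
#'
#' Window estimates ordered by stage then lambda are summed; standard
#' errors combine in quadrature (windows assumed independent). A gap in
#' lambda coverage within a stage is an error.
#'
#' @param estimates data.frame with columns stage, lambda_low, lambda_high,
#'   dg, stderr (one row per adjacent-lambda window).
#' @param stages expected stage order (default electrostatics first).
#' @return list with `dg`, `stderr`, `perStage` (named dg by stage).
#' @export
chainWindows <- function(estimates,
                         stages = c("electrostatics", "vdw_bonded")) {
  stages <- intersect(stages, unique(estimates$stage))
  extra <- setdiff(unique(estimates$stage), stages)
  if (length(extra)) stages <- c(stages, extra)
  perStage <- numeric(0)
  for (st in stages) {
    e <- estimates[estimates$stage == st, , drop = FALSE]
    e <- e[order(e$lambda_low), , drop = FALSE]
    gaps <- character()
    if (e$lambda_low[1] != 0)
      gaps <- c(gaps, sprintf("[0, %g]", e$lambda_low[1]))
    if (nrow(e) > 1L) {
      bad <- which(abs(e$lambda_high[-nrow(e)] - e$lambda_low[-1]) > 1e-12)
      gaps <- c(gaps, sprintf("[%g, %g]", e$lambda_high[bad],
                              e$lambda_low[bad + 1L]))
    }
    if (e$lambda_high[nrow(e)] != 1)
      gaps <- c(gaps, sprintf("[%g, 1]", e$lambda_high[nrow(e)]))
    if (length(gaps))
      stop("lambda coverage gap in stage '", st, "': ",
           paste(gaps, collapse = ", "), call. = FALSE)
    perStage[st] <- sum(e$dg)
  }
  list(dg = sum(estimates$dg),
       stderr = sqrt(sum(estimates$stderr^2)),
       perStage = perStage)
}

#' Relative binding free energy of a PTM transformation
#'
#' RBFE = dG(protein) - dG(water): the free-energy cost of the
#' cysteine-to-PTM transformation in the protein environment minus the same
#' transformation in water. More negative values mean the PTM is
#' energetically more favorable in the protein context.
#'
#' @param proteinDg,waterDg totals in the same units.
#' @param proteinStderr,waterStderr standard errors (propagated in
#'   quadrature).
#' @param site,ptmType optional annotations.
#' @return data.frame(site, ptm_type, dg_protein, dg_water, rbfe, stderr).
#' @export
rbfe <- function(proteinDg, waterDg, proteinStderr = 0, waterStderr = 0,
                 site = NA, ptmType = NA_character_) {
  .assertScalarNumber(proteinDg, "proteinDg")
  .assertScalarNumber(waterDg, "waterDg")
  data.frame(site = site, ptm_type = ptmType,
             dg_protein = proteinDg, dg_water = waterDg,
             rbfe = proteinDg - waterDg,
             stderr = sqrt(proteinStderr^2 + waterStderr^2),
             stringsAsFactors = FALSE)
}

#' L1 (Manhattan) summary of RBFEs per PTM type
#'
#' The Manhattan distance of a PTM type's RBFE vector from zero: the sum of
#' absolute RBFE values over that type's modified sites.
#'
#' @param results data.frame of [rbfe()] rows.
#' @param ptmType type to summarize; default: every type present.
#' @return data.frame(ptm_type, l1, n_sites).
#' @export
l1Norm <- function(results, ptmType = NULL) {
  if (is.null(ptmType)) ptmType <- unique(results$ptm_type)
  out <- lapply(ptmType, function(tp) {
    r <- results[results$ptm_type %in% tp, , drop = FALSE]
    if (!nrow(r)) stop("no RBFE results of type '", tp, "'", call. = FALSE)
    data.frame(ptm_type = tp, l1 = sum(abs(r$rbfe)), n_sites = nrow(r),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Read an alchemical work CSV
#'
#' Expected columns: stage, lambda_low, lambda_high, direction ("fwd" work
#' measured at lambda_low pushing toward lambda_high, "rev" the converse)
#' and work_kT.
#'
#' @param path CSV path.
#' @return data.frame of work samples.
#' @export
readWorkCSV <- function(path) {
  w <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("stage", "lambda_low", "lambda_high", "direction", "work_kT")
  missing <- setdiff(need, names(w))
  if (length(missing))
    stop("work CSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!all(w$direction %in% c("fwd", "rev")))
    stop("direction must be 'fwd' or 'rev'", call. = FALSE)
  w
}

#' BAR estimates for every window of a work table
#'
#' @param work data.frame as returned by [readWorkCSV()].
#' @param kT thermal energy unit (see [barEstimate()]).
#' @return data.frame(stage, lambda_low, lambda_high, dg, stderr,
#'   converged), one row per window.
#' @export
estimateWindows <- function(work, kT = 1) {
  keys <- unique(work[, c("stage", "lambda_low", "lambda_high")])
  keys <- keys[order(keys$stage, keys$lambda_low), , drop = FALSE]
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- work$stage == keys$stage[i] &
      work$lambda_low == keys$lambda_low[i] &
      work$lambda_high == keys$lambda_high[i]
    est <- barEstimate(list(forward = work$work_kT[sel & work$direction == "fwd"],
                            reverse = work$work_kT[sel & work$direction == "rev"]),
                       kT = kT)
    cbind(keys[i, , drop = FALSE], dg = est$dg, stderr = est$stderr,
          converged = est$converged)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
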