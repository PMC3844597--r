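#' Per-probe balanced two-way fixed-effects ANOVA
#'
#' Screens every probe with the standard fixed-effects decomposition for a
#' balanced drug x time design: main effects for the treatment factor (all
#' drug and vehicle groups as levels; the naive group is excluded) and the
#' time factor, plus their interaction. For the full emulated design (20
#' treatment levels x 4 time-points) the degrees of freedom are 19, 3 and 57.
#' P values come from the upper tail of the F distribution. The treatment-
#' factor P value is additionally Bonferroni- and Benjamini-Hochberg-adjusted
#' across probes.
#'
#' Unbalanced designs (unequal replication per drug x time cell) are rejected
#' rather than silently switching sums-of-squares types.
#'
#' @param x a \linkS4class{DrugExpressionSet} of normalized values, or a
#'   numeric matrix (then \code{drug} and \code{time} must be given)
#' @param drug,time factors per sample, used only for matrix input
#' @return data.frame (one row per probe): \code{probe_id, F_drug, p_drug,
#'   F_time, p_time, F_int, p_int, p_bonf, p_bh}, with the degrees of freedom
#'   in attribute \code{"df"} (named: drug, time, interaction, residual)
#' @examples
#' cfg <- syntheticConfig(nProbes = 20, networks = list(), seed = 3)
#' res <- twowayAnova(generateExperiment(cfg)$experiment)
#' attr(res, "df")
#' @export
twowayAnova <- function(x, drug = NULL, time = NULL) {
  if (is(x, "DrugExpressionSet")) {
    sheet <- sampleSheet(x)
    keep <- if ("role" %in% colnames(sheet)) sheet$role != "naive"
            else sheet$drug != "NAIVE"
    m <- exprValues(x)[, keep, drop = FALSE]
    drug <- sheet$drug[keep]
    time <- sheet$time_h[keep]
  } else {
    m <- as.matrix(x)
    if (is.null(drug) || is.null(time))
      stop("matrix input needs drug and time factors")
  }
  f1 <- factor(drug)
  f2 <- factor(time)
  a <- nlevels(f1)
  b <- nlevels(f2)
  cell <- interaction(f1, f2, drop = FALSE)
  counts <- table(cell)
  if (length(unique(as.integer(counts))) != 1L)
    stop("unbalanced design: unequal replication across drug x time cells")
  r <- as.integer(counts[1])
  if (r < 2) stop("need >= 2 replicates per cell")
  n <- ncol(m)

  ## group-mean operators (balanced, so plain averages)
  Z1 <- stats::model.matrix(~ 0 + f1)
  Z2 <- if (b > 1) stats::model.matrix(~ 0 + f2) else matrix(1, n, 1)
  Zc <- if (b > 1) stats::model.matrix(~ 0 + cell) else Z1
  M1 <- m %*% Z1 / (b * r)        # probe x drug-level means
  M2 <- m %*% Z2 / (a * r)        # probe x time-level means
  Mc <- m %*% Zc / r              # probe x cell means
  grand <- rowMeans(m)

  ss_total <- rowSums((m - grand)^2)
  ss_drug <- b * r * rowSums((M1 - grand)^2)
  ss_time <- a * r * rowSums((M2 - grand)^2)
  ss_cells <- r * rowSums((Mc - grand)^2)
  ss_int <- ss_cells - ss_drug - ss_time
  ss_err <- ss_total - ss_cells

  df <- c(drug = a - 1L, time = b - 1L,
          interaction = (a - 1L) * (b - 1L), residual = a * b * (r - 1L))
  mse <- ss_err / df["residual"]
  F_drug <- (ss_drug / df["drug"]) / mse
  p_drug <- stats::pf(F_drug, df["drug"], df["residual"], lower.tail = FALSE)
  if (b > 1) {
    F_time <- (ss_time / df["time"]) / mse
    F_int <- (ss_int / df["interaction"]) / mse
    p_time <- stats::pf(F_time, df["time"], df["residual"],
                        lower.tail = FALSE)
    p_int <- stats::pf(F_int, df["interaction"], df["residual"],
                       lower.tail = FALSE)
  } else {
    ## single time-point: no time or interaction term (one-way layout)
    F_time <- F_int <- p_time <- p_int <- rep(NA_real_, nrow(m))
  }

  out <- data.frame(probe_id = rownames(m),
                    F_drug = F_drug, p_drug = p_drug,
                    F_time = F_time, p_time = p_time,
                    F_int = F_int, p_int = p_int,
                    p_bonf = adjustPvalues(p_drug, "bonferroni"),
                    p_bh = adjustPvalues(p_drug, "bh"),
                    row.names = NULL)
  attr(out, "df") <- df
  attr(out, "ss") <- data.frame(probe_id = rownames(m), ss_drug = ss_drug,
                                ss_time = ss_time, ss_int = ss_int,
                                ss_err = ss_err, ss_total = ss_total,
                                row.names = NULL)
  out
}

#' Multiple-testing adjustment
#'
#' Bonferroni: \code{min(1, m * p)}; Benjamini-Hochberg: the step-up adjusted
#' values (monotone in P rank). Thin, validated wrapper over
#' \code{stats::p.adjust}.
#'
#' @param pvals numeric vector of raw P values in [0, 1]
#' @param method \code{"bonferroni"} or \code{"bh"}
#' @return adjusted P values
#' @examples
#' adjustPvalues(c(0.01, 0.02, 0.03, 0.04), "bh")  # all 0.04
#' @export
adjustPvalues <- function(pvals, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("P values must lie in [0, 1]")
  stats::p.adjust(pvals, method = if (method == "bh") "BH" else "bonferroni")
}

#' Estimated true positives over a range of false discovery rates
#'
#' For each FDR level q in the grid: R(q) = number of BH-adjusted P values at
#' or below q, and the expected number of true positives TP(q) = R(q)(1 - q)
#' (an approximation: at FDR q, about a fraction q of the R(q) discoveries are
#' false). The plateau summary is the maximum TP over the grid -- an estimate
#' of the total number of truly regulated transcripts.
#'
#' @param pvals raw P values
#' @param fdrGrid increasing FDR levels in (0, 1)
#' @return list: \code{curve} data.frame(q, discoveries, true_positives) and
#'   \code{plateau}, the grid maximum of TP
#' @export
estimateTruePositives <- function(pvals,
                                  fdrGrid = c(0.01, 0.02, 0.05, 0.1, 0.15,
                                              0.2, 0.3, 0.4, 0.5)) {
  if (!length(fdrGrid)) stop("empty FDR grid")
  if (any(fdrGrid <= 0 | fdrGrid >= 1) || is.unsorted(fdrGrid, strictly = TRUE))
    stop("fdrGrid must be increasing within (0, 1)")
  bh <- adjustPvalues(pvals, "bh")
  discoveries <- vapply(fdrGrid, function(q) sum(bh <= q), 0L)
  tp <- discoveries * (1 - fdrGrid)
  list(curve = data.frame(q = fdrGrid, discoveries = discoveries,
                          true_positives = tp),
       plateau = max(tp))
}

#' Write a screening result table to TSV
#'
#' @param screen result of \code{\link{twowayAnova}}
#' @param path output path
#' @return invisibly, the path
#' @export
writeScreenResult <- function(screen, path) {
  .writeTsv(screen[, c("probe_id", "F_drug", "p_drug", "F_time", "p_time",
                       "F_int", "p_int", "p_bonf", "p_bh")], path)
  invisible(path)
}
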