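#' Default drug panel
#'
#' Eighteen psychotropic drugs spanning antidepressants, antipsychotics,
#' anxiolytics, psychostimulants and opioids, each with its matched vehicle
#' (saline \code{SAL} or Tween 80 \code{TWE}), plus the two vehicle groups
#' themselves. The panel mirrors a typical acute-treatment striatal
#' profiling design: i.p. injection, sampling at 1, 2, 4 and 8 h.
#'
#' @return data.frame with columns \code{drug}, \code{control}, \code{class},
#'   \code{is_vehicle}
#' @export
defaultDrugTable <- function() {
  d <- rbind(
    c("MIA", "SAL", "antidepressant"),
    c("IMI", "SAL", "antidepressant"),
    c("FLU", "SAL", "antidepressant"),
    c("BUP", "SAL", "antidepressant"),
    c("TIA", "SAL", "antidepressant"),
    c("TRA", "SAL", "antidepressant"),
    c("MET", "SAL", "psychostimulant"),
    c("COC", "SAL", "psychostimulant"),
    c("NIC", "SAL", "psychostimulant"),
    c("HER", "SAL", "opioid"),
    c("MOR", "SAL", "opioid"),
    c("ETO", "SAL", "anxiolytic"),
    c("DIA", "TWE", "anxiolytic"),
    c("BUS", "SAL", "anxiolytic"),
    c("HYD", "SAL", "anxiolytic"),
    c("CLO", "TWE", "antipsychotic"),
    c("RIS", "TWE", "antipsychotic"),
    c("HAL", "TWE", "antipsychotic"))
  out <- data.frame(drug = d[, 1], control = d[, 2], class = d[, 3],
                    is_vehicle = FALSE)
  rbind(out,
        data.frame(drug = c("SAL", "TWE"), control = NA_character_,
                   class = "vehicle", is_vehicle = TRUE))
}

#' Default pharmacological mechanism panel
#'
#' Thirteen receptor/transporter/enzyme mechanisms covering the monoamine
#' transporters, monoamine oxidase, serotonin, histamine, adrenergic,
#' muscarinic and dopamine receptors, the GABA-A channel and the mu opioid
#' receptor.
#'
#' @return character vector of 13 mechanism names
#' @export
defaultMechanisms <- function() {
  c("SERT", "NET", "DAT", "MAO", "HTR1A", "HTR2A", "HTR2C", "HRH1",
    "ADRA1A", "CHRM", "DRD2", "GABAA", "OPRM1")
}

#' Default ground-truth drug x mechanism engagement matrix
#'
#' Engagement strengths on a pKi-like scale (primary target ~3, secondary
#' ~1.5, i.e. Ki around 10 nM resp. ~300 nM above a 10 uM floor). Values are
#' synthetic; the target assignments follow the drugs' known pharmacology.
#' Vehicle rows are all zero. Tianeptine (\code{TIA}) is given a weak
#' monoamine-transporter truth row so that signature-based inference has a
#' recoverable planted answer.
#'
#' @return 20 x 13 numeric matrix (18 drugs + 2 vehicles, 13 mechanisms)
#' @export
defaultBindingTruth <- function() {
  mech <- defaultMechanisms()
  drugs <- defaultDrugTable()$drug
  B <- matrix(0, length(drugs), length(mech), dimnames = list(drugs, mech))
  set_row <- function(drug, ...) {
    w <- c(...)
    B[drug, names(w)] <<- w
  }
  set_row("MIA", HRH1 = 3, HTR2C = 1.5, HTR2A = 1.5, ADRA1A = 1.5,
          NET = 1.5, CHRM = 1.5)
  set_row("IMI", SERT = 3, HRH1 = 1.5, NET = 1.5, ADRA1A = 1.5,
          HTR2C = 1.5, CHRM = 1.5)
  set_row("FLU", SERT = 3, NET = 1.5, HTR2C = 1.5)
  set_row("BUP", DAT = 3)
  set_row("TIA", SERT = 1.5, NET = 1.5, DAT = 1.5)
  set_row("TRA", MAO = 3)
  set_row("MET", NET = 3, DAT = 3)
  set_row("COC", DAT = 3, NET = 1.5, SERT = 1.5)
  set_row("NIC", DAT = 1.5, NET = 1.5)
  set_row("HER", OPRM1 = 3)
  set_row("MOR", OPRM1 = 3)
  set_row("ETO", GABAA = 3)
  set_row("DIA", GABAA = 3)
  set_row("BUS", HTR1A = 3)
  set_row("HYD", HRH1 = 3)
  set_row("CLO", DRD2 = 3, HRH1 = 1.5, HTR2A = 1.5, HTR2C = 1.5,
          CHRM = 1.5, ADRA1A = 1.5)
  set_row("RIS", HTR2A = 3, HTR2C = 1.5, DRD2 = 3, ADRA1A = 1.5, HRH1 = 1.5)
  set_row("HAL", DRD2 = 3, HTR2A = 1.5)
  B
}

#' Default planted co-expression module specification
#'
#' Three modules emulating the size structure of the major drug-inducible
#' striatal networks (about 100, 40 and 30 transcripts). Each module responds
#' through a signed mechanism-weight template; the positive main axis defines
#' the drug class driving the module and the negative off-axis entries plant
#' down-regulation and keep the module response archetypes mutually
#' anti-correlated, so that the modules occupy separated branches of the
#' co-expression tree:
#' \itemize{
#'   \item \code{net_1} (activity-dependent-like): induced by monoamine
#'     transporter blockers/releasers (DAT, NET).
#'   \item \code{net_2} (sedative-responsive): induced by GABA-A and mu-opioid
#'     agonists, suppressed by psychostimulants.
#'   \item \code{net_3} (antipsychotic-responsive): induced by D2/5-HT2A
#'     blockers, suppressed by stimulants and sedatives.
#' }
#'
#' @return named list; each element has \code{size} (member count) and
#'   \code{weights} (named, signed mechanism weights)
#' @export
defaultNetworkSpec <- function() {
  list(
    net_1 = list(size = 100L, weights = c(DAT = 1, NET = 1)),
    net_2 = list(size = 40L,
                 weights = c(GABAA = 1, OPRM1 = 1, DAT = -0.5, NET = -0.5)),
    net_3 = list(size = 30L,
                 weights = c(DRD2 = 1, HTR2A = 0.7, DAT = -0.4, NET = -0.4,
                             GABAA = -0.4, OPRM1 = -0.4)))
}

#' Configuration of a synthetic drug-perturbation experiment
#'
#' @slot nProbes number of probes
#' @slot drugTable data.frame(drug, control, class, is_vehicle)
#' @slot mechanisms declared mechanism names
#' @slot binding ground-truth drug x mechanism engagement
#' @slot networks planted module spec (list of size + signed mechanism weights)
#' @slot timePoints sampling times in hours, strictly increasing
#' @slot replicates arrays per drug x time cell
#' @slot noiseSd i.i.d. Gaussian noise sd, log2 units
#' @slot batchTable data.frame(batch, shift, scale): per-batch affine distortion
#' @slot upFraction probability that an auto-generated module weight is positive
#' @slot amplitudeRange per-probe peak |log2 fold change| range
#' @slot baselineRange baseline log2 intensity range
#' @slot shapeWidth log-scale width of the impulse time-response shape
#' @slot naiveCollapsed generate the naive group at a single pseudo-time-point
#' @slot seed RNG seed
#' @export
setClass("SyntheticConfig",
         representation(nProbes = "integer", drugTable = "data.frame",
                        mechanisms = "character", binding = "matrix",
                        networks = "list", timePoints = "numeric",
                        replicates = "integer", noiseSd = "numeric",
                        batchTable = "data.frame", upFraction = "numeric",
                        amplitudeRange = "numeric", baselineRange = "numeric",
                        shapeWidth = "numeric", naiveCollapsed = "logical",
                        seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  if (object@nProbes <= 0L || object@replicates <= 0L)
    return("counts must be positive")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (anyDuplicated(object@drugTable$drug)) return("duplicate drug names")
  if (any(diff(object@timePoints) <= 0))
    return("timePoints must be strictly increasing")
  if (!all(colnames(object@binding) == object@mechanisms))
    return("binding columns must match declared mechanisms")
  if (!all(rownames(object@binding) == object@drugTable$drug))
    return("binding rows must match declared drugs")
  veh <- object@drugTable$is_vehicle
  if (any(object@binding[veh, , drop = FALSE] != 0))
    return("vehicle rows of the binding matrix must be all zero")
  if (any(rowSums(object@binding[!veh, , drop = FALSE] > 0) < 1))
    return("every non-vehicle drug needs at least one positive binding entry")
  for (nw in object@networks) {
    bad <- setdiff(names(nw$weights), object@mechanisms)
    if (length(bad))
      return(paste0("network weight references undeclared mechanism: ",
                    paste(bad, collapse = ", ")))
  }
  sizes <- vapply(object@networks, function(nw) as.integer(nw$size), 0L)
  if (length(sizes) && sum(sizes) > object@nProbes)
    return("planted module sizes exceed nProbes")
  if (nrow(object@batchTable) < 1L) return("at least one batch required")
  TRUE
})

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig:", object@nProbes, "probes,",
      sum(!object@drugTable$is_vehicle), "drugs +",
      sum(object@drugTable$is_vehicle), "vehicles,",
      length(object@timePoints), "time-points x",
      object@replicates, "replicates; noiseSd =", object@noiseSd, "\n")
})

#' Build a synthetic experiment configuration
#'
#' Defaults state the emulated design: 18 drugs plus saline and Tween vehicles
#' and a naive group, time-points 1/2/4/8 h, 3 replicate arrays per drug and
#' time (12 arrays per drug), two hybridization batches with an affine
#' distortion, and three planted co-expression modules of sizes 100/40/30.
#'
#' The noise and signal defaults place the planted modules in the regime the
#' analysis assumes -- co-expressed transcripts with highly correlated
#' drug-response profiles over an uncorrelated background: \code{noiseSd}
#' 0.15 log2 units (typical replicate precision of expression arrays),
#' per-probe peak responses of 1-3 log2 units (2- to 8-fold, the range of
#' strongly drug-inducible striatal transcripts such as the immediate-early
#' genes), and impulse responses spanning adjacent points of the 1/2/4/8 h
#' grid (\code{shapeWidth} 0.8 on the log time axis).
#'
#' @param nProbes probe count
#' @param drugs either a drug table as from \code{\link{defaultDrugTable}} or
#'   a character vector of drug names (saline-controlled; a SAL vehicle row is
#'   appended automatically)
#' @param mechanisms mechanism names
#' @param binding ground-truth drug x mechanism matrix; defaults to
#'   \code{\link{defaultBindingTruth}} for the default panel, or unit
#'   engagement of every declared mechanism for custom panels
#' @param networks module spec list (see \code{\link{defaultNetworkSpec}}), a
#'   bare numeric vector of module sizes (mechanism weights are then drawn
#'   automatically, positive with probability \code{upFraction}), or an empty
#'   list for no planted structure
#' @param timePoints,replicates sampling design
#' @param noiseSd residual noise sd in log2 units
#' @param batchTable data.frame(batch, shift, scale)
#' @param upFraction fraction of auto-drawn module weights that are positive
#' @param amplitudeRange,baselineRange,shapeWidth signal-shape parameters
#' @param naiveCollapsed single pseudo-time-point for the naive group
#' @param seed RNG seed (integer)
#' @return a \linkS4class{SyntheticConfig}
#' @export
syntheticConfig <- function(nProbes = 1000L,
                            drugs = defaultDrugTable(),
                            mechanisms = NULL,
                            binding = NULL,
                            networks = defaultNetworkSpec(),
                            timePoints = c(1, 2, 4, 8),
                            replicates = 3L,
                            noiseSd = 0.15,
                            batchTable = data.frame(
                              batch = c("v1", "v2"),
                              shift = c(0, 0.5),
                              scale = c(1, 1.15)),
                            upFraction = 0.9,
                            amplitudeRange = c(1, 3),
                            baselineRange = c(6, 12),
                            shapeWidth = 0.8,
                            naiveCollapsed = TRUE,
                            seed = 1L) {
  if (is.character(drugs)) {
    drugs <- rbind(
      data.frame(drug = drugs, control = "SAL", class = "drug",
                 is_vehicle = FALSE),
      data.frame(drug = "SAL", control = NA_character_, class = "vehicle",
                 is_vehicle = TRUE))
  }
  default_panel <- identical(drugs$drug, defaultDrugTable()$drug)
  if (is.null(mechanisms))
    mechanisms <- if (default_panel) defaultMechanisms() else
      if (!is.null(binding)) colnames(binding) else "M1"
  if (is.null(binding)) {
    if (default_panel && identical(mechanisms, defaultMechanisms())) {
      binding <- defaultBindingTruth()
    } else {
      binding <- matrix(0, nrow(drugs), length(mechanisms),
                        dimnames = list(drugs$drug, mechanisms))
      binding[!drugs$is_vehicle, ] <- 1
    }
  }
  binding <- binding[drugs$drug, mechanisms, drop = FALSE]
  if (is.numeric(networks) && is.null(dim(networks))) {
    sizes <- networks
    if (is.null(names(sizes))) names(sizes) <- paste0("net_", seq_along(sizes))
    networks <- lapply(sizes, function(s) list(size = as.integer(s),
                                               weights = NULL))
  }
  new("SyntheticConfig", nProbes = as.integer(nProbes), drugTable = drugs,
      mechanisms = mechanisms, binding = binding, networks = networks,
      timePoints = as.numeric(timePoints), replicates = as.integer(replicates),
      noiseSd = noiseSd, batchTable = batchTable, upFraction = upFraction,
      amplitudeRange = amplitudeRange, baselineRange = baselineRange,
      shapeWidth = shapeWidth, naiveCollapsed = naiveCollapsed,
      seed = as.integer(seed))
}

# Impulse time-response: log-normal-like bump with peak time p, evaluated on
# the sampling grid and normalized so its grid maximum is 1.
.timeShape <- function(times, peak, width) {
  s <- exp(-(log(times) - log(peak))^2 / (2 * width^2))
  s / max(s)
}

#' Generate a synthetic drug-perturbation experiment with ground truth
#'
#' The expected log2 expression of probe \eqn{g} in a sample treated with drug
#' \eqn{d} at time \eqn{t} is
#' \deqn{scale_b (baseline_g + \sum_m A_{m g} B_{d m} s_d(t)) + shift_b}
#' where \eqn{A} holds planted mechanism sensitivities, \eqn{B} the drug's
#' mechanism engagement, \eqn{s_d} a per-drug impulse time shape with unit
#' peak, and \eqn{(shift_b, scale_b)} the batch distortion. Probes within a
#' planted module share a signed mechanism-weight vector, so their expected
#' response profiles are exact positive multiples of one another (expected
#' within-module Spearman correlation 1); the per-probe loading sets the peak
#' amplitude. i.i.d. Gaussian noise of sd \code{noiseSd} is added on top.
#' The same configuration and seed always yield a bit-identical result.
#'
#' @param config a \linkS4class{SyntheticConfig}
#' @return list with elements \code{experiment}
#'   (\linkS4class{DrugExpressionSet}, log2 scale) and \code{truth}
#'   (\linkS4class{SyntheticTruth})
#' @examples
#' cfg <- syntheticConfig(nProbes = 50, networks = list(), seed = 7)
#' sim <- generateExperiment(cfg)
#' table(sampleSheet(sim$experiment)$drug)["COC"]  # 12 arrays for one drug
#' @export
generateExperiment <- function(config) {
  validObject(config)
  dt <- config@drugTable
  times <- config@timePoints
  reps <- config@replicates
  mech <- config@mechanisms
  B <- config@binding
  probes <- sprintf("probe_%04d", seq_len(config@nProbes))

  withr::with_seed(config@seed, {
    baseline <- stats::runif(config@nProbes, config@baselineRange[1],
                             config@baselineRange[2])
    peaks <- sample(times, nrow(dt), replace = TRUE)
    names(peaks) <- dt$drug

    ## planted modules: signed mechanism weights (drawn when the spec gives
    ## none), positive member loadings
    networks <- config@networks
    for (i in seq_along(networks)) {
      if (is.null(networks[[i]]$weights)) {
        k <- min(2L, length(mech))
        picked <- mech[((i - 1L) * k + seq_len(k) - 1L) %% length(mech) + 1L]
        sgn <- ifelse(stats::runif(k) < config@upFraction, 1, -1)
        networks[[i]]$weights <- stats::setNames(sgn, picked)
      }
    }
    membership <- rep("background", config@nProbes)
    sizes <- vapply(networks, function(nw) as.integer(nw$size), 0L)
    if (length(sizes)) {
      idx <- 1L
      for (i in seq_along(networks)) {
        membership[idx:(idx + sizes[i] - 1L)] <- names(networks)[i]
        idx <- idx + sizes[i]
      }
    }
    names(membership) <- probes

    A <- matrix(0, length(mech), config@nProbes,
                dimnames = list(mech, probes))
    for (i in seq_along(networks)) {
      w <- networks[[i]]$weights
      wfull <- stats::setNames(numeric(length(mech)), mech)
      wfull[names(w)] <- w
      drive <- as.numeric(B %*% wfull)       # per-drug engagement of module
      norm <- max(abs(drive))
      if (norm == 0) norm <- 1
      members <- which(membership == names(networks)[i])
      loading <- stats::runif(length(members), config@amplitudeRange[1],
                              config@amplitudeRange[2])
      A[, members] <- outer(wfull / norm, loading)
    }

    ## sample sheet
    role <- ifelse(dt$is_vehicle, "vehicle", "treatment")
    groups <- data.frame(drug = rep(dt$drug, each = length(times)),
                         control = rep(dt$control, each = length(times)),
                         role = rep(role, each = length(times)),
                         is_vehicle = rep(dt$is_vehicle, each = length(times)),
                         time_h = rep(times, nrow(dt)))
    naive_times <- if (config@naiveCollapsed) times[1] else times
    groups <- rbind(groups,
                    data.frame(drug = "NAIVE", control = NA_character_,
                               role = "naive", is_vehicle = FALSE,
                               time_h = naive_times))
    sheet <- groups[rep(seq_len(nrow(groups)), each = reps), ]
    sheet$replicate <- rep(seq_len(reps), nrow(groups))
    sheet$sample_id <- sprintf("%s_t%g_r%d", sheet$drug, sheet$time_h,
                               sheet$replicate)
    grp_idx <- rep(seq_len(nrow(groups)), each = reps)
    nb <- nrow(config@batchTable)
    sheet$batch <- config@batchTable$batch[
      (grp_idx + sheet$replicate) %% nb + 1L]
    rownames(sheet) <- NULL
    sheet <- sheet[, c("sample_id", "drug", "time_h", "replicate", "batch",
                       "is_vehicle", "control", "role")]

    ## expected surface
    clean <- matrix(baseline, config@nProbes, nrow(sheet),
                    dimnames = list(probes, sheet$sample_id))
    treated <- which(sheet$role == "treatment")
    AB <- t(A) %*% t(B)                       # probe x drug total sensitivity
    for (j in treated) {
      d <- sheet$drug[j]
      s <- .timeShape(times, peaks[d], config@shapeWidth)
      st <- s[match(sheet$time_h[j], times)]
      clean[, j] <- clean[, j] + AB[, d] * st
    }
    bt <- config@batchTable
    shift <- bt$shift[match(sheet$batch, bt$batch)]
    scale <- bt$scale[match(sheet$batch, bt$batch)]
    mean_surface <- sweep(sweep(clean, 2, scale, "*"), 2, shift, "+")

    noise <- matrix(stats::rnorm(length(mean_surface)), nrow(mean_surface),
                    ncol(mean_surface)) * config@noiseSd
    values <- mean_surface + noise
  })

  experiment <- DrugExpressionSet(values, sheet)
  truth <- new("SyntheticTruth", membership = membership, A = A,
               B = B, meanSurface = mean_surface)
  list(experiment = experiment, truth = truth)
}

#' Ground-truth binding matrix of a configuration
#'
#' @param config a \linkS4class{SyntheticConfig}
#' @return the drug x mechanism engagement matrix used by
#'   \code{\link{generateExperiment}} (vehicle rows all zero)
#' @export
generateBindingMatrix <- function(config) {
  validObject(config)
  config@binding
}

#' Write a synthetic experiment to plain-text files
#'
#' Emits the expression matrix, sample sheet, truth tables (module membership,
#' sensitivities, binding) and a flat key=value configuration dump, all
#' tab-delimited UTF-8.
#'
#' @param sim result of \code{\link{generateExperiment}}
#' @param config the \linkS4class{SyntheticConfig} used
#' @param dir output directory (created if needed)
#' @return invisibly, the vector of written paths
#' @export
writeSyntheticExperiment <- function(sim, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    matrix = file.path(dir, "expression.tsv"),
    sheet = file.path(dir, "sample_sheet.tsv"),
    membership = file.path(dir, "truth_membership.tsv"),
    A = file.path(dir, "truth_sensitivity.tsv"),
    B = file.path(dir, "truth_binding.tsv"),
    surface = file.path(dir, "truth_mean_surface.tsv"),
    config = file.path(dir, "config.txt"))
  writeExpression(sim$experiment, paths["matrix"], paths["sheet"])
  truth <- sim$truth
  .writeTsv(data.frame(probe_id = names(trueMembership(truth)),
                       network = unname(trueMembership(truth))),
            paths["membership"])
  .writeMatrixTsv(trueSensitivity(truth), "mechanism", paths["A"])
  .writeMatrixTsv(trueBinding(truth), "drug", paths["B"])
  .writeMatrixTsv(meanSurface(truth), "probe_id", paths["surface"])
  kv <- c(nProbes = config@nProbes,
          drugs = paste(config@drugTable$drug, collapse = ","),
          mechanisms = paste(config@mechanisms, collapse = ","),
          timePoints = paste(config@timePoints, collapse = ","),
          replicates = config@replicates, noiseSd = config@noiseSd,
          upFraction = config@upFraction, seed = config@seed)
  writeLines(paste0(names(kv), "=", kv), paths["config"])
  invisible(paths)
}
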