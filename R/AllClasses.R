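#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

.REQUIRED_SAMPLE_COLS <- c("drug", "time_h", "replicate", "batch", "is_vehicle")

#' Container for a drug-perturbation expression experiment
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding a probes
#' \eqn{\times} samples matrix of (log2) intensities together with the sample
#' sheet describing the perturbation design: drug label, time after injection
#' in hours, replicate index, hybridization batch and a vehicle flag.
#' Two optional sample-sheet columns are understood downstream: \code{control}
#' (the vehicle label matched to each treated sample, e.g. saline vs Tween) and
#' \code{role} (\code{"treatment"}, \code{"vehicle"} or \code{"naive"}).
#'
#' @slot .\ inherits all slots from \code{SummarizedExperiment}.
#' @seealso \code{\link{DrugExpressionSet}} for the constructor,
#'   \code{\link{readExpression}} to build one from TSV files.
#' @export
setClass("DrugExpressionSet", contains = "SummarizedExperiment")

setValidity("DrugExpressionSet", function(object) {
  cd <- colData(object)
  missing_cols <- setdiff(.REQUIRED_SAMPLE_COLS, colnames(cd))
  if (length(missing_cols))
    return(paste0("sample sheet lacks column(s): ",
                  paste(missing_cols, collapse = ", ")))
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    return("probe ids must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    return("sample ids must be present and unique")
  if (anyNA(assay(object)))
    return("expression matrix contains missing values")
  if (!is.numeric(cd$time_h) || any(cd$time_h <= 0))
    return("time_h must be positive")
  if (!is.logical(cd$is_vehicle))
    return("is_vehicle must be logical")
  TRUE
})

#' Construct a DrugExpressionSet
#'
#' @param values numeric matrix, probes in rows, samples in columns; rownames
#'   are probe ids, colnames are sample ids matching \code{sampleSheet$sample_id}.
#' @param sampleSheet data.frame with columns \code{sample_id, drug, time_h,
#'   replicate, batch, is_vehicle} (and optionally \code{control}, \code{role}),
#'   one row per matrix column, in any order.
#' @return a \linkS4class{DrugExpressionSet}
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("p", 1:3), c("s1", "s2")))
#' sheet <- data.frame(sample_id = c("s1", "s2"), drug = "COC", time_h = 1,
#'                     replicate = 1:2, batch = "v1", is_vehicle = FALSE)
#' DrugExpressionSet(m, sheet)
#' @export
DrugExpressionSet <- function(values, sampleSheet) {
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("expression values must be numeric")
  if (!"sample_id" %in% colnames(sampleSheet))
    stop("sample sheet must have a sample_id column")
  missing_rows <- setdiff(colnames(values), sampleSheet$sample_id)
  if (length(missing_rows))
    stop("sample sheet has no row for sample(s): ",
         paste(missing_rows, collapse = ", "))
  extra <- setdiff(sampleSheet$sample_id, colnames(values))
  if (length(extra))
    stop("sample sheet row(s) without a matrix column: ",
         paste(extra, collapse = ", "))
  sampleSheet <- sampleSheet[match(colnames(values), sampleSheet$sample_id), ,
                             drop = FALSE]
  cd <- DataFrame(sampleSheet, row.names = sampleSheet$sample_id)
  se <- SummarizedExperiment(assays = list(exprs = values), colData = cd)
  new("DrugExpressionSet", se)
}

#' @describeIn DrugExpressionSet the sample sheet as a base data.frame
#' @param x a DrugExpressionSet
#' @export
sampleSheet <- function(x) {
  stopifnot(is(x, "DrugExpressionSet"))
  as.data.frame(colData(x))
}

#' @describeIn DrugExpressionSet the expression matrix
#' @export
exprValues <- function(x) {
  stopifnot(is(x, "DrugExpressionSet"))
  assay(x, "exprs")
}

#' Per-(probe, drug, time) fold changes against vehicle
#'
#' Long-format table of log2 fold changes (treated minus vehicle group mean)
#' and equal-variance two-sample t-test P values, plus the per-(probe, drug)
#' cross-time consistency summaries \code{foldmean} (mean signed log2 fold
#' change over the time course) and \code{foldsd} (its sample standard
#' deviation) that feed the selection score.
#'
#' @slot table data.frame: probe_id, drug, time_h, log2fc, fold, t_p
#' @slot summary data.frame: probe_id, drug, foldmean, foldsd
#' @slot probes,drugs,times the index sets, in output order
#' @seealso \code{\link{foldChanges}}, \code{\link{g2mScore}}
#' @export
setClass("FoldChangeTable",
         representation(table = "data.frame", summary = "data.frame",
                        probes = "character", drugs = "character",
                        times = "numeric"))

setValidity("FoldChangeTable", function(object) {
  tb <- object@table
  need <- c("probe_id", "drug", "time_h", "log2fc", "fold", "t_p")
  if (!all(need %in% colnames(tb)))
    return("table lacks required columns")
  if (any(tb$fold <= 0)) return("fold ratios must be positive")
  if (any(tb$t_p < 0 | tb$t_p > 1)) return("t_p outside [0, 1]")
  if (any(object@summary$foldsd < 0, na.rm = TRUE))
    return("foldsd must be >= 0")
  TRUE
})

#' @export
#' @describeIn FoldChangeTable the long (probe, drug, time) table
#' @param x a FoldChangeTable
fcTable <- function(x) { stopifnot(is(x, "FoldChangeTable")); x@table }

#' @export
#' @describeIn FoldChangeTable the per-(probe, drug) consistency summary
fcSummary <- function(x) { stopifnot(is(x, "FoldChangeTable")); x@summary }

setMethod("show", "FoldChangeTable", function(object) {
  cat("FoldChangeTable:", length(object@probes), "probes x",
      length(object@drugs), "drugs x", length(object@times), "time-points\n")
})

#' Selection-score table
#'
#' Scores per (probe, drug, time) from the composite selection score, with
#' drug-level aggregates (per-time score of maximal magnitude, sign retained)
#' and a per-probe global score (drug-level score of maximal magnitude).
#' (probe, drug) pairs with zero cross-time fold-change variance get an
#' undefined (NA) score and are excluded from the aggregates.
#'
#' @slot table data.frame: probe_id, drug, time_h, log2fc, t_p, score
#' @slot drugScores data.frame: probe_id, drug, score
#' @slot globalScores data.frame: probe_id, score
#' @slot excluded data.frame of (probe_id, drug) pairs with undefined scores
#' @seealso \code{\link{g2mScore}}, \code{\link{selectTranscripts}}
#' @export
setClass("G2MScoreTable",
         representation(table = "data.frame", drugScores = "data.frame",
                        globalScores = "data.frame", excluded = "data.frame"))

setMethod("show", "G2MScoreTable", function(object) {
  cat("G2MScoreTable:", nrow(object@globalScores), "probes,",
      length(unique(object@table$drug)), "drugs;",
      nrow(object@excluded), "undefined (probe, drug) pairs\n")
})

#' @export
#' @describeIn G2MScoreTable per-(probe, drug, time) scores
#' @param x a G2MScoreTable
scoreTable <- function(x) { stopifnot(is(x, "G2MScoreTable")); x@table }

#' @export
#' @describeIn G2MScoreTable per-(probe, drug) aggregated scores
drugScores <- function(x) { stopifnot(is(x, "G2MScoreTable")); x@drugScores }

#' @export
#' @describeIn G2MScoreTable per-probe global scores
globalScores <- function(x) { stopifnot(is(x, "G2MScoreTable")); x@globalScores }

#' Minimal-spanning-tree transcriptome map
#'
#' The co-expression tree: nodes are transcripts, edges carry the Spearman
#' correlation distance, and the graph is the minimum spanning tree of the
#' all-pairs distance matrix. Walk length (edge count along the unique tree
#' path) is the clustering metric for network extraction.
#'
#' @slot graph an \pkg{igraph} tree with vertex attribute \code{name} and edge
#'   attribute \code{weight}
#' @slot nodes transcript ids, in input order
#' @seealso \code{\link{buildMST}}, \code{\link{walkLength}},
#'   \code{\link{extractNetworks}}
#' @export
setClass("CoexpressionTree",
         representation(graph = "ANY", nodes = "character"))

setValidity("CoexpressionTree", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("graph slot must hold an igraph object")
  n <- igraph::vcount(g)
  if (igraph::ecount(g) != n - 1L) return("a tree must have n - 1 edges")
  if (!igraph::is_connected(g)) return("tree must be connected")
  TRUE
})

setMethod("show", "CoexpressionTree", function(object) {
  cat("CoexpressionTree:", length(object@nodes), "transcripts,",
      igraph::ecount(object@graph), "edges, total weight",
      format(sum(igraph::E(object@graph)$weight), digits = 5), "\n")
})

#' @export
#' @describeIn CoexpressionTree the underlying igraph object
#' @param x a CoexpressionTree
treeGraph <- function(x) { stopifnot(is(x, "CoexpressionTree")); x@graph }

#' @export
#' @describeIn CoexpressionTree transcript ids
treeNodes <- function(x) { stopifnot(is(x, "CoexpressionTree")); x@nodes }

#' Principal component analysis of drug expression profiles
#'
#' @slot scores drug x component coordinates
#' @slot loadings feature x component weights (orthonormal columns)
#' @slot varFrac fraction of total variance per retained component
#' @slot totalVarFrac variance fractions over all non-trivial components
#' @seealso \code{\link{pcaDrugs}}
#' @export
setClass("DrugPCA",
         representation(scores = "matrix", loadings = "matrix",
                        varFrac = "numeric", totalVarFrac = "numeric"))

setValidity("DrugPCA", function(object) {
  if (any(object@varFrac < 0 | object@varFrac > 1))
    return("variance fractions must lie in [0, 1]")
  if (sum(object@totalVarFrac) > 1 + 1e-9)
    return("variance fractions sum above 1")
  cp <- crossprod(object@loadings)
  if (max(abs(cp - diag(ncol(cp)))) > 1e-8)
    return("components must be orthonormal")
  TRUE
})

setMethod("show", "DrugPCA", function(object) {
  cat("DrugPCA:", nrow(object@scores), "drugs,", ncol(object@scores),
      "components explaining",
      sprintf("%.1f%%", 100 * sum(object@varFrac)), "of variance\n")
})

#' Ground truth of a synthetic drug-perturbation experiment
#'
#' @slot membership named character: probe id -> planted module label or
#'   \code{"background"}
#' @slot A mechanism x probe sensitivity matrix actually used to generate the
#'   signal
#' @slot B drug x mechanism engagement matrix (vehicle and naive rows all zero)
#' @slot meanSurface probes x samples expected log2 expression (baseline +
#'   planted effect + batch distortion, before noise)
#' @seealso \code{\link{generateExperiment}}
#' @export
setClass("SyntheticTruth",
         representation(membership = "character", A = "matrix", B = "matrix",
                        meanSurface = "matrix"))

setValidity("SyntheticTruth", function(object) {
  if (!all(is.finite(object@meanSurface)))
    return("mean surface must be finite")
  TRUE
})

setMethod("show", "SyntheticTruth", function(object) {
  sizes <- table(object@membership)
  cat("SyntheticTruth:", nrow(object@meanSurface), "probes;",
      "modules:", paste(names(sizes), sizes, sep = "=", collapse = ", "), "\n")
})

#' @export
#' @describeIn SyntheticTruth planted module labels per probe
#' @param x a SyntheticTruth
trueMembership <- function(x) { stopifnot(is(x, "SyntheticTruth")); x@membership }

#' @export
#' @describeIn SyntheticTruth planted mechanism x probe sensitivities
trueSensitivity <- function(x) { stopifnot(is(x, "SyntheticTruth")); x@A }

#' @export
#' @describeIn SyntheticTruth planted drug x mechanism engagement
trueBinding <- function(x) { stopifnot(is(x, "SyntheticTruth")); x@B }

#' @export
#' @describeIn SyntheticTruth expected (noise-free) expression surface
meanSurface <- function(x) { stopifnot(is(x, "SyntheticTruth")); x@meanSurface }

#' Named gene sets over a background universe
#'
#' @slot sets named list of character vectors (members within the universe;
#'   outsiders are dropped with a warning at construction)
#' @slot universe background transcript universe
#' @seealso \code{\link{setEnrichment}}, \code{\link{readGMT}}
#' @export
setClass("GeneSetCollection2",
         representation(sets = "list", universe = "character"))

setValidity("GeneSetCollection2", function(object) {
  if (!length(object@universe)) return("universe must be non-empty")
  if (is.null(names(object@sets)) || any(names(object@sets) == ""))
    return("gene sets must be named")
  if (any(!lengths(object@sets))) return("gene sets must be non-empty")
  TRUE
})

#' Construct a gene set collection
#'
#' Members outside the universe are dropped with a warning; duplicated ids
#' within a set are removed. Sets emptied by the filtering are dropped.
#'
#' @param sets named list of character vectors
#' @param universe character vector of background ids
#' @return a \linkS4class{GeneSetCollection2}
#' @export
geneSetCollection <- function(sets, universe) {
  universe <- unique(as.character(universe))
  sets <- lapply(sets, function(s) unique(as.character(s)))
  n_out <- sum(vapply(sets, function(s) sum(!s %in% universe), 0L))
  if (n_out > 0)
    warning(n_out, " set member(s) outside the universe dropped")
  sets <- lapply(sets, function(s) s[s %in% universe])
  sets <- sets[lengths(sets) > 0]
  new("GeneSetCollection2", sets = sets, universe = universe)
}

setMethod("show", "GeneSetCollection2", function(object) {
  cat("GeneSetCollection2:", length(object@sets), "sets over",
      length(object@universe), "background ids\n")
})

#' @export
#' @describeIn geneSetCollection the named list of sets
#' @param x a GeneSetCollection2
geneSets <- function(x) { stopifnot(is(x, "GeneSetCollection2")); x@sets }

#' @export
#' @describeIn geneSetCollection the background universe
setUniverse <- function(x) { stopifnot(is(x, "GeneSetCollection2")); x@universe }
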