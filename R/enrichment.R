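#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member ids, tab-separated.
#'
#' @param path GMT file path
#' @param universe background universe; defaults to the union of all set
#'   members
#' @return a \linkS4class{GeneSetCollection2}
#' @export
readGMT <- function(path, universe = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) stop("malformed GMT line(s): ", which(bad)[1])
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1)
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT")
  if (is.null(universe)) universe <- unique(unlist(sets, use.names = FALSE))
  geneSetCollection(sets, universe)
}

#' Write gene sets in GMT format
#'
#' @param collection a \linkS4class{GeneSetCollection2}
#' @param path output path
#' @return invisibly, the path
#' @export
writeGMT <- function(collection, path) {
  sets <- geneSets(collection)
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), ""), path)
  invisible(path)
}

#' Over-representation analysis of a transcript list
#'
#' One-sided (enrichment) Fisher's exact test of each gene set against the
#' selected list over the background universe. Sets overlapping the selection
#' by fewer than \code{minOverlap} transcripts (default 3) are not reported.
#' Fold enrichment is \eqn{(k/n)/(K/N)} with k = selected-and-in-set, n =
#' selected, K = set size in the universe, N = universe size. Results are
#' sorted by P. Duplicated ids are removed and selected ids outside the
#' universe are dropped with a warning.
#'
#' @param selected character vector of selected transcript ids
#' @param collection a \linkS4class{GeneSetCollection2}
#' @param minOverlap minimum k for a set to be reported
#' @param alpha significance level for the \code{significant} flag
#' @param adjust \code{"none"} (nominal P, the default) or \code{"bh"}
#' @return data.frame: set, k, n, K, N, fold, P, (P_bh,) significant
#' @export
setEnrichment <- function(selected, collection, minOverlap = 3, alpha = 0.05,
                          adjust = c("none", "bh")) {
  adjust <- match.arg(adjust)
  stopifnot(is(collection, "GeneSetCollection2"))
  universe <- setUniverse(collection)
  selected <- unique(selected)
  outside <- setdiff(selected, universe)
  if (length(outside)) {
    warning(length(outside), " selected id(s) outside the universe dropped")
    selected <- intersect(selected, universe)
  }
  if (!length(selected)) stop("empty selection after universe filtering")
  N <- length(universe)
  n <- length(selected)
  sets <- geneSets(collection)
  rows <- lapply(names(sets), function(nm) {
    members <- sets[[nm]]
    K <- length(members)
    k <- length(intersect(selected, members))
    if (k < minOverlap) return(NULL)
    p <- stats::fisher.test(
      matrix(c(k, K - k, n - k, N - K - (n - k)), 2, 2),
      alternative = "greater")$p.value
    data.frame(set = nm, k = k, n = n, K = K, N = N,
               fold = (k / n) / (K / N), P = p)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(set = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), fold = numeric(),
                      P = numeric())
  out <- out[order(out$P, out$set), , drop = FALSE]
  rownames(out) <- NULL
  if (adjust == "bh") {
    out$P_bh <- adjustPvalues(out$P, "bh")
    out$significant <- out$P_bh < alpha
  } else {
    out$significant <- out$P < alpha
  }
  out
}

#' Compare a scalar annotation between selected and background transcripts
#'
#' E.g. mRNA half-lives: reports the median annotation value in the selected
#' and background groups and a two-sided Wilcoxon rank-sum P value for a
#' distribution shift.
#'
#' @param selected selected transcript ids
#' @param scalarTable data.frame(gene_id, value) or a named numeric vector
#' @param background background transcript ids (default: all annotated ids
#'   not in the selection)
#' @return list: medianSelected, medianBackground, P, nSelected, nBackground
#' @export
compareScalarAnnotation <- function(selected, scalarTable, background = NULL) {
  if (is.data.frame(scalarTable)) {
    vals <- stats::setNames(scalarTable[[2]], scalarTable[[1]])
  } else vals <- scalarTable
  selected <- unique(selected)
  if (is.null(background)) background <- setdiff(names(vals), selected)
  vs <- vals[intersect(selected, names(vals))]
  vb <- vals[intersect(background, names(vals))]
  if (length(vs) < 5 || length(vb) < 5)
    stop("need >= 5 annotated transcripts in each group")
  p <- stats::wilcox.test(vs, vb, exact = FALSE)$p.value
  list(medianSelected = stats::median(vs),
       medianBackground = stats::median(vb),
       P = p, nSelected = length(vs), nBackground = length(vb))
}
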