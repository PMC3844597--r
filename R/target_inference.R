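# Moore-Penrose pseudoinverse via SVD; gives the minimum-norm least-squares
# solution for rank-deficient systems.
.pinv <- function(M, tol = 1e-10) {
  s <- svd(M)
  keep <- s$d > tol * max(s$d, .Machine$double.eps)
  if (!any(keep)) return(matrix(0, ncol(M), nrow(M)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Convert a Ki table to a binding matrix
#'
#' Engagement strength \eqn{B = \max(0, pKi - floor)} with
#' \eqn{pKi = -\log_{10}(Ki\ [M])}; the default floor of 5 corresponds to a
#' 10 uM affinity cutoff, so Ki = 1 nM gives B = 4. Missing (drug, mechanism)
#' pairs mean no measurable affinity and map to 0. Tighter binding always
#' gives larger B.
#'
#' @param kiTable data.frame with columns \code{drug}, \code{mechanism} and
#'   \code{Ki_nM} (positive, in nanomolar)
#' @param floor pKi floor (default 5)
#' @param drugs,mechanisms row/column order of the result; default: order of
#'   first appearance in the table
#' @return drug x mechanism numeric matrix
#' @examples
#' kiToBinding(data.frame(drug = "BUP", mechanism = "DAT", Ki_nM = 1))
#' @export
kiToBinding <- function(kiTable, floor = 5, drugs = NULL, mechanisms = NULL) {
  need <- c("drug", "mechanism", "Ki_nM")
  if (!all(need %in% colnames(kiTable)))
    stop("kiTable needs columns drug, mechanism, Ki_nM")
  if (any(!is.na(kiTable$Ki_nM) & kiTable$Ki_nM <= 0))
    stop("Ki values must be positive")
  if (is.null(drugs)) drugs <- unique(kiTable$drug)
  if (is.null(mechanisms)) mechanisms <- unique(kiTable$mechanism)
  B <- matrix(0, length(drugs), length(mechanisms),
              dimnames = list(drugs, mechanisms))
  ok <- !is.na(kiTable$Ki_nM)
  pki <- -log10(kiTable$Ki_nM[ok] * 1e-9)
  B[cbind(match(kiTable$drug[ok], drugs),
          match(kiTable$mechanism[ok], mechanisms))] <- pmax(0, pki - floor)
  B
}

#' Fit transcript sensitivities to mechanism activation
#'
#' Bilinear response model: the expression alteration of transcript \eqn{g}
#' under drug \eqn{d} is \eqn{E_{g d} = \sum_m A_{m g} B_{d m}}. Given the
#' observed response matrix E (transcript x drug) and the binding matrix B
#' (drug x mechanism), the sensitivities A are estimated per transcript by
#' least squares, \eqn{\min_A \|E^T - B A\|^2}; for rank-deficient B the
#' minimum-norm solution is returned. An optional ridge penalty stabilises
#' ill-conditioned binding matrices.
#'
#' @param E transcript x drug response matrix (e.g. from
#'   \code{\link{drugResponseMatrix}}); columns must align with B's rows
#' @param B drug x mechanism binding matrix
#' @param ridge ridge penalty (default 0 = plain least squares)
#' @return mechanism x transcript sensitivity matrix
#' @export
fitSensitivity <- function(E, B, ridge = 0) {
  E <- as.matrix(E); B <- as.matrix(B)
  if (ncol(E) != nrow(B))
    stop("E columns (", ncol(E), ") must match B rows (", nrow(B), ")")
  if (!is.null(colnames(E)) && !is.null(rownames(B)) &&
      !identical(colnames(E), rownames(B)))
    stop("drug names of E and B disagree")
  if (all(B == 0)) stop("binding matrix is all zero")
  A <- if (ridge > 0) {
    solve(crossprod(B) + diag(ridge, ncol(B)), t(B) %*% t(E))
  } else {
    .pinv(B) %*% t(E)
  }
  dimnames(A) <- list(colnames(B), rownames(E))
  A
}

#' Reduce a sensitivity matrix to the most sensitive transcripts
#'
#' Takes, for each mechanism, the \code{topK} transcripts of largest absolute
#' sensitivity (ties broken by transcript id) and returns the union,
#' duplicates removed.
#'
#' @param A mechanism x transcript sensitivity matrix
#' @param topK transcripts kept per mechanism (default 50)
#' @return list: \code{transcripts} (sorted union), \code{A} (reduced
#'   mechanism x transcript matrix), \code{unionSize}
#' @export
reduceSensitive <- function(A, topK = 50) {
  if (topK <= 0) stop("topK must be positive")
  if (topK > ncol(A)) stop("topK exceeds transcript count")
  ids <- colnames(A)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(A)))
  picked <- unique(unlist(lapply(seq_len(nrow(A)), function(m) {
    ord <- order(-abs(A[m, ]), ids)
    ids[ord[seq_len(topK)]]
  })))
  picked <- sort(picked)
  list(transcripts = picked,
       A = A[, picked, drop = FALSE],
       unionSize = length(picked))
}

#' Predict a query drug's mechanism activation from its signature
#'
#' Least-squares fit of the bilinear model to the query drug's expression
#' vector over the reduced transcript set: the activation vector b minimises
#' \eqn{\|E' - A'^T b\|^2} (minimum-norm solution if underdetermined).
#' Activations are signed; no non-negativity constraint is imposed.
#'
#' @param eQuery named response vector over the reduced transcript set
#' @param A reduced mechanism x transcript sensitivity matrix (as from
#'   \code{\link{reduceSensitive}})
#' @return list: \code{activation} (named per-mechanism vector),
#'   \code{residual} (Euclidean norm of the fit residual)
#' @export
predictMechanisms <- function(eQuery, A) {
  A <- as.matrix(A)
  if (!ncol(A)) stop("reduced transcript set is empty")
  if (!is.null(names(eQuery)) && !is.null(colnames(A))) {
    missing <- setdiff(colnames(A), names(eQuery))
    if (length(missing))
      stop("query lacks transcript(s): ",
           paste(utils::head(missing, 5), collapse = ", "))
    eQuery <- eQuery[colnames(A)]
  }
  if (length(eQuery) != ncol(A))
    stop("query length must match the reduced transcript set")
  b <- as.numeric(.pinv(t(A)) %*% eQuery)
  names(b) <- rownames(A)
  list(activation = b,
       residual = sqrt(sum((eQuery - as.numeric(t(A) %*% b))^2)))
}

#' Leave-one-out validation of mechanism prediction
#'
#' For each drug: refit the sensitivities without it, reduce to the most
#' sensitive transcripts, predict the held-out drug's activation vector from
#' its expression signature, and compare with its true binding row (cosine
#' similarity, and the rank of the drug's strongest true mechanism in the
#' predicted activations). A drug whose mechanisms are all unused by the
#' remaining drugs is flagged unpredictable (NA similarity/rank).
#'
#' @param E transcript x drug response matrix
#' @param B drug x mechanism binding matrix (aligned with E's columns)
#' @param topK transcripts per mechanism for the reduction step
#' @return data.frame: drug, cosine, rank_of_true, predictable
#' @export
looValidate <- function(E, B, topK = 50) {
  E <- as.matrix(E); B <- as.matrix(B)
  if (ncol(E) < 3) stop("need >= 3 drugs for leave-one-out validation")
  drugs <- colnames(E)
  if (is.null(drugs)) drugs <- as.character(seq_len(ncol(E)))
  res <- lapply(seq_along(drugs), function(d) {
    Bm <- B[-d, , drop = FALSE]
    identifiable <- colSums(abs(Bm)) > 0
    true_b <- B[d, ]
    predictable <- any(true_b[identifiable] != 0)
    if (!predictable)
      return(data.frame(drug = drugs[d], cosine = NA_real_,
                        rank_of_true = NA_real_, predictable = FALSE))
    A <- fitSensitivity(E[, -d, drop = FALSE], Bm)
    red <- reduceSensitive(A, topK = min(topK, ncol(A)))
    pred <- predictMechanisms(E[red$transcripts, d], red$A)$activation
    v1 <- pred[identifiable]
    v2 <- true_b[identifiable]
    cosine <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
    top_true <- which.max(abs(true_b * identifiable))
    rk <- rank(-pred)[top_true]
    data.frame(drug = drugs[d], cosine = cosine, rank_of_true = rk,
               predictable = TRUE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
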