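# Shared fixtures and independent oracles, built in code.

# A minimal one-drug-vs-saline experiment with hand-set values.
tinyExperiment <- function(drug_vals, veh_vals, times = c(1, 2, 4, 8),
                           drug = "COC") {
  n_rep <- 3L
  sheet <- expand.grid(replicate = seq_len(n_rep), time_h = times,
                       drug = c(drug, "SAL"), stringsAsFactors = FALSE)
  sheet$sample_id <- sprintf("%s_t%g_r%d", sheet$drug, sheet$time_h,
                             sheet$replicate)
  sheet$batch <- "b1"
  sheet$is_vehicle <- sheet$drug == "SAL"
  sheet$control <- ifelse(sheet$is_vehicle, NA_character_, "SAL")
  sheet$role <- ifelse(sheet$is_vehicle, "vehicle", "treatment")
  n_probe <- if (is.matrix(drug_vals)) nrow(drug_vals) else length(drug_vals)
  m <- matrix(NA_real_, n_probe, nrow(sheet),
              dimnames = list(sprintf("p%02d", seq_len(n_probe)),
                              sheet$sample_id))
  m[, sheet$drug == drug] <- drug_vals
  m[, sheet$drug == "SAL"] <- veh_vals
  DrugExpressionSet(m, sheet)
}

# Decode a Pruefer sequence into the edge list of the labelled tree on n
# nodes (smallest-leaf rule). Independent oracle for tree enumeration.
pruferToEdges <- function(s, n) {
  deg <- rep(1L, n)
  for (x in s) deg[x] <- deg[x] + 1L
  edges <- matrix(0L, n - 1L, 2L)
  for (i in seq_along(s)) {
    leaf <- which(deg == 1L)[1]
    edges[i, ] <- c(leaf, s[i])
    deg[leaf] <- 0L
    deg[s[i]] <- deg[s[i]] - 1L
  }
  edges[n - 1L, ] <- which(deg == 1L)
  edges
}

# Exhaustive minimum spanning tree weight by enumerating every labelled tree
# on n nodes (n^(n-2) Pruefer sequences).
bruteForceMSTWeight <- function(d) {
  n <- nrow(d)
  if (n == 2) return(d[1, 2])
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  best <- Inf
  for (r in seq_len(nrow(seqs))) {
    e <- pruferToEdges(seqs[r, ], n)
    w <- sum(d[e])
    if (w < best) best <- w
  }
  best
}

# Random tree as a CoexpressionTree, via a random Pruefer sequence.
randomTree <- function(n, seed) {
  withr::with_seed(seed, {
    s <- sample(n, max(n - 2L, 0L), replace = TRUE)
    e <- pruferToEdges(s, n)
    nodes <- sprintf("t%03d", seq_len(n))
    d <- matrix(1, n, n, dimnames = list(nodes, nodes))
    g <- igraph::graph_from_edgelist(matrix(nodes[e], ncol = 2),
                                     directed = FALSE)
    igraph::E(g)$weight <- 1
    g <- igraph::permute(g, match(igraph::V(g)$name, nodes))
    new("CoexpressionTree", graph = g, nodes = nodes)
  })
}

# Upper-tail hypergeometric probability by explicit binomial-coefficient
# summation; independent oracle for Fisher enrichment P values.
hyperTailOracle <- function(k, n, K, N) {
  hi <- min(n, K)
  if (k > hi) return(0)
  i <- k:hi
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}
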