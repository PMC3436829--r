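# Shared fixtures and independent oracles, all built in code.

# random typed pathway graph (70% proteins) with random signed edges
random_pathway <- function(n_ent, n_edge, seed) {
  set.seed(seed)
  kinds <- sample(c("protein", "complex", "family", "abstract-process"),
                  n_ent, replace = TRUE, prob = c(0.7, 0.1, 0.1, 0.1))
  ids <- sprintf("E%02d", seq_len(n_ent))
  src <- sample(ids, n_edge, replace = TRUE)
  tgt <- sample(ids, n_edge, replace = TRUE)
  keep <- src != tgt
  types <- sample(c("transcriptional-activation", "transcriptional-inhibition",
                    "protein-activation", "protein-inhibition",
                    "component-of", "member-of"),
                  sum(keep), replace = TRUE)
  ints <- unique(data.frame(source = src[keep], target = tgt[keep],
                            edge_type = types, stringsAsFactors = FALSE))
  pathway_graph(data.frame(id = ids, kind = kinds, stringsAsFactors = FALSE),
                ints)
}

# Exhaustive simple-path oracle for the minimum number of intervening
# proteins between each entity and the focus (component/member edges
# traversed both ways), fully independent of the Dijkstra implementation.
oracle_hop_dist <- function(graph, focus, direction) {
  e <- graph$interactions
  fr <- e$source; to <- e$target
  sym <- e$edge_type %in% c("component-of", "member-of")
  fr <- c(fr, e$target[sym]); to <- c(to, e$source[sym])
  if (direction == "to") { tmp <- fr; fr <- to; to <- tmp } # walk backwards
  adj <- split(to, fr)
  kind <- setNames(graph$entities$kind, graph$entities$id)
  best <- setNames(rep(Inf, nrow(graph$entities)), graph$entities$id)
  best[focus] <- 0
  dfs <- function(node, cost, visited) {
    for (nxt in adj[[node]]) {
      if (nxt %in% visited) next
      step <- if (node == focus) 0 else
        as.integer(kind[[node]] == "protein")
      nc <- cost + step
      if (nc < best[[nxt]]) best[nxt] <<- nc
      if (nc <= best[[nxt]])
        dfs(nxt, nc, c(visited, nxt))
    }
  }
  dfs(focus, 0, focus)
  best
}

oracle_neighborhood <- function(graph, focus, k) {
  up <- oracle_hop_dist(graph, focus, "to")
  dn <- oracle_hop_dist(graph, focus, "from")
  regulators <- setdiff(names(up)[up <= k], focus)
  targets <- setdiff(names(dn)[dn <= k], focus)
  both <- intersect(regulators, targets)
  list(regulators = sort(setdiff(regulators, both)),
       targets = sort(setdiff(targets, both)))
}

# independent average-rank implementation for the rank-ratio oracle
oracle_rank_ratio <- function(m) {
  x <- as.vector(m)
  n <- sum(!is.na(x))
  out <- vapply(x, function(v) {
    if (is.na(v)) return(NA_real_)
    r <- sum(x < v, na.rm = TRUE) + (sum(x == v, na.rm = TRUE) + 1) / 2
    (r - 1) / (n - 1)
  }, numeric(1))
  matrix(out, nrow = nrow(m), dimnames = dimnames(m))
}

# random tree-structured factor graph over ternary variables
random_tree_fg <- function(n, seed, ev = TRUE) {
  set.seed(seed)
  vars <- paste0("v", seq_len(n))
  facs <- if (n > 1)
    lapply(2:n, function(i)
      list(vars = c(sample(i - 1, 1), i), table = runif(9, 0.05, 1)))
  else list(list(vars = 1, table = runif(3, 0.05, 1)))
  pot <- if (ev) matrix(runif(3 * n, 0.1, 1), 3 * n, 1) else NULL
  factor_graph(vars, facs, pot)
}

# 8-variable loopy fixture: one directed cycle of pairwise factors
random_cycle_fg <- function(n, seed, lo = 0.3, hi = 1.7) {
  set.seed(seed)
  facs <- lapply(seq_len(n), function(i)
    list(vars = c(i, i %% n + 1), table = runif(9, lo, hi)))
  factor_graph(paste0("v", seq_len(n)), facs,
               matrix(runif(3 * n, 0.3, 1), 3 * n, 1))
}

# five-protein archetype: two regulators -> focus -> two targets
archetype_pathway <- function() {
  pathway_graph(
    data.frame(id = c("U1", "U2", "F", "T1", "T2"), kind = "protein",
               stringsAsFactors = FALSE),
    data.frame(source = c("U1", "U2", "F", "F"),
               target = c("F", "F", "T1", "T2"),
               edge_type = c("protein-activation", "protein-activation",
                             "transcriptional-activation",
                             "transcriptional-activation"),
               stringsAsFactors = FALSE))
}

# dataset of pre-transformed rank-ratios on the archetype entities
archetype_data <- function(u, f, t) {
  m <- matrix(c(u, u, f, t, t), nrow = 5, ncol = 2,
              dimnames = list(c("U1", "U2", "F", "T1", "T2"),
                              c("s1", "s2")))
  omics_dataset(m, m, transformed = TRUE)
}
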