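# Pathway graphs: typed entities (protein/complex/family/abstract-process)
# and signed directed interactions, read from the two/three-column
# tab-delimited convention used by curated "SuperPathway" files.

ENTITY_KINDS <- c("protein", "complex", "family", "abstract-process")

EDGE_CODES <- c(
  "-t>"        = "transcriptional-activation",
  "-t|"        = "transcriptional-inhibition",
  "-a>"        = "protein-activation",
  "-a|"        = "protein-inhibition",
  "component>" = "component-of",
  "member>"    = "member-of"
)

EDGE_SIGNS <- c(
  "transcriptional-activation" = 1,
  "transcriptional-inhibition" = -1,
  "protein-activation"         = 1,
  "protein-inhibition"         = -1,
  "component-of"               = 1,
  "member-of"                  = 1
)

#' Construct a pathway graph from entity and interaction tables
#'
#' @param entities data.frame with columns `id`, `kind` (one of `"protein"`,
#'   `"complex"`, `"family"`, `"abstract-process"`).
#' @param interactions data.frame with columns `source`, `target`,
#'   `edge_type` (full names as in [parse_pathway()]); a `sign` column is
#'   derived (−1 for inhibitions, +1 otherwise).
#' @return A `pshift_pathway` object.
#' @export
pathway_graph <- function(entities, interactions = NULL) {
  entities <- as.data.frame(entities, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "kind") %in% names(entities)))
  if (anyDuplicated(entities$id))
    stop("duplicate entity ids: ",
         paste(unique(entities$id[duplicated(entities$id)]), collapse = ", "))
  bad <- setdiff(unique(entities$kind), ENTITY_KINDS)
  if (length(bad)) stop("unknown entity kind(s): ", paste(bad, collapse = ", "))
  if (is.null(interactions) || nrow(interactions) == 0) {
    interactions <- data.frame(source = character(), target = character(),
                               edge_type = character(), sign = numeric(),
                               stringsAsFactors = FALSE)
  } else {
    interactions <- as.data.frame(interactions, stringsAsFactors = FALSE)
    stopifnot(all(c("source", "target", "edge_type") %in% names(interactions)))
    bad <- setdiff(unique(interactions$edge_type), unname(EDGE_CODES))
    if (length(bad)) stop("unknown edge type(s): ", paste(bad, collapse = ", "))
    miss <- setdiff(unique(c(interactions$source, interactions$target)),
                    entities$id)
    if (length(miss))
      stop("interaction references unknown entity: ",
           paste(miss, collapse = ", "))
    interactions$sign <- unname(EDGE_SIGNS[interactions$edge_type])
  }
  structure(list(entities = entities, interactions = interactions),
            class = "pshift_pathway")
}

#' Parse a tab-delimited pathway file
#'
#' The file mixes entity lines (`kind<TAB>id`) and interaction lines
#' (`source<TAB>target<TAB>code`) where `code` is one of `-t>` `-t|` `-a>`
#' `-a|` (transcriptional / protein-level activation and inhibition),
#' `component>` (component into complex) or `member>` (member into family).
#' Blank lines and lines starting with `#` are skipped.
#'
#' @param path path to the pathway file.
#' @return A `pshift_pathway` object.
#' @export
parse_pathway <- function(path) {
  if (!file.exists(path)) stop("pathway file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  ents <- list()
  ints <- list()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln)) || startsWith(trimws(ln), "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    f <- f[nzchar(f)]
    if (length(f) == 2) {
      if (!f[1] %in% ENTITY_KINDS)
        stop(sprintf("line %d: unknown entity kind '%s'", i, f[1]))
      ents[[length(ents) + 1L]] <- data.frame(id = f[2], kind = f[1],
                                              stringsAsFactors = FALSE)
    } else if (length(f) == 3) {
      if (!f[3] %in% names(EDGE_CODES))
        stop(sprintf("line %d: unknown edge-type code '%s'", i, f[3]))
      ints[[length(ints) + 1L]] <-
        data.frame(source = f[1], target = f[2],
                   edge_type = unname(EDGE_CODES[f[3]]),
                   stringsAsFactors = FALSE)
    } else {
      stop(sprintf("line %d: malformed line (expected 2 or 3 fields, got %d)",
                   i, length(f)))
    }
  }
  entities <- if (length(ents)) do.call(rbind, ents) else
    data.frame(id = character(), kind = character(), stringsAsFactors = FALSE)
  interactions <- if (length(ints)) do.call(rbind, ints) else NULL
  pathway_graph(entities, interactions)
}

#' @export
print.pshift_pathway <- function(x, ...) {
  cat(sprintf("pshift pathway graph: %d entities (%s), %d interactions\n",
              nrow(x$entities),
              paste(sprintf("%d %s", table(x$entities$kind),
                            names(table(x$entities$kind))), collapse = ", "),
              nrow(x$interactions)))
  invisible(x)
}

entity_kind <- function(graph, ids) {
  setNames(graph$entities$kind, graph$entities$id)[ids]
}

# Directed adjacency used for reachability.  component-of / member-of edges
# are traversed in both directions: a complex's activity both informs and is
# informed by its constituents.
reach_edges <- function(graph) {
  e <- graph$interactions
  if (nrow(e) == 0)
    return(data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE))
  out <- data.frame(from = e$source, to = e$target, stringsAsFactors = FALSE)
  sym <- e$edge_type %in% c("component-of", "member-of")
  if (any(sym))
    out <- rbind(out, data.frame(from = e$target[sym], to = e$source[sym],
                                 stringsAsFactors = FALSE))
  unique(out)
}

# Minimal number of *intervening proteins* (protein-kind nodes strictly
# between node and focus; complexes/families/processes are free hops) over
# directed paths.  direction = "to" gives cost of reaching `focus` FROM each
# node; "from" the cost of reaching each node from `focus`.  Dijkstra with
# 0/1 node weights.
protein_hop_dist <- function(graph, focus, direction = c("to", "from")) {
  direction <- match.arg(direction)
  edges <- reach_edges(graph)
  ids <- graph$entities$id
  kind <- entity_kind(graph, ids)
  # For "to": relax u -> x, cost added = weight of x (the node entered,
  #   unless it is the focus endpoint).  Traverse edges backwards from focus.
  # For "from": relax x -> u, cost added = weight of x (the node left,
  #   unless it is the focus endpoint).
  dist <- setNames(rep(Inf, length(ids)), ids)
  dist[focus] <- 0
  done <- setNames(rep(FALSE, length(ids)), ids)
  if (direction == "to") {
    nb <- split(edges$from, edges$to)        # expanding x reaches its in-nbrs
  } else {
    nb <- split(edges$to, edges$from)        # expanding x reaches its out-nbrs
  }
  repeat {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    x <- names(dist)[cand][which.min(dist[cand])]
    done[x] <- TRUE
    step <- if (x == focus) 0 else as.integer(kind[x] == "protein")
    for (u in nb[[x]] %||% character()) {
      if (dist[x] + step < dist[u]) dist[u] <- dist[x] + step
    }
  }
  dist
}

#' Extract the local upstream/downstream neighborhood of a focus gene
#'
#' Regulators are entities with a directed path to the focus containing at
#' most `k` intervening proteins (complexes, families and abstract processes
#' are free hops); targets are defined symmetrically downstream.  Entities
#' reachable in both directions (feedback circuitry) are excluded from both
#' sets.  All interactions among the retained entities and the focus are
#' kept.
#'
#' @param graph a `pshift_pathway`.
#' @param focus entity id of the focus gene.
#' @param k maximum number of intervening proteins on a qualifying path
#'   (default 1).
#' @return A `pshift_neighborhood` with elements `focus`, `regulators`,
#'   `targets`, `interactions`, `hop_limit` and `kinds`.
#' @export
extract_neighborhood <- function(graph, focus, k = 1) {
  stopifnot(k >= 0)
  if (!focus %in% graph$entities$id)
    stop("focus entity not in pathway: ", focus)
  up <- protein_hop_dist(graph, focus, "to")
  dn <- protein_hop_dist(graph, focus, "from")
  regulators <- setdiff(names(up)[up <= k], focus)
  targets <- setdiff(names(dn)[dn <= k], focus)
  both <- intersect(regulators, targets)     # feedback exclusion
  regulators <- setdiff(regulators, both)
  targets <- setdiff(targets, both)
  keep <- c(focus, regulators, targets)
  e <- graph$interactions
  e <- e[e$source %in% keep & e$target %in% keep, , drop = FALSE]
  rownames(e) <- NULL
  if (!length(regulators) && !length(targets))
    warning("focus '", focus, "' has an empty neighborhood at k = ", k)
  structure(list(focus = focus,
                 regulators = regulators,
                 targets = targets,
                 interactions = e,
                 hop_limit = k,
                 kinds = setNames(entity_kind(graph, keep), keep)),
            class = "pshift_neighborhood")
}

#' @export
print.pshift_neighborhood <- function(x, ...) {
  cat(sprintf(
    "pshift neighborhood of '%s' (k = %d): %d regulators, %d targets, %d interactions\n",
    x$focus, x$hop_limit, length(x$regulators), length(x$targets),
    nrow(x$interactions)))
  invisible(x)
}

# constituents (components / members) of a complex or family inside a
# neighborhood's retained interaction set
nbhd_constituents <- function(nbhd, id) {
  e <- nbhd$interactions
  e$source[e$target == id & e$edge_type %in% c("component-of", "member-of")]
}

#' Drop low-variance neighbors
#'
#' Protein neighbors whose rank-ratio-transformed expression has a standard
#' deviation across samples below `min_sd` are removed from the regulator and
#' target sets (default cut 0.10).  Complexes and families are kept as long
#' as at least one constituent survives; entities without an expression row
#' are retained (the filter targets uninformative data, not missing data);
#' the focus gene is never dropped.
#'
#' @param nbhd a `pshift_neighborhood`.
#' @param expr a `pshift_omics` dataset (rank-ratio expression is used).
#' @param min_sd minimum expression standard deviation (default 0.10).
#' @return The filtered `pshift_neighborhood`.
#' @export
variance_filter <- function(nbhd, expr, min_sd = 0.10) {
  stopifnot(min_sd >= 0)
  members <- c(nbhd$regulators, nbhd$targets)
  if (!length(members)) return(nbhd)
  sds <- setNames(rep(NA_real_, length(members)), members)
  have <- members[members %in% rownames(expr$expression)]
  if (length(have))
    sds[have] <- apply(expr$expression[have, , drop = FALSE], 1, sd,
                       na.rm = TRUE)
  drop <- members[nbhd$kinds[members] == "protein" &
                    !is.na(sds) & sds < min_sd]
  # complexes / families fall only if every in-neighborhood constituent fell
  prune_members(nbhd, drop)
}

#' Write a pathway graph to the tab-delimited format
#'
#' @param graph a `pshift_pathway`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pathway <- function(graph, path) {
  code_of <- setNames(names(EDGE_CODES), unname(EDGE_CODES))
  ent <- sprintf("%s\t%s", graph$entities$kind, graph$entities$id)
  int <- character(0)
  if (nrow(graph$interactions))
    int <- sprintf("%s\t%s\t%s", graph$interactions$source,
                   graph$interactions$target,
                   code_of[graph$interactions$edge_type])
  writeLines(c(ent, int), path)
  invisible(path)
}
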