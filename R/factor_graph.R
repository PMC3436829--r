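# Discrete ternary factor graphs: construction from a pathway neighborhood,
# sum-product belief propagation (C++ core, evidence columns batched), an
# exact-enumeration oracle, and inferred pathway levels (IPLs).

STATES <- c("inactive", "baseline", "active")

#' Construct a factor graph directly
#'
#' Mostly useful for tests and experimentation; [build_factor_graph()] is
#' the pathway-driven constructor.
#'
#' @param variables character vector of variable ids (all ternary).
#' @param factors list of factors, each a `list(vars = , table = )` where
#'   `vars` indexes `variables` (or names them) and `table` is a
#'   non-negative numeric vector of length `3^length(vars)` with the first
#'   variable varying fastest.
#' @param potentials optional `(3 * nvar) x ncol` matrix of unary evidence
#'   potentials (rows `3(v-1)+1 .. 3v` belong to variable `v`); `NULL`
#'   means no evidence.
#' @return A `pshift_fg` object.
#' @export
factor_graph <- function(variables, factors = list(), potentials = NULL) {
  nv <- length(variables)
  stopifnot(nv >= 1, !anyDuplicated(variables))
  factors <- lapply(factors, function(f) {
    v <- f$vars
    if (is.character(v)) v <- match(v, variables)
    v <- as.integer(v)
    if (anyNA(v) || any(v < 1) || any(v > nv))
      stop("factor scope refers to unknown variable")
    tab <- as.numeric(f$table)
    if (length(tab) != 3^length(v))
      stop("factor table must have 3^|scope| entries")
    if (any(tab < 0) || all(tab == 0))
      stop("factor tables must be non-negative and not all zero")
    list(vars = v, table = tab)
  })
  ncol <- 1L
  if (!is.null(potentials)) {
    potentials <- as.matrix(potentials)
    if (nrow(potentials) != 3 * nv)
      stop("potentials must have 3 * nvar rows")
    ncol <- ncol(potentials)
  }
  structure(list(variables = variables, factors = factors,
                 potentials = potentials, ncol = ncol, meta = list()),
            class = "pshift_fg")
}

#' @export
print.pshift_fg <- function(x, ...) {
  cat(sprintf("pshift factor graph: %d ternary variables, %d factors, %d evidence column(s)\n",
              length(x$variables), length(x$factors), x$ncol))
  invisible(x)
}

# epsilon-smoothed conditional table for one child given its parents.
# Scope order: (structural parents, vote parents, child), first var fastest.
# Structural parents combine by `rule` (min for complexes, max for
# families); vote parents contribute sign-weighted votes; the child's
# expected state is the sign of the combined value and receives mass
# 1 - 2*epsilon, all other states epsilon.
vote_table <- function(n_struct = 0, struct_rule = c("min", "max"),
                       vote_signs = numeric(0), epsilon = 0.2) {
  struct_rule <- match.arg(struct_rule)
  np <- n_struct + length(vote_signs)
  stopifnot(np >= 1, epsilon > 0, epsilon < 0.5)
  tab <- numeric(3^(np + 1))
  n_combo <- 3^np
  for (tp in 0:(n_combo - 1)) {
    tmp <- tp
    st <- integer(np)
    for (q in seq_len(np)) { st[q] <- tmp %% 3 - 1; tmp <- tmp %/% 3 }
    base <- 0
    if (n_struct > 0) {
      s <- st[seq_len(n_struct)]
      base <- if (struct_rule == "min") min(s) else max(s)
    }
    v <- base + sum(vote_signs * st[n_struct + seq_along(vote_signs)])
    expected <- sign(v) + 2          # 1..3
    for (s in 1:3)
      tab[1 + tp + (s - 1) * n_combo] <-
        if (s == expected) 1 - 2 * epsilon else epsilon
  }
  tab
}

# soft-evidence potentials for a vector of rank-ratio values; NA -> uniform
soft_evidence <- function(v, epsilon = 0.2, cutpoints = c(1 / 3, 2 / 3)) {
  n <- length(v)
  out <- matrix(epsilon, 3, n)
  state <- ifelse(v < cutpoints[1], 1L, ifelse(v > cutpoints[2], 3L, 2L))
  out[cbind(state, seq_len(n))] <- 1 - 2 * epsilon
  out[, is.na(v)] <- 1
  out
}

tier_var <- function(id, tier) {
  if (length(id) == 0) return(character(0)) # paste0 recycles 0-length to ""
  paste0(id, "__", tier)
}

# Mode-restricted factor-graph skeleton (structure + evidence slot map,
# no potentials yet).  Protein entities get a genome -> expression ->
# activity tier chain (copy number attaches to genome, expression to
# expression); complexes, families, abstract processes, and the focus gene
# in targets mode (whose cis data is excluded by construction) get a single
# activity variable.
fg_skeleton <- function(nbhd, mode = c("regulators", "targets"),
                        epsilon = 0.2) {
  mode <- match.arg(mode)
  members <- if (mode == "regulators") nbhd$regulators else nbhd$targets
  if (!length(members))
    stop("cannot build ", mode, " run for '", nbhd$focus,
         "': the ", mode, " set is empty, shift undeterminable")
  nodes <- c(nbhd$focus, members)
  kinds <- nbhd$kinds[nodes]
  e <- nbhd$interactions
  e <- unique(e[e$source %in% nodes & e$target %in% nodes, , drop = FALSE])

  tiered <- kinds == "protein" & !(nodes == nbhd$focus & mode == "targets")
  variables <- character(0)
  for (i in seq_along(nodes)) {
    variables <- c(variables,
                   if (tiered[i]) tier_var(nodes[i], c("genome", "expr",
                                                       "activity"))
                   else tier_var(nodes[i], "activity"))
  }
  vidx <- seq_along(variables)
  names(vidx) <- variables

  factors <- list()
  add_factor <- function(vars, table)
    factors[[length(factors) + 1L]] <<- list(vars = unname(vidx[vars]),
                                             table = table)
  for (i in seq_along(nodes)) {
    id <- nodes[i]
    act <- tier_var(id, "activity")
    inc <- e[e$target == id, , drop = FALSE]
    trans <- inc[inc$edge_type %in% c("transcriptional-activation",
                                      "transcriptional-inhibition"), ,
                 drop = FALSE]
    prot <- inc[inc$edge_type %in% c("protein-activation",
                                     "protein-inhibition"), , drop = FALSE]
    struct <- inc[inc$edge_type %in% c("component-of", "member-of"), ,
                  drop = FALSE]
    # a variable may enter a factor scope only once: collapse multi-edges
    struct <- struct[!duplicated(struct$source), , drop = FALSE]
    trans <- trans[!duplicated(trans$source), , drop = FALSE]
    prot <- prot[!duplicated(prot$source) &
                   !(prot$source %in% struct$source), , drop = FALSE]
    if (tiered[i]) {
      # expression <- genome + transcriptional regulators
      add_factor(c(tier_var(id, "genome"),
                   tier_var(trans$source, "activity"),
                   tier_var(id, "expr")),
                 vote_table(vote_signs = c(1, trans$sign), epsilon = epsilon))
      # activity <- expression + protein-level regulators (+ structural
      # edges into a protein, treated as plain votes)
      add_factor(c(tier_var(id, "expr"),
                   tier_var(c(prot$source, struct$source), "activity"), act),
                 vote_table(vote_signs = c(1, prot$sign,
                                           rep(1, nrow(struct))),
                            epsilon = epsilon))
    } else if (nrow(inc) > 0) {
      if (kinds[i] %in% c("complex", "family") && nrow(struct) > 0) {
        rule <- if (kinds[i] == "complex") "min" else "max"
        vote <- rbind(trans, prot)
        vote <- vote[!(vote$source %in% struct$source), , drop = FALSE]
        add_factor(c(tier_var(struct$source, "activity"),
                     tier_var(vote$source, "activity"), act),
                   vote_table(n_struct = nrow(struct), struct_rule = rule,
                              vote_signs = vote$sign, epsilon = epsilon))
      } else {
        src <- rbind(trans, prot, struct)
        src <- src[!duplicated(src$source), , drop = FALSE]
        add_factor(c(tier_var(src$source, "activity"), act),
                   vote_table(vote_signs = c(src$sign), epsilon = epsilon))
      }
    }
  }

  # evidence slots: expression rows attach to expr tiers, copy number to
  # genome tiers (only tiered = protein entities carry data)
  slots <- data.frame(entity = character(), type = character(),
                      var = integer(), stringsAsFactors = FALSE)
  for (i in which(tiered)) {
    slots <- rbind(slots,
                   data.frame(entity = nodes[i], type = c("expr", "cnv"),
                              var = unname(vidx[tier_var(nodes[i],
                                                         c("expr",
                                                           "genome"))]),
                              stringsAsFactors = FALSE))
  }
  list(variables = variables, factors = factors, slots = slots,
       focus_var = unname(vidx[tier_var(nbhd$focus, "activity")]),
       mode = mode, focus = nbhd$focus)
}

# Fill evidence potentials for a skeleton.  `samples` gives one dataset
# column per evidence column; `assign` optionally remaps entities to other
# genes' data tuples (a character matrix entities x ncol), which is how
# permutation backgrounds are generated.
fg_potentials <- function(skel, data, samples, assign = NULL,
                          epsilon = 0.2, cutpoints = c(1 / 3, 2 / 3)) {
  ncol <- length(samples)
  pot <- matrix(1, 3 * length(skel$variables), ncol)
  scol <- match(samples, data$sample_ids)
  if (anyNA(scol)) stop("unknown sample id(s)")
  for (j in seq_len(nrow(skel$slots))) {
    ent <- skel$slots$entity[j]
    mat <- if (skel$slots$type[j] == "expr") data$expression else
      data$copy_number
    if (is.null(mat)) next
    genes <- if (is.null(assign)) rep(ent, ncol) else assign[ent, ]
    grow <- match(genes, rownames(mat))
    vals <- rep(NA_real_, ncol)
    ok <- !is.na(grow)
    if (any(ok)) vals[ok] <- mat[cbind(grow[ok], scol[ok])]
    v <- skel$slots$var[j]
    pot[(3 * v - 2):(3 * v), ] <- soft_evidence(vals, epsilon, cutpoints)
  }
  pot
}

skel_to_fg <- function(skel, potentials = NULL) {
  fg <- factor_graph(skel$variables, skel$factors, potentials)
  fg$meta <- list(focus_var = skel$focus_var, mode = skel$mode,
                  focus = skel$focus)
  fg
}

#' Build the factor graph for one inference mode
#'
#' In `regulators` mode the focus gene is connected to its upstream
#' regulators only, with evidence on the regulators and on the focus gene's
#' own expression/copy-number data (cis data counts as regulatory
#' information).  In `targets` mode the focus is connected to its downstream
#' targets only, with evidence on the targets and never on the focus.  With
#' `with_evidence = FALSE` all observation factors are dropped, giving the
#' prior-only graph whose IPL is subtracted from the evidence run.
#'
#' @param nbhd a `pshift_neighborhood`.
#' @param data a `pshift_omics` dataset.
#' @param sample one or more sample ids (each becomes an evidence column).
#' @param mode `"regulators"` or `"targets"`.
#' @param with_evidence attach observation factors (default `TRUE`).
#' @param epsilon smoothing mass of the conditional tables (default 0.2).
#' @param cutpoints rank-ratio discretization cut-points (default 1/3, 2/3).
#' @return A `pshift_fg`.
#' @export
build_factor_graph <- function(nbhd, data, sample = data$sample_ids,
                               mode = c("regulators", "targets"),
                               with_evidence = TRUE, epsilon = 0.2,
                               cutpoints = c(1 / 3, 2 / 3)) {
  mode <- match.arg(mode)
  skel <- fg_skeleton(nbhd, mode, epsilon)
  pot <- if (with_evidence)
    fg_potentials(skel, data, sample, NULL, epsilon, cutpoints) else NULL
  skel_to_fg(skel, pot)
}

#' Run sum-product belief propagation
#'
#' Synchronous message schedule with running-average damping; convergence
#' when the largest absolute message change falls below `tol`.
#' Non-convergence is flagged, not fatal.
#'
#' @param fg a `pshift_fg`.
#' @param tol convergence tolerance (default `1e-9`).
#' @param max_iter maximum iterations (default `10000`).
#' @param damping running-average weight on the previous message
#'   (default 0.5).
#' @return A `pshift_marginals` object: array `p` of dimension
#'   `3 x nvar x ncol`, plus per-column `iterations` and `converged`.
#' @export
run_bp <- function(fg, tol = 1e-9, max_iter = 10000, damping = 0.5) {
  stopifnot(tol > 0, max_iter >= 1, damping >= 0, damping < 1)
  nv <- length(fg$variables)
  pot <- fg$potentials %||% matrix(1, 3 * nv, fg$ncol)
  res <- .bp_engine(nv,
                    lapply(fg$factors,
                           function(f) list(vars = f$vars - 1L,
                                            table = f$table)),
                    pot, tol, as.integer(max_iter), damping)
  if (!all(res$converged))
    warning(sum(!res$converged), " evidence column(s) did not converge in ",
            max_iter, " iterations")
  p <- array(res$marginals, dim = c(3, nv, ncol(pot)),
             dimnames = list(STATES, fg$variables, NULL))
  structure(list(p = p, iterations = res$iterations,
                 converged = res$converged, variables = fg$variables,
                 meta = fg$meta),
            class = "pshift_marginals")
}

#' Exact marginals by joint enumeration (test oracle)
#'
#' Enumerates all `3^n` joint states; limited to 12 variables.
#'
#' @param fg a `pshift_fg`.
#' @return A `pshift_marginals` object (with `iterations = 0`).
#' @export
exact_marginals <- function(fg) {
  nv <- length(fg$variables)
  if (nv > 12) stop("exact enumeration limited to 12 variables")
  G <- 3^nv
  state <- lapply(seq_len(nv),
                  function(v) (seq_len(G) - 1) %/% 3^(v - 1) %% 3 + 1)
  pot <- fg$potentials %||% matrix(1, 3 * nv, fg$ncol)
  p <- array(NA_real_, dim = c(3, nv, fg$ncol),
             dimnames = list(STATES, fg$variables, NULL))
  base_w <- rep(1, G)
  for (f in fg$factors) {
    idx <- rep(1L, G)
    for (q in seq_along(f$vars))
      idx <- idx + (state[[f$vars[q]]] - 1L) * 3L^(q - 1L)
    base_w <- base_w * f$table[idx]
  }
  for (col in seq_len(fg$ncol)) {
    w <- base_w
    for (v in seq_len(nv))
      w <- w * pot[3 * (v - 1) + state[[v]], col]
    z <- sum(w)
    if (z <= 0) stop("joint distribution has zero mass")
    for (v in seq_len(nv)) {
      m <- vapply(1:3, function(s) sum(w[state[[v]] == s]), numeric(1))
      p[, v, col] <- m / z
    }
  }
  structure(list(p = p, iterations = rep(0L, fg$ncol),
                 converged = rep(TRUE, fg$ncol), variables = fg$variables,
                 meta = fg$meta),
            class = "pshift_marginals")
}

#' Inferred pathway level from a marginal triple
#'
#' The IPL is a signed log-posterior-odds of the modal state against the
#' mean alternative: if `active` is modal, `log(2 P(active) / (1 -
#' P(active)))`; if `inactive` is modal, the negated odds of `inactive`;
#' if `baseline` is modal (or the modal state is tied), 0.  Measuring the
#' modal state against the *mean* of the other two states (rather than
#' their sum) keeps the sign aligned with the modal state for any ternary
#' posterior — the modal probability always exceeds 1/3, so the score is
#' zero only at indifference and its sign is positive exactly when
#' `active` is modal.  Natural log; the constant offset relative to plain
#' log-odds cancels in downstream Z-normalization.
#'
#' @param m a `pshift_marginals` object, or a probability triple
#'   (inactive, baseline, active).
#' @param gene entity id (its activity variable is used) or exact variable
#'   id; ignored when `m` is a triple.
#' @param col evidence column (default all columns).
#' @return Numeric IPL value(s).
#' @export
ipl_from_marginals <- function(m, gene = NULL, col = NULL) {
  if (is.numeric(m)) {
    stopifnot(length(m) == 3)
    return(ipl_triple(m))
  }
  stopifnot(inherits(m, "pshift_marginals"))
  var <- gene %||% m$variables[m$meta$focus_var]
  if (!var %in% m$variables) {
    var2 <- tier_var(var, "activity")
    if (!var2 %in% m$variables) stop("no variable for '", var, "'")
    var <- var2
  }
  cols <- col %||% seq_len(dim(m$p)[3])
  vapply(cols, function(cc) ipl_triple(m$p[, var, cc]), numeric(1))
}

ipl_triple <- function(p, tie_tol = 1e-12) {
  top <- max(p)
  modal <- which(p >= top - tie_tol)
  if (length(modal) > 1 || modal == 2) return(0)
  lpo <- log(2 * p[modal] / (1 - p[modal]))
  if (modal == 3) unname(lpo) else -unname(lpo)
}
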