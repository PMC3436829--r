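# Synthetic pathways and multi-omics cohorts with planted GOF/LOF/neutral
# mutation events, so every pipeline stage is testable without external
# data.

#' Simulation configuration
#'
#' @param n_genes number of focus (scored) genes.
#' @param n_samples cohort size.
#' @param n_mut_per_gene mutated samples per focus gene.
#' @param planted per-focus-gene effect class: a single value or named
#'   character vector over focus genes, values in `"GOF"`, `"LOF"`,
#'   `"neutral"` (default all neutral).
#' @param effect_size mean expression shift per activity state, in SD units
#'   of the emission noise (default 2).
#' @param noise_sd emission noise SD (default 1).
#' @param topology `"star"` (default), `"chain"`, `"random-dag"` or
#'   `"loopy"`.
#' @param n_reg,n_targ regulators / targets per focus gene for the star
#'   topologies (default 2 and 2 — the smallest motif that still exercises
#'   multi-parent vote factors; `"chain"` forces 1 and 1).
#' @param n_decoy unconnected decoy genes forming the shuffle universe
#'   (default 50).
#' @param eps_sim probability that a transmitted activity state is replaced
#'   by a uniform draw (default 0.05).
#' @param cnv_attenuation copy-number effect relative to expression
#'   (default 0.5).
#' @param penetrance probability that a mutant sample actually expresses
#'   the planted effect (default 1; below 1 emulates heterozygous events).
#' @param seed RNG seed.
#' @return a `pshift_sim_config` list.
#' @export
sim_config <- function(n_genes = 1, n_samples = 100, n_mut_per_gene = 20,
                       planted = "neutral", effect_size = 2, noise_sd = 1,
                       topology = c("star", "chain", "random-dag", "loopy"),
                       n_reg = 2, n_targ = 2, n_decoy = 50, eps_sim = 0.05,
                       cnv_attenuation = 0.5, penetrance = 1, seed = 1) {
  topology <- match.arg(topology)
  stopifnot(n_genes >= 1, n_samples >= 2, n_mut_per_gene >= 0,
            n_mut_per_gene <= n_samples, effect_size >= 0, noise_sd > 0,
            eps_sim >= 0, eps_sim <= 1, penetrance >= 0, penetrance <= 1)
  if (topology == "chain") { n_reg <- 1; n_targ <- 1 }
  genes <- sprintf("FG%03d", seq_len(n_genes))
  if (length(planted) == 1 && is.null(names(planted)))
    planted <- setNames(rep(planted, n_genes), genes)
  if (!all(names(planted) %in% genes))
    stop("planted names must be focus genes")
  full <- setNames(rep("neutral", n_genes), genes)
  full[names(planted)] <- planted
  if (!all(full %in% c("GOF", "LOF", "neutral")))
    stop("planted classes must be GOF, LOF or neutral")
  structure(list(n_genes = n_genes, n_samples = n_samples,
                 n_mut_per_gene = n_mut_per_gene, planted = full,
                 effect_size = effect_size, noise_sd = noise_sd,
                 topology = topology, n_reg = n_reg, n_targ = n_targ,
                 n_decoy = n_decoy, eps_sim = eps_sim,
                 cnv_attenuation = cnv_attenuation,
                 penetrance = penetrance, seed = seed),
            class = "pshift_sim_config")
}

maybe_flip <- function(state, eps) {
  n <- length(state)
  flip <- runif(n) < eps
  state[flip] <- base::sample(c(-1, 0, 1), sum(flip), replace = TRUE)
  state
}

#' Simulate a pathway plus cohort with planted mutation effects
#'
#' Hidden ternary activities are sampled uniformly at root regulators and
#' propagated (activation semantics, flip probability `eps_sim`).  The
#' focus gene's true activity follows its regulators; the activity it
#' *transmits* to targets is forced inactive for LOF mutants and active for
#' GOF mutants (subject to `penetrance`), and unaltered for neutral genes
#' and non-mutant samples.  Expression is emitted per gene as
#' `N(state * effect_size, noise_sd)`; copy number the same with the effect
#' attenuated.  The focus gene's own data follows its *regulator-driven*
#' activity, so its cis evidence agrees with the regulators run.
#'
#' @param config a [sim_config()].
#' @return list with `pathway` (a `pshift_pathway`), raw `expression` and
#'   `copy_number` matrices, `mutations` (a `pshift_mutations` table),
#'   `truth` (per gene x sample: mutated, class), `activity` (the hidden
#'   ternary emission states, useful for validation) and `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  cf <- config
  with_seed(cf$seed, {
    genes <- names(cf$planted)
    samples <- sprintf("S%03d", seq_len(cf$n_samples))
    regs <- lapply(genes, function(g) paste0(g, "_R", seq_len(cf$n_reg)))
    targs <- lapply(genes, function(g) paste0(g, "_T", seq_len(cf$n_targ)))
    decoys <- if (cf$n_decoy > 0) sprintf("D%03d", seq_len(cf$n_decoy))
      else character(0)
    all_genes <- c(genes, unlist(regs), unlist(targs), decoys)
    ents <- data.frame(id = all_genes, kind = "protein",
                       stringsAsFactors = FALSE)
    ints <- do.call(rbind, lapply(seq_along(genes), function(i) {
      g <- genes[i]
      e <- rbind(
        data.frame(source = regs[[i]], target = g,
                   edge_type = "protein-activation",
                   stringsAsFactors = FALSE),
        data.frame(source = g, target = targs[[i]],
                   edge_type = "transcriptional-activation",
                   stringsAsFactors = FALSE))
      if (cf$topology == "random-dag" && cf$n_reg >= 2)
        e <- rbind(e, data.frame(source = regs[[i]][1],
                                 target = regs[[i]][2],
                                 edge_type = "protein-activation",
                                 stringsAsFactors = FALSE))
      if (cf$topology == "loopy" && cf$n_targ >= 2)
        e <- rbind(e, data.frame(source = targs[[i]][1],
                                 target = targs[[i]][2],
                                 edge_type = "protein-activation",
                                 stringsAsFactors = FALSE),
                   data.frame(source = targs[[i]][2],
                              target = targs[[i]][1],
                              edge_type = "protein-activation",
                              stringsAsFactors = FALSE))
      e
    }))
    pathway <- pathway_graph(ents, ints)

    state <- matrix(0, length(all_genes), cf$n_samples,
                    dimnames = list(all_genes, samples))
    mut_rows <- list()
    truth_rows <- list()
    for (i in seq_along(genes)) {
      g <- genes[i]
      rs <- matrix(base::sample(c(-1, 0, 1),
                                cf$n_reg * cf$n_samples, replace = TRUE),
                   nrow = cf$n_reg)
      state[regs[[i]], ] <- rs
      act <- maybe_flip(sign(colSums(rs)), cf$eps_sim)
      state[g, ] <- act
      is_mut <- rep(FALSE, cf$n_samples)
      if (cf$n_mut_per_gene > 0)
        is_mut[base::sample(cf$n_samples, cf$n_mut_per_gene)] <- TRUE
      transmitted <- act
      eff <- is_mut & runif(cf$n_samples) < cf$penetrance
      if (cf$planted[g] == "LOF") transmitted[eff] <- -1
      if (cf$planted[g] == "GOF") transmitted[eff] <- 1
      for (tg in targs[[i]])
        state[tg, ] <- maybe_flip(transmitted, cf$eps_sim)
      if (any(is_mut))
        mut_rows[[length(mut_rows) + 1L]] <-
          data.frame(gene = g, sample = samples[is_mut],
                     stringsAsFactors = FALSE)
      truth_rows[[length(truth_rows) + 1L]] <-
        data.frame(gene = g, sample = samples, mutated = is_mut,
                   class = ifelse(is_mut, cf$planted[g], "none"),
                   stringsAsFactors = FALSE)
    }
    if (length(decoys))
      state[decoys, ] <- base::sample(c(-1, 0, 1),
                                      length(decoys) * cf$n_samples,
                                      replace = TRUE)
    expr <- state * cf$effect_size +
      matrix(rnorm(length(state), 0, cf$noise_sd), nrow(state))
    cnv <- state * cf$effect_size * cf$cnv_attenuation +
      matrix(rnorm(length(state), 0, cf$noise_sd), nrow(state))
    dimnames(expr) <- dimnames(cnv) <- dimnames(state)
    muts <- if (length(mut_rows))
      do.call(rbind, mut_rows) else
      data.frame(gene = character(), sample = character(),
                 stringsAsFactors = FALSE)
    muts$variant <- rep(NA_character_, nrow(muts))
    class(muts) <- c("pshift_mutations", "data.frame")
    truth <- do.call(rbind, truth_rows)
    rownames(truth) <- NULL
    list(pathway = pathway, expression = expr, copy_number = cnv,
         mutations = muts, truth = truth, activity = state, config = cf)
  })
}

#' Assemble the omics dataset of a simulated cohort
#' @param sim result of [simulate_cohort()].
#' @return a `pshift_omics` with the rank-ratio transform applied.
#' @export
as_omics <- function(sim) {
  omics_dataset(sim$expression, sim$copy_number, sim$mutations)
}

#' Write a simulated cohort to a directory
#'
#' Writes `pathway.tab`, `expr.tsv`, `cnv.tsv`, `muts.tsv`, `truth.tsv`.
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pathway(sim$pathway, file.path(dir, "pathway.tab"))
  write_matrix_tsv(sim$expression, file.path(dir, "expr.tsv"))
  write_matrix_tsv(sim$copy_number, file.path(dir, "cnv.tsv"))
  mut <- data.frame(Hugo_Symbol = sim$mutations$gene,
                    Tumor_Sample_Barcode = sim$mutations$sample)
  write.table(mut, file.path(dir, "muts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

write_matrix_tsv <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
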