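# End-to-end pipeline: configuration handling, per-gene orchestration and
# tabular outputs.

#' Pipeline configuration
#'
#' Defaults follow the method's standard operating point: BP tolerance
#' `1e-9` with at most `10000` iterations, `100` Z-normalization
#' permutations, `1000` neighborhood-null replicates, call threshold
#' `alpha = 0.10`, expression variance cut `0.10`, supervised t-filter
#' `t_min = 1.0` with 5 folds, neighborhood radius `k = 1`.
#'
#' @param pathway,expression,copy_number,mutations input file paths
#'   (optional when objects are passed to [run_all()] directly).
#' @param k neighborhood hop limit (intervening proteins).
#' @param min_sd expression variance cut.
#' @param epsilon factor-table smoothing mass.
#' @param cutpoints rank-ratio discretization cut-points.
#' @param tol,max_iter,damping BP settings.
#' @param n_perm Z-normalization background draws.
#' @param n_null neighborhood-null replicates.
#' @param alpha nominal false-positive rate for calls.
#' @param sided `"two"` or `"one"` (see [classify()]).
#' @param direction tail for one-sided calls.
#' @param t_min,folds supervised-selection settings.
#' @param min_mut minimum mutation count for a gene to be scored.
#' @param non_silent_only drop `Silent` records when reading mutations.
#' @param seed RNG seed (mandatory for any stochastic step).
#' @return a validated `pshift_config` list.
#' @export
pshift_config <- function(pathway = NULL, expression = NULL,
                          copy_number = NULL, mutations = NULL,
                          k = 1, min_sd = 0.10, epsilon = 0.2,
                          cutpoints = c(1 / 3, 2 / 3), tol = 1e-9,
                          max_iter = 10000, damping = 0.5, n_perm = 100,
                          n_null = 1000, alpha = 0.10, sided = "two",
                          direction = "lower", t_min = 1.0, folds = 5,
                          min_mut = 2, non_silent_only = FALSE,
                          seed = 17) {
  stopifnot(k >= 0, min_sd >= 0, epsilon > 0, epsilon < 0.5,
            length(cutpoints) == 2, cutpoints[1] < cutpoints[2],
            tol > 0, max_iter >= 1, n_perm >= 2, n_null >= 2,
            alpha > 0, alpha < 1, t_min >= 0, folds >= 2, min_mut >= 1)
  sided <- match.arg(sided, c("two", "one"))
  direction <- match.arg(direction, c("lower", "upper"))
  structure(list(pathway = pathway, expression = expression,
                 copy_number = copy_number, mutations = mutations,
                 k = k, min_sd = min_sd, epsilon = epsilon,
                 cutpoints = cutpoints, tol = tol, max_iter = max_iter,
                 damping = damping, n_perm = n_perm, n_null = n_null,
                 alpha = alpha, sided = sided, direction = direction,
                 t_min = t_min, folds = folds, min_mut = min_mut,
                 non_silent_only = non_silent_only,
                 seed = as.integer(seed)),
            class = "pshift_config")
}

#' Read a YAML configuration file
#'
#' Keys mirror the arguments of [pshift_config()]; unset keys take the
#' defaults.
#'
#' @param path YAML file path.
#' @return a `pshift_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pshift_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pshift_config, vals)
}

bp_args <- function(config) {
  list(epsilon = config$epsilon, cutpoints = config$cutpoints,
       tol = config$tol, max_iter = config$max_iter,
       damping = config$damping)
}

#' Run the full scoring pipeline over a cohort
#'
#' For every mutated gene present in the pathway with at least `min_mut`
#' mutations: extract and variance-filter the neighborhood, compute raw
#' shifts for all samples, Z-normalize against shuffled backgrounds, call
#' GOF/LOF/neutral at the configured false-positive rate, and assess the
#' mutant-separation statistic against the random-neighborhood permutation
#' null.
#'
#' @param config a `pshift_config`.
#' @param data a `pshift_omics` dataset (built from the config paths when
#'   omitted).
#' @param pathway a `pshift_pathway` (parsed from the config path when
#'   omitted).
#' @param out_dir optional output directory for `samples.tsv`,
#'   `summary.tsv` and `waterfall.tsv`.
#' @return list with `samples` (per gene x sample scores and calls),
#'   `summary` (per-gene statistics), `waterfall` (ordered summary) and
#'   `config`.
#' @export
run_all <- function(config, data = NULL, pathway = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pshift_config"))
  if (is.null(pathway)) pathway <- parse_pathway(config$pathway)
  if (is.null(data)) {
    data <- omics_dataset(
      read_matrix(config$expression),
      if (!is.null(config$copy_number)) read_matrix(config$copy_number),
      read_mutations(config$mutations, config$non_silent_only))
  }
  message(sprintf("pshift %s | seed %d | %d samples, %d genes in data, %d entities in pathway",
                  as.character(utils::packageVersion("pshift")),
                  config$seed, length(data$sample_ids),
                  length(data$gene_ids), nrow(pathway$entities)))
  if (is.null(data$mutations) || nrow(data$mutations) == 0) {
    warning("empty mutation table: nothing to score")
    empty <- data.frame()
    return(list(samples = empty, summary = empty, waterfall = empty,
                config = config))
  }
  counts <- table(data$mutations$gene)
  genes <- intersect(names(counts)[counts >= config$min_mut],
                     pathway$entities$id)
  message("scoring ", length(genes), " mutated gene(s): ",
          paste(genes, collapse = ", "))
  sample_rows <- list()
  summary_rows <- list()
  ba <- bp_args(config)
  for (i in seq_along(genes)) {
    g <- genes[i]
    gseed <- (config$seed + 1000L * i) %% .Machine$integer.max
    nb <- tryCatch(extract_neighborhood(pathway, g, config$k),
                   warning = function(w) {
                     message("gene ", g, ": ", conditionMessage(w))
                     suppressWarnings(extract_neighborhood(pathway, g,
                                                           config$k))
                   })
    nb <- variance_filter(nb, data, config$min_sd)
    if (!length(nb$regulators) || !length(nb$targets)) {
      message("gene ", g, ": empty mode set after filtering, skipped")
      next
    }
    nn <- do.call(neighborhood_null,
                  c(list(nbhd = nb, data = data, n_null = config$n_null,
                         seed = gseed, n_perm = config$n_perm,
                         sided = if (config$sided == "two") "two"
                                 else config$direction), ba))
    raw <- do.call(pshift, c(list(nbhd = nb, data = data), ba))
    mut <- mutated_in(data, g)
    calls <- classify(nn$z, nn$bg_z, config$alpha, config$sided,
                      config$direction)
    sample_rows[[length(sample_rows) + 1L]] <-
      data.frame(gene = g, sample = data$sample_ids, mutated = mut,
                 ipl_r = raw$ipl_r, ipl_t = raw$ipl_t,
                 raw_shift = raw$raw_shift,
                 z_shift = unname(nn$z), call = calls,
                 stringsAsFactors = FALSE)
    summary_rows[[length(summary_rows) + 1L]] <-
      gene_summary(g, nn$z, mut, nn$perm_p)
  }
  samples <- if (length(sample_rows)) do.call(rbind, sample_rows)
    else data.frame()
  summary <- if (length(summary_rows)) do.call(rbind, summary_rows)
    else data.frame()
  wf <- if (nrow(summary)) waterfall(summary) else summary
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(samples, file.path(out_dir, "samples.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(summary, file.path(out_dir, "summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(wf, file.path(out_dir, "waterfall.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    message("results written to ", out_dir)
  }
  list(samples = samples, summary = summary, waterfall = wf,
       config = config)
}
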