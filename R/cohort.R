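# Cohort-level significance: mutant-separation t-statistic, random-
# neighborhood permutation null, per-gene summaries and waterfall ordering.

#' Mutant-separation statistic
#'
#' Two-sample Student t-statistic (pooled variance), oriented mutant minus
#' non-mutant: negative values point in the loss-of-function direction.
#'
#' @param mut_scores shift scores of mutated samples (>= 2 values).
#' @param nonmut_scores shift scores of non-mutated samples (>= 2 values).
#' @return The t-statistic.
#' @export
msep <- function(mut_scores, nonmut_scores) {
  mut_scores <- mut_scores[!is.na(mut_scores)]
  nonmut_scores <- nonmut_scores[!is.na(nonmut_scores)]
  n1 <- length(mut_scores); n2 <- length(nonmut_scores)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 values")
  sp2 <- ((n1 - 1) * stats::var(mut_scores) +
            (n2 - 1) * stats::var(nonmut_scores)) / (n1 + n2 - 2)
  if (!is.finite(sp2) || sp2 <= 0) stop("zero pooled variance")
  (mean(mut_scores) - mean(nonmut_scores)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

#' Random-neighborhood permutation null for the m-sep statistic
#'
#' For each null replicate the neighborhood's evidence slots are assigned
#' the data tuples of uniformly drawn random genes (one fixed assignment
#' per replicate), the full shift + Z-normalization pipeline is re-run on
#' every sample, and the mutant-separation statistic is recorded.  The
#' permutation p-value uses the add-one convention
#' `(1 + #{null beats observed}) / (1 + n_null)`.
#'
#' @param nbhd a `pshift_neighborhood`.
#' @param data a `pshift_omics` dataset carrying mutation calls for the
#'   focus gene.
#' @param n_null number of random-neighborhood replicates (default 1000).
#' @param seed RNG seed.
#' @param n_perm background draws for the Z step (default 100).
#' @param sided `"two"` (on |m-sep|), `"lower"` or `"upper"`.
#' @param epsilon,cutpoints,tol,max_iter,damping inference parameters.
#' @return list with `msep_obs`, `null` (vector of null m-seps), `perm_p`,
#'   `z` (observed per-sample Z-shifts), `bg_z` (observed-gene background).
#' @export
neighborhood_null <- function(nbhd, data, n_null = 1000, seed,
                              n_perm = 100,
                              sided = c("two", "lower", "upper"),
                              epsilon = 0.2, cutpoints = c(1 / 3, 2 / 3),
                              tol = 1e-9, max_iter = 10000, damping = 0.5) {
  sided <- match.arg(sided)
  stopifnot(n_null >= 2)
  pars <- bp_params(epsilon, cutpoints, tol, max_iter, damping)
  samples <- data$sample_ids
  ns <- length(samples)
  mut <- mutated_in(data, nbhd$focus)
  if (sum(mut) < 2 || sum(!mut) < 2)
    stop("need >= 2 mutant and >= 2 non-mutant samples for m-sep")

  skelR <- fg_skeleton(nbhd, "regulators", epsilon)
  skelT <- fg_skeleton(nbhd, "targets", epsilon)
  priorR <- skel_prior_ipl(skelR, pars)
  priorT <- skel_prior_ipl(skelT, pars)
  entR <- unique(skelR$slots$entity)
  entT <- unique(skelT$slots$entity)

  # observed gene: raw shifts + Z
  raw_obs <- raw_shift_engine(skelR, skelT, priorR, priorT, data, samples,
                              NULL, NULL, pars)$raw
  zz <- zscore_normalize(nbhd, data, setNames(raw_obs, samples),
                         n_perm = n_perm, seed = seed, epsilon = epsilon,
                         cutpoints = cutpoints, tol = tol,
                         max_iter = max_iter, damping = damping)
  ms_obs <- msep(zz$z[mut], zz$z[!mut])

  # null replicates, batched: one fixed random assignment per replicate.
  # The per-gene Z step subtracts one mean and divides by one SD for all
  # samples of a replicate; the two-sample t-statistic is invariant under
  # that affine map, so each replicate's m-sep on the Z scale equals its
  # m-sep on the raw scale and the background stage needn't be recomputed.
  null_ms <- with_seed(seed + 1L, {
    aR <- random_assign(entR, n_null, data$gene_ids)
    aT <- random_assign(entT, n_null, data$gene_ids)
    big_samp <- rep(samples, times = n_null)
    rawN <- raw_shift_engine(skelR, skelT, priorR, priorT, data, big_samp,
                             aR[, rep(seq_len(n_null), each = ns),
                                drop = FALSE],
                             aT[, rep(seq_len(n_null), each = ns),
                                drop = FALSE], pars)$raw
    rawN <- matrix(rawN, nrow = ns)        # samples x replicates
    vapply(seq_len(n_null), function(r) {
      tryCatch(msep(rawN[mut, r], rawN[!mut, r]),
               error = function(e) NA_real_)
    }, numeric(1))
  })
  ok <- !is.na(null_ms)
  beats <- switch(sided,
                  two = sum(abs(null_ms[ok]) >= abs(ms_obs)),
                  lower = sum(null_ms[ok] <= ms_obs),
                  upper = sum(null_ms[ok] >= ms_obs))
  list(msep_obs = ms_obs, null = null_ms,
       perm_p = (1 + beats) / (1 + sum(ok)),
       z = zz$z, bg_z = zz$bg_z)
}

#' Per-gene summary of shift scores
#'
#' @param gene gene id.
#' @param z named per-sample Z-shifts.
#' @param mutated logical vector aligned with `z`.
#' @param perm_p permutation p-value from [neighborhood_null()] (optional).
#' @return one-row data.frame: `gene`, `n_mut`, `n_nonmut`, `msep`,
#'   `perm_p`, `mean_shift_mut`, `direction`, `low_power`.
#' @export
gene_summary <- function(gene, z, mutated, perm_p = NA_real_) {
  zm <- z[mutated & !is.na(z)]
  zn <- z[!mutated & !is.na(z)]
  ms <- tryCatch(msep(zm, zn), error = function(e) NA_real_)
  frac_pos <- if (length(zm)) mean(zm > 0) else NA_real_
  direction <- if (is.na(frac_pos)) NA_character_
    else if (frac_pos >= 2 / 3) "GOF"
    else if (frac_pos <= 1 / 3) "LOF"
    else "mixed"
  data.frame(gene = gene, n_mut = length(zm), n_nonmut = length(zn),
             msep = ms, perm_p = perm_p,
             mean_shift_mut = if (length(zm)) mean(zm) else NA_real_,
             direction = direction,
             low_power = length(zm) < 3,
             stringsAsFactors = FALSE)
}

#' Waterfall ordering of gene summaries
#'
#' @param summaries data.frame of [gene_summary()] rows.
#' @param by ordering column: `"msep"` (default) or `"mean_shift_mut"`.
#' @return The summaries sorted ascending by the chosen column.
#' @export
waterfall <- function(summaries, by = c("msep", "mean_shift_mut")) {
  by <- match.arg(by)
  stopifnot(nrow(summaries) >= 1)
  out <- summaries[order(summaries[[by]], na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Waterfall bar plot
#'
#' @param summaries data.frame of [gene_summary()] rows.
#' @param by ordering column, as in [waterfall()].
#' @param ... passed to [graphics::barplot()].
#' @return The ordered summaries, invisibly.
#' @export
plot_waterfall <- function(summaries, by = c("msep", "mean_shift_mut"),
                           ...) {
  by <- match.arg(by)
  ord <- waterfall(summaries, by)
  graphics::barplot(ord[[by]], names.arg = ord$gene, las = 2,
                    ylab = by, border = NA,
                    col = ifelse(ord[[by]] < 0, "#B2182B", "#2166AC"), ...)
  invisible(ord)
}
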