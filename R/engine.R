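# Per-(gene, sample) shift scoring: regulators run vs targets run, each
# prior-subtracted, plus shuffled-data Z-normalization, fixed-FPR calls and
# optional supervised neighbor selection.

bp_params <- function(epsilon = 0.2, cutpoints = c(1 / 3, 2 / 3),
                      tol = 1e-9, max_iter = 10000, damping = 0.5) {
  list(epsilon = epsilon, cutpoints = cutpoints, tol = tol,
       max_iter = max_iter, damping = damping)
}

# IPLs of the focus variable for one skeleton over arbitrary evidence
# columns (batched into a single BP call)
skel_ipls <- function(skel, data, samples, assign, pars) {
  fg <- skel_to_fg(skel, fg_potentials(skel, data, samples, assign,
                                       pars$epsilon, pars$cutpoints))
  m <- run_bp(fg, pars$tol, pars$max_iter, pars$damping)
  ipl_from_marginals(m)
}

skel_prior_ipl <- function(skel, pars) {
  m <- run_bp(skel_to_fg(skel, NULL), pars$tol, pars$max_iter, pars$damping)
  ipl_from_marginals(m)
}

# raw shift = (IPL_T - prior_T) - (IPL_R - prior_R), columns batched
raw_shift_engine <- function(skelR, skelT, priorR, priorT, data, samples,
                             assignR = NULL, assignT = NULL, pars) {
  iplR <- skel_ipls(skelR, data, samples, assignR, pars)
  iplT <- skel_ipls(skelT, data, samples, assignT, pars)
  list(ipl_r = iplR - priorR, ipl_t = iplT - priorT,
       raw = (iplT - priorT) - (iplR - priorR))
}

#' Raw pathway-shift scores for a focus gene
#'
#' For each sample, the focus gene's inferred pathway level from the
#' targets run minus that from the regulators run, each term
#' prior-subtracted (evidence graph minus prior-only graph).  Negative
#' shifts indicate downstream activity below what the regulators predict
#' (loss-of-function direction); positive shifts the reverse.
#'
#' @param nbhd a `pshift_neighborhood` (already variance-filtered as
#'   desired).
#' @param data a `pshift_omics` dataset.
#' @param sample sample ids to score (default all).
#' @param epsilon,cutpoints,tol,max_iter,damping inference parameters, see
#'   [build_factor_graph()] and [run_bp()].
#' @return data.frame with columns `sample`, `ipl_r`, `ipl_t`, `raw_shift`.
#'   If either mode set is empty the scores are `NA` with a warning.
#' @export
pshift <- function(nbhd, data, sample = data$sample_ids, epsilon = 0.2,
                   cutpoints = c(1 / 3, 2 / 3), tol = 1e-9,
                   max_iter = 10000, damping = 0.5) {
  pars <- bp_params(epsilon, cutpoints, tol, max_iter, damping)
  if (!length(nbhd$regulators) || !length(nbhd$targets)) {
    warning("gene '", nbhd$focus, "': empty ",
            if (!length(nbhd$regulators)) "regulator" else "target",
            " set, shift undefined")
    return(data.frame(sample = sample, ipl_r = NA_real_, ipl_t = NA_real_,
                      raw_shift = NA_real_, stringsAsFactors = FALSE))
  }
  skelR <- fg_skeleton(nbhd, "regulators", epsilon)
  skelT <- fg_skeleton(nbhd, "targets", epsilon)
  priorR <- skel_prior_ipl(skelR, pars)
  priorT <- skel_prior_ipl(skelT, pars)
  sc <- raw_shift_engine(skelR, skelT, priorR, priorT, data, sample,
                         NULL, NULL, pars)
  data.frame(sample = sample, ipl_r = sc$ipl_r, ipl_t = sc$ipl_t,
             raw_shift = sc$raw, stringsAsFactors = FALSE)
}

# entities x n matrix of uniformly drawn gene ids (the "data tuple"
# reassignment: one gene per neighborhood slot, expression + copy number
# rows move together)
random_assign <- function(entities, n, gene_ids) {
  matrix(base::sample(gene_ids, length(entities) * n, replace = TRUE),
         nrow = length(entities), dimnames = list(entities, NULL))
}

#' Z-normalize raw shifts against shuffled-data backgrounds
#'
#' Each gene's neighborhood can lean positive or negative for purely
#' structural reasons.  `n_perm` background shifts are generated by
#' reassigning every evidence-bearing neighborhood slot (including the
#' focus gene's own slot in the regulators run) the expression/copy-number
#' tuple of a uniformly drawn random gene, evaluated at a uniformly drawn
#' sample column.  Observed raw shifts are normalized by the background
#' mean and standard deviation.
#'
#' @param nbhd a `pshift_neighborhood`.
#' @param data a `pshift_omics` dataset.
#' @param raw_shifts named (by sample) vector of raw shifts, or the
#'   data.frame returned by [pshift()].
#' @param n_perm number of background draws (default 100).
#' @param seed RNG seed (required, for reproducibility).
#' @param epsilon,cutpoints,tol,max_iter,damping inference parameters.
#' @return list with `z` (named per-sample Z-shifts), `mu`, `sigma`,
#'   `bg_raw` and `bg_z` (background draws, raw and Z scale).
#' @export
zscore_normalize <- function(nbhd, data, raw_shifts, n_perm = 100, seed,
                             epsilon = 0.2, cutpoints = c(1 / 3, 2 / 3),
                             tol = 1e-9, max_iter = 10000, damping = 0.5) {
  stopifnot(n_perm >= 2)
  pars <- bp_params(epsilon, cutpoints, tol, max_iter, damping)
  if (is.data.frame(raw_shifts))
    raw_shifts <- setNames(raw_shifts$raw_shift, raw_shifts$sample)
  skelR <- fg_skeleton(nbhd, "regulators", epsilon)
  skelT <- fg_skeleton(nbhd, "targets", epsilon)
  priorR <- skel_prior_ipl(skelR, pars)
  priorT <- skel_prior_ipl(skelT, pars)
  bg <- with_seed(seed, {
    cols <- base::sample(data$sample_ids, n_perm, replace = TRUE)
    aR <- random_assign(unique(skelR$slots$entity), n_perm, data$gene_ids)
    aT <- random_assign(unique(skelT$slots$entity), n_perm, data$gene_ids)
    raw_shift_engine(skelR, skelT, priorR, priorT, data, cols, aR, aT,
                     pars)$raw
  })
  mu <- mean(bg)
  sigma <- sd(bg)
  if (!is.finite(sigma) || sigma == 0) {
    warning("gene '", nbhd$focus,
            "': zero background variance, Z-shifts undefined")
    return(list(z = raw_shifts * NA_real_, mu = mu, sigma = sigma,
                bg_raw = bg, bg_z = bg * NA_real_))
  }
  list(z = (raw_shifts - mu) / sigma, mu = mu, sigma = sigma,
       bg_raw = bg, bg_z = (bg - mu) / sigma)
}

#' Call GOF / LOF / neutral at a fixed false-positive rate
#'
#' Thresholds are empirical quantiles of the permutation background
#' (`bg_z` from [zscore_normalize()]).  One-sided tests spend all of
#' `alpha` in the configured tail; two-sided tests split it.
#'
#' @param z_shift numeric vector of Z-shifts.
#' @param background numeric vector of background (null) Z-shifts.
#' @param alpha nominal false-positive rate (default 0.10).
#' @param sided `"two"` or `"one"`.
#' @param direction tail for one-sided tests: `"lower"` (LOF) or
#'   `"upper"` (GOF).
#' @return character vector of calls among `"LOF"`, `"neutral"`, `"GOF"`.
#' @export
classify <- function(z_shift, background, alpha = 0.10,
                     sided = c("two", "one"),
                     direction = c("lower", "upper")) {
  sided <- match.arg(sided)
  direction <- match.arg(direction)
  stopifnot(alpha > 0, alpha < 1)
  call <- rep("neutral", length(z_shift))
  if (sided == "one") {
    if (direction == "lower") {
      call[z_shift < quantile(background, alpha, na.rm = TRUE)] <- "LOF"
    } else {
      call[z_shift > quantile(background, 1 - alpha, na.rm = TRUE)] <- "GOF"
    }
  } else {
    call[z_shift < quantile(background, alpha / 2, na.rm = TRUE)] <- "LOF"
    call[z_shift > quantile(background, 1 - alpha / 2, na.rm = TRUE)] <- "GOF"
  }
  call[is.na(z_shift)] <- NA_character_
  call
}

# pooled two-sample t on a matrix of expression rows (genes x samples)
row_tstat <- function(m, grp) {
  m1 <- m[, grp, drop = FALSE]
  m2 <- m[, !grp, drop = FALSE]
  n1 <- ncol(m1); n2 <- ncol(m2)
  v1 <- apply(m1, 1, var_na)
  v2 <- apply(m2, 1, var_na)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  (rowMeans(m1, na.rm = TRUE) - rowMeans(m2, na.rm = TRUE)) /
    sqrt(sp2 * (1 / n1 + 1 / n2))
}

var_na <- function(x) stats::var(x, na.rm = TRUE)

#' Supervised neighbor selection by cross-validated t-filter
#'
#' Stratified five-fold cross-validation: in each training split (80% of
#' samples) every candidate neighbor gets a two-sample Student t-statistic
#' of its expression against the focus gene's mutation status, neighbors
#' with `|t| >= t_min` are retained, and shift scores are computed on the
#' held-out 20% with the fold-specific neighborhood.
#'
#' @param nbhd a `pshift_neighborhood`.
#' @param data a `pshift_omics` dataset (must carry mutations).
#' @param folds number of folds (default 5).
#' @param t_min minimum absolute t-statistic (default 1.0).
#' @param seed RNG seed for fold assignment and Z backgrounds.
#' @param n_perm background draws for Z-normalization per fold.
#' @param ... inference parameters passed on to [pshift()].
#' @return list with `folds` (per-fold neighborhood, kept neighbors, test
#'   samples, scores) and `shifts` (combined held-out score table).
#' @export
supervised_select <- function(nbhd, data, folds = 5, t_min = 1.0, seed,
                              n_perm = 100, ...) {
  stopifnot(folds >= 2)
  mut <- mutated_in(data, nbhd$focus)
  samples <- data$sample_ids
  fold_of <- with_seed(seed, {
    f <- integer(length(samples))
    for (g in list(which(mut), which(!mut))) {
      if (length(g))
        f[g[base::sample(length(g))]] <-
          rep_len(seq_len(folds), length(g))
    }
    f
  })
  members <- c(nbhd$regulators, nbhd$targets)
  cand <- members[nbhd$kinds[members] == "protein" &
                    members %in% rownames(data$expression)]
  out_folds <- list()
  shift_rows <- list()
  for (k in seq_len(folds)) {
    test <- samples[fold_of == k]
    train <- samples[fold_of != k]
    if (sum(mut[fold_of != k]) < 2 || sum(!mut[fold_of != k]) < 2) {
      warning("fold ", k, ": fewer than 2 samples in a class, skipped")
      next
    }
    tstat <- row_tstat(data$expression[cand, train, drop = FALSE],
                       mut[fold_of != k])
    drop <- cand[is.na(tstat) | abs(tstat) < t_min]
    fn <- prune_members(nbhd, drop)
    res <- if (length(fn$regulators) && length(fn$targets)) {
      raw <- pshift(fn, data, test, ...)
      zz <- zscore_normalize(fn, data, raw, n_perm = n_perm,
                             seed = (seed + k) %% .Machine$integer.max, ...)
      transform(raw, z_shift = unname(zz$z[raw$sample]))
    } else {
      warning("fold ", k, ": selection emptied a mode set")
      NULL
    }
    out_folds[[length(out_folds) + 1L]] <-
      list(fold = k, neighborhood = fn, kept = setdiff(cand, drop),
           tstat = tstat, test_samples = test, scores = res)
    if (!is.null(res))
      shift_rows[[length(shift_rows) + 1L]] <- cbind(fold = k, res)
  }
  list(folds = out_folds,
       shifts = if (length(shift_rows)) do.call(rbind, shift_rows) else NULL)
}

# shared cascade used by variance_filter and supervised_select: drop the
# given members, then any complex/family whose in-neighborhood
# constituents all fell, then restrict interactions
prune_members <- function(nbhd, drop) {
  members <- c(nbhd$regulators, nbhd$targets)
  repeat {
    grp <- setdiff(members[nbhd$kinds[members] %in% c("complex", "family")],
                   drop)
    newly <- grp[vapply(grp, function(g) {
      cons <- setdiff(nbhd_constituents(nbhd, g), nbhd$focus)
      length(cons) > 0 && all(cons %in% drop)
    }, logical(1))]
    if (!length(newly)) break
    drop <- c(drop, newly)
  }
  nbhd$regulators <- setdiff(nbhd$regulators, drop)
  nbhd$targets <- setdiff(nbhd$targets, drop)
  keep <- c(nbhd$focus, nbhd$regulators, nbhd$targets)
  e <- nbhd$interactions
  nbhd$interactions <- e[e$source %in% keep & e$target %in% keep, ,
                         drop = FALSE]
  rownames(nbhd$interactions) <- NULL
  nbhd$kinds <- nbhd$kinds[keep]
  nbhd
}
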