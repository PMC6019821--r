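#' Mean pairwise distance (MPD) of a tip sample
#'
#' Mean patristic distance over all unordered pairs of tips in `sample`.
#' Presence-only (unweighted).
#'
#' @param sample Character vector of tip labels (at least 2, no duplicates).
#' @param dm Patristic distance matrix from [patristic_matrix()].
#' @return Numeric scalar, in branch-length units.
#' @export
mpd <- function(sample, dm) {
  idx <- sample_index(sample, dm)
  sub <- dm[idx, idx, drop = FALSE]
  sum(sub) / (length(idx) * (length(idx) - 1L))
}

#' Mean nearest taxon distance (MNTD) of a tip sample
#'
#' Mean, over tips in `sample`, of the distance to the nearest other tip
#' in the sample.
#'
#' @inheritParams mpd
#' @return Numeric scalar, in branch-length units.
#' @export
mntd <- function(sample, dm) {
  idx <- sample_index(sample, dm)
  sub <- dm[idx, idx, drop = FALSE]
  diag(sub) <- Inf
  mean(apply(sub, 1L, min))
}

sample_index <- function(sample, dm) {
  if (anyDuplicated(sample)) stop("duplicate labels in sample")
  if (length(sample) < 2L) stop("sample must contain at least 2 tips")
  idx <- match(sample, rownames(dm))
  if (anyNA(idx))
    stop("labels not in distance matrix: ",
         paste(sample[is.na(idx)], collapse = ", "))
  idx
}

#' Standardized effect size of MPD or MNTD under the tip-shuffling null
#'
#' The null model shuffles tip labels across the whole distance matrix
#' (the "taxa.labels" null), which is equivalent to drawing `|sample|`
#' tips uniformly without replacement; the metric is recomputed `runs`
#' times.  The standardized effect size is
#' `ses = (observed - null mean) / null sd` (sample sd, n-1 denominator),
#' and the community-phylogenetics indices are its negation:
#' NRI = -ses(MPD), NTI = -ses(MNTD), so positive index values indicate
#' phylogenetic clustering and negative values overdispersion.
#'
#' Permutation p-values use the +1 correction,
#' `p_lower = (#\{null <= obs\} + 1) / (runs + 1)` (and symmetrically for
#' `p_upper`), so p is never 0; the two-tailed p is
#' `min(1, 2 * min(p_lower, p_upper))`.  When the sample contains every
#' tip the null distribution is a point mass: the result is flagged
#' `degenerate`, with `ses = 0` and all p-values 1.
#'
#' @inheritParams mpd
#' @param metric `"mpd"` or `"mntd"`.
#' @param runs Number of null permutations (default 999).
#' @param seed Optional integer seed; recorded in the result so any run
#'   can be reproduced exactly.
#' @return An object of class `"ses_result"`: a list with elements
#'   `metric`, `obs`, `null_mean`, `null_sd`, `ses`, `index`
#'   (`NRI` or `NTI` value, `-ses`), `index_name`, `p_lower`, `p_upper`,
#'   `p_two`, `runs`, `seed`, `n_sample`, `n_tips`, `degenerate`.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' ses_dispersion(c("A", "B"), patristic_matrix(tr), "mpd", runs = 99, seed = 1)
#' @export
ses_dispersion <- function(sample, dm, metric = c("mpd", "mntd"),
                           runs = 999, seed = NULL) {
  metric <- match.arg(metric)
  stopifnot(runs >= 1)
  f <- if (metric == "mpd") mpd else mntd
  idx <- sample_index(sample, dm)
  k <- length(idx)
  n <- nrow(dm)
  obs <- f(sample, dm)

  if (!is.null(seed)) set.seed(seed)
  null <- vapply(seq_len(runs), function(r) {
    ridx <- sample.int(n, k)
    sub <- dm[ridx, ridx, drop = FALSE]
    if (metric == "mpd") {
      sum(sub) / (k * (k - 1L))
    } else {
      diag(sub) <- Inf
      mean(apply(sub, 1L, min))
    }
  }, numeric(1))

  null_mean <- mean(null)
  null_sd <- stats::sd(null)
  degenerate <- (k == n) || null_sd == 0
  if (degenerate) {
    ses <- 0
    p_lower <- p_upper <- p_two <- 1
  } else {
    ses <- (obs - null_mean) / null_sd
    p_lower <- (sum(null <= obs) + 1) / (runs + 1)
    p_upper <- (sum(null >= obs) + 1) / (runs + 1)
    p_two <- min(1, 2 * min(p_lower, p_upper))
  }
  structure(list(
    metric = metric, obs = obs, null_mean = null_mean, null_sd = null_sd,
    ses = ses, index = -ses,
    index_name = if (metric == "mpd") "NRI" else "NTI",
    p_lower = p_lower, p_upper = p_upper, p_two = p_two,
    runs = runs, seed = seed, n_sample = k, n_tips = n,
    degenerate = degenerate
  ), class = "ses_result")
}

#' @export
print.ses_result <- function(x, ...) {
  cat(sprintf("%s: obs = %.4g, null = %.4g (sd %.4g), %s = %.3f, two-tailed p = %.4g%s\n",
              toupper(x$metric), x$obs, x$null_mean, x$null_sd,
              x$index_name, x$index, x$p_two,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Classify phylogenetic structure from NRI and NTI
#'
#' Combines the deep-node signal (NRI, from MPD) and the terminal signal
#' (NTI, from MNTD) into one of the classical relatedness scenarios.
#' Each axis is called "clustering" when its index is significantly
#' positive, "overdispersion" when significantly negative, and "random"
#' otherwise (two-tailed test at `alpha`).
#'
#' @param ses_mpd,ses_mntd `"ses_result"` objects for MPD and MNTD on the
#'   same sample.
#' @param alpha Two-tailed significance level (default 0.05).
#' @return A list of class `"structure_class"` with elements `label`,
#'   `deep`, `terminal`, `alpha`.  `label` is `"clustering"` or
#'   `"overdispersion"` when both axes agree and are significant,
#'   `"random/random"` when neither is significant, and otherwise a
#'   `"terminal <t>, deep <d>"` description.
#' @export
classify_structure <- function(ses_mpd, ses_mntd, alpha = 0.05) {
  stopifnot(inherits(ses_mpd, "ses_result"), inherits(ses_mntd, "ses_result"))
  if (ses_mpd$metric != "mpd" || ses_mntd$metric != "mntd")
    stop("expected an MPD result and an MNTD result, in that order")
  axis <- function(s) {
    if (s$degenerate || s$p_two > alpha) "random"
    else if (s$index > 0) "clustering"
    else "overdispersion"
  }
  deep <- axis(ses_mpd)
  terminal <- axis(ses_mntd)
  label <- if (deep == "random" && terminal == "random") {
    "random/random"
  } else if (deep == terminal) {
    deep
  } else {
    sprintf("terminal %s, deep %s", terminal, deep)
  }
  structure(list(label = label, deep = deep, terminal = terminal, alpha = alpha),
            class = "structure_class")
}

#' @export
print.structure_class <- function(x, ...) {
  cat(sprintf("phylogenetic structure: %s (deep: %s, terminal: %s, alpha = %g)\n",
              x$label, x$deep, x$terminal, x$alpha))
  invisible(x)
}
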