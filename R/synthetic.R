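#' Simulation configuration for synthetic ethnoflora datasets
#'
#' Bundles the generator settings.  Defaults emulate the study conditions
#' of a large legume ethnoflora: roughly 10% of species with recorded
#' use, heavily overdispersed use-report counts averaging about 6 per
#' used species, study counts rank-correlated with use reports at
#' Spearman rho 0.36 with half of the used species never studied, and, in
#' the clustered scenario, an in-clade enrichment ratio of 8.
#'
#' @param n_tips Number of species in the simulated flora.
#' @param n_genera Number of genera; tips are labelled `Genus_species`
#'   with genera as monophyletic clades.  Default about one genus per 13
#'   species.
#' @param scenario Placement of used species on the tree: `"random"`
#'   (independent Bernoulli), `"clustered"` (elevated odds inside one
#'   clade of about `prevalence * n_tips` tips), or `"overdispersed"`
#'   (greedy maximin tip selection).
#' @param prevalence Expected fraction of used species (default 0.10).
#' @param clust_odds Enrichment ratio `p_in / p_out` of per-tip use
#'   probability inside vs outside the chosen clade for the clustered
#'   scenario (default 8).
#' @param report_mean,report_size Mean and dispersion (negative binomial
#'   `size`) of use-report counts for used species; counts are
#'   `1 + NegBin(mu = report_mean - 1, size = report_size)`.
#' @param study_mean,study_size Same for the study-count margin of
#'   studied species.
#' @param rho Target Spearman rank correlation between use reports and
#'   study counts across used species (default 0.36).
#' @param zero_inflation Fraction of used species with zero studies
#'   (default 0.5).
#' @param unused_study_prob Probability that an unused species has any
#'   studies (default 0.05); such species get `1 + Poisson(1)` studies.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_tips = 640, n_genera = max(2L, round(n_tips / 13)),
                       scenario = c("random", "clustered", "overdispersed"),
                       prevalence = 0.10, clust_odds = 8,
                       report_mean = 6, report_size = 0.5,
                       study_mean = 19, study_size = 0.4,
                       rho = 0.36, zero_inflation = 0.5,
                       unused_study_prob = 0.05) {
  scenario <- match.arg(scenario)
  stopifnot(n_tips >= 2, prevalence > 0, prevalence < 1,
            clust_odds > 0, report_mean > 1, study_mean > 1,
            rho > -1, rho < 1,
            zero_inflation >= 0, zero_inflation < 1)
  structure(list(n_tips = as.integer(n_tips), n_genera = as.integer(n_genera),
                 scenario = scenario, prevalence = prevalence,
                 clust_odds = clust_odds,
                 report_mean = report_mean, report_size = report_size,
                 study_mean = study_mean, study_size = study_size,
                 rho = rho, zero_inflation = zero_inflation,
                 unused_study_prob = unused_study_prob),
            class = "sim_config")
}

#' Simulate an ultrametric Yule tree with genus-structured tip labels
#'
#' Forward pure-birth simulation: starting from two lineages, each lineage
#' splits at rate `lambda`; the process stops when `n_tips` lineages
#' exist, pendant branches are extended by one further exponential waiting
#' time, and the tree is therefore exactly ultrametric.  By default depth
#' is rescaled to 1.  Tips are labelled `Gxxx_syyyy`, with genera formed
#' by recursively splitting the largest clade until `n_genera`
#' monophyletic groups exist, so congeners are each other's closest
#' relatives.
#'
#' @param n_tips Number of tips (`>= 2`).
#' @param n_genera Number of genera (monophyletic tip groups).
#' @param seed Integer seed (required; the generator is stochastic).
#' @param lambda Speciation rate (default 1); irrelevant after rescaling.
#' @param rescale Rescale tree depth to 1 (default `TRUE`).
#' @return An ultrametric `"phylo"` tree.
#' @export
simulate_tree <- function(n_tips, n_genera = max(2L, round(n_tips / 13)),
                          seed, lambda = 1, rescale = TRUE) {
  stopifnot(n_tips >= 2, n_genera >= 1, n_genera <= n_tips)
  if (missing(seed) || is.null(seed)) stop("seed is required")
  set.seed(seed)
  tree <- yule_tree(n_tips, lambda)
  if (rescale) {
    depth <- max(root_to_tip_depths(tree))
    tree$edge.length <- tree$edge.length / depth
  }
  block <- assign_genus_clades(tree, n_genera)
  ord <- cladewise_tip_order(tree)
  tree$tip.label[ord] <- sprintf("G%03d_s%04d", block[ord], seq_len(n_tips))
  tree
}

# Partition the tips into n_genera monophyletic clades by recursively
# splitting the largest current clade at its root.  Returns, per tip
# index, a genus number (1..n_genera, ordered along the cladewise tip
# sequence).
assign_genus_clades <- function(tree, n_genera) {
  n <- ape::Ntip(tree)
  desc <- descendant_tips(tree)
  tips_below <- function(v) if (v <= n) v else desc[[v - n]]
  root <- setdiff(unique(tree$edge[, 1]), tree$edge[, 2])
  groups <- root
  while (length(groups) < n_genera) {
    sizes <- vapply(groups, function(v) length(tips_below(v)), integer(1))
    splittable <- which(sizes >= 2)
    if (!length(splittable)) break
    g <- splittable[which.max(sizes[splittable])]
    kids <- tree$edge[tree$edge[, 1] == groups[g], 2]
    groups <- c(groups[-g], kids)
  }
  block <- integer(n)
  for (i in seq_along(groups)) block[tips_below(groups[i])] <- i
  # renumber genera in cladewise tip order
  ord <- cladewise_tip_order(tree)
  match(block, unique(block[ord]))
}

cladewise_tip_order <- function(tree) {
  eo <- ape::reorder.phylo(tree, "cladewise")
  eo$edge[eo$edge[, 2] <= ape::Ntip(tree), 2]
}

# Forward Yule simulation from two lineages; uses the session RNG.
# Lineages split at rate lambda each; when n_tips lineages exist the tree
# is cut one further Exp(n * lambda) waiting time later, so the last
# cherry has positive pendant length.
yule_tree <- function(n_tips, lambda = 1) {
  n_tips <- as.integer(n_tips)
  max_nodes <- 2L * n_tips - 1L
  parent <- integer(max_nodes)
  start <- numeric(max_nodes)  # time the edge above each node begins
  end <- numeric(max_nodes)    # time the node splits (internals) or present (tips)
  root <- 1L
  nxt <- 2L
  active <- integer(0)
  t <- 0
  for (ch in 1:2) {
    parent[nxt] <- root; start[nxt] <- 0
    active <- c(active, nxt); nxt <- nxt + 1L
  }
  while (length(active) < n_tips) {
    t <- t + stats::rexp(1, rate = lambda * length(active))
    i <- sample.int(length(active), 1L)
    v <- active[i]
    end[v] <- t
    for (ch in 1:2) {
      parent[nxt] <- v; start[nxt] <- t
      active <- c(active, nxt); nxt <- nxt + 1L
    }
    active <- active[-i]
  }
  present <- t + stats::rexp(1, rate = lambda * n_tips)
  end[active] <- present

  ids <- seq_len(max_nodes)
  is_tip <- ids %in% active
  num <- integer(max_nodes)
  num[active] <- seq_len(n_tips)                     # tips 1..n in creation order
  num[!is_tip] <- n_tips + seq_len(n_tips - 1L)      # root (created first) = n+1
  children <- ids[ids != root]
  edge <- cbind(num[parent[children]], num[children])
  list_tree <- list(edge = edge,
                    edge.length = end[children] - start[children],
                    tip.label = paste0("t", seq_len(n_tips)),
                    Nnode = n_tips - 1L)
  class(list_tree) <- "phylo"
  ape::reorder.phylo(list_tree, "cladewise")
}

#' Simulate which species are ethnomedicinally used
#'
#' Marks tips as used under the configured scenario:
#'
#' * `"random"`: independent Bernoulli(`prevalence`) per tip.
#' * `"clustered"`: the internal clade whose tip count is closest to
#'   `prevalence * n_tips` is chosen; tips inside it are used with
#'   elevated probability and tips outside with reduced probability, with
#'   odds ratio `clust_odds` and overall expected prevalence preserved.
#' * `"overdispersed"`: deterministic greedy maximin selection of
#'   `ceiling(prevalence * n_tips)` tips — seeded with the tree's most
#'   distant tip pair, then repeatedly adding the tip that maximizes the
#'   minimum patristic distance to the selected set (ties broken by the
#'   alphabetically lowest label).
#'
#' @param tree A `"phylo"` tree from [simulate_tree()] (or any tree with
#'   `Genus_species` tip labels).
#' @param config A [sim_config()].
#' @param seed Integer seed (required for the stochastic scenarios).
#' @return A `"species_dataset"` with `used` flags set and all counts 0.
#' @export
simulate_use <- function(tree, config, seed) {
  stopifnot(inherits(tree, "phylo"), inherits(config, "sim_config"))
  if (missing(seed) || is.null(seed)) stop("seed is required")
  set.seed(seed)
  n <- ape::Ntip(tree)
  labels <- tree$tip.label
  prev <- config$prevalence

  used <- switch(config$scenario,
    random = stats::runif(n) < prev,
    clustered = {
      target <- prev * n
      desc <- descendant_tips(tree)
      sizes <- lengths(desc)
      ok <- which(sizes < n)  # exclude the root clade
      if (!length(ok)) stop("no usable clade for the clustered scenario")
      node <- ok[which.min(abs(sizes[ok] - target))]
      inside <- logical(n); inside[desc[[node]]] <- TRUE
      pr <- clustered_probs(sum(inside), n - sum(inside), prev, config$clust_odds)
      stats::runif(n) < ifelse(inside, pr["p_in"], pr["p_out"])
    },
    overdispersed = {
      k <- ceiling(prev * n)
      sel <- maximin_tips(patristic_matrix(tree), k)
      labels %in% sel
    })
  species_dataset(data.frame(
    species = labels, genus = tip_genus(labels), used = used,
    n_use_reports = ifelse(used, 1L, 0L), n_studies = 0L,
    categories = "", stringsAsFactors = FALSE))
}

# Solve for (p_in, p_out) with p_in = odds * p_out and overall expected
# prevalence preserved; p_in is capped at 1 (p_out then re-solved).
clustered_probs <- function(n_in, n_out, prev, odds) {
  target <- prev * (n_in + n_out)
  p_out <- target / (odds * n_in + n_out)
  p_in <- odds * p_out
  if (p_in > 1) {
    p_in <- 1
    p_out <- (target - n_in) / n_out
    if (p_out < 0) stop("prevalence too low for the requested enrichment")
  }
  c(p_in = p_in, p_out = p_out)
}

#' Greedy maximin tip selection
#'
#' Deterministic spread-out selection used by the overdispersed scenario:
#' starts from the most distant pair of tips (the tree diameter) and
#' repeatedly adds the tip with the largest minimum distance to the
#' current selection; all ties are broken by the alphabetically lowest
#' label, so the result depends only on the tree.
#'
#' @param dm Patristic distance matrix.
#' @param k Number of tips to select (`>= 2`).
#' @return Character vector of `k` tip labels.
#' @export
maximin_tips <- function(dm, k) {
  labels <- rownames(dm)
  n <- length(labels)
  stopifnot(k >= 2, k <= n)
  ord <- order(labels)
  dmo <- dm[ord, ord, drop = FALSE]  # alphabetical order makes ties canonical
  best <- which(dmo == max(dmo), arr.ind = TRUE)
  best <- best[best[, 1] < best[, 2], , drop = FALSE]
  pick <- best[order(best[, 1], best[, 2])[1L], ]
  sel <- c(pick[[1]], pick[[2]])
  mind <- pmin(dmo[, sel[1]], dmo[, sel[2]])
  while (length(sel) < k) {
    mind[sel] <- -Inf
    nxt <- which.max(mind)  # first max = lowest label on ties
    sel <- c(sel, nxt)
    mind <- pmin(mind, dmo[, nxt])
  }
  rownames(dmo)[sel]
}

#' Simulate use-report and study counts
#'
#' For used species, use reports are `1 + NegBin` and study counts come
#' from a Gaussian copula against the report counts, so that the Spearman
#' correlation between the two (computed on the final, tied, zero-inflated
#' counts) hits `config$rho`.  Zero inflation is part of the study-count
#' margin: the lowest `zero_inflation` fraction of the copula grades maps
#' to zero studies, the rest to `1 + NegBin`.  The latent copula
#' correlation is calibrated by bisection against a large fixed-seed
#' Monte Carlo table of the same margins, so the attenuation from ties
#' and zero inflation is accounted for.  Unused species get zero use
#' reports and independent, mostly-zero study counts.
#'
#' @param dataset A `"species_dataset"` with `used` flags (e.g. from
#'   [simulate_use()]).
#' @param config A [sim_config()].
#' @param seed Integer seed (required).
#' @return The dataset with `n_use_reports` and `n_studies` filled in.
#' @export
simulate_counts <- function(dataset, config, seed) {
  stopifnot(inherits(dataset, "species_dataset"), inherits(config, "sim_config"))
  if (missing(seed) || is.null(seed)) stop("seed is required")
  r <- calibrate_copula(config)
  set.seed(seed)
  used <- which(dataset$used)
  n_u <- length(used)
  if (n_u > 0) {
    z1 <- stats::rnorm(n_u)
    z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n_u)
    counts <- copula_margins(stats::pnorm(z1), stats::pnorm(z2), config)
    dataset$n_use_reports[used] <- counts$reports
    dataset$n_studies[used] <- counts$studies
  }
  unused <- which(!dataset$used)
  if (length(unused) > 0) {
    any_study <- stats::runif(length(unused)) < config$unused_study_prob
    dataset$n_studies[unused] <- ifelse(
      any_study, 1L + stats::rpois(length(unused), 1), 0L)
    dataset$n_use_reports[unused] <- 0L
  }
  dataset
}

# Map uniform grades to the two count margins.
copula_margins <- function(u1, u2, config) {
  reports <- 1L + stats::qnbinom(u1, size = config$report_size,
                                 mu = config$report_mean - 1)
  zi <- config$zero_inflation
  studies <- integer(length(u2))
  pos <- u2 >= zi
  studies[pos] <- 1L + stats::qnbinom((u2[pos] - zi) / (1 - zi),
                                      size = config$study_size,
                                      mu = config$study_mean - 1)
  list(reports = as.integer(reports), studies = studies)
}

# Latent Gaussian correlation giving the target Spearman rho on the
# discrete margins.  Deterministic: a fixed-seed Monte Carlo grade table
# is shared across bisection steps, so the realized-rho curve is smooth
# and monotone in r.  Cached per margin configuration.
calibrate_copula <- function(config, n_mc = 20000L) {
  key <- paste(config$rho, config$report_mean, config$report_size,
               config$study_mean, config$study_size, config$zero_inflation,
               sep = "|")
  cached <- copula_cache[[key]]
  if (!is.null(cached)) return(cached)
  if (config$rho == 0) {
    copula_cache[[key]] <- 0
    return(0)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(106801L)
  z1 <- stats::rnorm(n_mc)
  z0 <- stats::rnorm(n_mc)
  realized <- function(r) {
    z2 <- r * z1 + sqrt(1 - r^2) * z0
    counts <- copula_margins(stats::pnorm(z1), stats::pnorm(z2), config)
    stats::cor(rank(counts$reports), rank(counts$studies))
  }
  f <- function(r) realized(r) - config$rho
  lo <- -1 + 1e-6; hi <- 1 - 1e-6
  r <- tryCatch(stats::uniroot(f, c(lo, hi), tol = 1e-4)$root,
                error = function(e) stop("target rho unattainable under these margins"))
  copula_cache[[key]] <- r
  r
}

copula_cache <- new.env(parent = emptyenv())

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulate a complete synthetic ethnoflora bundle
#'
#' Convenience wrapper: simulates the tree, the use flags and the counts
#' from one seed (sub-seeds are derived deterministically).
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A list: `tree`, `dataset`, `config`, `seed`.
#' @export
simulate_dataset <- function(config = sim_config(), seed) {
  if (missing(seed) || is.null(seed)) stop("seed is required")
  seeds <- derive_seeds(seed, 3L)
  tree <- simulate_tree(config$n_tips, config$n_genera, seed = seeds[1])
  ds <- simulate_use(tree, config, seed = seeds[2])
  ds <- simulate_counts(ds, config, seed = seeds[3])
  list(tree = tree, dataset = ds, config = config, seed = seed)
}

# Deterministic sub-seeds from one master seed (Park-Miller minimal
# standard generator; all arithmetic exact in doubles, results < 2^31).
derive_seeds <- function(seed, n) {
  m <- 2147483647  # 2^31 - 1
  x <- as.numeric(seed) %% m
  if (x <= 0) x <- x + m - 1
  out <- integer(n)
  for (i in seq_len(n)) {
    x <- (x * 48271) %% m
    out[i] <- as.integer(x)
  }
  out
}
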