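#' Spearman rank correlation with exact small-sample p-value
#'
#' Computes Spearman's rho as the Pearson correlation of mid-ranks
#' (tie-corrected).  The p-value is exact — obtained by enumerating all
#' `n!` permutations of one vector — for `n <= 8`, and uses the usual
#' t approximation (`t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` df)
#' otherwise.  Two-tailed by default.
#'
#' @param x,y Numeric vectors of equal length `>= 3` (typically counts:
#'   use reports and study counts; zeros are data, not missing).
#' @param alternative `"two.sided"` (default), `"greater"` (positive
#'   association) or `"less"`.
#' @return An object of class `"assoc_test"`: list with `statistic_name`
#'   (`"spearman_rho"`), `statistic`, `p`, `n`, `method` (`"exact"` or
#'   `"approximate"`), `ties` (logical), `alternative`, `degenerate`
#'   (TRUE when either vector is constant, in which case `statistic` is
#'   `NA` and `p` is 1).
#' @examples
#' spearman_test(c(1, 2, 3, 5), c(10, 20, 25, 90))
#' @export
spearman_test <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(structure(list(statistic_name = "spearman_rho", statistic = NA_real_,
                          p = 1, n = n, method = "degenerate", ties = ties,
                          alternative = alternative, degenerate = TRUE),
                     class = "assoc_test"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)

  if (n <= 8L) {
    method <- "exact"
    perm_rho <- apply(all_permutations(n), 1L, function(p) stats::cor(rx, ry[p]))
    eps <- 1e-12
    p <- switch(alternative,
      two.sided = mean(abs(perm_rho) >= abs(rho) - eps),
      greater   = mean(perm_rho >= rho - eps),
      less      = mean(perm_rho <= rho + eps))
  } else {
    method <- "approximate"
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- switch(alternative,
      two.sided = 2 * stats::pt(-abs(tstat), df = n - 2),
      greater   = stats::pt(tstat, df = n - 2, lower.tail = FALSE),
      less      = stats::pt(tstat, df = n - 2))
    p <- min(1, p)
  }
  structure(list(statistic_name = "spearman_rho", statistic = rho, p = p,
                 n = n, method = method, ties = ties,
                 alternative = alternative, degenerate = FALSE),
            class = "assoc_test")
}

#' Mann-Whitney rank-sum test with exact small-sample p-value
#'
#' Computes the Mann-Whitney U statistic for group `a` using mid-ranks.
#' The p-value is exact — full enumeration of all `choose(n1+n2, n1)`
#' group assignments of the observed (possibly tied) values — when
#' `n1 + n2 <= 12`, and otherwise uses the normal approximation with tie
#' correction and a 0.5 continuity correction.  Two-tailed p-values are
#' symmetric in U about `n1*n2/2`, so swapping the groups leaves them
#' unchanged.
#'
#' @param a,b Numeric vectors (each non-empty), e.g. study counts for
#'   species inside vs outside hotnode clades.
#' @param alternative `"two.sided"` (default), `"greater"` (`a` tends to
#'   exceed `b`) or `"less"`.
#' @return An `"assoc_test"` list with `statistic_name` (`"ranksum_U"`),
#'   `statistic` (U for group `a`, in `[0, n1*n2]`), `p`, `n1`, `n2`,
#'   `method`, `ties`, `alternative`.
#' @examples
#' ranksum_test(c(1, 2), c(3, 4))  # U = 0, complete separation
#' @export
ranksum_test <- function(a, b, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1L || n2 < 1L) stop("both groups must be non-empty")
  if (anyNA(a) || anyNA(b)) stop("missing values not allowed")
  pooled <- c(a, b)
  rk <- rank(pooled)
  ties <- anyDuplicated(pooled) > 0L
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2

  if (n1 + n2 <= 12L) {
    method <- "exact"
    combos <- utils::combn(n1 + n2, n1)
    Us <- apply(combos, 2L, function(idx) sum(rk[idx]) - n1 * (n1 + 1) / 2)
    eps <- 1e-9
    p <- switch(alternative,
      two.sided = mean(abs(Us - mu) >= abs(U - mu) - eps),
      greater   = mean(Us >= U - eps),
      less      = mean(Us <= U + eps))
  } else {
    method <- "approximate"
    nn <- n1 + n2
    tie_tab <- table(rk)
    tie_term <- sum(tie_tab^3 - tie_tab) / (nn * (nn - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((nn + 1) - tie_term))
    z_of <- function(u, side) (u - mu - side * 0.5) / sigma
    p <- switch(alternative,
      two.sided = min(1, 2 * stats::pnorm(-abs(z_of(U, sign(U - mu))))),
      greater   = stats::pnorm(z_of(U, +1), lower.tail = FALSE),
      less      = stats::pnorm(z_of(U, -1)))
  }
  structure(list(statistic_name = "ranksum_U", statistic = U, p = p,
                 n1 = n1, n2 = n2, method = method, ties = ties,
                 alternative = alternative, degenerate = FALSE),
            class = "assoc_test")
}

#' @export
print.assoc_test <- function(x, ...) {
  nlab <- if (!is.null(x$n)) sprintf("n = %d", x$n)
          else sprintf("n1 = %d, n2 = %d", x$n1, x$n2)
  cat(sprintf("%s = %.4g (%s, %s, %s): p = %.4g\n",
              x$statistic_name, x$statistic, nlab, x$method, x$alternative, x$p))
  invisible(x)
}

# All permutations of 1:n as rows (n! x n); recursion is fine for n <= 8.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (j in seq_len(nrow(sub))) {
      out[row, ] <- c(i, rest[sub[j, ]])
      row <- row + 1L
    }
  }
  out
}
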