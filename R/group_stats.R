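#' Kruskal-Wallis rank test across groups
#'
#' Nonparametric comparison of RI (or any numeric response) across two or
#' more groups via the tie-corrected Kruskal-Wallis H statistic with the
#' chi-square approximation (df = k - 1). Delegates to
#' [stats::kruskal.test()]; this wrapper fixes the input shape and the
#' reported fields. All observations identical gives H = 0, p = 1.
#'
#' @param groups List of numeric vectors, one per group (each non-empty).
#' @return List of class `kw_result`: `h_statistic`, `df`, `p_value`,
#'   `n_total`, `group_sizes`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes == 0)) stop("empty group", call. = FALSE)
  n <- sum(sizes)
  if (n < 3) stop("need total n >= 3", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), sizes))
  if (length(unique(x)) == 1) {
    res <- list(h_statistic = 0, df = length(groups) - 1L, p_value = 1,
                n_total = n, group_sizes = sizes)
  } else {
    kt <- stats::kruskal.test(x, g)
    res <- list(h_statistic = unname(kt$statistic),
                df = unname(kt$parameter), p_value = kt$p.value,
                n_total = n, group_sizes = sizes)
  }
  structure(res, class = "kw_result")
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.4g (N = %d)\n",
              x$h_statistic, x$df, x$p_value, x$n_total))
  invisible(x)
}

#' Rank-based multiple-comparison post hoc test
#'
#' Pairwise comparison of mean ranks after a Kruskal-Wallis rejection
#' (Siegel-Castellan construction): the pair (i, j) differs when
#' `|Rbar_i - Rbar_j|` exceeds
#' `z[1 - alpha / (k (k - 1))] * sqrt(N (N + 1) / 12 * (1/n_i + 1/n_j))`,
#' i.e. a normal critical value Bonferroni-adjusted over all ordered pairs.
#' Ranks are midranks over the pooled sample. A compact letter display is
#' derived from the significance matrix by greedy insert-absorb: groups
#' sharing a letter are not significantly different.
#'
#' @param groups List of numeric vectors, one per group.
#' @param labels Group names (default `g1`, `g2`, ...).
#' @param alpha Family-wise significance level (default 0.05).
#' @return List of class `posthoc_result`: `pairs` (data frame with
#'   `group_a`, `group_b`, `abs_mean_rank_diff`, `critical_diff`,
#'   `significant`), `alpha`, `letters` (named character vector).
#' @export
posthoc_mc <- function(groups, labels = NULL, alpha = 0.05) {
  k <- length(groups)
  if (k < 2) stop("need at least 2 groups", call. = FALSE)
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes == 0)) stop("empty group", call. = FALSE)
  if (is.null(labels)) labels <- paste0("g", seq_len(k))
  stopifnot(length(labels) == k)
  n <- sum(sizes)
  r <- rank(unlist(groups, use.names = FALSE))  # midranks
  gi <- rep(seq_len(k), sizes)
  rbar <- tapply(r, gi, mean)
  zcrit <- stats::qnorm(1 - alpha / (k * (k - 1)))
  comb <- utils::combn(k, 2)
  pairs <- data.frame(
    group_a = labels[comb[1, ]], group_b = labels[comb[2, ]],
    abs_mean_rank_diff = abs(rbar[comb[1, ]] - rbar[comb[2, ]]),
    critical_diff = zcrit * sqrt(n * (n + 1) / 12 *
                                   (1 / sizes[comb[1, ]] +
                                      1 / sizes[comb[2, ]])),
    stringsAsFactors = FALSE, row.names = NULL)
  pairs$significant <- pairs$abs_mean_rank_diff > pairs$critical_diff
  diff_mat <- matrix(FALSE, k, k, dimnames = list(labels, labels))
  for (p in seq_len(ncol(comb))) {
    a <- comb[1, p]; b <- comb[2, p]
    diff_mat[a, b] <- diff_mat[b, a] <- pairs$significant[p]
  }
  structure(list(pairs = pairs, alpha = alpha,
                 letters = .letter_display(diff_mat)),
            class = "posthoc_result")
}

# Insert-and-absorb compact letter display: start from one set holding all
# groups; each significant pair splits every set containing both; absorbed
# (subset) sets are dropped. Groups share a letter iff no significant
# difference separates them within that set.
.letter_display <- function(diff_mat) {
  labels <- rownames(diff_mat)
  k <- length(labels)
  sets <- list(seq_len(k))
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    if (!diff_mat[i, j]) next
    new_sets <- list()
    for (s in sets) {
      if (i %in% s && j %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
      } else new_sets <- c(new_sets, list(s))
    }
    # absorb sets contained in another
    keep <- rep(TRUE, length(new_sets))
    for (a in seq_along(new_sets)) for (b in seq_along(new_sets))
      if (a != b && keep[b] && all(new_sets[[a]] %in% new_sets[[b]]) &&
          (length(new_sets[[a]]) < length(new_sets[[b]]) || a > b))
        keep[a] <- FALSE
    sets <- new_sets[keep]
  }
  out <- vapply(seq_len(k), function(i)
    paste0(letters[which(vapply(sets, function(s) i %in% s, logical(1)))],
           collapse = ""), character(1))
  names(out) <- labels
  out
}

#' @export
print.posthoc_result <- function(x, ...) {
  cat(sprintf("Rank post hoc (alpha = %.3g):\n", x$alpha))
  print(x$pairs, row.names = FALSE)
  cat("Letters:\n")
  print(x$letters)
  invisible(x)
}
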