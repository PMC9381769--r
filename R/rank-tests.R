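# exact permutation machinery for the Spearman test ---------------------------

# all permutations of 1..n as an n! x n integer matrix (n <= 8 cached)
perm_matrix <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) {
      return(cache[[key]])
    }
    stopifnot(n >= 1, n <= 8)
    m <- matrix(1L, 1L, 1L)
    if (n > 1L) {
      for (k in 2:n) {
        prev <- m
        m <- matrix(0L, nrow(prev) * k, k)
        row <- 0L
        for (pos in seq_len(k)) {
          blk <- cbind(
            prev[, seq_len(pos - 1L), drop = FALSE], k,
            if (pos <= k - 1L) prev[, pos:(k - 1L), drop = FALSE]
          )
          m[row + seq_len(nrow(prev)), ] <- blk
          row <- row + nrow(prev)
        }
      }
    }
    cache[[key]] <<- m
    m
  }
})

# count permutations of ry whose rank product-sum with rx is >= / <= s_obs;
# streams over leading-element choices so n = 9, 10 stay in memory
perm_sum_counts <- function(rx, ry, s_obs, eps = 1e-9) {
  n <- length(rx)
  count <- function(rx_head_sum, rx_rest, ry_avail) {
    if (length(rx_rest) <= 8L) {
      pm <- perm_matrix(length(rx_rest))
      vals <- matrix(ry_avail[pm], nrow(pm), ncol(pm))
      s <- rx_head_sum + as.numeric(vals %*% rx_rest)
      c(ge = sum(s >= s_obs - eps), le = sum(s <= s_obs + eps),
        tot = length(s)
      )
    } else {
      acc <- c(ge = 0, le = 0, tot = 0)
      for (j in seq_along(ry_avail)) {
        acc <- acc + count(
          rx_head_sum + rx_rest[1] * ry_avail[j],
          rx_rest[-1], ry_avail[-j]
        )
      }
      acc
    }
  }
  count(0, rx, ry)
}

#' Spearman rank correlation with an exact permutation p-value
#'
#' Rank correlation with average ranks for ties. For `n <= 10` the p-value
#' is exact, computed by enumerating all `n!` pairings of the (possibly
#' tied) rank vectors; for larger n the t-distribution approximation
#' `t = r_s * sqrt((n-2)/(1-r_s^2))` is used. The tail direction is
#' explicit and defaults to one-sided.
#'
#' @param x,y paired numeric vectors, `n >= 3`, finite.
#' @param alternative `"less"` (negative association), `"greater"`, or
#'   `"two.sided"`.
#' @param exact_max largest n for exact enumeration.
#' @return list `rho`, `p_value`, `n`, `exact`.
#' @export
spearman_rank <- function(x, y, alternative = c("less", "greater", "two.sided"),
                          exact_max = 10L) {
  alternative <- match.arg(alternative)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop("constant input: rank correlation undefined")
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_max) {
    s_obs <- sum(rx * ry)
    cnt <- perm_sum_counts(rx, ry, s_obs)
    # large rank product-sum <=> positive correlation
    p <- switch(alternative,
      greater = cnt["ge"] / cnt["tot"],
      less = cnt["le"] / cnt["tot"],
      two.sided = min(1, 2 * min(cnt["ge"], cnt["le"]) / cnt["tot"])
    )
    return(list(rho = rho, p_value = unname(p), n = n, exact = TRUE))
  }
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  p <- switch(alternative,
    greater = stats::pt(tstat, n - 2, lower.tail = FALSE),
    less = stats::pt(tstat, n - 2),
    two.sided = 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
  )
  list(rho = rho, p_value = min(p, 1), n = n, exact = FALSE)
}
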