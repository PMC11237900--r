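## Independent oracle implementations used to cross-check the package.
## These are deliberately written from first principles (explicit loops,
## direct formulas) and never call the code paths they verify.

## local polynomial regression with tricube weights and bisquare
## robustness re-weighting, evaluated at every observed x
local_reg_oracle <- function(x, y, span, degree = 2, iterations = 4) {
  n <- length(x)
  q <- max(floor(span * n), degree + 1)
  rw <- rep(1, n)
  fitted <- y
  total_iter <- max(1, iterations)
  for (it in seq_len(total_iter)) {
    fitted <- vapply(seq_len(n), function(i) {
      d <- abs(x - x[i])
      h <- sort(d, partial = q)[q]
      w <- numeric(n)
      if (h > 0) {
        idx <- d <= h
        w[idx] <- (1 - (d[idx] / h)^3)^3
      } else w[d == 0] <- 1
      w <- w * rw
      X <- outer(x - x[i], 0:degree, "^")
      keep <- w > 0
      fit <- lm.wfit(X[keep, , drop = FALSE], y[keep], w[keep])
      fit$coefficients[1]
    }, numeric(1))
    if (it < total_iter) {
      res <- y - fitted
      s <- median(abs(res))
      u <- res / (6 * s)
      rw <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    }
  }
  fitted
}

## Spearman rho by brute force: mid-ranks, then the explicit Pearson
## product-moment formula
spearman_brute <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

## geNorm M and V by explicit loops over the definition
genorm_loop_oracle <- function(mat) {
  genes <- rownames(mat)
  lx <- log2(mat)
  sd_loop <- function(v) {
    m <- sum(v) / length(v)
    sqrt(sum((v - m)^2) / (length(v) - 1))
  }
  M <- sapply(genes, function(j) {
    vals <- c()
    for (k in setdiff(genes, j)) vals <- c(vals, sd_loop(lx[j, ] - lx[k, ]))
    mean(vals)
  })
  ## exclusion by recomputed M among remaining genes
  remaining <- genes; order_excl <- c()
  while (length(remaining) > 2) {
    m_now <- sapply(remaining, function(j) {
      vals <- c()
      for (k in setdiff(remaining, j)) vals <- c(vals, sd_loop(lx[j, ] - lx[k, ]))
      mean(vals)
    })
    worst <- names(which.max(m_now))
    order_excl <- c(order_excl, worst)
    remaining <- setdiff(remaining, worst)
  }
  ranking <- c(remaining, rev(order_excl))
  geo <- function(cols) apply(cols, 2, function(s) exp(mean(log(s))))
  V <- c()
  for (n in 2:(length(genes) - 1)) {
    nf_n <- geo(mat[ranking[1:n], , drop = FALSE])
    nf_n1 <- geo(mat[ranking[1:(n + 1)], , drop = FALSE])
    V[paste0("V", n, "/", n + 1)] <- sd_loop(log2(nf_n / nf_n1))
  }
  list(M = M, V = V, ranking = ranking)
}

## build a bilateral expression long table from a rats x (gene,side) value
## function; vals(gene, side, rat) -> numeric
make_expr_table <- function(genes, rats, vals, region = "HPT",
                            treatment = rep("sham", length(rats))) {
  grid <- expand.grid(rat = seq_along(rats), gene = genes,
                      side = c("left", "right"), stringsAsFactors = FALSE)
  data.frame(rat_id = rats[grid$rat], region = region, side = grid$side,
             gene = grid$gene,
             value = mapply(vals, grid$gene, grid$side, grid$rat),
             treatment = treatment[grid$rat], stringsAsFactors = FALSE)
}

## group_posterior with known draws, for contrast arithmetic checks
posterior_from_draws <- function(draws) {
  lrasym:::make_group_posterior(draws, colnames(draws),
                                diagnostics = list(converged = TRUE),
                                spec = NULL, scale = "response")
}

## small MCMC spec for unit tests (documented MC-error allowances in the
## assertions); acceptance checks use the larger calibrated spec
quick_spec <- function(seed = 1) {
  robust_model_spec(chains = 2, iterations = 2000, warmup = 500, seed = seed)
}
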