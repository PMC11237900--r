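test_that("reference normalization follows the geometric-mean identity", {
  cq <- rbind(g1 = c(24, 25), Actb = c(20, 22), Gapdh = c(22, 24))
  colnames(cq) <- c("s1", "s2")
  ## Cq_gene equal to the arithmetic mean of the reference Cqs -> value 1
  cq["g1", 1] <- mean(cq[c("Actb", "Gapdh"), 1])
  ## one cycle below the mean -> value 2
  cq["g1", 2] <- mean(cq[c("Actb", "Gapdh"), 2]) - 1
  norm <- normalize_to_references(cq, c("Actb", "Gapdh"))
  expect_equal(unname(norm["g1", ]), c(1, 2), tolerance = 1e-12)
})

test_that("normalization matches a per-sample loop oracle and is shift-invariant", {
  set.seed(21)
  cq <- matrix(rnorm(30, 25, 2), 5, 6,
               dimnames = list(c("a", "b", "c", "ref1", "ref2"), paste0("s", 1:6)))
  norm <- normalize_to_references(cq, c("ref1", "ref2"))
  for (s in 1:6) for (g in c("a", "b", "c")) {
    rq <- 2^(-cq[g, s])
    nf <- sqrt(2^(-cq["ref1", s]) * 2^(-cq["ref2", s]))
    expect_equal(norm[g, s], rq / nf, tolerance = 1e-12)
  }
  ## adding a constant to every Cq of a sample cancels
  cq2 <- cq; cq2[, 3] <- cq2[, 3] + 1.7
  norm2 <- normalize_to_references(cq2, c("ref1", "ref2"))
  expect_equal(norm2, norm, tolerance = 1e-12)
})

test_that("geNorm identifies stable genes and matches the loop oracle", {
  ## two exactly proportional candidates + one noisy one
  set.seed(22)
  base <- 2^rnorm(6, 5, 0.5)
  m <- rbind(p1 = base, p2 = 3 * base, noisy = 2^rnorm(6, 5, 0.5))
  g <- genorm(m)
  expect_equal(g$m[["p1"]], g$m[["p2"]], tolerance = 1e-12)
  expect_lt(g$m[["p1"]], g$m[["noisy"]])
  expect_equal(g$exclusion_order, "noisy")

  ## all candidates identical across samples: M = 0, V = 0
  const <- matrix(5, 4, 6, dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  gc <- genorm(const)
  expect_equal(unname(gc$m), rep(0, 4))
  expect_equal(unname(gc$v), rep(0, 2))

  ## constructed 4 x 6 matrix against the loop oracle
  set.seed(23)
  mat <- matrix(2^rnorm(24, 6, c(0.1, 0.15, 0.3, 0.6)), 4, 6,
                dimnames = list(c("r1", "r2", "mid", "wild"), paste0("s", 1:6)))
  got <- genorm(mat)
  orc <- genorm_loop_oracle(mat)
  expect_equal(got$m[names(orc$M)], orc$M, tolerance = 1e-10)
  expect_equal(got$v, orc$V, tolerance = 1e-10)
  expect_equal(got$ranking, orc$ranking)

  ## M is invariant to rescaling one candidate
  mat2 <- mat; mat2["mid", ] <- 7 * mat2["mid", ]
  expect_equal(genorm(mat2)$m, got$m, tolerance = 1e-12)

  expect_error(genorm(mat[1:2, ]), class = "lrasym_input_error")
  mat3 <- mat; mat3[1, 1] <- 0
  expect_error(genorm(mat3), class = "lrasym_domain_error")
})

test_that("fold-change tests report magnitude, direction and Bonferroni p", {
  df <- data.frame(gene = "g", treatment = rep(c("ubi", "sham"), each = 5),
                   value = c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5))
  fc <- fold_change_tests(df, case = "ubi", control = "sham", n_tests = 1)
  expect_equal(fc$fc, 1); expect_equal(fc$direction, "none")
  expect_equal(fc$p_adj, 1)

  df2 <- df; df2$value[df2$treatment == "ubi"] <- df2$value[df2$treatment == "ubi"] / 2
  fc2 <- fold_change_tests(df2, case = "ubi", control = "sham", n_tests = 1)
  expect_equal(fc2$fc, 2); expect_equal(fc2$direction, "down_in_case")

  ## Bonferroni arithmetic: p_adj = min(1, p * n)
  set.seed(24)
  df3 <- data.frame(gene = "g", treatment = rep(c("ubi", "sham"), each = 8),
                    value = c(rnorm(8, 3), rnorm(8, 0)))
  fc3a <- fold_change_tests(df3, case = "ubi", control = "sham", n_tests = 1)
  fc3b <- fold_change_tests(df3, case = "ubi", control = "sham", n_tests = 56)
  expect_equal(fc3b$p_raw, fc3a$p_raw)
  expect_equal(fc3b$p_adj, min(1, fc3a$p_raw * 56))

  ## swapping the groups flips the direction, preserves FC and p
  fc3c <- fold_change_tests(df3, case = "sham", control = "ubi", n_tests = 1)
  expect_equal(fc3c$fc, fc3a$fc)
  expect_equal(fc3c$p_raw, fc3a$p_raw)
  expect_true(fc3a$direction != fc3c$direction)
})

test_that("asymmetry-index tests follow the sign conventions", {
  rats <- sprintf("r%02d", 1:8)
  ## L = R everywhere -> AI 0, no lateralization
  sym <- make_expr_table("g1", rats, function(g, s, r) 10)
  ai <- asymmetry_index_tests(sym, case = "ubi", control = "sham",
                              pool = "always")
  expect_equal(ai$ai, 0)
  expect_equal(ai$p_zero_raw, 1)

  ## per-rat log2 ratio exactly 1 -> AI = 1
  twofold <- make_expr_table("g1", rats,
                             function(g, s, r) if (s == "left") 20 else 10)
  ai2 <- asymmetry_index_tests(twofold, case = "ubi", control = "sham",
                               pool = "always")
  expect_equal(ai2$ai, 1)
  expect_equal(ai2$ai_ratio_of_medians, 1)

  ## swapping sides negates the AI and keeps the test p-value
  set.seed(25)
  vals <- matrix(2^rnorm(16, 5, 0.4), 8, 2)
  noisy <- make_expr_table("g1", rats, function(g, s, r)
    vals[r, if (s == "left") 1 else 2])
  swapped <- noisy
  swapped$side <- ifelse(noisy$side == "left", "right", "left")
  a <- asymmetry_index_tests(noisy, case = "ubi", control = "sham", pool = "always")
  b <- asymmetry_index_tests(swapped, case = "ubi", control = "sham", pool = "always")
  expect_equal(b$ai, -a$ai)
  expect_equal(b$p_zero_raw, a$p_zero_raw)
})

test_that("lateralization power: a 0.8 log2 offset is detected after pooling", {
  hits <- 0L
  for (s in 1:20) {
    cfg <- simulation_config(n_ubi = 11L, n_sham = 11L, regions = "HPT",
                             genes = data.frame(gene = "g1", network = "LdN",
                                                lambda = 0.8, delta = 0),
                             seed = 700L + s)
    expr <- as.data.frame(simulate_expression_study(cfg)$expression)
    ai <- asymmetry_index_tests(expr, pool = "always")
    hits <- hits + (ai$p_zero_adj < 0.05)
  }
  expect_gte(hits, 18L)
})

test_that("the left-right fold-change concordance fit matches closed-form OLS", {
  x <- c(-1, -0.5, 0.2, 0.8, 1.5)
  ## exact fixtures provoke the "essentially perfect fit" lm warning
  cc <- suppressWarnings(fc_concordance(x, x))
  expect_equal(cc$slope, 1, tolerance = 1e-12)
  expect_equal(cc$intercept, 0, tolerance = 1e-12)
  expect_equal(cc$pearson$r, 1, tolerance = 1e-12)

  cc2 <- suppressWarnings(fc_concordance(x, 0.5 * x))
  expect_equal(cc2$slope, 0.5, tolerance = 1e-12)
  expect_equal(cc2$intercept, 0, tolerance = 1e-12)

  set.seed(26)
  xl <- rnorm(20); yr <- 0.6 * xl + rnorm(20, 0, 0.2)
  cc3 <- fc_concordance(xl, yr)
  X <- cbind(1, xl)
  beta <- solve(t(X) %*% X, t(X) %*% yr)
  expect_equal(cc3$intercept, beta[1], tolerance = 1e-10)
  expect_equal(cc3$slope, beta[2], tolerance = 1e-10)
  s2 <- sum((yr - X %*% beta)^2) / (20 - 2)
  se <- sqrt(diag(solve(t(X) %*% X)) * s2)
  tq <- qt(0.975, 18)
  expect_equal(cc3$slope_ci,
               unname(c(beta[2] - tq * se[2], beta[2] + tq * se[2])),
               tolerance = 1e-10)

  expect_error(fc_concordance(rep(1, 5), rnorm(5)), class = "lrasym_domain_error")
  expect_error(fc_concordance(1:3, 1:3), class = "lrasym_input_error")
})
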