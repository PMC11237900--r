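## small deterministic bilateral table used across several blocks
networks_fixture <- function(seed = 31, n = 10, genes = 6) {
  set.seed(seed)
  rats <- sprintf("r%02d", 1:n)
  gn <- sprintf("g%d", 1:genes)
  vals <- array(2^rnorm(n * genes * 2, 5, 0.5), c(n, genes, 2),
                dimnames = list(rats, gn, c("left", "right")))
  make_expr_table(gn, rats, function(g, s, r) vals[r, g, s],
                  treatment = rep(c("ubi", "sham"), length.out = n))
}

test_that("genes are assigned to networks by the sign of the AI criterion", {
  rats <- sprintf("r%d", 1:6)
  ai <- data.frame(rat_id = rep(rats, 2),
                   gene = rep(c("gL", "gR"), each = 6), region = "HPT",
                   ai = c(rep(0.3, 6), rep(-0.2, 6)),
                   treatment = rep(c("ubi", "sham"), 6))
  asg <- categorize_genes(ai, variant = 1)
  expect_equal(asg$label[asg$gene == "gL"], "LdN")
  expect_equal(asg$label[asg$gene == "gR"], "RdN")

  ## a gene whose sham-only median flips sign wobbles under variant 2:
  ## gL combined values (0.5, 0.5, 0.5, -0.1, -0.1, -0.1) give a combined
  ## median and mean of +0.2 (LdN) but a sham-only median of -0.1 (RdN)
  ai2 <- ai
  ai2$ai[ai2$gene == "gL" & ai2$treatment == "ubi"] <- 0.5
  ai2$ai[ai2$gene == "gL" & ai2$treatment == "sham"] <- -0.1
  all3 <- categorize_genes_all(ai2, control = "sham")
  gl <- all3[all3$gene == "gL", ]
  expect_equal(gl$label_v1, "LdN")
  expect_equal(gl$label_v2, "RdN")
  expect_false(gl$stable)
  expect_match(gl$wobble, "v2")
  expect_true(all3$stable[all3$gene == "gR"])

  ## an AI criterion of exactly zero leaves the gene unassigned
  ai3 <- ai; ai3$ai[ai3$gene == "gL"] <- c(-1, -1, -1, 1, 1, 1)
  expect_equal(categorize_genes(ai3, 1)$label[1], "unassigned")
})

test_that("with no true lateralization the labels split and wobble is common", {
  labs <- c(); wob <- c()
  for (s in 1:10) {
    cfg <- simulation_config(n_ubi = 11L, n_sham = 11L, regions = "HPT",
                             genes = default_gene_panel(lambda = 0, delta = 0),
                             seed = 800L + s)
    expr <- as.data.frame(simulate_expression_study(cfg)$expression)
    all3 <- categorize_genes_all(lrasym:::ai_per_rat(expr))
    labs <- c(labs, all3$label_v1)
    wob <- c(wob, !all3$stable)
  }
  frac_ldn <- mean(labs == "LdN")
  expect_gt(frac_ldn, 0.3); expect_lt(frac_ldn, 0.7)
  expect_gt(mean(wob), 0.05)
})

test_that("pattern correlations equal brute-force rank-then-Pearson", {
  rats <- sprintf("r%02d", 1:10)
  ## identical rank order -> rho 1, strength 1, proportion positive 1
  mono <- make_expr_table(c("a", "b"), rats, function(g, s, r)
    r * (if (g == "a") 2 else 5) + (if (s == "left") 0 else 100))
  asg <- data.frame(gene = c("a", "b"), region = "HPT",
                    label = c("LdN", "LdN"))
  pc <- pattern_correlations(mono, asg, "HPT", "left", "LdN")
  expect_equal(pc$pairs$rho, 1)
  expect_equal(pc$strength, 1); expect_equal(pc$prop_positive, 1)

  ## anti-monotone pair -> strength 1, proportion positive 0
  anti <- make_expr_table(c("a", "b"), rats, function(g, s, r)
    if (g == "a") r else 20 - r)
  pa <- pattern_correlations(anti, asg, "HPT", "left", "LdN")
  expect_equal(pa$strength, 1); expect_equal(pa$prop_positive, 0)

  ## random tables against the brute oracle
  for (s in 1:5) {
    expr <- networks_fixture(seed = 40 + s)
    asg6 <- data.frame(gene = sprintf("g%d", 1:6), region = "HPT",
                       label = "LdN")
    pc <- pattern_correlations(expr, asg6, "HPT", "left", "LdN")
    wide <- sapply(sprintf("g%d", 1:6), function(g)
      expr$value[expr$gene == g & expr$side == "left"][order(expr$rat_id[expr$gene == g & expr$side == "left"])])
    for (i in seq_len(nrow(pc$pairs))) {
      expect_equal(pc$pairs$rho[i],
                   spearman_brute(wide[, pc$pairs$gene_a[i]],
                                  wide[, pc$pairs$gene_b[i]]),
                   tolerance = 1e-12)
    }
    ## strength dominates |mean signed rho| (triangle inequality)
    expect_gte(pc$strength + 1e-12, abs(mean(pc$pairs$rho)))
  }
})

test_that("a statistic invariant under the relabeling gives p ~ 1", {
  rats <- sprintf("r%02d", 1:8)
  set.seed(51)
  base <- matrix(2^rnorm(8 * 4, 5, 0.5), 8, 4)
  ## left and right modules carry identical data: module swaps cannot
  ## change any statistic
  dup <- make_expr_table(sprintf("g%d", 1:4), rats,
                         function(g, s, r) base[r, as.integer(substring(g, 2))],
                         treatment = rep("sham", 8))
  asg <- data.frame(gene = sprintf("g%d", 1:4), region = "HPT", label = "LdN")
  res <- compare_patterns(dup, asg, task = 2, R = 200, seed = 1,
                          case = "sham", control = "sham", areas = "HPT",
                          include_group_contrasts = FALSE)
  expect_true(all(res$p_raw > 0.99))
  expect_true(all(abs(res$observed_diff) < 1e-12))
})

test_that("relabeling left-right everywhere swaps networks and pattern summaries", {
  expr <- networks_fixture(seed = 61)
  ai <- lrasym:::ai_per_rat(expr)
  asg <- categorize_genes(ai, 1)
  swapped <- expr
  swapped$side <- ifelse(expr$side == "left", "right", "left")
  asg_sw <- categorize_genes(lrasym:::ai_per_rat(swapped), 1)
  ## every LdN gene becomes RdN and vice versa
  m <- merge(asg, asg_sw, by = c("gene", "region"))
  flip <- c(LdN = "RdN", RdN = "LdN")
  expect_equal(m$label.y, unname(flip[m$label.x]))
  ## the left-module LdN pattern of the original equals the right-module
  ## RdN-relabelled pattern of the swapped data
  a <- pattern_correlations(expr, asg, "HPT", "left", "LdN")
  b <- pattern_correlations(swapped, asg_sw, "HPT", "right", "RdN")
  expect_equal(sort(a$pairs$rho), sort(b$pairs$rho), tolerance = 1e-12)
  expect_equal(a$strength, b$strength, tolerance = 1e-12)
  expect_equal(a$prop_positive, b$prop_positive, tolerance = 1e-12)
})

test_that("BH adjustment is monotone within each family and never below raw", {
  expr <- networks_fixture(seed = 71)
  asg <- categorize_genes(lrasym:::ai_per_rat(expr), 1)
  res <- compare_patterns(expr, asg, task = 1, R = 200, seed = 2,
                          case = "ubi", control = "sham", areas = "HPT")
  adj <- adjust_bh(res)
  expect_true(all(adj$p_adj >= adj$p_raw - 1e-12))
  for (f in unique(adj$family)) {
    d <- adj[adj$family == f, ]
    o <- order(d$p_raw)
    expect_true(all(diff(d$p_adj[o]) >= -1e-12))
  }
})

test_that("configuration errors in the permutation machinery are caught", {
  expr <- networks_fixture()
  asg <- categorize_genes(lrasym:::ai_per_rat(expr), 1)
  expect_error(compare_patterns(expr, asg, task = 1, R = 50),
               class = "lrasym_config_error")
  expect_error(compare_patterns(expr, asg, task = 8, R = 500),
               class = "lrasym_config_error")
  expect_error(compare_patterns(expr, asg, task = 1, R = 500,
                                scheme = "area_within_module", areas = "HPT"),
               class = "lrasym_config_error")
})

test_that("the full network analysis runs end to end with seeded determinism", {
  expr <- networks_fixture(seed = 81, n = 10)
  na1 <- network_analysis(expr, tasks = 1, R = 150, seed = 5,
                          case = "ubi", control = "sham", areas = "HPT")
  na2 <- network_analysis(expr, tasks = 1, R = 150, seed = 5,
                          case = "ubi", control = "sham", areas = "HPT")
  expect_identical(na1$results$p_raw, na2$results$p_raw)
  expect_true(all(na1$results$p_raw > 0 & na1$results$p_raw <= 1))
  expect_true(all(c("p_adj_v1", "p_adj_v2", "p_adj_v3",
                    "stringent_significant") %in% names(na1$summary)))
  expect_equal(nrow(na1$summary), nrow(na1$results) / 3)
})
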