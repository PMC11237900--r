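## qPCR expression statistics: delta-Cq normalization against the geometric
## mean of reference genes, geNorm reference-gene stability (M and V
## values), nonparametric fold-change tests, lateralization (log2 L/R
## asymmetry index) inference, and the left-right fold-change concordance
## fit. All hypothesis tests are nonparametric (Mann-Whitney / Wilcoxon
## signed-rank) with Bonferroni correction at a configured family size.

#' Normalize Cq values to reference genes
#'
#' Relative quantity per gene is `efficiency^(-Cq)` (default efficiency 2,
#' i.e. perfect doubling); the normalized value divides each gene's
#' relative quantity by the geometric mean of the reference genes' relative
#' quantities in the same sample. Samples missing any reference Cq are
#' excluded with a logged count.
#'
#' @param cq numeric matrix of Cq values, genes x samples
#' @param refs character vector of reference gene names (rows of `cq`)
#' @param efficiency amplification base (2 = 100% efficiency)
#' @return matrix of normalized expression (linear scale) for the
#'   non-reference genes, excluded samples dropped
#' @export
normalize_to_references <- function(cq, refs, efficiency = 2) {
  stopifnot(is.matrix(cq))
  if (length(refs) < 2L) stop_input("need >= 2 reference genes")
  miss <- setdiff(refs, rownames(cq))
  if (length(miss)) stop_input(paste("reference gene(s) not measured:",
                                     paste(miss, collapse = ", ")))
  ref_cq <- cq[refs, , drop = FALSE]
  bad <- apply(ref_cq, 2L, function(x) any(is.na(x)))
  if (any(bad)) {
    log_msg("WARN", sprintf("excluding %d sample(s) with missing reference Cq: %s",
                            sum(bad), paste(colnames(cq)[bad], collapse = ", ")))
    cq <- cq[, !bad, drop = FALSE]
    ref_cq <- ref_cq[, !bad, drop = FALSE]
  }
  rq <- efficiency^(-cq)
  nf <- apply(efficiency^(-ref_cq), 2L, geometric_mean)
  out <- sweep(rq, 2L, nf, "/")
  out[setdiff(rownames(cq), refs), , drop = FALSE]
}

#' geNorm reference-gene stability
#'
#' For candidate j, the stability measure M_j is the mean over all other
#' candidates k of the standard deviation across samples of
#' log2(x_j / x_k); low M means stable. Candidates are excluded one at a
#' time (highest M first, recomputing M among the remaining genes) until
#' two remain, giving the exclusion order and a stability ranking. The
#' pairwise variation V_{n/n+1} is the SD across samples of
#' log2(NF_n / NF_{n+1}), where NF_n is the geometric mean of the n most
#' stable candidates; V below 0.15 conventionally indicates that n
#' reference genes suffice.
#'
#' @param expr matrix of expression on the linear scale (candidates x
#'   samples, strictly positive), e.g. `2^-Cq`
#' @param candidates candidate gene names; default all rows
#' @return a `genorm_result` list: `m` (initial M per candidate),
#'   `exclusion_order`, `ranking` (most stable last pair first), `v`
#'   (named vector V_{2/3}, V_{3/4}, ...)
#' @export
genorm <- function(expr, candidates = rownames(expr)) {
  stopifnot(is.matrix(expr))
  if (length(candidates) < 3L) stop_input("need >= 3 candidate genes")
  if (ncol(expr) < 3L) stop_input("need >= 3 samples")
  x <- expr[candidates, , drop = FALSE]
  if (any(!is.finite(x)) || any(x <= 0))
    stop_domain("geNorm requires finite positive expression values")
  lx <- log2(x)
  m_of <- function(genes) {
    vapply(genes, function(j) {
      others <- setdiff(genes, j)
      mean(vapply(others, function(k) sd(lx[j, ] - lx[k, ]), numeric(1)))
    }, numeric(1))
  }
  m_initial <- m_of(candidates)
  remaining <- candidates
  exclusion <- character()
  while (length(remaining) > 2L) {
    m_now <- m_of(remaining)
    worst <- names(which.max(m_now))
    exclusion <- c(exclusion, worst)
    remaining <- setdiff(remaining, worst)
  }
  ## stability ranking: the final pair (tied, most stable) first, then the
  ## excluded genes in reverse exclusion order
  ranking <- c(remaining, rev(exclusion))
  ## V_{n/n+1}: add genes by stability rank
  v <- numeric(0)
  for (n in 2L:(length(candidates) - 1L)) {
    nf_n <- apply(x[ranking[seq_len(n)], , drop = FALSE], 2L, geometric_mean)
    nf_n1 <- apply(x[ranking[seq_len(n + 1L)], , drop = FALSE], 2L, geometric_mean)
    v[sprintf("V%d/%d", n, n + 1L)] <- sd(log2(nf_n / nf_n1))
  }
  structure(list(m = m_initial, exclusion_order = exclusion,
                 ranking = ranking, v = v),
            class = "genorm_result")
}

bonferroni <- function(p, n_tests) pmin(1, p * n_tests)

#' Fold-change tests between treatment groups
#'
#' Per gene: FC is the ratio of the larger group median to the smaller
#' (always >= 1) with a direction flag saying which reading of
#' "UBI relative to sham" it corresponds to; the group comparison is a
#' Mann-Whitney test with Bonferroni correction at the configured family
#' size. Ties use mid-ranks with the normal approximation and continuity
#' correction for larger samples, exact enumeration otherwise (the
#' [stats::wilcox.test()] rules).
#'
#' @param expr data.frame with columns `gene`, `value`, and a group column
#' @param group_col name of the group column
#' @param case,control group labels (e.g. UBI and sham); FC direction is
#'   case relative to control
#' @param n_tests Bonferroni family size (defaults to number of genes)
#' @return data.frame: gene, median_case, median_control, fc, direction,
#'   p_raw, p_adj
#' @export
fold_change_tests <- function(expr, group_col = "treatment",
                              case = "left_UBI", control = "sham",
                              n_tests = NULL) {
  df <- as.data.frame(expr)
  stopifnot(all(c("gene", "value", group_col) %in% names(df)))
  genes <- unique(df$gene)
  if (is.null(n_tests)) n_tests <- length(genes)
  out <- do.call(rbind, lapply(genes, function(g) {
    d <- df[df$gene == g, ]
    x <- d$value[d[[group_col]] == case]
    y <- d$value[d[[group_col]] == control]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 3L || length(y) < 3L) stop_input(
      sprintf("gene %s: need >= 3 rats per group", g))
    mx <- median(x); my <- median(y)
    if (mx == my) {
      fc <- 1; dir <- "none"
    } else if (mx > my) {
      fc <- mx / my; dir <- "up_in_case"
    } else {
      fc <- my / mx; dir <- "down_in_case"
    }
    p <- if (all(x == x[1L]) && all(y == y[1L]) && x[1L] == y[1L]) 1 else
      suppressWarnings(stats::wilcox.test(x, y)$p.value)
    data.frame(gene = g, median_case = mx, median_control = my,
               fc = fc, direction = dir, p_raw = p,
               stringsAsFactors = FALSE)
  }))
  out$p_adj <- bonferroni(out$p_raw, n_tests)
  rownames(out) <- NULL
  out
}

## per-rat log2(L/R) table from a bilateral expression table
ai_per_rat <- function(expr) {
  df <- as.data.frame(expr)
  stopifnot(all(c("rat_id", "gene", "side", "value") %in% names(df)))
  wide <- merge(df[df$side == "left", setdiff(names(df), "side")],
                df[df$side == "right", c("rat_id", "gene", "value")],
                by = c("rat_id", "gene"), suffixes = c("_left", "_right"))
  dropped <- nrow(df[df$side == "left", ]) - nrow(wide)
  if (dropped > 0)
    log_msg("WARN", sprintf("%d left-side measurement(s) without a right-side pair dropped", dropped))
  wide$ai <- log2(wide$value_left / wide$value_right)
  wide
}

#' Lateralization (asymmetry index) tests
#'
#' The asymmetry index of a gene is the median over rats of the per-rat
#' log2(L/R) expression ratio (the ratio-of-medians variant
#' log2(median L / median R) is also reported). Per gene, the AI is first
#' compared between the case and control groups (Mann-Whitney, Bonferroni
#' at `n_tests_group`); if no gene differs, the groups are pooled and each
#' gene's AI is tested against zero with a one-sample Wilcoxon signed-rank
#' test, Bonferroni-corrected over genes.
#'
#' @param expr bilateral expression data.frame (`rat_id`, `gene`, `side`,
#'   `value`, group column)
#' @param group_col,case,control group structure as in [fold_change_tests()]
#' @param n_tests_group Bonferroni family size for the group comparison
#'   (defaults to the number of genes)
#' @param pool `"auto"` pools the groups only when no gene shows a
#'   significant group difference; `"always"`/`"never"` force the choice
#' @return data.frame per gene: `ai` (median per-rat log2 L/R),
#'   `ai_ratio_of_medians`, group-difference p (raw/adjusted), pooled
#'   one-sample Wilcoxon p (raw/adjusted), `n_rats`, plus attribute
#'   `pooled` saying whether the groups were combined
#' @export
asymmetry_index_tests <- function(expr, group_col = "treatment",
                                  case = "left_UBI", control = "sham",
                                  n_tests_group = NULL,
                                  pool = c("auto", "always", "never")) {
  pool <- match.arg(pool)
  wide <- ai_per_rat(expr)
  stopifnot(group_col %in% names(wide))
  genes <- unique(wide$gene)
  if (is.null(n_tests_group)) n_tests_group <- length(genes)
  res <- do.call(rbind, lapply(genes, function(g) {
    d <- wide[wide$gene == g & is.finite(wide$ai), ]
    ai_case <- d$ai[d[[group_col]] == case]
    ai_ctrl <- d$ai[d[[group_col]] == control]
    p_grp <- if (length(ai_case) >= 3L && length(ai_ctrl) >= 3L)
      suppressWarnings(stats::wilcox.test(ai_case, ai_ctrl)$p.value) else NA_real_
    data.frame(gene = g,
               ai = median(d$ai),
               ai_ratio_of_medians = log2(median(d$value_left) / median(d$value_right)),
               n_rats = nrow(d),
               p_group_raw = p_grp,
               stringsAsFactors = FALSE)
  }))
  res$p_group_adj <- bonferroni(res$p_group_raw, n_tests_group)
  pooled <- switch(pool,
                   always = TRUE, never = FALSE,
                   auto = !any(res$p_group_adj <= 0.05, na.rm = TRUE))
  res$p_zero_raw <- vapply(genes, function(g) {
    d <- wide[wide$gene == g & is.finite(wide$ai), ]
    if (!pooled) d <- d[d[[group_col]] %in% c(case, control), ]
    x <- d$ai
    if (all(x == 0)) return(1)
    suppressWarnings(stats::wilcox.test(x, mu = 0)$p.value)
  }, numeric(1))
  res$p_zero_adj <- bonferroni(res$p_zero_raw, length(genes))
  rownames(res) <- NULL
  attr(res, "pooled") <- pooled
  res
}

#' Left-right fold-change concordance
#'
#' Tests whether injury effects on the two sides agree in direction and
#' how much the contralateral effect is attenuated: ordinary least squares
#' of the right-side log2 fold changes on the left-side ones
#' (logFC_right ~ a * logFC_left + b) with standard 95% confidence
#' intervals, Pearson and Spearman correlations, and a Wilcoxon signed-rank
#' test comparing |logFC| between sides.
#'
#' @param logfc_left,logfc_right per-gene log2 fold changes
#' @return list: `slope`, `slope_ci`, `intercept`, `intercept_ci`,
#'   `pearson` (r, p), `spearman` (rho, p), `wilcoxon_abs_p`, `n`
#' @export
fc_concordance <- function(logfc_left, logfc_right) {
  ok <- is.finite(logfc_left) & is.finite(logfc_right)
  x <- logfc_left[ok]; y <- logfc_right[ok]
  if (length(x) < 4L) stop_input("need >= 4 genes with both sides measured")
  if (sd(x) == 0) stop_domain("zero variance in left-side log fold changes")
  fit <- stats::lm(y ~ x)
  ci <- stats::confint(fit)
  pe <- stats::cor.test(x, y, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  wx <- suppressWarnings(stats::wilcox.test(abs(x), abs(y), paired = TRUE))
  list(slope = unname(coef(fit)[2L]), slope_ci = unname(ci[2L, ]),
       intercept = unname(coef(fit)[1L]), intercept_ci = unname(ci[1L, ]),
       pearson = list(r = unname(pe$estimate), p = pe$p.value),
       spearman = list(rho = unname(sp$estimate), p = sp$p.value),
       wilcoxon_abs_p = wx$p.value, n = length(x))
}
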