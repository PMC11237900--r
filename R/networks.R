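## Left/right dominant gene co-expression networks. Genes are assigned to a
## left-dominant (LdN, asymmetry index > 0) or right-dominant (RdN, AI < 0)
## network per region, under three categorization variants. A correlation
## pattern is a named set of gene-pair Spearman correlations (within a
## module, between modules, or between CNS areas); each pattern is
## summarized by its coordination strength (mean |rho|) and the proportion
## of strictly positive correlations. Patterns are compared by permutation
## tests under four resampling schemes, with Benjamini-Hochberg correction
## within pre-registered families and a stringent cross-variant
## significance rule.

#' Assign genes to the left- or right-dominant network
#'
#' Variant 1 uses the median per-rat AI in the combined case + control
#' group, variant 2 the median in the control (sham) group only, variant 3
#' the mean in the combined group. AI > 0 gives LdN, AI < 0 RdN; an AI of
#' exactly zero leaves the gene unassigned (and excluded from patterns).
#'
#' @param ai_table data.frame of per-rat asymmetry indices with columns
#'   `rat_id`, `gene`, `region`, `ai` and a group column
#' @param variant 1, 2 or 3
#' @param group_col,control group structure (variant 2 needs control rats)
#' @return data.frame: gene, region, criterion (the AI summary used),
#'   label (`"LdN"`, `"RdN"` or `"unassigned"`)
#' @export
categorize_genes <- function(ai_table, variant = 1L, group_col = "treatment",
                             control = "sham") {
  df <- as.data.frame(ai_table)
  stopifnot(all(c("gene", "region", "ai") %in% names(df)))
  if (!variant %in% 1:3) stop_config("variant must be 1, 2 or 3")
  if (variant == 2L) {
    if (!group_col %in% names(df)) stop_input("variant 2 needs group labels")
    df <- df[df[[group_col]] == control, ]
    if (!nrow(df)) stop_input("variant 2: no control rats")
  }
  fun <- if (variant == 3L) mean else median
  key <- interaction(df$gene, df$region, drop = TRUE)
  out <- do.call(rbind, lapply(split(df, key), function(d) {
    crit <- fun(d$ai[is.finite(d$ai)])
    data.frame(gene = d$gene[1L], region = d$region[1L], criterion = crit,
               label = if (crit > 0) "LdN" else if (crit < 0) "RdN" else "unassigned",
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Gene network assignment across all three categorization variants
#'
#' @inheritParams categorize_genes
#' @return data.frame: gene, region, label_v1, label_v2, label_v3,
#'   `stable` (same label under all variants), `wobble` (the disagreeing
#'   variants, comma-separated, or "")
#' @export
categorize_genes_all <- function(ai_table, group_col = "treatment",
                                 control = "sham") {
  labs <- lapply(1:3, function(v)
    categorize_genes(ai_table, v, group_col, control))
  out <- labs[[1L]][c("gene", "region")]
  out$label_v1 <- labs[[1L]]$label
  out$label_v2 <- labs[[2L]]$label[match(paste(out$gene, out$region),
                                         paste(labs[[2L]]$gene, labs[[2L]]$region))]
  out$label_v3 <- labs[[3L]]$label[match(paste(out$gene, out$region),
                                         paste(labs[[3L]]$gene, labs[[3L]]$region))]
  lab <- out[c("label_v1", "label_v2", "label_v3")]
  out$stable <- apply(lab, 1L, function(x) length(unique(x)) == 1L)
  out$wobble <- apply(lab, 1L, function(x) {
    maj <- names(sort(table(x), decreasing = TRUE))[1L]
    paste(paste0("v", which(x != maj)), collapse = ",")
  })
  out
}

## rats x measurements matrix from a bilateral expression long table;
## meta describes each column by (region, side, gene)
expression_matrix <- function(expr, group_col = "treatment") {
  df <- as.data.frame(expr)
  stopifnot(all(c("rat_id", "region", "side", "gene", "value") %in% names(df)))
  rats <- unique(df$rat_id)
  meta <- unique(df[c("region", "side", "gene")])
  rownames(meta) <- NULL
  colkey <- paste(meta$region, meta$side, meta$gene, sep = "\r")
  X <- matrix(NA_real_, length(rats), nrow(meta),
              dimnames = list(rats, paste(meta$region, meta$side, meta$gene, sep = ".")))
  idx <- cbind(match(df$rat_id, rats),
               match(paste(df$region, df$side, df$gene, sep = "\r"), colkey))
  X[idx] <- df$value
  treatment <- if (group_col %in% names(df))
    df[[group_col]][match(rats, df$rat_id)] else rep(NA_character_, length(rats))
  list(X = X, meta = meta, rats = rats, treatment = setNames(treatment, rats))
}

## selector for one module-side of a pattern
pattern_selector <- function(region, side, network) {
  list(region = region, side = side, network = network)
}

selector_label <- function(sel) {
  sprintf("%s-%sm%s", sel$region, substr(sel$side, 1L, 1L), sel$network)
}

## columns of the expression matrix matching a selector under an assignment
selector_columns <- function(meta, assignment, sel) {
  lab <- assignment$label[match(paste(meta$gene, meta$region),
                                paste(assignment$gene, assignment$region))]
  which(meta$region == sel$region & meta$side == sel$side &
          !is.na(lab) & lab == sel$network)
}

## unordered index pairs of a pattern: within one selector (no self-pairs)
## or all cross pairs between two selectors (a repeated gene symbol across
## modules/areas is two distinct measurements and is kept)
pattern_pair_indices <- function(meta, assignment, sel_a, sel_b = NULL) {
  ca <- selector_columns(meta, assignment, sel_a)
  if (is.null(sel_b)) {
    if (length(ca) < 2L) stop_input(
      sprintf("pattern %s needs >= 2 genes", selector_label(sel_a)))
    t(utils::combn(ca, 2L))
  } else {
    cb <- selector_columns(meta, assignment, sel_b)
    if (length(ca) < 1L || length(cb) < 1L) stop_input("empty pattern side")
    as.matrix(expand.grid(a = ca, b = cb))
  }
}

#' Pairwise Spearman correlations of a co-expression pattern
#'
#' Computes the Spearman rank correlation across rats for every gene pair
#' of a pattern, plus the pattern summary: coordination strength (mean
#' absolute rho) and proportion of strictly positive correlations.
#'
#' @param expr bilateral expression table (`rat_id`, `region`, `side`,
#'   `gene`, `value`)
#' @param assignment network assignment (gene, region, label) as from
#'   [categorize_genes()]
#' @param region,side,network selector of the first (or only) module
#' @param region_b,side_b,network_b optional second selector for
#'   between-module or between-area patterns
#' @param rats optional subset of rat ids (e.g. one treatment group)
#' @return list: `pairs` (gene_a, gene_b, rho), `strength`,
#'   `prop_positive`, `n_pairs`, `label`
#' @export
pattern_correlations <- function(expr, assignment, region, side, network,
                                 region_b = NULL, side_b = NULL,
                                 network_b = NULL, rats = NULL) {
  em <- expression_matrix(expr)
  if (nrow(em$X) < 4L) stop_input("need >= 4 rats")
  sel_a <- pattern_selector(region, side, network)
  sel_b <- if (!is.null(region_b))
    pattern_selector(region_b, side_b, network_b) else NULL
  pairs <- pattern_pair_indices(em$meta, assignment, sel_a, sel_b)
  rows <- if (is.null(rats)) seq_len(nrow(em$X)) else match(rats, em$rats)
  cols <- sort(unique(c(pairs[, 1L], pairs[, 2L])))
  sub <- em$X[rows, cols, drop = FALSE]
  r <- apply(sub, 2L, rank)
  C <- suppressWarnings(stats::cor(r))
  rho <- C[cbind(match(pairs[, 1L], cols), match(pairs[, 2L], cols))]
  pr <- data.frame(gene_a = em$meta$gene[pairs[, 1L]],
                   gene_b = em$meta$gene[pairs[, 2L]],
                   measurement_a = colnames(em$X)[pairs[, 1L]],
                   measurement_b = colnames(em$X)[pairs[, 2L]],
                   rho = rho, stringsAsFactors = FALSE)
  if (anyNA(rho)) {
    log_msg("WARN", sprintf("%d pair(s) with undefined correlation dropped",
                            sum(is.na(rho))))
    pr <- pr[is.finite(pr$rho), ]
  }
  label <- if (is.null(sel_b)) sprintf("%s--%s", selector_label(sel_a), selector_label(sel_a))
           else sprintf("%s--%s", selector_label(sel_a), selector_label(sel_b))
  list(pairs = pr, strength = mean(abs(pr$rho)),
       prop_positive = mean(pr$rho > 0), n_pairs = nrow(pr), label = label)
}

## ---- permutation schemes -------------------------------------------------

## matched column pairs whose entries a scheme may swap within a rat
side_swap_pairs <- function(meta) {
  l <- which(meta$side == "left")
  r <- which(meta$side == "right")
  m <- match(paste(meta$region[l], meta$gene[l]),
             paste(meta$region[r], meta$gene[r]))
  cbind(l[!is.na(m)], r[m[!is.na(m)]])
}

area_swap_pairs <- function(meta, areas) {
  a <- which(meta$region == areas[1L])
  b <- which(meta$region == areas[2L])
  m <- match(paste(meta$side[a], meta$gene[a]),
             paste(meta$side[b], meta$gene[b]))
  keep <- !is.na(m)
  list(pairs = cbind(a[keep], b[keep]), side = meta$side[a][keep])
}

swap_rows_cols <- function(X, flips, pairs) {
  if (!any(flips) || !nrow(pairs)) return(X)
  tmp <- X[flips, pairs[, 1L], drop = FALSE]
  X[flips, pairs[, 1L]] <- X[flips, pairs[, 2L], drop = FALSE]
  X[flips, pairs[, 2L]] <- tmp
  X
}

permutation_schemes <- c("rat_ids", "treatment", "module_within_rat",
                         "area_within_module")

## ---- pattern comparisons -------------------------------------------------

## both summary statistics of one or two pair sets from a single rank /
## correlation pass over the needed columns (mid-ranks, then Pearson on
## the ranks; a constant column yields non-finite rho and is dropped)
pair_stats <- function(sub, pairs_list) {
  r <- sub
  for (j in seq_len(ncol(sub))) r[, j] <- rank(sub[, j])
  C <- suppressWarnings(stats::cor(r))
  lapply(pairs_list, function(p) {
    rho <- C[p]
    rho <- rho[is.finite(rho)]
    if (!length(rho)) return(c(strength = NA_real_, prop_positive = NA_real_))
    c(strength = mean(abs(rho)), prop_positive = mean(rho > 0))
  })
}

## a comparison is either two patterns on the same rats ("pattern") or one
## pattern on two treatment groups ("group"); the data matrix is reduced to
## the columns the patterns and the scheme's swap partners touch
run_comparison <- function(em, cmp, scheme, R, ctx) {
  pairs_b <- if (cmp$type == "pattern") cmp$pairs_b else NULL
  needed <- sort(unique(c(cmp$pairs_a, pairs_b)))
  swap <- switch(scheme,
    module_within_rat = ctx$side_pairs,
    area_within_module = ctx$area$pairs,
    matrix(integer(), 0L, 2L))
  touches <- swap[, 1L] %in% needed | swap[, 2L] %in% needed
  swap <- swap[touches, , drop = FALSE]
  swap_side <- if (scheme == "area_within_module") ctx$area$side[touches] else NULL
  cols <- sort(unique(c(needed, swap)))
  X <- em$X[, cols, drop = FALSE]
  remap <- function(p) matrix(match(p, cols), ncol = 2L)
  pa <- remap(cmp$pairs_a)
  pb <- if (!is.null(pairs_b)) remap(pairs_b)
  swap <- remap(swap)
  treatment <- em$treatment
  ## for a fixed-group pattern comparison only that group's rows ever enter
  ## the statistic, and no scheme here exchanges data between rats, so the
  ## matrix can be restricted up front
  if (cmp$type == "pattern" && !is.null(cmp$group)) {
    keep <- which(treatment == cmp$group)
    X <- X[keep, , drop = FALSE]
    treatment <- treatment[keep]
    cmp$group <- NULL
  }
  n <- nrow(X)

  stat_diff <- function(Xp, tr) {
    if (cmp$type == "pattern") {
      rows <- if (is.null(cmp$group)) seq_len(n) else which(tr == cmp$group)
      s <- pair_stats(Xp[rows, , drop = FALSE], list(pa, pb))
      s[[1L]] - s[[2L]]
    } else {
      sa <- pair_stats(Xp[tr == cmp$case, , drop = FALSE], list(pa))[[1L]]
      sb <- pair_stats(Xp[tr == cmp$control, , drop = FALSE], list(pa))[[1L]]
      sa - sb
    }
  }
  permute_local <- function() {
    switch(scheme,
      rat_ids = {
        Xp <- X
        for (j in seq_len(ncol(Xp))) Xp[, j] <- Xp[sample.int(n), j]
        list(X = Xp, treatment = treatment)
      },
      treatment = list(X = X, treatment = sample(treatment)),
      module_within_rat = list(X = swap_rows_cols(X, runif(n) < 0.5, swap),
                               treatment = treatment),
      area_within_module = {
        Xp <- X
        for (s in unique(swap_side)) {
          Xp <- swap_rows_cols(Xp, runif(n) < 0.5,
                               swap[swap_side == s, , drop = FALSE])
        }
        list(X = Xp, treatment = treatment)
      })
  }

  obs <- stat_diff(X, treatment)
  null <- matrix(NA_real_, R, 2L)
  for (b in seq_len(R)) {
    p <- permute_local()
    null[b, ] <- stat_diff(p$X, p$treatment)
  }
  p_raw <- vapply(1:2, function(k) {
    nb <- null[is.finite(null[, k]), k]
    (sum(abs(nb) >= abs(obs[k]) - 1e-12) + 1) / (length(nb) + 1)
  }, numeric(1))
  data.frame(statistic = c("strength", "prop_positive"),
             observed_diff = unname(obs), p_raw = p_raw,
             scheme = scheme, R = R, stringsAsFactors = FALSE)
}

default_task_scheme <- function(task) {
  ## left/right module exchanges are the natural null for module contrasts
  ## (tasks 2, 5, 7); network-membership contrasts use full rat-id
  ## relabeling (tasks 1, 3, 4, 6)
  if (task %in% c(2L, 5L, 7L)) "module_within_rat" else "rat_ids"
}

build_task_comparisons <- function(task, meta, assignment, areas,
                                   groups, case, control) {
  sel <- pattern_selector
  cmp <- list(); add <- function(label, sel_a, sel_b, group = NULL) {
    cmp[[length(cmp) + 1L]] <<- list(label = label, sel_a = sel_a, sel_b = sel_b,
                                     group = group)
  }
  regions <- intersect(areas, unique(assignment$region))
  if (task %in% 1:3) {
    for (region in regions) for (g in groups) {
      tag <- function(x) sprintf("%s %s [%s]", region, x, g)
      if (task == 1L) {
        for (side in c("left", "right")) {
          m <- paste0(substr(side, 1, 1), "m")
          add(tag(sprintf("%sLdN-LdN vs %sRdN-RdN", m, m)),
              list(sel(region, side, "LdN")), list(sel(region, side, "RdN")), g)
          add(tag(sprintf("%sLdN-LdN vs %sLdN-RdN", m, m)),
              list(sel(region, side, "LdN")),
              list(sel(region, side, "LdN"), sel(region, side, "RdN")), g)
          add(tag(sprintf("%sRdN-RdN vs %sLdN-RdN", m, m)),
              list(sel(region, side, "RdN")),
              list(sel(region, side, "LdN"), sel(region, side, "RdN")), g)
        }
      } else if (task == 2L) {
        for (net in c("LdN", "RdN"))
          add(tag(sprintf("lm%s-%s vs rm%s-%s", net, net, net, net)),
              list(sel(region, "left", net)), list(sel(region, "right", net)), g)
      } else {
        add(tag("lmLdN-rmLdN vs lmRdN-rmRdN"),
            list(sel(region, "left", "LdN"), sel(region, "right", "LdN")),
            list(sel(region, "left", "RdN"), sel(region, "right", "RdN")), g)
      }
    }
  } else {
    if (length(regions) < 2L) stop_input("inter-area tasks need both areas")
    hpt <- regions[1L]; spc <- regions[2L]
    for (g in groups) {
      tag <- function(x) sprintf("%s [%s]", x, g)
      if (task == 4L) {
        for (side in c("left", "right")) {
          m <- paste0(substr(side, 1, 1), "m")
          add(tag(sprintf("%s(HPT-SpC)LdN vs %s(HPT-SpC)RdN", m, m)),
              list(sel(hpt, side, "LdN"), sel(spc, side, "LdN")),
              list(sel(hpt, side, "RdN"), sel(spc, side, "RdN")), g)
        }
      } else if (task == 5L) {
        for (net in c("LdN", "RdN"))
          add(tag(sprintf("lm(HPT-SpC)%s vs rm(HPT-SpC)%s", net, net)),
              list(sel(hpt, "left", net), sel(spc, "left", net)),
              list(sel(hpt, "right", net), sel(spc, "right", net)), g)
      } else if (task == 6L) {
        for (type in 1:2) {
          hs <- if (type == 1L) c("left", "right") else c("right", "left")
          add(tag(sprintf("contra%d LdN vs contra%d RdN", type, type)),
              list(sel(hpt, hs[1L], "LdN"), sel(spc, hs[2L], "LdN")),
              list(sel(hpt, hs[1L], "RdN"), sel(spc, hs[2L], "RdN")), g)
        }
      } else {
        for (net in c("LdN", "RdN"))
          add(tag(sprintf("contra1 %s vs contra2 %s", net, net)),
              list(sel(hpt, "left", net), sel(spc, "right", net)),
              list(sel(hpt, "right", net), sel(spc, "left", net)), g)
      }
    }
  }
  ## plus: each pattern of the task compared between case and control
  patterns <- unique(unlist(lapply(cmp, function(x) list(x$sel_a, x$sel_b)),
                            recursive = FALSE))
  group_cmp <- lapply(patterns, function(p) {
    lab <- paste(vapply(p, selector_label, character(1)), collapse = "--")
    list(label = sprintf("%s [%s vs %s]", lab, case, control),
         sel_a = p, sel_b = NULL, group = NULL, type = "group")
  })
  list(pattern = cmp, group = group_cmp)
}

resolve_pairs <- function(meta, assignment, sels) {
  if (length(sels) == 1L) pattern_pair_indices(meta, assignment, sels[[1L]])
  else pattern_pair_indices(meta, assignment, sels[[1L]], sels[[2L]])
}

#' Compare co-expression patterns by permutation
#'
#' Runs one of the seven comparison tasks: pattern-vs-pattern contrasts
#' (within a module, between left and right modules, between networks, or
#' between CNS areas) inside each treatment group, plus each pattern
#' compared between the case and control groups. Null distributions are
#' built by the named resampling scheme: `rat_ids` (independent row
#' permutation per measurement), `treatment` (group label permutation,
#' always used for the case-vs-control comparisons), `module_within_rat`
#' (left/right module swap per rat) or `area_within_module` (area swap per
#' rat and module). Two-sided p-values use the add-one estimator
#' (b + 1) / (R + 1).
#'
#' @param expr bilateral expression table
#' @param assignment network assignment for one categorization variant
#' @param task integer 1-7
#' @param R permutation replicates (>= 100)
#' @param seed RNG seed for the permutation draws
#' @param scheme resampling scheme for the pattern contrasts; default
#'   chooses module_within_rat for the module-exchange tasks (2, 5, 7) and
#'   rat_ids otherwise
#' @param group_col,case,control treatment structure
#' @param areas the two CNS areas, first = rostral ("HPT")
#' @param include_group_contrasts also run case-vs-control comparisons
#' @return data.frame: task, comparison, statistic (strength /
#'   prop_positive), observed_diff, p_raw, scheme, R
#' @export
compare_patterns <- function(expr, assignment, task, R = 10000L, seed = 1L,
                             scheme = NULL, group_col = "treatment",
                             case = "left_UBI", control = "sham",
                             areas = c("HPT", "SpC"),
                             include_group_contrasts = TRUE) {
  task <- as.integer(task)
  if (!task %in% 1:7) stop_config("task must be 1..7")
  R <- as.integer(R)
  if (R < 100L) stop_config("permutation count R must be >= 100")
  scheme <- scheme %||% default_task_scheme(task)
  if (!scheme %in% permutation_schemes)
    stop_config(paste("unknown scheme:", scheme))
  if (scheme == "area_within_module" && task %in% 1:3)
    stop_config("area permutation is incompatible with a single-area task")
  if (scheme == "treatment")
    stop_config("the treatment scheme is reserved for group contrasts; pick a pattern scheme")
  em <- expression_matrix(expr, group_col)
  groups <- c(case, control)
  built <- build_task_comparisons(task, em$meta, assignment, areas,
                                  groups, case, control)
  ctx <- list(side_pairs = side_swap_pairs(em$meta),
              area = area_swap_pairs(em$meta, areas))
  out <- list()
  set.seed(seed)
  ## a pattern without enough genes under this assignment (possible for a
  ## lopsided categorization variant) is skipped with a log entry rather
  ## than aborting the task
  try_pairs <- function(sels, label) {
    tryCatch(resolve_pairs(em$meta, assignment, sels),
             lrasym_input_error = function(e) {
               log_msg("WARN", sprintf("skipping '%s': %s", label,
                                       conditionMessage(e)))
               NULL
             })
  }
  for (cmp in built$pattern) {
    cmp$type <- "pattern"
    cmp$pairs_a <- try_pairs(cmp$sel_a, cmp$label)
    cmp$pairs_b <- try_pairs(cmp$sel_b, cmp$label)
    if (is.null(cmp$pairs_a) || is.null(cmp$pairs_b)) next
    res <- run_comparison(em, cmp, scheme, R, ctx)
    res$comparison <- cmp$label
    out[[length(out) + 1L]] <- res
  }
  if (include_group_contrasts) {
    for (cmp in built$group) {
      cmp$type <- "group"
      cmp$case <- case; cmp$control <- control
      cmp$pairs_a <- try_pairs(cmp$sel_a, cmp$label)
      if (is.null(cmp$pairs_a)) next
      res <- run_comparison(em, cmp, "treatment", R, ctx)
      res$comparison <- cmp$label
      out[[length(out) + 1L]] <- res
    }
  }
  if (!length(out)) stop_input("no runnable comparisons for this task")
  out <- do.call(rbind, out)
  out$task <- task
  out[c("task", "comparison", "statistic", "observed_diff", "p_raw",
        "scheme", "R")]
}

#' Benjamini-Hochberg adjustment within pre-registered families
#'
#' Families mirror the study design: separate sets for the coordination
#' strength and the proportion of positive correlations, split into
#' intra-area sets (per region, tasks 1-3) and the inter-area set
#' (tasks 4-7).
#'
#' @param results output of [compare_patterns()] (tasks may be row-bound),
#'   needing columns `task`, `comparison`, `statistic`, `p_raw`
#' @return `results` with columns `family` and `p_adj` added
#' @export
adjust_bh <- function(results) {
  res <- as.data.frame(results)
  area <- ifelse(res$task <= 3L,
                 paste0("intra_", sub("^([A-Za-z0-9]+).*", "\\1", res$comparison)),
                 "inter")
  res$family <- paste(res$statistic, area, sep = ".")
  res$p_adj <- NA_real_
  for (f in unique(res$family)) {
    i <- res$family == f
    res$p_adj[i] <- stats::p.adjust(res$p_raw[i], method = "BH")
  }
  res
}

#' Stringent cross-variant significance rule
#'
#' A comparison is significant when its adjusted p-value is <= .05 under
#' all three categorization variants, or under exactly two of them while
#' the third variant has raw p < .05 and adjusted p < .10.
#'
#' @param p_raw,p_adj numeric length-3 vectors, one entry per variant
#' @return logical
#' @export
stringent_significance <- function(p_raw, p_adj) {
  if (length(p_raw) != 3L || length(p_adj) != 3L || anyNA(p_raw) || anyNA(p_adj))
    stop_input("need raw and adjusted p-values for all three variants")
  hit <- p_adj <= 0.05
  if (all(hit)) return(TRUE)
  if (sum(hit) == 2L) {
    third <- which(!hit)
    return(p_raw[third] < 0.05 && p_adj[third] < 0.10)
  }
  FALSE
}

#' Full network analysis across variants and tasks
#'
#' Categorizes genes under all three variants, runs the requested
#' comparison tasks per variant, applies BH correction within families per
#' variant, and combines the three variant-wise p-value sets with the
#' stringent significance rule.
#'
#' @param expr bilateral expression table (both areas for tasks 4-7)
#' @param tasks integer vector of tasks to run
#' @param R,seed permutation settings
#' @param group_col,case,control,areas as in [compare_patterns()]
#' @param scheme optional scheme override applied to every task
#' @return list: `assignment` (cross-variant table), `results` (long, all
#'   variants with p_adj), `summary` (one row per comparison x statistic
#'   with variant-wise p-values and the stringent flag)
#' @export
network_analysis <- function(expr, tasks = 1:3, R = 10000L, seed = 1L,
                             group_col = "treatment", case = "left_UBI",
                             control = "sham", areas = c("HPT", "SpC"),
                             scheme = NULL) {
  ai <- ai_per_rat(expr)
  stopifnot("region" %in% names(ai))
  assignment_all <- categorize_genes_all(ai, group_col, control)
  res <- list()
  for (v in 1:3) {
    asg <- categorize_genes(ai, v, group_col, control)
    for (tk in tasks) {
      r <- compare_patterns(expr, asg, tk, R = R,
                            seed = seed + 17L * v + tk,
                            scheme = scheme, group_col = group_col,
                            case = case, control = control, areas = areas)
      r$variant <- v
      res[[length(res) + 1L]] <- r
    }
  }
  res <- do.call(rbind, res)
  adj <- do.call(rbind, lapply(split(res, res$variant), adjust_bh))
  key <- interaction(adj$task, adj$comparison, adj$statistic, drop = TRUE)
  summary <- do.call(rbind, lapply(split(adj, key), function(d) {
    d <- d[order(d$variant), ]
    if (nrow(d) != 3L) return(NULL)
    data.frame(task = d$task[1L], comparison = d$comparison[1L],
               statistic = d$statistic[1L],
               observed_diff_v1 = d$observed_diff[1L],
               p_raw_v1 = d$p_raw[1L], p_adj_v1 = d$p_adj[1L],
               p_raw_v2 = d$p_raw[2L], p_adj_v2 = d$p_adj[2L],
               p_raw_v3 = d$p_raw[3L], p_adj_v3 = d$p_adj[3L],
               stringent_significant = stringent_significance(
                 d$p_raw, d$p_adj),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(assignment = assignment_all, results = adj, summary = summary)
}
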