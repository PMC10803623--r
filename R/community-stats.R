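# Indicator species analysis (IndVal), SIMPER and the classical
# correlation / group-comparison tables.

# per-syntaxon per-group IndVal matrix; groups must partition the rows
#' @noRd
.indval_matrix <- function(comm, groups, type = "group-mean") {
  groups <- as.factor(groups)
  ng <- table(groups)
  gm <- rowsum(comm, groups) / as.vector(ng)        # group mean abundance
  abase <- if (type == "group-mean") gm else rowsum(comm, groups)
  tot <- colSums(abase)
  A <- sweep(abase, 2L, tot, "/")                   # specificity
  A[, tot == 0] <- 0
  B <- rowsum((comm > 0) + 0, groups) / as.vector(ng)  # fidelity
  A * B
}

#' Indicator value (IndVal) of syntaxa across groups
#'
#' Dufrene-Legendre indicator value: for syntaxon j and group g, IndVal =
#' A * B with specificity A = (mean abundance of j in g) / (sum of the
#' group mean abundances of j) and fidelity B = (occurrences of j in g) /
#' (transects in g). The reported value per syntaxon is the maximum over
#' groups. A syntaxon absent everywhere is skipped with a message.
#'
#' @param comm transect x syntaxon abundance matrix (relative covers).
#' @param groups group label per transect (e.g. slope classes); at least
#'   two non-empty groups.
#' @param type `"group-mean"` (Dufrene-Legendre, default) or
#'   `"total-abundance"` (specificity from group abundance sums, which
#'   weights groups by their size).
#' @return list: `indval` (group x syntaxon matrix), `summary` (data frame
#'   `syntaxon_code`, `best_group`, `indval`, `n_occurrences`).
#' @export
indval <- function(comm, groups, type = c("group-mean", "total-abundance")) {
  type <- match.arg(type)
  comm <- as.matrix(comm)
  if (is.null(colnames(comm)))
    colnames(comm) <- paste0("syn", seq_len(ncol(comm)))
  groups <- as.factor(groups)
  if (length(groups) != nrow(comm))
    stop("groups must label every row of the community matrix")
  if (nlevels(droplevels(groups)) < 2L)
    stop("need at least two non-empty groups")
  absent <- colSums(comm) == 0
  if (any(absent)) {
    message(sprintf("skipping %d syntaxon(s) absent from all transects: %s",
                    sum(absent),
                    paste(colnames(comm)[absent], collapse = ", ")))
    comm <- comm[, !absent, drop = FALSE]
  }
  iv <- .indval_matrix(comm, droplevels(groups), type = type)
  best <- max.col(t(iv), ties.method = "first")
  summary <- data.frame(
    syntaxon_code = colnames(comm),
    best_group = rownames(iv)[best],
    indval = iv[cbind(best, seq_len(ncol(iv)))],
    n_occurrences = colSums(comm > 0))
  rownames(summary) <- NULL
  list(indval = iv, summary = summary)
}

#' Permutation p-values for IndVal
#'
#' Group labels are permuted across transects; for each syntaxon the
#' p-value is (r + 1) / (n_perm + 1) where r counts permutations whose
#' maximum IndVal reaches the observed one.
#'
#' @inheritParams indval
#' @param n_perm number of permutations (>= 99), default 999.
#' @param seed optional integer seed for reproducibility.
#' @return data frame: `syntaxon_code`, `best_group`, `indval`,
#'   `p_value`, `n_occurrences`, and `indicator` - the conventional flag
#'   IndVal >= 0.50 and p < 0.05.
#' @export
indval_pvalue <- function(comm, groups, n_perm = 999L, seed = NULL,
                          type = c("group-mean", "total-abundance")) {
  type <- match.arg(type)
  if (n_perm < 99L) stop("use at least 99 permutations")
  comm <- as.matrix(comm)
  if (is.null(colnames(comm)))
    colnames(comm) <- paste0("syn", seq_len(ncol(comm)))
  obs <- indval(comm, groups, type = type)
  comm <- comm[, colSums(comm) > 0, drop = FALSE]
  groups <- droplevels(as.factor(groups))
  stat_obs <- obs$summary$indval

  run <- function() {
    exceed <- integer(length(stat_obs))
    for (b in seq_len(n_perm)) {
      ivp <- .indval_matrix(comm, sample(groups), type = type)
      exceed <- exceed + (apply(ivp, 2L, max) >= stat_obs - 1e-12)
    }
    exceed
  }
  exceed <- if (is.null(seed)) run() else .with_seed(seed, run())
  out <- obs$summary
  out$p_value <- (exceed + 1) / (n_perm + 1)
  out$indicator <- out$indval >= 0.50 & out$p_value < 0.05
  out[order(-out$indval), ]
}

#' SIMPER: similarity-percentage decomposition of Bray-Curtis
#'
#' For every pair of groups, the average Bray-Curtis dissimilarity over all
#' between-group transect pairs is decomposed into per-syntaxon
#' contributions (the Bray-Curtis numerator terms |x_ik - x_jk| over the
#' pair total, averaged across pairs). Contributions sum to the overall
#' average dissimilarity. Identical groups give zero dissimilarity and an
#' empty ranking.
#'
#' @inheritParams indval
#' @return list keyed `"g1_vs_g2"`; each element has `overall` (average
#'   between-group Bray-Curtis) and `contributions` (data frame
#'   `syntaxon_code`, `average`, `contrib_pct`, `cumulative_pct`, sorted
#'   by decreasing contribution).
#' @export
simper <- function(comm, groups) {
  comm <- as.matrix(comm)
  if (is.null(colnames(comm)))
    colnames(comm) <- paste0("syn", seq_len(ncol(comm)))
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) stop("need at least two groups")
  lev <- levels(groups)
  out <- list()
  for (a in seq_len(length(lev) - 1L)) {
    for (b in seq.int(a + 1L, length(lev))) {
      ia <- which(groups == lev[a]); ib <- which(groups == lev[b])
      acc <- numeric(ncol(comm))
      for (i in ia) {
        xi <- comm[i, ]
        for (j in ib) {
          xj <- comm[j, ]
          denom <- sum(xi + xj)
          if (denom > 0) acc <- acc + abs(xi - xj) / denom
        }
      }
      avg <- acc / (length(ia) * length(ib))
      overall <- sum(avg)
      contributions <- if (overall > 0) {
        ord <- order(avg, decreasing = TRUE)
        pct <- 100 * avg[ord] / overall
        data.frame(syntaxon_code = colnames(comm)[ord], average = avg[ord],
                   contrib_pct = pct, cumulative_pct = cumsum(pct))
      } else {
        data.frame(syntaxon_code = character(0), average = numeric(0),
                   contrib_pct = numeric(0), cumulative_pct = numeric(0))
      }
      rownames(contributions) <- NULL
      out[[paste(lev[a], "vs", lev[b], sep = "_")]] <-
        list(overall = overall, contributions = contributions)
    }
  }
  out
}

#' Spearman correlation table between indices and environment
#'
#' Rank correlations (average ranks for ties) between every macrophyte
#' metric column and every environmental column, with the reporting rule
#' of the transect-level tables: rows with p > 0.1 can be dropped and
#' 0.05 <= p <= 0.1 rows flagged as non-significant.
#'
#' @param indices data frame of macrophyte metrics (rows = transects).
#' @param env data frame of environmental variables, same row order.
#' @param filter drop pairs with p > 0.1 (the printed-table rule),
#'   default `FALSE` (keep everything, flags attached).
#' @return data frame: `metric`, `env_var`, `rho`, `p_value`, `shown`
#'   (p <= 0.1), `non_significant` (0.05 <= p <= 0.1). Constant variables
#'   give `NA` rho and are never shown.
#' @export
correlation_table <- function(indices, env, filter = FALSE) {
  stopifnot(nrow(indices) == nrow(env), nrow(indices) >= 4L)
  grid <- expand.grid(metric = names(indices), env_var = names(env),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(k) {
    x <- indices[[grid$metric[k]]]
    y <- env[[grid$env_var[k]]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 4L || length(unique(x[ok])) < 2L ||
        length(unique(y[ok])) < 2L)
      return(data.frame(rho = NA_real_, p_value = NA_real_))
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok],
                                           method = "spearman",
                                           exact = FALSE))
    data.frame(rho = unname(ct$estimate), p_value = ct$p.value)
  })
  out <- cbind(grid, do.call(rbind, res))
  out$shown <- !is.na(out$p_value) & out$p_value <= 0.1
  out$non_significant <- out$shown & out$p_value >= 0.05
  if (filter) out <- out[out$shown, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Kruskal-Wallis comparison of a metric across slope classes
#'
#' Kruskal-Wallis H (chi-squared statistic with tie correction) with
#' pairwise Mann-Whitney (Wilcoxon rank-sum) follow-up. Classes with fewer
#' than 2 members are excluded from the pairwise step with a warning.
#'
#' @param metric numeric values, one per transect.
#' @param classes class label per transect.
#' @param p_adjust p adjustment for the pairwise step, default `"none"`
#'   (the published tables apply none).
#' @return list: `H`, `df`, `p_value`, `medians` (per class), `pairwise`
#'   (matrix of Mann-Whitney p-values or `NULL`), `excluded` (classes
#'   dropped from the pairwise step).
#' @export
group_comparison <- function(metric, classes, p_adjust = "none") {
  classes <- droplevels(as.factor(classes))
  if (nlevels(classes) < 2L) stop("need at least two non-empty classes")
  ok <- !is.na(metric)
  kw <- stats::kruskal.test(metric[ok], classes[ok])
  small <- names(which(table(classes[ok]) < 2L))
  if (length(small))
    warning(sprintf("class(es) with < 2 members excluded from pairwise tests: %s",
                    paste(small, collapse = ", ")))
  keep <- ok & !(classes %in% small)
  pw <- NULL
  if (nlevels(droplevels(classes[keep])) >= 2L) {
    pw <- suppressWarnings(
      stats::pairwise.wilcox.test(metric[keep],
                                  droplevels(classes[keep]),
                                  p.adjust.method = p_adjust))$p.value
  }
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p_value = kw$p.value,
       medians = tapply(metric[ok], classes[ok], stats::median),
       pairwise = pw, excluded = small)
}
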