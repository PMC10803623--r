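# Synthetic per-transect macrophyte survey tables along a trophic gradient.

#' Specification of a synthetic macrophyte community
#'
#' Relative covers of the syntaxa present on a transect are drawn from a
#' Dirichlet distribution; the Dirichlet weights of charophyte syntaxa are
#' scaled by `exp(trophic_effect * z)` where `z` is the transect's total
#' phosphorus standardised to \eqn{[-1, 1]} over `tp_range_mgL`, so a
#' negative `trophic_effect` makes charophyte cover decline with TP.
#'
#' @param n_syntaxa number of syntaxa in the species pool.
#' @param hydrophyte_fraction fraction of the pool that is hydrophyte
#'   (charophytes included); the rest are helophytes.
#' @param charophyte_fraction fraction of the pool that is charophyte
#'   (must not exceed `hydrophyte_fraction`).
#' @param tp_range_mgL total phosphorus range (mg/l) of the emulated
#'   non-impacted lakes, default `c(0.015, 0.049)`.
#' @param trophic_effect signed effect linking TP to charophyte cover.
#' @param occupancy baseline probability that a syntaxon occurs on a
#'   transect.
#' @param cmax_range_m range of per-transect maximum colonisation depth
#'   (m), default `c(2, 8.5)`.
#' @param seed integer seed.
#' @return object of class `community_spec`.
#' @export
community_spec <- function(n_syntaxa = 30L, hydrophyte_fraction = 0.65,
                           charophyte_fraction = 0.25,
                           tp_range_mgL = c(0.015, 0.049),
                           trophic_effect = -2, occupancy = 0.35,
                           cmax_range_m = c(2, 8.5), seed = 1L) {
  stopifnot(n_syntaxa >= 3,
            hydrophyte_fraction >= 0, hydrophyte_fraction <= 1,
            charophyte_fraction >= 0,
            charophyte_fraction <= hydrophyte_fraction,
            all(tp_range_mgL > 0), diff(tp_range_mgL) >= 0,
            occupancy > 0, occupancy <= 1, diff(cmax_range_m) >= 0)
  structure(list(n_syntaxa = as.integer(n_syntaxa),
                 hydrophyte_fraction = hydrophyte_fraction,
                 charophyte_fraction = charophyte_fraction,
                 tp_range_mgL = tp_range_mgL,
                 trophic_effect = trophic_effect, occupancy = occupancy,
                 cmax_range_m = cmax_range_m, seed = as.integer(seed)),
            class = "community_spec")
}

#' Generate a per-transect macrophyte survey table
#'
#' @param lake a `synthetic_lake` from [make_lake()], or `NULL` when bare
#'   transects are supplied.
#' @param spec a [community_spec()].
#' @param transects list of [transect()]s; default the lake's.
#' @param tp total phosphorus (mg/l): a scalar (one lake) or a vector per
#'   transect (emulating a pool of lakes along the trophic gradient); drawn
#'   per transect from `tp_range_mgL` when `NULL`.
#' @param class_labels optional factor/character per transect (e.g. slope
#'   classes) used with `indicator_class`.
#' @param indicator_class optional class label; when given, an extra
#'   syntaxon (`"INDI SYNT"`, hydrophyte) is planted that occurs only on
#'   transects of that class.
#' @param indicator_occupancy occurrence probability of the planted
#'   indicator within its class, default 0.8.
#' @return object of class `survey_table`: `data` (long data frame
#'   `lake_id`, `transect_id`, `syntaxon_code`, `group`, `rel_cover_pct`
#'   summing to 100 per transect), `transect_info` (per-transect
#'   `total_cover_pct`, `c_max_tr`, `tp_mgL`), `syntaxa` (pool with group
#'   labels).
#' @export
make_survey <- function(lake = NULL, spec, transects = NULL, tp = NULL,
                        class_labels = NULL, indicator_class = NULL,
                        indicator_occupancy = 0.8) {
  stopifnot(inherits(spec, "community_spec"))
  if (is.null(transects)) {
    if (is.null(lake)) stop("supply a lake or a list of transects")
    transects <- lake$transects
  }
  nt <- length(transects)
  if (!nt) stop("no transects to survey")
  z_max <- if (!is.null(lake)) lake$geometry$z_max else Inf
  if (!is.null(indicator_class)) {
    if (is.null(class_labels) || length(class_labels) != nt)
      stop("indicator_class needs class_labels, one per transect")
    class_labels <- as.character(class_labels)
  }

  n <- spec$n_syntaxa
  n_ch <- round(spec$charophyte_fraction * n)
  n_hy <- round(spec$hydrophyte_fraction * n)
  group <- c(rep("charophyte", n_ch), rep("hydrophyte", n_hy - n_ch),
             rep("helophyte", n - n_hy))
  codes <- sprintf("SYN %03d", seq_len(n))
  syntaxa <- data.frame(syntaxon_code = codes, group = group)

  .with_seed(spec$seed, {
    tp_tr <- if (is.null(tp)) {
      stats::runif(nt, spec$tp_range_mgL[1L], spec$tp_range_mgL[2L])
    } else rep_len(tp, nt)
    mid <- mean(spec$tp_range_mgL)
    half <- max(diff(spec$tp_range_mgL) / 2, 1e-12)
    z <- (tp_tr - mid) / half

    base_w <- stats::rgamma(n, shape = 2, rate = 2) + 0.2
    rows <- vector("list", nt)
    info <- vector("list", nt)
    for (i in seq_len(nt)) {
      present <- stats::runif(n) < spec$occupancy
      if (!any(present)) present[sample.int(n, 1L)] <- TRUE
      w <- base_w
      w[group == "charophyte"] <- w[group == "charophyte"] *
        exp(spec$trophic_effect * z[i])
      cover <- numeric(n)
      cover[present] <- stats::rgamma(sum(present), shape = w[present],
                                      rate = 1)
      cover[present][cover[present] <= 0] <- 1e-6

      code_i <- codes[present]
      grp_i <- group[present]
      cov_i <- cover[present]
      if (!is.null(indicator_class) &&
          class_labels[i] == indicator_class &&
          stats::runif(1) < indicator_occupancy) {
        code_i <- c(code_i, "INDI SYNT")
        grp_i <- c(grp_i, "hydrophyte")
        cov_i <- c(cov_i, stats::rgamma(1, shape = 2, rate = 1) + 0.5)
      }
      rel <- 100 * cov_i / sum(cov_i)
      tid <- transects[[i]]$transect_id
      rows[[i]] <- data.frame(
        lake_id = transects[[i]]$lake_id, transect_id = tid,
        syntaxon_code = code_i, group = grp_i, rel_cover_pct = rel)
      info[[i]] <- data.frame(
        lake_id = transects[[i]]$lake_id, transect_id = tid,
        total_cover_pct = 100 * stats::rbeta(1, 4, 1.5),
        c_max_tr = min(stats::runif(1, spec$cmax_range_m[1L],
                                    spec$cmax_range_m[2L]),
                       0.95 * z_max),
        tp_mgL = tp_tr[i])
    }
    structure(list(data = do.call(rbind, rows),
                   transect_info = do.call(rbind, info),
                   syntaxa = if (is.null(indicator_class)) syntaxa else
                     rbind(syntaxa, data.frame(syntaxon_code = "INDI SYNT",
                                               group = "hydrophyte"))),
              class = "survey_table")
  })
}

#' @export
print.survey_table <- function(x, ...) {
  cat(sprintf("<survey_table> %d transects, %d syntaxa in pool, %d cover records\n",
              nrow(x$transect_info), nrow(x$syntaxa), nrow(x$data)))
  invisible(x)
}

#' Transect x syntaxon relative-cover matrix from a survey table
#'
#' @param survey a `survey_table` (or its long `data` data frame).
#' @param min_occurrences drop syntaxa observed on fewer transects than
#'   this (the multivariate analyses use syntaxa with more than three
#'   observations; set 4 to mirror that rule). Default 0 keeps everything.
#' @return numeric matrix, rows = transects, columns = syntaxa.
#' @export
community_matrix <- function(survey, min_occurrences = 0L) {
  d <- if (inherits(survey, "survey_table")) survey$data else survey
  m <- tapply(d$rel_cover_pct, list(d$transect_id, d$syntaxon_code), sum,
              default = 0)
  m <- unclass(m)
  if (min_occurrences > 0L) m <- m[, colSums(m > 0) >= min_occurrences,
                                   drop = FALSE]
  m
}
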