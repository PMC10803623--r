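# Macrophyte diversity, abundance and ecological-status indices.

#' Shannon diversity and Pielou evenness of a cover vector
#'
#' H' is the Shannon index over the positive cover proportions (natural
#' logarithm); J' = H'/ln(S) for S >= 2 syntaxa. For a monodominant stand
#' (S = 1) H'max = ln(1) = 0 leaves J' undefined; the conservative default
#' sets J' = 0 (the status index treats a one-community stand as maximally
#' uneven), switchable via `mono_evenness`.
#'
#' @param covers non-negative cover values (any common unit); at least one
#'   must be positive.
#' @param mono_evenness J' to report for single-syntaxon stands, default 0.
#' @return list with `H` (Shannon H'), `J` (Pielou J') and `S` (number of
#'   syntaxa with positive cover).
#' @export
shannon_evenness <- function(covers, mono_evenness = 0) {
  if (!length(covers) || anyNA(covers) || any(covers < 0))
    stop("covers must be non-negative and non-missing")
  p <- covers[covers > 0]
  if (!length(p)) stop("all covers are zero")
  p <- p / sum(p)
  H <- -sum(p * log(p))
  S <- length(p)
  J <- if (S >= 2L) H / log(S) else mono_evenness
  list(H = H, J = J, S = S)
}

#' Lake-level Ecological State Macrophyte Index (ESMI)
#'
#' \eqn{ESMI = 1 - \exp[-J' \cdot (N/iso_{2.5}) \cdot \exp(N/P)]}: the
#' syntaxonomic component is Pielou's evenness J', the abundance component
#' the colonisation index Z = N/iso2.5 (total vegetated area over the area
#' shallower than 2.5 m), boosted by exp(N/P) with P the lake area. Values
#' lie in \eqn{[0, 1)}; degraded lakes score low.
#'
#' @param J Pielou evenness in \eqn{[0, 1]}.
#' @param N total vegetated area, ha.
#' @param iso25 lake area enclosed by the 2.5 m isobath, ha (> 0).
#' @param P lake area, ha (> 0).
#' @return ESMI in \eqn{[0, 1)}.
#' @export
esmi_lake <- function(J, N, iso25, P) {
  if (any(iso25 <= 0)) stop("iso25 (area within the 2.5 m isobath) must be > 0")
  if (any(P <= 0)) stop("lake area P must be > 0")
  if (any(N < 0) || any(J < 0)) stop("need N >= 0 and J >= 0")
  pmin(pmax(1 - exp(-J * (N / iso25) * exp(N / P)), 0), 1 - 1e-15)
}

#' Transect-level ESMI (ESMI_TR)
#'
#' The transect modification substitutes the maximum colonisation depth of
#' the transect (C_max_TR, m) for the vegetated area N, the constant 2.5 m
#' for iso2.5 and the lake's maximum depth Z_max for the lake area:
#' \eqn{ESMI_{TR} = 1 - \exp[-J' \cdot (C_{maxTR}/2.5) \cdot
#' \exp(C_{maxTR}/Z_{max})]}.
#'
#' @param J Pielou evenness in \eqn{[0, 1]}.
#' @param c_max_tr maximum colonisation depth on the transect, m
#'   (0 <= c_max_tr <= z_max).
#' @param z_max maximum lake depth, m (> 0).
#' @return ESMI_TR in \eqn{[0, 1)}.
#' @export
esmi_transect <- function(J, c_max_tr, z_max) {
  if (any(z_max <= 0)) stop("z_max must be positive")
  if (any(c_max_tr < 0)) stop("c_max_tr must be non-negative")
  if (any(c_max_tr > z_max + 1e-9))
    stop("c_max_tr exceeds the lake's maximum depth z_max")
  if (any(J < 0)) stop("J must be non-negative")
  pmin(pmax(1 - exp(-J * (c_max_tr / 2.5) * exp(c_max_tr / z_max)), 0),
       1 - 1e-15)
}

#' Per-transect macrophyte metric block
#'
#' Counts and relative-cover sums by growth group for one transect:
#' S_TOT (all syntaxa), S_Hy (hydrophytes, charophytes included), S_Ch
#' (charophytes), S_He (helophytes), %N_Hy, %N_Ch, plus H' and J'.
#'
#' @param survey a `survey_table` or its long `data` data frame.
#' @param transect_id transect to summarise.
#' @param mono_evenness passed to [shannon_evenness()].
#' @return one-row data frame: `transect_id`, `s_tot`, `s_hy`, `s_ch`,
#'   `s_he`, `pn_hy`, `pn_ch`, `shannon_h`, `pielou_j`.
#' @export
transect_metrics <- function(survey, transect_id, mono_evenness = 0) {
  d <- if (inherits(survey, "survey_table")) survey$data else survey
  d <- d[d$transect_id == transect_id & d$rel_cover_pct > 0, , drop = FALSE]
  if (!nrow(d)) stop(sprintf("transect %s not present in survey",
                             transect_id))
  known <- c("hydrophyte", "charophyte", "helophyte")
  if (!all(d$group %in% known))
    stop(sprintf("unknown growth group label(s): %s",
                 paste(setdiff(unique(d$group), known), collapse = ", ")))
  is_ch <- d$group == "charophyte"
  is_hy <- d$group %in% c("hydrophyte", "charophyte")
  is_he <- d$group == "helophyte"
  sh <- shannon_evenness(d$rel_cover_pct, mono_evenness = mono_evenness)
  data.frame(transect_id = transect_id,
             s_tot = nrow(d), s_hy = sum(is_hy), s_ch = sum(is_ch),
             s_he = sum(is_he),
             pn_hy = sum(d$rel_cover_pct[is_hy]),
             pn_ch = sum(d$rel_cover_pct[is_ch]),
             shannon_h = sh$H, pielou_j = sh$J)
}

#' Transect-level index table for a whole survey
#'
#' [transect_metrics()] plus ESMI_TR for every transect in the survey.
#'
#' @param survey a `survey_table`.
#' @param z_max maximum lake depth (m); scalar or named by lake_id.
#' @param mono_evenness passed to [shannon_evenness()].
#' @return data frame with the metric block, `c_max_tr`, `total_cover_pct`
#'   and `esmi_tr` per transect.
#' @export
survey_indices <- function(survey, z_max, mono_evenness = 0) {
  stopifnot(inherits(survey, "survey_table"))
  info <- survey$transect_info
  zm <- if (length(z_max) > 1L) z_max[info$lake_id] else rep(z_max,
                                                            nrow(info))
  rows <- lapply(seq_len(nrow(info)), function(i) {
    m <- transect_metrics(survey, info$transect_id[i],
                          mono_evenness = mono_evenness)
    m$c_max_tr <- info$c_max_tr[i]
    m$total_cover_pct <- info$total_cover_pct[i]
    m$esmi_tr <- esmi_transect(m$pielou_j, info$c_max_tr[i], zm[i])
    m$lake_id <- info$lake_id[i]
    m
  })
  do.call(rbind, rows)
}
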