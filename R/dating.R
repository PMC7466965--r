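#' Divergence dating from shared synonymous variants
#'
#' Estimates what fraction of the focal strain's total divergence from the
#' reference ancestor accumulated since its split from a close relative.
#' Two variant patterns are counted over synonymous sites with no missing
#' data in either strain: sites where the relative carries an alternate
#' allele but the focal strain matches the reference (a mutation private to
#' the relative's branch, `c_rel`) and the converse (`c_focal`). A strain
#' "carries" a variant when its genotype holds at least one alternate
#' allele. The counts are averaged and divided by the number of synonymous
#' sites `S`, giving the per-site divergence of one private branch; the
#' branch fraction is
#' `f = (mean(c_focal, c_rel) / S) / (d_pair / 2)`,
#' where `d_pair` is the per-site allele-frequency-weighted synonymous
#' divergence between the focal strain and the reference and `d_pair / 2`
#' is one lineage's share of it under a clock. Then
#' `T_out = d_pair / (2 mu)`, `T_split = f * T_out`, and the split age in
#' years follows from the assumed generations-per-year range.
#'
#' @param vt a [variant_table()] containing both strains (variant sites;
#'   the reference allele is the outgroup state).
#' @param focal,relative strain names.
#' @param site_mask optional logical vector selecting synonymous sites
#'   (defaults to the `SYN` annotation when present, else all sites).
#' @param s_sites total number of synonymous sites with no missing data,
#'   including monomorphic ones. Required whenever `vt` holds only variant
#'   sites (the usual case); defaults to the masked row count with a
#'   warning.
#' @param mu per-site per-generation mutation rate.
#' @return list of class `DivergenceEstimate` with `c_focal`, `c_rel`, `S`,
#'   `d_pair`, `f`, `T_out`, `T_split` and `years_range`.
#' @export
branch_fraction <- function(vt, focal = "focal", relative = "relative",
                            site_mask = NULL, s_sites = NULL, mu = 1.67e-10) {
  for (s in c(focal, relative))
    if (!s %in% vt_strains(vt)) bt_stop("config", "strain '%s' not in table", s)
  use <- vt$sites$is_snp & !vt$sites$multiallelic
  if (is.null(site_mask) && !is.null(vt$site_ann) && "SYN" %in% names(vt$site_ann))
    site_mask <- vt$site_ann$SYN
  if (!is.null(site_mask)) use <- use & site_mask
  d <- alt_dosage(vt)
  ok <- use & !is.na(d[, focal]) & !is.na(d[, relative])
  if (is.null(s_sites)) {
    bt_warn("s_sites not given; using masked variant rows (%d) as S - only valid for all-site tables", sum(ok))
    s_sites <- sum(ok)
  }
  S <- s_sites
  if (S <= 0) bt_stop("config", "S = 0 synonymous sites")

  carrier_f <- d[ok, focal] >= 1L
  carrier_r <- d[ok, relative] >= 1L
  c_focal <- sum(carrier_f & !carrier_r)
  c_rel <- sum(carrier_r & !carrier_f)
  d_pair <- sum(d[ok, focal] / vt$ploidy[[focal]]) / S

  branch_div <- mean(c(c_focal, c_rel)) / S
  f <- if (d_pair > 0) min(max(branch_div / (d_pair / 2), 0), 1) else 0
  T_out <- clock_generations(d_pair, mu)
  T_split <- f * T_out
  structure(list(c_focal = c_focal, c_rel = c_rel, S = S, d_pair = d_pair,
                 f = f, T_out = T_out, T_split = T_split,
                 years_range = generations_to_years(T_split)),
            class = "DivergenceEstimate")
}

#' @export
print.DivergenceEstimate <- function(x, ...) {
  cat(sprintf(paste0(
    "DivergenceEstimate: c_focal=%d c_rel=%d S=%d\n",
    "  d_pair=%.4g  f=%.4g  T_out=%.4g gen  T_split=%.4g gen\n",
    "  split age: %d-%d years (2920 vs 150 generations/year)\n"),
    x$c_focal, x$c_rel, as.integer(x$S), x$d_pair, x$f, x$T_out, x$T_split,
    x$years_range[1], x$years_range[2]))
  invisible(x)
}

#' Molecular-clock conversion of divergence to generations
#'
#' `T = d / (2 mu)`: time back to the common ancestor, with each lineage
#' accruing `mu` substitutions per site per generation.
#'
#' @param d_pair per-site pairwise synonymous divergence.
#' @param mu per-site per-generation mutation rate (default 1.67e-10).
#' @return generations to the common ancestor.
#' @export
clock_generations <- function(d_pair, mu = 1.67e-10) {
  check_scalar(mu, "mu", 1e-300)
  d_pair / (2 * mu)
}

#' Convert generations to a calendar-year range
#'
#' Domesticated and laboratory yeast are thought to undergo between 150
#' and 2920 generations per year; the same generation count therefore maps
#' to a wide year range: the fast-growth bound is floored, the slow-growth
#' bound rounded.
#'
#' @param generations number of generations.
#' @param per_year_low,per_year_high bounds on generations per year.
#' @return integer vector `c(years_min, years_max)` =
#'   `(floor(g / per_year_high), round(g / per_year_low))`.
#' @export
generations_to_years <- function(generations, per_year_low = 150,
                                 per_year_high = 2920) {
  c(years_min = floor(generations / per_year_high),
    years_max = round(generations / per_year_low))
}
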