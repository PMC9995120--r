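#' Mixed-inhibition scheme parameters
#'
#' Describes the kinetic context in which an IC50 was measured for a mixed
#' inhibitor that binds one enzyme form tightly (Ki) and another form
#' `alpha`-fold more weakly: substrate concentration S, Michaelis constant
#' Km, and the affinity ratio alpha. The defaults are the published values
#' for blebbistatin inhibition of skeletal-muscle myosin actin-activated
#' ATPase: S = 43 uM actin, Km = 24 uM, alpha = 10 (the ADP*Pi-state
#' affinity is tenfold that of the ATP state).
#'
#' @param S Substrate concentration, uM.
#' @param Km Michaelis constant, uM.
#' @param alpha Weak-site / tight-site affinity ratio (> 0).
#' @return List of class `inhibition_scheme`.
#' @export
inhibition_scheme <- function(S = 43, Km = 24, alpha = 10) {
  stopifnot(S > 0, Km > 0, alpha > 0)
  structure(list(S = S, Km = Km, alpha = alpha),
            class = "inhibition_scheme")
}

#' Convert an IC50 to a Ki under mixed inhibition
#'
#' Uses the mixed-inhibition relation
#' `IC50 = (S + Km) / (Km / (alpha * Ki) + S / Ki)`,
#' i.e. `Ki = IC50 * (Km / alpha + S) / (S + Km)`, where the tight site acts
#' on the substrate-engaged branch and the weak site is scaled by alpha. At
#' alpha = 1 (pure noncompetitive inhibition) Ki equals IC50 exactly; at the
#' published S, Km and alpha the ratio IC50/Ki is about 1.48, which is why
#' IC50 is treated as essentially equal to Ki. `mode = "equal"` applies that
#' assumption directly.
#'
#' @param ic50 IC50, uM (> 0).
#' @param scheme An [inhibition_scheme()].
#' @param mode `"mixed"` (solve the relation) or `"equal"` (Ki = IC50).
#' @return Ki in uM.
#' @export
ic50_to_ki_mixed <- function(ic50, scheme = inhibition_scheme(),
                             mode = c("mixed", "equal")) {
  mode <- match.arg(mode)
  if (any(ic50 <= 0)) stop("IC50 must be positive")
  if (mode == "equal") return(ic50)
  ic50 * (scheme$Km / scheme$alpha + scheme$S) / (scheme$S + scheme$Km)
}

#' Binding free energy from an IC50
#'
#' `dG = RT * log(Ki [M])`, with Ki from [ic50_to_ki_mixed()].
#'
#' @param ic50 IC50, uM (> 0).
#' @param temperature Temperature in K (default 310, matching the
#'   prediction temperature for apples-to-apples comparison).
#' @param scheme An [inhibition_scheme()], or `NULL` to take Ki = IC50.
#' @return Binding free energy, kcal/mol (negative = favourable).
#' @export
affinity_from_ic50 <- function(ic50, temperature = 310, scheme = NULL) {
  ki_uM <- if (is.null(scheme)) ic50_to_ki_mixed(ic50, mode = "equal")
  else ic50_to_ki_mixed(ic50, scheme, mode = "mixed")
  Kd_to_deltaG(ki_uM * 1e-6, temperature)
}

#' Pool experimental affinities per isoform
#'
#' Converts per-study IC50s (or direct Kis) to binding free energies and
#' pools them per isoform by arithmetic mean, with the standard error of the
#' per-study values.
#'
#' @param table data.frame with columns `isoform`, `study`, and `IC50_uM`
#'   and/or `Ki_uM` (Ki preferred when both present).
#' @param temperature Temperature in K.
#' @param scheme Passed to [affinity_from_ic50()].
#' @return data.frame: `isoform`, `dG_exp` (kcal/mol), `se`, `n_studies`.
#' @export
pool_experimental_affinities <- function(table, temperature = 310,
                                         scheme = NULL) {
  ki <- if ("Ki_uM" %in% names(table)) table$Ki_uM else rep(NA_real_,
                                                            nrow(table))
  ic50 <- if ("IC50_uM" %in% names(table)) table$IC50_uM
  else rep(NA_real_, nrow(table))
  conc <- ifelse(is.na(ki), ic50, ki)
  if (anyNA(conc)) stop("every row needs IC50_uM or Ki_uM")
  dg <- ifelse(is.na(ki),
               affinity_from_ic50(conc, temperature, scheme),
               Kd_to_deltaG(conc * 1e-6, temperature))
  agg <- split(dg, table$isoform)
  out <- data.frame(
    isoform = names(agg),
    dG_exp = vapply(agg, mean, numeric(1)),
    se = vapply(agg, function(x) {
      if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
    }, numeric(1)),
    n_studies = vapply(agg, length, integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Compare predicted and experimental binding free energies
#'
#' R^2 is the squared Pearson correlation (the headline statistic);
#' `r_squared_identity` additionally reports 1 - SS_res/SS_tot about the
#' identity line. RMSE is the root mean squared difference in kcal/mol.
#'
#' @param predicted,experimental Equal-length numeric vectors (kcal/mol),
#'   length >= 2.
#' @return List of class `comparison_result`: `r_squared`, `rmse`,
#'   `r_squared_identity`, `pairs` (data.frame).
#' @export
compare_predictions <- function(predicted, experimental) {
  if (length(predicted) != length(experimental) || length(predicted) < 2L)
    stop("need equal-length vectors of at least 2 values")
  if (stats::sd(predicted) == 0 || stats::sd(experimental) == 0)
    stop("zero variance in predictions or experiments")
  r2 <- stats::cor(predicted, experimental)^2
  rmse <- sqrt(mean((predicted - experimental)^2))
  ss_res <- sum((experimental - predicted)^2)
  ss_tot <- sum((experimental - mean(experimental))^2)
  structure(list(r_squared = r2, rmse = rmse,
                 r_squared_identity = 1 - ss_res / ss_tot,
                 pairs = data.frame(predicted = predicted,
                                    experimental = experimental)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> R^2 = %.3f, RMSE = %.3f kcal/mol (n = %d)\n",
              x$r_squared, x$rmse, nrow(x$pairs)))
  invisible(x)
}
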