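#' Microcosm headspace gas time course
#'
#' Headspace concentrations of one gas species from one vial, sampled at
#' regular intervals (typically every 12 h over a 96-h incubation), plus the
#' physical constants needed to convert concentration to mass.
#'
#' @param time_h sampling times in hours, strictly increasing.
#' @param conc_ppmv headspace concentrations (ppmv), nonnegative.
#' @param unit,ecosystem,treatment experimental-unit labels.
#' @param species gas species: `"CO2"`, `"CH4"` or `"N2O"`.
#' @param soil_g soil dry mass in the vial (g, > 0).
#' @param headspace_mL headspace volume (mL).
#' @param temp_C,pressure_atm incubation temperature and pressure.
#' @return a list of class `gas_timecourse`.
#' @export
gas_timecourse <- function(time_h, conc_ppmv, unit = NA_character_,
                           ecosystem = NA_character_,
                           treatment = NA_character_,
                           species = c("CO2", "CH4", "N2O"),
                           soil_g = 3, headspace_mL = 37.7,
                           temp_C = 25, pressure_atm = 1) {
  species <- match.arg(species)
  if (length(conc_ppmv) != length(time_h))
    stopf("time_h and conc_ppmv must have equal length")
  if (any(diff(time_h) <= 0)) stopf("time_h must be strictly increasing")
  if (any(conc_ppmv < 0)) stopf("concentrations must be nonnegative")
  check_scalar_number(soil_g, "soil_g", lower = 0, strict_lower = TRUE)
  structure(list(time_h = as.numeric(time_h),
                 conc_ppmv = as.numeric(conc_ppmv),
                 unit = unit, ecosystem = ecosystem, treatment = treatment,
                 species = species, soil_g = soil_g,
                 headspace_mL = headspace_mL, temp_C = temp_C,
                 pressure_atm = pressure_atm),
            class = "gas_timecourse")
}

# atomic masses (g/mol) and atoms of the accounted element per molecule
.gas_element <- list(
  CO2 = list(element = "C", mass = 12.011, atoms = 1L),
  CH4 = list(element = "C", mass = 12.011, atoms = 1L),
  N2O = list(element = "N", mass = 14.007, atoms = 2L)
)

#' Element mass in a headspace at a given concentration
#'
#' Ideal-gas conversion from a mixing ratio to micrograms of the accounted
#' element (C for CO2 and CH4, N for N2O): total moles `n = P V / (R T)`,
#' species moles `n * conc * 1e-6`, element mass = species moles x
#' atoms-per-molecule x atomic mass. For 1000 ppmv CO2 in a 40-mL headspace
#' at 25 degC and 1 atm this gives 19.6 ug C.
#'
#' @param conc_ppmv mixing ratio of the species (ppmv), nonnegative.
#' @param headspace_mL headspace volume (mL).
#' @param temp_C temperature (degC).
#' @param pressure_atm pressure (atm).
#' @param species `"CO2"`, `"CH4"` or `"N2O"`.
#' @return element mass in micrograms.
#' @export
headspace_mass <- function(conc_ppmv, headspace_mL = 37.7, temp_C = 25,
                           pressure_atm = 1, species = c("CO2", "CH4", "N2O")) {
  species <- match.arg(species)
  if (any(conc_ppmv < 0)) stopf("concentration must be nonnegative")
  check_scalar_number(headspace_mL, "headspace_mL", lower = 0,
                      strict_lower = TRUE)
  check_scalar_number(pressure_atm, "pressure_atm", lower = 0,
                      strict_lower = TRUE)
  check_scalar_number(temp_C, "temp_C", lower = -273.15, strict_lower = TRUE)
  R <- 0.0820573661  # L atm / (mol K)
  n_total <- pressure_atm * (headspace_mL / 1000) / (R * (temp_C + 273.15))
  el <- .gas_element[[species]]
  n_total * conc_ppmv * 1e-6 * el$atoms * el$mass * 1e6  # ug
}

#' Net trace-gas production per gram soil
#'
#' Sums the signed element-mass change of the headspace over each sampling
#' interval and divides by soil mass, giving net production in ug element
#' (C or N) per g soil over the incubation. Negative values indicate net
#' consumption (e.g. CH4 uptake).
#'
#' The 1-mL aliquot removed at each sampling (about 2.5% of the headspace)
#' is not corrected for by default, `sampling_correction = TRUE` scales the
#' concentration change of each interval by the cumulative dilution factor
#' `(1 - sample_mL / headspace_mL)^(-k)` for the k-th interval.
#'
#' @param tc a [gas_timecourse()] with at least two time points.
#' @param sampling_correction apply cumulative headspace-dilution
#'   correction for removed aliquots?
#' @param sample_mL aliquot volume removed per sampling (mL).
#' @return a list of class `net_production`: `unit`, `ecosystem`,
#'   `treatment`, `species`, `value` (ug element / g soil), `per_interval`
#'   (signed increments, same units).
#' @export
net_production <- function(tc, sampling_correction = FALSE, sample_mL = 1) {
  stopifnot(inherits(tc, "gas_timecourse"))
  m <- length(tc$conc_ppmv)
  if (m < 2L) stopf("need at least 2 time points to compute net production")
  mass <- headspace_mass(tc$conc_ppmv, tc$headspace_mL, tc$temp_C,
                         tc$pressure_atm, tc$species)
  inc <- diff(mass)
  if (sampling_correction) {
    dil <- (1 - sample_mL / tc$headspace_mL)^(-(seq_len(m - 1L)))
    inc <- inc * dil
  }
  inc <- inc / tc$soil_g
  structure(list(unit = tc$unit, ecosystem = tc$ecosystem,
                 treatment = tc$treatment, species = tc$species,
                 value = sum(inc), per_interval = inc),
            class = "net_production")
}

#' Rewetted/dry fold change in net production
#'
#' @param rewetted,dry [net_production()] objects (or bare numbers).
#' @return the ratio `rewetted / dry`.
#' @export
fold_change <- function(rewetted, dry) {
  val <- function(x) if (inherits(x, "net_production")) x$value else
    check_scalar_number(x, "value")
  r <- val(rewetted); d <- val(dry)
  if (d == 0)
    stopf("undefined fold change: dry net production is 0 (rewetted = %g)", r)
  r / d
}

#' Two-way fixed-effects ANOVA for a balanced factorial
#'
#' Classic decomposition of a balanced two-factor design (e.g. ecosystem x
#' watering treatment) with interaction, as used to test rewetting effects
#' on trace-gas production and richness. Sums of squares partition exactly:
#' `SS_A + SS_B + SS_AB + SS_res = SS_total`.
#'
#' A degenerate design with zero residual variance but unequal cell means
#' yields `F = Inf`, `p = 0` and `degenerate = TRUE` attribute rather than
#' an error.
#'
#' @param values numeric response vector.
#' @param factor_a,factor_b factor labels, same length as `values`; the
#'   design must be a balanced full factorial with >= 2 replicates per cell.
#' @return data.frame with rows A, B, A:B, Residual and columns `term`,
#'   `df`, `sum_sq`, `mean_sq`, `F`, `p`; attribute `degenerate`.
#' @export
two_way_anova <- function(values, factor_a, factor_b) {
  if (length(values) != length(factor_a) ||
      length(values) != length(factor_b))
    stopf("values and factor labels must have equal length")
  a <- factor(factor_a); b <- factor(factor_b)
  if (nlevels(a) < 2L || nlevels(b) < 2L)
    stopf("both factors need at least 2 levels")
  cell_n <- table(a, b)
  if (any(cell_n < 2L) || length(unique(as.vector(cell_n))) != 1L)
    stopf("unsupported design: needs a balanced full factorial with >= 2 replicates per cell")
  fit <- stats::aov(values ~ a * b)
  tab <- summary(fit)[[1L]]
  ss <- tab[["Sum Sq"]]
  df <- tab[["Df"]]
  ms <- ss / df
  ms_res <- ms[4L]
  degenerate <- ms_res <= 1e-12 * max(ms[1:3], 1)
  if (degenerate) {
    Fv <- ifelse(ms[1:3] > 0, Inf, NaN)
    pv <- ifelse(ms[1:3] > 0, 0, NaN)
  } else {
    Fv <- ms[1:3] / ms_res
    pv <- stats::pf(Fv, df[1:3], df[4L], lower.tail = FALSE)
  }
  out <- data.frame(term = c("A", "B", "A:B", "Residual"),
                    df = df,
                    sum_sq = ss,
                    mean_sq = ms,
                    F = c(Fv, NA),
                    p = c(pv, NA))
  rownames(out) <- NULL
  attr(out, "degenerate") <- degenerate
  out
}

#' Tukey HSD comparisons among factorial cells with letter display
#'
#' Studentized-range pairwise tests among all cell means of a balanced
#' two-factor design (pooled residual from the full interaction model),
#' plus a compact letter display: cells sharing a letter are not
#' significantly different. Letters are assigned by the standard greedy
#' clique cover of the non-significance graph, cells ordered by ascending
#' mean.
#'
#' @param values numeric response vector.
#' @param factor_a,factor_b factor labels (balanced full factorial,
#'   >= 2 replicates per cell); omit `factor_b` for one-way comparisons
#'   among the levels of `factor_a` alone.
#' @param alpha family-wise significance level for the letter display.
#' @return list with `comparisons` (data.frame: `pair`, `diff`, `lwr`,
#'   `upr`, `p_adj`) and `letters` (data.frame: `cell`, `mean`, `letters`).
#' @export
tukey_hsd <- function(values, factor_a, factor_b = NULL, alpha = 0.05) {
  a <- factor(factor_a)
  if (is.null(factor_b)) {
    cell_n <- table(a)
    if (any(cell_n < 2L) || length(unique(as.vector(cell_n))) != 1L)
      stopf("unsupported design: needs equal group sizes with >= 2 replicates")
    cell <- a
  } else {
    b <- factor(factor_b)
    cell_n <- table(a, b)
    if (any(cell_n < 2L) || length(unique(as.vector(cell_n))) != 1L)
      stopf("unsupported design: needs a balanced full factorial with >= 2 replicates per cell")
    cell <- factor(paste(as.character(a), as.character(b), sep = ":"))
  }
  fit <- stats::aov(values ~ cell)
  tk <- stats::TukeyHSD(fit, "cell")$cell
  comparisons <- data.frame(pair = rownames(tk),
                            diff = tk[, "diff"], lwr = tk[, "lwr"],
                            upr = tk[, "upr"], p_adj = tk[, "p adj"],
                            row.names = NULL)
  means <- tapply(values, cell, mean)
  ord <- order(means)
  cells <- names(means)[ord]
  k <- length(cells)
  sig <- matrix(FALSE, k, k, dimnames = list(cells, cells))
  for (i in seq_len(nrow(comparisons))) {
    pr <- strsplit(comparisons$pair[i], "-", fixed = TRUE)[[1L]]
    if (isTRUE(comparisons$p_adj[i] < alpha)) {
      sig[pr[1L], pr[2L]] <- TRUE
      sig[pr[2L], pr[1L]] <- TRUE
    }
  }
  letters_df <- data.frame(cell = cells, mean = as.numeric(means[ord]),
                           letters = letter_display(sig),
                           row.names = NULL)
  list(comparisons = comparisons, letters = letters_df)
}

# Letter display = cover of the non-significance graph by its maximal
# cliques, one letter per clique, ordered by smallest (ascending-mean)
# member. Cell counts here are small, so cliques are enumerated exactly.
letter_display <- function(sig) {
  k <- nrow(sig)
  compat <- !sig
  diag(compat) <- TRUE
  is_clique <- function(idx) all(compat[idx, idx])
  cliques <- list()
  for (code in seq_len(2^k) - 1L) {
    idx <- which(bitwAnd(code, 2^(seq_len(k) - 1L)) > 0)
    if (!length(idx) || !is_clique(idx)) next
    # maximal: no outside vertex compatible with every member
    outside <- setdiff(seq_len(k), idx)
    if (!length(outside) ||
        !any(vapply(outside, function(v) all(compat[v, idx]), logical(1))))
      cliques[[length(cliques) + 1L]] <- idx
  }
  ord <- order(vapply(cliques, min, numeric(1)))
  cliques <- cliques[ord]
  out <- character(k)
  for (g in seq_along(cliques))
    out[cliques[[g]]] <- paste0(out[cliques[[g]]], letters[g])
  out
}

#' Gravimetric moisture after rewetting
#'
#' Gravimetric water content (g H2O per g dry soil) after adding a volume
#' of water to field-dry soil: e.g. 3 g of soil at 0.05 g/g receiving
#' 0.6 mL of water reaches 0.25 g/g, a five-fold increase.
#'
#' @param soil_g dry-soil mass (g).
#' @param initial_g_per_g initial gravimetric moisture (g H2O / g soil).
#' @param water_mL water volume added (mL; density 1 g/mL assumed).
#' @return gravimetric moisture after rewetting (g H2O / g soil).
#' @export
rewetted_moisture <- function(soil_g, initial_g_per_g, water_mL) {
  check_scalar_number(soil_g, "soil_g", lower = 0, strict_lower = TRUE)
  check_scalar_number(initial_g_per_g, "initial_g_per_g", lower = 0)
  check_scalar_number(water_mL, "water_mL", lower = 0)
  (soil_g * initial_g_per_g + water_mL) / soil_g
}
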