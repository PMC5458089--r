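#' Construct a rate-law specification
#'
#' A small library of rate-law forms covers the whole network:
#'
#' * `irreversible_mm` — product of independent Michaelis-Menten saturation
#'   terms, one per substrate with a Km entry:
#'   `v = Vmax * prod_s (c_s/Km_s)^n_s / (1 + c_s/Km_s + ... + (c_s/Km_s)^n_s)`.
#' * `reversible_mm` — multisubstrate reversible Michaelis-Menten in the
#'   convenience-kinetics form with a Haldane equilibrium constraint:
#'   `v = Vmax * (A - P/Keq') / D` with `A = prod_s (c_s/Km_s)^n_s`,
#'   `P = prod_p (c_p/Km_p)^n_p`, `Keq'` the Keq rescaled by the Km values so
#'   that net flux vanishes exactly when the mass-action ratio equals Keq, and
#'   `D = prod_s sum_j (c_s/Km_s)^j + prod_p sum_j (c_p/Km_p)^j - 1`.
#' * `mass_action` — `v = k * prod_s c_s^n_s`, with `k` taken from the vmax
#'   slot (interpreted as mM^(1-n) s^-1 after unit conversion).
#'
#' Species without a Km entry (water, clamped dissolved oxygen) take activity
#' one: they appear in the stoichiometry but not in the kinetics, so Keq
#' values are defined over the Km-listed species only (mM basis).
#'
#' @param form One of `"irreversible_mm"`, `"reversible_mm"`, `"mass_action"`.
#' @param vmax Maximal rate in U ml^-1 (or rate constant for mass action).
#' @param km Named numeric vector of Michaelis constants (mM); names are
#'   species ids. Must cover every kinetic substrate (and, for reversible
#'   forms, every kinetic product).
#' @param keq Equilibrium constant (mM basis over Km-listed species);
#'   required for `reversible_mm`.
#' @param substrates,products Named integer vectors of stoichiometric
#'   coefficients (positive numbers; direction is encoded by the slot).
#' @return An object of class `tf_rate_law`.
#' @export
rate_law <- function(form = c("irreversible_mm", "reversible_mm", "mass_action"),
                     vmax, km = numeric(), keq = NA_real_,
                     substrates, products = numeric()) {
  form <- match.arg(form)
  if (!is.numeric(vmax) || length(vmax) != 1L || !is.finite(vmax) || vmax < 0)
    stop("vmax must be a single non-negative number", call. = FALSE)
  if (length(km) && (any(!is.finite(km)) || any(km <= 0)))
    stop("all Km values must be positive and finite", call. = FALSE)
  if (form == "reversible_mm") {
    if (!is.finite(keq) || keq <= 0)
      stop("reversible_mm requires a positive Keq", call. = FALSE)
  }
  if (any(substrates <= 0) || (length(products) && any(products <= 0)))
    stop("stoichiometric coefficients must be positive", call. = FALSE)
  missing_km <- setdiff(names(substrates), c(names(km), c("H2O", "O2")))
  if (form != "mass_action" && length(missing_km))
    stop("missing Km for substrate(s): ", paste(missing_km, collapse = ", "),
         call. = FALSE)
  structure(
    list(form = form, vmax = vmax, km = km, keq = keq,
         substrates = substrates, products = products),
    class = "tf_rate_law"
  )
}

# saturation term (c/km)^n / (1 + c/km + ... + (c/km)^n), vectorised over one species
.sat_term <- function(c, km, n) {
  a <- c / km
  num <- a^n
  den <- 0
  for (j in 0:n) den <- den + a^j
  num / den
}

# geometric-series denominator sum_{j=0..n} (c/km)^j
.den_series <- function(c, km, n) {
  a <- c / km
  s <- 0
  for (j in 0:n) s <- s + a^j
  s
}

#' Evaluate the flux of a rate law at given concentrations
#'
#' @param rl A `tf_rate_law`.
#' @param conc Named numeric vector of concentrations (mM); must contain every
#'   Km-listed species. Negative concentrations are a domain error.
#' @return Signed flux in mM s^-1 (irreversible forms are always >= 0).
#' @export
flux <- function(rl, conc) {
  stopifnot(inherits(rl, "tf_rate_law"))
  need <- names(rl$km)
  if (rl$form == "mass_action") need <- names(rl$substrates)
  if (!all(need %in% names(conc)))
    stop("concentrations missing for: ",
         paste(setdiff(need, names(conc)), collapse = ", "), call. = FALSE)
  if (any(conc[need] < 0))
    stop("negative concentration supplied to flux()", call. = FALSE)
  vmax <- rl$vmax / 60  # U/ml -> mM/s

  if (rl$form == "mass_action") {
    v <- vmax
    for (s in names(rl$substrates)) v <- v * conc[[s]]^rl$substrates[[s]]
    return(unname(v))
  }

  kin_sub <- intersect(names(rl$substrates), names(rl$km))
  if (rl$form == "irreversible_mm") {
    v <- vmax
    for (s in kin_sub) v <- v * .sat_term(conc[[s]], rl$km[[s]], rl$substrates[[s]])
    return(unname(v))
  }

  # reversible_mm with Haldane constraint
  kin_prod <- intersect(names(rl$products), names(rl$km))
  A <- 1; Ds <- 1
  for (s in kin_sub) {
    A <- A * (conc[[s]] / rl$km[[s]])^rl$substrates[[s]]
    Ds <- Ds * .den_series(conc[[s]], rl$km[[s]], rl$substrates[[s]])
  }
  P <- 1; Dp <- 1
  for (p in kin_prod) {
    P <- P * (conc[[p]] / rl$km[[p]])^rl$products[[p]]
    Dp <- Dp * .den_series(conc[[p]], rl$km[[p]], rl$products[[p]])
  }
  # Keq' rescales Keq from concentration space into (c/Km) space so that
  # v = 0 exactly when the mass-action ratio Gamma equals Keq
  km_s <- prod(vapply(kin_sub, function(s) rl$km[[s]]^rl$substrates[[s]], 0))
  km_p <- prod(vapply(kin_prod, function(p) rl$km[[p]]^rl$products[[p]], 0))
  keq_scaled <- rl$keq * km_s / km_p
  unname(vmax * (A - P / keq_scaled) / (Ds + Dp - 1))
}

#' @export
print.tf_rate_law <- function(x, ...) {
  cat("<tf_rate_law>", x$form, " vmax =", x$vmax, "U/ml")
  if (is.finite(x$keq)) cat("  Keq =", x$keq)
  cat("\n  substrates:", paste(names(x$substrates), collapse = ", "), "\n")
  if (length(x$products))
    cat("  products:  ", paste(names(x$products), collapse = ", "), "\n")
  invisible(x)
}
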