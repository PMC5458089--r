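# Stiff ODE integration of the network with conserved-moiety auditing.
# Concentrations are mM, time is seconds, fluxes mM/s throughout.

# Precompute index structures so the ODE right-hand side avoids any name
# lookups; returns an environment reused across calls.
compile_model <- function(model) {
  if (!is.null(model$compiled)) return(model$compiled)
  S <- model$stoich
  sp_ids <- rownames(S)
  nr <- ncol(S)
  rx <- vector("list", nr)
  for (i in seq_len(nr)) {
    rl <- model$rate_laws[[i]]
    kin_sub <- intersect(names(rl$substrates), names(rl$km))
    kin_prod <- intersect(names(rl$products), names(rl$km))
    keq_scaled <- NA_real_
    if (rl$form == "reversible_mm") {
      km_s <- prod(vapply(kin_sub, function(s) rl$km[[s]]^rl$substrates[[s]], 0))
      km_p <- prod(vapply(kin_prod, function(p) rl$km[[p]]^rl$products[[p]], 0))
      keq_scaled <- rl$keq * km_s / km_p
    }
    rx[[i]] <- list(
      form = rl$form,
      vmax = rl$vmax / 60,
      si = match(kin_sub, sp_ids), skm = unname(rl$km[kin_sub]),
      sn = unname(rl$substrates[kin_sub]),
      pi = match(kin_prod, sp_ids), pkm = unname(rl$km[kin_prod]),
      pn = unname(rl$products[kin_prod]),
      mi = match(names(rl$substrates), sp_ids),
      mn = unname(rl$substrates),
      keq_scaled = keq_scaled
    )
  }
  env <- new.env(parent = emptyenv())
  env$S <- S
  env$rx <- rx
  env$const_idx <- which(model$species$constant)
  env
}

# fluxes for a raw concentration vector (ordered as model species)
eval_fluxes <- function(compiled, y) {
  rx <- compiled$rx
  v <- numeric(length(rx))
  for (i in seq_along(rx)) {
    r <- rx[[i]]
    if (r$vmax == 0) next
    if (r$form == "mass_action") {
      v[i] <- r$vmax * prod(y[r$mi]^r$mn)
    } else if (r$form == "irreversible_mm") {
      a <- y[r$si] / r$skm
      f <- r$vmax
      for (k in seq_along(a)) {
        n <- r$sn[k]
        den <- 1; p <- 1
        for (j in seq_len(n)) { p <- p * a[k]; den <- den + p }
        f <- f * p / den
      }
      v[i] <- f
    } else {
      a <- y[r$si] / r$skm
      b <- y[r$pi] / r$pkm
      A <- 1; Ds <- 1
      for (k in seq_along(a)) {
        n <- r$sn[k]; den <- 1; p <- 1
        for (j in seq_len(n)) { p <- p * a[k]; den <- den + p }
        A <- A * p; Ds <- Ds * den
      }
      P <- 1; Dp <- 1
      for (k in seq_along(b)) {
        n <- r$pn[k]; den <- 1; p <- 1
        for (j in seq_len(n)) { p <- p * b[k]; den <- den + p }
        P <- P * p; Dp <- Dp * den
      }
      v[i] <- r$vmax * (A - P / r$keq_scaled) / (Ds + Dp - 1)
    }
  }
  v
}

#' Simulate the batch reaction
#'
#' Integrates the model ODEs with a stiff solver (deSolve, lsoda) on an
#' adaptive internal grid, reports on `n_out` equally spaced output times
#' (or an explicit `times` grid), audits the five conserved moieties along
#' the trajectory and attaches derived observables (terpene titre in g/l,
#' total hexose + hexose-phosphates in mM, ATP in uM, Pi in mM). Rate laws
#' evaluate `max(c, 0)`; concentrations more negative than `-1e-9` mM at
#' output times are an integration-quality error.
#'
#' @param model A `tf_model`.
#' @param t_end End time in seconds (> 0).
#' @param n_out Number of output points (default 201).
#' @param times Optional explicit output-time grid (seconds, starting at 0).
#' @param rtol,atol Solver tolerances (defaults 1e-8 / 1e-12; concentrations
#'   span sub-uM to hundreds of mM, so the absolute floor sits well below the
#'   smallest meaningful pool).
#' @param conservation_tol Maximum tolerated relative drift of any conserved
#'   moiety total (default 1e-6); exceeding it is an error.
#' @param method deSolve integrator (default `"lsoda"`).
#' @return A `tf_timecourse`: `time`, concentration matrix `conc`, flux
#'   matrix `fluxes`, tidy `observables`, moiety `audit`, solver settings.
#' @export
simulate_timecourse <- function(model, t_end = 20000, n_out = 201L,
                                times = NULL, rtol = 1e-8, atol = 1e-12,
                                conservation_tol = 1e-6, method = "lsoda") {
  stopifnot(inherits(model, "tf_model"))
  if (is.null(times)) {
    if (!is.numeric(t_end) || t_end <= 0) stop("t_end must be > 0", call. = FALSE)
    times <- seq(0, t_end, length.out = n_out)
  }
  compiled <- compile_model(model)
  y0 <- model$init[rownames(compiled$S)]
  const_idx <- compiled$const_idx

  rhs <- function(t, y, parms) {
    y[y < 0] <- 0
    v <- eval_fluxes(compiled, y)
    dy <- as.vector(compiled$S %*% v)
    if (length(const_idx)) dy[const_idx] <- 0
    list(dy)
  }

  out <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = method, rtol = rtol, atol = atol)
  diag_ok <- attr(out, "istate")[1] >= 0 && nrow(out) == length(times)
  if (!diag_ok) {
    last <- out[nrow(out), ]
    stop("ODE solver failed at t = ", last[1], " s; last state attached.\n",
         paste(utils::capture.output(print(utils::head(last, 12))), collapse = "\n"),
         call. = FALSE)
  }
  conc <- out[, -1, drop = FALSE]
  if (min(conc) < -1e-9)
    stop("negative concentration beyond tolerance (min ",
         format(min(conc)), " mM): integration-quality error", call. = FALSE)
  conc[conc < 0] <- 0

  fl <- t(apply(conc, 1, function(y) eval_fluxes(compiled, y)))
  colnames(fl) <- colnames(compiled$S)

  moieties <- conserved_moieties(model, check = FALSE)
  audit <- vapply(moieties, function(m) {
    tot <- as.vector(conc %*% m[colnames(conc)])
    ref <- tot[1]
    if (ref == 0) max(abs(tot)) else max(abs(tot - ref)) / ref
  }, 0)
  if (any(audit > conservation_tol))
    stop("conserved-moiety drift exceeds tolerance: ",
         paste(sprintf("%s=%.2e", names(audit), audit)[audit > conservation_tol],
               collapse = ", "), call. = FALSE)

  mw <- model$metadata$product_mw
  observables <- data.frame(
    time_s = times,
    terpene_g_l = conc[, model$metadata$product_species] * mw / 1000,
    hexose_mM = rowSums(conc[, c("Glc", "G6P", "F6P", "FBP"), drop = FALSE]),
    atp_uM = conc[, "ATP"] * 1000,
    pi_mM = conc[, "Pi"]
  )

  structure(
    list(time = times, conc = conc, fluxes = fl, observables = observables,
         audit = audit, model = model,
         solver = list(method = method, rtol = rtol, atol = atol)),
    class = "tf_timecourse"
  )
}

#' @export
print.tf_timecourse <- function(x, ...) {
  n <- length(x$time)
  cat("<tf_timecourse> 0 -", x$time[n], "s (", n, "output points )\n")
  cat(sprintf("  terpene %.3f g/l | hexose %.2f mM | ATP %.1f uM | Pi %.2f mM (final)\n",
              x$observables$terpene_g_l[n], x$observables$hexose_mM[n],
              x$observables$atp_uM[n], x$observables$pi_mM[n]))
  cat("  max moiety drift:", format(max(x$audit), digits = 3), "\n")
  invisible(x)
}

#' Classify a trajectory as completed, stalled or still running
#'
#' A run is `completed` when the residual hexose pool (glucose plus hexose
#' phosphates) has fallen below `threshold_frac` of its initial value. If not
#' complete and every reaction flux stays below `flux_eps` over the trailing
#' `window` seconds, the run is `stalled`: the stall time and the depleted
#' pool(s) (ATP, Pi, NAD+, NADP+, CoA) are reported, along with whether
#' phosphate ended up sequestered in hexose phosphates. Otherwise the run is
#' still `running` at t_end.
#'
#' @param tc A `tf_timecourse`.
#' @param threshold_frac Completion threshold as a fraction of the initial
#'   hexose pool (default 0.01).
#' @param window Quiescence window in seconds (default: 10% of the
#'   trajectory); must not exceed the trajectory span.
#' @param flux_eps Quiescence flux threshold in mM/s (default: 1e-6 x the
#'   trajectory's peak flux).
#' @return List with `status`, `stall_time_s`, `limiting_pool`, `detail`.
#' @export
classify_outcome <- function(tc, threshold_frac = 0.01, window = NULL,
                             flux_eps = NULL) {
  stopifnot(inherits(tc, "tf_timecourse"))
  tmax <- tc$time[length(tc$time)]
  if (is.null(window)) window <- 0.1 * tmax
  if (window > tmax)
    stop("window longer than trajectory", call. = FALSE)
  hex0 <- tc$observables$hexose_mM[1]
  hex_end <- tc$observables$hexose_mM[length(tc$time)]
  if (hex0 == 0 || hex_end < threshold_frac * hex0) {
    return(list(status = "completed", stall_time_s = NA_real_,
                limiting_pool = NA_character_, detail = NULL))
  }
  vmaxabs <- apply(abs(tc$fluxes), 1, max)
  if (is.null(flux_eps)) flux_eps <- 1e-6 * max(vmaxabs)
  quiet <- vmaxabs < flux_eps
  # earliest time from which the system remains quiescent through t_end,
  # provided the quiescent tail covers at least `window` seconds
  stall_idx <- NA_integer_
  if (quiet[length(quiet)]) {
    run_start <- max(which(!quiet)) + 1L
    if (run_start <= length(quiet) &&
        tmax - tc$time[run_start] >= window * 0.999)
      stall_idx <- run_start
  }
  if (is.na(stall_idx)) {
    return(list(status = "running", stall_time_s = NA_real_,
                limiting_pool = NA_character_, detail = NULL))
  }
  final <- tc$conc[nrow(tc$conc), ]
  pools <- c(ATP = 1e-3, Pi = 0.05, NAD = 1e-3, NADP = 1e-3, CoA = 1e-3)
  depleted <- names(pools)[final[names(pools)] < pools]
  hexP <- sum(final[c("G6P", "F6P", "FBP")] * c(1, 1, 2))
  p_total <- sum(final * conserved_moieties(tc$model, check = FALSE)$total_phosphate[colnames(tc$conc)])
  detail <- list(final_pools = final[names(pools)],
                 hexose_phosphate_P_mM = hexP,
                 hexose_phosphate_P_frac = if (p_total > 0) hexP / p_total else 0)
  list(status = "stalled", stall_time_s = tc$time[stall_idx],
       limiting_pool = if (length(depleted)) depleted else "none",
       detail = detail)
}

#' Analytic pool bounds for a purge-valve-deficient system
#'
#' With the NADH oxidase removed there is no terminal electron acceptor.
#' Producing one monoterpene requires six acetyl-CoA, i.e. six turnovers of
#' the Gap step and six of pyruvate dehydrogenase (twelve nicotinamide
#' reductions), while HMG-CoA reductase re-oxidises only four NADPH per
#' monoterpene. The reversible Gap/mGap pair can interconvert the two pools
#' (forward mGap plus reverse Gap acts as a transhydrogenase), so the eight
#' net reductions per monoterpene are bounded by the combined nicotinamide
#' pool: terpene <= (NAD + NADP pools)/8 (mM). Glucose consumption is
#' bounded too: each glucose processed past the Gap step needs two
#' reductions (of which at most 4 per terpene are recycled by Hmgr), and
#' each glucose merely phosphorylated parks at least one transferable
#' phosphate, so consumed glucose is at most (pools + 4 Tmax)/2 plus the
#' total transferable phosphate pool.
#'
#' @param model A `tf_model` (bounds use its initial state).
#' @return List with `terpene_mM`, `terpene_g_l` and `glucose_mM` bounds.
#' @export
no_purge_bounds <- function(model) {
  stopifnot(inherits(model, "tf_model"))
  init <- model$init
  nad_pool <- init[["NAD"]] + init[["NADH"]]
  nadp_pool <- init[["NADP"]] + init[["NADPH"]]
  t_max <- (nad_pool + nadp_pool) / 8
  p_vec <- conserved_moieties(model, check = FALSE)$total_phosphate
  p_total <- sum(init * p_vec[names(init)])
  g_max <- (nad_pool + nadp_pool + 4 * t_max) / 2 + p_total
  list(terpene_mM = t_max,
       terpene_g_l = t_max * model$metadata$product_mw / 1000,
       glucose_mM = g_max)
}
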