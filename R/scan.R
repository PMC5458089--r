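# Parameter scans, bottleneck identification and purge-valve knockouts —
# the computational experiments over the assembled model.

#' Classify the shape of a scan readout
#'
#' Ties are broken toward `flat`: when the relative spread of the readout is
#' below `flat_tol` the scan is flat regardless of ordering. Otherwise the
#' position of the maximum decides between `interior-maximum` (rises then
#' clearly declines), `monotone-saturating` (the top of the grid is within
#' `edge_tol` of the maximum) and `monotone-decreasing` (the bottom is). The
#' edge tolerance absorbs the few-percent droop a saturating readout can show
#' past its threshold, so `interior-maximum` is reserved for a genuine
#' collapse beyond the optimum.
#'
#' @param values Readout per grid point (grid sorted ascending).
#' @param flat_tol Relative-spread threshold for `flat` (default 0.02).
#' @param edge_tol Relative closeness to the maximum for an endpoint to count
#'   as the maximum (default 0.05).
#' @return One of `"flat"`, `"interior-maximum"`, `"monotone-saturating"`,
#'   `"monotone-decreasing"`.
#' @export
classify_scan_shape <- function(values, flat_tol = 0.02, edge_tol = 0.05) {
  if (length(values) < 2L) return("flat")
  vmax <- max(values)
  if (vmax <= 0 || (vmax - min(values)) / vmax < flat_tol) return("flat")
  near_max <- values >= vmax * (1 - edge_tol)
  n <- length(values)
  if (near_max[n]) return("monotone-saturating")
  if (near_max[1]) return("monotone-decreasing")
  "interior-maximum"
}

#' Scan a parameter and read out the endpoint titre
#'
#' Runs one full simulation per grid point with everything else fixed,
#' reading out the terpene titre at `readout_time`. Fold ranges use a
#' logarithmic grid spanning `[base/sqrt(fold), base*sqrt(fold)]` (total span
#' `fold`), mirroring scans over 10- or 50-fold ranges in 20 steps; explicit
#' `bounds` override the fold range.
#'
#' @param model A `tf_model`.
#' @param target List with `type` (`"vmax"` or `"init"`) and `id` (catalyst
#'   name or species id).
#' @param fold Fold span of the grid (default 10).
#' @param n_steps Number of grid points (default 20; 1 degenerates to a plain
#'   simulation at the base value).
#' @param bounds Optional explicit `c(lo, hi)` bounds (both > 0).
#' @param t_end Simulation horizon in seconds (default 20,000, the model
#'   timescale; use 57,600 s = 16 h for experiment-scale scans).
#' @param readout_time Time of the titre readout (default `t_end`).
#' @param ... Passed to [simulate_timecourse()].
#' @return A `tf_scan_result` data frame (`value`, `terpene_g_l`) with the
#'   shape classification attached.
#' @export
scan_parameter <- function(model, target, fold = 10, n_steps = 20L,
                           bounds = NULL, t_end = 20000,
                           readout_time = t_end, ...) {
  stopifnot(inherits(model, "tf_model"))
  if (!is.list(target) || !all(c("type", "id") %in% names(target)))
    stop("target must be list(type=, id=)", call. = FALSE)
  if (n_steps < 1L) stop("n_steps must be >= 1", call. = FALSE)
  base <- switch(target$type,
                 vmax = get_vmax(model, target$id),
                 init = {
                   if (!target$id %in% model$species$id)
                     stop("unknown species: ", target$id, call. = FALSE)
                   model$init[[target$id]]
                 },
                 stop("target$type must be 'vmax' or 'init'", call. = FALSE))
  if (is.null(bounds)) {
    if (fold <= 1 && n_steps > 1L) stop("fold span must exceed 1", call. = FALSE)
    bounds <- c(base / sqrt(fold), base * sqrt(fold))
  }
  if (any(bounds <= 0)) stop("scan bounds must be positive", call. = FALSE)
  grid <- if (n_steps == 1L) base
          else exp(seq(log(bounds[1]), log(bounds[2]), length.out = n_steps))
  titre <- vapply(grid, function(val) {
    m <- if (target$type == "vmax") set_vmax(model, target$id, val)
         else set_initial(model, target$id, val)
    tc <- simulate_timecourse(m, t_end = t_end, ...)
    stats::approx(tc$time, tc$observables$terpene_g_l, xout = readout_time,
                  rule = 2)$y
  }, 0)
  res <- data.frame(value = grid, terpene_g_l = titre)
  attr(res, "target") <- target
  attr(res, "shape") <- classify_scan_shape(titre)
  attr(res, "readout_time_s") <- readout_time
  class(res) <- c("tf_scan_result", "data.frame")
  res
}

#' @export
print.tf_scan_result <- function(x, ...) {
  tg <- attr(x, "target")
  cat("<tf_scan_result>", tg$type, "scan of", tg$id, "-- shape:",
      attr(x, "shape"), "\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Identify bottleneck enzymes by loading titration
#'
#' Reconstructs the bottleneck-identification procedure: every enzyme except
#' hexokinase is loaded in large excess over Hex (`baseline_fold`), then each
#' in turn is reduced to a small excess (`reduced_fold`) and the reaction is
#' followed for `t_end` seconds. Catalysts whose reduction prevents the run
#' from completing (residual hexose above `threshold_frac` of input) are
#' flagged, ranked by endpoint titre deficit. The glucose load defaults to an
#' amount the Hex-limited baseline can just finish within `t_end`, so a
#' reduced enzyme whose ceiling falls below the required average flux fails
#' visibly. With `respect_model_loadings = TRUE` a probe never raises an
#' enzyme above its value in `model`, so a catalyst already loaded below the
#' reduced excess keeps its (deficient) loading and artificially throttled
#' enzymes are detected; by default probes use the pure fold rule, under
#' which equal baseline and reduced folds change nothing.
#'
#' @param model A `tf_model`.
#' @param baseline_fold Excess of every non-Hex enzyme over Hex in the
#'   baseline (default 250; the procedure uses 250-500).
#' @param reduced_fold Excess the probed enzyme is reduced to (default 5;
#'   the procedure uses 5-10).
#' @param t_end Horizon in seconds (default 20,000).
#' @param glucose_mM Glucose load for the probe runs (default 25).
#' @param threshold_frac Completion threshold for [classify_outcome()].
#' @param respect_model_loadings Cap each probe at the enzyme's loading in
#'   `model` (construct-and-detect mode); default FALSE.
#' @param ... Passed to [simulate_timecourse()].
#' @return Data frame (catalyst, endpoint titre, completed flag, titre
#'   deficit), flagged-and-ranked first; baseline endpoint as attribute.
#' @export
find_bottlenecks <- function(model, baseline_fold = 250, reduced_fold = 5,
                             t_end = 20000, glucose_mM = 25,
                             threshold_frac = 0.01,
                             respect_model_loadings = FALSE, ...) {
  stopifnot(inherits(model, "tf_model"))
  if (baseline_fold <= 1 || reduced_fold <= 1)
    stop("folds must exceed 1", call. = FALSE)
  if (reduced_fold > baseline_fold)
    stop("reduced_fold must not exceed baseline_fold", call. = FALSE)
  hex_u <- get_vmax(model, "Hex")
  others <- setdiff(model$reactions$catalyst, "Hex")
  base_model <- set_initial(model, "Glc", glucose_mM)
  for (cz in others) base_model <- set_vmax(base_model, cz, baseline_fold * hex_u)

  run <- function(m) {
    tc <- simulate_timecourse(m, t_end = t_end, ...)
    list(titre = tc$observables$terpene_g_l[length(tc$time)],
         outcome = classify_outcome(tc, threshold_frac = threshold_frac))
  }
  baseline <- run(base_model)
  if (baseline$outcome$status != "completed")
    warning("baseline (all enzymes in excess) did not complete; ",
            "bottleneck flags may be unreliable")

  rows <- lapply(others, function(cz) {
    probe_u <- reduced_fold * hex_u
    if (respect_model_loadings) probe_u <- min(probe_u, get_vmax(model, cz))
    res <- run(set_vmax(base_model, cz, probe_u))
    data.frame(catalyst = cz,
               terpene_g_l = res$titre,
               completed = res$outcome$status == "completed",
               deficit_g_l = baseline$titre - res$titre)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$completed, -out$deficit_g_l), ]
  rownames(out) <- NULL
  attr(out, "baseline_titre_g_l") <- baseline$titre
  attr(out, "flagged") <- out$catalyst[!out$completed]
  out
}

#' Component knockouts
#'
#' Sets the loading of each listed catalyst to zero (one at a time, unless
#' `combined = TRUE`) and compares endpoint titres against the full system.
#' The defaults mirror the purge-valve leave-one-out experiment: 250 mM
#' glucose, 16 h readout.
#'
#' @param model A `tf_model`.
#' @param components Character vector of catalysts to drop (may be empty).
#' @param glucose_mM Glucose load (default 250).
#' @param t_end Horizon in seconds (default 57,600 = 16 h).
#' @param combined Drop all components in one condition instead of one at a
#'   time.
#' @param ... Passed to [simulate_timecourse()].
#' @return Data frame (condition, terpene_g_l) with the full system first.
#' @export
knockout <- function(model, components = character(), glucose_mM = 250,
                     t_end = 57600, combined = FALSE, ...) {
  stopifnot(inherits(model, "tf_model"))
  components <- sort(unique(components))
  known <- unique(c(model$reactions$catalyst, "TerpeneSynthase"))
  bad <- setdiff(components, known)
  if (length(bad)) stop("unknown component(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  m0 <- set_initial(model, "Glc", glucose_mM)
  endpoint <- function(m) {
    tc <- simulate_timecourse(m, t_end = t_end, ...)
    tc$observables$terpene_g_l[length(tc$time)]
  }
  conditions <- list(full = character())
  if (combined && length(components)) {
    conditions[[paste0("minus_", paste(components, collapse = "_"))]] <- components
  } else {
    for (cz in components) conditions[[paste0("minus_", cz)]] <- cz
  }
  rows <- lapply(names(conditions), function(nm) {
    m <- m0
    for (cz in conditions[[nm]]) m <- set_vmax(m, cz, 0)
    data.frame(condition = nm, terpene_g_l = endpoint(m))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Kinase rebalancing experiment
#'
#' Scales hexokinase by `hex_fold` and the downstream kinase block (Pfk, Mvk,
#' Pmvk, Mdc) by `mevk_pfk_fold` over a full factorial grid, reading out the
#' endpoint titre. Raising the downstream kinases in proportion to an
#' elevated Hex restores the titre lost to hexose-phosphate sequestration.
#'
#' @param model A `tf_model`.
#' @param hex_fold,mevk_pfk_fold Positive fold factors (vectors; full grid).
#' @param glucose_mM Glucose load (default 250).
#' @param t_end Horizon in seconds (default 57,600 = 16 h).
#' @param ... Passed to [simulate_timecourse()].
#' @return Data frame (hex_fold, mevk_pfk_fold, terpene_g_l).
#' @export
rebalance_experiment <- function(model, hex_fold = c(1, 5),
                                 mevk_pfk_fold = c(1, 5),
                                 glucose_mM = 250, t_end = 57600, ...) {
  stopifnot(inherits(model, "tf_model"))
  if (any(hex_fold <= 0) || any(mevk_pfk_fold <= 0))
    stop("folds must be positive", call. = FALSE)
  block <- c("Pfk", "Mvk", "Pmvk", "Mdc")
  base_hex <- get_vmax(model, "Hex")
  base_block <- stats::setNames(vapply(block, function(cz) get_vmax(model, cz), 0),
                                block)
  m0 <- set_initial(model, "Glc", glucose_mM)
  grid <- expand.grid(hex_fold = hex_fold, mevk_pfk_fold = mevk_pfk_fold)
  grid$terpene_g_l <- vapply(seq_len(nrow(grid)), function(i) {
    m <- set_vmax(m0, "Hex", base_hex * grid$hex_fold[i])
    for (cz in block)
      m <- set_vmax(m, cz, base_block[[cz]] * grid$mevk_pfk_fold[i])
    tc <- simulate_timecourse(m, t_end = t_end, ...)
    tc$observables$terpene_g_l[length(tc$time)]
  }, 0)
  grid
}
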