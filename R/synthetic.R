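# Synthetic triplicate assay datasets emulating the day-scale batch
# measurements: terpene titre by GC-FID, residual glucose (total hexose +
# hexose phosphates) by coupled enzyme assay, ATP by luminescence, Pi by
# malachite green. Noise is multiplicative log-normal with per-assay CVs.

.default_cv <- c(terpene_g_l = 0.04, hexose_mM = 0.05,
                 atp_uM = 0.07, pi_mM = 0.05)

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a noisy triplicate assay dataset
#'
#' Simulates the ground-truth trajectory for the requested glucose load,
#' samples the four assay observables at the stated days, and applies
#' independent multiplicative log-normal noise per measurement with the
#' stated CV (mean-unbiased: `meanlog = log(mu) - sdlog^2/2`). Replicates are
#' i.i.d. around the single ground-truth trajectory; values are non-negative
#' by construction and a true zero stays exactly zero. The same seed
#' reproduces the dataset bit for bit.
#'
#' @param model A `tf_model`; its initial glucose is overridden by
#'   `glucose_mM`.
#' @param glucose_mM Glucose load (default 200).
#' @param days Sampling days (sorted, starting at 0; default 0:5).
#' @param cv Named CVs per observable; defaults 0.04 (terpene), 0.05
#'   (hexose), 0.07 (ATP), 0.05 (Pi), matching printed s.d. magnitudes of
#'   3-7%.
#' @param seed Integer seed.
#' @param n_reps Replicates per time point (default 3).
#' @param truth Optional precomputed `tf_timecourse` covering the day grid
#'   (re-used across seeds to avoid repeating the simulation).
#' @return Tidy data frame (day, replicate, observable, value, units) with
#'   the ground-truth table attached as attribute `"ground_truth"`.
#' @export
generate_assay_data <- function(model, glucose_mM = 200, days = 0:5,
                                cv = .default_cv, seed = 1L, n_reps = 3L,
                                truth = NULL) {
  stopifnot(inherits(model, "tf_model"))
  if (!length(days)) stop("empty day grid", call. = FALSE)
  if (is.unsorted(days)) stop("days must be sorted", call. = FALSE)
  cv_full <- .default_cv
  cv_full[names(cv)] <- cv
  if (any(cv_full < 0)) stop("CVs must be >= 0", call. = FALSE)

  if (is.null(truth)) {
    m <- set_initial(model, "Glc", glucose_mM)
    truth <- simulate_timecourse(m, times = unique(c(0, days)) * .S_PER_DAY)
  }
  obs <- truth$observables
  units <- c(terpene_g_l = "g/l", hexose_mM = "mM", atp_uM = "uM", pi_mM = "mM")
  truth_tab <- data.frame(day = days)
  for (o in names(units))
    truth_tab[[o]] <- stats::approx(obs$time_s / .S_PER_DAY, obs[[o]],
                                    xout = days, rule = 2)$y

  dat <- with_seed(seed, {
    rows <- expand.grid(replicate = seq_len(n_reps), day = days,
                        observable = names(units), stringsAsFactors = FALSE)
    rows <- rows[, c("day", "replicate", "observable")]
    rows$value <- vapply(seq_len(nrow(rows)), function(i) {
      mu <- truth_tab[truth_tab$day == rows$day[i], rows$observable[i]]
      s <- sqrt(log(1 + cv_full[[rows$observable[i]]]^2))
      if (mu <= 0 || s == 0) mu
      else stats::rlnorm(1, meanlog = log(mu) - s^2 / 2, sdlog = s)
    }, 0)
    rows
  })
  dat$units <- units[dat$observable]
  rownames(dat) <- NULL
  attr(dat, "ground_truth") <- truth_tab
  attr(dat, "cv") <- cv_full
  attr(dat, "seed") <- seed
  dat
}

#' Recover the yield from an assay dataset
#'
#' Per replicate: glucose consumed is the hexose measurement at day 0 minus
#' the hexose remaining at the final day, and the yield follows from
#' [percent_yield()] on the final titre. Reported as replicate mean with
#' standard deviation, the value-plus-minus-s.d. (n = 3) convention.
#'
#' @param dataset Output of [generate_assay_data()] (or a measured table in
#'   the same tidy layout).
#' @param mw Product molecular weight (g/mol).
#' @return A list of class `tf_yield_report`: per-replicate table, mean and
#'   s.d. of yield and titre, glucose consumed.
#' @export
recover_yield <- function(dataset, mw = MONOTERPENE_MW) {
  need <- c("day", "replicate", "observable", "value")
  if (!all(need %in% names(dataset)))
    stop("dataset must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  d0 <- min(dataset$day); dT <- max(dataset$day)
  if (!any(dataset$day == d0) || d0 != 0)
    stop("dataset must contain day-0 samples", call. = FALSE)
  reps <- sort(unique(dataset$replicate))
  get_val <- function(r, day, obs) {
    v <- dataset$value[dataset$replicate == r & dataset$day == day &
                         dataset$observable == obs]
    if (!length(v)) stop("missing ", obs, " at day ", day, call. = FALSE)
    v[1]
  }
  tab <- do.call(rbind, lapply(reps, function(r) {
    consumed <- get_val(r, d0, "hexose_mM") - get_val(r, dT, "hexose_mM")
    titre <- get_val(r, dT, "terpene_g_l")
    data.frame(replicate = r, titre_g_l = titre,
               glucose_consumed_mM = consumed,
               percent_yield = percent_yield(titre, consumed, mw = mw))
  }))
  structure(
    list(replicates = tab,
         titre_g_l = c(mean = mean(tab$titre_g_l), sd = stats::sd(tab$titre_g_l)),
         glucose_consumed_mM = c(mean = mean(tab$glucose_consumed_mM),
                                 sd = stats::sd(tab$glucose_consumed_mM)),
         percent_yield = c(mean = mean(tab$percent_yield),
                           sd = stats::sd(tab$percent_yield)),
         n = length(reps), mw = mw),
    class = "tf_yield_report"
  )
}

#' @export
print.tf_yield_report <- function(x, ...) {
  cat("<tf_yield_report> n =", x$n, "\n")
  cat(sprintf("  titre: %.3f +/- %.3f g/l\n", x$titre_g_l["mean"], x$titre_g_l["sd"]))
  cat(sprintf("  glucose consumed: %.1f +/- %.1f mM\n",
              x$glucose_consumed_mM["mean"], x$glucose_consumed_mM["sd"]))
  cat(sprintf("  yield: %.1f +/- %.1f %% of theoretical\n",
              x$percent_yield["mean"], x$percent_yield["sd"]))
  invisible(x)
}
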