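# Stoichiometric net-conversion solver and yield/productivity arithmetic.

# orthonormal nullspace basis of A (columns), via SVD
nullspace <- function(A, tol = 1e-9) {
  if (nrow(A) == 0L) return(diag(ncol(A)))
  sv <- svd(A, nu = 0, nv = ncol(A))
  r <- sum(sv$d >= tol * max(sv$d, 1))
  if (r == ncol(A)) return(matrix(0, ncol(A), 0))
  sv$v[, (r + 1L):ncol(A), drop = FALSE]
}

# snap near-rational numbers to fractions with small denominators
snap_rational <- function(x, max_den = 48L, tol = 1e-6) {
  for (d in 1:max_den) {
    y <- round(x * d) / d
    if (all(abs(y - x) < tol)) return(y)
  }
  x
}

#' Net conversion through a reaction subset
#'
#' Finds the unique non-negative combination of reaction fluxes whose net
#' effect consumes the source, produces the sink, and cancels every internal
#' carbon intermediate exactly (a right-nullspace computation on the
#' stoichiometric matrix restricted to the cancelled species). Cofactor pools
#' (ATP/ADP, NAD(H), NADP(H), CoA, Pi, PPi) are reported with their net
#' coefficients; pass them in `frozen` to force their nets to zero, which is
#' what pins down the Gap/mGap flux split in the full system.
#'
#' @param model A `tf_model` (typically a submodule from [subset_model()]).
#' @param source,sink Species ids of the overall substrate and product.
#' @param basis Named scalar fixing the reported scale, e.g. `c(IPP = 1)`
#'   (one unit of sink) or `c(Glc = 1.5)`; default is one unit of sink.
#' @param frozen Species ids whose net coefficient is constrained to zero.
#' @return A `tf_net_conversion` with the flux vector (`flux`), the net
#'   stoichiometry map (`net`, internal intermediates cancelled), and the
#'   per-cofactor nets (`cofactors`).
#' @export
net_conversion <- function(model, source, sink, basis = NULL,
                           frozen = character()) {
  stopifnot(inherits(model, "tf_model"))
  S <- model$stoich
  if (!source %in% rownames(S) || !sink %in% rownames(S))
    stop("source/sink must be model species", call. = FALSE)
  carbon <- stats::setNames(model$species$carbon, model$species$id)
  touched <- rownames(S)[rowSums(abs(S)) > 0]
  internal <- setdiff(touched[carbon[touched] > 0], c(source, sink, "CO2"))
  rows <- unique(c(internal, frozen))
  A <- S[rows, , drop = FALSE]
  N <- nullspace(A)
  if (ncol(N) == 0L) {
    # name an uncancellable intermediate: one consumed or produced by a
    # single reaction is a terminal dead end in the subset
    dead <- internal[vapply(internal, function(s) sum(S[s, ] != 0) == 1L, NA)]
    stop("no feasible net conversion",
         if (length(dead)) paste0("; uncancellable intermediate(s): ",
                                  paste(dead, collapse = ", ")),
         call. = FALSE)
  }
  if (ncol(N) > 1L)
    stop("net conversion is under-determined (nullspace dimension ",
         ncol(N), "); freeze cofactor pools via `frozen`", call. = FALSE)
  v <- as.vector(N[, 1])
  sink_net <- sum(S[sink, ] * v)
  if (abs(sink_net) < 1e-12)
    stop("the reaction subset cannot produce ", sink, call. = FALSE)
  if (sink_net < 0) v <- -v
  if (min(v) < -1e-8 * max(abs(v)))
    stop("no non-negative flux combination exists for this conversion",
         call. = FALSE)
  v[v < 0] <- 0

  # scale to the requested basis
  if (is.null(basis)) basis <- stats::setNames(1, sink)
  b_sp <- names(basis)[1]; b_amt <- basis[[1]]
  b_net <- abs(sum(S[b_sp, ] * v))
  if (b_net < 1e-12)
    stop("basis species ", b_sp, " has zero net in this conversion",
         call. = FALSE)
  v <- v * b_amt / b_net
  v <- snap_rational(v)

  net <- as.vector(S %*% v)
  names(net) <- rownames(S)
  net[abs(net) < 1e-9] <- 0
  net <- snap_rational(net)

  pool_cols <- c("adenine", "nicotinamide_nad", "nicotinamide_nadp", "coenzyme_a")
  pool_sp <- model$species$id[rowSums(model$species[pool_cols] != 0) > 0 &
                                model$species$carbon == 0]
  pool_sp <- union(pool_sp, c("Pi", "PPi"))
  structure(
    list(flux = stats::setNames(v, colnames(S)),
         net = net[net != 0],
         cofactors = net[intersect(pool_sp, names(net))],
         source = source, sink = sink, basis = basis, frozen = frozen),
    class = "tf_net_conversion"
  )
}

#' @export
print.tf_net_conversion <- function(x, ...) {
  fmt <- function(v) paste(sprintf("%s %s", format(MASS::fractions(abs(v))),
                                   names(v)), collapse = " + ")
  consumed <- x$net[x$net < 0]
  produced <- x$net[x$net > 0]
  cat("<tf_net_conversion> basis:", x$basis[[1]], names(x$basis), "\n  ")
  cat(fmt(consumed), "->", fmt(produced), "\n")
  invisible(x)
}

#' Percent of theoretical yield
#'
#' Three glucose are needed per monoterpene, so the theoretical product is
#' (glucose consumed)/3 and
#' `yield = 100 * (titre/MW * 1000) / (glucose_consumed / glucose_per_product)`
#' with the titre in g/l, MW in g/mol and glucose in mM. Yield is computed on
#' glucose consumed, not glucose input.
#'
#' @param titre_g_l Product titre (g/l, >= 0).
#' @param glucose_consumed_mM Glucose consumed (mM, > 0).
#' @param mw Product molecular weight (g/mol), default 136.24.
#' @param glucose_per_product Stoichiometric glucose requirement (default 3).
#' @return Percent of theoretical yield.
#' @export
percent_yield <- function(titre_g_l, glucose_consumed_mM,
                          mw = MONOTERPENE_MW, glucose_per_product = 3) {
  if (any(titre_g_l < 0)) stop("titre must be >= 0", call. = FALSE)
  if (any(!is.finite(glucose_consumed_mM)) || any(glucose_consumed_mM <= 0))
    stop("undefined yield: glucose consumed must be > 0", call. = FALSE)
  if (mw <= 0 || glucose_per_product <= 0)
    stop("mw and glucose_per_product must be > 0", call. = FALSE)
  product_mM <- titre_g_l / mw * 1000
  100 * product_mM / (glucose_consumed_mM / glucose_per_product)
}

#' Invert the yield relation for glucose consumed
#'
#' @param titre_g_l Product titre (g/l, > 0).
#' @param percent Percent of theoretical yield (> 0).
#' @inheritParams percent_yield
#' @return Implied glucose consumption (mM).
#' @export
glucose_consumed_for_yield <- function(titre_g_l, percent,
                                       mw = MONOTERPENE_MW,
                                       glucose_per_product = 3) {
  if (percent <= 0 || titre_g_l <= 0)
    stop("titre and percent must be > 0 for inversion", call. = FALSE)
  titre_g_l / mw * 1000 * glucose_per_product * 100 / percent
}

#' Volumetric productivity
#'
#' Mean productivity over the whole interval, `(titre_end - titre_0)/(t_end -
#' t_0)` in g/l/h, plus optionally the maximum over sliding windows.
#'
#' @param time_h Time stamps in hours (strictly increasing).
#' @param titre_g_l Titres (g/l), same length.
#' @param window_h Optional sliding-window width (hours) for the maximum
#'   windowed productivity.
#' @return List with `mean_g_l_h` and, when requested, `max_window_g_l_h`.
#' @export
productivity <- function(time_h, titre_g_l, window_h = NULL) {
  if (length(time_h) != length(titre_g_l) || length(time_h) < 2L)
    stop("need matching time/titre series of length >= 2", call. = FALSE)
  if (any(diff(time_h) <= 0))
    stop("time must be strictly increasing", call. = FALSE)
  n <- length(time_h)
  out <- list(mean_g_l_h = (titre_g_l[n] - titre_g_l[1]) / (time_h[n] - time_h[1]))
  if (!is.null(window_h)) {
    best <- -Inf
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (time_h[j] - time_h[i] >= window_h) {
          best <- max(best, (titre_g_l[j] - titre_g_l[i]) / (time_h[j] - time_h[i]))
          break
        }
      }
    }
    out$max_window_g_l_h <- if (is.finite(best)) best else out$mean_g_l_h
  }
  out
}

#' Cofactor turnover numbers along a trajectory
#'
#' For each recycled pool, the time-integrated production flux through the
#' pool divided by the pool size: how many times the pool was turned over.
#' ATP counts all ATP-producing flux over the adenine pool, NAD counts NADH
#' production over the NAD pool, NADP counts NADPH production over the NADP
#' pool, CoA counts acetyl-CoA formation over the CoA pool, and Pi counts
#' Pi release over the initial free-phosphate pool. In a completed run the
#' pools turn over many times; a pool that stops near one turnover was
#' consumed stoichiometrically rather than recycled.
#'
#' @param tc A `tf_timecourse` (fluxes are recorded by [simulate_timecourse()]).
#' @return Named numeric vector of turnover counts.
#' @export
cofactor_cycling_summary <- function(tc) {
  stopifnot(inherits(tc, "tf_timecourse"))
  if (is.null(tc$fluxes)) stop("trajectory has no flux records", call. = FALSE)
  S <- tc$model$stoich
  init <- tc$model$init
  trapz <- function(y) sum(diff(tc$time) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  # signed per-reaction contribution, positive part only (reversible
  # reactions produce when running in whichever direction has S[sp,]*v > 0)
  production_of <- function(sp) {
    contrib <- sweep(tc$fluxes, 2, S[sp, ], `*`)
    trapz(rowSums(pmax(contrib, 0)))
  }
  pools <- c(
    ATP = init[["ATP"]] + init[["ADP"]],
    NAD = init[["NAD"]] + init[["NADH"]],
    NADP = init[["NADP"]] + init[["NADPH"]],
    CoA = init[["CoA"]] + init[["AcCoA"]] + init[["AcAcCoA"]] + init[["HMGCoA"]],
    Pi = init[["Pi"]]
  )
  produced <- c(
    ATP = production_of("ATP"),
    NAD = production_of("NADH"),
    NADP = production_of("NADPH"),
    CoA = production_of("AcCoA"),
    Pi = production_of("Pi")
  )
  ifelse(pools > 0, produced / pools, 0)
}
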