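# Non-rectangular hyperbola (NRH) leaf photosynthesis and canopy
# integration. The NRH gives gross assimilation as the lower root of
# theta*A'^2 - (phi*I + Pmax)*A' + phi*I*Pmax = 0, and net A = A' - Rd.

#' Light-response parameters of the non-rectangular hyperbola
#'
#' @param Pmax light-saturated gross capacity (umol CO2 m-2 s-1), > 0.
#' @param phi initial quantum yield (mol CO2 mol-1 photons), in (0, 0.125).
#' @param theta convexity, in (0, 1].
#' @param Rd dark respiration (umol CO2 m-2 s-1), >= 0.
#' @param layer optional "up" or "bottom" tag.
#' @param variety optional variety tag.
#' @return object of class `LightResponseParams`.
#' @export
light_response_params <- function(Pmax, phi, theta, Rd, layer = NULL,
                                  variety = NULL) {
  if (Pmax <= 0) stopf("Pmax must be > 0")
  if (phi <= 0 || phi >= 0.125) stopf("phi must be in (0, 0.125)")
  if (theta < 0 || theta > 1) stopf("theta must be in [0, 1]")
  if (Rd < 0) stopf("Rd must be >= 0")
  structure(list(Pmax = Pmax, phi = phi, theta = theta, Rd = Rd,
                 layer = layer, variety = variety),
            class = "LightResponseParams")
}

#' @export
print.LightResponseParams <- function(x, ...) {
  cat(sprintf("LightResponseParams: Pmax = %.2f, phi = %.4f, theta = %.3f, Rd = %.2f\n",
              x$Pmax, x$phi, x$theta, x$Rd))
  invisible(x)
}

#' Leaf net assimilation from the non-rectangular hyperbola
#'
#' Lower root of the NRH quadratic minus dark respiration; continuous and
#' nondecreasing in `I`. The rectangular-hyperbola limit is used for
#' theta = 0.
#'
#' @param I incident (or absorbed) PPFD, umol m-2 s-1, >= 0, vectorized.
#' @param params a [light_response_params()] object.
#' @return net CO2 assimilation, umol m-2 s-1.
#' @export
leaf_A <- function(I, params) {
  stopifnot(inherits(params, "LightResponseParams"))
  if (any(I < 0)) stopf("PPFD must be >= 0")
  with(params, {
    b <- phi * I + Pmax
    if (theta < 1e-12) {
      gross <- ifelse(b > 0, phi * I * Pmax / b, 0)
    } else {
      disc <- pmax(b^2 - 4 * theta * phi * I * Pmax, 0)
      gross <- (b - sqrt(disc)) / (2 * theta)
    }
    gross - Rd
  })
}

#' Fit the non-rectangular hyperbola to light-response data
#'
#' Nonlinear least squares (Levenberg-Marquardt) with data-driven
#' initialization: Rd from the dark point, phi from the low-light slope,
#' Pmax from the high-light plateau, and box constraints matching the
#' parameter invariants. Non-convergence is reported through the
#' `converged` flag, not an error.
#'
#' @param ppfd,A paired PPFD and net assimilation measurements; at least 6
#'   distinct PPFD levels including a dark (PPFD = 0) point.
#' @param init optional named list overriding the automatic start values.
#' @param lower,upper box constraints in the order (Pmax, phi, theta, Rd).
#' @return list with `params` ([light_response_params()] or `NULL`),
#'   `converged`, `rmse`, `coefficients`, and the `fit` object.
#' @export
fit_light_response <- function(ppfd, A, init = NULL,
                               lower = c(Pmax = 0.5, phi = 1e-4,
                                         theta = 1e-3, Rd = 0),
                               upper = c(Pmax = 150, phi = 0.1249,
                                         theta = 1, Rd = 30)) {
  if (length(ppfd) != length(A)) stopf("ppfd and A must have equal length")
  if (length(unique(ppfd)) < 6) stopf("need >= 6 distinct PPFD levels")
  if (!any(ppfd == 0)) stopf("need a dark (PPFD = 0) point")
  if (sd(A) == 0)   # a constant response carries no light-response signal
    return(list(params = NULL, converged = FALSE, rmse = NA_real_,
                coefficients = NULL, fit = NULL))
  Rd0 <- max(-mean(A[ppfd == 0]), 0.01)
  low <- ppfd > 0 & ppfd <= quantile(ppfd[ppfd > 0], 0.4)
  phi0 <- if (sum(low) >= 2) {
    sl <- coef(lm(A[low] + Rd0 ~ 0 + ppfd[low]))[[1]]
    min(max(sl, 2e-3), 0.12)
  } else 0.05
  Pmax0 <- max(max(A) + Rd0, 1)
  start <- list(Pmax = Pmax0, phi = phi0, theta = 0.8, Rd = Rd0)
  if (!is.null(init)) start <- modifyList(start, init)
  start <- mapply(function(s, lo, hi) min(max(s, lo), hi), start, lower, upper,
                  SIMPLIFY = FALSE)
  nrh <- function(I, Pmax, phi, theta, Rd) {
    b <- phi * I + Pmax
    (b - sqrt(pmax(b^2 - 4 * theta * phi * I * Pmax, 0))) /
      (2 * pmax(theta, 1e-9)) - Rd
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(A ~ nrh(ppfd, Pmax, phi, theta, Rd), start = start,
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(params = NULL, converged = FALSE, rmse = NA_real_,
                coefficients = NULL, fit = NULL))
  cf <- coef(fit)
  params <- tryCatch(
    light_response_params(cf[["Pmax"]], cf[["phi"]], cf[["theta"]], cf[["Rd"]]),
    error = function(e) NULL)
  list(params = params,
       converged = !is.null(params) && fit$convInfo$isConv,
       rmse = sqrt(mean(residuals(fit)^2)),
       coefficients = cf, fit = fit)
}

#' Apparent quantum yield from the low-light slope
#'
#' Ordinary least-squares slope of A against PPFD restricted to the
#' measurement levels 50, 100, 150 and 200 umol m-2 s-1.
#'
#' @param ppfd,A paired measurements containing all four required levels.
#' @return the fitted slope (mol CO2 mol-1 photons).
#' @export
quantum_yield_slope <- function(ppfd, A) {
  levels <- c(50, 100, 150, 200)
  present <- vapply(levels, function(l) any(abs(ppfd - l) < 1e-9), logical(1))
  if (!all(present))
    stopf("missing PPFD levels: %s", paste(levels[!present], collapse = ", "))
  sel <- ppfd %in% levels
  coef(lm(A[sel] ~ ppfd[sel]))[[2]]
}

#' Canopy photosynthesis for one hour
#'
#' Sums facet net assimilation (from the layer's light-response parameters
#' driven by the facet's absorbed PPFD) times facet area over the scored
#' leaf facets, normalized by the scoring-region ground area.
#'
#' @param absorption a [trace()] result.
#' @param params named list of [light_response_params()] with elements
#'   `up` and `bottom` (layer 2 and 1).
#' @param scene the [build_canopy()] scene the absorption was traced on.
#' @return list with `A_c` (umol CO2 m-2 ground s-1), per-layer and
#'   per-leaf breakdowns.
#' @export
canopy_A <- function(absorption, params, scene) {
  facets <- absorption$facets
  sel <- facets$scored & facets$leaf > 0
  region_m2 <- unname(diff(scene$region[c("xmin", "xmax")]) *
                        diff(scene$region[c("ymin", "ymax")])) / 1e4
  if (region_m2 <= 0) stopf("zero ground area")
  f <- facets[sel, , drop = FALSE]
  layer_key <- ifelse(f$layer == 2, "up", "bottom")
  for (k in unique(layer_key))
    if (is.null(params[[k]]))
      stopf("no light-response parameters for layer '%s' (first facet %d)",
            k, f$facet[match(k, layer_key)])
  Aleaf <- numeric(nrow(f))
  for (k in unique(layer_key)) {
    i <- layer_key == k
    Aleaf[i] <- leaf_A(f$absorbed_ppfd[i], params[[k]])
  }
  flux <- Aleaf * f$area_cm2 / 1e4                # umol s-1 per facet
  per_layer <- tapply(flux, layer_key, sum) / region_m2
  per_leaf <- tapply(flux, list(plant = f$plant, leaf = f$leaf), sum) / region_m2
  list(A_c = sum(flux) / region_m2,
       per_layer = per_layer, per_leaf = per_leaf,
       ground_area_m2 = region_m2)
}

#' Diurnal canopy photosynthesis
#'
#' Hourly canopy rates summed to a daily total:
#' `A_c,d = sum(A_c) * 3600 / 1e6` in mol CO2 m-2 ground day-1. By default
#' only daylight hours (nonzero incident flux) contribute; with
#' `include_night = TRUE` dark hours add their respiration term.
#'
#' @param absorptions list of hourly [trace()] results
#'   (see [diurnal_trace()]).
#' @param params as in [canopy_A()].
#' @param scene the canopy scene.
#' @param include_night include dark-hour respiration (default FALSE).
#' @return list with `A_cd` (mol m-2 day-1) and the hourly table.
#' @export
diurnal_canopy_A <- function(absorptions, params, scene,
                             include_night = FALSE) {
  emitted <- vapply(absorptions, function(a) a$totals$emitted, numeric(1))
  use <- if (include_night) rep(TRUE, length(absorptions)) else emitted > 0
  hourly <- data.frame(
    hour = if (!is.null(names(absorptions))) as.numeric(names(absorptions))
           else seq_along(absorptions),
    emitted = emitted, A_c = NA_real_)
  for (i in which(use))
    hourly$A_c[i] <- canopy_A(absorptions[[i]], params, scene)$A_c
  list(A_cd = sum(hourly$A_c[use] * 3600 / 1e6),
       hourly = hourly, include_night = include_night)
}
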