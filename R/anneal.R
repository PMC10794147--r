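#' Temperature protocols
#'
#' A temperature protocol is a continuous piecewise-linear temperature
#' schedule, stored as ordered segments (start/end temperature, duration in
#' hours). Named presets reproduce the experimental anneals: all begin with
#' a melt ramp from 71 to 53 degrees C over 40 min followed by a 1 C/h ramp
#' down to the initial growth temperature, and end with a final cool to 39 C
#' at 1 C per 26 min. Between those, \code{"flag-constant"} holds 47 C for
#' 51 h, \code{"flag-ramp"} ramps 48 to 46 C over 100 h, and
#' \code{"recognition"} ramps 48 to 45 C over 150 h.
#'
#' @param x a preset name, or a data.frame with columns \code{T0, T1,
#'   hours} giving the segments in order.
#' @return object of class \code{TemperatureProtocol}: segment data.frame
#'   with cumulative times \code{t0, t1}.
#' @examples
#' pr <- makeProtocol("recognition")
#' temperatureAt(pr, c(0, 6, 100))
#' @export
makeProtocol <- function(x) {
  if (is.character(x)) {
    pre <- function(Tstart)
      data.frame(T0 = c(71, 53), T1 = c(53, Tstart),
                 hours = c(40 / 60, 53 - Tstart))
    post <- function(Tend)
      data.frame(T0 = Tend, T1 = 39, hours = (Tend - 39) * 26 / 60)
    seg <- switch(x,
      "flag-constant" = rbind(pre(47),
                              data.frame(T0 = 47, T1 = 47, hours = 51),
                              post(47)),
      "flag-ramp" = rbind(pre(48),
                          data.frame(T0 = 48, T1 = 46, hours = 100),
                          post(46)),
      "recognition" = rbind(pre(48),
                            data.frame(T0 = 48, T1 = 45, hours = 150),
                            post(45)),
      stop("unknown protocol preset '", x, "'"))
  } else {
    seg <- as.data.frame(x)
    stopifnot(all(c("T0", "T1", "hours") %in% names(seg)))
  }
  if (any(seg$hours <= 0)) stop("segment durations must be > 0")
  if (nrow(seg) > 1L && any(abs(seg$T0[-1L] - seg$T1[-nrow(seg)]) > 1e-9))
    stop("discontinuous segments: each must start where the previous ended")
  seg$t0 <- cumsum(c(0, seg$hours[-nrow(seg)]))
  seg$t1 <- cumsum(seg$hours)
  class(seg) <- c("TemperatureProtocol", class(seg))
  seg
}

#' @rdname makeProtocol
#' @param protocol a \code{TemperatureProtocol}.
#' @param t times in hours (clamped to the protocol range).
#' @return \code{temperatureAt} returns temperatures in Celsius.
#' @export
temperatureAt <- function(protocol, t) {
  t <- pmin(pmax(t, 0), max(protocol$t1))
  i <- findInterval(t, protocol$t0, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), nrow(protocol))
  frac <- (t - protocol$t0[i]) / protocol$hours[i]
  protocol$T0[i] + frac * (protocol$T1[i] - protocol$T0[i])
}

#' @rdname makeProtocol
#' @return \code{protocolDuration} returns the total duration in hours.
#' @export
protocolDuration <- function(protocol) max(protocol$t1)

## Internal: per-site growth bias of a shape at temperature T under free
## concentrations `pattern`: mean over layout sites of max(0, 1 - e^{dG})
## with dG = Gmc - 2 Gse (two-bond growth-front attachment). Zero at the
## balance point 2 Gse = Gmc, saturating at 1 deep in the growth regime.
.growthBias <- function(layout, pattern, params, tempC) {
  conc <- pattern[layout@grid[!is.na(layout@grid)]]
  gmc <- .gmc(unname(conc), params)
  dg <- gmc - 2 * gseAt(params, tempC)
  mean(pmax(0, 1 - exp(dg)))
}

#' Nucleation and growth rates versus temperature
#'
#' Evaluates, on a temperature grid, a shape's nucleation propensity (log
#' WNM score or log SGM rate at each temperature) and its growth bias (the
#' mean net two-bond attachment bias per growth site, zero at the balance
#' point \code{2 Gse = Gmc}). Nucleation requires temperature-dependent
#' bond energies (\code{\link{energyParams}} temperature mode). Rates are in
#' arbitrary consistent units; only ratios and crossing temperatures are
#' meaningful.
#'
#' @param layout a \linkS4class{ShapeLayout}.
#' @param pattern named concentrations (nM).
#' @param params an \linkS4class{EnergyParams} in temperature mode.
#' @param tempGrid temperatures (Celsius).
#' @param method "wnm" or "sgm" for the nucleation propensity.
#' @param k WNM window size.
#' @param nPaths SGM paths per start site.
#' @param seed optional integer seed (SGM).
#' @return data.frame with columns \code{tempC, Gse, logEta, growth}.
#' @export
ratesVsTemperature <- function(layout, pattern, params, tempGrid,
                               method = c("wnm", "sgm"), k = 2, nPaths = 20,
                               seed = NULL) {
  method <- match.arg(method)
  if (!length(tempGrid)) stop("empty temperature grid")
  logEta <- vapply(tempGrid, function(tc) {
    if (method == "wnm")
      attr(wnmScore(layout, pattern, params, k = k, tempC = tc), "logScore")
    else
      sgmEstimateRate(layout, pattern, params, nPaths = nPaths,
                      tempC = tc, seed = seed)$logRate
  }, numeric(1))
  growth <- vapply(tempGrid, function(tc)
    .growthBias(layout, pattern, params, tc), numeric(1))
  data.frame(tempC = tempGrid, Gse = gseAt(params, tempGrid),
             logEta = logEta, growth = growth)
}

#' Simulate competitive nucleation and growth over an anneal
#'
#' Mean-field winner-take-all model: as the protocol cools, each shape
#' nucleates new assemblies at a rate that switches on when its
#' (concentration-dependent) window nucleation score crosses unity, and
#' every incomplete assembly grows at the shape's growth bias, consuming its
#' constituent tiles pro rata from the shared free pool. Depletion of shared
#' tiles feeds back into the nucleation scores, and nucleation of a shape
#' shuts off entirely once any of its tiles falls below a floor fraction of
#' its initial concentration. Integration is explicit Euler with
#' proportional throttling so that free concentrations never go negative;
#' tile conservation (free + incorporated = initial) holds to numerical
#' tolerance at every step.
#'
#' @param system a \linkS4class{TileSystem}.
#' @param pattern named initial concentrations (nM) over all tiles.
#' @param protocol a \code{TemperatureProtocol}.
#' @param params an \linkS4class{EnergyParams} in temperature mode.
#' @param target the on-target shape name (defaults to the shape with the
#'   highest initial nucleation score).
#' @param kNuc nucleation rate scale (nM of assemblies per hour at
#'   saturation).
#' @param kGrow growth rate scale (tiles per hour per assembly at
#'   saturation).
#' @param seedSize tiles consumed by each nucleation event.
#' @param floorFrac nucleation shuts off for a shape when any of its tiles
#'   drops below this fraction of its initial concentration.
#' @param dt Euler step in hours.
#' @param k WNM window size for the nucleation score.
#' @param record record the state every this many hours.
#' @return object of class \code{WTATrajectory}: list with
#'   \code{trajectory} (data.frame: time_h, temp_C, per-shape nucleated nM
#'   and mass, selectivity), \code{selectivity} (final on-target fraction of
#'   nucleation, NA if nothing nucleated), \code{nucleated} (final per-shape
#'   totals), \code{target}, \code{conservationError} (max absolute
#'   deviation of free + incorporated from the initial concentrations, nM).
#' @export
simulateWTA <- function(system, pattern, protocol, params, target = NULL,
                        kNuc = 0.05, kGrow = 20, seedSize = 3,
                        floorFrac = 0.01, dt = 0.25, k = 2, record = 5) {
  shapes <- names(layouts(system))
  lys <- layouts(system)
  sizes <- vapply(lys, function(l) sum(!is.na(l@grid)), numeric(1))
  tilesOf <- lapply(lys, function(l) l@grid[!is.na(l@grid)])
  c0 <- fullPattern(system, pattern, fill = 0)
  if (any(c0 <= 0)) stop("pattern must cover every tile with c > 0")
  free <- c0
  bound <- stats::setNames(rep(0, length(c0)), names(c0))
  N <- M <- stats::setNames(rep(0, length(shapes)), shapes)
  tEnd <- protocolDuration(protocol)
  times <- seq(0, tEnd, by = dt)
  recAt <- seq(0, tEnd, by = record)
  traj <- vector("list", length(recAt))
  ri <- 1L
  logScore <- function(sh, tc)
    tryCatch(attr(wnmScore(lys[[sh]], free, params, k = k, tempC = tc),
                  "logScore"),
             error = function(e) -Inf)
  if (is.null(target)) {
    tc0 <- temperatureAt(protocol, 0)
    s0 <- vapply(shapes, logScore, numeric(1), tc = tc0)
    target <- shapes[which.max(s0)]
  }
  for (t in times) {
    tc <- temperatureAt(protocol, t)
    ls <- vapply(shapes, logScore, numeric(1), tc = tc)
    eta <- kNuc * stats::plogis(ls)          # saturating switch at score ~ 1
    for (sh in shapes) {
      if (any(free[tilesOf[[sh]]] < floorFrac * c0[tilesOf[[sh]]]))
        eta[[sh]] <- 0
    }
    g <- vapply(shapes, function(sh)
      kGrow * .growthBias(lys[[sh]], pmax(free, 1e-12), params, tc),
      numeric(1))
    active <- pmax(0, N - M / sizes)
    dN <- eta * dt
    dM <- pmin(g * active * dt, pmax(0, N * sizes - M)) + seedSize * dN
    ## per-tile demand, pro rata over each shape's tiles
    demand <- stats::setNames(rep(0, length(c0)), names(c0))
    for (i in seq_along(shapes)) {
      sh <- shapes[[i]]
      if (dM[[i]] > 0)
        demand[tilesOf[[sh]]] <- demand[tilesOf[[sh]]] + dM[[i]] / sizes[[i]]
    }
    ## per-shape throttling: a shape is limited by its own scarcest tile
    ## (shared tiles limit every shape that uses them)
    fTile <- ifelse(demand > 0, pmin(1, free / demand), 1)
    thr <- vapply(shapes, function(sh) min(fTile[tilesOf[[sh]]]), numeric(1))
    dN <- dN * thr; dM <- dM * thr
    demand[] <- 0
    for (i in seq_along(shapes)) {
      sh <- shapes[[i]]
      if (dM[[i]] > 0)
        demand[tilesOf[[sh]]] <- demand[tilesOf[[sh]]] + dM[[i]] / sizes[[i]]
    }
    free <- pmax(free - demand, 0)   # clamp float round-off
    bound <- bound + demand
    N <- N + dN
    M <- M + dM
    if (ri <= length(recAt) && t >= recAt[ri] - 1e-9) {
      row <- data.frame(time_h = t, temp_C = tc, stringsAsFactors = FALSE)
      for (sh in shapes) {
        row[[paste0("nuc_", sh)]] <- N[[sh]]
        row[[paste0("mass_", sh)]] <- M[[sh]]
      }
      row$selectivity <- if (sum(N) > 0) N[[target]] / sum(N) else NA_real_
      traj[[ri]] <- row
      ri <- ri + 1L
    }
  }
  consErr <- max(abs(free + bound - c0))
  structure(list(trajectory = do.call(rbind, traj[seq_len(ri - 1L)]),
                 selectivity = if (sum(N) > 0) N[[target]] / sum(N) else NA_real_,
                 nucleated = N, mass = M, target = target,
                 conservationError = consErr, freeFinal = free),
            class = "WTATrajectory")
}

#' @export
print.WTATrajectory <- function(x, ...) {
  cat(sprintf("WTATrajectory: target '%s', selectivity %s\n", x$target,
              if (is.na(x$selectivity)) "undefined (no nucleation)"
              else sprintf("%.3f", x$selectivity)))
  print(round(x$nucleated, 4))
  invisible(x)
}
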