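#' @include synthetic-data.R
NULL

#' Protocols referenced by the shape fixtures
#'
#' OGD/R protocols of varying OGD duration plus an FGF co-treatment arm
#' (FGF 1 ug/ml added at OGD onset).
#' @return named list of StimulusProtocol.
#' @export
fixtureProtocols <- function() {
  fgf <- makeOGDRProtocol(6, 24)
  fgf@phases[[1]]$ligand_doses <- c(FGF = convertDose(1000, 17500, 1e6))
  list(ogdr_1_24 = makeOGDRProtocol(1, 24),
       ogdr_3_24 = makeOGDRProtocol(3, 24),
       ogdr_6_24 = makeOGDRProtocol(6, 24),
       ogdr_24_24 = makeOGDRProtocol(24, 24),
       ogdr_6_24_fgf = fgf)
}

#' Default qualitative-shape fixtures
#'
#' Machine-checkable encodings of the qualitative OGD/R dynamics:
#' succinate accumulation during OGD and rapid oxidation on
#' reoxygenation, the post-reoxygenation ROS peak, the pAMPK double peak
#' (second peak 4-8 h post-reox), the p53 rise-and-return, HIF1a rise and
#' decline, cytokine monotonicity in OGD duration, growth-factor return
#' to baseline, OGD-duration-dependent Caspase3 reversibility, and
#' ROS-driven ZO-1/Claudin5 decline with FGF attenuation. Tolerances are
#' declared in \code{inst/extdata/shape_fixtures.yaml}.
#'
#' @return named list of fixtures (observable, protocol(s), constraint
#'   spec).
#' @export
defaultShapeFixtures <- function() {
  path <- system.file("extdata", "shape_fixtures.yaml", package = "bmecsim")
  if (!nzchar(path)) stop("fixture file not found")
  yaml::read_yaml(path)
}

.interp <- function(traj, observable, t) {
  stats::approx(traj@times, speciesSeries(traj, observable), xout = t,
                rule = 2)$y
}

.windowSeries <- function(traj, observable, window = NULL) {
  sel <- traj@times >= 0
  if (!is.null(window))
    sel <- traj@times >= window[1] & traj@times <= window[2]
  list(t = traj@times[sel], y = speciesSeries(traj, observable)[sel])
}

# local maxima with a simple prominence filter (fraction of series range)
.peaks <- function(t, y, minProm = 0.05) {
  idx <- which(diff(sign(diff(y))) < 0) + 1L
  if (!length(idx)) return(data.frame(t = numeric(0), y = numeric(0)))
  rng <- diff(range(y))
  keep <- vapply(idx, function(i) {
    left <- y[seq_len(i)]
    right <- y[seq(i, length(y))]
    hiL <- which(left > y[i])
    hiR <- which(right > y[i])
    vL <- min(left[seq(if (length(hiL)) max(hiL) else 1, i)])
    vR <- min(right[seq_len(if (length(hiR)) min(hiR) else length(right))])
    (y[i] - max(vL, vR)) >= minProm * rng
  }, logical(1))
  data.frame(t = t[idx[keep]], y = y[idx[keep]])
}

#' Evaluate one shape fixture against trajectories
#'
#' @param fixture one element of \code{\link{defaultShapeFixtures}}.
#' @param trajs named list of trajectories covering the fixture's
#'   protocol(s); baselines are taken at each trajectory's stimulus start.
#' @return list(pass, detail).
#' @export
evaluateFixture <- function(fixture, trajs) {
  obs <- fixture$observable
  protos <- fixture$protocol
  if (!is.null(fixture$protocols)) protos <- unlist(fixture$protocols)
  missing <- setdiff(protos, names(trajs))
  if (length(missing))
    stop("missing trajectories for protocol(s): ",
         paste(missing, collapse = ", "))
  tr <- trajs[[protos[1]]]
  base <- stimulusBaseline(tr)[obs]
  res <- switch(fixture$constraint,
    monotone_increasing = {
      w <- .windowSeries(tr, obs, unlist(fixture$window))
      ok <- all(diff(w$y) > -1e-9 * max(abs(w$y)))
      list(ok, sprintf("min step %.3g", min(diff(w$y))))
    },
    drop_after = {
      at <- fixture$at
      peak <- .interp(tr, obs, at)
      later <- .interp(tr, obs, at + fixture$within)
      rise <- peak - base
      ok <- rise > 0 && (peak - later) >= fixture$fraction_of_rise * rise
      list(ok, sprintf("dropped %.0f%% of rise", 100 * (peak - later) /
                         max(rise, 1e-12)))
    },
    peak_after = {
      w <- .windowSeries(tr, obs)
      ok <- w$t[which.max(w$y)] > fixture$t
      list(ok, sprintf("max at t=%.2f h", w$t[which.max(w$y)]))
    },
    two_peaks = {
      w <- .windowSeries(tr, obs)
      pk <- .peaks(w$t, w$y, fixture$min_prominence)
      w1 <- unlist(fixture$first_window); w2 <- unlist(fixture$second_window)
      in1 <- any(pk$t > w1[1] & pk$t <= w1[2])
      in2 <- any(pk$t >= w2[1] & pk$t <= w2[2])
      list(in1 && in2,
           paste("peaks at", paste(sprintf("%.1f", pk$t), collapse = ", ")))
    },
    rise_and_return = {
      w <- .windowSeries(tr, obs, unlist(fixture$peak_window))
      final <- .interp(tr, obs, max(tr@times))
      ok <- max(w$y) >= fixture$peak_factor * base &&
        final >= fixture$final_band[[1]] * base &&
        final <= fixture$final_band[[2]] * base
      list(ok, sprintf("peak %.2fx, final %.2fx", max(w$y) / base,
                       final / base))
    },
    elevated_then_declining = {
      atv <- .interp(tr, obs, fixture$at)
      w <- unlist(fixture$decline_window)
      ok <- atv >= fixture$factor * base &&
        .interp(tr, obs, w[2]) < .interp(tr, obs, w[1])
      list(ok, sprintf("%.2fx at t=%g", atv / base, fixture$at))
    },
    endpoint_monotone_across = {
      ends <- vapply(protos, function(p) {
        t2 <- trajs[[p]]
        .interp(t2, obs, max(t2@times)) / stimulusBaseline(t2)[obs]
      }, numeric(1))
      list(all(diff(ends) > -1e-6),
           paste(sprintf("%.2f", ends), collapse = " <= "))
    },
    pulse_return = {
      w <- .windowSeries(tr, obs)
      final <- w$y[length(w$y)]
      ok <- max(w$y) >= fixture$peak_factor * base &&
        final >= fixture$final_band[[1]] * base &&
        final <= fixture$final_band[[2]] * base
      list(ok, sprintf("peak %.2fx, final %.2fx", max(w$y) / base,
                       final / base))
    },
    decline_after_peak = {
      w <- .windowSeries(tr, obs, c(fixture$window_start, max(tr@times)))
      final <- w$y[length(w$y)]
      list(final <= fixture$final_max_fraction * max(w$y),
           sprintf("final/max = %.2f", final / max(w$y)))
    },
    stays_near_max = {
      w <- .windowSeries(tr, obs, c(fixture$window_start, max(tr@times)))
      final <- w$y[length(w$y)]
      list(final >= fixture$final_min_fraction * max(w$y),
           sprintf("final/max = %.2f", final / max(w$y)))
    },
    final_below = {
      final <- .interp(tr, obs, max(tr@times))
      list(final < fixture$factor * base,
           sprintf("final %.2fx baseline", final / base))
    },
    endpoint_higher_in_second = {
      e1 <- .interp(trajs[[protos[1]]], obs, max(trajs[[protos[1]]]@times))
      t2 <- trajs[[protos[2]]]
      e2 <- .interp(t2, obs, max(t2@times))
      list(e2 > e1, sprintf("%.3g vs %.3g", e2, e1))
    },
    stop("unknown constraint: ", fixture$constraint))
  list(pass = isTRUE(res[[1]]), detail = res[[2]])
}

#' Check all shape fixtures against a model
#'
#' Runs each protocol referenced by the fixtures once and evaluates every
#' fixture.
#'
#' @param network a ReactionNetwork.
#' @param params ParameterSet.
#' @param fixtures fixture list (default \code{\link{defaultShapeFixtures}}).
#' @param state quiescent starting state.
#' @param settings integration settings.
#' @return data.frame(fixture, pass, detail).
#' @export
checkShapeFixtures <- function(network, params = defaultParameters(network),
                               fixtures = defaultShapeFixtures(),
                               state = initialState(network),
                               settings = simSettings()) {
  protos <- fixtureProtocols()
  needed <- unique(unlist(lapply(fixtures, function(f)
    c(f$protocol, unlist(f$protocols)))))
  trajs <- lapply(protos[needed], function(p)
    runProtocol(network, params, state, p, settings))
  rows <- lapply(names(fixtures), function(id) {
    r <- evaluateFixture(fixtures[[id]], trajs)
    data.frame(fixture = id, pass = r$pass, detail = r$detail,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
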