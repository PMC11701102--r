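#' Fit a helical lattice model to a ring of spokes
#'
#' The central estimator of the package. Given per-spoke anchor points —
#' either an [anchor_set()] / coordinate matrix, or a `structure_model`
#' plus an ordered chain list from which anchors are extracted — it fits
#' the helical axis ([fit_axis()]) and estimates the lattice parameters
#' radius, twist per spoke and rise per spoke ([helical_parameters()]),
#' returning a classed model object with the usual accessor methods.
#'
#' For a gamma-tubulin ring complex the spokes are the gamma-tubulin
#' copies in ring order and the conventional anchor is the C-alpha of
#' Gln12; a ring in the microtubule-nucleation-competent ("closed")
#' conformation reproduces the 13-protofilament microtubule lattice
#' (see [microtubule_13pf_params()], [compare_lattices()]).
#'
#' @param x An `anchor_set`, an N x 3 coordinate matrix (spoke order), or
#'   a `structure_model`.
#' @param chains When `x` is a `structure_model`: chain ids in ring order.
#' @param residue,atom Anchor rule when extracting from a structure
#'   (defaults: residue 12, atom `"CA"`).
#' @param ... Unused.
#' @return Object of class `helix_fit`: list with `anchors`, `axis`
#'   (`helix_axis`), `params` (`helical_params`), `fitted` (ideal lattice
#'   positions), and `call`.
#' @examples
#' ring <- make_ring(n_spokes = 14, radius = 102.5, twist = 27.6,
#'                   rise = 9.2, noise_sd = 1, seed = 1)
#' fit <- helix_fit(ring$model, chains = ring$chains)
#' coef(fit)
#' summary(fit)
#' compare_lattices(fit, microtubule_13pf_params())
#' @export
helix_fit <- function(x, chains = NULL, residue = 12, atom = "CA", ...) {
  cl <- match.call()
  anchors <- if (inherits(x, "structure_model")) {
    if (is.null(chains)) stop("helix_fit on a structure needs an ordered chain list",
                              call. = FALSE)
    extract_anchors(x, chains = chains, residue = residue, atom = atom)
  } else if (inherits(x, "anchor_set")) {
    x
  } else {
    anchor_set(x)
  }
  axis <- fit_axis(anchors)
  params <- helical_parameters(anchors, axis)
  obj <- structure(list(anchors = anchors, axis = axis, params = params,
                        call = cl),
                   class = "helix_fit")
  obj$fitted <- predict(obj)
  obj
}

#' @export
coef.helix_fit <- function(object, ...) {
  p <- object$params
  c(radius = p$radius_mean, twist = p$twist_mean, rise = p$rise_mean)
}

#' @export
print.helix_fit <- function(x, ...) {
  cat("Helical lattice fit\n")
  cat("Call: ", deparse(x$call), "\n\n")
  print(x$params)
  invisible(x)
}

#' @export
summary.helix_fit <- function(object, ...) {
  res <- residuals(object)
  structure(list(fit = object,
                 rms_residual = sqrt(mean(rowSums(res^2))),
                 max_residual = max(sqrt(rowSums(res^2)))),
            class = "summary.helix_fit")
}

#' @export
print.summary.helix_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("\nresiduals vs ideal lattice: RMS %.3f Angstrom, max %.3f Angstrom\n",
              x$rms_residual, x$max_residual))
  p <- x$fit$params
  cat(sprintf("per-step spread: twist SD %.3f deg, rise SD %.3f Angstrom (n = %d steps)\n",
              p$twist_sd, p$rise_sd, p$n_steps))
  invisible(x)
}

#' Ideal lattice positions from a fitted helix
#'
#' Returns the positions of an ideal helix with the fitted mean radius,
#' twist and rise, phased by least squares to the observed anchors: the
#' angular origin and axial offset are the circular / ordinary means of
#' the per-spoke deviations from a uniform lattice.
#'
#' @param object A `helix_fit`.
#' @param spokes Integer spoke indices (default: the fitted spokes).
#' @param ... Unused.
#' @return Matrix of 3-D positions, one row per requested spoke.
#' @export
predict.helix_fit <- function(object, spokes = NULL, ...) {
  p <- object$params
  d <- p$detail
  n <- p$n_points
  if (is.null(spokes)) spokes <- seq_len(n)
  sense <- if (p$handedness == "right") 1 else -1
  # phase: mean deviation of observed angles from a uniform lattice
  k <- seq_len(n) - 1
  theta_ideal_obs <- sense * p$twist_mean * k
  dphi <- (d$theta - theta_ideal_obs + 180) %% 360 - 180
  phi0 <- mean(dphi) + theta_ideal_obs[1] - sense * p$twist_mean * 0
  z0 <- mean(d$z - p$rise_mean * k)
  u <- object$axis$direction
  B <- perp_basis(u)
  kk <- spokes - 1
  th <- (phi0 + sense * p$twist_mean * kk) * pi / 180
  zz <- z0 + p$rise_mean * kk
  out <- t(vapply(seq_along(kk), function(i) {
    object$axis$origin + p$radius_mean *
      (cos(th[i]) * B[, 1] + sin(th[i]) * B[, 2]) + zz[i] * u
  }, numeric(3)))
  colnames(out) <- c("x", "y", "z")
  out
}

#' @export
residuals.helix_fit <- function(object, ...) {
  object$anchors$points - predict(object)
}

#' Simulate rings from a fitted helical lattice
#'
#' Draws new synthetic rings with the fitted radius/twist/rise and a
#' coordinate noise level estimated from the fit residuals (RMS per-axis
#' deviation), via [make_ring()].
#'
#' @param object A `helix_fit`.
#' @param nsim Number of rings.
#' @param seed Integer seed.
#' @param noise_sd Coordinate noise; default: estimated from residuals.
#' @param ... Unused.
#' @return List of `nsim` outputs of [make_ring()].
#' @export
simulate.helix_fit <- function(object, nsim = 1, seed = 1, noise_sd = NULL, ...) {
  p <- coef(object)
  if (is.null(noise_sd)) {
    res <- residuals(object)
    noise_sd <- sqrt(mean(res^2))
  }
  lapply(seq_len(nsim), function(i) {
    make_ring(n_spokes = object$params$n_points, radius = p[["radius"]],
              twist = p[["twist"]], rise = p[["rise"]],
              noise_sd = noise_sd, seed = seed + i - 1L)
  })
}

#' Plot a fitted helical lattice
#'
#' Two panels: the anchors projected onto the plane perpendicular to the
#' fitted axis (with the fitted circle), and the per-step twist and rise
#' values with their means.
#'
#' @param x A `helix_fit`.
#' @param ... Passed to plotting functions.
#' @export
plot.helix_fit <- function(x, ...) {
  p <- x$params
  d <- p$detail
  u <- x$axis$direction
  B <- perp_basis(u)
  cen <- sweep(x$anchors$points, 2, x$axis$origin)
  a <- cen %*% B[, 1]; b <- cen %*% B[, 2]
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  lim <- range(a, b) * 1.1
  plot(a, b, asp = 1, xlim = lim, ylim = lim,
       xlab = "in-plane x (Angstrom)", ylab = "in-plane y (Angstrom)",
       main = "axis-normal projection", pch = 19, ...)
  tt <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(p$radius_mean * cos(tt), p$radius_mean * sin(tt),
                  col = "grey60")
  graphics::text(a, b, labels = x$anchors$labels$spoke, pos = 3, cex = 0.7)
  steps <- seq_len(p$n_steps)
  plot(steps, d$twist_steps, type = "b", pch = 19, col = "steelblue",
       ylim = range(d$twist_steps, d$rise_steps),
       xlab = "step", ylab = "twist (deg) / rise (Angstrom)",
       main = "per-step lattice values")
  graphics::points(steps, d$rise_steps, type = "b", pch = 17, col = "tomato")
  graphics::abline(h = c(p$twist_mean, p$rise_mean),
                   col = c("steelblue", "tomato"), lty = 2)
  graphics::legend("topright", legend = c("twist", "rise"),
                   col = c("steelblue", "tomato"), pch = c(19, 17), bty = "n")
  invisible(x)
}
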