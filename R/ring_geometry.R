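#' Extract per-spoke anchor points from a ring structure
#'
#' Picks one anchor atom per spoke (chain), in the supplied ring order. For
#' gamma-tubulin ring complexes the conventional anchor is the C-alpha of
#' Gln12 of each gamma-tubulin copy (Gln15 of alpha-tubulin for a
#' microtubule reference lattice).
#'
#' @param model A `structure_model`.
#' @param chains Character vector of chain ids in ring (spoke) order.
#' @param residue Author residue number of the anchor (default 12).
#' @param atom Anchor atom name (default `"CA"`).
#' @return An object of class `anchor_set`: list with `points` (N x 3
#'   matrix, Angstrom), `labels` (data.frame `spoke`, `chain`) and `source`
#'   (anchor rule description).
#' @examples
#' ring <- make_ring(n_spokes = 14, seed = 3)
#' anchors <- extract_anchors(ring$model, chains = ring$chains)
#' nrow(anchors$points)
#' @export
extract_anchors <- function(model, chains, residue = 12, atom = "CA") {
  stopifnot(inherits(model, "structure_model"), length(chains) >= 1)
  pts <- matrix(NA_real_, nrow = length(chains), ncol = 3,
                dimnames = list(chains, c("x", "y", "z")))
  for (i in seq_along(chains)) {
    hit <- select_atoms(model, selection(chains = chains[i],
                                         residues = residue, atoms = atom))
    if (nrow(hit) == 0L) {
      stop("anchor atom ", atom, " not found at residue ", residue,
           " of chain '", chains[i], "'", call. = FALSE)
    }
    pts[i, ] <- as.numeric(hit[1, c("x", "y", "z")])
  }
  anchor_set(pts, chains = chains,
             source = sprintf("residue %d atom %s", residue, atom))
}

#' Construct an anchor set from raw points
#'
#' @param points N x 3 numeric matrix of anchor coordinates (Angstrom),
#'   rows in spoke order.
#' @param chains Optional per-point chain labels.
#' @param source Description of the anchor rule.
#' @return An `anchor_set` object.
#' @export
anchor_set <- function(points, chains = NULL, source = "points") {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, all(is.finite(points)))
  n <- nrow(points)
  if (is.null(chains)) chains <- as.character(seq_len(n))
  structure(list(points = points,
                 labels = data.frame(spoke = seq_len(n),
                                     chain = as.character(chains),
                                     stringsAsFactors = FALSE),
                 source = source),
            class = "anchor_set")
}

#' @export
print.anchor_set <- function(x, ...) {
  cat("anchor_set:", nrow(x$points), "points (", x$source, ")\n")
  invisible(x)
}

as_points <- function(x) {
  if (inherits(x, "anchor_set")) x$points else as.matrix(x)
}

unit <- function(v) v / sqrt(sum(v^2))

# orthonormal basis perpendicular to unit vector u
perp_basis <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit(ref - sum(ref * u) * u)
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  cbind(e1, e2)
}

dir_from_angles <- function(theta, phi) {
  c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}

# variance of radial distances about an axis (origin o, direction u)
radial_var <- function(pts, o, u) {
  d <- sweep(pts, 2, o)
  ax <- d %*% u
  rad2 <- rowSums(d^2) - ax^2
  r <- sqrt(pmax(rad2, 0))
  mean((r - mean(r))^2)
}

# axis-fit objective: variance of radial distances plus variance of the
# per-step rise. A true helical lattice zeroes both; the rise term breaks
# the ties that the radial term alone leaves for small anchor counts
# (several axes can be exactly equidistant from 5 points) and sharpens
# the valley for wide shallow arcs.
axis_objective <- function(pts, o, u) {
  d <- sweep(pts, 2, o)
  ax <- as.numeric(d %*% u)
  rad2 <- rowSums(d^2) - ax^2
  r <- sqrt(pmax(rad2, 0))
  dz <- diff(ax)
  mean((r - mean(r))^2) + mean((dz - mean(dz))^2)
}

# algebraic (Kasa) circle-centre fit of points projected onto the plane
# perpendicular to direction u; exact for noise-free helices at the true
# direction, and a robust origin initialiser for short arcs
kasa_center <- function(pts, ctr, u) {
  B <- perp_basis(u)
  d <- sweep(pts, 2, ctr)
  a <- as.numeric(d %*% B[, 1])
  b <- as.numeric(d %*% B[, 2])
  X <- cbind(2 * a, 2 * b, 1)
  co <- tryCatch(qr.solve(X, a^2 + b^2), error = function(e) c(0, 0, 0))
  c(co[1], co[2])
}

#' Fit the helical axis of a ring of anchor points
#'
#' Two-stage fit: (1) candidate initial directions are the principal
#' components of the centred points, each paired with an in-plane origin
#' from an algebraic circle fit of the projected points; (2) four
#' parameters (two direction angles and two in-plane origin offsets) are
#' refined by nonlinear least squares minimising the variance of
#' point-axis radial distances plus the variance of the per-step rise —
#' both vanish on an ideal helical lattice, and the rise term makes the
#' axis identifiable even for rings of very few spokes, where several
#' axes can be exactly equidistant from the anchors. The best of the
#' three refined starts is returned, so the fit is deterministic for a
#' fixed input. The direction sign is fixed so that the mean per-step
#' rise along the axis is non-negative.
#'
#' @param anchors An `anchor_set` (or N x 3 matrix) with N >= 4
#'   non-collinear points, in spoke order.
#' @return An object of class `helix_axis`: list with `origin` (a point on
#'   the axis, Angstrom) and `direction` (unit 3-vector).
#' @examples
#' ring <- make_ring(n_spokes = 14, radius = 102.5, twist = 27.6,
#'                   rise = 9.2, seed = 1)
#' fit_axis(ring$anchors)
#' @export
fit_axis <- function(anchors) {
  pts <- as_points(anchors)
  n <- nrow(pts)
  if (n < 4L) stop("axis fitting needs at least 4 anchor points", call. = FALSE)
  ctr <- colMeans(pts)
  cen <- sweep(pts, 2, ctr)
  sv <- svd(cen, nu = 0)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1)) {
    stop("degenerate anchor geometry: points are collinear or coincident",
         call. = FALSE)
  }
  obj <- function(p) {
    u <- dir_from_angles(p[1], p[2])
    B <- perp_basis(u)
    o <- ctr + B %*% c(p[3], p[4])
    axis_objective(pts, as.numeric(o), u)
  }
  # refine from every principal-component direction (with the in-plane
  # origin initialised by an algebraic circle fit) and keep the best
  # minimum: short arcs have local minima that a single start can hit
  polish <- function(p0) {
    o1 <- stats::nlminb(p0, obj,
                        control = list(eval.max = 5000, iter.max = 2000,
                                       rel.tol = 1e-15, x.tol = 1e-14))
    # re-centre on the algebraic circle fit at the refined direction and
    # polish again; removes residual origin bias on flat valleys
    u1 <- dir_from_angles(o1$par[1], o1$par[2])
    p1 <- c(o1$par[1], o1$par[2], kasa_center(pts, ctr, u1))
    o2 <- stats::nlminb(p1, obj,
                        control = list(eval.max = 5000, iter.max = 2000,
                                       rel.tol = 1e-15, x.tol = 1e-14))
    if (o2$objective < o1$objective) o2 else o1
  }
  best <- NULL
  for (k in 1:3) {
    u0 <- sv$v[, k]
    theta0 <- acos(max(-1, min(1, u0[3])))
    phi0 <- atan2(u0[2], u0[1])
    opt <- polish(c(theta0, phi0, kasa_center(pts, ctr, u0)))
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  u <- dir_from_angles(best$par[1], best$par[2])
  B <- perp_basis(u)
  o <- as.numeric(ctr + B %*% best$par[3:4])
  # sign convention: mean rise along the axis over successive spokes >= 0
  if (n >= 2) {
    dz <- diff(pts %*% u)
    if (mean(dz) < 0) u <- -u
  }
  structure(list(origin = o, direction = unit(u)), class = "helix_axis")
}

#' @export
print.helix_axis <- function(x, ...) {
  cat(sprintf("helix_axis: origin (%.2f, %.2f, %.2f), direction (%.4f, %.4f, %.4f)\n",
              x$origin[1], x$origin[2], x$origin[3],
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

# cylindrical coordinates of points about an axis
cylindrical <- function(pts, axis) {
  u <- axis$direction
  B <- perp_basis(u)
  d <- sweep(pts, 2, axis$origin)
  zc <- as.numeric(d %*% u)
  a <- as.numeric(d %*% B[, 1])
  b <- as.numeric(d %*% B[, 2])
  list(r = sqrt(a^2 + b^2), theta = atan2(b, a) * 180 / pi, z = zc)
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Helical lattice parameters of an anchor set
#'
#' Computes cylindrical coordinates of each anchor about the axis and
#' summarises the lattice: radius over all N points, and twist (degrees per
#' spoke) and rise (Angstrom per spoke) over the N-1 successive inter-spoke
#' steps. Step angles are unwrapped into (0, 360) degrees assuming spokes
#' are supplied in ring order and advance monotonically in one rotational
#' sense; handedness is the sense of rotation relative to the rise
#' direction. Summaries are mean and population standard deviation
#' (divisor N), the descriptive convention for a fixed lattice.
#'
#' @param anchors `anchor_set` or N x 3 matrix, spoke order, N >= 3.
#' @param axis A `helix_axis`; fitted from the anchors when `NULL`.
#' @return An object of class `helical_params` with fields `n_points`,
#'   `n_steps`, `radius_mean`, `radius_sd`, `twist_mean`, `twist_sd`,
#'   `rise_mean`, `rise_sd`, `handedness`, plus per-point and per-step
#'   detail in `detail`.
#' @examples
#' ring <- make_ring(n_spokes = 14, radius = 102.5, twist = 27.6,
#'                   rise = 9.2, seed = 1)
#' helical_parameters(ring$anchors)
#' @export
helical_parameters <- function(anchors, axis = NULL) {
  pts <- as_points(anchors)
  n <- nrow(pts)
  if (n < 3L) stop("need at least 3 anchors (2 steps)", call. = FALSE)
  if (is.null(axis)) axis <- fit_axis(anchors)
  cyl <- cylindrical(pts, axis)
  dtheta_raw <- diff(cyl$theta)
  # wrap raw step angles into (-180, 180]
  dtheta <- ((dtheta_raw + 180) %% 360) - 180
  sense <- if (sum(dtheta) >= 0) 1 else -1
  twist_steps <- (sense * dtheta) %% 360   # in [0, 360)
  rise_steps <- diff(cyl$z)
  handedness <- if (sense > 0) "right" else "left"
  structure(list(
    n_points = n, n_steps = n - 1L,
    radius_mean = mean(cyl$r), radius_sd = pop_sd(cyl$r),
    twist_mean = mean(twist_steps), twist_sd = pop_sd(twist_steps),
    rise_mean = mean(rise_steps), rise_sd = pop_sd(rise_steps),
    handedness = handedness,
    detail = list(r = cyl$r, theta = cyl$theta, z = cyl$z,
                  twist_steps = twist_steps, rise_steps = rise_steps),
    axis = axis
  ), class = "helical_params")
}

#' Construct helical parameters from published summary values
#'
#' Builds a `helical_params` object directly from reported mean and SD
#' values, e.g. a literature reference lattice, for use with
#' [compare_lattices()].
#'
#' @param radius,twist,rise Means: Angstrom, degrees/spoke, Angstrom/spoke.
#' @param radius_sd,twist_sd,rise_sd Standard deviations (default 0).
#' @param n_points,n_steps Sample sizes behind the summaries.
#' @param handedness `"right"` or `"left"`.
#' @return A `helical_params` object (no per-point detail).
#' @export
helical_params <- function(radius, twist, rise,
                           radius_sd = 0, twist_sd = 0, rise_sd = 0,
                           n_points = NA_integer_, n_steps = NA_integer_,
                           handedness = "right") {
  stopifnot(radius > 0, twist > 0, twist < 360,
            radius_sd >= 0, twist_sd >= 0, rise_sd >= 0)
  structure(list(n_points = n_points, n_steps = n_steps,
                 radius_mean = radius, radius_sd = radius_sd,
                 twist_mean = twist, twist_sd = twist_sd,
                 rise_mean = rise, rise_sd = rise_sd,
                 handedness = handedness, detail = NULL, axis = NULL),
            class = "helical_params")
}

#' @export
print.helical_params <- function(x, digits = 2, ...) {
  cat("helical lattice parameters",
      if (!is.na(x$n_points)) sprintf("(%d points, %d steps)", x$n_points, x$n_steps),
      "\n")
  cat(sprintf("  radius: %8.*f +/- %.*f Angstrom\n", digits, x$radius_mean, digits, x$radius_sd))
  cat(sprintf("  twist : %8.*f +/- %.*f degrees/spoke\n", digits, x$twist_mean, digits, x$twist_sd))
  cat(sprintf("  rise  : %8.*f +/- %.*f Angstrom/spoke\n", digits, x$rise_mean, digits, x$rise_sd))
  cat("  handedness:", x$handedness, "\n")
  invisible(x)
}

#' Reference 13-protofilament microtubule lattice parameters
#'
#' Published helical lattice parameters of the S. cerevisiae
#' 13-protofilament microtubule (anchored at Gln15 of the alpha-tubulin
#' subunits): radius 101.8 +/- 0.1 Angstrom, rotation 27.6 +/- 0.0 degrees
#' per subunit, pitch increment 9.6 +/- 0.1 Angstrom per subunit. This is
#' the lattice a microtubule-nucleation-competent gamma-tubulin ring is
#' expected to template.
#'
#' @return A `helical_params` object.
#' @export
microtubule_13pf_params <- function() {
  helical_params(radius = 101.8, twist = 27.6, rise = 9.6,
                 radius_sd = 0.1, twist_sd = 0.0, rise_sd = 0.1,
                 n_points = 13L, n_steps = 13L)
}

#' Compare two helical lattices
#'
#' Absolute per-parameter differences between a query and a reference
#' lattice, flagged compatible when every difference is within the sum of
#' the two standard deviations — the operational reading of two lattices
#' being indistinguishable at the reported precision.
#'
#' @param query,reference `helical_params` objects (a `helix_fit` is
#'   accepted for either).
#' @return Object of class `lattice_comparison`: data.frame `table` with
#'   one row per parameter (query, reference, difference, sd_sum,
#'   compatible) and overall flag `compatible`.
#' @export
compare_lattices <- function(query, reference) {
  if (inherits(query, "helix_fit")) query <- query$params
  if (inherits(reference, "helix_fit")) reference <- reference$params
  stopifnot(inherits(query, "helical_params"),
            inherits(reference, "helical_params"))
  par <- c("radius", "twist", "rise")
  q <- c(query$radius_mean, query$twist_mean, query$rise_mean)
  qs <- c(query$radius_sd, query$twist_sd, query$rise_sd)
  r <- c(reference$radius_mean, reference$twist_mean, reference$rise_mean)
  rs <- c(reference$radius_sd, reference$twist_sd, reference$rise_sd)
  diff <- abs(q - r)
  tol <- qs + rs
  tab <- data.frame(parameter = par, query = q, reference = r,
                    difference = diff, sd_sum = tol,
                    compatible = diff <= tol,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, compatible = all(tab$compatible),
                 query = query, reference = reference),
            class = "lattice_comparison")
}

#' @export
print.lattice_comparison <- function(x, ...) {
  cat("lattice comparison (units: Angstrom, degrees/spoke, Angstrom/spoke)\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat(if (x$compatible) "=> lattices are compatible (all |diff| <= SD_query + SD_ref)\n"
      else "=> lattices differ\n")
  invisible(x)
}
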