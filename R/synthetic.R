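# Deterministic seeding: one user-facing seed is split into per-component
# streams so different generators never share a random stream; the caller's
# RNG state is always restored.
split_seed <- function(seed, stream) {
  streams <- c(ring = 101L, hinge = 211L, hx = 307L, gel = 401L)
  s <- (as.integer(seed) %% 1000000L) * 1009L + streams[[stream]]
  as.integer(s %% .Machine$integer.max)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

chain_alphabet <- function(n) {
  pool <- c(LETTERS, letters, as.character(0:9))
  if (n > length(pool)) stop("at most ", length(pool), " spokes supported",
                             call. = FALSE)
  pool[seq_len(n)]
}

atom_row <- function(chain, resno, resname, atom, element, xyz,
                     occ = 1, b = 0) {
  data.frame(chain = chain, resno = as.integer(resno), insert = "",
             resname = resname, atom = atom, element = element,
             x = xyz[1], y = xyz[2], z = xyz[3], occ = occ, b = b,
             het = FALSE, stringsAsFactors = FALSE)
}

#' Generate a synthetic helical ring with known ground truth
#'
#' Places one spoke per chain on an ideal helical lattice
#' `p_k = pose(r cos(k t), r sin(k t), k h)` for spoke `k = 0..N-1`, twist
#' `t` and rise `h`, mimicking the arrangement of gamma-tubulin subunits
#' in a ring complex (defaults: 14 spokes, radius 102.5 Angstrom, twist
#' 27.6 degrees, rise 9.2 Angstrom — a closed, microtubule-compatible
#' lattice). Each spoke is a single glutamine residue numbered 12 carrying
#' one C-alpha atom, matching the default anchor rule; `decorated = TRUE`
#' adds a short C-alpha helix (residues 13-20) per spoke for selection
#' tests. Isotropic Gaussian coordinate noise of sd `noise_sd` is added
#' after the pose; the noise-free anchor positions, the posed axis and
#' the generating parameters are returned as retrievable truth.
#'
#' @param n_spokes Number of spokes, >= 4 (default 14).
#' @param radius Lattice radius, Angstrom (default 102.5).
#' @param twist Rotation per spoke, degrees (default 27.6).
#' @param rise Axial rise per spoke, Angstrom (default 9.2).
#' @param noise_sd Isotropic coordinate noise sd, Angstrom (default 0).
#' @param seed Integer seed; identical inputs give identical output.
#' @param pose Optional rigid transform applied to the whole ring: list
#'   with 3 x 3 rotation `R` and 3-vector translation `t`.
#' @param decorated Add a dummy 8-residue C-alpha helix per spoke.
#' @return List with `model` (`structure_model`), `chains` (ring order),
#'   `anchors` (noisy `anchor_set`, as extracted from the model),
#'   `truth` (list: noise-free anchor matrix `anchors`, `axis_origin`,
#'   `axis_direction`, and the generating parameters).
#' @examples
#' ring <- make_ring(n_spokes = 14, seed = 1)
#' helical_parameters(ring$anchors)
#' @export
make_ring <- function(n_spokes = 14, radius = 102.5, twist = 27.6,
                      rise = 9.2, noise_sd = 0, seed = 1, pose = NULL,
                      decorated = FALSE) {
  if (n_spokes < 4) stop("a ring needs at least 4 spokes", call. = FALSE)
  if (radius <= 0 || noise_sd < 0) stop("invalid ring spec", call. = FALSE)
  chains <- chain_alphabet(n_spokes)
  k <- 0:(n_spokes - 1)
  th <- k * twist * pi / 180
  ideal <- cbind(radius * cos(th), radius * sin(th), k * rise)
  R <- if (is.null(pose)) diag(3) else pose$R
  tr <- if (is.null(pose)) c(0, 0, 0) else pose$t
  posed <- ideal %*% t(R) + matrix(tr, n_spokes, 3, byrow = TRUE)
  noisy <- with_seed(split_seed(seed, "ring"), {
    posed + matrix(stats::rnorm(3 * n_spokes, sd = noise_sd), n_spokes, 3)
  })
  rows <- vector("list", n_spokes)
  for (i in seq_len(n_spokes)) {
    r <- atom_row(chains[i], 12, "GLN", "CA", "C", noisy[i, ])
    if (decorated) {
      extra <- lapply(1:8, function(j) {
        # small ideal alpha-helix trace hanging off the anchor
        phi <- j * 100 * pi / 180
        atom_row(chains[i], 12 + j, "ALA", "CA", "C",
                 noisy[i, ] + c(2.3 * cos(phi), 2.3 * sin(phi), 1.5 * j))
      })
      r <- do.call(rbind, c(list(r), extra))
    }
    rows[[i]] <- r
  }
  model <- structure_model(do.call(rbind, rows),
                           identifier = sprintf("synthetic_ring_N%d", n_spokes),
                           provenance = list(path = NA, format = "synthetic"))
  list(model = model, chains = chains,
       anchors = anchor_set(noisy, chains = chains,
                            source = "synthetic ring anchors"),
       truth = list(anchors = posed,
                    axis_origin = as.numeric(R %*% c(0, 0, 0) + tr),
                    axis_direction = as.numeric(R %*% c(0, 0, 1)),
                    n_spokes = n_spokes, radius = radius, twist = twist,
                    rise = rise, noise_sd = noise_sd, seed = seed))
}

rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  a <- angle_deg * pi / 180
  c1 <- cos(a); s1 <- sin(a)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) * c1 + s1 * ux + (1 - c1) * (u %o% u)
}

#' Generate a pair of models related by a rigid domain hinge
#'
#' Builds a C-alpha trace of `n_static + n_mobile` residues (a smooth
#' random walk with realistic 3.8 Angstrom steps) as model A; model B is
#' identical except that the mobile block (the C-terminal
#' `n_mobile` residues) is rotated by `hinge_angle` about `hinge_axis`
#' through a pivot at the last static residue — the geometry of a
#' GRIP-domain-style hinge closure. The closed-form RMSD of the mobile
#' block under the hinge (`2 sin(angle/2)` times the RMS perpendicular
#' distance of its atoms from the hinge axis) is returned as truth.
#'
#' @param n_static,n_mobile Residues in the static and mobile blocks
#'   (defaults 60 and 60); residues are numbered 1..(n_static+n_mobile).
#' @param hinge_axis 3-vector, normalised internally (default z).
#' @param hinge_angle Degrees (default 12).
#' @param seed Integer seed for the backbone walk.
#' @return List with `model_a`, `model_b`, `static_sel`, `mobile_sel`
#'   ([selection()] objects for the two blocks), `pivot`, and `truth`
#'   (list: `mobile_rmsd` closed form, `rotation`, `hinge_angle`).
#' @examples
#' hp <- make_hinge_pair(hinge_angle = 12, seed = 5)
#' hp$truth$mobile_rmsd
#' @export
make_hinge_pair <- function(n_static = 60, n_mobile = 60,
                            hinge_axis = c(0, 0, 1), hinge_angle = 12,
                            seed = 1) {
  if (n_static < 3 || n_mobile < 3) {
    stop("each hinge block needs at least 3 residues", call. = FALSE)
  }
  n <- n_static + n_mobile
  coords <- with_seed(split_seed(seed, "hinge"), {
    # smooth self-avoiding-ish walk: unit direction diffusing on the sphere
    dirs <- matrix(0, n, 3)
    d <- c(1, 0, 0)
    for (i in seq_len(n)) {
      d <- unit(d + stats::rnorm(3, sd = 0.35))
      dirs[i, ] <- d
    }
    apply(dirs * 3.8, 2, cumsum)
  })
  pivot <- coords[n_static, ]
  R <- rotation_about_axis(hinge_axis, hinge_angle)
  coords_b <- coords
  mob <- (n_static + 1):n
  coords_b[mob, ] <- sweep(sweep(coords[mob, , drop = FALSE], 2, pivot) %*% t(R),
                           2, pivot, "+")
  build <- function(xyz, id) {
    rows <- lapply(seq_len(n), function(i) {
      atom_row("A", i, "ALA", "CA", "C", xyz[i, ])
    })
    structure_model(do.call(rbind, rows), identifier = id,
                    provenance = list(path = NA, format = "synthetic"))
  }
  # closed form: each atom at perpendicular distance d from the hinge axis
  # moves by 2 d sin(angle/2)
  u <- hinge_axis / sqrt(sum(hinge_axis^2))
  rel <- sweep(coords[mob, , drop = FALSE], 2, pivot)
  perp2 <- rowSums(rel^2) - (rel %*% u)^2
  mobile_rmsd <- 2 * abs(sin(hinge_angle * pi / 360)) * sqrt(mean(perp2))
  list(model_a = build(coords, "hinge_open"),
       model_b = build(coords_b, "hinge_closed"),
       static_sel = selection(chains = "A", residues = c(1, n_static)),
       mobile_sel = selection(chains = "A", residues = c(n_static + 1, n)),
       pivot = pivot,
       truth = list(mobile_rmsd = as.numeric(mobile_rmsd), rotation = R,
                    hinge_angle = hinge_angle, coords_a = coords,
                    coords_b = coords_b))
}

#' Generate synthetic hydrogen-exchange tables with known truth
#'
#' Builds baseline and ligand peptide tables over a protein of
#' `protein_length` residues. Peptides tile the sequence (`peptide_length`
#' residues, advancing by `peptide_step`). Per-residue baseline exchange
#' and ligand-induced protection profiles (percent) are averaged over each
#' peptide's span to give the peptide truth; centroid masses are then
#' constructed so the noise-free back-exchange corrected uptake equals the
#' truth exactly (`m0 = 1000 + 10 i`, `m100 = m0 +` number of residues,
#' i.e. roughly one exchangeable amide per residue), with Gaussian mass
#' noise `noise_sd` (Da) on the labelled centroids. The default profiles
#' emulate a receptor-fragment/polymerase-binding experiment: baseline
#' exchange varying between rigid (5%) and dynamic (85%) segments and
#' strong protection (80%) over one binding epitope.
#'
#' @param protein_length Residues (default 100).
#' @param peptide_length,peptide_step Coverage plan (defaults 10 and 5).
#' @param baseline_profile Per-residue baseline exchange percent
#'   (default: smooth profile between 5 and 85).
#' @param protection_profile Per-residue true protection percent
#'   (default: 80% over residues 41-60, zero elsewhere).
#' @param noise_sd Mass noise sd in Da (default 0).
#' @param seed Integer seed.
#' @return List with `baseline`, `ligand` (peptide tables), and `truth`
#'   (per-peptide data.frame: `start`, `end`, `baseline_pct`,
#'   `protection_pct`, `relative_exchange`, `shown`; plus the residue
#'   profiles).
#' @export
make_hx_tables <- function(protein_length = 100, peptide_length = 10,
                           peptide_step = 5, baseline_profile = NULL,
                           protection_profile = NULL, noise_sd = 0,
                           seed = 1) {
  L <- protein_length
  if (is.null(baseline_profile)) {
    baseline_profile <- 45 + 40 * sin(2 * pi * seq_len(L) / L)
  }
  if (is.null(protection_profile)) {
    protection_profile <- ifelse(seq_len(L) >= 41 & seq_len(L) <= 60, 80, 0)
  }
  stopifnot(length(baseline_profile) == L, length(protection_profile) == L)
  starts <- seq(1, L - peptide_length + 1, by = peptide_step)
  ends <- pmin(starts + peptide_length - 1, L)
  npep <- length(starts)
  base_pct <- vapply(seq_len(npep), function(i) {
    mean(baseline_profile[starts[i]:ends[i]])
  }, numeric(1))
  prot_pct <- vapply(seq_len(npep), function(i) {
    mean(protection_profile[starts[i]:ends[i]])
  }, numeric(1))
  lig_pct <- base_pct * (1 - prot_pct / 100)
  m0 <- 1000 + 10 * seq_len(npep)
  m100 <- m0 + (ends - starts + 1)
  mt_base <- m0 + (base_pct / 100) * (m100 - m0)
  mt_lig <- m0 + (lig_pct / 100) * (m100 - m0)
  if (noise_sd > 0) {
    noise <- with_seed(split_seed(seed, "hx"), {
      matrix(stats::rnorm(2 * npep, sd = noise_sd), npep, 2)
    })
    mt_base <- mt_base + noise[, 1]
    mt_lig <- mt_lig + noise[, 2]
  }
  ids <- sprintf("pep%03d", seq_len(npep))
  mk <- function(mt, condition) {
    data.frame(peptide_id = ids, start = starts, end = ends,
               sequence = "", condition = condition, charge = 2L,
               m0 = m0, m_t = mt, m100 = m100, stringsAsFactors = FALSE)
  }
  list(baseline = mk(mt_base, "baseline"),
       ligand = mk(mt_lig, "ligand"),
       truth = list(peptides = data.frame(
         peptide_id = ids, start = starts, end = ends,
         baseline_pct = base_pct, protection_pct = prot_pct,
         ligand_pct = lig_pct,
         relative_exchange = ifelse(base_pct > 0, 100 * lig_pct / base_pct,
                                    NA_real_),
         shown = base_pct >= 10, stringsAsFactors = FALSE),
         baseline_profile = baseline_profile,
         protection_profile = protection_profile))
}

#' Generate a synthetic densitometry gel from a true stoichiometry
#'
#' Draws band intensities `intensity = scale_rep * ratio_i * MW_i *
#' exp(noise)` with lognormal multiplicative noise of coefficient of
#' variation `cv` and an arbitrary per-replicate scale factor (gels are
#' only internally comparable), so the molecular-weight-normalised molar
#' ratios recover `true_ratios`. Defaults emulate a purified
#' gamma-tubulin small-complex oligomer: Spc97, Spc98, gamma-tubulin and
#' a receptor fragment in 1:1:2:2 molar ratio with realistic construct
#' masses.
#'
#' @param true_ratios Named positive molar ratios (default
#'   `c(Spc97 = 1, Spc98 = 1, gTub = 2, Spc72 = 2)`).
#' @param mws Named molecular weights, kDa (defaults 91, 98, 52.5, 69).
#' @param cv Multiplicative noise CV (default 0.05).
#' @param n_replicates Number of replicate gels (default 3).
#' @param seed Integer seed.
#' @return List with `bands` (data.frame `protein`, `replicate`,
#'   `intensity`, `mw_kda`) and `truth` (`ratios`, `mws`, `cv`).
#' @examples
#' gel <- make_gel(cv = 0, seed = 2)
#' molar_ratios(gel$bands, "Spc97")$table
#' @export
make_gel <- function(true_ratios = c(Spc97 = 1, Spc98 = 1, gTub = 2,
                                     Spc72 = 2),
                     mws = c(Spc97 = 91, Spc98 = 98, gTub = 52.5,
                             Spc72 = 69),
                     cv = 0.05, n_replicates = 3, seed = 1) {
  if (any(true_ratios <= 0) || any(mws <= 0) || cv < 0 || n_replicates < 1) {
    stop("invalid gel spec", call. = FALSE)
  }
  prots <- names(true_ratios)
  if (is.null(prots) || !setequal(prots, names(mws))) {
    stop("true_ratios and mws must share protein names", call. = FALSE)
  }
  sdlog <- sqrt(log(1 + cv^2))
  bands <- with_seed(split_seed(seed, "gel"), {
    do.call(rbind, lapply(seq_len(n_replicates), function(rep) {
      scale_rep <- 1000 * exp(stats::rnorm(1, sd = 0.2))
      noise <- if (cv > 0) exp(stats::rnorm(length(prots), sd = sdlog)) else 1
      data.frame(protein = prots, replicate = rep,
                 intensity = scale_rep * true_ratios[prots] *
                   mws[prots] * noise,
                 mw_kda = as.numeric(mws[prots]), stringsAsFactors = FALSE)
    }))
  })
  rownames(bands) <- NULL
  list(bands = bands, truth = list(ratios = true_ratios, mws = mws, cv = cv,
                                   n_replicates = n_replicates, seed = seed))
}
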