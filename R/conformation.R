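#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' paired coordinate sets, via the SVD of the covariance matrix with the
#' usual determinant sign correction.
#'
#' @param mobile,target N x 3 matrices of paired coordinates, N >= 3.
#' @return Object of class `superposition`: list with `rotation` (3 x 3,
#'   det +1), `translation` (applied as `x %*% t(R) + t`), `rmsd`
#'   (Angstrom), `n_atoms`, and `transform` (function mapping mobile
#'   coordinates into the target frame).
#' @examples
#' a <- matrix(rnorm(30), 10, 3)
#' k <- kabsch_superpose(a, a)
#' k$rmsd
#' @export
kabsch_superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (nrow(mobile) != nrow(target)) {
    stop("mobile and target must contain the same number of paired points",
         call. = FALSE)
  }
  n <- nrow(mobile)
  if (n < 3L) stop("superposition needs at least 3 paired points", call. = FALSE)
  mc <- colMeans(mobile); tc <- colMeans(target)
  A <- sweep(mobile, 2, mc); B <- sweep(target, 2, tc)
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  tr <- as.numeric(tc - R %*% mc)
  moved <- mobile %*% t(R) + matrix(tr, n, 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((moved - target)^2)))
  transform <- function(x) {
    x <- as.matrix(x)
    x %*% t(R) + matrix(tr, nrow(x), 3, byrow = TRUE)
  }
  structure(list(rotation = R, translation = tr, rmsd = rmsd,
                 n_atoms = n, transform = transform),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: %d paired atoms, RMSD %.3f Angstrom\n",
              x$n_atoms, x$rmsd))
  if (!is.null(x$n_dropped) && x$n_dropped > 0) {
    cat(sprintf("  (%d unpaired residues dropped)\n", x$n_dropped))
  }
  invisible(x)
}

#' Pair C-alpha atoms between two models
#'
#' Extracts C-alpha coordinates within a selection from both models and
#' pairs them by (chain, residue number, insertion code). Residues present
#' in only one model are dropped and counted — deposited models routinely
#' have unmodelled gaps.
#'
#' @param model_a,model_b `structure_model` objects.
#' @param sel An [selection()]; its atom-name criterion is forced to CA.
#' @return List with `coords_a`, `coords_b` (paired N x 3 matrices in
#'   model-a residue order), `n_pairs`, `n_dropped_a`, `n_dropped_b`, and
#'   `residues` (paired residue keys).
#' @export
paired_ca <- function(model_a, model_b, sel = selection()) {
  sel$atoms <- "CA"
  ca_a <- select_atoms(model_a, sel)
  ca_b <- select_atoms(model_b, sel)
  key <- function(df) paste(df$chain, df$resno, df$insert, sep = "|")
  ka <- key(ca_a); kb <- key(ca_b)
  common <- intersect(ka, kb)
  if (length(common) == 0L) {
    stop("no common C-alpha residues between the two models in this selection",
         call. = FALSE)
  }
  ia <- match(common, ka); ib <- match(common, kb)
  list(coords_a = as.matrix(ca_a[ia, c("x", "y", "z")]),
       coords_b = as.matrix(ca_b[ib, c("x", "y", "z")]),
       n_pairs = length(common),
       n_dropped_a = length(ka) - length(common),
       n_dropped_b = length(kb) - length(common),
       residues = common)
}

#' Domain-wise C-alpha RMSD between two models
#'
#' Quantifies a conformational change between two states of the same
#' protein: C-alpha atoms in `align_sel` are superposed by least squares,
#' and the RMSD is reported over `sel` *without re-fitting*. With the
#' default `align_sel = sel`, alignment and measurement use the same
#' domain — the single-number-per-domain convention. Supplying a distinct
#' `align_sel` (e.g. a static domain) measures how far `sel` has moved in
#' the frame of the alignment domain, which is how hinge motions are
#' characterised.
#'
#' @param model_a,model_b `structure_model` objects of the two states.
#' @param sel Selection measured (C-alpha only).
#' @param align_sel Selection superposed on (default: same as `sel`).
#' @return A `superposition` object; `rmsd` refers to `sel`, and the
#'   alignment transform, pair counts and selections are recorded.
#' @examples
#' hp <- make_hinge_pair(hinge_angle = 12, seed = 5)
#' domain_rmsd(hp$model_a, hp$model_b, sel = hp$static_sel)$rmsd  # ~0
#' @export
domain_rmsd <- function(model_a, model_b, sel, align_sel = sel) {
  al <- paired_ca(model_a, model_b, align_sel)
  fit <- kabsch_superpose(al$coords_b, al$coords_a)   # b onto a
  me <- paired_ca(model_a, model_b, sel)
  moved <- fit$transform(me$coords_b)
  rmsd <- sqrt(mean(rowSums((moved - me$coords_a)^2)))
  out <- fit
  out$rmsd <- rmsd
  out$n_atoms <- me$n_pairs
  out$n_dropped <- me$n_dropped_a + me$n_dropped_b
  out$measure_selection <- sel
  out$align_selection <- align_sel
  out
}

#' Displacement of a structural element after alignment
#'
#' Superposes model B onto model A using the paired C-alpha atoms of
#' `align_sel`, then reports the distance between the C-alpha centroid of
#' `measure_sel_a` in A and that of `measure_sel_b` in the transformed B.
#' The measured elements need not pair residue-for-residue (they may be
#' different proteins, e.g. the CM1 helices of different receptor
#' orthologs measured in a shared frame); centroids make the measure
#' robust to differing modelled lengths.
#'
#' @param model_a,model_b `structure_model` objects.
#' @param align_sel Selection pairing across both models.
#' @param measure_sel_a,measure_sel_b Element selections in A and B.
#' @return Object of class `displacement`: list with `displacement`
#'   (Angstrom), centroids, pair counts and the selections used.
#' @export
displacement_after_alignment <- function(model_a, model_b, align_sel,
                                         measure_sel_a, measure_sel_b) {
  al <- paired_ca(model_a, model_b, align_sel)
  fit <- kabsch_superpose(al$coords_b, al$coords_a)
  msa <- measure_sel_a; msa$atoms <- "CA"
  msb <- measure_sel_b; msb$atoms <- "CA"
  ca_a <- select_atoms(model_a, msa)
  ca_b <- select_atoms(model_b, msb)
  if (nrow(ca_a) == 0L || nrow(ca_b) == 0L) {
    stop("empty measure selection: no C-alpha atoms matched", call. = FALSE)
  }
  cen_a <- colMeans(as.matrix(ca_a[, c("x", "y", "z")]))
  cen_b <- colMeans(fit$transform(as.matrix(ca_b[, c("x", "y", "z")])))
  structure(list(displacement = sqrt(sum((cen_a - cen_b)^2)),
                 centroid_a = cen_a, centroid_b = cen_b,
                 n_align_pairs = al$n_pairs,
                 n_measure_a = nrow(ca_a), n_measure_b = nrow(ca_b),
                 align_selection = align_sel,
                 measure_selection_a = measure_sel_a,
                 measure_selection_b = measure_sel_b),
            class = "displacement")
}

#' @export
print.displacement <- function(x, ...) {
  cat(sprintf("element displacement after alignment: %.2f Angstrom (%d/%d measured CA, %d aligned pairs)\n",
              x$displacement, x$n_measure_a, x$n_measure_b, x$n_align_pairs))
  invisible(x)
}
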