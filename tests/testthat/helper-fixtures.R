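# shared fixtures and small oracles used across test files

# deterministic random rotation matrix (proper, det +1)
random_rotation <- function(seed) {
  set.seed(seed)
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

apply_rigid <- function(pts, R, t) {
  pts %*% t(R) + matrix(t, nrow(pts), 3, byrow = TRUE)
}

# minimal atom-table builder for constructed-geometry fixtures
fixture_atoms <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(chain = r$chain, resno = as.integer(r$resno), insert = "",
               resname = r$resname, atom = r$atom, element = r$element,
               x = r$xyz[1], y = r$xyz[2], z = r$xyz[3],
               occ = 1, b = r$b %||% 0, het = isTRUE(r$het),
               stringsAsFactors = FALSE)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fixture_model <- function(..., id = "fixture") {
  ringstat::structure_model(fixture_atoms(...), identifier = id)
}
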