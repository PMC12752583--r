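#' Elasticity phantoms
#'
#' Deterministic ground-truth (E, nu) maps on the cell grid, standing in
#' for shape-structured reference fields (e.g. two-level bitmap silhouettes).
#' Descriptors:
#' \describe{
#'   \item{homogeneous}{constant `E_bg`, `nu_bg`.}
#'   \item{inclusion}{one circular inclusion of radius `radius` (fraction of
#'     the shorter domain side) at `center` (fractions of the domain),
#'     values `E_inc`, `nu_inc` inside.}
#'   \item{multi_inclusion}{`n_inc` non-overlapping circular inclusions with
#'     seeded random centers/radii, all at `E_inc`, `nu_inc`.}
#'   \item{gradient}{E ramps linearly from `E_bg` (left) to `E_inc` (right);
#'     nu ramps from `nu_bg` to `nu_inc` bottom to top.}
#'   \item{bitmap_mask}{a logical matrix (`mask`, cell-grid shape) selects
#'     `E_inc`/`nu_inc` cells over the background.}
#' }
#' Defaults describe a soft-tissue-like phantom: background 1 (stress
#' units), a 3x stiffer inclusion of radius 0.25, nu 0.3 background and
#' 0.4 inclusion.
#'
#' @param descriptor pattern name, see Details
#' @param grid node [grid2d()]; the phantom lives on its cell grid
#' @param seed integer seed (only `multi_inclusion` draws random numbers)
#' @param E_bg,E_inc,nu_bg,nu_inc level parameters
#' @param radius inclusion radius as a fraction of the shorter domain side
#' @param center inclusion center as fractions (cx, cy) of the domain
#' @param n_inc number of inclusions for `multi_inclusion`
#' @param mask logical cell-grid matrix for `bitmap_mask`
#' @return an object of class `phantom` with elements `elast` and
#'   `descriptor`
#' @examples
#' g <- grid2d(16, 16)
#' ph <- make_phantom("inclusion", g)
#' length(unique(as.vector(ph$elast$E)))  # 2
#' @export
make_phantom <- function(descriptor = c("inclusion", "homogeneous",
                                        "multi_inclusion", "gradient",
                                        "bitmap_mask"),
                         grid, seed = 1L,
                         E_bg = 1, E_inc = 3, nu_bg = 0.3, nu_inc = 0.4,
                         radius = 0.25, center = c(0.5, 0.5),
                         n_inc = 3L, mask = NULL) {
  descriptor <- match.arg(descriptor)
  cc <- cell_coords(grid)
  Lx <- (grid$nx - 1) * grid$t; Ly <- (grid$ny - 1) * grid$h
  Lmin <- min(Lx, Ly)
  d <- cell_dim(grid)
  E <- matrix(E_bg, d[1], d[2])
  nu <- matrix(nu_bg, d[1], d[2])
  inside_circle <- function(cx, cy, r) {
    (cc$x - (grid$origin[1] + cx * Lx))^2 +
      (cc$y - (grid$origin[2] + cy * Ly))^2 <= (r * Lmin)^2
  }
  if (descriptor == "inclusion") {
    m <- inside_circle(center[1], center[2], radius)
    E[m] <- E_inc; nu[m] <- nu_inc
  } else if (descriptor == "multi_inclusion") {
    rng <- local_rng(seed)
    placed <- matrix(numeric(0), 0, 3)
    tries <- 0
    while (nrow(placed) < n_inc && tries < 1000) {
      tries <- tries + 1
      r <- rng$runif(1, 0.08, 0.18)
      cx <- rng$runif(1, r + 0.05, 0.95 - r)
      cy <- rng$runif(1, r + 0.05, 0.95 - r)
      ok <- TRUE
      if (nrow(placed) > 0) {
        dd <- sqrt((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2)
        ok <- all(dd > (placed[, 3] + r + 0.02))
      }
      if (ok) {
        placed <- rbind(placed, c(cx, cy, r))
        m <- inside_circle(cx, cy, r)
        E[m] <- E_inc; nu[m] <- nu_inc
      }
    }
  } else if (descriptor == "gradient") {
    fx <- (cc$x - grid$origin[1]) / Lx
    fy <- (cc$y - grid$origin[2]) / Ly
    E <- E_bg + (E_inc - E_bg) * fx
    nu <- nu_bg + (nu_inc - nu_bg) * fy
  } else if (descriptor == "bitmap_mask") {
    if (is.null(mask) || !identical(dim(mask), as.integer(d))) {
      stop("make_phantom: bitmap_mask needs a logical mask of cell-grid shape")
    }
    E[mask] <- E_inc; nu[mask] <- nu_inc
  }
  structure(list(elast = elasticity_field(E, nu, grid),
                 descriptor = list(name = descriptor, seed = seed,
                                   E_bg = E_bg, E_inc = E_inc,
                                   nu_bg = nu_bg, nu_inc = nu_inc)),
            class = "phantom")
}

# Seeded RNG scoped to a closure so package functions never disturb the
# caller's .Random.seed.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed))
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    s
  }
  with_state <- function(fun) {
    function(...) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$state, globalenv())
      out <- fun(...)
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
      out
    }
  }
  list(runif = with_state(stats::runif),
       rnorm = with_state(stats::rnorm),
       sample_int = with_state(function(n, k) sample.int(n, k)))
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom:%s> ", x$descriptor$name))
  print(x$elast)
  invisible(x)
}
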