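#' Positional encoding specification
#'
#' Each scalar coordinate x is expanded into `2 * omega` sinusoidal
#' features: for i = 1..omega the pair `sin(f^(2i/omega) x)` and
#' `cos(f^(2i/omega) x)` (interleaved). With the default minimum frequency
#' f = 1e-4 the frequency factors decay geometrically from `f^(2/omega)`
#' toward `f^2`, giving a multi-scale, bounded ([-1, 1]) representation.
#' The same encoding is applied independently to x and y and concatenated
#' (total `4 * omega` features); there is no raw-coordinate passthrough.
#' Coordinates are normalized to [-1, 1] per axis before encoding (the
#' encoding and the sine layers are scale-sensitive).
#'
#' @param f minimum frequency, > 0 (default 1e-4)
#' @param omega number of frequencies, integer >= 1 (default 64)
#' @return an object of class `encoding_spec`
#' @export
encoding_spec <- function(f = 1e-4, omega = 64L) {
  if (!is.finite(f) || f <= 0) stop("encoding_spec: f must be > 0")
  omega <- as.integer(omega)
  if (omega < 1L) stop("encoding_spec: omega must be >= 1")
  structure(list(f = f, omega = omega), class = "encoding_spec")
}

#' Encode scalar coordinates
#'
#' @param coord numeric vector of (normalized) coordinates
#' @param spec an [encoding_spec()]
#' @return a `length(coord) x (2 * omega)` matrix, columns interleaved
#'   sin/cos per frequency
#' @examples
#' positional_encode(0, encoding_spec(omega = 4))  # sines 0, cosines 1
#' @export
positional_encode <- function(coord, spec) {
  i <- seq_len(spec$omega)
  freqs <- spec$f^(2 * i / spec$omega)
  ang <- outer(as.numeric(coord), freqs)          # n x omega
  out <- matrix(0, length(coord), 2L * spec$omega)
  out[, seq(1L, 2L * spec$omega, 2L)] <- sin(ang)
  out[, seq(2L, 2L * spec$omega, 2L)] <- cos(ang)
  out
}

# Encode an (x, y) point set: normalize each axis to [-1, 1] over the
# supplied physical ranges, then concatenate the per-axis encodings.
encode_points <- function(x, y, spec, xlim, ylim) {
  nx <- if (diff(xlim) > 0) 2 * (x - xlim[1]) / diff(xlim) - 1 else x * 0
  ny <- if (diff(ylim) > 0) 2 * (y - ylim[1]) / diff(ylim) - 1 else y * 0
  cbind(positional_encode(nx, spec), positional_encode(ny, spec))
}

#' Coordinate network specification
#'
#' Fully connected multilayer perceptron on encoded coordinates. Hidden
#' layers use the sine activation (SIREN) by default; `ablation_activations()`
#' swaps in swish, tanh or relu for comparison studies. Output heads:
#' 2 for displacement (ux, uy), 3 for strain (exx, eyy, gxy), 2 for
#' elasticity. The elasticity network maps its raw outputs through
#' softplus for E (positivity by construction) and `0.5 * sigmoid` for nu
#' (keeps nu inside (0, 0.5) so the plane-stress constitutive matrix stays
#' positive-definite throughout training); other networks use identity
#' outputs.
#'
#' @param depth hidden-layer count (>= 1)
#' @param width neurons per hidden layer (>= 1)
#' @param out_heads number of outputs
#' @param activation hidden activation: `"siren"`, `"swish"`, `"tanh"`,
#'   `"relu"`
#' @param final one of `"identity"` or `"elasticity"` (softplus E head +
#'   bounded nu head)
#' @param omega0 first-layer sine frequency multiplier (SIREN convention)
#' @return an object of class `network_spec`
#' @export
network_spec <- function(depth = 16L, width = 128L, out_heads = 2L,
                         activation = c("siren", "swish", "tanh", "relu"),
                         final = c("identity", "elasticity"),
                         omega0 = 30) {
  activation <- match.arg(activation)
  final <- match.arg(final)
  depth <- as.integer(depth); width <- as.integer(width)
  if (depth < 1L || width < 1L) stop("network_spec: depth and width must be >= 1")
  structure(list(depth = depth, width = width, out_heads = as.integer(out_heads),
                 activation = activation, final = final, omega0 = omega0),
            class = "network_spec")
}

#' Activation-function ablation variants
#'
#' Returns a [network_spec()] identical to `base` except for the hidden
#' activation, enabling like-for-like activation comparisons.
#'
#' @param kind `"siren"`, `"swish"`, `"tanh"` or `"relu"`
#' @param base the spec to modify
#' @return a `network_spec`
#' @export
ablation_activations <- function(kind = c("siren", "swish", "tanh", "relu"),
                                 base = network_spec()) {
  kind <- match.arg(kind)
  base$activation <- kind
  base
}

activation_funs <- function(kind, omega0) {
  switch(kind,
    siren = list(
      first = function(z) sin(omega0 * z),
      dfirst = function(z) omega0 * cos(omega0 * z),
      hidden = function(z) sin(z),
      dhidden = function(z) cos(z)
    ),
    swish = {
      sw <- function(z) z * stats::plogis(z)
      dsw <- function(z) { s <- stats::plogis(z); s + z * s * (1 - s) }
      list(first = sw, dfirst = dsw, hidden = sw, dhidden = dsw)
    },
    tanh = list(first = tanh, dfirst = function(z) 1 - tanh(z)^2,
                hidden = tanh, dhidden = function(z) 1 - tanh(z)^2),
    relu = list(first = function(z) pmax(z, 0), dfirst = function(z) (z > 0) * 1,
                hidden = function(z) pmax(z, 0), dhidden = function(z) (z > 0) * 1)
  )
}

#' Build (initialize) a coordinate network
#'
#' Deterministic initialization for a given seed. Sine networks use the
#' SIREN scheme: first-layer weights U(-1/fan_in, 1/fan_in) (the sine
#' itself is scaled by omega0), deeper layers U(+/- sqrt(6/fan_in)). Other
#' activations use the same uniform fan-in scheme without the first-layer
#' special case. Biases start at zero.
#'
#' @param spec a [network_spec()]
#' @param in_dim input feature dimension (e.g. `4 * omega` encoded features)
#' @param seed integer seed
#' @return an object of class `mlp` (list of layer weight/bias pairs plus
#'   the spec)
#' @export
build_network <- function(spec, in_dim, seed = 1L) {
  rng <- local_rng(seed)
  dims <- c(in_dim, rep(spec$width, spec$depth), spec$out_heads)
  layers <- vector("list", length(dims) - 1L)
  for (l in seq_along(layers)) {
    fan_in <- dims[l]
    bound <- if (identical(spec$activation, "siren") && l == 1L) {
      1 / fan_in
    } else {
      sqrt(6 / fan_in)
    }
    W <- matrix(rng$runif(fan_in * dims[l + 1L], -bound, bound), fan_in, dims[l + 1L])
    layers[[l]] <- list(W = W, b = numeric(dims[l + 1L]))
  }
  structure(list(layers = layers, spec = spec, in_dim = in_dim, seed = seed),
            class = "mlp")
}

# Forward pass; returns raw head outputs (n x out_heads) and, if
# keep_cache, the per-layer inputs and pre-activations for backprop.
net_forward <- function(net, X, keep_cache = FALSE) {
  fa <- activation_funs(net$spec$activation, net$spec$omega0)
  L <- length(net$layers)
  cache <- if (keep_cache) vector("list", L) else NULL
  A <- X
  for (l in seq_len(L)) {
    Z <- A %*% net$layers[[l]]$W
    Z <- sweep_add(Z, net$layers[[l]]$b)
    if (keep_cache) cache[[l]] <- list(A = A, Z = Z)
    if (l < L) {
      A <- if (l == 1L) fa$first(Z) else fa$hidden(Z)
    } else {
      A <- Z  # linear head; any final nonlinearity is applied by the caller
    }
  }
  if (keep_cache) list(out = A, cache = cache) else A
}

sweep_add <- function(M, b) M + tcrossprod(rep.int(1, nrow(M)), b)

# Backward pass: grad_out is dLoss/d(raw outputs) (n x out_heads).
# Returns list(grads = per-layer list(W, b), dX = dLoss/dX if wanted).
net_backward <- function(net, cache, grad_out, want_dX = FALSE) {
  fa <- activation_funs(net$spec$activation, net$spec$omega0)
  L <- length(net$layers)
  grads <- vector("list", L)
  G <- grad_out
  for (l in rev(seq_len(L))) {
    if (l < L) {
      dact <- if (l == 1L) fa$dfirst(cache[[l]]$Z) else fa$dhidden(cache[[l]]$Z)
      G <- G * dact
    }
    grads[[l]] <- list(W = crossprod(cache[[l]]$A, G), b = colSums(G))
    if (l > 1L || want_dX) G <- tcrossprod(G, net$layers[[l]]$W)
  }
  list(grads = grads, dX = if (want_dX) G else NULL)
}

softplus <- function(z) ifelse(z > 30, z, log1p(exp(pmin(z, 30))))
dsoftplus <- function(z) stats::plogis(z)

#' Evaluate a network on (x, y) points
#'
#' Convenience wrapper: encodes the points, runs the forward pass and
#' applies the final activation of the spec (`"elasticity"`: softplus on
#' column 1, `0.5 * sigmoid` on column 2).
#'
#' @param net an `mlp` from [build_network()]
#' @param x,y coordinate vectors
#' @param enc an [encoding_spec()]
#' @param xlim,ylim physical axis ranges used for normalization
#' @return matrix of outputs, one row per point
#' @export
net_predict <- function(net, x, y, enc, xlim, ylim) {
  X <- encode_points(x, y, enc, xlim, ylim)
  out <- net_forward(net, X)
  if (identical(net$spec$final, "elasticity")) {
    out[, 1] <- softplus(out[, 1])
    out[, 2] <- 0.5 * stats::plogis(out[, 2])
  }
  out
}
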