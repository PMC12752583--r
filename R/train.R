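#' Training configuration and presets
#'
#' Bundles the loss weights, network/encoding sizes and iteration schedule
#' of the Phase-1 optimization. Three presets are provided:
#' \describe{
#'   \item{`paper_scale`}{depth 16 / width 128 networks, omega = 64
#'     encoding, 50k displacement-pretraining iterations, 100k strain
#'     iterations, 50k joint iterations, Adam lr 1e-4 (cosine-decayed).
#'     Intended for parity runs; takes hours on CPU.}
#'   \item{`reduced`}{depth 4 / width 64, omega = 16, 2k/4k/10k
#'     iterations, lr 2e-3. Desk-scale runs (minutes).}
#'   \item{`tiny`}{depth 3 / width 48, omega = 8, 800/1200/3000
#'     iterations, lr 2e-3. Used by the automated test suite so that a
#'     full study fits a CI budget; thresholds asserted by tests are the
#'     same as at larger scale.}
#' }
#' The learning rate belongs to the preset: the 1e-4 rate appropriate for
#' a 200k-iteration schedule cannot converge within the reduced budgets.
#'
#' @param weights named list `lam_u`, `lam_eps`, `lam_r`, `lam_E` (and
#'   optionally `lam_bc`) of non-negative loss weights. `lam_bc` > 0 adds
#'   the loading-boundary force residual
#'   `|sum_j sigma_xx(x_b, y_j) h - F| / F` to the joint objective -- the
#'   term reported to destabilize single-phase training; it is off by
#'   default and exists for that ablation (requires the dataset to carry
#'   the applied force)
#' @param depth,width,omega network depth/width and encoding size
#' @param pretrain_u_iters,pretrain_eps_iters,full_iters schedule
#' @param lr peak Adam learning rate (cosine-decayed to 1 percent per stage)
#' @param Ec modulus anchor used by the `lam_E` term (relative scale)
#' @param seed master seed; network initializations derive from it
#' @param spacing_mode finite-difference normalization, see
#'   [strain_from_displacement_fd()]
#' @param modulus_mode `"pointwise"` or `"mean_anchor"`, see [loss_modulus()]
#' @param activation hidden activation for all three networks
#' @param use_encoding set `FALSE` to feed raw normalized coordinates
#'   (encoding ablation)
#' @param pretrain set `FALSE` to skip the sequential pretraining stages and
#'   spend `pretrain_u_iters + pretrain_eps_iters + full_iters` on joint
#'   training (pretraining ablation at matched total cost)
#' @param el_lr_mult learning-rate multiplier for the elasticity network
#'   (it carries no data term and its field must travel farthest from a
#'   flat initialization; values around 3 speed modulus-contrast recovery
#'   at short schedules; default 1). The multiplier ramps in linearly over
#'   the first 20 percent of joint training.
#' @param mode `"full"` (three networks), `"displacement_only"` (no strain
#'   network; PDE strain comes from finite differences of the displacement
#'   network) or `"fd_direct"` (no displacement/strain networks; strain is
#'   the finite difference of the raw noisy data, only the elasticity
#'   network trains)
#' @return an object of class `train_config`
#' @export
train_config <- function(weights = list(lam_u = 10, lam_eps = 1, lam_r = 1, lam_E = 1e-3),
                         depth = 4L, width = 64L, omega = 16L,
                         pretrain_u_iters = 2000L, pretrain_eps_iters = 4000L,
                         full_iters = 10000L, lr = 2e-3,
                         Ec = 1, seed = 1L,
                         spacing_mode = "physical",
                         modulus_mode = "pointwise",
                         activation = "siren",
                         use_encoding = TRUE,
                         pretrain = TRUE,
                         el_lr_mult = 1,
                         mode = c("full", "displacement_only", "fd_direct")) {
  mode <- match.arg(mode)
  if (is.null(weights$lam_bc)) weights$lam_bc <- 0
  stopifnot(all(unlist(weights) >= 0), Ec > 0,
            pretrain_u_iters >= 0, pretrain_eps_iters >= 0, full_iters >= 0)
  structure(list(weights = weights, depth = as.integer(depth),
                 width = as.integer(width), omega = as.integer(omega),
                 pretrain_u_iters = as.integer(pretrain_u_iters),
                 pretrain_eps_iters = as.integer(pretrain_eps_iters),
                 full_iters = as.integer(full_iters),
                 lr = lr, Ec = Ec, seed = as.integer(seed),
                 spacing_mode = spacing_mode, modulus_mode = modulus_mode,
                 activation = activation, use_encoding = isTRUE(use_encoding),
                 pretrain = isTRUE(pretrain), el_lr_mult = el_lr_mult,
                 mode = mode),
            class = "train_config")
}

#' @rdname train_config
#' @param ... overrides forwarded to [train_config()]
#' @export
preset_paper <- function(...) {
  preset_build(list(depth = 16L, width = 128L, omega = 64L,
                    pretrain_u_iters = 50000L, pretrain_eps_iters = 100000L,
                    full_iters = 50000L, lr = 1e-4), list(...))
}

#' @rdname train_config
#' @export
preset_reduced <- function(...) {
  preset_build(list(depth = 4L, width = 64L, omega = 16L,
                    pretrain_u_iters = 2000L, pretrain_eps_iters = 4000L,
                    full_iters = 10000L, lr = 2e-3), list(...))
}

#' @rdname train_config
#' @export
preset_tiny <- function(...) {
  preset_build(list(depth = 3L, width = 48L, omega = 8L,
                    pretrain_u_iters = 800L, pretrain_eps_iters = 1200L,
                    full_iters = 3000L, lr = 2e-3), list(...))
}

preset_build <- function(defaults, overrides) {
  do.call(train_config, utils::modifyList(defaults, overrides))
}

# ---- Adam ------------------------------------------------------------

adam_init <- function(net) {
  lapply(net$layers, function(l) list(mW = l$W * 0, vW = l$W * 0,
                                      mb = l$b * 0, vb = l$b * 0))
}

adam_step <- function(net, grads, state, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  c1 <- 1 - b1^t; c2 <- 1 - b2^t
  for (l in seq_along(net$layers)) {
    g <- grads[[l]]; s <- state[[l]]
    s$mW <- b1 * s$mW + (1 - b1) * g$W
    s$vW <- b2 * s$vW + (1 - b2) * g$W^2
    s$mb <- b1 * s$mb + (1 - b1) * g$b
    s$vb <- b2 * s$vb + (1 - b2) * g$b^2
    net$layers[[l]]$W <- net$layers[[l]]$W - lr * (s$mW / c1) / (sqrt(s$vW / c2) + eps)
    net$layers[[l]]$b <- net$layers[[l]]$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state[[l]] <- s
  }
  list(net = net, state = state)
}

cosine_lr <- function(lr, t, total, floor_frac = 1e-3) {
  if (total <= 1) return(lr)
  lo <- lr * floor_frac
  lo + 0.5 * (lr - lo) * (1 + cos(pi * (t - 1) / (total - 1)))
}

# ---- training context ------------------------------------------------

# Precomputes everything the loss/grad evaluations reuse each iteration.
p1_context <- function(u_obs, config, F_bc = NULL) {
  grid <- u_obs$grid
  enc <- encoding_spec(omega = config$omega)
  ncrd <- node_coords(grid); ccrd <- cell_coords(grid)
  xlim <- range(ncrd$x); ylim <- range(ncrd$y)
  enc_fun <- function(x, y) {
    if (config$use_encoding) encode_points(x, y, enc, xlim, ylim)
    else cbind(2 * (x - xlim[1]) / diff(xlim) - 1, 2 * (y - ylim[1]) / diff(ylim) - 1)
  }
  X_node <- enc_fun(as.vector(ncrd$x), as.vector(ncrd$y))
  X_cell <- enc_fun(as.vector(ccrd$x), as.vector(ccrd$y))
  sm <- config$spacing_mode
  if (identical(sm, "physical")) { sx <- grid$t; sy <- grid$h } else { sx <- 1; sy <- 1 }
  fd_obs <- strain_from_displacement_fd(u_obs, sm)
  floor0 <- function(v) max(v, 1e-12)
  s_ux <- floor0(mean(abs(u_obs$ux))); s_uy <- floor0(mean(abs(u_obs$uy)))
  s_e <- c(floor0(mean(abs(fd_obs$exx))), floor0(mean(abs(fd_obs$eyy))),
           floor0(mean(abs(fd_obs$gxy))))
  # Per-term normalization scales: the four losses live in different
  # physical units (length, strain, strain/length, stress); dividing each
  # by a data-derived scale makes the lam weights dimensionless and keeps
  # the gradient pressure on each network balanced independently of grid
  # spacing and load magnitude.
  S_u <- s_ux + s_uy
  S_eps <- sum(s_e)
  S_r <- S_eps / (9 * min(sx, sy))
  list(grid = grid, enc = enc, xlim = xlim, ylim = ylim,
       X_node = X_node, X_cell = X_cell,
       ux_obs = u_obs$ux, uy_obs = u_obs$uy,
       fd_obs = fd_obs,
       s_ux = s_ux, s_uy = s_uy, s_e = s_e,
       S_u = S_u, S_eps = S_eps, S_r = S_r,
       sx = sx, sy = sy,
       rx_div_x = if (identical(sm, "physical")) 6 * grid$t else grid$h * grid$t,
       rx_div_y = if (identical(sm, "physical")) 6 * grid$h else grid$h * grid$t,
       k = fd_kernels(), F_bc = F_bc,
       nd = c(grid$nx, grid$ny), cd = cell_dim(grid), rd = residual_dim(grid))
}

# Displacement head: raw net outputs scaled by the data magnitudes.
p1_upred <- function(ctx, unet, keep_cache = FALSE) {
  fw <- net_forward(unet, ctx$X_node, keep_cache)
  raw <- if (keep_cache) fw$out else fw
  list(ux = matrix(raw[, 1] * ctx$s_ux, ctx$nd[1], ctx$nd[2]),
       uy = matrix(raw[, 2] * ctx$s_uy, ctx$nd[1], ctx$nd[2]),
       cache = if (keep_cache) fw$cache else NULL)
}

p1_epspred <- function(ctx, enet, keep_cache = FALSE) {
  fw <- net_forward(enet, ctx$X_cell, keep_cache)
  raw <- if (keep_cache) fw$out else fw
  list(exx = matrix(raw[, 1] * ctx$s_e[1], ctx$cd[1], ctx$cd[2]),
       eyy = matrix(raw[, 2] * ctx$s_e[2], ctx$cd[1], ctx$cd[2]),
       gxy = matrix(raw[, 3] * ctx$s_e[3], ctx$cd[1], ctx$cd[2]),
       cache = if (keep_cache) fw$cache else NULL)
}

NU_HEAD_SCALE <- 1

p1_elpred <- function(ctx, Enet, Ec, keep_cache = FALSE) {
  fw <- net_forward(Enet, ctx$X_cell, keep_cache)
  raw <- if (keep_cache) fw$out else fw
  kE <- Ec / log(2)
  z1 <- matrix(raw[, 1], ctx$cd[1], ctx$cd[2])
  z2 <- matrix(raw[, 2], ctx$cd[1], ctx$cd[2])
  list(E = kE * softplus(z1), nu = 0.5 * stats::plogis(NU_HEAD_SCALE * z2),
       z1 = z1, z2 = z2, kE = kE,
       cache = if (keep_cache) fw$cache else NULL)
}

# FD strain of a predicted displacement (matrices in, matrices out).
fd_strain_mats <- function(ctx, ux, uy) {
  k <- ctx$k
  list(exx = valid_convolve(ux, k$wx) / ctx$sx,
       eyy = valid_convolve(uy, k$wy) / ctx$sy,
       gxy = valid_convolve(ux, k$wy) / ctx$sy + valid_convolve(uy, k$wx) / ctx$sx)
}

# Adjoint of fd_strain_mats: given upstream grads on the three strain
# components, accumulate grads on (ux, uy).
fd_strain_adjoint <- function(ctx, gexx, geyy, ggxy) {
  k <- ctx$k
  dux <- convolve_adjoint(gexx / ctx$sx, k$wx, ctx$nd) +
    convolve_adjoint(ggxy / ctx$sy, k$wy, ctx$nd)
  duy <- convolve_adjoint(geyy / ctx$sy, k$wy, ctx$nd) +
    convolve_adjoint(ggxy / ctx$sx, k$wx, ctx$nd)
  list(dux = dux, duy = duy)
}

# Loss + gradients of the full Phase-1 objective for the active mode.
# nets: list(u = , eps = , el = ) (entries may be NULL depending on mode).
# Returns list(loss terms, total, grads per net).
p1_eval <- function(ctx, nets, config, stage = "joint") {
  w <- config$weights
  # dimensionless effective weights (see p1_context normalization scales)
  wu <- w$lam_u / ctx$S_u
  weps <- w$lam_eps / ctx$S_eps
  wr <- w$lam_r / ctx$S_r
  wE <- w$lam_E / config$Ec
  mode <- config$mode
  Nn <- prod(ctx$nd); Nc <- prod(ctx$cd); Mr <- prod(ctx$rd)
  out <- list(Lu = NA_real_, Leps = NA_real_, Lr = NA_real_, LE = NA_real_,
              Lbc = NULL)
  grads <- list()

  # ---- pretraining stages optimize their single (unweighted) term
  if (identical(stage, "u")) {
    up <- p1_upred(ctx, nets$u, keep_cache = TRUE)
    dux_l <- up$ux - ctx$ux_obs
    duy_l <- up$uy - ctx$uy_obs
    out$Lu <- mean(abs(dux_l) + abs(duy_l))
    gb <- net_backward(nets$u, up$cache,
                       cbind(as.vector(sign(dux_l)) * ctx$s_ux / Nn,
                             as.vector(sign(duy_l)) * ctx$s_uy / Nn))
    return(list(terms = out, total = out$Lu, grads = list(u = gb$grads)))
  }
  if (identical(stage, "eps")) {
    tgt <- ctx$eps_target  # FD strain of the (fixed) displacement net
    ep <- p1_epspred(ctx, nets$eps, keep_cache = TRUE)
    d1 <- ep$exx - tgt$exx; d2 <- ep$eyy - tgt$eyy; d3 <- ep$gxy - tgt$gxy
    out$Leps <- mean(abs(d1) + abs(d2) + abs(d3))
    graw <- cbind(as.vector(sign(d1)) * ctx$s_e[1] / Nc,
                  as.vector(sign(d2)) * ctx$s_e[2] / Nc,
                  as.vector(sign(d3)) * ctx$s_e[3] / Nc)
    gb <- net_backward(nets$eps, ep$cache, graw)
    return(list(terms = out, total = out$Leps, grads = list(eps = gb$grads)))
  }

  # ---- displacement branch
  has_u <- !identical(mode, "fd_direct")
  if (has_u) {
    up <- p1_upred(ctx, nets$u, keep_cache = TRUE)
    dux_l <- up$ux - ctx$ux_obs
    duy_l <- up$uy - ctx$uy_obs
    out$Lu <- mean(abs(dux_l) + abs(duy_l))
    g_ux <- wu * sign(dux_l) / Nn
    g_uy <- wu * sign(duy_l) / Nn
  }

  # strain used by the PDE branch, and its provenance
  if (identical(mode, "full")) {
    ep <- p1_epspred(ctx, nets$eps, keep_cache = TRUE)
    eps_pde <- ep
  } else if (identical(mode, "displacement_only")) {
    eps_u_mats <- fd_strain_mats(ctx, up$ux, up$uy)
    eps_pde <- eps_u_mats
  } else {
    eps_pde <- ctx$fd_obs  # fixed FD of the raw observations
  }

  # strain-consistency term (full mode only)
  if (identical(mode, "full")) {
    eps_u_mats <- fd_strain_mats(ctx, up$ux, up$uy)
    d1 <- ep$exx - eps_u_mats$exx
    d2 <- ep$eyy - eps_u_mats$eyy
    d3 <- ep$gxy - eps_u_mats$gxy
    out$Leps <- mean(abs(d1) + abs(d2) + abs(d3))
    g_eps <- list(exx = weps * sign(d1) / Nc,
                  eyy = weps * sign(d2) / Nc,
                  gxy = weps * sign(d3) / Nc)
  }

  # ---- elasticity branch + PDE residual
  el <- p1_elpred(ctx, nets$el, config$Ec, keep_cache = TRUE)
  E <- el$E; nu <- el$nu
  kfac <- E / (1 - nu^2)
  p <- eps_pde$exx + nu * eps_pde$eyy
  q <- nu * eps_pde$exx + eps_pde$eyy
  m <- (1 - nu) / 2 * eps_pde$gxy
  sxx <- kfac * p; syy <- kfac * q; txy <- kfac * m

  g_sxx_bc <- NULL
  if (w$lam_bc > 0 && !is.null(ctx$F_bc)) {
    bsum <- sum(sxx[nrow(sxx), ]) * ctx$grid$h
    out$Lbc <- abs(bsum - ctx$F_bc) / ctx$F_bc
    g_sxx_bc <- w$lam_bc * sign(bsum - ctx$F_bc) * ctx$grid$h / ctx$F_bc
  }

  kk <- ctx$k
  rx <- valid_convolve(sxx, kk$wxx_x) / ctx$rx_div_x +
    valid_convolve(txy, kk$wxy_x) / ctx$rx_div_y
  ry <- valid_convolve(txy, kk$wxy_y) / ctx$rx_div_x +
    valid_convolve(syy, kk$wyy_y) / ctx$rx_div_y
  Et <- box3_sum(E)
  if (any(Et <= 0)) stop("train: E_tilde <= 0 (modulus collapsed)")
  A <- abs(rx) + abs(ry)
  out$Lr <- mean(A / Et)
  out$LE <- loss_modulus(E, config$Ec, config$modulus_mode)

  # gradients of the (normalized) PDE term
  g_rx <- wr * sign(rx) / (Mr * Et)
  g_ry <- wr * sign(ry) / (Mr * Et)
  g_Et <- -wr * A / (Mr * Et^2)
  g_sxx <- convolve_adjoint(g_rx / ctx$rx_div_x, kk$wxx_x, ctx$cd)
  if (!is.null(g_sxx_bc)) g_sxx[nrow(g_sxx), ] <- g_sxx[nrow(g_sxx), ] + g_sxx_bc
  g_txy <- convolve_adjoint(g_rx / ctx$rx_div_y, kk$wxy_x, ctx$cd) +
    convolve_adjoint(g_ry / ctx$rx_div_x, kk$wxy_y, ctx$cd)
  g_syy <- convolve_adjoint(g_ry / ctx$rx_div_y, kk$wyy_y, ctx$cd)

  # constitutive backward
  g_exx_pde <- g_sxx * kfac + g_syy * kfac * nu
  g_eyy_pde <- g_sxx * kfac * nu + g_syy * kfac
  g_gxy_pde <- g_txy * kfac * (1 - nu) / 2
  g_E <- (g_sxx * p + g_syy * q + g_txy * m) / (1 - nu^2) +
    convolve_adjoint(g_Et, matrix(1, 3, 3), ctx$cd)
  dk_dnu <- E * 2 * nu / (1 - nu^2)^2
  g_nu <- g_sxx * (dk_dnu * p + kfac * eps_pde$eyy) +
    g_syy * (dk_dnu * q + kfac * eps_pde$exx) +
    g_txy * (dk_dnu * m - kfac * eps_pde$gxy / 2)

  # lam_E * LE
  if (identical(config$modulus_mode, "pointwise")) {
    g_E <- g_E + wE * sign(E - config$Ec) / Nc
  } else {
    g_E <- g_E + wE * sign(mean(E) - config$Ec) / Nc
  }

  # elasticity net raw-head gradients
  gz1 <- g_E * el$kE * dsoftplus(el$z1)
  s2 <- stats::plogis(NU_HEAD_SCALE * el$z2)
  gz2 <- g_nu * 0.5 * NU_HEAD_SCALE * s2 * (1 - s2)
  gb_el <- net_backward(nets$el, el$cache, cbind(as.vector(gz1), as.vector(gz2)))
  grads$el <- gb_el$grads

  if (identical(mode, "full")) {
    # strain net receives the consistency and PDE gradients
    graw <- cbind(as.vector(g_eps$exx + g_exx_pde) * ctx$s_e[1],
                  as.vector(g_eps$eyy + g_eyy_pde) * ctx$s_e[2],
                  as.vector(g_eps$gxy + g_gxy_pde) * ctx$s_e[3])
    gb_eps <- net_backward(nets$eps, ep$cache, graw)
    grads$eps <- gb_eps$grads
    # displacement net: data term minus consistency through FD
    adj <- fd_strain_adjoint(ctx, -g_eps$exx, -g_eps$eyy, -g_eps$gxy)
    graw_u <- cbind(as.vector(g_ux + adj$dux) * ctx$s_ux,
                    as.vector(g_uy + adj$duy) * ctx$s_uy)
    gb_u <- net_backward(nets$u, up$cache, graw_u)
    grads$u <- gb_u$grads
  } else if (identical(mode, "displacement_only")) {
    adj <- fd_strain_adjoint(ctx, g_exx_pde, g_eyy_pde, g_gxy_pde)
    graw_u <- cbind(as.vector(g_ux + adj$dux) * ctx$s_ux,
                    as.vector(g_uy + adj$duy) * ctx$s_uy)
    gb_u <- net_backward(nets$u, up$cache, graw_u)
    grads$u <- gb_u$grads
  }

  tot <- sum(c(wu * out$Lu, weps * out$Leps,
               wr * out$Lr, wE * out$LE,
               if (!is.null(out$Lbc)) w$lam_bc * out$Lbc), na.rm = TRUE)
  list(terms = out, total = tot, grads = grads)
}

run_stage <- function(ctx, nets, config, stage, iters, history, stage_name) {
  if (iters <= 0) return(list(nets = nets, history = history))
  if (identical(stage, "eps")) {
    if (is.null(nets$eps)) return(list(nets = nets, history = history))
    up <- p1_upred(ctx, nets$u)
    ctx$eps_target <- fd_strain_mats(ctx, up$ux, up$uy)
  }
  active <- names(nets)[!vapply(nets, is.null, TRUE)]
  active <- switch(stage, u = "u", eps = "eps", joint = active)
  states <- lapply(nets[active], adam_init)
  for (t in seq_len(iters)) {
    ev <- p1_eval(ctx, nets, config, stage)
    if (!is.finite(ev$total)) {
      stop(sprintf("train: loss diverged (non-finite) at %s iteration %d", stage_name, t))
    }
    lr <- cosine_lr(config$lr, t, iters)
    # elasticity net: linear warmup over the first 20% of the stage, then
    # the el_lr_mult boost; early joint gradients reflect a not-yet-formed
    # modulus field and slam the (data-term-free) nu head if taken at
    # full strength
    el_ramp <- min(1, t / max(1, 0.2 * iters))
    for (nm in names(ev$grads)) {
      lr_nm <- if (identical(nm, "el")) lr * config$el_lr_mult * el_ramp else lr
      st <- adam_step(nets[[nm]], ev$grads[[nm]], states[[nm]], lr_nm, t)
      nets[[nm]] <- st$net
      states[[nm]] <- st$state
    }
    history[[length(history) + 1L]] <-
      c(iter = t, Lu = ev$terms$Lu, Leps = ev$terms$Leps,
        Lr = ev$terms$Lr, LE = ev$terms$LE, total = ev$total)
    names(history)[length(history)] <- stage_name
  }
  list(nets = nets, history = history)
}

#' Sequential pretraining of the displacement and strain networks
#'
#' Stage 1 fits the displacement network to the observations with the
#' displacement loss alone; stage 2 then fits the strain network to the
#' finite-difference strain of the (now fixed, but still trainable later)
#' displacement network's output. The elasticity network is untouched.
#'
#' @param u_obs observed [displacement_field()]
#' @param config a [train_config()]
#' @param nets optional pre-built networks (list `u`, `eps`, `el`)
#' @return list with elements `nets` (warm-started) and `history`
#' @export
pretrain <- function(u_obs, config = preset_reduced(), nets = NULL) {
  ctx <- p1_context(u_obs, config)
  if (is.null(nets)) nets <- p1_init_nets(ctx, config)
  history <- list()
  st <- run_stage(ctx, nets, config, "u", config$pretrain_u_iters, history, "pretrain_u")
  st <- run_stage(ctx, st$nets, config, "eps", config$pretrain_eps_iters,
                  st$history, "pretrain_eps")
  list(nets = st$nets, history = st$history)
}

p1_init_nets <- function(ctx, config) {
  ind <- ncol(ctx$X_node)
  mk <- function(heads, final, seed_off) {
    build_network(network_spec(depth = config$depth, width = config$width,
                               out_heads = heads, activation = config$activation,
                               final = final),
                  in_dim = ind, seed = config$seed + seed_off)
  }
  nets <- list(u = NULL, eps = NULL, el = mk(2L, "elasticity", 3L))
  if (!identical(config$mode, "fd_direct")) nets$u <- mk(2L, "identity", 1L)
  if (identical(config$mode, "full")) nets$eps <- mk(3L, "identity", 2L)
  nets
}

history_frame <- function(history) {
  if (length(history) == 0) {
    return(data.frame(stage = character(), iter = integer(), Lu = numeric(),
                      Leps = numeric(), Lr = numeric(), LE = numeric(),
                      total = numeric()))
  }
  df <- as.data.frame(do.call(rbind, history))
  df$stage <- names(history)
  df[, c("stage", "iter", "Lu", "Leps", "Lr", "LE", "total")]
}

#' Phase-1 training: relative-scale elasticity recovery
#'
#' Jointly minimizes the four-term objective over the displacement, strain
#' and elasticity networks (warm-started by [pretrain()] unless
#' `config$pretrain` is FALSE, in which case the pretraining budget is
#' folded into joint training). Returns the trained networks and all
#' predicted fields evaluated on the data grid. The recovered modulus is on
#' an arbitrary scale centered near `Ec`; use [calibrate_scale()] /
#' [apply_calibration()] with a known boundary force to restore absolute
#' units.
#'
#' @param data either a [displacement_field()] of observations or a dataset
#'   list from [make_dataset()] (its `u_obs` is used)
#' @param config a [train_config()]
#' @return an object of class `phase1_result`: networks, predicted fields
#'   (`u`, `strain`, `stress`, `E_hat`, `nu_hat`), loss `history`
#'   data frame, `Ec`, `config`
#' @export
train_phase1 <- function(data, config = preset_reduced()) {
  u_obs <- if (inherits(data, "displacement_field")) data else data$u_obs
  F_bc <- if (inherits(data, "elast_dataset")) data$F else NULL
  ctx <- p1_context(u_obs, config, F_bc)
  nets <- p1_init_nets(ctx, config)
  history <- list()
  joint_iters <- config$full_iters
  if (config$pretrain && !identical(config$mode, "fd_direct")) {
    cfg_pre <- config
    if (!identical(config$mode, "full")) cfg_pre$pretrain_eps_iters <- 0L
    pre <- pretrain(u_obs, cfg_pre, nets)
    nets <- pre$nets
    history <- pre$history
  } else {
    extra <- config$pretrain_u_iters + config$pretrain_eps_iters
    if (!identical(config$mode, "fd_direct")) joint_iters <- joint_iters + extra
  }
  st <- run_stage(ctx, nets, config, "joint", joint_iters, history, "joint")
  nets <- st$nets

  # evaluate final fields
  up <- if (!identical(config$mode, "fd_direct")) {
    p <- p1_upred(ctx, nets$u)
    displacement_field(p$ux, p$uy, ctx$grid)
  } else u_obs
  eps_m <- if (identical(config$mode, "full")) {
    p1_epspred(ctx, nets$eps)
  } else if (identical(config$mode, "displacement_only")) {
    fd_strain_mats(ctx, up$ux, up$uy)
  } else ctx$fd_obs
  strain <- strain_field(eps_m$exx, eps_m$eyy, eps_m$gxy, ctx$grid)
  el <- p1_elpred(ctx, nets$el, config$Ec)
  nu_clamped <- pmin(pmax(el$nu, -1 + 2e-6), 0.5 - 2e-6)
  elast <- elasticity_field(pmax(el$E, 1e-12), nu_clamped, ctx$grid)
  stress <- stress_from_strain(strain, elast)
  structure(list(nets = nets, u = up, strain = strain, stress = stress,
                 E_hat = elast$E, nu_hat = elast$nu, elast = elast,
                 history = history_frame(st$history),
                 Ec = config$Ec, config = config, grid = ctx$grid,
                 scales = list(s_ux = ctx$s_ux, s_uy = ctx$s_uy, s_e = ctx$s_e)),
            class = "phase1_result")
}

#' @export
print.phase1_result <- function(x, ...) {
  cat(sprintf("<phase1_result> mode=%s, %d logged iterations, final total loss %.4g\n",
              x$config$mode, nrow(x$history),
              if (nrow(x$history)) x$history$total[nrow(x$history)] else NA_real_))
  cat(sprintf("  E_hat (relative, Ec=%g): [%.4g, %.4g]; nu_hat: [%.3g, %.3g]\n",
              x$Ec, min(x$E_hat), max(x$E_hat), min(x$nu_hat), max(x$nu_hat)))
  invisible(x)
}
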