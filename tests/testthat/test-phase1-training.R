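# Loss terms, pretraining, and the joint Phase-1 optimization mechanics.
# Training runs here use the micro config (a few hundred iterations):
# they verify contracts and invariances, not recovery quality (that lives
# in test-acceptance.R).

test_that("loss_displacement matches its definition", {
  g <- unit_grid(5)
  z <- matrix(0, 5, 5)
  u0 <- displacement_field(z, z, g)
  expect_equal(loss_displacement(u0, u0), 0)
  u1 <- displacement_field(z + 0.1, z, g)
  expect_equal(loss_displacement(u1, u0), 0.1)
  u2 <- displacement_field(z + 1, z + 2, g)
  expect_equal(loss_displacement(u2, u0), 3)
  expect_error(loss_displacement(u0, displacement_field(matrix(0, 6, 6),
                                                        matrix(0, 6, 6),
                                                        unit_grid(6))), "shape")
})

test_that("loss_strain sums component-wise absolute differences", {
  g <- unit_grid(5)
  d <- cell_dim(g)
  z <- matrix(0, d[1], d[2])
  s0 <- strain_field(z, z, z, g)
  expect_equal(loss_strain(s0, s0), 0)
  expect_equal(loss_strain(strain_field(z + 0.01, z, z, g), s0), 0.01)
  expect_equal(loss_strain(strain_field(z + 0.1, z + 0.2, z + 0.3, g), s0), 0.6)
})

test_that("loss_pde vanishes for uniform stress and is scale-invariant in E", {
  g <- unit_grid(8)
  d <- cell_dim(g)
  # homogeneous E, nu with uniform uniaxial strain -> uniform stress
  el <- homog_elast(g, E = 2, nu = 0.3)
  s <- strain_field(matrix(0.01, d[1], d[2]), matrix(-0.003, d[1], d[2]),
                    matrix(0, d[1], d[2]), g)
  expect_lt(loss_pde(s, el), 1e-10)
  # random strain: scaling E leaves the normalized loss unchanged
  set.seed(8)
  sr <- strain_field(matrix(rnorm(prod(d), 0, 0.01), d[1]),
                     matrix(rnorm(prod(d), 0, 0.01), d[1]),
                     matrix(rnorm(prod(d), 0, 0.01), d[1]), g)
  E <- matrix(runif(prod(d), 1, 2), d[1], d[2])
  nu <- matrix(0.25, d[1], d[2])
  l1 <- loss_pde(sr, elasticity_field(E, nu, g))
  l2 <- loss_pde(sr, elasticity_field(7.3 * E, nu, g))
  expect_equal(l1, l2, tolerance = 1e-12)
  expect_gt(l1, 0)
})

test_that("loss_modulus implements both anchoring modes", {
  E <- matrix(c(1, 3), 2, 2)
  expect_equal(loss_modulus(matrix(2, 2, 2), 2), 0)
  expect_equal(loss_modulus(matrix(3, 2, 2), 2), 1)
  expect_equal(loss_modulus(E, 2), 1)            # (1 + 1)/2
  expect_equal(loss_modulus(E, 2, "mean_anchor"), 0)
  expect_error(loss_modulus(E, -1), "Ec")
})

test_that("joint backprop matches directional finite differences (all modes)", {
  set.seed(99)
  g <- grid2d(6, 7, t = 0.15, h = 0.12)
  ds <- make_dataset(make_phantom("inclusion", g), g,
                     boundary_load("uniform_load", F = 0.02),
                     noise_spec("gaussian", 100, seed = 3))
  for (mode in c("full", "displacement_only", "fd_direct")) {
    cfg <- train_config(depth = 2L, width = 5L, omega = 2L, seed = 5L, mode = mode)
    ctx <- pinnelast:::p1_context(ds$u_obs, cfg)
    nets <- pinnelast:::p1_init_nets(ctx, cfg)
    for (nm in names(nets)) {
      if (is.null(nets[[nm]])) next
      for (l in seq_along(nets[[nm]]$layers)) {
        nets[[nm]]$layers[[l]]$W <- nets[[nm]]$layers[[l]]$W +
          matrix(rnorm(length(nets[[nm]]$layers[[l]]$W), 0, 0.05),
                 nrow(nets[[nm]]$layers[[l]]$W))
      }
    }
    ev <- pinnelast:::p1_eval(ctx, nets, cfg, "joint")
    dir <- lapply(nets, function(n) {
      if (is.null(n)) return(NULL)
      lapply(n$layers, function(l) list(W = matrix(rnorm(length(l$W)), nrow(l$W)),
                                        b = rnorm(length(l$b))))
    })
    an <- 0
    for (nm in names(ev$grads)) {
      for (l in seq_along(ev$grads[[nm]])) {
        an <- an + sum(ev$grads[[nm]][[l]]$W * dir[[nm]][[l]]$W) +
          sum(ev$grads[[nm]][[l]]$b * dir[[nm]][[l]]$b)
      }
    }
    shift <- function(nets, tt) {
      for (nm in names(nets)) {
        if (is.null(nets[[nm]])) next
        for (l in seq_along(nets[[nm]]$layers)) {
          nets[[nm]]$layers[[l]]$W <- nets[[nm]]$layers[[l]]$W + tt * dir[[nm]][[l]]$W
          nets[[nm]]$layers[[l]]$b <- nets[[nm]]$layers[[l]]$b + tt * dir[[nm]][[l]]$b
        }
      }
      nets
    }
    tt <- 1e-7
    fd <- (pinnelast:::p1_eval(ctx, shift(nets, tt), cfg, "joint")$total -
             pinnelast:::p1_eval(ctx, shift(nets, -tt), cfg, "joint")$total) / (2 * tt)
    expect_lt(abs(fd - an) / max(abs(an), 1e-12), 1e-4)
  }
})

test_that("pretraining fits clean displacements below a small fraction of |u|", {
  # L1 + Adam at the tiny preset converges ~1/iters; 2% of the signal
  # scale is what 1500 iterations buy (the paper-scale 50k-iteration
  # stage fits much deeper; see the methods vignette on reduced scale)
  ds <- quick_dataset(16, snr = NULL)
  cfg <- preset_tiny(pretrain_u_iters = 1500L, pretrain_eps_iters = 0L, seed = 2L)
  pre <- pretrain(ds$u_obs, cfg)
  hist <- pinnelast:::history_frame(pre$history)
  final_Lu <- hist$Lu[nrow(hist)]
  scale_u <- mean(abs(ds$u_obs$ux)) + mean(abs(ds$u_obs$uy))
  expect_lt(final_Lu / scale_u, 2e-2)
  # and the fit is far below where it started
  expect_lt(final_Lu, 0.05 * hist$Lu[1])
})

test_that("zero-iteration schedules leave parameters unchanged", {
  ds <- quick_dataset(12, snr = 1000)
  cfg <- micro_config(pretrain_u_iters = 0L, pretrain_eps_iters = 0L, seed = 4L)
  ctx <- pinnelast:::p1_context(ds$u_obs, cfg)
  nets0 <- pinnelast:::p1_init_nets(ctx, cfg)
  pre <- pretrain(ds$u_obs, cfg, nets0)
  expect_identical(pre$nets, nets0)
  expect_length(pre$history, 0)
})

test_that("training is deterministic for a fixed seed", {
  ds <- quick_dataset(12, snr = 500)
  cfg <- micro_config(seed = 11L)
  r1 <- train_phase1(ds, cfg)
  r2 <- train_phase1(ds, cfg)
  expect_identical(r1$history$total, r2$history$total)
  expect_identical(r1$E_hat, r2$E_hat)
  r3 <- train_phase1(ds, micro_config(seed = 12L))
  expect_false(identical(r1$E_hat, r3$E_hat))
})

test_that("total loss decreases in moving average on a short run", {
  ds <- quick_dataset(14, snr = 1000)
  cfg <- preset_tiny(pretrain_u_iters = 200L, pretrain_eps_iters = 200L,
                     full_iters = 600L, seed = 3L)
  res <- train_phase1(ds, cfg)
  tot <- res$history$total[res$history$stage == "joint"]
  k <- 100
  early <- mean(tot[seq_len(k)])
  late <- mean(tot[seq(length(tot) - k + 1, length(tot))])
  expect_lt(late, early)
})

test_that("without the PDE term the modulus collapses to the anchor", {
  ds <- quick_dataset(12, snr = 1000)
  cfg <- micro_config(seed = 5L, Ec = 2,
                      weights = list(lam_u = 1, lam_eps = 1, lam_r = 0, lam_E = 1))
  res <- train_phase1(ds, cfg)
  # with lam_r = 0 nothing couples E to the data: it hugs Ec
  expect_lt(mae(res$E_hat, matrix(2, nrow(res$E_hat), ncol(res$E_hat))) / 2, 0.05)
})

test_that("result fields respect the declared shape contracts", {
  ds <- quick_dataset(12, snr = 1000)
  res <- train_phase1(ds, micro_config(seed = 6L))
  g <- ds$grid
  expect_equal(dim(res$u$ux), c(g$nx, g$ny))
  expect_equal(dim(res$strain$exx), cell_dim(g))
  expect_equal(dim(res$stress$sxx), cell_dim(g))
  expect_true(all(res$E_hat > 0))
  expect_true(all(res$nu_hat > -1 & res$nu_hat < 0.5))
  expect_s3_class(res$elast, "elasticity_field")
  # history is complete and finite
  expect_true(all(is.finite(res$history$total)))
})

test_that("dataset bundles round-trip through CSV + JSON", {
  ds <- quick_dataset(10, snr = 200, seed = 8L)
  dir <- tempfile()
  write_dataset_bundle(ds, dir)
  back <- read_dataset_bundle(dir)
  expect_equal(back$u_obs$ux, ds$u_obs$ux, tolerance = 1e-12)
  expect_equal(back$elast_true$E, ds$elast_true$E, tolerance = 1e-12)
  expect_equal(back$meta$F, ds$F)
  expect_equal(back$meta$noise$snr, 200)
  unlink(dir, recursive = TRUE)
})
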