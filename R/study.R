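#' Absolute-error map
#'
#' Pointwise `|est - truth|` with an optional PNG rendering (fixed color
#' scale from 0 to `zmax`, grey ramp, written only when `file` is given).
#' The mean of the returned map equals `mae(est, truth)` by definition.
#'
#' @param est,truth matrices of equal shape
#' @param file optional PNG path
#' @param zmax fixed top of the color scale (defaults to max error)
#' @return the absolute-error matrix, invisibly carrying attribute
#'   `"file"` when a PNG was written
#' @export
error_map <- function(est, truth, file = NULL, zmax = NULL) {
  if (!identical(dim(est), dim(truth))) stop("error_map: shape mismatch")
  err <- abs(est - truth)
  if (!is.null(file)) {
    if (is.null(zmax)) zmax <- max(err, 1e-300)
    grDevices::png(file, width = 480, height = 480)
    op <- graphics::par(mar = c(2, 2, 2, 1))
    graphics::image(seq_len(nrow(err)), seq_len(ncol(err)),
                    pmin(err, zmax), zlim = c(0, zmax),
                    col = grDevices::gray.colors(64, start = 1, end = 0),
                    xlab = "", ylab = "", main = "|error|")
    graphics::par(op)
    grDevices::dev.off()
    attr(err, "file") <- file
  }
  invisible(err)
}

#' Experiment specification and study harness
#'
#' Re-runs the paper-style study designs at a configurable scale: noise
#' sweeps, noise-pattern comparison, boundary-condition robustness,
#' activation/encoding/pretraining/strain-network ablations and sweeps of
#' the modulus anchor Ec. Each condition x seed cell generates its own
#' dataset, trains Phase 1, calibrates Phase 2 with the true force, and
#' records MAE/MRE of both elastic fields. Everything is determined by
#' (spec, seeds): reruns reproduce the table bitwise on one device. Failed
#' runs are recorded as rows with `ok = FALSE`, never dropped.
#'
#' @param kind study kind, one of `"noise_sweep"`, `"noise_pattern"`,
#'   `"boundary_sweep"`, `"activation_ablation"`, `"encoding_ablation"`,
#'   `"pretrain_ablation"`, `"strain_net_ablation"`, `"Ec_sweep"`
#' @param phantom_descriptor passed to [make_phantom()]
#' @param snrs SNR levels for noise studies
#' @param seeds replicate seeds
#' @param grid_n grid size (grid_n x grid_n nodes)
#' @param config base [train_config()] for every run
#' @param F applied force
#' @return `experiment_spec()` returns an object of class
#'   `experiment_spec`
#' @export
experiment_spec <- function(kind = c("noise_sweep", "noise_pattern",
                                     "boundary_sweep", "activation_ablation",
                                     "encoding_ablation", "pretrain_ablation",
                                     "strain_net_ablation", "Ec_sweep"),
                            phantom_descriptor = "inclusion",
                            snrs = c(1000, 500, 100, 50, 20),
                            seeds = 1:5, grid_n = 24L,
                            config = preset_tiny(), F = 0.05) {
  kind <- match.arg(kind)
  if (length(seeds) == 0) stop("experiment_spec: need at least one seed")
  if (any(snrs <= 0)) stop("experiment_spec: SNR values must be positive")
  structure(list(kind = kind, phantom_descriptor = phantom_descriptor,
                 snrs = snrs, seeds = as.integer(seeds),
                 grid_n = as.integer(grid_n), config = config, F = F),
            class = "experiment_spec")
}

study_conditions <- function(spec) {
  base <- list(snr = 1000, noise_kind = "gaussian", profile = "uniform_load",
               activation = "siren", use_encoding = TRUE, pretrain = TRUE,
               mode = "full", Ec_factor = 1)
  mod <- function(label, ...) {
    cond <- utils::modifyList(base, list(...))
    cond$label <- label
    cond
  }
  switch(spec$kind,
    noise_sweep = lapply(spec$snrs, function(s) mod(paste0("snr_", s), snr = s)),
    noise_pattern = unlist(lapply(spec$snrs, function(s) list(
      mod(paste0("gaussian_", s), snr = s, noise_kind = "gaussian"),
      mod(paste0("structured_", s), snr = s, noise_kind = "structured")
    )), recursive = FALSE),
    boundary_sweep = lapply(c("uniform_strain", "uniform_load", "normal_load",
                              "central_uniform_load"),
                            function(p) mod(p, profile = p)),
    activation_ablation = lapply(c("siren", "swish", "tanh", "relu"),
                                 function(a) mod(a, activation = a)),
    encoding_ablation = list(mod("encoded", use_encoding = TRUE),
                             mod("raw_coords", use_encoding = FALSE)),
    pretrain_ablation = list(mod("pretrained", pretrain = TRUE),
                             mod("no_pretrain", pretrain = FALSE)),
    strain_net_ablation = list(mod("full", mode = "full"),
                               mod("displacement_only", mode = "displacement_only"),
                               mod("fd_direct", mode = "fd_direct")),
    Ec_sweep = lapply(c(0.1, 1, 10), function(f) mod(paste0("Ec_x", f), Ec_factor = f))
  )
}

#' Run one recovery experiment cell
#'
#' Dataset generation, Phase-1 training, Phase-2 calibration and error
#' metrics for a single (condition, seed) pair. Used by [run_study()] and
#' directly by tests.
#'
#' @param cond named list with `snr`, `noise_kind`, `profile`,
#'   `activation`, `use_encoding`, `pretrain`, `mode`, `Ec_factor`
#' @param seed replicate seed (drives phantom noise and network init)
#' @param spec an [experiment_spec()]
#' @return one-row data.frame of metrics
#' @export
run_cell <- function(cond, seed, spec) {
  g <- grid2d(spec$grid_n, spec$grid_n,
              t = 1 / (spec$grid_n - 1), h = 1 / (spec$grid_n - 1))
  ph <- make_phantom(spec$phantom_descriptor, g, seed = seed)
  load <- boundary_load(cond$profile, F = spec$F)
  nz <- noise_spec(cond$noise_kind, snr = cond$snr, seed = seed)
  ds <- make_dataset(ph, g, load, nz)
  cfg <- spec$config
  cfg$seed <- seed
  cfg$activation <- cond$activation
  cfg$use_encoding <- cond$use_encoding
  cfg$pretrain <- cond$pretrain
  cfg$mode <- cond$mode
  cfg$Ec <- cond$Ec_factor * mean(ds$elast_true$E)
  res <- train_phase1(ds, cfg)
  cal <- calibrate(res, ds$F)
  data.frame(label = cond$label, seed = seed, ok = TRUE,
             mae_E = mae(cal$E_absolute, ds$elast_true$E),
             mre_E = mre(cal$E_absolute, ds$elast_true$E),
             mae_nu = mae(cal$nu, ds$elast_true$nu),
             mre_nu = mre(cal$nu, ds$elast_true$nu),
             c_hat = cal$c_hat, Ec = cfg$Ec,
             stringsAsFactors = FALSE)
}

#' @rdname experiment_spec
#' @param spec an `experiment_spec`
#' @param out_dir optional directory for CSV tables and PNG error maps
#' @return `run_study()` returns a list with `rows` (per-seed results),
#'   `summary` (per-condition medians) and `spec`
#' @export
run_study <- function(spec, out_dir = NULL) {
  conds <- study_conditions(spec)
  rows <- list()
  for (cond in conds) {
    for (seed in spec$seeds) {
      row <- tryCatch(run_cell(cond, seed, spec),
                      error = function(e) data.frame(
                        label = cond$label, seed = seed, ok = FALSE,
                        mae_E = NA_real_, mre_E = NA_real_,
                        mae_nu = NA_real_, mre_nu = NA_real_,
                        c_hat = NA_real_, Ec = NA_real_,
                        stringsAsFactors = FALSE))
      rows[[length(rows) + 1L]] <- row
    }
  }
  rows <- do.call(rbind, rows)
  med <- function(v) stats::median(v, na.rm = TRUE)
  summary <- do.call(rbind, lapply(split(rows, rows$label), function(d) {
    data.frame(label = d$label[1], n_ok = sum(d$ok),
               mae_E = med(d$mae_E), mre_E = med(d$mre_E),
               mae_nu = med(d$mae_nu), mre_nu = med(d$mre_nu),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(rows, file.path(out_dir, "rows.csv"), row.names = FALSE)
    utils::write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
    jsonlite::write_json(list(kind = spec$kind, seeds = spec$seeds,
                              snrs = spec$snrs, grid_n = spec$grid_n),
                         file.path(out_dir, "spec.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(rows = rows, summary = summary, spec = spec)
}
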