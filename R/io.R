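#' Dataset and checkpoint serialization
#'
#' Plain-text interchange formats. A dataset bundle is a directory holding
#' one CSV per scalar component (header `x,y,value`, coordinates of the
#' grid the component lives on) and a `meta.json` sidecar with the grid,
#' load, noise and seed metadata. Network checkpoints are single JSON
#' files containing the layer weights, the architecture/encoding specs and
#' the seed.
#'
#' @param ds an `elast_dataset` from [make_dataset()]
#' @param path directory to create/populate
#' @return `write_dataset_bundle` returns `path` invisibly;
#'   `read_dataset_bundle` returns a list of fields and metadata.
#' @export
write_dataset_bundle <- function(ds, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  g <- ds$grid
  wf <- function(mat, coords, name) {
    df <- data.frame(x = as.vector(coords$x), y = as.vector(coords$y),
                     value = as.vector(mat))
    utils::write.csv(df, file.path(path, paste0(name, ".csv")), row.names = FALSE)
  }
  nc <- node_coords(g); cc <- cell_coords(g)
  wf(ds$u_clean$ux, nc, "ux_clean"); wf(ds$u_clean$uy, nc, "uy_clean")
  wf(ds$u_obs$ux, nc, "ux"); wf(ds$u_obs$uy, nc, "uy")
  wf(ds$elast_true$E, cc, "E"); wf(ds$elast_true$nu, cc, "nu")
  meta <- list(nx = g$nx, ny = g$ny, t = g$t, h = g$h,
               x0 = g$origin[1], y0 = g$origin[2],
               load = unclass(ds$load), F = ds$F,
               noise = if (is.null(ds$noise)) NULL else unclass(ds$noise))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_dataset_bundle
#' @param path bundle directory
#' @export
read_dataset_bundle <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  g <- grid2d(meta$nx, meta$ny, meta$t, meta$h, c(meta$x0, meta$y0))
  rf <- function(name, d) {
    df <- utils::read.csv(file.path(path, paste0(name, ".csv")))
    matrix(df$value, d[1], d[2])
  }
  nd <- c(g$nx, g$ny); cd <- cell_dim(g)
  list(
    grid = g,
    u_obs = displacement_field(rf("ux", nd), rf("uy", nd), g),
    u_clean = displacement_field(rf("ux_clean", nd), rf("uy_clean", nd), g),
    elast_true = elasticity_field(rf("E", cd), rf("nu", cd), g),
    meta = meta
  )
}

#' @rdname write_dataset_bundle
#' @param net an `mlp` from [build_network()]
#' @param file JSON file path
#' @export
save_checkpoint <- function(net, file) {
  obj <- list(spec = unclass(net$spec), in_dim = net$in_dim, seed = net$seed,
              layers = lapply(net$layers, function(l) {
                list(W = as.vector(l$W), dim = dim(l$W), b = l$b)
              }))
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_dataset_bundle
#' @export
load_checkpoint <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  spec <- do.call(network_spec, obj$spec[c("depth", "width", "out_heads",
                                           "activation", "final", "omega0")])
  layers <- lapply(obj$layers$W, identity)  # placeholder, rebuilt below
  L <- length(obj$layers$dim)
  layers <- vector("list", L)
  for (l in seq_len(L)) {
    d <- obj$layers$dim[[l]]
    layers[[l]] <- list(W = matrix(obj$layers$W[[l]], d[1], d[2]),
                        b = as.numeric(obj$layers$b[[l]]))
  }
  structure(list(layers = layers, spec = spec, in_dim = obj$in_dim,
                 seed = obj$seed), class = "mlp")
}
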