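## Configuration, presets, mesh/profile writers and the run manifest.

.preset_table <- function() list(
  # two-component tubular protrusion: anisotropic A on isotropic B
  fig19 = list(mode = "minimize", model = "two_component",
               kappa_A = 8, kappa_B = 1, Hm_A = 8, Hm_B = 1,
               Dm_A = 8, Dm_B = 0, a0 = 0.0016, kT = 1 / 30,
               v = 0.85, phi_ave = 0.15, include_mixing = TRUE),
  # isotropic bud formation at high phi_ave
  fig20 = list(mode = "minimize", model = "two_component",
               kappa_A = 8, kappa_B = 1, Hm_A = 16, Hm_B = 1,
               Dm_A = 0, Dm_B = 0, a0 = 0.0016, kT = 1 / 30,
               v = 0.95, phi_ave = 0.1, include_mixing = TRUE),
  # saddle-like A accumulating in the neck
  fig21 = list(mode = "minimize", model = "two_component",
               kappa_A = 8, kappa_B = 1, Hm_A = 0, Hm_B = 2,
               Dm_A = 8, Dm_B = 0, a0 = 0.0016, kT = 1 / 30,
               v = 0.8, phi_ave = 0.1, include_mixing = TRUE),
  # rod-stretched two-component membrane (undulated -> tubular)
  fig23 = list(mode = "stretch", model = "two_component",
               kappa_A = 1, kappa_B = 1, Hm_A = 12, Hm_B = 0,
               Dm_A = 0, Dm_B = 0, a0 = 0.0016, kT = 0,
               v = 0.70, phi_ave = 0.35, include_mixing = FALSE),
  # rod-stretched BAR-decorated membrane
  fig25 = list(mode = "stretch", model = "bar",
               Cp = 3.0, KpL0 = 2, kc = 1, C0 = 0, kT = 0, a0 = 0.0016,
               v = 0.70, phi_ave = 0.25, include_mixing = FALSE),
  # discocyte-like vs spiculated shear + non-local bending runs
  fig12a = list(mode = "minimize", model = "shear_nonlocal",
                kc = 1, kn = 8, Ds0 = 1.038, mu = 10, v = 0.6),
  fig12b = list(mode = "minimize", model = "shear_nonlocal",
                kc = 1, kn = 8, Ds0 = 6.8, mu = 10, v = 0.6),
  # MC budding with negative-curvature nanodomains
  fig14a = list(mode = "mc-run", kappa = 25, c = -1, rho = 0.05,
                w = 1.25, force = 0, kT = 1, sweeps = 10000,
                subdivisions = 3),
  fig14b = list(mode = "mc-run", kappa = 25, c = -1, rho = 0.05,
                w = 1.25, force = -0.5, kT = 1, sweeps = 10000,
                subdivisions = 3))

#' Named parameter presets for the documented study conditions
#'
#' @param name preset name (`fig12a`, `fig12b`, `fig14a`, `fig14b`,
#'   `fig19`, `fig20`, `fig21`, `fig23`, `fig25`).
#' @return config list (see [load_config()] for the schema).
#' @export
preset <- function(name) {
  tab <- .preset_table()
  if (!name %in% names(tab))
    stop("unknown preset: ", name, " (available: ",
         paste(names(tab), collapse = ", "), ")")
  tab[[name]]
}

.config_schema <- c(
  "mode", "model", "preset", "seed", "out_dir",
  "kappa_A", "kappa_B", "Hm_A", "Hm_B", "Dm_A", "Dm_B", "a0", "kT",
  "kc", "kG", "C0", "Cp", "KpL0", "kn", "Ds0", "mu",
  "v", "phi_ave", "h_min", "h_min_grid", "v_grid", "include_mixing",
  "n_modes", "n_grid", "seed_shape", "maxit", "rounds",
  "kappa", "c", "rho", "w", "r0", "force", "sweeps", "subdivisions",
  "step", "frame_every", "audit_every", "check_every", "warmup",
  "swap_rate",
  "theta_bar", "dtheta", "r0_core", "zeta", "kappa0", "C0_mono",
  "xi", "H0", "r_prot", "R0_parent", "w_agg", "kT_agg", "rho_agg",
  "i_max")

#' Load and validate a run configuration
#'
#' YAML file with a `mode` key (`minimize`, `phase-scan`, `stretch`,
#' `mc-run`, `aggregate`, `inclusion-map`) and mode-specific parameters;
#' a `preset` key merges the named preset underneath explicit keys.
#' Unknown keys are rejected; defaults (`n_modes = 30`, `n_grid = 1000`,
#' etc.) are resolved here so the run manifest records the full
#' configuration.
#'
#' @param path YAML config path.
#' @return validated config list with all defaults resolved.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

#' @rdname load_config
#' @param cfg raw config list.
#' @export
validate_config <- function(cfg) {
  if (!is.null(cfg$preset)) {
    base <- preset(cfg$preset)
    cfg <- utils::modifyList(base, cfg[setdiff(names(cfg), "preset")])
  }
  unknown <- setdiff(names(cfg), .config_schema)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (is.null(cfg$mode)) stop("config needs a 'mode' key")
  defaults <- list(n_modes = 30L, n_grid = 1000L, seed = 1L,
                   include_mixing = TRUE, seed_shape = "prolate",
                   maxit = 400L, rounds = 10L)
  cfg <- utils::modifyList(defaults, cfg)
  if (!is.null(cfg$phi_ave) && (cfg$phi_ave < 0 || cfg$phi_ave > 1))
    stop("phi_ave must lie in [0, 1]")
  if (!is.null(cfg$v) && (cfg$v <= 0 || cfg$v > 1))
    stop("v must lie in (0, 1]")
  cfg
}

#' Write a triangle mesh as ASCII PLY
#' @param mesh list with `vertices` (n x 3) and `triangles` (m x 3,
#'   1-based); optional `domains` written as a vertex quality flag.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_ply <- function(mesh, path) {
  V <- mesh$vertices; Tm <- mesh$triangles
  dom <- mesh$domains
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(V)),
               "property float x", "property float y", "property float z",
               if (!is.null(dom)) "property uchar quality",
               sprintf("element face %d", nrow(Tm)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  vl <- if (is.null(dom))
    sprintf("%.8g %.8g %.8g", V[, 1], V[, 2], V[, 3])
  else
    sprintf("%.8g %.8g %.8g %d", V[, 1], V[, 2], V[, 3], as.integer(dom))
  writeLines(vl, con)
  writeLines(sprintf("3 %d %d %d", Tm[, 1] - 1L, Tm[, 2] - 1L, Tm[, 3] - 1L),
             con)
  invisible(path)
}

#' Read an ASCII PLY written by [write_ply()]
#' @param path PLY path.
#' @return list with `vertices` and `triangles` (1-based).
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)))
  hdr <- which(lines == "end_header")
  vl <- lines[(hdr + 1):(hdr + nv)]
  V <- do.call(rbind, lapply(strsplit(vl, " "),
                             function(z) as.numeric(z[1:3])))
  fl <- lines[(hdr + nv + 1):(hdr + nv + nf)]
  Tm <- do.call(rbind, lapply(strsplit(fl, " "),
                              function(z) as.integer(z[2:4]) + 1L))
  list(vertices = V, triangles = Tm)
}

#' Write a triangle mesh as Wavefront OBJ
#' @inheritParams write_ply
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  V <- mesh$vertices; Tm <- mesh$triangles
  writeLines(sprintf("v %.8g %.8g %.8g", V[, 1], V[, 2], V[, 3]), con)
  writeLines(sprintf("f %d %d %d", Tm[, 1], Tm[, 2], Tm[, 3]), con)
  invisible(path)
}

#' Write a triangle mesh as legacy ASCII VTK PolyData
#' @inheritParams write_ply
#' @export
write_vtk <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  V <- mesh$vertices; Tm <- mesh$triangles
  writeLines(c("# vtk DataFile Version 3.0", "memshape surface", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(V))), con)
  writeLines(sprintf("%.8g %.8g %.8g", V[, 1], V[, 2], V[, 3]), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(Tm), 4L * nrow(Tm)), con)
  writeLines(sprintf("3 %d %d %d", Tm[, 1] - 1L, Tm[, 2] - 1L,
                     Tm[, 3] - 1L), con)
  if (!is.null(mesh$domains)) {
    writeLines(c(sprintf("POINT_DATA %d", nrow(V)),
                 "SCALARS nanodomain int 1", "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%d", as.integer(mesh$domains)), con)
  }
  invisible(path)
}

#' Write run outputs (profile CSV, mesh, manifest JSON)
#'
#' @param result a `minimization_result` or `mc_run`.
#' @param dir output directory (created if needed).
#' @param config the configuration that produced the result (echoed into
#'   the manifest together with its hash and the package version).
#' @param basename file stem.
#' @return named vector of written paths, invisibly.
#' @export
write_outputs <- function(result, dir, config = list(), basename = "run") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  manifest <- list(
    package = "memshape",
    version = as.character(utils::packageVersion("memshape")),
    config = config,
    config_hash = config_hash(config),
    seed = config$seed)
  if (inherits(result, "minimization_result")) {
    p <- file.path(dir, paste0(basename, "_profile.csv"))
    write_profile_csv(result$grid, p, phi = result$phi)
    paths["profile"] <- p
    mesh <- revolve_mesh(result$grid)
    pm <- file.path(dir, paste0(basename, "_surface.ply"))
    write_ply(mesh, pm)
    paths["surface"] <- pm
    manifest$energy <- result$energy
    manifest$residuals <- as.list(result$residuals)
    manifest$converged <- result$converged
  } else if (inherits(result, "mc_run")) {
    pe <- file.path(dir, paste0(basename, "_energy.csv"))
    utils::write.csv(result$energy, pe, row.names = FALSE)
    paths["energy"] <- pe
    if (!is.null(result$cluster_hist)) {
      ph <- file.path(dir, paste0(basename, "_clusters.csv"))
      utils::write.csv(
        data.frame(size = seq_along(result$cluster_hist),
                   mean_count = result$cluster_hist),
        ph, row.names = FALSE)
      paths["clusters"] <- ph
    }
    snap <- mc_snapshot(result$state)
    pm <- file.path(dir, paste0(basename, "_final.ply"))
    write_ply(snap, pm)
    paths["mesh"] <- pm
    manifest$energy <- list(Wb = snap$Wb, Wd = snap$Wd, WF = snap$WF)
    manifest$acceptance <- list(move = result$acc_move,
                                flip = result$acc_flip)
    manifest$max_drift <- result$max_drift
  }
  pj <- file.path(dir, paste0(basename, "_manifest.json"))
  jsonlite::write_json(manifest, pj, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths["manifest"] <- pj
  invisible(paths)
}

#' Deterministic hash of a configuration list
#' @param config config list.
#' @return hex string (31-bit polynomial hash over the canonical JSON).
#' @export
config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
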