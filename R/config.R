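# Configuration, validation and reproducibility plumbing.  One YAML file
# fully determines a run; unknown keys are rejected and every default is
# echoed back.

#' Default configuration
#'
#' The full nested parameter bundle with every default filled in.
#' Model-constrained values (theta0 = 0.2 rad, B = 174, k_intra = 310,
#' t_kin = 13 ms, k_hydr = 0.24 /s, T = 310 K, ...) sit alongside
#' artifact defaults (bond widths, longitudinal barrier, window depth,
#' detachment scan interval), which are flagged in the parameter
#' documentation.
#'
#' @return nested named list with sections `mechanics`, `interaction`,
#'   `kinetics`, `nucleotide_effect`, `ring`, `simulation`, `protocol`.
#' @export
default_config <- function() {
  list(
    mechanics = list(k_intra = 310, B = 174, theta0 = 0.2, r_tub = 2,
                     k_rep = 100),
    interaction = list(a_lat = 6.3, b_lat = 8, r_lat = 1.0,
                       a_long = 2.1, b_long = 7.0, r_long = 0.5),
    kinetics = list(k_on = 0.26, c_tub = 10, t_kin = 0.013,
                    k_hydr = 0.24, detach_threshold = 0.1,
                    detach_interval = 1e-7, window_dimers = 20,
                    time_compression = 1),
    nucleotide_effect = list(mode = "lateral-bond", b_lat_gtp = 8,
                             b_lat_gdp = 4.7, B_gtp = 174, B_gdp = 174),
    ring = list(R_dam1 = 3, l0 = 5, l_max = 6, k_linker = 0.01),
    simulation = list(dt = 2e-12, temperature = 310, eta = 1e-3,
                      duration = 1e-4, record_stride = 1000,
                      snap_stride = 0, seed = 1, max_disp = 10),
    protocol = list(type = "constant", n_dimers = 30, nucleotide = "GTP",
                    cap_dimers = 0, cap_length = 110)
  )
}

.merge_section <- function(section, defaults, user) {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown key(s) in [%s]: %s", section,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  modifyList(defaults, user)
}

#' Load and validate a configuration file
#'
#' Reads a YAML configuration, fills every missing value with its
#' default, rejects unknown keys, and validates all parameter invariants
#' by constructing the typed bundles.  An empty file yields the full
#' default bundle.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return list with `config` (the merged nested list) and `params`
#'   (validated bundles: `mech`, `inter`, `nuc`, `kin`, `ring`, `sim`,
#'   plus `protocol`).
#' @export
load_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else {
    .check(file.exists(path), paste("no such config file:", path))
    yaml::read_yaml(path) %||% list()
  }
  defaults <- default_config()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop(paste("unknown config section(s):",
               paste(unknown, collapse = ", ")), call. = FALSE)
  cfg <- lapply(names(defaults), function(s) {
    .merge_section(s, defaults[[s]], user[[s]])
  })
  names(cfg) <- names(defaults)
  config_params(cfg)
}

#' Build validated parameter bundles from a nested configuration
#'
#' @param cfg nested list as returned by [default_config()].
#' @return see [load_config()].
#' @export
config_params <- function(cfg) {
  m <- cfg$mechanics
  i <- cfg$interaction
  k <- cfg$kinetics
  ne <- cfg$nucleotide_effect
  r <- cfg$ring
  s <- cfg$simulation
  params <- list(
    mech = mechanical_params(m$k_intra, m$B, m$theta0, m$r_tub, m$k_rep),
    inter = interaction_params(i$a_lat, i$b_lat, i$r_lat, i$a_long,
                               i$b_long, i$r_long),
    nuc = nucleotide_effect(ne$mode, ne$b_lat_gtp, ne$b_lat_gdp,
                            ne$B_gtp, ne$B_gdp),
    kin = kinetic_params(k$k_on, k$c_tub, k$t_kin, k$k_hydr,
                         k$detach_threshold, k$detach_interval,
                         k$window_dimers, k$time_compression),
    ring = ring_params(r$R_dam1, r$l0, r$l_max, r$k_linker),
    sim = sim_config(s$dt, s$temperature, s$eta, s$duration,
                     s$record_stride, s$snap_stride, s$seed, s$max_disp),
    protocol = cfg$protocol)
  list(config = cfg, params = params)
}

#' Write a run manifest
#'
#' Records the configuration snapshot, seed, package version and an
#' inventory of output files with MD5 hashes, as
#' `<dir>/manifest.json`.
#'
#' @param dir output directory.
#' @param config nested configuration list.
#' @param seed the master seed of the run.
#' @param files character vector of produced files (paths relative to
#'   `dir` or absolute).
#' @return the manifest path, invisibly.
#' @export
write_manifest <- function(dir, config, seed, files = character()) {
  paths <- ifelse(file.exists(files), files, file.path(dir, files))
  inventory <- lapply(seq_along(files), function(i) {
    list(file = files[i],
         md5 = unname(tools::md5sum(paths[i])))
  })
  manifest <- list(
    package = "mtdyn",
    version = as.character(utils::packageVersion("mtdyn")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    outputs = inventory)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
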