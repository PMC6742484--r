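#' Serialize a microtubule model to JSON
#'
#' Documented layout: \code{geometry} (the lattice constants),
#' \code{config}, \code{pf_lengths}, and \code{placements} (protofilament
#' and layer indices; poses are reconstructed from the lattice
#' constants).
#'
#' @param mt A \code{microtubule_model}.
#' @param path Optional file; when NULL the JSON string is returned.
#' @return The path (invisibly) or the JSON string.
#' @export
mt_to_json <- function(mt, path = NULL) {
  obj <- list(geometry = mt$constants, config = mt$config,
              n_dimers = mt$n_dimers, pf_lengths = mt$pf_lengths,
              placements = mt$placements)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname mt_to_json
#' @param json Path to (or string of) JSON written by
#'   \code{mt_to_json}.
#' @export
mt_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  cst <- obj$geometry
  cfg <- obj$config
  if (cfg == "single_dimer") return(build_microtubule("single_dimer",
                                                      constants = cst))
  if (cfg == "tapered")
    return(build_microtubule("tapered", obj$n_dimers,
                             taper_profile = obj$pf_lengths,
                             constants = cst))
  mt <- build_microtubule(cfg, obj$n_dimers, constants = cst)
  stopifnot(identical(as.integer(mt$pf_lengths),
                      as.integer(obj$pf_lengths)))
  mt
}

#' Export a whole lattice assembly as OBJ
#'
#' @param mt A \code{microtubule_model}.
#' @param path Output OBJ path.
#' @return Invisibly the path.
#' @export
export_microtubule_obj <- function(mt, path) {
  shape <- build_tubulin_shape(mt$constants)
  write_obj(rep(list(shape), mt$n_dimers), path, poses = mt$poses)
}

.run_config_schema <- list(
  geometry = c("config", "n_dimers", "taper_profile"),
  physics = c("temperature", "viscosity", "binder_mode"),
  ensemble = c("n_molecules", "replicates", "seed", "max_steps"),
  analysis = c("include_seam"),
  output = c("dir", "prefix")
)

#' Read and validate a run configuration
#'
#' YAML file with blocks \code{geometry}, \code{physics},
#' \code{ensemble}, \code{analysis}, \code{output}; unknown blocks or
#' keys are rejected so typos fail loudly.
#'
#' @param path YAML file.
#' @return Validated configuration list of class \code{"run_config"}.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A configuration list.
#' @export
validate_run_config <- function(cfg) {
  schema <- .run_config_schema
  # "resolved" is the provenance block a run writes next to its outputs
  extra <- setdiff(names(cfg), c(names(schema), "resolved"))
  if (length(extra) > 0)
    stop("unknown config block(s): ", paste(extra, collapse = ", "))
  for (blk in setdiff(names(cfg), "resolved")) {
    bad <- setdiff(names(cfg[[blk]]), schema[[blk]])
    if (length(bad) > 0)
      stop(sprintf("unknown key(s) in block '%s': %s", blk,
                   paste(bad, collapse = ", ")))
  }
  geom <- cfg$geometry %||% list()
  if (!is.null(geom$config) &&
      !geom$config %in% c("blunt", "tapered", "sheet", "single_dimer"))
    stop("invalid geometry config tag: ", geom$config)
  phys <- cfg$physics %||% list()
  if (!is.null(phys$binder_mode) &&
      !phys$binder_mode %in% c("pocket", "face"))
    stop("invalid binder_mode: ", phys$binder_mode)
  structure(cfg, class = "run_config")
}

#' Run a simulation from a configuration
#'
#' Builds the geometry, enumerates sites, runs the ensemble and writes
#' the arrival table (CSV), the per-class fractions (CSV), the resolved
#' configuration (YAML) and the model (JSON) into the output directory,
#' so a run can be reproduced bit-identically from its own outputs.
#'
#' @param cfg A \code{run_config} (or path to one).
#' @return The arrival table, invisibly; side effect: files under
#'   \code{cfg$output$dir}.
#' @export
run_from_config <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  geom <- cfg$geometry %||% list()
  phys <- cfg$physics %||% list()
  ens <- cfg$ensemble %||% list()
  outp <- cfg$output %||% list()
  dir <- outp$dir %||% "."
  prefix <- outp$prefix %||% "run"
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  mt <- build_microtubule(geom$config %||% "blunt",
                          geom$n_dimers %||% 207L,
                          taper_profile = geom$taper_profile)
  mode <- phys$binder_mode %||% "pocket"
  sites <- enumerate_sites(mt, mode,
                           include_seam = cfg$analysis$include_seam %||% TRUE)
  binder <- build_binder_shape(mode)
  model <- diffusion_model(binder,
                           temperature = phys$temperature %||% 298,
                           viscosity = phys$viscosity %||% 8.9e-4)
  scfg <- simulation_config(seed = ens$seed %||% 1,
                            max_steps = ens$max_steps %||% 3e6)
  tab <- run_ensemble(mt, sites, binder, model, scfg,
                      n_molecules = ens$n_molecules %||% 1000L,
                      replicates = seq_len(ens$replicates %||% 1L))
  stem <- file.path(dir, prefix)
  utils::write.csv(tab, paste0(stem, "_arrivals.csv"), row.names = FALSE)
  utils::write.csv(per_site_class_fractions(tab, sites),
                   paste0(stem, "_fractions.csv"), row.names = FALSE)
  mt_to_json(mt, paste0(stem, "_model.json"))
  resolved <- cfg
  resolved$resolved <- list(
    package_version = as.character(utils::packageVersion("mtarrival")),
    binder_radius_nm = effective_radius(binder),
    n_sites = length(sites))
  yaml::write_yaml(resolved, paste0(stem, "_config.yaml"))
  invisible(tab)
}
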