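SNAPSHOT_SCHEMA <- 1L

# ---- snapshot persistence ------------------------------------------------------

#' Write a tissue snapshot to a JSON file
#'
#' The snapshot format is a human-inspectable, schema-versioned JSON document
#' holding vertices, walls (endpoints, rest length, incident cells, per-side
#' PIN), cell loops and per-cell state. Numbers are written at full precision,
#' so a write/read round trip reproduces every state field bit-exactly.
#'
#' @param mesh a `tissue_mesh`
#' @param path output file path
#' @param config_digest optional string identifying the generating
#'   configuration
#' @return `path`, invisibly
#' @export
write_snapshot <- function(mesh, path, config_digest = NULL) {
  doc <- list(
    schema = SNAPSHOT_SCHEMA,
    iteration = mesh$iteration,
    config_digest = config_digest,
    vertices = list(x = mesh$pos[, 1L], y = mesh$pos[, 2L]),
    walls = as.list(mesh$walls),
    cells = list(loops = mesh$loops, aux = mesh$aux, cuc = mesh$cuc,
                 delta = mesh$delta))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       na = "null", null = "null", pretty = FALSE)
  invisible(path)
}

#' Read a tissue snapshot written by [write_snapshot()]
#'
#' @param path snapshot file path
#' @return a `tissue_mesh`
#' @export
read_snapshot <- function(path) {
  if (!file.exists(path)) stop("snapshot file not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (is.null(doc$schema) || doc$schema != SNAPSHOT_SCHEMA)
    stop("snapshot schema mismatch: file has version ",
         if (is.null(doc$schema)) "none" else doc$schema,
         ", this package reads version ", SNAPSHOT_SCHEMA)
  pos <- cbind(doc$vertices$x, doc$vertices$y)
  w <- doc$walls
  walls <- data.frame(v1 = as.integer(w$v1), v2 = as.integer(w$v2),
                      rest = as.numeric(w$rest), c1 = as.integer(w$c1),
                      c2 = as.integer(w$c2), pin1 = as.numeric(w$pin1),
                      pin2 = as.numeric(w$pin2))
  loops <- lapply(doc$cells$loops, as.integer)
  mesh <- new_tissue_mesh(pos, walls, loops, as.numeric(doc$cells$aux),
                          as.numeric(doc$cells$cuc),
                          as.numeric(doc$cells$delta),
                          as.integer(doc$iteration))
  bad <- validate_mesh(mesh)
  if (length(bad)) stop("snapshot fails validation: ", paste(bad, collapse = "; "))
  mesh
}

# ---- run configuration files ---------------------------------------------------

config_defaults <- function() {
  list(genotype = "WT", growth_rate = 0.8, n_iterations = 100L, seed = 1L,
       snapshot_every = 10L, division_area_thres = 50, max_wall_len = 1,
       frozen_noise = FALSE, mechanics = list(), chemistry = list())
}

#' Load a simulation configuration from a JSON or YAML file
#'
#' Unspecified fields take the documented defaults (wild type, growth rate
#' 0.8, 100 iterations). `mechanics` and `chemistry` sub-tables override
#' individual [mechanics_params()] / [chem_params()] fields. Unknown keys,
#' type mismatches and out-of-range values are aggregated and reported
#' together.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file
#' @return a [sim_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    if (!nzchar(trimws(txt))) list() else
      jsonlite::fromJSON(txt, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  if (is.null(raw)) raw <- list()
  defaults <- config_defaults()
  problems <- character(0)
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    problems <- c(problems, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, raw[intersect(names(raw), names(defaults))])
  check_num <- function(name, lo = -Inf, strict = FALSE) {
    v <- cfg[[name]]
    if (!is.numeric(v) || length(v) != 1L)
      problems <<- c(problems, paste0(name, " must be a single number"))
    else if (if (strict) v <= lo else v < lo)
      problems <<- c(problems, paste0(name, " must be ", if (strict) "> " else ">= ", lo))
  }
  check_num("growth_rate", 0)
  check_num("n_iterations", 1)
  check_num("seed")
  check_num("snapshot_every", 1)
  check_num("division_area_thres", 0, strict = TRUE)
  check_num("max_wall_len", 0, strict = TRUE)
  gen <- tryCatch(genotype_preset(cfg$genotype), error = function(e) conditionMessage(e))
  if (is.character(gen)) problems <- c(problems, gen)
  mk <- function(ctor, overrides, label) {
    bad <- setdiff(names(overrides), names(formals(ctor)))
    if (length(bad)) {
      problems <<- c(problems, paste0("unknown ", label, " key(s): ",
                                      paste(bad, collapse = ", ")))
      overrides <- overrides[setdiff(names(overrides), bad)]
    }
    tryCatch(do.call(ctor, overrides), error = function(e) {
      problems <<- c(problems, paste0("invalid ", label, ": ", conditionMessage(e)))
      ctor()
    })
  }
  mech <- mk(mechanics_params, cfg$mechanics, "mechanics")
  chem <- mk(chem_params, cfg$chemistry, "chemistry")
  if (length(problems))
    stop("invalid configuration (", path, "):\n  - ",
         paste(problems, collapse = "\n  - "))
  sim_config(genotype = gen, growth_rate = cfg$growth_rate,
             n_iterations = as.integer(cfg$n_iterations),
             seed = as.integer(cfg$seed),
             snapshot_every = as.integer(cfg$snapshot_every),
             mechanics = mech, chemistry = chem,
             division_area_thres = cfg$division_area_thres,
             max_wall_len = cfg$max_wall_len,
             frozen_noise = isTRUE(cfg$frozen_noise))
}

#' Serialise the fully resolved parameter set of a configuration
#'
#' Emits a machine-readable record sufficient to reproduce a run.
#'
#' @param config a [sim_config()]
#' @param path optional file to write to
#' @return the JSON string, invisibly if written to a file
#' @export
config_record <- function(config, path = NULL) {
  rec <- list(genotype = config$genotype, growth_rate = config$growth_rate,
              n_iterations = config$n_iterations, seed = config$seed,
              snapshot_every = config$snapshot_every,
              mechanics = unclass(config$mechanics),
              chemistry = unclass(config$chemistry),
              division_area_thres = config$division_area_thres,
              max_wall_len = config$max_wall_len,
              frozen_noise = config$frozen_noise)
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
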