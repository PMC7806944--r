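## Key = value configuration files in the style of MD-automation tools.
##
## Arrays are given in bracketed whitespace- (or comma-) separated form,
## e.g. `attach_rest = [ 0.0 0.5 1.0 ... 100.0 ]`. Unknown keys are kept
## with a warning so engine-specific extras survive a round-trip.

CONFIG_NUMERIC_KEYS <- c(
  "l1_x", "l1_y", "l1_range", "l1_z", "l1_zm", "min_adis", "max_adis",
  "rec_distance_force", "rec_angle_force", "rec_discf_force",
  "rec_dihcf_force", "lig_distance_force", "lig_angle_force",
  "lig_discf_force", "lig_dihcf_force", "temperature", "dd_dist",
  "blocks", "seed", "num_waters", "buffer_x", "buffer_y", "lig_buffer",
  "num_cations", "num_cat_ligbox", "eq_steps1", "eq_steps2",
  "prep_steps1", "bb_start", "bb_end", "n_samples"
)
CONFIG_ARRAY_KEYS <- c("attach_rest", "lambdas", "weights", "release_eq")
CONFIG_TEXT_KEYS <- c("calc_type", "method", "dd_type", "components",
                      "P1", "P2", "P3", "water_model", "cation", "anion",
                      "neutralize_only", "lig_resname", "rec_bb",
                      "bb_equil", "poses_list")

#' Parse a key = value input file
#'
#' @param path path to a `key = value` configuration file. `#` starts a
#'   comment; arrays use `[v1 v2 ...]`.
#' @return Named list of class `abfe_config` (numeric, array and text keys
#'   typed; unknown keys kept verbatim with a warning).
#' @export
parse_input_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) != 3)
      stop("malformed config line: ", ln)
    key <- m[2]
    val <- trimws(m[3])
    if (grepl("^\\[", val)) {
      if (!grepl("\\]$", val)) stop("malformed array for key ", key)
      body <- gsub("^\\[|\\]$", "", val)
      parts <- strsplit(trimws(body), "[[:space:],]+")[[1]]
      parts <- parts[nzchar(parts)]
      num <- suppressWarnings(as.numeric(parts))
      if (any(is.na(num))) stop("malformed array for key ", key)
      cfg[[key]] <- num
    } else if (key %in% CONFIG_NUMERIC_KEYS) {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num)) stop("key ", key, " requires a numeric value")
      cfg[[key]] <- num
    } else {
      if (!key %in% c(CONFIG_TEXT_KEYS, CONFIG_ARRAY_KEYS))
        warning("unknown config key kept verbatim: ", key)
      cfg[[key]] <- val
    }
  }
  cfg <- apply_config_defaults(cfg)
  validate_config(cfg)
  structure(cfg, class = "abfe_config")
}

apply_config_defaults <- function(cfg) {
  defaults <- list(
    calc_type = "dock", method = "DD", dd_type = "TI-GQ",
    temperature = DEFAULT_TEMPERATURE, blocks = 4,
    components = if (identical(cfg$method, "SDR"))
      "a l t e v b c r" else "a l t e v w f b c r",
    lig_resname = "LIG", seed = 1,
    l1_x = 0, l1_y = 0, l1_range = 2.5, l1_z = 3, l1_zm = 9,
    min_adis = 2, max_adis = 7,
    rec_distance_force = 10, rec_angle_force = 100,
    rec_discf_force = 1, rec_dihcf_force = 150,
    lig_distance_force = 5, lig_angle_force = 250,
    lig_discf_force = 5, lig_dihcf_force = 70,
    attach_rest = c(0, 0.5, 1, 2, 4, 8, 16, 24, 32, 40, 48, 56, 64,
                    72, 80, 100),
    n_samples = 1000
  )
  for (k in names(defaults))
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  cfg
}

config_components <- function(cfg) {
  strsplit(trimws(cfg$components), "[[:space:],]+")[[1]]
}

#' Validate a configuration
#'
#' Checks the attach schedule domain, method/component compatibility (SDR
#' excludes `f` and `w`), lambda domain and temperature.
#'
#' @param cfg an `abfe_config` (or plain list).
#' @return The config, invisibly; errors on violation.
#' @export
validate_config <- function(cfg) {
  if (!cfg$method %in% c("DD", "SDR", "APR"))
    stop("method must be DD, SDR or APR")
  if (cfg$method == "APR")
    stop("the APR physical-pull path is not implemented here; ",
         "use method = DD or SDR")
  comps <- config_components(cfg)
  if (cfg$method == "SDR" && any(c("f", "w") %in% comps))
    stop("SDR does not include the f and w components")
  ar <- cfg$attach_rest
  if (ar[1] != 0 || ar[length(ar)] != 100 || is.unsorted(ar))
    stop("attach_rest must increase from 0 to 100")
  if (!is.null(cfg$lambdas) && any(cfg$lambdas < 0 | cfg$lambdas > 1))
    stop("lambdas outside [0, 1]")
  if (cfg$temperature <= 0) stop("temperature must be positive")
  if (cfg$method == "SDR" && is.null(cfg$dd_dist))
    stop("SDR requires dd_dist")
  invisible(cfg)
}

#' Serialize a configuration
#'
#' Inverse of [parse_input_file()]: `parse(serialize(parse(x)))` is the
#' identity on the typed values.
#'
#' @param cfg an `abfe_config`.
#' @param path output path.
#' @export
write_input_file <- function(cfg, path) {
  fmt <- function(v) {
    if (length(v) > 1) paste0("[ ", paste(format(v, digits = 15),
                                          collapse = " "), " ]")
    else if (is.numeric(v)) format(v, digits = 15)
    else as.character(v)
  }
  keys <- names(cfg)
  writeLines(paste0(keys, " = ", vapply(cfg[keys], fmt, character(1))),
             path)
  invisible(NULL)
}
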