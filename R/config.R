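## Run configuration resolution (YAML file + overrides) and output
## provenance. Parsing is strict: unknown keys are errors, with a
## nearest-match suggestion, so sweep configurations cannot silently
## misspell a constraint.

.CONFIG_KEYS <- c("preset", "energy", "seedRequired", "seedBP", "seedNoGU",
                  "seedMaxE", "seedMaxEhybrid", "seedMinPu",
                  "intLenMax", "intMaxE", "intMinPu", "maxLoop")

#' Resolve a prediction configuration from file and overrides
#'
#' Values are resolved in order: preset defaults, then the YAML config
#' file, then `overrides` (command-line flags win over file values).
#' Unknown keys are rejected with a suggestion for the nearest known key.
#'
#' Recognized keys: `preset` (`"default"`/`"recommended"`), `energy`
#' (parameter preset name or file), `seedRequired`, `seedBP`,
#' `seedNoGU`, `seedMaxE`, `seedMaxEhybrid`, `seedMinPu`, `intLenMax`,
#' `intMaxE`, `intMinPu`, `maxLoop`.
#'
#' @param file Optional path to a YAML config file.
#' @param overrides Named list of overriding values.
#' @return A `prediction_config`; the fully resolved key/value set is
#'   attached as attribute `"resolved"`.
#' @export
parse_run_config <- function(file = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(file)) {
    if (!file.exists(file)) stop("config file not found: ", file)
    vals <- yaml::read_yaml(file)
    if (is.null(vals)) vals <- list()
  }
  for (nm in names(overrides)) vals[[nm]] <- overrides[[nm]]
  unknown <- setdiff(names(vals), .CONFIG_KEYS)
  if (length(unknown) > 0L) {
    d <- utils::adist(unknown[1], .CONFIG_KEYS, ignore.case = TRUE)
    hint <- .CONFIG_KEYS[which.min(d)]
    stop("unknown config key '", unknown[1], "'",
         if (min(d) <= 3) paste0(" (did you mean '", hint, "'?)") else "")
  }
  preset <- if (is.null(vals$preset)) "default" else vals$preset
  energy <- if (is.null(vals$energy)) "default" else vals$energy
  cfg <- prediction_preset(preset, params = energy)
  s <- cfg$seed; it <- cfg$interaction
  num <- function(key, v) {
    x <- suppressWarnings(as.numeric(v))
    if (length(x) != 1L || is.na(x)) stop("config key '", key, "': expected a number, got '", v, "'")
    x
  }
  flag <- function(key, v) {
    if (is.logical(v) && length(v) == 1L && !is.na(v)) return(v)
    stop("config key '", key, "': expected true/false, got '", v, "'")
  }
  if (!is.null(vals$seedRequired)) s$seed_required <- flag("seedRequired", vals$seedRequired)
  if (!is.null(vals$seedBP)) s$seed_bp <- as.integer(num("seedBP", vals$seedBP))
  if (!is.null(vals$seedNoGU)) s$allow_gu <- !flag("seedNoGU", vals$seedNoGU)
  if (!is.null(vals$seedMaxE)) s$seed_max_e <- num("seedMaxE", vals$seedMaxE)
  if (!is.null(vals$seedMaxEhybrid)) s$seed_max_e_hybrid <- num("seedMaxEhybrid", vals$seedMaxEhybrid)
  if (!is.null(vals$seedMinPu)) s$seed_min_pu <- num("seedMinPu", vals$seedMinPu)
  if (!is.null(vals$intLenMax)) it$int_len_max <- as.integer(num("intLenMax", vals$intLenMax))
  if (!is.null(vals$intMaxE)) it$int_max_e <- num("intMaxE", vals$intMaxE)
  if (!is.null(vals$intMinPu)) it$int_min_pu <- num("intMinPu", vals$intMinPu)
  if (!is.null(vals$maxLoop)) it$max_loop <- as.integer(num("maxLoop", vals$maxLoop))
  out <- prediction_config(
    seed = do.call(seed_constraints, stats::setNames(
      s[c("seed_required", "seed_bp", "allow_gu", "seed_max_e",
          "seed_max_e_hybrid", "seed_min_pu")],
      c("seed_required", "seed_bp", "allow_gu", "seed_max_e",
        "seed_max_e_hybrid", "seed_min_pu"))),
    interaction = do.call(interaction_constraints, stats::setNames(
      it[c("int_len_max", "int_max_e", "int_min_pu", "max_loop")],
      c("int_len_max", "int_max_e", "int_min_pu", "max_loop"))),
    params = cfg$params)
  resolved <- list(preset = preset, energy = cfg$params$name,
                   seedRequired = out$seed$seed_required,
                   seedBP = out$seed$seed_bp,
                   seedNoGU = !out$seed$allow_gu,
                   seedMaxE = out$seed$seed_max_e,
                   seedMaxEhybrid = out$seed$seed_max_e_hybrid,
                   seedMinPu = out$seed$seed_min_pu,
                   intLenMax = out$interaction$int_len_max,
                   intMaxE = out$interaction$int_max_e,
                   intMinPu = out$interaction$int_min_pu,
                   maxLoop = out$interaction$max_loop)
  attr(out, "resolved") <- resolved
  out
}

#' Provenance header lines for an output file
#'
#' Machine-readable `#key=value` comment lines recording the tool
#' version, the fully resolved configuration and MD5 checksums of the
#' input files. All coordinates in outputs are 1-based inclusive.
#'
#' @param config A `prediction_config` (ideally from
#'   [parse_run_config()], so the resolved key set is attached).
#' @param inputs Character vector of input file paths to checksum.
#' @return Character vector of header lines starting with `#`.
#' @export
provenance_header <- function(config, inputs = character()) {
  resolved <- attr(config, "resolved")
  if (is.null(resolved)) {
    resolved <- list(seedRequired = config$seed$seed_required,
                     seedBP = config$seed$seed_bp,
                     seedNoGU = !config$seed$allow_gu,
                     seedMaxE = config$seed$seed_max_e,
                     seedMaxEhybrid = config$seed$seed_max_e_hybrid,
                     seedMinPu = config$seed$seed_min_pu,
                     intLenMax = config$interaction$int_len_max,
                     intMaxE = config$interaction$int_max_e,
                     intMinPu = config$interaction$int_min_pu,
                     maxLoop = config$interaction$max_loop,
                     energy = config$params$name)
  }
  fmt <- function(v) if (is.null(v)) "unset" else as.character(v)
  lines <- c(paste0("#seedscan=", as.character(utils::packageVersion("seedscan"))),
             "#coordinates=1-based inclusive",
             vapply(names(resolved), function(k) {
               paste0("#config.", k, "=", fmt(resolved[[k]]))
             }, character(1)))
  inputs <- inputs[file.exists(inputs)]
  if (length(inputs) > 0L) {
    sums <- tools::md5sum(inputs)
    lines <- c(lines, paste0("#input.", basename(inputs), ".md5=", unname(sums)))
  }
  unname(lines)
}

#' Write a table with a provenance header
#'
#' @param df Data frame.
#' @param path Output path.
#' @param config A `prediction_config` for the provenance header.
#' @param inputs Input paths to checksum.
#' @param sep Field separator (`","` for CSV, `"\t"` for TSV).
#' @return Invisibly, `path`.
#' @export
write_table_with_provenance <- function(df, path, config, inputs = character(),
                                        sep = ",") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(config, inputs), con)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}
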