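## Nearest-neighbor scoring of intermolecular hybrids.
##
## A parameter set consists of a 36-entry dyad stacking table, an
## interior-loop/bulge cost a + b*ln(u1+u2), a duplex initiation term,
## per-pair helix-end penalties, and per-pair energies for the
## intramolecular ensemble used by the accessibility module. Units are
## kcal/mol everywhere.

#' Names of the shipped energy parameter presets
#'
#' @return Character vector of preset names accepted by
#'   [load_energy_parameters()].
#' @export
energy_presets <- function() {
  files <- list.files(system.file("extdata", "energy", package = "seedscan"),
                      pattern = "\\.tsv$")
  sort(sub("\\.tsv$", "", files))
}

#' Load a nearest-neighbor energy parameter set
#'
#' Reads a parameter file in the documented sectioned TSV format
#' (`[meta]`, `[stack]`, `[loop]`, `[init]`, `[terminal]`).
#' `source` may be the name of a shipped preset (see [energy_presets()])
#' or a path to a parameter file. Missing or non-finite entries are an
#' error, never silently defaulted. The same parameter set drives both
#' hybridization scoring and the intramolecular accessibility ensemble.
#'
#' @param source Preset name or file path.
#' @return An object of class `energy_params`: a list with elements
#'   `name`, `temperature` (kelvin), `stack` (named numeric, 36 dyads
#'   `"P1/P2"`), `loop_a`, `loop_b`, `init`, `terminal` (named numeric,
#'   6 pairs).
#' @examples
#' p <- load_energy_parameters("default")
#' p$stack[["CG/CG"]]
#' @export
load_energy_parameters <- function(source) {
  stopifnot(is.character(source), length(source) == 1L)
  path <- source
  if (!file.exists(path)) {
    path <- system.file("extdata", "energy", paste0(source, ".tsv"),
                        package = "seedscan")
    if (!nzchar(path) || !file.exists(path)) {
      stop("unknown energy preset or missing file: '", source, "' (shipped presets: ",
           paste(energy_presets(), collapse = ", "), ")")
    }
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  section <- NA_character_
  vals <- list(meta = character(), stack = character(), loop = character(),
               init = character(), terminal = character())
  store <- lapply(vals, function(x) list())
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- sub("^\\[(.+)\\]$", "\\1", ln)
      if (!section %in% names(store)) {
        stop("malformed parameter file: unknown section [", section, "] in ", path)
      }
      next
    }
    if (is.na(section)) stop("malformed parameter file: data before first section in ", path)
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      stop("malformed parameter file: expected 'key<TAB>value', got '", ln, "'")
    }
    store[[section]][[parts[1]]] <- parts[2]
  }
  num <- function(section, key) {
    v <- store[[section]][[key]]
    if (is.null(v)) stop("incomplete parameter file: missing [", section, "] ", key)
    x <- suppressWarnings(as.numeric(v))
    if (!is.finite(x)) stop("malformed parameter file: non-finite value for [",
                            section, "] ", key)
    x
  }

  dyads <- as.vector(outer(.CANONICAL_PAIRS, .CANONICAL_PAIRS,
                           function(a, b) paste0(a, "/", b)))
  missing_stack <- setdiff(dyads, names(store$stack))
  if (length(missing_stack) > 0L) {
    stop("incomplete stacking table: missing ", length(missing_stack),
         " dyad(s), e.g. ", missing_stack[1])
  }
  extra <- setdiff(names(store$stack), dyads)
  if (length(extra) > 0L) {
    stop("malformed parameter file: unknown stack dyad '", extra[1], "'")
  }
  stack <- vapply(dyads, function(d) num("stack", d), numeric(1))

  terminal <- vapply(.CANONICAL_PAIRS, function(p) num("terminal", p), numeric(1))
  loop_a <- num("loop", "a")
  loop_b <- num("loop", "b")
  if (loop_b < 0) {
    stop("invalid parameter file: loop cost must be non-decreasing in loop size (b >= 0)")
  }
  temperature <- num("meta", "temperature")
  if (temperature <= 0) stop("invalid parameter file: temperature must be > 0")
  name <- store$meta[["name"]]
  if (is.null(name)) name <- basename(path)

  structure(list(name = name, temperature = temperature, stack = stack,
                 loop_a = loop_a, loop_b = loop_b, init = num("init", "init"),
                 terminal = terminal, source = path),
            class = "energy_params")
}

#' @export
print.energy_params <- function(x, ...) {
  cat("Energy parameter set '", x$name, "' (", x$source, ")\n", sep = "")
  cat("  temperature: ", x$temperature, " K\n", sep = "")
  cat("  stack table: 36 dyads, range [", min(x$stack), ", ", max(x$stack),
      "] kcal/mol\n", sep = "")
  cat("  loop cost:   ", x$loop_a, " + ", x$loop_b, " * ln(u1+u2) kcal/mol\n", sep = "")
  cat("  init:        ", x$init, " kcal/mol\n", sep = "")
  invisible(x)
}

.check_pair <- function(pair) {
  if (!is.character(pair) || length(pair) != 1L || !pair %in% .CANONICAL_PAIRS) {
    stop("non-canonical base pair: '", paste(pair, collapse = ""),
         "' (canonical pairs: ", paste(.CANONICAL_PAIRS, collapse = ", "), ")")
  }
  pair
}

#' Test whether a base pair is a GU wobble pair
#'
#' @param pair Two-character pair string such as `"GU"`.
#' @return `TRUE` iff the pair is `GU` or `UG`.
#' @export
is_gu_pair <- function(pair) {
  .check_pair(pair) %in% c("GU", "UG")
}

#' Dyad stacking energy
#'
#' Free-energy contribution of two adjacent intermolecular base pairs
#' (`left` is 5' of `right` on RNA1), read from the parameter set's
#' stacking table.
#'
#' @param params An `energy_params` object.
#' @param left,right Two-character pair strings (`"CG"`, `"AU"`, ...),
#'   written as RNA1-residue then RNA2-residue.
#' @return Stacking free energy in kcal/mol.
#' @export
stacking_energy <- function(params, left, right) {
  stopifnot(inherits(params, "energy_params"))
  unname(params$stack[[paste0(.check_pair(left), "/", .check_pair(right))]])
}

#' Interior loop / bulge cost
#'
#' Cost of an intermolecular interior loop or bulge with `u1` and `u2`
#' unpaired bases on the two strands (`u1 + u2 >= 1`):
#' `a + b * ln(u1 + u2)`.
#'
#' @param params An `energy_params` object.
#' @param u1,u2 Non-negative integer counts of unpaired bases.
#' @return Loop free energy in kcal/mol.
#' @export
loop_energy <- function(params, u1, u2) {
  stopifnot(inherits(params, "energy_params"), u1 >= 0, u2 >= 0, u1 + u2 >= 1)
  params$loop_a + params$loop_b * log(u1 + u2)
}

#' Hybridization energy of an intermolecular duplex
#'
#' Sums the nearest-neighbor terms of a duplex given its ordered base
#' pairs: duplex initiation, one stacking term per directly adjacent pair
#' dyad, one loop term per dyad separated by unpaired bases, and helix-end
#' penalties for the two terminal pairs.
#'
#' Pairs must be supplied 5'-to-3' with respect to RNA1: `pos1` strictly
#' increasing and `pos2` strictly decreasing (antiparallel duplex).
#'
#' @param params An `energy_params` object.
#' @param pairs A data frame with columns `pos1`, `pos2` (1-based
#'   positions) and `nt1`, `nt2` (residues, one of A/C/G/U).
#' @return Hybridization energy Eh in kcal/mol.
#' @examples
#' p <- load_energy_parameters("default")
#' hybridization_energy(p, data.frame(pos1 = 1, pos2 = 5,
#'                                    nt1 = "C", nt2 = "G"))
#' @export
hybridization_energy <- function(params, pairs) {
  stopifnot(inherits(params, "energy_params"), is.data.frame(pairs))
  if (nrow(pairs) == 0L) stop("empty pair list")
  pt <- paste0(pairs$nt1, pairs$nt2)
  bad <- !pt %in% .CANONICAL_PAIRS
  if (any(bad)) stop("non-canonical base pair: '", pt[which(bad)[1]], "'")
  n <- nrow(pairs)
  if (n > 1L) {
    if (any(diff(pairs$pos1) <= 0) || any(diff(pairs$pos2) >= 0)) {
      stop("crossing or unordered pairs: pos1 must strictly increase and pos2 strictly decrease")
    }
  }
  e <- params$init + params$terminal[[pt[1]]] + params$terminal[[pt[n]]]
  if (n > 1L) {
    u1 <- pairs$pos1[-1] - pairs$pos1[-n] - 1L
    u2 <- pairs$pos2[-n] - pairs$pos2[-1] - 1L
    for (t in seq_len(n - 1L)) {
      if (u1[t] == 0L && u2[t] == 0L) {
        e <- e + params$stack[[paste0(pt[t], "/", pt[t + 1L])]]
      } else {
        e <- e + loop_energy(params, u1[t], u2[t])
      }
    }
  }
  e
}
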