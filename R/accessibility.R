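## Region-wise unpaired probabilities and accessibility penalties.
##
## The intramolecular structure ensemble consists of all non-crossing
## canonical secondary structures with a minimal hairpin loop of 3 nt,
## Boltzmann-weighted with loop-resolved energies from the same parameter
## set as hybridization scoring: stack table for stacked dyads,
## loop_cost(u) = a + b*ln(u) for hairpin and interior/bulge loops
## (interior loop sides capped at 10 unpaired nt), constant cost a per
## multiloop, exterior bases free. Pu(i..j) is the exact probability that
## region i..j is completely unpaired in that ensemble; ED = -RT ln(Pu)
## is the energetic price of freeing the region for intermolecular
## pairing.

# per-side cap on intramolecular interior/bulge loops (model constant,
# mirrored in src/accessibility.cpp)
.INTRA_MAX_BULGE <- 10L

#' Accessibility penalty from an unpaired probability
#'
#' `ED = -R*T*ln(Pu)` with `R = 0.0019872` kcal/(mol K). Probabilities are
#' floored at `1e-10` before the logarithm so the penalty stays finite.
#'
#' @param pu Unpaired probability (vectorized), in `[0, 1]`.
#' @param temperature Temperature in kelvin.
#' @return ED in kcal/mol.
#' @examples
#' ed_penalty(1, 310.15)    # 0
#' ed_penalty(0.5, 310.15)  # ~0.427
#' @export
ed_penalty <- function(pu, temperature = 310.15) {
  if (any(!is.finite(pu)) || any(pu < 0) || any(pu > 1)) {
    stop("unpaired probability outside [0, 1]")
  }
  stopifnot(temperature > 0)
  -.RGAS * temperature * log(pmax(pu, .PU_FLOOR))
}

#' Compute an accessibility profile
#'
#' Exact unpaired probabilities `Pu(i..j)` for every region of length up
#' to `max_region_len`, from the McCaskill-style partition function of the
#' intramolecular ensemble (see the package vignette for the model).
#' Deterministic; runtime is cubic in sequence length.
#'
#' @param seq RNA string, or a length-1 named character vector (the name
#'   becomes the profile's sequence id).
#' @param params An `energy_params` object; its stack/loop terms and
#'   temperature define the intramolecular ensemble.
#' @param max_region_len Maximal region length to tabulate. Defaults to
#'   the full sequence length; in screens this is typically the maximal
#'   interaction length, which bounds precomputation time and space.
#' @param id Sequence id; defaults to `names(seq)` or `"seq"`.
#' @return An `accessibility_profile`: list with `sequence_id`, `length`,
#'   `max_region_len` and `pu`, an `n x max_region_len` matrix where
#'   `pu[i, d]` is `Pu(i .. i+d-1)` (NA outside the sequence).
#' @export
accessibility_profile <- function(seq, params, max_region_len = NULL, id = NULL) {
  stopifnot(inherits(params, "energy_params"))
  if (is.null(id)) id <- if (!is.null(names(seq))) names(seq)[1] else "seq"
  s <- normalize_rna(unname(seq[1]), id)
  n <- nchar(s)
  if (is.null(max_region_len)) max_region_len <- n
  stopifnot(max_region_len >= 1)
  L <- min(max_region_len, n)
  beta <- 1 / (.RGAS * params$temperature)
  pu <- .acc_pu_matrix(.encode_rna(s), .stack_matrix(params),
                       params$loop_a, params$loop_b, beta, L)
  structure(list(sequence_id = id, length = n, max_region_len = L, pu = pu),
            class = "accessibility_profile")
}

#' Look up an unpaired probability in a profile
#'
#' @param profile An `accessibility_profile`.
#' @param i,j 1-based inclusive region bounds, `j - i + 1` at most the
#'   profile's `max_region_len`.
#' @return `Pu(i..j)`.
#' @export
pu_region <- function(profile, i, j) {
  stopifnot(inherits(profile, "accessibility_profile"),
            i >= 1, j >= i, j <= profile$length,
            j - i + 1 <= profile$max_region_len)
  profile$pu[i, j - i + 1]
}

#' @export
print.accessibility_profile <- function(x, ...) {
  cat("Accessibility profile for '", x$sequence_id, "' (", x$length,
      " nt, regions up to ", x$max_region_len, " nt)\n", sep = "")
  cat("  mean single-position Pu: ",
      signif(mean(x$pu[, 1], na.rm = TRUE), 4), "\n", sep = "")
  invisible(x)
}

#' Write an accessibility profile to TSV
#'
#' Format: a header line `#seq_id<TAB>length`, then one row
#' `i<TAB>j<TAB>Pu` per region, 1-based inclusive coordinates.
#'
#' @param profile An `accessibility_profile`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_accessibility_profile <- function(profile, path) {
  stopifnot(inherits(profile, "accessibility_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", profile$sequence_id, "\t", profile$length), con)
  n <- profile$length
  for (d in seq_len(ncol(profile$pu))) {
    i <- which(!is.na(profile$pu[, d]))
    if (length(i) > 0L) {
      writeLines(sprintf("%d\t%d\t%.10g", i, i + d - 1L, profile$pu[i, d]), con)
    }
  }
  invisible(path)
}

#' Read an accessibility profile from TSV
#'
#' Validates that probabilities lie in `[0, 1]` and that subsequence
#' monotonicity holds (`Pu(i..j) <= Pu` of any subregion, up to `1e-9`);
#' violations are rejected.
#'
#' @param path Path to a profile TSV written by
#'   [write_accessibility_profile()].
#' @return An `accessibility_profile`.
#' @export
read_accessibility_profile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !startsWith(lines[1], "#")) {
    stop("malformed accessibility profile (missing '#seq_id\\tlength' header): ", path)
  }
  hdr <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
  if (length(hdr) != 2L) stop("malformed accessibility profile header in ", path)
  id <- hdr[1]
  n <- as.integer(hdr[2])
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0L) stop("accessibility profile has no rows: ", path)
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) != 3L)) stop("malformed accessibility profile row in ", path)
  i <- as.integer(vapply(parts, `[`, character(1), 1L))
  j <- as.integer(vapply(parts, `[`, character(1), 2L))
  p <- as.numeric(vapply(parts, `[`, character(1), 3L))
  if (anyNA(i) || anyNA(j) || anyNA(p)) stop("malformed accessibility profile row in ", path)
  if (any(i < 1L) || any(j < i) || any(j > n)) {
    stop("accessibility profile coordinates outside 1..", n, " in ", path)
  }
  if (any(p < 0) || any(p > 1)) {
    stop("accessibility profile probability outside [0, 1] in ", path)
  }
  L <- max(j - i + 1L)
  pu <- matrix(NA_real_, n, L)
  pu[cbind(i, j - i + 1L)] <- p
  # monotonicity: dropping one base from either end may only increase Pu
  for (d in 2:max(2L, L)) {
    if (d > L) break
    ii <- which(!is.na(pu[, d]))
    for (t in ii) {
      sub1 <- pu[t, d - 1L]
      sub2 <- pu[t + 1L, d - 1L]
      if ((!is.na(sub1) && pu[t, d] > sub1 + 1e-9) ||
          (!is.na(sub2) && pu[t, d] > sub2 + 1e-9)) {
        warning("subsequence monotonicity violated at region ", t, "..",
                t + d - 1L, " in ", path)
        stop("rejecting accessibility profile with monotonicity violation: ", path)
      }
    }
  }
  structure(list(sequence_id = id, length = n, max_region_len = L, pu = pu),
            class = "accessibility_profile")
}
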