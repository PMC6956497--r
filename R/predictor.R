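## Constrained MFE interaction prediction: configuration containers,
## seed enumeration and the predictor front end.

#' Seed constraint set
#'
#' Constraints on the seed subinteraction: a canonical helix of `seed_bp`
#' consecutively stacked base pairs that every reported interaction must
#' contain (when `seed_required`).
#'
#' @param seed_required Require a seed at all.
#' @param seed_bp Number of consecutive base pairs in the seed (>= 2).
#' @param allow_gu Allow GU wobble pairs inside seeds.
#' @param seed_max_e Upper bound (kcal/mol) on the seed's overall energy
#'   (standalone hybridization energy plus both seed-site ED penalties);
#'   `NULL` for no bound.
#' @param seed_max_e_hybrid Upper bound (kcal/mol) on the seed's
#'   hybridization energy alone; `NULL` for no bound.
#' @param seed_min_pu Minimal unpaired probability required of both
#'   seed regions; `NULL` for no bound.
#' @return A `seed_constraints` list.
#' @export
seed_constraints <- function(seed_required = TRUE, seed_bp = 7L,
                             allow_gu = TRUE, seed_max_e = NULL,
                             seed_max_e_hybrid = NULL, seed_min_pu = NULL) {
  seed_bp <- as.integer(seed_bp)
  if (seed_required && seed_bp < 2L) stop("seed_bp must be >= 2 when a seed is required")
  if (!is.null(seed_min_pu) && (seed_min_pu < 0 || seed_min_pu > 1)) {
    stop("seed_min_pu must be in [0, 1]")
  }
  structure(list(seed_required = isTRUE(seed_required), seed_bp = seed_bp,
                 allow_gu = isTRUE(allow_gu), seed_max_e = seed_max_e,
                 seed_max_e_hybrid = seed_max_e_hybrid,
                 seed_min_pu = seed_min_pu),
            class = "seed_constraints")
}

#' Interaction constraint set
#'
#' @param int_len_max Maximal interaction length (nt covered per RNA).
#' @param int_max_e Upper bound (kcal/mol) on the overall interaction
#'   energy E; only interactions with `E <= int_max_e` are reported.
#' @param int_min_pu Minimal unpaired probability required of both full
#'   interaction sites; `NULL` for no bound.
#' @param max_loop Maximal number of unpaired bases per strand in any
#'   intermolecular interior loop or bulge.
#' @return An `interaction_constraints` list.
#' @export
interaction_constraints <- function(int_len_max = 150L, int_max_e = 0,
                                    int_min_pu = NULL, max_loop = 16L) {
  int_len_max <- as.integer(int_len_max)
  max_loop <- as.integer(max_loop)
  stopifnot(int_len_max >= 1L, max_loop >= 0L)
  if (!is.null(int_min_pu) && (int_min_pu < 0 || int_min_pu > 1)) {
    stop("int_min_pu must be in [0, 1]")
  }
  structure(list(int_len_max = int_len_max, int_max_e = int_max_e,
                 int_min_pu = int_min_pu, max_loop = max_loop),
            class = "interaction_constraints")
}

#' Full prediction configuration
#'
#' @param seed A `seed_constraints` object.
#' @param interaction An `interaction_constraints` object.
#' @param params An `energy_params` object (or a preset name / file path
#'   passed to [load_energy_parameters()]).
#' @return A `prediction_config` list.
#' @export
prediction_config <- function(seed = seed_constraints(),
                              interaction = interaction_constraints(),
                              params = "default") {
  if (!inherits(params, "energy_params")) params <- load_energy_parameters(params)
  stopifnot(inherits(seed, "seed_constraints"),
            inherits(interaction, "interaction_constraints"))
  if (seed$seed_required && interaction$int_len_max < seed$seed_bp) {
    stop("int_len_max must be >= seed_bp")
  }
  structure(list(seed = seed, interaction = interaction, params = params),
            class = "prediction_config")
}

#' Named prediction presets
#'
#' `"default"` mirrors the customary screen defaults: canonical seed of 7
#' base pairs, GU pairs allowed in the seed, no seed energy or
#' accessibility thresholds, maximal interaction length 150, maximal
#' interior/bulge loop size 16, and a maximal overall interaction energy
#' of 0 kcal/mol. `"recommended"` is the constraint set found to maximize
#' verified-target recovery in systematic screening: 7 bp seeds without GU
#' pairs, minimal seed-site unpaired probability 0.001, maximal
#' interaction length 60, maximal loop size 8, and minimal unpaired
#' probability 0.001 of both interaction sites.
#'
#' @param name `"default"` or `"recommended"`.
#' @param params Energy parameter set (object, preset name or path).
#' @return A `prediction_config`.
#' @export
prediction_preset <- function(name = c("default", "recommended"),
                              params = "default") {
  name <- match.arg(name)
  if (name == "default") {
    prediction_config(
      seed = seed_constraints(seed_required = TRUE, seed_bp = 7L, allow_gu = TRUE),
      interaction = interaction_constraints(int_len_max = 150L, int_max_e = 0,
                                            max_loop = 16L),
      params = params)
  } else {
    prediction_config(
      seed = seed_constraints(seed_required = TRUE, seed_bp = 7L,
                              allow_gu = FALSE, seed_min_pu = 0.001),
      interaction = interaction_constraints(int_len_max = 60L, int_max_e = 0,
                                            int_min_pu = 0.001, max_loop = 8L),
      params = params)
  }
}

#' @export
print.prediction_config <- function(x, ...) {
  s <- x$seed; it <- x$interaction
  fmt <- function(v) if (is.null(v)) "unset" else format(v)
  cat("Prediction configuration\n")
  cat("  seed: ", if (s$seed_required) paste0(s$seed_bp, " bp") else "not required",
      ", GU ", if (s$allow_gu) "allowed" else "forbidden",
      ", maxE ", fmt(s$seed_max_e), ", maxEhybrid ", fmt(s$seed_max_e_hybrid),
      ", minPu ", fmt(s$seed_min_pu), "\n", sep = "")
  cat("  interaction: lenMax ", it$int_len_max, ", maxE ", it$int_max_e,
      ", minPu ", fmt(it$int_min_pu), ", maxLoop ", it$max_loop, "\n", sep = "")
  cat("  energy parameters: '", x$params$name, "'\n", sep = "")
  invisible(x)
}

# flatten config for the C++ kernels; NULL bounds become sentinels
.cfg_list <- function(cfg) {
  s <- cfg$seed; it <- cfg$interaction
  list(seed_required = s$seed_required,
       bp = s$seed_bp,
       allow_gu = s$allow_gu,
       seed_max_e = if (is.null(s$seed_max_e)) Inf else s$seed_max_e,
       seed_max_e_hybrid = if (is.null(s$seed_max_e_hybrid)) Inf else s$seed_max_e_hybrid,
       seed_min_pu = if (is.null(s$seed_min_pu)) -1 else s$seed_min_pu,
       L1 = it$int_len_max, L2 = it$int_len_max,
       max_loop = it$max_loop,
       int_max_e = it$int_max_e,
       int_min_pu = if (is.null(it$int_min_pu)) -1 else it$int_min_pu)
}

.stack_matrix <- function(params) {
  stack <- matrix(0, 6, 6, dimnames = list(.CANONICAL_PAIRS, .CANONICAL_PAIRS))
  for (p1 in .CANONICAL_PAIRS) for (p2 in .CANONICAL_PAIRS) {
    stack[p1, p2] <- params$stack[[paste0(p1, "/", p2)]]
  }
  stack
}

.par_list <- function(params) {
  list(stack = .stack_matrix(params), init = params$init,
       terminal = unname(params$terminal[.CANONICAL_PAIRS]),
       loop_a = params$loop_a, loop_b = params$loop_b,
       temperature = params$temperature)
}

.profile_for <- function(seq, id, params, cfg, profile) {
  n <- nchar(seq)
  need <- min(max(cfg$interaction$int_len_max, cfg$seed$seed_bp), n)
  if (is.null(profile)) {
    return(accessibility_profile(seq, params, max_region_len = need, id = id))
  }
  stopifnot(inherits(profile, "accessibility_profile"))
  if (profile$length != n) {
    stop("sequence/profile length mismatch for '", id, "': sequence ", n,
         " nt, profile ", profile$length, " nt")
  }
  if (profile$max_region_len < need) {
    stop("accessibility profile for '", id, "' covers regions up to ",
         profile$max_region_len, " nt but ", need, " nt are required")
  }
  profile
}

#' Enumerate seed interactions
#'
#' All position pairs whose `seed_bp`-long perfectly stacked complementary
#' helix passes every active seed filter, in deterministic order
#' (ascending start on RNA1, then on RNA2).
#'
#' @param s1,s2 RNA strings (optionally named; RNA1 is typically the sRNA,
#'   RNA2 the target).
#' @param sc A `seed_constraints` object.
#' @param params An `energy_params` object.
#' @param prof1,prof2 Optional precomputed `accessibility_profile`s.
#' @return Data frame with columns `start1`, `end1`, `start2`, `end2`,
#'   `eh_seed` (standalone hybridization energy), `e_seed` (overall seed
#'   energy including both ED penalties), `pu1`, `pu2`.
#' @export
enumerate_seeds <- function(s1, s2, sc = seed_constraints(), params = NULL,
                            prof1 = NULL, prof2 = NULL) {
  if (is.null(params)) params <- load_energy_parameters("default")
  cfg <- prediction_config(seed = sc,
                           interaction = interaction_constraints(
                             int_len_max = max(sc$seed_bp, 1L)),
                           params = params)
  id1 <- if (!is.null(names(s1))) names(s1)[1] else "RNA1"
  id2 <- if (!is.null(names(s2))) names(s2)[1] else "RNA2"
  q1 <- normalize_rna(unname(s1[1]), id1)
  q2 <- normalize_rna(unname(s2[1]), id2)
  p1 <- .profile_for(q1, id1, params, cfg, prof1)
  p2 <- .profile_for(q2, id2, params, cfg, prof2)
  out <- .enumerate_seeds_cpp(.encode_rna(q1), .encode_rna(q2),
                              .par_list(params), .cfg_list(cfg), p1$pu, p2$pu)
  out$end1 <- out$start1 + sc$seed_bp - 1L
  out$end2 <- out$start2 + sc$seed_bp - 1L
  out[, c("start1", "end1", "start2", "end2", "eh_seed", "e_seed", "pu1", "pu2")]
}

.interaction_from_cpp <- function(res, id1, id2, seed_bp) {
  pairs <- data.frame(pos1 = res$pairs[, 1], pos2 = res$pairs[, 2])
  seed <- NULL
  if (!is.na(res$seed_start1)) {
    seed <- list(start1 = res$seed_start1, end1 = res$seed_start1 + seed_bp - 1L,
                 start2 = res$seed_start2, end2 = res$seed_start2 + seed_bp - 1L)
  }
  structure(list(id1 = id1, id2 = id2,
                 start1 = res$i, end1 = res$j, start2 = res$k, end2 = res$l,
                 pairs = pairs, E = res$E, Eh = res$Eh,
                 ED1 = res$ED1, ED2 = res$ED2, seed = seed),
            class = "interaction")
}

#' Predict the minimum-free-energy RNA-RNA interaction
#'
#' Returns the interaction minimizing `E = Eh + ED1 + ED2` over all
#' non-crossing intermolecular duplexes satisfying every constraint in
#' `config` (seed containment, interaction length, loop size, energy and
#' accessibility thresholds), or `NULL` if no constraint-satisfying
#' interaction with `E <= int_max_e` exists. Deterministic; ties are
#' broken by smallest RNA1 start, then RNA2 start, then shortest regions.
#'
#' @param s1,s2 RNA strings (optionally named; RNA1 is typically the
#'   sRNA, RNA2 the target). The duplex is antiparallel: RNA1 positions
#'   ascend 5'->3' while paired RNA2 positions descend.
#' @param config A `prediction_config`.
#' @param prof1,prof2 Optional precomputed `accessibility_profile`s
#'   covering regions up to the maximal interaction length; computed on
#'   the fly when omitted.
#' @return An `interaction` object or `NULL`.
#' @export
predict_interaction <- function(s1, s2, config = prediction_preset("default"),
                                prof1 = NULL, prof2 = NULL) {
  stopifnot(inherits(config, "prediction_config"))
  id1 <- if (!is.null(names(s1))) names(s1)[1] else "RNA1"
  id2 <- if (!is.null(names(s2))) names(s2)[1] else "RNA2"
  q1 <- normalize_rna(unname(s1[1]), id1)
  q2 <- normalize_rna(unname(s2[1]), id2)
  p1 <- .profile_for(q1, id1, config$params, config, prof1)
  p2 <- .profile_for(q2, id2, config$params, config, prof2)
  res <- .predict_cpp(.encode_rna(q1), .encode_rna(q2), .par_list(config$params),
                      .cfg_list(config), p1$pu, p2$pu)
  if (!res$found) return(NULL)
  .interaction_from_cpp(res, id1, id2, config$seed$seed_bp)
}

#' Dot-bracket encoding of an interaction's hybrid
#'
#' RNA1's covered region 5'->3' using `(` for paired and `.` for unpaired
#' positions, then `&`, then RNA2's covered region 5'->3' using `)` / `.`.
#'
#' @param x An `interaction` object.
#' @return Character string.
#' @export
hybrid_dotbracket <- function(x) {
  stopifnot(inherits(x, "interaction"))
  r1 <- rep(".", x$end1 - x$start1 + 1L)
  r2 <- rep(".", x$end2 - x$start2 + 1L)
  r1[x$pairs$pos1 - x$start1 + 1L] <- "("
  r2[x$pairs$pos2 - x$start2 + 1L] <- ")"
  paste0(paste(r1, collapse = ""), "&", paste(r2, collapse = ""))
}

#' @export
print.interaction <- function(x, ...) {
  cat("RNA-RNA interaction ", x$id1, "[", x$start1, "..", x$end1, "] : ",
      x$id2, "[", x$start2, "..", x$end2, "]\n", sep = "")
  cat("  E = ", sprintf("%.3f", x$E), " kcal/mol (Eh = ", sprintf("%.3f", x$Eh),
      ", ED1 = ", sprintf("%.3f", x$ED1), ", ED2 = ", sprintf("%.3f", x$ED2),
      ")\n", sep = "")
  cat("  ", nrow(x$pairs), " base pairs: ", hybrid_dotbracket(x), "\n", sep = "")
  if (!is.null(x$seed)) {
    cat("  seed: [", x$seed$start1, "..", x$seed$end1, "] : [",
        x$seed$start2, "..", x$seed$end2, "]\n", sep = "")
  }
  invisible(x)
}

#' @export
as.data.frame.interaction <- function(x, ...) {
  data.frame(id1 = x$id1, start1 = x$start1, end1 = x$end1,
             id2 = x$id2, start2 = x$start2, end2 = x$end2,
             hybridDP = hybrid_dotbracket(x),
             E = x$E, Eh = x$Eh, ED1 = x$ED1, ED2 = x$ED2,
             seedStart1 = if (is.null(x$seed)) NA_integer_ else x$seed$start1,
             seedEnd1 = if (is.null(x$seed)) NA_integer_ else x$seed$end1,
             seedStart2 = if (is.null(x$seed)) NA_integer_ else x$seed$start2,
             seedEnd2 = if (is.null(x$seed)) NA_integer_ else x$seed$end2,
             stringsAsFactors = FALSE)
}
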