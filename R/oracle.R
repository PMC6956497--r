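## Exhaustive verification oracles.
##
## predict_interaction_bruteforce() re-solves the constrained MFE problem
## by enumerating every non-crossing intermolecular pair set and scoring
## it by direct summation, independently of the dynamic-programming
## kernels. enumerate_structures() lists the complete intramolecular
## ensemble of short sequences; its Boltzmann weights back the
## accessibility oracle used in the tests.

#' Brute-force constrained MFE interaction search
#'
#' Same contract as [predict_interaction()], computed by exhaustive
#' enumeration of all non-crossing intermolecular pair sets (RNA1
#' positions ascending, RNA2 positions descending) with direct
#' re-summation of every energy term. Intended as a verification oracle;
#' both sequences must be at most `max_len` nt.
#'
#' @param s1,s2 RNA strings.
#' @param config A `prediction_config`.
#' @param prof1,prof2 Optional `accessibility_profile`s.
#' @param max_len Enumeration bound on each sequence length.
#' @return An `interaction` object or `NULL`.
#' @export
predict_interaction_bruteforce <- function(s1, s2,
                                           config = prediction_preset("default"),
                                           prof1 = NULL, prof2 = NULL,
                                           max_len = 15L) {
  stopifnot(inherits(config, "prediction_config"))
  id1 <- if (!is.null(names(s1))) names(s1)[1] else "RNA1"
  id2 <- if (!is.null(names(s2))) names(s2)[1] else "RNA2"
  q1 <- normalize_rna(unname(s1[1]), id1)
  q2 <- normalize_rna(unname(s2[1]), id2)
  n1 <- nchar(q1); n2 <- nchar(q2)
  if (n1 > max_len || n2 > max_len) {
    stop("inputs exceed enumeration bound (", max_len, " nt)")
  }
  p1 <- .profile_for(q1, id1, config$params, config, prof1)
  p2 <- .profile_for(q2, id2, config$params, config, prof2)
  par <- config$params
  sc <- config$seed; ic <- config$interaction
  bp <- sc$seed_bp
  ml <- ic$max_loop
  L1 <- min(ic$int_len_max, n1); L2 <- min(ic$int_len_max, n2)
  RT <- .RGAS * par$temperature
  r1 <- strsplit(q1, "", fixed = TRUE)[[1]]
  r2 <- strsplit(q2, "", fixed = TRUE)[[1]]
  ptm <- outer(r1, r2, paste0)
  canm <- matrix(ptm %in% .CANONICAL_PAIRS, n1, n2)
  ed1 <- function(i, j) -RT * log(max(p1$pu[i, j - i + 1], .PU_FLOOR))
  ed2 <- function(k, l) -RT * log(max(p2$pu[k, l - k + 1], .PU_FLOOR))

  seed_window_ok <- function(p1v, p2v, ptv, from) {
    w <- from:(from + bp - 1L)
    if (!sc$allow_gu && any(ptv[w] %in% c("GU", "UG"))) return(FALSE)
    ehs <- par$init + par$terminal[[ptv[w[1]]]] + par$terminal[[ptv[w[bp]]]]
    for (t in seq_len(bp - 1L)) {
      ehs <- ehs + par$stack[[paste0(ptv[w[t]], "/", ptv[w[t + 1L]])]]
    }
    if (!is.null(sc$seed_max_e_hybrid) && ehs > sc$seed_max_e_hybrid) return(FALSE)
    w1 <- p1v[w[1]]; w2 <- p2v[w[bp]]
    q1w <- p1$pu[w1, bp]; q2w <- p2$pu[w2, bp]
    if (!is.null(sc$seed_min_pu) && (q1w < sc$seed_min_pu || q2w < sc$seed_min_pu)) {
      return(FALSE)
    }
    if (!is.null(sc$seed_max_e)) {
      es <- ehs - RT * log(max(q1w, .PU_FLOOR)) - RT * log(max(q2w, .PU_FLOOR))
      if (es > sc$seed_max_e) return(FALSE)
    }
    TRUE
  }

  best <- new.env(parent = emptyenv())
  best$E <- Inf
  best$tuple <- NULL
  best$p1v <- NULL

  consider <- function(p1v, p2v, ptv, m, ehsum, has_seed) {
    if (sc$seed_required && !has_seed) return(invisible())
    i <- p1v[1]; j <- p1v[m]; l <- p2v[1]; k <- p2v[m]
    q1r <- p1$pu[i, j - i + 1L]; q2r <- p2$pu[k, l - k + 1L]
    if (!is.null(ic$int_min_pu) && (q1r < ic$int_min_pu || q2r < ic$int_min_pu)) {
      return(invisible())
    }
    Eh <- par$init + ehsum + par$terminal[[ptv[1]]] + par$terminal[[ptv[m]]]
    E1 <- -RT * log(max(q1r, .PU_FLOOR)); E2 <- -RT * log(max(q2r, .PU_FLOOR))
    E <- Eh + E1 + E2
    if (E > ic$int_max_e) return(invisible())
    tuple <- c(i, k, j - i + 1L, l - k + 1L)
    take <- if (E < best$E) TRUE else if (E > best$E) FALSE else {
      d <- tuple - best$tuple
      nz <- which(d != 0)
      length(nz) > 0L && d[nz[1]] < 0
    }
    if (take) {
      best$E <- E
      best$tuple <- tuple
      best$p1v <- p1v[seq_len(m)]
      best$p2v <- p2v[seq_len(m)]
      best$Eh <- Eh; best$ED1 <- E1; best$ED2 <- E2
    }
    invisible()
  }

  extend <- function(p1v, p2v, ptv, m, ehsum, runlen, has_seed) {
    if (sc$seed_required && runlen >= bp) {
      if (seed_window_ok(p1v, p2v, ptv, m - bp + 1L)) has_seed <- TRUE
    }
    consider(p1v, p2v, ptv, m, ehsum, has_seed)
    li <- p1v[m]; lk <- p2v[m]
    ni_max <- min(n1, li + ml + 1L, p1v[1] + L1 - 1L)
    nk_min <- max(1L, lk - ml - 1L, p2v[1] - L2 + 1L)
    if (ni_max < li + 1L || lk - 1L < nk_min) return(invisible())
    for (ni in (li + 1L):ni_max) {
      for (nk in nk_min:(lk - 1L)) {
        if (!canm[ni, nk]) next
        u1 <- ni - li - 1L; u2 <- lk - nk - 1L
        dterm <- if (u1 == 0L && u2 == 0L) {
          par$stack[[paste0(ptv[m], "/", ptm[ni, nk])]]
        } else {
          par$loop_a + par$loop_b * log(u1 + u2)
        }
        p1v[m + 1L] <- ni; p2v[m + 1L] <- nk; ptv[m + 1L] <- ptm[ni, nk]
        extend(p1v, p2v, ptv, m + 1L, ehsum + dterm,
               if (u1 == 0L && u2 == 0L) runlen + 1L else 1L, has_seed)
      }
    }
    invisible()
  }

  for (i0 in seq_len(n1)) {
    for (k0 in seq_len(n2)) {
      if (!canm[i0, k0]) next
      extend(c(i0, integer(14L)), c(k0, integer(14L)),
             c(ptm[i0, k0], character(14L)), 1L, 0, 1L, FALSE)
    }
  }
  if (!is.finite(best$E)) return(NULL)

  m <- length(best$p1v)
  seed <- NULL
  if (sc$seed_required) {
    # report the first passing seed window for the winning chain
    ptv <- ptm[cbind(best$p1v, best$p2v)]
    runlen <- 1L
    for (t in seq_len(m)) {
      if (t > 1L) {
        runlen <- if (best$p1v[t] == best$p1v[t - 1L] + 1L &&
                      best$p2v[t] == best$p2v[t - 1L] - 1L) runlen + 1L else 1L
      }
      if (runlen >= bp && is.null(seed) &&
          seed_window_ok(best$p1v, best$p2v, ptv, t - bp + 1L)) {
        seed <- list(start1 = best$p1v[t - bp + 1L], end1 = best$p1v[t],
                     start2 = best$p2v[t], end2 = best$p2v[t - bp + 1L])
      }
    }
  }
  structure(list(id1 = id1, id2 = id2,
                 start1 = best$p1v[1], end1 = best$p1v[m],
                 start2 = best$p2v[m], end2 = best$p2v[1],
                 pairs = data.frame(pos1 = best$p1v, pos2 = best$p2v),
                 E = best$E, Eh = best$Eh, ED1 = best$ED1, ED2 = best$ED2,
                 seed = seed),
            class = "interaction")
}

#' Loop-resolved energy of one intramolecular structure
#'
#' Energy of an explicit non-crossing structure under the accessibility
#' module's ensemble model: stacked dyads score by the stack table,
#' hairpin loops cost `a + b*ln(u)`, interior/bulge loops cost
#' `a + b*ln(u1+u2)` with each side at most 10 unpaired nt (larger loops
#' make the structure inadmissible, returned as `Inf`), multiloops cost
#' the constant `a`, exterior bases are free.
#'
#' @param seq RNA string.
#' @param pairs 2-column matrix of base-pair positions (i < j).
#' @param params An `energy_params` object.
#' @return Energy in kcal/mol (`Inf` for inadmissible structures).
#' @export
structure_energy <- function(seq, pairs, params) {
  stopifnot(inherits(params, "energy_params"))
  if (is.null(pairs) || nrow(pairs) == 0L) return(0)
  r <- strsplit(normalize_rna(unname(seq[1])), "", fixed = TRUE)[[1]]
  pt <- paste0(r[pairs[, 1]], r[pairs[, 2]])
  stopifnot(all(pt %in% .CANONICAL_PAIRS))
  e <- 0
  for (t in seq_len(nrow(pairs))) {
    i <- pairs[t, 1]; j <- pairs[t, 2]
    inside <- which(pairs[, 1] > i & pairs[, 2] < j)
    direct <- inside[vapply(inside, function(u) {
      !any(pairs[inside, 1] < pairs[u, 1] & pairs[inside, 2] > pairs[u, 2])
    }, logical(1))]
    if (length(direct) == 0L) {
      e <- e + params$loop_a + params$loop_b * log(j - i - 1)
    } else if (length(direct) == 1L) {
      u1 <- pairs[direct, 1] - i - 1L
      u2 <- j - pairs[direct, 2] - 1L
      if (u1 == 0L && u2 == 0L) {
        e <- e + params$stack[[paste0(pt[t], "/", pt[direct])]]
      } else if (u1 <= .INTRA_MAX_BULGE && u2 <= .INTRA_MAX_BULGE) {
        e <- e + params$loop_a + params$loop_b * log(u1 + u2)
      } else {
        return(Inf)
      }
    } else {
      e <- e + params$loop_a
    }
  }
  e
}

#' Enumerate the complete intramolecular structure ensemble
#'
#' All non-crossing canonical secondary structures with a minimal hairpin
#' loop of 3 nt, with their loop-resolved energies (see
#' [structure_energy()]) and Boltzmann weights. Exhaustive; sequences are
#' limited to `max_len` nt. Inadmissible structures (oversized interior
#' loops) carry zero weight.
#'
#' @param seq RNA string.
#' @param params An `energy_params` object.
#' @param max_len Enumeration bound.
#' @return List with `structures` (list of 2-column pair matrices),
#'   `dotbracket` (character), `energies` (kcal/mol) and `weights`
#'   (Boltzmann probabilities, summing to 1).
#' @export
enumerate_structures <- function(seq, params, max_len = 15L) {
  stopifnot(inherits(params, "energy_params"))
  s <- normalize_rna(unname(seq[1]))
  n <- nchar(s)
  if (n > max_len) stop("sequence exceeds enumeration bound (", max_len, " nt)")
  r <- strsplit(s, "", fixed = TRUE)[[1]]
  can <- function(a, b) paste0(r[a], r[b]) %in% .CANONICAL_PAIRS
  rec <- function(a, b) {
    if (b - a < 4L) return(list(matrix(integer(0), 0L, 2L)))
    out <- rec(a, b - 1L)  # b unpaired
    for (k in a:(b - 4L)) {
      if (!can(k, b)) next
      left <- rec(a, k - 1L)
      inner <- rec(k + 1L, b - 1L)
      for (Lm in left) for (Im in inner) {
        out[[length(out) + 1L]] <- rbind(Lm, Im, c(k, b))
      }
    }
    out
  }
  structs <- if (n < 5L) list(matrix(integer(0), 0L, 2L)) else rec(1L, n)
  energies <- vapply(structs, function(m) structure_energy(s, m, params),
                     numeric(1))
  beta <- 1 / (.RGAS * params$temperature)
  w <- exp(-beta * energies)
  db <- vapply(structs, function(m) {
    v <- rep(".", n)
    if (nrow(m) > 0L) { v[m[, 1]] <- "("; v[m[, 2]] <- ")" }
    paste(v, collapse = "")
  }, character(1))
  list(structures = structs, dotbracket = db, energies = energies,
       weights = w / sum(w))
}
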