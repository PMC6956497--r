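# Shared test helpers: independent oracles and random-instance generators.

random_rna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# region-wise unpaired probabilities by exhaustive Boltzmann enumeration
# (independent of the partition-function kernel)
pu_oracle <- function(seq, params) {
  en <- enumerate_structures(seq, params)
  n <- nchar(seq)
  paired <- lapply(en$structures, function(m) {
    v <- logical(n)
    if (nrow(m) > 0L) { v[m[, 1]] <- TRUE; v[m[, 2]] <- TRUE }
    v
  })
  pu <- matrix(NA_real_, n, n)
  for (i in 1:n) for (j in i:n) {
    free <- vapply(paired, function(v) !any(v[i:j]), logical(1))
    pu[i, j - i + 1] <- sum(en$weights[free])
  }
  pu
}

# independent count of non-crossing canonical structures (min hairpin 3)
count_structures_oracle <- function(seq) {
  r <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(r)
  can <- function(a, b) paste0(r[a], r[b]) %in% c("AU", "UA", "CG", "GC", "GU", "UG")
  memo <- new.env(parent = emptyenv())
  cnt <- function(a, b) {
    if (b - a < 4L) return(1)
    key <- paste0(a, "_", b)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- cnt(a, b - 1L)
    for (k in a:(b - 4L)) {
      if (can(k, b)) v <- v + cnt(a, k - 1L) * cnt(k + 1L, b - 1L)
    }
    memo[[key]] <- v
    v
  }
  cnt(1L, n)
}

# randomized constraint configuration touching every flag
random_config <- function(params) {
  sc <- seed_constraints(
    seed_required = runif(1) < 0.7,
    seed_bp = sample(2:5, 1),
    allow_gu = runif(1) < 0.5,
    seed_max_e = if (runif(1) < 0.4) runif(1, -3, 4) else NULL,
    seed_max_e_hybrid = if (runif(1) < 0.4) runif(1, -3, 4) else NULL,
    seed_min_pu = if (runif(1) < 0.4) sample(c(0.001, 0.05, 0.3), 1) else NULL)
  ic <- interaction_constraints(
    int_len_max = sample(4:14, 1),
    int_max_e = sample(c(0, 5, -2), 1),
    int_min_pu = if (runif(1) < 0.3) sample(c(0.001, 0.05), 1) else NULL,
    max_loop = sample(0:3, 1))
  tryCatch(prediction_config(sc, ic, params), error = function(e) NULL)
}

# uniform (structure-free) accessibility profile, for tests that need to
# isolate hybridization energetics from accessibility
flat_profile <- function(seq, id = "flat") {
  n <- nchar(seq)
  structure(list(sequence_id = id, length = n, max_region_len = n,
                 pu = {
                   m <- matrix(NA_real_, n, n)
                   for (d in 1:n) m[1:(n - d + 1), d] <- 1
                   m
                 }),
            class = "accessibility_profile")
}

default_params <- function() load_energy_parameters("default")
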