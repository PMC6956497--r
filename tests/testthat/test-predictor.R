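test_that("presets carry the documented screening constraints", {
  d <- prediction_preset("default")
  expect_identical(d$seed$seed_bp, 7L)
  expect_true(d$seed$allow_gu)
  expect_null(d$seed$seed_min_pu)
  expect_identical(d$interaction$int_len_max, 150L)
  expect_identical(d$interaction$max_loop, 16L)
  expect_identical(d$interaction$int_max_e, 0)
  r <- prediction_preset("recommended")
  expect_identical(r$seed$seed_bp, 7L)
  expect_false(r$seed$allow_gu)
  expect_identical(r$seed$seed_min_pu, 0.001)
  expect_identical(r$interaction$int_len_max, 60L)
  expect_identical(r$interaction$max_loop, 8L)
  expect_identical(r$interaction$int_min_pu, 0.001)
  expect_error(prediction_preset("nope"))
})

test_that("seed enumeration finds planted sites and honors filters", {
  p <- default_params()
  # unique complementary 7-mer planted in an otherwise pair-free context
  s1 <- "AAAAGGGGCCCAAAA"          # 7-mer GGGGCCC at 5..11
  s2 <- "AAAAAGGGCCCCAAAAA"        # complement GGGCCCC at 6..12
  sc <- seed_constraints(seed_bp = 7L)
  seeds <- enumerate_seeds(s1, s2, sc, p)
  expect_identical(nrow(seeds), 1L)
  expect_identical(seeds$start1, 5L)
  expect_identical(seeds$start2, 6L)
  # deterministic order: ascending start1 then start2
  set.seed(3)
  r1 <- random_rna(20); r2 <- random_rna(25)
  all_seeds <- enumerate_seeds(r1, r2, seed_constraints(seed_bp = 3L), p)
  expect_false(is.unsorted(all_seeds$start1))
  expect_identical(order(all_seeds$start1, all_seeds$start2),
                   seq_len(nrow(all_seeds)))
  # a seed containing a GU pair vanishes under the no-GU filter
  s1g <- "AAAAGGGGCUCAAAA"         # pairs with s2g via one G:U
  s2g <- "AAAAAGGGCCCCAAAAA"       # GAGCCCC would need G:U at position 3
  sc_gu <- seed_constraints(seed_bp = 7L, allow_gu = TRUE)
  sc_nogu <- seed_constraints(seed_bp = 7L, allow_gu = FALSE)
  with_gu <- enumerate_seeds(s1g, s2g, sc_gu, p)
  no_gu <- enumerate_seeds(s1g, s2g, sc_nogu, p)
  expect_gt(nrow(with_gu), nrow(no_gu))
  # filter nesting: stricter seedMinPu gives a subset
  loose <- enumerate_seeds(r1, r2, seed_constraints(seed_bp = 3L,
                                                    seed_min_pu = 0.001), p)
  strict <- enumerate_seeds(r1, r2, seed_constraints(seed_bp = 3L,
                                                     seed_min_pu = 0.1), p)
  key <- function(df) paste(df$start1, df$start2)
  expect_true(all(key(strict) %in% key(loose)))
})

test_that("a perfect duplex is recovered as the optimum", {
  p <- default_params()
  s1 <- "GGCAUGCC"
  s2 <- reverse_complement_rna(s1)
  cfg <- prediction_config(seed_constraints(seed_bp = 4L),
                           interaction_constraints(int_len_max = 8L,
                                                   int_max_e = 10),
                           p)
  hit <- predict_interaction(s1, s2, cfg)
  bf <- predict_interaction_bruteforce(s1, s2, cfg)
  expect_identical(nrow(hit$pairs), 8L)
  expect_equal(hit$E, bf$E, tolerance = 1e-9)
  expect_identical(hit$start1, 1L)
  expect_identical(hit$end1, 8L)
})

test_that("no shared complementary 7-mer means no seeded interaction", {
  p <- default_params()
  cfg <- prediction_config(seed_constraints(seed_bp = 7L),
                           interaction_constraints(int_max_e = 100), p)
  expect_null(predict_interaction("AAAAAAAAAAAA", "AAAAAAAAAAAA", cfg))
  expect_null(predict_interaction_bruteforce("AAAAAAAAAAAA", "AAAAAAAAAAAA", cfg))
})

test_that("predictor agrees with the brute-force oracle under random configs", {
  p <- default_params()
  set.seed(2024)
  n_checked <- 0
  for (t in 1:120) {
    cfg <- random_config(p)
    if (is.null(cfg)) next
    s1 <- random_rna(sample(8:14, 1))
    s2 <- random_rna(sample(8:14, 1))
    a <- predict_interaction(s1, s2, cfg)
    b <- predict_interaction_bruteforce(s1, s2, cfg)
    if (is.null(a) || is.null(b)) {
      expect_true(is.null(a) && is.null(b))
    } else {
      expect_lt(abs(a$E - b$E), 1e-6)
    }
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 100)
})

test_that("reported interactions are self-consistent", {
  p <- default_params()
  set.seed(55)
  found <- 0
  while (found < 8) {
    s1 <- random_rna(15)
    s2 <- random_rna(30)
    cfg <- prediction_config(seed_constraints(seed_bp = 4L),
                             interaction_constraints(int_len_max = 12L,
                                                     int_max_e = 5),
                             p)
    hit <- predict_interaction(s1, s2, cfg)
    if (is.null(hit)) next
    found <- found + 1
    # E decomposes exactly
    expect_equal(hit$E, hit$Eh + hit$ED1 + hit$ED2, tolerance = 1e-9)
    # terminal pairs coincide with the region boundaries
    expect_identical(hit$pairs$pos1[1], hit$start1)
    expect_identical(hit$pairs$pos1[nrow(hit$pairs)], hit$end1)
    expect_identical(hit$pairs$pos2[1], hit$end2)
    expect_identical(hit$pairs$pos2[nrow(hit$pairs)], hit$start2)
    # Eh and the EDs recompute from the reported pairs and profiles
    r1 <- strsplit(s1, "")[[1]]; r2 <- strsplit(s2, "")[[1]]
    pairs <- data.frame(pos1 = hit$pairs$pos1, pos2 = hit$pairs$pos2,
                        nt1 = r1[hit$pairs$pos1], nt2 = r2[hit$pairs$pos2])
    expect_equal(hit$Eh, hybridization_energy(p, pairs), tolerance = 1e-9)
    pr1 <- accessibility_profile(s1, p)
    pr2 <- accessibility_profile(s2, p)
    expect_equal(hit$ED1,
                 ed_penalty(pu_region(pr1, hit$start1, hit$end1), p$temperature),
                 tolerance = 1e-9)
    expect_equal(hit$ED2,
                 ed_penalty(pu_region(pr2, hit$start2, hit$end2), p$temperature),
                 tolerance = 1e-9)
    # dot-bracket encoding pairs up
    db <- hybrid_dotbracket(hit)
    expect_identical(lengths(regmatches(db, gregexpr("(", db, fixed = TRUE))),
                     nrow(hit$pairs))
  }
})

test_that("equal-energy optima break ties towards the 5'-most sites", {
  p <- default_params()
  s1 <- "AAGGGCCCAA"
  site <- reverse_complement_rna("GGGCCC")
  s2 <- paste0("AAAA", site, "AAAAAAAA", site, "AAAA")
  cfg <- prediction_config(seed_constraints(seed_bp = 4L),
                           interaction_constraints(int_len_max = 10L), p)
  # uniform profiles isolate hybridization: both copies score identically
  hit <- predict_interaction(s1, s2, cfg,
                             prof1 = flat_profile(s1), prof2 = flat_profile(s2))
  expect_identical(hit$start2, 5L)
  # determinism across repeated calls
  hit2 <- predict_interaction(s1, s2, cfg,
                              prof1 = flat_profile(s1), prof2 = flat_profile(s2))
  expect_identical(as.data.frame(hit), as.data.frame(hit2))
})

test_that("sequence/profile mismatches are rejected", {
  p <- default_params()
  cfg <- prediction_preset("default")
  prof_short <- accessibility_profile("ACGUACGU", p)
  expect_error(predict_interaction(random_rna(20), random_rna(20), cfg,
                                   prof1 = prof_short),
               "length mismatch")
})

test_that("constraint tightening never improves the optimum", {
  p <- default_params()
  set.seed(77)
  dims <- c("seedBP", "noGU", "seedMaxE", "seedMaxEhybrid", "seedMinPu",
            "intLenMax", "intMaxE", "intMinPu", "maxLoop")
  for (t in 1:36) {
    s1 <- random_rna(sample(9:13, 1))
    s2 <- random_rna(sample(9:13, 1))
    base_sc <- seed_constraints(seed_bp = 3L)
    base_ic <- interaction_constraints(int_len_max = 12L, int_max_e = 2,
                                       max_loop = 3L)
    loose <- prediction_config(base_sc, base_ic, p)
    dim <- dims[(t - 1) %% length(dims) + 1]
    tight <- switch(dim,
      seedBP = prediction_config(seed_constraints(seed_bp = 4L), base_ic, p),
      noGU = prediction_config(seed_constraints(seed_bp = 3L, allow_gu = FALSE),
                               base_ic, p),
      seedMaxE = prediction_config(seed_constraints(seed_bp = 3L, seed_max_e = 1),
                                   base_ic, p),
      seedMaxEhybrid = prediction_config(
        seed_constraints(seed_bp = 3L, seed_max_e_hybrid = 1), base_ic, p),
      seedMinPu = prediction_config(
        seed_constraints(seed_bp = 3L, seed_min_pu = 0.05), base_ic, p),
      intLenMax = prediction_config(base_sc,
        interaction_constraints(int_len_max = 7L, int_max_e = 2, max_loop = 3L), p),
      intMaxE = prediction_config(base_sc,
        interaction_constraints(int_len_max = 12L, int_max_e = -1, max_loop = 3L), p),
      intMinPu = prediction_config(base_sc,
        interaction_constraints(int_len_max = 12L, int_max_e = 2,
                                int_min_pu = 0.05, max_loop = 3L), p),
      maxLoop = prediction_config(base_sc,
        interaction_constraints(int_len_max = 12L, int_max_e = 2, max_loop = 1L), p))
    a <- predict_interaction(s1, s2, loose)
    b <- predict_interaction(s1, s2, tight)
    if (is.null(a)) {
      expect_null(b)  # "none" can never become a hit under tightening
    } else if (!is.null(b)) {
      expect_gte(b$E + 1e-9, a$E)
    }
  }
})

test_that("seeds nest across seed length and GU policy", {
  p <- default_params()
  set.seed(31)
  for (t in 1:6) {
    s1 <- random_rna(15)
    s2 <- random_rna(15)
    for (bp in 2:4) {
      lo <- enumerate_seeds(s1, s2, seed_constraints(seed_bp = bp), p)
      hi <- enumerate_seeds(s1, s2, seed_constraints(seed_bp = bp + 1L), p)
      # every longer seed contains shorter seeds at both of its sub-helix
      # origins (region2 runs antiparallel, so trimming the 3' pair of
      # RNA1 trims the 5' end of region2)
      if (nrow(hi) > 0) {
        key_lo <- paste(lo$start1, lo$start2)
        expect_true(all(paste(hi$start1, hi$start2 + 1L) %in% key_lo))
        expect_true(all(paste(hi$start1 + 1L, hi$start2) %in% key_lo))
      }
      nogu <- enumerate_seeds(s1, s2,
                              seed_constraints(seed_bp = bp, allow_gu = FALSE), p)
      expect_true(all(paste(nogu$start1, nogu$start2) %in%
                      paste(lo$start1, lo$start2)))
    }
  }
})
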