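make_toy_genome <- function() {
  set.seed(88)
  contig <- random_rna(600)
  genome <- chartr("U", "T", contig)
  gff <- c("##gff-version 3",
           paste("chrT", "toy", "CDS", 300, 359, ".", "+", "0",
                 "ID=cds_gplus;locus_tag=gplus", sep = "\t"),
           paste("chrT", "toy", "CDS", 401, 460, ".", "-", "0",
                 "ID=cds_gminus;locus_tag=gminus", sep = "\t"),
           paste("chrT", "toy", "CDS", 50, 109, ".", "+", "0",
                 "ID=cds_gedge;locus_tag=gedge", sep = "\t"))
  gpath <- tempfile(fileext = ".fa")
  apath <- tempfile(fileext = ".gff3")
  write_rna_fasta(stats::setNames(genome, "chrT"), gpath)
  writeLines(gff, apath)
  list(contig = contig, genome = gpath, gff = apath)
}

test_that("target windows slice -200..+100 around the start codon", {
  toy <- make_toy_genome()
  win <- extract_target_windows(toy$genome, toy$gff)
  # plus-strand gene with start at 300: window = contig[100..400]
  expect_identical(win[["gplus"]], substr(toy$contig, 100, 400))
  expect_identical(nchar(win[["gplus"]]), 301L)
  # minus-strand gene anchored at its end coordinate (460)
  expect_identical(win[["gminus"]],
                   reverse_complement_rna(substr(toy$contig, 360, 660)))
  # gene at position 50: upstream truncated at the contig start
  expect_identical(win[["gedge"]], substr(toy$contig, 1, 150))
  expect_identical(nchar(win[["gedge"]]), 150L)
  trunc <- attr(win, "truncated")
  expect_true(trunc[["gedge"]])
  expect_false(trunc[["gplus"]])
  # missing contig
  bad <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               paste("chrMISSING", "toy", "CDS", 300, 359, ".", "+", "0",
                     "ID=x;locus_tag=x", sep = "\t")), bad)
  expect_error(extract_target_windows(toy$genome, bad), "missing contig")
})

test_that("rank_targets orders by energy with deterministic ties", {
  p <- default_params()
  cfg <- prediction_config(seed_constraints(seed_bp = 4L),
                           interaction_constraints(int_len_max = 12L,
                                                   int_max_e = 0),
                           p)
  srna <- c(s = "AAGGGGCCCCAA")
  strong <- paste0("AAAA", reverse_complement_rna("GGGGCCCC"), "AAAA")
  weak <- paste0("AAAAA", reverse_complement_rna("GGGC"), "AAAAAAA")
  none <- "AAAAAAAAAAAAAAAA"
  targets <- c(t_strong = strong, t_none = none, t_weak = weak)
  rk <- rank_targets(srna, targets, cfg)
  expect_identical(rk$target_id, c("t_strong", "t_weak", "t_none"))
  expect_true(is.na(rk$E[3]))
  expect_identical(rk$rank, 1:3)
  # equal energies: lexicographic id order
  dup <- c(zeta = strong, alpha = strong)
  rk2 <- rank_targets(srna, dup, cfg)
  expect_identical(rk2$target_id, c("alpha", "zeta"))
  # ranking is invariant under permutation of the input order
  rk3 <- rank_targets(srna, targets[c(2, 3, 1)], cfg)
  expect_identical(rk3, rk)
})

test_that("verified-pair tables reject duplicates", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("sRNA_id\ttarget_locus\torganism",
               "s1\tgA\torgX", "s1\tgB\torgX", "s1\tgA\torgX"), f)
  expect_error(read_verified_pairs(f), "duplicate verified pair")
  writeLines(c("sRNA_id\ttarget_locus\torganism",
               "s1\tgA\torgX", "s1\tgA\torgY"), f)
  v <- read_verified_pairs(f)
  expect_identical(nrow(v), 2L)  # same pair in two organisms is distinct
})

test_that("top-N recovery counts verified pairs by rank", {
  mk_rank <- function(ids) data.frame(target_id = ids,
                                      E = seq(-20, by = 0.1,
                                              length.out = length(ids)),
                                      rank = seq_along(ids),
                                      stringsAsFactors = FALSE)
  rankings <- list(orgX = list(s1 = mk_rank(sprintf("g%03d", 1:150))))
  verified <- data.frame(sRNA_id = c("s1", "s1"),
                         target_locus = c("g005", "g101"),
                         organism = c("orgX", "orgX"),
                         stringsAsFactors = FALSE)
  rec <- compute_recovery(rankings, verified, top_n = 100)
  expect_identical(rec$total_recovered, 1L)
  expect_identical(rec$detail$recovered, c(TRUE, FALSE))
  expect_identical(rec$detail$rank, c(5L, 101L))
  # boundary: rank 101 recovered once topN reaches it
  expect_identical(compute_recovery(rankings, verified, 101)$total_recovered, 2L)
  # empty prefix
  expect_identical(compute_recovery(rankings, verified, 0)$total_recovered, 0L)
  # monotone in topN
  recs <- vapply(c(0, 1, 5, 50, 100, 150), function(k) {
    compute_recovery(rankings, verified, k)$total_recovered
  }, integer(1))
  expect_true(all(diff(recs) >= 0))
  # per-sRNA bound and totals
  expect_true(all(rec$per_srna$recovered <=
                  pmin(rec$top_n, rec$per_srna$n_verified)))
  expect_identical(sum(rec$per_srna$recovered), rec$total_recovered)
  # verified sRNA missing from rankings
  verified_bad <- data.frame(sRNA_id = "s2", target_locus = "g001",
                             organism = "orgX", stringsAsFactors = FALSE)
  expect_error(compute_recovery(rankings, verified_bad, 100), "absent")
})

test_that("config sweeps normalize against the reference configuration", {
  p <- default_params()
  fx <- generate_fixture(fixture_spec(n_srna = 2, n_targets_per_organism = 6,
                                      n_verified = 3, organisms = "tiny",
                                      rng_seed = 9),
                         tempfile("fx"))
  profiles <- list(srna = precompute_profiles(fx$srnas, p, 60),
                   targets = lapply(fx$targets_by_organism, precompute_profiles,
                                    params = p, max_region_len = 60))
  base <- prediction_config(seed_constraints(seed_bp = 7L),
                            interaction_constraints(int_len_max = 60L,
                                                    max_loop = 8L), p)
  res1 <- sweep_configs(list(only = base), fx$srnas, fx$targets_by_organism,
                        fx$verified, top_n = 4, profiles = profiles)
  expect_identical(res1$summary$relative_recovery, 1)
  expect_identical(res1$summary$runtime_ratio, 1)
  # a degenerate accessibility filter recovers nothing
  dead <- prediction_config(seed_constraints(seed_bp = 7L, seed_min_pu = 1.0),
                            interaction_constraints(int_len_max = 60L,
                                                    max_loop = 8L), p)
  res2 <- sweep_configs(list(base = base, dead = dead), fx$srnas,
                        fx$targets_by_organism, fx$verified, top_n = 4,
                        profiles = profiles)
  expect_identical(res2$summary$recovered[res2$summary$config == "dead"], 0L)
  expect_error(sweep_configs(list(a = base), fx$srnas, fx$targets_by_organism,
                             fx$verified, reference = "missing"),
               "no reference config")
})
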