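## Deterministic desk-scale benchmark fixtures: synthetic sRNAs, target
## windows with planted complementary interaction sites, toy genomes with
## GFF3 annotation, and a verified-pair table.

#' Specification of a synthetic benchmark fixture
#'
#' The generator emulates an sRNA target screen: a set of sRNAs shared by
#' two synthetic organisms (as homologs are in real screens), one 301-nt
#' start-codon window per gene, and a subset of verified sRNA-target
#' pairs whose windows carry a planted site reverse-complementary to a
#' fixed region of their sRNA, placed just upstream of the start codon.
#'
#' @param n_srna Number of sRNAs.
#' @param n_targets_per_organism Target windows per organism.
#' @param n_verified Verified pairs per organism (each verified target
#'   carries one planted site; at most one per target, so this may not
#'   exceed `n_targets_per_organism`).
#' @param target_len Window length in nt (start codon first base at
#'   position `target_len - 100`, i.e. 201 for the default 301 =
#'   200 upstream + anchor + 100 downstream).
#' @param planted_site_len Length-2 integer range from which each sRNA's
#'   planted-site length is drawn.
#' @param planted_site_accessible Embed planted sites in low-structure
#'   context: sRNA backgrounds are G-free (so the C/A-rich source region
#'   cannot pair strongly within the sRNA) and target sites get pure A/U
#'   flanks.
#' @param gc_content GC fraction of the random background sequence.
#' @param srna_len sRNA length in nt.
#' @param organisms Character vector of organism labels.
#' @param rng_seed Integer seed; identical specs generate byte-identical
#'   fixtures.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_srna = 15L, n_targets_per_organism = 100L,
                         n_verified = 40L, target_len = 301L,
                         planted_site_len = c(9L, 12L),
                         planted_site_accessible = TRUE, gc_content = 0.5,
                         srna_len = 60L, organisms = c("synthA", "synthB"),
                         rng_seed = 1L) {
  stopifnot(n_srna >= 1L, n_targets_per_organism >= 1L, n_verified >= 0L,
            length(planted_site_len) == 2L,
            planted_site_len[1] <= planted_site_len[2],
            gc_content >= 0, gc_content <= 1, srna_len >= 20L,
            length(organisms) >= 1L)
  if (n_verified > n_srna * n_targets_per_organism) {
    stop("infeasible spec: n_verified exceeds n_srna * n_targets_per_organism")
  }
  if (n_verified > n_targets_per_organism) {
    stop("infeasible spec: at most one verified pair per target window")
  }
  if (target_len < 220L) stop("target_len must be >= 220")
  if (planted_site_len[2] > target_len) {
    stop("infeasible spec: planted site longer than target window")
  }
  if (planted_site_len[2] + 20L > srna_len) {
    stop("infeasible spec: planted site does not fit the sRNA source region")
  }
  structure(list(n_srna = as.integer(n_srna),
                 n_targets_per_organism = as.integer(n_targets_per_organism),
                 n_verified = as.integer(n_verified),
                 target_len = as.integer(target_len),
                 planted_site_len = as.integer(planted_site_len),
                 planted_site_accessible = isTRUE(planted_site_accessible),
                 gc_content = gc_content, srna_len = as.integer(srna_len),
                 organisms = organisms, rng_seed = as.integer(rng_seed)),
            class = "fixture_spec")
}

# scoped RNG: named generator, integer seeding, global state restored
.with_fixture_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

.random_rna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

.au_rich_rna <- function(n) {
  paste(sample(c("A", "U"), n, replace = TRUE, prob = c(0.6, 0.4)),
        collapse = "")
}

# sRNA background without G: the C/A-rich source region can then form no
# strong (CG) intramolecular pair, keeping it accessible
.gfree_rna <- function(n) {
  paste(sample(c("A", "U", "C"), n, replace = TRUE, prob = c(0.40, 0.35, 0.25)),
        collapse = "")
}

.ca_rich_rna <- function(n) {
  paste(sample(c("C", "A"), n, replace = TRUE, prob = c(0.55, 0.45)),
        collapse = "")
}

# accessibility floor enforced on planted sites: all seed-sized windows
# of the site must reach this unpaired probability (5x the customary
# screening threshold of 0.001, so planted sites pass with margin)
.SITE_PU_FLOOR <- 0.005

.site_accessible <- function(seq, from, to, params) {
  w <- min(7L, to - from + 1L)
  prof <- accessibility_profile(seq, params, max_region_len = w)
  v <- vapply(from:(to - w + 1L), function(i) pu_region(prof, i, i + w - 1L),
              numeric(1))
  min(v) >= .SITE_PU_FLOOR
}

.splice <- function(s, at, repl) {
  # overwrite substring of s starting at `at` with repl
  paste0(substr(s, 1L, at - 1L), repl,
         substr(s, at + nchar(repl), nchar(s)))
}

#' Generate a synthetic benchmark fixture
#'
#' Writes `srna.fa`, per-organism `genome_<org>.fa` + `genes_<org>.gff3`
#' (toy genomes with alternating-strand CDS features whose extracted
#' start-codon windows reproduce the target FASTA), per-organism
#' `targets_<org>.fa`, and `verified.tsv`. Identical specs produce
#' byte-identical files.
#'
#' @param spec A `fixture_spec`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory fixture: `srnas`,
#'   `targets_by_organism`, `verified`, `site_coords` (planted-site
#'   coordinates per verified pair) and the written `paths`.
#' @export
generate_fixture <- function(spec = fixture_spec(), dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  # reference model for the accessibility floor of planted sites
  params <- load_energy_parameters("default")
  .with_fixture_rng(spec$rng_seed, {
    anchor <- spec$target_len - 100L   # window position of the start codon
    upstream <- anchor - 1L
    site_src <- 20L                    # sRNA source region start
    site_at <- anchor - 16L            # window position of the planted site
    srna_ids <- sprintf("sRNA%02d", seq_len(spec$n_srna))
    slen <- sample(seq(spec$planted_site_len[1], spec$planted_site_len[2]),
                   spec$n_srna, replace = TRUE)
    srnas <- character(spec$n_srna)
    for (s in seq_len(spec$n_srna)) {
      if (spec$planted_site_accessible) {
        for (attempt in 1:25) {
          x <- .gfree_rna(spec$srna_len)
          x <- .splice(x, site_src, .ca_rich_rna(slen[s]))
          if (.site_accessible(x, site_src, site_src + slen[s] - 1L, params)) break
        }
      } else {
        x <- .random_rna(spec$srna_len, spec$gc_content)
      }
      srnas[s] <- x
    }
    names(srnas) <- srna_ids

    targets_by_organism <- list()
    verified <- NULL
    site_coords <- NULL
    paths <- list(srna = file.path(dir, "srna.fa"),
                  verified = file.path(dir, "verified.tsv"))
    for (org in spec$organisms) {
      tids <- sprintf("%s_g%03d", org, seq_len(spec$n_targets_per_organism))
      wins <- character(spec$n_targets_per_organism)
      for (g in seq_len(spec$n_targets_per_organism)) {
        if (g <= spec$n_verified) {
          s <- (g - 1L) %% spec$n_srna + 1L
          site <- reverse_complement_rna(
            substr(srnas[[s]], site_src, site_src + slen[s] - 1L))
          for (attempt in 1:25) {
            w <- .random_rna(spec$target_len, spec$gc_content)
            if (spec$planted_site_accessible) {
              w <- .splice(w, site_at - 20L, .au_rich_rna(20L))
              w <- .splice(w, site_at + nchar(site), .au_rich_rna(20L))
            }
            w <- .splice(w, site_at, site)
            w <- .splice(w, anchor, "AUG")
            if (!spec$planted_site_accessible ||
                .site_accessible(w, site_at, site_at + nchar(site) - 1L, params)) {
              break
            }
          }
          verified <- rbind(verified, data.frame(
            sRNA_id = srna_ids[s], target_locus = tids[g], organism = org,
            stringsAsFactors = FALSE))
          site_coords <- rbind(site_coords, data.frame(
            sRNA_id = srna_ids[s], target_locus = tids[g], organism = org,
            site_start = site_at, site_end = site_at + nchar(site) - 1L,
            srna_start = site_src, srna_end = site_src + slen[s] - 1L,
            stringsAsFactors = FALSE))
        } else {
          w <- .random_rna(spec$target_len, spec$gc_content)
          w <- .splice(w, anchor, "AUG")
        }
        wins[g] <- w
      }
      names(wins) <- tids
      targets_by_organism[[org]] <- wins

      # toy genome: one cassette per gene (30 nt flanks), alternating strands
      flank <- 30L
      cass_len <- spec$target_len + 2L * flank
      cassettes <- character(spec$n_targets_per_organism)
      gff <- c("##gff-version 3")
      contig_name <- paste0(org, "_chr")
      offset <- 0L
      cds_len <- 60L
      for (g in seq_len(spec$n_targets_per_organism)) {
        cass <- paste0(.au_rich_rna(flank), wins[g], .au_rich_rna(flank))
        strand <- if (g %% 2L == 1L) "+" else "-"
        if (strand == "+") {
          cassettes[g] <- cass
          a <- offset + flank + anchor
          gff <- c(gff, paste(contig_name, "seedscan", "CDS", a, a + cds_len - 1L,
                              ".", "+", "0",
                              paste0("ID=cds_", tids[g], ";locus_tag=", tids[g]),
                              sep = "\t"))
        } else {
          cassettes[g] <- reverse_complement_rna(cass)
          a <- offset + cass_len - (flank + anchor) + 1L
          gff <- c(gff, paste(contig_name, "seedscan", "CDS", a - cds_len + 1L, a,
                              ".", "-", "0",
                              paste0("ID=cds_", tids[g], ";locus_tag=", tids[g]),
                              sep = "\t"))
        }
        offset <- offset + cass_len
      }
      genome <- chartr("U", "T", paste(cassettes, collapse = ""))
      gpath <- file.path(dir, paste0("genome_", org, ".fa"))
      apath <- file.path(dir, paste0("genes_", org, ".gff3"))
      tpath <- file.path(dir, paste0("targets_", org, ".fa"))
      write_rna_fasta(stats::setNames(genome, contig_name), gpath)
      writeLines(gff, apath)
      write_rna_fasta(wins, tpath)
      paths[[paste0("genome_", org)]] <- gpath
      paths[[paste0("gff_", org)]] <- apath
      paths[[paste0("targets_", org)]] <- tpath
    }
    write_rna_fasta(srnas, paths$srna)
    vtab <- if (is.null(verified)) {
      data.frame(sRNA_id = character(), target_locus = character(),
                 organism = character(), stringsAsFactors = FALSE)
    } else verified
    utils::write.table(vtab, paths$verified, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(list(spec = spec, srnas = srnas,
                   targets_by_organism = targets_by_organism,
                   verified = vtab, site_coords = site_coords, paths = paths))
  })
}
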