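## sRNA target-screen benchmarking: start-codon window extraction,
## per-sRNA target ranking, top-N recovery of verified pairs and
## configuration sweeps.

#' Extract start-codon target windows from a genome
#'
#' For each protein-coding gene (GFF3 `CDS` features), extracts the
#' genomic region from `upstream` nt upstream to `downstream` nt
#' downstream of the start codon on the coding strand (positions
#' -upstream..+downstream with the start codon's first base at +1, window
#' length `upstream + downstream + 1`), reverse-complemented for
#' minus-strand genes, truncated at contig ends, and transcribed to the
#' RNA alphabet. Genes with multiple CDS records use the 5'-most start.
#'
#' @param genome Path to a genome FASTA file (DNA), or a named character
#'   vector of contig sequences.
#' @param annotation Path to a GFF3 file.
#' @param upstream,downstream Window extent in nt around the start codon.
#' @return Named character vector of RNA windows (names are locus tags)
#'   with a logical attribute `"truncated"` flagging windows clipped at
#'   contig ends.
#' @export
extract_target_windows <- function(genome, annotation, upstream = 200L,
                                   downstream = 100L) {
  stopifnot(upstream >= 0L, downstream >= 0L)
  contigs <- if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    set <- Biostrings::readBStringSet(genome)
    v <- toupper(as.character(set))
    names(v) <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
    v
  } else {
    stopifnot(is.character(genome), !is.null(names(genome)))
    toupper(genome)
  }
  gff <- rtracklayer::import(annotation, format = "gff3")
  cds <- gff[tolower(as.character(gff$type)) == "cds"]
  if (length(cds) == 0L) stop("no CDS features in ", annotation)
  mc <- S4Vectors::mcols(cds)
  locus <- rep(NA_character_, length(cds))
  for (field in c("locus_tag", "ID", "Name", "gene")) {
    if (field %in% colnames(mc)) {
      v <- as.character(mc[[field]])
      locus[is.na(locus) & !is.na(v)] <- v[is.na(locus) & !is.na(v)]
    }
  }
  if (anyNA(locus)) stop("CDS feature without locus identifier in ", annotation)
  df <- data.frame(locus = locus,
                   contig = as.character(GenomicRanges::seqnames(cds)),
                   start = GenomicRanges::start(cds),
                   end = GenomicRanges::end(cds),
                   strand = as.character(GenomicRanges::strand(cds)),
                   stringsAsFactors = FALSE)
  if (any(!df$strand %in% c("+", "-"))) {
    stop("CDS feature without start coordinate: strand must be + or -")
  }
  # one anchor per locus: the 5'-most start across its CDS records
  anchors <- do.call(rbind, lapply(split(df, df$locus), function(d) {
    d <- d[order(d$start), ]
    if (d$strand[1] == "+") {
      data.frame(locus = d$locus[1], contig = d$contig[1], anchor = min(d$start),
                 strand = "+", stringsAsFactors = FALSE)
    } else {
      data.frame(locus = d$locus[1], contig = d$contig[1], anchor = max(d$end),
                 strand = "-", stringsAsFactors = FALSE)
    }
  }))
  anchors <- anchors[order(anchors$locus), ]
  out <- character(nrow(anchors))
  truncated <- logical(nrow(anchors))
  for (t in seq_len(nrow(anchors))) {
    if (!anchors$contig[t] %in% names(contigs)) {
      stop("missing contig '", anchors$contig[t], "'")
    }
    ctg <- contigs[[anchors$contig[t]]]
    n <- nchar(ctg)
    a <- anchors$anchor[t]
    if (anchors$strand[t] == "+") {
      lo <- a - upstream; hi <- a + downstream
    } else {
      lo <- a - downstream; hi <- a + upstream
    }
    clo <- max(1L, lo); chi <- min(n, hi)
    truncated[t] <- clo != lo || chi != hi
    s <- substr(ctg, clo, chi)
    s <- chartr("T", "U", s)
    if (anchors$strand[t] == "-") s <- reverse_complement_rna(s)
    out[t] <- normalize_rna(s, anchors$locus[t])
  }
  names(out) <- anchors$locus
  attr(out, "truncated") <- stats::setNames(truncated, anchors$locus)
  out
}

#' Precompute accessibility profiles for a sequence set
#'
#' @param seqs Named character vector of RNA strings.
#' @param params An `energy_params` object.
#' @param max_region_len Maximal region length to tabulate (typically the
#'   largest interaction length of the configurations to be run).
#' @return Named list of `accessibility_profile`s.
#' @export
precompute_profiles <- function(seqs, params, max_region_len) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  out <- lapply(names(seqs), function(id) {
    accessibility_profile(seqs[[id]], params, max_region_len = max_region_len,
                          id = id)
  })
  stats::setNames(out, names(seqs))
}

#' Rank targets for one sRNA by predicted interaction energy
#'
#' Runs [predict_interaction()] for the sRNA against every target and
#' orders targets by ascending energy E. Targets with no reported
#' interaction are placed last; ties are broken lexicographically by
#' target id.
#'
#' @param srna Length-1 named character vector (the sRNA).
#' @param targets Named character vector of target windows.
#' @param config A `prediction_config`.
#' @param target_profiles Optional named list of `accessibility_profile`s
#'   for the targets (computed on the fly when omitted).
#' @param srna_profile Optional `accessibility_profile` for the sRNA.
#' @return Data frame with columns `target_id`, `E` (NA when no
#'   interaction is reported) and `rank`.
#' @export
rank_targets <- function(srna, targets, config = prediction_preset("default"),
                         target_profiles = NULL, srna_profile = NULL) {
  stopifnot(length(targets) >= 1L, !is.null(names(targets)))
  id1 <- if (!is.null(names(srna))) names(srna)[1] else "sRNA"
  q1 <- stats::setNames(normalize_rna(unname(srna[1]), id1), id1)
  if (is.null(srna_profile)) {
    srna_profile <- .profile_for(q1[[1]], id1, config$params, config, NULL)
  }
  E <- vapply(names(targets), function(tid) {
    prof <- if (is.null(target_profiles)) NULL else target_profiles[[tid]]
    hit <- predict_interaction(q1, stats::setNames(targets[[tid]], tid),
                               config, prof1 = srna_profile, prof2 = prof)
    if (is.null(hit)) NA_real_ else hit$E
  }, numeric(1))
  ord <- order(!is.finite(E) | is.na(E), E, names(targets))
  data.frame(target_id = names(targets)[ord], E = unname(E[ord]),
             rank = seq_along(E), stringsAsFactors = FALSE)
}

#' Read a verified sRNA-target pair table
#'
#' TSV with columns `sRNA_id`, `target_locus`, `organism` (a header line
#' is detected and skipped). Duplicate triples are an error.
#'
#' @param path Path to the TSV file.
#' @return Data frame with the three columns.
#' @export
read_verified_pairs <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("sRNA_id", "target_locus", "organism"),
                          colClasses = "character", comment.char = "#")
  if (nrow(df) > 0L && identical(tolower(df[1, 1]), "srna_id")) df <- df[-1, , drop = FALSE]
  if (nrow(df) == 0L) return(df)
  key <- paste(df$sRNA_id, df$target_locus, df$organism, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1, ]
    stop("duplicate verified pair: ", d$sRNA_id, " / ", d$target_locus,
         " / ", d$organism)
  }
  rownames(df) <- NULL
  df
}

#' Top-N recovery of verified sRNA-target pairs
#'
#' Counts how many verified pairs appear among the first `top_n` entries
#' of the corresponding sRNA's ranking. This is a lower bound on the
#' number of true targets among the top predictions.
#'
#' @param rankings Nested named list: `rankings[[organism]][[sRNA_id]]` is
#'   a ranking data frame from [rank_targets()].
#' @param verified Data frame from [read_verified_pairs()].
#' @param top_n Size of the top list (default 100).
#' @return A `recovery_report`: list with `per_srna` (data frame with
#'   `organism`, `sRNA_id`, `n_verified`, `recovered`), `detail` (per
#'   verified pair: rank and whether it was recovered), `total_recovered`,
#'   `total_verified` and `top_n`.
#' @export
compute_recovery <- function(rankings, verified, top_n = 100L) {
  stopifnot(top_n >= 0L)
  need <- unique(verified[, c("organism", "sRNA_id")])
  for (t in seq_len(nrow(need))) {
    org <- need$organism[t]; sid <- need$sRNA_id[t]
    if (is.null(rankings[[org]]) || is.null(rankings[[org]][[sid]])) {
      stop("verified sRNA '", sid, "' (", org, ") absent from rankings")
    }
  }
  detail <- verified
  detail$rank <- NA_integer_
  detail$recovered <- FALSE
  for (t in seq_len(nrow(detail))) {
    rk <- rankings[[detail$organism[t]]][[detail$sRNA_id[t]]]
    hit <- match(detail$target_locus[t], rk$target_id)
    if (!is.na(hit) && !is.na(rk$E[hit])) {
      detail$rank[t] <- rk$rank[hit]
      detail$recovered[t] <- rk$rank[hit] <= top_n
    }
  }
  per <- do.call(rbind, lapply(split(detail, paste(detail$organism, detail$sRNA_id, sep = "\r")),
    function(d) data.frame(organism = d$organism[1], sRNA_id = d$sRNA_id[1],
                           n_verified = nrow(d), recovered = sum(d$recovered),
                           stringsAsFactors = FALSE)))
  per <- per[order(per$organism, per$sRNA_id), ]
  rownames(per) <- NULL
  structure(list(per_srna = per, detail = detail,
                 total_recovered = sum(detail$recovered),
                 total_verified = nrow(detail), top_n = top_n),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Recovery report: ", x$total_recovered, "/", x$total_verified,
      " verified pairs within top-", x$top_n, "\n", sep = "")
  invisible(x)
}

#' Run the target-screen benchmark for one configuration
#'
#' @param srnas Named character vector of sRNA sequences.
#' @param targets_by_organism Named list (per organism) of named character
#'   vectors of target windows.
#' @param config A `prediction_config`.
#' @param verified Verified-pair data frame.
#' @param top_n Top-list size.
#' @param profiles Optional precomputed profiles: list with elements
#'   `srna` (named list) and per-organism target profile lists under
#'   `targets[[organism]]`.
#' @return List with `rankings` (nested list) and `recovery`
#'   (a `recovery_report`).
#' @export
run_benchmark <- function(srnas, targets_by_organism, config, verified,
                          top_n = 100L, profiles = NULL) {
  rankings <- lapply(names(targets_by_organism), function(org) {
    tg <- targets_by_organism[[org]]
    tprof <- if (is.null(profiles)) NULL else profiles$targets[[org]]
    rk <- lapply(names(srnas), function(sid) {
      sprof <- if (is.null(profiles)) NULL else profiles$srna[[sid]]
      rank_targets(srnas[sid], tg, config,
                   target_profiles = tprof, srna_profile = sprof)
    })
    stats::setNames(rk, names(srnas))
  })
  names(rankings) <- names(targets_by_organism)
  list(rankings = rankings,
       recovery = compute_recovery(rankings, verified, top_n))
}

#' Compare prediction configurations on a benchmark
#'
#' Runs the full screen for every configuration and reports recovered
#' verified pairs, recovery relative to a reference configuration, and
#' wall-clock runtime ratios (normalized to the reference configuration;
#' runtimes are hardware-dependent and reported for orientation only).
#'
#' @param configs Named list of `prediction_config`s.
#' @param srnas,targets_by_organism,verified,top_n As in
#'   [run_benchmark()].
#' @param reference Name of the reference configuration (defaults to the
#'   first).
#' @param profiles Optional precomputed profiles shared by all
#'   configurations (accessibility precomputation is excluded from the
#'   reported runtimes, matching screen practice).
#' @return List with `summary` (data frame: `config`, `recovered`,
#'   `relative_recovery`, `runtime_s`, `runtime_ratio`) and `detail`
#'   (per verified pair and configuration).
#' @export
sweep_configs <- function(configs, srnas, targets_by_organism, verified,
                          top_n = 100L, reference = NULL, profiles = NULL) {
  stopifnot(length(configs) >= 1L, !is.null(names(configs)))
  if (is.null(reference)) reference <- names(configs)[1]
  if (!reference %in% names(configs)) stop("no reference config '", reference, "'")
  if (is.null(profiles)) {
    lmax <- max(vapply(configs, function(cf) cf$interaction$int_len_max, numeric(1)))
    par0 <- configs[[reference]]$params
    profiles <- list(
      srna = precompute_profiles(srnas, par0, lmax),
      targets = lapply(targets_by_organism, precompute_profiles,
                       params = par0, max_region_len = lmax))
  }
  rows <- list(); details <- list()
  for (nm in names(configs)) {
    t0 <- proc.time()[["elapsed"]]
    res <- run_benchmark(srnas, targets_by_organism, configs[[nm]], verified,
                         top_n = top_n, profiles = profiles)
    dt <- proc.time()[["elapsed"]] - t0
    rows[[nm]] <- data.frame(config = nm,
                             recovered = res$recovery$total_recovered,
                             runtime_s = dt, stringsAsFactors = FALSE)
    d <- res$recovery$detail
    d$config <- nm
    details[[nm]] <- d
  }
  summary <- do.call(rbind, rows)
  ref <- summary[summary$config == reference, ]
  summary$relative_recovery <- if (ref$recovered > 0) {
    summary$recovered / ref$recovered
  } else NA_real_
  summary$runtime_ratio <- summary$runtime_s / max(ref$runtime_s, 1e-9)
  rownames(summary) <- NULL
  list(summary = summary[, c("config", "recovered", "relative_recovery",
                             "runtime_s", "runtime_ratio")],
       detail = do.call(rbind, details))
}
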