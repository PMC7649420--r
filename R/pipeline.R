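# End-to-end orchestration: simulate (or ingest) data, quantify s-traits and
# sc-traits, build the bin map, scan for QTLs, align trait sequences to the
# parental genomes, resolve local/distant, call hotspots, analyse LIR loci,
# and validate a run against the simulator's truth table.

#' Default pipeline configuration
#'
#' All stage parameters in one list. Thresholds default to the headline
#' values of the workflow: presence over half the population for s-traits,
#' normalized value >= 6 in more than 25 individuals for sc-traits, LOD >= 5,
#' 16-bp assembly overlap and the 60-bp final contig filter.
#'
#' @param seed master seed; every stochastic stage derives its stream from it.
#' @param design a `population_design` (defaults to
#'   `population_design(seed = seed)`).
#' @param ... overrides for any configuration entry.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(seed = 1, design = NULL, ...) {
  cfg <- list(
    seed = seed,
    design = design %||% population_design(seed = seed),
    length_range = c(18, 30),
    presence_min = NULL,          # default floor(n/2) at trait definition
    min_overlap = 16,
    min_contig_seed = 50,
    min_contig = 60,
    assembly = "pooled",          # or "both": per-library + pooled
    sc_min_value = 6,
    sc_min_libs = 25,
    lod_threshold = 5,
    lod_drop = 1.5,
    cofactors_k = 3,
    window = 10,
    max_mismatch = 0,
    max_dist = 1e6,
    min_arm = 200,
    max_spacer = 20000,
    min_identity = 0.9,
    seed_k = 15,
    max_hairpin_spacer = 1000,
    hotspot_min_traits = NULL,
    scan_sc_traits = TRUE
  )
  over <- list(...)
  cfg[names(over)] <- over
  class(cfg) <- "run_config"
  cfg
}

#' Simulate a complete synthetic scenario
#'
#' @param design a `population_design`.
#' @param lir_specs planted LIR structures.
#' @param ... forwarded to [make_truth_table()].
#' @return list: genomes, pop, truth, srna, mrna.
#' @export
simulate_scenario <- function(design = population_design(),
                              lir_specs = default_lir_specs(design), ...) {
  genomes <- simulate_parental_genomes(design, lir_specs)
  pop <- simulate_population(genomes, design)
  truth <- make_truth_table(genomes, pop, design, ...)
  srna <- simulate_srna_libraries(genomes, pop$imf2_genotypes, truth, design)
  mrna <- simulate_mrna_libraries(genomes, pop$imf2_genotypes, truth, design)
  list(genomes = genomes, pop = pop, truth = truth, srna = srna, mrna = mrna)
}

derive_lir_loci <- function(lirs_p1, lirs_p2, pad = 500) {
  recs <- rbind(lirs_p1, lirs_p2)
  if (nrow(recs) == 0)
    return(data.frame(name = character(0), chrom = character(0),
                      start = integer(0), end = integer(0)))
  recs$w_start <- pmax(1L, recs$arm1_start - pad)
  recs$w_end <- recs$arm2_end + pad
  out <- list()
  for (ch in unique(recs$chrom)) {
    r <- recs[recs$chrom == ch, ]
    r <- r[order(r$w_start), ]
    cur <- r[1, c("w_start", "w_end")]
    for (i in seq_len(nrow(r))[-1]) {
      if (r$w_start[i] <= cur$w_end) cur$w_end <- max(cur$w_end, r$w_end[i])
      else { out[[length(out) + 1]] <- data.frame(chrom = ch, cur); cur <-
               r[i, c("w_start", "w_end")] }
    }
    out[[length(out) + 1]] <- data.frame(chrom = ch, cur)
  }
  loci <- do.call(rbind, out)
  data.frame(name = paste0("lir_locus_", seq_len(nrow(loci))),
             chrom = loci$chrom, start = loci$w_start, end = loci$w_end)
}

#' Run the quantify-then-align pipeline
#'
#' Executes the stage order quantify (s-traits, sc-traits) -> bin map ->
#' scan -> align -> resolve local/distant -> hotspots -> LIR analysis on a
#' simulated scenario. Deterministic given the configuration's seeds.
#'
#' @param config a `run_config`.
#' @param sim a scenario from [simulate_scenario()]; simulated from
#'   `config$design` when omitted.
#' @param out_dir optional directory; when given, result tables and a run
#'   manifest (stage parameters) are written there.
#' @return list of class `srnaqtl_run` with the stage outputs.
#' @export
run_pipeline <- function(config = run_config(), sim = NULL, out_dir = NULL) {
  design <- config$design
  sim <- sim %||% simulate_scenario(design)

  # --- quantify: s-traits
  tags <- collapse_reads(sim$srna$libraries, config$length_range)
  rpm <- rpm_normalize(tags)
  straits <- define_s_traits(rpm, counts = tags$counts,
                             presence_min = config$presence_min)

  # --- quantify: sc-traits (assembly -> merge -> 60-bp filter -> counting)
  pooled_reads <- stats::setNames(rowSums(tags$counts), rownames(tags$counts))
  contigs <- assemble_clusters(pooled_reads, config$min_overlap,
                               config$min_contig_seed)
  if (identical(config$assembly, "both")) {
    per_lib <- lapply(sim$srna$libraries, function(lib)
      assemble_clusters(lib, config$min_overlap, config$min_contig_seed))
    contig_seqs <- unique(c(contigs$sequence,
                            unlist(lapply(per_lib, `[[`, "sequence"))))
  } else contig_seqs <- unique(contigs$sequence)
  clusters <- if (length(contig_seqs)) merge_contigs(contig_seqs) else
    data.frame(id = character(0), sequence = character(0),
               length = integer(0), n_contigs = integer(0))
  clusters <- filter_contigs(clusters, config$min_contig)
  if (nrow(clusters)) {
    ccounts <- count_cluster_reads(tags, clusters)
    sf <- suppressWarnings(size_factors(ccounts$counts, fallback = TRUE))
    cnorm <- normalize_counts(ccounts$counts, sf)
  } else {
    ccounts <- NULL; sf <- NULL
    cnorm <- matrix(0, 0, ncol(tags$counts),
                    dimnames = list(NULL, colnames(tags$counts)))
  }
  sctraits <- define_sc_traits(cnorm, config$sc_min_value, config$sc_min_libs)

  # --- genetic map
  binmap <- build_bin_map(sim$pop$ril_genotypes, sim$pop$markers,
                          chrom_len = design$chrom_len)
  imf2_bins <- deduce_imf2_genotypes(binmap, sim$pop$cross_table)
  enc <- encode_genotypes(imf2_bins)
  bin_chrom <- binmap$bins$chrom

  # --- scans
  s_calls <- scan_traits(straits$values, enc, bin_chrom,
                         k = config$cofactors_k, window = config$window,
                         lod_threshold = config$lod_threshold,
                         lod_drop = config$lod_drop)
  sc_calls <- if (isTRUE(config$scan_sc_traits) && nrow(sctraits$values) > 0)
    scan_traits(sctraits$values, enc, bin_chrom,
                k = config$cofactors_k, window = config$window,
                lod_threshold = config$lod_threshold,
                lod_drop = config$lod_drop)
  else NULL

  # --- align + resolve
  s_hits <- if (nrow(s_calls)) align_tags(
    stats::setNames(unique(s_calls$trait), unique(s_calls$trait)),
    sim$genomes, max_mismatch = config$max_mismatch, report = "all")
  else NULL
  if (nrow(s_calls))
    s_calls <- resolve_local_distant(s_calls, s_hits, binmap,
                                     config$max_dist)
  sc_hits <- if (!is.null(sc_calls) && nrow(sc_calls)) {
    cl_named <- stats::setNames(clusters$sequence, clusters$id)
    do.call(rbind, lapply(c("P1", "P2"), function(p) {
      h <- align_clusters(cl_named[unique(sc_calls$trait)],
                          sim$genomes$genomes[[p]],
                          min_identity = config$min_identity,
                          unique_only = TRUE)
      if (nrow(h)) h$genome <- p
      h
    }))
  } else NULL
  if (!is.null(sc_calls) && nrow(sc_calls))
    sc_calls <- resolve_local_distant(sc_calls, sc_hits, binmap,
                                      config$max_dist)

  # --- hotspots
  s_hotspots <- detect_hotspots(s_calls$peak_bin, nrow(binmap$bins),
                                bin_chrom, config$hotspot_min_traits)
  sc_hotspots <- if (!is.null(sc_calls) && nrow(sc_calls))
    detect_hotspots(sc_calls$peak_bin, nrow(binmap$bins), bin_chrom,
                    config$hotspot_min_traits)
  else NULL

  # --- LIR analysis
  lirs_p1 <- find_inverted_repeats(unlist(sim$genomes$genomes$P1),
                                   config$min_arm, config$max_spacer,
                                   config$min_identity, config$seed_k,
                                   config$max_hairpin_spacer)
  lirs_p2 <- find_inverted_repeats(unlist(sim$genomes$genomes$P2),
                                   config$min_arm, config$max_spacer,
                                   config$min_identity, config$seed_k,
                                   config$max_hairpin_spacer)
  loci <- derive_lir_loci(lirs_p1, lirs_p2)
  lir_classes <- if (nrow(loci))
    suppressWarnings(compare_lir_across_genomes(lirs_p1, lirs_p2, loci,
                                                sim$genomes))
  else NULL
  lir_expression <- NULL
  if (nrow(loci) && !is.null(sim$mrna)) {
    lir_expression <- lapply(seq_len(nrow(loci)), function(i) {
      w <- loci[i, ]
      mid <- (w$start + w$end) %/% 2
      b <- binmap$bins[binmap$bins$chrom == w$chrom &
                         binmap$bins$start <= mid &
                         binmap$bins$end >= mid, ]
      geno <- imf2_bins[, paste0("bin", b$bin[1])]
      ref_of <- function(recs, parent) {
        r <- recs[!is.na(recs$chrom) & recs$chrom == w$chrom &
                    recs$arm1_start <= w$end & recs$arm2_end >= w$start, ]
        if (nrow(r) == 0) return(NULL)
        r <- r[which.max(r$arm_len), ]
        substring(sim$genomes$genomes[[parent]][[w$chrom]],
                  r$arm1_start, r$arm2_end)
      }
      refs <- list(P1 = ref_of(lirs_p1, "P1"), P2 = ref_of(lirs_p2, "P2"))
      vals <- quantify_lir_expression(sim$mrna$libraries, refs, geno)
      list(locus = w$name, bin = b$bin[1], genotypes = geno, values = vals)
    })
    names(lir_expression) <- loci$name
  }

  res <- list(config = config, sim = sim, tags = tags, rpm = rpm,
              straits = straits, clusters = clusters,
              cluster_counts = ccounts, size_factors = sf,
              sctraits = sctraits, binmap = binmap, imf2_bins = imf2_bins,
              s_calls = s_calls, sc_calls = sc_calls, s_hits = s_hits,
              sc_hits = sc_hits, s_hotspots = s_hotspots,
              sc_hotspots = sc_hotspots, lirs_p1 = lirs_p1,
              lirs_p2 = lirs_p2, lir_loci = loci,
              lir_classes = lir_classes, lir_expression = lir_expression)
  class(res) <- "srnaqtl_run"
  if (!is.null(out_dir)) write_run(res, out_dir)
  res
}

#' Write pipeline result tables and a run manifest
#'
#' @param run an `srnaqtl_run`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(run$binmap$bins, file.path(out_dir, "bin_map.tsv"))
  write_tsv(data.frame(trait = rownames(run$straits$values),
                       run$straits$values, check.names = FALSE),
            file.path(out_dir, "s_traits.tsv"))
  write_tsv(run$clusters[, c("id", "sequence", "length")],
            file.path(out_dir, "clusters.tsv"))
  if (nrow(run$s_calls))
    write_tsv(run$s_calls, file.path(out_dir, "s_qtls.tsv"))
  if (!is.null(run$sc_calls) && nrow(run$sc_calls))
    write_tsv(run$sc_calls, file.path(out_dir, "sc_qtls.tsv"))
  if (nrow(run$s_hotspots))
    write_tsv(run$s_hotspots, file.path(out_dir, "s_hotspots.tsv"))
  if (!is.null(run$lir_classes))
    write_tsv(run$lir_classes, file.path(out_dir, "lir_classes.tsv"))
  manifest <- run$config
  manifest$design <- unclass(manifest$design)
  jsonlite::write_json(
    list(parameters = manifest[!vapply(manifest, is.null, logical(1))],
         n_s_traits = run$straits$n_retained,
         n_sc_traits = run$sctraits$n_retained,
         n_bins = nrow(run$binmap$bins),
         n_s_qtls = nrow(run$s_calls)),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Validate a pipeline run against the simulator's truth table
#'
#' For each planted effect set: the fraction of its traits that were defined
#' as s-traits, the fraction with a QTL whose peak lies within `tol_bins` of
#' the bin containing the planted controlling marker, and the local/distant
#' label accuracy among resolved calls.
#'
#' @param run an `srnaqtl_run`.
#' @param truth the scenario's `truth_table` (defaults to the run's own).
#' @param tol_bins peak-position tolerance in bins.
#' @return list: `per_effect` data.frame and `aggregate` list (recall and
#'   mode accuracy over planted effects).
#' @export
validate_against_truth <- function(run, truth = NULL, tol_bins = 2) {
  truth <- truth %||% run$sim$truth
  bins <- run$binmap$bins
  bin_of_marker <- function(mk) {
    b <- bins$bin[bins$first_marker <= mk & bins$last_marker >= mk]
    if (length(b)) b[1] else NA_integer_
  }
  per <- lapply(seq_len(nrow(truth$planted_qtls)), function(i) {
    q <- truth$planted_qtls[i, ]
    tags <- truth$tags$tag[truth$tags$set == q$set]
    true_bin <- bin_of_marker(q$ctrl_marker)
    defined <- tags[tags %in% rownames(run$straits$values)]
    calls <- run$s_calls[run$s_calls$trait %in% defined, , drop = FALSE]
    hit <- calls[abs(calls$peak_bin - true_bin) <= tol_bins, , drop = FALSE]
    resolved <- hit[!is.na(hit$mode) & hit$mode != "unresolved", ,
                    drop = FALSE]
    data.frame(set = q$set, mode_true = q$mode, true_bin = true_bin,
               n_tags = length(tags), n_defined = length(defined),
               n_detected = length(unique(hit$trait)),
               detection_rate = if (length(defined))
                 length(unique(hit$trait)) / length(defined) else NA,
               median_lod = if (nrow(hit)) stats::median(hit$lod) else NA,
               mode_accuracy = if (nrow(resolved))
                 mean(resolved$mode == q$mode) else NA)
  })
  per <- do.call(rbind, per)
  list(per_effect = per,
       aggregate = list(
         mean_detection = mean(per$detection_rate, na.rm = TRUE),
         mean_mode_accuracy = mean(per$mode_accuracy, na.rm = TRUE)))
}
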